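test_that("synthetic_config validates its inputs", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(n_mesocosms_per_soil = 0),
               class = "mesonet_config_error")
  expect_error(synthetic_config(coupling_rho_per_soil = c(0.5, 1.2)),
               class = "mesonet_config_error")
  expect_error(synthetic_config(years = 2012:2014),
               class = "mesonet_config_error")
  expect_error(synthetic_config(years = 2013:2019),
               class = "mesonet_config_error")
  expect_error(synthetic_config(specialist_fold_change = 0.5),
               class = "mesonet_config_error")
})

test_that("identical config and seed reproduce identical datasets", {
  a <- generate_dataset(small_config(seed = 3))
  b <- generate_dataset(small_config(seed = 3))
  expect_identical(a$plants, b$plants)
  expect_identical(a$chemistry, b$chemistry)
  expect_identical(a$prok_table$counts, b$prok_table$counts)
  expect_identical(a$fungal_table$counts, b$fungal_table$counts)
  c <- generate_dataset(small_config(seed = 4))
  expect_false(identical(a$prok_table$counts, c$prok_table$counts))
})

test_that("dataset shapes and labels are consistent", {
  cfg <- small_config(seed = 8)
  ds <- generate_dataset(cfg)
  n <- 2 * cfg$n_mesocosms_per_soil
  expect_equal(dim(ds$prok_table), c(n, cfg$n_prok_otus))
  expect_equal(dim(ds$fungal_table), c(n, cfg$n_fungal_otus))
  expect_equal(nrow(ds$chemistry), n)
  expect_setequal(unique(ds$plants$soil),
                  c("natural_grassland", "abandoned_arable"))
  # habitat labels must match the sample ids they annotate
  expect_equal(unname(ds$prok_table$habitat),
               unname(ds$chemistry$soil[match(
                 rownames(ds$prok_table$counts), ds$chemistry$mesocosm_id)]))
  expect_true(all(startsWith(
    rownames(ds$prok_table$counts)[ds$prok_table$habitat ==
                                     "natural_grassland"], "NG")))
  expect_true(all(startsWith(
    rownames(ds$prok_table$counts)[ds$prok_table$habitat ==
                                     "abandoned_arable"], "AA")))
  # truth object covers every OTU
  expect_equal(length(ds$truth$prok_cluster), cfg$n_prok_otus)
  expect_equal(sort(unique(ds$truth$prok_cluster)),
               seq_len(cfg$n_prok_clusters))
})

test_that("counts follow the sequencing-depth model", {
  ds <- generate_dataset(small_config(seed = 13))
  totals <- rowSums(ds$prok_table$counts)
  expect_true(all(totals >= 1))
  expect_true(all(ds$prok_table$counts >= 0))
  expect_true(all(ds$prok_table$counts == round(ds$prok_table$counts)))
  # depths scatter around the configured mean of 5000
  expect_gt(mean(totals), 2500)
  expect_lt(mean(totals), 10000)
})

test_that("generate_otu_counts respects depths and masses", {
  lat <- matrix(c(10, 1, 1, 10), 2, 2)
  rownames(lat) <- c("s1", "s2")
  counts <- generate_otu_counts(lat, membership = c(1, 1, 2, 2),
                                depth_mean = 2000, nb_dispersion = 0,
                                seed = 99)
  expect_equal(rowSums(counts), as.numeric(attr(counts, "depths")),
               ignore_attr = TRUE)
  # sample 1 is dominated by cluster-1 OTUs, sample 2 by cluster-2 OTUs
  expect_gt(sum(counts[1, 1:2]), sum(counts[1, 3:4]))
  expect_gt(sum(counts[2, 3:4]), sum(counts[2, 1:2]))
  expect_error(generate_otu_counts(-lat, c(1, 2)),
               class = "mesonet_data_error")
})

test_that("planted habitat specialists are enriched in their soil", {
  cfg <- small_config(seed = 21, specialist_fold_change = 8)
  ds <- generate_dataset(cfg)
  tab <- ds$prok_table
  spec <- ds$truth$prok_specialist
  pref <- ds$truth$prok_preferred_soil
  rel <- tab$counts / rowSums(tab$counts)
  ratios <- vapply(names(spec)[spec], function(o) {
    a <- mean(rel[tab$habitat == pref[o], o])
    b <- mean(rel[tab$habitat != pref[o], o])
    (a + 1e-9) / (b + 1e-9)
  }, numeric(1))
  # on average specialists are several-fold enriched in their soil
  expect_gt(exp(mean(log(ratios))), 2)
})

test_that("planted coupling contrast is visible in truth-cluster abundances", {
  ds <- generate_dataset(synthetic_config(
    n_prok_otus = 60, n_fungal_otus = 60,
    coupling_rho_per_soil = c(natural_grassland = 0.1,
                              abandoned_arable = 0.9),
    seed = 31))
  beta_soil <- vapply(c("natural_grassland", "abandoned_arable"), function(s) {
    idx <- which(ds$prok_table$habitat == s)
    pa <- cluster_abundances(ds$truth$prok_cluster,
                             subset_otu_table(ds$prok_table, samples = idx))
    fa <- cluster_abundances(ds$truth$fungal_cluster,
                             subset_otu_table(ds$fungal_table, samples = idx))
    mean(coupling_scores(pa, fa, k = 9)$beta)
  }, numeric(1))
  expect_gt(beta_soil[["abandoned_arable"]],
            beta_soil[["natural_grassland"]])
})

test_that("write_synthetic_dataset emits readable pipeline inputs", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(small_config(seed = 2))
  paths <- write_synthetic_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  hab <- setNames(ds$chemistry$soil, ds$chemistry$mesocosm_id)
  back <- read_otu_table(paths[["prok"]], habitat = hab,
                         domain = "prokaryote")
  expect_equal(back$counts[rownames(ds$prok_table$counts), ],
               ds$prok_table$counts)
})
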