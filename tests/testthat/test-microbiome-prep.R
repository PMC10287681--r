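make_table <- function(counts, habitat = rep("a", nrow(counts)),
                       domain = "prokaryote") {
  rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  colnames(counts) <- paste0("o", seq_len(ncol(counts)))
  otu_table(counts, habitat = habitat, domain = domain)
}

test_that("filter_otus applies both thresholds", {
  m <- cbind(rep(30, 5),            # total 150, present in 5
             c(99, 0, 0, 0, 0),     # total < 100
             c(96, 1, 1, 1, 1),     # total 100, present in 5
             c(50, 50, 0, 0, 0))    # total 100 but present in 2
  tab <- make_table(m)
  f <- filter_otus(tab, min_total_reads = 100, min_samples = 5)
  expect_equal(otu_ids(f), c("o1", "o3"))
  expect_error(filter_otus(tab, min_total_reads = 1e6),
               class = "mesonet_data_error")
})

test_that("rarefy equalizes totals and drops shallow samples", {
  m <- matrix(rpois(6 * 20, 40), 6, 20)
  m[6, ] <- 0; m[6, 1] <- 5  # shallow sample
  tab <- make_table(m)
  expect_warning(r <- rarefy(tab, depth = 100, seed = 1), "dropping 1")
  expect_equal(unname(sample_totals(r)), rep(100, 5))
  expect_true(all(r$counts <= tab$counts[seq_len(5), ]))
  # identical seed, identical draw
  r2 <- suppressWarnings(rarefy(tab, depth = 100, seed = 1))
  expect_identical(r$counts, r2$counts)
})

test_that("clr transform matches the hand oracle and centers rows", {
  # (1, 1, 8) with pseudocount 0: logs (0, 0, ln 8), mean ln(8)/3
  x <- matrix(c(1, 1, 8), 1, 3)
  got <- clr_transform(x, pseudocount = 0)
  expect_equal(as.numeric(got),
               c(-log(8) / 3, -log(8) / 3, log(8) * 2 / 3),
               tolerance = 1e-12)
  m <- matrix(rpois(50, 20), 5, 10)
  out <- clr_transform(m, pseudocount = 1)
  expect_equal(rowSums(out), rep(0, 5), tolerance = 1e-12)
  m[1, 1] <- 0
  expect_error(clr_transform(m, pseudocount = 0),
               class = "mesonet_data_error")
})

test_that("specialisation index matches Eq. 1 hand oracles", {
  # OTU A: counts (10, 10, 10, 10) -> sd/mu = 0, K = 2, N = 40:
  # SI = -sqrt(2/40) = -0.2236068
  # OTU B: counts (20, 0, 0, 0) -> mu 5, sd 10, SI = 2 - sqrt(2/20)
  m <- cbind(c(10, 10, 10, 10), c(20, 0, 0, 0))
  tab <- make_table(m, habitat = c("a", "a", "b", "b"))
  si <- specialisation_index(tab)
  expect_equal(si$K, 2)
  expect_equal(si$per_otu$si[1], -sqrt(2 / 40), tolerance = 1e-12)
  expect_equal(si$per_otu$si[2], 2 - sqrt(2 / 20), tolerance = 1e-12)
  # CWM per sample: weighted by relative reads of present OTUs
  w1 <- c(10, 20) / 30
  expect_equal(unname(si$per_sample[1]),
               sum(w1 * si$per_otu$si) / sum(w1), tolerance = 1e-12)
  # sample 2 contains only OTU A
  expect_equal(unname(si$per_sample[2]), si$per_otu$si[1], tolerance = 1e-12)
})

test_that("zero-read OTUs are excluded from the SI table", {
  m <- cbind(c(5, 5), c(0, 0))
  tab <- make_table(m)
  si <- specialisation_index(tab, K = 2)
  expect_equal(si$excluded, "o2")
  expect_equal(si$per_otu$otu_id, "o1")
})

test_that("cwm_si and boxplot fences behave", {
  expect_equal(cwm_si(c(1, 3), c(1, 1)), 2)
  expect_equal(cwm_si(c(1, 3), c(3, 1)), 1.5)
  expect_error(cwm_si(c(1, 2), c(-1, 1)), class = "mesonet_data_error")
  v <- c(1, 2, 3, 4, 100)
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  f <- mesonet:::boxplot_fences(v)
  expect_equal(unname(f), c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q)))
})

test_that("cluster specialisation classification follows the fence rule", {
  si_by_cluster <- list(
    gen = c(-0.5, -0.45, -0.55),     # all below mean, upper fence below
    spec = c(0.8, 0.85, 0.9),        # all above, lower fence above
    mid = c(-0.2, 0.3, 0.1)          # straddles the mean
  )
  out <- classify_cluster_specialisation(si_by_cluster, community_mean = 0)
  expect_equal(out$label[match(c("gen", "spec", "mid"), out$cluster)],
               c("generalist", "specialist", "intermediate"))
})

test_that("enrichment ratios and classification match the ln response ratio", {
  m <- rbind(c(40, 1), c(40, 1),   # habitat a
             c(1, 40), c(1, 40))   # habitat b
  tab <- make_table(m, habitat = c("a", "a", "b", "b"))
  membership <- c(o1 = 1L, o2 = 2L)
  enr <- enrichment_ratio_and_classify(tab, membership)
  expect_equal(enr$per_otu$ratio[1], log(81 / 3), tolerance = 1e-12)
  expect_equal(enr$per_otu$ratio[2], log(3 / 81), tolerance = 1e-12)
  expect_equal(enr$per_cluster$label, c("enriched-a", "enriched-b"))
})

test_that("otu_overlap counts shared and unique OTUs", {
  a <- make_table(cbind(c(1, 1), c(0, 0), c(2, 2)))
  b <- make_table(cbind(c(1, 1), c(3, 3), c(0, 0)))
  ov <- otu_overlap(a, b)
  expect_equal(unname(ov), c(1, 1, 1))
})

test_that("multi_rarefied_shannon is reproducible and sensible", {
  m <- matrix(rpois(4 * 30, 50), 4, 30)
  tab <- make_table(m)
  h1 <- multi_rarefied_shannon(tab, depth = 500, iterations = 20, seed = 7)
  h2 <- multi_rarefied_shannon(tab, depth = 500, iterations = 20, seed = 7)
  expect_identical(h1, h2)
  expect_true(all(h1 > 0 & h1 <= log(30)))
})
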