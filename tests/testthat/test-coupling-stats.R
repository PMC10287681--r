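test_that("coupling_beta equals the Pearson correlation of the vectors", {
  p <- c(0.5, 0.25, 0.125, 0.0625, 0.0625)
  cb <- coupling_beta(p, p, transform = "none")
  expect_equal(cb$beta, 1)
  expect_equal(cb$n_cluster_pairs, 5)
  f <- c(0.0625, 0.0625, 0.125, 0.25, 0.5)
  expect_equal(coupling_beta(p, f, transform = "none")$beta, cor(p, f))
  expect_equal(coupling_beta(p, f, transform = "ln")$beta,
               cor(log(p), log(f)))
  expect_error(coupling_beta(p, f[1:3]), class = "mesonet_data_error")
  expect_error(coupling_beta(p[1:2], f[1:2]), class = "mesonet_data_error")
})

test_that("coupling_scores returns one row per mesocosm over top-k clusters", {
  set.seed(2)
  pa <- matrix(runif(6 * 9, 0.01, 1), 6, 9,
               dimnames = list(paste0("m", 1:6), paste0("cluster", 1:9)))
  fa <- matrix(runif(6 * 9, 0.01, 1), 6, 9,
               dimnames = list(paste0("m", 1:6), paste0("cluster", 1:9)))
  sc <- coupling_scores(pa, fa, k = 9, transform = "none")
  expect_equal(nrow(sc), 6)
  expect_equal(sc$mesocosm_id, paste0("m", 1:6))
  expect_equal(sc$beta[3], cor(pa[3, ], fa[3, ]))
  # k is capped at the available columns
  sc5 <- coupling_scores(pa[, 1:5], fa, k = 9, transform = "none")
  expect_equal(unique(sc5$n_cluster_pairs), 5)
})

test_that("bonferroni_threshold reproduces the published thresholds", {
  expect_equal(bonferroni_threshold(0.05, 30)$alpha_rounded, 0.0017)
  expect_equal(bonferroni_threshold(0.05, 28)$alpha_rounded, 0.0018)
  expect_equal(bonferroni_threshold(0.05, 10)$alpha, 0.005)
  expect_error(bonferroni_threshold(0.05, 0), class = "mesonet_data_error")
})

test_that("cluster_correlations flags strong pairs and spares noise", {
  set.seed(14)
  n <- 40
  base <- rnorm(n)
  ab <- cbind(c1 = base + rnorm(n, 0, 0.1),
              c2 = base + rnorm(n, 0, 0.1),
              c3 = rnorm(n),
              c4 = rnorm(n))
  cc <- cluster_correlations(ab, transform = "none")
  expect_equal(cc$n_tests, 4)  # denominator "clusters"
  expect_equal(cc$alpha_per_test, 0.05 / 4)
  expect_equal(nrow(cc$table), 6)
  t12 <- cc$table[cc$table$cluster_a == "c1" & cc$table$cluster_b == "c2", ]
  expect_true(t12$significant)
  t34 <- cc$table[cc$table$cluster_a == "c3" & cc$table$cluster_b == "c4", ]
  expect_false(t34$significant)
  # pairs denominator
  cp <- cluster_correlations(ab, denominator = "pairs", transform = "none")
  expect_equal(cp$n_tests, 6)
})

test_that("mixed-model pairs use the grouping when it has two levels", {
  set.seed(15)
  n <- 30
  g <- rep(c("low", "high"), each = n / 2)
  ab <- cbind(c1 = rnorm(n), c2 = rnorm(n), c3 = rnorm(n))
  cc <- cluster_correlations(ab, grouping = g, transform = "none")
  expect_true(all(cc$table$mixed))
})

test_that("stability_coupling_test fits the mixed model and Wald chi-square", {
  set.seed(16)
  n <- 40
  soil <- rep(c("a", "b"), each = n / 2)
  beta <- runif(n, 0, 1)
  stab <- exp(1 - 1.5 * beta + rnorm(n, 0, 0.2))
  res <- stability_coupling_test(stab, beta, soil)
  expect_equal(res$random_effect, "soil")
  expect_equal(res$n, n)
  expect_equal(res$wald_chisq, (res$slope / res$se)^2)
  expect_equal(res$p, pchisq(res$wald_chisq, 1, lower.tail = FALSE))
  expect_lt(res$slope, 0)
  expect_error(stability_coupling_test(c(-1, 1, 2), c(1, 2, 3), soil[1:3]),
               class = "mesonet_data_error")
  expect_error(stability_coupling_test(c(1, 1, 2), c(2, 2, 2), soil[1:3]),
               class = "mesonet_degenerate_error")
  expect_warning(stability_coupling_test(stab, beta, rep("a", n)),
                 "fewer than 2 soils")
})
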