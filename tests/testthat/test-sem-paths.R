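test_that("path_spec rejects cyclic candidate sets", {
  expect_error(path_spec(data.frame(from = c("a", "b"), to = c("b", "a"))),
               class = "mesonet_spec_error")
  sp <- path_spec(data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_setequal(sp$nodes, c("a", "b", "c"))
})

test_that("dsep_basis_set matches hand-derived claims on small graphs", {
  # chain a -> b -> c: single claim a _||_ c | b
  cl <- dsep_basis_set(data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$x, "a")
  expect_equal(cl[[1]]$y, "c")
  expect_equal(cl[[1]]$conditioning, "b")
  # collider a -> c <- b: claim a _||_ b | {} (union of parents excl. pair)
  cl2 <- dsep_basis_set(data.frame(from = c("a", "b"), to = c("c", "c")))
  expect_length(cl2, 1)
  expect_setequal(c(cl2[[1]]$x, cl2[[1]]$y), c("a", "b"))
  expect_length(cl2[[1]]$conditioning, 0)
})

test_that("fishers_c follows -2 sum log p with 2k df", {
  fc <- fishers_c(c(0.2, 0.5))
  expect_equal(fc$C, -2 * (log(0.2) + log(0.5)))
  expect_equal(fc$df, 4L)
  expect_equal(fc$p, pchisq(fc$C, 4, lower.tail = FALSE))
  expect_equal(fishers_c(numeric(0)), list(C = 0, df = 0L, p = 1))
  expect_error(fishers_c(c(0.5, 1.2)), class = "mesonet_data_error")
  expect_warning(fishers_c(c(0.5, 0)), "clamped")
})

test_that("aicc applies the small-sample correction", {
  ll <- -12.3; n <- 20; k <- 4
  expect_equal(aicc(ll, n, k),
               -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  expect_error(aicc(ll, 5, 4), class = "mesonet_data_error")
})

test_that("fit_equation returns standardized betas matching lm", {
  set.seed(21)
  n <- 50
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 0.6 * d$x1 - 0.3 * d$x2 + rnorm(n, 0, 0.5)
  f <- fit_equation(d, "y", c("x1", "x2"), transform = "none")
  # standardized betas are invariant to the sd convention used for scaling
  ref <- coef(lm(scale(d$y) ~ scale(d$x1) + scale(d$x2)))[-1]
  expect_equal(f$coefficients$estimate, unname(ref), tolerance = 1e-10)
  expect_false(f$mixed)
  expect_equal(f$n, n)
  expect_equal(f$aicc, aicc(f$log_lik, n, f$k_params))
  # collinearity is reported, not silently dropped
  d$x3 <- d$x1
  expect_error(fit_equation(d, "y", c("x1", "x2", "x3"), transform = "none"),
               class = "mesonet_data_error")
  expect_error(fit_equation(d[1:4, ], "y", c("x1", "x2"), transform = "none"),
               class = "mesonet_data_error")
})

test_that("fit_equation uses a random intercept when grouping varies", {
  set.seed(22)
  n <- 40
  d <- data.frame(x = rnorm(n), g = rep(c("lo", "hi"), each = n / 2))
  d$y <- 0.5 * d$x + ifelse(d$g == "lo", -0.4, 0.4) + rnorm(n, 0, 0.3)
  f <- fit_equation(d, "y", "x", grouping = "g", transform = "none")
  expect_true(f$mixed)
  f1 <- fit_equation(d, "y", "x", grouping = NULL, transform = "none")
  expect_false(f1$mixed)
})

test_that("the transform policy reacts to skewed responses", {
  set.seed(23)
  n <- 60
  d <- data.frame(x = rnorm(n))
  d$y <- exp(1 + 0.8 * d$x + rnorm(n, 0, 0.3))
  f_auto <- fit_equation(d, "y", "x", transform = "auto")
  expect_true(f_auto$transform %in% c("ln", "sqrt"))
  f_ln <- fit_equation(d, "y", "x", transform = "ln")
  expect_equal(f_ln$transform, "ln")
})

test_that("backward_eliminate keeps planted edges and drops noise", {
  set.seed(24)
  n <- 60
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  d$m <- 0.8 * d$a + rnorm(n, 0, 0.4)
  d$y <- 0.9 * d$m + rnorm(n, 0, 0.4)
  spec <- path_spec(data.frame(from = c("a", "b", "m", "b"),
                               to = c("m", "m", "y", "y")))
  fit <- backward_eliminate(spec, d, transform = "none")
  got <- paste(fit$edges$from, fit$edges$to)
  expect_true(all(c("a m", "m y") %in% got))
  expect_false("b m" %in% got)
  expect_false("b y" %in% got)
  # AICc-minimal step is the one reported
  expect_equal(fit$aicc, min(fit$history$aicc))
  expect_equal(fit$n, n)
  # d-separation claims carry p-values and Fisher's C is their combination
  ps <- vapply(fit$claims, `[[`, numeric(1), "p")
  expect_equal(fit$fisher_c$C, -2 * sum(log(ps[is.finite(ps)])))
  # dsep switch skips the test
  fit2 <- backward_eliminate(spec, d, transform = "none", dsep = FALSE)
  expect_null(fit2$fisher_c)
  expect_identical(fit2$edges, fit$edges)
})

test_that("sem_microbe_inventory enumerates one variable per model", {
  inv <- sem_microbe_inventory(3, 2, 4)
  expect_length(inv, 9)
  expect_equal(inv[1], "biomass1")
  expect_equal(inv[4], "prok_cluster1")
  expect_equal(inv[9], "fung_cluster4")
  expect_length(sem_microbe_inventory(0, 2, 2), 4)
})

test_that("build_and_run_sems returns one fitted model per microbial variable", {
  set.seed(25)
  n <- 40
  d <- data.frame(
    productivity_sampling = rnorm(n),
    diversity_sampling = rnorm(n),
    axis1_impact = rnorm(n),
    sowing_density = rep(c("low", "high"), each = n / 2)
  )
  d$total_N <- 0.7 * d$productivity_sampling + rnorm(n, 0, 0.4)
  d$pH <- rnorm(n)
  d$prok_cluster1 <- 0.8 * d$total_N + rnorm(n, 0, 0.4)
  d$biomass1 <- rnorm(n)
  models <- build_and_run_sems(
    d, plant_vars = c("productivity_sampling", "diversity_sampling",
                      "axis1_impact"),
    chem_vars = c("total_N", "pH"),
    microbe_vars = c("prok_cluster1", "biomass1"),
    transform = "none", dsep = FALSE)
  expect_length(models, 2)
  expect_equal(models$prok_cluster1$microbe_var, "prok_cluster1")
  got <- paste(models$prok_cluster1$edges$from, models$prok_cluster1$edges$to)
  expect_true("total_N prok_cluster1" %in% got)
})

test_that("relative_contributions weights pathways by beta and size", {
  roles <- default_plant_roles(c("productivity_sampling", "axis1_impact"))
  cand <- data.frame(
    from = c("productivity_sampling", "axis1_impact", "total_N",
             "productivity_sampling", "axis1_impact"),
    to = c("total_N", "total_N", "m", "m", "m"),
    group = NA_character_)
  edges <- data.frame(
    from = c("productivity_sampling", "total_N", "axis1_impact"),
    to = c("total_N", "m", "m"),
    group = NA_character_,
    estimate = c(0.5, 0.4, 0.3),
    p = c(0.01, 0.01, 0.01))
  model <- structure(list(edges = edges, candidates = cand,
                          microbe_var = "m", var_roles = roles,
                          chem_vars = "total_N"),
                     class = "fitted_path_model")
  led <- relative_contributions(list(model), sizes = c(m = 0.5))
  get <- function(g, col) led[[col]][led$group == g]
  # indirect year.overall: |0.5 * 0.4| * 0.5, one chem mediator candidate
  expect_equal(get("year.overall.indirect", "raw"), 0.5 * 0.4 * 0.5)
  expect_equal(get("year.overall.indirect", "n_potential"), 1)
  # direct past.compositional: |0.3| * 0.5 over 1 candidate
  expect_equal(get("past.compositional.direct", "raw"), 0.3 * 0.5)
  # non-significant or absent groups are zero
  expect_equal(get("year.overall.direct", "raw"), 0)
  expect_equal(get("year.overall.direct", "n_potential"), 1)
  expect_equal(led$scaled, ifelse(led$n_potential > 0,
                                  led$raw / led$n_potential, 0))
  expect_error(relative_contributions(list(model), sizes = c(zz = 0.5)),
               class = "mesonet_data_error")
})
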