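test_that("signed_network validates and normalises edges", {
  nodes <- c("a", "b", "c")
  net <- signed_network(data.frame(from = "c", to = "a", weight = -0.5),
                        nodes)
  # edge endpoint order is normalised to node order
  expect_equal(net$edges$from, "a")
  expect_equal(net$edges$to, "c")
  expect_error(signed_network(data.frame(from = "a", to = "a", weight = 1),
                              nodes), class = "mesonet_data_error")
  expect_error(signed_network(data.frame(from = "a", to = "b", weight = 0),
                              nodes), class = "mesonet_data_error")
  expect_error(signed_network(data.frame(from = c("a", "b"),
                                         to = c("b", "a"),
                                         weight = c(1, 2)), nodes),
               class = "mesonet_data_error")
  expect_error(signed_network(data.frame(from = "a", to = "z", weight = 1),
                              nodes), class = "mesonet_data_error")
})

test_that("degree_sequence and adjacency agree with igraph", {
  set.seed(42)
  net <- random_signed_network(12, p_edge = 0.4)
  d <- degree_sequence(net)
  g <- as_igraph(net)
  expect_equal(unname(d[igraph::V(g)$name]), unname(igraph::degree(g)))
  A <- mesonet:::adjacency_matrix(net)
  expect_true(isSymmetric(A))
  expect_equal(sum(A != 0) / 2, nrow(net$edges))
})

test_that("network export round-trips through TSV and writes GraphML", {
  set.seed(1)
  net <- random_signed_network(8)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "net.tsv")
  write_signed_network(net, p)
  back <- read.delim(p)
  expect_equal(back$weight, net$edges$weight)
  g <- file.path(dir, "net.graphml")
  write_signed_network(net, g, format = "graphml")
  rg <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(rg), nrow(net$edges))
})

test_that("MB at lambda >= lambda_max yields an empty network", {
  set.seed(5)
  x <- matrix(rnorm(40 * 10), 40, 10)
  colnames(x) <- paste0("o", 1:10)
  xs <- mesonet:::standardize_columns(x)
  lmax <- mesonet:::lambda_max_mb(xs)
  net <- mb_neighborhood_selection(x, lmax * 1.05)
  expect_equal(nrow(net$edges), 0)
})

test_that("MB recovers a planted conditional-dependence structure", {
  # chain graph: precision matrix tridiagonal -> neighbours are adjacent
  set.seed(77)
  p <- 8; n <- 600
  Omega <- diag(p)
  for (i in seq_len(p - 1)) Omega[i, i + 1] <- Omega[i + 1, i] <- 0.45
  Sigma <- solve(Omega)
  L <- chol(Sigma)
  x <- matrix(rnorm(n * p), n, p) %*% L
  colnames(x) <- paste0("v", seq_len(p))
  net <- mb_neighborhood_selection(x, lambda = 0.1)
  got <- paste(net$edges$from, net$edges$to)
  want <- paste(paste0("v", 1:(p - 1)), paste0("v", 2:p))
  expect_setequal(got, want)
  # partial correlations of a chain are negative for positive off-diagonals
  expect_true(all(net$edges$weight < 0))
})

test_that("unpenalized MB (lambda 0) matches per-node OLS", {
  set.seed(9)
  x <- matrix(rnorm(30 * 5), 30, 5)
  colnames(x) <- paste0("v", 1:5)
  net <- mb_neighborhood_selection(x, lambda = 0)
  B <- attr(net, "coefficients")
  xs <- mesonet:::standardize_columns(x)
  ref <- coef(lm(xs[, 1] ~ xs[, -1]))[-1]
  expect_equal(unname(B[1, -1]), unname(ref), tolerance = 1e-10)
})

test_that("constant columns are isolated with a warning", {
  set.seed(3)
  x <- cbind(matrix(rnorm(40 * 4), 40, 4), 1)
  colnames(x) <- paste0("v", 1:5)
  expect_warning(net <- mb_neighborhood_selection(x, lambda = 0.05),
                 "constant")
  expect_false("v5" %in% c(net$edges$from, net$edges$to))
})

test_that("stars_select picks a stable penalty on structured data", {
  set.seed(101)
  p <- 10; n <- 80
  Omega <- diag(p)
  for (i in seq_len(p - 1)) Omega[i, i + 1] <- Omega[i + 1, i] <- 0.45
  L <- chol(solve(Omega))
  x <- matrix(rnorm(n * p), n, p) %*% L
  colnames(x) <- paste0("v", seq_len(p))
  st <- stars_select(x, n_lambda = 12, n_subsamples = 25, seed = 17)
  expect_true(st$lambda_opt %in% st$path$lambda)
  # monotonized instability is non-decreasing as lambda decreases
  expect_true(all(diff(st$path$instability_monotone) >= 0))
  expect_equal(st$path$instability_monotone,
               cummax(st$path$instability))
  # selected penalty is the smallest with monotone instability <= 0.05,
  # unless none qualifies
  ok <- which(st$path$instability_monotone <= 0.05)
  if (length(ok)) {
    expect_false(st$no_lambda_ok)
    expect_equal(st$lambda_opt, st$path$lambda[max(ok)])
  } else {
    expect_true(st$no_lambda_ok)
  }
  # densities lie in [0, 1] and the refit network is over the input columns
  expect_true(all(st$path$density >= 0 & st$path$density <= 1))
  expect_setequal(st$network$nodes, colnames(x))
  # reproducible
  st2 <- stars_select(x, n_lambda = 12, n_subsamples = 25, seed = 17)
  expect_equal(st$lambda_opt, st2$lambda_opt)
  expect_identical(st$network$edges, st2$network$edges)
})
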