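#' Signed weighted co-occurrence network
#'
#' Undirected simple graph over OTUs with signed real edge weights (positive
#' = co-occurrence, negative = mutual exclusion given all other OTUs).
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (nonzero);
#'   node order within an edge is normalised internally.
#' @param nodes character vector of all node ids (isolated nodes allowed).
#' @return an object of class `signed_network`.
#' @export
signed_network <- function(edges, nodes) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_data("duplicate node ids")
  if (nrow(edges)) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (any(edges$from == edges$to)) stop_data("self-loops are not allowed")
    if (!all(c(edges$from, edges$to) %in% nodes))
      stop_data("edge endpoints must be listed in `nodes`")
    if (any(edges$weight == 0) || any(!is.finite(edges$weight)))
      stop_data("edge weights must be nonzero and finite")
    swap <- match(edges$from, nodes) > match(edges$to, nodes)
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    if (anyDuplicated(edges[c("from", "to")])) stop_data("duplicate edges")
    edges <- edges[order(match(edges$from, nodes), match(edges$to, nodes)), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("<signed_network> %d nodes, %d edges (%d positive, %d negative)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight > 0),
              sum(x$edges$weight < 0)))
  invisible(x)
}

#' Degree sequence of a signed network
#' @param net a [signed_network].
#' @return named integer vector of unweighted degrees, one per node.
#' @export
degree_sequence <- function(net) {
  d <- setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    t1 <- table(net$edges$from); t2 <- table(net$edges$to)
    d[names(t1)] <- d[names(t1)] + as.integer(t1)
    d[names(t2)] <- d[names(t2)] + as.integer(t2)
  }
  d
}

# symmetric signed adjacency matrix (dense; networks here are small)
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    A[cbind(i, j)] <- net$edges$weight
    A[cbind(j, i)] <- net$edges$weight
  }
  A
}

#' Convert to an igraph object (weights kept as edge attribute)
#' @param net a [signed_network].
#' @return an igraph graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

from_igraph <- function(g, weights = NULL) {
  ed <- igraph::as_data_frame(g, what = "edges")
  w <- weights %||% ed$weight
  signed_network(data.frame(from = ed$from, to = ed$to, weight = w),
                 nodes = igraph::V(g)$name)
}

#' Export a signed network
#' @param net a [signed_network].
#' @param path output path; `format = "tsv"` writes a weighted edge list
#'   (node_i, node_j, weight), `"graphml"` writes GraphML via igraph.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_signed_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

# column-standardize with population sd; constant columns become all-zero
# and are reported in the "constant" attribute
standardize_columns <- function(x) {
  mu <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  const <- s == 0
  s[const] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, s, "/")
  xs[, const] <- 0
  attr(xs, "constant") <- const
  xs
}

# largest penalty with a non-empty graph on pop-standardized data
lambda_max_mb <- function(xs) {
  n <- nrow(xs)
  S <- crossprod(xs) / n
  diag(S) <- 0
  max(abs(S))
}

# lasso coefficient matrix for every node at each penalty in `lambda_vec`
# (decreasing). Returns p x p x L array; row j holds the regression of node j
# on the others.
mb_coef_path <- function(xs, lambda_vec) {
  p <- ncol(xs)
  const <- attr(xs, "constant") %||% rep(FALSE, p)
  out <- array(0, dim = c(p, p, length(lambda_vec)))
  for (j in seq_len(p)) {
    if (const[j]) next
    y <- xs[, j]
    fit <- glmnet::glmnet(xs[, -j, drop = FALSE], y, family = "gaussian",
                          lambda = lambda_vec, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-10)
    # glmnet may stop early on a degenerate path; align by lambda value
    co <- as.matrix(fit$beta)
    idx <- match(signif(fit$lambda, 8), signif(lambda_vec, 8))
    ok <- !is.na(idx)
    out[j, -j, idx[ok]] <- co[, ok]
  }
  out
}

#' Neighborhood selection (MB) at a fixed penalty
#'
#' Per OTU, an L1-penalized linear regression of its clr abundances on all
#' other OTUs (glmnet, on column-standardized data). An undirected edge is
#' kept when either directed coefficient is nonzero ("or" rule); the edge
#' weight is the coefficient of larger magnitude, keeping its sign.
#'
#' @param clr samples x OTUs matrix of clr-transformed counts.
#' @param lambda penalty on glmnet's scale for standardized data; `0` gives
#'   the unpenalized (OLS) partial regressions.
#' @return a [signed_network] over the OTUs; the directed coefficient matrix
#'   is attached as attribute `"coefficients"`.
#' @export
mb_neighborhood_selection <- function(clr, lambda) {
  if (nrow(clr) < 4L) stop_data("need at least 4 samples")
  if (lambda < 0) stop_config("`lambda` must be >= 0")
  xs <- standardize_columns(clr)
  const <- attr(xs, "constant")
  if (any(const))
    warning(sprintf("%d constant column(s) isolated", sum(const)))
  p <- ncol(xs)
  nodes <- colnames(clr) %||% paste0("otu", seq_len(p))
  if (lambda == 0) {
    B <- matrix(0, p, p)
    for (j in seq_len(p)) {
      if (const[j]) next
      keep <- which(!const & seq_len(p) != j)
      fit <- lm.fit(cbind(1, xs[, keep, drop = FALSE]), xs[, j])
      B[j, keep] <- fit$coefficients[-1L]
    }
  } else {
    lmax <- max(lambda_max_mb(xs), lambda)
    grid <- exp(seq(log(lmax * 1.0001), log(max(lambda, lmax * 1e-4)),
                    length.out = 25))
    # drop grid points numerically indistinguishable from the requested
    # penalty, so the exact value survives the per-node lambda matching
    grid <- grid[abs(grid / lambda - 1) > 1e-6]
    grid <- sort(unique(c(grid, lambda)), decreasing = TRUE)
    path <- mb_coef_path(xs, grid)
    B <- path[, , match(lambda, grid)]
  }
  edges <- mb_edges_from_coef(B, nodes)
  net <- signed_network(edges, nodes)
  attr(net, "coefficients") <- B
  net
}

# "or" symmetrization with max-magnitude signed weight
mb_edges_from_coef <- function(B, nodes) {
  p <- nrow(B)
  W <- ifelse(abs(B) >= abs(t(B)), B, t(B))
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
             weight = W[idx])
}

#' StARS stability selection for the MB network
#'
#' Fits the neighborhood-selection path on `n_subsamples` random subsamples
#' of the rows, records per-edge selection frequencies theta at each penalty
#' of a log-spaced grid, and computes the mean edge instability
#' D(lambda) = mean(2 theta (1 - theta)). The selected penalty is the
#' smallest one (densest graph) whose monotonized instability stays at or
#' below `beta_threshold`; the final network is refit on the full data at
#' that penalty.
#'
#' @param clr samples x OTUs clr matrix.
#' @param n_lambda number of grid points (default 20).
#' @param beta_threshold StARS instability threshold (default 0.05).
#' @param n_subsamples number of subsampling replications (default 999;
#'   desk-scale runs use far fewer).
#' @param subsample_fraction row fraction per subsample, without
#'   replacement.
#' @param lambda_min_ratio smallest penalty as a fraction of the empty-graph
#'   penalty.
#' @param seed RNG seed.
#' @return a list with `network` (the refit [signed_network]), `lambda_opt`,
#'   `path` (data.frame lambda, density, instability, monotone instability),
#'   `theta` (edge frequencies at `lambda_opt`), and `no_lambda_ok` (TRUE
#'   when no penalty met the threshold and the sparsest was returned).
#' @export
stars_select <- function(clr, n_lambda = 20, beta_threshold = 0.05,
                         n_subsamples = 999, subsample_fraction = 0.8,
                         lambda_min_ratio = 0.01, seed = NULL) {
  if (n_subsamples < 2L) stop_config("`n_subsamples` must be >= 2")
  if (subsample_fraction <= 0 || subsample_fraction >= 1)
    stop_config("`subsample_fraction` must be in (0, 1)")
  n <- nrow(clr); p <- ncol(clr)
  xs_full <- standardize_columns(clr)
  lmax <- lambda_max_mb(xs_full)
  grid <- exp(seq(log(lmax * 1.0001), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  b <- max(4L, floor(subsample_fraction * n))
  sel_count <- array(0, dim = c(p, p, n_lambda))
  with_seed(seed, {
    for (s in seq_len(n_subsamples)) {
      rows <- sample.int(n, b)
      xs <- standardize_columns(clr[rows, , drop = FALSE])
      path <- mb_coef_path(xs, grid)
      for (l in seq_len(n_lambda)) {
        Bl <- path[, , l]
        A <- (Bl != 0) | (t(Bl) != 0)
        sel_count[, , l] <- sel_count[, , l] + A
      }
    }
  })
  theta <- sel_count / n_subsamples
  n_pairs <- p * (p - 1) / 2
  instab <- vapply(seq_len(n_lambda), function(l) {
    th <- theta[, , l][upper.tri(theta[, , l])]
    mean(2 * th * (1 - th))
  }, numeric(1))
  density <- vapply(seq_len(n_lambda), function(l) {
    sum(theta[, , l][upper.tri(theta[, , l])] > 0.5) / n_pairs
  }, numeric(1))
  mono <- cummax(instab)  # grid is decreasing in lambda
  ok <- which(mono <= beta_threshold)
  no_lambda_ok <- length(ok) == 0L
  opt <- if (no_lambda_ok) 1L else max(ok)
  if (no_lambda_ok)
    warning("no penalty met the instability threshold; returning sparsest")
  lambda_opt <- grid[opt]
  network <- mb_neighborhood_selection(clr, lambda_opt)
  list(network = network, lambda_opt = lambda_opt,
       path = data.frame(lambda = grid, density = density,
                         instability = instab, instability_monotone = mono),
       theta = theta[, , opt], no_lambda_ok = no_lambda_ok)
}
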