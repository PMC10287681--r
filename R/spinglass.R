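#' Signed modularity of a partition
#'
#' Q = s_pos * Q_pos - s_neg * Q_neg where Q_pos (Q_neg) is the weighted
#' Newman-Girvan modularity of the positive (absolute negative) subgraph at
#' resolution gamma_pos (gamma_neg), and s_pos, s_neg are the shares of total
#' positive/negative strength. With equal resolutions of 1, present/absent
#' and positive/negative edges get equal importance. Q lies in [-1, 1].
#'
#' @param net a [signed_network].
#' @param membership named integer vector (node -> cluster) covering all
#'   nodes of `net`.
#' @param gamma_pos,gamma_neg resolution parameters for the null terms.
#' @return Q (unitless).
#' @export
signed_modularity <- function(net, membership, gamma_pos = 1, gamma_neg = 1) {
  missing <- setdiff(net$nodes, names(membership))
  if (length(missing))
    stop_data(paste("partition missing node(s):",
                    paste(head(missing, 5), collapse = ", ")))
  lab <- membership[net$nodes]
  W <- adjacency_matrix(net)
  part_q <- function(Wp, gamma) {
    two_m <- sum(Wp)
    if (two_m == 0) return(0)
    k <- rowSums(Wp)
    same <- outer(lab, lab, "==")
    sum((Wp / two_m - gamma * outer(k, k) / two_m^2) * same)
  }
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  a <- sum(Wp); b <- sum(Wn)
  if (a + b == 0) return(0)
  (a / (a + b)) * part_q(Wp, gamma_pos) - (b / (a + b)) * part_q(Wn, gamma_neg)
}

#' Spin-glass clustering of a signed network
#'
#' Partitions OTUs by maximizing [signed_modularity()] with simulated
#' annealing (geometric cooling, single-node moves, greedy polish, best of
#' `n_restarts` kept). Positive and negative edges and their weights all
#' enter the objective; the number of clusters is not constrained. Clusters
#' are renumbered by prevalence: descending total relative reads when an
#' [otu_table] is supplied (ties broken by the smallest member OTU id),
#' otherwise by descending cluster size.
#'
#' @param net a [signed_network].
#' @param table optional [otu_table] used for prevalence ordering and
#'   per-sample cluster abundances.
#' @param gamma_pos,gamma_neg resolution parameters (default 1, 1).
#' @param n_restarts annealing restarts (best Q kept).
#' @param t0,t_min,cooling annealing schedule: initial and final temperature
#'   and geometric cooling factor.
#' @param sweeps_per_temp proposed moves per node per temperature step.
#' @param seed RNG seed.
#' @return a `cluster_partition`: list with `membership` (node -> 1-based
#'   cluster, prevalence-ordered), `n_clusters`, `Q`, `order_key`, and
#'   `abundance` (samples x clusters summed relative reads) when `table`
#'   is given.
#' @export
spinglass_cluster <- function(net, table = NULL, gamma_pos = 1, gamma_neg = 1,
                              n_restarts = 5, t0 = 0.05, t_min = 1e-4,
                              cooling = 0.9, sweeps_per_temp = 20,
                              seed = NULL) {
  if (!length(net$nodes)) stop_data("empty network")
  n <- length(net$nodes)
  if (nrow(net$edges) == 0L) {
    membership <- setNames(seq_len(n), net$nodes)
    res <- list(membership = membership, Q = 0)
  } else {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    raw <- with_seed(seed, .anneal_signed_modularity(
      n, i, j, net$edges$weight, gamma_pos, gamma_neg,
      as.integer(n_restarts), as.integer(sweeps_per_temp),
      t0, t_min, cooling))
    res <- list(membership = setNames(raw$membership, net$nodes), Q = raw$Q)
  }
  partition_from_membership(res$membership, net = net, table = table,
                            Q = res$Q)
}

# renumber clusters by prevalence and attach per-sample abundances
partition_from_membership <- function(membership, net = NULL, table = NULL,
                                      Q = NA_real_) {
  nodes <- names(membership)
  if (!is.null(table)) {
    in_tab <- nodes %in% otu_ids(table)
    if (!all(in_tab))
      stop_data("partition has OTUs absent from the abundance table")
    rel <- table$counts / rowSums(table$counts)
    key <- tapply(colSums(rel[, nodes, drop = FALSE]), membership, sum)
  } else {
    key <- table(membership)
  }
  # descending prevalence; ties broken by the smallest member OTU id
  tie <- tapply(nodes, membership, function(id) min(id))
  ord <- order(-as.numeric(key), tie[names(key)])
  remap <- setNames(seq_along(ord), names(key)[ord])
  new_membership <- setNames(as.integer(remap[as.character(membership)]),
                             nodes)
  out <- list(membership = new_membership,
              n_clusters = length(unique(new_membership)),
              Q = Q,
              order_key = setNames(as.numeric(key)[ord], seq_along(ord)))
  if (!is.null(table))
    out$abundance <- cluster_abundances(new_membership, table)
  class(out) <- "cluster_partition"
  out
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition> %d nodes in %d clusters, Q = %.4f\n",
              length(x$membership), x$n_clusters, x$Q))
  invisible(x)
}

#' Per-sample summed relative cluster abundances
#'
#' For each sample, OTU counts are converted to relative abundances
#' (count / sample total) and summed within clusters; columns are ordered by
#' cluster index.
#'
#' @param membership named integer vector OTU -> cluster (or a
#'   `cluster_partition`).
#' @param table an [otu_table] containing at least the partition's OTUs.
#' @return samples x clusters numeric matrix.
#' @export
cluster_abundances <- function(membership, table) {
  if (inherits(membership, "cluster_partition"))
    membership <- membership$membership
  nodes <- names(membership)
  if (!all(nodes %in% otu_ids(table)))
    stop_data("partition has OTUs absent from the abundance table")
  totals <- rowSums(table$counts)
  if (any(totals == 0)) stop_data("sample with zero total reads")
  rel <- table$counts[, nodes, drop = FALSE] / totals
  ks <- sort(unique(membership))
  out <- vapply(ks, function(k) {
    rowSums(rel[, membership == k, drop = FALSE])
  }, numeric(nrow(rel)))
  out <- matrix(out, nrow = nrow(rel),
                dimnames = list(rownames(table$counts),
                                paste0("cluster", ks)))
  out
}

#' Write a cluster partition to TSV (columns: otu_id, cluster)
#' @param partition a `cluster_partition` or named membership vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  m <- if (inherits(partition, "cluster_partition")) partition$membership else partition
  write.table(data.frame(otu_id = names(m), cluster = as.integer(m)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
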