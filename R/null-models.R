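#' Degree-preserving rewiring of a signed network
#'
#' Randomizes the topology by repeated double edge swaps (igraph's
#' `keeping_degseq`, which forbids loops and parallel edges), so every
#' replicate has exactly the original degree sequence. The original signed
#' weight multiset is then reassigned to the new edge set by random
#' permutation, preserving the weight distribution.
#'
#' @param net a [signed_network].
#' @param n_swaps_per_edge attempted swaps per edge (burn-in; default 10).
#' @param seed RNG seed.
#' @return a rewired [signed_network] with identical degree sequence. When
#'   the network has fewer than 2 edges a copy is returned with attribute
#'   `"rewire_skipped" = TRUE`.
#' @export
rewire_preserving_degrees <- function(net, n_swaps_per_edge = 10,
                                      seed = NULL) {
  m <- nrow(net$edges)
  if (m < 2L) {
    warning("network too small to swap; returning a copy")
    out <- net
    attr(out, "rewire_skipped") <- TRUE
    return(out)
  }
  with_seed(seed, {
    g <- igraph::rewire(as_igraph(net),
                        igraph::keeping_degseq(loops = FALSE,
                                               niter = n_swaps_per_edge * m))
    from_igraph(g, weights = sample(net$edges$weight))
  })
}

empirical_p_lower <- function(replicates, observed) {
  # literal definition: proportion of randomized statistics smaller than the
  # observed; ties count as "not smaller"
  mean(replicates < observed)
}

#' Rewiring null test for clustering density (signed modularity)
#'
#' Rewires the network `R` times, reruns spin-glass clustering on every
#' replicate and compares the observed partition's signed modularity Q with
#' the null distribution. The empirical p is the proportion of replicate Qs
#' smaller than the observed Q (so p near 1 means the observed network is
#' more densely clustered than chance); both tails are reported.
#'
#' @param net a [signed_network].
#' @param R ensemble size (default 1000).
#' @param seed RNG seed.
#' @param ... passed to [spinglass_cluster()] (restarts, schedule, gammas).
#' @return a `rewired_ensemble`: list with `observed`, `replicates`,
#'   `p_lower` (= share of replicates below observed), `p_upper`, `R`.
#' @export
null_modularity_test <- function(net, R = 1000, seed = NULL, ...) {
  R <- check_count(R, "R")
  obs <- spinglass_cluster(net, seed = derive_seed(seed %||% 0, "obs"), ...)
  reps <- with_seed(seed, vapply(seq_len(R), function(r) {
    rw <- rewire_preserving_degrees(net)
    stopifnot(identical(degree_sequence(rw), degree_sequence(net)))
    spinglass_cluster(rw, ...)$Q
  }, numeric(1)))
  p <- empirical_p_lower(reps, obs$Q)
  structure(list(statistic = "signed_modularity", observed = obs$Q,
                 replicates = reps, p_lower = p, p_upper = 1 - p, R = R),
            class = "rewired_ensemble")
}

#' Rewiring null test for prokaryote-fungal cluster coupling
#'
#' Per replicate, both networks are rewired (degrees preserved), clusters
#' re-detected, per-sample cluster abundances recomputed, and the number of
#' Bonferroni-significant prokaryote-fungal cluster correlations counted via
#' [cluster_correlations()]. The empirical p is the proportion of replicate
#' counts smaller than the observed count.
#'
#' @param prok_net,fungal_net [signed_network]s.
#' @param prok_table,fungal_table matching [otu_table]s (same samples).
#' @param R ensemble size.
#' @param family_alpha family-wise alpha for the Bonferroni threshold.
#' @param denominator `"clusters"` or `"pairs"` (see
#'   [bonferroni_threshold()]).
#' @param grouping optional random-intercept factor passed to
#'   [cluster_correlations()].
#' @param seed RNG seed.
#' @param ... passed to [spinglass_cluster()].
#' @return a `rewired_ensemble` with the significant-correlation count as
#'   the statistic.
#' @export
null_coupling_correlation_test <- function(prok_net, fungal_net, prok_table,
                                           fungal_table, R = 1000,
                                           family_alpha = 0.05,
                                           denominator = "clusters",
                                           grouping = NULL, seed = NULL, ...) {
  R <- check_count(R, "R")
  count_sig <- function(pn, fn) {
    pp <- spinglass_cluster(pn, table = prok_table, ...)
    fp <- spinglass_cluster(fn, table = fungal_table, ...)
    ct <- cross_cluster_correlations(pp$abundance, fp$abundance,
                                     grouping = grouping,
                                     family_alpha = family_alpha,
                                     denominator = denominator)
    sum(ct$table$significant)
  }
  obs <- with_seed(derive_seed(seed %||% 0, "obs"),
                   count_sig(prok_net, fungal_net))
  reps <- with_seed(seed, vapply(seq_len(R), function(r) {
    rp <- rewire_preserving_degrees(prok_net)
    rf <- rewire_preserving_degrees(fungal_net)
    count_sig(rp, rf)
  }, numeric(1)))
  p <- empirical_p_lower(reps, obs)
  structure(list(statistic = "n_significant_correlations", observed = obs,
                 replicates = reps, p_lower = p, p_upper = 1 - p, R = R),
            class = "rewired_ensemble")
}

#' @export
print.rewired_ensemble <- function(x, ...) {
  cat(sprintf("<rewired_ensemble> %s: observed %.4g, R = %d, p_lower = %.3f\n",
              x$statistic, x$observed, x$R, x$p_lower))
  invisible(x)
}

#' Write an ensemble report
#' @param x a `rewired_ensemble`.
#' @param tsv_path optional TSV of per-replicate statistics.
#' @param json_path optional JSON summary (observed, p_lower, p_upper, R).
#' @return invisibly, a list of written paths.
#' @export
write_ensemble_report <- function(x, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(data.frame(replicate = seq_along(x$replicates),
                           statistic = x$replicates),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(statistic = x$statistic, observed = x$observed,
                              p_lower = x$p_lower, p_upper = x$p_upper,
                              R = x$R),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(tsv = tsv_path, json = json_path))
}
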