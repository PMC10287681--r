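#' Exclude rare OTUs
#'
#' Drops OTUs whose total read count is below `min_total_reads` or that are
#' present (count > 0) in fewer than `min_samples` samples. Defaults mirror
#' the usual pre-network filter for amplicon data: total < 100 reads or
#' presence in < 5 samples per soil origin.
#'
#' @param x an [otu_table].
#' @param min_total_reads minimum total reads to retain an OTU.
#' @param min_samples minimum number of samples with a positive count.
#' @return the filtered [otu_table]; sample set unchanged.
#' @export
filter_otus <- function(x, min_total_reads = 100, min_samples = 5) {
  totals <- colSums(x$counts)
  presence <- colSums(x$counts > 0)
  keep <- totals >= min_total_reads & presence >= min_samples
  if (!any(keep)) stop_data("filter removed every OTU")
  subset_otu_table(x, otus = which(keep))
}

#' Rarefy samples to a common depth
#'
#' Without-replacement subsampling of each sample's reads down to `depth`
#' (vegan's rrarefy). Samples whose total is below the depth are dropped with
#' a warning.
#'
#' @param x an [otu_table].
#' @param depth target reads per sample; default is the smallest sample
#'   total.
#' @param seed RNG seed.
#' @return a rarefied [otu_table]; each retained sample sums to `depth`.
#' @export
rarefy <- function(x, depth = NULL, seed = NULL) {
  totals <- sample_totals(x)
  depth <- depth %||% min(totals)
  if (depth < 1) stop_config("`depth` must be >= 1")
  keep <- which(totals >= depth)
  if (!length(keep)) stop_data("rarefaction depth exceeds every sample total")
  if (length(keep) < nrow(x$counts))
    warning(sprintf("dropping %d sample(s) with fewer than %d reads",
                    nrow(x$counts) - length(keep), depth))
  x <- subset_otu_table(x, samples = keep)
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic for
  # non-count data); our inputs are validated integer counts, so muffle it
  counts <- withCallingHandlers(
    with_seed(seed, vegan::rrarefy(x$counts, depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  otu_table(counts, habitat = x$habitat, domain = x$domain,
            taxonomy = x$taxonomy)
}

#' Mean Shannon diversity over repeated rarefactions
#'
#' Alpha diversity per sample as the mean Shannon H over `iterations`
#' independent rarefactions (default 1000), which removes the depth
#' dependence of a single rarefied draw.
#'
#' @inheritParams rarefy
#' @param iterations number of rarefaction draws.
#' @return named numeric vector of mean H per retained sample.
#' @export
multi_rarefied_shannon <- function(x, depth = NULL, iterations = 1000,
                                   seed = NULL) {
  iterations <- check_count(iterations, "iterations")
  totals <- sample_totals(x)
  depth <- depth %||% min(totals)
  with_seed(seed, {
    acc <- NULL
    for (i in seq_len(iterations)) {
      r <- rarefy(x, depth = depth)
      h <- apply(r$counts, 1L, shannon_diversity)
      acc <- if (is.null(acc)) h else acc + h
    }
    acc / iterations
  })
}

#' Centered log-ratio transform
#'
#' Per sample, clr(x)_i = ln(x_i + pc) - mean_j ln(x_j + pc). Rows of the
#' result sum to zero; a pseudocount is required when zeros are present.
#'
#' @param x an [otu_table] or a samples x OTUs count matrix.
#' @param pseudocount added to every count before taking logs.
#' @return samples x OTUs matrix of clr values.
#' @export
clr_transform <- function(x, pseudocount = 1) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  if (pseudocount < 0) stop_config("`pseudocount` must be >= 0")
  if (pseudocount == 0 && any(m == 0))
    stop_data("zero counts present: a positive pseudocount is required")
  lg <- log(m + pseudocount)
  lg - rowMeans(lg)
}

#' Habitat specialisation index per OTU
#'
#' SI_i = sigma_i / mu_i - sqrt(K / N_i): the coefficient of variation of the
#' OTU's reads across all samples minus a correction for under-sampling of
#' rare OTUs, with K the number of habitat classes and N_i the OTU's total
#' reads. Positive values indicate habitat specialists, negative values
#' generalists. Computed on rarefied counts; sigma is the sample (n-1)
#' standard deviation. Per-sample community-weighted mean SI uses relative
#' reads of the OTUs present in the sample as weights.
#'
#' @param x a rarefied [otu_table].
#' @param K number of habitat classes; default the number of distinct
#'   habitat labels in `x`.
#' @return a list: `per_otu` data.frame (otu_id, si, sigma, mu, n_reads, K),
#'   `per_sample` CWM SI, `excluded` ids of zero-read OTUs, `K`.
#' @export
specialisation_index <- function(x, K = NULL) {
  if (nrow(x$counts) == 0L) stop_data("no samples")
  K <- K %||% length(unique(x$habitat))
  if (K < 0) stop_config("`K` must be >= 0")
  mu <- colMeans(x$counts)
  excluded <- otu_ids(x)[mu == 0]
  keep <- mu > 0
  m <- x$counts[, keep, drop = FALSE]
  mu <- mu[keep]
  sigma <- apply(m, 2L, sd)
  n_reads <- colSums(m)
  si <- sigma / mu - sqrt(K / n_reads)
  per_otu <- data.frame(otu_id = colnames(m), si = si, sigma = sigma,
                        mu = mu, n_reads = n_reads, K = K,
                        row.names = NULL)
  rel <- m / rowSums(m)
  per_sample <- vapply(seq_len(nrow(m)), function(i) {
    w <- rel[i, ]
    cwm_si(si[w > 0], w[w > 0])
  }, numeric(1))
  names(per_sample) <- rownames(m)
  list(per_otu = per_otu, per_sample = per_sample, excluded = excluded, K = K)
}

#' Community-weighted mean of a specialisation index
#' @param si SI values.
#' @param weights non-negative weights (relative reads).
#' @return sum(w * si) / sum(w).
#' @export
cwm_si <- function(si, weights) {
  if (length(si) != length(weights)) stop_data("si and weights differ in length")
  if (any(weights < 0)) stop_data("weights must be >= 0")
  tot <- sum(weights)
  if (tot <= 0) stop_data("zero total weight")
  sum(weights * si) / tot
}

boxplot_fences <- function(v) {
  q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
}

#' Classify network clusters as habitat generalists or specialists
#'
#' A cluster is a relative habitat generalist when its central SI lies below
#' the community-wide mean SI and its whole distribution stays below it: the
#' upper box-plot fence (Q3 + 1.5 IQR) must not reach the mean. Specialists
#' are symmetric (CWM above the mean and lower fence Q1 - 1.5 IQR above it).
#' Everything else is intermediate.
#'
#' @param si_by_cluster named list of per-cluster SI value vectors (e.g. the
#'   per-sample CWM SI of each cluster).
#' @param community_mean community-wide mean SI.
#' @return data.frame with cluster, cwm_si, lower/upper fences and label.
#' @export
classify_cluster_specialisation <- function(si_by_cluster, community_mean) {
  out <- lapply(names(si_by_cluster), function(cl) {
    v <- si_by_cluster[[cl]]
    if (!length(v)) stop_data(sprintf("cluster %s has no SI values", cl))
    f <- boxplot_fences(v)
    m <- mean(v)
    label <- if (m < community_mean && f[["upper"]] < community_mean) {
      "generalist"
    } else if (m > community_mean && f[["lower"]] > community_mean) {
      "specialist"
    } else "intermediate"
    data.frame(cluster = cl, cwm_si = m, lower_fence = f[["lower"]],
               upper_fence = f[["upper"]], label = label)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Habitat enrichment of OTUs and network clusters
#'
#' Per OTU, the ln response ratio of habitat-summed rarefied reads,
#' ln((reads_A + pc) / (reads_B + pc)) with A the first habitat level. A
#' cluster is enriched in A when its median ratio is above zero and its lower
#' box-plot fence stays above zero; enriched in B symmetric; else neutral.
#'
#' @param x a rarefied [otu_table] with exactly two habitat labels.
#' @param membership named integer vector OTU -> cluster.
#' @param pseudocount added to habitat sums before the ratio.
#' @param center `"median"` (default) or `"mean"` for the sign condition.
#' @return list with `per_otu` (otu_id, cluster, ratio) and `per_cluster`
#'   (cluster, center, fences, label).
#' @export
enrichment_ratio_and_classify <- function(x, membership, pseudocount = 1,
                                          center = c("median", "mean")) {
  center <- match.arg(center)
  habs <- unique(x$habitat)
  if (length(habs) != 2L) stop_data("need exactly two habitat classes")
  in_a <- x$habitat == habs[1]
  if (!any(in_a) || all(in_a)) stop_data("a habitat has zero samples")
  sum_a <- colSums(x$counts[in_a, , drop = FALSE])
  sum_b <- colSums(x$counts[!in_a, , drop = FALSE])
  ratio <- log((sum_a + pseudocount) / (sum_b + pseudocount))
  ids <- intersect(otu_ids(x), names(membership))
  per_otu <- data.frame(otu_id = ids, cluster = membership[ids],
                        ratio = ratio[ids], row.names = NULL)
  cfun <- if (center == "median") median else mean
  per_cluster <- do.call(rbind, lapply(split(per_otu, per_otu$cluster),
                                       function(d) {
    f <- boxplot_fences(d$ratio)
    ct <- cfun(d$ratio)
    label <- if (ct > 0 && f[["lower"]] > 0) {
      paste0("enriched-", habs[1])
    } else if (ct < 0 && f[["upper"]] < 0) {
      paste0("enriched-", habs[2])
    } else "neutral"
    data.frame(cluster = d$cluster[1], center = ct,
               lower_fence = f[["lower"]], upper_fence = f[["upper"]],
               label = label)
  }))
  rownames(per_cluster) <- NULL
  list(per_otu = per_otu, per_cluster = per_cluster, habitats = habs)
}

#' OTU overlap between two tables
#' @param a,b [otu_table]s; an OTU counts as present on a side when it has a
#'   positive count in at least one sample there.
#' @return named vector `c(shared, unique_a, unique_b)`.
#' @export
otu_overlap <- function(a, b) {
  ids_a <- otu_ids(a)[colSums(a$counts) > 0]
  ids_b <- otu_ids(b)[colSums(b$counts) > 0]
  c(shared = length(intersect(ids_a, ids_b)),
    unique_a = length(setdiff(ids_a, ids_b)),
    unique_b = length(setdiff(ids_b, ids_a)))
}
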