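#' Prokaryote-fungal coupling beta for one community
#'
#' Standardized slope of the summed relative read counts in the most
#' prevalent fungal clusters (1..k) on the rank-matched prokaryote clusters
#' (1..k) within one mesocosm. After optional ln/sqrt transformation both
#' vectors are standardized, so the slope equals their Pearson correlation:
#' +1 means prokaryote and fungal reads are distributed identically over the
#' top clusters (coupled), 0 decoupled, negative values an opposing pattern.
#'
#' @param prok,fungal summed relative cluster abundances, rank-matched by
#'   cluster index (default use: clusters 1-9).
#' @param transform `"auto"` (Shapiro-Wilk-driven, see package vignette),
#'   `"none"`, `"ln"` or `"sqrt"`; applied to both vectors.
#' @return list with `beta`, `n_cluster_pairs`, `transform`.
#' @export
coupling_beta <- function(prok, fungal,
                          transform = c("auto", "none", "ln", "sqrt")) {
  transform <- match.arg(transform)
  if (length(prok) != length(fungal))
    stop_data("cluster vectors differ in length")
  if (length(prok) < 3L) stop_data("need at least 3 rank-matched clusters")
  tr <- select_transform(c(prok, fungal), function(t) {
    x <- standardize(apply_named_transform(prok, t), "prok")
    y <- standardize(apply_named_transform(fungal, t), "fungal")
    y - cor(x, y) * x
  }, policy = transform)
  x <- standardize(apply_named_transform(prok, tr), "prok")
  y <- standardize(apply_named_transform(fungal, tr), "fungal")
  list(beta = as.numeric(cor(x, y)), n_cluster_pairs = length(prok),
       transform = tr)
}

#' Coupling scores for every mesocosm
#'
#' @param prok_abund,fungal_abund samples x clusters matrices of summed
#'   relative reads (prevalence-ordered columns), same row order.
#' @param k number of most-prevalent rank-matched cluster pairs (default 9).
#' @inheritParams coupling_beta
#' @return data.frame: mesocosm_id, beta, n_cluster_pairs, transform.
#' @export
coupling_scores <- function(prok_abund, fungal_abund, k = 9,
                            transform = "auto") {
  k <- min(k, ncol(prok_abund), ncol(fungal_abund))
  if (k < 3L) stop_data("fewer than 3 cluster pairs available")
  ids <- rownames(prok_abund) %||% seq_len(nrow(prok_abund))
  out <- lapply(seq_len(nrow(prok_abund)), function(i) {
    cb <- coupling_beta(prok_abund[i, seq_len(k)],
                        fungal_abund[i, seq_len(k)], transform = transform)
    data.frame(mesocosm_id = ids[i], beta = cb$beta,
               n_cluster_pairs = cb$n_cluster_pairs,
               transform = cb$transform)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bonferroni per-test alpha
#'
#' `family_alpha / n_tests`. With the family alpha of 0.05 and the total
#' cluster inventory of a soil as denominator this reproduces the published
#' per-soil thresholds (0.05/30 -> 0.0017, 0.05/28 -> 0.0018 after 4-decimal
#' rounding).
#'
#' @param family_alpha family-wise error rate.
#' @param n_tests Bonferroni denominator.
#' @return list with `alpha` (full precision) and `alpha_rounded` (4
#'   decimals).
#' @export
bonferroni_threshold <- function(family_alpha, n_tests) {
  if (length(n_tests) != 1L || n_tests < 1) stop_data("`n_tests` must be >= 1")
  a <- family_alpha / n_tests
  list(alpha = a, alpha_rounded = round(a, 4))
}

# standardized simple fit of y on x, optionally with a random intercept.
# Returns estimate (= standardized beta), SE, p; grouping with < 2 levels
# falls back to plain least squares.
fit_pair <- function(x, y, grouping = NULL) {
  xs <- standardize(x, "x"); ys <- standardize(y, "y")
  use_lme <- !is.null(grouping) && length(unique(grouping)) >= 2L
  if (use_lme) {
    d <- data.frame(ys = ys, xs = xs, g = factor(grouping))
    fit <- tryCatch(
      nlme::lme(ys ~ xs, random = ~ 1 | g, data = d, method = "ML"),
      error = function(e) NULL)
    if (!is.null(fit)) {
      tt <- summary(fit)$tTable
      return(list(estimate = tt["xs", "Value"], se = tt["xs", "Std.Error"],
                  p = tt["xs", "p-value"], mixed = TRUE,
                  residuals = as.numeric(stats::resid(fit)),
                  logLik = as.numeric(logLik(fit))))
    }
  }
  fit <- lm(ys ~ xs)
  sm <- summary(fit)$coefficients
  list(estimate = sm["xs", "Estimate"], se = sm["xs", "Std. Error"],
       p = sm["xs", "Pr(>|t|)"], mixed = FALSE,
       residuals = stats::resid(fit), logLik = as.numeric(logLik(fit)))
}

# one pairwise correlation row with the shared transform policy applied to
# the response
pair_row <- function(a_name, b_name, x, y, grouping, transform) {
  tr <- select_transform(y, function(t) {
    fit_pair(x, apply_named_transform(y, t), grouping)$residuals
  }, policy = transform)
  f <- fit_pair(x, apply_named_transform(y, tr), grouping)
  data.frame(cluster_a = a_name, cluster_b = b_name,
             coefficient = f$estimate, p = f$p, transform = tr,
             mixed = f$mixed)
}

#' Pairwise cluster correlations with Bonferroni control
#'
#' For every unordered pair of cluster-abundance columns, fits a standardized
#' linear (mixed) model of one on the other — random intercept on `grouping`
#' when it has at least two levels, plain least squares otherwise — applies
#' the ln/sqrt residual-normality transform policy, and flags significance at
#' the Bonferroni per-test alpha.
#'
#' @param abund samples x clusters abundance matrix.
#' @param grouping optional random-intercept factor (e.g. sowing density).
#' @param family_alpha family-wise alpha (default 0.05).
#' @param denominator `"clusters"` (Bonferroni denominator = number of
#'   clusters, reproducing the published thresholds) or `"pairs"`.
#' @param n_tests explicit denominator overriding `denominator`.
#' @param transform transform policy for the response (`"auto"` default).
#' @return list with `table` (cluster_a, cluster_b, coefficient, p,
#'   significant), `alpha_per_test`, `n_tests`, `method`.
#' @export
cluster_correlations <- function(abund, grouping = NULL, family_alpha = 0.05,
                                 denominator = c("clusters", "pairs"),
                                 n_tests = NULL, transform = "auto") {
  denominator <- match.arg(denominator)
  k <- ncol(abund)
  if (nrow(abund) < 5L) stop_data("need >= 5 observations per pair")
  cn <- colnames(abund) %||% paste0("cluster", seq_len(k))
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  n_tests <- n_tests %||%
    if (denominator == "clusters") k else nrow(pairs)
  thr <- bonferroni_threshold(family_alpha, n_tests)
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    tryCatch(pair_row(cn[i], cn[j], abund[, i], abund[, j], grouping,
                      transform),
             mesonet_degenerate_error = function(e) NULL)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop_data("all pairwise fits degenerate")
  tab$significant <- tab$p < thr$alpha
  list(table = tab, alpha_per_test = thr$alpha, n_tests = n_tests,
       method = "bonferroni")
}

# cross-set variant: only prokaryote x fungal pairs; Bonferroni denominator
# "clusters" = total cluster inventory of the soil
cross_cluster_correlations <- function(a_abund, b_abund, grouping = NULL,
                                       family_alpha = 0.05,
                                       denominator = "clusters",
                                       transform = "auto") {
  ka <- ncol(a_abund); kb <- ncol(b_abund)
  n_tests <- if (denominator == "clusters") ka + kb else ka * kb
  thr <- bonferroni_threshold(family_alpha, n_tests)
  an <- colnames(a_abund) %||% paste0("A", seq_len(ka))
  bn <- colnames(b_abund) %||% paste0("B", seq_len(kb))
  rows <- list()
  for (i in seq_len(ka)) for (j in seq_len(kb)) {
    rows[[length(rows) + 1L]] <- tryCatch(
      pair_row(an[i], bn[j], a_abund[, i], b_abund[, j], grouping, transform),
      mesonet_degenerate_error = function(e) NULL)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(cluster_a = character(), cluster_b = character(),
                      coefficient = numeric(), p = numeric(),
                      transform = character(), mixed = logical())
  }
  tab$significant <- tab$p < thr$alpha
  list(table = tab, alpha_per_test = thr$alpha, n_tests = n_tests,
       method = "bonferroni")
}

#' Test of temporal stability against prokaryote-fungal coupling
#'
#' Fits ln(temporal stability) on the coupling beta with a random intercept
#' for soil origin and reports the slope with a type III Wald chi-square
#' (the squared z of the single fixed effect). With fewer than two soils a
#' plain regression is used with a warning.
#'
#' @param stability temporal stability per mesocosm (positive).
#' @param beta coupling beta per mesocosm.
#' @param soil soil origin label per mesocosm.
#' @return list with `slope`, `se`, `wald_chisq`, `p`, `n`, `random_effect`.
#' @export
stability_coupling_test <- function(stability, beta, soil) {
  if (any(stability <= 0)) stop_data("stability must be positive for ln")
  if (sd(beta) == 0) stop_degenerate("coupling beta has no variance")
  y <- log(stability)
  soils <- unique(soil)
  if (length(soils) >= 2L) {
    d <- data.frame(y = y, beta = beta, soil = factor(soil))
    fit <- nlme::lme(y ~ beta, random = ~ 1 | soil, data = d, method = "ML")
    tt <- summary(fit)$tTable
    est <- tt["beta", "Value"]; se <- tt["beta", "Std.Error"]
    re <- "soil"
  } else {
    warning("fewer than 2 soils; plain regression used")
    sm <- summary(lm(y ~ beta))$coefficients
    est <- sm["beta", "Estimate"]; se <- sm["beta", "Std. Error"]
    re <- "none"
  }
  w <- (est / se)^2
  list(slope = est, se = se, wald_chisq = w,
       p = pchisq(w, df = 1, lower.tail = FALSE),
       n = length(y), random_effect = re)
}
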