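#' Candidate path-model specification
#'
#' Directed acyclic candidate edge set for one piecewise path model, plus
#' the random-intercept grouping variable and optional variable role tags
#' used by the contribution ledger.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `group`
#'   (a pathway-group tag such as `"year.overall.direct"`).
#' @param grouping name of the random-intercept column (e.g. sowing
#'   density), or `NULL` for plain least squares.
#' @param var_roles optional data.frame (`variable`, `timing`, `axis`)
#'   tagging plant parameters as year/past and overall/compositional.
#' @return an object of class `path_spec`.
#' @export
path_spec <- function(edges, grouping = NULL, var_roles = NULL) {
  if (!all(c("from", "to") %in% names(edges)))
    stop_config("`edges` needs `from` and `to` columns")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$group)) edges$group <- NA_character_
  nodes <- unique(c(edges$from, edges$to))
  if (is.null(topological_order(edges, nodes)))
    stop_mesonet("candidate edge set contains a cycle",
                 "mesonet_spec_error")
  structure(list(edges = edges, nodes = nodes, grouping = grouping,
                 var_roles = var_roles),
            class = "path_spec")
}

# Kahn's algorithm; NULL when cyclic
topological_order <- function(edges, nodes) {
  indeg <- setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    kids <- edges$to[edges$from == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- sort(c(avail, k))
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

parents_of <- function(edges, v) unique(edges$from[edges$to == v])

#' d-separation basis set of a DAG
#'
#' For every non-adjacent pair of variables, one independence claim
#' "X independent of Y given parents(X) union parents(Y)", with Y the later
#' variable in topological order. Claim order is deterministic.
#'
#' @param spec a [path_spec] (or bare edge data.frame).
#' @param nodes optional full variable set; defaults to the variables
#'   appearing in the edges. Supplying it includes variables with no edges
#'   at all, whose independence claims are part of the basis set too.
#' @return list of claims, each a list with `x`, `y`, `conditioning`.
#' @export
dsep_basis_set <- function(spec, nodes = NULL) {
  edges <- if (inherits(spec, "path_spec")) spec$edges else spec
  nodes <- unique(c(nodes,
                    if (inherits(spec, "path_spec")) spec$nodes else
                      c(edges$from, edges$to)))
  ord <- topological_order(edges, nodes)
  if (is.null(ord)) stop_mesonet("graph is cyclic", "mesonet_spec_error")
  adj <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  claims <- list()
  n <- length(ord)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    x <- ord[i]; y <- ord[j]
    if (paste(pmin(x, y), pmax(x, y)) %in% adj) next
    cond <- setdiff(union(parents_of(edges, x), parents_of(edges, y)),
                    c(x, y))
    claims[[length(claims) + 1L]] <-
      list(x = x, y = y, conditioning = sort(cond))
  }
  claims
}

#' Fisher's C over a set of independence-claim p-values
#'
#' C = -2 sum(ln p_i), compared with a chi-square on 2k degrees of freedom;
#' the model is conventionally accepted when the resulting p exceeds 0.1.
#' An empty claim set (saturated model) returns (0, 0, 1).
#'
#' @param p claim p-values in (0, 1].
#' @return list with `C`, `df`, `p`.
#' @export
fishers_c <- function(p) {
  if (!length(p)) return(list(C = 0, df = 0L, p = 1))
  if (any(p > 1) || any(p < 0) || any(!is.finite(p)))
    stop_data("claim p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("claim p of 0 clamped to the smallest double")
    p[p == 0] <- .Machine$double.xmin
  }
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(C = C, df = df, p = pchisq(C, df, lower.tail = FALSE))
}

#' Small-sample corrected AIC
#'
#' AICc = AIC + 2k(k+1)/(n-k-1) with AIC = -2 logLik + 2k. Model-level
#' values for a piecewise path model sum the per-equation AICc.
#'
#' @param log_lik log-likelihood of one fitted equation.
#' @param n number of observations.
#' @param k_params number of estimated parameters.
#' @return AICc.
#' @export
aicc <- function(log_lik, n, k_params) {
  if (n <= k_params + 1)
    stop_data("AICc correction undefined: n must exceed k + 1")
  -2 * log_lik + 2 * k_params + 2 * k_params * (k_params + 1) / (n - k_params - 1)
}

#' Fit one standardized (mixed) regression equation
#'
#' Linear model of a standardized response on standardized predictors, with
#' a random intercept on `grouping` when it has at least two levels (nlme,
#' ML) and plain least squares otherwise, so coefficients are standardized
#' betas. The response may first be ln/sqrt transformed under the
#' residual-normality policy.
#'
#' @param data data.frame holding all variables.
#' @param response response column name.
#' @param predictors predictor column names (empty gives an intercept-only
#'   fit).
#' @param grouping random-intercept column name or `NULL`.
#' @param transform `"auto"`, `"none"`, `"ln"` or `"sqrt"` for the response.
#' @return list with `coefficients` (data.frame predictor, estimate, se, p),
#'   `log_lik`, `k_params`, `n`, `aicc`, `transform`, `mixed`.
#' @export
fit_equation <- function(data, response, predictors, grouping = NULL,
                         transform = "auto") {
  n <- nrow(data)
  if (n <= length(predictors) + 2L)
    stop_data("too few observations for the number of predictors")
  xs <- lapply(predictors, function(p) standardize(data[[p]], p))
  names(xs) <- predictors
  if (length(predictors) > 1L) {
    X <- do.call(cbind, xs)
    qx <- qr(cbind(1, X))
    if (qx$rank < ncol(X) + 1L) {
      drop_idx <- qx$pivot[seq(qx$rank + 1L, ncol(X) + 1L)] - 1L
      stop_data(paste("collinear predictor(s):",
                      paste(predictors[drop_idx], collapse = ", ")))
    }
  }
  yraw <- data[[response]]
  do_fit <- function(tr) {
    y <- standardize(apply_named_transform(yraw, tr), response)
    d <- data.frame(.y = y)
    for (p in predictors) d[[p]] <- xs[[p]]
    form <- as.formula(paste(".y ~",
                             if (length(predictors))
                               paste(sprintf("`%s`", predictors),
                                     collapse = " + ") else "1"))
    use_lme <- !is.null(grouping) && length(unique(data[[grouping]])) >= 2L
    if (use_lme) {
      d$.g <- factor(data[[grouping]])
      fit <- tryCatch(nlme::lme(form, random = ~ 1 | .g, data = d,
                                method = "ML"),
                      error = function(e) NULL)
      if (!is.null(fit)) return(list(fit = fit, mixed = TRUE))
    }
    list(fit = lm(form, data = d), mixed = FALSE)
  }
  tr <- select_transform(yraw, function(t) {
    as.numeric(stats::resid(do_fit(t)$fit))
  }, policy = transform)
  f <- do_fit(tr)
  ll <- logLik(f$fit)
  k <- as.integer(attr(ll, "df"))
  if (f$mixed) {
    tt <- summary(f$fit)$tTable
    co <- data.frame(predictor = rownames(tt), estimate = tt[, "Value"],
                     se = tt[, "Std.Error"], p = tt[, "p-value"],
                     row.names = NULL)
  } else {
    sm <- summary(f$fit)$coefficients
    co <- data.frame(predictor = rownames(sm), estimate = sm[, "Estimate"],
                     se = sm[, "Std. Error"], p = sm[, "Pr(>|t|)"],
                     row.names = NULL)
  }
  co <- co[co$predictor != "(Intercept)", , drop = FALSE]
  co$predictor <- gsub("`", "", co$predictor)
  list(coefficients = co, log_lik = as.numeric(ll), k_params = k, n = n,
       aicc = aicc(as.numeric(ll), n, k), transform = tr, mixed = f$mixed,
       residuals = as.numeric(stats::resid(f$fit)))
}

# fit all equations for a fixed response set (responses whose incoming edges
# were all eliminated get intercept-only fits, keeping the model-level AICc
# comparable across elimination steps); returns per-response fits and the
# summed AICc
fit_edge_set <- function(edges, data, grouping, transform,
                         responses = unique(edges$to)) {
  fits <- lapply(responses, function(r) {
    fit_equation(data, r, parents_of(edges, r), grouping = grouping,
                 transform = transform)
  })
  names(fits) <- responses
  list(fits = fits, aicc = sum(vapply(fits, `[[`, numeric(1), "aicc")))
}

edge_pvalues <- function(edges, fits) {
  vapply(seq_len(nrow(edges)), function(r) {
    co <- fits[[edges$to[r]]]$coefficients
    co$p[match(edges$from[r], co$predictor)]
  }, numeric(1))
}

edge_estimates <- function(edges, fits) {
  vapply(seq_len(nrow(edges)), function(r) {
    co <- fits[[edges$to[r]]]$coefficients
    co$estimate[match(edges$from[r], co$predictor)]
  }, numeric(1))
}

# test one independence claim: standardized regression of y on x plus the
# conditioning set; p of x's coefficient
test_claim <- function(claim, data, grouping, transform) {
  f <- tryCatch(
    fit_equation(data, claim$y, c(claim$x, claim$conditioning),
                 grouping = grouping, transform = transform),
    mesonet_error = function(e) NULL)
  if (is.null(f)) return(NA_real_)
  f$coefficients$p[match(claim$x, f$coefficients$predictor)]
}

#' Backward stepwise elimination of a piecewise path model
#'
#' Starting from all candidate edges, repeatedly refits the per-equation
#' regressions and removes the single retained edge with the largest
#' p-value (ties broken by the smaller absolute beta), letting endogenous
#' variables drop out entirely once they receive no edges. Model-level AICc
#' (sum of per-equation AICc over responses still in the model) is recorded
#' at every step down to the empty model, and the AICc-minimal step is
#' returned with its d-separation test.
#'
#' @param spec a [path_spec].
#' @param data data.frame with all variables (complete cases).
#' @param transform response transform policy (see [fit_equation()]).
#' @param dsep if `FALSE`, skip the d-separation test of the selected model
#'   (`fisher_c` and `claims` are `NULL`); useful when only the retained
#'   edges are needed and the basis set is large.
#' @return a `fitted_path_model`: list with `edges` (retained, with
#'   estimate/se/p/group), `fisher_c` (`C`, `df`, `p`), `claims`, `aicc`,
#'   `n`, `history` (step, n_edges, aicc, removed), `candidates` (the
#'   pre-elimination edge set), `spec`.
#' @export
backward_eliminate <- function(spec, data, transform = "auto", dsep = TRUE) {
  stopifnot(inherits(spec, "path_spec"))
  vars <- spec$nodes
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop_data(paste("data missing variable(s):",
                                    paste(miss, collapse = ", ")))
  data <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  grouping <- spec$grouping
  edges <- spec$edges
  responses <- unique(edges$to)
  history <- list()
  states <- list()
  step <- 0L
  fits <- NULL
  refit <- responses  # only responses whose parent set changed are refit
  repeat {
    fs <- tryCatch({
      new_fits <- lapply(refit, function(r) {
        fit_equation(data, r, parents_of(edges, r), grouping = grouping,
                     transform = transform)
      })
      names(new_fits) <- refit
      fits[refit] <- new_fits
      list(fits = fits,
           aicc = sum(vapply(fits, `[[`, numeric(1), "aicc")))
    }, mesonet_error = function(e) {
      stop_data(sprintf("fit failed at elimination step %d: %s",
                        step, conditionMessage(e)))
    })
    fits <- fs$fits
    if (nrow(edges) == 0L) {
      history[[step + 1L]] <- data.frame(step = step, n_edges = 0L,
                                         aicc = fs$aicc,
                                         removed = NA_character_)
      states[[step + 1L]] <- list(edges = edges, fits = fs$fits)
      break
    }
    pvals <- edge_pvalues(edges, fs$fits)
    betas <- edge_estimates(edges, fs$fits)
    history[[step + 1L]] <- data.frame(step = step, n_edges = nrow(edges),
                                       aicc = fs$aicc,
                                       removed = NA_character_)
    states[[step + 1L]] <- list(edges = cbind(edges, estimate = betas,
                                              p = pvals),
                                fits = fs$fits)
    # remove the weakest edge: largest p, ties by smaller |beta|
    worst <- order(-pvals, abs(betas))[1L]
    history[[step + 1L]]$removed <-
      paste(edges$from[worst], "->", edges$to[worst])
    refit <- edges$to[worst]
    edges <- edges[-worst, , drop = FALSE]
    step <- step + 1L
  }
  hist_df <- do.call(rbind, history)
  best <- which.min(hist_df$aicc)
  best_state <- states[[best]]
  best_edges <- best_state$edges
  if (is.null(best_edges$estimate)) {
    best_edges$estimate <- numeric(0); best_edges$p <- numeric(0)
  }
  if (dsep) {
    claims <- if (nrow(best_edges)) {
      dsep_basis_set(path_spec(best_edges[, c("from", "to", "group")],
                               grouping = grouping))
    } else list()
    claim_p <- vapply(claims, test_claim, numeric(1), data = data,
                      grouping = grouping, transform = transform)
    keep <- is.finite(claim_p)
    fc <- fishers_c(claim_p[keep])
    claims <- Map(function(cl, p) c(cl, list(p = p)),
                  claims, as.list(claim_p))
  } else {
    fc <- NULL
    claims <- NULL
  }
  structure(list(edges = best_edges, fisher_c = fc,
                 claims = claims,
                 aicc = hist_df$aicc[best], n = nrow(data),
                 history = hist_df, candidates = spec$edges, spec = spec),
            class = "fitted_path_model")
}

#' @export
print.fitted_path_model <- function(x, ...) {
  fc <- if (is.null(x$fisher_c)) "d-sep not run" else
    sprintf("Fisher's C = %.3f (df %d, p = %.3f)", x$fisher_c$C,
            x$fisher_c$df, x$fisher_c$p)
  cat(sprintf("<fitted_path_model> %d/%d edges retained, %s, AICc = %.2f\n",
              nrow(x$edges), nrow(x$candidates), fc, x$aicc))
  invisible(x)
}
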