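# Normality-driven transform policy shared by the correlation and path-model
# fits: keep the raw variable when model residuals pass Shapiro-Wilk at alpha
# 0.05, otherwise try ln (only for strictly positive data), then sqrt (only
# for non-negative data); the first transform whose residuals pass is kept,
# and the raw variable is retained when none passes.

apply_named_transform <- function(x, transform) {
  switch(transform,
         none = x,
         ln = { if (any(x <= 0)) stop_data("ln transform needs positives"); log(x) },
         sqrt = { if (any(x < 0)) stop_data("sqrt transform needs non-negatives"); sqrt(x) },
         stop_config(sprintf("unknown transform '%s'", transform)))
}

residuals_normal <- function(res, alpha = 0.05) {
  res <- res[is.finite(res)]
  if (length(res) < 3L || sd(res) == 0) return(TRUE)
  if (length(res) > 5000L) res <- res[seq_len(5000L)]
  shapiro.test(res)$p.value > alpha
}

# residual_fn(transform_name) -> residual vector for the model fit under
# that transform of the response
select_transform <- function(y, residual_fn, policy = "auto", alpha = 0.05) {
  if (policy != "auto") return(policy)
  candidates <- "none"
  if (all(y > 0)) candidates <- c(candidates, "ln")
  if (all(y >= 0)) candidates <- c(candidates, "sqrt")
  for (tr in candidates) {
    if (residuals_normal(residual_fn(tr), alpha)) return(tr)
  }
  "none"
}
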