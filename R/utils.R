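#' @useDynLib mesonet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.formula complete.cases cor lm lm.fit logLik median
#'   pchisq quantile rmultinom rnbinom rnorm runif sd setNames shapiro.test
#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

# classed conditions: callers can distinguish bad configuration, bad data and
# degenerate (zero-variance) inputs
stop_mesonet <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mesonet_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_config <- function(message) stop_mesonet(message, "mesonet_config_error")
stop_data <- function(message) stop_mesonet(message, "mesonet_data_error")
stop_degenerate <- function(message) stop_mesonet(message, "mesonet_degenerate_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards so seeded helpers do not perturb each other.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded child seed from a global seed and a stage label, so each
# pipeline stage gets an independent, reproducible stream.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_config(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_range <- function(x, name, lo, hi) {
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi))
    stop_config(sprintf("`%s` must lie in [%g, %g]", name, lo, hi))
  x
}

#' Population (divide-by-n) standard deviation
#' @param x numeric vector.
#' @return the root mean squared deviation from the mean.
#' @keywords internal
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# standardize to zero mean, unit sample sd; errors on zero variance
standardize <- function(x, name = "x") {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop_degenerate(sprintf("`%s` has zero variance; cannot standardize", name))
  (x - mean(x)) / s
}
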