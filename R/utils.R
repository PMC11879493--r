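#' @importFrom stats rbinom runif rnorm rnbinom var sd quantile pf pt setNames
#'   aggregate complete.cases
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr under a temporary RNG state so callers' streams are not disturbed.
# seed = NULL means "use the current stream" (still reproducible under an
# outer set.seed()).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(seed, expr)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("`%s` must be a single finite number", name)
  if (x < min || x > max)
    stop_config("`%s` must be in [%s, %s], got %s", name, min, max, x)
  if (integer && x != round(x))
    stop_config("`%s` must be an integer, got %s", name, x)
  invisible(x)
}

# residual sum of squares and rank of a least-squares fit y ~ X
rss_rank <- function(X, y) {
  qr_ <- qr(X)
  res <- qr.resid(qr_, y)
  list(rss = sum(res^2), rank = qr_$rank, qr = qr_)
}
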