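stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  as.integer(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1 && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok)
    stopf("`%s` must lie in %s%g, %g%s (got %s)", name,
          if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]",
          paste(format(x), collapse = ","))
  as.numeric(x)
}

assert_number <- function(x, name, positive = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || (positive && x <= 0))
    stopf("`%s` must be a single %snumber", name, if (positive) "positive " else "")
  as.numeric(x)
}

#' @importFrom withr with_seed
seeded <- function(seed, expr) {
  seed <- assert_count(seed, "seed", min = 0)
  withr::with_seed(seed, expr)
}

#' @importFrom stats rnorm rexp runif rmultinom rbinom quantile var pt pchisq phyper
#' @importFrom utils read.delim write.table
NULL
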