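.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x))
    .stopf("'%s' must be numeric and non-missing", name)
  bad <- if (lo_open) x <= lo else x < lo
  bad <- bad | if (hi_open) x >= hi else x > hi
  if (any(bad))
    .stopf("'%s' must lie in %s%g, %g%s (got %g)", name,
           if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]",
           x[bad][1L])
  invisible(x)
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(x != floor(x)) || any(x < min))
    .stopf("'%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

.clip01 <- function(x, eps = 0) pmin(1 - eps, pmax(eps, x))

# numerically stable log(1 + exp(z))
.softplus <- function(z) {
  out <- z
  pos <- !is.na(z) & z > 0
  out[pos] <- z[pos] + log1p(exp(-z[pos]))
  out[!pos] <- log1p(exp(z[!pos]))
  out
}

# stratified fold assignment: every stratum spread as evenly as possible over k folds
.stratified_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (idx in split(seq_along(strata), strata)) {
    if (length(idx))
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    .check_count(seed, "seed", min = 0L)
    set.seed(seed)
  }
  expr
}
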