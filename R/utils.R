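# Internal argument checks and small numeric helpers.

.stop_config <- function(...) {
  stop(structure(
    class = c("cmsihc_config_error", "error", "condition"),
    list(message = sprintf(...), call = sys.call(-1))
  ))
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    .stop_config("%s must be a probability in [0, 1]", name)
  invisible(x)
}

.check_simplex <- function(x, name, n = 4L, tol = 1e-9) {
  if (!is.numeric(x) || length(x) != n || anyNA(x) || any(x < 0))
    .stop_config("%s must be %d non-negative numbers", name, n)
  if (abs(sum(x) - 1) > tol)
    .stop_config("%s must sum to 1 (got %.12f)", name, sum(x))
  invisible(x)
}

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("%s must be TRUE or FALSE", name))
  invisible(x)
}

# Truncated normal draw on [lo, hi] by rejection with an inverse-CDF fallback
# for far-tail parameter settings.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(pmin(hi, pmax(lo, rep(mean, n))))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
    tries <- tries + 1L
  }
  if (length(bad)) {
    plo <- pnorm(lo, mean, sd)
    phi <- pnorm(hi, mean, sd)
    out[bad] <- stats::qnorm(runif(length(bad), plo, phi), mean, sd)
  }
  out
}

# One categorical draw per row of a probability matrix (rows sum to 1).
.sample_categorical <- function(prob, labels) {
  stopifnot(ncol(prob) == length(labels))
  u <- runif(nrow(prob))
  cum <- t(apply(prob, 1L, cumsum))
  idx <- rowSums(u > cum) + 1L
  idx[idx > length(labels)] <- length(labels)
  labels[idx]
}

# Seed scoping: run `expr` under a seed without clobbering the caller's RNG
# stream unless no seed is given.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L || is.na(seed)))
    .stop_config("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
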