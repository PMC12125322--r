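# Freeman-Halton (r x c Fisher) exact test.
#
# Two-sided p-value by the probability-mass criterion: the sum of the
# multivariate hypergeometric probabilities, over all tables sharing the
# observed margins, of every table whose probability does not exceed the
# observed table's (within a small relative slack for floating-point ties).
# Small tables are enumerated exactly; larger tables are handled by
# Monte-Carlo sampling of fixed-margin tables (Patefield's algorithm via
# stats::r2dtable), evaluating the same criterion on the sample.

#' Contingency table constructor
#'
#' @param counts Matrix (or coercible) of non-negative integer counts, at
#'   least 2 x 2 with a positive total.
#' @param row_labels,col_labels Optional dimension labels.
#' @return Validated integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  m <- as.matrix(counts)
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least 2 rows and 2 columns")
  if (sum(m) <= 0) stop("table total must be positive")
  storage.mode(m) <- "integer"
  if (!is.null(row_labels)) rownames(m) <- row_labels
  if (!is.null(col_labels)) colnames(m) <- col_labels
  class(m) <- c("contingency_table", class(m))
  m
}

# log multivariate-hypergeometric normalising constant for margins
.fh_logconst <- function(rs, cs) {
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(rs) + 1)
}

# Upper bound on the number of candidate tables under the margins (product
# over free rows of a bounded-composition count bound).
.fh_size_bound <- function(rs, cs) {
  r <- length(rs); cc <- length(cs)
  b <- 1
  for (i in seq_len(r - 1L)) {
    comp <- min(choose(rs[i] + cc - 1, cc - 1), prod(pmin(rs[i], cs) + 1))
    b <- b * comp
    if (!is.finite(b) || b > 1e300) return(Inf)
  }
  b
}

# Exact enumeration. Recurses over the cells of the first r-1 rows; the last
# free cell of the last free row is vectorised and the final row is implied
# by the remaining column margins.
.fh_exact <- function(tab, tie_slack) {
  rs <- rowSums(tab); cs <- colSums(tab)
  r <- nrow(tab); cc <- ncol(tab)
  logK <- .fh_logconst(rs, cs)
  log_cut <- (logK - sum(lgamma(tab + 1))) + log1p(tie_slack)
  lg <- lgamma(seq_len(sum(tab) + 1))  # lg[k+1] = lgamma(k + 1) = log(k!)
  psum <- 0

  rec <- function(row, j, rem, rc, acc) {
    if (row == r - 1L && j == cc - 1L) {
      # vectorise the last free cell; the final column of this row and the
      # whole last row are implied by the remaining column margins
      lo <- max(0L, rem - rc[cc]); hi <- min(rem, rc[j])
      if (lo > hi) return()
      x <- lo:hi
      y <- rem - x
      tot <- acc + lg[x + 1L] + lg[y + 1L] +
        lg[rc[j] - x + 1L] + lg[rc[cc] - y + 1L]
      if (j > 1L) tot <- tot + sum(lg[rc[seq_len(j - 1L)] + 1L])
      logp <- logK - tot
      psum <<- psum + sum(exp(logp[logp <= log_cut]))
      return()
    }
    if (j == cc) {  # last cell of a non-final free row is implied
      if (rem > rc[cc]) return()
      rc[cc] <- rc[cc] - rem
      rec(row + 1L, 1L, rs[row + 1L], rc, acc + lg[rem + 1L])
      return()
    }
    lo <- max(0L, rem - sum(rc[(j + 1L):cc]))
    hi <- min(rem, rc[j])
    if (lo > hi) return()
    for (v in lo:hi) {
      rc2 <- rc; rc2[j] <- rc[j] - v
      rec(row, j + 1L, rem - v, rc2, acc + lg[v + 1L])
    }
  }
  rec(1L, 1L, rs[1L], cs, 0)
  min(1, psum)
}

.fh_mc <- function(tab, reps, tie_slack, batch = 50000L) {
  rs <- rowSums(tab); cs <- colSums(tab)
  logK <- .fh_logconst(rs, cs)
  log_cut <- (logK - sum(lgamma(tab + 1))) + log1p(tie_slack)
  hits <- 0
  done <- 0L
  while (done < reps) {
    b <- min(batch, reps - done)
    sims <- r2dtable(b, rs, cs)
    m <- matrix(unlist(sims, use.names = FALSE), nrow = length(tab))
    logp <- logK - colSums(lgamma(m + 1))
    hits <- hits + sum(logp <= log_cut)
    done <- done + b
  }
  (hits + 1) / (reps + 1)
}

#' Freeman-Halton exact test on an r x c contingency table
#'
#' Two-sided exact test of independence using the probability-mass
#' criterion. `method = "exact"` enumerates every table with the observed
#' margins, guarded by `max_tables` candidate tables; `"monte_carlo"`
#' estimates the same p-value from `reps` fixed-margin tables sampled under
#' the null (include-observed estimator `(hits + 1) / (reps + 1)`);
#' `"auto"` enumerates when the size guard allows it and samples otherwise.
#'
#' @param table A [contingency_table()] or count matrix.
#' @param method `"auto"`, `"exact"`, or `"monte_carlo"`.
#' @param reps Monte-Carlo replicates (>= 10^4), default 10^6.
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @param tie_slack Relative slack when comparing table probabilities to the
#'   observed one, guarding against platform-dependent float ties.
#' @param max_tables Enumeration guard on the candidate-table bound.
#' @return List of class `fh_test`: `p_value`, `method`, `reps` (NA for
#'   exact), `table`.
#' @export
#' @examples
#' fisher_exact_rxc(rbind(c(3, 1), c(1, 3)))$p_value
fisher_exact_rxc <- function(table, method = c("auto", "exact", "monte_carlo"),
                             reps = 1e6, seed = NULL, tie_slack = 1e-7,
                             max_tables = 1e8) {
  method <- match.arg(method)
  if (!inherits(table, "contingency_table")) table <- contingency_table(table)
  bound <- .fh_size_bound(rowSums(table), colSums(table))
  if (method == "auto")
    method <- if (bound <= max_tables) "exact" else "monte_carlo"
  if (method == "exact") {
    if (bound > max_tables)
      stop("exact enumeration would visit up to ", format(bound, digits = 3),
           " tables (> max_tables); use method = 'monte_carlo'")
    p <- .fh_exact(table, tie_slack)
    out <- list(p_value = p, method = "exact", reps = NA_real_, table = table)
  } else {
    if (reps < 1e4) stop("monte_carlo requires reps >= 10^4")
    p <- .with_seed(seed, .fh_mc(table, as.integer(reps), tie_slack))
    out <- list(p_value = p, method = "monte_carlo", reps = reps, table = table)
  }
  class(out) <- "fh_test"
  out
}

#' @export
print.fh_test <- function(x, ...) {
  cat(sprintf("Freeman-Halton exact test (%s%s): p = %.6g\n", x$method,
              if (!is.na(x$reps)) sprintf(", %g reps", x$reps) else "",
              x$p_value))
  invisible(x)
}

#' Agreement check between the Monte-Carlo and exact p-values
#'
#' Runs both paths on the same table and reports whether the Monte-Carlo
#' estimate lies within three binomial standard errors of the exact value.
#'
#' @inheritParams fisher_exact_rxc
#' @return List: `p_exact`, `p_mc`, `se`, `agree`.
#' @export
mc_vs_exact_check <- function(table, reps = 1e5, seed = NULL) {
  ex <- fisher_exact_rxc(table, method = "exact")
  mc <- fisher_exact_rxc(table, method = "monte_carlo", reps = reps,
                         seed = seed)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / reps)
  list(p_exact = ex$p_value, p_mc = mc$p_value, se = se,
       agree = abs(mc$p_value - ex$p_value) <= max(3 * se, 3 / (reps + 1)))
}
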