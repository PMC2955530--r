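#' Family-wise error rate control (Bonferroni-Sidak)
#'
#' Rejects every p-value at or below the Sidak per-test level
#' `1 - (1 - alpha)^(1 / n_tests)`, which controls the probability of any
#' false positive among `n_tests` independent tests at `alpha`.
#'
#' @param p numeric vector or matrix of p-values (NA = untested site).
#' @param alpha family-wise error level.
#' @param n_tests number of tests performed; defaults to the number of
#'   non-NA p-values.
#' @return an object of class `detection_map`: `significant` (same shape as
#'   `p`), `threshold` (effective per-test level), `n_tests`, `control`.
#' @export
control_fwer_sidak <- function(p, alpha, n_tests = sum(!is.na(p))) {
  stopifnot(alpha > 0, alpha < 1)
  if (n_tests == 0L) stop("no tests performed")
  thr <- 1 - (1 - alpha)^(1 / n_tests)
  sig <- !is.na(p) & p <= thr
  if (is.matrix(p)) sig <- matrix(sig, nrow(p), ncol(p))
  structure(
    list(significant = sig, threshold = thr, n_tests = n_tests,
         control = "fwer"),
    class = "detection_map"
  )
}

#' False discovery rate control (Benjamini-Hochberg / Benjamini-Yekutieli)
#'
#' Step-up procedure at level `alpha`. With `dependent = TRUE` the
#' Benjamini-Yekutieli divisor `c(N) = sum_{i=1}^N 1/i` is applied, which
#' keeps the FDR guarantee under arbitrary dependence between tests (the
#' patch tests of neighbouring sites share pixels and are correlated). The
#' reported threshold is the step-up critical value at the largest rejected
#' rank, i.e. the largest p-value that is rejected bounds it from below.
#'
#' @param p numeric vector or matrix of p-values (NA = untested site).
#' @param alpha target false discovery rate.
#' @param dependent apply the dependence divisor.
#' @return a `detection_map` (see [control_fwer_sidak()]).
#' @export
control_fdr_bh <- function(p, alpha, dependent = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  pv <- p[!is.na(p)]
  if (length(pv) == 0L) stop("at least one p-value required")
  method <- if (dependent) "BY" else "BH"
  adj <- stats::p.adjust(pv, method = method)
  rej <- adj <= alpha
  n <- length(pv)
  cn <- if (dependent) sum(1 / seq_len(n)) else 1
  k_max <- if (any(rej)) max(rank(pv, ties.method = "max")[rej]) else 0L
  thr <- if (k_max > 0L) k_max * alpha / (n * cn) else 0
  sig <- !is.na(p)
  sig[sig] <- rej
  if (is.matrix(p)) sig <- matrix(sig, nrow(p), ncol(p))
  structure(
    list(significant = sig, threshold = thr, n_tests = n, control = "fdr",
         dependent = dependent),
    class = "detection_map"
  )
}

#' @export
print.detection_map <- function(x, ...) {
  cat(sprintf("detection_map (%s): %d / %d significant, threshold %.3g\n",
              toupper(x$control), sum(x$significant, na.rm = TRUE),
              x$n_tests, x$threshold))
  invisible(x)
}
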