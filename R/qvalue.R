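#' Storey q-values
#'
#' Estimates per-feature q-values from a vector of p-values, with the
#' proportion of true nulls (pi0) estimated by Storey's smoother: pi0 is
#' evaluated on a lambda grid as `mean(p > lambda) / (1 - lambda)`, a cubic
#' smoothing spline is fit across the grid, and the fitted value at the
#' largest lambda is used (clamped to (0, 1]). q-values are pi0 times the
#' Benjamini-Hochberg step-up quantity, enforced monotone non-decreasing in
#' p. With fewer than `min_pi0_n` p-values the smoother is unstable, so the
#' function falls back to BH (pi0 = 1) with a warning.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA`s are excluded and
#'   returned as `NA`.
#' @param lambda Grid for pi0 estimation.
#' @param pi0 Optional fixed pi0 (e.g. `1` recovers BH exactly).
#' @param min_pi0_n Minimum number of p-values for smoother estimation.
#' @return Numeric vector of q-values, same length/order as `p`, with
#'   attribute `pi0`.
#' @export
estimate_qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05), pi0 = NULL,
                             min_pi0_n = 10L) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (!length(pv)) return(out)
  if (any(pv < 0 | pv > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pv)
  if (is.null(pi0)) {
    if (m < min_pi0_n) {
      warning("fewer than ", min_pi0_n,
              " p-values; falling back to Benjamini-Hochberg (pi0 = 1)")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), 0)
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  }
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * pv[o] / (m:1)))[ro]
  out[ok] <- q
  attr(out, "pi0") <- pi0
  out
}
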