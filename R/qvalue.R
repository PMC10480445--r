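#' Storey q-values
#'
#' Estimates the null proportion pi0 from the flat right tail of the p-value
#' distribution (smoothed over a lambda grid) and converts p-values to
#' q-values; with `method = "bh"` (or whenever pi0 is forced to 1, e.g. for
#' a single p-value) the result equals Benjamini-Hochberg adjusted values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda grid for pi0 estimation.
#' @return q-values in the input order.
#' @export
qvalues <- function(p, method = c("storey", "bh"),
                    lambda = seq(0.05, 0.95, 0.05)) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  pi0 <- 1
  if (method == "storey" && n >= 20 && max(p) > min(lambda)) {
    lam <- lambda[lambda < max(p)]
    if (length(lam) >= 4) {
      pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- try(stats::smooth.spline(lam, pi0_lam, df = 3), silent = TRUE)
      est <- if (inherits(fit, "try-error")) min(pi0_lam) else
        stats::predict(fit, max(lam))$y
      pi0 <- min(1, max(est, 1 / n))   # keep strictly positive and <= 1
    }
  }
  o <- order(p)
  q <- pi0 * p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
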