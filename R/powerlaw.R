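# Power-law degree-distribution fitting and sampling.
#
# The exponent is the discrete maximum-likelihood estimate with the
# KS-minimising lower cutoff (Clauset-Shalizi-Newman procedure, via igraph's
# plfit implementation). The multiplicative constant of the printed form
# P(k) = c * k^(-gamma) comes from a least-squares fit of log P(k) on log k
# over the empirical distribution, reported for comparability with tools
# that print that constant; it is not the MLE.

#' Fit a discrete power law to a degree sequence
#'
#' Zero degrees are dropped. Fewer than 50 positive degrees triggers an
#' "unreliable" warning (the fit is still returned); fewer than two distinct
#' positive degree values is a degenerate-fit error.
#'
#' @param degrees Integer vector of node degrees.
#' @param xmin Optional fixed lower cutoff; by default chosen by KS
#'   minimisation.
#' @param ks_max KS-statistic threshold above which the power-law form is
#'   considered rejected for the `scale_free` flag (default 0.10).
#' @param p_value Also compute the KS goodness-of-fit p-value (slower); when
#'   available, rejection uses `p <= 0.1` instead of `ks_max`.
#' @return List of class `powerlaw_fit`: `gamma` (MLE exponent), `xmin`,
#'   `ks_stat`, `ks_p` (NA unless `p_value`), `coefficient` and
#'   `loglog_slope` (log-log regression constant and slope), `n`,
#'   `scale_free` (fit exists and not rejected), `hub_regime`
#'   (`gamma < 2`: hubs carry network integrity).
#' @export
fit_degree_powerlaw <- function(degrees, xmin = NULL, ks_max = 0.10,
                                p_value = FALSE) {
  k <- as.numeric(degrees)
  k <- k[is.finite(k) & k > 0]
  if (length(unique(k)) < 2) {
    stop("degenerate degree distribution: fewer than 2 distinct positive degrees",
         call. = FALSE)
  }
  if (length(k) < 50) {
    warning("fewer than 50 positive degrees; power-law fit is unreliable",
            call. = FALSE)
  }
  fl <- igraph::fit_power_law(k, xmin = xmin, implementation = "plfit",
                              p.value = p_value)
  tab <- table(k)
  kk <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(k)
  reg <- stats::lm(log(pk) ~ log(kk))
  co <- stats::coef(reg)
  rejected <- if (p_value && !is.null(fl$KS.p) && is.finite(fl$KS.p)) {
    fl$KS.p <= 0.1
  } else {
    fl$KS.stat > ks_max
  }
  structure(list(
    gamma = fl$alpha,
    xmin = as.integer(fl$xmin),
    ks_stat = fl$KS.stat,
    ks_p = if (!is.null(fl$KS.p)) fl$KS.p else NA_real_,
    coefficient = exp(unname(co[1])),
    loglog_slope = unname(co[2]),
    n = length(k),
    scale_free = is.finite(fl$alpha) && !rejected,
    hub_regime = is.finite(fl$alpha) && fl$alpha < 2
  ), class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Discrete power-law fit (n = %d positive degrees)\n", x$n))
  cat(sprintf("  gamma (MLE)     %.3f   xmin %d   KS %.4f%s\n", x$gamma,
              x$xmin, x$ks_stat,
              if (is.finite(x$ks_p)) sprintf("  (p = %.3f)", x$ks_p) else ""))
  cat(sprintf("  P(k) ~ %.2f * k^%.3f   (log-log regression)\n",
              x$coefficient, x$loglog_slope))
  cat(sprintf("  scale-free: %s   hub regime (gamma < 2): %s\n",
              x$scale_free, x$hub_regime))
  invisible(x)
}

#' Sample from a discrete power law
#'
#' Exact inverse-CDF sampling from P(k) proportional to k^(-exponent) for
#' k >= xmin, truncated at `kmax` (the omitted tail mass is negligible for
#' exponents above 2 at the default truncation).
#'
#' @param n Number of samples.
#' @param exponent Power-law exponent (> 1).
#' @param xmin Lower cutoff (default 1).
#' @param kmax Truncation point of the support (default 1e6).
#' @return Integer vector of samples.
#' @export
sample_power_law <- function(n, exponent, xmin = 1, kmax = 1e6) {
  stopifnot(exponent > 1, xmin >= 1, kmax > xmin)
  support <- seq.int(xmin, kmax)
  w <- support^(-exponent)
  cdf <- cumsum(w) / sum(w)
  u <- stats::runif(n)
  support[findInterval(u, cdf) + 1L]
}
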