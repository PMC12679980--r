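# Per-capita UPF indicators -------------------------------------------------
#
# Three complementary indicators of the UPF energy share E4RZ:
#   MAAT — weighted arithmetic mean of E4RZ over all children in a domain;
#   POCT — weighted percent of children with E4RZ > 0 (UPF consumers);
#   MRAT — retransformed mean: the square of the weighted mean of sqrt(E4RZ)
#          among consumers only.
# By Jensen's inequality (POCT/100) * MRAT <= MAAT, with equality iff E4RZ
# is constant among consumers.  The sqrt scale is the one a Box-Cox scan
# selects for this zero-inflated, right-skewed share.

#' Compute MAAT, POCT and MRAT with design-based confidence intervals
#'
#' All three estimates use survey weights and the linearized variance of
#' [weighted_ratio_estimate()].  The MRAT interval is obtained by squaring
#' the endpoints of the sqrt-scale interval (a monotone transform that
#' respects the \[0, 100\] range); the delta-method SE (2 x mean x sqrt-scale
#' SE) is also reported for diagnostics.  Consumers are children with
#' E4RZ strictly greater than zero.
#'
#' @param e4rz percent energy share per child, in \[0, 100\].
#' @param design a [design_spec()].
#' @param domain logical domain membership per child (default all).
#' @param level confidence level.
#' @return list with `maat`, `poct`, `mrat` (one-row data.frames as from
#'   [weighted_ratio_estimate()]; mrat on the retransformed scale with
#'   `se_delta`), plus counts `n_total`, `n_consumers`.
#' @export
upf_indicators <- function(e4rz, design, domain = NULL, level = 0.95) {
  stopifnot(inherits(design, "design_spec"))
  d <- if (is.null(domain)) rep(TRUE, design$n) else as.logical(domain)
  if (!any(d)) stop_upf("empty domain", class = "upf_domain_error")
  if (any(e4rz[d] < 0 | e4rz[d] > 100)) {
    stop_upf("e4rz outside [0, 100]", class = "upf_indicator_error")
  }
  consumer <- e4rz > 0 & d

  maat <- weighted_ratio_estimate(e4rz, design, d, level, "maat")
  poct <- weighted_ratio_estimate(100 * (e4rz > 0), design, d, level, "poct")

  if (any(consumer)) {
    sq <- weighted_ratio_estimate(sqrt(e4rz), design, consumer, level, "mrat")
    mrat <- data.frame(
      estimate = sq$estimate^2,
      se_delta = 2 * sq$estimate * sq$se,
      ci_low = max(sq$ci_low, 0)^2,
      ci_high = sq$ci_high^2,
      cv_pct = if (sq$estimate > 0) 100 * (2 * sq$estimate * sq$se) /
        sq$estimate^2 else NA_real_,
      n = sq$n, df = sq$df, domain = "mrat",
      sqrt_estimate = sq$estimate, sqrt_se = sq$se,
      stringsAsFactors = FALSE)
  } else {
    mrat <- NULL
  }
  list(maat = maat, poct = poct, mrat = mrat,
       n_total = sum(d), n_consumers = sum(consumer))
}

#' Box-Cox normalization scan
#'
#' Grid search over lambda in \[-1, 2\] (step 0.05) maximizing the Box-Cox
#' profile log-likelihood
#'   ll(lambda) = -n/2 log(sigma2_hat(lambda)) + (lambda - 1) sum(log y),
#' unweighted and exploratory, as used to justify analyzing the consumer
#' energy share on the square-root scale.
#'
#' @param y positive values (consumers' shares).
#' @param grid lambda grid.
#' @return list with `lambda` (maximizer), `grid`, `loglik`.
#' @export
boxcox_lambda <- function(y, grid = seq(-1, 2, by = 0.05)) {
  if (any(y <= 0)) {
    stop_upf("Box-Cox requires strictly positive values",
             class = "upf_boxcox_error")
  }
  n <- length(y)
  if (n < 10L) stop_upf("need n >= 10", class = "upf_boxcox_error")
  slog <- sum(log(y))
  ll <- vapply(grid, function(lam) {
    z <- if (abs(lam) < 1e-12) log(y) else (y^lam - 1) / lam
    s2 <- mean((z - mean(z))^2)
    -n / 2 * log(s2) + (lam - 1) * slog
  }, numeric(1))
  list(lambda = grid[which.max(ll)], grid = grid, loglik = ll)
}
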