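# Design-based estimation ---------------------------------------------------
#
# Point and variance estimation for weighted ratio means over a stratified
# two-stage sample, under the ultimate-cluster (with-replacement PSU)
# approximation: the variance of a linearized statistic is driven entirely
# by the between-PSU variability of residual totals within strata.
# Domains (subpopulations) are handled by zeroing non-domain residuals,
# never by subsetting clusters, so the design structure stays intact.

#' Construct a survey design specification
#'
#' @param strata stratum id per child.
#' @param cluster primary-sampling-unit id per child (unique across strata).
#' @param weights positive survey weights per child.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(strata, cluster, weights) {
  n <- length(weights)
  if (length(strata) != n || length(cluster) != n) {
    stop_upf("strata, cluster and weights must be aligned",
             class = "upf_design_error")
  }
  if (any(weights <= 0)) {
    stop_upf("weights must be positive", class = "upf_design_error")
  }
  structure(list(strata = as.character(strata),
                 cluster = as.character(cluster),
                 weights = as.numeric(weights), n = n),
            class = "design_spec")
}

design_df <- function(design) {
  length(unique(design$cluster)) - length(unique(design$strata))
}

# Ultimate-cluster variance of a vector (or matrix) of per-child residual
# contributions u: totals per PSU z_hc, then
#   var = sum_h n_h/(n_h - 1) * sum_c (z_hc - zbar_h)(z_hc - zbar_h)'.
# Strata with a single PSU contribute zero with a warning (lonely PSU).
ultimate_cluster_var <- function(u, design) {
  u <- as.matrix(u)
  p <- ncol(u)
  z <- rowsum(u, design$cluster, reorder = TRUE)
  cl_str <- tapply(design$strata, design$cluster, `[`, 1L)
  cl_str <- cl_str[rownames(z)]
  V <- matrix(0, p, p)
  lonely <- character(0)
  for (h in unique(cl_str)) {
    zh <- z[cl_str == h, , drop = FALSE]
    nh <- nrow(zh)
    if (nh < 2L) {
      lonely <- c(lonely, h)
      next
    }
    zc <- sweep(zh, 2, colMeans(zh))
    V <- V + nh / (nh - 1) * crossprod(zc)
  }
  if (length(lonely)) {
    warning(sprintf("lonely PSU in strata %s: contribution to variance is 0",
                    paste(lonely, collapse = ", ")))
  }
  V
}

#' Weighted ratio estimate with linearized variance
#'
#' Estimates the ratio mean theta = sum(w y d) / sum(w d) over a domain d,
#' with standard error by Taylor linearization under the ultimate-cluster
#' approximation, a t confidence interval on (clusters - strata) degrees of
#' freedom, and the coefficient of variation.  Percentages are estimated by
#' passing 0/100-coded indicators as y.
#'
#' @param y numeric outcome per child.
#' @param design a [design_spec()].
#' @param domain logical domain membership per child (default all).
#' @param level confidence level.
#' @param domain_label stored on the output row.
#' @return one-row data.frame: estimate, se, ci_low, ci_high, cv_pct, n,
#'   df, domain.
#' @export
weighted_ratio_estimate <- function(y, design, domain = NULL, level = 0.95,
                                    domain_label = "all") {
  stopifnot(inherits(design, "design_spec"))
  d <- if (is.null(domain)) rep(TRUE, design$n) else as.logical(domain)
  if (length(y) != design$n || length(d) != design$n) {
    stop_upf("y and domain must align with the design",
             class = "upf_design_error")
  }
  if (!any(d)) {
    stop_upf("empty domain '%s'", domain_label, class = "upf_domain_error")
  }
  w <- design$weights
  wd <- w * d
  denom <- sum(wd)
  theta <- sum(wd * ifelse(d, y, 0)) / denom

  # linearized residual contribution per child; zero off-domain
  u <- wd * (ifelse(d, y, 0) - theta) / denom
  V <- ultimate_cluster_var(u, design)
  se <- sqrt(V[1, 1])
  df <- design_df(design)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  data.frame(estimate = theta, se = se,
             ci_low = theta - tq * se, ci_high = theta + tq * se,
             cv_pct = if (abs(theta) > 0) 100 * se / abs(theta) else NA_real_,
             n = sum(d), df = df, domain = domain_label,
             stringsAsFactors = FALSE)
}

#' Rao-Wu rescaling bootstrap estimate
#'
#' Independent resampling oracle for the linearized variance: per stratum,
#' n_h - 1 PSUs are resampled with replacement and weights are rescaled by
#' m_hc * n_h / (n_h - 1), where m_hc counts how often PSU c was drawn; the
#' statistic is recomputed on each replicate and the SE is the SD over
#' replicates.
#'
#' @param y numeric outcome per child.
#' @param design a [design_spec()]; every stratum needs >= 2 PSUs.
#' @param statistic function of (y, weights) returning a scalar; default is
#'   the weighted mean.
#' @param B number of bootstrap replicates.
#' @param seed integer seed; the replicate set is deterministic given it.
#' @param domain optional logical domain (applied inside the default
#'   statistic as a ratio-mean domain).
#' @return one-row data.frame: estimate, se, B.
#' @export
bootstrap_estimate <- function(y, design, statistic = NULL, B = 500L,
                               seed = 1L, domain = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (B < 2L) stop_upf("need B >= 2", class = "upf_bootstrap_error")
  d <- if (is.null(domain)) rep(TRUE, design$n) else as.logical(domain)
  if (is.null(statistic)) {
    statistic <- function(y, w) sum(w * d * ifelse(d, y, 0)) / sum(w * d)
  }
  clusters <- unique(design$cluster)
  cl_str <- tapply(design$strata, design$cluster, `[`, 1L)[clusters]
  by_str <- split(clusters, cl_str)
  if (any(vapply(by_str, length, 0L) < 2L)) {
    stop_upf("bootstrap requires >= 2 PSUs per stratum",
             class = "upf_bootstrap_error")
  }
  cl_index <- match(design$cluster, clusters)

  est <- statistic(y, design$weights)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      mult <- numeric(length(clusters))
      for (h in seq_along(by_str)) {
        cl_h <- match(by_str[[h]], clusters)
        nh <- length(cl_h)
        draw <- sample(cl_h, nh - 1L, replace = TRUE)
        m <- tabulate(match(draw, cl_h), nbins = nh)
        mult[cl_h] <- m * nh / (nh - 1L)
      }
      statistic(y, design$weights * mult[cl_index])
    }, numeric(1))
  })
  data.frame(estimate = est, se = stats::sd(reps), B = B)
}
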