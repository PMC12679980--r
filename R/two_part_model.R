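# Two-part covariate model ---------------------------------------------------
#
# The zero-inflated UPF energy share is modeled in two components:
#   binomial  — logistic regression of the consumer indicator (E4RZ > 0)
#               on (log-age, district poverty), all children;
#   normal    — linear regression of sqrt(E4RZ) on (age, log-age, calendar
#               quarter) among consumers only, so its squared fitted mean is
#               the retransformed MRAT indicator.
# Coefficients are design-weighted maximum quasi-likelihood via iteratively
# reweighted least squares; standard errors are linearized (sandwich) with
# score contributions aggregated to PSUs within strata, the same
# ultimate-cluster scheme as the ratio estimator.  P-values use a t
# reference on (clusters - strata) degrees of freedom.

#' Model specification for the two components
#'
#' Terms are named transforms of the covariate record.  Defaults reproduce
#' the published final models: binomial — intercept, log age (natural log of
#' age in months), district poverty percent; normal — intercept, age in
#' months, log age, and quarter dummies with January-March (Q1) as the
#' reference.
#'
#' @param binomial_terms,normal_terms character vectors of term names among
#'   `"log_age"`, `"age"`, `"poverty"`, `"quarter"`, `"sex"`, `"year"`.
#'   The intercept is always included.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(binomial_terms = c("log_age", "poverty"),
                       normal_terms = c("age", "log_age", "quarter")) {
  known <- c("log_age", "age", "poverty", "quarter", "sex", "year")
  bad <- setdiff(c(binomial_terms, normal_terms), known)
  if (length(bad)) {
    stop_upf("unknown model terms: %s", paste(bad, collapse = ", "),
             class = "upf_model_error")
  }
  structure(list(binomial_terms = binomial_terms,
                 normal_terms = normal_terms), class = "model_spec")
}

# Design matrix for a term list; children must carry age_months,
# poverty_pct, quarter (Q1..Q4), sex, year.
build_design_matrix <- function(children, terms) {
  n <- nrow(children)
  cols <- list("(Intercept)" = rep(1, n))
  for (t in terms) {
    if (t == "log_age") cols[["log_age"]] <- log(children$age_months)
    else if (t == "age") cols[["age"]] <- children$age_months
    else if (t == "poverty") cols[["poverty"]] <- children$poverty_pct
    else if (t == "sex") cols[["sexM"]] <- as.numeric(children$sex == "M")
    else if (t == "year") cols[["year"]] <- children$year - min(children$year)
    else if (t == "quarter") {
      q <- children$quarter
      cols[["quarterQ2"]] <- as.numeric(q == "Q2")
      cols[["quarterQ3"]] <- as.numeric(q == "Q3")
      cols[["quarterQ4"]] <- as.numeric(q == "Q4")
    }
  }
  do.call(cbind, cols)
}

# Weighted IRLS for a canonical-link GLM (binomial/logit or gaussian/identity).
# Written from first principles: at each step solve the weighted least
# squares problem X' W_irls X beta = X' W_irls z for the working response z.
irls_fit <- function(X, y, w, family = c("binomial", "gaussian"),
                     tol = 1e-8, max_iter = 50L) {
  family <- match.arg(family)
  p <- ncol(X)
  beta <- rep(0, p)
  if (family == "gaussian") {
    # identity link: a single weighted least-squares solve is exact
    A <- crossprod(X, w * X)
    beta <- solve(A, crossprod(X, w * y))
    mu <- drop(X %*% beta)
    return(list(beta = drop(beta), mu = mu, info = A, converged = TRUE,
                iter = 1L))
  }
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    if (any(v < 1e-10)) {
      if (all(v < 1e-10)) {
        stop_upf("complete separation: fitted probabilities degenerate",
                 class = "upf_separation_error")
      }
      v <- pmax(v, 1e-10)
    }
    z <- eta + (y - mu) / v
    Wi <- w * v
    A <- crossprod(X, Wi * X)
    beta_new <- tryCatch(drop(solve(A, crossprod(X, Wi * z))),
                         error = function(e) {
                           stop_upf("singular information matrix in IRLS",
                                    class = "upf_model_error")
                         })
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      A <- crossprod(X, (w * mu * (1 - mu)) * X)
      if (max(abs(beta)) > 30) {
        stop_upf("non-convergence: coefficients diverging (separation?)",
                 class = "upf_separation_error")
      }
      return(list(beta = beta, mu = mu, info = A, converged = TRUE,
                  iter = it))
    }
    beta <- beta_new
  }
  stop_upf("IRLS did not converge in %d iterations", max_iter,
           class = "upf_model_error")
}

# Cluster-robust sandwich covariance: scores s_i = w_i x_i (y_i - mu_i)
# (canonical links), aggregated to PSUs within strata by the same
# ultimate-cluster scheme as the ratio estimator.
sandwich_vcov <- function(X, y, mu, w, info, design) {
  scores <- X * (w * (y - mu))
  G <- ultimate_cluster_var(scores, design)
  Ainv <- solve(info)
  V <- Ainv %*% G %*% Ainv
  (V + t(V)) / 2
}

fit_component <- function(children, y, design, terms, family) {
  X <- build_design_matrix(children, terms)
  fit <- irls_fit(X, y, design$weights, family)
  V <- sandwich_vcov(X, y, fit$mu, design$weights, fit$info, design)
  se <- sqrt(diag(V))
  df <- design_df(design)
  tval <- fit$beta / se
  list(terms = colnames(X), coef = stats::setNames(fit$beta, colnames(X)),
       se = stats::setNames(se, colnames(X)),
       p = stats::setNames(2 * stats::pt(-abs(tval), df), colnames(X)),
       vcov = V, n = nrow(X), df = df, family = family,
       iterations = fit$iter)
}

#' Fit the design-weighted two-part model
#'
#' @param children data.frame with age_months, poverty_pct, quarter (and sex,
#'   year if used by the spec), aligned with `e4rz`.
#' @param e4rz percent UPF energy share per child.
#' @param design a [design_spec()] aligned with `children`.
#' @param spec a [model_spec()].
#' @return object of class `two_part_fit` with components `binomial` and
#'   `normal` (each: terms, coef, se, p, vcov, n, df).
#' @export
fit_two_part <- function(children, e4rz, design, spec = model_spec()) {
  stopifnot(inherits(design, "design_spec"), inherits(spec, "model_spec"))
  if (nrow(children) != design$n || length(e4rz) != design$n) {
    stop_upf("children, e4rz and design must align", class = "upf_model_error")
  }
  consumer <- e4rz > 0

  bin <- NULL
  if (all(consumer) || !any(consumer)) {
    warning("degenerate consumer indicator (all or none): ",
            "binomial component skipped")
  } else {
    bin <- fit_component(children, as.numeric(consumer), design,
                         spec$binomial_terms, "binomial")
  }

  nrm <- NULL
  if (any(consumer)) {
    sub <- design_spec(design$strata[consumer], design$cluster[consumer],
                       design$weights[consumer])
    nrm <- fit_component(children[consumer, , drop = FALSE],
                         sqrt(e4rz[consumer]), sub,
                         spec$normal_terms, "gaussian")
  } else {
    warning("no consumers: normal component skipped")
  }
  structure(list(binomial = bin, normal = nrm, spec = spec),
            class = "two_part_fit")
}

#' @export
print.two_part_fit <- function(x, ...) {
  fmt <- function(f, label) {
    cat(sprintf("%s component (n = %d, design df = %d):\n", label, f$n, f$df))
    print(round(data.frame(coef = f$coef, se = f$se, p = f$p), 4))
  }
  if (!is.null(x$binomial)) fmt(x$binomial, "Binomial")
  if (!is.null(x$normal)) fmt(x$normal, "Normal (sqrt scale)")
  invisible(x)
}

#' Scenario predictions from a two-part fit
#'
#' For each profile row, the POCT curve is 100 x inverse-logit of the
#' binomial linear predictor, with its band obtained by transforming
#' eta +/- t * SE(eta); the MRAT curve is the square of the normal
#' (sqrt-scale) linear predictor, with the band the squared endpoints of the
#' sqrt-scale interval (negative endpoints floored at 0 before squaring).
#'
#' @param fit a [fit_two_part()] result.
#' @param profile data.frame of covariate profiles with age_months,
#'   poverty_pct, quarter (plus sex/year when the spec uses them).
#' @param level confidence level for the bands.
#' @return data.frame: one row per profile with poct, poct_low, poct_high,
#'   mrat, mrat_low, mrat_high.
#' @export
predict_scenario <- function(fit, profile, level = 0.95) {
  stopifnot(inherits(fit, "two_part_fit"))
  one <- function(component) {
    X <- build_design_matrix(profile, setdiff_terms(component$terms))
    if (!identical(colnames(X), component$terms)) {
      stop_upf("profile does not cover model terms", class = "upf_model_error")
    }
    eta <- drop(X %*% component$coef)
    se <- sqrt(pmax(rowSums((X %*% component$vcov) * X), 0))
    tq <- stats::qt(1 - (1 - level) / 2, component$df)
    list(eta = eta, lo = eta - tq * se, hi = eta + tq * se)
  }
  out <- data.frame(row.names = seq_len(nrow(profile)))
  if (!is.null(fit$binomial)) {
    b <- one(fit$binomial)
    out <- data.frame(poct = 100 * stats::plogis(b$eta),
                      poct_low = 100 * stats::plogis(b$lo),
                      poct_high = 100 * stats::plogis(b$hi))
  }
  if (!is.null(fit$normal)) {
    g <- one(fit$normal)
    out$mrat <- pmax(g$eta, 0)^2
    out$mrat_low <- pmax(g$lo, 0)^2
    out$mrat_high <- pmax(g$hi, 0)^2
  }
  cbind(profile, out)
}

# Recover the model_spec-style term list (in original order) from
# design-matrix column names.
setdiff_terms <- function(colnames) {
  map <- c("log_age" = "log_age", "age" = "age", "poverty" = "poverty",
           "sexM" = "sex", "year" = "year",
           "quarterQ2" = "quarter", "quarterQ3" = "quarter",
           "quarterQ4" = "quarter")
  unique(unname(map[colnames[colnames %in% names(map)]]))
}
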