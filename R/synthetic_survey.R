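# Synthetic survey generator ------------------------------------------------
#
# Emulates the design of repeated national nutrition surveys of children
# aged 6-35 months: stratified two-stage sampling (clusters within strata,
# households within clusters), random recall-day assignment by permutation,
# and a zero-inflated UPF energy share.  The share has a two-part ground
# truth: a Bernoulli consumer indicator whose probability is logistic in
# (log-age, district poverty), and, among consumers, a sqrt-scale share that
# is normal in (age, log-age, calendar-quarter), truncated to (0, 10] so
# that the squared share is a valid percentage.

#' Configuration for the synthetic survey generator
#'
#' Defaults encode the published "Total" two-part model coefficients as
#' ground truth: binomial component (intercept, log-age in months, district
#' poverty %) and normal component on the sqrt-percent scale (intercept,
#' age in months, log-age, offsets for quarters Q2-Q4 relative to Q1).
#'
#' @param n_strata number of design strata.
#' @param clusters_per_stratum clusters (PSUs) sampled per stratum.
#' @param households_per_cluster households sampled per cluster (one eligible
#'   child per household); at most 10, matching the recall-day scheduler.
#' @param frame_clusters_per_stratum sampling-frame cluster count per stratum
#'   (first-stage selection probability = clusters_per_stratum / this).
#' @param frame_households_per_cluster frame household count per cluster
#'   (second-stage probability = households_per_cluster / this; national
#'   census clusters hold roughly 100 households).
#' @param population_total projected population the weights are rescaled to.
#' @param age_range_months half-open eligibility interval for age in months.
#' @param poverty_range range of district poverty percentages; each cluster
#'   (= district here) draws one level uniformly from it.
#' @param true_binomial_coefs length-3 numeric: intercept, log-age, poverty.
#' @param true_normal_coefs length-6 numeric: intercept, age, log-age and
#'   Q2/Q3/Q4 offsets, all on the sqrt-percent scale.
#' @param sigma_sqrt residual SD of the sqrt-scale share among consumers.
#'   The default (1.2) is the largest round value for which the (0, 10]
#'   range restriction removes under ~0.5% of the normal mass anywhere in
#'   the covariate domain, so drawn shares genuinely follow the stated
#'   normal model.
#' @param mean_total_kcal,sd_total_kcal distribution of 24-hour energy intake.
#' @param dairy_upf_fraction fraction of each consumer's UPF energy carried by
#'   the evaporated-milk-style dairy item.
#' @param years calendar years sampled uniformly for interview dates.
#' @param survey_label label stored on every generated child.
#'
#' @return an object of class `survey_config` (a validated list).
#' @export
survey_config <- function(n_strata = 5L,
                          clusters_per_stratum = 10L,
                          households_per_cluster = 10L,
                          frame_clusters_per_stratum = 40L,
                          frame_households_per_cluster = 100L,
                          population_total = 1.5e6,
                          age_range_months = c(6, 36),
                          poverty_range = c(0, 90),
                          true_binomial_coefs = c(0.377, 0.943, -0.036),
                          true_normal_coefs = c(10.917, 0.145, -3.088,
                                                0.614, 0.296, 0.284),
                          sigma_sqrt = 1.2,
                          mean_total_kcal = 900,
                          sd_total_kcal = 180,
                          dairy_upf_fraction = 0.7,
                          years = 2015:2016,
                          survey_label = "SYNTH") {
  cfg <- list(
    n_strata = as.integer(n_strata),
    clusters_per_stratum = as.integer(clusters_per_stratum),
    households_per_cluster = as.integer(households_per_cluster),
    frame_clusters_per_stratum = as.integer(frame_clusters_per_stratum),
    frame_households_per_cluster = as.integer(frame_households_per_cluster),
    population_total = as.numeric(population_total),
    age_range_months = as.numeric(age_range_months),
    poverty_range = as.numeric(poverty_range),
    true_binomial_coefs = as.numeric(true_binomial_coefs),
    true_normal_coefs = as.numeric(true_normal_coefs),
    sigma_sqrt = as.numeric(sigma_sqrt),
    mean_total_kcal = as.numeric(mean_total_kcal),
    sd_total_kcal = as.numeric(sd_total_kcal),
    dairy_upf_fraction = as.numeric(dairy_upf_fraction),
    years = as.integer(years),
    survey_label = as.character(survey_label)
  )
  validate_survey_config(cfg)
  class(cfg) <- "survey_config"
  cfg
}

validate_survey_config <- function(cfg) {
  if (cfg$n_strata < 1L || cfg$clusters_per_stratum < 1L ||
      cfg$households_per_cluster < 1L) {
    stop_upf("all design counts must be >= 1", class = "upf_config_error")
  }
  if (cfg$clusters_per_stratum > cfg$frame_clusters_per_stratum ||
      cfg$households_per_cluster > cfg$frame_households_per_cluster) {
    stop_upf("sample counts cannot exceed frame counts",
             class = "upf_config_error")
  }
  if (cfg$sigma_sqrt <= 0) {
    stop_upf("sigma_sqrt must be positive", class = "upf_config_error")
  }
  if (cfg$dairy_upf_fraction < 0 || cfg$dairy_upf_fraction > 1) {
    stop_upf("dairy_upf_fraction must lie in [0, 1]",
             class = "upf_config_error")
  }
  if (length(cfg$true_binomial_coefs) != 3L) {
    stop_upf("true_binomial_coefs must be (intercept, log-age, poverty)",
             class = "upf_config_error")
  }
  if (length(cfg$true_normal_coefs) != 6L) {
    stop_upf("true_normal_coefs must be (intercept, age, log-age, Q2, Q3, Q4)",
             class = "upf_config_error")
  }
  invisible(cfg)
}

#' Assign 24-hour recall days to the households of one cluster
#'
#' The first seven households of a cluster receive the seven weekdays in a
#' random permutation (each day exactly once); households eight to ten
#' receive days drawn by simple random sampling (with replacement) from the
#' seven weekdays.
#'
#' @param households_per_cluster households to schedule (at most 10).
#' @param seed integer seed; the assignment is a deterministic function of it.
#' @return integer vector of weekday indices (1 = Monday ... 7 = Sunday),
#'   one per household.
#' @export
assign_recall_days <- function(households_per_cluster, seed) {
  households_per_cluster <- as.integer(households_per_cluster)
  if (households_per_cluster < 1L) {
    stop_upf("need at least one household", class = "upf_config_error")
  }
  if (households_per_cluster > 10L) {
    stop_upf("recall-day schedule supports at most 10 households per cluster",
             class = "upf_schedule_error")
  }
  with_seed(seed, {
    perm <- sample.int(7L)
    extra <- if (households_per_cluster > 7L) {
      sample.int(7L, households_per_cluster - 7L, replace = TRUE)
    } else integer(0)
    c(perm, extra)[seq_len(households_per_cluster)]
  })
}

#' Design weights from per-stage selection probabilities
#'
#' Base weight = 1 / (p1 * p2); weights are then rescaled so that they sum
#' to the projected population total.
#'
#' @param p_stage1,p_stage2 selection probabilities per child, each in (0, 1].
#' @param population_total target sum of the rescaled weights.
#' @return numeric weights, one per child, summing to `population_total`.
#' @export
compute_weights <- function(p_stage1, p_stage2, population_total) {
  if (length(p_stage1) != length(p_stage2)) {
    stop_upf("stage probabilities must be aligned", class = "upf_design_error")
  }
  if (any(p_stage1 <= 0 | p_stage1 > 1) || any(p_stage2 <= 0 | p_stage2 > 1)) {
    stop_upf("selection probabilities must lie in (0, 1]",
             class = "upf_design_error")
  }
  base <- 1 / (p_stage1 * p_stage2)
  base * (population_total / sum(base))
}

# Linear predictors of the two-part ground truth given covariate columns.
two_part_linpred <- function(cfg, age, poverty, quarter) {
  b <- cfg$true_binomial_coefs
  g <- cfg$true_normal_coefs
  eta_bin <- b[1] + b[2] * log(age) + b[3] * poverty
  qn <- as.integer(sub("^Q", "", quarter))
  eta_norm <- g[1] + g[2] * age + g[3] * log(age) +
    g[4] * (qn == 2L) + g[5] * (qn == 3L) + g[6] * (qn == 4L)
  list(bin = eta_bin, norm = eta_norm)
}

# Draw a truncated-normal sqrt-share on (0, 10]: rejection with a 50-draw
# cap, then clipping into [0.01, 10] as a last resort.
draw_sqrt_share <- function(mu, sigma) {
  n <- length(mu)
  s <- stats::rnorm(n, mu, sigma)
  bad <- which(s <= 0 | s > 10)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    s[bad] <- stats::rnorm(length(bad), mu[bad], sigma)
    bad <- which(s <= 0 | s > 10)
    tries <- tries + 1L
  }
  if (length(bad)) s[bad] <- pmin(pmax(s[bad], 0.01), 10)
  s
}

#' Bundled synthetic food composition table
#'
#' A small composition table (food code, description, group, kcal per 100 g)
#' used by the generator to turn drawn energy shares into itemized recall
#' lines.  Codes prefixed `U` are ultra-processed (Nova 4) products; the
#' remaining items span unprocessed foods, culinary ingredients and
#' processed foods across the main food groups.  All entries are synthetic
#' stand-ins with realistic energy densities, not survey data.
#'
#' @return data.frame with columns food_code, description, group,
#'   kcal_per_100g.
#' @export
synthetic_composition <- function() {
  data.frame(
    food_code = c("U001", "U002",
                  "N101", "N102", "N103", "N104", "N105", "N106", "N107"),
    description = c(
      "LECHE EVAPORADA MARCA COMERCIAL AZUCARADA",
      "GALLETA DULCE ENVASADA MARCA COMERCIAL",
      "ARROZ BLANCO COCIDO",
      "PAPA SANCOCHADA",
      "PLATANO MADURO",
      "POLLO GUISADO",
      "HUEVO DE GALLINA SANCOCHADO",
      "ACEITE VEGETAL",
      "AZUCAR RUBIA"
    ),
    group = c("milk_dairy", "cereals",
              "cereals", "tubers", "fruits", "meats", "eggs",
              "fats_oils", "sugary"),
    kcal_per_100g = c(134, 450, 130, 87, 89, 190, 155, 884, 387),
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic survey
#'
#' Builds the full stratified two-stage sample with known ground truth:
#' children with design coordinates, covariates and weights; a recall-day
#' schedule; and, optionally, itemized food records constructed so that
#' recomputing the UPF energy share E4RZ from them recovers the drawn share
#' to within 0.1 percentage points.
#'
#' @param config a [survey_config()].
#' @param seed integer master seed; output is a deterministic function of
#'   (config, seed).
#' @param make_foods generate itemized food records (set `FALSE` for model
#'   simulations that only need covariates and shares).
#' @return list with `children` (data.frame), `foods` (data.frame or NULL),
#'   `composition` (data.frame) and `truth` (the config).
#' @export
generate_survey <- function(config, seed, make_foods = TRUE) {
  validate_survey_config(config)
  cfg <- config

  n_clusters <- cfg$n_strata * cfg$clusters_per_stratum
  n_children <- n_clusters * cfg$households_per_cluster

  children <- with_seed(stage_seed(seed, "design"), {
    stratum_id <- rep(seq_len(cfg$n_strata),
                      each = cfg$clusters_per_stratum * cfg$households_per_cluster)
    cluster_within <- rep(rep(seq_len(cfg$clusters_per_stratum),
                              each = cfg$households_per_cluster),
                          times = cfg$n_strata)
    cluster_id <- (stratum_id - 1L) * cfg$clusters_per_stratum + cluster_within
    household_id <- seq_len(n_children)

    # district poverty: one level per cluster (a cluster plays the district)
    pov_cluster <- stats::runif(n_clusters, cfg$poverty_range[1],
                                cfg$poverty_range[2])
    poverty_pct <- pov_cluster[cluster_id]

    age_months <- stats::runif(n_children, cfg$age_range_months[1],
                               cfg$age_range_months[2])
    sex <- sample(c("F", "M"), n_children, replace = TRUE)
    area <- c("Lima", "urban", "rural")[1L + (stratum_id - 1L) %% 3L]
    year <- sample(cfg$years, n_children, replace = TRUE)
    # interview month uniform -> quarter
    month <- sample.int(12L, n_children, replace = TRUE)
    quarter <- paste0("Q", (month - 1L) %/% 3L + 1L)

    data.frame(child_id = sprintf("C%05d", seq_len(n_children)),
               stratum_id, cluster_id, household_id,
               age_months, sex, area, poverty_pct, quarter, year,
               survey_label = cfg$survey_label,
               stringsAsFactors = FALSE)
  })

  # recall-day schedule, one permutation stream per cluster
  sched_seed <- stage_seed(seed, "recall_days")
  # children rows are cluster-contiguous in cluster_id order, so the
  # per-cluster schedules concatenate into alignment
  children$recall_day <- unlist(lapply(seq_len(n_clusters), function(cl) {
    assign_recall_days(cfg$households_per_cluster, sched_seed + cl)
  }))

  # equal-probability emulation of PPS: probabilities recorded explicitly
  p1 <- rep(cfg$clusters_per_stratum / cfg$frame_clusters_per_stratum,
            n_children)
  p2 <- rep(cfg$households_per_cluster / cfg$frame_households_per_cluster,
            n_children)
  children$weight <- compute_weights(p1, p2, cfg$population_total)

  children <- with_seed(stage_seed(seed, "outcome"), {
    eta <- two_part_linpred(cfg, children$age_months, children$poverty_pct,
                            children$quarter)
    consumer <- stats::rbinom(n_children, 1L, stats::plogis(eta$bin)) == 1L
    sqrt_share <- rep(0, n_children)
    if (any(consumer)) {
      sqrt_share[consumer] <- draw_sqrt_share(eta$norm[consumer],
                                              cfg$sigma_sqrt)
    }
    children$e4rz_true <- sqrt_share^2
    children
  })

  foods <- NULL
  if (make_foods) {
    foods <- with_seed(stage_seed(seed, "foods"), {
      make_food_records(children, cfg)
    })
  }

  list(children = children, foods = foods,
       composition = synthetic_composition(), truth = cfg)
}

# Itemize each child's 24-hour energy: one dairy-UPF item carrying
# dairy_upf_fraction of UPF kcal, one other-UPF item, and 2-5 non-UPF items
# splitting the remainder by a symmetric Dirichlet.
make_food_records <- function(children, cfg) {
  comp <- synthetic_composition()
  dens <- stats::setNames(comp$kcal_per_100g, comp$food_code)
  non_upf_codes <- comp$food_code[!startsWith(comp$food_code, "U")]

  n <- nrow(children)
  total_kcal <- pmax(stats::rnorm(n, cfg$mean_total_kcal, cfg$sd_total_kcal),
                     250)
  upf_kcal <- children$e4rz_true / 100 * total_kcal

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    kcal <- numeric(0)
    code <- character(0)
    if (upf_kcal[i] > 0) {
      code <- c("U001", "U002")
      kcal <- c(cfg$dairy_upf_fraction, 1 - cfg$dairy_upf_fraction) * upf_kcal[i]
      keep <- kcal > 0
      code <- code[keep]; kcal <- kcal[keep]
    }
    k <- sample(2:5, 1L)
    picks <- sample(non_upf_codes, k)
    g <- stats::rgamma(k, shape = 1)
    kcal <- c(kcal, (total_kcal[i] - upf_kcal[i]) * g / sum(g))
    code <- c(code, picks)
    rows[[i]] <- data.frame(child_id = children$child_id[i],
                            food_code = code,
                            kcal = kcal,
                            stringsAsFactors = FALSE)
  }
  foods <- do.call(rbind, rows)
  foods$grams <- foods$kcal / (dens[foods$food_code] / 100)
  rownames(foods) <- NULL
  foods[, c("child_id", "food_code", "grams", "kcal")]
}
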