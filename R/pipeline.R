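# End-to-end pipeline --------------------------------------------------------
#
# simulate (or ingest) -> classify -> summarize -> estimate -> model ->
# report tables.  Every stage logs row counts; exclusions are recorded with
# reason codes in a run manifest so no record is lost silently.  Outputs are
# a deterministic function of (config, seed).

#' Run the full analysis pipeline on a synthetic survey
#'
#' Generates a survey, classifies its foods, computes per-child energy
#' summaries, estimates covariate distributions (table1), processing
#' indicators by covariate level (table2), the group-by-Nova energy
#' breakdown (table3), the two-part model (table4) and scenario-prediction
#' curves (fig2_data), and writes everything plus a run manifest to
#' `out_dir`.
#'
#' @param config a [survey_config()].
#' @param seed master integer seed.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing and returns the tables invisibly.
#' @param ruleset Nova rule set; defaults to [default_ruleset()].
#' @param by covariate columns for the table2 domain breakdown.
#' @return (invisibly) list of tables and the manifest.
#' @export
run_pipeline <- function(config = survey_config(), seed = 1L, out_dir = NULL,
                         ruleset = default_ruleset(),
                         by = c("sex", "age_group", "area", "poverty_band",
                                "quarter", "year")) {
  log_msg <- function(...) message(sprintf(...))

  log_msg("[simulate] generating survey (seed %d)", seed)
  sim <- generate_survey(config, seed)
  children <- band_covariates(sim$children)
  n_generated <- nrow(children)

  log_msg("[classify] applying Nova rules")
  nova <- classify_foods(sim$composition, ruleset)
  nova_map <- stats::setNames(nova, sim$composition$food_code)

  log_msg("[summarize] per-child energy accounting")
  summaries <- summarize_intake(sim$foods, sim$composition, nova_map)
  excluded <- data.frame(child_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  keep <- children$child_id %in% summaries$child_id
  if (any(!keep)) {
    excluded <- rbind(excluded, data.frame(
      child_id = children$child_id[!keep], reason = "zero_energy",
      stringsAsFactors = FALSE))
  }
  inel <- children$age_months < 6 | children$age_months >= 36
  if (any(inel & keep)) {
    excluded <- rbind(excluded, data.frame(
      child_id = children$child_id[inel & keep], reason = "ineligible_age",
      stringsAsFactors = FALSE))
    keep <- keep & !inel
  }
  children <- children[keep, , drop = FALSE]
  summaries <- summaries[match(children$child_id, summaries$child_id), ,
                         drop = FALSE]
  design <- design_spec(children$stratum_id, children$cluster_id,
                        children$weight)
  e4rz <- summaries$e4rz

  log_msg("[estimate] covariate distribution and indicators")
  table1 <- do.call(rbind, lapply(by, function(v) {
    lv <- sort(unique(as.character(children[[v]])))
    do.call(rbind, lapply(lv, function(l) {
      est <- weighted_ratio_estimate(100 * (as.character(children[[v]]) == l),
                                     design,
                                     domain_label = paste0(v, "=", l))
      cbind(covariate = v, level = l, est)
    }))
  }))

  domain_rows <- c(list(list(covariate = "total", level = "all",
                             d = rep(TRUE, nrow(children)))),
                   unlist(lapply(by, function(v) {
                     lapply(sort(unique(as.character(children[[v]]))),
                            function(l) list(covariate = v, level = l,
                                             d = as.character(children[[v]]) == l))
                   }), recursive = FALSE))
  table2 <- do.call(rbind, lapply(domain_rows, function(dr) {
    contrib <- vapply(1:4, function(k) {
      weighted_ratio_estimate(
        100 * summaries[[paste0("kcal_nova", k)]] / summaries$total_kcal,
        design, dr$d, domain_label = "contrib")$estimate
    }, numeric(1))
    ind <- upf_indicators(e4rz, design, dr$d)
    data.frame(covariate = dr$covariate, level = dr$level, n = ind$n_total,
               nova1 = contrib[1], nova2 = contrib[2], nova3 = contrib[3],
               nova4_maat = ind$maat$estimate,
               maat_low = ind$maat$ci_low, maat_high = ind$maat$ci_high,
               poct = ind$poct$estimate,
               poct_low = ind$poct$ci_low, poct_high = ind$poct$ci_high,
               maat_cv_flag = !is.na(ind$maat$cv_pct) & ind$maat$cv_pct > 15,
               stringsAsFactors = FALSE)
  }))

  table3 <- group_nova_breakdown(summaries,
                                 stats::setNames(children$weight,
                                                 children$child_id))

  log_msg("[model] two-part fit and scenario predictions")
  fit <- fit_two_part(children, e4rz, design)
  table4 <- rbind(
    data.frame(component = "binomial", term = fit$binomial$terms,
               coef = unname(fit$binomial$coef), se = unname(fit$binomial$se),
               p = unname(fit$binomial$p), stringsAsFactors = FALSE),
    data.frame(component = "normal", term = fit$normal$terms,
               coef = unname(fit$normal$coef), se = unname(fit$normal$se),
               p = unname(fit$normal$p), stringsAsFactors = FALSE))

  # "average child" scenario curves: age sweep at 30% poverty, Q3
  profile <- data.frame(age_months = seq(6, 35.5, by = 0.5),
                        poverty_pct = 30, quarter = "Q3")
  fig2 <- predict_scenario(fit, profile)

  manifest <- list(
    seed = seed,
    config = unclass(config),
    n_generated = n_generated,
    n_included = nrow(children),
    n_excluded = nrow(excluded),
    exclusions = excluded,
    n_consumers = sum(e4rz > 0),
    stages = c("simulate", "classify", "summarize", "estimate", "model"))

  tables <- list(table1 = table1, table2 = table2, table3 = table3,
                 table4 = table4, fig2_data = fig2, manifest = manifest,
                 children = children, summaries = summaries, fit = fit)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
    wr(table1, "table1"); wr(table2, "table2"); wr(table3, "table3")
    wr(table4, "table4"); wr(fig2, "fig2_data")
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg("[report] wrote 6 files to %s", out_dir)
  }
  invisible(tables)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write synthetic survey CSVs), `classify` (apply a
#' rule sheet to a foods CSV), `run-all` (full pipeline).  Invoke from a
#' shell as
#' `Rscript -e 'upfsurvey::upf_cli()' simulate --seed 17 --out dir/`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return exit status, invisibly.
#' @export
upf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: upf_cli <simulate|classify|run-all> [--seed N] [--out DIR]",
    "               [--rules rules.csv] [--foods foods.csv]", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[[1]]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[[i + 1L]] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "upf_out")

  if (cmd == "simulate") {
    sim <- generate_survey(survey_config(), seed)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sim$children, file.path(out, "children.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$foods, file.path(out, "foods.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$composition, file.path(out, "composition.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(sim$truth), file.path(out, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (cmd == "classify") {
    rules <- opt("--rules")
    foods <- opt("--foods")
    ruleset <- if (is.null(rules)) default_ruleset() else
      read_rule_sheet(rules)
    items <- utils::read.csv(foods, stringsAsFactors = FALSE)
    items$nova <- classify_foods(items, ruleset)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(items, file.path(out, "classified.csv"),
                     row.names = FALSE)
    audit <- audit_classification(items, ruleset)
    jsonlite::write_json(audit, file.path(out, "audit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (cmd == "run-all") {
    run_pipeline(seed = seed, out_dir = out)
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
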