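# Nova classification rule engine -------------------------------------------
#
# Foods are assigned to Nova categories 1-4 by a computerized sequence of
# rules defined per food group in a spreadsheet-shaped table.  A rule can
# restrict by explicit food codes, by key terms required present in the
# (normalized) description, and by key terms required absent.  Within a
# group, rules fire in a declared order; the first match wins.  Unmatched
# foods are an error, never silently defaulted: a silent misclassification
# biases the UPF energy share.

#' Normalize food descriptions and rule terms for matching
#'
#' The normalization is fixed so that rule sheets are portable: convert to
#' uppercase, strip diacritics by transliteration to ASCII, collapse runs of
#' whitespace to single spaces and trim the ends.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(x) {
  # explicit diacritic folding (iconv //TRANSLIT is locale-dependent and can
  # introduce apostrophes); any remaining non-ASCII byte is dropped
  x <- chartr("áéíóúÁÉÍÓÚàèìòùäëïöüâêîôûñÑçÇ",
              "aeiouAEIOUaeiouaeiouaeiounNcC", x)
  x <- iconv(x, from = "UTF-8", to = "ASCII", sub = "")
  x <- toupper(x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

split_terms <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- normalize_text(v)
    v[nzchar(v)]
  })
}

#' Compile a tabular rule sheet into a validated rule set
#'
#' @param rule_table data.frame with columns `rule_id`, `group`, `codes`
#'   (semicolon-separated food codes, may be empty), `require_terms`,
#'   `exclude_terms` (semicolon-separated key terms), `nova` (1-4) and
#'   `order` (rank within group).
#' @return an object of class `nova_ruleset`.
#' @export
compile_rules <- function(rule_table) {
  required <- c("rule_id", "group", "codes", "require_terms",
                "exclude_terms", "nova", "order")
  missing_cols <- setdiff(required, names(rule_table))
  if (length(missing_cols)) {
    stop_upf("rule sheet lacks columns: %s",
             paste(missing_cols, collapse = ", "),
             class = "upf_rules_error")
  }
  if (nrow(rule_table) == 0L) {
    stop_upf("rule sheet is empty", class = "upf_rules_error")
  }
  if (anyDuplicated(rule_table$rule_id)) {
    stop_upf("duplicate rule_id: %s",
             paste(unique(rule_table$rule_id[duplicated(rule_table$rule_id)]),
                   collapse = ", "),
             class = "upf_rules_error")
  }
  nova <- suppressWarnings(as.integer(rule_table$nova))
  if (anyNA(nova) || any(!nova %in% 1:4)) {
    stop_upf("nova values must be integers in 1..4", class = "upf_rules_error")
  }
  ord <- suppressWarnings(as.numeric(rule_table$order))
  if (anyNA(ord)) {
    stop_upf("order must be numeric", class = "upf_rules_error")
  }
  grp <- normalize_text(as.character(rule_table$group))
  for (g in unique(grp)) {
    if (anyDuplicated(ord[grp == g])) {
      stop_upf("duplicate order within group '%s'", g,
               class = "upf_rules_error")
    }
  }
  rules <- data.frame(rule_id = as.character(rule_table$rule_id),
                      group = grp, nova = nova, order = ord,
                      stringsAsFactors = FALSE)
  rules$codes <- split_terms(as.character(rule_table$codes))
  rules$require_terms <- split_terms(as.character(rule_table$require_terms))
  rules$exclude_terms <- split_terms(as.character(rule_table$exclude_terms))
  rules <- rules[order(rules$group, rules$order), ]
  rownames(rules) <- NULL
  structure(list(rules = rules), class = "nova_ruleset")
}

#' @export
print.nova_ruleset <- function(x, ...) {
  cat(sprintf("<nova_ruleset> %d rules over %d food groups\n",
              nrow(x$rules), length(unique(x$rules$group))))
  invisible(x)
}

# TRUE where a single rule matches each of the supplied items (vectorized
# over items): group equal, code in code_set (if the rule has one), all
# required terms present, no excluded term present.
rule_matches <- function(rule, group, code, desc) {
  ok <- group == rule$group
  if (length(rule$codes[[1]])) {
    ok <- ok & code %in% rule$codes[[1]]
  }
  for (t in rule$require_terms[[1]]) ok <- ok & grepl(t, desc, fixed = TRUE)
  for (t in rule$exclude_terms[[1]]) ok <- ok & !grepl(t, desc, fixed = TRUE)
  ok
}

#' Classify foods into Nova categories
#'
#' Applies the compiled rule sequence to each food: within the food's group,
#' rules fire in their declared order and the first match assigns the Nova
#' category.  Classification is deterministic and invariant to input
#' ordering and to case/accents of descriptions.
#'
#' @param items data.frame with columns `food_code`, `description`, `group`.
#' @param ruleset a compiled [compile_rules()] rule set.
#' @param on_unmatched `"error"` (default) to fail on any unclassified food,
#'   `"na"` to return NA for it.
#' @return integer vector of Nova categories (1-4), one per item.
#' @export
classify_foods <- function(items, ruleset, on_unmatched = c("error", "na")) {
  on_unmatched <- match.arg(on_unmatched)
  stopifnot(inherits(ruleset, "nova_ruleset"))
  group <- normalize_text(as.character(items$group))
  code <- normalize_text(as.character(items$food_code))
  desc <- normalize_text(as.character(items$description))

  nova <- rep(NA_integer_, nrow(items))
  rules <- ruleset$rules
  for (r in seq_len(nrow(rules))) {         # rules are pre-sorted by order
    todo <- is.na(nova)
    if (!any(todo)) break
    hit <- todo
    hit[todo] <- rule_matches(rules[r, ], group[todo], code[todo], desc[todo])
    nova[hit] <- rules$nova[r]
  }
  if (anyNA(nova) && on_unmatched == "error") {
    bad <- items$food_code[is.na(nova)]
    stop_upf("unclassified foods: %s",
             paste(utils::head(bad, 10L), collapse = ", "),
             class = "upf_unclassified_error")
  }
  nova
}

#' @rdname classify_foods
#' @param food_code,description,group fields of a single food item.
#' @export
classify_food <- function(food_code, description, group, ruleset) {
  classify_foods(data.frame(food_code = food_code, description = description,
                            group = group, stringsAsFactors = FALSE),
                 ruleset)
}

#' Audit a rule set against a set of foods
#'
#' Report-only quality control: counts classified items per Nova category,
#' lists unclassified food codes, and flags pairs of rules within a group
#' that both match at least one supplied item before order resolution (the
#' items whose classification depends on rule order).
#'
#' @inheritParams classify_foods
#' @return list with `n_classified` (named counts for categories 1-4),
#'   `unclassified` (character codes) and `overlaps` (data.frame of rule-id
#'   pairs with an example food code).
#' @export
audit_classification <- function(items, ruleset) {
  stopifnot(inherits(ruleset, "nova_ruleset"))
  nova <- classify_foods(items, ruleset, on_unmatched = "na")
  group <- normalize_text(as.character(items$group))
  code <- normalize_text(as.character(items$food_code))
  desc <- normalize_text(as.character(items$description))

  rules <- ruleset$rules
  match_mat <- vapply(seq_len(nrow(rules)), function(r) {
    rule_matches(rules[r, ], group, code, desc)
  }, logical(nrow(items)))
  if (nrow(items) == 1L) match_mat <- matrix(match_mat, nrow = 1L)

  overlaps <- list()
  for (g in unique(rules$group)) {
    idx <- which(rules$group == g)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        both <- match_mat[, idx[a]] & match_mat[, idx[b]]
        if (any(both)) {
          overlaps[[length(overlaps) + 1L]] <- data.frame(
            rule_a = rules$rule_id[idx[a]], rule_b = rules$rule_id[idx[b]],
            example_code = items$food_code[which(both)[1L]],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  overlaps <- if (length(overlaps)) do.call(rbind, overlaps) else
    data.frame(rule_a = character(0), rule_b = character(0),
               example_code = character(0), stringsAsFactors = FALSE)

  list(
    n_classified = stats::setNames(
      vapply(1:4, function(k) sum(nova == k, na.rm = TRUE), integer(1)),
      paste0("nova", 1:4)),
    unclassified = items$food_code[is.na(nova)],
    overlaps = overlaps
  )
}

#' Read / write rule sheets
#'
#' The on-disk sheet is a plain CSV with semicolon-separated code and term
#' lists.  Writing a compiled rule set back and recompiling yields identical
#' classifications.
#'
#' @param path CSV file path.
#' @return `read_rule_sheet`: a compiled `nova_ruleset`.
#' @export
read_rule_sheet <- function(path) {
  compile_rules(utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = "character"))
}

#' @rdname read_rule_sheet
#' @param ruleset a compiled rule set.
#' @export
write_rule_sheet <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "nova_ruleset"))
  r <- ruleset$rules
  out <- data.frame(
    rule_id = r$rule_id, group = r$group,
    codes = vapply(r$codes, paste, "", collapse = ";"),
    require_terms = vapply(r$require_terms, paste, "", collapse = ";"),
    exclude_terms = vapply(r$exclude_terms, paste, "", collapse = ";"),
    nova = r$nova, order = r$order, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Default rule sheet for the bundled synthetic composition table
#'
#' Mirrors the published cereals-group example semantics: grains, flours,
#' flakes and noodles are Nova 1; cornstarch Nova 2; freshly baked bread and
#' pre-cooked sweetened flakes Nova 3; branded/labeled products Nova 4 —
#' plus analogous rules for the other synthetic groups.
#'
#' @return a compiled `nova_ruleset`.
#' @export
default_ruleset <- function() {
  compile_rules(data.frame(
    rule_id = c("MD4", "MD1", "CE4", "CE2", "CE3", "CE1",
                "TU1", "FR1", "ME1", "EG1", "FA2", "SU2"),
    group = c("milk_dairy", "milk_dairy",
              "cereals", "cereals", "cereals", "cereals",
              "tubers", "fruits", "meats", "eggs", "fats_oils", "sugary"),
    codes = "",
    require_terms = c("MARCA COMERCIAL", "", "MARCA COMERCIAL", "MAICENA",
                      "PAN FRESCO", "", "", "", "", "", "", ""),
    exclude_terms = "",
    nova = c(4, 1, 4, 2, 3, 1, 1, 1, 1, 1, 2, 2),
    order = c(1, 2, 1, 2, 3, 4, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE))
}
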