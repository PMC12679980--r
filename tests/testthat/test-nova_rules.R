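test_that("the cereals fixture compiles and reproduces the stated assignments", {
  rs <- compile_rules(cereal_rule_sheet())
  expect_s3_class(rs, "nova_ruleset")
  expect_equal(nrow(rs$rules), 4)

  items <- cereal_items()
  expect_equal(classify_foods(items, rs), c(1L, 2L, 3L, 4L))
  expect_equal(classify_food("X", "MAICENA", "cereals", rs), 2L)
  expect_equal(classify_food("X", "PAN FRESCO HORNEADO", "cereals", rs), 3L)
  expect_equal(classify_food("X", "CEREAL AZUCARADO MARCA COMERCIAL",
                             "cereals", rs), 4L)
})

test_that("rule-sheet validation fails loudly", {
  sheet <- cereal_rule_sheet()
  dup <- rbind(sheet, sheet[1, ])
  expect_error(compile_rules(dup), class = "upf_rules_error")
  expect_error(compile_rules(sheet[0, ]), class = "upf_rules_error")
  bad <- sheet; bad$nova[1] <- 7
  expect_error(compile_rules(bad), class = "upf_rules_error")
  two <- sheet; two$order <- c(1, 1, 2, 3)
  expect_error(compile_rules(two), class = "upf_rules_error")
  expect_error(compile_rules(sheet[, -1]), class = "upf_rules_error")
})

test_that("classification is invariant to case, accents and item order", {
  rs <- compile_rules(cereal_rule_sheet())
  items <- cereal_items()
  fancy <- items
  fancy$description <- c("trigo grano  entero",
                         "Maícena (almidón de maíz)",
                         "pán fresco horneado del día",
                         "Pan de Molde  MARCA  Comercial")
  expect_equal(classify_foods(fancy, rs), classify_foods(items, rs))

  perm <- sample(nrow(items))
  expect_equal(classify_foods(items[perm, ], rs),
               classify_foods(items, rs)[perm])
})

test_that("unmatched foods error, carrying the offending codes", {
  rs <- compile_rules(cereal_rule_sheet())
  stranger <- data.frame(food_code = "Z9", description = "QUESO FRESCO",
                         group = "milk_dairy", stringsAsFactors = FALSE)
  expect_error(classify_foods(stranger, rs),
               class = "upf_unclassified_error")
  expect_error(classify_foods(stranger, rs), "Z9")
  expect_equal(classify_foods(stranger, rs, on_unmatched = "na"),
               NA_integer_)
})

test_that("audit counts, lists unclassified items and finds planted overlaps", {
  rs <- compile_rules(cereal_rule_sheet())
  items <- rbind(cereal_items(),
                 data.frame(food_code = "Z9", description = "QUESO",
                            group = "milk_dairy", stringsAsFactors = FALSE))
  rep1 <- audit_classification(items, rs)
  expect_equal(sum(rep1$n_classified), 4)
  expect_equal(rep1$unclassified, "Z9")

  # plant an overlap: two rules both matching "HOJUELAS AZUCARADAS"
  sheet <- rbind(cereal_rule_sheet(), data.frame(
    rule_id = "C5", group = "cereals", codes = "",
    require_terms = "HOJUELAS AZUCARADAS", exclude_terms = "",
    nova = 3, order = 5, stringsAsFactors = FALSE))
  flakes <- data.frame(food_code = "F05",
                       description = "HOJUELAS AZUCARADAS MARCA COMERCIAL",
                       group = "cereals", stringsAsFactors = FALSE)
  rep2 <- audit_classification(rbind(cereal_items(), flakes),
                               compile_rules(sheet))
  expect_true(nrow(rep2$overlaps) >= 1)
  hit <- rep2$overlaps[rep2$overlaps$example_code == "F05", ]
  expect_setequal(unlist(hit[1, c("rule_a", "rule_b")]), c("C1", "C5"))

  # brute-force oracle: every within-group rule pair matching a common item
  oracle_pairs <- local({
    all_items <- rbind(cereal_items(), flakes)
    rs2 <- compile_rules(sheet)$rules
    pairs <- character(0)
    for (a in 1:(nrow(rs2) - 1)) for (b in (a + 1):nrow(rs2)) {
      if (rs2$group[a] != rs2$group[b]) next
      for (i in seq_len(nrow(all_items))) {
        da <- upfsurvey:::rule_matches(rs2[a, ],
                                       normalize_text(all_items$group[i]),
                                       normalize_text(all_items$food_code[i]),
                                       normalize_text(all_items$description[i]))
        db <- upfsurvey:::rule_matches(rs2[b, ],
                                       normalize_text(all_items$group[i]),
                                       normalize_text(all_items$food_code[i]),
                                       normalize_text(all_items$description[i]))
        if (da && db) {
          pairs <- c(pairs, paste(rs2$rule_id[a], rs2$rule_id[b]))
          break
        }
      }
    }
    sort(unique(pairs))
  })
  expect_setequal(paste(rep2$overlaps$rule_a, rep2$overlaps$rule_b),
                  oracle_pairs)
})

test_that("rule sheets round-trip through CSV with identical classifications", {
  rs <- compile_rules(cereal_rule_sheet())
  path <- withr::local_tempfile(fileext = ".csv")
  write_rule_sheet(rs, path)
  rs2 <- read_rule_sheet(path)
  items <- cereal_items()
  expect_equal(classify_foods(items, rs2), classify_foods(items, rs))
})

test_that("code-set rules and exclude terms restrict matching", {
  sheet <- data.frame(
    rule_id = c("R1", "R2"),
    group = "cereals",
    codes = c("F77;F78", ""),
    require_terms = c("", ""),
    exclude_terms = c("", "AZUCARADO"),
    nova = c(4, 1), order = c(1, 2), stringsAsFactors = FALSE)
  rs <- compile_rules(sheet)
  expect_equal(classify_food("F77", "CUALQUIERA", "cereals", rs), 4L)
  expect_equal(classify_food("F01", "GRANO", "cereals", rs), 1L)
  expect_error(classify_food("F01", "GRANO AZUCARADO", "cereals", rs),
               class = "upf_unclassified_error")
})
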