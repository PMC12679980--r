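# Shared fixtures, built in code.

# Cereals-group rule sheet mirroring the published example semantics:
# grains/flours/flakes/noodles -> Nova 1, cornstarch -> Nova 2, freshly
# baked bread and pre-cooked sweetened flakes -> Nova 3, branded -> Nova 4.
cereal_rule_sheet <- function() {
  data.frame(
    rule_id = c("C1", "C2", "C3", "C4"),
    group = "cereals",
    codes = "",
    require_terms = c("MARCA COMERCIAL", "MAICENA",
                      "PAN FRESCO;HORNEADO", ""),
    exclude_terms = c("", "", "", ""),
    nova = c(4, 2, 3, 1),
    order = c(1, 2, 3, 4),
    stringsAsFactors = FALSE)
}

cereal_items <- function() {
  data.frame(
    food_code = c("F01", "F02", "F03", "F04"),
    description = c("TRIGO GRANO ENTERO",
                    "MAICENA (ALMIDON DE MAIZ)",
                    "PAN FRESCO HORNEADO DEL DIA",
                    "PAN DE MOLDE MARCA COMERCIAL"),
    group = "cereals",
    stringsAsFactors = FALSE)
}

# Tiny composition + records where the energy split is known by hand.
tiny_composition <- function() {
  data.frame(food_code = c("A", "B", "C"),
             description = c("RICE", "EVAPORATED MILK BRAND", "OIL"),
             group = c("cereals", "milk_dairy", "fats_oils"),
             kcal_per_100g = c(100, 200, 800),
             stringsAsFactors = FALSE)
}

tiny_nova <- function() c(A = 1L, B = 4L, C = 2L)

# Balanced 2-strata x 2-cluster x 2-observation design with listed values;
# used for the hand-evaluated ultimate-cluster variance fixture.
eight_number_design <- function() {
  list(y = c(1, 3, 2, 6, 4, 5, 9, 7),
       w = c(1, 2, 1.5, 1, 2, 2, 1, 3),
       strata = rep(c("s1", "s2"), each = 4),
       cluster = rep(c("c1", "c2", "c3", "c4"), each = 2))
}

# Independent oracle: ultimate-cluster SE of the weighted ratio mean,
# written out directly from the formula (kept separate from the package
# implementation on purpose).
oracle_ratio_se <- function(y, w, strata, cluster) {
  theta <- sum(w * y) / sum(w)
  u <- w * (y - theta) / sum(w)
  z <- tapply(u, cluster, sum)
  cl_str <- tapply(strata, cluster, `[`, 1)
  v <- 0
  for (h in unique(cl_str)) {
    zh <- z[cl_str == h]
    nh <- length(zh)
    v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  sqrt(v)
}

# One-stratum, child-per-cluster design (an SRS-like frame) for model tests.
srs_design <- function(n, weights = rep(1, n)) {
  design_spec(rep("s1", n), paste0("c", seq_len(n)), weights)
}
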