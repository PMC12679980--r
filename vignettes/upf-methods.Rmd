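---
title: "Methods: UPF energy-share indicators under complex survey designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UPF energy-share indicators under complex survey designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upfsurvey)
```

## The outcome and its two-part structure

For a child with an itemized 24-hour recall, the UPF energy share is
E4RZ = 100 × kcal from Nova-4 foods / total kcal. Empirically this
variable is bimodal under a log-like transformation: an atom of
non-consumers at exactly 0, and a continuous, right-skewed positive part.
A Box-Cox scan of the positive part selects a power close to 0.5, so the
consumer share is analyzed on the square-root scale, where it is
approximately normal.

Accordingly the package treats E4RZ as a two-part (hurdle) outcome:

1. a **binomial component** for the consumer indicator 1{E4RZ > 0},
   logistic in ln(age in months) and district poverty (%), fitted on all
   children;
2. a **normal component** for √E4RZ among consumers, linear in age,
   ln(age) and calendar quarter (January–March is the reference), whose
   squared fitted mean is the retransformed consumer-only indicator MRAT.

The three reported indicators are MAAT (weighted mean of E4RZ, all
children), POCT (weighted percent with E4RZ > 0) and MRAT
((weighted mean of √E4RZ among consumers)²). They are deliberately
non-redundant: MAAT mixes the extensive margin (who consumes) with the
intensive margin (how much, given consumption); POCT and MRAT separate
them. Jensen's inequality gives (POCT/100)·MRAT ≤ MAAT, with equality only
when consumers all share one value — a property the test suite checks by
brute force.

### Weighting choices

All three indicators use survey weights, including the mean of square
roots inside MRAT. The weighting of MRAT is a documented choice: the
indicator's definition ("arithmetic mean of square roots") is silent on
weights, but every estimate in this pipeline is design-adjusted, and an
unweighted MRAT next to weighted MAAT/POCT would not be comparable across
domains. The Box-Cox scan, by contrast, is unweighted and restricted to
consumers: it is an exploratory scale diagnostic, not an estimate.

The MRAT confidence interval squares the endpoints of the sqrt-scale t
interval. The transform is monotone on the non-negative line, so coverage
is inherited and the interval respects [0, 100]; the delta-method SE
(2·mean·SE) is also reported for diagnostics but is not used for the
interval, since it can breach the range near the boundaries.

## Design-based variance estimation

The samples are stratified and two-stage: clusters (PSUs) within strata,
then households. Variances use Taylor linearization with the
**ultimate-cluster** approximation: stage-1 sampling is treated as
with-replacement, so only between-PSU variability of residual totals
matters. For the ratio mean θ = Σwyd / Σwd over domain d, the linearized
contributions u_i = w_i d_i (y_i − θ̂)/Σwd are summed to PSU totals z_hc
and

&nbsp;&nbsp;&nbsp;&nbsp;v̂(θ̂) = Σ_h n_h/(n_h−1) Σ_c (z_hc − z̄_h)².

Domains are handled by zeroing non-domain residuals, never by dropping
clusters, so empty-in-domain PSUs still contribute their (zero) totals —
the standard way to keep domain variances honest. Confidence intervals use
a t quantile on (number of PSUs − number of strata) degrees of freedom;
the standard convention for complex surveys, chosen because nothing in
the printed tables can adjudicate between t and normal quantiles at these
sizes. Ignoring finite-population corrections is slightly conservative for
without-replacement PPS designs. A stratum with a single PSU contributes
zero variance and triggers a loud warning rather than an error (lonely-PSU
handling); the bootstrap oracle, which cannot limp along that way, refuses
such designs.

The **Rao–Wu rescaling bootstrap** is implemented purely as an independent
oracle: per stratum, n_h − 1 PSUs are resampled with replacement and
weights rescaled by m_hc·n_h/(n_h−1); the SD of the recomputed statistic
over B replicates estimates the SE. Tests require the two routes to agree
within 15% relative error across a grid of synthetic designs, and the
linearized estimator to match a hand-evaluated formula on an 8-observation
fixture to 10 decimals.

Model coefficients use the same scheme: weighted maximum quasi-likelihood
by IRLS (tolerance 1e−8 on coefficients, max 50 iterations,
non-convergence and separation are errors, except the genuinely degenerate
all-consumer/no-consumer indicator, which skips the component with a
warning), then a sandwich covariance A⁻¹GA⁻¹ where G is the
ultimate-cluster variance of score totals and A the weighted information.
With equal weights and each child its own PSU, the point estimates match
`stats::glm`/`lm` to numerical precision — a dual-route test.

## The Nova rule engine

Foods are classified by an ordered rule sequence per food group, compiled
from a spreadsheet-shaped CSV (rule id, group, optional code list,
required key terms, excluded key terms, Nova category, order). Matching
is by substring on a normalized description — uppercased, diacritics
folded by an explicit character map (locale-independent), whitespace
collapsed — with first-match-wins precedence inside a group. Unmatched
foods raise an error rather than defaulting: a silent default would bias
E4RZ directly. An audit operation reports category counts, unclassified
codes, and all within-group rule pairs that both match some supplied item,
i.e. exactly the items whose class depends on rule order.

## What the synthetic generator states, and what it does not

The generator emulates: stratified two-stage selection (equal-probability
clusters from a configurable frame standing in for PPS — the real frame's
size measures are unavailable, so probabilities are recorded explicitly
and weights remain exact, rescaled to a projected population total);
random recall-day assignment (a random permutation of the 7 weekdays over
the first 7 households per cluster, plus simple random sampling with
replacement for households 8–10); cluster-level district poverty; and the
two-part outcome with the published "Total" coefficients as ground truth.

Key stated-world parameters, with rationale:

- **Two-part coefficients**: binomial (0.377, 0.943, −0.036) on
  (1, ln age, poverty); normal (10.917, 0.145, −3.088) plus quarter
  offsets (0.614, 0.296, 0.284) on the sqrt-percent scale.
- **sigma_sqrt = 1.2** (residual SD of √E4RZ among consumers; stated
  nowhere): truncating draws to (0, 10] must remove a negligible share of
  normal mass for the generator's own model statement — "√share is normal"
  — to be true, and 1.2 is the largest round value keeping the worst-case
  truncated mass below ~0.5% anywhere in the covariate domain. Larger
  values (e.g. 1.8) make the truncation materially bias an untruncated
  normal fit, contradicting the generator's stated model.
- **Truncation**: rejection sampling with a 50-draw cap, then clipping —
  guarantees validity while preserving approximate normality.
- **Energy totals** ~ Normal(900, 180) kcal/day floored at 250: a
  realistic 24-hour energy intake for children aged 6–35 months.
- **Food records**: one dairy-UPF item carrying 70% of UPF energy (the
  evaporated-milk dominance pattern), one other-UPF item, and 2–5 non-UPF
  items splitting the remainder by a symmetric Dirichlet. This reproduces
  the group-level dominance structure without modeling full diets.

Not emulated: nonresponse and replacement, anthropometric inclusion
criteria, true PPS with unequal cluster sizes, within-cluster covariate
correlation beyond poverty, multi-day recalls, and seasonality of energy
totals. A green test therefore establishes that the *estimators* are
correct for the stated design and model, not that the generator matches
any real population's joint distribution.

## Numerical conventions

- Age in floating months = days / 30.4375; natural logarithms throughout.
- Consumer threshold is exactly E4RZ > 0 — no epsilon, matching the
  non-consumer atom at zero.
- Reporting bands: age 6–11/12–17/18–23/24–29/30–35 months; poverty
  0–14/15–19/20–39/40–90%.
- Internal accounting at full precision; report tables round to 1 decimal.
- Recall kcal recomputed as grams × density/100; supplied kcal accepted
  with a cross-check warning above 2% relative discrepancy.
- Reproducibility: each pipeline stage draws from a sub-seed derived by
  hashing (master seed, stage name), so stages can be reproduced in
  isolation and reruns are byte-identical.

## Known limitations

- The ultimate-cluster approximation ignores second-stage variance; for
  designs with few large clusters it is conservative.
- MRAT's endpoint-transformed interval is asymmetric and can be wide when
  the sqrt-scale mean is small.
- The Box-Cox scan is only informative when the scale is identifiable: for
  a near-constant positive variable (sd ≪ mean) the profile is flat over
  the whole grid and the maximizer is noise.
- The two-part model assumes the stated final term lists; no term
  selection machinery is provided, by design.
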