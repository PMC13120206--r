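---
title: "Methods: probabilistic sediment heavy-metal risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic sediment heavy-metal risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedrisk)
```

`sedrisk` assesses heavy-metal contamination of lake surface sediments and
the ecological and human health risks it implies. This vignette is the
package's own account of the models it implements, the parameters that
matter, the numerical choices behind them, and what its synthetic data can
and cannot tell you about real surveys.

## Pollution and ecological-risk indices

For each site and metal (As, Cd, Cr, Cu, Hg, Mn, Ni, Pb, Zn; mg/kg dry
weight) the package computes:

* **Geo-accumulation index** `Igeo = log2(C / (1.5 C0))`, Müller's scale
  against the geochemical background `C0`, with the constant 1.5 absorbing
  natural diagenetic variation. Graded 0–5 from "uncontaminated"
  (`Igeo <= 0`) to "extremely contaminated" (`Igeo > 4`).
* **Enrichment factor** `EF = (Ci/Al)_sample / (Ci/Al)_background`, the
  double ratio against aluminium as a conservative reference element, which
  cancels grain-size and mineralogy effects. Graded 0–5 with breakpoints
  1, 2, 5, 20, 40.
* **Contamination factor** `Cf = Ci / Cn` and **single-metal potential
  ecological risk** `Er`, summed over the nine metals into the
  comprehensive **risk index** `RI`, graded from "slight risk"
  (`RI <= 150`) to "extremely high risk" (`RI > 1200`).

All classification intervals are closed on their upper end: a value exactly
on a breakpoint takes the lower grade, matching the `<=` convention of the
printed grading tables. The `RI` grading skips grade 4, as the standard
table does.

### The two forms of Er

The literature-standard Hakanson definition is `Er = Tr * Cf`, the
toxic-response factor times the contamination factor. The survey that this
package's defaults reproduce, however, both prints and numerically uses the
reciprocal form `Er = Tr / Cf`: its published mean Er values match the
division form closely for essentially every metal (e.g. Pb:
`5 * 23.3 / 31.98 * (1 + cv^2) ≈ 3.77`), while the product form would give
values an order of magnitude different (Hg would be ≈ 145 rather than
≈ 13). `single_metal_risk()` therefore defaults to
`mode = "paper_division"`, and offers `mode = "hakanson_product"` for the
canonical definition. Note that the division form *rewards* contamination
below background (`Cf < 1` inflates Er), so the two modes are not
interchangeable scientifically; the flag exists so users can choose
explicitly.

Under a lognormal concentration model the division form has the closed-form
expectation `E[Er] = Tr * Cn * (1 + cv^2) / mean`, which the test suite
uses as an analytic oracle for the Monte Carlo engine.

### Backgrounds

Defaults are the Dongting Lake water-system background values
(`default_reference()`), which are the values the reproduced survey's
printed results are consistent with. Both the background and toxic-response
vectors are fully configurable through `reference_table()`. The aluminium
background is a nominal crustal value (70,000 mg/kg); because the
enrichment factor depends only on the *ratio* of sample to background
aluminium, its absolute level cancels.

## Human health risk model

The two-pathway USEPA-style exposure model for adult males, adult females
and children:

```
CDD_ing  = C * IR * ED * EF * CF / (BW * AT)
CDD_derm = C * SA * AF * ABS * ED * EF * CF / (BW * AT)
```

with `HQ = CDD / RfD`, `HI = sum(HQ)` (potential non-carcinogenic risk iff
`HI > 1`, strictly), `CR = CDD * SF` where a route-specific slope factor
exists (ingestion: As, Cd, Cr, Pb; dermal: As, Cd) and `TCR = sum(CR)`
classed negligible below 1e-6, acceptable in [1e-6, 1e-4), unacceptable at
or above 1e-4. The boundary 1e-4 itself is classed unacceptable: the usual
prose ("< 1e-4 acceptable", "> 1e-4 unacceptable") leaves the point
ambiguous, and the conservative reading was chosen.

Parameter conventions that matter:

* **Averaging time.** Non-carcinogenic doses use `AT = 365 * ED` days, so
  exposure duration cancels analytically (the test suite asserts this
  identity). Carcinogenic doses use `AT = 365 * 70` days, so they scale as
  `ED / 70` — 18/70 for children, 70/70 for adults.
* **Skin-area unit bridge.** Exposure tables give SA in m² but the
  adherence factor AF in mg/(cm²·d); `cdd_dermal()` converts SA to cm²
  (factor 1e4) before multiplying. Omitting this bridge changes dermal
  doses by four orders of magnitude; the conversion is what reproduces the
  published child dermal hazard index (≈ 0.5).
* **Heavy-tailed adherence factor.** AF is lognormal with sd larger than
  its mean (0.65 ± 1.2 for children). It is parameterized from the
  arithmetic mean/sd through the same moment bridge as the concentration
  models, truncated below at zero naturally by lognormality, with no upper
  truncation. This tail is the main driver of the dermal exceedance
  probability.
* **Exposure frequency** is named `ef_freq` throughout to avoid any
  collision with the enrichment factor EF.

`default_exposure_profile()` encodes the published distributions for the
three groups (ingestion rate 114/114/200 mg/d; ED 70/70/18 a; EF_freq
triangular 345 (180–365) d/a; adult body weight lognormal 67.55 ± 8.72 and
57.59 ± 8.03 kg, child triangular 29.30 (5.20–56.80) kg; triangular skin
areas; CF = 1e-6). One caveat is documented rather than resolved: the
published adult-female ingestion HI (0.31) is not derivable from the
published female parameters (body weight alone differs from males by ~15%,
not a factor of two), so female results are computed exactly as
parameterized and excluded from reproduction checks.

## Distribution toolkit

`fit_by_moments()` maps a family tag plus summary statistics (min, max,
mean, sd or CV) to a fully parameterized distribution:

* lognormal: `sdlog² = ln(1 + cv²)`, `meanlog = ln(mean) − sdlog²/2`
  (matches arithmetic mean and CV exactly);
* uniform: support `[min, max]` (its mean is then the midpoint — the one
  family whose mean is pinned by the range rather than matched);
* triangular: mode `c = 3·mean − min − max`, clamped into `[min, max]`;
  unclamped, its mean equals the requested mean exactly;
* scaled beta on `[min, max]`: shapes from the rescaled mean/variance,
  with an infeasibility error when the variance exceeds what the support
  allows;
* Weibull: shape solved from the CV by `uniroot` on
  `Γ(1+2/k)/Γ(1+1/k)² − 1 = cv²` (bracket 0.08–400, tol 1e-12), scale from
  the mean;
* discrete uniform: a finite value set cannot be recovered from summary
  statistics, so the fit falls back to the triangular rule by default, or
  to the lognormal rule with `discrete_fallback = "lognormal"` (the
  expectation-based reproduction targets use the lognormal route, stated
  per target).

The Anderson–Darling statistic is computed literally as
`A² = −n − (1/n) Σ (2i−1)[ln F(x(i)) + ln(1 − F(x(n+1−i)))]`, with the
probability integrals clipped to `[1e-12, 1 − 1e-12]` to keep the
logarithms finite. It is used *comparatively* for family selection
(`select_family()` ranks candidates ascending, ties broken by candidate
order); no p-values or critical tables are attached, since the selection
needs only an ordering. For a normal fit from the sample's own moments the
statistic coincides with the classical estimated-parameters case, which the
test suite cross-checks against an independent implementation.

## Monte Carlo engine

`run_mc()` samples every named input independently, evaluates the model on
the joint draws, and reports the mean, median and a percentile confidence
interval (2.5/97.5 at the default `ci_level = 0.95` — the plain percentile
method, since nothing more specific is standard here). The default
iteration count is 10,000, the conventional size for stable 95% intervals
in this genre of risk assessment; the reproduction script uses 100,000 for
tighter means.

* **Substreams.** Each input draws from a seed derived from the root seed
  plus a stable hash of the input's *name*, with the caller's RNG state
  saved and restored. Adding or removing an input therefore never perturbs
  the other inputs' draws, and identical configurations are bitwise
  reproducible.
* **Independence.** All inputs are sampled independently; no correlation
  model is imposed. Real inter-metal concentrations are correlated
  (sites polluted in Cu tend to be polluted in Pb/Zn/Cd), so joint
  statements across metals from independent draws understate dependence —
  single-metal and single-group summaries are unaffected.
* **Class and exceedance probabilities** are empirical fractions of draws;
  exceedance uses strict `>` to mirror the `HI > 1` rule, making the two
  exactly consistent at a class breakpoint. Either an empirical sample or
  a fitted distribution can drive them; the package supports both routes
  and they differ exactly to the extent that the fit mis-describes the
  sample.
* **Sensitivity.** The published sensitivity percentages name no method;
  the package uses the signed contribution-to-variance display that
  commercial risk-simulation tools made standard: each input's squared
  Spearman rank correlation with the output, normalized to sum to 100 in
  absolute value and signed by the correlation. Exact percentages from
  other tools are therefore comparable in pattern, not digit-for-digit.

## Synthetic surveys

`default_liuye_profile()` encodes a published 21-site urban-lake survey as
summary statistics (per-metal min/max/median/mean/CV), best-fitting
families (Cd/Zn beta, Pb/Ni Weibull, As/Hg lognormal, Cr triangular, Cu
uniform, Mn discrete-uniform via its fallback), backgrounds and
toxic-response factors. The per-metal sd is rebuilt from the CV column
(`sd = mean * cv / 100`) rather than taken from the independently rounded
SD column, so mean and CV are matched exactly; where the two columns
disagree (they do at the second decimal), the CV wins. One inconsistency in
the source is recorded, not resolved: the summary table caps Hg at 0.30
mg/kg while the prose reports a maximum of 0.52; the profile follows the
table.

`generate_samples()` draws each metal from its moment-fitted family on its
own substream. Families with unbounded support (lognormal, Weibull, normal)
are truncated to the profile's `[min, max]` by rejection sampling — simple
and exact — so synthetic surveys stay inside observed ranges. Truncation
necessarily shifts the realized mean of a heavy-tailed metal slightly below
its profile mean (Hg most visibly, since ~9% of its untruncated mass lies
above the recorded maximum); the expectation-based reproduction targets
therefore use *untruncated* lognormal models, and the generator's realism
check asserts closeness, not moment equality, for truncated families.

The aluminium column is generated as `ratio × Al background` with
`ratio ~ normal(1.655, cv 10%)` truncated positive. The 1.655 is
reverse-engineered: the survey's published enrichment factors sit uniformly
≈ 1.65× below its contamination factors across metals, implying that mean
sample aluminium ran ≈ 1.655× its background. It is a calibration constant,
configurable, not a measurement.

What the generator does **not** emulate: spatial structure (inflow/outflow
enrichment, nearshore gradients), inter-metal correlation (the observed
Cu–Pb–Zn–Cd cluster), detection-limit censoring, or analytical error.
Passing tests on synthetic data therefore demonstrate that the *methods*
are implemented correctly and reproduce the published summary-level
results; they do not validate spatial or multivariate claims about any real
lake.

## Problem sizes and reproducibility

The test suite runs index Monte Carlos at 5e4–1e5 draws, health-risk
simulations at 5e4, and generator checks at up to 2e4 sites — sizes chosen
so that Monte Carlo standard errors are comfortably inside the assertion
tolerances while the full suite stays fast on a single CPU. The
reproduction script (`scripts/acceptance.R`) uses 1e5 iterations
throughout. Every stochastic quantity is driven by one root seed through
named substreams.

## Known limitations

* Only ingestion and dermal pathways; no inhalation, no age-interpolated
  child cohorts, no physiologically based lead modelling.
* No Nemerow or single-factor composite indices.
* No censored-data handling: concentrations must be strictly positive, and
  zeros are rejected rather than imputed.
* No Latin hypercube or quasi-random sampling; plain Monte Carlo only.
* The optional dependence between concentration columns is not modelled;
  all Monte Carlo inputs are independent.
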