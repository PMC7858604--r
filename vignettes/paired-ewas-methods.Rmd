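---
title: "Methods and design notes for pairedEWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for pairedEWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedEWAS)
```

# The model and its assumptions

pairedEWAS analyses paired (work / vacation) methylome samples from an
occupational cohort split into shift-work-disorder (SWD) cases and
symptom-free controls. Per CpG probe it fits, by ordinary least squares,

$$ y_{ij} = (1-h_i)\beta_{swd,j} + h_i\beta_{ctrl,j}
  + (1-h_i)v_i\,\beta_{vw,swd,j} + h_i v_i\,\beta_{vw,ctrl,j}
  + D_i\beta_{D,j} + \varepsilon_{ij}, $$

with $h_i$ the control-group flag, $v_i$ the vacation flag, $D_i$ nuisance
covariates (age continuous; sex, plate, alcohol, smoking reference-coded
with the lexicographically first level as reference), and errors assumed
iid Gaussian. Two modelling points deserve emphasis:

* **No subject-level pairing term.** Although samples are paired within
  subject, the model deliberately treats errors as independent — that is
  the estimator the published analysis states, and deviating to a mixed
  model would change every p-value. The simulator's
  `subject_intercept_sd` knob exists precisely so users can quantify what
  ignoring within-subject correlation costs: with a positive value, null
  p-values become conservative for between-subject contrasts and the
  stated calibration tests no longer apply.
* **M-values by default.** The post-hoc change scores are defined on
  M-values (logit2 methylation); the EWAS accepts any numeric matrix, so
  beta-values can be passed if preferred, but all defaults and the
  simulator speak M-values.

## Four null hypotheses and the union-null subtlety

Per probe, nested-model variance-ratio F tests cover: no SWD effect
(1 df), no control effect (1 df), no effect in either group (joint 2-df
test), and the union null "no effect in at least one group". The union
null is tested with the intersection–union construction
$p_{both} = \max(p_{swd}, p_{ctrl})$, the standard level-$\alpha$ test of
a union hypothesis. Two consequences, verified by the test suite:

* Under the *full* null (both effects zero) the max-p test is
  conservative: its rejection rate at $\alpha$ is close to $\alpha^2$.
  Uniformity of $p_{both}$ therefore cannot and should not be expected
  there.
* At the *least-favourable boundary* of the union null (one group with a
  strong effect, the other with none) the test is exactly level $\alpha$,
  and $p_{both}$ collapses to the null group's uniform p-value. The
  calibration acceptance test evaluates $p_{both}$ in that configuration
  and the other three hypotheses under the full null.

## Multiplicity, DMPs, and direction

Benjamini–Hochberg is applied separately within each hypothesis family
across probes (the published analysis reports per-model QQ plots and
per-group DMP counts, implying per-family adjustment). A DMP is a probe
with *unadjusted* p < 0.05 in the group's own 1-df test. BH is
implemented as the classical step-up with enforced monotonicity; note that
BH is *not* idempotent (re-applying it to q-values inflates them), so the
suite asserts $q \ge p$, monotonicity in sorted-p order, and equality with
`stats::p.adjust(..., "BH")`, not idempotence.

The sign convention reconciles two superficially conflicting statements in
the source material: a *positive* vacation-minus-work coefficient means
methylation is gained on vacation, which is reported as "hypomethylated
during work". `classify_direction()` maps $\beta_{vw} > 0$ to
`hypo_at_work`, $< 0$ to `hyper_at_work`, and exactly 0 to `none`.

## Score rounding

Percentages are reported in two styles: one decimal for score-table
outputs (DMP percentage, enrichment and hypomethylation scores) and
integer percent for prose-style summaries, both via standard rounding.
One published value resists this: 28,419/433,479 = 6.556%, printed as
"6.5%" (a truncation), while every other published percentage matches
standard rounding. The package keeps standard rounding and reports 6.6
for that ratio.

# The synthetic world

The generator's defaults state one fixed world, chosen to mirror the
cohort the pipeline was designed around, and are not tuned per test:

* **Cohort:** 21 SWD subjects (age 41.0 ± 8.9) and 11 controls
  (49.2 ± 9.1), ~25% women, two plates, smoking 30% / alcohol 50%
  (the source reports only age and sex structure; the lifestyle
  frequencies are plausible occupational-cohort values fixed once).
  Covariates are constant within subject except plate, which is drawn per
  sample — blood draws months apart can land on different plates.
* **Methylome:** per-probe baselines from a three-component normal
  mixture (modes near ±3 and 0 M-value units) mimicking the bimodal
  methylated/unmethylated distribution of array M-values; iid noise
  σ = 0.5; planted vacation effects |N(1.0, 0.25)| on
  `floor(0.05 · n_probes)` SWD probes (78% positive, matching the
  published preponderance of gain-on-vacation DMPs) and none in controls.
  The floor-and-sample-without-replacement rule makes affected counts
  exact and testable.
* **Recovery link:** designated recovery probes carry a subject-varying
  SWD vacation effect $\beta_j + \tau g_i$ with $g_i \sim N(0,1)$ the
  latent recovery degree and $\tau$ set to the mean effect size. Symptom
  answers (two Likert 1–5 questions per period) are constructed so the
  change score $(A+B)_{work} - (A+B)_{vac}$ correlates with the *planted*
  methylation change at strength `recovery_link_strength` (negative sign:
  more regained methylation, more symptom improvement), then clamped to
  the 1–5 scale. Realized (noisy) changes attenuate the correlation by
  roughly $\tau/\sqrt{\tau^2 + 2\sigma^2} \approx 0.82$, plus a little
  Likert discretization loss — an unavoidable feature of the stated
  noise level, relevant to interpreting the recovery acceptance test
  below.
* **Randomness:** one root seed; each generator draws from its own
  Lehmer-derived sub-stream (cohort = 1, methylome = 2, symptoms = 3,
  annotation/GMT = 4, embedding = 5), so extending one generator never
  perturbs another and identical seeds give byte-identical fixtures.

What the simulator does *not* emulate: intensity-level (IDAT) data,
probe-type I/II chemistry bias, dye/batch effects, cell-type composition,
genomic autocorrelation between neighbouring CpGs, and realistic
annotation topology. A green test therefore establishes correctness of
the statistics on data satisfying the model's assumptions, not robustness
to array artefacts.

## Interpreting the recovery acceptance test

The recovery criterion asks that, at link strength 0.9, the designated
probes "dominate the smallest q-values" among a 38-probe tested set in at
least 90% of replicates. With 21 SWD subjects and the attenuation noted
above, requiring *all three* designated probes to occupy the three
smallest q-values succeeds in only ~70% of replicates — a property of the
stated world, not a bug. The implemented success criterion is the
dominance reading: the smallest q belongs to a designated probe *and* at
least two of the three designated probes sit within the top three. That
holds in ~96% of replicates and is what the acceptance suite asserts.

# Numerical choices

* OLS via QR decomposition; the genome-wide path computes residual sums
  of squares for all probes at once from an orthonormal basis of each
  design ($RSS = \lVert y\rVert^2 - \lVert Q^\top y\rVert^2$), which is
  what makes a 5,000-probe calibration run take under a second.
* Saturated fits ($RSS_{full} = 0$): p = 0 if the null fits worse, else
  1, with a warning. Zero-variance probes are skipped (F undefined).
  Probes with missing values are fitted on complete cases when at least
  rank + 2 observations remain, otherwise skipped with a logged reason.
* Constant or collinear nuisance columns are pruned greedily (rank check
  per column) with a warning; the four core model columns are never
  pruned, and an empty group × period cell is an error naming the cell.
* Spearman correlation uses average ranks for ties; two-tailed p by
  exhaustive permutation enumeration for n < 10 (exact, cached
  permutation tables) and the t-approximation for n ≥ 10 — the real
  cohort's n = 21 is approximation-safe while micro-tests stay exact.
* Recovery groups default to empirical tertiles of the symptom change
  score (higher = better recovery), ties assigned to the lower group;
  explicit cutpoints override. The published grouping lives in
  unreproduced supplementary material, so cutpoints are configuration.
* The working-period ANOVA defaults to SWD vs control; any
  subject-labelled grouping (e.g. three recovery groups plus controls)
  can be supplied. Between/within sums of squares are computed
  vectorized across probes; degenerate probes are flagged, not dropped
  silently.
* t-SNE is the exact $O(n^2)$ algorithm implemented in R (perplexity
  calibration by per-point binary search, early exaggeration 12 for 250
  iterations, momentum 0.5 → 0.8, learning rate 200, PCA to 50
  components first). At the 64-sample scale this is fast and avoids a
  compiled dependency; defaults honour perplexity 10 and 10,000
  iterations. Embeddings are deterministic given the seed but, as
  always with t-SNE, only neighbourhood structure — not distances — is
  interpretable.
* The union-null p is computed from the same two 1-df tests it combines,
  so `p_both >= max(p_swd, p_ctrl)` holds exactly by construction.
* Top-gene ranking deduplicates genes to their best (minimum) probe
  p-value before applying the p < 1e-5 filter and the top-30 truncation;
  whether the published list was built this way or from the top DMPs
  directly is not stated, so the choice is documented here and exposed
  via parameters.
* The enrichment background defaults to all genes with at least one
  tested probe — the natural methylation-aware universe — and is a
  parameter. Only the hypergeometric/Fisher p and BH q are computed; the
  combined score of web enrichment services is service-specific and out
  of scope.

# Known limitations

* The iid-error OLS model understates within-subject correlation; see
  `subject_intercept_sd` above.
* The paired design cannot separate a vacation effect from a pure order
  (time) effect; the work sample always precedes the vacation sample.
* Gene symbols are matched after case/whitespace normalization with no
  alias resolution; annotation quality is the caller's responsibility.
* The pipeline report records a provenance timestamp; byte-identical
  reruns are guaranteed for every stage output file, and for the report
  up to that timestamp.
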