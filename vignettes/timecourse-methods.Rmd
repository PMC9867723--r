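---
title: "Methods: time-resolved differential expression in activated CD4+ T cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved differential expression in activated CD4+ T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcellkinetics)
```

This vignette is the package's own account of the statistical procedure it
implements: the model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical conventions, and the known limitations.

## The study design the package targets

The pipeline analyses time-resolved RNA expression of peripheral CD4+
T cells after in vitro activation, comparing a patient group (`PD`) with
healthy controls (`HC`). The emulated design is 5 donors per group sampled
at 0, 2, 4, 8, 12 and 24 h — 60 samples per assay (transcriptome and
miRNA), hybridised in batches, with one donor's 4 h transcriptome sample
missing. The three activation windows used for interpretation are early
(0–2 h), intermediary (4–8 h) and late (12–24 h).

## Intensity model and the synthetic generator

`simulate_cohort()` draws raw single-channel intensities as

$$X_{fs} = B_{fs} + A_f \, 2^{L_{fs}},\qquad
B_{fs} \sim \mathcal N(\mu_b, \sigma_b^2),\quad
A_f \sim \mathrm{Exp}(\text{mean } \alpha_s),$$

with the latent log2 modulation
$L_{fs} = \text{activation}_f(t_s) + \Delta_f(t_s)\,[\text{group}=PD] +
\beta_{f,b(s)} + \varepsilon_{fs}$.

Design choices, made once:

* **Per-feature exponential amplitude.** The exponential component is drawn
  per feature and shared across samples. Across features at a fixed sample
  this reproduces the normal + exponential marginal that normexp
  background correction assumes, while within-feature noise stays at
  `noise_sd` log2 units. (An exponential drawn per observation would put
  coefficient-of-variation-1 noise on every measurement and no two-group
  design at n = 5 could recover effects from it.)
* **Defaults**: `background_mean = 50`, `background_sd = 5` intensity
  units and `signal_rate = 500` give a realistic single-channel regime —
  abundances spanning about three orders of magnitude over a dim, narrow
  background; `noise_sd = 0.4` log2 units is a typical between-donor
  residual spread; `batch_sd = 0.2` log2 units is a moderate batch
  footprint (its true magnitude in the emulated design is unknown, so it
  is configurable).
* **Activation kinetics** use a saturating ramp $1 - e^{-t/4\,\mathrm h}$,
  zero at baseline and plateauing by 8–12 h, matching the qualitative
  shape of canonical activation markers (CD69, IFIT3, NME1). Only the
  overlap of the two groups' kinetics matters downstream, not the exact
  curve.
* **Spike classes** (`sim_signals()`): `activation_shared` (both groups),
  `group_up`/`group_down` (PD-only, confined to chosen windows,
  default |log2 FC| = 2), `mixed_direction` (+ in the early, − in the
  intermediary window), and `mirna_coupled` pairs — a miRNA and a target
  gene with equal and opposite window-shaped group effects (amplitude 3
  log2 units; latent profile correlation exactly −1, i.e. strong
  regulation spikes for recovery testing), with window patterns cycling
  over five shapes so that pair profiles differ.
* Raw intensities are clamped at `1e-6`: the normal background can in
  principle go non-positive, and strictly positive intensities are part of
  the contract.

The generator is seeded and bit-reproducible. It does **not** emulate
probe-level replicate spots, dye chemistry, scanner saturation,
heavy-tailed donor outliers, or correlated gene modules; passing recovery
tests on it therefore demonstrates correctness of the procedure under its
own assumptions, not performance on real arrays.

## Preprocessing

Order is fixed and enforced by stage tags on the cohort object:
`raw → bgcorr → qnorm → log2 → batchcorr`; each step refuses out-of-order
input.

1. **normexp background correction** (`normexp_correct()`, offset 16).
   Per-sample maximum-likelihood fit of the Normal + Exponential
   convolution, then each intensity is replaced by the analytic conditional
   expectation `E[S | X = x] + 16`. A moment-matching fallback
   (`method = "moments"`) is available for ill-conditioned columns. The
   offset keeps values strictly positive and damps log-ratio variance at
   low intensities.
2. **Quantile normalization**: every column receives the mean of the
   across-column order statistics at its ranks; ties receive the mean of
   the tied rank means, which makes the operation deterministic,
   order-independent and exactly idempotent.
3. **log2 transform** (all values positive by construction).
4. **Batch removal** (`remove_batch_effect()`): per feature, OLS on the
   preserved group×time cells plus sum-to-zero batch contrasts; the fitted
   batch component is subtracted, so preserved-design fitted means are
   unchanged. Confounded designs abort with the aliased terms listed.
   Following the emulated study, the transcriptome assay is batch-corrected
   by default and the miRNA assay is not (`batch_correct = FALSE`); the
   flag extends correction to any assay.

Dropped samples are simply absent columns; nothing is imputed.

## The two-step differential procedure

**Step 1 — time-course gate** (`tc_gate()`). For each feature and each
donor trajectory, deviations `value(t) − value(0)` are computed over all
available `t > 0` and the deviation of maximum magnitude is kept *with its
sign* (first maximising time point on ties). The signed per-donor scores
are aggregated per group by the median, and the feature passes when
`|median| ≥ gate_log2` in PD or HC. Signed-then-aggregate is a deliberate
choice: it preserves direction, makes the null symmetric around zero, and
lets random-signed donor noise cancel in the median. The default gate is
`gate_log2 = 0.5`, consistent with the 0.5-log2 gates used throughout the
classification; a 1.5-fold variant (`gate_log2 = log2(1.5) ≈ 0.585`) is
one argument away. With even group sizes (after a dropped sample, n = 4)
the median is the usual midpoint of the two central values.

**Step 2 — group comparison per time point** (`differential_table()`).
The effect estimate is the difference of group medians of log2 expression
(`median_log2fc`). Inference uses the distribution-free James–Stein
shrinkage variance estimator: within each group, per-feature variances
$v_g$ are shrunk toward their median $v_\bullet$ with intensity

$$\lambda^\* = \min\Big(1,\ \frac{\sum_g \widehat{\mathrm{Var}}(v_g)}
{\sum_g (v_g - v_\bullet)^2}\Big),\qquad
\widehat{\mathrm{Var}}(v_g) = \frac{n}{(n-1)^3}\sum_k (w_{kg} - \bar w_g)^2,$$

with $w_{kg}$ the squared centred observations, and
$t = (\bar x_{PD} - \bar x_{HC}) / \sqrt{v^*_{PD}/n_{PD} + v^*_{HC}/n_{HC}}$.
Each group gets its own $\lambda^\*$ and target. When all variances are
equal the denominator is zero and $\lambda^\*$ is set to 1, which is a
no-op because target and variances coincide.

*p-values.* The shrinkage statistic has no exact finite-sample null. The
package uses the Student-t reference with $n_{PD}+n_{HC}-2$ degrees of
freedom — deterministic and conservative relative to the pooled-variance
limit — with a normal approximation as an option. This is an
interpretation, and it is stated as such here rather than hidden.

*Multiplicity.* BH runs across features separately within each time point
(six adjustments): the per-timepoint adjusted values are what the
downstream classification consumes, and the per-timepoint scope matches
how results are reported per hour. Ties share the minimal adjusted value
per the standard step-up rule. By default the tested universe is the
gate-surviving set, so adjusted p-values are interpreted within the gated
universe; passing `features = NULL` tests all features instead — both
modes are exposed because either convention is defensible.

**Core classification** (`classify_core()`): a feature is core when
`p_adj ≤ alpha` *and* `|median_log2fc| ≥ grp_log2fc` at ≥ 1 time point
(defaults 0.05 and 0.5). Core time points map to windows; direction is
`increased`/`decreased` when all core fold changes share a sign, `mixed`
otherwise; recurrence counts core time points (`min_recurrence = 2` marks
recurrently deregulated genes). `venn_windows()` reports the
exclusive/shared window partition, which always sums to the core count.

**Marker QC** (`marker_qc()`): activation markers must rise from baseline
in both groups, and no per-timepoint group difference may be significant.
The comparison uses the classic equal-variance unpaired t-test (Welch via
`var_equal = FALSE`), judged on BH-adjusted p-values across the
marker×timepoint report — with 3 markers × 6 time points a raw-α rule
would reject spuriously in most null cohorts, defeating the purpose of a
comparability check.

## Ordination

`sample_distances()` computes pairwise Euclidean distances either per
sample or in combined mode: one vector per donor, concatenating the
donor's per-timepoint columns feature-wise. A time point missing for any
donor is excluded from the concatenation for all donors — deterministic,
and unbiased between donors. `classical_mds()` is Torgerson scaling
(double-centred squared distances, eigendecomposition, top-k eigenvectors
scaled by root eigenvalues, k = 2); negative eigenvalues are reported,
never used for coordinates. Features are not standardised before the
distance computation — preprocessing already places features on a common
log2 scale, and reweighting low-variance features would change what
"distance" means here.

## miRNA–target matching

For each analysed feature, the fold-change profile is the vector of six
per-timepoint `median_log2fc` values (`fc_profiles()`); correlation is
computed between median-FC profiles, not per-sample values, because the
quantity being matched is the time-course *change pattern*. A (miRNA,
gene) pair matches when `PCC ≤ −0.5` and the gene shows a
direction-consistent median FC of at least 0.3 in magnitude at **one or
more** time points (increased miRNA ⇒ gene ≤ −0.3 somewhere; decreased ⇒
≥ +0.3). The ≥ 1-time-point reading of the FC gate is the default because
the stricter "all significant miRNA time points" variant (available via
configuration of the calling code) prunes far more aggressively than the
target-set sizes this procedure is meant to produce. Zero-variance
profiles and pairs with fewer than 3 shared time points are skipped and
logged, never silently dropped. Candidate genes default to *all* genes
with computable profiles, not only the gated set — secondary and indirect
miRNA effects are part of what inverse correlation is meant to surface.
`intersect_validated()` adds a `validated` flag for pairs present with
case-insensitive evidence tier `"strong"` in a validated-target table
(schema: `mirna_id`, `gene_id`, `evidence`; a synthetic toy fixture ships
in `inst/extdata/`).

## Over-representation analysis

`ora()` is the upper-tail hypergeometric test
$p = P(X \ge k \mid N, K, n)$ against a user-supplied reference universe
(e.g. all protein-coding genes), the conventional ORA statistic (and
numerically identical to one-sided Fisher). Core genes are split by
direction first (`direction_split()`); mixed-direction genes are excluded
from enrichment because neither an "increased" nor a "decreased" pathway
interpretation fits them. Sets smaller than `min_size = 2` inside the
reference are skipped and listed. BH runs across all tested sets jointly
by default, producing a single adjusted ranking; per-collection adjustment
is a matter of subsetting the input.

## Numerical conventions and degenerate inputs

* Stage tags make the preprocessing order explicit and non-bypassable.
* Constant intensity columns cannot be normexp-fitted and abort with
  guidance to skip correction for that sample.
* `log2_transform()` names the first offending feature and sample on
  non-positive input.
* `t = 0` is reported (not NA) when both group means and shrunk variances
  coincide.
* Deviation ties (two time points with the same |deviation|) resolve to
  the earlier time point.
* TSV writers emit doubles as `%.17g` and the matrix reader parses with
  base R's correctly rounded parser, so fixtures round-trip bit-exactly;
  every written file carries a `# tcellkinetics <version> seed=… config=…`
  header line.
* All randomness flows from the single config seed; repeated pipeline runs
  with one seed produce byte-identical JSON reports.

## Scale of the validation suite

The test and acceptance runs use the scaled-down default fixture — 2,000
transcript features, 200 miRNAs, 5+5 donors — chosen as the smallest size
at which the gate, shrinkage and matching behave as they would on a
full-size array (tens of thousands of features are supported but add
nothing to the properties being checked). Stochastic properties use 20
seeds each: null cohorts at `noise_sd = 0.1` for false-call rates, spiked
cohorts (100 early-window spikes at |log2 FC| = 2, `noise_sd = 0.4`) for
sensitivity / false-discovery proportion / window accuracy, and one
200×2,000 cohort with 50 coupled pairs for matching recovery.

## Limitations

* The shrinkage-t p-value calibration is a stated convention, not an exact
  null; ranking and gating are the primary uses.
* Donors are treated as independent samples within groups; there is no
  paired or longitudinal random-effects modelling.
* The gate median over 5 donors is robust but coarse; with `noise_sd`
  well above ~0.3 log2 units an appreciable share of null features passes
  step 1 (step 2's FDR control is what keeps core calls clean).
* ORA treats genes as exchangeable; no gene-length, expression-level or
  correlation-aware correction is applied.
* The synthetic generator's independence assumptions (no gene–gene
  correlation, Gaussian noise) make recovery tests necessary but not
  sufficient evidence for real-data performance.
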