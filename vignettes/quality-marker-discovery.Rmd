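---
title: "Spectrum-effect quality-marker discovery: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrum-effect quality-marker discovery: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmarker)
```

## The problem

Herbal products are chemically complex, and pharmacopoeial quality control
often tracks a single marker compound that may have little to do with the
product's efficacy. Spectrum-effect analysis addresses this by treating the
chromatographic fingerprint — the peak areas of identified constituents
across many batches — as a predictor block X, and batch-level bioassay
readouts (radical scavenging, ferric reduction, NO-production inhibition in
stimulated macrophages) as responses Y. Constituents whose abundance
consistently tracks activity across batches become candidate *quality
markers*; a pharmacokinetic plausibility filter then decides which
candidates could act in vivo at all.

`qmarker` implements that full evidence chain: grey relational analysis
(GRA) as corroborating evidence, per-assay partial least squares regression
(PLSR) with VIP/coefficient screening as the primary selector, union of
candidates across assays of the same activity, and a drug-likeness /
gastrointestinal-absorption admission stage with a high-content override.

## Grey relational analysis

For a reference series $x_0$ (an assay, over samples) and comparison series
$x_i$ (a compound), both normalized, GRA forms deviations
$\Delta_i(k) = |x_0'(k) - x_i'(k)|$ and coefficients

$$\xi_i(k) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                 {\Delta_i(k) + \rho\,\Delta_{\max}},$$

whose mean over samples is the grey relational degree (GRD) in $(0, 1]$.
Three choices are open in the literature and fixed here as defaults:

* **Distinguishing coefficient** $\rho = 0.5$, the near-universal
  convention; smaller $\rho$ spreads the degrees apart, larger compresses
  them towards 1. It is a contrast knob, not an inference parameter.
* **Normalization**: division by the series mean. It is invariant to the
  arbitrary ordering of samples (initial-value normalization is not) and
  keeps heterogeneous units comparable. Initial-value, min–max and no
  normalization are selectable for sensitivity analysis.
* **$\Delta_{\min}/\Delta_{\max}$ convention**: computed per assay over all
  compounds and samples jointly (the *global* convention). A per-compound
  variant exists; with it every compound's own worst deviation rescales its
  coefficients, which weakens cross-compound comparability.

Because the upstream study ran GRA on a statistics platform whose settings
(normalization, $\rho$, $\Delta$ convention) are not disclosed, printed GRD
tables cannot be reproduced digit-for-digit from raw data; the package
therefore ships them as fixtures and uses them for rank-logic checks only.
GRA is deliberately **corroborative**: degrees annotate candidates (with a
flag below a 0.9 floor) but never remove them, mirroring how such analyses
are used when all degrees are high.

## PLS regression, VIP and screening

Each assay is modelled separately by single-response NIPALS PLSR. Both X
and y are autoscaled by default — the convention of the commercial
chemometrics suites, and the only scale on which a fixed coefficient
threshold (0.1) is meaningful across compounds. With one response, each
component's weight vector is $w \propto X^\top y$ in closed form (no inner
iteration can fail to converge), followed by deflation of X and y.

Model size $A$ is chosen by K-fold cross-validation:
$Q^2(A) = 1 - \mathrm{PRESS}(A)/\mathrm{TSS}$, preprocessing re-estimated
inside every training fold, folds assigned as contiguous blocks of a seeded
shuffle, $K = 7$ by default (again the suite convention). The default
selection rule takes the smallest $A$ within 0.01 of the maximal $Q^2$;
$Q^2_{cum}$ is reported as $1 - \mathrm{PRESS}(A)/\mathrm{TSS}$ at the
selected $A$ (the single-number convention) rather than the multiplicative
per-component form. TSS is taken about the overall mean of y.

Variable importance in the projection is

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a \mathrm{SSY}_a\, w_{ja}^2}
                                   {\sum_a \mathrm{SSY}_a}},$$

with $\mathrm{SSY}_a = q_a^2\, t_a^\top t_a$; its squares average to one, so
VIP > 1 means above-average importance. A compound becomes a candidate for
an assay when **VIP > 1 and standardized coefficient > 0.1, both strict**;
boundary values are excluded. The coefficient rule is applied to the signed
value by default (an absolute-value mode is selectable): a constituent that
*suppresses* activity is not a quality marker for it, and in the worked
examples all printed coefficients are positive, so the readings agree.

Candidates from assays probing the same activity (DPPH and FRAP for
antioxidation) are merged by set union, trading a few false positives for
fewer false negatives from assay-specific sensitivity. The
anti-inflammatory group holds a single assay, so its union is trivially
that assay's set; the grouping machinery is exercised all the same.

Overfitting is checked by Y-permutation: refit with y shuffled, record
$R^2Y$ and $Q^2$, and compare the observed statistics against the permuted
distribution (empirical p with the add-one rule) and the regression
intercepts of statistic versus $|\mathrm{cor}(y_{perm}, y)|$, the observed
model included at correlation 1. The default count, 199, gives p-value
resolution 0.005. Inside `screen_pipeline()` the permutation test is **off
by default** (`n_perm = 0`): it multiplies cost by roughly the permutation
count while selecting nothing — it validates. Run it per final model, or
pass `n_perm` explicitly.

Two open readings were settled as follows. Whether X should be raw peak
area or row-normalized "relative content" is unstated upstream; the package
defaults to raw areas + autoscaling (autoscaling already removes
per-compound magnitude, and row-normalization introduces spurious negative
dependence between compounds), and a user can row-normalize before
constructing the table if desired. And the screening threshold applies to
signed coefficients, as above.

## The synthetic-data generator

No raw batch data were released with the study this package's worked
examples come from, so the generator is the test bed, and its defaults *are*
the study conditions rather than tunable knobs:

* 31 samples in two species groups (17 + 14); 22 compounds, 9
  phenylpropionic acids and 13 flavonoids.
* Log-normal abundances (log-SD 0.4); compounds of a class share a latent
  factor giving within-class correlation 0.3 on the log scale; group 2 has
  lower caftaric/caffeic/cichoric acid and higher luteolin (log shifts
  −0.5/+0.4); compound 7 (cichoric acid) is set ~25-fold more abundant,
  matching its dominant-constituent role.
* Activities are linear in *autoscaled* abundances —
  $y = \alpha + s\,(\sum_{j \in \text{active}} w_j z_j + \varepsilon)$ —
  so the configured weights live on the standardized-coefficient scale the
  screening rule uses. The antioxidant assays share the active set
  {1, 3, 5, 7, 18} with weights taken from the printed standardized
  coefficients; the anti-inflammatory assay uses the 8-compound set
  {8, 9, 13, 17, 18, 19, 20, 21} likewise.
* Noise SDs (0.32, 0.39, 0.60 for DPPH/FRAP/NO-inhibition on the
  standardized scale) were calibrated once, by simulation over 30 seeds, so
  that fitted $R^2Y$ lands near the three reported model qualities
  (0.90 / 0.86 / 0.62), and then frozen.
* One master seed derives fixed per-stage substreams (abundances,
  activities, CV folds, permutations), so each stage is independently
  reproducible.

What the generator does **not** emulate: chromatographic drift,
retention-time misalignment, censoring at the limit of quantitation,
non-linear dose–activity saturation, and batch effects beyond the two-group
mean shift. Passing recovery tests therefore show the chain works when its
linear additive premise holds at realistic n, p, collinearity and noise —
not that the premise holds for any particular real extract.

## Bioassay arithmetic

The assay layer returns **fractions**, never percent (the presentation
layer multiplies by 100): DPPH scavenging $1 - (A_2 - A_0)/A_1$;
NO-inhibition $(\text{stim} - \text{treated})/(\text{stim} -
\text{unstim})$, clipped to $[0,1]$ with a flag; FRAP as inverse OLS
calibration scaled to µmol Fe(II)/g. IC50 comes from a four-parameter
logistic fitted by Levenberg–Marquardt least squares, initialized at the
interpolated midpoint with a positive Hill slope (sign unconstrained);
non-convergent or out-of-window fits fall back to log-linear interpolation
between the doses bracketing 50%, flagged as such, and responses that never
bracket 50% yield a censored "> max dose" (or "< min dose") result rather
than a number. Reference-standard equivalents (e.g. Trolox) are computed as
a ratio of calibration slopes — an assumption, documented, since protocols
rarely print that conversion.

## Drug-likeness admission

The rule engine never computes molecular descriptors; it consumes a
descriptor table (the bundled one for the seven named markers was computed
with RDKit, whose Wildman–Crippen logP fills all three logP fields — the
Moriguchi and XLOGP estimators are not available there, and the table
records that). The five rule sets (Lipinski, Ghose, Veber, Egan, Muegge)
live in one editable threshold table transcribed from their original
publications; only Lipinski tolerates one violation. Gastrointestinal
absorption is a closed point-in-rotated-ellipse test in the (TPSA, WLOGP)
plane with the published high-absorption ellipse as a replaceable default.

Admission reads the upstream phrase "over two parameters of drug-likeness"
strictly as **≥ 3 of 5** rule sets, requires high GA, and grants an
exception when a compound's content exceeds 20× the median of the others —
the dominant-constituent case (cichoric acid) in which plasma exposure is
expected despite poor predicted absorption. Admission is monotone:
improving a verdict or raising content can never revoke admissibility.

## Numerical choices and degenerate inputs

* GRA with all normalized series identical ($\Delta_{\max} = 0$) defines
  every coefficient as 1 rather than 0/0.
* Zero-variance compound columns are a hard error under autoscaling (named
  in the message), dropped with a warning in PCA, and undefined (NA, not 0)
  in correlation output.
* NIPALS stops early if the residual X block is numerically exhausted
  (weight or score norm < 1e-14); requesting more components than the rank
  silently yields the attainable number.
* Missing cells are never imputed anywhere; they are validation errors.
* Tie-breaks in GRD ranking are by compound id ascending (numeric-aware).
* PCA score signs follow the largest-loading-positive convention so runs
  are platform-stable.

## Problem sizes in the test suite

The repeated-simulation checks use sizes chosen to make sampling error
negligible relative to the asserted margins at interactive runtimes: 100
random 5×4 instances for the GRA oracle equivalence, 100 random fits for
the VIP identity, 50 null datasets × 99 permutations for permutation
calibration, and 100 paper-sized datasets (31 × 22) for marker recovery.
The acceptance script summarizes model quality over 50 replicate draws.

## Known limitations

* Single-response PLS only (per-assay models, as in the source strategy);
  no OPLS, multi-block or sparse variants.
* The GRA fixtures certify rank logic, not digit-level reproduction, for
  the reasons above.
* The admission stage is only as good as the supplied descriptors; the
  package deliberately refuses to guess them.
* IC50 censoring reports a bound, not an extrapolated value — comparisons
  across censored compounds are order statements only.
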