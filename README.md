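# qmarker

Spectrum–effect quality-marker discovery for herbal products.

Pharmacopoeial quality control of complex botanicals (the motivating case
is dandelion, *Taraxacum mongolicum* / *T. officinale*) often rests on a
single marker compound chosen for measurability, not efficacy. `qmarker`
is for analysts who have, across many herb batches, (a) a chromatographic
peak-area table of identified constituents and (b) batch-level bioassay
readouts (e.g. DPPH radical scavenging, FRAP ferric reduction,
NO-production inhibition), and who want to know **which constituents drive
the activity and deserve to be quality markers**.

## The method

For each assay `y` over batches, with autoscaled peak areas `X`:

1. **Grey relational analysis** (corroboration). Deng's degree
   `GRD_i = mean_k (Δmin + ρΔmax) / (Δ_i(k) + ρΔmax)` with
   `Δ_i(k) = |x0'(k) − xi'(k)|`, ρ = 0.5, mean-normalized series.
2. **NIPALS PLS regression** (selection). Components chosen by 7-fold
   cross-validated `Q² = 1 − PRESS/TSS`; model quality reported as
   `R²Y(cum)` and `Q²(cum)`; overfitting probed by Y-permutation.
   A compound is a candidate when `VIP > 1` **and** standardized
   coefficient `> 0.1` (both strict), where
   `VIP_j = sqrt(p · Σ_a SSY_a w²_ja / Σ_a SSY_a)`.
3. **Across-assay union.** Candidates from assays probing the same
   activity (DPPH ∪ FRAP for antioxidation) are merged to cut false
   negatives.
4. **ADME admission.** A candidate is admitted as a quality marker when
   predicted gastrointestinal absorption is *high* (point-in-ellipse test
   in the TPSA/WLOGP plane) and ≥ 3 of the 5 drug-likeness rule sets
   (Lipinski, Ghose, Veber, Egan, Muegge) pass — or when its content
   exceeds 20× the median of the other constituents (the
   dominant-constituent override).

A synthetic-data generator with known ground-truth active compounds (31
batches × 22 compounds by default, activities linear in autoscaled
abundances plus Gaussian noise) makes the whole chain testable end to end.

## Worked example

```r
library(qmarker)

d <- generate_dataset(synthetic_config(seed = 42))   # paper-like scenario
res <- screen_pipeline(d$peaks, d$acts, seed = 42)
res
#> Spectrum-effect screening: 31 samples x 22 compounds, 3 assay(s)
#>   DPPH: A = 5, R2Y = 0.974, Q2 = 0.868, selected {1,2,3,5,7}
#>   FRAP: A = 2, R2Y = 0.811, Q2 = 0.586, selected {1,2,5,7}
#>   NO_inhibition: A = 2, R2Y = 0.797, Q2 = 0.581, selected {9,13,17,19,21,22}
#>   group antioxidant: union {1,2,3,5,7}
#>   group antiinflammatory: union {9,13,17,19,21,22}

attr(d$acts, "ground_truth")$active_sets$DPPH
#> [1] "1"  "3"  "5"  "7"  "18"
```

Reading: each assay line shows the chosen component count, training
`R²Y(cum)`, cross-validated `Q²(cum)` (> 0.5 indicates useful
predictivity), and the compounds passing the VIP/coefficient rule. At this
seed the antioxidant union recovers four of the five planted actives
(peak 18, the weakest, is missed; peak 2 is a false positive) — across 100
seeds the union catches ≥ 4 of 5 actives about 94% of the time.

The admission stage, on the bundled RDKit-derived descriptors for the
seven named markers (contents are an illustrative synthetic table):

```r
desc <- load_fixture("marker_descriptors")
cont <- load_fixture("marker_contents_synthetic")
druglikeness_report(desc, setNames(cont$relative_content, cont$compound_id))
#>   compound_id rules_passed ga_class content_ratio admissible override_applied
#> 1           5            3     high     4.2000000       TRUE            FALSE
#> 2           7            2      low    60.0000000       TRUE             TRUE
#> 3           8            3     high     0.6666667       TRUE            FALSE
#> 4          18            5     high     2.4000000       TRUE            FALSE
#> 5          19            5     high     0.4571429       TRUE            FALSE
#> 6          20            5     high     0.5142857       TRUE            FALSE
#> 7          21            5     high     0.4000000       TRUE            FALSE
```

Compound 7 (cichoric acid) fails on ADME grounds — a very polar diester,
low predicted absorption, 2/5 rules — but is admitted through the
high-content override (60× the median of the others).

`run_full()` wraps the chain and writes a report bundle (evidence CSV, GRD
CSV, admission CSV, JSON summary with version/seed/config-hash header, and
a per-stage log).

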