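---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaharmony)
library(data.table)
```

# The problem

Multi-laboratory DIA proteomics studies need two things before their
quantitative results can be pooled: a system-suitability gate that
keeps each LC-MS platform inside a common performance envelope, and a
peptide-to-protein roll-up whose output is comparable across sites.
`diaharmony` implements both, together with a synthetic-study
generator that provides ground truth: defined mixtures of human,
yeast and E. coli digests in which every organism's between-sample
abundance ratio is known by construction (sample A = 65/15/20% w/w
human/yeast/E. coli, sample B = 65/30/5%, hence theoretical A/B
ratios of 1, 0.5 and 4).

# Acquisition geometry

The HRMS1-DIA method quantifies on MS1 signal; MS2 scans serve
identification only. The geometry is modelled as a tiling of the
precursor range (m/z 400–1210) by 15 Da isolation windows grouped in
subcycles of 18 MS2 scans between successive MS1 scans: 54 windows,
3 subcycles, an MS1-to-MS1 period of ~1.7 s and an overall MS2 cycle
of ~5.2 s.

Two numerical choices here:

* **Half-open windows.** Intervals are `[low, high)`, so every m/z
  maps to exactly one window; boundary handling is otherwise
  undefined by the method description.
* **Floor with a guard.** `points_per_peak()` returns
  `floor(width / cycle * (1 + 1e-9))`: the guaranteed number of
  complete cycles under arbitrary clock phase. The epsilon guard
  protects exact quotients from binary-float truncation (17/1.7 must
  be 10, not 9). The real-valued `expected_points()` is exposed
  alongside, because the printed 8–11 MS1 band is the image of the
  14–20 s peak-width band under the floored quotient at 1.7 s.
* **Cycle-time reading.** The method text can be read as either
  "MS1 every 1.7 s, MS2 cycle 5.2 s" or "MS1-to-MS1 time 5.2 s". Only
  the first reading is consistent with 8–11 MS1 points across a
  17 ± 3 s peak, so the model adopts it: `ms1_cycle_time = 1.7`,
  `ms2_cycle_time = 5.2`.

# The synthetic-study generator

`simulate_study()` emits one Spectronaut-dialect report per slot of
the published acquisition schedule (days 1, 3, 5, 7: QC, A and B in
triplicate; days 2, 4, 6: single A and B bracketed by QC). Its world
is stated once, in `sim_config()`:

| parameter | default | why |
|---|---|---|
| proteins per organism | 400 / 200 / 100 | desk-scale ~1/10 of full-scale observed counts |
| peptides per protein | 1 + Poisson(4) | right-skewed, minimum one surrogate peptide |
| protein base abundance | 10^Normal(5, 0.8) | ~4 decades of dynamic range |
| peptide efficiency | ×10^Normal(0, 0.3) | peptides of one protein correlate in intensity |
| replicate noise | log-normal, CV 10% | typical label-free technical variability |
| lab effect | 2^Normal(0, 0.05) per lab × peptide | multiplicative bias that cancels in within-lab A/B ratios |
| missingness | logistic in log10 intensity (midpoint 3.0, slope 1.5) + 2% MCAR | low-abundance records vanish first |
| charge duplication | 20%, minor state at 40% share | sub-optimal precursors for the charge-selection filter |
| q-values | 99% of records below 0.01 | identification layer is upstream; only the filter's input is modelled |
| peak width | Normal(17 s, 1.5 s), truncated > 4 s | the QC reference band is 17 ± 3 s |
| iRT spike-ins | 11 fixed sequences, organism `other` | shows the filters excluding non-sample peptides |

The distributional *forms* are package choices — the source study
reports no per-peptide noise magnitudes — picked for standard-practice
realism and analytic tractability, and they are not revisited per
test. Two structural choices deserve a note:

* **Protein-level abundance with a peptide layer.** Base abundance is
  drawn per protein and peptides scatter around it (0.3 decades).
  Marginally each precursor is still log-normal; the correlation makes
  whole proteins drop out together under intensity-dependent
  missingness, which is what a sensitivity failure looks like.
* **QC runs are pure human digest** (plus iRT), mirroring the
  HeLa-digest QC standard.

What the generator does **not** emulate: retention-time drift,
interference between co-isolated precursors, cross-run normalization
artefacts, decoy/FDR mechanics beyond the q-value column, and any
spectrum-level structure. A green test therefore establishes the
correctness of the computational pipeline on data with the assumed
statistical shape — not the behaviour of any real instrument.

`inject_failure()` produces the two archetypal degradations the QC
triage must separate: `chromatographic` inflates peak widths by
`1 + 2·severity` with a mild quantity perturbation (CV `0.1·severity`);
`ms_sensitivity` leaves chromatography untouched, removes the lowest
`0.7·severity` quantile of records (thresholded on the pooled
distribution, so the loss is systematic across injections) and
attenuates the remainder.

# System suitability

`compute_qc_metrics()` evaluates six metrics from triplicate QC runs:
median LC peak width (pooled q-passing records), MS1 and MS2 points
across that median peak, mean per-injection precursor count, protein
groups identified in *every* injection, and the inter-injection
median precursor CV. Decisions that the printed criteria leave open:

* **CV uses the sample standard deviation** (n−1): triplicates,
  unbiased under normality.
* **Precursor counts are averaged per injection** rather than pooled,
  because the full-scale criterion (>48,000) is on the scale of a
  single analysis.
* **Protein counting requires presence in every injection**,
  matching per-day reporting from triplicates.
* **Bands are inclusive** (`17 ± 3 s` is the closed interval
  [14, 20]); count minima are strict (`>`), the CV bound inclusive
  (`≤`), as printed.
* CV is computed on quantities as read; upstream normalization is
  assumed already applied.

Desk-scale studies cannot reach the full-scale counts, so
`derive_qc_criteria()` rebases the two count minima on baseline QC
runs (85% of the observed baseline), keeping the physical bands
fixed. This mirrors how the published criteria were themselves
established from reference-laboratory baselines, and it is done
before — never after — a gating decision is tested.

`evaluate_qc()` triages failures: any failing metric in
{peak width, MS1 points, MS2 points} implicates chromatography; count
or CV failures with clean chromatographic metrics implicate the mass
spectrometer (the collision-cell-maintenance pattern); both groups
failing is `mixed`. Absent metrics fail conservatively.

# Peptide-to-protein roll-up

Controlled-mixture mode (`rollup_pairwise()`), per analysis group
(one laboratory × day, as the analyses were grouped):

1. keep records with q ≤ 0.01 (inclusive) and a present quantity;
2. drop peptides observed in more than one organism and all
   `organism = "other"` records (iRT, cross-organism groups);
3. per peptide, keep the single charge state with quantitative data
   in the most runs (ties: higher summed intensity, then lower
   charge — the tie-break is a package choice);
4. per peptide, count inter-sample combinations
   `|A replicates with data| × |B replicates with data|`; per
   protein, sum over its peptides; retain proteins with ≥ 8;
5. for retained proteins, estimate the A/B ratio from all pairwise
   peptide ratios.

**The "geometric median" of scalar ratios** is implemented as
`exp(median(log r))`: in one dimension the geometric median reduces
to the median, and log space treats A/B and B/A symmetrically. An
even-length median averages the two central log-ratios. Because the
term could also be read as the geometric *mean*, the estimator is
pluggable (`central_ratio(..., "geometric_mean")`); the median is the
default for its 50% breakdown robustness, which the test suite
exercises directly.

Tissue mode (`sum_rollup()`), per site × patient: after the same
filters, a protein is retained when its peptides contribute at least
3 observations across the patient's triplicate; abundance per
replicate is the summed peptide intensity, per patient the mean
across replicates, and `log2fc_vs_mean()` expresses each sample
relative to the protein's mean across all samples. Moderated
differential testing is deliberately out of scope — the package stops
at the log2 matrix such tools consume.

# Performance scoring

`performance_summary()` reproduces the evaluation logic:
percent deviation `100·|r − t|/t` of each retained ratio from the
organism's theoretical ratio (reference bands: 10% for human and
yeast, 20% for E. coli), inter-day CV of per-day ratio estimates
(sample sd over typically 4 evaluation days; replicate-level CV is a
separate output of the QC layer), per-lab completeness
(intersection/union over days), cross-lab co-quantification and the
everyday-everywhere core set. Deviation is reported both per
(lab, day) row and as per-(lab, organism) medians; Spearman
correlations use average ranks for ties, and cross-site agreement is
summarised as mean ± sd over site pairs (the ± could equally be taken
over patients; both aggregations are available from the pair table).

# Degenerate inputs and tolerances

* Ratio estimation refuses non-positive or non-finite ratios.
* `interday_cv()` and the cross-site correlation return `NA` rather
  than a number when fewer than 2 estimates (or a constant vector)
  are available.
* Round-trip I/O is asserted to 1e-9 relative on quantities; the
  writer emits plain decimal notation at 15 significant digits.
* Missing-quantity spellings accepted on input: empty, `NaN`, `NA`,
  `Filtered`, `#N/A`. Decimal separator is `.` only — no locale
  guessing.
* Study configuration is JSON (no YAML parser is assumed at run
  time).

# Known limitations

* The generator's noise magnitudes are plausible defaults, not fits
  to any laboratory; absolute identification counts at desk scale are
  ~1/10 of full scale by design.
* Protein groups are taken as given strings; no parsimony
  re-grouping.
* No retention-time modelling, no interference correction, no
  normalization — all assumed applied upstream by the search engine.
* The acquisition-gating helper reports which days pass; scheduling
  substitute days (e.g. day 9 standing in for a failed day 7) is the
  caller's decision, applied by filtering the manifest.

# A worked example

```{r example, eval = FALSE}
st <- simulate_study(sim = sim_config(seed = 1),
                     labs = c("Lab01", "Lab02"), days = c(1, 3, 5, 7))
tbl <- study_table(st$reports)
proteins <- rollup_pairwise(tbl)
summary <- performance_summary(proteins)
summary$median_deviation
summary$per_lab
```
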