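# diaharmony

Benchmarking label-free quantification for multi-laboratory
**HRMS1-DIA** proteomics: synthetic controlled-sample studies with
known ground truth, LC-MS system-suitability gating, and
ratio-based peptide-to-protein roll-up.

## The problem

When many laboratories acquire DIA data on nominally identical
platforms, two questions decide whether their quantitative results can
be pooled:

1. **Is each platform inside a common performance envelope?** A QC
   standard (a HeLa digest) is run in triplicate and scored against
   six system-suitability metrics — median LC peak width (17 ± 3 s),
   MS1/MS2 data points across the peak (8–11 / 3–4), precursor and
   protein identifications at 1% FDR, and the inter-injection median
   precursor CV (≤ 15%). Failures are triaged as *chromatographic*
   (peak-shape metrics out of band) or *mass-spectrometric* (counts or
   CV low with clean chromatography), which points at the root cause.
2. **Does the roll-up recover known abundance changes?** Controlled
   samples are defined mixtures of three organisms' digests
   (A = 65% human / 15% yeast / 20% E. coli; B = 65% / 30% / 5%),
   so every organism's A/B protein ratio is known: 1, 0.5 and 4.

## The core statistic

Within one laboratory × day analysis group, after filtering at
q ≤ 0.01, removing peptides shared between organisms, and keeping the
best-covered charge state per peptide, each peptide contributes all
inter-sample pairings with data on both sides
(`|A present| × |B present|` combinations). A protein with at least
**8** combinations over its peptides is considered reliably
quantifiable, and its A/B ratio is the **geometric median of the
peptide pairwise ratios**:

    r̂ = exp( median{ log(q_a / q_b) : peptide p, run a ∈ A, run b ∈ B } )

For positive scalars the geometric median reduces to the log-space
median, which gives the estimator a 50% breakdown point — corrupting
fewer than half of a protein's pairwise ratios cannot drag the
estimate outside the span of the clean ones. Performance is scored as
the percent deviation `100·|r̂ − t|/t` from the theoretical ratio *t*,
plus inter-day CV, per-lab completeness, and cross-lab
co-quantification.

All of this is testable without any acquisition: `simulate_study()`
generates multi-lab, multi-day studies with log-normal abundances,
multiplicative replicate noise, per-lab biases, intensity-dependent
missingness, charge-state duplication and iRT spike-ins — and returns
the ground truth alongside.

## Worked example

```r
library(diaharmony)

st  <- simulate_study(sim = sim_config(seed = 1), labs = "Lab01", days = c(1, 3))
tbl <- study_table(st$reports)

## QC gate on day 1
qc   <- st$reports[vapply(st$reports, \(r) r$sample == "QC" && r$day == 1, logical(1))]
crit <- derive_qc_criteria(qc)         # rebases count minima at desk scale
compute_qc_metrics(qc)
#> <qc_metrics>
#>   median peak width : 17.02 s
#>   MS1 / MS2 points  : 10 / 3
#>   precursors (mean) : 2133.7
#>   protein groups    : 401
#>   median CV         : 7.923%  (3 injections)
evaluate_qc(compute_qc_metrics(qc), crit)
#> <qc_verdict> PASS (triage: ok)

## roll-up and scoring
proteins <- rollup_pairwise(tbl)
ps <- performance_summary(proteins)
ps$median_deviation
#>       lab organism median_dev     n
#> 1:  Lab01    ecoli   3.614627   161
#> 2:  Lab01    human   2.960770   773
#> 3:  Lab01    yeast   3.112910   369
ps$per_lab
#>       lab total average complete completeness
#> 1:  Lab01   667   651.5      636    0.9535232
```

The QC standard passes all six criteria (peak width 17 s gives the
expected 10 MS1 and 3 MS2 sampling points). Across the two evaluation
days the roll-up retains ~650 proteins per day with 95% complete
profiles, and the median deviation from the known mixture ratios is
~3% for every organism — well inside the 10% (human/yeast) and 20%
(E. coli) reference bands.

## Command line

A thin CLI wraps the main entry points:

```sh
Rscript inst/cli/diaharmony.R simulate --out study/ --seed 3 --labs LabA,LabB
Rscript inst/cli/diaharmony.R qc      --manifest study/manifest.tsv --out qc.tsv
Rscript inst/cli/diaharmony.R rollup  --manifest study/manifest.tsv --out proteins.tsv
Rscript inst/cli/diaharmony.R evaluate --proteins proteins.tsv --out summary/
Rscript inst/cli/diaharmony.R method describe
```

See `vignettes/diaharmony-methods.Rmd` for the model, the generator's
stated world, numerical choices and limitations.
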