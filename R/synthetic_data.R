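## Synthetic multi-laboratory DIA studies with known ground truth.
##
## The generator emulates the statistical structure the downstream
## analysis assumes: per-protein log-normal abundances with per-peptide
## ionisation efficiencies, the fixed mixture fractions of the two
## controlled samples, multiplicative replicate noise, per-lab peptide
## biases, intensity-dependent (logistic MNAR) + completely-at-random
## missingness, charge-state duplication, a q-value mixture, iRT
## spike-ins and per-precursor chromatographic peak widths.

IRT_SEQUENCES <- c(
  "LGGNEQVTR", "GAGSSEPVTGLDAK", "VEATFGVDESNAK", "YILAGVENSK",
  "TPVISGGPYEYR", "TPVITGAPYEYR", "DGLDAASYYAPVR", "ADVTPADFSEWSK",
  "GTFIIDPGGVIR", "GTFIIDPAAVIR", "LFLQFGAQGSPFLK")

#' Simulation configuration
#'
#' Defaults are desk-scale stand-ins (roughly 1/10 of the protein
#' counts observed at full scale) chosen so the whole pipeline runs in
#' seconds while preserving the study's statistical shape.
#'
#' @param n_proteins Named integer vector: proteins per organism
#'   (default human 400, yeast 200, ecoli 100).
#' @param peptide_lambda Peptides per protein are `1 + Poisson(lambda)`
#'   (default lambda 4).
#' @param log10_mean,log10_sd Protein base abundance is
#'   `10^Normal(log10_mean, log10_sd)` (defaults 5 and 0.8).
#' @param peptide_log10_sd Per-peptide ionisation-efficiency spread on
#'   the log10 scale (default 0.3), multiplying the protein base.
#' @param noise_cv Fractional CV of multiplicative log-normal replicate
#'   noise (default 0.10).
#' @param lab_effect_sd SD of the per-lab per-peptide log2 bias
#'   (default 0.05); cancels in within-lab A/B ratios.
#' @param missingness List `(midpoint, slope, mcar)` of the logistic
#'   missing-not-at-random model on log10 intensity plus a
#'   completely-at-random rate, or `NULL` for no missingness. Default
#'   midpoint 3.0, slope 1.5, mcar 0.02.
#' @param charge_dup_prob Probability a peptide is observed at two
#'   charge states (default 0.2); the minor charge carries 40% of the
#'   major's intensity and independent noise.
#' @param qvalue_pass_rate Fraction of emitted records whose q-value
#'   falls below `fdr_q` (default 0.99).
#' @param fdr_q FDR threshold the q-value mixture is anchored to
#'   (default 0.01).
#' @param peak_width_mean,peak_width_sd,peak_width_min Per-record LC
#'   peak width: Normal(17 s, 1.5 s) truncated above `peak_width_min`
#'   (4 s).
#' @param irt Emit the 11 iRT spike-in precursors (organism `"other"`)
#'   in every run (default TRUE).
#' @param seed Integer seed; identical config + seed gives identical
#'   output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = c(human = 400, yeast = 200, ecoli = 100),
                       peptide_lambda = 4,
                       log10_mean = 5, log10_sd = 0.8,
                       peptide_log10_sd = 0.3,
                       noise_cv = 0.10,
                       lab_effect_sd = 0.05,
                       missingness = list(midpoint = 3.0, slope = 1.5,
                                          mcar = 0.02),
                       charge_dup_prob = 0.2,
                       qvalue_pass_rate = 0.99,
                       fdr_q = 0.01,
                       peak_width_mean = 17, peak_width_sd = 1.5,
                       peak_width_min = 4,
                       irt = TRUE,
                       seed = NULL) {
  if (is.null(names(n_proteins)) || any(!names(n_proteins) %in% organism_levels()))
    dh_stop("n_proteins must be named by organism", "config_error")
  if (any(n_proteins < 1))
    dh_stop("zero proteins requested for an organism", "config_error")
  probs <- c(charge_dup_prob, qvalue_pass_rate)
  if (any(probs < 0 | probs > 1))
    dh_stop("probabilities must lie in [0, 1]", "config_error")
  if (noise_cv < 0 || lab_effect_sd < 0)
    dh_stop("noise_cv and lab_effect_sd must be >= 0", "config_error")
  if (!is.null(missingness)) {
    stopifnot(all(c("midpoint", "slope", "mcar") %in% names(missingness)))
    if (missingness$mcar < 0 || missingness$mcar > 1)
      dh_stop("mcar rate must lie in [0, 1]", "config_error")
  }
  structure(as.list(environment()), class = "sim_config")
}

random_sequences <- function(n, min_len = 8, max_len = 16) {
  aa <- strsplit("ACDEFGHIKLMNPQSTVWY", "")[[1]]
  gen <- function(m) {
    len <- sample(min_len:max_len, m, replace = TRUE)
    body <- vapply(len, function(l)
      paste(sample(aa, l - 1L, replace = TRUE), collapse = ""), character(1))
    paste0(body, sample(c("K", "R"), m, replace = TRUE))  # tryptic termini
  }
  out <- gen(n)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- gen(length(dup))
  }
  out
}

## Build the precursor-level "library" of a study: one row per
## precursor with its expected intensity share.
build_precursors <- function(sim) {
  tag <- c(human = "HUM", yeast = "YEA", ecoli = "ECO")
  prot <- data.table::rbindlist(lapply(names(sim$n_proteins), function(org) {
    n <- sim$n_proteins[[org]]
    data.table::data.table(
      protein_group = sprintf("P%05d_%s", seq_len(n), tag[[org]]),
      organism = org)
  }))
  prot[, base := 10^rnorm(.N, sim$log10_mean, sim$log10_sd)]
  n_pep <- 1L + rpois(nrow(prot), sim$peptide_lambda)
  pep <- prot[rep(seq_len(.N), n_pep)]
  pep[, stripped_sequence := random_sequences(.N)]
  pep[, peptide_id := stripped_sequence]
  ## peptide intensity = protein abundance x ionisation efficiency
  pep[, base := base * 10^rnorm(.N, 0, sim$peptide_log10_sd)]
  ## charge-state duplication: major charge always, minor at 40% share
  dup <- rbinom(nrow(pep), 1L, sim$charge_dup_prob) == 1L
  major <- data.table::copy(pep)[, charge := sample(c(2L, 3L), .N, replace = TRUE,
                                                    prob = c(0.7, 0.3))]
  minor <- pep[dup][, charge := 5L]  # placeholder, fixed below
  minor[, charge := ifelse(major$charge[dup] == 2L, 3L, 2L)]
  minor[, base := base * 0.4]
  prec <- data.table::rbindlist(list(major, minor))
  if (isTRUE(sim$irt)) {
    irt <- data.table::data.table(
      protein_group = "Biognosys|iRT-Kit_WR_fusion", organism = "other",
      base = 10^rnorm(length(IRT_SEQUENCES), sim$log10_mean, 0.2),
      stripped_sequence = IRT_SEQUENCES, peptide_id = IRT_SEQUENCES,
      charge = 2L)
    prec <- data.table::rbindlist(list(prec, irt), use.names = TRUE)
  }
  prec[, precursor_id := paste0("_", stripped_sequence, "_.", charge)]
  data.table::setcolorder(prec, c("precursor_id", "stripped_sequence",
                                  "charge", "protein_group", "organism",
                                  "base"))
  prec[]
}

## Expand precursors over a manifest and apply the noise / missingness
## / q-value machinery.  `frac_fun(sample, organism)` gives the
## expected composition fraction of each record.
generate_runs <- function(prec, manifest, sim, frac_fun) {
  labs <- unique(manifest$lab)
  ## per-lab per-peptide log2 bias, shared by both charge states
  peps <- unique(prec$peptide_id)
  bias <- data.table::CJ(lab = labs, peptide_id = peps)
  bias[, log2_bias := if (sim$lab_effect_sd > 0)
    rnorm(.N, 0, sim$lab_effect_sd) else 0]

  reports <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    mrow <- manifest[i]
    rec <- data.table::copy(prec)
    rec[, frac := frac_fun(mrow$sample, organism)]
    rec <- rec[frac > 0]
    rec[, log2_bias := 0]
    rec[bias[lab == mrow$lab], log2_bias := i.log2_bias, on = "peptide_id"]
    rec[, true_quantity := base * frac * 2^log2_bias]
    sdlog <- sqrt(log(1 + sim$noise_cv^2))
    noise_f <- if (sim$noise_cv > 0)
      exp(rnorm(nrow(rec), -sdlog^2 / 2, sdlog)) else 1
    rec[, quantity := true_quantity * noise_f]
    if (!is.null(sim$missingness)) {
      ms <- sim$missingness
      p1 <- plogis(ms$slope * (ms$midpoint - log10(rec$true_quantity)))
      p <- 1 - (1 - p1) * (1 - ms$mcar)
      rec[runif(.N) < p, quantity := NA_real_]
    }
    passed <- runif(nrow(rec)) < sim$qvalue_pass_rate
    rec[, q_value := ifelse(passed, runif(.N) * sim$fdr_q,
                            sim$fdr_q + runif(.N) * (1 - sim$fdr_q))]
    rec[, peak_width := pmax(rnorm(.N, sim$peak_width_mean,
                                   sim$peak_width_sd),
                             sim$peak_width_min + 0.01)]
    reports[[i]] <- run_report(
      mrow$run_id, mrow$lab, mrow$day, mrow$sample, mrow$replicate,
      rec[, .(precursor_id, stripped_sequence, charge, protein_group,
              organism, q_value, quantity, peak_width)])
  }
  reports
}

## bias join above is belt-and-braces; keep a simpler internal used in
## tests to cross-check would be overkill -- the join is exercised by
## the ratio-conservation property.

#' Simulate a multi-laboratory controlled-sample study
#'
#' Generates one run per manifest slot following the published
#' schedule: QC-standard runs contain human (plus iRT) precursors only;
#' sample A and B runs scale each organism's peptides by the design's
#' weight fractions. Peptide quantity is
#' `base x fraction x 2^lab_bias x log-normal noise`; records removed
#' by the missingness model keep their row with absent quantity;
#' q-values are drawn so that `qvalue_pass_rate` of records pass
#' `fdr_q`.
#'
#' @param design A [study_design()].
#' @param sim A [sim_config()].
#' @param labs,days Laboratory ids and acquisition days used to build
#'   the default schedule (ignored when `manifest` is given).
#' @param manifest Optional explicit manifest ([default_manifest()]).
#' @return List with `reports` (list of `run_report`), `truth`
#'   (`ground_truth`: per-protein true abundance per sample and the
#'   peptide-level bases) and `manifest`.
#' @examples
#' st <- simulate_study(sim = sim_config(
#'   n_proteins = c(human = 5, yeast = 3, ecoli = 2), seed = 1),
#'   labs = "Lab01", days = 1)
#' length(st$reports)
#' @export
simulate_study <- function(design = study_design(),
                           sim = sim_config(),
                           labs = "Lab01", days = c(1L, 3L, 5L, 7L),
                           manifest = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(sim, "sim_config"))
  if (!is.null(sim$seed)) set.seed(sim$seed)
  manifest <- manifest %||% default_manifest(labs, days)
  prec <- build_precursors(sim)

  comp_A <- design$composition_A
  comp_B <- design$composition_B
  frac_fun <- function(sample_role, organism) {
    if (sample_role == "QC") {
      ## QC standard is a pure human digest (+ iRT spike-ins)
      ifelse(organism == "human" | organism == "other", 1, 0)
    } else {
      comp <- if (sample_role == "A") comp_A else comp_B
      out <- comp[organism]
      out[organism == "other"] <- 1  # iRT added to both samples alike
      unname(ifelse(is.na(out), 0, out))
    }
  }
  reports <- generate_runs(prec, manifest, sim, frac_fun)

  ## peptide-level base = the major charge state's share
  pep_truth <- prec[organism != "other",
                    .(base = max(base)),
                    by = .(peptide_id, protein_group, organism)]
  prot <- pep_truth[, .(base = sum(base)), by = .(protein_group, organism)]
  prot[, `:=`(
    abundance_A = base * ifelse(is.na(comp_A[organism]), 0, comp_A[organism]),
    abundance_B = base * ifelse(is.na(comp_B[organism]), 0, comp_B[organism]))]
  truth <- structure(list(proteins = prot[, .(protein_group, organism,
                                              abundance_A, abundance_B)],
                          peptides = pep_truth, design = design),
                     class = "ground_truth")
  list(reports = reports, truth = truth, manifest = manifest)
}

#' Degrade runs with a controlled failure mode
#'
#' Two archetypal failure modes seen in multi-site operation:
#' `"chromatographic"` (degraded separations: peak widths inflated by
#' `1 + 2*severity`, quantities mildly perturbed) and
#' `"ms_sensitivity"` (detector/collision-cell loss: peak widths
#' untouched, the lowest-intensity fraction of records removed and the
#' rest attenuated). The QC triage distinguishes the two.
#'
#' @param reports List of `run_report`.
#' @param mode `"chromatographic"` or `"ms_sensitivity"`.
#' @param severity Degradation severity in `[0, 1]`; 0 is a no-op.
#' @return List of degraded `run_report`s.
#' @export
inject_failure <- function(reports, mode = c("chromatographic",
                                             "ms_sensitivity"),
                           severity) {
  if (!length(reports)) dh_stop("no reports to degrade", "invalid_parameter")
  mode <- match.arg(mode)
  if (!is.numeric(severity) || severity < 0 || severity > 1)
    dh_stop("severity must lie in [0, 1]", "invalid_parameter")
  if (severity == 0) return(reports)

  if (mode == "ms_sensitivity") {
    ## pooled threshold so the same low-abundance precursors vanish
    ## from every injection (sensitivity loss is systematic, not random)
    pooled <- unlist(lapply(reports, function(r) r$records$quantity))
    thr <- quantile(pooled, probs = min(0.7 * severity, 0.99),
                    na.rm = TRUE, names = FALSE)
  }
  lapply(reports, function(r) {
    rec <- data.table::copy(r$records)
    if (mode == "chromatographic") {
      rec[, peak_width := peak_width * (1 + 2 * severity)]
      cv <- 0.1 * severity
      sdlog <- sqrt(log(1 + cv^2))
      rec[!is.na(quantity),
          quantity := quantity * exp(rnorm(.N, -sdlog^2 / 2, sdlog))]
    } else {
      rec[!is.na(quantity) & quantity < thr, quantity := NA_real_]
      rec[!is.na(quantity), quantity := quantity * (1 - 0.5 * severity)]
    }
    run_report(r$run_id, r$lab, r$day, r$sample, r$replicate, rec)
  })
}

#' Simulate a multi-site tissue cohort
#'
#' Two labeled histotype groups of patients, each analysed in three
#' technical replicates at every site. A designated subset of
#' "signature" proteins carries the stated log2 fold-change between
#' groups; all other proteins differ only by noise. All proteins are
#' human.
#'
#' @param n_patients_per_histotype Patients per group (>= 1).
#' @param n_signature_proteins Number of proteins carrying the effect.
#' @param effect_log2fc Log2 fold-change (group 2 over group 1) on the
#'   signature proteins.
#' @param sim A [sim_config()]; only the human protein count is used.
#' @param sites Character vector of analytical site ids.
#' @param n_replicates Technical replicates per patient per site
#'   (default 3).
#' @return List with `reports`, `truth` (adds `signature`, a character
#'   vector of signature protein groups, and `histotype`, a named
#'   vector patient -> group) and `manifest`.
#' @export
simulate_tissue_cohort <- function(n_patients_per_histotype,
                                   n_signature_proteins,
                                   effect_log2fc,
                                   sim = sim_config(),
                                   sites = c("Lab02", "Lab05", "Lab09"),
                                   n_replicates = 3L) {
  stopifnot(inherits(sim, "sim_config"))
  if (n_patients_per_histotype < 1)
    dh_stop("need at least one patient per histotype", "config_error")
  if (!is.null(sim$seed)) set.seed(sim$seed)
  sim$n_proteins <- sim$n_proteins["human"]
  prec <- build_precursors(sim)
  prots <- unique(prec[organism == "human", protein_group])
  if (n_signature_proteins > length(prots))
    dh_stop("more signature proteins than simulated proteins", "config_error")
  signature <- head(prots, n_signature_proteins)

  groups <- c("HGSOC", "OCCC")
  patients <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", g, seq_len(n_patients_per_histotype))))
  histotype <- stats::setNames(rep(groups, each = n_patients_per_histotype),
                               patients)
  mf <- data.table::CJ(lab = sites, patient = patients,
                       replicate = seq_len(n_replicates))
  mf[, `:=`(sample = paste0("tissue:", patient), day = 1L)]
  mf[, run_id := sprintf("%s_%s_r%d", lab, patient, replicate)]
  manifest <- mf[, .(run_id, lab, day, sample, replicate)]

  fc <- 2^effect_log2fc
  ## the histotype effect is applied by pre-scaling a patient-specific
  ## copy of the peptide library: exact and reproducible
  reports <- vector("list", nrow(manifest))
  done <- 0L
  for (pat in patients) {
    sub_mf <- manifest[sample == paste0("tissue:", pat)]
    prec_p <- data.table::copy(prec)
    if (histotype[[pat]] == "OCCC")
      prec_p[protein_group %in% signature, base := base * fc]
    reps <- generate_runs(prec_p, sub_mf, sim,
                          function(s, org) rep(1, length(org)))
    reports[done + seq_along(reps)] <- reps
    done <- done + length(reps)
  }
  ord <- match(manifest$run_id, vapply(reports, `[[`, "", "run_id"))
  reports <- reports[ord]

  pep_truth <- prec[organism != "other", .(base = max(base)),
                    by = .(peptide_id, protein_group, organism)]
  prot <- pep_truth[, .(base = sum(base)), by = .(protein_group, organism)]
  truth <- structure(list(proteins = prot, peptides = pep_truth,
                          signature = signature, histotype = histotype),
                     class = "ground_truth")
  list(reports = reports, truth = truth, manifest = manifest)
}

#' Write a simulated study to disk
#'
#' Writes `manifest.tsv`, one Spectronaut-dialect TSV per run and
#' `ground_truth.tsv` under `dir`.
#'
#' @param study Result of [simulate_study()] or
#'   [simulate_tissue_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mf <- data.table::copy(study$manifest)
  mf[, file := paste0(run_id, ".tsv")]  # relative to the manifest
  data.table::fwrite(mf, file.path(dir, "manifest.tsv"), sep = "\t")
  for (r in study$reports)
    write_report(r, file.path(dir, paste0(r$run_id, ".tsv")))
  data.table::fwrite(study$truth$proteins, file.path(dir, "ground_truth.tsv"),
                     sep = "\t")
  invisible(dir)
}
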