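## Peptide-to-protein quantification.
##
## Controlled-mixture mode: q-filter -> removal of peptides shared by
## different organisms -> best-charge selection -> inter-sample
## combination counting with the >= 8 retention rule -> geometric
## median of peptide pairwise ratios.
## Tissue mode: summed peptide intensities with a minimum of 3
## observations across a patient's replicates.

#' Filter records at an FDR threshold
#'
#' Keeps records with `q_value <= fdr_q` (inclusive, matching a 1% FDR
#' criterion keeping q <= 0.01) and a present quantity.
#'
#' @param records Records table (or long [study_table()]).
#' @param fdr_q FDR threshold in (0, 1).
#' @return Filtered table.
#' @export
filter_q <- function(records, fdr_q = 0.01) {
  if (fdr_q <= 0 || fdr_q >= 1)
    dh_stop("fdr_q must lie in (0, 1)", "invalid_parameter")
  rec <- data.table::as.data.table(records)
  rec[q_value <= fdr_q & !is.na(quantity)]
}

#' Remove peptides shared by different organisms
#'
#' Drops every stripped sequence observed with more than one distinct
#' organism anywhere in the table, and all records with organism
#' `"other"` (iRT spike-ins and cross-organism protein groups).
#'
#' @param records Records table with organisms assigned.
#' @return Filtered table.
#' @export
remove_shared_peptides <- function(records) {
  rec <- data.table::as.data.table(records)
  if (!nrow(rec)) return(rec)
  shared <- rec[, .(n = data.table::uniqueN(organism)),
                by = stripped_sequence][n > 1L, stripped_sequence]
  rec[!stripped_sequence %in% shared & organism != "other"]
}

#' Keep the best-covered charge state per peptide
#'
#' Among a peptide's charge states, keeps exactly the one with
#' quantitative data in the greatest number of runs of the analysis
#' group (ties: higher total summed quantity, then lower charge). The
#' kept precursor's quantities become the peptide's quantities.
#'
#' @param records q-filtered records within one analysis group (long
#'   table with `run_id`).
#' @return Peptide matrix: long table with one retained charge state
#'   per `stripped_sequence`.
#' @export
select_best_charge <- function(records) {
  rec <- data.table::as.data.table(records)
  if (!nrow(rec)) return(rec)
  stats <- rec[!is.na(quantity),
               .(n_runs = data.table::uniqueN(run_id),
                 total_q = sum(quantity)),
               by = .(stripped_sequence, charge)]
  data.table::setorder(stats, stripped_sequence, -n_runs, -total_q, charge)
  keep <- stats[!duplicated(stripped_sequence),
                .(stripped_sequence, keep_charge = charge)]
  rec[keep, on = "stripped_sequence", nomatch = NULL][charge == keep_charge][
    , keep_charge := NULL][]
}

#' Inter-sample combination count of one peptide
#'
#' The number of (sample A replicate, sample B replicate) pairings in
#' which the peptide has quantitative data in both members:
#' `|A present| x |B present|`.
#'
#' @param quantities_A,quantities_B Peptide quantities across the A and
#'   B replicates (NA = absent).
#' @return Integer combination count.
#' @examples
#' count_combinations(c(1, 2, 3), c(4, 5, 6))  # 9
#' count_combinations(c(1, 2, NA), c(4, NA, NA))  # 2
#' @export
count_combinations <- function(quantities_A, quantities_B) {
  sum(!is.na(quantities_A)) * sum(!is.na(quantities_B))
}

#' All peptide pairwise A/B ratios of an analysis group
#'
#' Expands every peptide of the matrix into all available inter-sample
#' pairings; the number of rows per peptide equals its combination
#' count.
#'
#' @param matrix Peptide matrix ([select_best_charge()]) whose `sample`
#'   column partitions runs into `"A"` and `"B"`.
#' @return data.table: `stripped_sequence`, `protein_group`,
#'   `organism`, `run_A`, `run_B`, `ratio` (= quantity_A / quantity_B).
#' @export
pairwise_ratios <- function(matrix) {
  mat <- data.table::as.data.table(matrix)
  a <- mat[sample == "A" & !is.na(quantity),
           .(stripped_sequence, protein_group, organism,
             run_A = run_id, q_A = quantity)]
  b <- mat[sample == "B" & !is.na(quantity),
           .(stripped_sequence, run_B = run_id, q_B = quantity)]
  pr <- merge(a, b, by = "stripped_sequence", allow.cartesian = TRUE)
  pr[, ratio := q_A / q_B][]
}

#' Central ratio estimators
#'
#' The geometric median of positive scalars reduces to the ordinary
#' median in log space, so `"log_median"` returns
#' `exp(median(log(r)))` (even-length medians average the two central
#' log-ratios). `"geometric_mean"` (`exp(mean(log(r)))`) is provided
#' as the alternative reading of "geometric median".
#'
#' @param r Positive ratios.
#' @param estimator `"log_median"` (default) or `"geometric_mean"`.
#' @return Scalar central ratio.
#' @examples
#' central_ratio(c(2, 2, 8))                    # 2
#' central_ratio(c(2, 2, 8), "geometric_mean")  # ~3.17
#' @export
central_ratio <- function(r, estimator = c("log_median", "geometric_mean")) {
  estimator <- match.arg(estimator)
  if (!length(r) || any(r <= 0) || any(!is.finite(r)))
    dh_stop("ratios must be positive and finite", "invalid_parameter")
  switch(estimator,
         log_median = exp(median(log(r))),
         geometric_mean = exp(mean(log(r))))
}

#' Protein A/B ratio from peptide pairwise ratios
#'
#' @param matrix Peptide matrix of one analysis group.
#' @param protein The protein group string.
#' @inheritParams central_ratio
#' @return Scalar ratio (A over B).
#' @export
pairwise_ratio <- function(matrix, protein,
                           estimator = c("log_median", "geometric_mean")) {
  pr <- pairwise_ratios(data.table::as.data.table(matrix)[
    protein_group == protein])
  if (!nrow(pr))
    dh_stop(sprintf("no inter-sample pairings for %s", protein),
            "internal_consistency")
  central_ratio(pr$ratio, estimator)
}

#' Protein retention by combination count
#'
#' A protein's combination count is the sum over its surrogate
#' peptides of their inter-sample combination counts; proteins are
#' considered reliably quantifiable when at least `threshold` (default
#' 8) combinations are available.
#'
#' @param matrix Peptide matrix of one analysis group.
#' @param threshold Minimum combination count (default 8).
#' @return data.table per protein: `protein_group`, `organism`,
#'   `n_peptides`, `n_combinations`, `retained`.
#' @export
retain_proteins <- function(matrix, threshold = 8L) {
  mat <- data.table::as.data.table(matrix)
  pep <- unique(mat[, .(stripped_sequence, protein_group, organism)])
  pr <- pairwise_ratios(mat)
  nc <- pr[, .(n_comb = .N), by = stripped_sequence]
  pep[, n_comb := 0L]
  pep[nc, n_comb := i.n_comb, on = "stripped_sequence"]
  out <- pep[, .(n_peptides = .N, n_combinations = sum(n_comb)),
             by = .(protein_group, organism)]
  out[, retained := n_combinations >= threshold][]
}

#' Pairwise-ratio protein roll-up over a controlled-sample study
#'
#' Runs the full quantification pipeline within each analysis group
#' (by default one group per laboratory and day, as the analyses were
#' grouped): FDR filter, shared-peptide removal, charge-state
#' selection, combination counting with the retention rule, and the
#' central pairwise-ratio estimate for retained proteins.
#'
#' @param tbl Long [study_table()] of the sample A and B runs (QC runs
#'   are ignored).
#' @param fdr_q FDR threshold (default 0.01).
#' @param threshold Minimum protein combination count (default 8).
#' @inheritParams central_ratio
#' @param by Grouping columns defining an analysis group (default
#'   `c("lab", "day")`).
#' @return data.table per group and protein: grouping columns,
#'   `protein_group`, `organism`, `n_peptides`, `n_combinations`,
#'   `retained`, `ratio_AB` (NA when not retained).
#' @export
rollup_pairwise <- function(tbl, fdr_q = 0.01, threshold = 8L,
                            estimator = c("log_median", "geometric_mean"),
                            by = c("lab", "day")) {
  estimator <- match.arg(estimator)
  tbl <- data.table::as.data.table(tbl)[sample %in% c("A", "B")]
  if (!nrow(tbl)) return(data.table::data.table())
  groups <- unique(tbl[, by, with = FALSE])
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- tbl[groups[i], on = by]
    mat <- select_best_charge(remove_shared_peptides(filter_q(g, fdr_q)))
    prot <- retain_proteins(mat, threshold)
    pr <- pairwise_ratios(mat)
    est <- pr[, .(ratio_AB = central_ratio(ratio, estimator)),
              by = protein_group]
    prot[, ratio_AB := NA_real_]
    prot[est, ratio_AB := ifelse(retained, i.ratio_AB, NA_real_),
         on = "protein_group"]
    out[[i]] <- cbind(groups[i], prot)
  }
  data.table::rbindlist(out)
}

#' Summed-intensity roll-up for tissue cohorts
#'
#' For each analysis group (by default one per site and patient): after
#' FDR filtering, shared-peptide removal and charge selection, a
#' protein is retained when the total number of peptide observations
#' across the group's replicates is at least `min_obs` (default 3). Its
#' abundance per replicate is the sum of peptide intensities, and the
#' per-patient abundance the mean across replicates.
#'
#' @param tbl Long [study_table()] of tissue runs (`sample` =
#'   `"tissue:<patient>"`).
#' @param fdr_q FDR threshold (default 0.01).
#' @param min_obs Minimum total peptide observations (default 3).
#' @param by Grouping columns (default `c("lab", "patient")`; a
#'   `patient` column is derived from `sample` if absent).
#' @return data.table per group and protein: grouping columns,
#'   `protein_group`, `organism`, `n_peptides`, `n_obs`, `retained`,
#'   `abundance` (mean of per-replicate summed intensities; NA when
#'   not retained).
#' @export
sum_rollup <- function(tbl, fdr_q = 0.01, min_obs = 3L,
                       by = c("lab", "patient")) {
  tbl <- data.table::as.data.table(tbl)
  if ("patient" %in% by && !"patient" %in% names(tbl))
    tbl[, patient := sub("^tissue:", "", sample)]
  groups <- unique(tbl[, by, with = FALSE])
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- tbl[groups[i], on = by]
    mat <- select_best_charge(remove_shared_peptides(filter_q(g, fdr_q)))
    if (!nrow(mat)) { out[[i]] <- NULL; next }
    prot <- mat[, .(n_peptides = data.table::uniqueN(stripped_sequence),
                    n_obs = sum(!is.na(quantity))),
                by = .(protein_group, organism)]
    per_rep <- mat[!is.na(quantity),
                   .(abundance = sum(quantity)),
                   by = .(protein_group, run_id)]
    per_prot <- per_rep[, .(abundance = mean(abundance)), by = protein_group]
    prot[, retained := n_obs >= min_obs]
    prot[, abundance := NA_real_]
    prot[per_prot, abundance := ifelse(retained, i.abundance, NA_real_),
         on = "protein_group"]
    out[[i]] <- cbind(groups[i], prot)
  }
  data.table::rbindlist(out)
}

#' Log2 fold-change relative to the per-protein mean abundance
#'
#' Adds `log2fc = log2(abundance / mean abundance of the protein
#' across all samples)` to a [sum_rollup()] result (retained rows
#' only).
#'
#' @param sum_result Output of [sum_rollup()].
#' @return Copy with a `log2fc` column.
#' @export
log2fc_vs_mean <- function(sum_result) {
  dt <- data.table::as.data.table(sum_result)[retained == TRUE &
                                                !is.na(abundance)]
  dt[, log2fc := log2(abundance / mean(abundance)), by = protein_group]
  dt[]
}
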