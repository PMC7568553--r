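## Quantitative-performance scoring: deviation from theoretical
## mixture ratios, inter-day CV, co-quantification / completeness
## across laboratories, cross-site rank correlation and signature RSD.

#' Percent deviation from a theoretical ratio
#'
#' `100 * |ratio - theoretical| / theoretical`. Reference bands at
#' full scale: below 10% for human and yeast, below 20% for E. coli.
#'
#' @param ratio Measured ratio(s), positive.
#' @param theoretical Theoretical ratio(s), positive.
#' @return Percent deviation (vectorised).
#' @examples
#' deviation_from_theoretical(3.2, 4)  # 20
#' @export
deviation_from_theoretical <- function(ratio, theoretical) {
  if (any(!is.finite(ratio)) || any(ratio <= 0) ||
      any(!is.finite(theoretical)) || any(theoretical <= 0))
    dh_stop("ratios must be positive and finite", "invalid_parameter")
  100 * abs(ratio - theoretical) / theoretical
}

#' Inter-day coefficient of variation of a protein's ratio
#'
#' `100 * sample sd / mean` over per-day ratio estimates (typically the
#' four evaluation days of one laboratory).
#'
#' @param ratios Numeric vector of day-level estimates.
#' @return Percent CV, or NA when fewer than 2 estimates.
#' @export
interday_cv <- function(ratios) {
  r <- ratios[is.finite(ratios)]
  if (length(r) < 2L) return(NA_real_)
  100 * sd(r) / mean(r)
}

#' Co-quantification and completeness across laboratories and days
#'
#' From the per-(lab, day) sets of quantified proteins computes, per
#' laboratory: `total` (union over days), `average` (mean per-day
#' count), `complete` (intersection over days -- proteins with a
#' complete profile) and `completeness = complete / total`; plus the
#' pairwise cross-laboratory intersection sizes (on each lab's total
#' set) and the core set quantified by every laboratory on every day.
#'
#' @param retained_sets data.table/data.frame with columns `lab`,
#'   `day`, `protein_group`: one row per quantified protein per
#'   laboratory-day.
#' @return List: `per_lab` (data.table lab/total/average/complete/
#'   completeness), `cross_lab` (data.table lab1/lab2/n_shared),
#'   `core` (character vector), `per_lab_day` (data.table of counts).
#' @export
co_quantification <- function(retained_sets) {
  dt <- unique(data.table::as.data.table(retained_sets)[
    , .(lab, day, protein_group)])
  if (!nrow(dt)) dh_stop("no quantified proteins", "invalid_parameter")
  per_lab_day <- dt[, .(n_quantified = .N), by = .(lab, day)]

  per_lab <- dt[, {
    days <- unique(day)
    sets <- lapply(days, function(d) protein_group[day == d])
    comp <- Reduce(intersect, sets)
    tot <- unique(protein_group)
    .(total = length(tot),
      average = mean(lengths(sets)),
      complete = length(comp),
      completeness = length(comp) / length(tot))
  }, by = lab]

  lab_sets <- lapply(split(dt$protein_group, dt$lab), unique)
  labs <- names(lab_sets)
  cross <- if (length(labs) >= 2L) {
    cmb <- utils::combn(labs, 2L)
    data.table::data.table(
      lab1 = cmb[1, ], lab2 = cmb[2, ],
      n_shared = apply(cmb, 2L, function(p)
        length(intersect(lab_sets[[p[1]]], lab_sets[[p[2]]]))))
  } else data.table::data.table(lab1 = character(), lab2 = character(),
                                n_shared = integer())

  complete_sets <- dt[, .(set = list(Reduce(intersect,
    split(protein_group, day)))), by = lab]$set
  core <- Reduce(intersect, complete_sets)

  list(per_lab = per_lab, cross_lab = cross, core = core,
       per_lab_day = per_lab_day)
}

#' Cross-site Spearman correlation of protein abundances
#'
#' Rank correlation (ties: average ranks) for every pair of sites on
#' their co-quantified proteins, with the mean and sd across pairs.
#'
#' @param abundances Numeric matrix, proteins x sites (log2 or raw;
#'   rank correlation is scale-free). NA = not quantified at that site.
#' @param min_shared Minimum co-quantified proteins per pair
#'   (default 3).
#' @return List: `pairs` (data.table site1/site2/rho/n), `mean_rho`,
#'   `sd_rho`.
#' @export
cross_site_correlation <- function(abundances, min_shared = 3L) {
  m <- as.matrix(abundances)
  if (is.null(colnames(m))) colnames(m) <- paste0("site", seq_len(ncol(m)))
  if (ncol(m) < 2L) dh_stop("need at least 2 sites", "invalid_parameter")
  cmb <- utils::combn(colnames(m), 2L)
  rows <- apply(cmb, 2L, function(p) {
    x <- m[, p[1]]; y <- m[, p[2]]
    ok <- is.finite(x) & is.finite(y)
    rho <- if (sum(ok) >= min_shared && sd(x[ok]) > 0 && sd(y[ok]) > 0)
      cor(x[ok], y[ok], method = "spearman") else NA_real_
    list(site1 = p[1], site2 = p[2], rho = rho, n = sum(ok))
  })
  pairs <- data.table::rbindlist(rows)
  rho <- pairs$rho[is.finite(pairs$rho)]
  list(pairs = pairs,
       mean_rho = if (length(rho)) mean(rho) else NA_real_,
       sd_rho = if (length(rho) >= 2L) sd(rho) else NA_real_)
}

#' Cross-site RSD of signature-protein abundances
#'
#' For each (protein, patient): `RSD = 100 * sd / mean` of the summed
#' abundances across sites; summarised as the mean RSD with its
#' standard error over all (protein, patient) pairs.
#'
#' @param abundances data.table/data.frame with columns
#'   `protein_group`, `patient`, `site` (or `lab`), `abundance`.
#' @return List: `values` (data.table protein_group/patient/rsd),
#'   `mean_rsd`, `se_rsd`.
#' @export
signature_rsd <- function(abundances) {
  dt <- data.table::as.data.table(abundances)
  if (!"site" %in% names(dt) && "lab" %in% names(dt))
    data.table::setnames(dt, "lab", "site")
  vals <- dt[is.finite(abundance),
             .(rsd = if (.N >= 2L) 100 * sd(abundance) / mean(abundance)
               else NA_real_),
             by = .(protein_group, patient)][is.finite(rsd)]
  if (!nrow(vals)) dh_stop("need >= 2 sites per protein/patient",
                           "invalid_parameter")
  list(values = vals,
       mean_rsd = mean(vals$rsd),
       se_rsd = if (nrow(vals) >= 2L) sd(vals$rsd) / sqrt(nrow(vals))
                else NA_real_)
}

#' Performance summary of a controlled-sample roll-up
#'
#' Scores a [rollup_pairwise()] result against the study design:
#' per-(lab, day, organism) quantified counts, percent deviation of
#' every retained ratio from the organism's theoretical ratio with
#' per-(lab, organism) medians, inter-day CV per protein with
#' per-(lab, organism) medians, and the co-quantification /
#' completeness summary.
#'
#' @param proteins Output of [rollup_pairwise()].
#' @param design The [study_design()] supplying theoretical ratios.
#' @return List of data.tables: `deviations` (per retained row),
#'   `median_deviation` (per lab x organism), `interday`
#'   (per lab x protein), `median_cv` (per lab x organism),
#'   `n_quantified` (per lab x day x organism), plus the
#'   [co_quantification()] fields.
#' @export
performance_summary <- function(proteins, design = study_design()) {
  dt <- data.table::as.data.table(proteins)[retained == TRUE &
                                              is.finite(ratio_AB)]
  if (!nrow(dt)) dh_stop("no retained proteins", "invalid_parameter")
  theo <- theoretical_ratio(design)
  dt[, theoretical := theo[organism]]
  dt[, deviation_pct := deviation_from_theoretical(ratio_AB, theoretical)]

  median_deviation <- dt[, .(median_dev = median(deviation_pct), n = .N),
                         by = .(lab, organism)]
  n_quantified <- dt[, .(n_quantified = .N), by = .(lab, day, organism)]

  interday <- dt[, .(cv = interday_cv(ratio_AB), n_days = .N),
                 by = .(lab, protein_group, organism)]
  median_cv <- interday[is.finite(cv),
                        .(median_cv = median(cv), n = .N),
                        by = .(lab, organism)]

  cq <- co_quantification(dt[, .(lab, day, protein_group)])
  c(list(deviations = dt[], median_deviation = median_deviation,
         interday = interday, median_cv = median_cv,
         n_quantified = n_quantified), cq)
}
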