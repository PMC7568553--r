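## Spectronaut-dialect report I/O, run manifests and study designs.
##
## A "records" table is a data.table with one row per quantified
## precursor: precursor_id, stripped_sequence, charge, protein_group,
## organism, q_value, quantity, peak_width.  quantity and peak_width
## may be NA (absent); q_value is always in [0, 1].

REPORT_COLUMNS <- c(
  "EG.PrecursorId", "PG.ProteinAccessions", "PG.ProteinDescriptions",
  "EG.Qvalue", "PEP.Quantity", "PG.Quantity", "PG.FastaFiles",
  "PG.ProteinGroups"
)
MANDATORY_COLUMNS <- c("EG.PrecursorId", "PG.ProteinAccessions",
                       "EG.Qvalue", "PEP.Quantity")

#' Default fasta-file substring patterns for organism inference
#'
#' Matched case-insensitively against the `PG.FastaFiles` field; a field
#' matching zero or more than one organism yields `"other"`.
#'
#' @return Named character vector (names: human, yeast, ecoli).
#' @export
default_organism_patterns <- function() {
  c(human = "sapiens", yeast = "cerevisiae", ecoli = "coli")
}

#' Split precursor ids into stripped sequence and charge
#'
#' Precursor ids follow the `MODIFIED_SEQUENCE.CHARGE` convention, e.g.
#' `"PEPT[+80]IDER.2"`. The stripped sequence removes bracketed
#' modification annotations and surrounding underscores.
#'
#' @param ids Character vector of precursor ids.
#' @return data.table with columns `stripped_sequence` and `charge`.
#' @export
parse_precursor_id <- function(ids) {
  m <- regmatches(ids, regexpr("\\.[0-9]+$", ids))
  if (length(m) != length(ids) || any(!grepl("\\.[0-9]+$", ids)))
    dh_stop("precursor id without terminal .CHARGE suffix", "format_error")
  charge <- as.integer(sub("^\\.", "", m))
  seqs <- sub("\\.[0-9]+$", "", ids)
  stripped <- gsub("\\[[^]]*\\]|_", "", seqs)
  data.table::data.table(stripped_sequence = stripped, charge = charge)
}

infer_organism <- function(fasta_files, accessions,
                           patterns = default_organism_patterns(),
                           accession_map = NULL) {
  n <- length(fasta_files)
  out <- rep("other", n)
  ## order matters for substring overlap ("coli" is a substring hazard
  ## only if patterns are chosen carelessly; hits are counted per
  ## organism so a multi-organism match stays "other")
  hit <- vapply(names(patterns), function(org) {
    grepl(patterns[[org]], fasta_files, ignore.case = TRUE)
  }, logical(n))
  if (n == 1L) hit <- matrix(hit, nrow = 1L, dimnames = list(NULL, names(patterns)))
  nhit <- rowSums(hit)
  one <- which(nhit == 1L)
  if (length(one))
    out[one] <- names(patterns)[apply(hit[one, , drop = FALSE], 1L, which)]
  ## fall back to an accession -> organism map where the fasta field
  ## was uninformative (empty / unmatched)
  if (!is.null(accession_map)) {
    need <- which(nhit == 0L)
    for (i in need) {
      accs <- strsplit(accessions[i], ";", fixed = TRUE)[[1]]
      orgs <- unique(stats::na.omit(accession_map[accs]))
      if (length(orgs) == 1L) out[i] <- orgs
    }
  }
  out
}

parse_quantity <- function(x) {
  ## Spectronaut dialects encode missing quantities as empty cells,
  ## "NaN" or "Filtered"; all map to NA.  Decimal separator is "." only.
  x <- trimws(as.character(x))
  x[x %in% c("", "NaN", "NA", "Filtered", "#N/A")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Construct a run report
#'
#' @param run_id Unique run identifier.
#' @param lab Laboratory identifier.
#' @param day Acquisition day (integer >= 1).
#' @param sample Sample role: `"QC"`, `"A"`, `"B"` or `"tissue:<patient>"`.
#' @param replicate Technical replicate number (integer >= 1).
#' @param records data.table of precursor records (see [read_report()]).
#' @return Object of class `run_report`.
#' @export
run_report <- function(run_id, lab, day, sample, replicate, records) {
  records <- data.table::as.data.table(records)
  validate_records(records)
  if (anyDuplicated(records$precursor_id))
    dh_stop("duplicate precursor_id within one run", "format_error")
  structure(list(run_id = as.character(run_id), lab = as.character(lab),
                 day = as.integer(day), sample = as.character(sample),
                 replicate = as.integer(replicate), records = records),
            class = "run_report")
}

validate_records <- function(records) {
  need <- c("precursor_id", "stripped_sequence", "charge", "protein_group",
            "organism", "q_value", "quantity", "peak_width")
  miss <- setdiff(need, names(records))
  if (length(miss))
    dh_stop(paste("records missing column(s):", paste(miss, collapse = ", ")),
            "format_error")
  if (any(records$q_value < 0 | records$q_value > 1, na.rm = TRUE))
    dh_stop("q_value outside [0, 1]", "format_error")
  if (any(records$quantity <= 0, na.rm = TRUE))
    dh_stop("non-positive quantity", "format_error")
  invisible(records)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s: lab %s day %d sample %s rep %d, %d records\n",
              x$run_id, x$lab, x$day, x$sample, x$replicate, nrow(x$records)))
  invisible(x)
}

#' Read a Spectronaut-dialect precursor report
#'
#' Parses a TSV export carrying at least `EG.PrecursorId`,
#' `PG.ProteinAccessions`, `EG.Qvalue` and `PEP.Quantity`. Organism is
#' inferred from `PG.FastaFiles` substring patterns, falling back to an
#' accession map, else `"other"`. Unparseable quantities become absent
#' (NA). Duplicate precursor ids collapse to the row with the lowest
#' q-value (with a message). Filtering (e.g. at 1% FDR) is *not*
#' applied here; see [filter_q()].
#'
#' @param path TSV file path.
#' @param manifest_entry List or one-row data.frame with `run_id`,
#'   `lab`, `day`, `sample`, `replicate`.
#' @param organism_patterns Named patterns, see
#'   [default_organism_patterns()].
#' @param accession_map Optional named character vector mapping
#'   accession to organism.
#' @param peak_width_col Column carrying per-precursor chromatographic
#'   peak widths in seconds (an extension of the dialect; default
#'   `"EG.PeakWidth"`, absent columns give NA widths).
#' @return A `run_report`.
#' @export
read_report <- function(path, manifest_entry,
                        organism_patterns = default_organism_patterns(),
                        accession_map = NULL,
                        peak_width_col = "EG.PeakWidth") {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character",
                          header = TRUE)
  miss <- setdiff(MANDATORY_COLUMNS, names(dt))
  if (length(miss))
    dh_stop(paste("report missing mandatory column(s):",
                  paste(miss, collapse = ", ")), "format_error")
  if (nrow(dt) == 0L) {
    warning("empty report: ", path, call. = FALSE)
    rec <- empty_records()
  } else {
    parsed <- parse_precursor_id(dt[["EG.PrecursorId"]])
    fasta <- if ("PG.FastaFiles" %in% names(dt)) dt[["PG.FastaFiles"]]
             else rep("", nrow(dt))
    rec <- data.table::data.table(
      precursor_id = dt[["EG.PrecursorId"]],
      stripped_sequence = parsed$stripped_sequence,
      charge = parsed$charge,
      protein_group = dt[["PG.ProteinAccessions"]],
      organism = infer_organism(fasta, dt[["PG.ProteinAccessions"]],
                                organism_patterns, accession_map),
      q_value = suppressWarnings(as.numeric(dt[["EG.Qvalue"]])),
      quantity = parse_quantity(dt[["PEP.Quantity"]]),
      peak_width = if (peak_width_col %in% names(dt))
        parse_quantity(dt[[peak_width_col]]) else NA_real_
    )
    if (anyDuplicated(rec$precursor_id)) {
      n0 <- nrow(rec)
      rec <- rec[order(q_value)][!duplicated(precursor_id)]
      data.table::setorder(rec, precursor_id)
      message(sprintf("collapsed %d duplicate precursor row(s) in %s",
                      n0 - nrow(rec), basename(path)))
    }
  }
  run_report(manifest_entry$run_id, manifest_entry$lab, manifest_entry$day,
             manifest_entry$sample, manifest_entry$replicate, rec)
}

empty_records <- function() {
  data.table::data.table(
    precursor_id = character(), stripped_sequence = character(),
    charge = integer(), protein_group = character(), organism = character(),
    q_value = numeric(), quantity = numeric(), peak_width = numeric())
}

#' Write a run report as a Spectronaut-dialect TSV
#'
#' Emits the verbatim column names of the dialect; reading the file back
#' with [read_report()] reproduces the report up to column order.
#'
#' @param report A `run_report`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  rec <- report$records
  fasta_of <- c(human = "uniprot_sapiens.fasta",
                yeast = "uniprot_cerevisiae.fasta",
                ecoli = "uniprot_ecoli_k12.fasta",
                other = "contaminants_irt.fasta")
  out <- data.table::data.table(
    "EG.PrecursorId" = rec$precursor_id,
    "PG.ProteinAccessions" = rec$protein_group,
    "PG.ProteinDescriptions" = "",
    "EG.Qvalue" = format_num(rec$q_value),
    "PEP.Quantity" = format_num(rec$quantity),
    "PG.Quantity" = "",
    "PG.FastaFiles" = fasta_of[rec$organism],
    "PG.ProteinGroups" = rec$protein_group,
    "EG.PeakWidth" = format_num(rec$peak_width)
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "",
                     eol = "\n")
  invisible(path)
}

format_num <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE),
    character(1))
  out
}

#' Read a run manifest
#'
#' A manifest is a TSV/CSV with columns `run_id`, `lab`, `day`,
#' `sample`, `replicate` and optionally `file` (path of the per-run
#' report). The key `(lab, day, sample, replicate)` must be unique.
#'
#' @param path Manifest file path.
#' @return data.table of validated run metadata.
#' @export
read_manifest <- function(path) {
  mf <- data.table::fread(path, header = TRUE)
  validate_manifest(mf)
}

validate_manifest <- function(mf) {
  mf <- data.table::as.data.table(mf)
  if (nrow(mf) == 0L) return(mf)
  need <- c("run_id", "lab", "day", "sample", "replicate")
  miss <- setdiff(need, names(mf))
  if (length(miss))
    dh_stop(paste("manifest missing column(s):", paste(miss, collapse = ", ")),
            "manifest_error")
  key <- mf[, paste(lab, day, sample, replicate)]
  if (anyDuplicated(key))
    dh_stop(paste("duplicate manifest key:", key[duplicated(key)][1]),
            "manifest_error")
  mf[, day := as.integer(day)][, replicate := as.integer(replicate)]
  mf[]
}

#' Default acquisition schedule manifest
#'
#' The published 7-day schedule per laboratory: on days 1, 3, 5 and 7
#' the QC standard and both controlled samples are each run in
#' triplicate; on days 2, 4 and 6 samples A and B are run once each and
#' the QC standard once before and after.
#'
#' @param labs Character vector of laboratory ids.
#' @param days Integer vector of acquisition days (default 1:7).
#' @return Manifest data.table (`run_id`, `lab`, `day`, `sample`,
#'   `replicate`).
#' @export
default_manifest <- function(labs = "Lab01", days = 1:7) {
  rows <- list()
  for (lb in labs) for (d in days) {
    if (d %% 2L == 1L) {
      sch <- data.table::CJ(sample = c("QC", "A", "B"), replicate = 1:3)
    } else {
      sch <- data.table::data.table(
        sample = c("QC", "A", "B", "QC"), replicate = c(1L, 1L, 1L, 2L))
    }
    sch[, `:=`(lab = lb, day = as.integer(d))]
    rows[[length(rows) + 1L]] <- sch
  }
  mf <- data.table::rbindlist(rows)
  mf[, run_id := sprintf("%s_d%d_%s_r%d", lab, day, sample, replicate)]
  data.table::setcolorder(mf, c("run_id", "lab", "day", "sample", "replicate"))
  validate_manifest(mf)
}

#' Controlled-sample study design
#'
#' Encodes the w/w composition of the two controlled mixtures. The
#' default is the published design: Sample A = 65% human / 15% yeast /
#' 20% E. coli; Sample B = 65% / 30% / 5%, giving theoretical A/B
#' ratios of 1.0 (human), 0.5 (yeast) and 4.0 (E. coli).
#'
#' @param composition_A,composition_B Named numeric vectors of weight
#'   fractions per organism; each must sum to 1 (tolerance 1e-9).
#' @param qc_criteria A `qc_criteria` object ([qc_criteria()]).
#' @return Object of class `study_design`.
#' @export
study_design <- function(
    composition_A = c(human = 0.65, yeast = 0.15, ecoli = 0.20),
    composition_B = c(human = 0.65, yeast = 0.30, ecoli = 0.05),
    qc_criteria = NULL) {
  for (comp in list(composition_A, composition_B)) {
    if (is.null(names(comp)) || any(!names(comp) %in% organism_levels()))
      dh_stop("compositions must be named by organism", "invalid_parameter")
    if (abs(sum(comp) - 1) > 1e-9)
      dh_stop("composition fractions must sum to 1", "invalid_parameter")
    if (any(comp < 0))
      dh_stop("negative composition fraction", "invalid_parameter")
  }
  structure(list(composition_A = composition_A,
                 composition_B = composition_B,
                 qc_criteria = qc_criteria),
            class = "study_design")
}

#' Theoretical A/B abundance ratio per organism
#'
#' @param design A `study_design`.
#' @param organism Organism name(s); default: all organisms in the
#'   design.
#' @return Named numeric vector of `fraction_A / fraction_B`.
#' @examples
#' theoretical_ratio(study_design())  # human 1, yeast 0.5, ecoli 4
#' @export
theoretical_ratio <- function(design, organism = NULL) {
  stopifnot(inherits(design, "study_design"))
  orgs <- organism %||% names(design$composition_A)
  out <- design$composition_A[orgs] / design$composition_B[orgs]
  names(out) <- orgs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten run reports into one long study table
#'
#' Binds the records of all reports, annotated with run metadata
#' columns (`run_id`, `lab`, `day`, `sample`, `replicate`). Most
#' roll-up and QC functions consume this shape.
#'
#' @param reports List of `run_report` objects.
#' @return Long data.table.
#' @export
study_table <- function(reports) {
  if (inherits(reports, "run_report")) reports <- list(reports)
  data.table::rbindlist(lapply(reports, function(r) {
    rec <- data.table::copy(r$records)
    rec[, `:=`(run_id = r$run_id, lab = r$lab, day = r$day,
               sample = r$sample, replicate = r$replicate)]
    rec
  }))
}

#' Read a study configuration (JSON)
#'
#' A study config bundles the mixture design, QC criteria, DIA method
#' parameters and simulation settings. JSON is the supported format.
#'
#' @param path JSON file path.
#' @return List with any of `design` (`study_design`), `qc_criteria`
#'   (`qc_criteria`), `dia_method` (`dia_method`), `sim` (`sim_config`).
#' @export
read_study_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(cfg$design))
    out$design <- study_design(unlist(cfg$design$composition_A),
                               unlist(cfg$design$composition_B))
  if (!is.null(cfg$qc_criteria))
    out$qc_criteria <- do.call(qc_criteria, as.list(cfg$qc_criteria))
  if (!is.null(cfg$dia_method))
    out$dia_method <- do.call(build_window_scheme, as.list(cfg$dia_method))
  if (!is.null(cfg$sim))
    out$sim <- do.call(sim_config, as.list(cfg$sim))
  out
}
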