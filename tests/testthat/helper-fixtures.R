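library(data.table)

## one precursor record row
rec_row <- function(seq, charge = 2L, protein = paste0("P_", seq),
                    organism = "human", q = 0.001, quantity = 100,
                    peak_width = 17) {
  data.table(
    precursor_id = paste0(seq, ".", charge),
    stripped_sequence = seq, charge = as.integer(charge),
    protein_group = protein, organism = organism,
    q_value = q, quantity = quantity, peak_width = peak_width)
}

make_run <- function(run_id, records, lab = "L1", day = 1L, sample = "A",
                     replicate = 1L) {
  run_report(run_id, lab, day, sample, replicate, records)
}

## long study table built from per-run quantity vectors of one or more
## peptides: quants is a named list peptide -> list(A = c(...), B = c(...))
## with NA meaning absent; all peptides share one protein per organism
## unless protein is given per peptide.
make_group_table <- function(quants, organism = "human", protein = NULL,
                             charge = 2L) {
  rows <- list()
  for (pep in names(quants)) {
    prot <- if (is.null(protein)) paste0("PROT_", organism) else protein[[pep]]
    for (smp in c("A", "B")) {
      qs <- quants[[pep]][[smp]]
      for (i in seq_along(qs)) {
        if (is.na(qs[i])) next
        r <- rec_row(pep, charge = charge, protein = prot,
                     organism = organism, quantity = qs[i])
        r[, `:=`(run_id = paste0(smp, i), lab = "L1", day = 1L,
                 sample = smp, replicate = as.integer(i))]
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  rbindlist(rows)
}

## random records for round-trip tests
random_records <- function(n, seed = 1) {
  set.seed(seed)
  seqs <- replicate(n, paste(sample(LETTERS[1:20], 9, TRUE), collapse = ""))
  data.table(
    precursor_id = paste0(seqs, ".", sample(2:4, n, TRUE)),
    stripped_sequence = seqs,
    charge = NA_integer_,
    protein_group = sprintf("Q%05d", sample(1e4, n)),
    organism = sample(c("human", "yeast", "ecoli"), n, TRUE),
    q_value = runif(n, 0, 0.05),
    quantity = ifelse(runif(n) < 0.1, NA_real_, 10^runif(n, 2, 7)),
    peak_width = rnorm(n, 17, 2)
  )[, charge := as.integer(sub(".*\\.", "", precursor_id))][]
}

## independent brute-force oracle for the pairwise roll-up of one
## protein: nested loops over peptides and replicate pairings
oracle_rollup <- function(quants) {
  logs <- c(); n_comb <- 0L
  for (pep in names(quants)) {
    A <- quants[[pep]]$A; B <- quants[[pep]]$B
    for (a in A[!is.na(A)]) for (b in B[!is.na(B)]) {
      logs <- c(logs, log(a / b)); n_comb <- n_comb + 1L
    }
  }
  list(n_combinations = n_comb,
       ratio = if (n_comb > 0) exp(median(logs)) else NA_real_)
}

qc_triplicate <- function(quant_sets, peak_width = 17, seqs = NULL) {
  ## quant_sets: list of per-injection quantity vectors (same length)
  n <- length(quant_sets[[1]])
  seqs <- seqs %||% sprintf("PEPTIDE%03d", seq_len(n))
  lapply(seq_along(quant_sets), function(i) {
    rec <- rbindlist(lapply(seq_len(n), function(j)
      rec_row(seqs[j], protein = sprintf("PR%03d", j),
              quantity = quant_sets[[i]][j], peak_width = peak_width)))
    make_run(paste0("QC", i), rec, sample = "QC", replicate = i)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
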