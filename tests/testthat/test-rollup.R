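test_that("filter_q keeps q <= threshold with present quantity", {
  rec <- rbind(rec_row("AK", q = 0.005), rec_row("CK", q = 0.01),
               rec_row("DK", q = 0.011), rec_row("EK", q = 0.001,
                                                 quantity = NA))
  kept <- filter_q(rec, 0.01)
  expect_equal(kept$stripped_sequence, c("AK", "CK"))  # inclusive bound
  expect_equal(nrow(filter_q(rec[0], 0.01)), 0L)
  all_pass <- rbind(rec_row("AK"), rec_row("CK"))
  expect_equal(nrow(filter_q(all_pass, 0.01)), 2L)
  expect_error(filter_q(rec, 0), class = "invalid_parameter")
})

test_that("shared peptides and 'other' records are removed", {
  rec <- rbind(
    rec_row("SHAREDK", organism = "human"),
    rec_row("SHAREDK", charge = 3, organism = "yeast"),
    rec_row("HUMK", organism = "human"),
    rec_row("YEAK", organism = "yeast"),
    rec_row("IRTK", organism = "other"))
  kept <- remove_shared_peptides(rec)
  expect_setequal(kept$stripped_sequence, c("HUMK", "YEAK"))
  ## disjoint organisms -> identity
  dis <- rbind(rec_row("AK", organism = "human"),
               rec_row("BK", organism = "ecoli"))
  expect_equal(nrow(remove_shared_peptides(dis)), 2L)
})

test_that("best-charge selection counts runs with data, with tie-breaks", {
  mk <- function(seq, charge, runs, quants) {
    data.table::rbindlist(lapply(seq_along(runs), function(i) {
      r <- rec_row(seq, charge = charge, quantity = quants[i])
      r[, run_id := runs[i]]
      r
    }))
  }
  runs6 <- paste0("r", 1:6)
  ## charge 2 present in 6/6 runs, charge 3 in 4/6 -> charge 2 kept
  rec <- rbind(mk("PEPK", 2, runs6, rep(10, 6)),
               mk("PEPK", 3, runs6[1:4], rep(99, 4)))
  out <- select_best_charge(rec)
  expect_equal(unique(out$charge), 2L)
  expect_equal(nrow(out), 6L)

  ## single charge state -> kept
  single <- mk("ONEK", 3, runs6[1:2], c(5, 6))
  expect_equal(nrow(select_best_charge(single)), 2L)

  ## tie on run count -> higher summed quantity wins
  tie <- rbind(mk("TIEK", 2, runs6[1:5], rep(1, 5)),
               mk("TIEK", 3, runs6[1:5], rep(100, 5)))
  expect_equal(unique(select_best_charge(tie)$charge), 3L)
  ## still tied -> lower charge
  tie2 <- rbind(mk("TIEK", 4, runs6[1:5], rep(7, 5)),
                mk("TIEK", 3, runs6[1:5], rep(7, 5)))
  expect_equal(unique(select_best_charge(tie2)$charge), 3L)
})

test_that("combination counting follows |A present| x |B present|", {
  expect_equal(count_combinations(c(1, 2, 3), c(4, 5, 6)), 9L)
  expect_equal(count_combinations(c(1, 2, NA), c(4, NA, NA)), 2L)
  expect_equal(count_combinations(c(NA, NA, NA), c(1, 2, 3)), 0L)
})

test_that("protein retention sums peptide combinations against >= 8", {
  ## one peptide with 9 combinations (3x3) -> retained
  t1 <- make_group_table(list(PEPAK = list(A = c(1, 2, 3), B = c(4, 5, 6))))
  r1 <- retain_proteins(select_best_charge(t1))
  expect_equal(r1$n_combinations, 9L)
  expect_true(r1$retained)

  ## two peptides with 4 + 3 = 7 -> not retained
  t2 <- make_group_table(list(
    PEPAK = list(A = c(1, 2), B = c(4, 5)),        # 4
    PEPCK = list(A = c(1, 2, 3), B = c(4, NA, NA)) # 3
  ))
  r2 <- retain_proteins(select_best_charge(t2))
  expect_equal(r2$n_combinations, 7L)
  expect_false(r2$retained)

  ## threshold monotonicity: lowering threshold never shrinks retention
  r_lo <- retain_proteins(select_best_charge(t2), threshold = 4L)
  expect_true(all(r2[r_lo, on = "protein_group"]$retained <= r_lo$retained))
})

test_that("pairwise ratio is the log-space median over all pairings", {
  ## all peptide quantities equal in A and B -> ratio 1
  eq <- make_group_table(list(PEPAK = list(A = c(7, 7, 7), B = c(7, 7, 7))))
  expect_equal(pairwise_ratio(select_best_charge(eq), "PROT_human"), 1.0)

  ## ratios {2, 2, 8}: log-median 2, geometric mean 32^(1/3)
  expect_equal(central_ratio(c(2, 2, 8)), 2.0)
  expect_equal(central_ratio(c(2, 2, 8), "geometric_mean"), 32^(1/3),
               tolerance = 1e-12)
  expect_error(central_ratio(c(1, -1)), class = "invalid_parameter")

  ## no pairings despite request -> consistency error
  a_only <- make_group_table(list(PEPAK = list(A = c(1, 2), B = c(NA, NA))))
  expect_error(pairwise_ratio(select_best_charge(a_only), "PROT_human"),
               class = "internal_consistency")
})

test_that("roll-up agrees with exhaustive enumeration (oracle)", {
  set.seed(424242)
  for (rep in 1:20) {
    n_pep <- sample(1:5, 1)
    quants <- stats::setNames(lapply(seq_len(n_pep), function(i) {
      nA <- sample(1:3, 1); nB <- sample(1:3, 1)
      A <- 10^runif(3, 1, 4); B <- 10^runif(3, 1, 4)
      A[sample(3, 3 - nA)] <- NA; B[sample(3, 3 - nB)] <- NA
      list(A = A, B = B)
    }), paste0("PEP", LETTERS[seq_len(n_pep)], "K"))
    tbl <- make_group_table(quants)
    mat <- select_best_charge(filter_q(tbl))
    got <- retain_proteins(mat, threshold = 1L)
    want <- oracle_rollup(quants)
    expect_equal(got$n_combinations, want$n_combinations)
    if (want$n_combinations > 0)
      expect_equal(pairwise_ratio(mat, "PROT_human"), want$ratio,
                   tolerance = 1e-12)
  }
})

test_that("ratio estimator is equivariant and robust", {
  quants <- list(PEPAK = list(A = c(100, 120, 90), B = c(50, 55, 60)),
                 PEPCK = list(A = c(10, 12, 9), B = c(5, 6, 5)))
  mat <- select_best_charge(make_group_table(quants))
  r0 <- pairwise_ratio(mat, "PROT_human")
  scaled <- data.table::copy(mat)[sample == "A", quantity := quantity * 7]
  expect_equal(pairwise_ratio(scaled, "PROT_human"), 7 * r0,
               tolerance = 1e-12)

  ## median breakdown: corrupting < 50% of pairwise ratios by a large
  ## factor keeps the estimate within the uncorrupted span
  set.seed(99)
  r <- exp(rnorm(21, log(2), 0.1))
  span <- range(r)
  corrupt <- r
  corrupt[1:9] <- corrupt[1:9] * 1e4  # 9/21 < 50%
  est <- central_ratio(corrupt)
  expect_gte(est, span[1])
  expect_lte(est, span[2] * 1.0001)
})

test_that("grouped roll-up recovers design ratios on simulated data", {
  sz <- sim_config(n_proteins = c(human = 20, yeast = 15, ecoli = 10),
                   noise_cv = 0, lab_effect_sd = 0, missingness = NULL,
                   seed = 55)
  st <- simulate_study(sim = sz, labs = c("L1", "L2"), days = 1)
  ru <- rollup_pairwise(study_table(st$reports))
  theo <- theoretical_ratio(study_design())
  ret <- ru[retained == TRUE]
  expect_gt(nrow(ret), 0)
  expect_true(all(abs(ret$ratio_AB - theo[ret$organism]) < 1e-9))
  ## group columns preserved
  expect_setequal(unique(ret$lab), c("L1", "L2"))

  ## default-noise convergence: median per organism near design ratio
  sn <- sim_config(n_proteins = c(human = 40, yeast = 30, ecoli = 20),
                   seed = 56)
  st2 <- simulate_study(sim = sn, labs = "L1", days = 1)
  ru2 <- rollup_pairwise(study_table(st2$reports))
  med <- ru2[retained == TRUE, .(m = median(ratio_AB)), by = organism]
  expect_true(all(abs(med$m / theo[med$organism] - 1) < 0.10))
})

test_that("sum roll-up applies the minimum-observation rule", {
  ## 1 peptide seen in 3/3 replicates -> retained (3 >= 3)
  mk_tissue <- function(quants) {
    tbl <- make_group_table(quants)
    tbl[sample == "A", sample := "tissue:PT1"]
    tbl[sample == "B", sample := "tissue:PT2"]
    tbl
  }
  t1 <- mk_tissue(list(PEPAK = list(A = c(10, 10, 10), B = c(NA, NA, NA))))
  s1 <- sum_rollup(t1)
  expect_true(s1[patient == "PT1", retained])
  expect_equal(s1[patient == "PT1", abundance], 10)

  ## 2 peptides seen once each -> 2 observations < 3 -> dropped
  t2 <- mk_tissue(list(PEPAK = list(A = c(10, NA, NA), B = c(NA, NA, NA)),
                       PEPCK = list(A = c(20, NA, NA), B = c(NA, NA, NA))))
  s2 <- sum_rollup(t2)
  expect_false(s2[patient == "PT1", retained])
  expect_true(is.na(s2[patient == "PT1", abundance]))

  ## abundance = per-replicate peptide sum, averaged across replicates
  t3 <- mk_tissue(list(PEPAK = list(A = c(10, 20, 30), B = c(NA, NA, NA)),
                       PEPCK = list(A = c(1, 2, 3), B = c(NA, NA, NA))))
  s3 <- sum_rollup(t3)
  expect_equal(s3[patient == "PT1", abundance], mean(c(11, 22, 33)))

  ## identical samples -> all log2 fold-changes zero
  t4 <- mk_tissue(list(PEPAK = list(A = c(5, 5, 5), B = c(5, 5, 5))))
  fc <- log2fc_vs_mean(sum_rollup(t4))
  expect_true(all(abs(fc$log2fc) < 1e-12))
})
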