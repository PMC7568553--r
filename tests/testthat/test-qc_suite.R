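test_that("qc metrics: peak width, sampling points, counts and CV", {
  ## three injections where one precursor has quantities (100, 110, 90):
  ## sample sd 10, mean 100 -> CV 10.0%
  qc <- qc_triplicate(list(c(100, 50, 10), c(110, 50, 10), c(90, 50, 10)))
  m <- compute_qc_metrics(qc)
  expect_equal(m$median_peak_width, 17)
  expect_equal(m$ms1_points, 10L)   # floor(17 / 1.7)
  expect_equal(m$ms2_points, 3L)    # floor(17 / 5.2)
  expect_equal(m$n_precursors, 3)
  expect_equal(m$n_proteins, 3L)
  expect_equal(m$median_precursor_cv, 0)  # two of three precursors constant

  one_var <- compute_qc_metrics(qc_triplicate(
    list(c(100), c(110), c(90))))
  expect_equal(one_var$median_precursor_cv, 10.0, tolerance = 1e-9)

  ## identical injections -> zero CV
  same <- qc_triplicate(list(c(5, 6), c(5, 6), c(5, 6)))
  expect_equal(compute_qc_metrics(same)$median_precursor_cv, 0)

  ## all q-failing records -> degenerate-input error naming the run
  bad <- qc_triplicate(list(c(100), c(100), c(100)))
  for (i in seq_along(bad)) bad[[i]]$records$q_value <- 0.5
  expect_error(compute_qc_metrics(bad), class = "degenerate_input")
})

test_that("protein counting requires presence in every injection", {
  qc <- qc_triplicate(list(c(10, 10), c(10, NA), c(10, 10)))
  ## second precursor absent (quantity NA) in injection 2 but its
  ## q-passing record still exists -> identification counting keeps it
  m <- compute_qc_metrics(qc)
  expect_equal(m$n_proteins, 2L)
  ## remove the record entirely from injection 2 -> not in every injection
  qc2 <- qc_triplicate(list(c(10, 10), c(10, 10), c(10, 10)))
  qc2[[2]]$records <- qc2[[2]]$records[1]
  expect_equal(compute_qc_metrics(qc2)$n_proteins, 1L)
})

test_that("CV is scale invariant and not increased by a duplicate injection", {
  base <- list(c(100, 30, 7), c(120, 33, 6), c(95, 28, 8))
  m1 <- compute_qc_metrics(qc_triplicate(base))
  m2 <- compute_qc_metrics(qc_triplicate(lapply(base, `*`, 1e3)))
  expect_equal(m1$median_precursor_cv, m2$median_precursor_cv,
               tolerance = 1e-12)

  with_dup <- qc_triplicate(c(base, base[3]))
  m3 <- compute_qc_metrics(with_dup)
  expect_lte(m3$median_precursor_cv, m1$median_precursor_cv + 1e-9)
})

test_that("evaluate_qc applies printed bounds and triages failures", {
  crit <- qc_criteria(min_precursors = 100, min_proteins = 10)
  ok <- structure(list(median_peak_width = 17, ms1_points = 10L,
                       ms2_points = 3L, n_precursors = 150,
                       n_proteins = 20L, median_precursor_cv = 8,
                       n_injections = 3L), class = "qc_metrics")
  v <- evaluate_qc(ok, crit)
  expect_true(v$pass)
  expect_equal(v$triage, "ok")
  expect_length(v$failed_metrics, 0)

  ## count minima are strict, CV bound inclusive
  edge <- ok; edge$n_proteins <- 10L
  expect_false(evaluate_qc(edge, crit)$pass)
  edge2 <- ok; edge2$median_precursor_cv <- 15
  expect_true(evaluate_qc(edge2, crit)$pass)
  ## peak-width band inclusive at both edges
  for (pw in c(14, 20)) {
    e <- ok; e$median_peak_width <- pw
    e$ms1_points <- points_per_peak(pw, 1.7)
    e$ms2_points <- points_per_peak(pw, 5.2)
    r <- evaluate_qc(e, qc_criteria(min_precursors = 100,
                                    min_proteins = 10,
                                    ms2_points_band = c(2, 4)))
    expect_false("median_peak_width" %in% r$failed_metrics)
  }

  ## the maintenance pattern: counts low, chromatographic metrics in band
  hcd <- ok; hcd$n_proteins <- 4L
  r <- evaluate_qc(hcd, crit)
  expect_false(r$pass)
  expect_equal(r$triage, "mass_spectrometric")

  chrom <- ok; chrom$median_peak_width <- 35
  r2 <- evaluate_qc(chrom, crit)
  expect_equal(r2$triage, "chromatographic")

  both <- chrom; both$n_proteins <- 4L
  expect_equal(evaluate_qc(both, crit)$triage, "mixed")

  ## absent metrics fail conservatively
  na_m <- ok; na_m$median_precursor_cv <- NA_real_
  r3 <- evaluate_qc(na_m, crit)
  expect_false(r3$pass)
  expect_true("median_precursor_cv" %in% r3$failed_metrics)
})

test_that("evaluate_qc is monotone: worsening one metric never unfails", {
  crit <- qc_criteria(min_precursors = 100, min_proteins = 10)
  base <- structure(list(median_peak_width = 17, ms1_points = 10L,
                         ms2_points = 3L, n_precursors = 150,
                         n_proteins = 20L, median_precursor_cv = 8,
                         n_injections = 3L), class = "qc_metrics")
  worsen <- list(
    median_peak_width = function(m) { m$median_peak_width <- 50; m },
    n_precursors = function(m) { m$n_precursors <- m$n_precursors - 100; m },
    n_proteins = function(m) { m$n_proteins <- 0L; m },
    median_precursor_cv = function(m) { m$median_precursor_cv <- 40; m })
  for (w in worsen) {
    v0 <- evaluate_qc(base, crit)
    v1 <- evaluate_qc(w(base), crit)
    expect_true(v0$pass >= v1$pass)
    expect_gte(length(v1$failed_metrics), length(v0$failed_metrics))
  }
})

test_that("derived criteria pass the baseline and gate degraded runs", {
  st <- simulate_study(sim = sim_config(
    n_proteins = c(human = 120, yeast = 5, ecoli = 5), seed = 77),
    labs = "L1", days = 1)
  qc <- st$reports[vapply(st$reports, function(r) r$sample == "QC",
                          logical(1))]
  crit <- derive_qc_criteria(qc)
  expect_true(evaluate_qc(compute_qc_metrics(qc), crit)$pass)

  ms <- inject_failure(qc, "ms_sensitivity", 0.5)
  v_ms <- evaluate_qc(compute_qc_metrics(ms), crit)
  expect_false(v_ms$pass)
  expect_equal(v_ms$triage, "mass_spectrometric")
  expect_true(all(v_ms$failed_metrics %in%
                    c("n_precursors", "n_proteins", "median_precursor_cv")))

  ch <- inject_failure(qc, "chromatographic", 0.8)
  v_ch <- evaluate_qc(compute_qc_metrics(ch), crit)
  expect_false(v_ch$pass)
  expect_true(v_ch$triage %in% c("chromatographic", "mixed"))
  expect_true("median_peak_width" %in% v_ch$failed_metrics)
})

test_that("qc_timecourse gates sample days per laboratory", {
  v <- data.table::data.table(
    lab = c(rep("L5", 5), rep("L10", 4)),
    day = c(1, 3, 5, 7, 9, 1, 3, 5, 7),
    pass = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  tc <- qc_timecourse(v)
  expect_equal(proceed_days(tc, "L5"), c(1L, 3L, 5L, 9L))
  expect_equal(proceed_days(tc, "L10"), integer(0))
  all_ok <- qc_timecourse(data.table::data.table(
    lab = "L1", day = c(1, 3, 5, 7), pass = TRUE))
  expect_equal(proceed_days(all_ok, "L1"), c(1L, 3L, 5L, 7L))
})
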