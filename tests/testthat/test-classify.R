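# Run validity, concentration acceptance, gene calls, prediction.

test_that("a well-behaved run passes all four acceptance criteria", {
  rec <- make_run()
  v <- check_run_validity(rec, epi2sensa_criteria())
  expect_true(v$valid)
  expect_length(v$failed, 0)
})

test_that("each acceptance criterion fails independently and all are reported", {
  cs <- epi2sensa_criteria()
  # clotrimazole IL-8 at 3.9 is below its cut-off of 4
  rec <- make_run(pc_clot_folds = c(ATF3 = 20, GCLM = 1.5, DNAJB4 = 1.5,
                                    IL8 = 3.9))
  v <- check_run_validity(rec, cs)
  expect_false(v$valid)
  expect_identical(v$failed, "pc_clotrimazole_induction")

  # only one vehicle tissue at or above 95%
  rec <- make_run(vehicle_viab = c(112, 94, 94))
  v <- check_run_validity(rec, cs)
  expect_identical(v$failed, "vehicle_viability")

  # one positive control below 80% mean viability
  rec <- make_run(pc_viab = c(clot = 79, nbb = 90))
  expect_identical(check_run_validity(rec, cs)$failed, "pc_viability")

  # multiple failures are all listed (no short-circuit)
  rec <- make_run(vehicle_viab = c(112, 94, 94),
                  pc_4nbb_folds = c(ATF3 = 2, GCLM = 1.9, DNAJB4 = 4.5,
                                    IL8 = 1.5))
  v <- check_run_validity(rec, cs)
  expect_setequal(v$failed, c("vehicle_viability", "pc_4nbb_induction"))
})

test_that("a structurally incomplete run errors rather than failing validity", {
  rec <- as.data.frame(make_run())
  expect_error(check_run_validity(rec[rec$role != "pc_4nbb", ],
                                  epi2sensa_criteria()),
               "missing pc_4nbb")
})

test_that("concentration acceptance respects both thresholds, boundary inclusive", {
  vrm <- vrm_criteria(); epi <- epi2sensa_criteria()
  expect_false(accept_concentrations(79.9, 0, vrm))
  expect_true(accept_concentrations(79.9, 0, epi))
  expect_true(accept_concentrations(80, 0, vrm))
  expect_true(accept_concentrations(60, 0, epi))
  expect_false(accept_concentrations(59.9, 0, epi))
  # GAPDH drift beyond one cycle rejects under both
  expect_false(accept_concentrations(100, 2, vrm))
  expect_false(accept_concentrations(100, 2, epi))
  expect_true(accept_concentrations(100, -1, epi))
})

test_that("gene activation is strictly above the cut-off", {
  cs <- epi2sensa_criteria()
  expect_length(call_genes(c(ATF3 = 15, GCLM = 2, DNAJB4 = 2, IL8 = 4), cs), 0)
  expect_identical(call_genes(c(ATF3 = 16, GCLM = 1, DNAJB4 = 1, IL8 = 1), cs),
                   "ATF3")
  expect_setequal(call_genes(c(ATF3 = 3, GCLM = 2.5, DNAJB4 = 2.1, IL8 = 20),
                             cs),
                  c("GCLM", "DNAJB4", "IL8"))
})

test_that("the prediction rule depends on the minimum-gene requirement", {
  expect_identical(predict_call(TRUE, 2L, "ATF3", epi2sensa_criteria()),
                   "non_sensitizer")
  expect_identical(predict_call(TRUE, 2L, "ATF3", vrm_criteria()),
                   "sensitizer")
  expect_identical(predict_call(TRUE, 2L, c("GCLM", "DNAJB4"),
                                epi2sensa_criteria()),
                   "sensitizer")
  expect_identical(predict_call(TRUE, 1L, character(0), epi2sensa_criteria()),
                   "non_sensitizer")
  expect_identical(predict_call(TRUE, 0L, character(0), epi2sensa_criteria()),
                   "no_accepted_concentration")
  expect_identical(predict_call(FALSE, 3L, c("ATF3", "IL8"),
                                epi2sensa_criteria()),
                   "invalid_run")
})

test_that("evaluate_run integrates viability, QC, Imax and the call", {
  # dose 1: viability 70 (accepted at 60, not at 80), strong two-gene folds
  # dose 2: viability 95, modest folds
  rec <- make_run(doses = c(12.5, 6.25), viability = c(70, 95),
                  folds = fold_matrix(c(20, 3, 1.5, 6), c(4, 1.6, 1.1, 2)))
  ev <- evaluate_run(rec, epi2sensa_criteria())
  expect_true(ev$valid)
  expect_equal(ev$per_concentration$accepted, c(TRUE, TRUE))
  expect_equal(unname(ev$imax), c(20, 3, 1.5, 6), tolerance = 1e-9)
  expect_setequal(ev$active_genes, c("ATF3", "GCLM", "IL8"))
  expect_identical(ev$call, "sensitizer")

  # VRM criteria reject the 70% dose; only the weak dose remains
  ev_vrm <- evaluate_run(rec, vrm_criteria())
  expect_equal(ev_vrm$per_concentration$accepted, c(FALSE, TRUE))
  expect_equal(unname(ev_vrm$imax), c(4, 1.6, 1.1, 2), tolerance = 1e-9)
  expect_identical(ev_vrm$call, "non_sensitizer")
})

test_that("a valid run with no accepted concentration is its own call", {
  rec <- make_run(doses = c(25, 12.5), viability = c(30, 40))
  ev <- evaluate_run(rec, epi2sensa_criteria())
  expect_true(ev$valid)
  expect_identical(ev$call, "no_accepted_concentration")

  # GAPDH drift alone can also exclude every concentration
  rec <- make_run(doses = c(25, 12.5), viability = c(90, 95),
                  gapdh_shift = c(1.8, -1.6))
  ev <- evaluate_run(rec, epi2sensa_criteria())
  expect_identical(ev$call, "no_accepted_concentration")
  expect_false(any(ev$per_concentration$gapdh_pass))
})

test_that("an invalid run yields invalid_run, not an exception", {
  rec <- make_run(vehicle_viab = c(112, 94, 94),
                  folds = fold_matrix(c(20, 3, 3, 6)), doses = 12.5,
                  viability = 80)
  ev <- evaluate_run(rec, epi2sensa_criteria())
  expect_false(ev$valid)
  expect_identical(ev$call, "invalid_run")
})

test_that("sensitizers under the two-gene rule are a subset of the one-gene rule", {
  set.seed(41)
  one <- criteria_set(min_active_genes = 1L, name = "one")
  two <- criteria_set(min_active_genes = 2L, name = "two")
  for (i in 1:50) {
    imax <- setNames(2^runif(4, -1, 5), marker_genes())
    active <- call_genes(imax, one)
    call1 <- predict_call(TRUE, 1L, active, one)
    call2 <- predict_call(TRUE, 1L, active, two)
    if (call2 == "sensitizer") expect_identical(call1, "sensitizer")
  }
})

test_that("relaxing the viability threshold only grows the accepted set and Imax", {
  set.seed(42)
  for (i in 1:15) {
    n_dose <- 4L
    doses <- 50 / 2^(seq_len(n_dose) - 1)
    viab <- sort(runif(n_dose, 30, 105))
    folds <- fold_matrix(2^runif(4, -0.5, 5), 2^runif(4, -0.5, 4),
                         2^runif(4, -0.5, 3), 2^runif(4, -0.5, 2))
    rec <- make_run(doses = doses, viability = viab, folds = folds)
    ev80 <- evaluate_run(rec, vrm_criteria())
    ev60 <- evaluate_run(rec, epi2sensa_criteria())
    a80 <- ev80$per_concentration$accepted
    a60 <- ev60$per_concentration$accepted
    expect_true(all(a60[a80]))  # accepted at 80 => accepted at 60
    both <- !is.na(ev80$imax) & !is.na(ev60$imax)
    expect_true(all(ev60$imax[both] >= ev80$imax[both]))
  }
})

test_that("evaluate_study handles multi-chemical runs sharing controls", {
  rec <- as.data.frame(make_run(doses = c(12.5, 6.25), viability = c(70, 95),
                                folds = fold_matrix(c(20, 3, 1.5, 6),
                                                    c(4, 1.5, 1.2, 2)),
                                chemical = "A"))
  other <- as.data.frame(make_run(doses = 12.5, viability = 90,
                                  folds = fold_matrix(c(1, 1, 1, 1)),
                                  chemical = "B"))
  extra <- other[other$role == "test", ]
  extra$tissue_id <- paste0("B", seq_len(nrow(extra)))
  both <- validate_tissue_records(rbind(rec, extra))
  out <- evaluate_study(both, epi2sensa_criteria())
  expect_identical(nrow(out), 2L)
  expect_identical(out$call[out$chemical_code == "A"], "sensitizer")
  expect_identical(out$call[out$chemical_code == "B"], "non_sensitizer")
  # evaluate_run demands an explicit chemical when several are present
  expect_error(evaluate_run(both, epi2sensa_criteria()), "chemical")
  expect_identical(evaluate_run(both, epi2sensa_criteria(),
                                chemical = "B")$call, "non_sensitizer")
})
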