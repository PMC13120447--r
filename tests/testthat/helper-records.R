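# Deterministic builder for single-run tissue-record tables.
#
# Inverts the viability formula and the comparative-Ct arithmetic so a run
# with exactly the requested per-tissue viabilities, per-dose fold
# inductions and GAPDH drifts can be constructed without noise. Vehicle
# delta-abs mean is 0.12, killed mean 1.12 (span 1.0), GAPDH baseline Ct
# 18, marker baselines ATF3 24 / GCLM 22 / DNAJB4 25 / IL8 26.
#
# `vehicle_viab` must average 100: per-tissue vehicle viabilities are
# relative to their own mean delta-abs, so they always average 100%.

.BASE_CT <- c(ATF3 = 24, GCLM = 22, DNAJB4 = 25, IL8 = 26)

make_run <- function(lab_id = "L1", run_id = "R1", chemical = "X",
                     doses = c(25, 12.5),
                     viability = rep(95, length(doses)),
                     folds = NULL, gapdh_shift = rep(0, length(doses)),
                     vehicle_viab = c(100, 100, 100),
                     pc_clot_folds = c(ATF3 = 30, GCLM = 1.5,
                                       DNAJB4 = 1.5, IL8 = 8),
                     pc_4nbb_folds = c(ATF3 = 2, GCLM = 4.5,
                                       DNAJB4 = 4.5, IL8 = 1.5),
                     pc_viab = c(clot = 88, nbb = 85),
                     n_test = 2L, n_killed = 2L) {
  stopifnot(abs(mean(vehicle_viab) - 100) < 1e-9)
  if (is.null(folds))
    folds <- matrix(1, length(doses), 4,
                    dimnames = list(NULL, names(.BASE_CT)))
  vc_dab <- 0.12
  killed_dab <- 1.12
  dab_of <- function(v) vc_dab + (1 - v / 100) * (killed_dab - vc_dab)

  tissue_n <- 0L
  mk <- function(n, role, chem, conc, dab, fold = NULL, shift = 0) {
    ids <- paste0("T", tissue_n + seq_len(n)); tissue_n <<- tissue_n + n
    out <- data.frame(lab_id = lab_id, run_id = run_id, tissue_id = ids,
                      role = role, chemical_code = chem, vehicle = "AOO",
                      concentration = conc, abs_490 = 0.05 + dab,
                      abs_ref = 0.05, mtt_viability_pct = NA_real_,
                      stringsAsFactors = FALSE)
    for (g in names(.BASE_CT)) out[[paste0("ct_", g)]] <- NA_real_
    out$ct_GAPDH <- NA_real_
    if (!is.null(fold)) {
      out$ct_GAPDH <- 18 + shift
      for (g in names(.BASE_CT))
        out[[paste0("ct_", g)]] <- .BASE_CT[[g]] + shift - log2(fold[[g]])
    }
    out
  }

  unit <- c(ATF3 = 1, GCLM = 1, DNAJB4 = 1, IL8 = 1)
  pieces <- list(
    mk(length(vehicle_viab), "vehicle", "", 0, dab_of(vehicle_viab), unit),
    mk(n_killed, "killed", "", 0, rep(killed_dab, n_killed)),
    mk(2L, "pc_clotrimazole", "", 1.56, rep(dab_of(pc_viab[["clot"]]), 2),
       pc_clot_folds),
    mk(2L, "pc_4nbb", "", 0.78, rep(dab_of(pc_viab[["nbb"]]), 2),
       pc_4nbb_folds))
  for (i in seq_along(doses))
    pieces[[length(pieces) + 1L]] <-
      mk(n_test, "test", chemical, doses[i],
         rep(dab_of(viability[i]), n_test), folds[i, ], gapdh_shift[i])
  rec <- do.call(rbind, pieces)
  validate_tissue_records(rec)
}

# Fold matrix helper: rows = doses, columns = the four markers.
fold_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- names(.BASE_CT)
  m
}
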