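## Run validity, concentration acceptance, gene activation, prediction.

#' Check the four run-acceptance criteria
#'
#' A run is valid when all four criteria hold:
#' \enumerate{
#'   \item `vehicle_viability`: at least `vehicle_min_tissues` (default 2)
#'     vehicle-control tissues have viability >= 95%;
#'   \item `pc_viability`: the mean viability of each positive control
#'     (clotrimazole and 4-nitrobenzyl bromide) is >= 80%;
#'   \item `pc_clotrimazole_induction`: clotrimazole's mean fold inductions
#'     of ATF3 and IL-8 exceed their cut-offs;
#'   \item `pc_4nbb_induction`: 4-NBB's mean fold inductions of GCLM and
#'     DNAJB4 exceed their cut-offs.
#' }
#' All four checks are always evaluated (no short-circuit) so the failure
#' list is complete. A run lacking a vehicle, positive-control or killed
#' tissue entirely is a structural error, not a validity failure.
#'
#' @param records tissue records of a single run.
#' @param criteria a [criteria_set()].
#' @param viability,folds optional precomputed [per_tissue_viability()] /
#'   fold summaries for the run (computed if omitted).
#' @return List with `valid` (logical) and `failed` (character vector of
#'   failed check names, empty when valid).
#' @export
check_run_validity <- function(records, criteria = epi2sensa_criteria(),
                               viability = NULL, folds = NULL) {
  records <- as.data.frame(records)
  stopifnot(length(unique(records$run_id)) == 1L)
  for (r in c("vehicle", "pc_clotrimazole", "pc_4nbb"))
    if (!any(records$role == r))
      stop("run ", records$run_id[1], ": missing ", r,
           " tissues; run structure incomplete", call. = FALSE)
  if (is.null(viability)) viability <- per_tissue_viability(records)
  if (is.null(folds)) folds <- run_fold_summaries(records)

  failed <- character(0)
  veh_v <- viability$viability_pct[viability$role == "vehicle"]
  if (sum(veh_v >= criteria$vehicle_viability_min_pct) <
      criteria$vehicle_min_tissues)
    failed <- c(failed, "vehicle_viability")

  pc_mean <- function(role)
    mean(viability$viability_pct[viability$role == role])
  if (!(pc_mean("pc_clotrimazole") >= criteria$pc_viability_min_pct &&
        pc_mean("pc_4nbb") >= criteria$pc_viability_min_pct))
    failed <- c(failed, "pc_viability")

  pc_induced <- function(role, genes) {
    f <- folds[folds$role == role & folds$gene %in% genes, , drop = FALSE]
    length(genes) > 0 && nrow(f) == length(genes) &&
      all(f$mean_fold > criteria$gene_cutoffs[f$gene])
  }
  if (!pc_induced("pc_clotrimazole", criteria$pc_clotrimazole_genes))
    failed <- c(failed, "pc_clotrimazole_induction")
  if (!pc_induced("pc_4nbb", criteria$pc_4nbb_genes))
    failed <- c(failed, "pc_4nbb_induction")

  list(valid = length(failed) == 0L, failed = failed)
}

#' Concentration acceptance
#'
#' A tested concentration is accepted when its mean tissue viability is at
#' or above the criteria threshold (80% under VRM, 60% under the modified
#' Epi2SensA criteria) and the GAPDH Ct drift passes QC. Both comparisons
#' are boundary inclusive.
#'
#' @param mean_viability numeric vector of per-concentration mean
#'   viabilities (percent).
#' @param gapdh_delta_ct matching vector of GAPDH Ct drifts.
#' @param criteria a [criteria_set()].
#' @return Logical vector of acceptance flags.
#' @export
accept_concentrations <- function(mean_viability, gapdh_delta_ct,
                                  criteria = epi2sensa_criteria()) {
  mean_viability >= criteria$viability_threshold_pct &
    gapdh_qc(gapdh_delta_ct, criteria)
}

#' Gene activation calls from maximal fold inductions
#'
#' A gene is activated when its Imax — the maximum mean fold induction
#' over the accepted concentrations — strictly exceeds its cut-off
#' (ATF3 > 15, GCLM > 2, DNAJB4 > 2, IL8 > 4). A fold exactly at the
#' cut-off is not an activation.
#'
#' @param imax named numeric vector of per-gene maximal mean folds.
#' @param criteria a [criteria_set()].
#' @return Character vector of activated marker genes (possibly empty).
#' @examples
#' call_genes(c(ATF3 = 16, GCLM = 2, DNAJB4 = 1, IL8 = 4.2))
#' @export
call_genes <- function(imax, criteria = epi2sensa_criteria()) {
  genes <- intersect(.MARKERS, names(imax))
  genes[!is.na(imax[genes]) & imax[genes] > criteria$gene_cutoffs[genes]]
}

#' Sensitizer call from run evaluation components
#'
#' The prediction model: an invalid run yields `invalid_run`; a valid run
#' with no accepted concentration yields the distinct call
#' `no_accepted_concentration` (retesting at lower doses is a study-design
#' decision, not a negative result); otherwise the chemical is a
#' `sensitizer` when at least `min_active_genes` marker genes are
#' activated (1 under VRM, 2 under the modified criteria), else a
#' `non_sensitizer`. Activation is judged on each gene's Imax across all
#' accepted concentrations; two genes need not exceed their cut-offs at
#' the same concentration.
#'
#' @param valid run validity flag.
#' @param n_accepted number of accepted concentrations.
#' @param active_genes character vector of activated genes
#'   (from [call_genes()]).
#' @param criteria a [criteria_set()].
#' @return One of `"sensitizer"`, `"non_sensitizer"`,
#'   `"no_accepted_concentration"`, `"invalid_run"`.
#' @export
predict_call <- function(valid, n_accepted, active_genes,
                         criteria = epi2sensa_criteria()) {
  if (!valid) return("invalid_run")
  if (n_accepted == 0L) return("no_accepted_concentration")
  if (length(active_genes) >= criteria$min_active_genes) "sensitizer"
  else "non_sensitizer"
}

#' Evaluate one run: validity, acceptance, gene calls, prediction
#'
#' Runs the whole per-run pipeline on the tissue records of a single run:
#' per-tissue viability, fold-induction summaries, the four run-acceptance
#' checks, per-concentration acceptance, per-gene Imax over accepted
#' concentrations, and the sensitizer call — for one test chemical (a run
#' may carry several coded chemicals sharing its controls; use `chemical`
#' to pick one, or [evaluate_study()] to get all).
#'
#' @param records tissue records of one run.
#' @param criteria a [criteria_set()].
#' @param chemical chemical code to evaluate (defaults to the single test
#'   chemical present; required if the run carries several).
#' @return An object of class `run_evaluation`: a list with `lab_id`,
#'   `run_id`, `chemical_code`, `criteria_name`, `valid`,
#'   `failed_criteria`, `per_concentration` (data frame with
#'   `concentration, mean_viability, gapdh_delta_ct, gapdh_pass, accepted`
#'   and per-gene mean-fold columns), `imax`, `active_genes`, `call`.
#' @export
evaluate_run <- function(records, criteria = epi2sensa_criteria(),
                         chemical = NULL) {
  records <- as.data.frame(records)
  stopifnot(length(unique(paste(records$lab_id, records$run_id))) == 1L)
  chems <- unique(records$chemical_code[records$role == "test"])
  if (is.null(chemical)) {
    if (length(chems) != 1L)
      stop("run carries ", length(chems),
           " test chemicals; pass `chemical` or use evaluate_study()",
           call. = FALSE)
    chemical <- chems
  } else if (!chemical %in% chems) {
    stop("chemical ", chemical, " not present in run ", records$run_id[1],
         call. = FALSE)
  }
  viability <- per_tissue_viability(records)
  folds <- run_fold_summaries(records)
  validity <- check_run_validity(records, criteria, viability, folds)
  .evaluate_chemical(records, chemical, criteria, viability, folds, validity)
}

.evaluate_chemical <- function(records, chemical, criteria, viability, folds,
                               validity) {
  tv <- viability[viability$role == "test" &
                    viability$chemical_code == chemical, , drop = FALSE]
  tf <- folds[folds$role == "test" & folds$chemical_code == chemical, ,
              drop = FALSE]
  conc <- sort(unique(tv$concentration), decreasing = TRUE)
  mean_viab <- vapply(conc, function(cc)
    mean(tv$viability_pct[tv$concentration == cc]), numeric(1))
  gdc <- vapply(conc, function(cc) {
    d <- unique(tf$gapdh_delta_ct[tf$concentration == cc])
    if (length(d)) d[1] else NA_real_
  }, numeric(1))
  gpass <- !is.na(gdc) & gapdh_qc(gdc, criteria)
  accepted <- accept_concentrations(mean_viab, ifelse(is.na(gdc), Inf, gdc),
                                    criteria)

  per_conc <- data.frame(concentration = conc, mean_viability = mean_viab,
                         gapdh_delta_ct = gdc, gapdh_pass = gpass,
                         accepted = accepted)
  for (g in .MARKERS)
    per_conc[[paste0("fold_", g)]] <- vapply(conc, function(cc) {
      f <- tf$mean_fold[tf$concentration == cc & tf$gene == g]
      if (length(f)) f[1] else NA_real_
    }, numeric(1))

  imax <- vapply(.MARKERS, function(g) {
    f <- per_conc[[paste0("fold_", g)]][accepted]
    if (length(f) && any(!is.na(f))) max(f, na.rm = TRUE) else NA_real_
  }, numeric(1))
  active <- if (validity$valid && any(accepted))
    call_genes(imax, criteria) else character(0)
  call <- predict_call(validity$valid, sum(accepted), active, criteria)

  structure(
    list(lab_id = records$lab_id[1], run_id = records$run_id[1],
         chemical_code = chemical, criteria_name = criteria$name,
         valid = validity$valid, failed_criteria = validity$failed,
         per_concentration = per_conc, imax = imax, active_genes = active,
         call = call),
    class = "run_evaluation")
}

#' @export
print.run_evaluation <- function(x, ...) {
  cat("<run_evaluation> lab ", x$lab_id, ", run ", x$run_id,
      ", chemical ", x$chemical_code, " [", x$criteria_name, "]\n", sep = "")
  cat("  valid:", x$valid,
      if (!x$valid) paste0(" (failed: ",
                           paste(x$failed_criteria, collapse = ", "), ")"),
      "\n")
  cat("  accepted concentrations:",
      sum(x$per_concentration$accepted), "of",
      nrow(x$per_concentration), "\n")
  cat("  Imax:", paste(names(x$imax), round(x$imax, 2), sep = "=",
                       collapse = ", "), "\n")
  cat("  active genes:",
      if (length(x$active_genes)) paste(x$active_genes, collapse = ", ")
      else "none", "\n")
  cat("  call:", x$call, "\n")
  invisible(x)
}

#' Evaluate every (run, chemical) of a study
#'
#' Applies [evaluate_run()] to each run of a multi-run record table and
#' each test chemical it carries, returning the flat per-run call table
#' consumed by the validation statistics.
#'
#' @param records tissue records covering one or more runs.
#' @param criteria a [criteria_set()].
#' @return Data frame with one row per (lab, run, chemical): `lab_id,
#'   run_id, chemical_code, criteria_name, valid, failed_criteria
#'   (";"-joined), call, active_genes (";"-joined), n_accepted` and
#'   `imax_ATF3 .. imax_IL8`.
#' @export
evaluate_study <- function(records, criteria = epi2sensa_criteria()) {
  records <- as.data.frame(records)
  runs <- split(records, paste(records$lab_id, records$run_id))
  rows <- lapply(runs, function(run) {
    viability <- per_tissue_viability(run)
    folds <- run_fold_summaries(run)
    validity <- check_run_validity(run, criteria, viability, folds)
    chems <- unique(run$chemical_code[run$role == "test"])
    evs <- lapply(chems, function(ch)
      .evaluate_chemical(run, ch, criteria, viability, folds, validity))
    do.call(rbind, lapply(evs, .run_eval_row))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lab_id, out$chemical_code, out$run_id), ]
  rownames(out) <- NULL
  out
}

.run_eval_row <- function(ev) {
  row <- data.frame(lab_id = ev$lab_id, run_id = ev$run_id,
                    chemical_code = ev$chemical_code,
                    criteria_name = ev$criteria_name, valid = ev$valid,
                    failed_criteria = paste(ev$failed_criteria,
                                            collapse = ";"),
                    call = ev$call,
                    active_genes = paste(ev$active_genes, collapse = ";"),
                    n_accepted = sum(ev$per_concentration$accepted),
                    stringsAsFactors = FALSE)
  for (g in .MARKERS) row[[paste0("imax_", g)]] <- unname(ev$imax[g])
  row
}
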