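## LDH-based tissue viability, killed-control referencing, dose finding.

#' LDH viability of one tissue
#'
#' Viability from LDH release into the culture medium, referenced to the
#' vehicle control (0% release baseline) and the killed control (maximum
#' release, tissues fully lysed with Triton X-100 in the basolateral
#' medium):
#'
#' \deqn{viability\% = 100 - \frac{\Delta abs_{test} - \Delta abs_{vc}}
#'   {\overline{\Delta abs}_{killed} - \Delta abs_{vc}} \times 100}
#'
#' where each \eqn{\Delta abs} is absorbance at 490 nm minus the reference
#' wavelength (>= 650 nm). The result is not clamped: values above 100%
#' (test releases less LDH than the vehicle mean) and below 0% are
#' returned as computed, since acceptance logic uses `>=` comparisons.
#'
#' @param delta_abs_test \eqn{\Delta abs} of the test-treated tissue
#'   (vectorized).
#' @param delta_abs_vehicle mean \eqn{\Delta abs} of the vehicle-control
#'   tissues.
#' @param mean_delta_abs_killed mean \eqn{\Delta abs} of the killed-control
#'   tissues; must strictly exceed `delta_abs_vehicle`, otherwise the lysis
#'   failed and the killed control is unusable as a 100%-release reference.
#' @return Viability in percent.
#' @examples
#' compute_viability(0.35, 0.10, 1.10)  # 75
#' @export
compute_viability <- function(delta_abs_test, delta_abs_vehicle,
                              mean_delta_abs_killed) {
  if (!isTRUE(mean_delta_abs_killed > delta_abs_vehicle))
    stop("degenerate killed control: mean killed-control delta-abs (",
         format(mean_delta_abs_killed), ") does not exceed the vehicle ",
         "delta-abs (", format(delta_abs_vehicle),
         "); tissue lysis failed to release LDH", call. = FALSE)
  100 - (delta_abs_test - delta_abs_vehicle) /
    (mean_delta_abs_killed - delta_abs_vehicle) * 100
}

#' Per-tissue viability for assay runs
#'
#' Computes a viability for every non-killed tissue of each run. The
#' reference terms are per-run means: the vehicle reference is the mean
#' \eqn{\Delta abs} over that run's vehicle tissues, the killed reference
#' the mean over its killed tissues. Tissues carrying an externally
#' measured `mtt_viability_pct` (the MTT path, used for chemicals that
#' interfere with the LDH readout) take that value verbatim with
#' `method = "MTT_supplied"`.
#'
#' Values above 110% are flagged (`suspicious = TRUE`) as a soft QC signal
#' but are not altered or removed.
#'
#' @param records tissue records (one or more runs), as returned by
#'   [read_tissue_records()] or [simulate_study()].
#' @return Data frame with one row per non-killed tissue: `lab_id, run_id,
#'   tissue_id, role, chemical_code, concentration, delta_abs,
#'   viability_pct, method, suspicious`.
#' @export
per_tissue_viability <- function(records) {
  records <- as.data.frame(records)
  out <- lapply(split(records, paste(records$lab_id, records$run_id)),
                .run_viability)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.run_viability <- function(run) {
  dab <- run$abs_490 - run$abs_ref
  is_veh <- run$role == "vehicle"
  is_kill <- run$role == "killed"
  target <- !is_kill
  has_mtt <- !is.na(run$mtt_viability_pct)

  viab <- rep(NA_real_, nrow(run))
  method <- rep(NA_character_, nrow(run))
  ldh_needed <- target & !has_mtt
  if (any(ldh_needed)) {
    if (!any(is_kill))
      stop("run ", run$run_id[1], ": no killed-control tissues and no ",
           "supplied MTT viability; LDH viability needs a killed reference",
           call. = FALSE)
    if (sum(is_veh) < 2L)
      stop("run ", run$run_id[1], ": fewer than two vehicle-control tissues",
           call. = FALSE)
    vc_mean <- mean(dab[is_veh])
    killed_mean <- mean(dab[is_kill])
    viab[ldh_needed] <- compute_viability(dab[ldh_needed], vc_mean, killed_mean)
    method[ldh_needed] <- "LDH"
  }
  viab[target & has_mtt] <- run$mtt_viability_pct[target & has_mtt]
  method[target & has_mtt] <- "MTT_supplied"

  data.frame(lab_id = run$lab_id[target], run_id = run$run_id[target],
             tissue_id = run$tissue_id[target], role = run$role[target],
             chemical_code = run$chemical_code[target],
             concentration = run$concentration[target],
             delta_abs = dab[target], viability_pct = viab[target],
             method = method[target],
             suspicious = viab[target] > 110,
             stringsAsFactors = FALSE)
}

#' Evaluate a dose-finding run and pick main-study concentrations
#'
#' Dose finding exposes duplicate tissues to up to six concentrations and
#' asks whether at least one concentration keeps mean viability at or
#' above the acceptance threshold (80% under VRM criteria, 60% under the
#' modified criteria). If so the run is valid and the main-study doses are
#' the highest concentration meeting the threshold plus the next three
#' lower tested concentrations (fewer if unavailable), highest first —
#' giving the "typically four concentrations" of the main study.
#'
#' @param viabilities data frame with columns `concentration` and
#'   `viability_pct` (one row per tissue; duplicates share a
#'   concentration), or a named list mapping concentration to a numeric
#'   vector of viabilities.
#' @param criteria a [criteria_set()]; only `viability_threshold_pct` is
#'   used here.
#' @return List with `per_concentration` (named vector of mean viabilities,
#'   concentrations decreasing), `valid` and `selected_doses`.
#' @examples
#' v <- data.frame(concentration = rep(c(50, 25, 12.5, 6.25), each = 2),
#'                 viability_pct = c(9, 11, 38, 42, 69, 71, 94, 96))
#' evaluate_dose_finding(v, epi2sensa_criteria())$selected_doses  # 12.5 6.25
#' @export
evaluate_dose_finding <- function(viabilities, criteria = epi2sensa_criteria()) {
  if (is.list(viabilities) && !is.data.frame(viabilities)) {
    viabilities <- data.frame(
      concentration = rep(as.numeric(names(viabilities)),
                          lengths(viabilities)),
      viability_pct = unlist(viabilities, use.names = FALSE))
  }
  if (nrow(viabilities) == 0L)
    stop("no dose-finding viability data", call. = FALSE)
  means <- tapply(viabilities$viability_pct, viabilities$concentration, mean)
  conc <- sort(as.numeric(names(means)), decreasing = TRUE)
  if (length(conc) > 6L)
    warning("dose finding normally uses at most six concentrations; got ",
            length(conc))
  means <- means[as.character(conc)]
  ok <- means >= criteria$viability_threshold_pct
  valid <- any(ok)
  selected <- if (valid) {
    top <- which(ok)[1]  # highest concentration meeting the threshold
    conc[top:min(top + 3L, length(conc))]
  } else numeric(0)
  list(per_concentration = setNames(as.numeric(means), names(means)),
       valid = valid, selected_doses = selected)
}
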