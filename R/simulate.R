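## Synthetic multi-lab assay-data generator with known ground truth.
##
## Emulates the plate structure the pipeline expects: per run, triplicate
## test tissues at each main-study dose, vehicle controls, duplicate
## clotrimazole and 4-NBB positive controls, and killed controls.
## Cytotoxicity follows a Hill curve in concentration; marker induction a
## saturating Hill curve; noise is Gaussian in Ct space (lognormal on
## folds) and in absorbance; laboratory effects are a multiplicative
## (log2-Gaussian) bias on folds only.

#' Ground-truth dose-response profile of a simulated chemical
#'
#' Defines what a simulated chemical "really" does: its cytotoxicity
#' midpoint and slope, and per-marker maximal fold induction and
#' half-maximal concentration. Profile validity mirrors the prediction
#' model: a ground-truth sensitizer must be able to activate at least two
#' markers (emax above cut-off), a non-sensitizer none — except through
#' the spurious single-gene mechanism, which with probability
#' `spurious_single_gene_prob` per run drives exactly one random marker
#' above its cut-off (the isolated, non-specific signal that motivates
#' the two-gene rule).
#'
#' @param code chemical code.
#' @param truth `"sensitizer"` or `"non_sensitizer"`.
#' @param ic50 cytotoxicity midpoint, percent concentration.
#' @param hill Hill slope of the viability curve (> 0).
#' @param gene_emax named vector, maximal additional fold induction per
#'   marker at a saturating sub-cytotoxic dose (fold = 1 + emax at
#'   saturation). Defaults: a clear multi-gene inducer for sensitizers, a
#'   flat profile for non-sensitizers.
#' @param gene_ec50 named vector of half-maximal concentrations per marker
#'   (default `ic50 / 4`, induction preceding cytotoxicity).
#' @param spurious_single_gene_prob per-run probability of the spurious
#'   single-gene activation (non-sensitizers only).
#' @param gene_cutoffs cut-offs used to check profile/truth coherence.
#' @return Object of class `chemical_profile`.
#' @export
chemical_profile <- function(code, truth = c("sensitizer", "non_sensitizer"),
                             ic50 = 10, hill = 2,
                             gene_emax = NULL, gene_ec50 = NULL,
                             spurious_single_gene_prob = 0,
                             gene_cutoffs = c(ATF3 = 15, GCLM = 2,
                                              DNAJB4 = 2, IL8 = 4)) {
  truth <- match.arg(truth)
  stopifnot(ic50 > 0, hill > 0,
            spurious_single_gene_prob >= 0, spurious_single_gene_prob <= 1)
  if (is.null(gene_emax))
    gene_emax <- if (truth == "sensitizer")
      c(ATF3 = 30, GCLM = 5, DNAJB4 = 5, IL8 = 10)
    else c(ATF3 = 0.3, GCLM = 0.15, DNAJB4 = 0.15, IL8 = 0.3)
  gene_emax <- gene_emax[.MARKERS]
  if (is.null(gene_ec50))
    gene_ec50 <- setNames(rep(ic50 / 4, 4), .MARKERS)
  gene_ec50 <- gene_ec50[.MARKERS]
  stopifnot(!anyNA(gene_emax), !anyNA(gene_ec50), all(gene_ec50 > 0))

  over <- (1 + gene_emax) > gene_cutoffs[.MARKERS]
  if (truth == "sensitizer" && sum(over) < 2L)
    stop("sensitizer profile must have >= 2 markers with saturating fold ",
         "above cut-off", call. = FALSE)
  if (truth == "non_sensitizer" && any(over))
    stop("non-sensitizer profile may not exceed cut-offs except via the ",
         "spurious single-gene mechanism", call. = FALSE)
  structure(list(code = code, truth = truth, ic50 = ic50, hill = hill,
                 gene_emax = gene_emax, gene_ec50 = gene_ec50,
                 spurious_single_gene_prob = spurious_single_gene_prob),
            class = "chemical_profile")
}

#' Simulation configuration
#'
#' Study-level knobs of the generator. The defaults mirror the validation
#' study design: three laboratories, three runs per chemical, triplicate
#' main-study tissues at four 2-fold-spaced doses (chosen per chemical
#' from its noiseless viability curve when `doses` is `NULL`), GAPDH
#' baseline around Ct 18. Noise magnitudes are free parameters (no
#' instrument-level error figures are published): 0.15 Ct technical noise,
#' 0.1 log2 units of per-lab fold bias, and 0.01 absorbance units on
#' \eqn{\Delta abs}.
#'
#' @param n_labs number of laboratories.
#' @param runs_per_chemical independent runs per (lab, chemical).
#' @param doses main-study concentrations (percent, in (0, 50]); `NULL` =
#'   auto-select per chemical via the dose-finding rule at the 60%
#'   threshold.
#' @param ct_noise_sd per-well Ct technical noise SD.
#' @param lab_fold_bias_sd SD of the per-(lab, gene) log2 fold bias.
#' @param seed integer seed; fully determines the output.
#' @param gapdh_ct_mean,gapdh_ct_sd GAPDH baseline Ct distribution.
#' @param marker_baseline_ct named vector of vehicle-level marker Cts.
#' @param vehicle_delta_abs,killed_delta_abs mean \eqn{\Delta abs} of
#'   vehicle and killed controls.
#' @param abs_noise_sd absorbance noise SD.
#' @param abs_ref reference-wavelength absorbance (constant).
#' @param n_test_tissues,n_vehicle_tissues,n_pc_tissues,n_killed_tissues
#'   tissues per role and run.
#' @param pc_fail if `TRUE`, generate failing positive controls (the
#'   clotrimazole IL-8 response is suppressed), for exercising the
#'   run-invalidity path.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_labs = 3L, runs_per_chemical = 3L,
                              doses = NULL, ct_noise_sd = 0.15,
                              lab_fold_bias_sd = 0.1, seed = 1L,
                              gapdh_ct_mean = 18, gapdh_ct_sd = 0.2,
                              marker_baseline_ct = c(ATF3 = 24, GCLM = 22,
                                                     DNAJB4 = 25, IL8 = 26),
                              vehicle_delta_abs = 0.12,
                              killed_delta_abs = 1.12,
                              abs_noise_sd = 0.01, abs_ref = 0.05,
                              n_test_tissues = 3L, n_vehicle_tissues = 3L,
                              n_pc_tissues = 2L, n_killed_tissues = 2L,
                              pc_fail = FALSE) {
  if (!is.null(doses) && (any(doses <= 0) || any(doses > 50)))
    stop("doses must lie in (0, 50] percent", call. = FALSE)
  stopifnot(ct_noise_sd >= 0, lab_fold_bias_sd >= 0, abs_noise_sd >= 0,
            killed_delta_abs > vehicle_delta_abs,
            n_vehicle_tissues >= 2L, n_killed_tissues >= 1L)
  structure(as.list(environment()), class = "simulation_config")
}

## Hill curves: viability and fold induction as functions of dose
.sim_viability <- function(c, profile)
  100 / (1 + (c / profile$ic50)^profile$hill)

.sim_fold <- function(c, emax, ec50, hill = 2)
  1 + emax * c^hill / (c^hill + ec50^hill)

#' Simulate a complete multi-laboratory study
#'
#' Generates per-tissue records (absorbances and Ct values) for every
#' (laboratory, chemical, run) with known ground truth, in exactly the
#' schema [read_tissue_records()] produces, so the full pipeline —
#' [evaluate_study()], [summarize_chemicals()], [compute_study_metrics()]
#' — runs on it unchanged. Each simulated run carries one chemical with
#' its own vehicle, positive-control and killed tissues.
#'
#' Mechanics: tissue viability at dose c follows
#' \eqn{v(c) = 100 / (1 + (c/ic50)^{hill})}; the tissue's \eqn{\Delta abs}
#' is back-computed as
#' \eqn{\Delta abs_{vc} + (1 - v/100)(\Delta abs_{killed} - \Delta abs_{vc})}
#' plus Gaussian noise. Marker fold follows
#' \eqn{1 + emax \cdot c^h / (c^h + ec50^h)}, multiplied by the lab's
#' log2-Gaussian bias; Ct values are synthesized around the GAPDH baseline
#' so that the comparative-Ct computation recovers the folds up to the
#' configured Ct noise. Positive controls are generated to pass the
#' run-acceptance criteria (or to fail them when `config$pc_fail`).
#'
#' @param profiles list of [chemical_profile()]s.
#' @param config a [simulation_config()]. The RNG is seeded locally from
#'   `config$seed`; global RNG state is left untouched.
#' @return A `tissue_records` data frame; attribute `truth` carries the
#'   named ground-truth vector.
#' @examples
#' prof <- list(chemical_profile("S1", "sensitizer"),
#'              chemical_profile("N1", "non_sensitizer"))
#' rec <- simulate_study(prof, simulation_config(n_labs = 1, seed = 7))
#' table(rec$role)
#' @export
simulate_study <- function(profiles, config = simulation_config()) {
  if (inherits(profiles, "chemical_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "chemical_profile")))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  labs <- paste0("L", seq_len(config$n_labs))
  ## per-(lab, gene) multiplicative fold bias, constant across runs
  lab_bias <- matrix(rnorm(config$n_labs * 4, 0, config$lab_fold_bias_sd),
                     nrow = config$n_labs,
                     dimnames = list(labs, .MARKERS))
  rows <- list()
  for (lab in labs) {
    for (p in profiles) {
      doses <- config$doses %||% .auto_doses(p)
      for (r in seq_len(config$runs_per_chemical)) {
        run_id <- paste0(lab, "_", p$code, "_R", r)
        spurious_gene <- if (p$truth == "non_sensitizer" &&
                             runif(1) < p$spurious_single_gene_prob)
          sample(.MARKERS, 1) else NULL
        rows[[run_id]] <- .simulate_run(lab, run_id, p, doses,
                                        2^lab_bias[lab, ], spurious_gene,
                                        config)
      }
    }
  }
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  rec <- validate_tissue_records(rec)
  attr(rec, "truth") <- setNames(
    vapply(profiles, `[[`, character(1), "truth"),
    vapply(profiles, `[[`, character(1), "code"))
  rec
}

## dose-finding rule applied to the noiseless viability curve over the
## 2-fold grid: highest dose meeting the threshold plus the next three
.auto_doses <- function(profile, threshold = 60) {
  grid <- dilution_series()
  ok <- .sim_viability(grid, profile) >= threshold
  if (!any(ok))
    stop("profile ", profile$code, ": cytotoxic over the whole dilution grid",
         call. = FALSE)
  top <- which(ok)[1]
  grid[top:min(top + 3L, length(grid))]
}

.simulate_run <- function(lab, run_id, profile, doses, bias_fold,
                          spurious_gene, config) {
  tissue_n <- 0L
  mk_rows <- function(n, role, chem, vehicle, conc, viability, folds) {
    ids <- paste0(run_id, "_T", tissue_n + seq_len(n))
    tissue_n <<- tissue_n + n
    dab <- config$vehicle_delta_abs +
      (1 - viability / 100) *
        (config$killed_delta_abs - config$vehicle_delta_abs) +
      rnorm(n, 0, config$abs_noise_sd)
    out <- data.frame(lab_id = lab, run_id = run_id, tissue_id = ids,
                      role = role, chemical_code = chem, vehicle = vehicle,
                      concentration = conc,
                      abs_490 = config$abs_ref + dab,
                      abs_ref = config$abs_ref,
                      mtt_viability_pct = NA_real_,
                      stringsAsFactors = FALSE)
    for (cc in .ct_cols()) out[[cc]] <- NA_real_
    if (!is.null(folds)) {
      gapdh <- rnorm(n, config$gapdh_ct_mean, config$gapdh_ct_sd)
      out$ct_GAPDH <- gapdh
      for (g in .MARKERS)
        out[[paste0("ct_", g)]] <- config$marker_baseline_ct[g] +
          (gapdh - config$gapdh_ct_mean) - log2(folds[g]) +
          rnorm(n, 0, config$ct_noise_sd)
    }
    out
  }

  unit_folds <- setNames(rep(1, 4), .MARKERS)
  pieces <- list(
    mk_rows(config$n_vehicle_tissues, "vehicle", "", "AOO", 0,
            rep(100, config$n_vehicle_tissues), unit_folds),
    ## viability 0 puts the killed-control delta-abs at the lysis maximum
    mk_rows(config$n_killed_tissues, "killed", "", "AOO", 0,
            rep(0, config$n_killed_tissues), NULL),
    mk_rows(config$n_pc_tissues, "pc_clotrimazole", "", "AOO", 1.56,
            rep(88, config$n_pc_tissues),
            c(ATF3 = 30, GCLM = 1.5, DNAJB4 = 1.5,
              IL8 = if (config$pc_fail) 2 else 8)),
    mk_rows(config$n_pc_tissues, "pc_4nbb", "", "AOO", 0.78,
            rep(85, config$n_pc_tissues),
            c(ATF3 = 2, GCLM = 4.5, DNAJB4 = 4.5, IL8 = 1.5)))

  for (d in doses) {
    folds <- .sim_fold(d, profile$gene_emax, profile$gene_ec50,
                       profile$hill) * bias_fold
    if (!is.null(spurious_gene)) {
      cutoffs <- c(ATF3 = 15, GCLM = 2, DNAJB4 = 2, IL8 = 4)
      folds[spurious_gene] <- cutoffs[spurious_gene] * 2.5
    }
    pieces[[length(pieces) + 1L]] <-
      mk_rows(config$n_test_tissues, "test", profile$code, "AOO", d,
              rep(.sim_viability(d, profile), config$n_test_tissues), folds)
  }
  do.call(rbind, pieces)
}

#' Specificity gain of the two-gene rule
#'
#' Reproduces, on synthetic non-sensitizers with a spurious single-gene
#' activation mechanism, the phenomenon that motivated the modified
#' prediction model: isolated single-gene signals create false positives
#' under the one-gene rule that the two-gene rule suppresses. The same
#' simulated records are evaluated under both rules (identical criteria
#' except `min_active_genes`), so the comparison isolates the rule change.
#'
#' @param config a [simulation_config()].
#' @param n_chemicals number of non-sensitizer profiles.
#' @param spurious_prob per-run probability of the spurious activation.
#' @return List with `per_chemical` (data frame: `chemical_code, lab_id,
#'   call_one_gene, call_two_gene`), and specificities (percent)
#'   `specificity_one_gene`, `specificity_two_gene`.
#' @export
scenario_specificity_gain <- function(config = simulation_config(),
                                      n_chemicals = 20L,
                                      spurious_prob = 0.5) {
  profiles <- lapply(seq_len(n_chemicals), function(i)
    chemical_profile(sprintf("N%02d", i), "non_sensitizer",
                     spurious_single_gene_prob = spurious_prob))
  rec <- simulate_study(profiles, config)
  one <- criteria_set(min_active_genes = 1L, viability_threshold_pct = 60,
                      name = "one-gene")
  two <- criteria_set(min_active_genes = 2L, viability_threshold_pct = 60,
                      name = "two-gene")
  modal <- function(criteria)
    summarize_chemicals(evaluate_study(rec, criteria))
  m1 <- modal(one)
  m2 <- modal(two)
  stopifnot(identical(m1[c("lab_id", "chemical_code")],
                      m2[c("lab_id", "chemical_code")]))
  spec_pct <- function(m) 100 * mean(m$modal_call == "non_sensitizer")
  list(per_chemical = data.frame(chemical_code = m1$chemical_code,
                                 lab_id = m1$lab_id,
                                 call_one_gene = m1$modal_call,
                                 call_two_gene = m2$modal_call,
                                 stringsAsFactors = FALSE),
       specificity_one_gene = spec_pct(m1),
       specificity_two_gene = spec_pct(m2))
}
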