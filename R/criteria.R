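## Marker genes and tunable decision criteria.

.MARKERS <- c("ATF3", "GCLM", "DNAJB4", "IL8")
.REF_GENE <- "GAPDH"
.ROLES <- c("test", "vehicle", "pc_clotrimazole", "pc_4nbb", "killed")
.VEHICLES <- c("AOO", "DW", "EtOH50")
.CALLS <- c("sensitizer", "non_sensitizer", "no_accepted_concentration",
            "invalid_run")

#' Marker and reference genes
#'
#' The assay quantifies four marker genes covering the inflammatory
#' (ATF3, IL-8) and cytoprotective/antioxidant (GCLM, DNAJB4) arms of
#' keratinocyte activation. GAPDH is the reference gene used for
#' normalization only; it never carries an induction cut-off.
#'
#' @return `marker_genes()` returns the four marker gene names;
#'   `reference_gene()` returns `"GAPDH"`.
#' @export
marker_genes <- function() .MARKERS

#' @rdname marker_genes
#' @export
reference_gene <- function() .REF_GENE

#' Decision criteria for run acceptance and classification
#'
#' Bundles every tunable threshold of the prediction model: per-gene fold
#' induction cut-offs, the minimum number of activated genes for a positive
#' call, the concentration-acceptance viability threshold, control
#' acceptance thresholds, and the GAPDH Ct drift tolerance.
#'
#' Two named presets are provided. `vrm_criteria()` is the validated
#' reference method: concentrations accepted at >= 80% viability and a
#' single activated gene suffices for a sensitizer call.
#' `epi2sensa_criteria()` is the modified rule set for the EpiDerm tissue:
#' viability threshold lowered to 60% (the LDH assay tends to overestimate
#' cytotoxicity on this model) and at least two genes must be activated,
#' which suppresses positives driven by an isolated, non-specific signal.
#' Gene cut-offs (ATF3 > 15, GCLM > 2, DNAJB4 > 2, IL8 > 4) are shared.
#'
#' @param gene_cutoffs named numeric, fold-induction cut-off per marker gene
#'   (strict `>` comparison).
#' @param min_active_genes integer in 1..4, minimum number of genes above
#'   cut-off for a sensitizer call.
#' @param viability_threshold_pct percent viability required for a test
#'   concentration to be accepted (boundary inclusive).
#' @param vehicle_viability_min_pct per-tissue viability the vehicle-control
#'   tissues must reach.
#' @param vehicle_min_tissues how many vehicle tissues must reach it.
#' @param pc_viability_min_pct mean viability both positive controls must
#'   reach.
#' @param gapdh_dct_tolerance allowed |mean GAPDH Ct drift| vs the vehicle
#'   control, in Ct units (boundary inclusive).
#' @param pc_clotrimazole_genes,pc_4nbb_genes marker genes each positive
#'   control must induce above cut-off for the run to be valid.
#' @param name label carried through reports.
#' @return An object of class `criteria_set`.
#' @examples
#' epi2sensa_criteria()
#' criteria_set(min_active_genes = 2, viability_threshold_pct = 70,
#'              name = "custom")
#' @export
criteria_set <- function(gene_cutoffs = c(ATF3 = 15, GCLM = 2, DNAJB4 = 2, IL8 = 4),
                         min_active_genes = 2L,
                         viability_threshold_pct = 60,
                         vehicle_viability_min_pct = 95,
                         vehicle_min_tissues = 2L,
                         pc_viability_min_pct = 80,
                         gapdh_dct_tolerance = 1,
                         pc_clotrimazole_genes = c("ATF3", "IL8"),
                         pc_4nbb_genes = c("GCLM", "DNAJB4"),
                         name = "custom") {
  gene_cutoffs <- unlist(gene_cutoffs)
  if (!setequal(names(gene_cutoffs), .MARKERS))
    stop("gene_cutoffs must be named exactly for the four marker genes: ",
         paste(.MARKERS, collapse = ", "), call. = FALSE)
  gene_cutoffs <- gene_cutoffs[.MARKERS]
  min_active_genes <- as.integer(min_active_genes)
  if (is.na(min_active_genes) || min_active_genes < 1L || min_active_genes > 4L)
    stop("min_active_genes must be an integer in 1..4", call. = FALSE)
  if (!all(pc_clotrimazole_genes %in% .MARKERS) ||
      !all(pc_4nbb_genes %in% .MARKERS))
    stop("positive-control gene sets must be marker genes", call. = FALSE)
  stopifnot(viability_threshold_pct > 0, gapdh_dct_tolerance >= 0,
            vehicle_min_tissues >= 1)
  structure(
    list(gene_cutoffs = gene_cutoffs,
         min_active_genes = min_active_genes,
         viability_threshold_pct = viability_threshold_pct,
         vehicle_viability_min_pct = vehicle_viability_min_pct,
         vehicle_min_tissues = as.integer(vehicle_min_tissues),
         pc_viability_min_pct = pc_viability_min_pct,
         gapdh_dct_tolerance = gapdh_dct_tolerance,
         pc_clotrimazole_genes = pc_clotrimazole_genes,
         pc_4nbb_genes = pc_4nbb_genes,
         name = name),
    class = "criteria_set")
}

#' @rdname criteria_set
#' @export
vrm_criteria <- function() {
  criteria_set(min_active_genes = 1L, viability_threshold_pct = 80,
               name = "VRM")
}

#' @rdname criteria_set
#' @export
epi2sensa_criteria <- function() {
  criteria_set(min_active_genes = 2L, viability_threshold_pct = 60,
               name = "Epi2SensA")
}

#' @export
print.criteria_set <- function(x, ...) {
  cat("<criteria_set: ", x$name, ">\n", sep = "")
  cat("  gene cut-offs (fold >):",
      paste(names(x$gene_cutoffs), x$gene_cutoffs, sep = " ", collapse = ", "),
      "\n")
  cat("  sensitizer if >=", x$min_active_genes, "gene(s) activated\n")
  cat("  concentration accepted at viability >=",
      x$viability_threshold_pct, "% and |GAPDH dCt| <=",
      x$gapdh_dct_tolerance, "\n")
  cat("  run validity: >=", x$vehicle_min_tissues, "vehicle tissues >=",
      x$vehicle_viability_min_pct, "%; PC mean viability >=",
      x$pc_viability_min_pct, "%\n")
  invisible(x)
}

#' Read a criteria configuration file
#'
#' Reads a YAML file selecting a named preset (`criteria: VRM` or
#' `criteria: Epi2SensA`) with optional `overrides:` for individual
#' thresholds, e.g.
#'
#' ```yaml
#' criteria: Epi2SensA
#' overrides:
#'   viability_threshold_pct: 70
#'   min_active_genes: 1
#' ```
#'
#' @param path path to a YAML configuration file.
#' @return A [criteria_set()].
#' @export
read_criteria_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base_name <- cfg$criteria %||% "Epi2SensA"
  base <- switch(tolower(base_name),
                 "vrm" = vrm_criteria(),
                 "epi2sensa" = epi2sensa_criteria(),
                 stop("unknown criteria preset: ", base_name, call. = FALSE))
  ov <- cfg$overrides
  if (length(ov)) {
    allowed <- setdiff(names(base), "name")
    bad <- setdiff(names(ov), allowed)
    if (length(bad))
      stop("unknown override field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    args <- base[allowed]
    args[names(ov)] <- ov
    args$name <- paste0(base$name, "*")
    base <- do.call(criteria_set, args)
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Assay reports round `x.x5` upward (91.65 -> 91.7), unlike base R's
#' round-half-to-even. Used for display only; all comparisons in the
#' package use unrounded values.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
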