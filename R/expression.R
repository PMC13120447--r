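## Fold induction of marker genes from Ct values, GAPDH-normalized.

#' Fold induction of the marker genes for one treatment group
#'
#' Standard comparative-Ct quantification with GAPDH as the sole reference
#' gene and amplification efficiency fixed at 2: per tissue and marker,
#' \eqn{\Delta Ct = Ct_{gene} - Ct_{GAPDH}}; \eqn{\Delta\Delta Ct =
#' \Delta Ct_{test} - \overline{\Delta Ct}_{vehicle}}; fold =
#' \eqn{2^{-\Delta\Delta Ct}}. Per-tissue folds are averaged on the linear
#' scale (the run-acceptance criteria speak of mean fold inductions).
#'
#' Also reported is the GAPDH drift `gapdh_delta_ct` = mean test GAPDH Ct
#' minus mean vehicle GAPDH Ct, the quantity checked by [gapdh_qc()].
#'
#' @param test_ct numeric matrix of Ct values for the treated tissues
#'   (rows = tissues, columns named with marker genes present plus
#'   `GAPDH`).
#' @param vehicle_ct same layout for the vehicle-control tissues.
#' @return List with `per_tissue_fold` (tissues x markers matrix),
#'   `mean_fold` (named vector over markers) and `gapdh_delta_ct`.
#' @examples
#' vc <- rbind(c(ATF3 = 25, GCLM = 23, DNAJB4 = 26, IL8 = 27, GAPDH = 18))
#' te <- vc; te[, "ATF3"] <- 21   # 4 cycles earlier: 16-fold
#' fold_induction(te, vc)$mean_fold[["ATF3"]]
#' @export
fold_induction <- function(test_ct, vehicle_ct) {
  test_ct <- .as_ct_matrix(test_ct, "test")
  vehicle_ct <- .as_ct_matrix(vehicle_ct, "vehicle")
  genes <- intersect(.MARKERS, colnames(test_ct))
  if (!length(genes))
    stop("no marker-gene Ct values in test tissues", call. = FALSE)
  if (!all(genes %in% colnames(vehicle_ct)))
    stop("vehicle tissues lack Ct for: ",
         paste(setdiff(genes, colnames(vehicle_ct)), collapse = ", "),
         call. = FALSE)

  dct <- function(m) m[, genes, drop = FALSE] - m[, .REF_GENE]
  vehicle_dct_mean <- colMeans(dct(vehicle_ct))
  ddct <- sweep(dct(test_ct), 2, vehicle_dct_mean)
  folds <- 2^(-ddct)
  list(per_tissue_fold = folds,
       mean_fold = colMeans(folds),
       gapdh_delta_ct = mean(test_ct[, .REF_GENE]) -
         mean(vehicle_ct[, .REF_GENE]))
}

.as_ct_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (is.null(colnames(m)))
    stop(what, " Ct matrix must have gene column names", call. = FALSE)
  if (!(.REF_GENE %in% colnames(m)) || anyNA(m[, .REF_GENE]))
    stop("missing GAPDH Ct in ", what, " tissue(s)",
         if (!is.null(rownames(m)) && .REF_GENE %in% colnames(m))
           paste0(": ", paste(rownames(m)[is.na(m[, .REF_GENE])],
                              collapse = ", ")) else "",
         call. = FALSE)
  keep <- colSums(!is.na(m)) > 0
  m <- m[, keep, drop = FALSE]
  if (any(m <= 0, na.rm = TRUE))
    stop("non-positive Ct value in ", what, " tissues", call. = FALSE)
  m
}

#' GAPDH Ct drift quality control
#'
#' A tested concentration is only interpretable if its mean GAPDH Ct is
#' within the tolerance (default +-1 cycle, boundary inclusive) of the
#' vehicle control's mean GAPDH Ct; larger drift signals global
#' transcription shutdown or RNA degradation rather than specific marker
#' induction.
#'
#' @param gapdh_delta_ct mean test GAPDH Ct minus mean vehicle GAPDH Ct
#'   (from [fold_induction()]); vectorized.
#' @param criteria a [criteria_set()].
#' @return Logical: `TRUE` when |drift| <= tolerance.
#' @export
gapdh_qc <- function(gapdh_delta_ct, criteria = epi2sensa_criteria()) {
  abs(gapdh_delta_ct) <= criteria$gapdh_dct_tolerance
}

## Fold-induction summaries for every treatment group of every run:
## one row per (lab, run, role, chemical, concentration, gene).
run_fold_summaries <- function(records) {
  records <- as.data.frame(records)
  out <- lapply(split(records, paste(records$lab_id, records$run_id)),
                .run_folds)
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

.run_folds <- function(run) {
  veh <- run[run$role == "vehicle", , drop = FALSE]
  if (nrow(veh) == 0L)
    stop("run ", run$run_id[1], ": no vehicle-control tissues for ",
         "fold-induction referencing", call. = FALSE)
  vehicle_ct <- .ct_matrix_of(veh)
  treated <- run[!(run$role %in% c("vehicle", "killed")), , drop = FALSE]
  grp <- paste(treated$role, treated$chemical_code, treated$concentration,
               sep = "\r")
  pieces <- lapply(split(seq_len(nrow(treated)), grp), function(ix) {
    g <- treated[ix, , drop = FALSE]
    ctm <- .ct_matrix_of(g)
    if (is.null(ctm)) return(NULL)
    fi <- fold_induction(ctm, vehicle_ct)
    genes <- names(fi$mean_fold)
    data.frame(lab_id = g$lab_id[1], run_id = g$run_id[1], role = g$role[1],
               chemical_code = g$chemical_code[1],
               concentration = g$concentration[1],
               gene = genes, mean_fold = unname(fi$mean_fold),
               gapdh_delta_ct = fi$gapdh_delta_ct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

.ct_matrix_of <- function(g) {
  m <- as.matrix(g[.ct_cols()])
  colnames(m) <- sub("^ct_", "", colnames(m))
  rownames(m) <- g$tissue_id
  if (all(is.na(m))) return(NULL)  # no qPCR on this group (e.g. MTT-only)
  m
}
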