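## CSV readers/writers for per-tissue assay records.
##
## One row per tissue. Ct values either as wide columns (ct_ATF3 ..
## ct_GAPDH) in the same file, or as a long-format companion file
## (run_id,tissue_id,gene,ct) -- qPCR exports vary, the long form is the
## preferred interchange format.

.ROLE_ALIASES <- c(
  "test" = "test",
  "vehicle" = "vehicle", "vc" = "vehicle", "vehicle_control" = "vehicle",
  "pc_clotrimazole" = "pc_clotrimazole", "clotrimazole" = "pc_clotrimazole",
  "pc_4nbb" = "pc_4nbb", "4nbb" = "pc_4nbb", "4-nbb" = "pc_4nbb",
  "killed" = "killed", "killed_control" = "killed", "kc" = "killed")

.VEHICLE_ALIASES <- setNames(
  c("AOO", "DW", "DW", "EtOH50", "EtOH50", "EtOH50", NA_character_),
  c("aoo", "dw", "water", "etoh50", "50% etoh", "50%etoh", ""))

.MANDATORY_COLS <- c("lab_id", "run_id", "tissue_id", "role", "chemical_code",
                     "vehicle", "concentration", "abs_490", "abs_ref")

.ct_cols <- function() paste0("ct_", c(.MARKERS, .REF_GENE))

.normalize_token <- function(x, table, what, rows) {
  key <- tolower(trimws(x))
  out <- unname(table[key])
  bad <- which(is.na(out) & !(key %in% names(table)))
  if (length(bad))
    stop("unknown ", what, " token(s) ",
         paste0("'", unique(x[bad]), "'", collapse = ", "),
         " at row(s) ", paste(rows[bad], collapse = ", "), call. = FALSE)
  out
}

.as_num <- function(x, col, rows, allow_na = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & (!allow_na | !(is.na(x) | trimws(x) == "")))
  if (length(bad))
    stop("non-numeric value in column '", col, "' at row(s) ",
         paste(rows[bad], collapse = ", "), call. = FALSE)
  out
}

#' Read per-tissue assay records
#'
#' Reads one row per RhE tissue with its identifiers, role, applied
#' chemical/vehicle/concentration, LDH absorbances and (optionally) an
#' externally supplied MTT viability. Ct values may be supplied either as
#' wide `ct_ATF3 .. ct_GAPDH` columns of the same file or as a long-format
#' companion table (`run_id,tissue_id,gene,ct`) via `ct_path`.
#'
#' Role and vehicle tokens are matched case-insensitively
#' (`"Killed"` -> `killed`). Malformed rows are rejected with row-numbered
#' diagnostics; duplicate `(run_id, tissue_id)` pairs and killed-control
#' rows carrying Ct values are integrity errors.
#'
#' @param path CSV with header columns
#'   `lab_id,run_id,tissue_id,role,chemical_code,vehicle,concentration,abs_490,abs_ref`
#'   and optionally `mtt_viability_pct` and/or wide Ct columns.
#' @param ct_path optional long-format Ct companion CSV with columns
#'   `run_id,tissue_id,gene,ct`.
#' @return A data frame of validated tissue records (class
#'   `tissue_records`), one row per tissue, with numeric Ct columns
#'   `ct_ATF3 .. ct_GAPDH` (NA when not measured).
#' @seealso [write_tissue_records()], [simulate_study()]
#' @export
read_tissue_records <- function(path, ct_path = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.MANDATORY_COLS, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  n <- nrow(raw)
  rows <- seq_len(n) + 1L  # header is line 1

  rec <- data.frame(
    lab_id = trimws(raw$lab_id),
    run_id = trimws(raw$run_id),
    tissue_id = trimws(raw$tissue_id),
    role = .normalize_token(raw$role, .ROLE_ALIASES, "role", rows),
    chemical_code = trimws(raw$chemical_code),
    vehicle = .normalize_token(raw$vehicle, .VEHICLE_ALIASES, "vehicle", rows),
    concentration = .as_num(raw$concentration, "concentration", rows),
    abs_490 = .as_num(raw$abs_490, "abs_490", rows),
    abs_ref = .as_num(raw$abs_ref, "abs_ref", rows),
    stringsAsFactors = FALSE)
  rec$mtt_viability_pct <-
    if ("mtt_viability_pct" %in% names(raw))
      .as_num(raw$mtt_viability_pct, "mtt_viability_pct", rows, allow_na = TRUE)
    else NA_real_

  for (cc in .ct_cols())
    rec[[cc]] <- if (cc %in% names(raw))
      .as_num(raw[[cc]], cc, rows, allow_na = TRUE) else NA_real_

  if (!is.null(ct_path)) {
    ct <- utils::read.csv(ct_path, stringsAsFactors = FALSE)
    need <- c("run_id", "tissue_id", "gene", "ct")
    if (!all(need %in% names(ct)))
      stop("Ct companion file must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    gene <- toupper(gsub("[-_ ]", "", ct$gene))
    gene[gene == "IL-8"] <- "IL8"
    bad <- !(gene %in% c(.MARKERS, .REF_GENE))
    if (any(bad))
      stop("unknown gene token(s) in Ct file: ",
           paste(unique(ct$gene[bad]), collapse = ", "), call. = FALSE)
    idx <- match(paste(ct$run_id, ct$tissue_id),
                 paste(rec$run_id, rec$tissue_id))
    if (anyNA(idx))
      stop("Ct file references unknown (run_id, tissue_id): ",
           paste(unique(paste(ct$run_id, ct$tissue_id)[is.na(idx)]),
                 collapse = "; "), call. = FALSE)
    for (i in seq_along(idx))
      rec[[paste0("ct_", gene[i])]][idx[i]] <- as.numeric(ct$ct[i])
  }

  validate_tissue_records(rec, rows)
}

#' Validate a tissue-record table
#'
#' Enforces the structural invariants of the record schema: no duplicate
#' `(run_id, tissue_id)`, non-negative absorbances and concentrations,
#' positive concentration for test tissues, positive Ct values, and no Ct
#' values on killed tissues.
#'
#' @param rec a tissue-record data frame.
#' @param rows original file line numbers used in diagnostics (defaults to
#'   data row index).
#' @return `rec`, invisibly classed as `tissue_records`.
#' @export
validate_tissue_records <- function(rec, rows = seq_len(nrow(rec))) {
  key <- paste(rec$run_id, rec$tissue_id)
  if (anyDuplicated(key))
    stop("duplicate (run_id, tissue_id): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)

  chk <- function(bad, msg) {
    if (any(bad, na.rm = TRUE))
      stop(msg, " at row(s) ", paste(rows[which(bad)], collapse = ", "),
           call. = FALSE)
  }
  chk(is.na(rec$abs_490), "missing abs_490")
  chk(is.na(rec$abs_ref), "missing abs_ref")
  chk(rec$abs_490 < 0 | rec$abs_ref < 0, "negative absorbance")
  chk(is.na(rec$concentration) | rec$concentration < 0,
      "missing or negative concentration")
  chk(rec$role == "test" & rec$concentration <= 0,
      "test tissue with non-positive concentration")
  chk(rec$role == "test" & rec$chemical_code == "",
      "test tissue without chemical_code")
  ctm <- as.matrix(rec[.ct_cols()])
  chk(rec$role == "killed" & rowSums(!is.na(ctm)) > 0,
      "killed-control tissue carries Ct values")
  chk(apply(ctm, 1, function(z) any(!is.na(z) & z <= 0)),
      "non-positive Ct value")
  class(rec) <- c("tissue_records", "data.frame")
  invisible(rec)
}

#' Write per-tissue assay records
#'
#' Inverse of [read_tissue_records()]. With `ct_path`, Ct values are
#' written to a long-format companion file and omitted from the main file;
#' otherwise they are written as wide columns. A read of the written
#' file(s) reproduces the input field-for-field.
#'
#' @param records a tissue-record data frame.
#' @param path output CSV path.
#' @param ct_path optional path for the long-format Ct companion file.
#' @return `records`, invisibly.
#' @export
write_tissue_records <- function(records, path, ct_path = NULL) {
  out <- as.data.frame(records)
  if (!is.null(ct_path)) {
    ctm <- as.matrix(out[.ct_cols()])
    keep <- which(!is.na(ctm), arr.ind = TRUE)
    ct_long <- data.frame(
      run_id = out$run_id[keep[, 1]],
      tissue_id = out$tissue_id[keep[, 1]],
      gene = sub("^ct_", "", .ct_cols()[keep[, 2]]),
      ct = ctm[keep])
    ct_long <- ct_long[order(ct_long$run_id, ct_long$tissue_id, ct_long$gene), ]
    utils::write.csv(ct_long, ct_path, row.names = FALSE, quote = FALSE)
    out <- out[setdiff(names(out), .ct_cols())]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(records)
}
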