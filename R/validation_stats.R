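## Mode aggregation, WLR/BLR, predictivity, Performance-Standards report.

#' Aggregate repeated run calls for one chemical in one laboratory
#'
#' Chemicals tested in several independent runs are summarized by the
#' mode of the valid run calls (the most frequent result). Invalid runs
#' are excluded before aggregation. A three-way tie (all calls different)
#' has no mode and is surfaced as an error, never silently broken.
#'
#' @param calls character vector of run calls
#'   (`sensitizer` / `non_sensitizer` / ...).
#' @return List with `modal_call`, `concordant` (all valid calls
#'   identical) and `n_valid`.
#' @examples
#' aggregate_runs(c("sensitizer", "sensitizer", "non_sensitizer"))
#' @export
aggregate_runs <- function(calls) {
  calls <- as.character(calls)  # factors would retain zero-count levels
  calls <- calls[calls != "invalid_run"]
  if (length(calls) == 0L)
    stop("no valid runs to aggregate", call. = FALSE)
  tab <- sort(table(calls), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2])
    stop("unresolved mode: run calls tie (",
         paste(names(tab), tab, sep = "x", collapse = ", "), ")",
         call. = FALSE)
  list(modal_call = names(tab)[1],
       concordant = length(tab) == 1L,
       n_valid = length(calls))
}

#' Per-(laboratory, chemical) modal calls
#'
#' Applies [aggregate_runs()] to every (lab, chemical) group of a per-run
#' call table, the shape produced by [evaluate_study()] (or the packaged
#' [load_study_calls()] fixture after renaming its call column to `call`).
#'
#' @param run_calls data frame with columns `lab_id, chemical_code, call`.
#' @return Data frame with one row per (lab, chemical): `lab_id,
#'   chemical_code, modal_call, concordant, n_valid`.
#' @export
summarize_chemicals <- function(run_calls) {
  stopifnot(all(c("lab_id", "chemical_code", "call") %in% names(run_calls)))
  grp <- split(run_calls, list(run_calls$lab_id, run_calls$chemical_code),
               drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    agg <- aggregate_runs(g$call)
    data.frame(lab_id = g$lab_id[1], chemical_code = g$chemical_code[1],
               modal_call = agg$modal_call, concordant = agg$concordant,
               n_valid = agg$n_valid, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$lab_id, out$chemical_code), ]
  rownames(out) <- NULL
  out
}

#' Within-laboratory reproducibility
#'
#' The fraction of repeat-tested chemicals whose valid run calls are fully
#' concordant within one laboratory. The reproducibility panel holds 12
#' chemicals tested in three independent runs; a different count is
#' computed over what is available, with a warning.
#'
#' @param summaries per-chemical summaries for one laboratory
#'   ([summarize_chemicals()] rows with `n_valid >= 2`, or all rows —
#'   single-run chemicals are dropped here).
#' @return Fraction in \[0, 1\].
#' @export
wlr <- function(summaries) {
  rep_tested <- summaries[summaries$n_valid >= 2L, , drop = FALSE]
  if (nrow(rep_tested) != 12L)
    warning("WLR panel normally holds 12 repeat-tested chemicals; computing ",
            "over ", nrow(rep_tested), call. = FALSE)
  if (nrow(rep_tested) == 0L) return(NA_real_)
  mean(rep_tested$concordant)
}

#' Between-laboratory reproducibility
#'
#' The fraction of panel chemicals whose modal calls agree across every
#' laboratory that tested them. Chemicals tested by fewer than two
#' laboratories are excluded with a warning. Note the available-lab
#' denominator: in the validation design the three main laboratories test
#' all 20 chemicals while the fourth contributes single runs on an
#' 8-chemical subset, so concordance is over 3 or 4 laboratories depending
#' on the chemical.
#'
#' @param summaries [summarize_chemicals()] output across laboratories.
#' @return Fraction in \[0, 1\].
#' @export
blr <- function(summaries) {
  grp <- split(summaries, summaries$chemical_code)
  n_labs <- vapply(grp, nrow, integer(1))
  if (any(n_labs < 2L)) {
    warning("excluding chemical(s) tested by <2 laboratories: ",
            paste(names(grp)[n_labs < 2L], collapse = ", "), call. = FALSE)
    grp <- grp[n_labs >= 2L]
  }
  if (!length(grp)) return(NA_real_)
  mean(vapply(grp, function(g) length(unique(g$modal_call)) == 1L,
              logical(1)))
}

#' Predictive capacity against in vivo reference classes
#'
#' Compares modal calls to the in vivo (LLNA-derived) classes of the
#' reference panel. `sensitizer` against an in vivo sensitizer is a true
#' positive, etc. Chemicals whose call is `no_accepted_concentration` are
#' excluded from the confusion matrix; their count is reported.
#'
#' @param modal_calls named character vector (names = chemical codes) of
#'   calls, or a [summarize_chemicals()] data frame for one laboratory.
#' @param reference reference panel data frame ([load_reference_panel()])
#'   or named character vector of in vivo classes.
#' @return List with `confusion` (`tp, fp, tn, fn`), `n_classified`,
#'   `n_unclassified`, and percents `sensitivity, specificity, accuracy,
#'   balanced_accuracy` (unrounded; use [round_half_up()] at 1 decimal for
#'   display).
#' @export
predictivity <- function(modal_calls, reference = load_reference_panel()) {
  if (is.data.frame(modal_calls))
    modal_calls <- setNames(modal_calls$modal_call,
                            modal_calls$chemical_code)
  if (is.data.frame(reference))
    reference <- setNames(reference$in_vivo_class, reference$code)
  if (!all(names(modal_calls) %in% names(reference)))
    stop("call(s) for chemical(s) absent from the reference panel: ",
         paste(setdiff(names(modal_calls), names(reference)), collapse = ", "),
         call. = FALSE)
  unclassified <- modal_calls %in%
    c("no_accepted_concentration", "invalid_run")
  calls <- modal_calls[!unclassified]
  truth <- reference[names(calls)]
  tp <- sum(calls == "sensitizer" & truth == "sensitizer")
  fp <- sum(calls == "sensitizer" & truth == "non_sensitizer")
  tn <- sum(calls == "non_sensitizer" & truth == "non_sensitizer")
  fn <- sum(calls == "non_sensitizer" & truth == "sensitizer")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  list(confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       n_classified = length(calls),
       n_unclassified = sum(unclassified),
       sensitivity = sens, specificity = spec,
       accuracy = 100 * (tp + tn) / (tp + fp + tn + fn),
       balanced_accuracy = (sens + spec) / 2)
}

#' Study-level reproducibility and predictivity metrics
#'
#' Computes, from a per-run call table, everything the interlaboratory
#' validation reports: per-laboratory WLR and the unweighted average over
#' the repeat-testing laboratories, BLR across all laboratories,
#' per-laboratory confusion matrices and predictivity percentages with
#' their unweighted averages, and pass/fail against the Performance
#' Standards minima (see [ps_report()]). Averages over laboratories are
#' unweighted arithmetic means of the per-laboratory percentages;
#' laboratories that only contribute single runs (no WLR panel) enter BLR
#' but neither the WLR nor the predictivity averages.
#'
#' @param run_calls data frame with columns `lab_id, chemical_code, call`
#'   (one row per valid run; see [evaluate_study()]).
#' @param reference reference panel ([load_reference_panel()]).
#' @param criteria_name label carried into the report.
#' @return Object of class `study_metrics`: per-lab and average WLR
#'   (percent), BLR (percent), per-lab confusion and predictivity, average
#'   sensitivity/specificity/accuracy/balanced accuracy, and `ps_pass`.
#' @export
compute_study_metrics <- function(run_calls,
                                  reference = load_reference_panel(),
                                  criteria_name = "Epi2SensA") {
  summaries <- summarize_chemicals(run_calls)
  labs <- unique(summaries$lab_id)
  per_lab <- split(summaries, summaries$lab_id)

  wlr_labs <- labs[vapply(per_lab, function(s) any(s$n_valid >= 2L),
                          logical(1))[labs]]
  wlr_per_lab <- vapply(per_lab[wlr_labs], function(s) 100 * wlr(s),
                        numeric(1))
  pred_per_lab <- lapply(per_lab[wlr_labs], predictivity,
                         reference = reference)
  avg <- function(field)
    mean(vapply(pred_per_lab, `[[`, numeric(1), field))

  metrics <- structure(
    list(criteria_name = criteria_name,
         wlr_per_lab = wlr_per_lab,
         wlr_average = mean(wlr_per_lab),
         blr = 100 * blr(summaries),
         per_lab_predictivity = pred_per_lab,
         sensitivity = avg("sensitivity"),
         specificity = avg("specificity"),
         accuracy = avg("accuracy"),
         balanced_accuracy = avg("balanced_accuracy")),
    class = "study_metrics")
  metrics$ps_pass <- .ps_pass(metrics)
  metrics
}

## OECD Performance Standards minima for EpiSensA-like methods
.PS_MINIMA <- c(wlr_average = 80, blr = 80, sensitivity = 85,
                specificity = 65, accuracy = 85)

.ps_pass <- function(metrics) {
  vapply(names(.PS_MINIMA), function(k)
    isTRUE(metrics[[k]] >= .PS_MINIMA[[k]]), logical(1))
}

#' Performance-Standards pass/fail table
#'
#' Compares the study metrics to the OECD Performance Standards minima
#' for EpiSensA-like methods: average WLR >= 80%, BLR >= 80%,
#' sensitivity >= 85%, specificity >= 65%, accuracy >= 85%. Comparisons
#' use unrounded values; the displayed values are rounded half-up to one
#' decimal, the convention of assay reports.
#'
#' @param metrics a `study_metrics` object, or a named numeric vector with
#'   entries `wlr_average, blr, sensitivity, specificity, accuracy`
#'   (percents).
#' @return Data frame with one row per criterion: `criterion, minimum_pct,
#'   value_pct, pass`.
#' @export
ps_report <- function(metrics) {
  vals <- if (inherits(metrics, "study_metrics"))
    vapply(names(.PS_MINIMA), function(k) metrics[[k]], numeric(1))
  else unlist(metrics)[names(.PS_MINIMA)]
  data.frame(criterion = names(.PS_MINIMA),
             minimum_pct = unname(.PS_MINIMA),
             value_pct = round_half_up(unname(vals), 1),
             pass = unname(vals >= .PS_MINIMA),
             row.names = NULL)
}

#' @export
print.study_metrics <- function(x, ...) {
  r1 <- function(v) format(round_half_up(v, 1), nsmall = 1)
  cat("<study_metrics> criteria:", x$criteria_name, "\n")
  cat("  WLR per lab:",
      paste(names(x$wlr_per_lab), r1(x$wlr_per_lab), sep = "=",
            collapse = ", "),
      "| average:", r1(x$wlr_average), "%\n")
  cat("  BLR:", r1(x$blr), "%\n")
  cat("  average sensitivity:", r1(x$sensitivity),
      "% specificity:", r1(x$specificity),
      "% accuracy:", r1(x$accuracy),
      "% balanced accuracy:", r1(x$balanced_accuracy), "%\n")
  cat("  Performance Standards:",
      if (all(x$ps_pass)) "all criteria met"
      else paste("FAILS", paste(names(x$ps_pass)[!x$ps_pass],
                                collapse = ", ")), "\n")
  invisible(x)
}
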