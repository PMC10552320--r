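#' Diagnostic report objects
#'
#' A diagnostic report bundles the validation-phase outputs for one panel:
#' the LOOCV ROC (AUC with 95% CI), the Youden cutoff, the confusion counts
#' and derived metrics with exact confidence intervals, and subgroup
#' detection rates. Reports serialize to versioned JSON.
#'
#' @param auc AUC on \[0, 1\].
#' @param auc_ci Length-2 numeric 95% CI for the AUC.
#' @param cutoff Youden threshold on the score scale.
#' @param confusion Tibble from [confusion_metrics()].
#' @param subgroups Optional tibble of subgroup detection rates.
#' @param panel Character vector of marker ids.
#' @return A `mp_report` list.
#' @export
diagnostic_report <- function(auc, auc_ci = c(NA_real_, NA_real_), cutoff = NA_real_,
                              confusion, subgroups = NULL, panel = character()) {
  if (is.null(confusion) || !all(c("metric", "estimate") %in% names(confusion))) {
    mp_stop("report requires a confusion-metric table with counts",
            class = "methpanel_schema_error")
  }
  structure(
    list(schema_version = 1L, panel = panel, auc = auc, auc_ci = auc_ci,
         cutoff = cutoff, confusion = confusion, subgroups = subgroups),
    class = "mp_report"
  )
}

#' Write a diagnostic report to JSON
#'
#' @param report An `mp_report` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "mp_report")) {
    mp_stop("write_report expects an mp_report", class = "methpanel_schema_error")
  }
  payload <- report
  class(payload) <- NULL
  payload$confusion <- as.data.frame(report$confusion)
  if (!is.null(report$subgroups)) payload$subgroups <- as.data.frame(report$subgroups)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a diagnostic report from JSON
#'
#' @param path JSON path written by [write_report()].
#' @return An `mp_report` object.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$confusion)) {
    mp_stop("report JSON lacks the confusion table",
            class = "methpanel_schema_error")
  }
  diagnostic_report(
    auc = payload$auc,
    auc_ci = as.numeric(payload$auc_ci),
    cutoff = payload$cutoff %||% NA_real_,
    confusion = tibble::as_tibble(payload$confusion),
    subgroups = if (!is.null(payload$subgroups)) tibble::as_tibble(payload$subgroups),
    panel = as.character(payload$panel %||% character())
  )
}
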