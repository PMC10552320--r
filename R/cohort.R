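#' Clinical finding categories and the neoplasia class they map to
#'
#' Subjects are classified by their most advanced colorectal finding. Advanced
#' neoplasia (AN) comprises advanced adenomas (AA) and colorectal cancer (CRC);
#' everything else — no colorectal findings (NCF), benign pathology
#' (hemorrhoids, diverticula) and non-advanced adenomas (NAA) — counts as no
#' neoplasia (NN).
#'
#' @name cohort-vocabulary
#' @keywords internal
NULL

finding_levels <- function() {
  c("NCF", "BEN_hemorrhoids", "BEN_diverticula", "NAA", "AA", "CRC")
}

stage_levels <- function() c("I", "II", "III", "IV", "none")
location_levels <- function() c("distal", "proximal", "none")
cohort_levels <- function() {
  c("discovery", "evaluation", "validation", "external_tumor", "unassigned")
}

#' Derive the binary neoplasia class from a colorectal finding
#'
#' Total, deterministic mapping: `AA` and `CRC` are advanced neoplasia
#' (`"AN"`); `NCF`, `BEN_hemorrhoids`, `BEN_diverticula` and `NAA` are no
#' neoplasia (`"NN"`).
#'
#' @param finding Character vector of finding codes (see Details).
#' @return Character vector of `"NN"` / `"AN"`, same length as `finding`.
#' @export
#' @examples
#' an_class(c("NCF", "AA", "CRC", "NAA"))
an_class <- function(finding) {
  bad <- setdiff(unique(finding), finding_levels())
  if (length(bad) > 0L) {
    mp_stop(sprintf("unknown finding value(s): %s", paste(bad, collapse = ", ")),
            class = "methpanel_validation_error")
  }
  ifelse(finding %in% c("AA", "CRC"), "AN", "NN")
}

#' Pathological group used for pooling
#'
#' Maps finding + lesion location + stage to the seven pooling groups:
#' `NCF`, `BEN`, `NAA`, `P-AA`, `D-AA`, `CRC_I-II`, `CRC_III-IV`.
#'
#' @param finding,location,stage Vectors as in a cohort table.
#' @return Character vector of group labels.
#' @export
pathological_group <- function(finding, location, stage) {
  dplyr::case_when(
    finding == "NCF" ~ "NCF",
    finding %in% c("BEN_hemorrhoids", "BEN_diverticula") ~ "BEN",
    finding == "NAA" ~ "NAA",
    finding == "AA" & location == "proximal" ~ "P-AA",
    finding == "AA" & location == "distal" ~ "D-AA",
    finding == "CRC" & stage %in% c("I", "II") ~ "CRC_I-II",
    finding == "CRC" & stage %in% c("III", "IV") ~ "CRC_III-IV",
    TRUE ~ NA_character_
  )
}

#' Validate a cohort table
#'
#' Checks the invariants a cohort table must satisfy: closed category sets,
#' stage present iff CRC, lesion location present iff AA/CRC, screening ages
#' within the recruitment window (50-75 years; subjects in the
#' `external_tumor` cohort are exempt), and a derivable NN/AN class.
#'
#' @param cohort A data frame with columns `subject_id`, `sex`, `age`,
#'   `hospital`, `finding`, and optionally `stage`, `location`, `cohort`,
#'   `tumor_type`.
#' @param age_window Integer length-2 inclusion window for screening subjects.
#' @return The validated cohort as a tibble, with a `class` column added.
#' @export
validate_cohort <- function(cohort, age_window = c(50L, 75L)) {
  cohort <- tibble::as_tibble(cohort)
  assert_columns(cohort, c("subject_id", "sex", "age", "hospital", "finding"),
                 "cohort table")
  if (nrow(cohort) == 0L) {
    cohort$class <- character(0)
    return(cohort)
  }
  if (anyDuplicated(cohort$subject_id)) {
    mp_stop("duplicated subject_id in cohort table",
            class = "methpanel_validation_error")
  }
  if (!all(cohort$sex %in% c("male", "female"))) {
    mp_stop("sex must be 'male' or 'female'",
            class = "methpanel_validation_error")
  }
  assert_in_range(cohort$age, 18, 120, "age")
  if (!("stage" %in% names(cohort))) cohort$stage <- "none"
  if (!("location" %in% names(cohort))) cohort$location <- "none"
  if (!("cohort" %in% names(cohort))) cohort$cohort <- "unassigned"
  if (!all(cohort$stage %in% stage_levels())) {
    mp_stop("stage outside {I, II, III, IV, none}",
            class = "methpanel_validation_error")
  }
  if (!all(cohort$location %in% location_levels())) {
    mp_stop("location outside {distal, proximal, none}",
            class = "methpanel_validation_error")
  }
  if (!all(cohort$cohort %in% cohort_levels())) {
    mp_stop("unknown cohort assignment value",
            class = "methpanel_validation_error")
  }
  screening <- cohort$cohort != "external_tumor"
  out_of_window <- screening &
    (cohort$age < age_window[1] | cohort$age > age_window[2])
  if (any(out_of_window)) {
    mp_stop(sprintf(
      "%d screening subject(s) outside the [%d, %d] year inclusion window",
      sum(out_of_window), age_window[1], age_window[2]),
      class = "methpanel_validation_error")
  }
  stage_bad <- (cohort$finding == "CRC") != (cohort$stage != "none")
  if (any(stage_bad)) {
    mp_stop("stage must be set iff finding is CRC (violations present)",
            class = "methpanel_validation_error")
  }
  loc_bad <- (cohort$finding %in% c("AA", "CRC")) != (cohort$location != "none")
  if (any(loc_bad)) {
    mp_stop("location must be set iff finding is AA or CRC",
            class = "methpanel_validation_error")
  }
  cohort$class <- an_class(cohort$finding)
  cohort
}

#' Read a sample sheet
#'
#' Reads a subject-level CSV sample sheet (one row per subject) and validates
#' it. Required columns: `subject_id`, `sex`, `age`, `hospital`, `finding`;
#' optional: `stage`, `location`, `cohort`, `aa_histology`, `aa_dysplasia`,
#' `tumor_type`. Unknown finding strings and invariant violations are
#' rejected with an informative error. The binary NN/AN class is derived and
#' attached.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated cohort tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(df)
}

#' Write a cohort table to CSV
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}
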