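#' Default composition of the synthetic study population
#'
#' One row per (cohort, finding, location, stage) cell, giving the number of
#' subjects to generate. The defaults mirror the three-cohort screening
#' design: a 280-subject discovery cohort (130 NN / 150 AN, sized so that
#' every pooling group holds a multiple of ten sex-balanced subjects), a
#' 48-subject biomarker evaluation cohort (21 NN / 27 AN) and a 105-subject
#' model validation cohort (39 NN, 23 distal AA, 19 proximal AA, 24 CRC).
#'
#' @return A tibble with columns `cohort`, `finding`, `location`, `stage`, `n`.
#' @export
cohort_composition <- function() {
  tribble_row <- function(cohort, finding, location, stage, n) {
    tibble::tibble(cohort = cohort, finding = finding, location = location,
                   stage = stage, n = n)
  }
  dplyr::bind_rows(
    # discovery: 280 = NCF 30 + BEN 50 + NAA 50 + AA 100 + CRC 50
    tribble_row("discovery", "NCF", "none", "none", 30L),
    tribble_row("discovery", "BEN_hemorrhoids", "none", "none", 25L),
    tribble_row("discovery", "BEN_diverticula", "none", "none", 25L),
    tribble_row("discovery", "NAA", "none", "none", 50L),
    tribble_row("discovery", "AA", "distal", "none", 50L),
    tribble_row("discovery", "AA", "proximal", "none", 50L),
    tribble_row("discovery", "CRC", "distal", "I", 12L),
    tribble_row("discovery", "CRC", "distal", "II", 11L),
    tribble_row("discovery", "CRC", "distal", "III", 11L),
    tribble_row("discovery", "CRC", "distal", "IV", 5L),
    tribble_row("discovery", "CRC", "proximal", "I", 4L),
    tribble_row("discovery", "CRC", "proximal", "II", 3L),
    tribble_row("discovery", "CRC", "proximal", "III", 3L),
    tribble_row("discovery", "CRC", "proximal", "IV", 1L),
    # evaluation: 48 = 21 NN + 16 AA + 11 CRC
    tribble_row("evaluation", "NCF", "none", "none", 7L),
    tribble_row("evaluation", "BEN_hemorrhoids", "none", "none", 3L),
    tribble_row("evaluation", "BEN_diverticula", "none", "none", 4L),
    tribble_row("evaluation", "NAA", "none", "none", 7L),
    tribble_row("evaluation", "AA", "distal", "none", 8L),
    tribble_row("evaluation", "AA", "proximal", "none", 8L),
    tribble_row("evaluation", "CRC", "distal", "I", 3L),
    tribble_row("evaluation", "CRC", "distal", "II", 2L),
    tribble_row("evaluation", "CRC", "distal", "III", 3L),
    tribble_row("evaluation", "CRC", "distal", "IV", 1L),
    tribble_row("evaluation", "CRC", "proximal", "II", 1L),
    tribble_row("evaluation", "CRC", "proximal", "III", 1L),
    # validation: 105 = 39 NN + 42 AA + 24 CRC
    tribble_row("validation", "NCF", "none", "none", 15L),
    tribble_row("validation", "BEN_hemorrhoids", "none", "none", 8L),
    tribble_row("validation", "BEN_diverticula", "none", "none", 5L),
    tribble_row("validation", "NAA", "none", "none", 11L),
    tribble_row("validation", "AA", "distal", "none", 23L),
    tribble_row("validation", "AA", "proximal", "none", 19L),
    tribble_row("validation", "CRC", "distal", "I", 4L),
    tribble_row("validation", "CRC", "distal", "II", 4L),
    tribble_row("validation", "CRC", "distal", "III", 1L),
    tribble_row("validation", "CRC", "distal", "IV", 3L),
    tribble_row("validation", "CRC", "proximal", "I", 4L),
    tribble_row("validation", "CRC", "proximal", "II", 4L),
    tribble_row("validation", "CRC", "proximal", "III", 1L),
    tribble_row("validation", "CRC", "proximal", "IV", 3L)
  )
}

#' Generate a synthetic screening cohort
#'
#' Expands a composition table into per-subject records: sexes are balanced
#' within each (cohort, pathological group) stratum — alternating
#' male/female, so any stratum of even size splits exactly 50/50 and pool
#' construction can always find 5 men and 5 women per group — ages are drawn
#' uniformly on the screening inclusion window \[50, 75\], and subjects are
#' cycled through the recruitment hospitals. Deterministic for a fixed seed.
#'
#' @param composition Tibble as returned by [cohort_composition()].
#' @param seed Integer seed.
#' @param hospitals Character vector of recruitment hospital labels.
#' @param age_range Inclusive integer age window.
#' @return A validated cohort tibble with a derived `class` column.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' table(cohort$cohort)
generate_cohort <- function(composition = cohort_composition(), seed = 1L,
                            hospitals = paste0("H", 1:4),
                            age_range = c(50L, 75L)) {
  composition <- tibble::as_tibble(composition)
  if (nrow(composition) == 0L || sum(composition$n) == 0L) {
    return(validate_cohort(tibble::tibble(
      subject_id = character(), sex = character(), age = integer(),
      hospital = character(), finding = character(), stage = character(),
      location = character(), cohort = character()
    )))
  }
  assert_columns(composition, c("cohort", "finding", "location", "stage", "n"),
                 "cohort composition")
  with_seed(derive_seed(seed, 1L), {
    rows <- purrr::pmap(composition, function(cohort, finding, location, stage, n) {
      if (n == 0L) return(NULL)
      tibble::tibble(cohort = cohort, finding = finding, location = location,
                     stage = stage)[rep(1L, n), ]
    })
    out <- dplyr::bind_rows(rows)
    out$group <- pathological_group(out$finding, out$location, out$stage)
    out <- out |>
      dplyr::group_by(.data$cohort, .data$group) |>
      dplyr::mutate(sex = rep(c("male", "female"), length.out = dplyr::n())) |>
      dplyr::ungroup() |>
      dplyr::select(-"group")
    out$subject_id <- sprintf("S%04d", seq_len(nrow(out)))
    out$age <- as.integer(floor(runif(nrow(out), age_range[1], age_range[2] + 1L)))
    out$hospital <- rep(hospitals, length.out = nrow(out))
    validate_cohort(out[, c("subject_id", "sex", "age", "hospital", "finding",
                            "stage", "location", "cohort")])
  })
}
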