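#' Construct a beta-value matrix
#'
#' A beta matrix holds methylation fractions (beta-values, in \[0, 1\]) as a
#' numeric matrix with probes in rows and samples in columns. The `level`
#' attribute records whether columns are individual subjects or cfDNA pools.
#' Missing measurements are `NA` (explicitly flagged), never out-of-range
#' numbers.
#'
#' @param values Numeric matrix with unique rownames (probe ids) and unique
#'   colnames (sample ids).
#' @param level `"individual"` or `"pool"`.
#' @return The validated matrix with class `mp_beta` and a `level` attribute.
#' @export
beta_matrix <- function(values, level = c("individual", "pool")) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values)) {
    mp_stop("beta values must be a numeric matrix",
            class = "methpanel_validation_error")
  }
  if (nrow(values) == 0L && is.null(rownames(values))) {
    rownames(values) <- character(0)
  }
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    mp_stop("beta matrix needs probe rownames and sample colnames",
            class = "methpanel_validation_error")
  }
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    mp_stop(sprintf("duplicated probe id(s): %s",
                    paste(head(dups, 5L), collapse = ", ")),
            class = "methpanel_validation_error")
  }
  if (anyDuplicated(colnames(values))) {
    mp_stop("duplicated sample ids in beta matrix",
            class = "methpanel_validation_error")
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    first <- bad[1L, ]
    mp_stop(sprintf(
      "beta values outside [0,1]: %d cell(s); first at probe %s, sample %s",
      nrow(bad), rownames(values)[first[1L]], colnames(values)[first[2L]]),
      class = "methpanel_validation_error")
  }
  structure(values, level = level, class = c("mp_beta", class(values)))
}

#' @export
print.mp_beta <- function(x, ...) {
  cat(sprintf("<beta matrix: %d probes x %d %s samples, %d missing>\n",
              nrow(x), ncol(x), attr(x, "level"), sum(is.na(x))))
  invisible(x)
}

beta_level <- function(beta) attr(beta, "level") %||% "individual"

#' Read a beta-value matrix from TSV
#'
#' First column must hold probe ids; remaining columns are numeric
#' beta-values in \[0, 1\]. Duplicated probe ids, non-numeric cells and
#' out-of-range values are rejected with their location.
#'
#' @param path TSV file path.
#' @param level Measurement level of the columns (`"individual"` or `"pool"`).
#' @return An `mp_beta` matrix.
#' @export
read_beta_matrix <- function(path, level = c("individual", "pool")) {
  level <- match.arg(level)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2L) {
    mp_stop("beta matrix TSV needs a probe-id column plus >= 1 sample column",
            class = "methpanel_schema_error")
  }
  probe_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppress <- suppressWarnings(num <- apply(vals, 2L, as.numeric))
  nonnum <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(nonnum) > 0L) {
    first <- nonnum[1L, ]
    mp_stop(sprintf("non-numeric cell at probe %s, sample %s: '%s'",
                    probe_ids[first[1L]], colnames(vals)[first[2L]],
                    vals[first[1L], first[2L]]),
            class = "methpanel_parse_error")
  }
  num <- matrix(num, nrow = length(probe_ids),
                dimnames = list(probe_ids, colnames(vals)))
  beta_matrix(num, level = level)
}

#' Write a beta-value matrix to TSV
#'
#' Values are written at fixed decimal precision so that write/read round
#' trips are lossless at that precision.
#'
#' @param beta An `mp_beta` matrix.
#' @param path Output TSV path.
#' @param digits Decimal digits retained (default 6).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, digits = 6L) {
  df <- tibble::as_tibble(round(unclass(beta), digits), rownames = "probe_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' TSV with columns `probe_id`, `chrom`, `pos` (1-based GRCh37),
#' `gene_symbol`, `island_relation` (Island / Shore / Shelf / OpenSea) and
#' `genic_feature` (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR,
#' intergenic).
#'
#' @param path TSV file path.
#' @return A tibble, one row per probe.
#' @export
read_probe_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(ann, c("probe_id", "chrom", "pos", "island_relation",
                        "genic_feature"), "probe annotation")
  if (anyDuplicated(ann$probe_id)) {
    mp_stop("duplicated probe_id in annotation",
            class = "methpanel_validation_error")
  }
  if (!all(ann$island_relation %in% island_levels())) {
    mp_stop("island_relation outside {Island, Shore, Shelf, OpenSea}",
            class = "methpanel_validation_error")
  }
  if (!all(ann$genic_feature %in% genic_levels())) {
    mp_stop("unknown genic_feature value",
            class = "methpanel_validation_error")
  }
  tibble::as_tibble(ann)
}

island_levels <- function() c("Island", "Shore", "Shelf", "OpenSea")
genic_levels <- function() {
  c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR", "intergenic")
}

#' Read / write a pyrosequencing table
#'
#' Long-format CSV with columns `sample_id`, `marker_id`,
#' `percent_methylation` (0-100, `NA` allowed for failed assays). Duplicate
#' (sample, marker) pairs are rejected.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_pyro_table <- function(path) {
  pyro <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_pyro(pyro)
}

validate_pyro <- function(pyro) {
  pyro <- tibble::as_tibble(pyro)
  assert_columns(pyro, c("sample_id", "marker_id", "percent_methylation"),
                 "pyrosequencing table")
  assert_in_range(pyro$percent_methylation, 0, 100, "percent_methylation",
                  na_ok = TRUE)
  if (anyDuplicated(pyro[, c("sample_id", "marker_id")])) {
    mp_stop("duplicated (sample_id, marker_id) pair in pyrosequencing table",
            class = "methpanel_validation_error")
  }
  pyro
}

#' @rdname read_pyro_table
#' @param pyro A validated pyrosequencing tibble.
#' @export
write_pyro_table <- function(pyro, path) {
  readr::write_csv(validate_pyro(pyro), path, progress = FALSE)
  invisible(path)
}
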