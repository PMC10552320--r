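#' Build the multivariate design for penalized panel selection
#'
#' Pivots a long pyrosequencing table to samples-by-markers, joins age and
#' sex from the cohort table, applies the configured transform
#' (`log10(x + 1)` so a 0% measurement maps to 0, or raw percents), and
#' standardizes every feature to zero mean / unit variance, storing the
#' scaling for back-transformation. Samples missing any marker are dropped
#' with a log message; zero-variance features are dropped with a warning.
#'
#' @param pyro Long pyrosequencing tibble.
#' @param cohort Cohort tibble supplying `age`, `sex` and the NN/AN class.
#' @param transform `"log10"` or `"raw"`.
#' @return An `mp_design` list: `x` (standardized feature matrix), `y`
#'   (factor NN/AN), `sample_id`, `center`, `scale`, `transform`,
#'   `dropped_samples`.
#' @export
build_design <- function(pyro, cohort, transform = c("log10", "raw")) {
  transform <- match.arg(transform)
  pyro <- validate_pyro(pyro)
  wide <- tidyr::pivot_wider(pyro, id_cols = "sample_id",
                             names_from = "marker_id",
                             values_from = "percent_methylation")
  complete <- stats::complete.cases(wide)
  dropped <- wide$sample_id[!complete]
  if (length(dropped) > 0L) {
    inform(sprintf("dropped %d sample(s) with missing marker measurements",
                   length(dropped)))
  }
  wide <- wide[complete, ]
  cohort <- validate_cohort(cohort)
  idx <- match(wide$sample_id, cohort$subject_id)
  if (anyNA(idx)) {
    mp_stop("pyrosequencing samples absent from the cohort table",
            class = "methpanel_validation_error")
  }
  markers <- as.matrix(wide[, -1L, drop = FALSE])
  if (transform == "log10") markers <- log10(markers + 1)
  x <- cbind(markers,
             age = cohort$age[idx],
             sex = as.numeric(cohort$sex[idx] == "male"))
  keep <- apply(x, 2L, sd) > 0
  if (any(!keep)) {
    warn(sprintf("dropped zero-variance feature(s): %s",
                 paste(colnames(x)[!keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2L, sd)
  x_std <- scale(x, center = center, scale = scale_)
  structure(list(
    x = x_std, x_raw = x, y = factor(cohort$class[idx], levels = c("NN", "AN")),
    sample_id = wide$sample_id, center = center, scale = scale_,
    transform = transform, dropped_samples = dropped
  ), class = "mp_design")
}

#' Penalized logistic panel selection
#'
#' Fits the lasso (`alpha = 1`) or elastic net along a penalty grid with
#' stratified k-fold cross-validation and picks the penalty minimizing the
#' mean CV error (misclassification error by default, binomial deviance
#' optionally; with tied minima the largest, i.e. sparsest, penalty is
#' chosen). Returns the nonzero feature set at the chosen penalty and the
#' full CV curve.
#'
#' @param design `mp_design` from [build_design()].
#' @param penalty `"lasso"` or `"elastic_net"`.
#' @param mixing Elastic-net mixing parameter (ignored for the lasso).
#' @param folds CV folds (default 10).
#' @param loss `"class"` (misclassification) or `"deviance"`.
#' @param seed Integer seed.
#' @return An `mp_penalized` list: `penalty`, `mixing`, `lambda`,
#'   `selected`, `coef`, `cv_curve`, `cvfit`.
#' @export
fit_penalized <- function(design, penalty = c("lasso", "elastic_net"),
                          mixing = 0.5, folds = 10L,
                          loss = c("class", "deviance"), seed = 1L) {
  penalty <- match.arg(penalty)
  loss <- match.arg(loss)
  alpha <- if (penalty == "lasso") 1 else mixing
  y01 <- as.integer(design$y == "AN")
  if (min(table(y01)) < folds) {
    folds <- max(3L, min(table(y01)))
  }
  with_seed(derive_seed(seed, 15L), {
    foldid <- stratified_folds(y01, folds)
    cvfit <- glmnet::cv.glmnet(design$x, y01, family = "binomial",
                               alpha = alpha, foldid = foldid,
                               type.measure = loss, standardize = FALSE)
  })
  lambda <- cvfit$lambda.min
  cf <- coef(cvfit, s = "lambda.min")
  nz <- rownames(cf)[which(as.numeric(cf) != 0)]
  selected <- setdiff(nz, "(Intercept)")
  structure(list(
    penalty = penalty, mixing = alpha, lambda = lambda, selected = selected,
    coef = setNames(as.numeric(cf), rownames(cf)),
    cv_curve = tibble::tibble(lambda = cvfit$lambda, mean_cv_error = cvfit$cvm,
                              se = cvfit$cvsd, nonzero = unname(cvfit$nzero)),
    cvfit = cvfit
  ), class = "mp_penalized")
}

#' @export
print.mp_penalized <- function(x, ...) {
  cat(sprintf("<%s fit: lambda* = %.4g, %d feature(s): %s>\n",
              x$penalty, x$lambda, length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Derive the sparse and extended marker panels
#'
#' Translates the penalized fits into named panels: the lasso-derived
#' sparse panel, the elastic-net-derived panel, and the extended panel
#' (all candidate markers the extended fit retains, sex included if
#' selected). Marker features are kept; `age` is reported but panels are
#' defined by their markers. The sparse-in-extended containment property is
#' checked and a warning (not an error) is raised when violated, since it
#' is data dependent.
#'
#' @param lasso_fit,enet_fit `mp_penalized` fits on the evaluation design.
#' @param extended_fit Optional `mp_penalized` for the extended panel; when
#'   `NULL` the extended panel is the union of all candidate markers in the
#'   design plus `sex`.
#' @param all_markers Character vector of all candidate marker ids (used
#'   for the default extended panel).
#' @return A tibble: `panel`, `feature`.
#' @export
derive_panels <- function(lasso_fit, enet_fit, extended_fit = NULL,
                          all_markers = NULL) {
  extended <- if (!is.null(extended_fit)) {
    extended_fit$selected
  } else {
    c(all_markers %||% union(lasso_fit$selected, enet_fit$selected), "sex")
  }
  panels <- dplyr::bind_rows(
    tibble::tibble(panel = "lasso", feature = lasso_fit$selected),
    tibble::tibble(panel = "elastic_net", feature = enet_fit$selected),
    tibble::tibble(panel = "extended", feature = extended)
  )
  sparse <- setdiff(union(lasso_fit$selected, enet_fit$selected),
                    c("age", "sex"))
  if (!all(sparse %in% setdiff(extended, c("age", "sex")))) {
    warn("sparse-panel markers are not all contained in the extended panel")
  }
  panels
}
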