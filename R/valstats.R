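#' Fit a multivariate logistic panel model
#'
#' Maximum-likelihood logistic regression of the NN/AN class on the panel
#' features; when the data separate, a Jeffreys-prior bias-reduced fit is
#' used instead and flagged.
#'
#' @param design `mp_design` from [build_design()] (the raw, unstandardized
#'   features are used, so coefficients are on the measurement scale).
#' @param panel Character vector of feature names.
#' @return An `mp_panel_model` list: `panel`, `coef`, `separated`,
#'   `transform`, and a `predict(newx)` closure returning probabilities.
#' @export
fit_panel_logistic <- function(design, panel) {
  x <- as.data.frame(design$x_raw, check.names = FALSE)
  missing <- setdiff(panel, colnames(x))
  if (length(missing) > 0L) {
    mp_stop(sprintf("panel feature(s) absent from design: %s",
                    paste(missing, collapse = ", ")),
            class = "methpanel_validation_error")
  }
  xm <- as.matrix(x[, panel, drop = FALSE])
  qrx <- qr(cbind(1, xm))
  if (qrx$rank < ncol(xm) + 1L) {
    mp_stop("collinear panel features: design is rank deficient",
            class = "methpanel_validation_error")
  }
  fit <- fit_logistic(x, design$y, panel)
  structure(list(panel = panel, coef = fit$coef, separated = fit$separated,
                 transform = design$transform, predict = fit$predict),
            class = "mp_panel_model")
}

#' @export
print.mp_panel_model <- function(x, ...) {
  cat(sprintf("<logistic panel model: %s%s>\n",
              paste(x$panel, collapse = " + "),
              if (x$separated) " (bias-reduced fit)" else ""))
  invisible(x)
}

#' Leave-one-out cross-validated panel scores
#'
#' For every sample, the panel model is refit on all other samples and the
#' held-out sample is scored; the pooled out-of-fold probabilities feed the
#' ROC construction.
#'
#' @inheritParams fit_panel_logistic
#' @return A tibble: `sample_id`, `truth`, `score`.
#' @export
loocv_scores <- function(design, panel) {
  n <- length(design$y)
  if (n < 10L) {
    mp_stop("leave-one-out validation needs n >= 10",
            class = "methpanel_validation_error")
  }
  if (min(table(design$y)) < 2L) {
    mp_stop("each class needs >= 2 samples so folds never lose a class",
            class = "methpanel_validation_error")
  }
  x <- as.data.frame(design$x_raw, check.names = FALSE)
  # zero-variance features carry no information; keep the scoring rule
  # constant across folds by dropping them once, up front
  usable <- panel[vapply(panel, function(f) sd(x[[f]]) > 0, logical(1))]
  if (length(usable) < length(panel)) {
    inform(sprintf("dropped constant panel feature(s): %s",
                   paste(setdiff(panel, usable), collapse = ", ")))
  }
  if (length(usable) == 0L) {
    prev <- mean(design$y == "AN")
    return(tibble::tibble(sample_id = design$sample_id,
                          truth = as.character(design$y),
                          score = rep(prev, n)))
  }
  scores <- vapply(seq_len(n), function(i) {
    fit <- fit_logistic(x[-i, , drop = FALSE], design$y[-i], usable)
    as.numeric(fit$predict(x[i, , drop = FALSE]))
  }, numeric(1))
  tibble::tibble(sample_id = design$sample_id, truth = as.character(design$y),
                 score = scores)
}

#' Empirical ROC curve with AUC, DeLong CI and Youden cutoff
#'
#' Builds the empirical ROC over all distinct score thresholds (a sample is
#' called positive when its score is at or above the threshold). The AUC is
#' the Mann-Whitney concordance probability with ties counted one half
#' (equal to the trapezoidal area), its 95% CI uses the DeLong variance,
#' and the Youden cutoff maximizes sensitivity + specificity - 1 with ties
#' broken toward higher specificity.
#'
#' @param scores Numeric score per sample (higher = more AN-like).
#' @param labels Class labels; `positive` marks the positive class.
#' @param positive Positive-class label (default `"AN"`).
#' @return An `mp_roc` list: `points` (tibble `threshold`, `sensitivity`,
#'   `specificity`), `auc`, `auc_ci`, `youden` (one-row tibble).
#' @export
roc_auc <- function(scores, labels, positive = "AN") {
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    mp_stop("both classes must be present to build a ROC curve",
            class = "methpanel_validation_error")
  }
  thresholds <- c(sort(unique(scores)), Inf)
  points <- purrr::map_dfr(thresholds, function(t) {
    called <- scores >= t
    tibble::tibble(threshold = t,
                   sensitivity = mean(called[pos]),
                   specificity = mean(!called[!pos]))
  })
  # Mann-Whitney with half ties
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ci <- tryCatch({
    suppressWarnings(suppressMessages(as.numeric(pROC::ci.auc(
      pROC::roc(response = pos, predictor = scores, quiet = TRUE,
                direction = "<", levels = c(FALSE, TRUE)),
      method = "delong")))[c(1L, 3L)])
  }, error = function(e) c(NA_real_, NA_real_))
  j <- points$sensitivity + points$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  # ties broken toward higher specificity
  best <- best[which.max(points$specificity[best])]
  youden <- tibble::tibble(threshold = points$threshold[best],
                           sensitivity = points$sensitivity[best],
                           specificity = points$specificity[best],
                           j = j[best])
  structure(list(points = points, auc = auc, auc_ci = ci, youden = youden),
            class = "mp_roc")
}

#' @export
print.mp_roc <- function(x, ...) {
  cat(sprintf("<ROC: AUC %.3f (95%% CI %.3f-%.3f), Youden cutoff %.3g (J = %.3f)>\n",
              x$auc, x$auc_ci[1L], x$auc_ci[2L], x$youden$threshold,
              x$youden$j))
  invisible(x)
}

#' @rdname roc_auc
#' @param roc An `mp_roc` object.
#' @return For `youden_cutoff()`: the one-row Youden tibble.
#' @export
youden_cutoff <- function(roc) roc$youden

#' Confusion counts and diagnostic metrics with exact CIs
#'
#' Sensitivity, specificity, negative and positive predictive values from
#' the 2x2 confusion table, each with an exact 95% Clopper-Pearson binomial
#' confidence interval. Metrics with an empty denominator are reported as
#' `NA` (undefined), not propagated as NaN.
#'
#' @param pred Predicted labels.
#' @param truth True labels.
#' @param positive Positive-class label (default `"AN"`).
#' @return A tibble with columns `metric`, `numerator`, `denominator`,
#'   `estimate`, `conf_low`, `conf_high` (percent scale); the integer
#'   counts are in `attr(, "counts")` (`tp`, `fp`, `tn`, `fn`).
#' @export
confusion_metrics <- function(pred, truth, positive = "AN") {
  if (length(pred) != length(truth)) {
    mp_stop("pred and truth must be aligned", class = "methpanel_validation_error")
  }
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  tn <- sum(pred != positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  one <- function(metric, k, n) {
    if (n == 0L) {
      return(tibble::tibble(metric = metric, numerator = k, denominator = n,
                            estimate = NA_real_, conf_low = NA_real_,
                            conf_high = NA_real_))
    }
    ci <- binom.test(k, n)$conf.int
    tibble::tibble(metric = metric, numerator = k, denominator = n,
                   estimate = 100 * k / n, conf_low = 100 * ci[1L],
                   conf_high = 100 * ci[2L])
  }
  out <- dplyr::bind_rows(
    one("sensitivity", tp, tp + fn),
    one("specificity", tn, tn + fp),
    one("npv", tn, tn + fn),
    one("ppv", tp, tp + fp)
  )
  attr(out, "counts") <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  out
}

#' Subgroup detection rates and the distal-versus-proximal comparison
#'
#' Percent of true-AN samples called positive within clinical subgroups
#' (advanced adenomas by lesion location, CRC by stage, plus overall rates)
#' and the two-sided Fisher exact test comparing detection of distal versus
#' proximal advanced adenomas.
#'
#' @param pred Tibble with `sample_id` and predicted label `pred`.
#' @param cohort Cohort tibble with findings, location and stage.
#' @param positive Positive-class label.
#' @return A list: `rates` (tibble `subgroup`, `detected`, `n`,
#'   `percent`) and `fisher_distal_proximal` (p-value among AA).
#' @export
subgroup_detection <- function(pred, cohort, positive = "AN") {
  cohort <- validate_cohort(cohort)
  df <- dplyr::inner_join(pred, cohort,
                          by = c(sample_id = "subject_id"))
  df <- df[df$class == "AN", ]
  df$hit <- df$pred == positive
  rate_row <- function(label, sel) {
    n <- sum(sel)
    tibble::tibble(subgroup = label, detected = sum(df$hit[sel]), n = n,
                   percent = if (n > 0L) 100 * sum(df$hit[sel]) / n else NA_real_)
  }
  rates <- dplyr::bind_rows(
    rate_row("AA_all", df$finding == "AA"),
    rate_row("AA_distal", df$finding == "AA" & df$location == "distal"),
    rate_row("AA_proximal", df$finding == "AA" & df$location == "proximal"),
    rate_row("CRC_all", df$finding == "CRC"),
    rate_row("CRC_stage_I", df$finding == "CRC" & df$stage == "I"),
    rate_row("CRC_stage_II", df$finding == "CRC" & df$stage == "II"),
    rate_row("CRC_stage_III", df$finding == "CRC" & df$stage == "III"),
    rate_row("CRC_stage_IV", df$finding == "CRC" & df$stage == "IV")
  )
  aa <- df[df$finding == "AA" & df$location %in% c("distal", "proximal"), ]
  fisher_p <- if (nrow(aa) > 0L && length(unique(aa$location)) == 2L) {
    tab <- table(factor(aa$location, levels = c("distal", "proximal")),
                 factor(aa$hit, levels = c(TRUE, FALSE)))
    fisher.test(tab)$p.value
  } else {
    NA_real_
  }
  list(rates = rates, fisher_distal_proximal = fisher_p)
}

#' Rank-based two-group and paired comparisons
#'
#' Wilcoxon rank-sum test for two independent groups (exact when both
#' groups have at most 25 untied observations, normal approximation with
#' tie correction otherwise) or the Wilcoxon signed-rank test for matched
#' pairs (zero differences dropped by convention). All-tied input yields
#' p = 1 with a warning.
#'
#' @param values Numeric measurements (unpaired), or the first member of
#'   each pair (paired).
#' @param groups Two-level grouping (unpaired only).
#' @param paired_values Second member of each pair (paired only).
#' @return A one-row tibble: `statistic`, `p_value`, `method`.
#' @export
group_tests <- function(values, groups = NULL, paired_values = NULL) {
  if (is.null(paired_values)) {
    g <- factor(groups)
    if (nlevels(g) != 2L) {
      mp_stop("exactly two groups are required", class = "methpanel_validation_error")
    }
    a <- values[g == levels(g)[1L]]
    b <- values[g == levels(g)[2L]]
    if (length(unique(values)) == 1L) {
      warn("all values tied; p = 1")
      return(tibble::tibble(statistic = NA_real_, p_value = 1,
                            method = "Wilcoxon rank-sum"))
    }
    exact <- max(length(a), length(b)) <= 25L && !any(duplicated(values))
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
    tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                   method = "Wilcoxon rank-sum")
  } else {
    d <- values - paired_values
    d <- d[d != 0]
    if (length(d) == 0L) {
      warn("all paired differences are zero; p = 1")
      return(tibble::tibble(statistic = NA_real_, p_value = 1,
                            method = "Wilcoxon signed-rank"))
    }
    exact <- length(d) <= 25L && !any(duplicated(abs(d)))
    wt <- suppressWarnings(wilcox.test(d, exact = exact, correct = !exact))
    tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                   method = "Wilcoxon signed-rank")
  }
}

#' Per-sample average methylation over a probe set
#'
#' Arithmetic mean of the available probes per sample (used e.g. for the
#' three-probe promoter average of SEPT9). Probes absent from the matrix
#' are logged and skipped; an all-missing probe set is an error.
#'
#' @param beta `mp_beta` matrix.
#' @param probe_ids Probes to average.
#' @return A tibble: `sample_id`, `mean_beta`.
#' @export
average_probe_set <- function(beta, probe_ids) {
  present <- intersect(probe_ids, rownames(beta))
  absent <- setdiff(probe_ids, present)
  if (length(present) == 0L) {
    mp_stop("none of the requested probes are present",
            class = "methpanel_validation_error")
  }
  if (length(absent) > 0L) {
    inform(sprintf("probe(s) missing from matrix, skipped: %s",
                   paste(absent, collapse = ", ")))
  }
  sub <- unclass(beta)[present, , drop = FALSE]
  tibble::tibble(sample_id = colnames(sub),
                 mean_beta = unname(colMeans(sub)))
}

#' Evaluate a frozen panel model on non-colorectal tumor sera
#'
#' Applies a fitted panel model and classification cutoff to tumor serum
#' measurements and reports how many are (mis)classified as advanced
#' neoplasia, overall and per tumor type.
#'
#' @param model `mp_panel_model`.
#' @param pyro Long pyrosequencing tibble of the tumor sera.
#' @param cutoff Probability cutoff (e.g. the Youden threshold).
#' @param subjects Optional tibble with `sample_id`, `tumor_type`.
#' @param transform Transform matching the model (default the model's).
#' @return A list: `n`, `n_misclassified`, `rate_percent`, `by_type`,
#'   `calls`.
#' @export
evaluate_offtarget <- function(model, pyro, cutoff, subjects = NULL,
                               transform = model$transform) {
  pyro <- validate_pyro(pyro)
  wide <- tidyr::pivot_wider(pyro, id_cols = "sample_id",
                             names_from = "marker_id",
                             values_from = "percent_methylation")
  markers <- setdiff(model$panel, c("age", "sex"))
  missing_markers <- setdiff(markers, colnames(wide))
  if (length(missing_markers) > 0L) {
    mp_stop(sprintf("panel marker(s) not measured: %s",
                    paste(missing_markers, collapse = ", ")),
            class = "methpanel_validation_error")
  }
  complete <- stats::complete.cases(wide[, markers])
  if (any(!complete)) {
    inform(sprintf("excluded %d sample(s) with unmeasured markers",
                   sum(!complete)))
  }
  wide <- wide[complete, ]
  x <- as.matrix(wide[, markers, drop = FALSE])
  if (transform == "log10") x <- log10(x + 1)
  x <- as.data.frame(x, check.names = FALSE)
  score <- as.numeric(model$predict(x))
  calls <- tibble::tibble(sample_id = wide$sample_id, score = score,
                          called_an = score >= cutoff)
  if (!is.null(subjects)) {
    calls <- dplyr::left_join(calls, subjects, by = "sample_id")
  }
  by_type <- if ("tumor_type" %in% names(calls)) {
    calls |>
      dplyr::group_by(.data$tumor_type) |>
      dplyr::summarise(n = dplyr::n(), misclassified = sum(.data$called_an),
                       .groups = "drop")
  } else {
    NULL
  }
  list(n = nrow(calls), n_misclassified = sum(calls$called_an),
       rate_percent = 100 * mean(calls$called_an), by_type = by_type,
       calls = calls)
}
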