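#' Statistically equivalent signatures (SES) feature selection
#'
#' Constraint-based forward-backward selection over the DMP features with
#' enumeration of statistically equivalent substitutes. Association is
#' measured by the likelihood-ratio chi-square test between nested logistic
#' models. Forward phase: a feature is eliminated once it is conditionally
#' independent of the class given any subset (size <= `max_k`) of the
#' selected set, and the strongest remaining feature (smallest maximal
#' conditional p-value) is selected. Backward phase: selected features that
#' become conditionally independent given subsets of the others are dropped.
#' For each surviving feature, candidates whose substitution changes the
#' model deviance by less than the chi-square(1) critical value at `alpha`
#' (and which are themselves significant given the rest of the signature)
#' are recorded as equivalents; the returned signatures are the cartesian
#' product of the equivalence classes, all of the minimal selected size.
#'
#' @param x Samples-by-features data frame or matrix of DMP beta-values.
#' @param y Class labels (`"NN"`/`"AN"`, factor or character) per row of `x`.
#' @param alpha Significance level of the conditional-independence tests.
#' @param max_k Maximum conditioning-set size.
#' @param max_signatures Cap on the enumerated cartesian product.
#' @return An `mp_signatures` list: `selected` (the reference signature),
#'   `equivalents` (named list), `signatures` (list of character vectors),
#'   `alpha`, `max_k`.
#' @export
ses_select <- function(x, y, alpha = 0.05, max_k = 3L, max_signatures = 10000L) {
  if (alpha <= 0 || alpha >= 1) {
    mp_stop("alpha must lie in (0, 1)", class = "methpanel_validation_error")
  }
  x <- as.data.frame(x, check.names = FALSE)
  features <- colnames(x)
  y01 <- as.integer(as.character(y) == "AN")

  max_cond_p <- function(f, selected) {
    # largest p over conditioning subsets: f survives only if no subset
    # renders it independent of the class
    subsets <- list(character())
    for (k in seq_len(min(max_k, length(selected)))) {
      combs <- utils::combn(selected, k, simplify = FALSE)
      subsets <- c(subsets, combs)
    }
    worst <- 0
    for (z in subsets) {
      p <- lrt_pvalue(x, y01, f, z)
      worst <- max(worst, p)
      if (worst > alpha) break
    }
    worst
  }

  remaining <- features
  selected <- character()
  repeat {
    if (length(remaining) == 0L) break
    pvals <- vapply(remaining, max_cond_p, numeric(1), selected = selected)
    remaining <- remaining[pvals <= alpha]
    pvals <- pvals[pvals <= alpha]
    if (length(remaining) == 0L) break
    best <- remaining[which.min(pvals)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  # backward: drop features conditionally independent given the others
  repeat {
    dropped <- FALSE
    for (f in selected) {
      others <- setdiff(selected, f)
      if (max_cond_p(f, others) > alpha) {
        selected <- others
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }

  equivalents <- list()
  if (length(selected) > 0L) {
    crit <- qchisq(1 - alpha, df = 1L)
    for (f in selected) {
      rest <- setdiff(selected, f)
      dev_f <- logistic_deviance(x, y01, c(rest, f))
      eq <- f
      for (g in setdiff(features, selected)) {
        if (lrt_pvalue(x, y01, g, rest) > alpha) next
        dev_g <- logistic_deviance(x, y01, c(rest, g))
        if (abs(dev_g - dev_f) < crit) eq <- c(eq, g)
      }
      equivalents[[f]] <- eq
    }
  }
  n_prod <- prod(lengths(equivalents))
  if (n_prod > max_signatures) {
    warn(sprintf("equivalence classes enumerate %d signatures; capped at %d",
                 n_prod, max_signatures))
  }
  signatures <- if (length(equivalents) == 0L) {
    list()
  } else {
    grid <- expand.grid(equivalents, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- utils::head(grid, max_signatures)
    grid <- grid[!apply(grid, 1L, anyDuplicated), , drop = FALSE]
    unname(lapply(seq_len(nrow(grid)), function(i) {
      unname(sort(unlist(grid[i, ], use.names = FALSE)))
    }))
  }
  signatures <- unique(signatures)
  structure(list(selected = selected, equivalents = equivalents,
                 signatures = signatures, alpha = alpha,
                 max_k = as.integer(max_k)),
            class = "mp_signatures")
}

#' @export
print.mp_signatures <- function(x, ...) {
  cat(sprintf("<SES result: %d signature(s) of size %d (alpha %.3g, max_k %d)>\n",
              length(x$signatures), length(x$selected), x$alpha, x$max_k))
  invisible(x)
}

stratified_folds <- function(y, k, seed_offset = 0L) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(vapply(split(y, fold), function(g) length(unique(g)), integer(1)) < 2L)) {
    mp_stop("a fold lost a class: re-stratify with fewer folds",
            class = "methpanel_validation_error")
  }
  fold
}

cv_error_one <- function(x, y01, cols, learner, folds, repeats) {
  errs <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y01, folds)
    pred <- numeric(length(y01))
    for (k in seq_len(folds)) {
      test <- fold == k
      xtr <- x[!test, cols, drop = FALSE]
      ytr <- y01[!test]
      xte <- x[test, cols, drop = FALSE]
      pred[test] <- switch(
        learner,
        logistic = {
          fit <- fit_logistic(xtr, ytr, cols)
          as.integer(fit$predict(xte) >= 0.5)
        },
        random_forest = {
          fit <- randomForest::randomForest(
            x = xtr, y = factor(ytr, levels = c(0, 1)), ntree = 500)
          as.integer(as.character(predict(fit, xte)))
        },
        svm = {
          fit <- e1071::svm(x = as.matrix(xtr),
                            y = factor(ytr, levels = c(0, 1)),
                            kernel = "linear", scale = FALSE)
          as.integer(as.character(predict(fit, as.matrix(xte))))
        })
    }
    errs <- c(errs, mean(pred != y01))
  }
  mean(errs)
}

#' Cross-validated ranking of candidate probes
#'
#' Estimates the stratified k-fold (repeated) misclassification error of
#' every signature under three learners — logistic regression, random
#' forest, and a linear-kernel support vector machine — and ranks probes:
#' each probe inherits the minimum error over the signatures containing it
#' and the learners, then probes are ordered lexicographically by
#' (error ascending, |delta-beta| descending, q-value ascending).
#'
#' @param signatures `mp_signatures` from [ses_select()] (or a list of
#'   probe-id vectors).
#' @param x Samples-by-features data frame of beta-values.
#' @param y Class labels per row.
#' @param fits Probe fits tibble supplying `delta_beta` and `q_value`.
#' @param folds,repeats CV scheme (default 5-fold, 10 repeats).
#' @param learners Learner subset to run.
#' @param seed Integer seed.
#' @return A tibble: `probe_id`, `min_cv_error`, `delta_beta`, `q_value`,
#'   `rank`; per-signature errors in `attr(, "signature_errors")`.
#' @export
cv_rank_candidates <- function(signatures, x, y, fits, folds = 5L,
                               repeats = 10L,
                               learners = c("logistic", "random_forest", "svm"),
                               seed = 1L) {
  sig_list <- if (inherits(signatures, "mp_signatures")) {
    signatures$signatures
  } else {
    signatures
  }
  if (length(sig_list) == 0L) {
    mp_stop("no signatures to rank", class = "methpanel_validation_error")
  }
  x <- as.data.frame(x, check.names = FALSE)
  y01 <- as.integer(as.character(y) == "AN")
  with_seed(derive_seed(seed, 13L), {
    sig_err <- purrr::map_dfr(seq_along(sig_list), function(i) {
      cols <- sig_list[[i]]
      errs <- vapply(learners, function(l) {
        cv_error_one(x, y01, cols, l, folds, repeats)
      }, numeric(1))
      tibble::tibble(signature = paste(cols, collapse = "+"),
                     learner = learners, cv_error = unname(errs))
    })
  })
  probe_err <- purrr::map_dfr(seq_along(sig_list), function(i) {
    tibble::tibble(probe_id = sig_list[[i]],
                   signature = paste(sig_list[[i]], collapse = "+"))
  }) |>
    dplyr::inner_join(sig_err, by = "signature",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(min_cv_error = min(.data$cv_error), .groups = "drop")
  ranked <- probe_err |>
    dplyr::left_join(fits[, c("probe_id", "delta_beta", "q_value")],
                     by = "probe_id") |>
    dplyr::arrange(.data$min_cv_error, dplyr::desc(abs(.data$delta_beta)),
                   .data$q_value, .data$probe_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(ranked, "signature_errors") <- sig_err
  ranked
}

#' Probes with zero cross-validated error for advanced-adenoma detection
#'
#' Single-probe logistic models on the NN-vs-AA sub-problem, scored by
#' stratified repeated CV; returns the probes with zero misclassification.
#'
#' @param x Samples-by-features data frame (NN and AA samples only).
#' @param y_aa Labels `"NN"` / `"AA"` per row.
#' @param probes Probes to consider.
#' @param folds,repeats CV scheme.
#' @param seed Integer seed.
#' @return Character vector of zero-error probe ids.
#' @export
aa_zero_error_probes <- function(x, y_aa, probes = colnames(x), folds = 5L,
                                 repeats = 10L, seed = 1L) {
  x <- as.data.frame(x, check.names = FALSE)
  y01 <- as.integer(as.character(y_aa) == "AA")
  with_seed(derive_seed(seed, 14L), {
    errs <- vapply(probes, function(p) {
      cv_error_one(x, y01, p, "logistic", folds, repeats)
    }, numeric(1))
  })
  names(errs)[errs == 0]
}

#' Concordance filter against a bisulfite-sequencing differential table
#'
#' Keeps probes whose sequencing-based methylation difference exceeds
#' `min_diff` in magnitude with the same sign as the array delta-beta.
#'
#' @param fits Probe fits tibble (`probe_id`, `delta_beta`).
#' @param rrbs Differential table (`cpg_id`, `meth_diff`).
#' @param min_diff Magnitude threshold (default 0.30).
#' @return A tibble: `probe_id`, `meth_diff`, `delta_beta`.
#' @export
rrbs_concordance_filter <- function(fits, rrbs, min_diff = 0.30) {
  joined <- dplyr::inner_join(fits[, c("probe_id", "delta_beta")],
                              rrbs, by = c(probe_id = "cpg_id"))
  joined[abs(joined$meth_diff) > min_diff &
           sign(joined$meth_diff) == sign(joined$delta_beta), ,
         drop = FALSE]
}

#' Assemble the candidate biomarker list
#'
#' Union of the top-`n_top` ranked probes, up to `max_aa` additional
#' zero-error advanced-adenoma probes not already chosen, and the
#' sequencing-concordant probes, with provenance recorded per candidate.
#' With the default layout this yields 15 + 3 + 8 = 26 candidates.
#'
#' @param ranked Ranked tibble from [cv_rank_candidates()].
#' @param n_top Number of top-ranked probes (default 15).
#' @param aa_zero Character vector from [aa_zero_error_probes()].
#' @param rrbs_probes Character vector from [rrbs_concordance_filter()].
#' @param max_aa Cap on added zero-error probes (default 3).
#' @return A tibble: `probe_id`, `source`, `rank`.
#' @export
select_candidates <- function(ranked, n_top = 15L, aa_zero = character(),
                              rrbs_probes = character(), max_aa = 3L) {
  if (nrow(ranked) < n_top) {
    mp_stop(sprintf("only %d ranked probes; %d requested", nrow(ranked), n_top),
            class = "methpanel_validation_error")
  }
  top <- ranked$probe_id[seq_len(n_top)]
  aa_new <- head(setdiff(aa_zero, top), max_aa)
  rrbs_new <- setdiff(rrbs_probes, c(top, aa_new))
  dropped <- (length(aa_zero) - length(setdiff(aa_zero, top))) +
    (length(rrbs_probes) - length(rrbs_new))
  if (dropped > 0L) {
    inform(sprintf("%d candidate(s) overlapped an earlier source; deduplicated",
                   dropped))
  }
  out <- tibble::tibble(
    probe_id = c(top, aa_new, rrbs_new),
    source = rep(c("ses_top15", "aa_zero_error", "rrbs_concordant"),
                 c(length(top), length(aa_new), length(rrbs_new)))
  )
  out$rank <- ranked$rank[match(out$probe_id, ranked$probe_id)]
  out
}
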