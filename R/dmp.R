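#' Probe quality-control filter
#'
#' Removes probes that cannot feed the per-probe linear model: any probe
#' with a flagged-missing value in any sample ("failed position"), and any
#' probe whose two-group regression residuals fail a Shapiro-Wilk normality
#' screen at `shapiro_alpha` (the linear-model assumption check).
#'
#' @param beta Pool-level `mp_beta` matrix.
#' @param classes Character vector of `"NN"`/`"AN"` per column of `beta`
#'   (named or positional).
#' @param shapiro_alpha Screen level; probes with Shapiro-Wilk p below it
#'   are discarded. Default 0.01.
#' @return A list: `beta` (filtered matrix) and `removed`
#'   (tibble `probe_id`, `reason`).
#' @export
qc_filter_probes <- function(beta, classes, shapiro_alpha = 0.01) {
  classes <- align_classes(beta, classes)
  if (min(table(classes)) < 3L) {
    mp_stop("need at least 3 samples per class for the per-probe model",
            class = "methpanel_validation_error")
  }
  vals <- unclass(beta)
  failed <- rowSums(is.na(vals)) > 0L
  removed <- tibble::tibble(probe_id = rownames(vals)[failed],
                            reason = "failed position")
  keep <- vals[!failed, , drop = FALSE]
  if (nrow(keep) > 0L) {
    is_an <- classes == "AN"
    resid <- keep
    resid[, is_an] <- keep[, is_an] - rowMeans(keep[, is_an, drop = FALSE])
    resid[, !is_an] <- keep[, !is_an] - rowMeans(keep[, !is_an, drop = FALSE])
    sw_p <- apply(resid, 1L, function(r) {
      if (sd(r) == 0) return(1)
      shapiro.test(r)$p.value
    })
    nonnormal <- sw_p < shapiro_alpha
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      probe_id = rownames(keep)[nonnormal], reason = "non-normal residuals"))
    keep <- keep[!nonnormal, , drop = FALSE]
  }
  list(beta = beta_matrix(keep, level = beta_level(beta)), removed = removed)
}

align_classes <- function(beta, classes) {
  if (!is.null(names(classes))) {
    missing <- setdiff(colnames(beta), names(classes))
    if (length(missing) > 0L) {
      mp_stop("class labels missing for some samples",
              class = "methpanel_validation_error")
    }
    classes <- classes[colnames(beta)]
  }
  if (length(classes) != ncol(beta)) {
    mp_stop("one class label per sample is required",
            class = "methpanel_validation_error")
  }
  if (!all(classes %in% c("NN", "AN"))) {
    mp_stop("classes must be 'NN' or 'AN'", class = "methpanel_validation_error")
  }
  unname(classes)
}

#' Per-probe two-group linear models on the beta scale
#'
#' Fits the class contrast (AN minus NN) by least squares for every probe:
#' the effect is the difference of group means (delta-beta), with pooled
#' residual variance on `n - 2` degrees of freedom and the ordinary
#' t-statistic. Row-wise vectorized; results do not depend on sample order.
#'
#' @inheritParams qc_filter_probes
#' @return A tibble: `probe_id`, `delta_beta`, `s2`, `df`, `t_ordinary`.
#' @export
fit_probe_models <- function(beta, classes) {
  classes <- align_classes(beta, classes)
  vals <- unclass(beta)
  is_an <- classes == "AN"
  n1 <- sum(is_an)
  n0 <- sum(!is_an)
  if (n1 < 2L || n0 < 2L) {
    mp_stop("need >= 2 samples per class (rank-deficient design otherwise)",
            class = "methpanel_validation_error")
  }
  m1 <- rowMeans(vals[, is_an, drop = FALSE])
  m0 <- rowMeans(vals[, !is_an, drop = FALSE])
  rss <- rowSums((vals[, is_an, drop = FALSE] - m1)^2) +
    rowSums((vals[, !is_an, drop = FALSE] - m0)^2)
  df <- n1 + n0 - 2L
  s2 <- rss / df
  v <- 1 / n1 + 1 / n0
  delta <- m1 - m0
  tibble::tibble(
    probe_id = rownames(vals),
    delta_beta = unname(delta),
    s2 = unname(s2),
    df = df,
    stdev_unscaled = sqrt(v),
    t_ordinary = unname(delta / sqrt(s2 * v))
  )
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing function).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of probe variances
#'
#' Shrinks each probe's residual variance toward a prior estimated by a
#' method of moments on the log-variances: with residual degrees of freedom
#' `d`, `log(s^2)` has expectation `log(sigma^2) + digamma(d/2) - log(d/2)`
#' and excess variance `trigamma(d/2)`; matching the observed spread of
#' `log(s^2)` to `trigamma(d/2) + trigamma(d0/2)` yields the prior degrees
#' of freedom `d0` and prior variance `s0^2` (scaled inverse-chi-square
#' prior). The posterior variance is `(d0 s0^2 + d s^2) / (d0 + d)`, the
#' moderated t is the effect over its posterior standard error, and p-values
#' come from a t distribution on `d + d0` degrees of freedom. When the
#' observed spread is no larger than the sampling noise, `d0` is infinite
#' and every probe is assigned the common prior variance.
#'
#' @param fits Tibble from [fit_probe_models()].
#' @param d0 Optional forced prior degrees of freedom (`0` reproduces the
#'   ordinary t; `Inf` fully pools variances). Default `NULL`: estimated.
#' @return A list: `prior` (tibble `d0`, `s0_sq`) and `fits` (input tibble
#'   plus `s2_post`, `t_moderated`, `p_value`).
#' @export
ebayes_moderate <- function(fits, d0 = NULL) {
  ok <- is.finite(fits$s2) & fits$s2 > 0
  if (!any(ok)) {
    mp_stop("all residual variances are zero: moderation is degenerate",
            class = "methpanel_validation_error")
  }
  if (sum(ok) < 2L && is.null(d0)) {
    mp_stop("need >= 2 probes with positive residual variance to estimate the prior",
            class = "methpanel_validation_error")
  }
  d <- fits$df
  z <- log(fits$s2[ok])
  dg <- d[ok] / 2
  e <- z - digamma(dg) + log(dg)
  if (is.null(d0)) {
    excess <- mean((e - mean(e))^2) * length(e) / (length(e) - 1) -
      mean(trigamma(dg))
    if (is.finite(excess) && excess > 0) {
      d0 <- 2 * trigamma_inverse(excess)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    }
  } else {
    s0_sq <- if (d0 <= 0 || is.infinite(d0)) {
      exp(mean(e))  # with d0 = 0 the prior variance never enters the posterior
    } else {
      exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, nrow(fits))
  } else {
    (d0 * s0_sq + d * fits$s2) / (d0 + d)
  }
  t_mod <- fits$delta_beta / (sqrt(s2_post) * fits$stdev_unscaled)
  df_total <- d + d0
  p <- 2 * pt(-abs(t_mod), df = df_total)
  fits$s2_post <- s2_post
  fits$t_moderated <- t_mod
  fits$p_value <- p
  list(prior = tibble::tibble(d0 = d0, s0_sq = s0_sq), fits = fits)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  assert_in_range(p, 0, 1, "p-values")
  p.adjust(p, method = "BH")
}

#' Call differentially methylated positions
#'
#' Thresholds BH q-values at the FDR level, labels each called probe
#' hypermethylated or hypomethylated in AN by the sign of its delta-beta,
#' and attaches summary counts (total, hyper, hypo, percent hyper).
#'
#' @param fits Moderated fits tibble (needs `p_value`; `q_value` is computed
#'   if absent).
#' @param fdr FDR threshold (default 0.10).
#' @return A tibble of called DMPs with a `direction` column; summary counts
#'   in `attr(, "summary")` (see [dmp_summary()]).
#' @export
call_dmps <- function(fits, fdr = 0.10) {
  if (!("q_value" %in% names(fits))) fits$q_value <- bh_adjust(fits$p_value)
  calls <- fits[fits$q_value <= fdr, , drop = FALSE]
  calls$direction <- ifelse(calls$delta_beta > 0, "hyper", "hypo")
  calls <- calls[order(calls$q_value, calls$p_value, calls$probe_id), ]
  n_hyper <- sum(calls$direction == "hyper")
  summary <- tibble::tibble(
    n_total = nrow(calls),
    n_hyper = n_hyper,
    n_hypo = nrow(calls) - n_hyper,
    pct_hyper = if (nrow(calls) > 0) 100 * n_hyper / nrow(calls) else NA_real_,
    fdr = fdr
  )
  attr(calls, "summary") <- summary
  class(calls) <- c("mp_dmps", class(calls))
  calls
}

#' @rdname call_dmps
#' @param dmps A DMP call tibble from `call_dmps()`.
#' @export
dmp_summary <- function(dmps) {
  attr(dmps, "summary") %||%
    mp_stop("no summary attribute: not a call_dmps() result",
            class = "methpanel_validation_error")
}

#' Discovery-phase differential methylation in one call
#'
#' Convenience wrapper chaining [qc_filter_probes()], [fit_probe_models()],
#' [ebayes_moderate()], [bh_adjust()] and [call_dmps()].
#'
#' @inheritParams qc_filter_probes
#' @param fdr FDR threshold for calling.
#' @return A list: `dmps`, `fits` (all probes, with q-values), `prior`,
#'   `removed`.
#' @export
discover_dmps <- function(beta, classes, fdr = 0.10, shapiro_alpha = 0.01) {
  qc <- qc_filter_probes(beta, classes, shapiro_alpha = shapiro_alpha)
  fits <- fit_probe_models(qc$beta, classes)
  mod <- ebayes_moderate(fits)
  mod$fits$q_value <- bh_adjust(mod$fits$p_value)
  dmps <- call_dmps(mod$fits, fdr = fdr)
  list(dmps = dmps, fits = mod$fits, prior = mod$prior, removed = qc$removed)
}
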