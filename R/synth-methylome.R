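#' Plan the planted differentially methylated positions
#'
#' Chooses which probes carry a true group difference, the signed effect
#' size on the beta scale (AN minus NN), the direction split, and baseline
#' distribution parameters per probe. By default 86.7% of planted effects
#' are hypermethylated in AN. Baseline means are drawn so that both group
#' means stay strictly inside (0, 1) after the effect is added.
#'
#' @param probe_ids Probe identifier pool to plant into.
#' @param n_dmp Number of planted DMPs.
#' @param delta_beta Absolute effect size on the beta scale, in (0, 1).
#' @param frac_hyper Fraction of planted effects with positive sign.
#' @param precision Beta-distribution precision (a + b) of individual
#'   methylomes at the planted probes.
#' @param seed Integer seed.
#' @return A tibble with columns `probe_id`, `delta_beta`, `direction`,
#'   `base_mean`, `precision`.
#' @export
marker_plan <- function(probe_ids, n_dmp, delta_beta = 0.20,
                        frac_hyper = 0.867, precision = 60, seed = 1L) {
  if (delta_beta <= 0 || delta_beta >= 1) {
    mp_stop("delta_beta must lie in (0, 1)", class = "methpanel_validation_error")
  }
  if (n_dmp > length(probe_ids)) {
    mp_stop("more planted DMPs requested than probes available",
            class = "methpanel_validation_error")
  }
  with_seed(derive_seed(seed, 2L), {
    ids <- sample(probe_ids, n_dmp)
    n_hyper <- round(frac_hyper * n_dmp)
    direction <- rep(c("hyper", "hypo"), c(n_hyper, n_dmp - n_hyper))
    margin <- 0.05
    base_mean <- ifelse(
      direction == "hyper",
      runif(n_dmp, margin, 1 - margin - delta_beta),
      runif(n_dmp, margin + delta_beta, 1 - margin)
    )
    tibble::tibble(
      probe_id = ids,
      delta_beta = ifelse(direction == "hyper", delta_beta, -delta_beta),
      direction = direction,
      base_mean = base_mean,
      precision = precision
    )
  })
}

#' Generate individual-level synthetic methylomes
#'
#' Each subject's beta-value at each probe is drawn from a beta distribution
#' parameterized by (mean, precision). Baseline per-probe means are drawn
#' from a broad distribution on (0.05, 0.95); at planted probes, AN subjects
#' have their mean shifted by the planned signed effect. Non-planted probes
#' have zero expected group difference by construction.
#'
#' @param cohort Cohort tibble (uses `subject_id` and the derived `class`).
#' @param n_probes Total probes simulated; probe ids are `cg%06d`.
#' @param plan Tibble from [marker_plan()]; its `probe_id`s must be a subset
#'   of the simulated probes. `NULL` plants nothing.
#' @param precision Beta precision at non-planted probes.
#' @param seed Integer seed.
#' @return An individual-level `mp_beta` matrix (probes x subjects).
#' @export
generate_methylome <- function(cohort, n_probes, plan = NULL, precision = 60,
                               seed = 1L) {
  probe_ids <- sprintf("cg%06d", seq_len(n_probes))
  if (!is.null(plan) && !all(plan$probe_id %in% probe_ids)) {
    mp_stop("marker plan names probes outside the simulated probe set",
            class = "methpanel_validation_error")
  }
  if (!("class" %in% names(cohort))) cohort$class <- an_class(cohort$finding)
  with_seed(derive_seed(seed, 3L), {
    base_mean <- runif(n_probes, 0.05, 0.95)
    prec <- rep(precision, n_probes)
    delta <- setNames(numeric(n_probes), probe_ids)
    if (!is.null(plan)) {
      idx <- match(plan$probe_id, probe_ids)
      base_mean[idx] <- plan$base_mean
      prec[idx] <- plan$precision
      delta[idx] <- plan$delta_beta
      shifted <- base_mean[idx] + plan$delta_beta
      bad <- shifted <= 0 | shifted >= 1
      if (any(bad)) {
        mp_stop(sprintf("planted effect pushes mean outside (0,1) at probe %s",
                        plan$probe_id[which(bad)[1L]]),
                class = "methpanel_validation_error")
      }
    }
    n_sub <- nrow(cohort)
    mu <- matrix(base_mean, nrow = n_probes, ncol = n_sub)
    is_an <- cohort$class == "AN"
    if (any(is_an)) mu[, is_an] <- mu[, is_an] + delta
    prec_mat <- matrix(prec, nrow = n_probes, ncol = n_sub)
    vals <- matrix(
      rbeta(n_probes * n_sub, shape1 = mu * prec_mat,
            shape2 = (1 - mu) * prec_mat),
      nrow = n_probes,
      dimnames = list(probe_ids, cohort$subject_id)
    )
    out <- beta_matrix(vals, level = "individual")
    attr(out, "true_delta") <- delta
    out
  })
}

#' Simulate pooled array measurements
#'
#' The pooled beta-value at each probe is the unweighted arithmetic mean of
#' the ten member betas (equal cfDNA amounts per member), perturbed by
#' logit-scale measurement noise and kept inside (0, 1).
#'
#' @param individual Individual-level `mp_beta` matrix.
#' @param pools Pool membership tibble with columns `pool_id`, `subject_id`
#'   (from [build_pools()]).
#' @param noise_sd Logit-scale noise standard deviation; 0 gives exact means.
#' @param seed Integer seed.
#' @return A pool-level `mp_beta` matrix (probes x pools).
#' @export
simulate_array_pools <- function(individual, pools, noise_sd = 0.10, seed = 1L) {
  pools <- tibble::as_tibble(pools)
  assert_columns(pools, c("pool_id", "subject_id"), "pool specification")
  sizes <- table(pools$pool_id)
  if (any(sizes != 10L)) {
    mp_stop(sprintf("pool(s) without exactly 10 members: %s",
                    paste(names(sizes)[sizes != 10L], collapse = ", ")),
            class = "methpanel_validation_error")
  }
  missing <- setdiff(pools$subject_id, colnames(individual))
  if (length(missing) > 0L) {
    bad <- pools$pool_id[match(missing[1L], pools$subject_id)]
    mp_stop(sprintf("pool %s member %s absent from the beta matrix",
                    bad, missing[1L]),
            class = "methpanel_validation_error")
  }
  pool_ids <- unique(pools$pool_id)
  means <- vapply(pool_ids, function(p) {
    rowMeans(unclass(individual)[, pools$subject_id[pools$pool_id == p],
                                 drop = FALSE])
  }, numeric(nrow(individual)))
  dimnames(means) <- list(rownames(individual), pool_ids)
  if (noise_sd > 0) {
    with_seed(derive_seed(seed, 4L), {
      eps <- 1e-6
      z <- qlogis(pmin(pmax(means, eps), 1 - eps))
      means <- plogis(z + rnorm(length(z), sd = noise_sd))
    })
  }
  beta_matrix(means, level = "pool")
}

#' Simulate pyrosequencing percent methylation
#'
#' Percent methylation is 100 x beta plus zero-centered noise, clipped to
#' \[0, 100\]. With zero noise the percent equals 100 x beta exactly.
#'
#' @param individual Individual-level `mp_beta` matrix.
#' @param markers Probe ids to assay (must exist in the matrix).
#' @param noise_sd Percent-scale noise standard deviation.
#' @param seed Integer seed.
#' @return A long pyrosequencing tibble (`sample_id`, `marker_id`,
#'   `percent_methylation`).
#' @export
simulate_pyrosequencing <- function(individual, markers, noise_sd = 5,
                                    seed = 1L) {
  unknown <- setdiff(markers, rownames(individual))
  if (length(unknown) > 0L) {
    mp_stop(sprintf("unknown marker id(s): %s",
                    paste(head(unknown, 5L), collapse = ", ")),
            class = "methpanel_validation_error")
  }
  sub <- unclass(individual)[markers, , drop = FALSE]
  with_seed(derive_seed(seed, 5L), {
    pct <- 100 * sub
    if (noise_sd > 0) pct <- pct + rnorm(length(pct), sd = noise_sd)
    pct <- pmin(pmax(pct, 0), 100)
    tibble::tibble(
      sample_id = rep(colnames(sub), each = length(markers)),
      marker_id = rep(markers, times = ncol(sub)),
      percent_methylation = as.numeric(pct)
    )
  })
}

#' Generate a synthetic bisulfite-sequencing differential table
#'
#' Emulates the external serum/tissue reduced-representation bisulfite
#' sequencing comparison: a table of CpG sites with signed methylation
#' differences, built so that exactly `n_concordant` planted probes exceed
#' `min_diff` with the same sign as their planned array effect, while every
#' other row stays below the threshold.
#'
#' @param plan Marker plan tibble.
#' @param n_concordant Number of array-concordant sites (<= planted count).
#' @param min_diff Concordance threshold on the methylation-difference
#'   scale, in (0, 1).
#' @param n_extra Additional non-planted CpG rows included as background.
#' @param seed Integer seed.
#' @return A tibble with columns `cpg_id`, `meth_diff`.
#' @export
generate_rrbs_table <- function(plan, n_concordant = 8L, min_diff = 0.30,
                                n_extra = 50L, seed = 1L) {
  if (min_diff <= 0 || min_diff >= 1) {
    mp_stop("min_diff must lie in (0, 1)", class = "methpanel_validation_error")
  }
  if (n_concordant > nrow(plan)) {
    mp_stop("n_concordant exceeds the planted DMP count",
            class = "methpanel_validation_error")
  }
  with_seed(derive_seed(seed, 6L), {
    conc_idx <- if (n_concordant > 0L) sample(nrow(plan), n_concordant) else integer()
    headroom <- min(0.95 - min_diff, 0.25)
    conc <- tibble::tibble(
      cpg_id = plan$probe_id[conc_idx],
      meth_diff = sign(plan$delta_beta[conc_idx]) *
        runif(n_concordant, min_diff + 0.01, min_diff + headroom)
    )
    rest_idx <- setdiff(seq_len(nrow(plan)), conc_idx)
    rest <- tibble::tibble(
      cpg_id = plan$probe_id[rest_idx],
      meth_diff = runif(length(rest_idx), -0.8 * min_diff, 0.8 * min_diff)
    )
    extra <- tibble::tibble(
      cpg_id = sprintf("rrbs_bg%04d", seq_len(n_extra)),
      meth_diff = runif(n_extra, -0.8 * min_diff, 0.8 * min_diff)
    )
    dplyr::bind_rows(conc, rest, extra)
  })
}

#' Generate non-colorectal tumor sera and matched serum/plasma pairs
#'
#' Non-colorectal tumor sera are drawn from the NN-like methylation
#' distribution of the panel markers, except for a configurable
#' contamination fraction whose marker values land in the AN region. Matched
#' plasma values equal the serum values plus zero-centered offset noise.
#'
#' @param plan Marker plan rows for the assayed markers (uses `probe_id`,
#'   `base_mean`, `delta_beta`, `precision`).
#' @param n Number of tumor serum samples.
#' @param contamination Fraction of samples drawn from the AN-like
#'   distribution, in \[0, 1\]; the contaminated count is `round(n *
#'   contamination)`.
#' @param tumor_types Labels cycled over the samples.
#' @param noise_sd Percent-scale assay noise.
#' @param seed Integer seed.
#' @return A list: `pyro` (long pyrosequencing tibble) and `subjects`
#'   (tibble with `sample_id`, `tumor_type`, `an_like`).
#' @export
generate_offtarget <- function(plan, n = 16L, contamination = 3 / 16,
                               tumor_types = c("lung", "breast", "kidney",
                                               "prostate", "ovary"),
                               noise_sd = 3, seed = 1L) {
  if (contamination < 0 || contamination > 1) {
    mp_stop("contamination fraction must lie in [0, 1]",
            class = "methpanel_validation_error")
  }
  with_seed(derive_seed(seed, 7L), {
    n_an <- round(n * contamination)
    an_like <- sample(rep(c(TRUE, FALSE), c(n_an, n - n_an)))
    subjects <- tibble::tibble(
      sample_id = sprintf("T%03d", seq_len(n)),
      tumor_type = rep(tumor_types, length.out = n),
      an_like = an_like
    )
    pyro <- purrr::pmap_dfr(
      plan[, c("probe_id", "base_mean", "delta_beta", "precision")],
      function(probe_id, base_mean, delta_beta, precision) {
        mu <- ifelse(subjects$an_like, base_mean + delta_beta, base_mean)
        beta <- rbeta(n, mu * precision, (1 - mu) * precision)
        pct <- pmin(pmax(100 * beta + rnorm(n, sd = noise_sd), 0), 100)
        tibble::tibble(sample_id = subjects$sample_id, marker_id = probe_id,
                       percent_methylation = pct)
      })
    list(pyro = validate_pyro(pyro), subjects = subjects)
  })
}

#' @rdname generate_offtarget
#' @param n_pairs Number of matched serum/plasma pairs (drawn NN-like).
#' @param offset_sd Percent-scale serum-vs-plasma offset noise; 0 makes the
#'   two specimens identical.
#' @return For `generate_paired_serum_plasma()`: a tibble with columns
#'   `sample_id`, `marker_id`, `serum_percent`, `plasma_percent`.
#' @export
generate_paired_serum_plasma <- function(plan, n_pairs = 8L, offset_sd = 2,
                                         noise_sd = 3, seed = 1L) {
  with_seed(derive_seed(seed, 8L), {
    ids <- sprintf("P%03d", seq_len(n_pairs))
    purrr::pmap_dfr(
      plan[, c("probe_id", "base_mean", "precision")],
      function(probe_id, base_mean, precision) {
        beta <- rbeta(n_pairs, base_mean * precision,
                      (1 - base_mean) * precision)
        serum <- pmin(pmax(100 * beta + rnorm(n_pairs, sd = noise_sd), 0), 100)
        plasma <- if (offset_sd > 0) {
          pmin(pmax(serum + rnorm(n_pairs, sd = offset_sd), 0), 100)
        } else {
          serum
        }
        tibble::tibble(sample_id = ids, marker_id = probe_id,
                       serum_percent = serum, plasma_percent = plasma)
      })
  })
}
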