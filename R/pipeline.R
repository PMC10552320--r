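#' Run the full discovery-evaluation-validation pipeline
#'
#' Executes the three study phases end to end on synthetic data drawn from
#' the configuration: (i) discovery — generate the cohort and individual
#' methylomes, build sex-balanced pools, simulate pooled array
#' measurements, call DMPs and test annotation enrichment; (ii)
#' prioritization — SES search over the DMPs, cross-validated ranking,
#' zero-error advanced-adenoma probes and sequencing-concordance filter,
#' assembling the candidate set; (iii) evaluation and validation —
#' pyrosequencing simulation, penalized panel selection on the evaluation
#' cohort, logistic panel models with LOOCV ROC, Youden cutoffs, confusion
#' metrics and subgroup rates on the validation cohort, plus non-colorectal
#' tumor and matched serum/plasma checks. Fully deterministic for a fixed
#' configuration.
#'
#' @param config `mp_config` from [methpanel_config()].
#' @param stages Subset of `c("discovery", "prioritize", "evaluate",
#'   "validate")`; later stages require earlier ones. Stopping early
#'   returns a partial report.
#' @return An `mp_pipeline` list of per-stage results.
#' @export
run_pipeline <- function(config = methpanel_config(),
                         stages = c("discovery", "prioritize", "evaluate",
                                    "validate")) {
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- config$seed
  report <- list(config = config)

  # --- discovery -----------------------------------------------------------
  cohort <- generate_cohort(seed = seed)
  plan <- marker_plan(sprintf("cg%06d", seq_len(config$n_probes)),
                      n_dmp = config$n_dmp, delta_beta = config$delta_beta,
                      frac_hyper = config$frac_hyper, seed = seed)
  methylome <- generate_methylome(cohort, n_probes = config$n_probes,
                                  plan = plan, seed = seed)
  pools <- build_pools(cohort, seed = seed)
  pools <- assign_to_slides(pools, seed = seed)
  pool_beta <- simulate_array_pools(methylome, pools,
                                    noise_sd = config$array_noise_sd,
                                    seed = seed)
  pool_class <- dplyr::distinct(pools, .data$pool_id, .data$class, .data$group)
  classes <- setNames(pool_class$class, pool_class$pool_id)
  disc <- discover_dmps(pool_beta, classes, fdr = config$fdr,
                        shapiro_alpha = config$shapiro_alpha)
  annotation <- generate_probe_annotation(rownames(methylome),
                                          island_bias = plan$probe_id,
                                          seed = seed)
  enrichment <- enrich_dmps(disc$dmps, annotation,
                            background = disc$fits$probe_id)
  report$cohort <- cohort
  report$plan <- plan
  report$pools <- pools
  report$age_balance <- check_pool_age_balance(pools)
  report$dmps <- disc$dmps
  report$dmp_summary <- dmp_summary(disc$dmps)
  report$prior <- disc$prior
  report$enrichment <- enrichment
  if (!("prioritize" %in% stages)) return(structure(report, class = "mp_pipeline"))

  # --- prioritization ------------------------------------------------------
  dmp_ids <- disc$dmps$probe_id
  if (length(dmp_ids) < 2L) {
    mp_stop("too few DMPs to prioritize; increase effect size or probe count",
            class = "methpanel_validation_error")
  }
  x_pool <- as.data.frame(t(unclass(pool_beta)[dmp_ids, , drop = FALSE]),
                          check.names = FALSE)
  y_pool <- classes[rownames(x_pool)]
  ses <- ses_select(x_pool, y_pool, alpha = config$ses_alpha,
                    max_k = config$ses_max_k)
  sigs <- ses$signatures
  # guarantee enough ranked probes for the top-15 rule: pad the signature
  # list with singletons of the strongest remaining DMPs
  covered <- unique(unlist(sigs))
  need <- 20L - length(covered)
  if (need > 0L) {
    pool_order <- disc$dmps$probe_id[order(disc$dmps$q_value,
                                           -abs(disc$dmps$delta_beta))]
    extra <- setdiff(pool_order, covered)[seq_len(min(need, length(
      setdiff(pool_order, covered))))]
    sigs <- c(sigs, as.list(extra))
  }
  ranked <- cv_rank_candidates(sigs, x_pool, y_pool, fits = disc$fits,
                               folds = config$cv_folds,
                               repeats = config$cv_repeats, seed = seed)
  aa_sel <- pool_class$group %in% c("P-AA", "D-AA", "NCF", "BEN", "NAA")
  aa_pools <- pool_class$pool_id[aa_sel]
  y_aa <- ifelse(pool_class$group[aa_sel] %in% c("P-AA", "D-AA"), "AA", "NN")
  aa_zero <- aa_zero_error_probes(x_pool[aa_pools, , drop = FALSE],
                                  y_aa, probes = dmp_ids,
                                  folds = config$cv_folds,
                                  repeats = min(config$cv_repeats, 5L),
                                  seed = seed)
  rrbs <- generate_rrbs_table(plan, n_concordant = 8L, min_diff = 0.30,
                              seed = seed)
  rrbs_set <- rrbs_concordance_filter(disc$fits, rrbs, min_diff = 0.30)
  candidates <- select_candidates(ranked, n_top = 15L, aa_zero = aa_zero,
                                  rrbs_probes = rrbs_set$probe_id)
  report$ses <- ses
  report$ranked <- ranked
  report$candidates <- candidates
  if (!("evaluate" %in% stages)) return(structure(report, class = "mp_pipeline"))

  # --- evaluation ----------------------------------------------------------
  markers <- candidates$probe_id
  eval_ids <- cohort$subject_id[cohort$cohort == "evaluation"]
  eval_pyro <- simulate_pyrosequencing(methylome[, eval_ids, drop = FALSE],
                                       markers,
                                       noise_sd = config$pyro_noise_sd,
                                       seed = derive_seed(seed, 20L))
  design_eval <- build_design(eval_pyro, cohort[cohort$cohort == "evaluation", ],
                              transform = config$transform)
  lasso <- fit_penalized(design_eval, "lasso", folds = config$penalty_folds,
                         seed = seed)
  enet <- fit_penalized(design_eval, "elastic_net", mixing = config$enet_alpha,
                        folds = config$penalty_folds, seed = seed)
  panels <- derive_panels(lasso, enet, all_markers = markers)
  report$pyro_evaluation <- eval_pyro
  report$lasso <- lasso
  report$elastic_net <- enet
  report$panels <- panels
  if (!("validate" %in% stages)) return(structure(report, class = "mp_pipeline"))

  # --- validation ----------------------------------------------------------
  val_ids <- cohort$subject_id[cohort$cohort == "validation"]
  val_cohort <- cohort[cohort$cohort == "validation", ]
  val_pyro <- simulate_pyrosequencing(methylome[, val_ids, drop = FALSE],
                                      markers,
                                      noise_sd = config$pyro_noise_sd,
                                      seed = derive_seed(seed, 21L))
  design_val <- build_design(val_pyro, val_cohort,
                             transform = config$transform)
  validation <- purrr::map(split(panels$feature, panels$panel), function(feats) {
    feats <- intersect(feats, colnames(design_val$x_raw))
    if (length(feats) == 0L) return(NULL)
    validate_panel(design_val, feats, val_cohort)
  })
  # SEPT9-like comparator: the average of three probes carrying no planted
  # signal, evaluated exactly like a one-feature panel
  null_probes <- head(setdiff(rownames(methylome), plan$probe_id), 3L)
  sept9_beta <- average_probe_set(methylome[, val_ids, drop = FALSE],
                                  null_probes)
  sept9_pyro <- tibble::tibble(sample_id = sept9_beta$sample_id,
                               marker_id = "SEPT9",
                               percent_methylation = pmin(pmax(
                                 100 * sept9_beta$mean_beta, 0), 100))
  design_sept9 <- build_design(sept9_pyro, val_cohort,
                               transform = config$transform)
  validation$sept9 <- validate_panel(design_sept9, "SEPT9", val_cohort)
  report$validation <- validation

  # --- off-target and matched-specimen checks -----------------------------
  sparse_markers <- setdiff(
    validation$lasso$panel %||% character(), c("age", "sex"))
  if (length(sparse_markers) == 0L) sparse_markers <- head(markers, 2L)
  plan_sub <- plan[match(sparse_markers, plan$probe_id), , drop = FALSE]
  plan_sub <- plan_sub[!is.na(plan_sub$probe_id), , drop = FALSE]
  if (nrow(plan_sub) > 0L) {
    off <- generate_offtarget(plan_sub, n = config$n_offtarget,
                              contamination = config$contamination,
                              seed = seed)
    sparse_model <- fit_panel_logistic(design_val, sparse_markers)
    sparse_roc <- validation$lasso$roc %||%
      roc_auc(loocv_scores(design_val, sparse_markers)$score,
              as.character(design_val$y))
    report$offtarget <- evaluate_offtarget(
      sparse_model, off$pyro, cutoff = sparse_roc$youden$threshold,
      subjects = off$subjects)
    paired <- generate_paired_serum_plasma(plan_sub,
                                           n_pairs = config$n_paired,
                                           offset_sd = config$plasma_offset_sd,
                                           seed = seed)
    report$serum_plasma <- paired |>
      dplyr::group_by(.data$marker_id) |>
      dplyr::group_modify(~ group_tests(.x$serum_percent,
                                        paired_values = .x$plasma_percent)) |>
      dplyr::ungroup()
  }
  structure(report, class = "mp_pipeline")
}

# One panel's validation block: model, LOOCV ROC, Youden labels, confusion
# metrics, subgroup rates.
validate_panel <- function(design, feats, cohort) {
  model <- fit_panel_logistic(design, feats)
  scores <- loocv_scores(design, feats)
  roc <- roc_auc(scores$score, scores$truth)
  cut <- roc$youden$threshold
  pred <- ifelse(scores$score >= cut, "AN", "NN")
  cm <- confusion_metrics(pred, scores$truth)
  sub <- subgroup_detection(
    tibble::tibble(sample_id = scores$sample_id, pred = pred), cohort)
  list(panel = feats, model = model, loocv = scores, roc = roc,
       cutoff = cut, confusion = cm, subgroups = sub)
}

#' @export
print.mp_pipeline <- function(x, ...) {
  cat("<methpanel pipeline report>\n")
  if (!is.null(x$pools)) {
    cat(sprintf("  pools: %d (%s)\n", length(unique(x$pools$pool_id)),
                paste(sprintf("%s %d", names(table(dplyr::distinct(
                  x$pools, .data$pool_id, .data$class)$class)),
                  table(dplyr::distinct(x$pools, .data$pool_id,
                                        .data$class)$class)),
                  collapse = ", ")))
  }
  if (!is.null(x$dmp_summary)) {
    cat(sprintf("  DMPs: %d (%.1f%% hyper)\n", x$dmp_summary$n_total,
                x$dmp_summary$pct_hyper))
  }
  if (!is.null(x$candidates)) {
    cat(sprintf("  candidates: %d (%s)\n", nrow(x$candidates),
                paste(sprintf("%s %d", names(table(x$candidates$source)),
                              table(x$candidates$source)), collapse = ", ")))
  }
  if (!is.null(x$validation)) {
    for (nm in names(x$validation)) {
      v <- x$validation[[nm]]
      if (is.null(v)) next
      cat(sprintf("  %s panel: AUC %.3f\n", nm, v$roc$auc))
    }
  }
  invisible(x)
}
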