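test_that("panel logistic fits match an independent IRLS oracle", {
  withr::local_seed(21)
  x <- data.frame(a = rnorm(20), b = rnorm(20))
  y01 <- rbinom(20, 1, plogis(0.5 * x$a - 0.3 * x$b))
  fit <- fit_logistic(x, y01, c("a", "b"))
  oracle <- irls_logistic(as.matrix(x), y01)
  expect_false(fit$separated)
  expect_equal(unname(fit$coef), unname(oracle), tolerance = 1e-6)
})

test_that("separated fits fall back to the bias-reduced estimate", {
  d <- make_val_design(n_per_class = 12, shift = 60, noise = 1, seed = 2)
  model <- fit_panel_logistic(d$design, "M1")
  expect_true(model$separated)
  expect_true(all(is.finite(model$coef)))
  # score ordering preserved: higher marker -> higher probability
  x <- as.data.frame(d$design$x_raw)
  expect_gt(cor(x$M1, model$predict(x)), 0.9)

  dd <- d$design
  dd$x_raw <- cbind(dd$x_raw, M1_copy = dd$x_raw[, "M1"])
  expect_error(fit_panel_logistic(dd, c("M1", "M1_copy")),
               class = "methpanel_validation_error")
})

test_that("null features give well-calibrated coefficient inference", {
  covered <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      df <- data.frame(a = rnorm(40), y = rbinom(40, 1, 0.5))
      fit <- suppressWarnings(glm(y ~ a, family = binomial(), data = df))
      ci <- suppressMessages(confint.default(fit))["a", ]
      ci[1] < 0 && ci[2] > 0
    })
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("LOOCV scores are out-of-fold and not optimistic", {
  optimism_ok <- vapply(1:10, function(s) {
    d <- make_val_design(n_per_class = 10, shift = 15, noise = 12, seed = s)
    scores <- loocv_scores(d$design, "M1")
    model <- fit_panel_logistic(d$design, "M1")
    train_scores <- model$predict(as.data.frame(d$design$x_raw))
    auc_cv <- roc_auc(scores$score, scores$truth)$auc
    auc_train <- roc_auc(train_scores, as.character(d$design$y))$auc
    auc_cv <= auc_train + 1e-9
  }, logical(1))
  expect_gte(mean(optimism_ok), 0.9)

  d <- make_val_design(seed = 3)
  small <- d$design
  keep <- 1:8
  small$x_raw <- small$x_raw[keep, , drop = FALSE]
  small$y <- small$y[keep]
  small$sample_id <- small$sample_id[keep]
  expect_error(loocv_scores(small, "M1"), class = "methpanel_validation_error")
})

test_that("a constant feature scores every sample equally (AUC 0.5)", {
  d <- make_val_design(seed = 4)
  des <- d$design
  des$x_raw[, "M2"] <- 50
  scores <- loocv_scores(des, "M2")
  expect_equal(length(unique(round(scores$score, 10))), 1L)
  expect_equal(roc_auc(scores$score, scores$truth)$auc, 0.5)
})

test_that("ROC and AUC match the exhaustive pair-counting oracle", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c("AN", "AN", "NN", "NN"))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden$j, 1)
  expect_equal(perfect$youden$sensitivity, 1)
  expect_equal(perfect$youden$specificity, 1)

  tied <- roc_auc(c(0.9, 0.8, 0.8, 0.1), c("AN", "AN", "NN", "NN"))
  expect_equal(tied$auc, 0.875)
  expect_equal(tied$auc,
               auc_bruteforce(c(0.9, 0.8, 0.8, 0.1),
                              c("AN", "AN", "NN", "NN")))

  for (s in 1:20) {
    withr::with_seed(s, {
      n <- sample(10:50, 1)
      labels <- sample(c("NN", "AN"), n, TRUE)
      if (length(unique(labels)) < 2) labels[1:2] <- c("NN", "AN")
      scores <- round(runif(n), 2)  # force some ties
      r <- roc_auc(scores, labels)
      expect_equal(r$auc, auc_bruteforce(scores, labels), tolerance = 1e-12)
      oracle <- youden_bruteforce(scores, labels)
      expect_equal(r$youden$j, oracle$j, tolerance = 1e-12)
      expect_equal(r$youden$specificity, oracle$spec, tolerance = 1e-12)
    })
  }
  expect_error(roc_auc(1:3, rep("AN", 3)), class = "methpanel_validation_error")
})

test_that("random scores give null-range AUC", {
  aucs <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      roc_auc(runif(200), rep(c("NN", "AN"), 100))$auc
    })
  }, numeric(1))
  expect_gte(mean(aucs >= 0.42 & aucs <= 0.58), 0.95)
})

test_that("Youden ties break toward higher specificity", {
  # two cutoffs with equal J = 0.5: spec 1/sens 0.5 and spec 0.5/sens 1
  scores <- c(0.9, 0.4, 0.6, 0.1)
  labels <- c("AN", "AN", "NN", "NN")
  y <- youden_cutoff(roc_auc(scores, labels))
  expect_equal(y$specificity, 1)
  expect_equal(y$sensitivity, 0.5)
})

test_that("confusion metrics reproduce the published validation arithmetic", {
  # 2-marker panel row: sens 78.8% of 66 AN, spec 100% of 39 NN
  truth <- rep(c("AN", "NN"), c(66, 39))
  pred <- c(rep("AN", 52), rep("NN", 14), rep("NN", 39))
  cm <- confusion_metrics(pred, truth)
  est <- setNames(cm$estimate, cm$metric)
  expect_equal(round(est[["sensitivity"]], 1), 78.8)
  expect_equal(est[["specificity"]], 100)
  expect_equal(round(est[["npv"]], 1), 73.6)
  expect_equal(est[["ppv"]], 100)
  sens_ci <- round(c(cm$conf_low[cm$metric == "sensitivity"],
                     cm$conf_high[cm$metric == "sensitivity"]))
  expect_equal(sens_ci, c(67, 88))
  spec_ci <- round(c(cm$conf_low[cm$metric == "specificity"],
                     cm$conf_high[cm$metric == "specificity"]))
  expect_equal(spec_ci, c(91, 100))

  # 4-marker panel row: TP 41, FN 25, TN 38, FP 1
  truth4 <- rep(c("AN", "NN"), c(66, 39))
  pred4 <- c(rep("AN", 41), rep("NN", 25), rep("AN", 1), rep("NN", 38))
  cm4 <- confusion_metrics(pred4, truth4)
  est4 <- setNames(cm4$estimate, cm4$metric)
  expect_equal(round(est4[["npv"]], 1), 60.3)
  expect_equal(round(est4[["ppv"]], 1), 97.6)

  all_good <- confusion_metrics(rep("AN", 5), rep("AN", 5))
  expect_equal(all_good$estimate[all_good$metric == "sensitivity"], 100)
  expect_true(is.na(all_good$estimate[all_good$metric == "specificity"]))
  expect_equal(all_good$conf_high[all_good$metric == "sensitivity"], 100)
})

test_that("confusion metrics are order-invariant and exact in counts", {
  withr::local_seed(31)
  truth <- sample(c("AN", "NN"), 60, TRUE)
  pred <- sample(c("AN", "NN"), 60, TRUE)
  cm1 <- confusion_metrics(pred, truth)
  perm <- sample(60)
  cm2 <- confusion_metrics(pred[perm], truth[perm])
  expect_equal(cm1, cm2)
  counts <- attr(cm1, "counts")
  expect_equal(sum(counts), 60L)
})

test_that("subgroup detection reproduces published rates and the location test", {
  cohort <- generate_cohort(seed = 8)
  val <- cohort[cohort$cohort == "validation", ]
  aa <- val$subject_id[val$finding == "AA"]
  crc <- val$subject_id[val$finding == "CRC"]
  aa_d <- val$subject_id[val$finding == "AA" & val$location == "distal"]
  aa_p <- val$subject_id[val$finding == "AA" & val$location == "proximal"]
  # detect 20/23 distal AA, 13/19 proximal AA, 19/24 CRC
  detected <- c(aa_d[1:20], aa_p[1:13], crc[1:19])
  pred <- tibble::tibble(
    sample_id = val$subject_id,
    pred = ifelse(val$subject_id %in% detected, "AN", "NN")
  )
  res <- subgroup_detection(pred, val)
  rates <- setNames(res$rates$percent, res$rates$subgroup)
  expect_equal(round(rates[["AA_all"]], 1), 78.6)
  expect_equal(round(rates[["CRC_all"]], 1), 79.2)
  expect_equal(round(rates[["AA_distal"]], 0), 87)
  expect_equal(round(rates[["AA_proximal"]], 1), 68.4)
  expect_gt(res$fisher_distal_proximal, 0.05)
  expect_equal(res$fisher_distal_proximal,
               fisher.test(matrix(c(20, 3, 13, 6), 2))$p.value)

  all_hit <- tibble::tibble(sample_id = val$subject_id, pred = "AN")
  expect_equal(subgroup_detection(all_hit, val)$fisher_distal_proximal, 1)
})

test_that("rank tests match the enumeration oracle and conventions", {
  res <- group_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, ranksum_bruteforce(c(1, 2, 3), c(4, 5, 6)))

  for (s in 1:10) {
    withr::with_seed(s, {
      a <- sample(1:100, sample(3:4, 1))
      b <- sample(101:200, sample(3:4, 1)) - sample(50:150, 1)
      if (!any(duplicated(c(a, b)))) {
        res <- group_tests(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
        expect_equal(res$p_value, ranksum_bruteforce(a, b), tolerance = 1e-12)
      }
    })
  }
  expect_warning(res_tied <- group_tests(rep(1, 6), rep(c("a", "b"), 3)))
  expect_equal(res_tied$p_value, 1)
  expect_warning(res_paired <- group_tests(1:5, paired_values = 1:5))
  expect_equal(res_paired$p_value, 1)
  v <- c(3, 5, 8, 1, 9)
  w <- c(2, 8, 4, 6, 2)
  expect_equal(group_tests(v, paired_values = w)$p_value,
               wilcox.test(v, w, paired = TRUE, exact = TRUE)$p.value)
})

test_that("probe-set averaging handles present, missing and absent probes", {
  vals <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 3,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  b <- beta_matrix(vals)
  avg <- average_probe_set(b, c("p1", "p2", "p3"))
  expect_equal(avg$mean_beta, unname(colMeans(vals)))
  expect_equal(average_probe_set(b, "p2")$mean_beta, unname(vals["p2", ]))
  expect_message(two <- average_probe_set(b, c("p1", "p2", "ghost")), "ghost")
  expect_equal(two$mean_beta, unname(colMeans(vals[1:2, ])))
  expect_error(average_probe_set(b, "ghost"),
               class = "methpanel_validation_error")
})

test_that("off-target evaluation reports the contaminated fraction", {
  d <- make_val_design(n_per_class = 20, shift = 40, noise = 3, seed = 6)
  model <- fit_panel_logistic(d$design, "M1")
  scores <- loocv_scores(d$design, "M1")
  cutoff <- roc_auc(scores$score, scores$truth)$youden$threshold

  plan <- tibble::tibble(probe_id = "M1", delta_beta = 0.4,
                         direction = "hyper", base_mean = 0.30, precision = 400)
  for (k in c(0L, 1L, 3L)) {
    off <- generate_offtarget(plan, n = 16, contamination = k / 16,
                              noise_sd = 1, seed = 9)
    res <- evaluate_offtarget(model, off$pyro, cutoff, subjects = off$subjects)
    expect_equal(res$n_misclassified, k)
    expect_equal(res$rate_percent, 100 * k / 16)
  }
  expect_error(
    evaluate_offtarget(model, tibble::tibble(sample_id = "x", marker_id = "ZZ",
                                             percent_methylation = 1), 0.5),
    class = "methpanel_validation_error")
})
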