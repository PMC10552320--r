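# Small two-class datasets for the SES and ranking tests.
make_signal_data <- function(n = 200, p_noise = 49, seed = 1,
                             informative_shift = 2) {
  withr::with_seed(seed, {
    y <- rep(c("NN", "AN"), each = n / 2)
    x <- matrix(rnorm(n * (p_noise + 1)), n)
    colnames(x) <- c("inf1", paste0("noise", seq_len(p_noise)))
    x[y == "AN", "inf1"] <- x[y == "AN", "inf1"] + informative_shift
    list(x = as.data.frame(x), y = y)
  })
}

test_that("SES isolates a single informative feature among noise", {
  hits <- vapply(1:10, function(s) {
    d <- make_signal_data(n = 200, p_noise = 49, seed = s)
    res <- ses_select(d$x, d$y, alpha = 0.05, max_k = 3)
    length(res$selected) >= 1 && "inf1" %in% unlist(res$signatures)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("duplicated informative columns yield two equivalent signatures", {
  d <- make_signal_data(n = 120, p_noise = 3, seed = 4)
  d$x$inf_dup <- d$x$inf1
  res <- ses_select(d$x, d$y, alpha = 0.05, max_k = 2)
  single <- vapply(res$signatures, length, integer(1))
  expect_true(all(single == length(res$selected)))
  flat <- vapply(res$signatures, paste, character(1), collapse = "+")
  expect_true(any(grepl("inf1", flat)) && any(grepl("inf_dup", flat)))
  expect_gte(length(res$signatures), 2L)
})

test_that("SES signatures are competitive with exhaustive pair search", {
  withr::local_seed(9)
  n <- 80
  y <- rep(c("NN", "AN"), each = n / 2)
  x <- matrix(rnorm(n * 10), n)
  colnames(x) <- paste0("f", 1:10)
  x[y == "AN", "f1"] <- x[y == "AN", "f1"] + 1.2
  x[y == "AN", "f2"] <- x[y == "AN", "f2"] + 1.0
  x <- as.data.frame(x)

  cv_err <- function(cols, seed) {
    df <- data.frame(yy = (y == "AN"), x[, cols, drop = FALSE])
    withr::with_seed(seed, {
      fold <- rep_len(1:5, n)[sample(n)]
      errs <- vapply(1:5, function(k) {
        fit <- suppressWarnings(glm(yy ~ ., data = df[fold != k, ],
                                    family = binomial()))
        pred <- predict(fit, newdata = df[fold == k, ], type = "response")
        mean((pred >= 0.5) != df$yy[fold == k])
      }, numeric(1))
      c(mean(errs), sd(errs) / sqrt(5))
    })
  }
  pairs <- utils::combn(colnames(x), 2, simplify = FALSE)
  pair_err <- vapply(seq_along(pairs), function(i) cv_err(pairs[[i]], 100)[1],
                     numeric(1))
  best <- min(pair_err)
  best_se <- cv_err(pairs[[which.min(pair_err)]], 100)[2]

  res <- ses_select(x, y, alpha = 0.05, max_k = 2)
  sig <- res$signatures[[1]]
  sig_cols <- if (length(sig) >= 2) sig[1:2] else c(sig, setdiff(colnames(x), sig)[1])
  sig_err <- cv_err(sig_cols, 100)[1]
  expect_lte(sig_err, best + best_se + 1e-9)
})

test_that("CV ranking orders probes by error then effect size", {
  withr::local_seed(2)
  n <- 40
  y <- rep(c("NN", "AN"), each = n / 2)
  x <- data.frame(
    clean = c(rnorm(n / 2, 0.2, 0.02), rnorm(n / 2, 0.6, 0.02)),
    weak = rnorm(n, 0.5, 0.1)
  )
  fits <- tibble::tibble(probe_id = c("clean", "weak"),
                         delta_beta = c(0.4, 0.01), q_value = c(1e-5, 0.5))
  ranked <- cv_rank_candidates(list("clean", "weak"), x, y, fits,
                               folds = 5, repeats = 2, seed = 1)
  expect_equal(ranked$probe_id[1], "clean")
  expect_equal(ranked$min_cv_error[1], 0)
  expect_equal(ranked$rank, 1:2)
})

test_that("probes tied on error rank by larger absolute effect", {
  withr::local_seed(3)
  n <- 40
  y <- rep(c("NN", "AN"), each = n / 2)
  x <- data.frame(
    a = c(rnorm(n / 2, 0.2, 0.01), rnorm(n / 2, 0.8, 0.01)),
    b = c(rnorm(n / 2, 0.3, 0.01), rnorm(n / 2, 0.7, 0.01))
  )
  fits <- tibble::tibble(probe_id = c("a", "b"), delta_beta = c(0.6, 0.4),
                         q_value = c(1e-4, 1e-4))
  ranked <- cv_rank_candidates(list("a", "b"), x, y, fits,
                               folds = 5, repeats = 2,
                               learners = "logistic", seed = 2)
  expect_equal(ranked$min_cv_error, c(0, 0))
  expect_equal(ranked$probe_id, c("a", "b"))
})

test_that("ranking is stable across seeds on separable data", {
  withr::local_seed(8)
  n <- 60
  y <- rep(c("NN", "AN"), each = n / 2)
  shifts <- seq(0.15, 0.5, length.out = 8)
  x <- as.data.frame(vapply(shifts, function(s) {
    c(rnorm(n / 2, 0.3, 0.08), rnorm(n / 2, 0.3 + s, 0.08))
  }, numeric(n)))
  colnames(x) <- paste0("m", 1:8)
  fits <- tibble::tibble(probe_id = colnames(x), delta_beta = shifts,
                         q_value = 1e-4)
  sigs <- as.list(colnames(x))
  r1 <- cv_rank_candidates(sigs, x, y, fits, folds = 5, repeats = 3,
                           learners = "logistic", seed = 1)
  r2 <- cv_rank_candidates(sigs, x, y, fits, folds = 5, repeats = 3,
                           learners = "logistic", seed = 99)
  rho <- cor(r1$rank[match(colnames(x), r1$probe_id)],
             r2$rank[match(colnames(x), r2$probe_id)], method = "spearman")
  expect_gte(rho, 0.8)
  expect_identical(
    r1,
    cv_rank_candidates(sigs, x, y, fits, folds = 5, repeats = 3,
                       learners = "logistic", seed = 1)
  )
})

test_that("candidate assembly unions the three sources with provenance", {
  ranked <- tibble::tibble(probe_id = sprintf("cg%03d", 1:30),
                           min_cv_error = seq(0, 0.29, by = 0.01),
                           delta_beta = 0.2, q_value = 0.01, rank = 1:30)
  aa <- sprintf("aa%02d", 1:3)
  rrbs <- sprintf("rr%02d", 1:8)
  cand <- select_candidates(ranked, n_top = 15, aa_zero = aa,
                            rrbs_probes = rrbs)
  expect_equal(nrow(cand), 26L)
  expect_equal(as.integer(table(cand$source)[c("ses_top15", "aa_zero_error",
                                               "rrbs_concordant")]),
               c(15L, 3L, 8L))

  cand18 <- select_candidates(ranked, n_top = 15, aa_zero = aa,
                              rrbs_probes = character())
  expect_equal(nrow(cand18), 18L)

  # overlap deduplicates and is logged
  expect_message(
    cand_overlap <- select_candidates(ranked, n_top = 15,
                                      aa_zero = ranked$probe_id[1:3],
                                      rrbs_probes = rrbs),
    "dedup"
  )
  expect_equal(nrow(cand_overlap), 23L)
  expect_error(select_candidates(ranked[1:10, ], n_top = 15),
               class = "methpanel_validation_error")
})

test_that("zero-error advanced-adenoma probes are found on separable data", {
  withr::local_seed(12)
  n <- 30
  y <- rep(c("NN", "AA"), each = n / 2)
  x <- data.frame(
    sep = c(rnorm(n / 2, 0.2, 0.01), rnorm(n / 2, 0.8, 0.01)),
    junk = rnorm(n, 0.5, 0.1)
  )
  zero <- aa_zero_error_probes(x, y, folds = 5, repeats = 2, seed = 3)
  expect_true("sep" %in% zero)
  expect_false("junk" %in% zero)
})
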