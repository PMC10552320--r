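test_that("the default synthetic cohort reproduces the study composition", {
  cohort <- generate_cohort(seed = 1)
  expect_equal(nrow(cohort), 433L)
  val <- cohort[cohort$cohort == "validation", ]
  expect_equal(sum(val$class == "NN"), 39L)
  expect_equal(sum(val$class == "AN"), 66L)
  expect_true(all(cohort$age >= 50 & cohort$age <= 75))
  # sex balance within every pooling stratum is at worst one subject off
  balance <- cohort |>
    dplyr::mutate(group = pathological_group(finding, location, stage)) |>
    dplyr::count(cohort, group, sex) |>
    tidyr::pivot_wider(names_from = sex, values_from = n, values_fill = 0L)
  expect_true(all(abs(balance$male - balance$female) <= 1L))
})

test_that("cohort generation is deterministic and handles empty configs", {
  expect_identical(generate_cohort(seed = 7), generate_cohort(seed = 7))
  empty <- generate_cohort(cohort_composition()[0, ], seed = 1)
  expect_equal(nrow(empty), 0L)
})

test_that("marker plans respect the hypermethylated fraction and bounds", {
  plan <- marker_plan(sprintf("cg%06d", 1:5000), 300, 0.2, seed = 2)
  expect_equal(mean(plan$delta_beta > 0), round(0.867 * 300) / 300,
               tolerance = 1e-12)
  expect_true(all(plan$base_mean > 0 & plan$base_mean < 1))
  expect_true(all(plan$base_mean + plan$delta_beta > 0 &
                    plan$base_mean + plan$delta_beta < 1))
  expect_error(marker_plan(letters, 30, 0.2), class = "methpanel_validation_error")
  expect_error(marker_plan(letters, 3, 1.2), class = "methpanel_validation_error")
})

test_that("planted effects are recovered as mean differences", {
  cohort <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:400), sex = "male", age = 60L,
    hospital = "H1", finding = rep(c("NCF", "AA"), each = 200),
    location = rep(c("none", "distal"), each = 200), stage = "none",
    class = rep(c("NN", "AN"), each = 200)
  )
  plan <- tibble::tibble(probe_id = "cg000001", delta_beta = 0.2,
                         direction = "hyper", base_mean = 0.4, precision = 60)
  meth <- generate_methylome(cohort, 50L, plan, seed = 7)
  diff <- mean(meth["cg000001", cohort$class == "AN"]) -
    mean(meth["cg000001", cohort$class == "NN"])
  expect_lt(abs(diff - 0.2), 0.03)

  bad_plan <- plan
  bad_plan$base_mean <- 0.9
  err <- expect_error(generate_methylome(cohort, 50L, bad_plan, seed = 7),
                      class = "methpanel_validation_error")
  expect_match(conditionMessage(err), "cg000001")
})

test_that("without planted effects the generator is null-calibrated", {
  cohort <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:60), sex = "male", age = 60L,
    hospital = "H1", finding = rep(c("NCF", "AA"), each = 30),
    location = rep(c("none", "distal"), each = 30), stage = "none",
    class = rep(c("NN", "AN"), each = 30)
  )
  meth <- generate_methylome(cohort, 2000L, plan = NULL, seed = 5)
  an <- cohort$class == "AN"
  pvals <- apply(unclass(meth), 1L, function(v) t.test(v[an], v[!an])$p.value)
  # rejection rate at alpha = 0.05 should sit near 0.05 (binomial MC error)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.015)
})

test_that("pooled array values are member means perturbed by bounded noise", {
  cohort <- pool_ready_cohort(10L, "NCF", seed = 2)
  pools <- build_pools(cohort, groups = "NCF", seed = 2)
  vals <- matrix(0.4, 3, 10,
                 dimnames = list(paste0("cg", 1:3), cohort$subject_id))
  b <- beta_matrix(vals)
  pb <- simulate_array_pools(b, pools, noise_sd = 0, seed = 1)
  expect_true(all(abs(unclass(pb) - 0.4) < 1e-12))

  vals2 <- vals
  vals2[2, ] <- rep(c(0, 1), each = 5)
  pb2 <- simulate_array_pools(beta_matrix(vals2), pools, noise_sd = 0, seed = 1)
  expect_equal(unname(unclass(pb2)[2, 1]), 0.5)

  cohort2 <- pool_ready_cohort(40L, c("NCF", "D-AA"), seed = 3)
  pools2 <- build_pools(cohort2, groups = c("NCF", "D-AA"), seed = 3)
  meth <- generate_methylome(cohort2, 1000L, plan = NULL, seed = 3)
  pb3 <- simulate_array_pools(meth, pools2, noise_sd = 0.1, seed = 3)
  exact <- simulate_array_pools(meth, pools2, noise_sd = 0, seed = 3)
  cors <- vapply(colnames(pb3), function(p) {
    cor(unclass(pb3)[, p], unclass(exact)[, p])
  }, numeric(1))
  expect_true(all(cors > 0.95))

  pools_bad <- pools
  pools_bad$subject_id[1] <- "ghost"
  err <- expect_error(simulate_array_pools(b, pools_bad, 0, 1),
                      class = "methpanel_validation_error")
  expect_match(conditionMessage(err), "ghost")
  expect_error(simulate_array_pools(b, pools[-1, ], 0, 1),
               class = "methpanel_validation_error")
})

test_that("pyrosequencing simulation is 100x beta with clipped noise", {
  vals <- matrix(c(0.11, 0.52, 0.93, 0.4), 2,
                 dimnames = list(c("cgA", "cgB"), c("s1", "s2")))
  b <- beta_matrix(vals)
  py <- simulate_pyrosequencing(b, c("cgA", "cgB"), noise_sd = 0, seed = 1)
  wide <- tidyr::pivot_wider(py, names_from = marker_id,
                             values_from = percent_methylation)
  expect_equal(wide$cgA, unname(100 * vals["cgA", ]))
  expect_error(simulate_pyrosequencing(b, "nope", 0, 1),
               class = "methpanel_validation_error")
  py2 <- simulate_pyrosequencing(b, "cgA", noise_sd = 5, seed = 2)
  expect_true(all(py2$percent_methylation >= 0 & py2$percent_methylation <= 100))
})

test_that("doubling pyrosequencing noise lowers pool-individual concordance", {
  cohort <- pool_ready_cohort(20L, c("NCF", "D-AA"), seed = 4)
  plan <- marker_plan(sprintf("cg%06d", 1:200), 26, 0.2, seed = 4)
  meth <- generate_methylome(cohort, 200L, plan, seed = 4)
  pools <- build_pools(cohort, groups = c("NCF", "D-AA"), seed = 4)
  pb <- simulate_array_pools(meth, pools, 0.1, seed = 4)
  pool_class <- dplyr::distinct(pools, pool_id, class)
  concordance <- function(noise_sd, seed) {
    py <- simulate_pyrosequencing(meth, plan$probe_id, noise_sd, seed = seed)
    cohort_cls <- setNames(cohort$class, cohort$subject_id)
    py$class <- cohort_cls[py$sample_id]
    ind <- py |>
      dplyr::group_by(marker_id, class) |>
      dplyr::summarise(pct = mean(percent_methylation), .groups = "drop")
    pool_means <- purrr::map_dfr(c("NN", "AN"), function(cl) {
      ids <- pool_class$pool_id[pool_class$class == cl]
      tibble::tibble(
        marker_id = plan$probe_id, class = cl,
        pool_beta = rowMeans(unclass(pb)[plan$probe_id, ids, drop = FALSE])
      )
    })
    j <- dplyr::inner_join(ind, pool_means, by = c("marker_id", "class"))
    cor(j$pct / 100, j$pool_beta)
  }
  rs <- vapply(1:5, function(s) {
    concordance(5, s) - concordance(10, s)
  }, numeric(1))
  expect_true(mean(rs > 0) >= 0.8)
})

test_that("sequencing-concordance tables contain exactly the planned hits", {
  plan <- marker_plan(sprintf("cg%06d", 1:500), 40, 0.2, seed = 6)
  rrbs <- generate_rrbs_table(plan, n_concordant = 8, min_diff = 0.30, seed = 6)
  fits <- tibble::tibble(probe_id = plan$probe_id, delta_beta = plan$delta_beta)
  hits <- rrbs_concordance_filter(fits, rrbs, 0.30)
  expect_equal(nrow(hits), 8L)

  none <- generate_rrbs_table(plan, n_concordant = 0, min_diff = 0.30, seed = 6)
  expect_equal(nrow(rrbs_concordance_filter(fits, none, 0.30)), 0L)

  flipped <- rrbs
  flipped$meth_diff <- -flipped$meth_diff
  expect_equal(nrow(rrbs_concordance_filter(fits, flipped, 0.30)), 0L)

  expect_error(generate_rrbs_table(plan, 8, min_diff = 1.2),
               class = "methpanel_validation_error")
  expect_error(generate_rrbs_table(plan, nrow(plan) + 1L, 0.3),
               class = "methpanel_validation_error")
})

test_that("off-target sera carry the configured contamination", {
  plan <- marker_plan(sprintf("cg%06d", 1:50), 4, 0.3, seed = 8)
  off <- generate_offtarget(plan[1:2, ], n = 16, contamination = 3 / 16,
                            seed = 8)
  expect_equal(sum(off$subjects$an_like), 3L)
  expect_equal(nrow(off$pyro), 32L)
  off0 <- generate_offtarget(plan[1:2, ], n = 16, contamination = 0, seed = 8)
  expect_equal(sum(off0$subjects$an_like), 0L)
  expect_error(generate_offtarget(plan[1:2, ], contamination = 2),
               class = "methpanel_validation_error")
})

test_that("zero-offset serum/plasma pairs are identical with signed-rank p = 1", {
  plan <- marker_plan(sprintf("cg%06d", 1:50), 4, 0.3, seed = 9)
  paired <- generate_paired_serum_plasma(plan[1:2, ], n_pairs = 8,
                                         offset_sd = 0, seed = 9)
  expect_identical(paired$serum_percent, paired$plasma_percent)
  one <- paired[paired$marker_id == paired$marker_id[1], ]
  expect_warning(
    res <- group_tests(one$serum_percent, paired_values = one$plasma_percent),
    "zero"
  )
  expect_equal(res$p_value, 1)
})

test_that("generators are deterministic for a fixed seed", {
  plan <- marker_plan(sprintf("cg%06d", 1:100), 10, 0.2, seed = 3)
  expect_identical(plan, marker_plan(sprintf("cg%06d", 1:100), 10, 0.2, seed = 3))
  cohort <- pool_ready_cohort(10L, "NCF", seed = 3)
  m1 <- generate_methylome(cohort, 100L, plan, seed = 3)
  m2 <- generate_methylome(cohort, 100L, plan, seed = 3)
  expect_identical(unclass(m1), unclass(m2))
  expect_false(identical(unclass(m1),
                         unclass(generate_methylome(cohort, 100L, plan, seed = 4))))
})
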