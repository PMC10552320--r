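#' Stratified random assignment into study cohorts
#'
#' Allocates subjects to the requested cohorts by stratified random sampling
#' with proportional allocation and largest-remainder rounding: within every
#' stratum the target cohort sizes are split proportionally to the stratum
#' size, fractional seats go to the largest remainders (so realized totals
#' match the targets exactly), and membership within a stratum is drawn at
#' random. Subjects not allocated remain `"unassigned"`.
#'
#' @param cohort Cohort tibble.
#' @param target_sizes Named integer vector, e.g.
#'   `c(evaluation = 48, validation = 105)`.
#' @param strata Character vector of stratifying columns (default finding
#'   and sex, the stratification used for the screening split).
#' @param seed Integer seed.
#' @return The cohort tibble with its `cohort` column filled in.
#' @export
stratified_split <- function(cohort, target_sizes,
                             strata = c("finding", "sex"), seed = 1L) {
  cohort <- tibble::as_tibble(cohort)
  assert_columns(cohort, strata, "cohort table")
  if (sum(target_sizes) > nrow(cohort)) {
    mp_stop("target sizes exceed the cohort size",
            class = "methpanel_validation_error")
  }
  if (is.null(names(target_sizes)) || any(!nzchar(names(target_sizes)))) {
    mp_stop("target_sizes must be a named vector of cohort names",
            class = "methpanel_validation_error")
  }
  stratum <- interaction(cohort[strata], drop = TRUE, sep = "|")
  n_total <- nrow(cohort)
  strata_levels <- levels(stratum)
  stratum_sizes <- as.integer(table(stratum))

  # seats[s, c]: subjects of stratum s allocated to cohort c
  seats <- matrix(0L, nrow = length(strata_levels), ncol = length(target_sizes),
                  dimnames = list(strata_levels, names(target_sizes)))
  for (j in seq_along(target_sizes)) {
    quota <- stratum_sizes * target_sizes[j] / n_total
    base <- floor(quota)
    rem <- target_sizes[j] - sum(base)
    order_rem <- order(quota - base, decreasing = TRUE)
    extra <- integer(length(quota))
    if (rem > 0L) extra[order_rem[seq_len(rem)]] <- 1L
    seats[, j] <- as.integer(base + extra)
  }
  over <- rowSums(seats) > stratum_sizes
  if (any(over)) {
    mp_stop(sprintf("stratum %s too small for its allocation",
                    strata_levels[which(over)[1L]]),
            class = "methpanel_validation_error")
  }
  assignment <- rep("unassigned", n_total)
  with_seed(derive_seed(seed, 9L), {
    for (s in seq_along(strata_levels)) {
      members <- sample(which(stratum == strata_levels[s]))
      offset <- 0L
      for (j in seq_along(target_sizes)) {
        take <- seats[s, j]
        if (take > 0L) {
          assignment[members[offset + seq_len(take)]] <- names(target_sizes)[j]
          offset <- offset + take
        }
      }
    }
  })
  cohort$cohort <- assignment
  cohort
}

#' Build sex-balanced cfDNA pools
#'
#' Constructs pools of exactly ten subjects — five men and five women from
#' the same pathological group — using every eligible subject exactly once.
#' Within each group, subjects of each sex are sorted by age and dealt to
#' the group's pools in snake order, so every pool receives a comparable
#' spread of ages and mean age does not differ systematically between
#' pools (the design check enforced downstream by
#' [check_pool_age_balance()]).
#'
#' @param cohort Cohort tibble; pooling uses the rows whose `cohort` equals
#'   `from_cohort`.
#' @param groups Pathological groups to pool; default all seven.
#' @param from_cohort Which study cohort supplies the subjects.
#' @param seed Integer seed (tie-breaking among equal ages).
#' @return A tibble with one row per pool member: `pool_id`, `subject_id`,
#'   `group`, `class`, `sex`, `age`.
#' @export
build_pools <- function(cohort,
                        groups = c("NCF", "BEN", "NAA", "P-AA", "D-AA",
                                   "CRC_I-II", "CRC_III-IV"),
                        from_cohort = "discovery", seed = 1L) {
  cohort <- validate_cohort(cohort)
  pool_src <- cohort[cohort$cohort == from_cohort, ]
  pool_src$group <- pathological_group(pool_src$finding, pool_src$location,
                                       pool_src$stage)
  pool_src <- pool_src[pool_src$group %in% groups, ]
  out <- list()
  counter <- 0L
  with_seed(derive_seed(seed, 10L), {
    for (g in groups) {
      sub <- pool_src[pool_src$group == g, ]
      if (nrow(sub) == 0L) next
      n_pools <- nrow(sub) / 10
      males <- sub[sub$sex == "male", ]
      females <- sub[sub$sex == "female", ]
      if (nrow(sub) %% 10 != 0 || nrow(males) != nrow(females)) {
        deficit <- abs(nrow(males) - nrow(females))
        mp_stop(sprintf(
          "group %s cannot form 5M+5F pools (%d male, %d female; deficit %d)",
          g, nrow(males), nrow(females), deficit),
          class = "methpanel_validation_error")
      }
      # age balancing: sort each sex by age (subject id as the
      # deterministic tie-break, so pooling is invariant to row order) and
      # deal to pools in snake order so pool mean ages are nearly equal
      males <- males[order(males$age, males$subject_id), ]
      females <- females[order(females$age, females$subject_id), ]
      deal <- rep(c(seq_len(n_pools), rev(seq_len(n_pools))),
                  length.out = 5L * n_pools)
      base_counter <- counter
      counter <- counter + n_pools
      for (k in seq_len(n_pools)) {
        members <- dplyr::bind_rows(males[deal == k, ], females[deal == k, ])
        out[[base_counter + k]] <- tibble::tibble(
          pool_id = sprintf("pool_%02d_%s", base_counter + k, g),
          subject_id = members$subject_id,
          group = g,
          class = if (g %in% c("NCF", "BEN", "NAA")) "NN" else "AN",
          sex = members$sex,
          age = members$age
        )
      }
    }
  })
  if (length(out) == 0L) {
    return(tibble::tibble(pool_id = character(), subject_id = character(),
                          group = character(), class = character(),
                          sex = character(), age = integer()))
  }
  dplyr::bind_rows(out)
}

#' Randomly allocate pools to array slides, one group per slide
#'
#' Emulates the slide randomization used to decouple pathological group from
#' beadchip: pools are dealt to slides of the given capacity so that no
#' slide carries two pools of the same pathological group, with the order of
#' deal randomized per seed.
#'
#' @param pools Pool tibble from [build_pools()].
#' @param slide_capacity Samples per beadchip (8 for the EPIC array).
#' @param n_slides Number of slides; by default just enough for both the
#'   capacity and the group-uniqueness constraint (a group with `m` pools
#'   needs at least `m` slides).
#' @param seed Integer seed.
#' @return `pools` with a `slide` column added.
#' @export
assign_to_slides <- function(pools, slide_capacity = 8L, n_slides = NULL,
                             seed = 1L) {
  spec <- dplyr::distinct(pools, .data$pool_id, .data$group)
  n_slides <- n_slides %||%
    max(ceiling(nrow(spec) / slide_capacity), max(table(spec$group)))
  if (n_slides * slide_capacity < nrow(spec) ||
      any(table(spec$group) > n_slides)) {
    mp_stop("more pools of one group than slides: no group-unique assignment exists",
            class = "methpanel_validation_error")
  }
  with_seed(derive_seed(seed, 11L), {
    # deal groups in decreasing multiplicity, random slide order per pool
    slots <- rep(slide_capacity, n_slides)
    slide_of <- setNames(integer(nrow(spec)), spec$pool_id)
    group_order <- names(sort(table(spec$group), decreasing = TRUE))
    for (g in group_order) {
      ids <- sample(spec$pool_id[spec$group == g])
      # prefer slides with most free capacity (random tie-break) so the
      # greedy deal never strands capacity
      open <- order(-slots, runif(n_slides))
      open <- open[slots[open] > 0L][seq_along(ids)]
      if (anyNA(open)) {
        mp_stop("slide allocation infeasible at the requested capacity",
                class = "methpanel_validation_error")
      }
      slide_of[ids] <- open
      slots[open] <- slots[open] - 1L
    }
    pools$slide <- unname(slide_of[pools$pool_id])
    pools
  })
}

#' One-way ANOVA of member ages across pools
#'
#' Classical fixed-effects one-way ANOVA of subject age grouped by pool,
#' used as the design check that pooling did not confound age.
#'
#' @param pools Pool tibble with `pool_id` and `age` (or supply `cohort` to
#'   look ages up by `subject_id`).
#' @param cohort Optional cohort tibble supplying ages.
#' @return A one-row tibble: `f`, `df1`, `df2`, `p_value`.
#' @export
check_pool_age_balance <- function(pools, cohort = NULL) {
  if (!("age" %in% names(pools))) {
    assert_columns(pools, c("pool_id", "subject_id"), "pool table")
    if (is.null(cohort)) {
      mp_stop("pools carry no ages and no cohort table was supplied",
              class = "methpanel_validation_error")
    }
    pools$age <- cohort$age[match(pools$subject_id, cohort$subject_id)]
  }
  if (length(unique(pools$pool_id)) < 2L) {
    mp_stop("at least two pools are required", class = "methpanel_validation_error")
  }
  if (any(table(pools$pool_id) < 2L)) {
    mp_stop("every pool needs at least two members for the ANOVA",
            class = "methpanel_validation_error")
  }
  fit <- stats::aov(age ~ factor(pool_id), data = pools)
  tab <- summary(fit)[[1L]]
  f <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  # identical age multisets across pools give zero between-group variance
  if (is.na(f) || tab[["Sum Sq"]][1L] < 1e-12) {
    f <- 0
    p <- 1
  }
  tibble::tibble(f = f, df1 = tab[["Df"]][1L], df2 = tab[["Df"]][2L],
                 p_value = p)
}
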