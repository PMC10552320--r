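#' Annotate DMPs to CpG-island relation and genic feature
#'
#' Counts called DMPs per annotation category along the two classification
#' axes (island relation; genic feature), for all DMPs and for the
#' hypermethylated / hypomethylated subsets. Probes absent from the
#' annotation are counted in an explicit `unannotated` category, never
#' dropped silently. Fractions sum to one within each (axis, subset).
#'
#' @param dmps DMP tibble with `probe_id` and `direction`.
#' @param annotation Probe annotation tibble (see [read_probe_annotation()]).
#' @return A tibble: `axis`, `category`, `subset`, `k`, `n`, `fraction`.
#' @export
annotate_dmps <- function(dmps, annotation) {
  if (nrow(dmps) == 0L) {
    return(tibble::tibble(axis = character(), category = character(),
                          subset = character(), k = integer(), n = integer(),
                          fraction = numeric()))
  }
  ann <- annotation[match(dmps$probe_id, annotation$probe_id), ]
  dmps$island_relation <- dplyr::coalesce(ann$island_relation, "unannotated")
  dmps$genic_feature <- dplyr::coalesce(ann$genic_feature, "unannotated")
  one_axis <- function(df, axis, subset) {
    counts <- df |>
      dplyr::count(category = .data[[axis]], name = "k") |>
      dplyr::mutate(axis = axis, subset = subset, n = nrow(df),
                    fraction = .data$k / nrow(df))
    counts[, c("axis", "category", "subset", "k", "n", "fraction")]
  }
  subsets <- list(all = dmps,
                  hyper = dmps[dmps$direction == "hyper", ],
                  hypo = dmps[dmps$direction == "hypo", ])
  purrr::imap_dfr(subsets, function(df, nm) {
    if (nrow(df) == 0L) return(NULL)
    dplyr::bind_rows(one_axis(df, "island_relation", nm),
                     one_axis(df, "genic_feature", nm))
  })
}

#' One-sided Fisher enrichment of a category
#'
#' Tests whether a category is over-represented among `k` of `n` DMPs
#' relative to `K` of `N` background probes: fold enrichment
#' `(k/n) / (K/N)` and the hypergeometric upper-tail probability
#' `P[X >= k]` for `X ~ Hypergeom(N, K, n)` (the one-sided Fisher exact
#' test).
#'
#' @param k DMPs in the category.
#' @param n Total DMPs in the subset.
#' @param K Background probes in the category.
#' @param N Total background probes.
#' @return A one-row tibble: `fold`, `p_value`.
#' @export
fisher_enrichment <- function(k, n, K, N) {
  if (k > n || n > N || k > K || K > N || min(k, n, K, N) < 0) {
    mp_stop("inconsistent enrichment margins (need k <= n <= N, k <= K <= N)",
            class = "methpanel_validation_error")
  }
  fold <- if (n == 0L || K == 0L) NA_real_ else (k / n) / (K / N)
  p <- phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  tibble::tibble(fold = fold, p_value = p)
}

#' Direction-split enrichment of DMP annotation categories
#'
#' Runs [fisher_enrichment()] for every annotation category along both
#' axes, separately for all DMPs and the hyper/hypo subsets, against the
#' background of analyzable probes (by default all probes surviving QC, not
#' the full manifest).
#'
#' @param dmps DMP tibble (`probe_id`, `direction`).
#' @param annotation Probe annotation tibble covering the background.
#' @param background Character vector of background probe ids.
#' @param alpha Per-category enrichment level for the `enriched` flag.
#' @return A tibble: `axis`, `category`, `subset`, `k`, `n`, `K`, `N`,
#'   `fold`, `p_value`, `enriched`.
#' @export
enrich_dmps <- function(dmps, annotation, background, alpha = 0.05) {
  counts <- annotate_dmps(dmps, annotation)
  if (nrow(counts) == 0L) return(counts)
  bg_ann <- annotation[match(background, annotation$probe_id), ]
  bg <- tibble::tibble(
    island_relation = dplyr::coalesce(bg_ann$island_relation, "unannotated"),
    genic_feature = dplyr::coalesce(bg_ann$genic_feature, "unannotated")
  )
  N <- length(background)
  counts$K <- purrr::map2_int(counts$axis, counts$category,
                              function(a, cat) sum(bg[[a]] == cat))
  counts$N <- N
  res <- purrr::pmap_dfr(counts[, c("k", "n", "K", "N")], fisher_enrichment)
  counts$fold <- res$fold
  counts$p_value <- res$p_value
  counts$enriched <- counts$p_value < alpha
  counts
}

#' Generate a synthetic probe annotation table
#'
#' Draws island relation and genic feature per probe from category
#' frequencies shaped like the array manifest (open sea most common,
#' promoter features rarer). Optionally biases a subset of probes (e.g.
#' planted DMPs) toward islands so enrichment is detectable by
#' construction.
#'
#' @param probe_ids Probes to annotate.
#' @param island_bias Optional character vector of probes whose island
#'   probability is boosted to `bias_prob`.
#' @param bias_prob Island probability for biased probes.
#' @param seed Integer seed.
#' @return A probe annotation tibble.
#' @export
generate_probe_annotation <- function(probe_ids, island_bias = NULL,
                                      bias_prob = 0.5, seed = 1L) {
  with_seed(derive_seed(seed, 12L), {
    n <- length(probe_ids)
    island_p <- c(Island = 0.20, Shore = 0.15, Shelf = 0.10, OpenSea = 0.55)
    genic_p <- c(TSS1500 = 0.10, TSS200 = 0.06, "5'UTR" = 0.08,
                 "1stExon" = 0.04, Body = 0.35, "3'UTR" = 0.04,
                 intergenic = 0.33)
    island <- sample(names(island_p), n, replace = TRUE, prob = island_p)
    if (!is.null(island_bias)) {
      idx <- which(probe_ids %in% island_bias)
      boosted <- island_p * (1 - bias_prob) / (1 - island_p[["Island"]])
      boosted[["Island"]] <- bias_prob
      island[idx] <- sample(names(boosted), length(idx), replace = TRUE,
                            prob = boosted)
    }
    tibble::tibble(
      probe_id = probe_ids,
      chrom = paste0("chr", sample(c(1:22, "X"), n, replace = TRUE)),
      pos = sample.int(2.4e8, n, replace = TRUE),
      gene_symbol = sprintf("GENE%05d", sample.int(20000L, n, replace = TRUE)),
      island_relation = island,
      genic_feature = sample(names(genic_p), n, replace = TRUE, prob = genic_p)
    )
  })
}
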