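# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

toy_beta <- function(values, level = "pool") {
  beta_matrix(values, level = level)
}

# Two-class pool matrix with known constant group values at every probe.
constant_pool_matrix <- function(n_probes = 5L, n_per_class = 4L,
                                 nn = 0.5, an = 0.7) {
  vals <- cbind(
    matrix(nn, n_probes, n_per_class),
    matrix(an, n_probes, n_per_class)
  )
  dimnames(vals) <- list(sprintf("cg%06d", seq_len(n_probes)),
                         c(sprintf("NN%d", seq_len(n_per_class)),
                           sprintf("AN%d", seq_len(n_per_class))))
  list(beta = beta_matrix(vals, "pool"),
       classes = rep(c("NN", "AN"), each = n_per_class))
}

# Random two-class pool matrix (gaussian on the beta scale, clipped).
random_pool_matrix <- function(n_probes = 200L, n_per_class = 10L, sd = 0.05,
                               seed = 1L) {
  withr::with_seed(seed, {
    mu <- runif(n_probes, 0.2, 0.8)
    vals <- matrix(rnorm(n_probes * 2 * n_per_class, mean = mu, sd = sd),
                   nrow = n_probes)
    vals <- pmin(pmax(vals, 0), 1)
    dimnames(vals) <- list(sprintf("cg%06d", seq_len(n_probes)),
                           sprintf("P%02d", seq_len(2L * n_per_class)))
    list(beta = beta_matrix(vals, "pool"),
         classes = rep(c("NN", "AN"), each = n_per_class))
  })
}

# Minimal valid cohort rows.
toy_cohort <- function(findings = c("NCF", "AA", "CRC"),
                       location = c("none", "distal", "distal"),
                       stage = c("none", "none", "II")) {
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_along(findings)),
    sex = rep(c("male", "female"), length.out = length(findings)),
    age = 60L,
    hospital = "H1",
    finding = findings,
    location = location,
    stage = stage
  )
}

# Discovery-style cohort with a small Table-1-like layout for pooling tests.
pool_ready_cohort <- function(n_per_group = 10L, groups = c("NCF", "D-AA"),
                              seed = 1L) {
  comp <- dplyr::bind_rows(lapply(groups, function(g) {
    tibble::tibble(
      cohort = "discovery",
      finding = switch(g, "NCF" = "NCF", "BEN" = "BEN_hemorrhoids",
                       "NAA" = "NAA", "D-AA" = "AA", "P-AA" = "AA",
                       "CRC_I-II" = "CRC", "CRC_III-IV" = "CRC"),
      location = switch(g, "D-AA" = "distal", "P-AA" = "proximal",
                        "CRC_I-II" = "distal", "CRC_III-IV" = "distal",
                        "none"),
      stage = switch(g, "CRC_I-II" = "I", "CRC_III-IV" = "IV", "none"),
      n = as.integer(n_per_group)
    )
  }))
  generate_cohort(comp, seed = seed)
}

# Evaluation-cohort-like pyrosequencing data with signal in a known marker
# subset. Returns the pyro table and the matching cohort slice.
make_eval_data <- function(n_markers = 26, signal = c("CG01", "CG02"),
                           shift = 25, noise = 6, seed = 1) {
  comp <- cohort_composition()
  comp <- comp[comp$cohort == "evaluation", ]
  cohort <- generate_cohort(comp, seed = seed)
  markers <- sprintf("CG%02d", seq_len(n_markers))
  withr::with_seed(seed + 1000, {
    pyro <- purrr::map_dfr(markers, function(m) {
      base <- runif(1, 15, 45)
      mu <- base + (m %in% signal) * shift * (cohort$class == "AN")
      tibble::tibble(
        sample_id = cohort$subject_id, marker_id = m,
        percent_methylation = pmin(pmax(rnorm(nrow(cohort), mu, noise), 0), 100)
      )
    })
  })
  list(pyro = pyro, cohort = cohort)
}

# A validation-like design with one informative marker (M1) and one null
# marker (M2).
make_val_design <- function(n_per_class = 20, shift = 30, noise = 8,
                            seed = 1, transform = "raw") {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    cohort <- tibble::tibble(
      subject_id = sprintf("V%03d", 1:n),
      sex = rep(c("male", "female"), n / 2),
      age = sample(50:75, n, TRUE),
      hospital = "H1",
      finding = rep(c("NCF", "CRC"), each = n_per_class),
      location = rep(c("none", "distal"), each = n_per_class),
      stage = rep(c("none", "II"), each = n_per_class)
    )
    pyro <- tibble::tibble(
      sample_id = rep(cohort$subject_id, 2),
      marker_id = rep(c("M1", "M2"), each = n),
      percent_methylation = pmin(pmax(c(
        rnorm(n, 30 + shift * (cohort$finding == "CRC"), noise),
        rnorm(n, 40, noise)), 0), 100)
    )
    list(design = build_design(pyro, cohort, transform), cohort = cohort)
  })
}

# Brute-force oracles -------------------------------------------------------

# Step-up BH by the explicit min-over-tail definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    q[i] <- min(sorted[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# AUC by exhaustive pair counting with half ties.
auc_bruteforce <- function(scores, labels, positive = "AN") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Youden by exhaustive scan over observed thresholds (ties -> higher spec).
youden_bruteforce <- function(scores, labels, positive = "AN") {
  thr <- c(sort(unique(scores)), Inf)
  best <- NULL
  for (t in thr) {
    called <- scores >= t
    sens <- mean(called[labels == positive])
    spec <- mean(!called[labels != positive])
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(threshold = t, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# Hypergeometric upper tail by direct summation.
hyper_tail_bruteforce <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
ranksum_bruteforce <- function(a, b) {
  values <- c(a, b)
  n <- length(values)
  na <- length(a)
  r <- rank(values)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(n, na)
  sums <- apply(combs, 2L, function(idx) sum(r[idx]))
  mu <- na * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# Independent IRLS logistic fit (Newton-Raphson on the canonical link).
irls_logistic <- function(x, y, max_iter = 50L, tol = 1e-12) {
  x <- cbind(1, as.matrix(x))
  beta <- rep(0, ncol(x))
  for (i in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    z <- eta + (y - p) / w
    beta_new <- solve(crossprod(x, x * w), crossprod(x, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  beta
}
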