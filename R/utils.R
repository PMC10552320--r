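#' @importFrom rlang %||% .data abort warn inform
#' @importFrom stats as.formula binom.test coef dbeta dhyper dt fisher.test
#'   glm lm median model.matrix p.adjust pchisq phyper plogis pnorm predict
#'   pt qbeta qchisq qlogis qnorm quantile rbeta rbinom rnorm runif sd
#'   setNames shapiro.test t.test var wilcox.test oneway.test binomial
#' @importFrom utils head modifyList
NULL

# Consistent internal error helper: all user-facing failures carry a class so
# tests can assert on them.
mp_stop <- function(msg, class = "methpanel_error") {
  rlang::abort(msg, class = class)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    mp_stop(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = "methpanel_schema_error"
    )
  }
  invisible(df)
}

assert_in_range <- function(x, lo, hi, what, na_ok = FALSE) {
  bad <- if (na_ok) !is.na(x) & (x < lo | x > hi) else is.na(x) | x < lo | x > hi
  if (any(bad)) {
    mp_stop(
      sprintf("%s must lie in [%s, %s]; %d value(s) violate this", what,
              format(lo), format(hi), sum(bad)),
      class = "methpanel_validation_error"
    )
  }
  invisible(x)
}

# Derive a stream-specific seed from a master seed; stays below 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9176L) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
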