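# Logistic fitting helpers shared by the SES search and the panel models.
#
# Maximum-likelihood logistic regression via glm(); when the fit separates
# (fitted probabilities collapse to 0/1 or coefficients diverge) we fall
# back to Jeffreys-prior penalized likelihood (Firth's bias reduction),
# which always has a finite maximizer and preserves the score ordering.

logistic_separated <- function(fit) {
  eps <- 1e-8
  probs <- fit$fitted.values
  !fit$converged || any(probs < eps) || any(probs > 1 - eps) ||
    any(abs(coef(fit)) > 1e3, na.rm = TRUE)
}

# Firth-penalized logistic regression by Newton iteration on the modified
# score U*(b) = U(b) + X' (h * (1/2 - p)); returns coefficients and the
# penalized log-likelihood.
firth_logistic <- function(x, y, max_iter = 100L, tol = 1e-8) {
  x <- cbind(`(Intercept)` = 1, x)
  beta <- rep(0, ncol(x))
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    xw <- x * sqrt(w)
    info <- crossprod(xw)
    info_inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(info_inv)) {
      info_inv <- solve(info + diag(1e-6, ncol(info)))
    }
    h <- rowSums((x %*% info_inv) * x) * w
    score <- drop(crossprod(x, (y - p) + h * (0.5 - p)))
    step <- drop(info_inv %*% score)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(x %*% beta)
  p <- plogis(eta)
  w <- p * (1 - p)
  info <- crossprod(x * sqrt(w))
  loglik <- sum(y * log(p) + (1 - y) * log1p(-p)) +
    0.5 * determinant(info, logarithm = TRUE)$modulus
  list(coefficients = setNames(beta, colnames(x)),
       fitted = p, loglik = as.numeric(loglik))
}

# Fit y ~ x[, cols]; returns list(deviance, coef, separated, predict).
# Deviance from the ML fit when well behaved, otherwise -2 * penalized
# log-likelihood from the Firth fallback (comparable across nested models
# fitted the same way).
fit_logistic <- function(x, y, cols = colnames(x)) {
  y01 <- if (is.numeric(y)) y else as.integer(y == "AN")
  xs <- x[, cols, drop = FALSE]
  df <- data.frame(.y = y01, xs, check.names = FALSE)
  fml <- as.formula(paste(
    ".y ~", if (length(cols) == 0L) "1" else {
      paste(sprintf("`%s`", cols), collapse = " + ")
    }))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  if (length(cols) > 0L && logistic_separated(fit)) {
    ff <- firth_logistic(as.matrix(xs), y01)
    return(list(deviance = -2 * ff$loglik, coef = ff$coefficients,
                separated = TRUE,
                predict = function(newx) {
                  plogis(drop(cbind(1, as.matrix(newx[, cols, drop = FALSE])) %*%
                                ff$coefficients))
                }))
  }
  list(deviance = fit$deviance, coef = coef(fit), separated = FALSE,
       predict = function(newx) {
         nd <- as.data.frame(newx[, cols, drop = FALSE])
         names(nd) <- cols
         predict(fit, newdata = nd, type = "response")
       })
}

# Deviance of y ~ x[, cols]; `penalized = TRUE` forces the Firth fit so two
# models entering one likelihood-ratio test are fitted consistently.
logistic_deviance <- function(x, y, cols, penalized = FALSE) {
  if (penalized) {
    y01 <- if (is.numeric(y)) y else as.integer(y == "AN")
    ff <- firth_logistic(as.matrix(x[, cols, drop = FALSE]), y01)
    return(-2 * ff$loglik)
  }
  fit_logistic(x, y, cols)$deviance
}

# Likelihood-ratio p-value for adding `f` to conditioning set `z`.
lrt_pvalue <- function(x, y, f, z) {
  fit0 <- fit_logistic(x, y, z)
  fit1 <- fit_logistic(x, y, c(z, f))
  if (fit0$separated || fit1$separated) {
    dev0 <- logistic_deviance(x, y, z, penalized = TRUE)
    dev1 <- logistic_deviance(x, y, c(z, f), penalized = TRUE)
  } else {
    dev0 <- fit0$deviance
    dev1 <- fit1$deviance
  }
  stat <- max(dev0 - dev1, 0)
  pchisq(stat, df = 1L, lower.tail = FALSE)
}
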