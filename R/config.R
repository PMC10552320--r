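#' Pipeline run configuration
#'
#' Assembles the tunable parameters of the whole pipeline with the defaults
#' used throughout the package: 10% FDR for DMP calling, a 0.01
#' Shapiro-Wilk screen for the per-probe regression assumptions, SES at
#' alpha 0.05 with conditioning sets up to size 3, 5-fold x 10-repeat CV for
#' candidate ranking, 10-fold CV for the penalty path, and the log10
#' transform for pyrosequencing percents. All randomness is governed by the
#' explicit `seed`; stage-specific streams are derived from it.
#'
#' @param seed Master integer seed.
#' @param fdr Benjamini-Hochberg FDR threshold for DMP calling, in (0, 1).
#' @param shapiro_alpha Significance level of the residual-normality screen.
#' @param ses_alpha,ses_max_k SES equivalence level and maximum conditioning
#'   set size.
#' @param cv_folds,cv_repeats Stratified CV scheme for candidate ranking.
#' @param penalty_folds CV folds for the glmnet penalty path.
#' @param enet_alpha Elastic-net mixing parameter.
#' @param transform `"log10"` or `"raw"` pyrosequencing feature transform.
#' @param n_probes Number of array probes simulated by the generator.
#' @param n_dmp Number of planted differentially methylated positions.
#' @param delta_beta Absolute planted effect size on the beta scale.
#' @param frac_hyper Fraction of planted DMPs that are hypermethylated in AN.
#' @param array_noise_sd Logit-scale array measurement noise (pools).
#' @param pyro_noise_sd Percent-scale pyrosequencing noise.
#' @param plasma_offset_sd Percent-scale serum-vs-plasma offset noise.
#' @param n_offtarget,n_paired Non-colorectal tumor sera and matched
#'   serum/plasma pair counts.
#' @param contamination Fraction of non-colorectal tumor sera drawn from the
#'   AN-like methylation distribution.
#' @return A `mp_config` list.
#' @export
methpanel_config <- function(seed = 1L,
                             fdr = 0.10,
                             shapiro_alpha = 0.01,
                             ses_alpha = 0.05,
                             ses_max_k = 3L,
                             cv_folds = 5L,
                             cv_repeats = 10L,
                             penalty_folds = 10L,
                             enet_alpha = 0.5,
                             transform = c("log10", "raw"),
                             n_probes = 10000L,
                             n_dmp = 100L,
                             delta_beta = 0.20,
                             frac_hyper = 0.867,
                             array_noise_sd = 0.10,
                             pyro_noise_sd = 5,
                             plasma_offset_sd = 2,
                             n_offtarget = 16L,
                             n_paired = 8L,
                             contamination = 3 / 16) {
  transform <- match.arg(transform)
  for (x in list(fdr = fdr, shapiro_alpha = shapiro_alpha, ses_alpha = ses_alpha)) {
    if (!is.numeric(x) || x <= 0 || x >= 1) {
      mp_stop("thresholds must lie in (0, 1)", class = "methpanel_validation_error")
    }
  }
  if (contamination < 0 || contamination > 1) {
    mp_stop("contamination fraction must lie in [0, 1]",
            class = "methpanel_validation_error")
  }
  structure(list(
    seed = as.integer(seed), fdr = fdr, shapiro_alpha = shapiro_alpha,
    ses_alpha = ses_alpha, ses_max_k = as.integer(ses_max_k),
    cv_folds = as.integer(cv_folds), cv_repeats = as.integer(cv_repeats),
    penalty_folds = as.integer(penalty_folds), enet_alpha = enet_alpha,
    transform = transform, n_probes = as.integer(n_probes),
    n_dmp = as.integer(n_dmp), delta_beta = delta_beta,
    frac_hyper = frac_hyper, array_noise_sd = array_noise_sd,
    pyro_noise_sd = pyro_noise_sd, plasma_offset_sd = plasma_offset_sd,
    n_offtarget = as.integer(n_offtarget), n_paired = as.integer(n_paired),
    contamination = contamination
  ), class = "mp_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the package defaults
#' of [methpanel_config()].
#'
#' @param path YAML file path.
#' @return A `mp_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(methpanel_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    mp_stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
            class = "methpanel_schema_error")
  }
  do.call(methpanel_config, raw)
}
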