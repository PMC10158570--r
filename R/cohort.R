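#' Default cohort hyperparameters
#'
#' Population distributions for the latent subject profile. Learners (a
#' fraction `learner_fraction` of the cohort) draw a positive word-rate
#' learning gain `lambda`; non-learners have `lambda = 0`. The acoustic
#' word-rate gain `kappa` is present in every subject and in both conditions.
#' Behavioral effects are coupled to `lambda` through fixed links:
#' `p2afc = 0.5 + a * lambda` (clipped to `[0.5, 0.95]`),
#' `rt_effect = b * lambda` (s), `hit_effect = c * lambda`.
#'
#' @param learner_fraction fraction of subjects with `lambda > 0`.
#' @param lambda_mean,lambda_sd learner `lambda` distribution (truncated at 0).
#' @param kappa_mean,kappa_sd acoustic gain distribution (truncated at 0).
#' @param syllable_gain_mean,syllable_gain_sd 4 Hz response amplitude.
#' @param noise_sigma_mean,noise_sigma_sd noise scale.
#' @param noise_exponent 1/f spectral slope of the noise.
#' @param a,b,c behavioral link constants (per unit `lambda`).
#' @return named list of hyperparameters.
#' @export
default_hyperparams <- function(learner_fraction = 0.7,
                                lambda_mean = 1, lambda_sd = 0.35,
                                kappa_mean = 0.6, kappa_sd = 0.15,
                                syllable_gain_mean = 1, syllable_gain_sd = 0.1,
                                noise_sigma_mean = 13.5, noise_sigma_sd = 1,
                                noise_exponent = 1,
                                a = 0.05, b = 0.2, c = 0.25) {
  as.list(environment())
}

rnorm_trunc0 <- function(n, mean, sd) pmax(rnorm(n, mean, sd), 0)

#' Sample a cohort of subject profiles
#'
#' Draws per-subject latent parameters from the population distributions and
#' applies the behavioral coupling to `lambda`.
#'
#' @param n_subjects number of subjects, `>= 1`.
#' @param hyperparams list from [default_hyperparams()].
#' @param seed integer seed.
#' @return tibble with one row per subject: `subject_id`, `learner`,
#'   `lambda`, `kappa`, `syllable_gain`, `noise_sigma`, `noise_exponent`,
#'   `p2afc`, `rt_effect`, `hit_effect`, `seed`.
#' @export
sample_cohort <- function(n_subjects, hyperparams = default_hyperparams(),
                          seed = 1L) {
  check_scalar_number(n_subjects, "n_subjects", lower = 1)
  h <- hyperparams
  bad <- vapply(h, function(x) !is.numeric(x) || !is.finite(x), TRUE)
  if (any(bad)) abort("All hyperparameters must be finite numbers.")
  if (h$learner_fraction < 0 || h$learner_fraction > 1) {
    abort("`learner_fraction` must be in [0, 1].")
  }
  if (any(c(h$lambda_sd, h$kappa_sd, h$syllable_gain_sd, h$noise_sigma_sd) < 0)) {
    abort("Distribution sds must be nonnegative.")
  }
  n <- as.integer(n_subjects)
  withr::with_seed(as.integer(seed), {
    learner <- runif(n) < h$learner_fraction
    lambda <- ifelse(learner, rnorm_trunc0(n, h$lambda_mean, h$lambda_sd), 0)
    tibble::tibble(
      subject_id = sprintf("sub-%02d", seq_len(n)),
      learner = learner,
      lambda = lambda,
      kappa = rnorm_trunc0(n, h$kappa_mean, h$kappa_sd),
      syllable_gain = rnorm_trunc0(n, h$syllable_gain_mean, h$syllable_gain_sd),
      noise_sigma = rnorm_trunc0(n, h$noise_sigma_mean, h$noise_sigma_sd),
      noise_exponent = h$noise_exponent,
      p2afc = pmin(pmax(0.5 + h$a * lambda, 0.5), 0.95),
      rt_effect = h$b * lambda,
      hit_effect = h$c * lambda,
      seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
}
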