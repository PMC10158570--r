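#' One-tailed paired t test
#'
#' Paired t test on language-minus-baseline differences with an a priori
#' direction (+ expects language > baseline, as at the word-related
#' frequencies; - expects the reverse, as at the syllable rate).
#'
#' @param language,baseline paired per-subject values (equal length, n >= 2).
#' @param direction `"greater"` or `"less"` (expected sign of
#'   language - baseline).
#' @return one-row tibble with `t`, `df`, `p`.
#' @export
paired_t_one_tailed <- function(language, baseline,
                                direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(language) != length(baseline)) abort("Paired vectors must have equal length.")
  if (length(language) < 2) abort("Need at least 2 pairs.")
  d <- language - baseline
  if (isTRUE(all.equal(var(d), 0)) || var(d) == 0) {
    abort("Zero variance of paired differences; the t statistic is undefined.")
  }
  fit <- t.test(language, baseline, paired = TRUE, alternative = direction)
  tibble::tibble(t = unname(fit$statistic), df = unname(fit$parameter),
                 p = fit$p.value)
}

# exact density of the noncentral t distribution via its integral
# representation (R's dt(ncp=) is only accurate to ~1e-8 and warns); used by
# the Bayes factor quadrature
dt_noncentral <- function(t, df, ncp) {
  integrate(function(s) s * dnorm(t * s - ncp) * 2 * df * s * dchisq(df * s^2, df),
            0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
}

#' Directional default-prior (JZS) Bayes factor from a t statistic
#'
#' Bayes factor for the one-sided alternative against the point null, with
#' the default Cauchy prior of scale `prior_scale` on the standardised
#' effect, truncated to the a priori direction:
#' `BF = 2 * int_0^inf f(t | df, delta * sqrt(n)) Cauchy(delta; 0, r) d delta / f(t | df, 0)`.
#' Computed by nested numerical quadrature on the exact noncentral-t
#' integral representation.
#'
#' @param t observed paired t statistic.
#' @param n number of pairs (df = n - 1).
#' @param prior_scale Cauchy prior scale (default `sqrt(2)/2`).
#' @param direction `"greater"` or `"less"`: the a priori sign of the
#'   effect. `t` is interpreted on the language-minus-baseline scale, so a
#'   negative `t` with `direction = "less"` is evidence *for* the
#'   alternative.
#' @param two_sided if `TRUE`, the untruncated (two-sided) default BF.
#' @return the Bayes factor (scalar, > 0).
#' @export
jzs_bf_directional <- function(t, n, prior_scale = sqrt(2) / 2,
                               direction = c("greater", "less"),
                               two_sided = FALSE) {
  if (!is.finite(t)) abort("`t` must be finite.")
  check_scalar_number(n, "n", lower = 2)
  direction <- match.arg(direction)
  df <- n - 1
  tt <- if (direction == "less" && !two_sided) -t else t
  marginal <- function(lo, hi, fold) {
    integrate(Vectorize(function(d) {
      dt_noncentral(tt, df, d * sqrt(n)) * fold * dcauchy(d, 0, prior_scale)
    }), lo, hi, rel.tol = 1e-9)$value
  }
  num <- if (two_sided) marginal(-Inf, Inf, 1) else marginal(0, Inf, 2)
  num / dt(tt, df)
}

#' Helmert-style forward contrasts
#'
#' Column `j` compares the mean of levels `1..j` with level `j + 1`
#' (labels "1 vs 2", "1 & 2 vs 3", ...). Columns sum to zero.
#'
#' @param levels number of factor levels (>= 2).
#' @return a `levels x (levels - 1)` contrast matrix with descriptive
#'   column names.
#' @export
helmert_contrasts <- function(levels = 3) {
  check_scalar_number(levels, "levels", lower = 2)
  levels <- as.integer(levels)
  m <- matrix(0, levels, levels - 1)
  for (j in seq_len(levels - 1)) {
    m[seq_len(j), j] <- 1 / j
    m[j + 1, j] <- -1
  }
  colnames(m) <- vapply(seq_len(levels - 1), function(j) {
    sprintf("%s vs %d", paste(seq_len(j), collapse = " & "), j + 1)
  }, "")
  rownames(m) <- seq_len(levels)
  m
}

#' By-block mixed-model regression of ITPC
#'
#' Fits `ITPC ~ Condition * Block + (1 | Participant)` by REML, with the
#' condition coded +1 (language) / -1 (baseline) and block coded with
#' forward Helmert contrasts ([helmert_contrasts()]). Inference per fixed
#' effect uses Satterthwaite degrees of freedom. When the random-intercept
#' variance is estimated at (or the model degenerates to) zero the fit
#' coincides with ordinary least squares, to which the function falls back
#' if the mixed fit fails (e.g. noiseless data).
#'
#' @param table tibble with columns `participant`, `condition`
#'   (`"language"`/`"baseline"`), `block` (1-3), `itpc`; one row per
#'   participant x condition x block (balanced).
#' @return object of class `ft_block_fit`: list with `coefficients` tibble
#'   (`term`, `estimate`, `std.error`, `statistic`, `df`, `p.value`),
#'   `ranef_sd`, `sigma`, `fit` (the underlying model object), `engine`.
#' @export
fit_block_model <- function(table) {
  need <- c("participant", "condition", "block", "itpc")
  if (!all(need %in% names(table))) {
    abort(sprintf("`table` needs columns %s.", paste(need, collapse = ", ")))
  }
  tab <- stats::xtabs(~ participant + condition + block, data = table)
  if (any(tab != 1)) {
    abort("Unbalanced table: need exactly one row per participant x condition x block.")
  }
  df <- tibble::tibble(
    participant = factor(table$participant),
    condition = factor(table$condition, levels = c("language", "baseline")),
    block = factor(table$block),
    itpc = table$itpc
  )
  nb <- nlevels(df$block)
  stats::contrasts(df$condition) <- matrix(
    c(1, -1), 2, 1, dimnames = list(NULL, "language vs baseline"))
  stats::contrasts(df$block) <- helmert_contrasts(nb)

  fit <- tryCatch(
    suppressMessages(suppressWarnings(lmerTest::lmer(
      itpc ~ condition * block + (1 | participant), data = df, REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    sm <- suppressWarnings(summary(fit))$coefficients
    vc <- lme4::VarCorr(fit)
    coefs <- tibble::tibble(
      term = rownames(sm), estimate = unname(sm[, "Estimate"]),
      std.error = unname(sm[, "Std. Error"]),
      statistic = unname(sm[, "t value"]),
      df = unname(sm[, "df"]), p.value = unname(sm[, "Pr(>|t|)"]))
    out <- list(coefficients = coefs,
                ranef_sd = attr(vc$participant, "stddev")[[1]],
                sigma = stats::sigma(fit), fit = fit, engine = "lmer")
  } else {
    ols <- stats::lm(itpc ~ condition * block, data = df)
    sm <- suppressWarnings(summary(ols))$coefficients
    coefs <- tibble::tibble(
      term = rownames(sm), estimate = unname(sm[, "Estimate"]),
      std.error = unname(sm[, "Std. Error"]),
      statistic = unname(sm[, "t value"]),
      df = ols$df.residual, p.value = unname(sm[, "Pr(>|t|)"]))
    out <- list(coefficients = coefs, ranef_sd = 0,
                sigma = stats::sigma(ols), fit = ols, engine = "lm")
  }
  structure(out, class = "ft_block_fit")
}

#' @export
print.ft_block_fit <- function(x, ...) {
  cat(sprintf("<ft_block_fit> engine=%s, random-intercept sd=%.4g, sigma=%.4g\n",
              x$engine, x$ranef_sd, x$sigma))
  print(x$coefficients)
  invisible(x)
}

#' Group FOI tests
#'
#' For each frequency of interest: one-tailed paired t test on the
#' electrode-averaged ITPC (direction from [foi_set()]) and the matching
#' directional JZS Bayes factor.
#'
#' @param summaries tibble of per-subject FOI summaries (rows from
#'   [foi_summary()] for both conditions, i.e. columns `subject_id`,
#'   `condition`, `foi`, `itpc`).
#' @param fois tibble from [foi_set()].
#' @return tibble with one row per FOI: `foi`, `freq`, `direction`, `n`,
#'   `mean_language`, `mean_baseline`, `t`, `df`, `p`, `bf`.
#' @export
group_foi_tests <- function(summaries, fois = foi_set()) {
  wide <- tidyr::pivot_wider(
    dplyr::select(summaries, "subject_id", "condition", "foi", "itpc"),
    names_from = "condition", values_from = "itpc")
  purrr::pmap_dfr(fois, function(foi, freq, direction, word_related) {
    sub <- dplyr::filter(wide, .data$foi == !!foi)
    dirstr <- if (direction > 0) "greater" else "less"
    tt <- paired_t_one_tailed(sub$language, sub$baseline, dirstr)
    bf <- jzs_bf_directional(tt$t, nrow(sub), direction = dirstr)
    tibble::tibble(foi = foi, freq = freq, direction = direction,
                   n = nrow(sub),
                   mean_language = mean(sub$language),
                   mean_baseline = mean(sub$baseline),
                   t = tt$t, df = tt$df, p = tt$p, bf = bf)
  })
}
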