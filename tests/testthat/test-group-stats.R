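test_that("one-tailed paired t has the right df, sign symmetry and error contract", {
  withr::with_seed(1, {
    lang <- rnorm(39, 0.15, 0.05)
    base <- rnorm(39, 0.12, 0.05)
  })
  res <- paired_t_one_tailed(lang, base, "greater")
  expect_equal(res$df, 38)
  ref <- t.test(lang - base, alternative = "greater")
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  # swapping conditions negates t and maps one-tailed p to 1 - p
  swapped <- paired_t_one_tailed(base, lang, "greater")
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, 1 - res$p, tolerance = 1e-12)
  expect_error(paired_t_one_tailed(rep(1, 5), rep(0.5, 5)), "Zero variance")
  expect_error(paired_t_one_tailed(1, 2), "at least 2")
})

test_that("directional JZS Bayes factor behaves like a one-sided default-prior BF", {
  expect_lt(jzs_bf_directional(0, 30), 1)
  # strictly increasing in t for t > 0
  ts <- c(0.5, 1, 1.5, 2, 2.5, 3)
  bfs <- vapply(ts, jzs_bf_directional, 0, n = 25)
  expect_true(all(diff(bfs) > 0))
  # direction symmetry: evidence for a negative effect mirrors the positive case
  expect_equal(jzs_bf_directional(-2.2, 30, direction = "less"),
               jzs_bf_directional(2.2, 30, direction = "greater"),
               tolerance = 1e-8)
  # two-sided BF averages the two directional ones
  b_plus <- jzs_bf_directional(1.8, 20)
  b_minus <- jzs_bf_directional(1.8, 20, direction = "less")
  b_two <- jzs_bf_directional(1.8, 20, two_sided = TRUE)
  expect_equal(b_two, (b_plus + b_minus) / 2, tolerance = 1e-6)
  expect_error(jzs_bf_directional(Inf, 10), "finite")
})

test_that("JZS Bayes factor matches an independent quadrature oracle", {
  # oracle: same integral through R's own (lower-precision) noncentral-t
  # density instead of the package's integral representation
  oracle <- function(t, n, r = sqrt(2) / 2) {
    num <- integrate(function(d) {
      vapply(d, function(di) {
        suppressWarnings(dt(t, n - 1, ncp = di * sqrt(n))) * 2 * dcauchy(di, 0, r)
      }, 0)
    }, 0, Inf, rel.tol = 1e-8)$value
    num / dt(t, n - 1)
  }
  for (case in list(c(1.5, 15), c(2.5, 40), c(-1, 25))) {
    expect_equal(jzs_bf_directional(case[1], case[2]),
                 oracle(case[1], case[2]), tolerance = 1e-4)
  }
})

test_that("Helmert forward contrasts carry the reported comparisons", {
  m <- helmert_contrasts(3)
  expect_equal(colnames(m), c("1 vs 2", "1 & 2 vs 3"))
  expect_equal(unname(m[, 1]), c(1, -1, 0))
  expect_equal(unname(m[, 2]), c(0.5, 0.5, -1))
  expect_equal(colSums(m), c("1 vs 2" = 0, "1 & 2 vs 3" = 0))
  m2 <- helmert_contrasts(2)
  expect_equal(unname(m2[, 1]), c(1, -1))
  expect_error(helmert_contrasts(1), "levels")
})

make_block_table <- function(n_subj, beta, ranef_sd = 0, sigma = 0, seed = 1) {
  tab <- tidyr::expand_grid(participant = sprintf("s%02d", seq_len(n_subj)),
                            condition = c("language", "baseline"),
                            block = 1:3)
  cm <- helmert_contrasts(3)
  X <- cbind(1, ifelse(tab$condition == "language", 1, -1),
             cm[tab$block, 1], cm[tab$block, 2])
  X <- cbind(X, X[, 2] * X[, 3], X[, 2] * X[, 4])
  withr::with_seed(seed, {
    b <- rnorm(n_subj, 0, ranef_sd)
    tab$itpc <- as.vector(X %*% beta) + b[match(tab$participant,
                                                unique(tab$participant))] +
      rnorm(nrow(tab), 0, sigma)
  })
  tab
}

test_that("block model recovers noiseless coefficients to machine precision", {
  beta <- c(0.2, 0.05, 0.01, -0.02, 0.008, -0.004)
  tab <- make_block_table(15, beta)
  fit <- fit_block_model(tab)
  expect_equal(tidy(fit)$estimate, beta, tolerance = 1e-8)
  # unbalanced tables are refused
  expect_error(fit_block_model(tab[-1, ]), "Unbalanced")
})

test_that("REML variance ratio matches a profile-criterion oracle and the OLS limit", {
  tab <- make_block_table(24, c(0.2, 0.03, 0, 0, 0, 0), ranef_sd = 0.05,
                          sigma = 0.03, seed = 42)
  fit <- fit_block_model(tab)
  expect_equal(fit$engine, "lmer")

  # independent oracle: 1-D REML profile over the variance ratio
  # gamma = var_b / var_e for y ~ X beta + Z b + e
  df <- tibble::tibble(
    participant = factor(tab$participant),
    condition = factor(tab$condition, levels = c("language", "baseline")),
    block = factor(tab$block), itpc = tab$itpc)
  Z <- stats::model.matrix(~ 0 + participant, df)
  cm <- helmert_contrasts(3)
  X <- cbind(1, ifelse(df$condition == "language", 1, -1),
             cm[as.integer(df$block), ])
  X <- cbind(X, X[, 2] * X[, 3], X[, 2] * X[, 4])
  y <- df$itpc
  n <- length(y); p <- ncol(X)
  reml_crit <- function(log_gamma) {
    V <- diag(n) + exp(log_gamma) * tcrossprod(Z)
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
    (n - p) * log(s2) + determinant(V)$modulus + determinant(XtVX)$modulus
  }
  opt <- stats::optimize(reml_crit, c(-10, 10))
  gamma_oracle <- exp(opt$minimum)
  gamma_lmer <- (fit$ranef_sd / fit$sigma)^2
  expect_equal(gamma_lmer, gamma_oracle, tolerance = 1e-3)

  # when the variance estimate hits the zero boundary the fit reduces to
  # ordinary least squares; centring residuals within participant forces
  # the between-participant variance below its null expectation, so the
  # REML estimate is exactly 0
  tab0 <- make_block_table(24, c(0.2, 0.03, 0, 0, 0, 0), ranef_sd = 0,
                           sigma = 0.03, seed = 7)
  resid0 <- tab0$itpc - stats::ave(tab0$itpc, tab0$participant)
  tab0$itpc <- resid0 + 0.2
  fit0 <- fit_block_model(tab0)
  expect_lt(fit0$ranef_sd / fit0$sigma, 1e-6)
  df0 <- tibble::tibble(
    participant = factor(tab0$participant),
    condition = factor(tab0$condition, levels = c("language", "baseline")),
    block = factor(tab0$block), itpc = tab0$itpc)
  stats::contrasts(df0$condition) <- matrix(c(1, -1), 2, 1)
  stats::contrasts(df0$block) <- helmert_contrasts(3)
  ref <- stats::lm(itpc ~ condition * block, data = df0)
  expect_equal(tidy(fit0)$estimate, unname(coef(ref)), tolerance = 1e-6)
})

test_that("condition-label permutations within participants reject at the nominal rate", {
  n_rep <- 200
  pvals <- withr::with_seed(99, {
    vapply(seq_len(n_rep), function(k) {
      tab <- make_block_table(12, c(0.2, 0, 0, 0, 0, 0), ranef_sd = 0.04,
                              sigma = 0.03, seed = 1e6 + k)
      # permuting condition labels within participant == the null holds
      fit <- fit_block_model(tab)
      tidy(fit)$p.value[2]
    }, 0)
  })
  rate <- mean(pvals <= 0.05)
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("group FOI tests combine t and BF per frequency with directions", {
  withr::with_seed(3, {
    subj <- sprintf("s%02d", 1:24)
    fois <- foi_set()
    summaries <- tidyr::expand_grid(subject_id = subj,
                                    condition = c("language", "baseline"),
                                    foi = fois$foi)
    # strong injected word-related effect so detection power is ~1
    summaries$itpc <- 0.1 + 0.05 * (summaries$condition == "language" &
                                      summaries$foi != "syllable_rate") +
      rnorm(nrow(summaries), 0, 0.02)
  })
  g <- group_foi_tests(summaries)
  expect_equal(nrow(g), 4)
  expect_equal(g$n, rep(24, 4))
  expect_equal(g$df, rep(23, 4))
  word <- g[g$foi == "third_harmonic", ]
  expect_lt(word$p, 0.05)
  expect_gt(word$bf, 1)
  # BF consistency with the direct call
  expect_equal(word$bf, jzs_bf_directional(word$t, 24), tolerance = 1e-8)
})
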