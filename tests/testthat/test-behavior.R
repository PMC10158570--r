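lex <- build_lexicon()

test_that("2AFC trial builder enumerates all 36 pseudoword x part-word pairs", {
  trials <- build_2afc_trials(lex)
  expect_equal(nrow(trials), 36)
  expect_equal(anyDuplicated(trials[, c("word", "part_word")]), 0)
  expect_setequal(unique(trials$word), lex$pseudowords$word)
  expect_setequal(unique(trials$part_word), lex$part_words$part_word)
})

test_that("simulated 2AFC sessions follow the Bernoulli model", {
  trials <- build_2afc_trials(lex)
  perfect <- simulate_2afc(quick_profile() |> dplyr::mutate(p2afc = 1),
                           trials, seed = 1)
  expect_equal(sum(perfect$correct), 36)
  # accuracy under guessing is centred at 50%
  accs <- vapply(1:2000, function(s) {
    mean(simulate_2afc(quick_profile(), trials, seed = s)$correct)
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 4 * sqrt(0.25 / 36 / 2000))
  # full-distribution check at p2afc = 0.65 against the exact binomial
  k65 <- vapply(1:4000, function(s) {
    p <- quick_profile() |> dplyr::mutate(p2afc = 0.65)
    sum(simulate_2afc(p, trials, seed = 10000 + s)$correct)
  }, 0)
  grp <- cut(k65, c(-1, 19, 22, 24, 26, 37))
  expected <- diff(pbinom(c(-1, 19, 22, 24, 26, 37), 36, 0.65))
  gof <- suppressWarnings(chisq.test(table(grp), p = expected))
  expect_gt(gof$p.value, 1e-3)
})

test_that("2AFC scoring computes exact binomial tail probabilities", {
  trials <- build_2afc_trials(lex)
  session <- simulate_2afc(quick_profile() |> dplyr::mutate(p2afc = 1),
                           trials, seed = 1)
  res <- score_2afc(session)
  expect_equal(res$accuracy, 1)
  expect_equal(res$p_binomial, 0.5^36)

  session$correct <- rep(FALSE, 36)
  expect_equal(score_2afc(session)$p_binomial, 1)

  session$correct <- rep(c(TRUE, FALSE), c(23, 13))
  # oracle: direct summation of the binomial pmf from 23 to 36
  expect_equal(score_2afc(session)$p_binomial, sum(dbinom(23:36, 36, 0.5)),
               tolerance = 1e-12)
  session$correct[1:2] <- NA
  expect_warning(res_na <- score_2afc(session), "missing")
  expect_equal(res_na$n_correct, 21)
})

test_that("the simulated guessing null matches Binomial(36, 0.5) with a ~65% cutoff", {
  null <- simulate_2afc_null(36, 10000, seed = 2)
  expect_lt(abs(mean(null$values) - 0.5), 4 * sqrt(0.25 / 36 / 10000))
  # cutoff: linear interpolation between the exact binomial quantiles 23/36
  # and 24/36 (63.9% - 66.7%)
  expect_gte(null$cutoff, 23 / 36 - 1e-9)
  expect_lte(null$cutoff, 24 / 36 + 1e-9)
  # empirical CDF against the exact binomial CDF (DKW-style bound)
  ks <- max(abs(vapply(0:36, function(k) {
    mean(null$values <= k / 36) - pbinom(k, 36, 0.5)
  }, 0)))
  expect_lt(ks, 0.02)
  expect_equal(null$percentile(0.95), null$cutoff)
})

test_that("target-detection trials respect the task geometry", {
  td <- build_target_detection_trials(lex, seed = 3)
  expect_equal(td$trial_duration, 22.5)
  expect_equal(dplyr::n_distinct(td$targets$trial), 24)
  # 4 trials per position-3 target syllable
  per_target <- dplyr::distinct(td$targets, .data$trial, .data$target_syllable)
  expect_equal(unname(table(per_target$target_syllable)), rep(4L, 6),
               ignore_attr = TRUE)
  counts <- table(td$targets$trial)
  expect_true(all(counts >= 4 & counts <= 8))
  # syllables at 2 Hz; target onsets at least 1 s apart (windows never overlap)
  seq1 <- td$sequences[td$sequences$trial == 1, ]
  expect_equal(diff(seq1$onset), rep(0.5, 44))
  gaps <- tapply(td$targets$onset, td$targets$trial,
                 function(x) if (length(x) > 1) min(diff(sort(x))) else Inf)
  expect_true(all(gaps >= 1))
  # recorded onsets really carry the target syllable, in the right category
  joined <- dplyr::inner_join(td$targets, td$sequences,
                              by = c("trial", "onset"))
  expect_equal(nrow(joined), nrow(td$targets))
  expect_true(all(joined$syllable == joined$target_syllable))
  pw3 <- joined[joined$category == "pseudoword_3rd", ]
  words3 <- setNames(lex$pseudowords$s3, lex$pseudowords$word)
  expect_true(all(pw3$target_syllable %in% words3))
})

test_that("detection simulation and scoring implement the window and press rules", {
  td <- build_target_detection_trials(lex, seed = 5)
  sess <- simulate_target_detection(
    quick_profile(), td, seed = 1, base_hit = 1, fa_rate = 0)
  scored <- score_target_detection(sess)
  expect_equal(scored$summary$hit_rate_pseudoword, 1)
  expect_equal(scored$summary$hit_rate_nonword, 1)
  expect_equal(scored$summary$n_false_alarms, 0)
  # press conservation: hits + false alarms = presses
  expect_equal(sum(scored$per_target$hit) + scored$summary$n_false_alarms,
               scored$summary$n_presses)

  # hand-built session: hit at +0.5 s, false alarm at +1.2 s, and a second
  # press inside an occupied window
  hand <- structure(list(
    targets = tibble::tibble(trial = 1L, target_syllable = "Va",
                             onset = c(2, 6),
                             category = c("pseudoword_3rd", "nonword_1st")),
    presses = tibble::tibble(trial = 1L, time = c(2.5, 2.8, 7.2)),
    trial_duration = 22.5, subject_id = "sub-01"), class = "ft_td_session")
  sc <- score_target_detection(hand)
  expect_equal(sc$per_target$hit, c(TRUE, FALSE))
  expect_equal(sc$per_target$rt[1], 0.5)
  expect_equal(sc$summary$n_false_alarms, 2)   # 2.8 (window taken) and 7.2
  bad <- hand
  bad$presses$time[1] <- -0.5
  expect_error(score_target_detection(bad), "before trial start")
})

test_that("an rt_effect shifts mean RTs by its size at scale", {
  td <- build_target_detection_trials(lex, seed = 6)
  diffs <- vapply(1:40, function(s) {
    prof <- quick_profile() |> dplyr::mutate(rt_effect = 0.15, hit_effect = 0)
    sess <- simulate_target_detection(prof, td, seed = s, base_hit = 1,
                                      fa_rate = 0)
    score_target_detection(sess)$summary$delta_rt
  }, 0)
  # ~5800 targets pooled; lognormal medians differ by 0.15 s
  expect_lt(abs(mean(diffs) - 0.15), 0.02)
})

test_that("detection permutation handles nulls, effects and degenerate input", {
  td <- build_target_detection_trials(lex, seed = 7)
  null_sess <- simulate_target_detection(quick_profile(), td, seed = 3)
  scored <- score_target_detection(null_sess)
  res <- detection_permutation(scored$per_target, n_perm = 300, seed = 1)
  expect_setequal(res$measure, c("delta_hr", "delta_rt"))
  expect_true(all(res$p > 0 & res$p <= 1, na.rm = TRUE))
  # invariance of the RT p value to a constant RT shift
  shifted <- scored$per_target
  shifted$rt <- shifted$rt + 5
  res_shift <- detection_permutation(shifted, n_perm = 300, seed = 1)
  expect_equal(res_shift$p[res_shift$measure == "delta_rt"],
               res$p[res$measure == "delta_rt"])
  # strong effect -> significant
  prof <- quick_profile() |> dplyr::mutate(rt_effect = 0.15, hit_effect = 0.15)
  eff <- score_target_detection(
    simulate_target_detection(prof, td, seed = 4, base_hit = 0.8, fa_rate = 0))
  res_eff <- detection_permutation(eff$per_target, n_perm = 300, seed = 2)
  expect_lt(res_eff$p[res_eff$measure == "delta_rt"], 0.05)
  # all-identical responses: observed difference 0, p = 1
  const <- scored$per_target
  const$hit <- TRUE
  const$rt <- 0.4
  res_const <- detection_permutation(const, n_perm = 100, seed = 1)
  expect_equal(res_const$observed, c(0, 0))
  expect_true(all(res_const$p > 0.05))
  expect_error(detection_permutation(scored$per_target[1:6, ]),
               "at least 5 targets")
})

test_that("correlations and Welch comparisons match textbook formulas", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_measures(x, 2 * x + 1)$r, 1)
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  expect_equal(correlate_measures(a, b)$r, 0)
  y <- c(2.3, 1.1, 4.8, 3.0, 0.7)
  oracle_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_measures(x, y)$r, oracle_r, tolerance = 1e-12)
  expect_equal(correlate_measures(c(x, NA), c(y, 1))$n, 5)
  expect_error(correlate_measures(x[1:2], y[1:2]), "at least 3")
  expect_error(correlate_measures(rep(1, 5), y), "Zero variance")

  neural <- tibble::tibble(
    subject_id = sprintf("s%d", 1:6),
    itpc_word_avg = c(0.2, 0.25, 0.3, 0.1, 0.12, 0.14),
    learner_flag = rep(c(TRUE, FALSE), each = 3))
  behavior <- tibble::tibble(subject_id = sprintf("s%d", 1:6),
                             delta_rt = c(1, 2, 3, 1, 2, 3))
  nbc <- neural_behavior_comparison(neural, behavior)
  # equal means, equal n, equal variance: t = 0, df = 2n - 2
  expect_equal(nbc$group_tests$t, 0)
  expect_equal(nbc$group_tests$df, 4)
  # Welch oracle on unequal groups
  g1 <- c(0.30, 0.21, 0.28, 0.35); g2 <- c(0.18, 0.22)
  behavior2 <- tibble::tibble(subject_id = sprintf("s%d", 1:6),
                              m = c(g1[1:3], g2, g1[4]))
  neural2 <- neural
  neural2$learner_flag <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  t_num <- mean(g1) - mean(g2)
  v1 <- var(g1) / 4; v2 <- var(g2) / 2
  t_oracle <- t_num / sqrt(v1 + v2)
  df_oracle <- (v1 + v2)^2 / (v1^2 / 3 + v2^2 / 1)
  res2 <- neural_behavior_comparison(neural2, behavior2)$group_tests
  expect_equal(res2$t, t_oracle, tolerance = 1e-12)
  expect_equal(res2$df, df_oracle, tolerance = 1e-12)
  neural$learner_flag <- c(TRUE, rep(FALSE, 5))
  expect_error(neural_behavior_comparison(neural, behavior), "fewer than 2")
})
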