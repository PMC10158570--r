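#' Build the 2AFC test trials
#'
#' All 36 pseudoword x part-word pairs (6 x 6), the full explicit
#' recognition test.
#'
#' @param lexicon an `ft_lexicon`.
#' @return tibble with columns `trial`, `word`, `part_word`.
#' @export
build_2afc_trials <- function(lexicon) {
  stopifnot(inherits(lexicon, "ft_lexicon"))
  grid <- tidyr::expand_grid(word = lexicon$pseudowords$word,
                             part_word = lexicon$part_words$part_word)
  dplyr::mutate(grid, trial = dplyr::row_number(), .before = 1)
}

#' Simulate a 2AFC session
#'
#' Each trial is an independent Bernoulli draw: the familiar pseudoword is
#' chosen with probability `p2afc`; presentation order is randomised per
#' trial.
#'
#' @param profile subject profile row (needs `p2afc`, optionally
#'   `subject_id`).
#' @param trials tibble from [build_2afc_trials()] (36 rows).
#' @param seed integer seed.
#' @return tibble of class `ft_2afc_session` with columns `trial`, `word`,
#'   `part_word`, `word_first`, `choice` (`"first"`/`"second"`), `correct`.
#' @export
simulate_2afc <- function(profile, trials, seed = 1L) {
  if (nrow(trials) != 36) abort("A 2AFC session has exactly 36 trials.")
  profile <- as.list(profile)
  withr::with_seed(as.integer(seed), {
    word_first <- runif(36) < 0.5
    correct <- runif(36) < profile$p2afc
  })
  choice <- ifelse(correct == word_first, "first", "second")
  out <- dplyr::mutate(trials, word_first = word_first, choice = choice,
                       correct = correct)
  structure(out, class = c("ft_2afc_session", class(out)),
            subject_id = profile$subject_id %||% NA_character_)
}

#' Score a 2AFC session
#'
#' Accuracy out of 36 and the exact binomial tail probability
#' `P(X >= n_correct | n = 36, p = 0.5)`. Missing choices count as
#' incorrect, with a warning.
#'
#' @param session tibble with a logical `correct` column (36 rows).
#' @return one-row tibble: `subject_id`, `n_correct`, `accuracy`,
#'   `p_binomial`.
#' @export
score_2afc <- function(session) {
  if (nrow(session) != 36) abort("A 2AFC session has exactly 36 trials.")
  correct <- session$correct
  if (anyNA(correct)) {
    warn(sprintf("%d missing choices scored as incorrect.", sum(is.na(correct))))
    correct[is.na(correct)] <- FALSE
  }
  k <- sum(correct)
  tibble::tibble(
    subject_id = attr(session, "subject_id") %||% NA_character_,
    n_correct = k,
    accuracy = k / 36,
    p_binomial = pbinom(k - 1, 36, 0.5, lower.tail = FALSE)
  )
}

#' Simulated 2AFC guessing null
#'
#' Simulates `n_sims` sessions of random guessing (`Bernoulli(0.5)` over
#' `n_trials` trials) and reports the 95th percentile of the accuracy
#' distribution (linear interpolation), the chance-level significance
#' cutoff.
#'
#' @param n_trials trials per simulated session.
#' @param n_sims number of simulated sessions.
#' @param seed integer seed.
#' @return object of class `ft_null`: list with `values` (accuracies),
#'   `cutoff` (95th percentile), `percentile` (interpolating quantile
#'   function).
#' @export
simulate_2afc_null <- function(n_trials = 36, n_sims = 1000, seed = 1L) {
  check_scalar_number(n_trials, "n_trials", lower = 1)
  check_scalar_number(n_sims, "n_sims", lower = 1)
  values <- withr::with_seed(as.integer(seed),
                             rbinom(n_sims, n_trials, 0.5) / n_trials)
  structure(list(
    values = values,
    cutoff = unname(quantile(values, 0.95, type = 7)),
    percentile = function(p) unname(quantile(values, p, type = 7))
  ), class = "ft_null")
}

# ---- target detection -------------------------------------------------------

# non-adjacent slot sampler: k slots from 1..n with pairwise gaps >= 2
sample_nonadjacent <- function(n, k) {
  stopifnot(k <= ceiling(n / 2))
  repeat {
    s <- sort(sample.int(n, k))
    if (k == 1 || min(diff(s)) >= 2) return(s)
  }
}

random_nonword <- function(ids, target, lexicon, target_pos) {
  words <- apply(as.matrix(lexicon$pseudowords[, c("s1", "s2", "s3")]), 1, paste0,
                 collapse = "\r")
  repeat {
    others <- sample(setdiff(ids, target), 2)
    tri <- switch(target_pos,
                  first = c(target, others),
                  third = c(others, target))
    if (!paste0(tri, collapse = "\r") %in% words) return(tri)
  }
}

#' Build target-detection trials
#'
#' 24 trials (4 per position-3 target syllable): per trial a 45-syllable
#' sequence at 2 Hz (22.5 s) containing 4-8 occurrences of the target
#' syllable, each either as the 3rd syllable of its pseudoword
#' (`pseudoword_3rd`) or as the 1st/3rd syllable of a non-word
#' (`nonword_1st` / `nonword_3rd`). Target-bearing triplets occupy
#' non-adjacent triplet slots so that the 1 s response windows never
#' overlap; remaining slots are filled with pseudowords or random non-words
#' that do not contain the target.
#'
#' @param lexicon an `ft_lexicon`.
#' @param seed integer seed.
#' @return list of class `ft_td_trials`: `targets` tibble (`trial`,
#'   `target_syllable`, `onset`, `category`), `sequences` tibble (`trial`,
#'   `onset`, `syllable`), `trial_duration` (22.5 s).
#' @export
build_target_detection_trials <- function(lexicon, seed = 1L) {
  stopifnot(inherits(lexicon, "ft_lexicon"))
  pw <- lexicon$pseudowords
  ids <- lexicon$syllables$id
  n_slots <- 15  # triplets per trial (45 syllables at 2 Hz = 22.5 s)
  cats <- c("pseudoword_3rd", "nonword_1st", "nonword_3rd")

  res <- withr::with_seed(as.integer(seed), {
    targets <- list(); sequences <- list()
    trial <- 0L
    for (w in seq_len(6)) {
      target <- pw$s3[w]
      for (rep_i in seq_len(4)) {
        trial <- trial + 1L
        n_tgt <- sample(4:8, 1)
        slots <- sample_nonadjacent(n_slots, n_tgt)
        cat_i <- sample(rep(cats, length.out = n_tgt))
        seq_mat <- matrix(NA_character_, n_slots, 3)
        pos_in_trip <- ifelse(cat_i == "nonword_1st", 1L, 3L)
        for (j in seq_along(slots)) {
          seq_mat[slots[j], ] <- switch(
            cat_i[j],
            pseudoword_3rd = c(pw$s1[w], pw$s2[w], pw$s3[w]),
            nonword_1st = random_nonword(ids, target, lexicon, "first"),
            nonword_3rd = random_nonword(ids, target, lexicon, "third"))
        }
        for (s in setdiff(seq_len(n_slots), slots)) {
          if (runif(1) < 0.5) {
            cand <- sample(setdiff(seq_len(6), w), 1)  # other pseudoword
            seq_mat[s, ] <- c(pw$s1[cand], pw$s2[cand], pw$s3[cand])
          } else {
            seq_mat[s, ] <- sample(setdiff(ids, target), 3)
          }
        }
        syl <- as.vector(t(seq_mat))
        onset <- 0.5 * (seq_along(syl) - 1)
        t_onsets <- onset[(slots - 1) * 3 + pos_in_trip]
        targets[[trial]] <- tibble::tibble(
          trial = trial, target_syllable = target, onset = t_onsets,
          category = cat_i)
        sequences[[trial]] <- tibble::tibble(trial = trial, onset = onset,
                                             syllable = syl)
      }
    }
    list(targets = dplyr::bind_rows(targets),
         sequences = dplyr::bind_rows(sequences))
  })
  structure(c(res, list(trial_duration = 22.5)), class = "ft_td_trials")
}

#' Simulate a target-detection session
#'
#' Per target: a hit occurs with probability `base_hit` (+ `hit_effect` for
#' `pseudoword_3rd` targets, clipped at 1); hit reaction times are
#' log-normal with median `base_rt` (- `rt_effect` for `pseudoword_3rd`,
#' floored at 0.15 s), truncated to the scoreable (0, 1] s window.
#' False-alarm presses arrive as a low-rate Poisson process outside
#' response windows.
#'
#' @param profile subject profile row (needs `hit_effect`, `rt_effect`).
#' @param trials an `ft_td_trials` from [build_target_detection_trials()].
#' @param seed integer seed.
#' @param base_hit baseline hit probability.
#' @param base_rt baseline median RT (s).
#' @param rt_sdlog log-normal RT dispersion.
#' @param fa_rate false-alarm rate (presses per second outside windows).
#' @return list of class `ft_td_session`: `targets` tibble (with hidden
#'   ground truth dropped), `presses` tibble (`trial`, `time`),
#'   `trial_duration`, `subject_id`.
#' @export
simulate_target_detection <- function(profile, trials, seed = 1L,
                                      base_hit = 0.8, base_rt = 0.45,
                                      rt_sdlog = 0.25, fa_rate = 0.02) {
  stopifnot(inherits(trials, "ft_td_trials"))
  profile <- as.list(profile)
  tg <- trials$targets
  withr::with_seed(as.integer(seed), {
    is_pw <- tg$category == "pseudoword_3rd"
    p_hit <- pmin(base_hit + profile$hit_effect * is_pw, 1)
    hit <- runif(nrow(tg)) < p_hit
    med <- pmax(base_rt - profile$rt_effect * is_pw, 0.15)
    rt <- rlnorm(nrow(tg), log(med), rt_sdlog)
    for (i in which(hit & rt > 1)) {  # truncate to the scoreable window
      for (try in 1:50) {
        rt[i] <- rlnorm(1, log(med[i]), rt_sdlog)
        if (rt[i] <= 1) break
      }
      if (rt[i] > 1) rt[i] <- 1
    }
    presses <- tibble::tibble(trial = tg$trial[hit], time = tg$onset[hit] + rt[hit])
    if (fa_rate > 0) {
      for (tr in unique(tg$trial)) {
        n_fa <- rpois(1, fa_rate * trials$trial_duration)
        if (n_fa > 0) {
          cand <- runif(n_fa, 0, trials$trial_duration)
          wins <- tg[tg$trial == tr, ]
          inside <- vapply(cand, function(tt) {
            any(tt > wins$onset & tt <= wins$onset + 1)
          }, TRUE)
          if (any(!inside)) {
            presses <- dplyr::bind_rows(
              presses, tibble::tibble(trial = tr, time = cand[!inside]))
          }
        }
      }
    }
  })
  structure(list(targets = tg,
                 presses = dplyr::arrange(presses, .data$trial, .data$time),
                 trial_duration = trials$trial_duration,
                 subject_id = profile$subject_id %||% NA_character_),
            class = "ft_td_session")
}

#' Score a target-detection session
#'
#' A press is a hit if it falls within `(onset, onset + window]` of a target
#' (first press in a window counts; further presses and all other presses
#' are false alarms). Hit rate and mean RT are reported per category with
#' `nonword_1st` and `nonword_3rd` pooled, along with the effect sizes
#' `delta_hr = HR(pseudoword) - HR(nonword)` and `delta_rt = RT(nonword) -
#' RT(pseudoword)` (both positive under learning).
#'
#' @param session an `ft_td_session`.
#' @param window response window (s).
#' @return list of class `ft_detection`: `per_target` tibble (`trial`,
#'   `onset`, `category`, `pooled_category`, `hit`, `rt`), `summary`
#'   one-row tibble (`subject_id`, hit rates, mean RTs, `delta_hr`,
#'   `delta_rt`, `n_false_alarms`, `n_presses`).
#' @export
score_target_detection <- function(session, window = 1.0) {
  stopifnot(inherits(session, "ft_td_session"))
  tg <- dplyr::arrange(session$targets, .data$trial, .data$onset)
  pr <- session$presses
  if (any(pr$time < 0)) abort("Press before trial start.")
  tg$hit <- FALSE
  tg$rt <- NA_real_
  n_fa <- 0L
  for (tr in unique(tg$trial)) {
    ti <- which(tg$trial == tr)
    press_t <- sort(pr$time[pr$trial == tr])
    used <- logical(length(press_t))
    for (i in ti) {
      ok <- which(!used & press_t > tg$onset[i] & press_t <= tg$onset[i] + window)
      if (length(ok) > 0) {
        tg$hit[i] <- TRUE
        tg$rt[i] <- press_t[ok[1]] - tg$onset[i]
        used[ok[1]] <- TRUE
      }
    }
    n_fa <- n_fa + sum(!used)
  }
  tg$pooled_category <- ifelse(tg$category == "pseudoword_3rd",
                               "pseudoword", "nonword")
  by_cat <- dplyr::summarise(
    dplyr::group_by(tg, .data$pooled_category),
    hit_rate = mean(.data$hit),
    mean_rt = mean(.data$rt[.data$hit]),
    .groups = "drop")
  g <- function(cat, col) {
    v <- by_cat[[col]][by_cat$pooled_category == cat]
    if (length(v) == 0) NA_real_ else v
  }
  summary <- tibble::tibble(
    subject_id = session$subject_id,
    hit_rate_pseudoword = g("pseudoword", "hit_rate"),
    hit_rate_nonword = g("nonword", "hit_rate"),
    rt_pseudoword = g("pseudoword", "mean_rt"),
    rt_nonword = g("nonword", "mean_rt"),
    delta_hr = g("pseudoword", "hit_rate") - g("nonword", "hit_rate"),
    delta_rt = g("nonword", "mean_rt") - g("pseudoword", "mean_rt"),
    n_false_alarms = n_fa,
    n_presses = nrow(pr)
  )
  structure(list(per_target = tibble::as_tibble(tg), summary = summary),
            class = "ft_detection")
}

#' Permutation test for target-detection effects
#'
#' Null distributions for the hit-rate and RT condition effects are built by
#' randomly relabelling the per-target records into two groups of the
#' original category sizes and taking the difference of means (hit indicator
#' over all targets; RT over hits only). One-tailed with the add-one
#' correction; an effect is significant when the observed difference falls
#' in the top fifth percentile of its null.
#'
#' @param per_target tibble from [score_target_detection()]`$per_target`
#'   (needs `pooled_category`, `hit`, `rt`).
#' @param n_perm number of relabelings.
#' @param seed integer seed.
#' @return tibble with rows for `delta_hr` and `delta_rt`: `measure`,
#'   `observed`, `p`. The RT row is `NA` (with a message) when a category
#'   has no hits.
#' @export
detection_permutation <- function(per_target, n_perm = 1000, seed = 1L) {
  is_pw <- per_target$pooled_category == "pseudoword"
  if (sum(is_pw) < 5 || sum(!is_pw) < 5) abort("Need at least 5 targets per category.")
  hit <- as.numeric(per_target$hit)
  obs_hr <- mean(hit[is_pw]) - mean(hit[!is_pw])

  hits <- per_target[per_target$hit, ]
  rt_ok <- any(hits$pooled_category == "pseudoword") &&
    any(hits$pooled_category == "nonword")
  if (!rt_ok) inform("A category has zero hits; RT permutation test skipped.")
  obs_rt <- if (rt_ok) {
    mean(hits$rt[hits$pooled_category == "nonword"]) -
      mean(hits$rt[hits$pooled_category == "pseudoword"])
  } else NA_real_

  res <- withr::with_seed(as.integer(seed), {
    n1 <- sum(is_pw)
    null_hr <- vapply(seq_len(n_perm), function(k) {
      pick <- sample(seq_along(hit), n1)
      mean(hit[pick]) - mean(hit[-pick])
    }, 0)
    null_rt <- if (rt_ok) {
      n1r <- sum(hits$pooled_category == "pseudoword")
      vapply(seq_len(n_perm), function(k) {
        pick <- sample(seq_len(nrow(hits)), n1r)
        mean(hits$rt[-pick]) - mean(hits$rt[pick])
      }, 0)
    } else rep(NA_real_, n_perm)
    list(hr = null_hr, rt = null_rt)
  })
  tibble::tibble(
    measure = c("delta_hr", "delta_rt"),
    observed = c(obs_hr, obs_rt),
    p = c((1 + sum(res$hr >= obs_hr)) / (1 + n_perm),
          if (rt_ok) (1 + sum(res$rt >= obs_rt)) / (1 + n_perm) else NA_real_)
  )
}

#' Pearson correlation between two per-subject measures
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped
#'   (complete-case analysis), at least 3 must remain.
#' @return one-row tibble: `r`, `p` (two-sided), `n`.
#' @export
correlate_measures <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in a measure.")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Neural-behavioral correspondence analyses
#'
#' (a) Pearson correlation of the word-related-FOI-averaged ITPC (language
#' condition) with each behavioral measure; (b) subjects split by the
#' neural learner flag and each behavioral measure compared between groups
#' with Welch's unequal-variance t test.
#'
#' @param neural tibble with `subject_id`, `itpc_word_avg`, `learner_flag`.
#' @param behavior tibble with `subject_id` and one column per behavioral
#'   measure (e.g. `accuracy`, `delta_hr`, `delta_rt`); missing values are
#'   dropped per measure (complete-case).
#' @return object of class `ft_nbc`: list of tibbles `correlations`
#'   (`measure`, `r`, `p`, `n`) and `group_tests` (`measure`, Welch `t`,
#'   `df`, `p`, group means and sizes).
#' @export
neural_behavior_comparison <- function(neural, behavior) {
  stopifnot(all(c("subject_id", "itpc_word_avg", "learner_flag") %in% names(neural)))
  measures <- setdiff(names(behavior), "subject_id")
  joined <- dplyr::inner_join(neural, behavior, by = "subject_id")
  correlations <- purrr::map_dfr(measures, function(m) {
    dplyr::mutate(correlate_measures(joined$itpc_word_avg, joined[[m]]),
                  measure = m, .before = 1)
  })
  group_tests <- purrr::map_dfr(measures, function(m) {
    v <- joined[[m]]
    keep <- !is.na(v)
    flag <- joined$learner_flag[keep]; v <- v[keep]
    if (sum(flag) < 2 || sum(!flag) < 2) {
      abort(sprintf("Group with fewer than 2 subjects for measure `%s`.", m))
    }
    wt <- t.test(v[flag], v[!flag], var.equal = FALSE)
    tibble::tibble(measure = m, t = unname(wt$statistic),
                   df = unname(wt$parameter), p = wt$p.value,
                   mean_flagged = mean(v[flag]), mean_unflagged = mean(v[!flag]),
                   n_flagged = sum(flag), n_unflagged = sum(!flag))
  })
  structure(list(correlations = correlations, group_tests = group_tests),
            class = "ft_nbc")
}
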