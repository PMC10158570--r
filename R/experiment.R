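#' Default experiment configuration
#'
#' The default scale mirrors the study design: a cohort of 30 subjects, 3
#' exposure blocks per condition of 256 triplets each (192 s at the 4 Hz
#' syllable rate, i.e. ~3.2 min) with 5 s amplitude ramps, 64-channel
#' recordings at 256 Hz, 4.5 s epochs, and 1000-permutation tests at
#' alpha = 0.05.
#'
#' @param seed master integer seed; every stochastic stage draws its own
#'   child seed from it.
#' @param n_subjects cohort size.
#' @param n_triplets triplets per stream (block).
#' @param n_blocks exposure blocks per condition.
#' @param sample_rate EEG sampling rate (Hz).
#' @param baseline_variant `"tp02"` or `"all_combinations"`.
#' @param hyperparams population distributions ([default_hyperparams()]).
#' @param n_perm_individual,n_perm_cluster,n_perm_detection permutation
#'   counts.
#' @param alpha significance level.
#' @param ramp_duration stream amplitude ramp (s).
#' @param out_dir directory for result files (`NULL`: a fresh temporary
#'   directory).
#' @return named list of class `ft_config`.
#' @export
default_config <- function(seed = 1L, n_subjects = 30, n_triplets = 256,
                           n_blocks = 3, sample_rate = 256,
                           baseline_variant = "tp02",
                           hyperparams = default_hyperparams(),
                           n_perm_individual = 1000, n_perm_cluster = 1000,
                           n_perm_detection = 1000, alpha = 0.05,
                           ramp_duration = 5, out_dir = NULL) {
  structure(as.list(environment()), class = "ft_config")
}

#' Run the full simulated experiment
#'
#' Generates the lexicon, exposure streams and cohort; simulates per-subject
#' EEG (blocks x conditions) and behavioral sessions; and runs the complete
#' analysis chain: pooled and per-block ITPC, group FOI tests with Bayes
#' factors, cluster-based electrode permutation, the by-block mixed-model
#' regression, per-participant permutation tests (all electrodes and, when a
#' significant cluster exists, the cluster electrode subset), behavioral
#' scoring with chance-level nulls, and the neural-behavioral correspondence
#' analyses. Core result tables are written to `config$out_dir` and
#' checksummed in the run manifest.
#'
#' @param config an `ft_config` from [default_config()].
#' @return object of class `ft_experiment`: list with `group_foi`,
#'   `clusters`, `block_models`, `individual` (learner classification, all
#'   electrodes), `individual_subset` (cluster-electrode subset or `NULL`),
#'   `behavior` (per-subject table), `chance_cutoff`, `correspondence`,
#'   `cohort`, `config`, `manifest`.
#' @export
run_experiment <- function(config = default_config()) {
  stages <- character()
  run_stage <- function(name, expr) {
    stages <<- c(stages, name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage `%s` failed after completing [%s]: %s",
                    name, paste(head(stages, -1), collapse = ", "),
                    conditionMessage(e)))
    })
  }
  seeds <- child_seeds(config$seed, 6)
  fois <- foi_set()
  word_fois <- fois$foi[fois$word_related]

  lexicon <- run_stage("lexicon", build_lexicon(seed = seeds[1]))
  montage <- make_montage()
  adjacency <- electrode_adjacency(montage)

  streams <- run_stage("streams", {
    stream_seeds <- child_seeds(seeds[2], 2 * config$n_blocks)
    list(
      language = lapply(seq_len(config$n_blocks), function(b) {
        generate_language_stream(lexicon, config$n_triplets,
                                 seed = stream_seeds[b],
                                 ramp_duration = config$ramp_duration)
      }),
      baseline = lapply(seq_len(config$n_blocks), function(b) {
        generate_baseline_stream(lexicon, config$n_triplets,
                                 seed = stream_seeds[config$n_blocks + b],
                                 variant = config$baseline_variant,
                                 ramp_duration = config$ramp_duration)
      })
    )
  })

  cohort <- run_stage("cohort", sample_cohort(config$n_subjects,
                                              config$hyperparams, seeds[3]))

  eeg <- run_stage("eeg_itpc", {
    subj_seeds <- child_seeds(seeds[4], config$n_subjects)
    res <- lapply(seq_len(config$n_subjects), function(i) {
      profile <- cohort[i, ]
      rec_seeds <- child_seeds(subj_seeds[i], 2 * config$n_blocks + 2)
      per_cond <- lapply(c(language = "language", baseline = "baseline"),
                         function(cond) {
        ep <- lapply(seq_len(config$n_blocks), function(b) {
          s <- (if (cond == "language") 0 else config$n_blocks) + b
          rec <- simulate_eeg(streams[[cond]][[b]], profile, montage,
                              config$sample_rate, seed = rec_seeds[s],
                              block = b)
          epoch_recording(rec)
        })
        pooled <- combine_epochs(ep)
        itpc <- compute_itpc(pooled)
        block_rows <- purrr::map_dfr(ep, function(e) foi_summary(compute_itpc(e), fois))
        list(itpc = itpc, pooled = pooled, summary = foi_summary(itpc, fois),
             block_rows = block_rows)
      })
      # FOI phasors are the sufficient statistic for the permutation tests;
      # keeping them (not the epochs) keeps the cohort in memory
      ph_lang <- foi_phasors(per_cond$language$pooled, fois)
      ph_base <- foi_phasors(per_cond$baseline$pooled, fois)
      perm <- individual_permutation_phasors(
        ph_lang, ph_base, fois, n_perm = config$n_perm_individual,
        seed = rec_seeds[2 * config$n_blocks + 1],
        subject_id = profile$subject_id)
      foi_bins <- match_foi_bins(per_cond$language$itpc$freqs, fois$freq)
      list(
        summary = dplyr::bind_rows(per_cond$language$summary,
                                   per_cond$baseline$summary),
        block_rows = dplyr::bind_rows(per_cond$language$block_rows,
                                      per_cond$baseline$block_rows),
        foi_mat_language = per_cond$language$itpc$values[, foi_bins],
        foi_mat_baseline = per_cond$baseline$itpc$values[, foi_bins],
        perm = perm,
        phasors = list(language = ph_lang, baseline = ph_base),
        perm_seed = rec_seeds[2 * config$n_blocks + 1]
      )
    })
    res
  })

  summaries <- dplyr::bind_rows(lapply(eeg, `[[`, "summary"))
  group_foi <- run_stage("group_stats", group_foi_tests(summaries, fois))

  clusters <- run_stage("cluster_stats", {
    cl_seeds <- child_seeds(seeds[5], nrow(fois))
    setNames(lapply(seq_len(nrow(fois)), function(j) {
      L <- t(vapply(eeg, function(s) s$foi_mat_language[, j],
                    numeric(nrow(montage))))
      B <- t(vapply(eeg, function(s) s$foi_mat_baseline[, j],
                    numeric(nrow(montage))))
      cluster_permutation(L, B, adjacency, n_perm = config$n_perm_cluster,
                          direction = if (fois$direction[j] > 0) "greater" else "less",
                          seed = cl_seeds[j])
    }), fois$foi)
  })

  block_models <- run_stage("block_regression", {
    block_tab <- dplyr::bind_rows(lapply(seq_along(eeg), function(i) {
      dplyr::mutate(eeg[[i]]$block_rows, participant = cohort$subject_id[i])
    }))
    setNames(lapply(fois$foi, function(f) {
      tab <- dplyr::filter(block_tab, .data$foi == !!f)
      fit_block_model(tibble::tibble(participant = tab$participant,
                                     condition = tab$condition,
                                     block = tab$block, itpc = tab$itpc))
    }), fois$foi)
  })

  individual <- run_stage("individual_stats",
                          classify_learners(lapply(eeg, `[[`, "perm"),
                                            config$alpha))

  # re-analysis restricted to the significant-cluster electrodes (if any)
  subset_electrodes <- unique(unlist(lapply(clusters, function(cl) {
    unlist(cl$electrodes[cl$p <= config$alpha])
  })))
  individual_subset <- NULL
  if (length(subset_electrodes) > 0) {
    individual_subset <- run_stage("individual_stats_subset", {
      perms <- lapply(seq_along(eeg), function(i) {
        individual_permutation_phasors(
          eeg[[i]]$phasors$language, eeg[[i]]$phasors$baseline,
          fois, n_perm = config$n_perm_individual, seed = eeg[[i]]$perm_seed,
          subject_id = cohort$subject_id[i],
          electrodes = subset_electrodes, channel_labels = montage$label)
      })
      classify_learners(perms, config$alpha)
    })
  }

  behavior <- run_stage("behavior", {
    beh_seeds <- child_seeds(seeds[6], 2 * config$n_subjects + 2)
    trials_2afc <- build_2afc_trials(lexicon)
    td_trials <- build_target_detection_trials(lexicon,
                                               seed = beh_seeds[2 * config$n_subjects + 1])
    null_2afc <- simulate_2afc_null(36, 1000,
                                    seed = beh_seeds[2 * config$n_subjects + 2])
    tab <- purrr::map_dfr(seq_len(config$n_subjects), function(i) {
      profile <- cohort[i, ]
      s2 <- score_2afc(simulate_2afc(profile, trials_2afc, beh_seeds[i]))
      det <- score_target_detection(
        simulate_target_detection(profile, td_trials,
                                  beh_seeds[config$n_subjects + i]))
      dp <- detection_permutation(det$per_target,
                                  n_perm = config$n_perm_detection,
                                  seed = beh_seeds[config$n_subjects + i])
      tibble::tibble(
        subject_id = profile$subject_id,
        accuracy = s2$accuracy, p_binomial = s2$p_binomial,
        explicit_above_cutoff = s2$accuracy > null_2afc$cutoff,
        delta_hr = det$summary$delta_hr, delta_rt = det$summary$delta_rt,
        p_delta_hr = dp$p[dp$measure == "delta_hr"],
        p_delta_rt = dp$p[dp$measure == "delta_rt"],
        implicit_significant = dp$p[dp$measure == "delta_hr"] <= config$alpha |
          (!is.na(dp$p[dp$measure == "delta_rt"]) &&
             dp$p[dp$measure == "delta_rt"] <= config$alpha)
      )
    })
    list(table = tab, cutoff = null_2afc$cutoff)
  })

  correspondence <- run_stage("correspondence", {
    neural <- tibble::tibble(
      subject_id = cohort$subject_id,
      itpc_word_avg = vapply(eeg, function(s) {
        sm <- s$summary
        mean(sm$itpc[sm$condition == "language" & sm$foi %in% word_fois])
      }, 0),
      learner_flag = individual$subjects$learner_flag)
    beh <- behavior$table[, c("subject_id", "accuracy", "delta_hr", "delta_rt")]
    tryCatch(neural_behavior_comparison(neural, beh), error = function(e) {
      inform(paste("Correspondence analysis skipped:", conditionMessage(e)))
      NULL
    })
  })

  out <- list(group_foi = group_foi, clusters = clusters,
              block_models = block_models, individual = individual,
              individual_subset = individual_subset,
              subset_electrodes = subset_electrodes,
              behavior = behavior$table, chance_cutoff = behavior$cutoff,
              correspondence = correspondence, cohort = cohort,
              config = config)
  out$manifest <- run_stage("manifest", write_results(out, config$out_dir))
  structure(out, class = "ft_experiment")
}

# write core result tables and build the checksum manifest
write_results <- function(results, out_dir) {
  out_dir <- out_dir %||% file.path(tempfile("freqtagsl-run-"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- results$config
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  readr::write_tsv(results$group_foi, file.path(out_dir, "group_foi.tsv"))
  cluster_tab <- purrr::map_dfr(names(results$clusters), function(f) {
    cl <- results$clusters[[f]]
    if (nrow(cl) == 0) return(NULL)
    tibble::tibble(foi = f, cluster = cl$cluster,
                   electrodes = vapply(cl$electrodes, paste, "", collapse = ","),
                   stat = cl$stat, p = cl$p)
  })
  readr::write_tsv(cluster_tab, file.path(out_dir, "clusters.tsv"))
  block_tab <- purrr::map_dfr(names(results$block_models), function(f) {
    dplyr::mutate(results$block_models[[f]]$coefficients, foi = f, .before = 1)
  })
  readr::write_tsv(block_tab, file.path(out_dir, "block_regression.tsv"))
  readr::write_tsv(results$individual$subjects,
                   file.path(out_dir, "individual.tsv"))
  readr::write_tsv(results$behavior, file.path(out_dir, "behavior.tsv"))
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  attr(manifest, "timestamp") <- format(Sys.time(), tz = "UTC")
  attr(manifest, "out_dir") <- out_dir
  manifest
}

#' @export
print.ft_experiment <- function(x, ...) {
  cat("<ft_experiment>\n\nGroup FOI tests (one-tailed paired t + directional BF):\n")
  print(x$group_foi)
  cat(sprintf("\nIndividual analysis: %d/%d subjects significant at a word-related FOI\n",
              x$individual$n_flagged, x$individual$n_total))
  cat(sprintf("Behavioral: mean 2AFC accuracy %.1f%% (chance cutoff %.1f%%); %d/%d implicit-task significant\n",
              100 * mean(x$behavior$accuracy), 100 * x$chance_cutoff,
              sum(x$behavior$implicit_significant), nrow(x$behavior)))
  invisible(x)
}
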