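## End-to-end composition: simulate -> preprocess -> statistical maps ->
## LOSO windows -> ANOVA/post-hoc -> behavioral analysis, with provenance.

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Generates the dataset described by `config$sim`, preprocesses every
#' recording (epoch, reject, re-reference, filter, baseline, average),
#' builds the six statistical maps (three K-C contrasts and their three
#' between-task double differences) with the temporal-extent criterion,
#' draws topographic t maps for the group-level early and later windows,
#' defines per-subject component windows by leave-one-subject-out selection
#' on the window-defining task, extracts mean amplitudes, and runs the
#' task x hemisphere repeated-measures ANOVAs with post-hoc paired tests,
#' plus the behavioral one-way ANOVAs on simulated trial logs. Deterministic
#' given the configuration (all seeds included in it).
#'
#' @param config A [pipeline_config()].
#' @param window_task Task whose K-C map defines the component windows.
#' @param verbose Print stage progress.
#' @return An `icerp_report`; see [print.icerp_report()].
#' @export
run_pipeline <- function(config = pipeline_config(), window_task = "KF",
                         verbose = FALSE) {
  sim <- config$sim
  say <- function(...) if (verbose) message(sprintf(...))
  prov <- list(package_version = as.character(utils::packageVersion("icerp")),
               config_hash = config_hash(config),
               min_run_samples = min_run_from_duration(config$min_run_ms,
                                                       sim$fs),
               stages = list())
  log_stage <- function(name, ...) {
    prov$stages[[length(prov$stages) + 1L]] <<- c(list(stage = name),
                                                  list(...))
  }

  say("simulating and preprocessing %d subjects x %d tasks",
      sim$n_subjects, length(sim$tasks))
  log_stage("simulate", n_subjects = sim$n_subjects,
            n_trials_per_task = sim$n_trials_per_task, seed = sim$seed)
  erps <- list()  # [[task]][[subject]] -> list of eeg_erp by condition
  counts <- list()
  for (s in seq_len(sim$n_subjects)) {
    for (tk in sim$tasks) {
      rec <- generate_recording(sim, s, tk,
                                contamination_window = c(config$pre,
                                                         config$post),
                                contamination_threshold = config$eog_threshold)
      pp <- preprocess_recording(rec, config)
      erps[[tk]][[rec$subject]] <- pp$erps
      counts[[length(counts) + 1L]] <-
        cbind(subject = rec$subject, task = tk, pp$counts)
    }
  }
  counts <- do.call(rbind, counts)
  log_stage("preprocess", pre = config$pre, post = config$post,
            pad = config$pad, eog_threshold = config$eog_threshold,
            band = config$band, baseline = config$baseline,
            epochs_kept = sum(counts$kept),
            epochs_rejected = sum(counts$rejected))

  K <- sim$conditions[1]; C <- sim$conditions[2]
  waves <- list()  # [[task]] -> list of per-subject erp_diff
  for (tk in sim$tasks)
    waves[[tk]] <- lapply(erps[[tk]], function(e)
      difference_wave(e[[K]], e[[C]]))

  say("statistical maps")
  mrs <- prov$min_run_samples
  statmaps <- list()
  for (tk in sim$tasks)
    statmaps[[sprintf("%s %s-%s", tk, K, C)]] <-
      temporal_extent_mask(pointwise_paired_t(waves[[tk]]),
                           alpha = config$alpha, min_run_samples = mrs)
  tk3 <- sim$tasks
  dd_pairs <- list(c(1, 2), c(2, 3), c(1, 3))
  for (pr in dd_pairs) {
    lab <- sprintf("(%s %s-%s)-(%s %s-%s)", tk3[pr[1]], K, C,
                   tk3[pr[2]], K, C)
    dd <- mapply(double_difference, waves[[tk3[pr[1]]]],
                 waves[[tk3[pr[2]]]], SIMPLIFY = FALSE)
    statmaps[[lab]] <- temporal_extent_mask(pointwise_paired_t(dd),
                                            alpha = config$alpha,
                                            min_run_samples = mrs)
  }
  log_stage("statmap", alpha = config$alpha, min_run_ms = config$min_run_ms,
            min_run_samples = mrs)

  say("group windows and topographic maps")
  group_windows <- find_significant_windows(
    waves[[window_task]], electrodes = config$electrodes_of_interest,
    alpha = config$alpha, min_run_samples = mrs)
  topomaps <- list()
  for (cname in names(config$search_ranges)) {
    win <- select_interval(group_windows, config$search_ranges[[cname]])
    if (anyNA(win)) next
    for (tk in sim$tasks)
      topomaps[[paste(cname, tk)]] <-
        topo_stat_map(waves[[tk]], window = win, layout = sim$layout,
                      alpha = config$alpha, min_extent = config$min_extent)
  }
  log_stage("topomap", min_extent = config$min_extent)

  say("LOSO windows, amplitudes, ANOVA")
  loso <- loso_define_windows(waves[[window_task]],
                              electrodes = config$electrodes_of_interest,
                              search_ranges = config$search_ranges,
                              alpha = config$alpha, min_run_samples = mrs)
  amplitudes <- extract_amplitudes(waves, loso,
                                   hemisphere_sets = config$hemisphere_sets)
  anovas <- list(); posthocs <- list()
  for (cname in unique(amplitudes$component)) {
    sub <- amplitudes[amplitudes$component == cname, ]
    if (length(unique(sub$subject)) < 3) {
      warning("component ", cname, " has fewer than 3 surviving subjects ",
              "after LOSO; skipping its ANOVA")
      next
    }
    anovas[[cname]] <- rm_anova(sub, dv = "amplitude", subject = "subject",
                                within = c("task", "hemisphere"))
    posthocs[[cname]] <- posthoc_pairs(sub, dv = "amplitude",
                                       subject = "subject", within = "task")
  }
  log_stage("inference", electrodes = config$electrodes_of_interest,
            search_ranges = config$search_ranges)

  say("behavioral analysis")
  behavior_trials <- simulate_behavior(n_subjects = sim$n_subjects,
                                       n_trials = sim$n_trials_per_task,
                                       tasks = sim$tasks,
                                       seed = substream_seed(sim$seed,
                                                             "behavior"))
  behavior_table <- behavioral_summarize(behavior_trials)
  behavior <- behavioral_anova(behavior_table)
  log_stage("behavior", n_trials = sim$n_trials_per_task)

  structure(list(config = config, provenance = prov, counts = counts,
                 erps = erps, waves = waves, statmaps = statmaps,
                 group_windows = group_windows, topomaps = topomaps,
                 loso_windows = loso, amplitudes = amplitudes,
                 anovas = anovas, posthocs = posthocs,
                 behavior_table = behavior_table, behavior = behavior),
            class = "icerp_report")
}

#' Print an analysis report
#'
#' Mirrors the structure of the study's results: behavioral ANOVAs, epoch
#' counts, component windows, ERP ANOVAs with Greenhouse-Geisser correction,
#' and post-hoc comparisons with effect sizes.
#'
#' @param x An `icerp_report` from [run_pipeline()].
#' @param ... Unused.
#' @export
print.icerp_report <- function(x, ...) {
  cfg <- x$config
  cat("=== icerp analysis report ===\n")
  cat(sprintf("config %s | %d subjects, %d trials/task, %d channels\n",
              substr(x$provenance$config_hash, 1, 8), cfg$sim$n_subjects,
              cfg$sim$n_trials_per_task, nrow(cfg$sim$layout)))
  cat(sprintf("epochs kept %d / rejected %d (EOG +/-%g microvolts)\n",
              sum(x$counts$kept), sum(x$counts$rejected),
              cfg$eog_threshold))

  cat("\n-- Behavioral --\n")
  for (m in names(x$behavior)) {
    a <- x$behavior[[m]]$anova
    cat(sprintf("%s: F(%g, %g) = %.2f, p = %.4g, partial eta^2 = %.2f\n",
                m, a$df_num[1], a$df_den[1], a$F[1], a$p[1],
                a$partial_eta_sq[1]))
    ph <- x$behavior[[m]]$posthoc
    for (i in seq_len(nrow(ph)))
      cat(sprintf("   %s: t(%d) = %.2f, p = %.4g, eta^2 = %.2f\n",
                  ph$pair[i], ph$df[i], ph$t[i], ph$p[i], ph$eta_sq[i]))
  }

  cat("\n-- Significant windows (", cfg$electrodes_of_interest, ") --\n")
  if (nrow(x$group_windows))
    for (i in seq_len(nrow(x$group_windows)))
      cat(sprintf("  %g-%g ms\n", x$group_windows$start_ms[i],
                  x$group_windows$end_ms[i]))
  else cat("  none\n")

  cat("\n-- ERP amplitudes (LOSO windows) --\n")
  for (cname in names(x$anovas)) {
    cat(sprintf("[%s]\n", cname))
    print(x$anovas[[cname]])
    ph <- x$posthocs[[cname]]
    for (i in seq_len(nrow(ph)))
      cat(sprintf("   %s: t(%d) = %.2f, p = %.4g, eta^2 = %.2f\n",
                  ph$pair[i], ph$df[i], ph$t[i], ph$p[i], ph$eta_sq[i]))
  }
  invisible(x)
}
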