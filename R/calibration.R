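## Simulation studies: false-positive calibration under the null and
## recovery of the encoded two-stage effect pattern.

# Minimal posterior montage used by the replicated studies (plus EOG).
calibration_layout <- function() {
  layout_subset(read_layout(),
                c("PZ", "P3", "P4", "POZ", "PO5", "PO6", "O1", "O2",
                  "HEOG", "VEOG"))
}

# Preprocess one simulated subject x task cell into a K-C difference wave.
simulate_difference_wave <- function(sim, subject, task, config) {
  rec <- generate_recording(sim, subject, task)
  pp <- preprocess_recording(rec, config)
  difference_wave(pp$erps[[sim$conditions[1]]],
                  pp$erps[[sim$conditions[2]]])
}

#' Null calibration of the windowed pairwise tests
#'
#' Simulates replicate experiments with no illusory-contour effect (both IC
#' component amplitudes zero; P1/N1 present but identical across
#' conditions), runs the full preprocessing chain, and (a) performs the six
#' windowed pairwise task comparisons (early and later fixed windows,
#' electrodes of interest averaged, hemispheres combined) recording
#' false-positive rates, and (b) records, for one occipito-parietal channel
#' of the window-defining task's K-C map, whether at least one temporal run
#' survives the extent criterion at each `min_run` in `min_run_grid` —
#' which must be monotone non-increasing in `min_run`.
#'
#' @param n_rep Number of replicate experiments.
#' @param n_subjects,n_trials Scaled design per replicate.
#' @param windows Named list of fixed component windows (ms).
#' @param min_run_grid Run-length criteria (samples) for the survival curve.
#' @param channel Channel inspected for surviving runs.
#' @param alpha Significance level.
#' @param seed Master seed.
#' @return List: `fp_rates` (per comparison), `fp_overall`, `run_rates`
#'   (named by min_run), `n_rep`, `n_tests`.
#' @export
null_calibration <- function(n_rep = 500, n_subjects = 14, n_trials = 12,
                             windows = list(early = c(130, 166),
                                            later = c(234, 290)),
                             min_run_grid = c(1, 5, 10, 15),
                             channel = "PO5", alpha = 0.05, seed = 1L) {
  lay <- layout_subset(read_layout(),
                       c("PZ", "POZ", "PO5", "PO6", "HEOG", "VEOG"))
  config <- pipeline_config(sim = scaled_config())  # stage params only
  tasks <- c("KF", "CC", "PC")
  pairs <- list(c("KF", "CC"), c("KF", "PC"), c("CC", "PC"))
  comp_names <- names(windows)
  fp <- matrix(0L, nrow = length(comp_names), ncol = length(pairs),
               dimnames = list(comp_names,
                               vapply(pairs, paste, "", collapse = " vs ")))
  runs <- stats::setNames(integer(length(min_run_grid)),
                          as.character(min_run_grid))
  eoi <- config$electrodes_of_interest

  for (r in seq_len(n_rep)) {
    sim <- simulation_config(
      n_subjects = n_subjects, n_trials_per_task = n_trials, layout = lay,
      components = default_components(early_amplitude = 0,
                                      later_amplitude = 0),
      seed = substream_seed(seed, "null", r))
    waves <- list()
    for (tk in tasks)
      waves[[tk]] <- lapply(seq_len(n_subjects), function(s)
        simulate_difference_wave(sim, s, tk, config))

    ta <- waves[[1]][[1]]$time_axis
    for (cn in comp_names) {
      wi <- which(ta >= windows[[cn]][1] - 1e-9 &
                    ta <= windows[[cn]][2] + 1e-9)
      amp <- vapply(tasks, function(tk)
        vapply(waves[[tk]], function(w)
          mean(w$data[eoi, wi, drop = FALSE]), numeric(1)),
        numeric(n_subjects))
      for (pi in seq_along(pairs)) {
        pt <- posthoc_paired_t(amp[, pairs[[pi]][1]], amp[, pairs[[pi]][2]])
        if (pt$p < alpha) fp[cn, pi] <- fp[cn, pi] + 1L
      }
    }

    kf_map <- pointwise_paired_t(waves[["KF"]])
    pvec <- kf_map$p[channel, ]
    for (g in seq_along(min_run_grid)) {
      keep <- run_filter(pvec < alpha, min_run_grid[g])
      if (any(keep)) runs[g] <- runs[g] + 1L
    }
  }
  list(fp_rates = fp / n_rep, fp_overall = sum(fp) / (n_rep * length(fp)),
       run_rates = runs / n_rep, n_rep = n_rep, n_tests = length(fp))
}

# Overlap of a window with a reference interval, as a fraction of the
# reference length.
interval_overlap <- function(win, ref) {
  if (anyNA(win)) return(0)
  max(0, min(win[2], ref[2]) - max(win[1], ref[1])) / (ref[2] - ref[1])
}

#' Recovery of the two-stage effect pattern
#'
#' Simulates replicate experiments with the encoded effect structure (early
#' IC component present in KF and CC, absent in PC; later IC component
#' present only in KF), runs preprocessing, LOSO window definition,
#' amplitude extraction and the post-hoc comparisons, and scores each
#' replicate for (a) the full qualitative significance pattern — early:
#' KF vs CC n.s., KF > PC significant, CC > PC significant; later: KF > CC
#' and KF > PC significant, CC vs PC n.s. ("larger" meaning the more
#' negative difference amplitude) — and (b) the overlap of every fold's
#' early LOSO window with the injected 130-166 ms support.
#'
#' @param n_rep Number of replicate experiments.
#' @param n_subjects,n_trials Scaled design per replicate.
#' @param alpha Significance level.
#' @param seed Master seed.
#' @return List: `pattern_rate`, `fold_overlap` (vector over all early
#'   folds pooled across replicates), `mean_fold_overlap`,
#'   `prop_folds_ge_80`, `n_rep`.
#' @export
pattern_recovery <- function(n_rep = 100, n_subjects = 14, n_trials = 60,
                             alpha = 0.05, seed = 1L) {
  lay <- calibration_layout()
  config <- pipeline_config(sim = scaled_config())
  tasks <- c("KF", "CC", "PC")
  early_ref <- c(130, 166)
  pattern_hits <- 0L
  overlaps <- numeric(0)

  for (r in seq_len(n_rep)) {
    sim <- simulation_config(
      n_subjects = n_subjects, n_trials_per_task = n_trials, layout = lay,
      seed = substream_seed(seed, "pattern", r))
    waves <- list()
    for (tk in tasks)
      waves[[tk]] <- lapply(seq_len(n_subjects), function(s)
        simulate_difference_wave(sim, s, tk, config))

    loso <- suppressWarnings(loso_define_windows(
      waves[["KF"]], electrodes = config$electrodes_of_interest,
      search_ranges = config$search_ranges, alpha = alpha,
      min_run_samples = min_run_from_duration(config$min_run_ms,
                                              sim$fs)))
    early <- loso[loso$component == "early", ]
    overlaps <- c(overlaps, vapply(seq_len(nrow(early)), function(i)
      interval_overlap(c(early$start_ms[i], early$end_ms[i]), early_ref),
      numeric(1)))

    amp <- extract_amplitudes(waves, loso,
                              hemisphere_sets = config$hemisphere_sets)
    ok <- TRUE
    for (cn in c("early", "later")) {
      sub <- amp[amp$component == cn, ]
      if (length(unique(sub$subject)) < n_subjects) { ok <- FALSE; break }
      ph <- posthoc_pairs(sub, dv = "amplitude", subject = "subject",
                          within = "task")
      sig <- ph$p < alpha
      neg <- ph$mean_diff < 0
      want <- if (cn == "early")
        !sig[1] && (sig[2] && neg[2]) && (sig[3] && neg[3])
      else
        (sig[1] && neg[1]) && (sig[2] && neg[2]) && !sig[3]
      if (!want) { ok <- FALSE; break }
    }
    if (ok) pattern_hits <- pattern_hits + 1L
  }
  list(pattern_rate = pattern_hits / n_rep, fold_overlap = overlaps,
       mean_fold_overlap = mean(overlaps),
       prop_folds_ge_80 = mean(overlaps >= 0.8), n_rep = n_rep)
}
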