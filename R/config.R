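#' ERP component specification
#'
#' Describes one simulated ERP component as a smooth raised-cosine (Hann)
#' bump: maximal at `peak_latency`, compactly supported on
#' `peak_latency +/- temporal_width` (full width `2 * temporal_width`).
#' Cell amplitudes are signed mean amplitudes in microvolts per
#' (task, condition) cell; the spatial pattern is a named weight vector over
#' channels in `[-1, 1]`.
#'
#' Inter-subject variability is a single Gaussian amplitude offset per
#' (subject, component), drawn once and applied to every cell in which the
#' component is present (nominal amplitude non-zero), so that a subject with
#' a large component has it large in all tasks. Inter-trial variability is an
#' independent Gaussian amplitude jitter per trial.
#'
#' @param name Component label, e.g. `"P1"`, `"N1"`, `"earlyIC"`, `"laterIC"`.
#' @param peak_latency Peak latency in ms after stimulus onset.
#' @param temporal_width Half-width of the bump in ms (support is
#'   `peak_latency +/- temporal_width`); must be positive.
#' @param amplitude_by_cell Numeric matrix (tasks x conditions, dimnames
#'   required) of signed amplitudes in microvolts.
#' @param topography Named numeric vector of channel weights in `[-1, 1]`;
#'   at least one non-zero weight.
#' @param inter_subject_sd SD (microvolts) of the per-subject amplitude offset.
#' @param inter_trial_sd SD (microvolts) of the per-trial amplitude jitter.
#' @return A `component_spec` list.
#' @export
component_spec <- function(name, peak_latency, temporal_width,
                           amplitude_by_cell, topography,
                           inter_subject_sd = 0, inter_trial_sd = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(peak_latency), length(peak_latency) == 1L,
            is.numeric(temporal_width), length(temporal_width) == 1L)
  if (temporal_width <= 0) stop("temporal_width must be > 0")
  if (!is.matrix(amplitude_by_cell) || is.null(dimnames(amplitude_by_cell)))
    stop("amplitude_by_cell must be a (task x condition) matrix with dimnames")
  if (is.null(names(topography)) || !any(topography != 0))
    stop("topography must be a named vector with at least one non-zero weight")
  if (any(abs(topography) > 1))
    stop("topography weights must lie in [-1, 1]")
  if (inter_subject_sd < 0 || inter_trial_sd < 0)
    stop("variability SDs must be >= 0")
  structure(list(name = name, peak_latency = peak_latency,
                 temporal_width = temporal_width,
                 amplitude_by_cell = amplitude_by_cell,
                 topography = topography,
                 inter_subject_sd = inter_subject_sd,
                 inter_trial_sd = inter_trial_sd),
            class = "component_spec")
}

#' Background-noise specification
#'
#' Additive channel noise is the sum of white Gaussian noise and `1/f^alpha`
#' ("pink") noise, generated independently per channel.
#'
#' @param white_sd SD of the white component, microvolts.
#' @param pink_sd SD of the pink component, microvolts.
#' @param pink_exponent Spectral exponent alpha of the `1/f^alpha` component.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(white_sd = 0.4, pink_sd = 0.5, pink_exponent = 1) {
  if (white_sd < 0 || pink_sd < 0) stop("noise SDs must be >= 0")
  structure(list(white_sd = white_sd, pink_sd = pink_sd,
                 pink_exponent = pink_exponent),
            class = "noise_spec")
}

#' Blink-artifact specification
#'
#' Blinks are raised-cosine deflections of `amplitude` microvolts on VEOG
#' (projection weight 1), occurring as a Poisson process at `rate` events per
#' minute, and projected onto scalp channels with weights that decay with
#' distance from the frontal pole. The default amplitude (80) is chosen so
#' that contaminated epochs violate the +/-50 microvolt EOG rejection
#' criterion.
#'
#' @param rate Blink rate, events per minute.
#' @param amplitude Peak VEOG amplitude, microvolts (> 0).
#' @param width Half-width of the blink in ms (support `+/- width`).
#' @param veog_projection Weight on the VEOG channel (1 by default).
#' @param scalp_projection Named weight vector for non-VEOG channels, or
#'   `NULL` to derive frontally-decaying weights from the layout at
#'   simulation time.
#' @return A `blink_spec` list.
#' @export
blink_spec <- function(rate = 2, amplitude = 80, width = 150,
                       veog_projection = 1, scalp_projection = NULL) {
  if (amplitude <= 0) stop("blink amplitude must be > 0")
  if (rate < 0) stop("blink rate must be >= 0")
  if (width <= 0) stop("blink width must be > 0")
  structure(list(rate = rate, amplitude = amplitude, width = width,
                 veog_projection = veog_projection,
                 scalp_projection = scalp_projection),
            class = "blink_spec")
}

#' Default simulated component set
#'
#' Four components: stimulus-evoked P1 and N1 (identical for Kanizsa and
#' control stimuli, hence absent from difference waves), and two
#' illusory-contour-sensitive negative difference components carried by the
#' Kanizsa condition only. The early IC component (support 130-166 ms) is
#' present in the KF and CC tasks and absent in the PC task; the later IC
#' component (support 234-290 ms) is present only in the KF task. Topographies
#' are occipito-parietal, centred on PO5/PO6 for the IC components.
#'
#' @param tasks Task labels (default KF, CC, PC).
#' @param conditions Condition labels (default K, C).
#' @param early_amplitude,later_amplitude Signed amplitudes (microvolts) of
#'   the IC components in the cells where they are present.
#' @return List of [component_spec()] objects.
#' @export
default_components <- function(tasks = c("KF", "CC", "PC"),
                               conditions = c("K", "C"),
                               early_amplitude = -1.5,
                               later_amplitude = -2.0) {
  cellmat <- function(vals) {
    m <- matrix(vals, nrow = length(tasks), ncol = length(conditions),
                dimnames = list(tasks, conditions))
    m
  }
  both <- cellmat(1)                       # present in every cell
  ic_topo <- c(PO5 = 1, PO6 = 1, PO7 = 0.6, PO8 = 0.6, PO3 = 0.6, PO4 = 0.6,
               P5 = 0.35, P6 = 0.35, O1 = 0.3, O2 = 0.3)
  early <- cellmat(0); early[c("KF", "CC"), "K"] <- early_amplitude
  later <- cellmat(0); later["KF", "K"] <- later_amplitude
  list(
    component_spec("P1", peak_latency = 100, temporal_width = 30,
                   amplitude_by_cell = 2.0 * both,
                   topography = c(O1 = 1, OZ = 1, O2 = 1, PO3 = 0.7,
                                  POZ = 0.8, PO4 = 0.7, PO5 = 0.5, PO6 = 0.5),
                   inter_subject_sd = 0.4, inter_trial_sd = 0.8),
    component_spec("N1", peak_latency = 170, temporal_width = 35,
                   amplitude_by_cell = -3.0 * both,
                   topography = c(PO7 = 1, PO8 = 1, PO5 = 0.8, PO6 = 0.8,
                                  P7 = 0.7, P8 = 0.7, O1 = 0.5, O2 = 0.5),
                   inter_subject_sd = 0.5, inter_trial_sd = 1.0),
    component_spec("earlyIC", peak_latency = 148, temporal_width = 18,
                   amplitude_by_cell = early, topography = ic_topo,
                   inter_subject_sd = 0.3, inter_trial_sd = 0.5),
    component_spec("laterIC", peak_latency = 262, temporal_width = 28,
                   amplitude_by_cell = later, topography = ic_topo,
                   inter_subject_sd = 0.3, inter_trial_sd = 0.5)
  )
}

#' Simulation configuration
#'
#' Describes one synthetic multi-subject experiment: a 3-task x 2-condition
#' design with equal numbers of Kanizsa (K) and control (C) stimuli per task,
#' a fixed stimulus sequence shared across the three tasks of a subject,
#' stimulus duration 150 ms, inter-stimulus intervals uniform in
#' `isi_range`, and 500 Hz sampling.
#'
#' @param n_subjects Number of subjects (>= 2; study default 14).
#' @param tasks Ordered task labels.
#' @param conditions Condition labels (first is the "target" Kanizsa figure).
#' @param n_trials_per_task Trials per task; must split equally over
#'   conditions.
#' @param fs Sampling rate, Hz.
#' @param stimulus_duration Stimulus duration, ms.
#' @param isi_range Length-2 ms range (min, max) of inter-stimulus intervals
#'   (stimulus offset to next onset).
#' @param layout An [read_layout()] object naming the simulated channels.
#' @param components List of [component_spec()] objects.
#' @param noise A [noise_spec()].
#' @param blink A [blink_spec()].
#' @param seed Master seed; all randomness is derived from it through named
#'   substreams per (subject, task, purpose).
#' @param min_epoch_span Smallest stimulus-onset asynchrony the design must
#'   accommodate (ms); configs whose minimum SOA
#'   (`stimulus_duration + min(isi_range)`) falls below it are rejected,
#'   since adjacent epochs of interest would collide.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 14,
                              tasks = c("KF", "CC", "PC"),
                              conditions = c("K", "C"),
                              n_trials_per_task = 400,
                              fs = 500,
                              stimulus_duration = 150,
                              isi_range = c(900, 1200),
                              layout = read_layout(),
                              components = default_components(tasks, conditions),
                              noise = noise_spec(),
                              blink = blink_spec(),
                              seed = 1L,
                              min_epoch_span = 500) {
  cfg <- structure(list(n_subjects = as.integer(n_subjects),
                        tasks = tasks, conditions = conditions,
                        n_trials_per_task = as.integer(n_trials_per_task),
                        fs = fs, stimulus_duration = stimulus_duration,
                        isi_range = isi_range, layout = layout,
                        components = components, noise = noise, blink = blink,
                        seed = as.integer(seed),
                        min_epoch_span = min_epoch_span),
                   class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_subjects < 2) stop("n_subjects must be >= 2")
  if (cfg$fs <= 0) stop("fs must be > 0")
  if (length(cfg$isi_range) != 2 || cfg$isi_range[1] > cfg$isi_range[2])
    stop("isi_range must be (min, max) with min <= max")
  k <- length(cfg$conditions)
  if (cfg$n_trials_per_task %% k != 0)
    stop("n_trials_per_task must split equally over the ", k, " conditions")
  if (cfg$stimulus_duration + cfg$isi_range[1] < cfg$min_epoch_span)
    stop("record-length overflow: minimum SOA ",
         cfg$stimulus_duration + cfg$isi_range[1],
         " ms cannot accommodate the ", cfg$min_epoch_span,
         " ms epoch span; rejecting configuration")
  for (cmp in cfg$components) {
    bad <- setdiff(names(cmp$topography), cfg$layout$name)
    # weights on channels outside the montage are silently dropped at
    # simulation time; requiring none present would forbid reduced montages
    if (!any(names(cmp$topography) %in% cfg$layout$name))
      stop("component ", cmp$name, " has no topography weight on any ",
           "channel of the montage")
    miss <- setdiff(rownames(cmp$amplitude_by_cell), cfg$tasks)
    if (length(miss) || !setequal(colnames(cmp$amplitude_by_cell),
                                  cfg$conditions))
      stop("component ", cmp$name,
           " amplitude_by_cell dimnames must match tasks x conditions")
  }
  invisible(cfg)
}

#' Scaled-down study configuration
#'
#' The study design at desk scale: 14 subjects and 60 trials per task
#' (instead of 400), optionally on a reduced posterior-plus-midline montage.
#' Used throughout the package's tests and calibration studies.
#'
#' @param n_subjects,n_trials_per_task Scaled design sizes.
#' @param reduced_montage If `TRUE`, simulate 16 scalp channels plus
#'   HEOG/VEOG instead of the full 64-channel cap.
#' @param ... Passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
scaled_config <- function(n_subjects = 14, n_trials_per_task = 60,
                          reduced_montage = TRUE, ...) {
  lay <- read_layout()
  if (reduced_montage) {
    keep <- c("FZ", "FCZ", "CZ", "PZ", "P3", "P4", "PO7", "PO5", "PO3", "POZ",
              "PO4", "PO6", "PO8", "O1", "OZ", "O2", "HEOG", "VEOG")
    lay <- layout_subset(lay, keep)
  }
  simulation_config(n_subjects = n_subjects,
                    n_trials_per_task = n_trials_per_task,
                    layout = lay, ...)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> %d subjects, tasks %s, ",
                     "%d trials/task (%s), fs %g Hz\n"),
              x$n_subjects, paste(x$tasks, collapse = "/"),
              x$n_trials_per_task, paste(x$conditions, collapse = "/"), x$fs))
  cat(sprintf("  stimulus %g ms, ISI %g-%g ms, %d channels, seed %d\n",
              x$stimulus_duration, x$isi_range[1], x$isi_range[2],
              nrow(x$layout), x$seed))
  cat(sprintf("  components: %s\n",
              paste(vapply(x$components, `[[`, "", "name"), collapse = ", ")))
  cat(sprintf("  noise: white %g, pink %g (1/f^%g) microvolts; blinks %g/min\n",
              x$noise$white_sd, x$noise$pink_sd, x$noise$pink_exponent,
              x$blink$rate))
  invisible(x)
}

#' Full pipeline configuration
#'
#' All stage parameters of the analysis chain with the study's values as
#' defaults: epoch window -100..400 ms padded by 300 ms, +/-50 microvolt EOG
#' rejection, average reference, 0.5-30 Hz zero-phase band-pass, -100..0 ms
#' baseline, point-wise alpha 0.05 with a 20 ms temporal-extent criterion and
#' a two-electrode spatial-extent criterion, PO5/PO6 electrodes of interest,
#' and leave-one-subject-out search ranges of 100-200 ms (early component)
#' and 200-320 ms (later component).
#'
#' @param sim A [simulation_config()].
#' @param pre,post,pad Epoch window and padding, ms.
#' @param eog_threshold EOG rejection threshold, microvolts.
#' @param band Band-pass edges `(lo, hi)`, Hz.
#' @param baseline Baseline window, ms.
#' @param alpha Point-wise significance level.
#' @param min_run_ms Temporal-extent criterion, ms.
#' @param min_extent Spatial-extent criterion, electrodes.
#' @param electrodes_of_interest Channels averaged for window definition.
#' @param hemisphere_sets Named list with `left` and `right` electrode sets
#'   for the task x hemisphere ANOVA. The default is `PO5` / `PO6`; the
#'   extended preset is `PO3,PO5,PO7` / `PO4,PO6,PO8`.
#' @param search_ranges Named list with `early` and `later` ms ranges
#'   searched during LOSO window definition.
#' @param seed Analysis-level seed (only the simulation consumes randomness).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = scaled_config(),
                            pre = 100, post = 400, pad = 300,
                            eog_threshold = 50,
                            band = c(0.5, 30),
                            baseline = c(-100, 0),
                            alpha = 0.05,
                            min_run_ms = 20,
                            min_extent = 2,
                            electrodes_of_interest = c("PO5", "PO6"),
                            hemisphere_sets = list(left = "PO5",
                                                   right = "PO6"),
                            search_ranges = list(early = c(100, 200),
                                                 later = c(200, 320)),
                            seed = sim$seed) {
  stopifnot(pre >= 0, post > 0, pad >= 0, eog_threshold > 0,
            length(band) == 2, band[1] < band[2],
            length(baseline) == 2, baseline[1] < baseline[2],
            alpha > 0, alpha < 1, min_run_ms > 0, min_extent >= 1)
  structure(list(sim = sim, pre = pre, post = post, pad = pad,
                 eog_threshold = eog_threshold, band = band,
                 baseline = baseline, alpha = alpha,
                 min_run_ms = min_run_ms, min_extent = min_extent,
                 electrodes_of_interest = electrodes_of_interest,
                 hemisphere_sets = hemisphere_sets,
                 search_ranges = search_ranges, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Extended occipito-parietal hemisphere sets
#'
#' Preset mirroring the wider electrode grouping (PO3/PO5/PO7 left,
#' PO4/PO6/PO8 right) used as a robustness check of the PO5/PO6 analysis.
#' @return Named list with `left` and `right` character vectors.
#' @export
hemisphere_sets_extended <- function() {
  list(left = c("PO3", "PO5", "PO7"), right = c("PO4", "PO6", "PO8"))
}
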