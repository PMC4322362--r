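## Synthetic multi-subject EEG generator for the 3-task x 2-condition design.

# Deterministic substream seed from a master seed and a path of labels.
# Polynomial string hash mod (2^31 - 1); exact in double arithmetic.
substream_seed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (tag in as.character(list(...))) {
    for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% m
    h <- (h * 31 + 7) %% m
  }
  as.integer(h)
}

with_substream <- function(master, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, ...))
  expr
}

#' Evaluate a component's waveform on a time axis
#'
#' The bump kernel is a Hann (raised-cosine) window: smooth, compactly
#' supported on `peak_latency +/- temporal_width` (full width
#' `2 * temporal_width`), with no ringing. Maximum magnitude occurs at
#' `peak_latency` and the sign follows the cell amplitude.
#'
#' @param spec A [component_spec()].
#' @param time_axis Numeric vector of times, ms (must cover `peak_latency`).
#' @param task,condition Cell whose amplitude to use; defaults to the
#'   largest-magnitude cell of the component.
#' @param amplitude Explicit amplitude override, microvolts.
#' @return Numeric series, microvolts, same length as `time_axis`.
#' @examples
#' spec <- default_components()[[3]]  # early IC component
#' w <- component_waveform(spec, seq(-100, 400, by = 2), task = "KF",
#'                         condition = "K")
#' @export
component_waveform <- function(spec, time_axis, task = NULL, condition = NULL,
                               amplitude = NULL) {
  if (is.null(amplitude)) {
    amplitude <- if (!is.null(task) && !is.null(condition))
      spec$amplitude_by_cell[task, condition]
    else {
      cells <- spec$amplitude_by_cell
      cells[which.max(abs(cells))]
    }
  }
  if (min(time_axis) > spec$peak_latency || max(time_axis) < spec$peak_latency)
    stop("time axis does not cover peak latency ", spec$peak_latency, " ms")
  hann_bump(time_axis, spec$peak_latency, spec$temporal_width, amplitude)
}

# Raised-cosine bump: amplitude * 0.5 * (1 + cos(pi * (t - peak)/width))
# on |t - peak| <= width, zero outside.
hann_bump <- function(t, peak, width, amplitude) {
  u <- (t - peak) / width
  out <- numeric(length(t))
  inside <- abs(u) <= 1
  out[inside] <- amplitude * 0.5 * (1 + cos(pi * u[inside]))
  out
}

#' Generate 1/f^alpha ("pink") noise
#'
#' Spectral synthesis: Gaussian Fourier coefficients shaped by
#' `f^(-alpha/2)`, inverse-transformed and standardized to unit SD.
#'
#' @param n Number of samples.
#' @param alpha Spectral exponent (power spectrum proportional to
#'   `1/f^alpha`).
#' @return Numeric vector of length `n` with (sample) SD 1.
#' @export
pink_noise <- function(n, alpha = 1) {
  if (n < 2) return(numeric(n))
  # synthesize at a highly composite length for FFT speed, then truncate
  nfast <- stats::nextn(n, c(2, 3, 5))
  if (nfast > n) return(pink_noise_exact(nfast, alpha)[seq_len(n)])
  pink_noise_exact(n, alpha)
}

pink_noise_exact <- function(n, alpha) {
  pink_noise_matrix_exact(n, 1L, alpha)[, 1]
}

# Several independent pink-noise series at once (columns), at a fast length.
pink_noise_matrix <- function(n, ncol, alpha = 1) {
  nfast <- stats::nextn(n, c(2, 3, 5))
  pink_noise_matrix_exact(nfast, ncol, alpha)[seq_len(n), , drop = FALSE]
}

pink_noise_matrix_exact <- function(n, ncol, alpha) {
  nfreq <- floor(n / 2)
  amp <- seq_len(nfreq)^(-alpha / 2)
  re <- matrix(stats::rnorm(nfreq * ncol), nfreq, ncol) * amp
  im <- matrix(stats::rnorm(nfreq * ncol), nfreq, ncol) * amp
  if (n %% 2 == 0) im[nfreq, ] <- 0
  spec <- matrix(complex(real = re, imaginary = im), nfreq, ncol)
  mirror <- if (n %% 2 == 0) Conj(spec[rev(seq_len(nfreq - 1)), ,
                                       drop = FALSE])
            else Conj(spec[rev(seq_len(nfreq)), , drop = FALSE])
  full <- rbind(matrix(complex(real = 0), 1, ncol), spec, mirror)
  x <- Re(stats::mvfft(full, inverse = TRUE)) / n
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  sweep(x, 2, s, "/")
}

#' Generate the full synthetic dataset
#'
#' One continuous recording per subject x task. Within a subject the stimulus
#' sequence (condition order and onset times) is identical across the three
#' tasks, mirroring the study procedure; trials split equally between the K
#' and C conditions. Records start 1 s before the first stimulus and end 1 s
#' after the last, leaving full padded-epoch margins. The output is
#' bit-reproducible from `config$seed`: every random draw comes from a named
#' substream per (subject, task, purpose), so e.g. enabling blink injection
#' does not perturb the noise.
#'
#' @param config A [simulation_config()].
#' @param contamination_window Epoch window (`c(pre, post)`, ms) used for the
#'   ground-truth blink bookkeeping, matching the epoch of interest.
#' @param contamination_threshold EOG amplitude (microvolts) above which an
#'   epoch overlapping a blink counts as contaminated.
#' @return List of `eeg_raw` recordings (subject-major, task-minor order).
#'   Each has fields `subject`, `task`, `data` (channel x sample matrix,
#'   microvolts), `fs`, `events` (data frame: `sample`, `onset_ms`,
#'   `condition`), `layout`, and attribute-like field
#'   `contaminated_events` (indices into `events` whose epoch a blink
#'   pushed over the threshold).
#' @examples
#' cfg <- scaled_config(n_subjects = 2, n_trials_per_task = 8, seed = 7)
#' recs <- generate_dataset(cfg)
#' length(recs)  # 2 subjects x 3 tasks
#' @export
generate_dataset <- function(config, contamination_window = c(100, 400),
                             contamination_threshold = 50) {
  validate_simulation_config(config)
  lapply(subject_task_grid(config), function(st) {
    generate_recording(config, st$subject, st$task,
                       contamination_window, contamination_threshold)
  })
}

subject_task_grid <- function(config) {
  out <- list()
  for (s in seq_len(config$n_subjects))
    for (tk in config$tasks)
      out[[length(out) + 1L]] <- list(subject = s, task = tk)
  out
}

subject_id <- function(i) sprintf("S%02d", i)

# Stimulus sequence for one subject: shared across tasks.
subject_sequence <- function(config, subject) {
  n <- config$n_trials_per_task
  k <- length(config$conditions)
  with_substream(config$seed, subject_id(subject), "sequence", expr = {
    cond <- sample(rep(config$conditions, each = n / k))
    isi <- stats::runif(n, config$isi_range[1], config$isi_range[2])
    onset_ms <- 1000 + cumsum(c(0, (config$stimulus_duration + isi)[-n]))
    data.frame(sample = round(onset_ms * config$fs / 1000) + 1L,
               onset_ms = onset_ms, condition = cond,
               stringsAsFactors = FALSE)
  })
}

# Per-subject component amplitude offsets, shared across that subject's cells.
subject_component_offsets <- function(config, subject) {
  with_substream(config$seed, subject_id(subject), "subjvar", expr = {
    vapply(config$components,
           function(cmp) stats::rnorm(1, 0, cmp$inter_subject_sd), numeric(1))
  })
}

generate_recording <- function(config, subject, task,
                               contamination_window = c(100, 400),
                               contamination_threshold = 50) {
  fs <- config$fs
  events <- subject_sequence(config, subject)
  n_samples <- max(events$sample) + round(1 * fs)
  chans <- config$layout$name
  data <- matrix(0, nrow = length(chans), ncol = n_samples,
                 dimnames = list(chans, NULL))

  offsets <- subject_component_offsets(config, subject)
  half <- function(w) ceiling(w * fs / 1000)

  # Component signal: per component, one source time course summed over
  # events, then projected through the topography.
  for (ci in seq_along(config$components)) {
    cmp <- config$components[[ci]]
    nominal <- cmp$amplitude_by_cell[task, events$condition]
    present <- nominal != 0
    if (!any(present)) next
    jitter <- with_substream(config$seed, subject_id(subject), task,
                             "trialvar", cmp$name, expr = {
      stats::rnorm(nrow(events), 0, cmp$inter_trial_sd)
    })
    amps <- ifelse(present, nominal + offsets[ci] + jitter, 0)
    hw <- half(cmp$temporal_width)
    koff <- seq(-hw, hw)
    shape <- hann_bump(koff * 1000 / fs, 0, cmp$temporal_width, 1)
    src <- numeric(n_samples)
    peak_off <- round(cmp$peak_latency * fs / 1000)
    for (e in which(present)) {
      idx <- events$sample[e] + peak_off + koff
      ok <- idx >= 1 & idx <= n_samples
      src[idx[ok]] <- src[idx[ok]] + amps[e] * shape[ok]
    }
    topo <- cmp$topography[names(cmp$topography) %in% chans]
    if (!length(topo)) next
    data[names(topo), ] <- data[names(topo), , drop = FALSE] +
      outer(unname(topo), src)
  }

  # Channel noise: independent white + 1/f^alpha per channel.
  ns <- config$noise
  if (ns$white_sd > 0 || ns$pink_sd > 0) {
    noise <- with_substream(config$seed, subject_id(subject), task, "noise",
                            expr = {
      nz <- matrix(0, n_samples, length(chans))
      if (ns$white_sd > 0)
        nz <- nz + matrix(stats::rnorm(n_samples * length(chans),
                                       0, ns$white_sd),
                          n_samples, length(chans))
      if (ns$pink_sd > 0)
        nz <- nz + ns$pink_sd * pink_noise_matrix(n_samples, length(chans),
                                                  ns$pink_exponent)
      nz
    })
    data <- data + t(noise)
  }

  rec <- structure(list(subject = subject_id(subject), task = task,
                        data = data, fs = fs, events = events,
                        layout = config$layout,
                        contaminated_events = integer(0)),
                   class = "eeg_raw")

  if (config$blink$rate > 0) {
    rec <- inject_blinks(rec, config$blink,
                         seed = substream_seed(config$seed,
                                               subject_id(subject), task,
                                               "blinks"),
                         window = contamination_window,
                         threshold = contamination_threshold)
  }
  rec
}

#' @export
print.eeg_raw <- function(x, ...) {
  cat(sprintf("<eeg_raw> %s / %s: %d channels x %d samples @ %g Hz, %d events\n",
              x$subject, x$task, nrow(x$data), ncol(x$data), x$fs,
              nrow(x$events)))
  if (length(x$contaminated_events))
    cat(sprintf("  %d blink-contaminated event(s)\n",
                length(x$contaminated_events)))
  invisible(x)
}

#' Inject blink artifacts into a recording
#'
#' Blinks occur as a Poisson process at `spec$rate` per minute; each is a
#' raised-cosine deflection of `spec$amplitude` microvolts on VEOG, projected
#' onto the other channels with frontally-decaying weights. Returns the
#' recording plus exact ground truth: the indices of events whose epoch of
#' interest contains blink-driven EOG exceeding `threshold`, which equals
#' the set later rejected by the amplitude criterion whenever background EOG
#' noise is far below threshold.
#'
#' @param record An `eeg_raw` recording with a VEOG channel.
#' @param spec A [blink_spec()].
#' @param seed Seed for blink timing.
#' @param window Epoch window `c(pre, post)` in ms used for bookkeeping.
#' @param threshold Contamination threshold, microvolts.
#' @param times Optional explicit blink centre times (ms) overriding the
#'   Poisson draw (used for targeted tests).
#' @return The recording with blinks added and `contaminated_events` set.
#' @export
inject_blinks <- function(record, spec, seed = 1L, window = c(100, 400),
                          threshold = 50, times = NULL) {
  chans <- rownames(record$data)
  if (!"VEOG" %in% chans) stop("VEOG channel required for blink injection")
  fs <- record$fs
  n <- ncol(record$data)
  dur_min <- n / fs / 60

  if (is.null(times)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    n_blinks <- stats::rpois(1, spec$rate * dur_min)
    times <- sort(stats::runif(n_blinks, 0, n / fs * 1000))
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }

  proj <- blink_projection(spec, record$layout)
  hw <- ceiling(spec$width * fs / 1000)
  koff <- seq(-hw, hw)
  shape <- hann_bump(koff * 1000 / fs, 0, spec$width, spec$amplitude)

  veog_blink <- numeric(n)  # blink-only VEOG trace for exact bookkeeping
  for (tm in times) {
    c0 <- round(tm * fs / 1000) + 1L
    idx <- c0 + koff
    ok <- idx >= 1 & idx <= n
    if (!any(ok)) next
    veog_blink[idx[ok]] <- veog_blink[idx[ok]] + shape[ok]
    for (ch in names(proj)) {
      record$data[ch, idx[ok]] <- record$data[ch, idx[ok]] +
        proj[[ch]] * shape[ok]
    }
  }

  pre_s <- round(window[1] * fs / 1000)
  post_s <- round(window[2] * fs / 1000)
  contaminated <- which(vapply(seq_len(nrow(record$events)), function(e) {
    i0 <- record$events$sample[e]
    idx <- max(1, i0 - pre_s):min(n, i0 + post_s)
    max(abs(veog_blink[idx])) > threshold
  }, logical(1)))

  record$contaminated_events <- contaminated
  record
}

# Projection weights of a blink onto each channel (VEOG has weight
# veog_projection; others decay with distance from the frontal pole).
blink_projection <- function(spec, layout) {
  if (!is.null(spec$scalp_projection)) {
    w <- as.list(spec$scalp_projection)
    w$VEOG <- spec$veog_projection
    return(w)
  }
  frontal <- layout[layout$name %in% c("FPZ", "FP1", "FP2"), c("x", "y", "z")]
  if (nrow(frontal) == 0)
    frontal <- layout[layout$name == "VEOG", c("x", "y", "z")]
  ref <- colMeans(frontal)
  w <- list()
  for (i in seq_len(nrow(layout))) {
    nm <- layout$name[i]
    if (nm == "VEOG") { w[[nm]] <- spec$veog_projection; next }
    d <- sqrt(sum((unlist(layout[i, c("x", "y", "z")]) - ref)^2))
    w[[nm]] <- 0.6 * exp(-d / 0.07)
  }
  w
}

#' Simulate behavioral trial logs
#'
#' Per-trial correctness (Bernoulli with subject-level logit variability) and
#' reaction times (Gaussian around task means with subject and trial
#' variability) for the three tasks. Defaults encode the study's qualitative
#' pattern: accuracy highest in the KF task and lowest in the CC task;
#' responses fastest in KF and slowest in CC.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per task.
#' @param tasks Task labels.
#' @param accuracy Named task-mean probabilities of a correct response.
#' @param rt_mean Named task-mean reaction times, ms.
#' @param subject_acc_sd SD of the subject effect on the logit of accuracy.
#' @param subject_rt_sd,trial_rt_sd SDs of subject and trial RT effects, ms.
#' @param seed Seed.
#' @return Data frame: `subject`, `task`, `trial`, `correct` (0/1),
#'   `rt_ms`.
#' @export
simulate_behavior <- function(n_subjects = 14, n_trials = 60,
                              tasks = c("KF", "CC", "PC"),
                              accuracy = c(KF = 0.95, CC = 0.80, PC = 0.85),
                              rt_mean = c(KF = 450, CC = 560, PC = 520),
                              subject_acc_sd = 0.25,
                              subject_rt_sd = 30, trial_rt_sd = 100,
                              seed = 1L) {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    acc_off <- with_substream(seed, subject_id(s), "behav-subj",
                              expr = stats::rnorm(2))
    for (tk in tasks) {
      dat <- with_substream(seed, subject_id(s), tk, "behav", expr = {
        p <- stats::plogis(stats::qlogis(accuracy[[tk]]) +
                             subject_acc_sd * acc_off[1])
        correct <- stats::rbinom(n_trials, 1, p)
        rt <- stats::rnorm(n_trials, rt_mean[[tk]] +
                             subject_rt_sd * acc_off[2], trial_rt_sd)
        data.frame(subject = subject_id(s), task = tk,
                   trial = seq_len(n_trials), correct = correct,
                   rt_ms = pmax(rt, 150), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- dat
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
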