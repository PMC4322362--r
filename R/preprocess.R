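## ERP preprocessing chain: epoch -> reject -> re-reference -> filter ->
## baseline -> average, in the order the analysis prescribes.

#' Cut a continuous recording into stimulus-locked epochs
#'
#' The epoch of interest spans `-pre` to `+post` ms around each event,
#' inclusive of both endpoint samples (251 samples at 500 Hz for the default
#' 100/400 ms window), padded by `pad` ms on both sides so that later
#' filtering transients fall outside the window of interest. Time 0 is the
#' sample at the event index.
#'
#' @param record An `eeg_raw` recording.
#' @param pre,post Epoch-of-interest extent, ms (positive numbers).
#' @param pad Padding retained on each side, ms.
#' @return Named list (one `eeg_epochs` per condition present in the event
#'   table). Each holds `epochs` (trial x channel x time array, microvolts),
#'   `time_axis` (ms, padded extent), `pad` (ms), `event_index` (row of the
#'   recording's event table each trial came from), and bookkeeping fields.
#' @export
cut_epochs <- function(record, pre = 100, post = 400, pad = 300) {
  fs <- record$fs
  pre_s <- round(pre * fs / 1000)
  post_s <- round(post * fs / 1000)
  pad_s <- round(pad * fs / 1000)
  offs <- seq(-(pre_s + pad_s), post_s + pad_s)
  n <- ncol(record$data)
  ev <- record$events
  bad <- which(ev$sample - (pre_s + pad_s) < 1 |
                 ev$sample + post_s + pad_s > n)
  if (length(bad))
    stop("event(s) without a full padded epoch inside the record: ",
         paste(bad, collapse = ", "))
  time_axis <- offs * 1000 / fs
  chans <- rownames(record$data)
  out <- list()
  for (cond in unique(ev$condition)) {
    rows <- which(ev$condition == cond)
    arr <- array(NA_real_, dim = c(length(rows), length(chans), length(offs)),
                 dimnames = list(NULL, chans, NULL))
    for (i in seq_along(rows))
      arr[i, , ] <- record$data[, ev$sample[rows[i]] + offs, drop = FALSE]
    out[[cond]] <- structure(list(subject = record$subject,
                                  task = record$task, condition = cond,
                                  epochs = arr, fs = fs,
                                  time_axis = time_axis,
                                  pre = pre, post = post, pad = pad,
                                  event_index = rows,
                                  layout = record$layout),
                             class = "eeg_epochs")
  }
  out
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %s / %s / %s: %d epochs x %d channels, %g..%g ms (pad %g)\n",
              x$subject, x$task, x$condition, dim(x$epochs)[1],
              dim(x$epochs)[2], -x$pre, x$post, x$pad))
  invisible(x)
}

# Index range of the epoch of interest within the padded time axis.
interest_index <- function(epochs) {
  which(epochs$time_axis >= -epochs$pre - 1e-9 &
          epochs$time_axis <= epochs$post + 1e-9)
}

#' Reject epochs with large EOG amplitude
#'
#' An epoch is removed iff the maximum absolute value over the named EOG
#' channels within the epoch of interest (padding excluded) strictly exceeds
#' the threshold ("exceeding +/-50 microvolts"); an epoch peaking exactly at
#' the threshold is retained. Retained epochs are passed through unchanged.
#'
#' @param epochs An `eeg_epochs` object.
#' @param eog_channels EOG channel names; all must be present.
#' @param threshold Rejection threshold, microvolts.
#' @return List with `epochs` (the retained subset) and `rejected`
#'   (positions within the input epoch set, possibly empty).
#' @export
reject_eog_epochs <- function(epochs, eog_channels = c("HEOG", "VEOG"),
                              threshold = 50) {
  miss <- setdiff(eog_channels, dimnames(epochs$epochs)[[2]])
  if (length(miss))
    stop("EOG channel(s) missing from epochs: ", paste(miss, collapse = ", "))
  ii <- interest_index(epochs)
  sub <- epochs$epochs[, eog_channels, ii, drop = FALSE]
  peak <- apply(abs(sub), 1, max)
  rejected <- which(peak > threshold)
  kept <- epochs
  if (length(rejected)) {
    kept$epochs <- epochs$epochs[-rejected, , , drop = FALSE]
    kept$event_index <- epochs$event_index[-rejected]
  }
  list(epochs = kept, rejected = rejected)
}

#' Re-reference epochs to the average reference
#'
#' Subtracts, at every sample of every epoch, the mean over scalp channels.
#' EOG channels are excluded from the reference set and left unreferenced
#' (they are only used for rejection, which runs earlier in the chain).
#'
#' @param epochs An `eeg_epochs` object.
#' @param scalp_channels Channels forming the reference set; defaults to the
#'   layout's `scalp` role.
#' @return The re-referenced `eeg_epochs`.
#' @export
rereference_average <- function(epochs, scalp_channels = NULL) {
  chans <- dimnames(epochs$epochs)[[2]]
  if (is.null(scalp_channels))
    scalp_channels <- intersect(chans,
                                epochs$layout$name[epochs$layout$role == "scalp"])
  scalp_channels <- intersect(scalp_channels, chans)
  if (length(scalp_channels) < 2)
    stop("average reference needs at least 2 scalp channels")
  sub <- epochs$epochs[, scalp_channels, , drop = FALSE]
  ref <- colMeans(aperm(sub, c(2, 1, 3)))  # trial x time mean over channels
  for (ch in scalp_channels)
    epochs$epochs[, ch, ] <- epochs$epochs[, ch, ] - ref
  epochs
}

#' Frequency response of the zero-phase band-pass filter
#'
#' The filter is applied in the frequency domain with an exactly zero-phase,
#' real response: unity in the pass band, raised-cosine transitions of width
#' `lo` Hz around the low edge and `trans_hi` Hz around the high edge, zero
#' outside (the DC bin is always zero).
#'
#' @param f Frequencies, Hz.
#' @param lo,hi Band edges, Hz.
#' @param trans_hi Transition width at the high edge, Hz.
#' @return Gain in `[0, 1]` at each frequency.
#' @export
bandpass_response <- function(f, lo = 0.5, hi = 30, trans_hi = 5) {
  ramp <- function(x) 0.5 * (1 - cos(pi * pmin(pmax(x, 0), 1)))
  lo1 <- lo / 2; lo2 <- 1.5 * lo
  hi1 <- hi - trans_hi / 2; hi2 <- hi + trans_hi / 2
  g <- ramp((f - lo1) / (lo2 - lo1)) * (1 - ramp((f - hi1) / (hi2 - hi1)))
  g[f <= 0] <- 0
  g
}

# Zero-phase FFT band-pass of the rows of a matrix (series along columns).
fft_bandpass_rows <- function(m, fs, lo, hi, trans_hi = 5) {
  n <- ncol(m)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided axis folded to [0, fs/2]
  h <- bandpass_response(f, lo, hi, trans_hi)
  spec <- stats::mvfft(t(m))
  Re(t(stats::mvfft(spec * h, inverse = TRUE))) / n
}

#' Zero-phase band-pass filter epochs
#'
#' Applied over the full padded epoch, before the padding is trimmed, so
#' transition transients fall outside the epoch of interest. The realization
#' is a frequency-domain multiplication with a real, non-negative response
#' ([bandpass_response()]), hence exactly zero phase: a symmetric test pulse
#' keeps its peak latency.
#'
#' @param epochs An `eeg_epochs` object.
#' @param lo,hi Band edges, Hz (requires `hi < fs/2`).
#' @param trans_hi Transition width at the high edge, Hz.
#' @return The filtered `eeg_epochs`.
#' @export
bandpass <- function(epochs, lo = 0.5, hi = 30, trans_hi = 5) {
  if (hi >= epochs$fs / 2)
    stop("high edge ", hi, " Hz must be below the Nyquist frequency ",
         epochs$fs / 2, " Hz")
  d <- dim(epochs$epochs)
  dn <- dimnames(epochs$epochs)
  m <- matrix(aperm(epochs$epochs, c(3, 1, 2)), nrow = d[3])  # time x series
  filt <- fft_bandpass_rows(t(m), epochs$fs, lo, hi, trans_hi)
  epochs$epochs <- aperm(array(t(filt), dim = c(d[3], d[1], d[2])),
                         c(2, 3, 1))
  dimnames(epochs$epochs) <- dn
  epochs
}

#' Baseline-correct epochs
#'
#' Removes, from every channel of every epoch, the mean over the baseline
#' window (default -100..0 ms, endpoints included).
#'
#' @param epochs An `eeg_epochs` object.
#' @param window Baseline window `c(from, to)`, ms.
#' @return The corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(-100, 0)) {
  bi <- which(epochs$time_axis >= window[1] - 1e-9 &
                epochs$time_axis <= window[2] + 1e-9)
  if (!length(bi)) stop("empty baseline window")
  d <- dim(epochs$epochs)
  base <- rowMeans(matrix(epochs$epochs[, , bi, drop = FALSE],
                          nrow = d[1] * d[2]))  # per (trial, channel)
  epochs$epochs <- epochs$epochs - as.vector(base)  # recycles over time dim
  epochs
}

#' Average epochs into a subject-level ERP
#'
#' Point-wise arithmetic mean over epochs; the padding is trimmed so the ERP
#' covers exactly the epoch of interest.
#'
#' @param epochs An `eeg_epochs` object with at least one epoch.
#' @return An `eeg_erp`: `erp` (channel x time matrix), `time_axis` (ms),
#'   `n_epochs_averaged`, and identification fields.
#' @export
average_erp <- function(epochs) {
  n <- dim(epochs$epochs)[1]
  if (n < 1)
    stop("no epochs to average in cell ", epochs$subject, "/", epochs$task,
         "/", epochs$condition)
  ii <- interest_index(epochs)
  erp <- colMeans(epochs$epochs[, , ii, drop = FALSE])  # channel x time
  rownames(erp) <- dimnames(epochs$epochs)[[2]]
  structure(list(subject = epochs$subject, task = epochs$task,
                 condition = epochs$condition, erp = erp,
                 time_axis = epochs$time_axis[ii], fs = epochs$fs,
                 n_epochs_averaged = n, layout = epochs$layout),
            class = "eeg_erp")
}

#' @export
print.eeg_erp <- function(x, ...) {
  cat(sprintf("<eeg_erp> %s / %s / %s: %d channels x %d samples (%g..%g ms), %d epochs averaged\n",
              x$subject, x$task, x$condition, nrow(x$erp), ncol(x$erp),
              min(x$time_axis), max(x$time_axis), x$n_epochs_averaged))
  invisible(x)
}

#' Plot a subject-level ERP
#'
#' @param x An `eeg_erp`.
#' @param channels Channels to draw (default PO5/PO6 when present).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.eeg_erp <- function(x, channels = intersect(c("PO5", "PO6"),
                                                 rownames(x$erp)), ...) {
  if (!length(channels)) channels <- rownames(x$erp)[1]
  graphics::matplot(x$time_axis, t(x$erp[channels, , drop = FALSE]),
                    type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "amplitude (microvolts)", ...)
  graphics::abline(v = 0, h = 0, col = "grey70")
  graphics::legend("topright", legend = channels, lty = 1,
                   col = seq_along(channels), bty = "n")
  invisible(x)
}

#' Run the full preprocessing chain on one recording
#'
#' Applies, in order: epoching, EOG-based rejection, average reference,
#' zero-phase band-pass, baseline correction, and averaging — producing one
#' ERP per condition plus per-cell epoch counts.
#'
#' @param record An `eeg_raw` recording.
#' @param config A [pipeline_config()] supplying stage parameters.
#' @return List with `erps` (named by condition), `counts` (data frame:
#'   condition, kept, rejected), and `rejected_events` (global event-table
#'   indices of rejected epochs).
#' @export
preprocess_recording <- function(record, config = pipeline_config()) {
  sets <- cut_epochs(record, pre = config$pre, post = config$post,
                     pad = config$pad)
  erps <- list()
  counts <- list()
  rejected_events <- integer(0)
  for (cond in names(sets)) {
    rj <- reject_eog_epochs(sets[[cond]], threshold = config$eog_threshold)
    rejected_events <- c(rejected_events,
                         sets[[cond]]$event_index[rj$rejected])
    ep <- rereference_average(rj$epochs)
    ep <- bandpass(ep, lo = config$band[1], hi = config$band[2])
    ep <- baseline_correct(ep, window = config$baseline)
    erps[[cond]] <- average_erp(ep)
    counts[[cond]] <- data.frame(condition = cond,
                                 kept = dim(rj$epochs$epochs)[1],
                                 rejected = length(rj$rejected))
  }
  list(erps = erps, counts = do.call(rbind, counts),
       rejected_events = sort(rejected_events))
}
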