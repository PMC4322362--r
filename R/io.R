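## File interchange: events TSV, a documented array-on-disk raw container
## with JSON sidecar, minimal EDF (16-bit) read/write, and YAML configs.

#' Write / read an events table
#'
#' Tab-separated with columns `onset_sample`, `onset_ms`, `condition`,
#' `task`, `subject`. Onset samples must be strictly increasing; violations
#' are rejected with the offending row number.
#'
#' @param record An `eeg_raw` recording.
#' @param path Output path.
#' @return `write_events` returns `path` invisibly; `read_events` returns
#'   the validated data frame.
#' @export
write_events <- function(record, path) {
  ev <- data.frame(onset_sample = record$events$sample,
                   onset_ms = record$events$onset_ms,
                   condition = record$events$condition,
                   task = record$task, subject = record$subject)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("onset_sample", "onset_ms", "condition", "task", "subject")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("events file missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(diff(ev$onset_sample) <= 0)
  if (length(bad))
    stop("event onsets not strictly increasing at row ", bad[1] + 1)
  ev
}

#' Write / read a raw recording in the package container
#'
#' The container is an array-on-disk layout: `<stem>.dat` holds the
#' channel x sample matrix as little-endian float64 in channel-major order,
#' and `<stem>.json` is a sidecar with dimensions, channel names and roles,
#' sampling rate, identification, and the event table. The round trip is
#' bit-exact.
#'
#' @param record An `eeg_raw` recording.
#' @param stem Path without extension.
#' @return `write_raw_container` returns `stem` invisibly;
#'   `read_raw_container` returns the `eeg_raw`.
#' @export
write_raw_container <- function(record, stem) {
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(record$data), con, size = 8, endian = "little")
  meta <- list(n_channels = nrow(record$data), n_samples = ncol(record$data),
               channels = rownames(record$data),
               roles = record$layout$role[match(rownames(record$data),
                                                record$layout$name)],
               fs = record$fs, subject = record$subject, task = record$task,
               events = record$events,
               contaminated_events = record$contaminated_events,
               order = "channel-major", dtype = "float64-le")
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_raw_container
#' @export
read_raw_container <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  data <- matrix(x, nrow = meta$n_channels,
                 dimnames = list(meta$channels, NULL))
  layout <- data.frame(name = meta$channels, role = meta$roles,
                       x = NA_real_, y = NA_real_, z = NA_real_)
  structure(list(subject = meta$subject, task = meta$task, data = data,
                 fs = meta$fs, events = as.data.frame(meta$events),
                 layout = layout,
                 contaminated_events = as.integer(meta$contaminated_events)),
            class = "eeg_raw")
}

#' Write / read an epoch set in the package container
#'
#' Same array-on-disk layout as the raw container: `<stem>.dat` holds the
#' trial x channel x time array as little-endian float64 in R's
#' column-major order, `<stem>.json` the dimensions, axes and cell
#' identification. Bit-exact round trip.
#'
#' @param epochs An `eeg_epochs` object.
#' @param stem Path without extension.
#' @return `write_epochs_container` returns `stem` invisibly;
#'   `read_epochs_container` the `eeg_epochs` (without layout coordinates).
#' @export
write_epochs_container <- function(epochs, stem) {
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$epochs), con, size = 8, endian = "little")
  meta <- list(dim = dim(epochs$epochs),
               channels = dimnames(epochs$epochs)[[2]],
               roles = epochs$layout$role[match(dimnames(epochs$epochs)[[2]],
                                                epochs$layout$name)],
               fs = epochs$fs, time_axis = epochs$time_axis,
               pre = epochs$pre, post = epochs$post, pad = epochs$pad,
               subject = epochs$subject, task = epochs$task,
               condition = epochs$condition,
               event_index = epochs$event_index)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_epochs_container
#' @export
read_epochs_container <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = prod(meta$dim), size = 8,
               endian = "little")
  arr <- array(x, dim = meta$dim,
               dimnames = list(NULL, meta$channels, NULL))
  structure(list(subject = meta$subject, task = meta$task,
                 condition = meta$condition, epochs = arr, fs = meta$fs,
                 time_axis = meta$time_axis, pre = meta$pre,
                 post = meta$post, pad = meta$pad,
                 event_index = as.integer(meta$event_index),
                 layout = data.frame(name = meta$channels,
                                     role = meta$roles,
                                     x = NA_real_, y = NA_real_,
                                     z = NA_real_)),
            class = "eeg_epochs")
}

## --- minimal EDF (European Data Format, 16-bit) ------------------------

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write / read a recording as EDF
#'
#' Minimal EDF implementation: one data record per second, all channels at
#' the sampling rate, 16-bit samples scaled between the per-channel physical
#' extrema (physical dimension uV). The final partial record is zero-padded;
#' the true sample count is recorded in the reserved header field and used
#' by the reader to trim. Quantization limits the round trip to the 16-bit
#' amplitude resolution.
#'
#' @param record An `eeg_raw` recording (fs must be a positive integer).
#' @param path Output `.edf` path.
#' @return `write_edf` returns `path` invisibly; `read_edf` returns an
#'   `eeg_raw` (without events, which travel separately as TSV).
#' @export
write_edf <- function(record, path) {
  fs <- record$fs
  if (fs != round(fs) || fs <= 0) stop("EDF export needs integer fs")
  nchan <- nrow(record$data)
  ns <- ncol(record$data)
  nrec <- ceiling(ns / fs)
  # round the physical range up to the 2 decimals stored in the header so
  # the writer and reader use identical scale factors
  phys_max <- ceiling(pmax(apply(abs(record$data), 1, max), 1e-2) * 100) / 100
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(record$subject, 80)
  wr(paste("task", record$task), 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (nchan + 1), 8)
  wr(paste("nsamples", ns), 44)  # reserved: true sample count
  wr(nrec, 8); wr(1, 8); wr(nchan, 4)
  for (ch in rownames(record$data)) wr(ch, 16)
  for (i in seq_len(nchan)) wr("", 80)
  for (i in seq_len(nchan)) wr("uV", 8)
  for (i in seq_len(nchan)) wr(sprintf("%.2f", -phys_max[i]), 8)
  for (i in seq_len(nchan)) wr(sprintf("%.2f", phys_max[i]), 8)
  for (i in seq_len(nchan)) wr(-32768, 8)
  for (i in seq_len(nchan)) wr(32767, 8)
  for (i in seq_len(nchan)) wr("", 80)
  for (i in seq_len(nchan)) wr(fs, 8)
  for (i in seq_len(nchan)) wr("", 32)
  padded <- cbind(record$data,
                  matrix(0, nchan, nrec * fs - ns))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(nchan)) {
      dig <- round((padded[i, idx] + phys_max[i]) /
                     (2 * phys_max[i]) * 65535) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)
  subject <- rd(80)
  task <- sub("^task ", "", rd(80))
  rd(8); rd(8); rd(8)
  reserved <- rd(44)
  nrec <- as.integer(rd(8)); rd(8)
  nchan <- as.integer(rd(4))
  labels <- vapply(seq_len(nchan), function(i) rd(16), "")
  for (i in seq_len(nchan)) rd(80)
  for (i in seq_len(nchan)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(nchan), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nchan), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nchan), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nchan), function(i) rd(8), ""))
  for (i in seq_len(nchan)) rd(80)
  spr <- as.integer(vapply(seq_len(nchan), function(i) rd(8), ""))
  for (i in seq_len(nchan)) rd(32)
  fs <- spr[1]
  data <- matrix(0, nchan, nrec * fs, dimnames = list(labels, NULL))
  for (r in seq_len(nrec)) {
    for (i in seq_len(nchan)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      data[i, ((r - 1) * fs + 1):(r * fs)] <-
        pmin_[i] + (dig - dmin[i]) / (dmax[i] - dmin[i]) *
          (pmax_[i] - pmin_[i])
    }
  }
  if (grepl("^nsamples ", reserved)) {
    ns <- as.integer(sub("^nsamples ", "", reserved))
    data <- data[, seq_len(ns), drop = FALSE]
  }
  structure(list(subject = subject, task = task, data = data, fs = fs,
                 events = data.frame(sample = integer(0),
                                     onset_ms = numeric(0),
                                     condition = character(0)),
                 layout = data.frame(name = labels, role = "scalp",
                                     x = NA_real_, y = NA_real_,
                                     z = NA_real_),
                 contaminated_events = integer(0)),
            class = "eeg_raw")
}

## --- YAML configuration -------------------------------------------------

sim_config_to_list <- function(cfg) {
  list(
    n_subjects = cfg$n_subjects, tasks = cfg$tasks,
    conditions = cfg$conditions, n_trials_per_task = cfg$n_trials_per_task,
    fs = cfg$fs, stimulus_duration = cfg$stimulus_duration,
    isi_range = cfg$isi_range,
    channels = cfg$layout$name,
    components = lapply(cfg$components, function(cmp) list(
      name = cmp$name, peak_latency = cmp$peak_latency,
      temporal_width = cmp$temporal_width,
      amplitude_by_cell = stats::setNames(
        lapply(rownames(cmp$amplitude_by_cell), function(tk)
          as.list(stats::setNames(cmp$amplitude_by_cell[tk, ],
                                  colnames(cmp$amplitude_by_cell)))),
        rownames(cmp$amplitude_by_cell)),
      topography = as.list(cmp$topography),
      inter_subject_sd = cmp$inter_subject_sd,
      inter_trial_sd = cmp$inter_trial_sd)),
    noise = unclass(cfg$noise),
    blink = Filter(Negate(is.null), unclass(cfg$blink)),
    seed = cfg$seed, min_epoch_span = cfg$min_epoch_span)
}

#' Write / read a simulation configuration as YAML
#'
#' The YAML document mirrors the configuration field-for-field (the montage
#' is stored as the channel-name list and resolved against a layout on
#' read). Unknown keys are rejected.
#'
#' @param cfg A [simulation_config()].
#' @param path YAML path.
#' @param layout Layout against which channel names are resolved on read.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns the `simulation_config`.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(sim_config_to_list(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path, layout = read_layout()) {
  raw <- yaml::read_yaml(path)
  known <- c("n_subjects", "tasks", "conditions", "n_trials_per_task", "fs",
             "stimulus_duration", "isi_range", "channels", "components",
             "noise", "blink", "seed", "min_epoch_span")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  comps <- lapply(raw$components, function(cl) {
    tasks <- names(cl$amplitude_by_cell)
    conds <- names(cl$amplitude_by_cell[[1]])
    m <- do.call(rbind, lapply(cl$amplitude_by_cell, function(row)
      unlist(row)[conds]))
    dimnames(m) <- list(tasks, conds)
    component_spec(cl$name, cl$peak_latency, cl$temporal_width, m,
                   unlist(cl$topography), cl$inter_subject_sd,
                   cl$inter_trial_sd)
  })
  bl <- raw$blink
  simulation_config(
    n_subjects = raw$n_subjects, tasks = unlist(raw$tasks),
    conditions = unlist(raw$conditions),
    n_trials_per_task = raw$n_trials_per_task, fs = raw$fs,
    stimulus_duration = raw$stimulus_duration,
    isi_range = unlist(raw$isi_range),
    layout = layout_subset(layout, unlist(raw$channels)),
    components = comps,
    noise = do.call(noise_spec, raw$noise),
    blink = blink_spec(rate = bl$rate, amplitude = bl$amplitude,
                       width = bl$width,
                       veog_projection = bl$veog_projection %||% 1,
                       scalp_projection =
                         if (!is.null(bl$scalp_projection))
                           unlist(bl$scalp_projection)),
    seed = raw$seed, min_epoch_span = raw$min_epoch_span %||% 500)
}

#' Write / read a subject-level ERP as TSV
#'
#' Plain-text channel x time matrix (first column `channel`, remaining
#' columns the time axis in ms) with a JSON sidecar carrying sampling rate,
#' cell identification and the epoch count.
#'
#' @param erp An `eeg_erp`.
#' @param stem Path without extension.
#' @return `write_erp_tsv` returns `stem` invisibly; `read_erp_tsv` the
#'   `eeg_erp` (without layout coordinates).
#' @export
write_erp_tsv <- function(erp, stem) {
  tab <- data.frame(channel = rownames(erp$erp), erp$erp,
                    check.names = FALSE)
  names(tab)[-1] <- format(erp$time_axis, trim = TRUE)
  utils::write.table(tab, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(subject = erp$subject, task = erp$task,
                            condition = erp$condition, fs = erp$fs,
                            n_epochs_averaged = erp$n_epochs_averaged,
                            time_axis = erp$time_axis),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_erp_tsv
#' @export
read_erp_tsv <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  tab <- utils::read.table(paste0(stem, ".tsv"), header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$channel
  colnames(m) <- NULL
  structure(list(subject = meta$subject, task = meta$task,
                 condition = meta$condition, erp = m,
                 time_axis = meta$time_axis, fs = meta$fs,
                 n_epochs_averaged = meta$n_epochs_averaged,
                 layout = data.frame(name = rownames(m), role = "scalp",
                                     x = NA_real_, y = NA_real_,
                                     z = NA_real_)),
            class = "eeg_erp")
}

#' Export a significance mask as TSV
#'
#' One row per surviving run: `channel`, `start_ms`, `end_ms`.
#'
#' @param map An `erp_statmap` with `mask_temporal` filled in.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tsv <- function(map, path) {
  if (is.null(map$mask_temporal))
    stop("apply temporal_extent_mask() first")
  rows <- list()
  for (ch in seq_len(nrow(map$mask_temporal))) {
    runs <- mask_runs(map$mask_temporal[ch, ], map$time_axis)
    if (nrow(runs)) {
      runs <- cbind(channel = map$channels[ch], runs)
      rows[[length(rows) + 1L]] <- runs
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(channel = character(0), start_ms = numeric(0),
                         end_ms = numeric(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
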