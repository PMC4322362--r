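## Mass-univariate group statistics: difference waves, point-wise paired t
## maps with a temporal-extent criterion, and t-value topographic maps with a
## spatial-extent criterion.

#' Difference wave between two ERPs
#'
#' Point-wise subtraction `a - b` of two condition ERPs of the same subject
#' on identical channel sets and time axes (e.g. Kanizsa minus control).
#'
#' @param a,b `eeg_erp` objects.
#' @param label Contrast label; composed from the operands by default.
#' @return An `erp_diff`: `data` (channel x time, microvolts), `time_axis`,
#'   `subject`, `label`.
#' @export
difference_wave <- function(a, b, label = NULL) {
  if (!identical(a$subject, b$subject))
    stop("operands belong to different subjects")
  check_axes(a$erp, a$time_axis, b$erp, b$time_axis)
  if (is.null(label))
    label <- sprintf("%s %s-%s", a$task, a$condition, b$condition)
  structure(list(subject = a$subject, label = label,
                 data = a$erp - b$erp, time_axis = a$time_axis,
                 fs = a$fs, layout = a$layout),
            class = "erp_diff")
}

#' Double difference of two difference waves
#'
#' Compares a K-C effect between tasks, e.g. `(KF K-C) - (CC K-C)`.
#'
#' @param d1,d2 `erp_diff` objects of the same subject.
#' @param label Contrast label; composed from the operands by default.
#' @return An `erp_diff`.
#' @export
double_difference <- function(d1, d2, label = NULL) {
  if (!identical(d1$subject, d2$subject))
    stop("operands belong to different subjects")
  check_axes(d1$data, d1$time_axis, d2$data, d2$time_axis)
  if (is.null(label)) label <- sprintf("(%s)-(%s)", d1$label, d2$label)
  structure(list(subject = d1$subject, label = label,
                 data = d1$data - d2$data, time_axis = d1$time_axis,
                 fs = d1$fs, layout = d1$layout),
            class = "erp_diff")
}

check_axes <- function(ma, ta, mb, tb) {
  if (!identical(dim(ma), dim(mb)) ||
      !identical(rownames(ma), rownames(mb)))
    stop("channel sets do not match")
  if (length(ta) != length(tb) || max(abs(ta - tb)) > 1e-9)
    stop("time axes do not match")
  invisible(TRUE)
}

#' @export
print.erp_diff <- function(x, ...) {
  cat(sprintf("<erp_diff> %s [%s]: %d channels x %d samples\n",
              x$subject, x$label, nrow(x$data), ncol(x$data)))
  invisible(x)
}

# Stack a list of per-subject difference waves into n x channel x time.
stack_waves <- function(waves) {
  stopifnot(length(waves) >= 1)
  for (w in waves[-1])
    check_axes(waves[[1]]$data, waves[[1]]$time_axis, w$data, w$time_axis)
  arr <- array(NA_real_,
               dim = c(length(waves), nrow(waves[[1]]$data),
                       ncol(waves[[1]]$data)),
               dimnames = list(NULL, rownames(waves[[1]]$data), NULL))
  for (i in seq_along(waves)) arr[i, , ] <- waves[[i]]$data
  arr
}

# Vectorized one-sample t against zero over the first margin of an array.
# Zero-variance convention: t = 0, p = 1 when the mean is also (numerically)
# zero; otherwise t = +/-Inf, p = 0. A `zero_variance` attribute counts the
# affected points.
one_sample_t_array <- function(arr) {
  n <- dim(arr)[1]
  m <- colMeans(arr)
  centred <- arr - array(rep(m, each = n), dim(arr))
  ss <- colSums(centred^2)
  s <- sqrt(ss / (n - 1))
  se <- s / sqrt(n)
  t <- m / se
  zv <- se < .Machine$double.eps^0.75
  nz <- zv & abs(m) < .Machine$double.eps^0.5
  t[zv] <- sign(m[zv]) * Inf
  t[nz] <- 0
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  p[nz] <- 1
  list(t = t, p = p, df = n - 1L, n_zero_variance = sum(zv))
}

#' Point-wise paired t map over subjects
#'
#' At every (channel, time) point, a one-sample t test of the subjects'
#' difference-wave values against zero (equivalent to a paired t between the
#' two conditions), two-tailed, df = n - 1. Points with zero variance across
#' subjects get t = 0, p = 1 when the mean is also zero and p = 0 otherwise,
#' with a count recorded in the map (documented convention rather than
#' silent NaN).
#'
#' @param waves List of per-subject `erp_diff` objects (>= 3 subjects) on
#'   identical axes.
#' @param label Map label; taken from the first wave by default.
#' @return An `erp_statmap` with `t`, `p` (channel x time), `df`,
#'   `time_axis`, and empty significance masks (see
#'   [temporal_extent_mask()]).
#' @export
pointwise_paired_t <- function(waves, label = NULL) {
  if (length(waves) < 3) stop("need at least 3 subjects")
  arr <- stack_waves(waves)
  res <- one_sample_t_array(arr)
  if (res$n_zero_variance > 0)
    warning(res$n_zero_variance,
            " point(s) had zero variance across subjects")
  structure(list(label = label %||% waves[[1]]$label,
                 t = res$t, p = res$p, df = res$df,
                 n_zero_variance = res$n_zero_variance,
                 time_axis = waves[[1]]$time_axis, fs = waves[[1]]$fs,
                 channels = rownames(waves[[1]]$data),
                 layout = waves[[1]]$layout,
                 alpha = NA_real_, min_run_samples = NA_integer_,
                 mask_raw = NULL, mask_temporal = NULL),
            class = "erp_statmap")
}

#' Temporal-extent significance criterion
#'
#' Per channel, a time point survives iff it belongs to a run of consecutive
#' `p < alpha` points at least `min_run_samples` long (the study's criterion:
#' p < 0.05 for at least 10 consecutive points, i.e. 20 ms at 500 Hz).
#'
#' @param map An `erp_statmap`.
#' @param alpha Point-wise significance level.
#' @param min_run_samples Minimum run length in samples (>= 1).
#' @return The map with `mask_raw` (`p < alpha`) and `mask_temporal`
#'   (after the run-length criterion) filled in.
#' @export
temporal_extent_mask <- function(map, alpha = 0.05, min_run_samples = 10) {
  if (min_run_samples < 1) stop("min_run_samples must be >= 1")
  raw <- map$p < alpha
  keep <- t(apply(raw, 1, run_filter, min_run = min_run_samples))
  if (nrow(raw) == 1) keep <- matrix(keep, nrow = 1)
  dimnames(keep) <- dimnames(raw)
  map$alpha <- alpha
  map$min_run_samples <- as.integer(min_run_samples)
  map$mask_raw <- raw
  map$mask_temporal <- keep
  map
}

# Keep only TRUE-runs of length >= min_run in a logical vector.
run_filter <- function(x, min_run) {
  r <- rle(as.logical(x))
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}

#' Convert the temporal-extent criterion from ms to samples
#'
#' @param duration_ms Minimum duration, ms (> 0).
#' @param fs Sampling rate, Hz.
#' @return Integer number of samples (nearest-integer rounding); 20 ms at
#'   500 Hz gives 10 samples.
#' @export
min_run_from_duration <- function(duration_ms = 20, fs = 500) {
  if (fs <= 0) stop("fs must be > 0")
  if (duration_ms <= 0) stop("duration must be > 0")
  as.integer(round(duration_ms * fs / 1000))
}

#' @export
print.erp_statmap <- function(x, ...) {
  cat(sprintf("<erp_statmap> [%s]: %d channels x %d samples, df = %d\n",
              x$label, nrow(x$t), ncol(x$t), x$df))
  if (!is.null(x$mask_temporal))
    cat(sprintf("  alpha %g, min run %d samples: %d significant points\n",
                x$alpha, x$min_run_samples, sum(x$mask_temporal)))
  invisible(x)
}

#' Plot a statistical map
#'
#' Image of the t values (channels x time) with surviving points of the
#' temporal-extent mask overlaid.
#'
#' @param x An `erp_statmap`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.erp_statmap <- function(x, ...) {
  ch <- seq_len(nrow(x$t))
  graphics::image(x$time_axis, ch, t(x$t), xlab = "time (ms)",
                  ylab = "channel", col = grDevices::hcl.colors(64, "Blue-Red"),
                  ...)
  if (!is.null(x$mask_temporal) && any(x$mask_temporal)) {
    idx <- which(x$mask_temporal, arr.ind = TRUE)
    graphics::points(x$time_axis[idx[, 2]], idx[, 1], pch = ".", col = "black")
  }
  invisible(x)
}

#' Topographic t map with spatial-extent criterion
#'
#' Per electrode, a one-sample t of the subjects' mean difference-wave value
#' within a time window against zero; t values (not microvolts) form the
#' topographic map. The significance mask keeps only adjacency-connected
#' sets of at least `min_extent` significant electrodes (the study's
#' two-electrode criterion).
#'
#' @param waves List of per-subject `erp_diff` objects.
#' @param window Time window `c(from, to)`, ms; must lie within the axis.
#' @param layout An `eeg_layout` providing electrode adjacency.
#' @param alpha Point-wise significance level.
#' @param min_extent Minimum connected significant-electrode count.
#' @param label Map label.
#' @return An `erp_topomap`: per-electrode `t`, `p`, logical `mask`, and the
#'   surviving connected `clusters`.
#' @export
topo_stat_map <- function(waves, window, layout = waves[[1]]$layout,
                          alpha = 0.05, min_extent = 2, label = NULL) {
  ta <- waves[[1]]$time_axis
  if (window[1] < min(ta) - 1e-9 || window[2] > max(ta) + 1e-9)
    stop("window outside the time axis")
  wi <- which(ta >= window[1] - 1e-9 & ta <= window[2] + 1e-9)
  arr <- stack_waves(waves)
  scalp <- intersect(dimnames(arr)[[2]],
                     layout$name[layout$role == "scalp"])
  vals <- apply(arr[, scalp, wi, drop = FALSE], c(1, 2), mean)
  res <- one_sample_t_array(array(vals, dim = c(dim(vals), 1),
                                  dimnames = list(NULL, scalp, NULL)))
  t_e <- res$t[, 1]; p_e <- res$p[, 1]
  names(t_e) <- names(p_e) <- scalp
  sig <- names(p_e)[p_e < alpha]
  adj <- attr(layout, "adjacency")[scalp, scalp, drop = FALSE]
  comps <- adjacency_components(adj, sig)
  keep <- comps[vapply(comps, length, integer(1)) >= min_extent]
  mask <- stats::setNames(scalp %in% unlist(keep), scalp)
  structure(list(label = label %||% waves[[1]]$label, window = window,
                 t = t_e, p = p_e, df = res$df, mask = mask,
                 clusters = keep, alpha = alpha,
                 min_extent = as.integer(min_extent), layout = layout),
            class = "erp_topomap")
}

#' @export
print.erp_topomap <- function(x, ...) {
  cat(sprintf("<erp_topomap> [%s] %g..%g ms: %d electrodes, %d significant after extent >= %d\n",
              x$label, x$window[1], x$window[2], length(x$t), sum(x$mask),
              x$min_extent))
  for (cl in x$clusters)
    cat("  cluster:", paste(cl, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a topographic t map
#'
#' Schematic head-frame scatter of electrode t values (colour-coded), with
#' electrodes surviving the spatial-extent criterion circled.
#'
#' @param x An `erp_topomap`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.erp_topomap <- function(x, ...) {
  lay <- x$layout[match(names(x$t), x$layout$name), ]
  pal <- grDevices::hcl.colors(64, "Blue-Red")
  tv <- x$t
  tv[!is.finite(tv)] <- max(abs(tv[is.finite(tv)]), 1) * sign(tv[!is.finite(tv)])
  rng <- max(abs(tv), 1e-9)
  col <- pal[pmax(1, pmin(64, round((tv + rng) / (2 * rng) * 63) + 1))]
  graphics::plot(lay$x, lay$y, pch = 21, bg = col, cex = 2, asp = 1,
                 xlab = "x (m)", ylab = "y (m)", ...)
  sel <- x$mask[names(x$t)]
  if (any(sel))
    graphics::points(lay$x[sel], lay$y[sel], pch = 1, cex = 3, lwd = 2)
  graphics::text(lay$x, lay$y, names(x$t), pos = 3, cex = 0.5)
  invisible(x)
}

#' Find significant time windows on an electrode-average series
#'
#' Averages the difference waves over the electrodes of interest (matching
#' how PO5/PO6 enter the follow-up ANOVAs), runs the point-wise paired t with
#' the temporal-extent criterion on the resulting single series, and reports
#' the surviving contiguous intervals as closed ms ranges at sample
#' resolution.
#'
#' @param waves List of per-subject `erp_diff` objects.
#' @param electrodes Electrodes of interest (averaged before testing).
#' @param alpha Point-wise significance level.
#' @param min_run_samples Temporal-extent criterion, samples.
#' @param per_electrode If `TRUE`, test each electrode separately and report
#'   per-electrode interval tables instead of the electrode-average mode.
#' @return Data frame with columns `start_ms`, `end_ms` (and `channel` in
#'   per-electrode mode); zero rows when nothing survives.
#' @export
find_significant_windows <- function(waves, electrodes = c("PO5", "PO6"),
                                     alpha = 0.05, min_run_samples = 10,
                                     per_electrode = FALSE) {
  miss <- setdiff(electrodes, rownames(waves[[1]]$data))
  if (length(miss))
    stop("electrode(s) not present: ", paste(miss, collapse = ", "))
  roi <- if (per_electrode) waves else lapply(waves, function(w) {
    w$data <- matrix(colMeans(w$data[electrodes, , drop = FALSE]), nrow = 1,
                     dimnames = list("ROI", NULL))
    w
  })
  if (per_electrode)
    roi <- lapply(roi, function(w) {
      w$data <- w$data[electrodes, , drop = FALSE]; w
    })
  map <- temporal_extent_mask(pointwise_paired_t(roi), alpha = alpha,
                              min_run_samples = min_run_samples)
  out <- list()
  for (ch in rownames(map$mask_temporal)) {
    runs <- mask_runs(map$mask_temporal[ch, ], map$time_axis)
    if (nrow(runs) && per_electrode) runs$channel <- ch
    out[[ch]] <- runs
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(start_ms = numeric(0),
                                      end_ms = numeric(0))
  rownames(res) <- NULL
  res
}

mask_runs <- function(mask, time_axis) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  data.frame(start_ms = time_axis[starts[sel]], end_ms = time_axis[ends[sel]])
}
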