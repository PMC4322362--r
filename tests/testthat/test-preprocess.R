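test_that("epoching yields the 251-sample epoch of interest with exact counts", {
  cfg <- silent_config(n_subjects = 2, n_trials = 20)
  rec <- icerp:::generate_recording(cfg, 1, "KF")
  rec$data[] <- 3.25  # constant record
  sets <- cut_epochs(rec)
  expect_setequal(names(sets), c("K", "C"))
  for (cond in names(sets)) {
    ep <- sets[[cond]]
    ii <- icerp:::interest_index(ep)
    expect_length(ii, 251)  # 0.5 s x 500 Hz + 1, inclusive endpoints
    expect_equal(dim(ep$epochs)[1], 10)
    expect_equal(ep$time_axis[ii][1], -100)
    expect_equal(ep$time_axis[ii][251], 400)
    # constant record -> every epoch constant at that value
    expect_equal(max(abs(ep$epochs - 3.25)), 0)
  }
  # time 0 is the sample at the event index
  i0 <- which(abs(sets$K$time_axis) < 1e-9)
  expect_length(i0, 1)
})

test_that("events without a full padded window are rejected by name", {
  cfg <- silent_config(n_subjects = 2, n_trials = 6)
  rec <- icerp:::generate_recording(cfg, 1, "KF")
  rec$data <- rec$data[, 1:(rec$events$sample[6] + 10)]  # truncate tail
  expect_error(cut_epochs(rec), "event\\(s\\) without a full padded epoch.*6")
})

test_that("EOG rejection is strict-threshold on the epoch of interest only", {
  arr <- array(0, dim = c(3, 3, 551),
               dimnames = list(NULL, c("PO5", "HEOG", "VEOG"), NULL))
  arr[1, "VEOG", 300] <- 60    # inside epoch of interest -> rejected
  arr[2, "VEOG", 300] <- 50    # exactly at threshold -> retained
  arr[3, "VEOG", 10] <- 500    # only inside padding -> retained
  ep <- make_epochs(arr)
  out <- reject_eog_epochs(ep)
  expect_equal(out$rejected, 1L)
  expect_equal(dim(out$epochs$epochs)[1], 2)
  # retained data values are untouched (original epoch 2 is now first)
  expect_equal(unname(out$epochs$epochs[1, "VEOG", 300]), 50)
  expect_error(reject_eog_epochs(ep, eog_channels = "NOPE"), "missing")
})

test_that("rejection counts equal the simulator's contamination ground truth", {
  cfg <- tiny_config(n_subjects = 2, n_trials = 30, seed = 9,
                     noise = noise_spec(white_sd = 0.1, pink_sd = 0.1),
                     blink_rate = 30)
  rec <- icerp:::generate_recording(cfg, 1, "KF")
  truth <- rec$contaminated_events
  expect_gt(length(truth), 0)  # rate chosen so some blinks land on epochs
  sets <- cut_epochs(rec)
  rejected <- sort(unname(unlist(lapply(sets, function(ep)
    ep$event_index[reject_eog_epochs(ep)$rejected]))))
  expect_equal(rejected, truth)
  kept <- sum(vapply(sets, function(ep)
    dim(reject_eog_epochs(ep)$epochs$epochs)[1], numeric(1)))
  expect_equal(kept, 30 - length(truth))
})

test_that("average reference zeroes the scalp mean and is idempotent", {
  set.seed(4)
  arr <- array(rnorm(2 * 4 * 551), dim = c(2, 4, 551),
               dimnames = list(NULL, c("PO5", "PO6", "POZ", "VEOG"), NULL))
  ep <- make_epochs(arr)
  out <- rereference_average(ep)
  scalp <- c("PO5", "PO6", "POZ")
  expect_lt(max(abs(apply(out$epochs[, scalp, , drop = FALSE], c(1, 3),
                          mean))), 1e-12)
  # idempotence
  out2 <- rereference_average(out)
  expect_equal(out2$epochs, out$epochs, tolerance = 1e-12)
  # VEOG untouched
  expect_equal(out$epochs[, "VEOG", ], arr[, "VEOG", ])
})

test_that("two-channel toy re-references to +/-(a-b)/2", {
  arr <- array(0, dim = c(1, 2, 551), dimnames = list(NULL, c("A", "B"), NULL))
  arr[1, "A", ] <- 3; arr[1, "B", ] <- 1
  ep <- make_epochs(arr, roles = c("scalp", "scalp"))
  out <- rereference_average(ep)
  expect_equal(unique(out$epochs[1, "A", ]), 1)   #  (a-b)/2
  expect_equal(unique(out$epochs[1, "B", ]), -1)  # -(a-b)/2
})

test_that("band-pass is zero-phase with the specified magnitude response", {
  fs <- 500
  ta <- seq(-400, 700, by = 1000 / fs)
  ii <- ta >= -100 & ta <= 400
  as_ep <- function(x) {
    arr <- array(x, dim = c(1, 1, length(x)), dimnames = list(NULL, "CZ", NULL))
    make_epochs(arr, roles = "scalp")
  }
  # 10 Hz unit sinusoid passes at unit gain
  sine <- sin(2 * pi * 10 * ta / 1000)
  out <- bandpass(as_ep(sine))$epochs[1, 1, ]
  expect_gt(max(abs(out[ii])), 0.95)
  expect_lt(max(abs(out[ii])), 1.05)
  # DC is removed almost entirely
  dc <- bandpass(as_ep(rep(1, length(ta))))$epochs[1, 1, ]
  expect_lt(max(abs(dc[ii])), 0.05)
  # symmetric pulse keeps its peak latency (zero phase)
  pulse <- icerp:::hann_bump(ta, 150, 60, 1)
  outp <- bandpass(as_ep(pulse))$epochs[1, 1, ]
  expect_lte(abs(ta[which.max(outp)] - 150), 1000 / fs)
  # Nyquist guard
  expect_error(bandpass(as_ep(sine), hi = 250), "Nyquist")
})

test_that("baseline correction zeroes the baseline mean", {
  fs <- 500
  ta <- seq(-400, 700, by = 1000 / fs)
  bi <- ta >= -100 & ta <= 0
  as_ep <- function(x) {
    arr <- array(x, dim = c(1, 1, length(x)), dimnames = list(NULL, "CZ", NULL))
    make_epochs(arr, roles = "scalp")
  }
  # constant value c -> all zeros
  out <- baseline_correct(as_ep(rep(7, length(ta))))
  expect_equal(max(abs(out$epochs)), 0)
  # zero baseline, 5 uV after onset -> unchanged
  step <- ifelse(ta > 0, 5, 0)
  out2 <- baseline_correct(as_ep(step))
  expect_equal(out2$epochs[1, 1, ], step)
  # linear ramp -> baseline mean exactly zero afterwards
  ramp <- seq_along(ta) * 0.01
  out3 <- baseline_correct(as_ep(ramp))
  expect_lt(abs(mean(out3$epochs[1, 1, bi])), 1e-12)
  expect_error(baseline_correct(as_ep(ramp), window = c(900, 950)), "empty")
})

test_that("averaging is the point-wise mean with padding trimmed", {
  arr <- array(0, dim = c(2, 1, 551), dimnames = list(NULL, "CZ", NULL))
  v <- sin(seq_len(551) / 20)
  arr[1, 1, ] <- v; arr[2, 1, ] <- v
  ep <- make_epochs(arr, roles = "scalp")
  erp <- average_erp(ep)
  expect_equal(dim(erp$erp), c(1L, 251L))
  expect_equal(erp$n_epochs_averaged, 2)
  expect_equal(erp$erp[1, ], v[icerp:::interest_index(ep)])
  # +v and -v average to zero
  arr[2, 1, ] <- -v
  expect_equal(max(abs(average_erp(make_epochs(arr, roles = "scalp"))$erp)), 0)
  # zero epochs after rejection -> error naming the cell
  ep0 <- ep; ep0$epochs <- ep$epochs[0, , , drop = FALSE]
  expect_error(average_erp(ep0), "S01/KF/K")
})

test_that("noise-free injected component survives the chain at its amplitude", {
  cfg <- silent_config(n_subjects = 2, n_trials = 20)
  # re-enable only the early IC component at -1.5 uV
  cfg$components <- default_components(early_amplitude = -1.5,
                                       later_amplitude = 0)
  cfg$components <- lapply(cfg$components, function(cmp) {
    if (cmp$name %in% c("P1", "N1")) cmp$amplitude_by_cell[] <- 0
    cmp$inter_subject_sd <- 0; cmp$inter_trial_sd <- 0
    cmp
  })
  rec <- icerp:::generate_recording(cfg, 1, "KF")
  pp <- preprocess_recording(rec, pipeline_config(sim = cfg))
  dw <- difference_wave(pp$erps$K, pp$erps$C)
  peak <- dw$data["PO5", which.min(abs(dw$time_axis - 148))]
  # average reference and the 30 Hz edge shave a predictable fraction;
  # the oracle is the chain applied to the known injected bump
  shrink <- local({
    lay <- cfg$layout
    topo <- cfg$components[[3]]$topography
    w <- topo[names(topo) %in% lay$name[lay$role == "scalp"]]
    1 - sum(w) / sum(lay$role == "scalp")
  })
  # oracle: the shrunken bump pushed through an independently coded
  # zero-phase band-pass (same documented response, plain fft arithmetic)
  ta_pad <- seq(-400, 700, by = 2)
  bump <- icerp:::hann_bump(ta_pad, 148, 18, -1.5 * shrink)
  N <- length(bump)
  f <- pmin((seq_len(N) - 1) * 500 / N, 500 - (seq_len(N) - 1) * 500 / N)
  ramp <- function(x) 0.5 * (1 - cos(pi * pmin(pmax(x, 0), 1)))
  H <- ramp((f - 0.25) / 0.5) * (1 - ramp((f - 27.5) / 5))
  H[f <= 0] <- 0
  filt <- Re(stats::fft(stats::fft(bump) * H, inverse = TRUE)) / N
  keep <- ta_pad >= -100 & ta_pad <= 400
  base <- mean(filt[ta_pad >= -100 & ta_pad <= 0])
  oracle_peak <- min(filt[keep] - base)
  expect_equal(unname(peak), oracle_peak, tolerance = 0.02)
  expect_equal(unname(dw$data["PO5", which.min(abs(dw$time_axis + 50))]), 0,
               tolerance = 0.02)
})

test_that("difference of ERPs equals ERP of differences (chain linearity)", {
  cfg <- tiny_config(n_subjects = 2, n_trials = 12, seed = 3)
  rec <- icerp:::generate_recording(cfg, 1, "KF")
  config <- pipeline_config(sim = cfg)
  sets <- cut_epochs(rec, pre = config$pre, post = config$post,
                     pad = config$pad)
  chain <- function(ep) {
    ep <- rereference_average(ep)
    ep <- bandpass(ep, config$band[1], config$band[2])
    baseline_correct(ep, config$baseline)
  }
  a <- chain(sets$K); b <- chain(sets$C)
  expect_equal(dim(a$epochs)[1], dim(b$epochs)[1])  # no rejection configured
  # ERP(K) - ERP(C) == ERP of the trial-wise K-C differences
  d1 <- average_erp(a)$erp - average_erp(b)$erp
  diff_ep <- sets$K
  diff_ep$epochs <- sets$K$epochs - sets$C$epochs
  d2 <- average_erp(chain(diff_ep))$erp
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("re-reference and filter stages commute (linear-phase documentation)", {
  cfg <- tiny_config(n_subjects = 2, n_trials = 8, seed = 6)
  rec <- icerp:::generate_recording(cfg, 1, "CC")
  sets <- cut_epochs(rec)
  a <- bandpass(rereference_average(sets$K))
  b <- rereference_average(bandpass(sets$K))
  scalp <- cfg$layout$name[cfg$layout$role == "scalp"]
  expect_lt(max(abs(a$epochs[, scalp, ] - b$epochs[, scalp, ])), 1e-6)
})
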