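# Shared fixtures: tiny configurations and hand-rolled oracles.

tiny_config <- function(n_subjects = 2, n_trials = 8, seed = 42,
                        blink_rate = 0, noise = noise_spec(), ...) {
  scaled_config(n_subjects = n_subjects, n_trials_per_task = n_trials,
                seed = seed, noise = noise,
                blink = blink_spec(rate = blink_rate), ...)
}

silent_config <- function(n_subjects = 2, n_trials = 8, seed = 42, ...) {
  # no components, no noise, no blinks: all-zero data channels
  cfg <- tiny_config(n_subjects = n_subjects, n_trials = n_trials,
                     seed = seed,
                     noise = noise_spec(white_sd = 0, pink_sd = 0), ...)
  cfg$components <- lapply(cfg$components, function(cmp) {
    cmp$amplitude_by_cell[] <- 0
    cmp$inter_subject_sd <- 0
    cmp$inter_trial_sd <- 0
    cmp
  })
  cfg
}

# Build an eeg_epochs object directly from an array (trial x channel x time).
make_epochs <- function(arr, fs = 500, pre = 100, post = 400, pad = 300,
                        roles = NULL) {
  chans <- dimnames(arr)[[2]]
  if (is.null(roles)) roles <- ifelse(chans %in% c("HEOG", "VEOG"),
                                      "eog", "scalp")
  pre_s <- round(pre * fs / 1000); post_s <- round(post * fs / 1000)
  pad_s <- round(pad * fs / 1000)
  stopifnot(dim(arr)[3] == pre_s + post_s + 2 * pad_s + 1)
  structure(list(subject = "S01", task = "KF", condition = "K",
                 epochs = arr, fs = fs,
                 time_axis = seq(-(pre_s + pad_s), post_s + pad_s) * 1000 / fs,
                 pre = pre, post = post, pad = pad,
                 event_index = seq_len(dim(arr)[1]),
                 layout = data.frame(name = chans, role = roles,
                                     x = 0, y = 0, z = 0)),
            class = "eeg_epochs")
}

# Difference wave built directly from a channel x time matrix.
make_wave <- function(data, subject = "S01", fs = 500, label = "toy",
                      time_axis = NULL) {
  if (is.null(time_axis)) time_axis <- seq(0, ncol(data) - 1) * 1000 / fs
  structure(list(subject = subject, label = label, data = data,
                 time_axis = time_axis, fs = fs, layout = NULL),
            class = "erp_diff")
}

# Stack per-subject matrices (same dims) into a list of erp_diff waves.
make_wave_set <- function(mats, fs = 500) {
  lapply(seq_along(mats), function(i)
    make_wave(mats[[i]], subject = sprintf("S%02d", i), fs = fs))
}

# Brute-force one-sample t oracle (textbook arithmetic, scalar loops).
oracle_one_sample_t <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / (n - 1)
  t <- m / sqrt(v / n)
  p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
  list(t = t, p = p, df = n - 1)
}

# Brute-force within-subject ANOVA decomposition with explicit loops
# (one or two factors; Y is subject x cell with cells in a-major order).
oracle_rm_anova <- function(Y, a, b = 1) {
  n <- nrow(Y)
  g <- mean(Y)
  idxA <- rep(seq_len(a), each = b)
  idxB <- rep(seq_len(b), times = a)
  m_a <- sapply(seq_len(a), function(i) mean(Y[, idxA == i, drop = FALSE]))
  m_b <- sapply(seq_len(b), function(j) mean(Y[, idxB == j, drop = FALSE]))
  m_s <- rowMeans(Y)
  SS_A <- 0
  for (i in seq_len(a)) SS_A <- SS_A + n * b * (m_a[i] - g)^2
  SS_AS <- 0
  for (s in seq_len(n)) for (i in seq_len(a)) {
    mas <- mean(Y[s, idxA == i])
    SS_AS <- SS_AS + b * (mas - m_a[i] - m_s[s] + g)^2
  }
  out <- list(A = list(SS = SS_A, SSe = SS_AS,
                       F = (SS_A / (a - 1)) / (SS_AS / ((a - 1) * (n - 1)))))
  if (b > 1) {
    SS_B <- 0
    for (j in seq_len(b)) SS_B <- SS_B + n * a * (m_b[j] - g)^2
    SS_BS <- 0
    for (s in seq_len(n)) for (j in seq_len(b)) {
      mbs <- mean(Y[s, idxB == j])
      SS_BS <- SS_BS + a * (mbs - m_b[j] - m_s[s] + g)^2
    }
    SS_AB <- 0
    for (i in seq_len(a)) for (j in seq_len(b)) {
      mab <- mean(Y[, idxA == i & idxB == j])
      SS_AB <- SS_AB + n * (mab - m_a[i] - m_b[j] + g)^2
    }
    SS_tot <- sum((Y - g)^2)
    SS_S <- a * b * sum((m_s - g)^2)
    SS_ABS <- SS_tot - SS_A - SS_B - SS_AB - SS_S - SS_AS - SS_BS
    out$B <- list(SS = SS_B, SSe = SS_BS,
                  F = (SS_B / (b - 1)) / (SS_BS / ((b - 1) * (n - 1))))
    out$AB <- list(SS = SS_AB, SSe = SS_ABS,
                   F = (SS_AB / ((a - 1) * (b - 1))) /
                     (SS_ABS / ((a - 1) * (b - 1) * (n - 1))))
  }
  out
}

# Textbook Greenhouse-Geisser epsilon from a k x k covariance matrix,
# via the classical element-wise formula.
oracle_gg_epsilon <- function(S) {
  k <- nrow(S)
  mean_diag <- mean(diag(S))
  mean_all <- mean(S)
  row_means <- rowMeans(S)
  num <- (k * (mean_diag - mean_all))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * mean_all^2)
  num / den
}
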