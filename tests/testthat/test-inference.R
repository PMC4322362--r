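ic_waveset <- function(n = 10, noise_sd = 0.05, early = -1.5, later = -2,
                       seed = 33) {
  ta <- seq(-100, 400, by = 2)
  shape <- icerp:::hann_bump(ta, 148, 18, early) +
    icerp:::hann_bump(ta, 262, 28, later)
  set.seed(seed)
  mats <- lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(2 * length(ta), 0, noise_sd), 2, length(ta),
                dimnames = list(c("PO5", "PO6"), NULL))
    m + rep(shape, each = 2)
  })
  lapply(make_wave_set(mats), function(w) { w$time_axis <- ta; w })
}

test_that("LOSO windows are independent of the left-out subject", {
  waves <- ic_waveset(n = 8)
  w1 <- loso_define_windows(waves)
  # arbitrarily corrupt subject 3's data: its own windows must not move
  waves2 <- waves
  waves2[[3]]$data <- waves2[[3]]$data + matrix(rnorm(length(waves2[[3]]$data),
                                                      0, 50),
                                                nrow(waves2[[3]]$data))
  w2 <- suppressWarnings(loso_define_windows(waves2))
  s3 <- "S03"
  expect_identical(w1[w1$subject == s3, ], w2[w2$subject == s3, ])
})

test_that("LOSO recovers injected windows with high overlap in every fold", {
  waves <- ic_waveset(n = 10)
  wins <- loso_define_windows(waves)
  expect_true(all(wins$ok))
  early <- wins[wins$component == "early", ]
  later <- wins[wins$component == "later", ]
  for (i in seq_len(nrow(early)))
    expect_gte(icerp:::interval_overlap(c(early$start_ms[i],
                                          early$end_ms[i]), c(130, 166)),
               0.8)
  for (i in seq_len(nrow(later)))
    expect_gte(icerp:::interval_overlap(c(later$start_ms[i],
                                          later$end_ms[i]), c(234, 290)),
               0.8)
})

test_that("null data flags folds as having no interval", {
  # moderately smooth null series mimic filtered noise
  set.seed(44)
  ta <- seq(-100, 400, by = 2)
  nrep <- 40
  flagged <- vapply(seq_len(nrep), function(r) {
    mats <- lapply(1:8, function(i) {
      x <- stats::filter(rnorm(length(ta) + 20), rep(1 / 4, 4), sides = 1)
      m <- matrix(x[21:(20 + length(ta))], 1, length(ta),
                  dimnames = list("PO5", NULL))
      rbind(PO5 = m[1, ], PO6 = m[1, ] + rnorm(length(ta), 0, 0.5))
    })
    waves <- lapply(make_wave_set(mats), function(w) { w$time_axis <- ta; w })
    wins <- suppressWarnings(loso_define_windows(waves))
    all(!wins$ok)
  }, logical(1))
  expect_gte(mean(flagged), 0.95)
})

test_that("amplitude extraction averages window x hemisphere correctly", {
  waves <- ic_waveset(n = 6, noise_sd = 0)
  wins <- suppressWarnings(loso_define_windows(waves))
  amp <- extract_amplitudes(list(KF = waves), wins)
  # constant-by-symmetry: left and right hemispheres identical here
  left <- amp$amplitude[amp$hemisphere == "left"]
  right <- amp$amplitude[amp$hemisphere == "right"]
  expect_equal(left, right, tolerance = 1e-12)
  # early window mean of the -1.5 uV Hann bump over ~130..166 ms:
  # oracle = mean of the known shape over the selected window
  ta <- waves[[1]]$time_axis
  e1 <- wins[wins$component == "early" & wins$subject == "S01", ]
  ti <- which(ta >= e1$start_ms - 1e-9 & ta <= e1$end_ms + 1e-9)
  shape <- icerp:::hann_bump(ta, 148, 18, -1.5) +
    icerp:::hann_bump(ta, 262, 28, -2)
  oracle <- mean(shape[ti])
  got <- amp$amplitude[amp$subject == "S01" & amp$component == "early" &
                         amp$hemisphere == "left"]
  expect_equal(got, oracle, tolerance = 1e-12)
  # a constant wave yields that constant whatever the window
  cwaves <- lapply(waves, function(w) { w$data[] <- 0.7; w })
  campl <- extract_amplitudes(list(KF = cwaves), wins)
  expect_equal(unique(round(campl$amplitude, 12)), 0.7)
})

test_that("RM-ANOVA reproduces the design's degrees of freedom", {
  set.seed(1)
  d <- expand.grid(subject = 1:14, task = c("KF", "CC", "PC"))
  d$amplitude <- rnorm(nrow(d))
  a <- rm_anova(d, within = "task")
  expect_equal(a$df_num, 2)
  expect_equal(a$df_den, 26)
  # all cells equal -> F = 0, p = 1
  d$amplitude <- 3
  a0 <- suppressWarnings(rm_anova(d, within = "task"))
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)
})

test_that("RM-ANOVA matches the brute-force decomposition and aov", {
  set.seed(77)
  for (rep in 1:8) {
    n <- sample(4:8, 1); a <- sample(2:4, 1); b <- sample(1:3, 1)
    d <- expand.grid(subject = factor(seq_len(n)),
                     task = paste0("T", seq_len(a)),
                     hemisphere = paste0("H", seq_len(b)))
    d$amplitude <- rnorm(nrow(d))
    within <- if (b > 1) c("task", "hemisphere") else "task"
    res <- rm_anova(d, within = within)
    Y <- matrix(NA_real_, n, a * b)
    for (s in seq_len(n)) for (i in seq_len(a)) for (j in seq_len(b))
      Y[s, (i - 1) * b + j] <-
        d$amplitude[d$subject == s & d$task == paste0("T", i) &
                      d$hemisphere == paste0("H", j)]
    o <- oracle_rm_anova(Y, a, b)
    expect_equal(res$SS_effect[1], o$A$SS, tolerance = 1e-8)
    expect_equal(res$SS_error[1], o$A$SSe, tolerance = 1e-8)
    expect_equal(res$F[1], o$A$F, tolerance = 1e-8)
    if (b > 1) {
      expect_equal(res$SS_effect[2], o$B$SS, tolerance = 1e-8)
      expect_equal(res$F[2], o$B$F, tolerance = 1e-8)
      expect_equal(res$SS_effect[3], o$AB$SS, tolerance = 1e-8)
      expect_equal(res$F[3], o$AB$F, tolerance = 1e-8)
    }
    # independent route: stats::aov error strata
    form <- if (b > 1)
      amplitude ~ task * hemisphere + Error(subject / (task * hemisphere))
    else amplitude ~ task + Error(subject / task)
    sv <- summary(stats::aov(form, data = d))
    aov_task <- sv[["Error: subject:task"]][[1]]
    expect_equal(res$F[1], aov_task["task", "F value"], tolerance = 1e-8)
  }
})

test_that("partial eta squared is consistent with its definition", {
  set.seed(3)
  d <- expand.grid(subject = 1:8, task = c("a", "b", "c"))
  d$amplitude <- rnorm(24) + as.numeric(factor(d$task))
  a <- rm_anova(d, within = "task")
  expect_equal(a$partial_eta_sq,
               a$SS_effect / (a$SS_effect + a$SS_error))
  expect_true(all(a$partial_eta_sq >= 0 & a$partial_eta_sq <= 1))
})

test_that("GG epsilon matches the textbook estimator and its bounds", {
  # k = 2 is always spherical
  set.seed(10)
  expect_equal(gg_epsilon(cov(matrix(rnorm(40), 20, 2))), 1)
  # compound symmetry -> 1
  cs <- matrix(0.4, 5, 5); diag(cs) <- 1
  expect_equal(gg_epsilon(cs), 1)
  # random 4-level covariances vs the classical element-wise formula,
  # plus bounds, over many draws
  for (rep in 1:200) {
    X <- matrix(rnorm(10 * 4), 10, 4) %*% matrix(rnorm(16), 4, 4)
    S <- cov(X)
    e <- gg_epsilon(S)
    o <- oracle_gg_epsilon(S)
    expect_equal(e, min(max(o, 1 / 3), 1), tolerance = 1e-10)
    expect_gte(e, 1 / 3)
    expect_lte(e, 1)
  }
  expect_warning(gg_epsilon(matrix(0, 3, 3)), "singular")
})

test_that("post-hoc paired t matches t.test with the standard effect size", {
  set.seed(6)
  x <- rnorm(14, 1); y <- rnorm(14)
  r <- posthoc_paired_t(x, y)
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  expect_equal(r$df, 13L)
  expect_equal(r$eta_sq, r$t^2 / (r$t^2 + 13), tolerance = 1e-12)
  # identical members -> t = 0, eta^2 = 0
  r0 <- posthoc_paired_t(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$eta_sq, 0)
  expect_error(posthoc_paired_t(1, numeric(0)), "paired")
})

test_that("behavioral summary and ANOVA follow the trial-log contracts", {
  # all trials correct at 500 ms -> rate 1, mean RT 500
  log1 <- data.frame(subject = rep(c("S01", "S02"), each = 6),
                     task = rep(c("KF", "CC", "PC"), 4),
                     correct = 1, rt_ms = 500)
  tab <- behavioral_summarize(log1)
  expect_true(all(tab$correct_rate == 1))
  expect_true(all(tab$mean_rt == 500))
  # RT over correct trials only
  log2 <- data.frame(subject = "S01", task = "KF",
                     correct = c(1, 0, 1), rt_ms = c(400, 9000, 600))
  expect_equal(behavioral_summarize(log2)$mean_rt, 500)
  # task with zero correct trials -> error
  log3 <- data.frame(subject = "S01", task = "KF", correct = 0, rt_ms = 500)
  expect_error(behavioral_summarize(log3), "no correct trials")
  # dfs of the one-way ANOVA at the study size
  trials <- simulate_behavior(n_subjects = 14, n_trials = 40, seed = 8)
  ba <- behavioral_anova(behavioral_summarize(trials))
  expect_equal(ba$correct_rate$anova$df_num, 2)
  expect_equal(ba$correct_rate$anova$df_den, 26)
  expect_equal(unique(ba$mean_rt$posthoc$df), 13L)
})

test_that("behavioral post-hoc ordering is recovered across replicates", {
  hits <- vapply(1:30, function(r) {
    trials <- simulate_behavior(n_subjects = 14, n_trials = 400, seed = 100 + r)
    tab <- behavioral_summarize(trials)
    ph <- posthoc_pairs(tab, dv = "correct_rate", subject = "subject",
                        within = "task")
    # KF > CC, KF > PC significant; CC < PC significant
    ph$p[1] < 0.05 && ph$mean_diff[1] > 0 &&
      ph$p[2] < 0.05 && ph$mean_diff[2] > 0 &&
      ph$p[3] < 0.05 && ph$mean_diff[3] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Holm adjustment is available but off by default", {
  set.seed(9)
  d <- expand.grid(subject = 1:10, task = c("a", "b", "c"))
  d$amplitude <- rnorm(30)
  p0 <- posthoc_pairs(d)$p
  p1 <- posthoc_pairs(d, adjust = "holm")$p
  expect_true(all(p1 >= p0))
})
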