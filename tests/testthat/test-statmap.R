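test_that("difference waves subtract point-wise and compose labels", {
  erp <- function(cond, val) {
    structure(list(subject = "S01", task = "KF", condition = cond,
                   erp = matrix(val, 2, 5,
                                dimnames = list(c("PO5", "PO6"), NULL)),
                   time_axis = 0:4 * 2, fs = 500, layout = NULL,
                   n_epochs_averaged = 3),
              class = "eeg_erp")
  }
  d <- difference_wave(erp("K", 2), erp("C", 0.5))
  expect_equal(unique(as.vector(d$data)), 1.5)
  expect_equal(d$label, "KF K-C")
  # a = b -> all zero
  expect_equal(max(abs(difference_wave(erp("K", 1), erp("C", 1))$data)), 0)
  # double difference of identical waves is zero, with composed label
  dd <- double_difference(d, d)
  expect_equal(max(abs(dd$data)), 0)
  expect_equal(dd$label, "(KF K-C)-(KF K-C)")
  # axis mismatch rejected
  b <- erp("C", 1); b$time_axis <- b$time_axis + 1
  expect_error(difference_wave(erp("K", 1), b), "time axes")
})

test_that("point-wise t matches the brute-force oracle and t.test", {
  vals <- c(1.0, 1.1, 0.9, 1.2, 0.8)
  waves <- make_wave_set(lapply(vals, function(v) matrix(v, 1, 1,
    dimnames = list("PO5", NULL))))
  map <- pointwise_paired_t(waves)
  o <- oracle_one_sample_t(vals)
  expect_equal(unname(map$t[1, 1]), o$t, tolerance = 1e-12)
  expect_equal(unname(map$p[1, 1]), o$p, tolerance = 1e-12)
  expect_equal(map$df, 4L)
  tt <- t.test(vals)
  expect_equal(unname(map$t[1, 1]), unname(tt$statistic), tolerance = 1e-12)
  expect_equal(unname(map$p[1, 1]), tt$p.value, tolerance = 1e-12)
})

test_that("point-wise t equals the oracle on random small inputs", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:8, 1); nch <- sample(1:4, 1); nt <- sample(2:20, 1)
    mats <- lapply(seq_len(n), function(i)
      matrix(rnorm(nch * nt), nch, nt,
             dimnames = list(paste0("C", seq_len(nch)), NULL)))
    map <- pointwise_paired_t(make_wave_set(mats))
    for (ch in seq_len(nch)) for (tp in seq_len(nt)) {
      x <- vapply(mats, function(m) m[ch, tp], numeric(1))
      o <- oracle_one_sample_t(x)
      expect_equal(unname(map$t[ch, tp]), o$t, tolerance = 1e-10)
      expect_equal(unname(map$p[ch, tp]), o$p, tolerance = 1e-10)
    }
  }
})

test_that("point-wise t is sign-equivariant and handles degenerate inputs", {
  set.seed(5)
  mats <- lapply(1:6, function(i) matrix(rnorm(8), 2, 4,
    dimnames = list(c("A", "B"), NULL)))
  m1 <- pointwise_paired_t(make_wave_set(mats))
  m2 <- pointwise_paired_t(make_wave_set(lapply(mats, function(m) -m)))
  expect_equal(m2$t, -m1$t)
  expect_equal(m2$p, m1$p)
  # all-zero inputs: t = 0, p = 1 everywhere (zero-variance convention)
  zmats <- lapply(1:5, function(i) matrix(0, 1, 3,
    dimnames = list("A", NULL)))
  mz <- suppressWarnings(pointwise_paired_t(make_wave_set(zmats)))
  expect_true(all(mz$t == 0))
  expect_true(all(mz$p == 1))
  # constant non-zero: p = 0 with warning
  cmats <- lapply(1:5, function(i) matrix(2, 1, 3,
    dimnames = list("A", NULL)))
  expect_warning(mc <- pointwise_paired_t(make_wave_set(cmats)),
                 "zero variance")
  expect_true(all(mc$p == 0))
  expect_error(pointwise_paired_t(make_wave_set(zmats[1:2])), "at least 3")
})

test_that("temporal-extent criterion keeps only runs of the minimum length", {
  # craft p-values with runs of 9, 10, 12 and 3 significant samples
  p <- matrix(1, 3, 40, dimnames = list(c("A", "B", "C"), NULL))
  p["A", 5:13] <- 0.01          # 9 samples -> masked out
  p["B", 5:14] <- 0.01          # 10 samples -> survives intact
  p["C", c(2:13, 20:22)] <- 0.01  # 12 and 3 -> only the 12 survives
  map <- structure(list(t = p * 0, p = p, df = 13, time_axis = (0:39) * 2,
                        channels = rownames(p), fs = 500),
                   class = "erp_statmap")
  out <- temporal_extent_mask(map, alpha = 0.05, min_run_samples = 10)
  expect_false(any(out$mask_temporal["A", ]))
  expect_equal(which(out$mask_temporal["B", ]), 5:14)
  expect_equal(which(out$mask_temporal["C", ]), 2:13)
  # mask_temporal is a subset of mask_raw
  expect_true(all(!out$mask_temporal | out$mask_raw))
  expect_error(temporal_extent_mask(map, min_run_samples = 0), ">= 1")
})

test_that("temporal mask is monotone in the run-length criterion", {
  set.seed(12)
  mats <- lapply(1:8, function(i) matrix(rnorm(2 * 60, mean = 0.4), 2, 60,
    dimnames = list(c("A", "B"), NULL)))
  map <- pointwise_paired_t(make_wave_set(mats))
  prev <- NULL
  for (mr in c(1, 5, 10, 15)) {
    cur <- temporal_extent_mask(map, min_run_samples = mr)$mask_temporal
    if (!is.null(prev)) expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("min-run conversion rounds the duration criterion correctly", {
  expect_identical(min_run_from_duration(20, 500), 10L)
  expect_identical(min_run_from_duration(20, 250), 5L)
  expect_identical(min_run_from_duration(21, 500), 10L)  # nearest integer
  expect_error(min_run_from_duration(0, 500), "> 0")
  expect_error(min_run_from_duration(20, 0), "fs")
})

test_that("spatial-extent criterion drops isolated electrodes", {
  lay <- read_layout()
  chans <- c("PO5", "PO7", "FZ", "OZ", "POZ")
  set.seed(8)
  base <- lapply(1:10, function(i)
    matrix(rnorm(length(chans) * 20, 0, 0.3), length(chans), 20,
           dimnames = list(chans, NULL)))
  # strong effect at adjacent PO5/PO7 and at isolated FZ
  mats <- lapply(base, function(m) {
    m[c("PO5", "PO7"), ] <- m[c("PO5", "PO7"), ] + 2
    m["FZ", ] <- m["FZ", ] + 2
    m
  })
  waves <- lapply(make_wave_set(mats), function(w) { w$layout <- lay; w })
  tm <- topo_stat_map(waves, window = c(0, 38), layout = lay)
  expect_true(tm$mask[["PO5"]] && tm$mask[["PO7"]])
  expect_false(tm$mask[["FZ"]])   # significant but spatially isolated
  expect_lt(tm$p[["FZ"]], 0.05)
  # null data -> empty mask
  null_waves <- lapply(make_wave_set(base), function(w) { w$layout <- lay; w })
  tnull <- topo_stat_map(null_waves, window = c(0, 38), layout = lay)
  expect_equal(sum(tnull$mask), 0)
  expect_error(topo_stat_map(waves, window = c(-500, 0), layout = lay),
               "outside")
})

test_that("spatial mask is monotone in the extent criterion", {
  lay <- read_layout()
  chans <- c("PO3", "PO5", "PO7", "POZ", "O1")
  set.seed(15)
  mats <- lapply(1:10, function(i)
    matrix(rnorm(length(chans) * 10, 1, 1), length(chans), 10,
           dimnames = list(chans, NULL)))
  waves <- lapply(make_wave_set(mats), function(w) { w$layout <- lay; w })
  prev <- NULL
  for (me in 1:4) {
    cur <- topo_stat_map(waves, window = c(0, 18), layout = lay,
                         min_extent = me)$mask
    if (!is.null(prev)) expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("significant windows recover injected intervals and order them", {
  fs <- 500
  nt <- 251
  ta <- seq(-100, 400, by = 1000 / fs)
  shape1 <- icerp:::hann_bump(ta, 148, 18, -1.5)
  shape2 <- icerp:::hann_bump(ta, 262, 28, -2)
  set.seed(21)
  mats <- lapply(1:12, function(i) {
    m <- matrix(rnorm(2 * nt, 0, 0.05), 2, nt,
                dimnames = list(c("PO5", "PO6"), NULL))
    m["PO5", ] <- m["PO5", ] + shape1 + shape2
    m["PO6", ] <- m["PO6", ] + shape1 + shape2
    m
  })
  waves <- lapply(make_wave_set(mats), function(w) { w$time_axis <- ta; w })
  wins <- find_significant_windows(waves, electrodes = c("PO5", "PO6"))
  expect_equal(nrow(wins), 2)
  expect_lt(wins$end_ms[1], wins$start_ms[2])  # disjoint and ordered
  ov1 <- icerp:::interval_overlap(unlist(wins[1, ]), c(130, 166))
  ov2 <- icerp:::interval_overlap(unlist(wins[2, ]), c(234, 290))
  expect_gte(ov1, 0.8)
  expect_gte(ov2, 0.8)
  # null data -> empty table
  null_waves <- lapply(make_wave_set(lapply(1:12, function(i)
    matrix(rnorm(2 * nt, 0, 0.05), 2, nt,
           dimnames = list(c("PO5", "PO6"), NULL)))),
    function(w) { w$time_axis <- ta; w })
  expect_equal(nrow(find_significant_windows(null_waves,
                                             c("PO5", "PO6"))), 0)
  expect_error(find_significant_windows(waves, electrodes = "XX"),
               "not present")
})
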