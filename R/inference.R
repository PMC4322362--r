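## Leave-one-subject-out window definition, mean-amplitude extraction,
## repeated-measures ANOVA with Greenhouse-Geisser correction, and post-hoc
## paired tests with effect sizes.

#' Leave-one-subject-out definition of component time windows
#'
#' For each subject i, the early and later component windows are defined from
#' the other n - 1 subjects only (avoiding circular selection): their
#' difference waves are averaged over the electrodes of interest, tested
#' point-wise against zero with the temporal-extent criterion, and within
#' each component's search range the surviving interval with the largest
#' overlap with the range is selected (clipped to the range). Ties are broken
#' by the interval whose midpoint is nearest the range midpoint. Folds with
#' no surviving interval in range are flagged and excluded from that
#' component's amplitude table, with a warning.
#'
#' @param waves List of per-subject `erp_diff` objects (the window-defining
#'   task's K-C waves; >= 4 subjects).
#' @param electrodes Electrodes of interest, averaged before testing.
#' @param search_ranges Named list of ms ranges, e.g.
#'   `list(early = c(100, 200), later = c(200, 320))`.
#' @param alpha Point-wise significance level.
#' @param min_run_samples Temporal-extent criterion, samples.
#' @return A `loso_windows` data frame: `subject`, `component`, `start_ms`,
#'   `end_ms`, `ok` (FALSE for flagged folds, with `NA` window).
#' @export
loso_define_windows <- function(waves, electrodes = c("PO5", "PO6"),
                                search_ranges = list(early = c(100, 200),
                                                     later = c(200, 320)),
                                alpha = 0.05, min_run_samples = 10) {
  if (length(waves) < 4) stop("need at least 4 subjects for LOSO")
  subjects <- vapply(waves, `[[`, "", "subject")
  rows <- list()
  for (i in seq_along(waves)) {
    wins <- find_significant_windows(waves[-i], electrodes = electrodes,
                                     alpha = alpha,
                                     min_run_samples = min_run_samples)
    for (cname in names(search_ranges)) {
      rng <- search_ranges[[cname]]
      sel <- select_interval(wins, rng)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subjects[i], component = cname,
        start_ms = sel[1], end_ms = sel[2], ok = !anyNA(sel),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("loso_windows", "data.frame")
  if (any(!out$ok))
    warning(sum(!out$ok), " fold(s) had no surviving interval in range; ",
            "affected subjects are excluded from that component")
  out
}

# Pick from `wins` (data frame start_ms/end_ms) the interval with largest
# overlap with `rng`, clipped to `rng`; ties broken by midpoint proximity.
select_interval <- function(wins, rng) {
  if (!nrow(wins)) return(c(NA_real_, NA_real_))
  lo <- pmax(wins$start_ms, rng[1])
  hi <- pmin(wins$end_ms, rng[2])
  ov <- hi - lo
  ok <- which(ov >= 0)
  if (!length(ok)) return(c(NA_real_, NA_real_))
  mid_d <- abs((lo + hi) / 2 - mean(rng))
  best <- ok[order(-ov[ok], mid_d[ok])][1]
  c(lo[best], hi[best])
}

#' @export
print.loso_windows <- function(x, ...) {
  cat(sprintf("<loso_windows> %d folds x %d components\n",
              length(unique(x$subject)), length(unique(x$component))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Extract mean amplitudes in subject-specific windows
#'
#' Mean of each subject's difference wave over (that subject's LOSO window) x
#' (each hemisphere's electrode set), for every task. Produces the fully
#' crossed subject x task x hemisphere x component table used by the
#' repeated-measures ANOVA.
#'
#' @param waves_by_task Named list (task -> list of per-subject `erp_diff`).
#' @param windows A `loso_windows` table.
#' @param hemisphere_sets Named list with `left` and `right` electrode sets.
#' @return Data frame: `subject`, `task`, `hemisphere`, `component`,
#'   `amplitude` (microvolts). Flagged subjects are absent for the affected
#'   component.
#' @export
extract_amplitudes <- function(waves_by_task, windows,
                               hemisphere_sets = list(left = "PO5",
                                                      right = "PO6")) {
  rows <- list()
  for (task in names(waves_by_task)) {
    waves <- waves_by_task[[task]]
    subjects <- vapply(waves, `[[`, "", "subject")
    for (i in seq_along(waves)) {
      w <- waves[[i]]
      for (cname in unique(windows$component)) {
        win <- windows[windows$subject == subjects[i] &
                         windows$component == cname, ]
        if (nrow(win) != 1)
          stop("no LOSO window for subject ", subjects[i],
               ", component ", cname)
        if (!win$ok) next
        ti <- which(w$time_axis >= win$start_ms - 1e-9 &
                      w$time_axis <= win$end_ms + 1e-9)
        for (hemi in names(hemisphere_sets)) {
          el <- hemisphere_sets[[hemi]]
          miss <- setdiff(el, rownames(w$data))
          if (length(miss))
            stop("electrode(s) not present: ", paste(miss, collapse = ", "))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subjects[i], task = task, hemisphere = hemi,
            component = cname,
            amplitude = mean(w$data[el, ti, drop = FALSE]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(subject = character(0), task = character(0),
                      hemisphere = character(0), component = character(0),
                      amplitude = numeric(0)))
  rownames(out) <- NULL
  out
}

orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Greenhouse-Geisser epsilon
#'
#' The standard estimator from the sample covariance of the repeated
#' measures: with `S = C' Sigma C` for an orthonormal contrast basis `C` of
#' the k levels, `epsilon = tr(S)^2 / ((k - 1) tr(S^2))`, clipped to
#' `[1/(k - 1), 1]`. Always 1 for k = 2 and for compound-symmetric
#' covariance. A (numerically) singular contrast covariance returns the
#' lower bound with a warning.
#'
#' @param sigma k x k covariance matrix of the within-subject measures
#'   (or, with `contrasts_applied = TRUE`, the (k-1) x (k-1) covariance of
#'   orthonormal within-subject contrasts).
#' @param contrasts_applied Whether `sigma` is already in contrast space.
#' @return Epsilon in `[1/(k - 1), 1]`.
#' @export
gg_epsilon <- function(sigma, contrasts_applied = FALSE) {
  sigma <- as.matrix(sigma)
  if (contrasts_applied) {
    S <- sigma
    k <- nrow(S) + 1L
  } else {
    k <- nrow(sigma)
    if (k < 2) stop("need at least 2 levels")
    C <- orth_contrasts(k)
    S <- t(C) %*% sigma %*% C
  }
  m <- k - 1L
  tr <- sum(diag(S))
  tr2 <- sum(S * t(S))
  if (tr2 < .Machine$double.eps) {
    warning("singular contrast covariance; returning the lower bound")
    return(1 / m)
  }
  eps <- tr^2 / (m * tr2)
  min(max(eps, 1 / m), 1)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical within-subject sums-of-squares decomposition for one or two
#' fully crossed within-subject factors. Each effect is tested against its
#' own effect-by-subject interaction; Greenhouse-Geisser epsilon is estimated
#' from the sample covariance of the effect's orthonormal within-subject
#' contrasts and scales both degrees of freedom for the p value. Partial
#' eta squared is `SS_effect / (SS_effect + SS_error)`. An effect with
#' (numerically) zero SS is reported as F = 0, p = 1.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject-identifier column.
#' @param within Character vector of one or two within-subject factor
#'   columns; the design must be complete (one observation per subject per
#'   cell).
#' @return An `icerp_anova` data frame: one row per effect with `SS_effect`,
#'   `SS_error`, `df_num`, `df_den`, `epsilon`, `F`, `p` (GG-corrected),
#'   `partial_eta_sq`.
#' @examples
#' amp <- data.frame(subject = rep(1:6, each = 3),
#'                   task = rep(c("KF", "CC", "PC"), 6),
#'                   amplitude = rnorm(18))
#' rm_anova(amp, dv = "amplitude", subject = "subject", within = "task")
#' @export
rm_anova <- function(data, dv = "amplitude", subject = "subject",
                     within = "task") {
  if (!length(within) %in% 1:2)
    stop("within must name one or two factors")
  data <- as.data.frame(data)
  for (v in c(dv, subject, within))
    if (!v %in% names(data)) stop("column not found: ", v)
  subj <- factor(data[[subject]])
  f <- lapply(within, function(v) factor(data[[v]],
                                         levels = unique(data[[v]])))
  names(f) <- within
  lv <- lapply(f, levels)
  k <- vapply(lv, length, integer(1))
  n <- nlevels(subj)
  if (any(k < 2)) stop("each within factor needs >= 2 levels")

  # subject x cell response matrix, cells in factor-major order
  cell <- if (length(f) == 2)
    factor(paste(f[[1]], f[[2]], sep = "."),
           levels = as.vector(t(outer(lv[[1]], lv[[2]], paste, sep = "."))))
  else f[[1]]
  tab <- table(subj, cell)
  if (any(tab != 1))
    stop("design must be complete with one observation per subject per cell")
  Y <- matrix(NA_real_, n, nlevels(cell),
              dimnames = list(levels(subj), levels(cell)))
  Y[cbind(as.integer(subj), as.integer(cell))] <- data[[dv]]

  if (n < 2) stop("need at least 2 subjects")
  a <- k[1]; b <- if (length(k) == 2) k[2] else 1L
  grand <- mean(Y)
  m_s <- rowMeans(Y)
  idxA <- rep(seq_len(a), each = b)
  idxB <- rep(seq_len(b), times = a)
  m_a <- vapply(seq_len(a), function(i) mean(Y[, idxA == i, drop = FALSE]),
                numeric(1))
  m_b <- vapply(seq_len(b), function(i) mean(Y[, idxB == i, drop = FALSE]),
                numeric(1))
  m_as <- vapply(seq_len(a), function(i)
    rowMeans(Y[, idxA == i, drop = FALSE]), numeric(n))
  m_bs <- vapply(seq_len(b), function(i)
    rowMeans(Y[, idxB == i, drop = FALSE]), numeric(n))
  m_ab <- matrix(0, a, b)
  for (i in seq_len(a)) for (j in seq_len(b))
    m_ab[i, j] <- mean(Y[, idxA == i & idxB == j])

  SS_A <- n * b * sum((m_a - grand)^2)
  SS_AS <- b * sum((m_as - outer(rep(1, n), m_a) - m_s + grand)^2)
  effects <- list()
  CA <- orth_contrasts(a)
  onesb <- matrix(1 / sqrt(b), b, 1)
  eps_A <- gg_epsilon(t(kronecker(CA, onesb)) %*% stats::cov(Y) %*%
                        kronecker(CA, onesb), contrasts_applied = TRUE)
  effects[[within[1]]] <- list(SS = SS_A, SSe = SS_AS,
                               df1 = a - 1, df2 = (a - 1) * (n - 1),
                               eps = eps_A)
  if (b > 1) {
    SS_B <- n * a * sum((m_b - grand)^2)
    SS_BS <- a * sum((m_bs - outer(rep(1, n), m_b) - m_s + grand)^2)
    SS_AB <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                        outer(rep(1, a), m_b) + grand)^2)
    cellmean <- as.vector(t(m_ab))  # a-major order, matching Y's columns
    resid <- Y -
      m_as[, idxA, drop = FALSE] - m_bs[, idxB, drop = FALSE] +
      outer(m_s, rep(1, a * b)) +
      outer(rep(1, n), m_a[idxA] + m_b[idxB] - cellmean - grand)
    SS_ABS <- sum(resid^2)
    CB <- orth_contrasts(b)
    onesa <- matrix(1 / sqrt(a), a, 1)
    eps_B <- gg_epsilon(t(kronecker(onesa, CB)) %*% stats::cov(Y) %*%
                          kronecker(onesa, CB), contrasts_applied = TRUE)
    CAB <- kronecker(CA, CB)
    eps_AB <- gg_epsilon(t(CAB) %*% stats::cov(Y) %*% CAB,
                         contrasts_applied = TRUE)
    effects[[within[2]]] <- list(SS = SS_B, SSe = SS_BS,
                                 df1 = b - 1, df2 = (b - 1) * (n - 1),
                                 eps = eps_B)
    effects[[paste(within, collapse = ":")]] <-
      list(SS = SS_AB, SSe = SS_ABS, df1 = (a - 1) * (b - 1),
           df2 = (a - 1) * (b - 1) * (n - 1), eps = eps_AB)
  }

  out <- do.call(rbind, lapply(names(effects), function(nm) {
    e <- effects[[nm]]
    MS <- e$SS / e$df1
    MSe <- e$SSe / e$df2
    if (e$SS < .Machine$double.eps) {
      Fv <- 0; p <- 1
    } else if (MSe < .Machine$double.eps) {
      Fv <- Inf; p <- 0
    } else {
      Fv <- MS / MSe
      p <- stats::pf(Fv, e$eps * e$df1, e$eps * e$df2, lower.tail = FALSE)
    }
    data.frame(effect = nm, SS_effect = e$SS, SS_error = e$SSe,
               df_num = e$df1, df_den = e$df2, epsilon = e$eps,
               F = Fv, p = p,
               partial_eta_sq = if (e$SS + e$SSe < .Machine$double.eps) 0
                                else e$SS / (e$SS + e$SSe),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("icerp_anova", "data.frame")
  attr(out, "n_subjects") <- n
  out
}

#' @export
print.icerp_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (n = %d), Greenhouse-Geisser corrected\n",
              attr(x, "n_subjects")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s: F(%g, %g) = %.2f, eps = %.3f, p = %.4g, partial eta^2 = %.2f\n",
                x$effect[i], x$df_num[i], x$df_den[i], x$F[i], x$epsilon[i],
                x$p[i], x$partial_eta_sq[i]))
  invisible(x)
}

#' Post-hoc paired t test with effect size
#'
#' Two-tailed paired t (df = n - 1), uncorrected (matching how the follow-up
#' comparisons are reported), with eta squared `t^2 / (t^2 + df)`. A
#' zero-variance difference gives t = 0, p = 1 when the mean difference is
#' zero and p = 0 otherwise. An optional Holm adjustment over a family of
#' comparisons is available via [posthoc_pairs()].
#'
#' @param x,y Paired numeric vectors (n >= 2).
#' @return List: `t`, `df`, `p`, `eta_sq`, `mean_diff`.
#' @export
posthoc_paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  if (s < .Machine$double.eps^0.75) {
    t <- if (abs(m) < .Machine$double.eps^0.5) 0 else sign(m) * Inf
    p <- if (t == 0) 1 else 0
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  }
  eta <- if (is.infinite(t)) 1 else t^2 / (t^2 + df)
  list(t = t, df = df, p = p, eta_sq = eta, mean_diff = m)
}

#' All pairwise post-hoc comparisons of a within-subject factor
#'
#' @param data Long-format data frame (one observation per subject per
#'   level; multiple rows per cell, e.g. two hemispheres, are averaged
#'   first, mirroring the combine-then-compare reporting).
#' @param dv,subject,within Column names.
#' @param adjust `"none"` (default, matching the study's reporting) or
#'   `"holm"`.
#' @return Data frame: `pair`, `t`, `df`, `p`, `eta_sq`, `mean_diff`.
#' @export
posthoc_pairs <- function(data, dv = "amplitude", subject = "subject",
                          within = "task", adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  agg <- stats::aggregate(data[[dv]],
                          by = list(subject = data[[subject]],
                                    level = data[[within]]),
                          FUN = mean)
  lv <- unique(as.character(data[[within]]))
  rows <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    xi <- agg$x[agg$level == lv[i]][order(agg$subject[agg$level == lv[i]])]
    xj <- agg$x[agg$level == lv[j]][order(agg$subject[agg$level == lv[j]])]
    r <- posthoc_paired_t(xi, xj)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(lv[i], "vs", lv[j]), t = r$t, df = r$df, p = r$p,
      eta_sq = r$eta_sq, mean_diff = r$mean_diff, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Summarize a behavioral trial log
#'
#' Correct rate over all trials and mean reaction time over correct trials,
#' per subject and task.
#'
#' @param trials Data frame with columns `subject`, `task`, `correct`
#'   (0/1), `rt_ms`.
#' @return Data frame: `subject`, `task`, `correct_rate`, `mean_rt`.
#' @export
behavioral_summarize <- function(trials) {
  need <- c("subject", "task", "correct", "rt_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  rows <- list()
  for (s in unique(trials$subject)) for (tk in unique(trials$task)) {
    sub <- trials[trials$subject == s & trials$task == tk, ]
    if (!nrow(sub)) next
    ok <- sub$correct == 1
    if (!any(ok))
      stop("subject ", s, ", task ", tk,
           " has no correct trials; mean RT undefined")
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, task = tk, correct_rate = mean(sub$correct),
      mean_rt = mean(sub$rt_ms[ok]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way repeated-measures ANOVA of behavioral measures
#'
#' Runs [rm_anova()] with the factor task on the correct rate and on the
#' mean reaction time, plus uncorrected pairwise post-hoc tests.
#'
#' @param table Output of [behavioral_summarize()].
#' @return Named list per measure (`correct_rate`, `mean_rt`), each holding
#'   `anova` (an `icerp_anova`) and `posthoc` (pairwise table).
#' @export
behavioral_anova <- function(table) {
  out <- list()
  for (m in c("correct_rate", "mean_rt")) {
    out[[m]] <- list(
      anova = rm_anova(table, dv = m, subject = "subject", within = "task"),
      posthoc = posthoc_pairs(table, dv = m, subject = "subject",
                              within = "task"))
  }
  out
}
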