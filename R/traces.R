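#' Idealize a recording into current bursts and flickers
#'
#' Contiguous supra-threshold activity separated by sub-threshold gaps
#' shorter than `min_burst_gap` is one burst; a sub-threshold gap of at
#' least `min_burst_gap` terminates the burst. Within a burst,
#' sub-threshold intervals of at least `min_dwell` are blocked dwells
#' (flickers); shorter sub-threshold blips are absorbed into the open
#' state, and isolated supra-threshold blips shorter than `min_dwell` are
#' discarded as noise.
#'
#' @param trace A [current_trace()], uniformly sampled.
#' @param open_threshold Conductance threshold separating open pore from
#'   baseline, pS. Default 25.
#' @param min_burst_gap Minimum baseline gap that terminates a burst, ms.
#'   Default 500.
#' @param min_dwell Minimum dwell duration resolved by the idealizer, ms.
#'   Default 1.
#' @return A list of `pore_burst` objects; each has `t_on`, `t_off` (ms),
#'   `dwells` (data.frame: `state`, `t_start_ms`, `t_end_ms`,
#'   `duration_ms`, `mean_G_pS`), `samples` (conductance samples within the
#'   burst), `open_idx` (logical index of open-dwell samples), and
#'   `sample_interval`.
#' @export
detect_bursts <- function(trace, open_threshold = 25, min_burst_gap = 500,
                          min_dwell = 1) {
  stopifnot(inherits(trace, "current_trace"))
  if (open_threshold <= 0 || min_burst_gap <= 0 || min_dwell <= 0) {
    stop("detect_bursts: thresholds must be > 0")
  }
  n <- length(trace$conductance)
  if (n == 0) return(list())
  dt <- trace$metadata$sample_interval
  if (is.null(dt)) dt <- stats::median(diff(trace$time))

  above <- trace$conductance > open_threshold
  if (!any(above)) return(list())

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts, end = ends, len = r$lengths,
                     open = r$values)
  # drop supra-threshold blips shorter than min_dwell
  min_len <- max(1L, round(min_dwell / dt))
  runs$open[runs$open & runs$len < min_len] <- FALSE
  # re-merge adjacent runs with equal state
  runs <- merge_runs(runs)
  open_runs <- which(runs$open)
  if (!length(open_runs)) return(list())

  gap_len <- round(min_burst_gap / dt)
  # group open runs: a new burst starts when the preceding baseline gap
  # is >= min_burst_gap
  grp <- integer(length(open_runs))
  g <- 1L
  grp[1] <- g
  if (length(open_runs) > 1) {
    for (k in 2:length(open_runs)) {
      gap <- runs$start[open_runs[k]] - runs$end[open_runs[k - 1]] - 1
      if (gap >= gap_len) g <- g + 1L
      grp[k] <- g
    }
  }

  t <- trace$time
  out <- list()
  for (gi in unique(grp)) {
    members <- open_runs[grp == gi]
    i0 <- runs$start[members[1]]
    i1 <- runs$end[members[length(members)]]
    seg_open <- rep(FALSE, i1 - i0 + 1)
    for (m in members) seg_open[(runs$start[m]:runs$end[m]) - i0 + 1] <- TRUE
    # sub-threshold intervals shorter than min_dwell inside the burst are
    # absorbed into the open state
    rr <- rle(seg_open)
    ee <- cumsum(rr$lengths); ss <- ee - rr$lengths + 1
    for (j in seq_along(rr$values)) {
      if (!rr$values[j] && rr$lengths[j] < min_len) {
        seg_open[ss[j]:ee[j]] <- TRUE
      }
    }
    rr <- rle(seg_open)
    ee <- cumsum(rr$lengths); ss <- ee - rr$lengths + 1
    samples <- trace$conductance[i0:i1]
    dwells <- data.frame(
      state = ifelse(rr$values, "open", "blocked"),
      t_start_ms = t[i0 + ss - 1],
      t_end_ms = t[i0 + ee - 1] + dt,
      duration_ms = rr$lengths * dt,
      mean_G_pS = vapply(seq_along(rr$values),
                         function(j) mean(samples[ss[j]:ee[j]]), numeric(1)))
    out[[length(out) + 1]] <- structure(list(
      t_on = t[i0], t_off = t[i1] + dt, dwells = dwells,
      samples = samples, open_idx = seg_open, sample_interval = dt),
      class = "pore_burst")
  }
  out
}

merge_runs <- function(runs) {
  if (nrow(runs) <= 1) return(runs)
  keep <- c(TRUE, runs$open[-1] != runs$open[-nrow(runs)])
  grp <- cumsum(keep)
  data.frame(start = tapply(runs$start, grp, min),
             end = tapply(runs$end, grp, max),
             len = tapply(runs$len, grp, sum),
             open = tapply(runs$open, grp, any))
}

#' @export
print.pore_burst <- function(x, ...) {
  nf <- sum(x$dwells$state == "blocked")
  cat(sprintf("pore_burst: T_o = %.1f ms, %d flicker(s), %d samples\n",
              x$t_off - x$t_on, nf, length(x$samples)))
  invisible(x)
}

#' Per-burst pore metrics
#'
#' Computes the standard single-pore metrics from an idealized burst:
#' mean point-by-point open-pore conductance `G_po`, burst lifetime `T_o`,
#' flicker count `N_flickers`, flicker rate `N_flickers / T_o`, open
#' probability `P_o` (fraction of the burst spent open), and the
#' conductance fluctuation (RMS deviation of open-dwell samples about
#' `G_po`).
#'
#' @param burst A `pore_burst` from [detect_bursts()], or a compatible
#'   list with `dwells`, `samples`, `open_idx`, `t_on`, `t_off`.
#' @return A one-row data.frame of class `burst_metrics` with columns
#'   `G_po_pS`, `T_o_ms`, `n_flickers`, `flicker_rate_hz`, `P_o`,
#'   `fluctuation_pS`.
#' @export
burst_metrics <- function(burst) {
  d <- burst$dwells
  T_o <- burst$t_off - burst$t_on
  open_time <- sum(d$duration_ms[d$state == "open"])
  if (open_time <= 0 || !any(burst$open_idx)) {
    stop("burst_metrics: burst has zero open time")
  }
  open_samples <- burst$samples[burst$open_idx]
  G_po <- mean(open_samples)
  n_fl <- sum(d$state == "blocked")
  out <- data.frame(
    G_po_pS = G_po,
    T_o_ms = T_o,
    n_flickers = n_fl,
    flicker_rate_hz = n_fl / (T_o / 1000),
    P_o = open_time / T_o,
    fluctuation_pS = sqrt(mean((open_samples - G_po)^2)))
  class(out) <- c("burst_metrics", "data.frame")
  out
}

#' Metrics for a list of bursts
#'
#' @param bursts A list of `pore_burst` objects.
#' @return A data.frame with one row per burst.
#' @export
bursts_metrics <- function(bursts) {
  do.call(rbind, lapply(bursts, burst_metrics))
}

#' Pool point-by-point open-pore conductance samples
#'
#' Concatenates the conductance samples of all open dwells across bursts;
#' the result is an order-independent multiset used for conductance and
#' radius probability density functions.
#'
#' @param bursts A list of `pore_burst` objects (at least one).
#' @return Numeric vector of conductance samples, pS.
#' @export
pool_point_conductances <- function(bursts) {
  if (!length(bursts)) stop("pool_point_conductances: no bursts")
  unlist(lapply(bursts, function(b) b$samples[b$open_idx]), use.names = FALSE)
}

#' Construct a per-patch summary
#'
#' @param recording A `patch_recording` (from
#'   [simulate_patch_recording()]), or pass counts explicitly.
#' @param n_bursts,observation_time,censored,exposure_min Explicit fields
#'   (used when `recording` is `NULL`): burst count, patch observation
#'   time (min), whether the patch hit the per-patch pore cap, and the
#'   censoring-aware exposure (min; time up to the last countable pore for
#'   censored patches, full observation time otherwise).
#' @return A one-row data.frame of class `patch_summary`.
#' @export
patch_summary <- function(recording = NULL, n_bursts = NULL,
                          observation_time = NULL, censored = FALSE,
                          exposure_min = NULL) {
  if (!is.null(recording)) {
    stopifnot(inherits(recording, "patch_recording"))
    n_bursts <- nrow(recording$annotations)
    observation_time <- recording$params$patch_duration
    censored <- recording$censored
    exposure_min <- recording$exposure_min
  }
  if (is.null(exposure_min)) exposure_min <- observation_time
  if (observation_time <= 0) stop("patch_summary: observation_time must be > 0")
  out <- data.frame(n_bursts = n_bursts,
                    observation_time = observation_time,
                    censored = censored,
                    exposure_min = exposure_min,
                    pores_per_min = n_bursts / observation_time)
  class(out) <- c("patch_summary", "data.frame")
  out
}

#' Pore nucleation (fusion) rate across patches
#'
#' Aggregates per-patch burst counts into a pooled nucleation rate in
#' pores/min. Two estimators are returned: the naive rate
#' `sum(n) / sum(observation_time)`, which systematically underestimates
#' the true rate when patches are censored at a per-patch pore cap, and a
#' censoring-aware rate that ends each censored patch's exposure at its
#' last countable pore (`sum(n) / sum(exposure)`); by the optional-stopping
#' property of the Poisson process the latter is asymptotically unbiased.
#' Standard errors are Poisson (`sqrt(n)/T`). With zero pores the naive
#' rate is 0 with a one-sided 95% upper bound `3.689/T` (exact Poisson).
#'
#' @param summaries A data.frame of stacked [patch_summary()] rows, or a
#'   list of them, or a list of `patch_recording` objects.
#' @return A list with `naive`, `naive_se`, `censoring_aware`,
#'   `censoring_aware_se`, `upper95` (for the zero-count case),
#'   `n_pores`, `total_time_min`, `total_exposure_min`.
#' @export
nucleation_rate <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, function(s) {
      if (inherits(s, "patch_recording")) patch_summary(s) else s
    }))
  }
  stopifnot(is.data.frame(summaries))
  if (any(summaries$observation_time <= 0) ||
      sum(summaries$observation_time) <= 0) {
    stop("nucleation_rate: total observation time must be > 0")
  }
  n <- sum(summaries$n_bursts)
  Tt <- sum(summaries$observation_time)
  Te <- sum(summaries$exposure_min)
  list(naive = n / Tt,
       naive_se = sqrt(n) / Tt,
       censoring_aware = n / Te,
       censoring_aware_se = sqrt(n) / Te,
       upper95 = if (n == 0) 3.689 / Tt else NA_real_,
       n_pores = n, total_time_min = Tt, total_exposure_min = Te)
}

#' Pore expansion rate from time-aligned averaged conductance
#'
#' Bursts are aligned at their first supra-threshold sample and averaged
#' point-wise over the first `window` ms. With `G_ref` the averaged
#' conductance at the window end, the expansion rate is
#' `0.8 * G_ref / (t90 - t10)` where `t10` and `t90` are the first
#' crossings of 10% and 90% of `G_ref`. For an instantaneous step the two
#' crossings coincide and the denominator is clamped to one sample
#' interval. pS/ms equals nS/s, so the rate is reported in nS/s.
#'
#' @param bursts List of `pore_burst` objects.
#' @param window Averaging window after pore opening, ms. Default 100.
#' @return A list with `rate_nS_per_s`, `G_ref_pS`, `t10_ms`, `t90_ms`,
#'   `n_bursts`, and `aligned` (data.frame `t_ms`, `mean_G_pS`).
#' @export
expansion_rate <- function(bursts, window = 100) {
  if (!length(bursts)) stop("expansion_rate: no bursts")
  dt <- bursts[[1]]$sample_interval
  n_win <- round(window / dt)
  long <- Filter(function(b) length(b$samples) >= n_win, bursts)
  if (!length(long)) {
    stop("expansion_rate: all bursts shorter than the alignment window")
  }
  mat <- vapply(long, function(b) b$samples[seq_len(n_win)],
                numeric(n_win))
  avg <- rowMeans(mat)
  t <- (seq_len(n_win) - 1) * dt
  G_ref <- avg[n_win]
  if (G_ref <= 0) stop("expansion_rate: non-positive averaged conductance")
  t10 <- t[which(avg >= 0.1 * G_ref)[1]]
  t90 <- t[which(avg >= 0.9 * G_ref)[1]]
  rise <- max(t90 - t10, dt)
  list(rate_nS_per_s = 0.8 * G_ref / rise,  # pS/ms == nS/s
       G_ref_pS = G_ref, t10_ms = t10, t90_ms = t90,
       n_bursts = length(long),
       aligned = data.frame(t_ms = t, mean_G_pS = avg))
}

#' Write per-burst metrics or patch summaries as delimited text
#'
#' @param x A data.frame (e.g. from [bursts_metrics()]).
#' @param path Output path (tab-delimited).
#' @export
write_metrics <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
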