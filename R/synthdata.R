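#' Generator parameters for synthetic patch recordings
#'
#' Parameters of the stochastic model used to emulate single fusion-pore
#' patch-clamp recordings: pores nucleate as a Poisson process per patch,
#' burst lifetimes `T_o` are exponential, flicker counts `N_flickers` are
#' geometric (support 0, 1, 2, ...), flicker (blocked) dwell durations are
#' exponential, and the open-pore level carries point-wise Gaussian noise
#' around a condition mean that can follow the calcium Hill law.
#'
#' `open_mean_dwell` is by default derived from the other gating parameters
#' so that the expected burst composition is self-consistent:
#' `open_mean_dwell = p * burst_mean_duration - (1 - p) * flicker_mean_closed`
#' with `p = flicker_success_prob`. The expected open fraction of a burst is
#' then `open_mean_dwell / (open_mean_dwell + (1 - p) * flicker_mean_closed)`.
#'
#' @param nucleation_rate Pore nucleation rate per patch, pores/min.
#' @param burst_mean_duration Mean burst lifetime `T_o`, ms.
#' @param flicker_success_prob Geometric parameter `p` for `N_flickers`
#'   (mean flicker count `(1-p)/p`), in (0, 1].
#' @param flicker_mean_closed Mean blocked (flicker) dwell, ms.
#' @param open_mean_dwell Mean open dwell, ms, or `NULL` to derive (see
#'   Details).
#' @param mean_open_conductance Open-pore conductance level, pS, or the
#'   string `"hill"` to take the level from the calcium Hill law.
#' @param conductance_noise_sd Point-wise SD of open-level noise, pS.
#' @param baseline_noise_sd Point-wise SD of baseline noise, pS.
#' @param sample_interval Sampling interval, ms (default 0.1 = 10 kHz).
#' @param holding_potential Holding potential, mV (default 15; the assay
#'   uses potentials below 20 mV).
#' @param patch_duration Recording duration per patch, min.
#' @param max_pores_per_patch Maximum number of pores analyzed per patch
#'   (recordings with more are censored at this count).
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(nucleation_rate = 0.5,
                             burst_mean_duration = 3000,
                             flicker_success_prob = 0.25,
                             flicker_mean_closed = 20,
                             open_mean_dwell = NULL,
                             mean_open_conductance = "hill",
                             conductance_noise_sd = 30,
                             baseline_noise_sd = 5,
                             sample_interval = 0.1,
                             holding_potential = 15,
                             patch_duration = 10,
                             max_pores_per_patch = 3,
                             seed = 1L) {
  p <- flicker_success_prob
  if (!is.numeric(p) || p <= 0 || p > 1) {
    stop("generator_params: flicker_success_prob must be in (0, 1]")
  }
  if (is.null(open_mean_dwell)) {
    open_mean_dwell <- p * burst_mean_duration - (1 - p) * flicker_mean_closed
  }
  obj <- structure(list(
    nucleation_rate = nucleation_rate,
    burst_mean_duration = burst_mean_duration,
    flicker_success_prob = p,
    flicker_mean_closed = flicker_mean_closed,
    open_mean_dwell = open_mean_dwell,
    mean_open_conductance = mean_open_conductance,
    conductance_noise_sd = conductance_noise_sd,
    baseline_noise_sd = baseline_noise_sd,
    sample_interval = sample_interval,
    holding_potential = holding_potential,
    patch_duration = patch_duration,
    max_pores_per_patch = max_pores_per_patch,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "generator_params")
  validate_generator_params(obj)
  obj
}

validate_generator_params <- function(x) {
  pos <- c("nucleation_rate", "burst_mean_duration", "flicker_mean_closed",
           "open_mean_dwell", "sample_interval", "patch_duration")
  for (f in pos) {
    if (f == "nucleation_rate") {
      if (x[[f]] < 0) stop("generator_params: nucleation_rate must be >= 0")
    } else if (!is.numeric(x[[f]]) || x[[f]] <= 0) {
      stop(sprintf("generator_params: %s must be > 0", f))
    }
  }
  if (x$max_pores_per_patch < 1) {
    stop("generator_params: max_pores_per_patch must be >= 1")
  }
  dwells <- c(x$flicker_mean_closed, x$open_mean_dwell)
  if (x$sample_interval >= min(dwells) / 5) {
    stop("generator_params: sample_interval must be < mean dwells / 5")
  }
  invisible(x)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Synthetic patch generator parameters:\n")
  cat(sprintf("  nucleation %g pores/min (cap %d/patch), patch %g min @ %g ms\n",
              x$nucleation_rate, x$max_pores_per_patch, x$patch_duration,
              x$sample_interval))
  cat(sprintf("  T_o ~ Exp(%g ms), N_flickers ~ Geom(p=%g), blocked ~ Exp(%g ms)\n",
              x$burst_mean_duration, x$flicker_success_prob,
              x$flicker_mean_closed))
  lev <- if (identical(x$mean_open_conductance, "hill")) "Hill law"
         else sprintf("%g pS", x$mean_open_conductance)
  cat(sprintf("  open level: %s +/- %g pS; baseline noise %g pS\n",
              lev, x$conductance_noise_sd, x$baseline_noise_sd))
  invisible(x)
}

#' Experimental condition presets
#'
#' Named presets reproducing the direction of the condition effects seen in
#' the nanodisc-cell fusion assay: full-length Syt1 or its wild-type C2AB
#' fragment (and the avid membrane-inserting 4W mutant) make the open-pore
#' conductance calcium-sensitive via the Hill law, provided PI(4,5)P2 is
#' present; the calcium-binding (D309N), polybasic-patch (K326A/K327A),
#' SNARE-interface (R398Q/R399Q) and membrane-insertion (4A) mutants
#' collapse to the SNARE-alone level.
#'
#' @param label One of `"no_syt"`, `"syt1_full"`, `"c2ab_wt"`,
#'   `"c2ab_D309N"`, `"c2ab_K326A_K327A"`, `"c2ab_R398Q_R399Q"`,
#'   `"c2ab_4A"`, `"c2ab_4W"`.
#' @param calcium Free calcium, uM. Default 100.
#' @param pip2_present Is exogenous PI(4,5)P2 present? Default `TRUE`.
#' @param conductance_scale Multiplicative conductance scale. Default 1.
#' @param nucleation_scale Multiplicative nucleation-rate scale.
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(label = "c2ab_wt", calcium = 100,
                             pip2_present = TRUE, conductance_scale = 1,
                             nucleation_scale = NULL) {
  labels <- c("no_syt", "syt1_full", "c2ab_wt", "c2ab_D309N",
              "c2ab_K326A_K327A", "c2ab_R398Q_R399Q", "c2ab_4A", "c2ab_4W")
  label <- match.arg(label, labels)
  if (calcium < 0) stop("condition_preset: calcium must be >= 0")
  if (conductance_scale <= 0) stop("condition_preset: scales must be > 0")
  active <- label %in% c("syt1_full", "c2ab_wt", "c2ab_4W") && pip2_present
  if (is.null(nucleation_scale)) {
    nucleation_scale <- if (active && calcium > 0) 3 else 1
  }
  if (nucleation_scale <= 0) stop("condition_preset: scales must be > 0")
  structure(list(label = label, calcium = calcium,
                 pip2_present = pip2_present,
                 conductance_scale = conductance_scale,
                 nucleation_scale = nucleation_scale,
                 hill_active = active),
            class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("Condition '%s': [Ca2+] = %g uM, PI(4,5)P2 %s, %s\n",
              x$label, x$calcium, if (x$pip2_present) "present" else "absent",
              if (x$hill_active) "calcium-sensitive (Hill law)"
              else "calcium-insensitive (SNARE-alone level)"))
  invisible(x)
}

# Mean open level for a preset under a Hill law (pS, before noise)
preset_open_level <- function(params, preset, law = hill_law()) {
  base <- if (identical(params$mean_open_conductance, "hill")) {
    if (preset$hill_active) hill_conductance(preset$calcium, law) else law$c
  } else {
    params$mean_open_conductance
  }
  base * preset$conductance_scale
}

#' Simulate one fusion-pore burst
#'
#' Draws a burst lifetime `T_o ~ Exp(burst_mean_duration)` and a flicker
#' count `N_flickers ~ Geom(flicker_success_prob)` (support 0, 1, 2, ...),
#' then places `N_flickers` transient full closures (durations
#' `Exp(flicker_mean_closed)`) inside the burst with Dirichlet-distributed
#' open spacings, each open segment at least `max(10 * sample_interval, 5)`
#' ms long (flickers that cannot fit are dropped). The burst begins and
#' ends with an open dwell and terminates in a permanent closure.
#'
#' Uses the current R random-number state; seed control belongs to the
#' caller (see [simulate_patch_recording()]).
#'
#' @param params A [generator_params()] object.
#' @param preset A [condition_preset()] (supplies calcium and scaling).
#' @param law A [hill_law()] mapping calcium to the mean open level.
#' @return A list with `dwells` (data.frame: `state`, `duration_ms`,
#'   `level_pS`), `T_o` (ms), `n_flickers` and `G_open` (pS).
#' @export
simulate_burst <- function(params, preset = condition_preset(),
                           law = hill_law()) {
  stopifnot(inherits(params, "generator_params"),
            inherits(preset, "condition_preset"))
  T_o <- stats::rexp(1, rate = 1 / params$burst_mean_duration)
  n_fl <- stats::rgeom(1, prob = params$flicker_success_prob)
  closed <- if (n_fl > 0) {
    stats::rexp(n_fl, rate = 1 / params$flicker_mean_closed)
  } else {
    numeric(0)
  }
  m_open <- max(10 * params$sample_interval, 5)

  # Flickers must fit inside the burst with every open segment >= m_open.
  # Rescale closed dwells when they spill over (keeps the geometric
  # flicker-count marginal intact); only if even minimal closures cannot
  # fit (very short bursts) are flickers dropped.
  if (n_fl > 0) {
    spare <- T_o - (n_fl + 1) * m_open
    if (spare <= n_fl * 0.5) {
      while (n_fl > 0 && (T_o - (n_fl + 1) * m_open) <= n_fl * 0.5) {
        closed <- closed[-length(closed)]
        n_fl <- n_fl - 1L
      }
    }
    if (n_fl > 0 && sum(closed) > 0.95 * spare) {
      closed <- closed * 0.95 * spare / sum(closed)
    }
  }

  G_open <- preset_open_level(params, preset, law)
  if (n_fl == 0) {
    dwells <- data.frame(state = "open", duration_ms = T_o, level_pS = G_open)
  } else {
    spare <- T_o - sum(closed) - (n_fl + 1) * m_open
    w <- stats::rexp(n_fl + 1)
    open_seg <- m_open + spare * w / sum(w)
    state <- rep(c("open", "blocked"), length.out = 2 * n_fl + 1)
    dur <- numeric(2 * n_fl + 1)
    dur[seq(1, 2 * n_fl + 1, by = 2)] <- open_seg
    dur[seq(2, 2 * n_fl, by = 2)] <- closed
    dwells <- data.frame(state = state, duration_ms = dur,
                         level_pS = ifelse(state == "open", G_open, 0))
  }
  list(dwells = dwells, T_o = T_o, n_flickers = n_fl, G_open = G_open)
}

#' Simulate a full patch recording with ground-truth annotations
#'
#' Pore onsets are drawn from a Poisson process at
#' `nucleation_rate * nucleation_scale` per minute, truncated at
#' `max_pores_per_patch` countable pores (further pores are censored, as in
#' the assay where only a few pores can be analyzed per patch). Bursts that
#' would start before the previous burst has been separated by at least
#' 1.2 s of baseline are dropped. Gaussian baseline noise is added
#' everywhere; open samples carry additional open-level noise. A fixed
#' `params$seed` makes the output bit-reproducible.
#'
#' @inheritParams simulate_burst
#' @return An object of class `patch_recording`: a list with
#'   `trace` (a [current_trace()]), `annotations` (data.frame: `burst_id`,
#'   `t_on_ms`, `t_off_ms`, `n_flickers_true`, `mean_G_true`), `dwells`
#'   (per-dwell ground-truth idealization), `n_nucleated` (pre-censoring
#'   count), `censored`, `exposure_min` (observation time up to the last
#'   countable pore when censored), `params`, `preset`.
#' @export
simulate_patch_recording <- function(params, preset = condition_preset(),
                                     law = hill_law()) {
  stopifnot(inherits(params, "generator_params"),
            inherits(preset, "condition_preset"))
  if (params$patch_duration <= 0) {
    stop("simulate_patch_recording: patch_duration must be > 0")
  }
  if (!is.null(params$seed)) set.seed(params$seed)

  T_ms <- params$patch_duration * 60 * 1000
  dt <- params$sample_interval
  n <- floor(T_ms / dt)
  rate_min <- params$nucleation_rate * preset$nucleation_scale
  k_raw <- if (rate_min > 0) {
    stats::rpois(1, rate_min * params$patch_duration)
  } else 0L
  onsets <- sort(stats::runif(k_raw, 0, T_ms))

  cond <- rnormv(n, 0, params$baseline_noise_sd)
  ann <- list()
  dwl <- list()
  kept <- 0L
  last_off <- -Inf
  censor_time <- T_ms
  censored <- FALSE
  for (t_on in onsets) {
    if (kept >= params$max_pores_per_patch) {
      censored <- TRUE
      break
    }
    if (t_on < last_off + 1200) next
    b <- simulate_burst(params, preset, law)
    kept <- kept + 1L
    t_edges <- t_on + cumsum(c(0, b$dwells$duration_ms))
    t_off <- min(t_edges[length(t_edges)], T_ms)
    for (j in seq_len(nrow(b$dwells))) {
      t0 <- t_edges[j]; t1 <- min(t_edges[j + 1], T_ms)
      if (t0 >= T_ms) break
      if (b$dwells$state[j] == "open") {
        i0 <- floor(t0 / dt) + 1; i1 <- min(floor(t1 / dt), n)
        if (i1 >= i0) {
          idx <- i0:i1
          cond[idx] <- cond[idx] + b$G_open +
            rnormv(length(idx), 0, params$conductance_noise_sd)
        }
      }
      dwl[[length(dwl) + 1]] <- data.frame(
        burst_id = kept, state = b$dwells$state[j],
        t_start_ms = t0, t_end_ms = t1, level_pS = b$dwells$level_pS[j])
    }
    ann[[kept]] <- data.frame(
      burst_id = kept, t_on_ms = t_on, t_off_ms = t_off,
      n_flickers_true = b$n_flickers, mean_G_true = b$G_open)
    last_off <- t_off
    censor_time <- t_on
  }

  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(burst_id = integer(0), t_on_ms = numeric(0),
               t_off_ms = numeric(0), n_flickers_true = integer(0),
               mean_G_true = numeric(0))
  dwells <- if (length(dwl)) do.call(rbind, dwl) else
    data.frame(burst_id = integer(0), state = character(0),
               t_start_ms = numeric(0), t_end_ms = numeric(0),
               level_pS = numeric(0))

  trace <- current_trace(
    time = (seq_len(n) - 1) * dt, conductance = cond,
    metadata = list(condition = preset$label, calcium = preset$calcium,
                    seed = params$seed, sample_interval = dt,
                    holding_potential = params$holding_potential))
  structure(list(trace = trace, annotations = annotations, dwells = dwells,
                 n_nucleated = k_raw, censored = censored,
                 exposure_min = (if (censored) censor_time else T_ms) / 60000,
                 params = params, preset = preset),
            class = "patch_recording")
}

# rnorm that returns exactly 0-sd draws quickly
rnormv <- function(n, mean, sd) {
  if (sd <= 0) rep(mean, n) else stats::rnorm(n, mean, sd)
}

#' Simulate several patches from one master seed
#'
#' The master seed spawns an independent sub-seed per patch, so any single
#' patch can be regenerated in isolation.
#'
#' @param n_patches Number of patches.
#' @inheritParams simulate_burst
#' @return A list of `patch_recording` objects.
#' @export
simulate_patches <- function(n_patches, params, preset = condition_preset(),
                             law = hill_law()) {
  stopifnot(n_patches >= 1)
  if (!is.null(params$seed)) set.seed(params$seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, n_patches)
  lapply(seq_len(n_patches), function(i) {
    p <- params
    p$seed <- subseeds[i]
    simulate_patch_recording(p, preset, law)
  })
}

#' Sampled conductance time series
#'
#' Container for a uniformly sampled single-pore conductance recording.
#'
#' @param time Time stamps, ms, strictly increasing and uniform.
#' @param conductance Conductance samples, pS.
#' @param metadata Named list; recognized entries include `condition`,
#'   `calcium` (uM), `seed`, `sample_interval` (ms), `holding_potential`
#'   (mV).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(time, conductance, metadata = list()) {
  stopifnot(is.numeric(time), is.numeric(conductance),
            length(time) == length(conductance))
  if (length(time) >= 2) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("current_trace: time must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * stats::median(dt)) {
      stop("current_trace: non-uniform sampling")
    }
    if (is.null(metadata$sample_interval)) {
      metadata$sample_interval <- stats::median(dt)
    }
  }
  if (!all(is.finite(conductance))) {
    stop("current_trace: conductance must be finite")
  }
  structure(list(time = time, conductance = conductance, metadata = metadata),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("current_trace: %d samples @ %g ms (%.2f s total)\n",
              length(x$time), md$sample_interval %||% NA,
              diff(range(x$time)) / 1000))
  if (!is.null(md$condition)) {
    cat(sprintf("  condition %s, [Ca2+] = %g uM\n", md$condition,
                md$calcium %||% NA))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write conductance traces as annotated text
#'
#' Traces are stored as two-column whitespace-delimited text
#' (`time_ms`, `conductance_pS`) preceded by `# key = value` metadata
#' header lines.
#'
#' @param trace A [current_trace()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [current_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  md <- trace$metadata
  hdr <- vapply(names(md), function(k) {
    sprintf("# %s = %s", k, as.character(md[[k]] %||% "NA"))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "time_ms conductance_pS"), con)
  utils::write.table(
    data.frame(time_ms = trace$time, conductance_pS = trace$conductance),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 100)
  hdr <- grep("^#", lines, value = TRUE)
  md <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    k <- trimws(sub("=.*$", "", kv))
    v <- trimws(sub("^[^=]*=", "", kv))
    num <- suppressWarnings(as.numeric(v))
    md[[k]] <- if (!is.na(num)) num else if (v == "NA") NULL else v
  }
  dat <- utils::read.table(path, header = TRUE, skip = length(hdr))
  current_trace(dat$time_ms, dat$conductance_pS, metadata = md)
}

#' Read and write ground-truth burst annotation tables
#'
#' @param annotations Data frame as produced by
#'   [simulate_patch_recording()].
#' @param path File path (tab-delimited text).
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
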