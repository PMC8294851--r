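# Shared fixtures. The membrane table is the expensive piece (one to two
# minutes); it is calcium-independent, so one table serves every ensemble
# test in the session. Cached across test files via the global env.

model_cache <- function() {
  if (!exists(".fusepore_test_cache", envir = globalenv())) {
    lp <- lever_params()
    tab <- membrane_table(lp)
    assign(".fusepore_test_cache", list(lp = lp, tab = tab),
           envir = globalenv())
  }
  get(".fusepore_test_cache", envir = globalenv())
}

cached_ensemble <- function(calcium, lp = NULL) {
  cache <- model_cache()
  params <- if (is.null(lp)) cache$lp else lp
  ensemble_statistics(params, calcium, table = cache$tab)
}

# rise of the free-energy profile between two radii
profile_rise_of <- function(ensemble, r1, r2) {
  g <- ensemble$grid[is.finite(ensemble$grid$U), ]
  u <- stats::approx(g$r, g$U, xout = c(r1, r2))$y
  u[2] - u[1]
}

# reconstruct pore_burst objects from a patch recording's ground-truth
# dwell table, so burst metrics can be tested against generator truth
# without going through threshold detection
truth_bursts <- function(rec) {
  dt <- rec$params$sample_interval
  cond <- rec$trace$conductance
  lapply(unique(rec$dwells$burst_id), function(id) {
    dw <- rec$dwells[rec$dwells$burst_id == id, ]
    i0 <- floor(dw$t_start_ms[1] / dt) + 1
    i1 <- min(floor(dw$t_end_ms[nrow(dw)] / dt), length(cond))
    samples <- cond[i0:i1]
    t_sample <- (i0:i1 - 1) * dt
    open_idx <- rep(FALSE, length(samples))
    for (j in which(dw$state == "open")) {
      open_idx[t_sample >= dw$t_start_ms[j] + dt &
                 t_sample < dw$t_end_ms[j] - dt] <- TRUE
    }
    dwells <- data.frame(
      state = dw$state,
      t_start_ms = dw$t_start_ms, t_end_ms = dw$t_end_ms,
      duration_ms = dw$t_end_ms - dw$t_start_ms,
      mean_G_pS = dw$level_pS)
    structure(list(t_on = dw$t_start_ms[1], t_off = dw$t_end_ms[nrow(dw)],
                   dwells = dwells, samples = samples, open_idx = open_idx,
                   sample_interval = dt),
              class = "pore_burst")
  })
}

# a quick noisy patch set for detection tests: 1-minute patches at high
# nucleation so a single simulation yields many ground-truth bursts
sim_patch_set <- function(n_patches = 20, seed = 421, calcium = 100,
                          nucleation = 3, dt = 0.2, cap = 60) {
  gp <- generator_params(nucleation_rate = nucleation, patch_duration = 1,
                         sample_interval = dt, max_pores_per_patch = cap,
                         seed = seed)
  simulate_patches(n_patches, gp, condition_preset("c2ab_wt",
                                                   calcium = calcium))
}
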