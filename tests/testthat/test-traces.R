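square_pulse_trace <- function(level = 300, on_ms = 500, dur_ms = 1000,
                               total_ms = 3000, dt = 0.1, noise = 0) {
  n <- total_ms / dt
  t <- (seq_len(n) - 1) * dt
  g <- if (noise > 0) rnorm(n, 0, noise) else numeric(n)
  g[t >= on_ms & t < on_ms + dur_ms] <-
    g[t >= on_ms & t < on_ms + dur_ms] + level
  current_trace(t, g, metadata = list(sample_interval = dt))
}

test_that("flat noise gives no bursts; a square pulse gives exactly one", {
  set.seed(12)
  noise <- current_trace((0:49999) * 0.1, rnorm(50000, 0, 5),
                         metadata = list(sample_interval = 0.1))
  expect_identical(detect_bursts(noise), list())

  tr <- square_pulse_trace()
  b <- detect_bursts(tr)
  expect_length(b, 1)
  m <- burst_metrics(b[[1]])
  expect_equal(m$G_po_pS, 300)
  expect_equal(m$P_o, 1)
  expect_equal(m$T_o_ms, 1000, tolerance = 0.001)
  expect_identical(m$n_flickers, 0L)
  expect_equal(m$fluctuation_pS, 0)
})

test_that("burst metric arithmetic on a constructed flickering burst", {
  # open 400 ms / blocked 200 ms / open 400 ms at 300 pS
  dt <- 0.1
  n <- 10000
  t <- (seq_len(n) - 1) * dt
  g <- numeric(n)
  g[t < 400] <- 300
  g[t >= 600 & t < 1000] <- 300
  burst <- structure(list(
    t_on = 0, t_off = 1000,
    dwells = data.frame(state = c("open", "blocked", "open"),
                        t_start_ms = c(0, 400, 600),
                        t_end_ms = c(400, 600, 1000),
                        duration_ms = c(400, 200, 400),
                        mean_G_pS = c(300, 0, 300)),
    samples = g, open_idx = g > 0, sample_interval = dt),
    class = "pore_burst")
  m <- burst_metrics(burst)
  expect_identical(m$n_flickers, 1L)
  expect_equal(m$P_o, 0.8)
  expect_equal(m$T_o_ms, 1000)
  expect_equal(m$flicker_rate_hz, 1)
  expect_equal(m$G_po_pS, 300)
})

test_that("detection recovers generator ground truth on noisy traces", {
  recs <- sim_patch_set(n_patches = 20, seed = 421)
  n_true <- 0; n_found <- 0; bound_err <- c()
  n_fl_true <- n_fl_det <- 0
  for (rec in recs) {
    det <- detect_bursts(rec$trace)
    ann <- rec$annotations
    n_true <- n_true + nrow(ann)
    for (k in seq_len(nrow(ann))) {
      hit <- which(vapply(det, function(b) {
        b$t_on < ann$t_off_ms[k] && b$t_off > ann$t_on_ms[k]
      }, logical(1)))
      if (length(hit) >= 1) {
        n_found <- n_found + 1
        b <- det[[hit[1]]]
        bound_err <- c(bound_err, abs(b$t_on - ann$t_on_ms[k]),
                       abs(b$t_off - ann$t_off_ms[k]))
        n_fl_true <- n_fl_true + ann$n_flickers_true[k]
        n_fl_det <- n_fl_det +
          sum(b$dwells$state == "blocked")
      }
    }
  }
  expect_gt(n_true, 40)
  expect_gte(n_found / n_true, 0.95)
  expect_lt(stats::quantile(bound_err, 0.95), 5)
  # flicker counts: sub-resolution closures are lost but the totals agree
  # within 10%
  expect_lt(abs(n_fl_det - n_fl_true) / max(n_fl_true, 1), 0.10)
})

test_that("metric means match generator parameters on ground-truth bursts", {
  recs <- sim_patch_set(n_patches = 20, seed = 99)
  bursts <- unlist(lapply(recs, truth_bursts), recursive = FALSE)
  met <- bursts_metrics(bursts)
  n <- nrow(met)
  expect_gt(n, 40)
  law <- hill_law()
  g_true <- hill_conductance(100, law)
  within3se <- function(x, target) abs(mean(x) - target) < 3 * sd(x) / sqrt(length(x)) + 1e-9
  expect_true(within3se(met$G_po_pS, g_true))
  # burst lifetimes are right-censored by the 1-minute patch window;
  # compare against the censored expectation from the drawn lifetimes
  t_true <- unlist(lapply(recs, function(r)
    r$annotations$t_off_ms - r$annotations$t_on_ms))
  expect_lt(abs(mean(met$T_o_ms) - mean(t_true)), 1)
  p_o_target <- 735 / (735 + 0.75 * 20)
  p_o_pooled <- sum(met$P_o * met$T_o_ms) / sum(met$T_o_ms)
  expect_lt(abs(p_o_pooled - p_o_target) / p_o_target, 0.02)
  # per burst, open and blocked fractions sum to one exactly
  blocked_frac <- vapply(bursts, function(b) {
    sum(b$dwells$duration_ms[b$dwells$state == "blocked"]) /
      (b$t_off - b$t_on)
  }, numeric(1))
  expect_equal(met$P_o + blocked_frac, rep(1, n), tolerance = 1e-9)
})

test_that("pooled point conductances are order-invariant and complete", {
  recs <- sim_patch_set(n_patches = 4, seed = 15)
  bursts <- unlist(lapply(recs, truth_bursts), recursive = FALSE)
  pooled <- pool_point_conductances(bursts)
  shuffled <- pool_point_conductances(rev(bursts))
  expect_equal(sort(pooled), sort(shuffled))
  expect_equal(length(pooled),
               sum(vapply(bursts, function(b) sum(b$open_idx), integer(1))))
  # distribution matches the generator's open-level law (KS at alpha 0.01)
  law <- hill_law()
  sd_tot <- sqrt(30^2 + 5^2)
  set.seed(1)
  sub <- sample(pooled, 2000)
  expect_gt(ks.test(sub, "pnorm", hill_conductance(100, law),
                    sd_tot)$p.value, 0.01)
  expect_error(pool_point_conductances(list()), "bursts")
})

test_that("nucleation-rate estimators handle censoring and zero counts", {
  s <- data.frame(n_bursts = c(2, 1, 3), observation_time = c(2, 2, 2),
                  censored = FALSE, exposure_min = c(2, 2, 2))
  est <- nucleation_rate(s)
  expect_equal(est$naive, 1)
  expect_equal(est$censoring_aware, 1)
  z <- data.frame(n_bursts = 0, observation_time = 10, censored = FALSE,
                  exposure_min = 10)
  ez <- nucleation_rate(z)
  expect_equal(ez$naive, 0)
  expect_equal(ez$upper95, 3.689 / 10, tolerance = 1e-4)

  # censoring study: at a high true rate with a per-patch cap the naive
  # estimator underestimates; the exposure-based one does not
  set.seed(202)
  rate <- 2; T_obs <- 10; cap <- 3
  sims <- lapply(1:4000, function(i) {
    times <- cumsum(rexp(50, rate))
    times <- times[times <= T_obs]
    k <- length(times)
    if (k > cap) {
      patch_summary(n_bursts = cap, observation_time = T_obs,
                    censored = TRUE, exposure_min = times[cap])
    } else {
      patch_summary(n_bursts = k, observation_time = T_obs,
                    censored = FALSE)
    }
  })
  est <- nucleation_rate(do.call(rbind, sims))
  expect_lt(est$naive, 0.9 * rate)
  expect_lt(abs(est$censoring_aware - rate), 0.05 * rate)
  expect_lt(abs(est$naive - rate), abs(est$censoring_aware - rate) + rate)
  expect_error(nucleation_rate(data.frame(n_bursts = 1,
                                          observation_time = 0,
                                          censored = FALSE,
                                          exposure_min = 0)), "time")
})

test_that("expansion rate reproduces analytic ramp and step limits", {
  dt <- 0.1
  n <- 2000
  ramp <- structure(list(
    t_on = 0, t_off = 200, dwells = data.frame(),
    samples = seq(0, 1000, length.out = n), open_idx = rep(TRUE, n),
    sample_interval = dt), class = "pore_burst")
  er <- expansion_rate(list(ramp), window = 100)
  # 10-90% rise of a linear ramp: rate = 0.8 * G100 / (0.8 * 100 ms)
  expect_equal(er$rate_nS_per_s, 0.8 * er$G_ref_pS / 80, tolerance = 0.03)
  expect_equal(er$rate_nS_per_s, 10, tolerance = 0.7)

  step <- ramp
  step$samples <- rep(1000, n)
  es <- expansion_rate(list(step), window = 100)
  expect_equal(es$t90_ms - es$t10_ms, 0)        # both cross at sample 1
  expect_equal(es$rate_nS_per_s, 0.8 * 1000 / dt)  # clamped to one sample
  short <- ramp; short$samples <- short$samples[1:10]
  expect_error(expansion_rate(list(short), window = 100), "window")
})
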