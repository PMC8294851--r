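test_that("parameter and preset invariants are enforced", {
  expect_error(generator_params(flicker_success_prob = 1.5), "flicker")
  expect_error(generator_params(flicker_success_prob = 0), "flicker")
  expect_error(generator_params(burst_mean_duration = -1), "burst_mean")
  expect_error(generator_params(sample_interval = 10), "sample_interval")
  expect_error(condition_preset(calcium = -1), "calcium")
  expect_error(condition_preset(conductance_scale = 0), "scales")
  # derived open dwell is consistent with the stated expectation identity
  p <- generator_params()
  expect_equal(p$open_mean_dwell,
               0.25 * 3000 - 0.75 * 20)
})

test_that("condition presets reproduce the direction of condition effects", {
  law <- hill_law()
  wt_ca <- condition_preset("c2ab_wt", calcium = 100)
  wt_0 <- condition_preset("c2ab_wt", calcium = 0)
  none <- condition_preset("no_syt", calcium = 100)
  muts <- lapply(c("c2ab_D309N", "c2ab_K326A_K327A",
                   "c2ab_R398Q_R399Q", "c2ab_4A"),
                 condition_preset, calcium = 100)
  gp <- generator_params()
  lvl <- function(pr) fusepore:::preset_open_level(gp, pr, law)
  # calcium roughly triples the wild-type level; mutants collapse to the
  # calcium-insensitive (SNARE-alone) level
  expect_gt(lvl(wt_ca) / lvl(none), 2.5)
  expect_equal(lvl(wt_0), law$c, tolerance = 1e-9)
  for (m in muts) expect_equal(lvl(m), lvl(none))
  # PI(4,5)P2 withdrawal disables the calcium response
  no_pip2 <- condition_preset("c2ab_wt", calcium = 100, pip2_present = FALSE)
  expect_equal(lvl(no_pip2), law$c)
  # 4W keeps the wild-type calcium response
  expect_equal(lvl(condition_preset("c2ab_4W", calcium = 100)), lvl(wt_ca))
})

test_that("burst draws follow the stated dwell-time distributions", {
  set.seed(101)
  gp <- generator_params(seed = NULL)
  pre <- condition_preset("c2ab_wt", calcium = 100)
  n <- 10000
  Ns <- Ts <- numeric(n); open_t <- tot_t <- 0
  for (i in seq_len(n)) {
    b <- simulate_burst(gp, pre)
    Ns[i] <- b$n_flickers; Ts[i] <- b$T_o
    open_t <- open_t + sum(b$dwells$duration_ms[b$dwells$state == "open"])
    tot_t <- tot_t + b$T_o
    # bursts begin and end open
    expect_identical(b$dwells$state[1], "open")
    expect_identical(b$dwells$state[nrow(b$dwells)], "open")
  }
  # sample means within 3 SE of the generative parameters
  expect_lt(abs(mean(Ts) - 3000), 3 * sd(Ts) / sqrt(n))
  expect_lt(abs(mean(Ns) - (1 - 0.25) / 0.25), 3 * sd(Ns) / sqrt(n))
  # goodness of fit at alpha = 0.01
  expect_gt(ks.test(Ts, "pexp", 1 / 3000)$p.value, 0.01)
  obs <- table(factor(pmin(Ns, 15), levels = 0:15))
  pg <- dgeom(0:15, 0.25); pg[16] <- 1 - pgeom(14, 0.25)
  expect_gt(suppressWarnings(chisq.test(obs, p = pg))$p.value, 0.01)
  # open fraction converges to open/(open + expected closed) within 2%
  expect_equal(open_t / tot_t, 735 / (735 + 0.75 * 20), tolerance = 0.02)
})

test_that("degenerate geometric parameter gives flicker-free bursts", {
  set.seed(5)
  gp <- generator_params(flicker_success_prob = 1, seed = NULL)
  pre <- condition_preset("c2ab_wt")
  for (i in 1:50) {
    b <- simulate_burst(gp, pre)
    expect_identical(b$n_flickers, 0L)
    expect_identical(nrow(b$dwells), 1L)
  }
})

test_that("patch recordings are deterministic and annotated", {
  gp <- generator_params(patch_duration = 0.5, seed = 77)
  pre <- condition_preset("c2ab_wt", calcium = 100)
  r1 <- simulate_patch_recording(gp, pre)
  r2 <- simulate_patch_recording(gp, pre)
  expect_identical(r1$trace$conductance, r2$trace$conductance)
  expect_identical(r1$annotations, r2$annotations)
  expect_equal(length(r1$trace$time),
               floor(0.5 * 60 * 1000 / gp$sample_interval))
  if (nrow(r1$annotations) > 0) {
    expect_true(all(r1$annotations$t_off_ms > r1$annotations$t_on_ms))
    # dwell tables tile each burst
    for (id in r1$annotations$burst_id) {
      dw <- r1$dwells[r1$dwells$burst_id == id, ]
      expect_equal(dw$t_start_ms[-1], dw$t_end_ms[-nrow(dw)],
                   tolerance = 1e-9)
    }
  }
})

test_that("zero nucleation yields a pure-noise trace with no annotations", {
  gp <- generator_params(nucleation_rate = 0, patch_duration = 0.2, seed = 3)
  rec <- simulate_patch_recording(gp, condition_preset("no_syt"))
  expect_identical(nrow(rec$annotations), 0L)
  expect_lt(max(abs(rec$trace$conductance)), 6 * gp$baseline_noise_sd)
  gp$patch_duration <- -1
  expect_error(simulate_patch_recording(gp, condition_preset()),
               "patch_duration")
})

test_that("trace and annotation files round-trip through text", {
  gp <- generator_params(nucleation_rate = 30, patch_duration = 0.2,
                         seed = 9)
  rec <- simulate_patch_recording(gp, condition_preset("c2ab_wt",
                                                       calcium = 50))
  expect_gt(nrow(rec$annotations), 0)
  tf <- tempfile(fileext = ".txt")
  write_trace(rec$trace, tf)
  back <- read_trace(tf)
  expect_equal(back$conductance, rec$trace$conductance, tolerance = 1e-6)
  expect_equal(back$metadata$calcium, 50)
  expect_equal(back$metadata$sample_interval,
               rec$trace$metadata$sample_interval)
  af <- tempfile(fileext = ".tsv")
  write_annotations(rec$annotations, af)
  expect_equal(read_annotations(af), rec$annotations, tolerance = 1e-9)
  unlink(c(tf, af))
})

test_that("simulated calcium grid follows the Hill law of the generator", {
  set.seed(88)
  law <- hill_law()
  gp <- generator_params(seed = NULL)
  for (ca in c(0, 10, 30, 100)) {
    pre <- condition_preset("c2ab_wt", calcium = ca)
    g <- replicate(200, simulate_burst(gp, pre)$G_open)
    expect_equal(mean(g), hill_conductance(ca, law), tolerance = 1e-9)
  }
})
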