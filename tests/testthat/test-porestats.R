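test_that("cylinder model reproduces the reference conductance-radius pairs", {
  expect_equal(conductance_to_radius(200), 0.76, tolerance = 0.01)
  expect_equal(conductance_to_radius(1000), 1.70, tolerance = 0.005)
  g5 <- radius_to_conductance(5) / 1000       # 10 nm diameter pore, in nS
  expect_gt(g5, 8.5)
  expect_lt(g5, 9.5)
  expect_equal(conductance_to_radius(0), 0)
  expect_equal(radius_to_conductance(0), 0)
  expect_error(conductance_to_radius(-1), "G")
  expect_error(radius_to_conductance(-1), "r")
})

test_that("radius-conductance round trip is exact and monotone", {
  for (model in list(conductance_model(),
                     conductance_model(include_access_resistance = TRUE))) {
    r <- c(0.5, 1, 2, 5)
    expect_equal(conductance_to_radius(radius_to_conductance(r, model), model),
                 r, tolerance = 1e-10)
    g <- seq(10, 5000, length.out = 50)
    expect_true(all(diff(conductance_to_radius(g, model)) > 0))
  }
})

test_that("access resistance lowers conductance, vanishing as r/L -> 0", {
  cyl <- conductance_model()
  acc <- conductance_model(include_access_resistance = TRUE)
  r <- c(0.2, 0.5, 1, 2, 5)
  g_cyl <- radius_to_conductance(r, cyl)
  g_acc <- radius_to_conductance(r, acc)
  expect_true(all(g_acc < g_cyl))
  ratio <- g_acc / g_cyl      # -> 1 as the pore narrows relative to L
  expect_true(all(diff(ratio) < 0))
  expect_gt(ratio[1], 0.95)
})

test_that("histogram density estimates behave as densities", {
  p1 <- estimate_pdf(rep(3.14, 500), bin_width = 0.1)
  expect_equal(sum(p1$density > 0), 1)
  expect_equal(max(p1$density), 1 / 0.1)
  set.seed(2)
  u <- runif(20000)
  pu <- estimate_pdf(u, bin_width = 0.1)
  inner <- pu$density[pu$mid > 0.05 & pu$mid < 0.95]
  expect_true(all(abs(inner - 1) < 0.1))
  # Gamma-distributed samples: density within 3 SE of truth per bin
  g <- rgamma(50000, shape = 3, rate = 2)
  pg <- estimate_pdf(g, bin_width = 0.1)
  keep <- pg$count >= 50
  truth <- dgamma(pg$mid[keep], 3, 2)
  se <- sqrt(pg$density[keep] / (50000 * 0.1))
  expect_true(mean(abs(pg$density[keep] - truth) < 3 * pmax(se, 1e-3)) > 0.95)
  expect_error(estimate_pdf(numeric(0), 0.1), "samples")
  expect_error(estimate_pdf(1:10, -1), "bin_width")
})

test_that("Boltzmann inversion recovers known free-energy shapes", {
  # uniform density -> flat profile at 0
  flat <- data.frame(mid = 1:10, density = rep(0.1, 10), count = rep(100, 10))
  expect_true(all(boltzmann_invert(flat)$U == 0))
  # Gaussian density -> quadratic with curvature 1/s^2
  s <- 0.3
  x <- seq(-1, 1, by = 0.02)
  gauss <- data.frame(mid = x, density = dnorm(x, 0, s),
                      count = rep(1000, length(x)))
  prof <- boltzmann_invert(gauss)
  expect_equal(prof$U, 0.5 * (x / s)^2, tolerance = 1e-8)
  expect_error(boltzmann_invert(data.frame(mid = 1, density = 0, count = 0)),
               "positive")
})

test_that("sampling from exp(-U) and inverting recovers U", {
  # prescribed double-well-free profile: quadratic about 1.5 nm
  r_grid <- seq(0.5, 3, by = 0.001)
  U_true <- function(r) 4 * (r - 1.5)^2
  pdf_true <- exp(-U_true(r_grid))
  cdf <- cumsum(pdf_true) / sum(pdf_true)
  set.seed(31)
  samples <- approx(cdf, r_grid, xout = runif(1e5), rule = 2)$y
  est <- estimate_pdf(samples, bin_width = 0.05)
  prof <- boltzmann_invert(est, min_count = 100)
  err <- (prof$U - min(prof$U)) -
    (U_true(prof$r) - min(U_true(prof$r)))
  expect_lt(sqrt(mean(err^2)), 0.2)
  expect_lt(max(abs(err[est$count[est$density > 0 &
                                  est$count >= 100] >= 500])), 0.2)
})

test_that("barrier heights convert to the reference forces", {
  prof <- data.frame(r = c(1, 2.5), P = exp(-c(0, 2)), U = c(0, 2))
  class(prof) <- c("free_energy_profile", "data.frame")
  bf <- barrier_force(prof, 1, 2.5)
  expect_equal(bf$dU_kT, 2)
  expect_equal(bf$force_pN, 2 * 4.114 / 1.5, tolerance = 1e-10)  # ~5.5 pN
  expect_gt(bf$force_pN, 4.5); expect_lt(bf$force_pN, 6)
  prof2 <- prof; prof2$U <- c(0, 6.5)
  f2 <- barrier_force(prof2, 1, 2.5)$force_pN
  expect_gt(f2, 16); expect_lt(f2, 19)                            # 17.8 pN
  prof0 <- prof; prof0$U <- c(0, 0)
  expect_equal(barrier_force(prof0, 1, 2.5)$force_pN, 0)
  expect_error(barrier_force(prof, 2.5, 1), "r1 < r2")
  expect_error(barrier_force(prof, 0.1, 2), "support")
})
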