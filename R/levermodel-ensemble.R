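#' Full lever-model parameter bundle
#'
#' Collects the membrane, scaffold, SNARE, C2B and conductance-model
#' parameters plus the numerical grids for the mechanical model of
#' calcium-triggered fusion pore dilation. Defaults are the calibrated
#' values frozen by [calibrate_lever_model()]: with the Hill burial
#' response, tilt geometry, SNARE count and disc size pinned to their
#' measured values, the remaining mechanical parameters were fitted
#' within literature ranges so that the zero-calcium ensemble reproduces
#' the reference pore statistics; the with-calcium behavior is then a
#' parameter-free prediction.
#'
#' @param mem A [membrane_params()].
#' @param scaf A [scaffold_params()].
#' @param snares A [snare_params()].
#' @param c2b A [c2b_params()].
#' @param conduct A [conductance_model()] used to map radii to
#'   conductances.
#' @param r_grid Waist radii (nm) at which the free energy is evaluated.
#' @param h_grid Rim heights (nm) scanned when minimizing over height.
#' @param untilted_constrains Does the unburied (parallel) complex impose
#'   its minimum-thickness separation on the pore? Default `FALSE` (the
#'   unburied complex lies flat and imposes no constraint); set `TRUE`
#'   to impose the minimum-thickness separation in the unburied state
#'   too.
#' @param n_nodes Collocation nodes per shape-solver segment.
#' @return An object of class `lever_params`.
#' @export
lever_params <- function(mem = membrane_params(),
                         scaf = scaffold_params(),
                         snares = snare_params(),
                         c2b = c2b_params(),
                         conduct = conductance_model(),
                         r_grid = seq(0.3, 4, by = 0.05),
                         h_grid = seq(2, 16, by = 0.5),
                         untilted_constrains = FALSE,
                         n_nodes = 12) {
  stopifnot(inherits(mem, "membrane_params"),
            inherits(scaf, "scaffold_params"),
            inherits(snares, "snare_params"),
            inherits(c2b, "c2b_params"),
            inherits(conduct, "conductance_model"))
  if (any(diff(r_grid) <= 0) || any(r_grid <= 0)) {
    stop("lever_params: r_grid must be positive and increasing")
  }
  structure(list(mem = mem, scaf = scaf, snares = snares, c2b = c2b,
                 conduct = conduct, r_grid = r_grid, h_grid = h_grid,
                 untilted_constrains = isTRUE(untilted_constrains),
                 n_nodes = n_nodes),
            class = "lever_params")
}

#' @export
print.lever_params <- function(x, ...) {
  cat("Lever model parameters:\n")
  cat(sprintf("  membrane: kappa = %g kT, gamma = %g kT/nm^2\n",
              x$mem$kappa, x$mem$gamma))
  cat(sprintf("  scaffold: disc %g nm (%s)\n", x$scaf$disc_radius,
              x$scaf$edge))
  cat(sprintf("  SNAREs: N = %d, dG_zip = %g kT, rod %g nm\n",
              x$snares$N, x$snares$dG_zip, x$snares$rod_footprint))
  cat(sprintf("  C2B: Hill n = %g, K = %g uM, tilt %g deg, capsule %g x %g nm\n",
              x$c2b$hill_n, x$c2b$hill_K, x$c2b$tilt_angle,
              x$c2b$complex_length, x$c2b$complex_diameter))
  cat(sprintf("  grids: r in [%g, %g] (%d), h in [%g, %g] (%d)\n",
              min(x$r_grid), max(x$r_grid), length(x$r_grid),
              min(x$h_grid), max(x$h_grid), length(x$h_grid)))
  invisible(x)
}

#' Membrane energy and clearance tables over the (r, h) grid
#'
#' Solves the membrane shape problem on a lattice of waist radii and rim
#' heights (warm-starting each solve from its neighbor) and records the
#' membrane energy, the waist height, and the untilted/tilted clearance
#' margins of the SNARE-C2B capsule. The table is calcium-independent,
#' so one table serves a whole calcium titration. Radii are solved on a
#' decimated sub-grid (every `r_stride`-th ensemble radius) and energies
#' and margins are interpolated linearly in r back onto the full grid.
#'
#' @param params A [lever_params()].
#' @param r_stride Solve every `r_stride`-th radius of `r_grid`.
#'   Default 2.
#' @param verbose Print progress.
#' @return An object of class `membrane_table`: list with `r`, `h`,
#'   matrices `E`, `z_w`, `margin_u`, `margin_t`, `converged` (rows = r,
#'   columns = h).
#' @export
membrane_table <- function(params, r_stride = 2, verbose = FALSE) {
  stopifnot(inherits(params, "lever_params"))
  r_all <- params$r_grid
  idx <- unique(c(seq(1, length(r_all), by = r_stride), length(r_all)))
  r_solve <- r_all[idx]
  h <- params$h_grid
  nr <- length(r_solve); nh <- length(h)
  E <- zw <- mu <- mt <- matrix(NA_real_, nr, nh)
  cv <- matrix(FALSE, nr, nh)
  col_init <- NULL
  for (i in seq_len(nr)) {
    init <- col_init
    for (j in seq_len(nh)) {
      sh <- solve_shape(r_solve[i], h[j], params$mem, params$scaf,
                        n_nodes = params$n_nodes, init = init)
      init <- sh$opt_par
      if (j == 1) col_init <- sh$opt_par
      E[i, j] <- sh$energy
      zw[i, j] <- sh$z_w
      mu[i, j] <- clearance_margin(sh, tilted = FALSE, params$c2b)
      mt[i, j] <- clearance_margin(sh, tilted = TRUE, params$c2b)
      cv[i, j] <- sh$converged
    }
    if (verbose) {
      message(sprintf("membrane_table: r = %.2f nm (%d/%d)",
                      r_solve[i], i, nr))
    }
  }
  interp_r <- function(M) {
    apply(M, 2, function(col) stats::approx(r_solve, col, xout = r_all)$y)
  }
  structure(list(r = r_all, h = h,
                 E = interp_r(E), z_w = interp_r(zw),
                 margin_u = interp_r(mu), margin_t = interp_r(mt),
                 converged = apply(cv, 2, function(col) {
                   stats::approx(r_solve, as.numeric(col), xout = r_all,
                                 method = "constant", f = 0)$y > 0.5
                 }),
                 r_solve = r_solve),
            class = "membrane_table")
}

# ln of the clearance-gated Boltzmann state sum at one (r, h, p_buried)
gated_lnZ <- function(r, ok_u, ok_t, p, params) {
  sn <- params$snares
  lnw <- snare_state_lnw(r, sn)   # n_zip = 0..N
  n <- 0:sn$N
  if (!params$untilted_constrains) ok_u <- TRUE
  gate <- ifelse(n == 0, 1,
                 (1 - p)^n * as.numeric(ok_u) +
                   (1 - (1 - p)^n) * as.numeric(ok_t))
  logsumexp(lnw + log(gate))
}

#' Total free energy of the pore at one radius, minimized over height
#'
#' For each height on the grid, adds the membrane (+ scaffold) energy to
#' the free energy of the clearance-gated SNARE-C2B state sum (zippered
#' counts 0..N, burial patterns Bernoulli(`p_buried`) per zippered
#' complex, with the tilted constraint applying whenever at least one
#' zippered complex is buried), and returns the minimum over height and
#' the minimizing height (parabolically refined around the grid
#' minimum).
#'
#' @param r Waist radius, nm (within the model range).
#' @param calcium Free calcium, uM.
#' @param params A [lever_params()].
#' @param table Optional precomputed [membrane_table()]; if `NULL`,
#'   shapes are solved on the fly for this radius.
#' @return A list with `U` (kT), `h_star` (nm), and `detail`
#'   (data.frame `h`, `E_mem`, `U`).
#' @export
total_free_energy <- function(r, calcium, params = lever_params(),
                              table = NULL) {
  stopifnot(inherits(params, "lever_params"))
  p <- buried_probability(calcium, params$c2b)
  h <- params$h_grid
  if (is.null(table)) {
    E <- mu <- mt <- numeric(length(h))
    conv <- logical(length(h))
    init <- NULL
    for (j in seq_along(h)) {
      sh <- solve_shape(r, h[j], params$mem, params$scaf,
                        n_nodes = params$n_nodes, init = init)
      init <- sh$opt_par
      E[j] <- sh$energy
      mu[j] <- clearance_margin(sh, FALSE, params$c2b)
      mt[j] <- clearance_margin(sh, TRUE, params$c2b)
      conv[j] <- sh$converged
    }
  } else {
    i <- which.min(abs(table$r - r))
    if (abs(table$r[i] - r) > 1e-6) {
      stop("total_free_energy: r not on the table grid")
    }
    E <- table$E[i, ]; mu <- table$margin_u[i, ]; mt <- table$margin_t[i, ]
    conv <- table$converged[i, ]
  }
  lnz <- vapply(seq_along(h), function(j) {
    gated_lnZ(r, mu[j] >= 0, mt[j] >= 0, p, params)
  }, numeric(1))
  U <- ifelse(conv, E - lnz, Inf)
  j <- which.min(U)
  if (!is.finite(U[j])) {
    return(list(U = Inf, h_star = NA_real_,
                detail = data.frame(h = h, E_mem = E, U = U)))
  }
  h_star <- h[j]; U_star <- U[j]
  if (j > 1 && j < length(h) && all(is.finite(U[(j - 1):(j + 1)]))) {
    # parabolic refinement through the three bracketing grid points
    y1 <- U[j - 1]; y2 <- U[j]; y3 <- U[j + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom > 1e-12) {
      delta <- 0.5 * (y1 - y3) / denom
      delta <- max(-1, min(1, delta))
      h_star <- h[j] + delta * (h[j + 1] - h[j])
      U_star <- y2 - 0.25 * (y1 - y3) * delta
    }
  }
  list(U = U_star, h_star = h_star,
       detail = data.frame(h = h, E_mem = E, U = U))
}

#' Boltzmann ensemble of pore radii at a given calcium concentration
#'
#' Evaluates the height-minimized total free energy `U(r)` on the model's
#' radius grid, forms `P(r) ~ exp(-U(r))` (normalized on the grid), and
#' reports the ensemble means of radius, height and conductance. The
#' reported mean pore height is the structural height of the pore: the
#' rim height of the solved midplane profile plus one bilayer thickness
#' (the distance between the outer monolayer midplanes of the cell
#' membrane and the nanodisc).
#'
#' @param params A [lever_params()].
#' @param calcium Free calcium, uM.
#' @param table A [membrane_table()]; computed on demand when `NULL`
#'   (expensive - reuse one table across calcium values).
#' @return An object of class `model_ensemble`: data.frame-like list with
#'   `grid` (data.frame `r`, `U`, `P`, `h_star`), `mean_r`, `mean_h`,
#'   `mean_G`, `var_r`, `calcium`.
#' @export
ensemble_statistics <- function(params = lever_params(), calcium = 0,
                                table = NULL) {
  stopifnot(inherits(params, "lever_params"))
  if (is.null(table)) table <- membrane_table(params)
  res <- lapply(params$r_grid, function(r) {
    total_free_energy(r, calcium, params, table = table)
  })
  U <- vapply(res, `[[`, numeric(1), "U")
  h_star <- vapply(res, `[[`, numeric(1), "h_star")
  keep <- is.finite(U)
  if (!any(keep)) stop("ensemble_statistics: no feasible radius")
  r <- params$r_grid
  Un <- U - min(U[keep])
  P <- ifelse(keep, exp(-Un), 0)
  P <- P / sum(P)
  G <- radius_to_conductance(r, params$conduct)
  mean_r <- sum(P * r)
  out <- list(grid = data.frame(r = r, U = Un, P = P, h_star = h_star),
              mean_r = mean_r,
              # pore height = rim height of the midplane profile plus one
              # bilayer thickness (distance between the outer monolayer
              # midplanes of the two membranes)
              mean_h = sum(P[keep] * h_star[keep]) / sum(P[keep]) +
                params$mem$thickness,
              mean_G = sum(P * G),
              var_r = sum(P * (r - mean_r)^2),
              calcium = calcium)
  class(out) <- "model_ensemble"
  out
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf(
    "model_ensemble @ [Ca2+] = %g uM: <r> = %.3f nm, <h> = %.2f nm, <G> = %.0f pS\n",
    x$calcium, x$mean_r, x$mean_h, x$mean_G))
  invisible(x)
}

#' Calcium titration of the lever model
#'
#' Runs [ensemble_statistics()] across a calcium grid, reusing one
#' membrane table, and reports fold-changes of mean radius and mean
#' conductance relative to zero calcium.
#'
#' @param params A [lever_params()].
#' @param calcium Vector of free calcium concentrations, uM (should
#'   include 0 for the fold-change reference).
#' @param table Optional precomputed [membrane_table()].
#' @param verbose Print progress.
#' @return A data.frame with columns `calcium`, `mean_r`, `mean_h`,
#'   `mean_G`, `var_r`, `fold_r`, `fold_G`; the membrane table is
#'   attached as attribute `"table"`.
#' @export
lever_titration <- function(params = lever_params(),
                            calcium = c(0, 5, 10, 20, 30, 50, 100, 300, 1000),
                            table = NULL, verbose = FALSE) {
  if (is.null(table)) table <- membrane_table(params, verbose = verbose)
  rows <- lapply(calcium, function(ca) {
    e <- ensemble_statistics(params, ca, table = table)
    data.frame(calcium = ca, mean_r = e$mean_r, mean_h = e$mean_h,
               mean_G = e$mean_G, var_r = e$var_r)
  })
  out <- do.call(rbind, rows)
  ref <- which(out$calcium == 0)[1]
  if (is.na(ref)) ref <- which.min(out$calcium)
  out$fold_r <- out$mean_r / out$mean_r[ref]
  out$fold_G <- out$mean_G / out$mean_G[ref]
  attr(out, "table") <- table
  out
}

#' Calibrate the lever model against reference pore statistics
#'
#' Grid search over candidate mechanical parameters (those not pinned by
#' direct measurement) minimizing a weighted squared error to the
#' zero-calcium calibration targets: mean pore radius, mean pore height,
#' and the free-energy rise from 1 to 2.5 nm. Candidates are given as a
#' named list of value vectors (names among `kappa`, `gamma`, `dG_zip`,
#' `rod_footprint`, `complex_length`, `complex_diameter`); all
#' combinations are evaluated. The with-calcium behavior is never part
#' of the objective: it stays a prediction.
#'
#' @param params Base [lever_params()] (grids may be coarsened for
#'   speed).
#' @param candidates Named list of candidate values per parameter.
#' @param targets List with `mean_r` (nm), `mean_h` (nm), `barrier` (kT
#'   from 1 to 2.5 nm).
#' @param weights Relative weights of the three target errors.
#' @param verbose Print each candidate's score.
#' @return A list with `best` (the winning `lever_params`), `results`
#'   (data.frame of all candidates and their statistics), sorted by
#'   score.
#' @export
calibrate_lever_model <- function(params = lever_params(),
                                  candidates,
                                  targets = list(mean_r = 0.9, mean_h = 9.0,
                                                 barrier = 6.5),
                                  weights = c(mean_r = 1, mean_h = 0.2,
                                              barrier = 0.3),
                                  verbose = TRUE) {
  grid <- do.call(expand.grid, candidates)
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    pk <- apply_candidate(params, grid[k, , drop = FALSE])
    tab <- membrane_table(pk)
    e0 <- ensemble_statistics(pk, 0, table = tab)
    bar <- profile_rise(e0, 1, 2.5)
    score <- weights[["mean_r"]] * (e0$mean_r - targets$mean_r)^2 +
      weights[["mean_h"]] * (e0$mean_h - targets$mean_h)^2 +
      weights[["barrier"]] * (bar - targets$barrier)^2
    rows[[k]] <- cbind(grid[k, , drop = FALSE],
                       data.frame(mean_r = e0$mean_r, mean_h = e0$mean_h,
                                  barrier = bar, score = score))
    if (verbose) {
      message(sprintf("calibrate[%d/%d]: %s -> r %.2f h %.2f bar %.2f (%.4f)",
                      k, nrow(grid),
                      paste(names(grid), grid[k, ], sep = "=",
                            collapse = ", "),
                      e0$mean_r, e0$mean_h, bar, score))
    }
  }
  results <- do.call(rbind, rows)
  results <- results[order(results$score), ]
  best <- apply_candidate(params, results[1, names(candidates),
                                          drop = FALSE])
  list(best = best, results = results)
}

apply_candidate <- function(params, row) {
  p <- params
  for (nm in names(row)) {
    v <- row[[nm]]
    if (nm == "kappa") p$mem$kappa <- v
    else if (nm == "gamma") p$mem$gamma <- v
    else if (nm == "dG_zip") p$snares$dG_zip <- v
    else if (nm == "rod_footprint") p$snares$rod_footprint <- v
    else if (nm == "trans_area") p$snares$trans_area <- v
    else if (nm == "complex_length") p$c2b$complex_length <- v
    else if (nm == "complex_diameter") p$c2b$complex_diameter <- v
    else stop("calibrate_lever_model: unknown parameter ", nm)
  }
  p
}

# U(r2) - U(r1) from a model ensemble's free-energy grid
profile_rise <- function(ensemble, r1, r2) {
  g <- ensemble$grid[is.finite(ensemble$grid$U), ]
  u <- stats::approx(g$r, g$U, xout = c(r1, r2))$y
  u[2] - u[1]
}
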