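#' Membrane mechanical parameters
#'
#' Helfrich-framework parameters of the fusion pore membrane: bending
#' modulus, lateral tension and spontaneous curvature, plus the radius of
#' the remote boundary where the membrane joins the (flat) target cell
#' with zero slope.
#'
#' @param kappa Bending modulus, kT. Default 12 (calibrated; soft
#'   fluid-phase bilayer).
#' @param gamma Membrane tension, kT/nm^2. Default 0.12 (calibrated;
#'   ~0.5 mN/m).
#' @param c0 Spontaneous curvature, 1/nm. Default 0.
#' @param remote_radius Radial position of the remote (flat, zero-slope)
#'   boundary, nm. Default 50 (four disc radii, several tension decay
#'   lengths). Absolute energies retain a slowly decaying boundary
#'   offset, but energy differences across (r, h) - which set the
#'   ensemble - are insensitive to doubling it.
#' @param thickness Bilayer steric thickness, nm (default 4). The solved
#'   surfaces are bilayer midplanes; the sterically available pore lumen
#'   is the membrane separation minus this thickness.
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(kappa = 12, gamma = 0.12, c0 = 0,
                            remote_radius = 50, thickness = 4) {
  if (kappa <= 0) stop("membrane_params: kappa must be > 0")
  if (gamma < 0) stop("membrane_params: gamma must be >= 0")
  if (remote_radius <= 0) stop("membrane_params: remote_radius must be > 0")
  if (thickness < 0) stop("membrane_params: thickness must be >= 0")
  structure(list(kappa = kappa, gamma = gamma, c0 = c0,
                 remote_radius = remote_radius, thickness = thickness),
            class = "membrane_params")
}

#' Nanodisc scaffold parameters
#'
#' The ApoE scaffold bounding the nanodisc is represented by its ring
#' radius and an edge condition: `clamped_ring` (membrane meets the ring
#' horizontally), `hinged_ring` (free contact angle), or `elastic_ring`
#' (free angle and a stretchable ring radius with a quadratic stretch
#' energy).
#'
#' @param disc_radius Nanodisc radius, nm. Default 12.5 (~25 nm NLP).
#' @param edge One of `"clamped_ring"`, `"hinged_ring"`, `"elastic_ring"`.
#' @param ring_modulus Ring stretch modulus, kT/nm^2 (elastic ring only).
#' @return An object of class `scaffold_params`.
#' @export
scaffold_params <- function(disc_radius = 12.5, edge = "clamped_ring",
                            ring_modulus = 5) {
  edge <- match.arg(edge, c("clamped_ring", "hinged_ring", "elastic_ring"))
  if (disc_radius <= 0) stop("scaffold_params: disc_radius must be > 0")
  structure(list(disc_radius = disc_radius, edge = edge,
                 ring_modulus = ring_modulus),
            class = "scaffold_params")
}

# --- collocation machinery -------------------------------------------------
#
# The pore profile is one axisymmetric curve in the (rho, z) plane,
# traversed from the remote boundary (rho = R_out, z = 0, tangent angle
# phi = pi) through the waist (rho = r, phi = pi/2) to the disc rim
# (rho ~ disc_radius, phi = 0 when clamped). With rho' = cos(phi),
# z' = sin(phi), the principal curvatures are phi' and sin(phi)/rho and
# the Helfrich energy is (kappa/2) Int (phi' + sin(phi)/rho - c0)^2 dA
# + gamma * excess area. phi(t) on each of the two segments is a natural
# cubic spline through control values at nodes graded toward the waist,
# evaluated on a finer graded quadrature grid; the unknowns are the
# interior control values and the two segment arc lengths.

.basis_cache <- new.env(parent = emptyenv())

# value and derivative basis matrices mapping control values at `ct`
# to natural-spline values at `tq`
spline_basis <- function(ct, tq) {
  key <- paste(length(ct), length(tq), signif(ct[2], 6), sep = "_")
  hit <- .basis_cache[[key]]
  if (!is.null(hit)) return(hit)
  nc <- length(ct)
  S <- matrix(0, length(tq), nc)
  D <- matrix(0, length(tq), nc)
  for (j in seq_len(nc)) {
    e <- numeric(nc); e[j] <- 1
    f <- stats::splinefun(ct, e, method = "natural")
    S[, j] <- f(tq)
    D[, j] <- f(tq, deriv = 1)
  }
  out <- list(S = S, D = D)
  .basis_cache[[key]] <- out
  out
}

# graded grids: dense near the waist end of each segment
shape_grids <- function(n_ctrl, n_quad, grade = 2.2) {
  u_c <- seq(0, 1, length.out = n_ctrl)
  u_q <- seq(0, 1, length.out = n_quad)
  g1c <- 1 - (1 - u_c)^grade   # segment 1: waist at t = 1
  g1q <- 1 - (1 - u_q)^grade
  g2c <- u_c^grade             # segment 2: waist at t = 0
  g2q <- u_q^grade
  list(b1 = spline_basis(g1c, g1q), b2 = spline_basis(g2c, g2q),
       t1 = g1q, t2 = g2q)
}

cumtrapz_nu <- function(y, x) c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(x)))
trapz_nu <- function(y, x) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

shape_cpp_args <- function(r, h, mem, scaf, gr) {
  list(r = r, h = h, kappa = mem$kappa, gamma = mem$gamma, c0 = mem$c0,
       R_out = mem$remote_radius, R_d = scaf$disc_radius,
       hinged = as.integer(scaf$edge != "clamped_ring"),
       elastic = as.integer(scaf$edge == "elastic_ring"),
       ring_modulus = scaf$ring_modulus,
       S1 = gr$b1$S, D1 = gr$b1$D, S2 = gr$b2$S, D2 = gr$b2$D,
       t1 = gr$t1, t2 = gr$t2)
}

shape_eval <- function(par, r, h, mem, scaf, gr) {
  do.call(shape_eval_cpp,
          c(list(par = par), shape_cpp_args(r, h, mem, scaf, gr)))
}

default_shape_init <- function(r, h, mem, scaf, nc) {
  R_out <- mem$remote_radius
  R_d <- scaf$disc_radius
  u <- seq(0, 1, length.out = nc)
  t1 <- 1 - (1 - u)^2.2
  phi1 <- pi - (pi / 2) * t1^6          # flat skirt, sharp rise at the waist
  L1 <- (R_out - r) * 1.1
  t2 <- u^2.2
  phi2 <- (pi / 2) * (1 - t2)
  L2 <- max(sqrt((R_d - r)^2 + max(h - 1, 1)^2), R_d - r) * 1.15
  par <- c(phi1[2:(nc - 1)], log(L1))
  if (scaf$edge != "clamped_ring") par <- c(par, 0)
  par <- c(par, phi2[2:(nc - 1)], log(L2))
  if (scaf$edge == "elastic_ring") par <- c(par, log(R_d))
  par
}

#' Minimum-energy axisymmetric fusion pore shape
#'
#' Solves for the energy-minimizing axisymmetric membrane profile
#' connecting the nanodisc membrane (edge at `disc_radius`, per the
#' scaffold edge condition) to the flat cell membrane (zero slope at the
#' remote boundary) through a waist of radius `r`, with the disc rim a
#' height `h` above the cell membrane plane. The tangent angle along the
#' curve is represented by natural cubic splines on two arc-length
#' segments (remote-to-waist, waist-to-rim) with nodes graded toward the
#' waist, and the discretized Helfrich energy (bending + tension, plus
#' ring stretch for an elastic scaffold edge) is minimized with boundary
#' and waist conditions enforced by a quadratic penalty ramp; the
#' stationary discretized energy is the collocated membrane shape
#' equation.
#'
#' @param r Waist radius, nm (> 0).
#' @param h Disc rim height above the cell membrane, nm (>= 0).
#' @param mem A [membrane_params()].
#' @param scaf A [scaffold_params()].
#' @param n_nodes Spline control nodes per segment. Default 9.
#' @param n_quad Quadrature nodes per segment. Default 33.
#' @param init Optional warm-start parameter vector from a previous
#'   `pore_shape` (`$opt_par`), e.g. the solution at a neighboring
#'   (r, h); warm starts skip the soft penalty round.
#' @param penalty Penalty weights for the constraint ramp.
#' @return An object of class `pore_shape`: `profile` (data.frame `s`,
#'   `rho`, `z`, `phi`, `two_H`, `segment`), `r`, `h`, `z_w` (waist
#'   height), `energy`, `bending`, `tension`, `ring`, `converged`,
#'   `constraint_viol`, `opt_par`, `mem`, `scaf`.
#' @export
solve_shape <- function(r, h, mem = membrane_params(),
                        scaf = scaffold_params(), n_nodes = 9,
                        n_quad = 33, init = NULL, penalty = c(100, 1e4)) {
  if (r <= 0) stop("solve_shape: r must be > 0")
  if (h < 0) stop("solve_shape: h must be >= 0")
  if (r >= scaf$disc_radius) {
    stop("solve_shape: waist radius must be smaller than the disc radius")
  }
  gr <- shape_grids(n_nodes, n_quad)
  warm <- !is.null(init)
  par <- if (warm) init else default_shape_init(r, h, mem, scaf, n_nodes)
  if (warm) penalty <- penalty[length(penalty)]

  args <- shape_cpp_args(r, h, mem, scaf, gr)
  obj <- function(p, w) {
    do.call(shape_objective_cpp, c(list(par = p), args, list(w = w)))
  }
  grad <- function(p, w) {
    do.call(shape_gradient_cpp, c(list(par = p), args, list(w = w)))
  }
  conv <- TRUE
  for (w in penalty) {
    op <- stats::optim(par, obj, gr = grad, w = w, method = "BFGS",
                       control = list(maxit = 300, reltol = 1e-9))
    par <- op$par
    conv <- conv && op$convergence %in% c(0, 1)
  }
  ev <- shape_eval(par, r, h, mem, scaf, gr)
  viol <- max(abs(ev$constraints))
  n1 <- length(ev$rho1)
  profile <- data.frame(
    s = c(ev$s1, ev$s1[n1] + ev$s2),
    rho = c(ev$rho1, ev$rho2), z = c(ev$z1, ev$z2),
    phi = c(ev$phi1, ev$phi2),
    two_H = c(ev$m1 + mem$c0, ev$m2 + mem$c0),
    segment = rep(1:2, c(n1, length(ev$rho2))))
  structure(list(profile = profile, r = r, h = h, z_w = ev$z_w,
                 energy = ev$energy, bending = ev$bending,
                 tension = ev$tension, ring = ev$ring,
                 converged = conv && viol < 0.02,
                 constraint_viol = viol, opt_par = par,
                 mem = mem, scaf = scaf),
            class = "pore_shape")
}

#' @export
print.pore_shape <- function(x, ...) {
  cat(sprintf(
    "pore_shape: r = %.2f nm, h = %.2f nm, E = %.2f kT (bend %.2f, tens %.2f)%s\n",
    x$r, x$h, x$energy, x$bending, x$tension,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Bending energy of the neck region of a solved shape
#'
#' Integrates the Helfrich bending energy density over the part of the
#' profile with `rho <= rho_max`. For a tension-free membrane the neck
#' approaches a catenoid (zero mean curvature) and this energy approaches
#' zero.
#'
#' @param shape A `pore_shape`.
#' @param rho_max Radial cutoff defining the neck, nm.
#' @return Energy in kT.
#' @export
neck_bending_energy <- function(shape, rho_max = shape$r + 2) {
  pr <- shape$profile
  keep <- pr$rho <= rho_max
  if (sum(keep) < 2) return(0)
  kap <- shape$mem$kappa
  idx <- which(keep)
  ds <- diff(pr$s[idx])
  dens <- pi * kap * (pr$two_H[idx] - shape$mem$c0)^2 * pmax(pr$rho[idx], 0.05)
  sum((dens[-1] + dens[-length(dens)]) / 2 * ds)
}
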