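#' SNARE subsystem parameters
#'
#' Each of the `N` SNARE complexes is either *trans* (partially zippered,
#' free to roam an area `trans_area` of the nanodisc face) or fully
#' zippered *cis* at the pore waist, where zippered complexes behave as
#' one-dimensional hard rods (a Tonks gas) of length `rod_footprint` on
#' the waist circumference. Full zippering releases `dG_zip` (kT); rod
#' crowding at a narrow waist opposes it.
#'
#' @param N Number of SNARE complexes. Default 4.
#' @param dG_zip Zippering free-energy gain of cis vs trans, kT
#'   (default 7, calibrated). This is the increment released by the final
#'   C-terminal zippering step from the membrane-spanning trans state,
#'   not the ~35 kT total assembly energy; only this last stage competes
#'   with crowding at the waist.
#' @param rod_footprint In-plane width of a zippered SNARE at the waist,
#'   nm.
#' @param trans_area Area available to a trans SNARE, nm^2. Default ~the
#'   nanodisc face.
#' @return An object of class `snare_params`.
#' @export
snare_params <- function(N = 4, dG_zip = 7, rod_footprint = 2.7,
                         trans_area = 490) {
  if (N < 0) stop("snare_params: N must be >= 0")
  if (rod_footprint <= 0) stop("snare_params: rod_footprint must be > 0")
  if (trans_area <= 0) stop("snare_params: trans_area must be > 0")
  structure(list(N = as.integer(N), dG_zip = dG_zip,
                 rod_footprint = rod_footprint, trans_area = trans_area),
            class = "snare_params")
}

#' Syt1 C2B domain parameters
#'
#' Geometry and calcium response of the C2B domain bound to each zippered
#' SNARE complex at the primary interface. With calcium, the C2B
#' calcium-binding loops bury ~1 nm into the cell membrane with a Hill
#' probability, tilting the rigid SNARE-C2B complex upward by
#' `tilt_angle`; without calcium the complex lies parallel to the
#' membrane with the polybasic patch `patch_height` above it.
#'
#' @param hill_n Hill coefficient of loop burial. Default 2.3.
#' @param hill_K Half-saturation calcium for burial, uM. Default 20 (the
#'   C2AB affinity for PI(4,5)P2 membranes; the conductance titration's
#'   fitted 23 uM is the experimental analogue).
#' @param tilt_angle Upward tilt of the buried-state complex, degrees.
#'   Default 15.
#' @param loop_depth Penetration depth of the calcium-binding loops, nm.
#' @param patch_height Height of the polybasic patch above the membrane
#'   in the unburied state, nm.
#' @param complex_length Rigid SNARE-C2B capsule length, nm.
#' @param complex_diameter Capsule diameter (maximum thickness), nm.
#' @param anchor_exempt Arc distance from the waist-embedded end to the
#'   C2B membrane anchor, nm; the membrane-proximal part before it (TMD
#'   and juxtamembrane linker) is exempt from the clearance test.
#' @param tilt_anchor How burial anchors the tilted complex: `"pivot"`
#'   (default) tilts about the membrane contact point, so the distal end
#'   rises by the lever arm times `sin(tilt_angle)`; `"buried"`
#'   additionally pulls the anchored end down to `loop_depth` below the
#'   membrane surface.
#' @return An object of class `c2b_params`.
#' @export
c2b_params <- function(hill_n = 2.3, hill_K = 20, tilt_angle = 15,
                       loop_depth = 1.0, patch_height = 0.5,
                       complex_length = 13, complex_diameter = 3.0,
                       anchor_exempt = 4, tilt_anchor = "pivot") {
  tilt_anchor <- match.arg(tilt_anchor, c("pivot", "buried"))
  if (tilt_angle <= 0 || tilt_angle >= 90) {
    stop("c2b_params: tilt_angle must be in (0, 90) degrees")
  }
  if (loop_depth < 0 || patch_height < 0) {
    stop("c2b_params: depths must be >= 0")
  }
  if (hill_n <= 0 || hill_K <= 0) stop("c2b_params: Hill parameters must be > 0")
  if (complex_length <= 0 || complex_diameter <= 0) {
    stop("c2b_params: complex dimensions must be > 0")
  }
  structure(list(hill_n = hill_n, hill_K = hill_K, tilt_angle = tilt_angle,
                 loop_depth = loop_depth, patch_height = patch_height,
                 complex_length = complex_length,
                 complex_diameter = complex_diameter,
                 anchor_exempt = anchor_exempt, tilt_anchor = tilt_anchor),
            class = "c2b_params")
}

#' Probability that the C2B calcium-binding loops are buried
#'
#' `p = 1 / (1 + (hill_K / calcium)^hill_n)`; 0 at zero calcium, 1/2 at
#' `hill_K`, 1 at saturating calcium.
#'
#' @param calcium Free calcium, uM (>= 0). Vectorized.
#' @param c2b A [c2b_params()].
#' @return Burial probability in [0, 1].
#' @export
buried_probability <- function(calcium, c2b = c2b_params()) {
  if (any(calcium < 0)) stop("buried_probability: calcium must be >= 0")
  1 / (1 + (c2b$hill_K / calcium)^c2b$hill_n)
}

# ln partition factor of n hard rods of length b on a ring of
# circumference L (Tonks gas), with a 1 nm reference length:
# Z_n = L (L - n b)^(n-1) / (n! * 1^n); Z_0 = 1. States with L < n b have
# zero weight (excluded volume).
tonks_ring_lnZ <- function(n, L, b) {
  if (n == 0) return(0)
  Lf <- L - n * b
  if (Lf <= 0) return(-Inf)
  log(L) + (n - 1) * log(Lf) - lfactorial(n)
}

#' Free energy of the SNARE subsystem at a given waist radius
#'
#' Boltzmann sum over the number of zippered SNAREs,
#' \deqn{F(r) = -\ln \sum_{n=0}^{N} \binom{N}{n} e^{n \Delta G_{zip}}
#'   Z_{crowd}(n, r)\, Z_{trans}^{N-n},}
#' with `Z_crowd` the Tonks hard-rod partition factor on the waist
#' circumference `2 pi r` and `Z_trans = trans_area` (1 nm reference
#' units) the ideal translational factor of an unzippered complex.
#' Geometrically excluded states (`2 pi r < n * rod_footprint`) carry zero
#' weight. Returns 0 when `N = 0`.
#'
#' @param r Waist radius, nm (> 0). Vectorized.
#' @param snares A [snare_params()].
#' @return Free energy in kT (negative log of the state sum).
#' @export
snare_free_energy <- function(r, snares = snare_params()) {
  if (any(r <= 0)) stop("snare_free_energy: r must be > 0")
  vapply(r, function(ri) {
    if (snares$N == 0) return(0)
    lt <- snare_state_lnw(ri, snares)
    -logsumexp(lt)
  }, numeric(1))
}

# ln weights of the n_zip = 0..N states (no clearance gating)
snare_state_lnw <- function(r, snares) {
  n <- 0:snares$N
  vapply(n, function(k) {
    lchoose(snares$N, k) + k * snares$dG_zip +
      tonks_ring_lnZ(k, 2 * pi * r, snares$rod_footprint) +
      (snares$N - k) * log(snares$trans_area)
  }, numeric(1))
}

logsumexp <- function(x) {
  x <- x[is.finite(x)]  # zero-weight (-Inf) states drop out of the sum
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Clearance margin of the SNARE-C2B capsule under a pore shape
#'
#' The rigid SNARE-C2B complex is approximated as a capsule of length
#' `complex_length` and diameter `complex_diameter` lying in the wedge
#' between the two membranes, anchored near the pore waist with the C2B
#' domain bound to the cell membrane at its pivot point
#' (`anchor_exempt` nm from the waist-embedded end; the part before the
#' pivot is flexible/membrane-embedded and exempt). Because the solved
#' membrane surfaces are bilayer midplanes, the sterically available
#' lumen is the rim height `h` minus the bilayer thickness
#' (`mem$thickness`). Untilted (loops unburied): the capsule lies
#' parallel to the cell membrane with the polybasic patch
#' `patch_height` above it, so the pore must provide a separation of at
#' least `thickness + patch_height + complex_diameter` - the complex
#' thickness sets the minimum membrane separation. Tilted (loops
#' buried): the capsule pivots upward about the C2B membrane contact by
#' `tilt_angle`, raising the distal end by the lever arm
#' `(complex_length - anchor_exempt) * sin(tilt_angle)` and increasing
#' the required separation accordingly (in `tilt_anchor = "buried"`
#' mode the anchor is additionally pulled down by
#' `loop_depth + patch_height`, shortening the effective lever). The
#' margin is `h` minus the required separation; the capsule fits iff it
#' is >= 0.
#'
#' @param shape A converged `pore_shape` from [solve_shape()].
#' @param tilted Logical: buried/tilted (TRUE) or unburied/parallel
#'   (FALSE) configuration.
#' @param c2b A [c2b_params()].
#' @return `clearance_margin()` returns the signed margin in nm;
#'   `clearance_ok()` returns `TRUE` iff the capsule fits.
#' @export
clearance_margin <- function(shape, tilted, c2b = c2b_params()) {
  stopifnot(inherits(shape, "pore_shape"))
  shape$h - required_separation(tilted, c2b, shape$mem$thickness)
}

# minimum rim height (midplane to midplane) accommodating the capsule
required_separation <- function(tilted, c2b, thickness) {
  d <- c2b$complex_diameter
  if (!tilted) return(thickness + c2b$patch_height + d)
  theta <- c2b$tilt_angle * pi / 180
  arm <- max(c2b$complex_length - c2b$anchor_exempt, 0)
  drop <- if (identical(c2b$tilt_anchor, "buried")) {
    c2b$loop_depth + c2b$patch_height
  } else 0
  thickness + c2b$patch_height + d * cos(theta) + arm * sin(theta) - drop
}

#' @rdname clearance_margin
#' @export
clearance_ok <- function(shape, tilted, c2b = c2b_params()) {
  clearance_margin(shape, tilted, c2b) >= 0
}
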