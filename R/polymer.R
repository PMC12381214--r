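#' Freely rotating chain (FRC) parameters
#'
#' The FRC pictures the polypeptide as rigid bonds of length `b` joined at a
#' fixed angle `gamma`. It captures force-extension behaviour over the wide
#' force range (tens to hundreds of pN) encountered when a complex can
#' rupture anywhere between 20 and 700 pN, where the worm-like chain
#' interpolation degrades. Defaults are the standard polypeptide values
#' b = 0.4 nm, gamma = 41 degrees, c = 2.
#'
#' @param bond_length_b Bond length in nm (> 0).
#' @param bond_angle_gamma Fixed bond angle in radians, in (0, pi/2).
#' @param correction_c Dimensionless high-force correction constant (> 0).
#' @param temperature Temperature in K used with these parameters.
#' @return An object of class `frc_params`.
#' @examples
#' frc <- frc_params()
#' frc_kuhn_length(frc)
#' @export
frc_params <- function(bond_length_b = 0.4,
                       bond_angle_gamma = 41 * pi / 180,
                       correction_c = 2,
                       temperature = 298.15) {
  if (!is.numeric(bond_length_b) || bond_length_b <= 0)
    stop("bond_length_b must be > 0 nm")
  if (!is.numeric(bond_angle_gamma) ||
      bond_angle_gamma <= 0 || bond_angle_gamma >= pi / 2)
    stop("bond_angle_gamma must lie in (0, pi/2) radians")
  if (!is.numeric(correction_c) || correction_c <= 0)
    stop("correction_c must be > 0")
  structure(
    list(b = bond_length_b, gamma = bond_angle_gamma,
         c = correction_c, temperature = temperature),
    class = "frc_params"
  )
}

#' @export
print.frc_params <- function(x, ...) {
  cat(sprintf("<frc_params> b = %.3f nm, gamma = %.1f deg, c = %g\n",
              x$b, x$gamma * 180 / pi, x$c))
  invisible(x)
}

#' Kuhn length of a freely rotating chain
#'
#' a = b (1 + cos gamma) / ((1 - cos gamma) cos(gamma/2)).
#'
#' @param params An [frc_params()] object.
#' @return Kuhn length in nm.
#' @export
frc_kuhn_length <- function(params) {
  stopifnot(inherits(params, "frc_params"))
  cg <- cos(params$gamma)
  if (1 - cg <= 0) stop("gamma = 0 leaves the Kuhn length undefined")
  params$b * (1 + cg) / ((1 - cg) * cos(params$gamma / 2))
}

#' Persistence length of a freely rotating chain
#'
#' p = b cos(gamma/2) / |ln(cos gamma)|. Requires cos gamma > 0 (the
#' logarithm is undefined otherwise), which the `frc_params` constructor
#' already guarantees by restricting gamma to (0, pi/2).
#'
#' @inheritParams frc_kuhn_length
#' @return Persistence length in nm.
#' @export
frc_persistence_length <- function(params) {
  stopifnot(inherits(params, "frc_params"))
  cg <- cos(params$gamma)
  if (cg <= 0) stop("cos(gamma) must be > 0 for the persistence length")
  params$b * cos(params$gamma / 2) / abs(log(cg))
}

#' Relative extension of a freely rotating chain under force
#'
#' Piecewise force-extension law. With a = Kuhn length, p = persistence
#' length, and the dimensionless force f = F b / kBT:
#' \itemize{
#'   \item low force (f < b/p):      x/L = F a / (3 kBT)
#'   \item intermediate (b/p <= f <= p/b): x/L = 1 - (4 F p / kBT)^(-1/2)
#'   \item high force (f > p/b):     x/L = 1 - (c F b / kBT)^(-1)
#' }
#' Boundary equalities are assigned to the intermediate branch (closed
#' interval); the published inequalities are strict and leave the
#' boundaries open, so this is a documented convention. Results are
#' clamped to [0, 1).
#'
#' @param force Force in pN (vectorised, must be >= 0).
#' @param params An [frc_params()] object.
#' @param ctx A [thermal_context()]. Defaults to the params' temperature.
#' @return Relative extension x/L in [0, 1).
#' @export
frc_relative_extension <- function(force, params,
                                   ctx = thermal_context(params$temperature)) {
  stopifnot(inherits(params, "frc_params"))
  if (any(force < 0)) stop("force must be >= 0 pN")
  kBT <- ctx$kBT
  a <- frc_kuhn_length(params)
  p <- frc_persistence_length(params)
  b <- params$b
  f <- force * b / kBT
  lo <- force * a / (3 * kBT)
  mid <- 1 - (4 * force * p / kBT)^(-1 / 2)
  hi <- 1 - (params$c * force * b / kBT)^(-1)
  out <- ifelse(f < b / p, lo, ifelse(f <= p / b, mid, hi))
  out[force == 0] <- 0
  pmin(pmax(out, 0), 1 - 1e-12)
}

#' Diagnose FRC branch-boundary discontinuities
#'
#' The piecewise law is not forced to be continuous at the two branch
#' boundaries; this reports the jump in x/L at each boundary instead of
#' masking it.
#'
#' @inheritParams frc_kuhn_length
#' @param ctx A [thermal_context()].
#' @return A data.frame with one row per boundary: boundary force (pN),
#'   x/L approached from below and above, and the jump.
#' @export
frc_branch_diagnostics <- function(params,
                                   ctx = thermal_context(params$temperature)) {
  stopifnot(inherits(params, "frc_params"))
  kBT <- ctx$kBT
  b <- params$b
  p <- frc_persistence_length(params)
  f_bounds <- c(low_mid = (b / p) * kBT / b, mid_high = (p / b) * kBT / b)
  eps <- 1e-9
  below <- frc_relative_extension(pmax(f_bounds * (1 - eps), 0), params, ctx)
  above <- frc_relative_extension(f_bounds * (1 + eps), params, ctx)
  data.frame(
    boundary = names(f_bounds),
    force_pN = as.numeric(f_bounds),
    x_over_L_below = below,
    x_over_L_above = above,
    jump = above - below,
    row.names = NULL
  )
}

#' Contour length from a (force, extension) sample
#'
#' Inverts the FRC relation pointwise: L = extension / (x/L)(F). Samples
#' with force below the noise floor amplify measurement noise and are
#' returned as NA (flagged, not zeroed).
#'
#' @param force Force in pN (vectorised).
#' @param extension Extension in nm (same length or scalar, > 0).
#' @param params An [frc_params()] object.
#' @param noise_floor_pN Minimum force at which the inversion is trusted.
#'   Samples with `force < noise_floor_pN` come back NA. Default 10 pN.
#' @param ctx A [thermal_context()].
#' @return Contour lengths in nm; NA where the force is below the floor.
#' @export
frc_contour_length <- function(force, extension, params,
                               noise_floor_pN = 10,
                               ctx = thermal_context(params$temperature)) {
  if (any(extension <= 0, na.rm = TRUE)) stop("extension must be > 0 nm")
  n <- max(length(force), length(extension))
  force <- rep_len(force, n)
  extension <- rep_len(extension, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(force) & force >= noise_floor_pN
  if (any(ok)) {
    xl <- frc_relative_extension(force[ok], params, ctx)
    out[ok] <- extension[ok] / xl
  }
  out
}

#' Force on a freely rotating chain at a given relative extension
#'
#' Analytic inverse of [frc_relative_extension()], used to render synthetic
#' force-extension curves. Each branch inverts in closed form; the branch
#' whose validity condition holds at the inverted force is selected, with
#' the intermediate branch preferred at boundary overlap.
#'
#' @param rel_ext Relative extension x/L in [0, 1).
#' @param params An [frc_params()] object.
#' @param ctx A [thermal_context()].
#' @return Force in pN.
#' @export
frc_force <- function(rel_ext, params,
                      ctx = thermal_context(params$temperature)) {
  stopifnot(inherits(params, "frc_params"))
  if (any(rel_ext < 0 | rel_ext >= 1)) stop("rel_ext must lie in [0, 1)")
  kBT <- ctx$kBT
  a <- frc_kuhn_length(params)
  p <- frc_persistence_length(params)
  b <- params$b
  f_lo <- 3 * kBT * rel_ext / a
  f_mid <- kBT / (4 * p * (1 - rel_ext)^2)
  f_hi <- kBT / (params$c * b * (1 - rel_ext))
  cond <- function(force) force * b / kBT  # dimensionless force
  out <- numeric(length(rel_ext))
  for (i in seq_along(rel_ext)) {
    if (cond(f_mid[i]) >= b / p && cond(f_mid[i]) <= p / b) {
      out[i] <- f_mid[i]
    } else if (cond(f_lo[i]) < b / p) {
      out[i] <- f_lo[i]
    } else if (cond(f_hi[i]) > p / b) {
      out[i] <- f_hi[i]
    } else {
      # inside the gap opened by a branch discontinuity: pin to boundary
      out[i] <- (b / p) * kBT / b
    }
  }
  out
}

#' Worm-like chain (WLC) parameters
#'
#' @param contour_length_L Contour length in nm (> 0).
#' @param persistence_length_p Persistence length in nm (> 0).
#' @param temperature Temperature in K.
#' @return An object of class `wlc_params`.
#' @export
wlc_params <- function(contour_length_L, persistence_length_p = 0.4,
                       temperature = 298.15) {
  if (!is.numeric(contour_length_L) || contour_length_L <= 0)
    stop("contour_length_L must be > 0 nm")
  if (!is.numeric(persistence_length_p) || persistence_length_p <= 0)
    stop("persistence_length_p must be > 0 nm")
  structure(
    list(L = contour_length_L, p = persistence_length_p,
         temperature = temperature),
    class = "wlc_params"
  )
}

#' Worm-like chain force at a given extension
#'
#' Marko-Siggia interpolation:
#' F = (kBT/p) (1/(4 (1 - x/L)^2) - 1/4 + x/L),
#' strictly increasing in extension and divergent as x -> L.
#'
#' @param extension Extension in nm, 0 <= extension < L (vectorised).
#' @param params A [wlc_params()] object.
#' @param ctx A [thermal_context()].
#' @return Force in pN.
#' @export
wlc_force <- function(extension, params,
                      ctx = thermal_context(params$temperature)) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(extension < 0 | extension >= params$L))
    stop("extension must satisfy 0 <= extension < contour length")
  xl <- extension / params$L
  (ctx$kBT / params$p) * (1 / (4 * (1 - xl)^2) - 1 / 4 + xl)
}
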