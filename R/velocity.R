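#' Conduction-velocity model parameters
#'
#' Parameters of the generalized Rushton relation
#' \eqn{v = s \, d \, (-\ln g)^\alpha} with \eqn{d = g D}: the absolute
#' scaling factor `s` (in µs⁻¹; the default 7.5 reproduces absolute
#' velocities calibrated against biophysical simulation of myelinated
#' fibers) and the exponent `alpha` (default 0.68, the empirically
#' optimized value; the classical cable-equation derivation gives 0.5,
#' and reversing the optimal-g argument at the observed mean g-ratio
#' gives [derive_alpha()]).
#'
#' @param scaling_s scaling factor, µs⁻¹ (> 0).
#' @param alpha dimensionless exponent in (0, 1].
#' @return a list of class `velocity_model`.
#' @export
velocity_model <- function(scaling_s = 7.5, alpha = 0.68) {
  if (scaling_s <= 0) stop_domain("scaling_s must be > 0")
  if (alpha <= 0 || alpha > 1) stop_domain("alpha must be in (0, 1]")
  structure(list(scaling_s = scaling_s, alpha = alpha),
            class = "velocity_model")
}

check_g <- function(g) {
  if (any(!is.finite(g) | g <= 0 | g >= 1))
    stop_domain("g-ratio must lie strictly between 0 and 1")
}

#' Conduction velocity from fiber geometry
#'
#' Generalized Rushton relation: `v = s * (g * D) * (-ln g)^alpha`,
#' where `D` is the outer fiber diameter (µm) and `g * D = d` the axon
#' diameter. With `s` in µs⁻¹ and `D` in µm the result is in
#' µm µs⁻¹ = m s⁻¹.
#'
#' @param outer_diameter_um outer fiber diameter `D`, µm (> 0).
#' @param g_ratio g-ratio in (0, 1).
#' @param model a [velocity_model()].
#' @return velocity in m/s (vectorized).
#' @examples
#' conduction_velocity(0.94, 0.54)  # ~2.7 m/s
#' @export
conduction_velocity <- function(outer_diameter_um, g_ratio,
                                model = velocity_model()) {
  if (any(!is.finite(outer_diameter_um) | outer_diameter_um <= 0))
    stop_domain("outer diameter must be > 0")
  check_g(g_ratio)
  model$scaling_s * g_ratio * outer_diameter_um *
    (-log(g_ratio))^model$alpha
}

#' Exponent alpha derived from the observed g-ratio
#'
#' Reverses the optimal-g argument: if the observed mean g-ratio is the
#' velocity-optimal one, the exponent of the generalized Rushton
#' relation must be `alpha = -ln(g)`. At the observed mean g = 0.54 this
#' gives 0.62.
#'
#' @param g_ratio g-ratio in (0, 1).
#' @return dimensionless exponent (vectorized).
#' @export
derive_alpha <- function(g_ratio) {
  check_g(g_ratio)
  -log(g_ratio)
}

#' Velocity change between two exponents
#'
#' Percent change in estimated conduction velocity when exponent
#' `alpha_a` replaces `alpha_b` at a fixed g-ratio:
#' `100 * ((-ln g)^alpha_a / (-ln g)^alpha_b - 1)`.
#'
#' @param g_ratio g-ratio in (0, 1).
#' @param alpha_a,alpha_b exponents to compare.
#' @return percent change.
#' @examples
#' velocity_ratio(0.54, derive_alpha(0.54), 0.68)  # ~ +3 %
#' @export
velocity_ratio <- function(g_ratio, alpha_a, alpha_b) {
  check_g(g_ratio)
  100 * ((-log(g_ratio))^alpha_a / (-log(g_ratio))^alpha_b - 1)
}

#' Conduction time over a path
#'
#' @param path_length_m path length in meters (> 0).
#' @param velocity_mps conduction velocity in m/s (> 0).
#' @return time in milliseconds.
#' @examples
#' travel_time(0.04, 2.7)  # ~14.8 ms for a 4-cm association fiber
#' @export
travel_time <- function(path_length_m, velocity_mps) {
  if (any(path_length_m <= 0) || any(velocity_mps <= 0))
    stop_domain("path length and velocity must be > 0")
  path_length_m / velocity_mps * 1000
}

#' Relative internode length
#'
#' Evolutionary-optimization relation for internode length,
#' `L ∝ d * (-ln g)^0.5` with `d = g D`. Only the relative scale is
#' meaningful (no absolute calibration is claimed). Maximal over g at
#' `g = exp(-1/2) ≈ 0.607` for fixed D.
#'
#' @param outer_diameter_um outer fiber diameter `D`, µm.
#' @param g_ratio g-ratio in (0, 1).
#' @return relative internode length (arbitrary units, vectorized).
#' @export
internode_length_relative <- function(outer_diameter_um, g_ratio) {
  if (any(outer_diameter_um <= 0)) stop_domain("outer diameter must be > 0")
  check_g(g_ratio)
  g_ratio * outer_diameter_um * sqrt(-log(g_ratio))
}

#' Velocity-optimal g-ratio for a given exponent
#'
#' The g maximizing `g * (-ln g)^alpha` is `exp(-alpha)` — the
#' closed-form inverse of [derive_alpha()].
#'
#' @param alpha exponent (> 0).
#' @return optimal g-ratio in (0, 1).
#' @export
optimal_g <- function(alpha) {
  if (any(alpha <= 0)) stop_domain("alpha must be > 0")
  exp(-alpha)
}

#' Per-fiber conduction velocities for a measurement table
#'
#' Appends a `v_mps` column to a fiber-record table using each fiber's
#' outer minor-axis diameter and either its own measured g-ratio
#' (default, matching how per-fiber velocity distributions are built) or
#' a fixed population g-ratio.
#'
#' @param records fiber-record data.frame with `outer_minor_um` and
#'   `g_ratio` columns.
#' @param model a [velocity_model()].
#' @param g_mode `"per_fiber"` (default) or `"population"`.
#' @param g_population fixed g used when `g_mode = "population"`.
#' @return `records` with an appended `v_mps` column (NA where inputs
#'   are missing or out of domain).
#' @export
fiber_velocities <- function(records, model = velocity_model(),
                             g_mode = c("per_fiber", "population"),
                             g_population = 0.54) {
  g_mode <- match.arg(g_mode)
  g <- if (g_mode == "per_fiber") records$g_ratio else
    rep(g_population, nrow(records))
  D <- records$outer_minor_um
  ok <- is.finite(g) & g > 0 & g < 1 & is.finite(D) & D > 0
  v <- rep(NA_real_, nrow(records))
  v[ok] <- conduction_velocity(D[ok], g[ok], model)
  records$v_mps <- v
  records
}
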