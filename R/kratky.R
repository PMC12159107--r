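## Kratky transforms and small closed-form reference calculators.

#' Kratky transform
#'
#' Standard mode returns \eqn{(q, q^2 I)}; normalized (dimensionless) mode
#' returns \eqn{(qR_g, (qR_g)^2 I/I_0)}, which for compact particles shows
#' a primary maximum near \eqn{qR_g \approx 1.7} and for flexible chains a
#' plateau with no return to baseline.  The location and height of the
#' first interior maximum, if one exists, are reported.
#'
#' @param profile a [sas_profile].
#' @param mode `"standard"` or `"normalized"`.
#' @param guinier a [guinier_fit] supplying Rg and I0 (required for
#'   normalized mode), or explicit `rg`/`i0`.
#' @param rg,i0 explicit values overriding `guinier`.
#' @return data.frame with columns `x` and `y`, plus attributes
#'   `peak_x`/`peak_y` (NA when no interior maximum exists) and `mode`.
#' @export
kratky_transform <- function(profile, mode = c("standard", "normalized"),
                             guinier = NULL, rg = NULL, i0 = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "sas_profile"))
  q <- profile$q; I <- profile$intensity
  if (mode == "standard") {
    x <- q; y <- q^2 * I
  } else {
    if (is.null(rg) && !is.null(guinier)) rg <- guinier$rg
    if (is.null(i0) && !is.null(guinier)) i0 <- guinier$i0
    if (is.null(rg) || is.null(i0))
      stop("normalized mode requires Rg and I0 (guinier= or rg=/i0=)")
    x <- q * rg; y <- (q * rg)^2 * I / i0
  }
  out <- data.frame(x = x, y = y)
  # first interior maximum: y[i] > y[i-1] and y[i] >= y[i+1]
  n <- length(y)
  peak <- NA_integer_
  if (n >= 3) {
    up <- diff(y) > 0
    for (i in 2:(n - 1)) if (up[i - 1] && !up[i]) { peak <- i; break }
  }
  attr(out, "mode") <- mode
  attr(out, "peak_x") <- if (is.na(peak)) NA_real_ else x[peak]
  attr(out, "peak_y") <- if (is.na(peak)) NA_real_ else y[peak]
  out
}

#' Rigid-rod reference metrics for B-form DNA
#'
#' Contour length, radius of gyration and maximum dimension of a thin
#' rigid rod of `n_bp` base pairs: \eqn{L = n_{bp} \cdot rise},
#' \eqn{R_g = L/\sqrt{12}}, \eqn{D_{max} = L}.  For 147 bp this gives the
#' fully extended reference \eqn{R_g \approx 144} A, \eqn{D_{max} \approx
#' 500} A.
#'
#' @param n_bp base-pair count (>= 1).
#' @param rise_per_bp helical rise, Angstrom/bp (B-form 3.4).
#' @return list with `contour_length`, `rg`, `dmax` (Angstrom).
#' @export
rigid_rod_metrics <- function(n_bp, rise_per_bp = 3.4) {
  if (!is.numeric(n_bp) || n_bp < 1) stop("n_bp must be >= 1")
  L <- n_bp * rise_per_bp
  list(contour_length = L, rg = L / sqrt(12), dmax = L)
}

#' Stokes-Einstein hydrodynamic radius
#'
#' \eqn{R_h = k_B T / (6 \pi \eta D)}, returned in Angstrom.
#'
#' @param diffusion_coeff translational diffusion coefficient, cm^2/s.
#' @param temperature absolute temperature, K.
#' @param viscosity solvent viscosity, poise (g cm^-1 s^-1).
#' @return hydrodynamic radius, Angstrom.
#' @export
stokes_einstein_radius <- function(diffusion_coeff, temperature,
                                   viscosity) {
  if (any(c(diffusion_coeff, temperature, viscosity) <= 0))
    stop("all inputs must be positive")
  kB <- 1.380649e-16  # erg/K
  r_cm <- kB * temperature / (6 * pi * viscosity * diffusion_coeff)
  r_cm * 1e8
}

#' Hydrostatic pressure at the bottom of a spinning centrifuge cell
#'
#' \eqn{P = P_{ambient} + \rho \omega^2 (r_b^2 - r_m^2)/2} with
#' \eqn{\omega = 2\pi \cdot rpm/60}; the integral of \eqn{\rho\omega^2 r}
#' from meniscus to base.
#'
#' @param rpm rotor speed, revolutions per minute (>= 0).
#' @param r_meniscus,r_bottom radial positions, cm (bottom > meniscus > 0).
#' @param solvent_density g/mL.
#' @param ambient ambient pressure, MPa.
#' @return total pressure at the cell base, MPa.
#' @export
auc_cell_pressure <- function(rpm, r_meniscus, r_bottom,
                              solvent_density = 1.0, ambient = 0.1013) {
  if (rpm < 0) stop("rpm must be >= 0")
  if (!(r_bottom > r_meniscus && r_meniscus > 0))
    stop("geometry inverted: need r_bottom > r_meniscus > 0")
  omega <- 2 * pi * rpm / 60                      # rad/s
  dyn_cm2 <- 0.5 * solvent_density * omega^2 * (r_bottom^2 - r_meniscus^2)
  ambient + dyn_cm2 * 1e-7                        # dyn/cm^2 -> MPa
}
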