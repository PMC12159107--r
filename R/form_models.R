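## Forward scattering models: orientationally averaged core-shell cylinder,
## Debye-formula bead models (direct and distance-histogram accelerated),
## and the Gaussian-coil reference curve; plus global multi-contrast
## fitting of shared cylinder geometry.

#' Core-shell cylinder parameters
#'
#' Geometry and scattering-length densities of a core-shell cylinder with
#' a uniform shell on all faces: core radius `core_radius` and length
#' `length`; outer cylinder radius `core_radius + shell_thickness`, length
#' `length + 2*shell_thickness`.  For a nucleosome the core maps to the
#' histone octamer, the shell to the DNA wrap (`shell_thickness` is the
#' DNA-wrap radius) and the cylinder length to the gyre height.
#'
#' @param core_radius,shell_thickness,length Angstrom (> 0).
#' @param sld_core,sld_shell,sld_solvent 1e-6 A^-2.
#' @param scale multiplicative scale (> 0).
#' @param background flat additive background.
#' @return list of class `core_shell_cylinder`.
#' @export
core_shell_cylinder <- function(core_radius, shell_thickness, length,
                                sld_core, sld_shell, sld_solvent,
                                scale = 1, background = 0) {
  if (any(c(core_radius, shell_thickness, length) <= 0))
    stop("all lengths must be positive")
  if (scale <= 0) stop("scale must be positive")
  structure(list(core_radius = core_radius,
                 shell_thickness = shell_thickness, length = length,
                 sld_core = sld_core, sld_shell = sld_shell,
                 sld_solvent = sld_solvent, scale = scale,
                 background = background), class = "core_shell_cylinder")
}

# single-orientation amplitude factor of a homogeneous cylinder
# (radius R, length L) at tilt angle gamma between q and the axis
.cyl_shape <- function(q, R, L, singam, cosgam) {
  a <- outer(q, cosgam) * (L / 2)
  b <- outer(q, singam) * R
  sinc <- ifelse(abs(a) < 1e-8, 1 - a^2 / 6, sin(a) / a)
  bess <- ifelse(abs(b) < 1e-8, 0.5 - b^2 / 16, besselJ(b, 1) / b)
  sinc * 2 * bess
}

#' Core-shell cylinder intensity
#'
#' Orientationally averaged \eqn{I(q)} of the core-shell cylinder by
#' Gauss-Legendre quadrature over the tilt angle: the amplitude is the sum
#' of the core cylinder at contrast (sld_core - sld_shell) and the outer
#' cylinder at contrast (sld_shell - sld_solvent).  At q -> 0 the
#' intensity approaches `scale * (V_core drho_core + V_shell drho_shell)^2
#' + background` with the contrasts taken against the solvent.
#'
#' @param params a [core_shell_cylinder].
#' @param q momentum transfer vector, 1/Angstrom (> 0).
#' @param n_quad quadrature order over the tilt angle (>= 16; default 76).
#' @return intensity vector.  Absolute prefactor uses SLD * volume in
#'   (1e-6 A^-2 * A^3)^2, i.e. units of 1e-12 A^2, times `scale`.
#' @export
core_shell_cylinder_intensity <- function(params, q, n_quad = 76) {
  stopifnot(inherits(params, "core_shell_cylinder"))
  if (any(q <= 0)) stop("q must be positive")
  if (n_quad < 16) stop("quadrature order below 16 rejected")
  gl <- pracma::gaussLegendre(n_quad, 0, pi / 2)
  singam <- sin(gl$x); cosgam <- cos(gl$x)
  Rc <- params$core_radius; t <- params$shell_thickness
  Lc <- params$length
  Ro <- Rc + t; Lo <- Lc + 2 * t
  Vc <- pi * Rc^2 * Lc; Vo <- pi * Ro^2 * Lo
  d1 <- params$sld_core - params$sld_shell
  d2 <- params$sld_shell - params$sld_solvent
  amp <- d1 * Vc * .cyl_shape(q, Rc, Lc, singam, cosgam) +
         d2 * Vo * .cyl_shape(q, Ro, Lo, singam, cosgam)
  avg <- drop((amp^2 %*% (gl$w * singam)))  # integral of A^2 sin(g) dg
  params$scale * avg + params$background
}

#' Contrast-weighted Rg of a core-shell cylinder
#'
#' Closed form \eqn{R_g^2 = \sum_i w_i S_i / \sum_i w_i} with
#' \eqn{w_i = V_i \Delta\rho_i} over the core and the shell region, where
#' the second moment of a solid cylinder is \eqn{R^2/2 + L^2/12} and the
#' shell term is the annular difference of the outer and core moments.
#'
#' @param params a [core_shell_cylinder].
#' @return Rg in Angstrom.
#' @export
cylinder_rg <- function(params) {
  stopifnot(inherits(params, "core_shell_cylinder"))
  Rc <- params$core_radius; t <- params$shell_thickness
  Lc <- params$length; Ro <- Rc + t; Lo <- Lc + 2 * t
  Vc <- pi * Rc^2 * Lc; Vo <- pi * Ro^2 * Lo; Vs <- Vo - Vc
  Sc <- Rc^2 / 2 + Lc^2 / 12
  So <- Ro^2 / 2 + Lo^2 / 12
  Ss <- (Vo * So - Vc * Sc) / Vs
  wc <- Vc * (params$sld_core - params$sld_solvent)
  ws <- Vs * (params$sld_shell - params$sld_solvent)
  if (abs(wc + ws) < 1e-300)
    stop("zero total contrast weight: Rg undefined")
  rg2 <- (wc * Sc + ws * Ss) / (wc + ws)
  if (rg2 < 0) stop("negative contrast-weighted Rg^2")
  sqrt(rg2)
}

#' Bead model
#'
#' @param x,y,z coordinates, Angstrom.
#' @param scattering_length per-bead excess scattering length (arbitrary
#'   consistent units, e.g. fm or electrons).
#' @param component_tag `"protein"` or `"dna"` per bead.
#' @param volume optional per-bead displaced volume, A^3 (used when
#'   contrasts are applied per tag).
#' @return object of class `bead_model` (a data.frame).
#' @export
bead_model <- function(x, y, z, scattering_length,
                       component_tag = "protein", volume = NA_real_) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, n >= 1)
  if (any(!is.finite(c(x, y, z)))) stop("coordinates must be finite")
  structure(data.frame(x = x, y = y, z = z,
                       scattering_length = rep_len(scattering_length, n),
                       component_tag = rep_len(component_tag, n),
                       volume = rep_len(volume, n),
                       stringsAsFactors = FALSE),
            class = c("bead_model", "data.frame"))
}

.bead_b <- function(model, contrast_per_tag) {
  if (is.null(contrast_per_tag)) return(model$scattering_length)
  if (any(is.na(model$volume)))
    stop("contrast_per_tag requires per-bead volumes")
  dr <- contrast_per_tag[model$component_tag]
  if (any(is.na(dr)))
    stop("contrast_per_tag missing tag(s): ",
         paste(setdiff(unique(model$component_tag),
                       names(contrast_per_tag)), collapse = ", "))
  as.numeric(dr) * model$volume
}

#' Debye-formula intensity of a bead model
#'
#' \eqn{I(q) = \sum_i \sum_j b_i b_j \sin(q r_{ij})/(q r_{ij})}.  The
#' `"direct"` method evaluates the double sum exactly; the `"histogram"`
#' method (default for more than 400 beads) bins the pair distances at
#' `bin_width` and evaluates one sinc per bin, agreeing with the direct
#' sum to the binning resolution.
#'
#' @param model a [bead_model].
#' @param q momentum transfer vector.
#' @param contrast_per_tag optional named vector mapping component tags to
#'   contrasts; when given, per-bead amplitudes are `contrast * volume`.
#' @param method `"auto"`, `"direct"` or `"histogram"`.
#' @param bin_width histogram bin width, Angstrom.
#' @return intensity vector.
#' @export
debye_intensity <- function(model, q, contrast_per_tag = NULL,
                            method = c("auto", "direct", "histogram"),
                            bin_width = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(model, "bead_model"), nrow(model) >= 1)
  b <- .bead_b(model, contrast_per_tag)
  n <- nrow(model)
  if (n == 1) return(rep(b^2, length(q)))
  if (method == "auto") method <- if (n > 400) "histogram" else "direct"
  xyz <- as.matrix(model[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  bb <- outer(b, b)
  if (method == "direct") {
    iu <- upper.tri(d)
    dv <- d[iu]; wv <- bb[iu]
    self <- sum(b^2)
    return(vapply(q, function(qq) {
      x <- qq * dv
      self + 2 * sum(wv * ifelse(x < 1e-8, 1 - x^2 / 6, sin(x) / x))
    }, 0))
  }
  iu <- upper.tri(d)
  dv <- d[iu]; wv <- bb[iu]
  bins <- floor(dv / bin_width)
  wsum <- tapply(wv, bins, sum)
  # amplitude-weighted mean distance per bin (second-order accurate)
  centers <- tapply(wv * dv, bins, sum) / wsum
  self <- sum(b^2)
  vapply(q, function(qq) {
    x <- qq * centers
    self + 2 * sum(wsum * ifelse(x < 1e-8, 1 - x^2 / 6, sin(x) / x))
  }, 0)
}

#' Gaussian-coil (Debye) intensity
#'
#' \eqn{I(q) = I_0 \cdot 2 (e^{-x} + x - 1)/x^2}, \eqn{x = (q R_g)^2}: the
#' reference curve for a fully flexible chain (the entirely unfolded
#' polymer regime of extreme-pressure series).
#'
#' @param rg coil radius of gyration, Angstrom (> 0).
#' @param i0 forward intensity.
#' @param q momentum transfer vector.
#' @return intensity vector.
#' @export
gaussian_coil_intensity <- function(rg, i0, q) {
  if (rg <= 0) stop("rg must be positive")
  x <- (q * rg)^2
  # series branch avoids catastrophic cancellation of exp(-x) + x - 1
  ifelse(x < 1e-2, i0 * (1 - x / 3 + x^2 / 12),
         i0 * 2 * (exp(-x) + x - 1) / x^2)
}

#' Global multi-contrast core-shell cylinder fit
#'
#' Fits shared cylinder geometry (core radius, shell thickness, length)
#' across several profiles measured at different contrasts, with
#' per-curve scale and flat background profiled out by weighted linear
#' least squares at each geometry evaluation.  Per-profile SLDs are
#' computed from the composition and each profile's source and D2O
#' fraction (X-ray profiles use the electron-density contrasts on a
#' common relative scale).  Optimization is Levenberg-Marquardt
#' least squares with box bounds and an optional seeded multi-start.
#'
#' @param profiles list of [sas_profile] objects.
#' @param comp a [composition_spec].
#' @param start a [core_shell_cylinder] with starting geometry.
#' @param fixed character subset of `c("core_radius", "shell_thickness",
#'   "length")` to hold at the start values.
#' @param lower,upper named bounds on the free geometry parameters.
#' @param n_starts multi-start count (> 1 perturbs the start randomly).
#' @param seed RNG seed for the multi-start perturbations.
#' @param n_quad quadrature order passed to the model.
#' @return list of class `global_cv_fit` with `params` (fitted geometry),
#'   `se`, per-curve `scales`/`backgrounds`, `chi2red` (global),
#'   `per_curve_chi2red`, `degenerate` flag and convergence info.
#' @export
global_cv_fit <- function(profiles, comp, start,
                          fixed = character(),
                          lower = c(core_radius = 5, shell_thickness = 5,
                                    length = 10),
                          upper = c(core_radius = 80, shell_thickness = 60,
                                    length = 300),
                          n_starts = 1, seed = 1, n_quad = 40) {
  stopifnot(inherits(start, "core_shell_cylinder"),
            inherits(comp, "composition_spec"))
  if (length(profiles) < 1) stop("need at least one profile")
  geom_names <- c("core_radius", "shell_thickness", "length")
  fixed <- intersect(fixed, geom_names)
  free <- setdiff(geom_names, fixed)
  n_data <- sum(vapply(profiles, function(p) length(p$q), 0L))
  n_par <- length(free) + 2 * length(profiles)
  degenerate <- length(profiles) == 1 && length(free) == 3
  if (n_data <= n_par) stop("fewer data points than parameters")

  slds <- lapply(profiles, function(p) {
    if (p$meta$source == "neutron") {
      list(core = .component_sld(comp, "protein", p$meta$fraction_d2o),
           shell = .component_sld(comp, "dna", p$meta$fraction_d2o),
           solvent = solvent_sld(p$meta$fraction_d2o))
    } else {
      # electron densities on the 1e-6 A^-2-like relative scale (e-/nm^3
      # scaled by 1e-2): only contrast ratios matter, scale is per-curve
      list(core = (xray_contrast(comp, "protein") + 334) * 1e-2,
           shell = (xray_contrast(comp, "dna") + 334) * 1e-2,
           solvent = 334 * 1e-2)
    }
  })

  model_matrix <- function(geom) {
    lapply(seq_along(profiles), function(j) {
      pr <- core_shell_cylinder(geom["core_radius"],
                                geom["shell_thickness"], geom["length"],
                                slds[[j]]$core, slds[[j]]$shell,
                                slds[[j]]$solvent)
      core_shell_cylinder_intensity(pr, profiles[[j]]$q, n_quad = n_quad)
    })
  }

  resid_fun <- function(par_free) {
    geom <- c(core_radius = start$core_radius,
              shell_thickness = start$shell_thickness,
              length = start$length)
    geom[free] <- par_free
    mods <- model_matrix(geom)
    unlist(lapply(seq_along(profiles), function(j) {
      p <- profiles[[j]]
      m <- mods[[j]]
      w <- 1 / p$sigma^2
      # profile out scale and background by weighted LS (model column
      # normalized for conditioning)
      mm <- max(abs(m))
      X <- cbind(m / mm, 1)
      cf <- tryCatch(drop(solve(t(X * w) %*% X, t(X * w) %*% p$intensity)),
                     error = function(e) c(0, mean(p$intensity)))
      (p$intensity - drop(X %*% cf)) / p$sigma
    }))
  }

  start_vec <- c(core_radius = start$core_radius,
                 shell_thickness = start$shell_thickness,
                 length = start$length)[free]
  runs <- list()
  set.seed(seed)
  for (s in seq_len(max(1, n_starts))) {
    sv <- if (s == 1) start_vec
          else pmin(pmax(start_vec * exp(stats::rnorm(length(free), 0, 0.25)),
                         lower[free] * 1.01), upper[free] * 0.99)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = sv, fn = resid_fun,
                         lower = lower[free], upper = upper[free],
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) runs[[length(runs) + 1]] <- fit
  }
  if (!length(runs)) stop("global fit failed to converge from any start")
  dev <- vapply(runs, function(f) f$deviance, 0)
  best <- runs[[which.min(dev)]]
  converged <- best$info %in% 1:4
  geom <- c(core_radius = start$core_radius,
            shell_thickness = start$shell_thickness,
            length = start$length)
  geom[free] <- best$par
  # per-curve linear parameters and chi2 at the optimum
  mods <- model_matrix(geom)
  scales <- backgrounds <- numeric(length(profiles))
  per_chi <- numeric(length(profiles))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]; m <- mods[[j]]; w <- 1 / p$sigma^2
    mm <- max(abs(m))
    X <- cbind(m / mm, 1)
    cf <- drop(solve(t(X * w) %*% X, t(X * w) %*% p$intensity))
    scales[j] <- cf[1] / mm; backgrounds[j] <- cf[2]
    per_chi[j] <- sum(((p$intensity - drop(X %*% cf)) / p$sigma)^2) /
      max(1, length(p$q) - 2)
  }
  dof <- n_data - n_par
  se <- rep(NA_real_, length(free)); names(se) <- free
  cv <- tryCatch(chol2inv(chol(best$hessian)), error = function(e) NULL)
  if (!is.null(cv)) {
    s2 <- best$deviance / max(1, dof)
    se <- sqrt(pmax(diag(cv), 0) * 2 * s2)
    names(se) <- free
  }
  structure(list(
    params = core_shell_cylinder(geom["core_radius"],
                                 geom["shell_thickness"], geom["length"],
                                 start$sld_core, start$sld_shell,
                                 start$sld_solvent),
    geometry = geom, se = se, free = free, fixed = fixed,
    scales = scales, backgrounds = backgrounds,
    chi2red = best$deviance / max(1, dof),
    per_curve_chi2red = per_chi,
    degenerate = degenerate, converged = converged,
    n_starts = n_starts), class = "global_cv_fit")
}

#' @export
print.global_cv_fit <- function(x, ...) {
  g <- x$geometry
  cat(sprintf(
    "Global CV fit: R_core = %.2f A, t_shell = %.2f A, L = %.2f A (chi2red %.3g)%s%s\n",
    g["core_radius"], g["shell_thickness"], g["length"], x$chi2red,
    if (x$degenerate) "  [degenerate: single curve, all free]" else "",
    if (!x$converged) "  [not converged]" else ""))
  invisible(x)
}

#' Write a bead model as PDB-format records
#'
#' One HETATM record per bead; the component tag is written in the
#' element/segment columns.  Round-trips through [read_bead_pdb].
#'
#' @param model a [bead_model].
#' @param path output path.
#' @export
write_bead_pdb <- function(model, path) {
  stopifnot(inherits(model, "bead_model"))
  tag <- ifelse(model$component_tag == "protein", "PRO", "DNA")
  recs <- sprintf(
    "HETATM%5d  C   %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(model)) %% 100000, tag, seq_len(nrow(model)) %% 10000,
    model$x, model$y, model$z, 1.0, model$scattering_length, "C")
  writeLines(c(recs, "END"), path)
  invisible(path)
}

#' @rdname write_bead_pdb
#' @export
read_bead_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "HETATM") | startsWith(lines, "ATOM")]
  if (!length(lines)) stop("no atom records in ", path)
  tag <- trimws(substr(lines, 18, 20))
  bead_model(x = as.numeric(substr(lines, 31, 38)),
             y = as.numeric(substr(lines, 39, 46)),
             z = as.numeric(substr(lines, 47, 54)),
             scattering_length = as.numeric(substr(lines, 61, 66)),
             component_tag = ifelse(tag == "DNA", "dna", "protein"))
}
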