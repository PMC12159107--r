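## Multi-contrast inference from absolute-scale forward intensities:
## component molecular weights from I(0) across a D2O series, and per-q
## decomposition of a contrast series into protein, DNA and cross-term
## intensities.

.NAVO_CGS <- 6.02214076e23

#' Component molecular weights from a contrast series
#'
#' Solves the two-component forward-scattering relation
#' \deqn{\sqrt{I_0/n} = \frac{|\Delta\rho_{PROT}|}{N_a d_{prot}} MW_{PROT}
#'   + \frac{|\Delta\rho_{DNA}|}{N_a d_{DNA}} MW_{DNA}}
#' by weighted least squares across contrast points, with the particle
#' number density \eqn{n = c N_a / MW_{total}} iterated to
#' self-consistency (the total mass appears on both sides through n).
#'
#' @param fraction_d2o,i0_abs,concentration vectors per contrast point:
#'   D2O fraction, absolute-scale forward intensity (1/cm), concentration
#'   (mg/mL).
#' @param comp a [composition_spec] supplying contrasts and densities.
#' @param sigma_i0 optional I0 uncertainties for weighting.
#' @param mw_total_init starting guess for the total mass, Da.
#' @param max_iter,tol self-consistency controls.
#' @return object of class `component_mw` with `mw_protein`, `mw_dna`,
#'   `mw_total`, standard errors, the per-point design table and a
#'   `negative_flag` when a solved mass is negative (reported, not
#'   clamped).
#' @export
component_molecular_weights <- function(fraction_d2o, i0_abs, concentration,
                                        comp, sigma_i0 = NULL,
                                        mw_total_init = 2e5,
                                        max_iter = 60, tol = 1e-10) {
  n_pt <- length(fraction_d2o)
  stopifnot(length(i0_abs) == n_pt, length(concentration) == n_pt)
  if (n_pt < 2) stop("need at least 2 contrast points")
  if (length(unique(fraction_d2o)) < 2)
    stop("need at least 2 distinct D2O fractions")
  if (any(i0_abs <= 0) || any(concentration <= 0))
    stop("i0_abs and concentration must be positive")
  stopifnot(inherits(comp, "composition_spec"))
  drp <- component_contrast(comp, "protein", fraction_d2o) * 1e10  # cm^-2
  drd <- component_contrast(comp, "dna", fraction_d2o) * 1e10
  ap <- abs(drp) / (.NAVO_CGS * comp$mass_density_protein)
  ad <- abs(drd) / (.NAVO_CGS * comp$mass_density_dna)
  X <- cbind(protein = ap, dna = ad)
  sv <- svd(X)$d
  if (sv[2] < 1e-10 * sv[1])
    stop("degenerate: contrast coefficient vectors are collinear")
  c_gcm3 <- concentration * 1e-3
  w0 <- if (is.null(sigma_i0)) rep(1, n_pt) else 1 / sigma_i0^2
  mw_tot <- mw_total_init
  cf <- c(NA_real_, NA_real_)
  V <- NULL
  for (it in seq_len(max_iter)) {
    nden <- c_gcm3 * .NAVO_CGS / mw_tot               # particles / cm^3
    y <- sqrt(i0_abs / nden)                          # cm
    # delta-method weights on y when sigma_i0 supplied
    w <- if (is.null(sigma_i0)) w0 else 1 / (sigma_i0 / (2 * sqrt(i0_abs * nden)))^2
    XtW <- t(X * w)
    M <- XtW %*% X
    cf_new <- drop(solve(M, XtW %*% y))
    V <- solve(M)
    mw_new <- sum(cf_new)
    if (mw_new <= 0)
      stop("iteration produced non-positive total mass")
    conv <- abs(mw_new - mw_tot) / mw_tot < tol
    mw_tot <- mw_new; cf <- cf_new
    if (conv) break
  }
  resid <- sqrt(i0_abs / (c_gcm3 * .NAVO_CGS / mw_tot)) - drop(X %*% cf)
  dof <- n_pt - 2
  if (is.null(sigma_i0)) V <- V * if (dof > 0) sum(w0 * resid^2) / dof else 1
  se <- sqrt(diag(V))
  structure(list(
    mw_protein = unname(cf[1]), mw_dna = unname(cf[2]),
    mw_total = unname(sum(cf)),
    mw_protein_se = unname(se[1]), mw_dna_se = unname(se[2]),
    negative_flag = any(cf < 0),
    iterations = it,
    points = data.frame(fraction_d2o = fraction_d2o, i0_abs = i0_abs,
                        concentration = concentration,
                        drho_protein = drp / 1e10, drho_dna = drd / 1e10)),
    class = "component_mw")
}

#' @export
print.component_mw <- function(x, ...) {
  cat(sprintf(
    "Component MW: protein %.1f +/- %.1f kDa, DNA %.1f +/- %.1f kDa, total %.1f kDa%s\n",
    x$mw_protein / 1e3, x$mw_protein_se / 1e3, x$mw_dna / 1e3,
    x$mw_dna_se / 1e3, x$mw_total / 1e3,
    if (x$negative_flag) "  [WARNING: negative component mass]" else ""))
  invisible(x)
}

#' Decompose a contrast series into component intensities
#'
#' Per-q weighted linear solve of the contrast-variation decomposition
#' \deqn{I(q) = \Delta\rho_P^2 I_P(q) + \Delta\rho_P \Delta\rho_D
#'   I_{PD}(q) + \Delta\rho_D^2 I_D(q)}
#' across at least three profiles at distinct contrasts, after
#' interpolation onto a common q grid.  (The coefficient of the last term
#' is the DNA contrast squared -- the standard form of the decomposition.)
#' Covariances are propagated per q from the per-profile uncertainties.
#' An optional per-profile constant background nuisance term can be
#' included for series where incoherent background subtraction is in
#' doubt.
#'
#' @param profiles list of [sas_profile] objects at distinct D2O
#'   fractions.
#' @param comp a [composition_spec] supplying the component contrasts.
#' @param q_grid common q grid; default is the interior intersection grid
#'   of the inputs.
#' @param fit_background logical: add a per-profile flat background
#'   nuisance (estimated from the high-q tail) before decomposition.
#' @return object of class `component_intensities`: list with `q`,
#'   `i_protein`, `i_dna`, `i_cross`, per-q standard errors, and the
#'   contrast table.
#' @export
decompose_component_intensities <- function(profiles, comp, q_grid = NULL,
                                            fit_background = FALSE) {
  stopifnot(is.list(profiles))
  if (length(profiles) < 3)
    stop("need at least 3 profiles at distinct contrasts")
  stopifnot(inherits(comp, "composition_spec"))
  fr <- vapply(profiles, function(p) p$meta$fraction_d2o, 0)
  if (length(unique(round(fr, 6))) < 3)
    stop("need at least 3 distinct D2O fractions")
  drp <- component_contrast(comp, "protein", fr)
  drd <- component_contrast(comp, "dna", fr)
  if (is.null(q_grid)) {
    lo <- max(vapply(profiles, function(p) min(p$q), 0))
    hi <- min(vapply(profiles, function(p) max(p$q), 0))
    if (lo >= hi) stop("profiles have no common q range")
    q_grid <- profiles[[1]]$q[profiles[[1]]$q >= lo & profiles[[1]]$q <= hi]
  }
  nq <- length(q_grid)
  Imat <- Smat <- matrix(NA_real_, nq, length(profiles))
  for (j in seq_along(profiles)) {
    ip <- .interp_profile(profiles[[j]], q_grid)
    Imat[, j] <- ip$i; Smat[, j] <- ip$s
    if (fit_background) {
      tail_idx <- profiles[[j]]$q >= stats::quantile(profiles[[j]]$q, 0.9)
      Imat[, j] <- Imat[, j] - stats::median(profiles[[j]]$intensity[tail_idx])
    }
  }
  X <- cbind(p = drp^2, pd = drp * drd, d = drd^2)
  if (qr(X)$rank < 3) stop("singular per-q system: contrasts too clustered")
  ip <- idn <- ix <- matrix(NA_real_, nq, 2,
                            dimnames = list(NULL, c("est", "se")))
  for (k in seq_len(nq)) {
    w <- 1 / Smat[k, ]^2
    XtW <- t(X * w)
    M <- XtW %*% X
    cf <- drop(solve(M, XtW %*% Imat[k, ]))
    V <- solve(M)
    se <- sqrt(diag(V))
    ip[k, ] <- c(cf[1], se[1]); ix[k, ] <- c(cf[2], se[2])
    idn[k, ] <- c(cf[3], se[3])
  }
  structure(list(q = q_grid,
                 i_protein = ip[, 1], i_protein_se = ip[, 2],
                 i_dna = idn[, 1], i_dna_se = idn[, 2],
                 i_cross = ix[, 1], i_cross_se = ix[, 2],
                 contrasts = data.frame(fraction_d2o = fr,
                                        drho_protein = drp,
                                        drho_dna = drd)),
            class = "component_intensities")
}

#' Reconstruct a measured profile from decomposed components
#'
#' Forward application of the decomposition at one contrast point; used
#' for self-consistency checks.
#'
#' @param ci a `component_intensities` object.
#' @param drho_protein,drho_dna contrasts (1e-6 A^-2).
#' @return intensity vector on `ci$q`.
#' @export
reconstruct_intensity <- function(ci, drho_protein, drho_dna) {
  drho_protein^2 * ci$i_protein +
    drho_protein * drho_dna * ci$i_cross +
    drho_dna^2 * ci$i_dna
}
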