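## Stuhrmann analysis: dependence of the observed radius of gyration on
## the mean particle contrast,
##   Rg^2 = Rc^2 + alpha/drho - beta/drho^2,
## fitted by weighted least squares in (Rg^2, 1/drho) space.

#' Stuhrmann fit
#'
#' Fits the contrast dependence of \eqn{R_g^2} across a contrast-variation
#' series: \eqn{R_g^2 = R_c^2 + \alpha/\Delta\rho - \beta/\Delta\rho^2}.
#' \eqn{R_c} is the radius of gyration at infinite contrast (the shape
#' term); \eqn{\alpha > 0} places the higher-SLD component peripherally;
#' \eqn{\beta \neq 0} indicates displaced component centers of mass (for a
#' centrosymmetric two-phase body \eqn{\beta = 0}).  Weights derive from
#' the Guinier \eqn{\sigma_{R_g}} propagated to \eqn{\sigma_{R_g^2} = 2
#' R_g \sigma_{R_g}}; `weighted = FALSE` gives the unweighted plot-space
#' fit.
#'
#' @param delta_rho mean particle contrasts, 1e-6 A^-2 (nonzero).
#' @param rg radii of gyration, Angstrom.
#' @param sigma_rg Rg uncertainties (used for weighting; optional for
#'   `model = "linear"` or unweighted fits).
#' @param model `"hyperbolic"` (3 parameters, needs >= 3 points) or
#'   `"linear"` (beta fixed at 0, needs >= 2 points).
#' @param weighted logical.
#' @return object of class `stuhrmann_fit` with `rc`, `rc_se`, `alpha`,
#'   `alpha_se`, `beta`, `beta_se`, `ill_conditioned` flag, `model` and
#'   the `points` table.
#' @export
stuhrmann_fit <- function(delta_rho, rg, sigma_rg = NULL,
                          model = c("hyperbolic", "linear"),
                          weighted = TRUE) {
  model <- match.arg(model)
  n <- length(delta_rho)
  stopifnot(length(rg) == n)
  if (any(delta_rho == 0)) stop("delta_rho must be nonzero everywhere")
  need <- if (model == "hyperbolic") 3 else 2
  if (n < need)
    stop(model, " Stuhrmann fit needs at least ", need, " points, got ", n)
  y <- rg^2
  x1 <- 1 / delta_rho
  w <- if (weighted && !is.null(sigma_rg)) 1 / (2 * rg * sigma_rg)^2
       else rep(1, n)
  X <- if (model == "hyperbolic") cbind(1, x1, -x1^2) else cbind(1, x1)
  XtW <- t(X * w)
  M <- XtW %*% X
  cond <- kappa(M, exact = TRUE)
  ill <- is.na(cond) || cond > 1e10 ||
    (max(abs(x1)) / max(min(abs(x1)), 1e-300) < 1.5)
  cf <- drop(solve(M, XtW %*% y))
  resid <- y - drop(X %*% cf)
  dof <- n - ncol(X)
  s2 <- if (dof > 0) sum(w * resid^2) / dof else 1
  # with true sigmas the covariance is (X'WX)^-1; rescale by s2 otherwise
  V <- solve(M)
  if (!weighted || is.null(sigma_rg)) V <- V * s2
  rc2 <- cf[1]
  if (rc2 <= 0) stop("fit gives non-positive Rc^2 (", format(rc2), ")")
  rc <- sqrt(rc2)
  rc_se <- sqrt(V[1, 1]) / (2 * rc)
  alpha <- cf[2]; alpha_se <- sqrt(V[2, 2])
  beta <- if (model == "hyperbolic") cf[3] else 0
  beta_se <- if (model == "hyperbolic") sqrt(V[3, 3]) else 0
  structure(list(
    rc = unname(rc), rc_se = unname(rc_se),
    alpha = unname(alpha), alpha_se = unname(alpha_se),
    beta = unname(beta), beta_se = unname(beta_se),
    model = model, ill_conditioned = ill, dof = dof,
    chi2red = if (dof > 0) sum(w * resid^2) / dof else NA_real_,
    points = data.frame(delta_rho = delta_rho, rg = rg,
                        sigma_rg = if (is.null(sigma_rg)) NA_real_
                                   else sigma_rg)),
    class = "stuhrmann_fit")
}

#' @export
print.stuhrmann_fit <- function(x, ...) {
  cat(sprintf(
    "Stuhrmann (%s): Rc = %.2f +/- %.2f A, alpha = %.3g +/- %.2g, beta = %.3g +/- %.2g%s\n",
    x$model, x$rc, x$rc_se, x$alpha, x$alpha_se, x$beta, x$beta_se,
    if (x$ill_conditioned) "  [ill-conditioned]" else ""))
  invisible(x)
}

#' Exact Rg(contrast) of a multi-phase body
#'
#' Closed-form contrast-weighted radius of gyration of a body built from
#' homogeneous phases (volume, own Rg about its center, SLD, center
#' coordinates) in a solvent of SLD `rho_solvent`:
#' \eqn{R_g^2 = \sum_i w_i (R_{g,i}^2 + |c_i - X|^2) / \sum_i w_i} with
#' \eqn{w_i = V_i (\rho_i - \rho_s)} and X the contrast-weighted center.
#' Used as the analytic oracle for Stuhrmann parameter recovery; returns
#' NA when the total contrast weight vanishes.
#'
#' @param volumes,rgs,slds numeric vectors per phase.
#' @param centers matrix (n_phase x 3) of center coordinates, Angstrom.
#' @param rho_solvent solvent SLD, same units as `slds`.
#' @return list with `rg2` (may be negative near the match point),
#'   `delta_rho_mean` (volume-mean contrast).
#' @export
multiphase_rg2 <- function(volumes, rgs, slds, centers, rho_solvent) {
  centers <- rbind(centers)
  w <- volumes * (slds - rho_solvent)
  tw <- sum(w)
  dr_mean <- tw / sum(volumes)
  if (abs(tw) < 1e-300) return(list(rg2 = NA_real_,
                                    delta_rho_mean = dr_mean))
  X <- colSums(centers * w) / tw
  d2 <- rowSums((centers - matrix(X, nrow(centers), 3, byrow = TRUE))^2)
  list(rg2 = sum(w * (rgs^2 + d2)) / tw, delta_rho_mean = dr_mean)
}
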