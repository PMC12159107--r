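## Guinier analysis: weighted linear fit of ln I vs q^2 with automatic
## self-consistent window selection under a qRg ceiling.

#' Guinier fit
#'
#' Weighted least-squares fit of \eqn{\ln I = \ln I_0 - q^2 R_g^2/3} over a
#' low-q window.  With `auto_window = TRUE` (default) the window starts at
#' the first usable (positive-intensity) point -- after rejecting low-q
#' outliers with studentized residuals above 3 -- and is grown to the
#' largest self-consistent window satisfying
#' \eqn{q_{max} R_g \le} `qrg_max`, iterating the \eqn{R_g} estimate to a
#' relative tolerance of 1e-4.
#'
#' @param profile a [sas_profile].
#' @param qrg_max upper bound on \eqn{q_{max} R_g} (default 1.2, the
#'   conventional ceiling for compact particles).
#' @param auto_window grow the window automatically; when FALSE the fit
#'   uses `q_window` as given.
#' @param q_window explicit `(qmin, qmax)` window when `auto_window = FALSE`.
#' @param min_points minimum number of points in the window.
#' @return object of class `guinier_fit` with fields `rg`, `rg_se`, `i0`,
#'   `i0_se`, `q_window`, `qrg_window`, `n_points`, `fit_r2`, `residuals`.
#' @export
guinier_fit <- function(profile, qrg_max = 1.2, auto_window = TRUE,
                        q_window = NULL, min_points = 3) {
  stopifnot(inherits(profile, "sas_profile"))
  q <- profile$q; I <- profile$intensity; s <- profile$sigma
  pos <- I > 0
  if (sum(pos) < min_points)
    stop("fewer than ", min_points, " positive-intensity points")
  first <- which(pos)[1]

  fit_window <- function(idx) {
    x <- q[idx]^2; y <- log(I[idx]); w <- (I[idx] / s[idx])^2
    fit <- stats::lm(y ~ x, weights = w)
    cf <- stats::coef(fit)
    if (cf[2] >= 0) return(NULL)  # non-physical: growing intensity
    rg <- sqrt(-3 * unname(cf[2]))
    V <- stats::vcov(fit)
    list(fit = fit, rg = rg, rg_se = sqrt(V[2, 2]) * 3 / (2 * rg),
         i0 = exp(unname(cf[1])), i0_se = exp(unname(cf[1])) * sqrt(V[1, 1]),
         idx = idx)
  }

  if (!auto_window) {
    if (is.null(q_window)) stop("q_window required when auto_window = FALSE")
    idx <- which(q >= q_window[1] & q <= q_window[2] & pos)
    if (length(idx) < min_points)
      stop("fewer than ", min_points, " points in the requested window")
    res <- fit_window(idx)
    if (is.null(res)) stop("non-physical fit (Rg^2 <= 0) in window")
  } else {
    # reject leading outliers by studentized residual on a generous window
    idx0 <- which(pos)
    idx0 <- idx0[seq_len(min(length(idx0), 25))]
    if (length(idx0) >= min_points + 2) {
      f0 <- fit_window(idx0)
      if (!is.null(f0)) {
        rs <- stats::rstudent(f0$fit)
        lead_bad <- which(abs(rs) > 3)
        lead_bad <- lead_bad[lead_bad <= 3]  # only leading points
        if (length(lead_bad)) first <- idx0[max(lead_bad) + 1L]
      }
    }
    cand <- which(pos & seq_along(q) >= first)
    if (length(cand) < min_points)
      stop("fewer than ", min_points, " points available")
    nwin <- min(length(cand), max(min_points + 2, 8))
    res <- fit_window(cand[seq_len(nwin)])
    if (is.null(res)) stop("non-physical initial Guinier fit")
    seen <- character()
    for (iter in 1:100) {
      keep <- cand[q[cand] * res$rg <= qrg_max]
      if (length(keep) < min_points) keep <- cand[seq_len(min_points)]
      sig <- paste(range(keep), collapse = "-")
      if (identical(keep, res$idx)) break        # fixed point
      new <- fit_window(keep)
      if (is.null(new)) break
      conv <- abs(new$rg - res$rg) / res$rg < 1e-4
      res <- new
      # a revisited window means a limit cycle: accept the current fit
      if (conv || sig %in% seen) break
      seen <- c(seen, sig)
      if (iter == 100) stop("Guinier window iteration did not converge")
    }
    if (length(res$idx) < min_points)
      stop("fewer than ", min_points, " points satisfy qRg <= ", qrg_max)
    if (q[res$idx[1]] * res$rg > qrg_max)
      stop("no usable points below the qRg bound: the lowest measured q ",
           "already has qRg = ", format(q[res$idx[1]] * res$rg,
                                        digits = 3))
  }
  idx <- res$idx
  r2 <- summary(res$fit)$r.squared
  structure(list(
    rg = res$rg, rg_se = res$rg_se, i0 = res$i0, i0_se = res$i0_se,
    q_window = c(q[idx[1]], q[idx[length(idx)]]),
    qrg_window = c(q[idx[1]], q[idx[length(idx)]]) * res$rg,
    n_points = length(idx), fit_r2 = r2,
    residuals = stats::residuals(res$fit), index = idx),
    class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "Guinier: Rg = %.2f +/- %.2f A, I0 = %.4g +/- %.2g, qRg %.2f-%.2f (n=%d, R2=%.4f)\n",
    x$rg, x$rg_se, x$i0, x$i0_se, x$qrg_window[1], x$qrg_window[2],
    x$n_points, x$fit_r2))
  invisible(x)
}
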