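## One-dimensional scattering profiles: construction, validation, file I/O,
## and merging of multi-configuration data.
##
## File dialect: whitespace-separated 3-column ASCII (q, I, sigma), '#'
## header lines optionally carrying key=value metadata.  q is in inverse
## Angstrom everywhere; a header line "q_units=nm^-1" declares nm^-1 input,
## converted on read.  Numbers are written with 8 significant digits using
## the C "%.8g" format (the fixed significant-digit policy of the module).

.profile_meta_defaults <- function() {
  list(source = "xray", fraction_d2o = 0, concentration = NA_real_,
       pressure = 0.1013, temperature = 20, absolute_scale = FALSE,
       label = "", sigma_imputed = FALSE)
}

#' Construct a scattering profile
#'
#' Bundles a one-dimensional scattering curve \eqn{(q, I(q), \sigma)} with
#' its experiment metadata and validates the invariants: strictly
#' increasing positive `q`, equal lengths of at least 8, strictly positive
#' uncertainties, \eqn{f_{D_2O} \in [0,1]} and non-negative pressure.
#'
#' @param q momentum transfer, 1/Angstrom (\eqn{q = 4\pi\sin\theta/\lambda}).
#' @param intensity scattered intensity; 1/cm when `absolute_scale` is TRUE,
#'   otherwise arbitrary units.
#' @param sigma one-standard-deviation uncertainties, same units as
#'   `intensity`.  If `NULL`, imputed as `impute_frac * |intensity|` and
#'   flagged in the metadata (`sigma_imputed`).
#' @param source `"xray"` or `"neutron"`.
#' @param fraction_d2o solvent D2O volume fraction, 0 to 1.
#' @param concentration sample concentration, mg/mL (NA if unknown).
#' @param pressure hydrostatic pressure, MPa (ambient is 0.1013).
#' @param temperature temperature, degrees C.
#' @param absolute_scale logical; TRUE when intensities are on the absolute
#'   (1/cm) scale.
#' @param label free-text sample label.
#' @param sigma_imputed logical flag; set automatically when `sigma` is NULL.
#' @param impute_frac fraction of `|I|` used when imputing sigma.
#' @return An object of class `sas_profile`.
#' @export
sas_profile <- function(q, intensity, sigma = NULL, source = "xray",
                        fraction_d2o = 0, concentration = NA_real_,
                        pressure = 0.1013, temperature = 20,
                        absolute_scale = FALSE, label = "",
                        sigma_imputed = FALSE, impute_frac = 0.02) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (is.null(sigma)) {
    sigma <- impute_frac * pmax(abs(intensity), .Machine$double.eps)
    sigma_imputed <- TRUE
  }
  sigma <- as.numeric(sigma)
  n <- length(q)
  if (length(intensity) != n || length(sigma) != n)
    stop("q, intensity and sigma must have equal length")
  if (n < 8) stop("profile needs at least 8 points, got ", n)
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q must be finite and strictly positive")
  dq <- diff(q)
  if (any(dq <= 0)) {
    bad <- which(dq <= 0)[1] + 1L
    stop("q must be strictly increasing; violation at row ", bad,
         " (q = ", format(q[bad]), ")")
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be finite and strictly positive")
  if (!is.finite(fraction_d2o) || fraction_d2o < 0 || fraction_d2o > 1)
    stop("fraction_d2o must lie in [0, 1]")
  if (!is.finite(pressure) || pressure < 0) stop("pressure must be >= 0")
  source <- match.arg(source, c("xray", "neutron"))
  structure(
    list(q = q, intensity = intensity, sigma = sigma,
         meta = list(source = source, fraction_d2o = fraction_d2o,
                     concentration = concentration, pressure = pressure,
                     temperature = temperature,
                     absolute_scale = isTRUE(absolute_scale),
                     label = as.character(label),
                     sigma_imputed = isTRUE(sigma_imputed))),
    class = "sas_profile")
}

#' @export
print.sas_profile <- function(x, ...) {
  m <- x$meta
  cat(sprintf("sas_profile: %d points, q = [%.4g, %.4g] 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  cat(sprintf("  source=%s fD2O=%.2f conc=%s mg/mL P=%.4g MPa%s%s\n",
              m$source, m$fraction_d2o,
              if (is.na(m$concentration)) "NA" else format(m$concentration),
              m$pressure,
              if (m$absolute_scale) " [abs 1/cm]" else "",
              if (nzchar(m$label)) paste0(" label=", m$label) else ""))
  invisible(x)
}

.meta_serialize <- function(meta) {
  vapply(names(meta), function(k) {
    v <- meta[[k]]
    v <- if (is.logical(v)) ifelse(v, "true", "false") else as.character(v)
    paste0("# ", k, "=", v)
  }, character(1))
}

.meta_parse_value <- function(key, value) {
  if (key %in% c("absolute_scale", "sigma_imputed"))
    return(tolower(value) %in% c("true", "1", "yes"))
  if (key %in% c("fraction_d2o", "concentration", "pressure", "temperature"))
    return(suppressWarnings(as.numeric(value)))
  value
}

#' Read a scattering profile from 3-column ASCII
#'
#' Parses the de-facto SAS `.dat` convention: numeric rows of `q I [sigma]`
#' with optional `#`-prefixed header lines; `# key=value` headers populate
#' the profile metadata.  Two-column files get sigma imputed as 2% of the
#' intensity, flagged via `sigma_imputed` in the metadata.  A header
#' `q_units=nm^-1` triggers conversion of q to 1/Angstrom on read.
#'
#' @param path path to the file.
#' @param impute_frac sigma imputation fraction for 2-column files.
#' @return A [sas_profile].
#' @export
read_profile <- function(path, impute_frac = 0.02) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error: empty file ", path)
  is_hdr <- startsWith(trimws(lines), "#")
  meta <- .profile_meta_defaults()
  q_scale <- 1
  for (h in lines[is_hdr]) {
    h <- sub("^\\s*#\\s*", "", h)
    if (!grepl("=", h, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", h))
    val <- trimws(sub("^[^=]*=", "", h))
    if (key == "q_units") {
      if (val %in% c("nm^-1", "1/nm", "nm-1")) q_scale <- 0.1
      next
    }
    if (key %in% c("units")) next
    if (key %in% names(meta)) meta[[key]] <- .meta_parse_value(key, val)
  }
  rows <- lines[!is_hdr]
  if (!length(rows)) stop("format error: no data rows in ", path)
  parsed <- lapply(strsplit(trimws(rows), "\\s+"), function(x)
    suppressWarnings(as.numeric(x)))
  ncols <- lengths(parsed)
  if (any(vapply(parsed, function(x) any(is.na(x)), logical(1))) ||
      !all(ncols %in% c(2L, 3L)) || length(unique(ncols)) != 1L)
    stop("format error: rows must be 2 or 3 numeric columns")
  m <- do.call(rbind, parsed)
  q <- m[, 1] * q_scale
  i <- m[, 2]
  s <- if (ncol(m) == 3) m[, 3] else NULL
  if (!is.null(s) && any(s < 0)) stop("format error: negative sigma")
  if (!is.null(s) && any(s == 0)) stop("format error: zero sigma")
  dq <- diff(q)
  if (any(dq <= 0))
    stop("format error: q not strictly increasing at data row ",
         which(dq <= 0)[1] + 1L)
  do.call(sas_profile, c(list(q = q, intensity = i, sigma = s,
                              impute_frac = impute_frac), meta))
}

#' Write a scattering profile to 3-column ASCII
#'
#' Writes all metadata as `# key=value` header lines followed by
#' whitespace-separated `q I sigma` columns at 8 significant digits.
#' Profiles on the absolute scale also record `units=cm^-1` in the header.
#' The written file round-trips through [read_profile] losslessly at that
#' precision.
#'
#' @param profile a [sas_profile].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sas_profile"))
  if (!is.character(path) || length(path) != 1 || !nzchar(path))
    stop("path must be a non-empty string")
  hdr <- .meta_serialize(profile$meta)
  if (isTRUE(profile$meta$absolute_scale)) hdr <- c(hdr, "# units=cm^-1")
  body <- sprintf("%.8g %.8g %.8g", profile$q, profile$intensity,
                  profile$sigma)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

.interp_profile <- function(profile, q) {
  list(i = stats::approx(profile$q, profile$intensity, xout = q)$y,
       s = stats::approx(profile$q, profile$sigma, xout = q)$y)
}

#' Merge overlapping q-range segments of one sample
#'
#' Combines two or more profiles of the same sample measured over different
#' (overlapping) q windows -- e.g. multiple sample-to-detector distances --
#' into one profile on the union grid.  With
#' `overlap_policy = "scale-to-first"` each later profile is rescaled to the
#' running merge by a weighted least-squares factor determined on the
#' common-q interpolants of the overlap window.  Within overlaps, points
#' are averaged with inverse-variance weights and the uncertainty floor of
#' the contributing points is preserved (the merged sigma never drops below
#' the smallest input sigma at that q).
#'
#' @param profiles list of [sas_profile] objects, ordered by preference
#'   (the first defines the reference scale).
#' @param overlap_policy `"scale-to-first"` or `"no-scale"`.
#' @return A single merged [sas_profile]; scale factors applied to each
#'   input are recorded in `attr(, "scale_factors")`.
#' @export
trim_and_merge <- function(profiles,
                           overlap_policy = c("scale-to-first", "no-scale")) {
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(is.list(profiles), length(profiles) >= 1)
  lapply(profiles, function(p) stopifnot(inherits(p, "sas_profile")))
  if (length(profiles) == 1) {
    attr(profiles[[1]], "scale_factors") <- 1
    return(profiles[[1]])
  }
  ref_meta <- profiles[[1]]$meta
  for (p in profiles[-1]) {
    for (k in c("source", "fraction_d2o", "pressure")) {
      if (!identical(p$meta[[k]], ref_meta[[k]]))
        stop("inconsistent metadata across profiles: ", k,
             " differs (", format(ref_meta[[k]]), " vs ",
             format(p$meta[[k]]), ")")
    }
  }
  cur <- profiles[[1]]
  scales <- rep(1, length(profiles))
  for (j in seq_along(profiles)[-1]) {
    p <- profiles[[j]]
    lo <- max(min(cur$q), min(p$q)); hi <- min(max(cur$q), max(p$q))
    if (lo >= hi)
      stop("no q overlap between merged profile and profile ", j)
    fac <- 1
    if (overlap_policy == "scale-to-first") {
      qo <- sort(unique(c(cur$q[cur$q >= lo & cur$q <= hi],
                          p$q[p$q >= lo & p$q <= hi])))
      a <- .interp_profile(cur, qo); b <- .interp_profile(p, qo)
      w <- 1 / (a$s^2 + b$s^2)
      ok <- is.finite(w) & is.finite(a$i) & is.finite(b$i)
      # minimize sum w (a - fac*b)^2
      fac <- sum(w[ok] * a$i[ok] * b$i[ok]) / sum(w[ok] * b$i[ok]^2)
    }
    scales[j] <- fac
    qs <- c(cur$q, p$q)
    is <- c(cur$intensity, fac * p$intensity)
    ss <- c(cur$sigma, abs(fac) * p$sigma)
    ord <- order(qs)
    qs <- qs[ord]; is <- is[ord]; ss <- ss[ord]
    # collapse duplicated q by inverse-variance weighting, keep sigma floor
    grp <- cumsum(c(TRUE, diff(qs) > 1e-12 * max(qs)))
    agg_i <- tapply(seq_along(qs), grp, function(idx) {
      w <- 1 / ss[idx]^2
      sum(w * is[idx]) / sum(w)
    })
    agg_s <- tapply(seq_along(qs), grp, function(idx) {
      w <- 1 / ss[idx]^2
      max(sqrt(1 / sum(w)), min(ss[idx]))
    })
    agg_q <- tapply(qs, grp, function(x) x[1])
    cur <- sas_profile(q = as.numeric(agg_q), intensity = as.numeric(agg_i),
                       sigma = as.numeric(agg_s),
                       source = ref_meta$source,
                       fraction_d2o = ref_meta$fraction_d2o,
                       concentration = ref_meta$concentration,
                       pressure = ref_meta$pressure,
                       temperature = ref_meta$temperature,
                       absolute_scale = ref_meta$absolute_scale,
                       label = ref_meta$label,
                       sigma_imputed = ref_meta$sigma_imputed)
  }
  attr(cur, "scale_factors") <- scales
  cur
}

#' Read or write a JSON-lines profile manifest
#'
#' A manifest binds `.dat` files to their series metadata (one JSON object
#' per line with at least a `path` field; remaining fields override the
#' file headers).  Used by the series-level operations and the command-line
#' interface.
#'
#' @param path manifest path.
#' @param base_dir directory against which relative `path` fields resolve;
#'   defaults to the manifest's directory.
#' @return list of [sas_profile] objects with manifest metadata applied.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    if (is.null(rec$path)) stop("manifest record missing 'path' field")
    f <- rec$path
    if (!file.exists(f)) f <- file.path(base_dir, rec$path)
    p <- read_profile(f)
    for (k in intersect(names(rec), names(p$meta)))
      p$meta[[k]] <- .meta_parse_value(k, as.character(rec[[k]]))
    p
  })
}

#' @rdname read_manifest
#' @param profiles list of [sas_profile] objects to index.
#' @param paths character vector of the `.dat` paths the records point to.
#' @export
write_manifest <- function(profiles, paths, path) {
  stopifnot(length(profiles) == length(paths))
  recs <- vapply(seq_along(profiles), function(i) {
    m <- profiles[[i]]$meta
    jsonlite::toJSON(c(list(path = paths[i]), m), auto_unbox = TRUE)
  }, character(1))
  writeLines(recs, path)
  invisible(path)
}
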