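#' Construct a hill list
#'
#' The discrete representation of the metadynamics bias \eqn{V(s,t)}: a
#' time-ordered table of deposited Gaussian hills. Heights are stored in kT.
#'
#' @param time deposition times (non-decreasing, >= 0).
#' @param center hill centers, CV units.
#' @param sigma hill widths (> 0), CV units.
#' @param height hill heights in kT (>= 0).
#' @return An object of class `hills` (a data.frame with columns `time`,
#'   `center`, `sigma`, `height`).
#' @export
hills <- function(time = numeric(), center = numeric(),
                  sigma = numeric(), height = numeric()) {
  n <- length(time)
  stopifnot(length(center) == n, length(height) == n)
  if (length(sigma) == 1L && n > 1L) sigma <- rep(sigma, n)
  stopifnot(length(sigma) == n)
  if (n > 0L) {
    if (any(!is.finite(time)) || any(time < 0)) stop("hill times must be finite and >= 0")
    if (is.unsorted(time)) stop("hill times must be non-decreasing")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("hill sigmas must be > 0")
    if (any(!is.finite(height)) || any(height < 0)) stop("hill heights must be finite and >= 0")
  }
  structure(
    data.frame(time = as.numeric(time), center = as.numeric(center),
               sigma = as.numeric(sigma), height = as.numeric(height)),
    class = c("hills", "data.frame")
  )
}

#' @export
print.hills <- function(x, ...) {
  cat(sprintf("hills: %d deposited Gaussian(s)", nrow(x)))
  if (nrow(x) > 0L) {
    cat(sprintf(", t in [%g, %g], total height %.3g kT",
                min(x$time), max(x$time), sum(x$height)))
  }
  cat("\n")
  if (nrow(x) > 0L) print.data.frame(head(as.data.frame(x), 5L))
  invisible(x)
}

as_hills <- function(x) {
  if (inherits(x, "hills")) return(x)
  if (is.data.frame(x) && all(c("time", "center", "sigma", "height") %in% names(x))) {
    return(hills(x$time, x$center, x$sigma, x$height))
  }
  stop("expected a `hills` object")
}

#' Well-tempered hill height
#'
#' The tempering rule \eqn{w = w_0 \exp(-V(s,t) / ((\gamma - 1) kT))}:
#' the height of a new hill decays exponentially with the bias already
#' accumulated at its deposition point, so the bias converges instead of
#' growing without bound.
#'
#' @param w0 initial hill height, kT (>= 0).
#' @param current_bias_at_center bias already present at the deposition
#'   point, kT (>= 0).
#' @param thermo a [thermo_params()] (supplies `gamma`; gamma <= 1 is
#'   rejected at construction).
#' @return the tempered height, in (0, w0].
#' @export
wt_hill_height <- function(w0, current_bias_at_center, thermo) {
  thermo <- as_thermo(thermo)
  stopifnot(is.numeric(w0), all(w0 >= 0),
            is.numeric(current_bias_at_center), all(current_bias_at_center >= 0))
  w0 * exp(-current_bias_at_center / (thermo$gamma - 1))
}

#' Deposit one well-tempered hill
#'
#' Appends a hill at the current CV value, with height given by
#' [wt_hill_height()] evaluated at the bias present there before the
#' deposition.
#'
#' @param hl a [hills()] list.
#' @param s_now current CV value (the new hill center).
#' @param t_now deposition time; must be >= the last hill time.
#' @param w0 initial hill height, kT.
#' @param sigma hill width, CV units.
#' @param thermo a [thermo_params()].
#' @return the extended `hills` object.
#' @export
deposit_hill <- function(hl, s_now, t_now, w0, sigma, thermo) {
  hl <- as_hills(hl)
  thermo <- as_thermo(thermo)
  if (nrow(hl) > 0L && t_now < hl$time[nrow(hl)]) {
    stop(sprintf("out-of-order deposition: t = %g precedes last hill time %g",
                 t_now, hl$time[nrow(hl)]))
  }
  h <- wt_hill_height(w0, bias_value(hl, s_now, t_now), thermo)
  out <- rbind(as.data.frame(hl),
               data.frame(time = t_now, center = s_now, sigma = sigma, height = h))
  structure(out, class = c("hills", "data.frame"))
}

#' Evaluate the metadynamics bias V(s, t)
#'
#' Sums the Gaussians of all hills deposited up to and including time `t`:
#' \eqn{V(s,t) = \sum_{t_k \le t} h_k \exp(-(s - s_k)^2 / (2\sigma_k^2))}.
#' Non-negative, and pointwise non-decreasing in `t`.
#'
#' @param hl a [hills()] list.
#' @param s CV value(s); vectorised.
#' @param t time cutoff; default `Inf` includes every hill.
#' @return bias in kT, same length as `s`.
#' @export
bias_value <- function(hl, s, t = Inf) {
  hl <- as_hills(hl)
  stopifnot(is.numeric(s))
  keep <- hl$time <= t
  if (!any(keep)) return(numeric(length(s)) )
  bias_sum_cpp(as.numeric(s), hl$center[keep], hl$sigma[keep], hl$height[keep])
}

#' Write hills to a PLUMED-style HILLS file
#'
#' Single-CV PLUMED dialect with header
#' `#! FIELDS time cv sigma_cv height biasf`. Heights are converted from the
#' internal kT to kJ/mol (the PLUMED convention) using the temperature in
#' `thermo`; the `biasf` column records \eqn{\gamma}.
#'
#' @param hl a [hills()] list (heights in kT).
#' @param path output file path.
#' @param thermo a [thermo_params()] giving the temperature for unit
#'   conversion and the bias factor written to `biasf`.
#' @param cv_name name of the collective variable in the header (default
#'   `"cv"`).
#' @return `path`, invisibly.
#' @export
write_hills <- function(hl, path, thermo, cv_name = "cv") {
  hl <- as_hills(hl)
  thermo <- as_thermo(thermo)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#! FIELDS time %s sigma_%s height biasf", cv_name, cv_name), con)
  if (nrow(hl) > 0L) {
    writeLines(sprintf("%.15g %.15g %.15g %.15g %.15g",
                       hl$time, hl$center, hl$sigma,
                       hl$height * thermo$kT_kj, thermo$gamma), con)
  }
  invisible(path)
}

#' Read a PLUMED-style HILLS file
#'
#' Parses the single-CV dialect written by [write_hills()] (and by PLUMED
#' for a 1D CV). Heights in kJ/mol are converted to kT at
#' `thermo$temperature`. Malformed lines are reported with their line
#' numbers; a `biasf` column inconsistent with `thermo$gamma` raises a
#' warning.
#'
#' @param path HILLS file path.
#' @param thermo a [thermo_params()].
#' @return a [hills()] object (heights in kT).
#' @export
read_hills <- function(path, thermo) {
  thermo <- as_thermo(thermo)
  if (!file.exists(path)) stop(sprintf("HILLS file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0L) stop(sprintf("%s: empty file, missing FIELDS header", path))
  m <- regmatches(lines[1L],
    regexec("^#!\\s*FIELDS\\s+time\\s+(\\S+)\\s+(\\S+)\\s+height(\\s+biasf)?\\s*$",
            lines[1L]))[[1L]]
  if (length(m) == 0L) {
    stop(sprintf("%s:1: malformed HILLS header: %s", path, lines[1L]))
  }
  cv_name <- m[2L]
  if (m[3L] != paste0("sigma_", cv_name)) {
    stop(sprintf("%s:1: sigma column '%s' does not match CV '%s'",
                 path, m[3L], cv_name))
  }
  has_biasf <- nzchar(m[4L])
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  n_fields <- if (has_biasf) 5L else 4L
  parse_line <- function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(toks) != n_fields) {
      stop(sprintf("%s:%d: expected %d fields, found %d", path, i, n_fields, length(toks)))
    }
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals))) {
      stop(sprintf("%s:%d: non-numeric token in '%s'", path, i, lines[i]))
    }
    vals
  }
  if (length(body_idx) == 0L) {
    return(hills())
  }
  mat <- t(vapply(body_idx, parse_line, numeric(n_fields)))
  if (is.unsorted(mat[, 1L])) {
    bad <- body_idx[which(diff(mat[, 1L]) < 0)[1L] + 1L]
    stop(sprintf("%s:%d: non-monotone hill time", path, bad))
  }
  if (has_biasf) {
    bf <- unique(mat[, 5L])
    if (any(abs(bf - thermo$gamma) > 1e-6 * max(1, thermo$gamma))) {
      warning(sprintf(
        "%s: biasf column (%s) differs from thermo gamma = %g",
        path, paste(signif(bf, 6), collapse = ", "), thermo$gamma
      ))
    }
  }
  hills(time = mat[, 1L], center = mat[, 2L], sigma = mat[, 3L],
        height = mat[, 4L] / thermo$kT_kj)
}
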