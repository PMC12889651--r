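#' Integration grid over the collective-variable domain
#'
#' The c(t) integrals run over the accessible range of the biased CV. The
#' default domain for a toy run is `[0, wall_position + 3 * sigma_max]`:
#' from the RMSD floor to just past the restraint wall.
#'
#' @param s_min,s_max domain bounds, `s_max > s_min`.
#' @param n_points number of uniformly spaced quadrature nodes (>= 2;
#'   default 1000).
#' @return an object of class `ct_grid` with fields `s` (node positions),
#'   `s_min`, `s_max`, `n_points`, `spacing`.
#' @export
ct_grid <- function(s_min = 0, s_max = 1, n_points = 1000L) {
  stopifnot(is.numeric(s_min), is.numeric(s_max), length(s_min) == 1L,
            length(s_max) == 1L, is.finite(s_min), is.finite(s_max))
  if (!(s_max > s_min)) stop("`s_max` must exceed `s_min`")
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2) {
    stop("`n_points` must be >= 2")
  }
  n_points <- as.integer(n_points)
  structure(
    list(s = seq(s_min, s_max, length.out = n_points),
         s_min = s_min, s_max = s_max, n_points = n_points,
         spacing = (s_max - s_min) / (n_points - 1)),
    class = "ct_grid"
  )
}

#' Default grid for a model potential
#'
#' @param spec a [potential_spec()].
#' @param sigma_max largest hill width expected on the landscape.
#' @param n_points quadrature nodes.
#' @return a [ct_grid()] spanning `[0, wall_position + 3 * sigma_max]`.
#' @export
default_grid <- function(spec, sigma_max = 0.02, n_points = 1000L) {
  stopifnot(inherits(spec, "potential_spec"))
  ct_grid(0, spec$wall_position + 3 * sigma_max, n_points)
}

# log(sum(exp(x) * w)) with the max subtracted first; w are positive weights
logsumexp_w <- function(x, logw) {
  m <- max(x)
  m + log(sum(exp(x - m + logw - max(logw))) ) + max(logw)
}

trapezoid_logw <- function(grid) {
  w <- rep(grid$spacing, grid$n_points)
  w[c(1L, grid$n_points)] <- grid$spacing / 2
  log(w)
}

#' Reversible-work estimator c(t) at a single time
#'
#' Evaluates
#' \deqn{c(t) = \frac{1}{\beta}\log
#'   \frac{\int ds\, \exp[\frac{\gamma}{\gamma-1}\beta V(s,t)]}
#'        {\int ds\, \exp[\frac{1}{\gamma-1}\beta V(s,t)]}}
#' by trapezoidal quadrature on `grid`, with both integrals computed in log
#' space (per-integrand maximum subtracted before exponentiating) so the
#' result stays finite for biases of hundreds of kT per node. With no
#' deposited bias c(t) = 0 exactly; a constant bias offset shifts c(t) by
#' exactly that offset; and for any bias, \eqn{\min_s V \le c(t) \le
#' \max_s V} (the ratio is a weighted average of \eqn{e^{\beta V}}).
#'
#' A warning is raised when a hill center lies within 3 sigma of a grid
#' edge, since the quadrature domain then misses part of the deposited
#' bias. For a reflecting CV whose hills pile up against s = 0 this
#' truncation is intentional (no boundary images are added) and the warning
#' can be silenced with `warn_edges = FALSE`.
#'
#' @param hl a [hills()] list (heights in kT).
#' @param t time at which to evaluate (hills with `time <= t` contribute).
#' @param grid a [ct_grid()].
#' @param thermo a [thermo_params()].
#' @param warn_edges warn about hills within 3 sigma of a grid edge
#'   (default TRUE).
#' @return c(t) in kT.
#' @export
ct_value <- function(hl, t = Inf, grid, thermo, warn_edges = TRUE) {
  hl <- as_hills(hl)
  stopifnot(inherits(grid, "ct_grid"))
  thermo <- as_thermo(thermo)
  keep <- hl$time <= t
  if (any(keep) && warn_edges) {
    near_edge <- hl$center[keep] - 3 * hl$sigma[keep] < grid$s_min |
      hl$center[keep] + 3 * hl$sigma[keep] > grid$s_max
    if (any(near_edge)) {
      warning(sprintf(
        "%d hill center(s) within 3 sigma of a grid edge; quadrature domain may truncate the bias",
        sum(near_edge)
      ))
    }
  }
  V <- bias_value(hl, grid$s, t)
  if (any(!is.finite(V))) stop("non-finite bias on the quadrature grid")
  ct_from_bias(V, grid, thermo)
}

# core quadrature shared by ct_value and ct_series; V in kT on grid nodes
ct_from_bias <- function(V, grid, thermo) {
  g <- thermo$gamma
  logw <- trapezoid_logw(grid)
  bV <- thermo$beta * V
  num <- logsumexp_w(g / (g - 1) * bV, logw)
  den <- logsumexp_w(1 / (g - 1) * bV, logw)
  (num - den) / thermo$beta
}

#' c(t) evaluated on a regular time stride
#'
#' Computes c(t) at `t = 0, stride, 2 stride, ...` up to the last hill
#' time, accumulating the bias on the grid hill by hill so the whole series
#' costs the same as a single terminal evaluation. The incremental result
#' equals independent per-time evaluation to within floating-point
#' summation order (~1e-10 kT).
#'
#' @param hl a [hills()] list.
#' @param stride time stride (> 0).
#' @param grid a [ct_grid()].
#' @param thermo a [thermo_params()].
#' @return an object of class `ct_series`: data.frame with columns `time`
#'   and `ct` (kT). With no hills, a single row `(0, 0)`.
#' @export
ct_series <- function(hl, stride, grid, thermo) {
  hl <- as_hills(hl)
  stopifnot(inherits(grid, "ct_grid"))
  thermo <- as_thermo(thermo)
  if (!is.numeric(stride) || length(stride) != 1L || stride <= 0) {
    stop("`stride` must be a single positive time")
  }
  if (nrow(hl) == 0L) {
    return(structure(data.frame(time = 0, ct = 0),
                     class = c("ct_series", "data.frame")))
  }
  t_last <- hl$time[nrow(hl)]
  times <- stride * (0:floor(t_last / stride))
  V <- numeric(grid$n_points)
  ct <- numeric(length(times))
  k <- 1L
  n_hills <- nrow(hl)
  for (i in seq_along(times)) {
    while (k <= n_hills && hl$time[k] <= times[i]) {
      V <- V + bias_sum_cpp(grid$s, hl$center[k], hl$sigma[k], hl$height[k])
      k <- k + 1L
    }
    ct[i] <- ct_from_bias(V, grid, thermo)
  }
  structure(data.frame(time = times, ct = ct),
            class = c("ct_series", "data.frame"))
}

#' @export
print.ct_series <- function(x, ...) {
  cat(sprintf("ct_series: %d points, t in [%g, %g], terminal c(t) = %.4f kT\n",
              nrow(x), x$time[1L], x$time[nrow(x)], x$ct[nrow(x)]))
  invisible(x)
}
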