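#' Analytic one-dimensional model potentials
#'
#' Defines the landscape on which the toy collective variable (CV) moves:
#' a stand-in for the free-energy surface the ligand-RMSD coordinate sees in
#' a real pose-stability run. Three forms are available:
#'
#' * `"gaussian_well"`: \eqn{U(s) = -D e^{-(s-c)^2 / (2 w^2)}} — an
#'   attractive well of depth `depth` (kT) and width `width`, the bound-pose
#'   analog; deeper wells model more stable poses.
#' * `"double_well"`: two Gaussian wells of the same depth/width at
#'   `centers`.
#' * `"harmonic"`: \eqn{U(s) = \tfrac12 k (s-c)^2} with
#'   `k = wall_stiffness`.
#'
#' Every form additionally carries a half-harmonic upper wall,
#' \eqn{\tfrac12 k_w (s - s_w)^2} for \eqn{s > s_w}, mimicking the RMSD
#' restraint wall that keeps a ligand from drifting away in production runs
#' (disable with `wall_stiffness = 0` for `"gaussian_well"`/`"double_well"`;
#' the harmonic form uses `wall_stiffness` as its spring constant and has no
#' extra wall).
#'
#' @param form one of `"gaussian_well"`, `"double_well"`, `"harmonic"`.
#' @param depth well depth in kT (>= 0); ignored for `"harmonic"`.
#' @param width Gaussian well width in CV units (> 0).
#' @param center well center (or harmonic center), CV units.
#' @param centers for `"double_well"`: the two well centers.
#' @param wall_position onset of the half-harmonic wall (> 0), CV units.
#' @param wall_stiffness wall spring constant in kT per CV^2 (>= 0); for
#'   `"harmonic"` this is the spring constant of the potential itself.
#' @return An object of class `potential_spec`.
#' @examples
#' pot <- potential_spec("gaussian_well", depth = 5, width = 0.5)
#' potential_energy(pot, 0)  # -5 at the well bottom
#' @export
potential_spec <- function(form = c("gaussian_well", "double_well", "harmonic"),
                           depth = 5, width = 0.5, center = 0,
                           centers = c(0, 1),
                           wall_position = 1, wall_stiffness = 100) {
  form <- match.arg(form)
  stopifnot(
    is.numeric(depth), length(depth) == 1L, is.finite(depth), depth >= 0,
    is.numeric(width), length(width) == 1L, is.finite(width), width > 0,
    is.numeric(wall_position), length(wall_position) == 1L, wall_position > 0,
    is.numeric(wall_stiffness), length(wall_stiffness) == 1L,
    is.finite(wall_stiffness), wall_stiffness >= 0
  )
  if (form == "double_well" && length(centers) != 2L) {
    stop("`centers` must give the two well centers for form = \"double_well\"")
  }
  structure(
    list(form = form, depth = depth, width = width, center = center,
         centers = centers, wall_position = wall_position,
         wall_stiffness = wall_stiffness),
    class = "potential_spec"
  )
}

gaussian_well_u <- function(s, depth, width, center) {
  -depth * exp(-(s - center)^2 / (2 * width^2))
}

gaussian_well_f <- function(s, depth, width, center) {
  # F = -dU/ds; dU/ds = depth * (s-c)/w^2 * exp(...)
  -depth * (s - center) / width^2 * exp(-(s - center)^2 / (2 * width^2))
}

#' Potential energy of the model landscape
#'
#' @param spec a [potential_spec()].
#' @param s CV value(s); vectorised.
#' @return energy in kT, same length as `s`.
#' @export
potential_energy <- function(spec, s) {
  stopifnot(inherits(spec, "potential_spec"), is.numeric(s))
  u <- switch(spec$form,
    gaussian_well = gaussian_well_u(s, spec$depth, spec$width, spec$center),
    double_well = gaussian_well_u(s, spec$depth, spec$width, spec$centers[1]) +
      gaussian_well_u(s, spec$depth, spec$width, spec$centers[2]),
    harmonic = 0.5 * spec$wall_stiffness * (s - spec$center)^2
  )
  if (spec$form != "harmonic" && spec$wall_stiffness > 0) {
    over <- pmax(s - spec$wall_position, 0)
    u <- u + 0.5 * spec$wall_stiffness * over^2
  }
  u
}

#' Force of the model landscape
#'
#' Analytic \eqn{-dU/ds}; matches the central finite difference of
#' [potential_energy()] to within 1e-6 relative.
#'
#' @inheritParams potential_energy
#' @return force in kT per CV unit, same length as `s`.
#' @export
potential_force <- function(spec, s) {
  stopifnot(inherits(spec, "potential_spec"), is.numeric(s))
  f <- switch(spec$form,
    gaussian_well = gaussian_well_f(s, spec$depth, spec$width, spec$center),
    double_well = gaussian_well_f(s, spec$depth, spec$width, spec$centers[1]) +
      gaussian_well_f(s, spec$depth, spec$width, spec$centers[2]),
    harmonic = -spec$wall_stiffness * (s - spec$center)
  )
  if (spec$form != "harmonic" && spec$wall_stiffness > 0) {
    over <- pmax(s - spec$wall_position, 0)
    f <- f - spec$wall_stiffness * over
  }
  f
}

#' Dynamics parameters for overdamped Langevin propagation
#'
#' @param dt integration time step (> 0), toy time units.
#' @param friction friction coefficient (> 0), inverse time; the diffusion
#'   constant is `kT / friction`.
#' @param kT thermal energy (> 0); 1 by internal convention.
#' @param n_steps number of steps (>= 1). The default 5e4 keeps a
#'   metadynamics run deliberately short (100 hills at the default pace):
#'   the stability score relies on the run ending while stable poses are
#'   still resisting the bias, not on converged sampling.
#' @param seed integer RNG seed; runs are bit-reproducible given the seed.
#' @return An object of class `dyn_params`.
#' @export
dyn_params <- function(dt = 0.001, friction = 1, kT = 1,
                       n_steps = 50000L, seed = 1L) {
  stopifnot(
    is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0,
    is.numeric(friction), length(friction) == 1L, is.finite(friction), friction > 0,
    is.numeric(kT), length(kT) == 1L, is.finite(kT), kT > 0,
    is.numeric(n_steps), length(n_steps) == 1L, n_steps >= 1,
    is.numeric(seed), length(seed) == 1L, is.finite(seed)
  )
  structure(
    list(dt = dt, friction = friction, kT = kT,
         n_steps = as.integer(n_steps), seed = as.integer(seed)),
    class = "dyn_params"
  )
}

#' One overdamped Euler--Maruyama step
#'
#' \deqn{s' = s + F \, dt/\xi + \sqrt{2 kT \, dt/\xi}\, \eta}
#' with friction \eqn{\xi} and a standard-normal draw \eqn{\eta} supplied by
#' the caller, so the update is deterministic given its inputs.
#'
#' @param s current CV value.
#' @param total_force total force at `s` (potential + bias), kT per CV unit.
#' @param params a [dyn_params()].
#' @param noise standard normal draw.
#' @return the updated CV value.
#' @export
step_langevin <- function(s, total_force, params, noise) {
  stopifnot(inherits(params, "dyn_params"))
  if (!all(is.finite(s)) || !all(is.finite(total_force)) || !all(is.finite(noise))) {
    stop("non-finite state, force or noise in Langevin step")
  }
  s + total_force * params$dt / params$friction +
    sqrt(2 * params$kT * params$dt / params$friction) * noise
}

#' Unbiased Langevin trajectory on a model potential
#'
#' Propagates the CV with [step_langevin()] under [potential_force()] alone
#' (no metadynamics bias), with a reflecting boundary at s = 0 so the
#' coordinate stays on the non-negative side like an RMSD. Used for
#' equilibrium checks; biased runs go through [run_wtmetad()].
#'
#' @param spec a [potential_spec()].
#' @param params a [dyn_params()].
#' @param s0 initial CV value (default: the well center, floored at 0).
#' @param reflect reflect at s = 0 (default TRUE, the RMSD-like convention).
#' @return A `trajectory`: data.frame with columns `time` and `cv`
#'   (`n_steps + 1` rows, including the initial state at time 0).
#' @export
run_langevin <- function(spec, params, s0 = NULL, reflect = TRUE) {
  stopifnot(inherits(spec, "potential_spec"), inherits(params, "dyn_params"))
  if (is.null(s0)) s0 <- max(spec$center, 0)
  n <- params$n_steps
  set.seed(params$seed)
  noise <- rnorm(n)
  amp <- sqrt(2 * params$kT * params$dt / params$friction)
  cv <- numeric(n + 1L)
  cv[1L] <- s0
  s <- s0
  dtf <- params$dt / params$friction
  for (i in seq_len(n)) {
    s <- s + potential_force(spec, s) * dtf + amp * noise[i]
    if (reflect && s < 0) s <- -s
    cv[i + 1L] <- s
  }
  structure(
    data.frame(time = params$dt * (0:n), cv = cv),
    class = c("trajectory", "data.frame")
  )
}

#' Root mean squared displacement between two coordinate sets
#'
#' \eqn{\sqrt{\frac{1}{n}\sum_i \|x_i - x_i^{ref}\|^2}} over atoms, with no
#' rotational or translational superposition: this is the plain displacement
#' RMSD used as the biased CV in pose-stability metadynamics, where the
#' receptor frame already defines the reference orientation.
#'
#' @param frame numeric matrix, one row per atom (any fixed number of
#'   Cartesian columns), or a numeric vector for 1D coordinates.
#' @param reference same shape as `frame`.
#' @return non-negative scalar; 0 iff the coordinate sets are identical.
#' @examples
#' rmsd(matrix(c(3, 4, 0), 1), matrix(0, 1, 3))  # 5
#' @export
rmsd <- function(frame, reference) {
  frame <- as.matrix(frame)
  reference <- as.matrix(reference)
  if (!all(dim(frame) == dim(reference))) {
    stop(sprintf(
      "coordinate sets differ in shape: %s vs %s atoms x dims",
      paste(dim(frame), collapse = "x"), paste(dim(reference), collapse = "x")
    ))
  }
  if (nrow(frame) < 1L) stop("need at least one atom")
  sqrt(mean(rowSums((frame - reference)^2)))
}

#' Write / read a trajectory as COLVAR-style two-column text
#'
#' Plain delimited text with a `#! FIELDS time cv` header line, the dialect
#' PLUMED uses for COLVAR files.
#'
#' @param traj a trajectory data.frame with columns `time` and `cv`.
#' @param path file path.
#' @return `write_colvar` returns `path` invisibly; `read_colvar` returns a
#'   `trajectory` data.frame.
#' @export
write_colvar <- function(traj, path) {
  stopifnot(is.data.frame(traj), all(c("time", "cv") %in% names(traj)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv", con)
  writeLines(sprintf("%.15g %.15g", traj$time, traj$cv), con)
  invisible(path)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^#!\\s*FIELDS\\s+time\\s+cv\\s*$", lines[1L])) {
    stop("not a COLVAR file: expected a '#! FIELDS time cv' header")
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    return(structure(data.frame(time = numeric(), cv = numeric()),
                     class = c("trajectory", "data.frame")))
  }
  vals <- strsplit(trimws(body), "\\s+")
  mat <- vapply(vals, function(v) as.numeric(v[1:2]), numeric(2))
  structure(data.frame(time = mat[1, ], cv = mat[2, ]),
            class = c("trajectory", "data.frame"))
}
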