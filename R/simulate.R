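#' Metadynamics deposition parameters
#'
#' Hill height is given in kJ/mol (the PLUMED convention) and converted to
#' internal kT at the simulation temperature when a run starts.
#'
#' @param w0_kj initial hill height in kJ/mol (default 1.2, a conventional
#'   production choice; about 0.48 kT at 300 K).
#' @param sigma hill width in CV units (default 0.02).
#' @param pace deposit a hill every `pace` dynamics steps (default 500).
#' @return an object of class `metad_params`.
#' @export
metad_params <- function(w0_kj = 1.2, sigma = 0.02, pace = 500L) {
  stopifnot(
    is.numeric(w0_kj), length(w0_kj) == 1L, is.finite(w0_kj), w0_kj >= 0,
    is.numeric(sigma), length(sigma) == 1L, is.finite(sigma), sigma > 0,
    is.numeric(pace), length(pace) == 1L, pace >= 1
  )
  structure(list(w0_kj = w0_kj, sigma = sigma, pace = as.integer(pace)),
            class = "metad_params")
}

#' Run a well-tempered metadynamics trajectory on a model potential
#'
#' Overdamped Langevin dynamics under the model potential plus the
#' accumulated Gaussian bias, with well-tempered hill deposition every
#' `metad$pace` steps at the current CV value. The coordinate reflects at
#' s = 0 (the CV is RMSD-like and non-negative); hills are deposited as
#' plain Gaussians with no boundary images. The inner loop runs in compiled
#' code and is bit-reproducible given `params$seed`.
#'
#' @param spec a [potential_spec()].
#' @param params a [dyn_params()] (its `seed` drives the run).
#' @param metad a [metad_params()].
#' @param thermo a [thermo_params()] (bias factor and file-unit
#'   temperature).
#' @param s0 initial CV value; defaults to the well center floored at 0.
#' @return a [hills()] object with one row per deposited hill (heights in
#'   kT), with the final CV value in attribute `s_final`.
#' @examples
#' th <- thermo_params(300, 10)
#' hl <- run_wtmetad(potential_spec("gaussian_well", depth = 4, width = 0.1),
#'                   dyn_params(n_steps = 20000, seed = 7),
#'                   metad_params(), th)
#' nrow(hl)  # 40 hills at pace 500
#' @export
run_wtmetad <- function(spec, params, metad = metad_params(),
                        thermo = thermo_params(), s0 = NULL) {
  stopifnot(inherits(spec, "potential_spec"), inherits(params, "dyn_params"),
            inherits(metad, "metad_params"))
  thermo <- as_thermo(thermo)
  if (is.null(s0)) s0 <- max(spec$center, 0)
  form_code <- match(spec$form, c("gaussian_well", "double_well", "harmonic")) - 1L
  grid_max <- spec$wall_position + 12 * metad$sigma
  grid_n <- max(500L, as.integer(ceiling(grid_max / (metad$sigma / 5))))
  w0_kt <- metad$w0_kj / thermo$kT_kj
  res <- run_wtmetad_cpp(
    form_code, spec$depth, spec$width,
    if (spec$form == "double_well") spec$centers[1] else spec$center,
    if (spec$form == "double_well") spec$centers[2] else 0,
    spec$wall_position, spec$wall_stiffness,
    params$dt, params$friction, params$kT,
    params$n_steps, params$seed,
    metad$pace, w0_kt, metad$sigma, thermo$gamma,
    0, grid_max, grid_n, s0
  )
  hl <- hills(time = res$time, center = res$center,
              sigma = metad$sigma, height = res$height)
  attr(hl, "s_final") <- res$s_final
  hl
}
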