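#' Thermodynamic parameters for well-tempered metadynamics
#'
#' Bundles the simulation temperature and the well-tempered bias factor
#' \eqn{\gamma}. All energies inside the package are expressed in units of
#' kT at this temperature, so the inverse temperature is \eqn{\beta = 1} in
#' internal units; the kelvin temperature is only used to convert energies
#' to and from kJ/mol at file boundaries (the PLUMED HILLS convention).
#'
#' @param temperature temperature in kelvin (> 0). Default 300.
#' @param gamma well-tempered bias factor \eqn{\gamma > 1}; the limit
#'   \eqn{\gamma \to \infty} recovers non-tempered metadynamics. Default 10.
#' @return An object of class `thermo_params`: a list with fields
#'   `temperature`, `gamma`, `beta` (always 1; energies are in kT) and
#'   `kT_kj` (kT in kJ/mol at `temperature`).
#' @examples
#' th <- thermo_params(300, 10)
#' th$kT_kj  # ~2.494 kJ/mol
#' @export
thermo_params <- function(temperature = 300, gamma = 10) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 1) {
    stop("`gamma` must be a single value > 1 (well-tempered bias factor)")
  }
  structure(
    list(
      temperature = temperature,
      gamma = gamma,
      beta = 1,
      kT_kj = kT_kj_per_mol(temperature)
    ),
    class = "thermo_params"
  )
}

#' kT in kJ/mol at a given temperature
#'
#' Uses the molar gas constant R = 0.00831446261815324 kJ/(mol K),
#' so kT at 300 K is 2.494 kJ/mol.
#'
#' @param temperature kelvin
#' @return kT in kJ/mol
#' @export
kT_kj_per_mol <- function(temperature) {
  0.00831446261815324 * temperature
}

#' Convert energies between kJ/mol and kT
#'
#' @param x energy value(s)
#' @param temperature kelvin
#' @return converted energy value(s)
#' @rdname energy_units
#' @export
kj_to_kt <- function(x, temperature = 300) x / kT_kj_per_mol(temperature)

#' @rdname energy_units
#' @export
kt_to_kj <- function(x, temperature = 300) x * kT_kj_per_mol(temperature)

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "thermo_params: T = %g K (kT = %.4f kJ/mol), gamma = %g, energies in kT\n",
    x$temperature, x$kT_kj, x$gamma
  ))
  invisible(x)
}

as_thermo <- function(x) {
  if (!inherits(x, "thermo_params")) stop("expected a `thermo_params` object")
  x
}
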