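#' Specify an oscillating electric field
#'
#' The applied field is \eqn{E(t) = A u \cos(2\pi\nu t + \phi)} with amplitude
#' \code{A} in V/nm, unit polarization vector \code{u}, frequency \eqn{\nu} in
#' THz and phase \eqn{\phi} in rad. The angular frequency \eqn{\omega =
#' 2\pi\nu} is always derived, never stored. With time in ps, THz is the
#' natural unit (1 THz = 1/ps).
#'
#' @param amplitude field amplitude A, V/nm; >= 0.
#' @param frequency frequency nu, THz; >= 0.
#' @param direction polarization u, length-3 unit vector (default z).
#' @param phase phase phi, rad (default 0).
#' @return An object of class \code{field_spec}.
#' @examples
#' f <- field_spec(amplitude = 0.5, frequency = 34.5)
#' field_at(f, t = 0)  # (0, 0, 0.5) V/nm
#' @export
field_spec <- function(amplitude, frequency, direction = c(0, 0, 1),
                       phase = 0) {
  if (amplitude < 0) stop("amplitude must be >= 0 (V/nm)")
  if (frequency < 0) stop("frequency must be >= 0 (THz)")
  direction <- as.numeric(direction)
  if (length(direction) != 3L) stop("direction must be a length-3 vector")
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) {
    if (nrm == 0) stop("direction must be a unit vector")
    direction <- direction / nrm
  }
  structure(list(amplitude = amplitude, frequency = frequency,
                 direction = direction, phase = phase),
            class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> A = %g V/nm, nu = %g THz, u = (%g, %g, %g), phi = %g rad\n",
              x$amplitude, x$frequency, x$direction[1], x$direction[2],
              x$direction[3], x$phase))
  invisible(x)
}

#' Field vector at time t
#'
#' @param field a \code{field_spec}.
#' @param t time, ps.
#' @return Length-3 field vector, V/nm.
#' @export
field_at <- function(field, t) {
  field$amplitude * cos(2 * pi * field$frequency * t + field$phase) *
    field$direction
}

#' Per-atom force exerted by the field
#'
#' \eqn{F_i(t) = q_i A \cos(2\pi\nu t + \phi) u}, converted from e·V/nm to
#' kJ/mol/nm. Neutral atoms feel nothing.
#'
#' @param system a \code{particle_system} with charges assigned.
#' @param field a \code{field_spec}.
#' @param t time, ps.
#' @return n x 3 matrix of forces, kJ/mol/nm.
#' @export
field_force <- function(system, field, t) {
  E <- field_at(field, t)                      # V/nm
  outer(system$charges * md_constants$eV_to_kJmol, E)
}
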