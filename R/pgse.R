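## Canonical units throughout the package: time ms, length um, diffusivity
## um^2/ms, b-value ms/um^2, gradient mT/m.

#' Gyromagnetic ratio of the proton
#'
#' In package units: rad ms^-1 um^-1 per (mT/m), i.e. 2.6752e8 rad s^-1 T^-1
#' expressed in ms / um / mT/m.
#'
#' @export
GYROMAGNETIC_RATIO <- 2.6752e-4

#' b-value of a pulsed gradient spin echo (PGSE) encoding
#'
#' Computes b = gamma^2 G^2 delta^2 (Delta - delta/3) for rectangular
#' diffusion-encoding gradient pulses of amplitude \code{G} (mT/m), duration
#' \code{delta} (ms) and separation \code{Delta} (ms).
#'
#' @param G gradient amplitude, mT/m (vectorised)
#' @param delta gradient pulse duration, ms
#' @param Delta gradient pulse separation, ms; must exceed \code{delta}
#' @return b-value in ms/um^2
#' @seealso [gradientFromB()] for the algebraic inversion
#' @examples
#' bFromPGSE(660, 9.6, 12)   # ~25.3 ms/um^2
#' @export
bFromPGSE <- function(G, delta, Delta) {
  if (any(G < 0)) stop("gradient amplitude G must be non-negative")
  .checkPulseTimes(delta, Delta)
  (GYROMAGNETIC_RATIO * G * delta)^2 * (Delta - delta / 3)
}

#' Gradient amplitude that yields a given PGSE b-value
#'
#' @param b b-value, ms/um^2
#' @param delta gradient pulse duration, ms
#' @param Delta gradient pulse separation, ms
#' @return gradient amplitude in mT/m
#' @export
gradientFromB <- function(b, delta, Delta) {
  if (any(b < 0)) stop("b must be non-negative")
  .checkPulseTimes(delta, Delta)
  sqrt(b / (delta^2 * (Delta - delta / 3))) / GYROMAGNETIC_RATIO
}

.checkPulseTimes <- function(delta, Delta) {
  ok <- is.na(delta) | is.na(Delta) | (delta > 0 & delta < Delta)
  if (!all(ok))
    stop("pulse timing requires 0 < delta < Delta")
  invisible(TRUE)
}
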