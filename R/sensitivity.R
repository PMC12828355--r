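## ---------------------------------------------------------------------------
## Axon-diameter sensitivity range
## ---------------------------------------------------------------------------

#' Sensitivity-analysis configuration
#'
#' Settings for the axon-diameter sensitivity criterion: the cylinder signal
#' is considered measurable when it can be statistically distinguished both
#' from the zero-diameter (stick) signal and from the noise floor.
#'
#' @slot d0 intrinsic diffusivity of the cylinder interior, um^2/ms
#' @slot dpara parallel diffusivity used for the stick reference (defaults
#'   to d0)
#' @slot snrB0 SNR of a single b = 0 measurement
#' @slot ndirs number of directions averaged per shell
#' @slot alpha one-sided significance level
#' @slot zalpha optional explicit z-threshold overriding qnorm(1 - alpha)
#' @slot gridLo,gridHi,gridStep diameter search grid, um
#' @slot highB b-value threshold (ms/um^2) above which shells enter the
#'   upper-bound search
#' @export
setClass("SensitivityConfig",
  representation(d0 = "numeric", dpara = "numeric", snrB0 = "numeric",
                 ndirs = "numeric", alpha = "numeric", zalpha = "numeric",
                 gridLo = "numeric", gridHi = "numeric",
                 gridStep = "numeric", highB = "numeric"),
  prototype(d0 = 0.6, dpara = NA_real_, snrB0 = 100, ndirs = 32,
            alpha = 0.05, zalpha = NA_real_, gridLo = 0.1, gridHi = 20,
            gridStep = 0.01, highB = 15))

setValidity("SensitivityConfig", function(object) {
  msg <- character(0)
  if (object@snrB0 <= 0) msg <- c(msg, "snrB0 must be > 0")
  if (object@ndirs < 1) msg <- c(msg, "ndirs must be >= 1")
  if (object@gridLo >= object@gridHi || object@gridStep <= 0)
    msg <- c(msg, "diameter grid must have lo < hi and step > 0")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname SensitivityConfig-class
#' @param d0,dpara,snrB0,ndirs,alpha,zalpha,gridLo,gridHi,gridStep,highB
#'   see slots
#' @export
sensitivityConfig <- function(d0 = 0.6, dpara = NA, snrB0 = 100, ndirs = 32,
                              alpha = 0.05, zalpha = NA, gridLo = 0.1,
                              gridHi = 20, gridStep = 0.01, highB = 15) {
  new("SensitivityConfig", d0 = d0, dpara = as.numeric(dpara),
      snrB0 = snrB0, ndirs = ndirs, alpha = alpha,
      zalpha = as.numeric(zalpha), gridLo = gridLo, gridHi = gridHi,
      gridStep = gridStep, highB = highB)
}

#' Minimal robustly detectable signal attenuation
#'
#' sigma_bar = z_alpha / (SNR sqrt(n)): the smallest attenuation of the
#' direction-averaged signal that can be distinguished from noise at
#' one-sided level alpha, given the b = 0 SNR of a single measurement and
#' n averaged directions.
#'
#' @param snrB0 b = 0 SNR of one measurement
#' @param ndirs number of directions averaged
#' @param alpha one-sided significance level (default 0.05, z = 1.64)
#' @param zalpha explicit z-threshold (overrides alpha)
#' @return sigma_bar, on the normalised signal scale
#' @export
minDetectableAttenuation <- function(snrB0, ndirs, alpha = 0.05,
                                     zalpha = NULL) {
  if (snrB0 <= 0 || ndirs < 1) stop("snrB0 and ndirs must be positive")
  if (is.null(zalpha) || is.na(zalpha)) {
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    zalpha <- stats::qnorm(1 - alpha)
  }
  zalpha / (snrB0 * sqrt(ndirs))
}

.sensitivityGrid <- function(cfg) {
  seq(cfg@gridLo, cfg@gridHi, by = cfg@gridStep)
}

## Cylinder spherical-mean signal over a diameter grid for a set of shells.
## Returns a length(grid) x nshells matrix.
.cylGridSignals <- function(grid, shells, cfg) {
  dpar <- if (is.na(cfg@dpara)) cfg@d0 else cfg@dpara
  out <- matrix(NA_real_, length(grid), nrow(shells))
  for (i in seq_len(nrow(shells))) {
    la <- gpdLogAttenuation("cylinder", grid / 2, cfg@d0, shells$G[i],
                            shells$delta[i], shells$Delta[i])
    dperp <- -la / shells$b[i]
    out[, i] <- exp(la) * .smFactor(shells$b[i] * (dpar - dperp))
  }
  out
}

.completeShells <- function(shells) {
  shells <- as.data.frame(shells)
  if (is.null(shells$G))
    shells$G <- gradientFromB(shells$b, shells$delta, shells$Delta)
  if (is.null(shells$b))
    shells$b <- bFromPGSE(shells$G, shells$delta, shells$Delta)
  chk <- bFromPGSE(shells$G, shells$delta, shells$Delta)
  if (any(abs(chk - shells$b) > 1e-6 * pmax(shells$b, 1)))
    stop("shell b, G, delta, Delta are mutually inconsistent")
  shells
}

#' Axon-diameter sensitivity bounds for a single b-value
#'
#' The lower bound is the smallest grid diameter whose cylinder signal
#' drops below S_stick - sigma_bar (distinguishable from a zero-diameter
#' axon); the upper bound is the largest diameter whose signal still
#' exceeds sigma_bar (distinguishable from the noise floor). Bounds that
#' hit the grid edge are flagged unbounded.
#'
#' @param shell list/data.frame with b (ms/um^2), delta, Delta (ms), and
#'   optionally G (mT/m, derived from b otherwise)
#' @param cfg a [SensitivityConfig-class]
#' @return list(dmin, dmax, sigmaBar, unbounded = logical(2), empty): NA
#'   bounds with \code{empty = TRUE} when the shell cannot separate the
#'   stick signal from the noise floor (S_stick < 2 sigma_bar)
#' @export
diameterBoundsSingleB <- function(shell, cfg = sensitivityConfig()) {
  sh <- .completeShells(as.data.frame(shell))
  stopifnot(nrow(sh) == 1)
  sb <- minDetectableAttenuation(cfg@snrB0, cfg@ndirs, cfg@alpha, cfg@zalpha)
  dpar <- if (is.na(cfg@dpara)) cfg@d0 else cfg@dpara
  sstick <- .smStick(sh$b, dpar)
  if (sstick < 2 * sb)
    return(list(dmin = NA_real_, dmax = NA_real_, sigmaBar = sb,
                unbounded = c(FALSE, FALSE), empty = TRUE))
  grid <- .sensitivityGrid(cfg)
  scyl <- .cylGridSignals(grid, sh, cfg)[, 1]
  below <- which(scyl <= sstick - sb)
  above <- which(scyl >= sb)
  dmin <- if (length(below)) grid[below[1]] else NA_real_
  dmax <- if (length(above)) grid[above[length(above)]] else NA_real_
  unb <- c(length(below) > 0 && below[1] == 1,
           length(above) > 0 && above[length(above)] == length(grid))
  list(dmin = dmin, dmax = dmax, sigmaBar = sb, unbounded = unb,
       empty = FALSE)
}

#' Axon-diameter sensitivity bounds for multiple b-shells
#'
#' With several shells, the signal bounds become vectors and the sensitivity
#' range is approximated by the diameters whose cylinder signals have
#' minimal summed squared error against the bounds: the lower bound
#' minimises the error to S_stick - sigma_bar across all shells; the upper
#' bound minimises the error to sigma_bar across the high-b shells only
#' (low-b shells remain sensitive to arbitrarily large axons and would
#' dominate the MSE). Ties break toward the smaller diameter.
#'
#' @param shells data.frame with columns b, delta, Delta (and optionally G)
#' @param cfg a [SensitivityConfig-class]; \code{cfg@highB} selects the
#'   upper-bound shell subset
#' @return list(dmin, dmax, sigmaBar, nHighB)
#' @export
diameterBoundsMultiB <- function(shells, cfg = sensitivityConfig()) {
  sh <- .completeShells(shells)
  sb <- minDetectableAttenuation(cfg@snrB0, cfg@ndirs, cfg@alpha, cfg@zalpha)
  dpar <- if (is.na(cfg@dpara)) cfg@d0 else cfg@dpara
  sstick <- .smStick(sh$b, dpar)
  grid <- .sensitivityGrid(cfg)
  scyl <- .cylGridSignals(grid, sh, cfg)     # length(grid) x nshells
  lowerMSE <- colSums((t(scyl) - (sstick - sb))^2)
  hb <- which(sh$b >= cfg@highB)
  if (!length(hb)) stop("no shells at or above the high-b threshold (",
                        cfg@highB, " ms/um^2)")
  upperMSE <- colSums((t(scyl[, hb, drop = FALSE]) - sb)^2)
  list(dmin = grid[which.min(lowerMSE)], dmax = grid[which.min(upperMSE)],
       sigmaBar = sb, nHighB = length(hb))
}
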