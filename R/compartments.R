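## ---------------------------------------------------------------------------
## Tissue compartments: spherical-mean forward models and Legendre kernels
## ---------------------------------------------------------------------------

#' @name Compartment-classes
#' @title Tissue compartment classes
#'
#' @description
#' Each compartment stores its microstructural parameters and predicts a
#' normalised signal per protocol shell via [compartmentSignals()].
#' Diffusivities are in um^2/ms, lengths in um, times in ms. A \code{t2} of 0
#' is the sentinel for "no relaxation term": the e^(-TE/T2) factor is applied
#' only when \code{t2 > 0} and the protocol carries echo times.
#'
#' \itemize{
#' \item \code{Stick}: zero perpendicular diffusivity (axons at moderate b).
#' \item \code{Zeppelin}: axially symmetric tensor; the perpendicular
#'   diffusivity is \code{dperpFrac * dpara} with \code{dperpFrac} in [0, 1].
#' \item \code{Cylinder}: perpendicular attenuation from the Gaussian phase
#'   distribution (GPD) approximation for restriction in a cylinder of
#'   diameter \code{da} with intrinsic diffusivity \code{d0}.
#' \item \code{Sphere}: GPD-restricted diffusion in a sphere of radius
#'   \code{rs} with diffusivity \code{dis} (cell soma).
#' \item \code{Iso}: isotropic Gaussian diffusion; \code{d = 0} is the
#'   immobile-water "dot" compartment.
#' }
#'
#' The kernel variants (\code{StickKernel}, \code{ZeppelinKernel},
#' \code{IsoKernel}) carry the same parameters but represent the projection
#' of the single-fibre response onto Legendre polynomials, for
#' rotational-invariant modelling; \code{FODF} holds the fibre orientation
#' distribution invariants (p_0 = 1, p_2 in [0, 1]).
NULL

setClass("Compartment", representation("VIRTUAL"))

#' @rdname Compartment-classes
#' @export
setClass("Stick", contains = "Compartment",
         representation(dpara = "numeric", t2 = "numeric"),
         prototype(dpara = 0.6, t2 = 0))

#' @rdname Compartment-classes
#' @export
setClass("Zeppelin", contains = "Compartment",
         representation(dpara = "numeric", dperpFrac = "numeric",
                        t2 = "numeric"),
         prototype(dpara = 0.6, dperpFrac = 0.3, t2 = 0))

#' @rdname Compartment-classes
#' @export
setClass("Cylinder", contains = "Compartment",
         representation(da = "numeric", d0 = "numeric", dpara = "numeric",
                        t2 = "numeric"),
         prototype(da = 2, d0 = 0.6, dpara = 0.6, t2 = 0))

#' @rdname Compartment-classes
#' @export
setClass("Sphere", contains = "Compartment",
         representation(dis = "numeric", rs = "numeric", t2 = "numeric"),
         prototype(dis = 3, rs = 5, t2 = 0))

#' @rdname Compartment-classes
#' @export
setClass("Iso", contains = "Compartment",
         representation(d = "numeric", t2 = "numeric"),
         prototype(d = 2, t2 = 0))

setClass("KernelCompartment", representation("VIRTUAL"))

#' @rdname Compartment-classes
#' @export
setClass("StickKernel", contains = c("Stick", "KernelCompartment"))

#' @rdname Compartment-classes
#' @export
setClass("ZeppelinKernel", contains = c("Zeppelin", "KernelCompartment"))

#' @rdname Compartment-classes
#' @export
setClass("IsoKernel", contains = c("Iso", "KernelCompartment"))

#' @rdname Compartment-classes
#' @export
setClass("FODF", representation(p2 = "numeric"), prototype(p2 = 0.5))

setValidity("Stick", function(object) {
  if (object@dpara < 0 || object@dpara > 4)
    return("dpara must lie in [0, 4] um^2/ms")
  if (object@t2 < 0) return("t2 must be >= 0")
  TRUE
})
setValidity("Zeppelin", function(object) {
  if (object@dperpFrac < 0 || object@dperpFrac > 1)
    return("dperpFrac must lie in [0, 1]")
  TRUE
})
setValidity("Cylinder", function(object) {
  if (object@da <= 0) return("da must be > 0")
  if (object@d0 <= 0) return("d0 must be > 0")
  TRUE
})
setValidity("Sphere", function(object) {
  if (object@rs <= 0) return("rs must be > 0")
  if (object@dis <= 0) return("dis must be > 0")
  TRUE
})
setValidity("Iso", function(object) {
  if (object@d < 0) return("d must be >= 0")
  TRUE
})
setValidity("FODF", function(object) {
  if (object@p2 < 0 || object@p2 > 1) return("p2 must lie in [0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## Bessel roots for the GPD series
## ---------------------------------------------------------------------------

.rootCache <- new.env(parent = emptyenv())

#' Bessel-root conditions of the GPD approximation
#'
#' Dimensionless roots beta_m used by the restricted-diffusion series:
#' for cylinders, the m-th positive root of J1'(beta) = 0; for spheres, the
#' m-th positive root of (1/beta) J_{3/2}(beta) = J_{5/2}(beta). Roots are
#' cached and strictly increasing.
#'
#' @param kind "cylinder" or "sphere"
#' @param m root index (vectorised, m >= 1)
#' @return the root(s) beta_m
#' @examples
#' besselRoot("cylinder", 1)  # 1.8412
#' besselRoot("sphere", 1)    # 2.0816
#' @export
besselRoot <- function(kind = c("cylinder", "sphere"), m) {
  kind <- match.arg(kind)
  if (any(m < 1)) stop("root index m must be >= 1")
  mmax <- max(m)
  roots <- .rootCache[[kind]]
  if (is.null(roots) || length(roots) < mmax) {
    roots <- .computeBesselRoots(kind, max(mmax, 24L))
    .rootCache[[kind]] <- roots
  }
  roots[m]
}

.computeBesselRoots <- function(kind, n) {
  f <- if (kind == "cylinder") {
    function(x) 0.5 * (besselJ(x, 0) - besselJ(x, 2))     # J1'(x)
  } else {
    function(x) besselJ(x, 1.5) / x - besselJ(x, 2.5)
  }
  ## Roots are interlaced roughly every pi; scan on a fine grid for sign
  ## changes, then polish with uniroot.
  hi <- (n + 3) * pi
  xs <- seq(0.2, hi, by = 0.02)
  fx <- f(xs)
  sgn <- which(fx[-1] * fx[-length(fx)] < 0)
  roots <- vapply(sgn[seq_len(n)], function(i)
    stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-13)$root, numeric(1))
  sort(roots)
}

## ---------------------------------------------------------------------------
## GPD restricted-diffusion log attenuation
## ---------------------------------------------------------------------------

#' Gaussian-phase-distribution log attenuation
#'
#' Log signal attenuation of water restricted in a cylinder (perpendicular
#' direction) or sphere under PGSE encoding, via the GPD series
#' \deqn{-2 \gamma^2 G^2 \sum_m \frac{\psi(D_0 \alpha_m^2; \delta, \Delta)}
#'   {D_0^2 \alpha_m^6 (r^2\alpha_m^2 - c)}}
#' with \eqn{\alpha_m = \beta_m / r}, c = 1 for cylinders and c = 2 for
#' spheres, and time factor
#' \eqn{\psi = 2 D \alpha^2 \delta - 2 + 2 e^{-D\alpha^2\delta}
#'   + 2 e^{-D\alpha^2\Delta} - e^{-D\alpha^2(\Delta-\delta)}
#'   - e^{-D\alpha^2(\Delta+\delta)}}.
#'
#' @param kind "cylinder" or "sphere"
#' @param radius restriction radius, um
#' @param d0 intrinsic diffusivity, um^2/ms
#' @param G gradient amplitude, mT/m (vectorised over shells)
#' @param delta,Delta pulse duration/separation, ms (recycled over shells)
#' @param nterms number of series terms (cached Bessel roots)
#' @return log attenuation (<= 0), one value per shell
#' @export
gpdLogAttenuation <- function(kind = c("cylinder", "sphere"), radius, d0,
                              G, delta, Delta, nterms = 20L) {
  kind <- match.arg(kind)
  if (any(radius <= 0)) stop("radius must be > 0")
  if (d0 <= 0) stop("d0 must be > 0")
  if (nterms < 1) stop("nterms must be >= 1")
  n <- max(length(G), length(radius))
  G <- rep_len(G, n); radius <- rep_len(radius, n)
  delta <- rep_len(delta, n); Delta <- rep_len(Delta, n)
  beta <- besselRoot(kind, seq_len(nterms))
  am2 <- outer(beta^2, 1 / radius^2)                # alpha_m^2, nterms x n
  cc <- if (kind == "cylinder") 1 else 2
  r2 <- matrix(radius^2, nterms, n, byrow = TRUE)
  denom <- d0^2 * am2^3 * (r2 * am2 - cc)           # D0^2 a^6 (r^2 a^2 - c)
  da2 <- d0 * am2
  dl <- matrix(delta, nterms, n, byrow = TRUE)
  DL <- matrix(Delta, nterms, n, byrow = TRUE)
  psi <- 2 * da2 * dl - 2 + 2 * exp(-da2 * dl) + 2 * exp(-da2 * DL) -
         exp(-da2 * (DL - dl)) - exp(-da2 * (DL + dl))
  terms <- psi / denom
  s <- colSums(terms)
  conv <- abs(terms[nterms, ]) <= 1e-8 * pmax(abs(s), .Machine$double.eps)
  if (any(!conv))
    warning(sprintf("GPD series not converged for %d shell(s); last-term residual up to %.2e",
                    sum(!conv), max(abs(terms[nterms, !conv] / s[!conv]))))
  -2 * GYROMAGNETIC_RATIO^2 * G^2 * s
}

## ---------------------------------------------------------------------------
## Spherical-mean forward models (plain numeric kernels)
## ---------------------------------------------------------------------------

## sqrt(pi/(4x)) * erf(sqrt(x)) with the x -> 0 limit of 1; the spherical
## mean of exp(-x xi^2) over xi in [0, 1].
.smFactor <- function(x) {
  out <- rep(1, length(x))
  pos <- x > 1e-12
  if (any(pos)) {
    sx <- sqrt(x[pos])
    out[pos] <- sqrt(pi) / (2 * sx) * .erf(sx)
  }
  out
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

## Relaxation weighting: applied only when t2 > 0 and TEs are present.
.relaxWeight <- function(t2, techo) {
  if (t2 > 0 && any(!is.na(techo))) {
    w <- rep(1, length(techo))
    ok <- !is.na(techo)
    w[ok] <- exp(-techo[ok] / t2)
    w
  } else rep(1, length(techo))
}

.smStick <- function(b, dpara) .smFactor(b * dpara)

.smZeppelin <- function(b, dpara, dperp) {
  if (any(dperp > dpara + 1e-12)) stop("zeppelin requires dperp <= dpara")
  exp(-b * dperp) * .smFactor(b * (dpara - dperp))
}

.smCylinder <- function(b, dpara, d0, da, G, delta, Delta, nterms = 20L) {
  out <- rep(1, length(b))
  pos <- b > 0
  if (!any(pos)) return(out)
  if (any(is.na(G[pos]) | is.na(delta[pos]) | is.na(Delta[pos])))
    stop("cylinder signals require G, delta, Delta on every b > 0 shell")
  la <- gpdLogAttenuation("cylinder", da / 2, d0, G[pos], delta[pos],
                          Delta[pos], nterms)
  dperp <- -la / b[pos]
  out[pos] <- .smZeppelin(b[pos], dpara, pmin(dperp, dpara))
  out
}

.smSphere <- function(b, dis, rs, G, delta, Delta, nterms = 20L) {
  out <- rep(1, length(b))
  pos <- b > 0
  if (!any(pos)) return(out)
  if (any(is.na(G[pos]) | is.na(delta[pos]) | is.na(Delta[pos])))
    stop("sphere signals require G, delta, Delta on every b > 0 shell")
  out[pos] <- exp(gpdLogAttenuation("sphere", rs, dis, G[pos], delta[pos],
                                    Delta[pos], nterms))
  out
}

.smIso <- function(b, d) exp(-b * d)

## ---------------------------------------------------------------------------
## compartmentSignals generic
## ---------------------------------------------------------------------------

#' Normalised spherical-mean signal of a compartment
#'
#' Evaluates the compartment's forward model on every shell of a protocol.
#' Signals are normalised (1 at b = 0 for single-TE protocols); when the
#' protocol is multi-TE and the compartment's \code{t2 > 0}, the e^(-TE/T2)
#' relaxation factor is included.
#'
#' @param compartment a compartment object
#' @param protocol an [AcquisitionProtocol-class]
#' @param ... further arguments (e.g. \code{nterms} for GPD compartments)
#' @return numeric vector, one signal per protocol record
#' @export
setGeneric("compartmentSignals",
           function(compartment, protocol, ...)
             standardGeneric("compartmentSignals"))

#' @rdname compartmentSignals
#' @export
setMethod("compartmentSignals", "Stick", function(compartment, protocol, ...) {
  .relaxWeight(compartment@t2, protocol@techo) *
    .smStick(protocol@bval, compartment@dpara)
})

#' @rdname compartmentSignals
#' @export
setMethod("compartmentSignals", "Zeppelin", function(compartment, protocol, ...) {
  .relaxWeight(compartment@t2, protocol@techo) *
    .smZeppelin(protocol@bval, compartment@dpara,
                compartment@dperpFrac * compartment@dpara)
})

#' @rdname compartmentSignals
#' @export
setMethod("compartmentSignals", "Cylinder",
          function(compartment, protocol, nterms = 20L, ...) {
  .relaxWeight(compartment@t2, protocol@techo) *
    .smCylinder(protocol@bval, compartment@dpara, compartment@d0,
                compartment@da, protocol@gradient, protocol@tsmalldel,
                protocol@tdelta, nterms)
})

#' @rdname compartmentSignals
#' @export
setMethod("compartmentSignals", "Sphere",
          function(compartment, protocol, nterms = 20L, ...) {
  .relaxWeight(compartment@t2, protocol@techo) *
    .smSphere(protocol@bval, compartment@dis, compartment@rs,
              protocol@gradient, protocol@tsmalldel, protocol@tdelta, nterms)
})

#' @rdname compartmentSignals
#' @export
setMethod("compartmentSignals", "Iso", function(compartment, protocol, ...) {
  .relaxWeight(compartment@t2, protocol@techo) *
    .smIso(protocol@bval, compartment@d)
})

## ---------------------------------------------------------------------------
## Legendre-projected kernels and rotational-invariant signals
## ---------------------------------------------------------------------------

## K_l = int_0^1 exp(-b Dpar xi^2 - b Dperp (1 - xi^2)) P_l(xi) dxi,
## relaxation-weighted. Adaptive quadrature to abs tol 1e-10 (integrands
## become peaked at xi = 0 for high b).
.kernelIntegral <- function(b, dpara, dperp, l, relax) {
  vapply(seq_along(b), function(i) {
    f <- function(xi)
      exp(-b[i] * dpara * xi^2 - b[i] * dperp * (1 - xi^2)) * legendreP(l, xi)
    relax[i] * stats::integrate(f, 0, 1, abs.tol = 1e-10,
                                rel.tol = 1e-10, subdivisions = 400L)$value
  }, numeric(1))
}

#' Legendre-projected kernel of an axially symmetric compartment
#'
#' Computes K_l, the projection of the single-fibre response onto the
#' order-l Legendre polynomial over xi = cos(angle between gradient and
#' fibre) in [0, 1]. K_0 equals the spherical-mean signal of the wrapped
#' compartment.
#'
#' @param kernel a \code{StickKernel}, \code{ZeppelinKernel} or
#'   \code{IsoKernel}
#' @param protocol an [AcquisitionProtocol-class]
#' @param l even order (0, 2, 4, ...)
#' @return numeric vector of K_l per protocol record
#' @export
setGeneric("kernelInvariant",
           function(kernel, protocol, l) standardGeneric("kernelInvariant"))

.checkEvenL <- function(l) {
  if (l < 0 || l %% 2 != 0) stop("order l must be even and non-negative")
}

#' @rdname kernelInvariant
#' @export
setMethod("kernelInvariant", "StickKernel", function(kernel, protocol, l) {
  .checkEvenL(l)
  .kernelIntegral(protocol@bval, kernel@dpara, 0, l,
                  .relaxWeight(kernel@t2, protocol@techo))
})

#' @rdname kernelInvariant
#' @export
setMethod("kernelInvariant", "ZeppelinKernel", function(kernel, protocol, l) {
  .checkEvenL(l)
  .kernelIntegral(protocol@bval, kernel@dpara,
                  kernel@dperpFrac * kernel@dpara, l,
                  .relaxWeight(kernel@t2, protocol@techo))
})

#' @rdname kernelInvariant
#' @export
setMethod("kernelInvariant", "IsoKernel", function(kernel, protocol, l) {
  .checkEvenL(l)
  ## integrand independent of xi: K_l = S * int_0^1 P_l = 0 for l > 0
  if (l == 0) {
    .relaxWeight(kernel@t2, protocol@techo) * .smIso(protocol@bval, kernel@d)
  } else rep(0, length(protocol@bval))
})

#' Rotational-invariant signal S_l = p_l K_l
#'
#' Combines an fODF rotational invariant with a kernel: the measured
#' rotational invariant at order l factorises as S_l = p_l K_l with p_0 = 1.
#'
#' @param fodf an \code{FODF} object
#' @param kernel a kernel compartment
#' @param protocol an [AcquisitionProtocol-class]
#' @param l even order (0 or 2 supported by the fODF invariants stored)
#' @return numeric vector of S_l per protocol record
#' @export
riSignal <- function(fodf, kernel, protocol, l) {
  .checkEvenL(l)
  pl <- switch(as.character(l), "0" = 1, "2" = fodf@p2,
               stop("fODF invariant p_", l, " is not defined"))
  pl * kernelInvariant(kernel, protocol, l)
}
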