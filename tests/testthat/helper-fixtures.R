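## Shared fixtures and independent closed-form oracles for the tests.

erfOracle <- function(x) 2 * pnorm(x * sqrt(2)) - 1

## Spherical-mean closed forms written independently of the package path
## (quadrature where the package uses the erf expression, and vice versa).
stickOracleQuad <- function(b, d) {
  vapply(b, function(bb)
    integrate(function(xi) exp(-bb * d * xi^2), 0, 1, rel.tol = 1e-12)$value,
    numeric(1))
}

zeppelinOracleQuad <- function(b, dpar, dperp) {
  vapply(b, function(bb)
    integrate(function(xi) exp(-bb * (dperp + (dpar - dperp) * xi^2)),
              0, 1, rel.tol = 1e-12)$value, numeric(1))
}

## Plain-loop reference implementation of the GPD series (matrix-free),
## independent of the vectorised package version.
gpdOracle <- function(kind, radius, d0, G, delta, Delta, nterms) {
  beta <- microfit::besselRoot(kind, seq_len(nterms))
  cc <- if (kind == "cylinder") 1 else 2
  total <- 0
  for (m in seq_len(nterms)) {
    a2 <- (beta[m] / radius)^2
    psi <- 2 * d0 * a2 * delta - 2 + 2 * exp(-d0 * a2 * delta) +
      2 * exp(-d0 * a2 * Delta) - exp(-d0 * a2 * (Delta - delta)) -
      exp(-d0 * a2 * (Delta + delta))
    total <- total + psi / (d0^2 * a2^3 * (radius^2 * a2 - cc))
  }
  -2 * microfit::GYROMAGNETIC_RATIO^2 * G^2 * total
}

## Ground truth of the ex vivo white-matter evaluation voxel.
gtExcaliber <- c("f.axon" = 0.7, "f.dot" = 0.15, "axon.da" = 2,
                 "axon.dpara" = 0.6, "extra.dperpFrac" = 0.3)

## One-compartment isotropic model (conjugate-style toy for the MCMC tests).
toyIsoModel <- function(d = 1, bounds = c(0, 3)) {
  new("BiophysicalModel", name = "toyIso",
      compartments = list(iso = new("Iso", d = d, t2 = 0)),
      fractions = c(iso = 1), freeParams = "iso.d",
      bounds = list("iso.d" = bounds), links = list(),
      fixed = numeric(0), riorder = 0L)
}

## Two-compartment stick+iso mixture, with a variant whose compartment
## order is permuted, for the order-invariance property.
stickIsoModel <- function(swap = FALSE) {
  comps <- list(a = new("Stick", dpara = 1.5, t2 = 0),
                b = new("Iso", d = 0.8, t2 = 0))
  fr <- c(a = 0.6, b = 0.4)
  if (swap) { comps <- rev(comps); fr <- rev(fr) }
  new("BiophysicalModel", name = "stickIso", compartments = comps,
      fractions = fr, freeParams = paste0("f.", names(comps)[1]),
      bounds = stats::setNames(list(c(0, 1)), paste0("f.", names(comps)[1])),
      links = list(), fixed = numeric(0), riorder = 0L)
}

## Cache for expensive trained estimators shared across test blocks.
.testCache <- new.env(parent = emptyenv())

cachedSMTEstimator <- function() {
  if (is.null(.testCache$smt)) {
    m <- makeModel("SMT")
    p <- protocolPreset("hcp_smt")
    na <- networkArg(m, p, nsamples = 30000, snr = 50, seed = 3)
    .testCache$smt <- trainEstimator(na, trainingArg(epochs = 120,
                                                     patience = 20))
  }
  .testCache$smt
}
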