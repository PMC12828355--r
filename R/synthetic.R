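## ---------------------------------------------------------------------------
## Synthetic voxels, phantoms and protocol presets
## ---------------------------------------------------------------------------

#' Protocol presets
#'
#' Shell tables of the acquisition protocols used throughout the package's
#' evaluations:
#' \describe{
#' \item{hcp_smt}{3 T human protocol: b = 1, 2, 3 ms/um^2, 90 directions
#'   per shell, plus a b = 0 shell averaged from 18 volumes.}
#' \item{connectome_sandi}{ultra-high-gradient human protocol, short
#'   diffusion time: delta/Delta = 8/19 ms, b = 0, 0.35, 0.8, 1.5, 2.4,
#'   3.45, 4.75, 6.0 ms/um^2; 32 directions below b = 2.4 and 64 at or
#'   above.}
#' \item{prisma_mte_smi}{multi-TE clinical protocol: 8 TEs (62-132 ms,
#'   10 ms spacing), b = 0 (4 averages), 0.7 and 2.0 ms/um^2 (30 directions)
#'   per TE, delta/Delta = 15.2/25.2 ms; rotational invariants to order 2
#'   (order-0 block then order-2 block for the b > 0 shells).}
#' \item{excaliber_exvivo_dt12}{preclinical ex vivo: delta/Delta = 9.6/12
#'   ms, b = 1, 2.5, 5, 7.5, 11.1, 18.1, 25.0 ms/um^2, 32 directions.}
#' \item{excaliber_exvivo_dt15}{delta/Delta = 11/15.192 ms, the shells
#'   above plus b = 43.0 (8 b-values).}
#' \item{excaliber_exvivo_dt21}{delta/Delta = 11/21 ms, plus b = 64.0
#'   (9 b-values).}
#' }
#'
#' @param name preset name
#' @return an [AcquisitionProtocol-class]
#' @export
protocolPreset <- function(name = c("hcp_smt", "connectome_sandi",
                                    "prisma_mte_smi",
                                    "excaliber_exvivo_dt12",
                                    "excaliber_exvivo_dt15",
                                    "excaliber_exvivo_dt21")) {
  name <- match.arg(name)
  switch(name,
    hcp_smt = acquisitionProtocol(
      bval = c(0, 1, 2, 3), ndirs = c(18L, 90L, 90L, 90L)),
    connectome_sandi = {
      b <- c(0, 0.35, 0.8, 1.5, 2.4, 3.45, 4.75, 6.0)
      acquisitionProtocol(bval = b, tdelta = 19, tsmalldel = 8,
                          ndirs = ifelse(b < 2.4, 32L, 64L))
    },
    prisma_mte_smi = {
      te <- seq(62, 132, by = 10)
      b1 <- c(0, 0.7, 2.0)
      nd <- c(4L, 30L, 30L)
      bv <- rep(b1, times = length(te))
      tev <- rep(te, each = length(b1))
      ndv <- rep(nd, times = length(te))
      ## order-0 block for all shells, order-2 block for b > 0 shells
      pos <- bv > 0
      acquisitionProtocol(bval = c(bv, bv[pos]),
                          techo = c(tev, tev[pos]),
                          tdelta = 25.2, tsmalldel = 15.2,
                          ndirs = c(ndv, ndv[pos]),
                          lorder = c(rep(0L, length(bv)),
                                     rep(2L, sum(pos))))
    },
    excaliber_exvivo_dt12 = acquisitionProtocol(
      bval = c(1, 2.5, 5, 7.5, 11.1, 18.1, 25.0),
      tdelta = 12, tsmalldel = 9.6, ndirs = 32L),
    excaliber_exvivo_dt15 = acquisitionProtocol(
      bval = c(1, 2.5, 5, 7.5, 11.1, 18.1, 25.0, 43.0),
      tdelta = 15.192, tsmalldel = 11, ndirs = 32L),
    excaliber_exvivo_dt21 = acquisitionProtocol(
      bval = c(1, 2.5, 5, 7.5, 11.1, 18.1, 25.0, 43.0, 64.0),
      tdelta = 21, tsmalldel = 11, ndirs = 32L))
}

#' Combine protocols (e.g. multiple diffusion times)
#' @param ... [AcquisitionProtocol-class] objects
#' @return a single concatenated protocol
#' @export
combineProtocols <- function(...) {
  ps <- list(...)
  acquisitionProtocol(
    bval = unlist(lapply(ps, slot, "bval")),
    techo = unlist(lapply(ps, slot, "techo")),
    tdelta = unlist(lapply(ps, slot, "tdelta")),
    tsmalldel = unlist(lapply(ps, slot, "tsmalldel")),
    ndirs = unlist(lapply(ps, slot, "ndirs")),
    lorder = unlist(lapply(ps, slot, "lorder")))
}

#' Synthesise noisy voxel measurements
#'
#' Computes the forward model at the ground-truth parameter values and adds
#' Gaussian noise of std 1/snr directly on the normalised spherical-mean
#' (or rotational-invariant) scale, as appropriate for model-level fitting
#' evaluations. Use [synthDirectional()] to emulate per-direction noise
#' instead.
#'
#' @param model a [BiophysicalModel-class]
#' @param gt named vector of ground-truth free-parameter values (fractions
#'   as \code{f.<comp>})
#' @param protocol an [AcquisitionProtocol-class]
#' @param snr SNR of the spherical-mean measurements (noise std = 1/snr);
#'   Inf gives noise-free rows
#' @param nrealizations number of noisy realisations (rows)
#' @param seed integer seed
#' @return nrealizations x nshells matrix
#' @export
synthVoxel <- function(model, gt, protocol, snr = 100, nrealizations = 1,
                       seed = 1L) {
  set.seed(seed)
  clean <- modelSignals(model, protocol, values = gt)
  m <- matrix(rep(clean, each = nrealizations), nrealizations)
  if (is.finite(snr))
    m <- m + matrix(stats::rnorm(length(m), 0, 1 / snr), nrealizations)
  m
}

#' Approximately uniform directions on the sphere
#'
#' Fibonacci-spiral point set; adequate for synthesising direction-resolved
#' test data.
#'
#' @param n number of directions
#' @return n x 3 matrix of unit vectors
#' @export
sphereDirections <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Direction-resolved synthetic signals for axially symmetric compartments
#'
#' Directional signal e^(-b (Dperp + (Dpar - Dperp) (g.n)^2)) for Stick
#' (Dperp = 0), Zeppelin, or Iso compartments with fibre orientation
#' \code{fibre}; used to test the direction-averaging pipeline against the
#' closed-form spherical means.
#'
#' @param comp a Stick, Zeppelin or Iso compartment
#' @param bval b-value(s), one per shell
#' @param dirs ndirs x 3 matrix of unit gradient directions
#' @param fibre fibre orientation unit vector
#' @return length(bval) x ndirs matrix of signals
#' @export
synthDirectional <- function(comp, bval, dirs, fibre = c(0, 0, 1)) {
  fibre <- fibre / sqrt(sum(fibre^2))
  xi2 <- as.vector(dirs %*% fibre)^2
  dpar <- switch(class(comp)[1],
    Stick = , StickKernel = comp@dpara,
    Zeppelin = , ZeppelinKernel = comp@dpara,
    Iso = , IsoKernel = comp@d,
    stop("directional synthesis supports Stick/Zeppelin/Iso"))
  dperp <- switch(class(comp)[1],
    Stick = , StickKernel = 0,
    Zeppelin = , ZeppelinKernel = comp@dperpFrac * comp@dpara,
    Iso = , IsoKernel = comp@d)
  outer(bval, xi2, function(b, x) exp(-b * (dperp + (dpar - dperp) * x)))
}

#' Accuracy/precision sweep over ground-truth values
#'
#' For each ground-truth setting, synthesises \code{nrealizations} noisy
#' voxels, runs the estimator, and summarises the estimates of
#' \code{target} as boxplot statistics; the Pearson correlation between
#' per-GT mean estimates and the ground truth quantifies how well the
#' protocol discriminates the swept parameter.
#'
#' @param model a [BiophysicalModel-class]
#' @param gtGrid data.frame, one row per ground-truth setting (columns are
#'   free-parameter names)
#' @param protocol an [AcquisitionProtocol-class]
#' @param snr spherical-mean SNR used for synthesis
#' @param nrealizations noise realisations per GT point
#' @param estimator function(meas, protocol) returning a named vector of
#'   parameter estimates
#' @param target name of the swept parameter (for the correlation)
#' @param seed base seed
#' @return list(stats = data.frame of per-GT boxplot statistics, pearson,
#'   estimates = matrix of per-realisation estimates)
#' @export
sweepEvaluation <- function(model, gtGrid, protocol, snr, nrealizations,
                            estimator, target, seed = 1L) {
  ng <- nrow(gtGrid)
  est <- matrix(NA_real_, ng, nrealizations)
  nfail <- 0L
  for (i in seq_len(ng)) {
    gt <- unlist(gtGrid[i, , drop = TRUE])
    meas <- synthVoxel(model, gt, protocol, snr, nrealizations,
                       seed = seed + i)
    for (r in seq_len(nrealizations)) {
      e <- tryCatch(estimator(meas[r, ], protocol),
                    error = function(e) NULL)
      if (is.null(e)) nfail <- nfail + 1L
      else est[i, r] <- e[[target]]
    }
  }
  qs <- t(apply(est, 1, stats::quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE))
  stats_ <- data.frame(gt = gtGrid[[target]],
                       mean = rowMeans(est, na.rm = TRUE), qs,
                       check.names = FALSE)
  means <- rowMeans(est, na.rm = TRUE)
  pearson <- if (stats::sd(means) == 0 || stats::sd(gtGrid[[target]]) == 0)
    NA_real_ else stats::cor(gtGrid[[target]], means)
  list(stats = stats_, pearson = pearson, estimates = est,
       nfailed = nfail)
}

#' Write a synthetic phantom to NIfTI + side-car files
#'
#' Synthesises a spatial phantom of repeated ground-truth voxels under a
#' protocol preset, writes the 4D volume (one volume per shell record,
#' spherical-mean scale) together with plain-text side-cars
#' (\code{.bvals}, \code{.techo}, \code{.tdelta}, \code{.tsmalldel}) and an
#' optional mask, so that the files round-trip through [readDWI()] /
#' [readAcquisition()].
#'
#' @param model a [BiophysicalModel-class]
#' @param gt named ground-truth vector
#' @param protocol an [AcquisitionProtocol-class]
#' @param dim3 spatial grid dimensions
#' @param snr spherical-mean SNR (Inf = noise-free)
#' @param seed integer seed
#' @param outStem output path stem
#' @return invisibly, the list of written file paths
#' @export
writePhantom <- function(model, gt, protocol, dim3 = c(4, 4, 2), snr = Inf,
                         seed = 1L, outStem) {
  nvox <- prod(dim3)
  meas <- synthVoxel(model, gt, protocol, snr, nrealizations = nvox,
                     seed = seed)
  arr <- array(meas, c(dim3, length(protocol)))
  vs <- volumeSeries(arr)
  paths <- c(dwi = paste0(outStem, ".nii.gz"),
             bvals = paste0(outStem, ".bvals"))
  writeVolume(vs, paths["dwi"])
  writeLines(paste(protocol@bval, collapse = " "), paths["bvals"])
  writeSide <- function(vals, ext) {
    if (all(is.na(vals))) return(NULL)
    p <- paste0(outStem, ".", ext)
    writeLines(paste(vals, collapse = " "), p)
    p
  }
  paths <- c(paths,
             techo = writeSide(protocol@techo, "techo"),
             tdelta = writeSide(protocol@tdelta, "tdelta"),
             tsmalldel = writeSide(protocol@tsmalldel, "tsmalldel"))
  invisible(paths)
}
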