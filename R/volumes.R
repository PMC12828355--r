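## ---------------------------------------------------------------------------
## Volume container and NIfTI I/O
## ---------------------------------------------------------------------------

#' 4D volume series
#'
#' Container for a series of 3D volumes (x, y, z, measurement) with voxel
#' size, affine, and an optional mask.
#'
#' @slot data 4D numeric array
#' @slot voxdim voxel size in mm (length 3)
#' @slot affine 4 x 4 voxel-to-world matrix
#' @slot mask logical 3D array (may be empty for "no mask")
#' @export
setClass("VolumeSeries",
  representation(data = "array", voxdim = "numeric", affine = "matrix",
                 mask = "array"),
  prototype(voxdim = c(1, 1, 1), affine = diag(4),
            mask = array(logical(0), c(0, 0, 0))))

setValidity("VolumeSeries", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array")
  if (length(object@mask) &&
      !identical(dim(object@mask), dim(object@data)[1:3]))
    msg <- c(msg, "mask dimensions must match the volume grid")
  if (length(msg)) msg else TRUE
})

#' Construct a VolumeSeries
#' @param data 4D array (a 3D array is promoted to a single volume)
#' @param voxdim voxel size, mm
#' @param affine 4 x 4 affine
#' @param mask optional logical 3D array
#' @export
volumeSeries <- function(data, voxdim = c(1, 1, 1), affine = diag(4),
                         mask = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (is.null(mask)) mask <- array(logical(0), c(0, 0, 0))
  new("VolumeSeries", data = data, voxdim = as.numeric(voxdim),
      affine = affine, mask = mask)
}

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeSeries: %d x %d x %d grid, %d volumes, voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(object@voxdim, 3), collapse = " x ")))
  if (length(object@mask))
    cat(sprintf("  mask: %d voxels\n", sum(object@mask)))
})

#' @rdname volumeData
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' Access the data array of a VolumeSeries
#' @param x a [VolumeSeries-class]
#' @return the 4D numeric array
#' @rdname volumeData
#' @export
setMethod("volumeData", "VolumeSeries", function(x) x@data)

#' Read a DWI series from NIfTI
#' @param path NIfTI file (.nii or .nii.gz)
#' @param maskPath optional mask NIfTI
#' @return a [VolumeSeries-class]
#' @export
readDWI <- function(path, maskPath = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  mask <- NULL
  if (!is.null(maskPath))
    mask <- as.array(RNifti::readNifti(maskPath)) > 0
  volumeSeries(arr, voxdim = RNifti::pixdim(img)[1:3],
               affine = unclass(RNifti::xform(img)), mask = mask)
}

#' Write a VolumeSeries to NIfTI
#' @param vs a [VolumeSeries-class]
#' @param path output path (.nii or .nii.gz)
#' @export
writeVolume <- function(vs, path) {
  img <- structure(vs@data, pixdim = vs@voxdim)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

.maskIndices <- function(vs) {
  if (length(vs@mask)) which(vs@mask) else seq_len(prod(dim(vs@data)[1:3]))
}

## ---------------------------------------------------------------------------
## Real symmetric spherical harmonics
## ---------------------------------------------------------------------------

## Associated Legendre P_l^m(x) (Condon-Shortley phase), scalar l, m >= 0,
## vectorised in x.
.assocLegendre <- function(l, m, x) {
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

## Orthonormal real SH design matrix for even orders 0..lmax at unit
## directions (N x 3). Columns ordered (l, m) with m = -l..l.
.shBasis <- function(dirs, lmax) {
  theta <- acos(pmin(1, pmax(-1, dirs[, 3])))
  phi <- atan2(dirs[, 2], dirs[, 1])
  ct <- cos(theta)
  cols <- list()
  for (l in seq(0, lmax, by = 2)) {
    for (m in -l:l) {
      am <- abs(m)
      nlm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      p <- .assocLegendre(l, am, ct)
      y <- if (m == 0) nlm * p
           else if (m > 0) sqrt(2) * nlm * p * cos(am * phi)
           else sqrt(2) * nlm * p * sin(am * phi)
      cols[[length(cols) + 1L]] <- y
    }
  }
  do.call(cbind, cols)
}

.nshCoef <- function(lmax) sum(2 * seq(0, lmax, by = 2) + 1)

#' Legendre polynomial P_l(x)
#' @param l order (non-negative integer)
#' @param x evaluation points in [-1, 1]
#' @export
legendreP <- function(l, x) {
  if (l == 0) return(rep(1, length(x)))
  if (l == 1) return(x)
  pm2 <- rep(1, length(x)); pm1 <- x
  for (ll in 2:l) {
    p <- ((2 * ll - 1) * x * pm1 - (ll - 1) * pm2) / ll
    pm2 <- pm1; pm1 <- p
  }
  pm1
}

## ---------------------------------------------------------------------------
## Spherical mean, SH rotational invariants, SNR map
## ---------------------------------------------------------------------------

#' Spherical mean of a DWI series
#'
#' Averages the DW measurements across gradient directions for each unique
#' combination of (b, TE, Delta, delta). b = 0 volumes (b below
#' \code{b0Threshold}) are averaged per echo time. Output shells are ordered
#' by ascending (TE, b).
#'
#' @param dwi a [VolumeSeries-class]
#' @param table an [AcquisitionTable-class] covering every volume
#' @param b0Threshold b-values below this (ms/um^2) count as b = 0
#' @return list with elements \code{volumes} (a [VolumeSeries-class], one
#'   volume per shell) and \code{protocol} (an [AcquisitionProtocol-class]
#'   with per-shell direction counts)
#' @export
sphericalMean <- function(dwi, table, b0Threshold = 0.05) {
  stopifnot(is(dwi, "VolumeSeries"), is(table, "AcquisitionTable"))
  nvol <- dim(dwi@data)[4]
  if (length(table) != nvol)
    stop(sprintf("table covers %d volumes but series has %d",
                 length(table), nvol))
  keys <- .shellKeys(table, b0Threshold)
  shells <- .uniqueShells(keys)
  ns <- nrow(shells)
  d3 <- dim(dwi@data)[1:3]
  out <- array(NA_real_, c(d3, ns))
  ndirs <- integer(ns)
  for (i in seq_len(ns)) {
    sel <- .shellMembers(keys, shells[i, ])
    ndirs[i] <- length(sel)
    sub <- dwi@data[, , , sel, drop = FALSE]
    out[, , , i] <- rowMeans(sub, dims = 3)
  }
  if (length(dwi@mask) && anyNA(out[, , , 1][dwi@mask]))
    warning("NaN/NA values inside the mask were propagated")
  proto <- acquisitionProtocol(shells$b, techo = shells$te,
                               tdelta = shells$dd, tsmalldel = shells$sd,
                               ndirs = pmax(ndirs, 1L), lorder = 0L)
  list(volumes = volumeSeries(out, dwi@voxdim, dwi@affine, .nullIfEmpty(dwi@mask)),
       protocol = proto)
}

.nullIfEmpty <- function(mask) if (length(mask)) mask else NULL

.shellMembers <- function(keys, shell) {
  same <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  which(same(keys$b, shell$b) & same(keys$te, shell$te) &
        same(keys$dd, shell$dd) & same(keys$sd, shell$sd))
}

#' Rotational invariants from a spherical-harmonic fit
#'
#' Fits the per-shell directional measurements to a real, symmetric
#' (even-order) SH basis and extracts rotational invariants
#' S_l = ||c_l|| / sqrt(4 pi (2l + 1)). With this normalisation S_0 equals
#' the spherical mean, and for an axially symmetric kernel S_l equals the
#' order-l Legendre-projected kernel value. Output volumes are ordered by
#' order block (all S_0 shells, then all S_2 shells, ...), shells ascending
#' (TE, b) within a block; b = 0 shells report S_0 = mean and S_l = 0 for
#' l > 0. Negative input values are clamped to 0 before the fit.
#'
#' @param dwi a [VolumeSeries-class]
#' @param table an [AcquisitionTable-class] with gradient directions
#' @param lmax maximum (even) SH order
#' @param b0Threshold b-values below this count as b = 0
#' @return list(volumes, protocol) as in [sphericalMean()]
#' @export
sphericalFit <- function(dwi, table, lmax = 0, b0Threshold = 0.05) {
  stopifnot(is(dwi, "VolumeSeries"), is(table, "AcquisitionTable"))
  if (lmax %% 2 != 0) stop("lmax must be even")
  if (lmax > 0 && !nrow(table@bvec))
    stop("gradient directions are required for lmax > 0")
  sm <- sphericalMean(dwi, table, b0Threshold)
  if (lmax == 0) return(sm)

  keys <- .shellKeys(table, b0Threshold)
  shells <- .uniqueShells(keys)
  ns <- nrow(shells)
  d3 <- dim(dwi@data)[1:3]
  nvoxall <- prod(d3)
  orders <- seq(0, lmax, by = 2)
  out <- array(0, c(d3, ns * length(orders)))
  nneg <- 0L
  flat <- matrix(dwi@data, nrow = nvoxall)
  for (i in seq_len(ns)) {
    sel <- .shellMembers(keys, shells[i, ])
    if (shells$b[i] == 0) {
      out[, , , i] <- sm$volumes@data[, , , i]
      next
    }
    ncoef <- .nshCoef(lmax)
    if (length(sel) < ncoef)
      stop(sprintf("shell b=%g TE=%s has %d directions but %d SH coefficients",
                   shells$b[i], format(shells$te[i]), length(sel), ncoef))
    Y <- .shBasis(table@bvec[sel, , drop = FALSE], lmax)
    qr.Y <- qr(Y)
    if (qr.Y$rank < ncoef)
      stop(sprintf("rank-deficient SH design for shell b=%g", shells$b[i]))
    sig <- t(flat[, sel, drop = FALSE])
    nneg <- nneg + sum(sig < 0)
    sig[sig < 0] <- 0
    coef <- qr.coef(qr.Y, sig)              # ncoef x nvox
    off <- 0
    for (k in seq_along(orders)) {
      l <- orders[k]
      idx <- off + seq_len(2 * l + 1)
      off <- off + 2 * l + 1
      sl <- sqrt(colSums(coef[idx, , drop = FALSE]^2)) /
            sqrt(4 * pi * (2 * l + 1))
      out[, , , (k - 1) * ns + i] <- array(sl, d3)
    }
  }
  if (nneg > 0)
    message(nneg, " negative values clamped to 0 before the SH fit")
  proto <- acquisitionProtocol(rep(shells$b, length(orders)),
                               techo = rep(shells$te, length(orders)),
                               tdelta = rep(shells$dd, length(orders)),
                               tsmalldel = rep(shells$sd, length(orders)),
                               ndirs = rep(sm$protocol@ndirs, length(orders)),
                               lorder = rep(orders, each = ns))
  list(volumes = volumeSeries(out, dwi@voxdim, dwi@affine, .nullIfEmpty(dwi@mask)),
       protocol = proto)
}

#' Voxelwise SNR map from repeated b = 0 measurements
#'
#' SNR is the ratio of the voxelwise mean and sample standard deviation of
#' the b = 0 volumes, computed separately at each echo time. Voxels with
#' zero variance (infinite SNR) are set to NA.
#'
#' @param dwi a [VolumeSeries-class]
#' @param table an [AcquisitionTable-class]
#' @param b0Threshold b-values below this count as b = 0
#' @return a [VolumeSeries-class] with one SNR volume per echo time; echo
#'   times are attached as attribute \code{"techo"}
#' @export
snrMap <- function(dwi, table, b0Threshold = 0.05) {
  keys <- .shellKeys(table, b0Threshold)
  isb0 <- keys$b == 0
  if (!any(isb0)) stop("no b = 0 volumes found")
  tes <- unique(keys$te[isb0])
  d3 <- dim(dwi@data)[1:3]
  out <- array(NA_real_, c(d3, length(tes)))
  for (k in seq_along(tes)) {
    sel <- which(isb0 & (is.na(keys$te) & is.na(tes[k]) |
                         !is.na(keys$te) & !is.na(tes[k]) & keys$te == tes[k]))
    if (length(sel) < 2)
      stop(sprintf("need >= 2 b=0 volumes per TE (TE=%s has %d)",
                   format(tes[k]), length(sel)))
    sub <- matrix(dwi@data[, , , sel], ncol = length(sel))
    mu <- rowMeans(sub)
    sd_ <- apply(sub, 1, stats::sd)
    snr <- mu / sd_
    snr[!is.finite(snr)] <- NA_real_
    out[, , , k] <- array(snr, d3)
  }
  res <- volumeSeries(out, dwi@voxdim, dwi@affine, .nullIfEmpty(dwi@mask))
  attr(res, "techo") <- tes
  res
}
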