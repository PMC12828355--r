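#' @import methods
NULL

## ---------------------------------------------------------------------------
## Per-volume acquisition table
## ---------------------------------------------------------------------------

#' Per-volume acquisition parameters
#'
#' One record per DWI volume: b-value (ms/um^2), optional unit gradient
#' direction, echo time, and PGSE pulse separation/duration (ms). Slots for
#' absent side-car files have length zero.
#'
#' @slot bval numeric, one b-value per volume (ms/um^2)
#' @slot bvec N x 3 matrix of unit gradient directions (rows may be zero for
#'   b = 0 volumes), or a 0 x 3 matrix when absent
#' @slot techo echo times in ms, or length 0
#' @slot tdelta gradient pulse separation Delta in ms, or length 0
#' @slot tsmalldel gradient pulse duration delta in ms, or length 0
#' @export
setClass("AcquisitionTable",
  representation(bval = "numeric", bvec = "matrix", techo = "numeric",
                 tdelta = "numeric", tsmalldel = "numeric"),
  prototype(bvec = matrix(numeric(0), 0, 3)))

setValidity("AcquisitionTable", function(object) {
  n <- length(object@bval)
  msg <- character(0)
  if (any(object@bval < 0)) msg <- c(msg, "b-values must be non-negative")
  for (s in c("techo", "tdelta", "tsmalldel")) {
    v <- slot(object, s)
    if (length(v) && length(v) != n)
      msg <- c(msg, sprintf("'%s' length (%d) != number of volumes (%d)",
                            s, length(v), n))
  }
  if (nrow(object@bvec)) {
    if (nrow(object@bvec) != n)
      msg <- c(msg, "bvec row count != number of volumes")
    nrm <- sqrt(rowSums(object@bvec^2))
    if (any(nrm > 1e-6 & abs(nrm - 1) > 1e-3))
      msg <- c(msg, "gradient directions must be unit vectors (or zero)")
  }
  if (length(object@tdelta) && length(object@tsmalldel) &&
      any(object@tsmalldel >= object@tdelta, na.rm = TRUE))
    msg <- c(msg, "pulse duration delta must be smaller than separation Delta")
  if (length(msg)) msg else TRUE
})

#' Construct an acquisition table in memory
#'
#' @param bval b-values; values above 100 are interpreted as s/mm^2 (FSL
#'   convention) and converted to ms/um^2
#' @param bvec optional N x 3 (or 3 x N) matrix of gradient directions
#' @param techo,tdelta,tsmalldel optional per-volume times in ms
#' @return an [AcquisitionTable-class] object
#' @export
acquisitionTable <- function(bval, bvec = NULL, techo = numeric(0),
                             tdelta = numeric(0), tsmalldel = numeric(0)) {
  bval <- .canonicalBval(as.numeric(bval))
  if (is.null(bvec)) {
    bvec <- matrix(numeric(0), 0, 3)
  } else {
    bvec <- as.matrix(bvec)
    if (ncol(bvec) != 3 && nrow(bvec) == 3) bvec <- t(bvec)
  }
  new("AcquisitionTable", bval = bval, bvec = bvec,
      techo = as.numeric(techo), tdelta = as.numeric(tdelta),
      tsmalldel = as.numeric(tsmalldel))
}

## FSL-style b-values are written in s/mm^2; 1 s/mm^2 = 1e-3 ms/um^2.
.canonicalBval <- function(b) if (max(b, 0) > 100) b / 1000 else b

#' Read acquisition side-car text files
#'
#' Reads whitespace-delimited per-volume acquisition files: b-values
#' (required), and optionally gradient directions (3 x N or N x 3,
#' auto-detected), echo times, pulse separations and durations. b-values with
#' magnitude above 100 are taken to be in s/mm^2 and converted to ms/um^2;
#' all times are expected in ms.
#'
#' @param bvalPath path to the b-value file
#' @param bvecPath,techoPath,tdeltaPath,tsmalldelPath optional side-car paths
#' @return an [AcquisitionTable-class]
#' @export
readAcquisition <- function(bvalPath, bvecPath = NULL, techoPath = NULL,
                            tdeltaPath = NULL, tsmalldelPath = NULL) {
  if (!file.exists(bvalPath)) stop("b-value file not found: ", bvalPath)
  bval <- scan(bvalPath, quiet = TRUE)
  n <- length(bval)
  readSide <- function(path, what) {
    if (is.null(path)) return(numeric(0))
    v <- scan(path, quiet = TRUE)
    if (length(v) != n)
      stop(sprintf("'%s' has %d entries but %d volumes expected",
                   what, length(v), n))
    v
  }
  bvec <- NULL
  if (!is.null(bvecPath)) {
    m <- as.matrix(utils::read.table(bvecPath))
    if (nrow(m) == 3 && ncol(m) == n) m <- t(m)
    if (nrow(m) != n || ncol(m) != 3)
      stop("bvec file is not 3x", n, " or ", n, "x3")
    bvec <- unname(m)
  }
  acquisitionTable(bval, bvec,
                   techo = readSide(techoPath, "techo"),
                   tdelta = readSide(tdeltaPath, "tdelta"),
                   tsmalldel = readSide(tsmalldelPath, "tsmalldel"))
}

#' @export
setMethod("length", "AcquisitionTable", function(x) length(x@bval))

setMethod("show", "AcquisitionTable", function(object) {
  cat(sprintf("AcquisitionTable: %d volumes, b in [%.3g, %.3g] ms/um^2\n",
              length(object@bval), min(object@bval), max(object@bval)))
  if (length(object@techo))
    cat("  echo times:", paste(unique(object@techo), collapse = ", "), "ms\n")
  if (length(object@tdelta))
    cat("  delta/Delta:",
        paste(unique(paste0(object@tsmalldel, "/", object@tdelta)),
              collapse = ", "), "ms\n")
})

## ---------------------------------------------------------------------------
## Per-shell protocol
## ---------------------------------------------------------------------------

#' Per-shell acquisition protocol
#'
#' One record per measurement used in model fitting: b-value, echo time,
#' pulse times, derived gradient amplitude, the number of directions averaged
#' into the measurement, and the rotational-invariant order of the
#' measurement (0 for the spherical mean).
#'
#' @slot bval per-shell b-values, ms/um^2
#' @slot techo echo times, ms (NA when single-TE)
#' @slot tdelta,tsmalldel PGSE pulse separation/duration, ms (NA when unused)
#' @slot gradient gradient amplitude derived via the PGSE relation, mT/m
#' @slot ndirs number of directions per shell
#' @slot lorder rotational-invariant order of each record (0, 2, ...)
#' @slot riorder maximum rotational-invariant order of the protocol
#' @export
setClass("AcquisitionProtocol",
  representation(bval = "numeric", techo = "numeric", tdelta = "numeric",
                 tsmalldel = "numeric", gradient = "numeric",
                 ndirs = "integer", lorder = "integer", riorder = "integer"))

setValidity("AcquisitionProtocol", function(object) {
  n <- length(object@bval)
  msg <- character(0)
  for (s in c("techo", "tdelta", "tsmalldel", "gradient", "ndirs", "lorder"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' length != number of shells", s))
  if (length(msg)) return(msg)
  if (any(object@ndirs < 1L)) msg <- c(msg, "ndirs must be >= 1")
  key <- paste(round(object@bval, 3), round(object@techo, 3),
               round(object@tdelta, 3), round(object@tsmalldel, 3),
               object@lorder)
  if (anyDuplicated(key))
    msg <- c(msg, "shells must be unique on (b, TE, Delta, delta, order)")
  has <- !is.na(object@gradient) & !is.na(object@tdelta) &
         !is.na(object@tsmalldel) & object@bval > 0
  if (any(has)) {
    bchk <- bFromPGSE(object@gradient[has], object@tsmalldel[has],
                      object@tdelta[has])
    if (any(abs(bchk - object@bval[has]) > 1e-6 * pmax(object@bval[has], 1)))
      msg <- c(msg, "gradient inconsistent with b via the PGSE relation")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a shell protocol
#'
#' The gradient amplitude is derived from b and the pulse times via the PGSE
#' relation when both times are given.
#'
#' @param bval per-shell b-values in canonical ms/um^2 units (no s/mm^2
#'   auto-detection here, since ultra-high-b protocols are legitimate)
#' @param techo echo times, ms; NA for single-TE protocols
#' @param tdelta,tsmalldel pulse separation/duration, ms; NA when not used
#' @param ndirs directions per shell (recycled)
#' @param lorder rotational-invariant order per record (default all 0)
#' @return an [AcquisitionProtocol-class]
#' @export
acquisitionProtocol <- function(bval, techo = NA_real_, tdelta = NA_real_,
                                tsmalldel = NA_real_, ndirs = 1L,
                                lorder = 0L) {
  bval <- as.numeric(bval)
  n <- length(bval)
  techo <- rep_len(as.numeric(techo), n)
  tdelta <- rep_len(as.numeric(tdelta), n)
  tsmalldel <- rep_len(as.numeric(tsmalldel), n)
  ndirs <- rep_len(as.integer(ndirs), n)
  lorder <- rep_len(as.integer(lorder), n)
  grad <- rep(NA_real_, n)
  has <- !is.na(tdelta) & !is.na(tsmalldel)
  if (any(has))
    grad[has] <- gradientFromB(bval[has], tsmalldel[has], tdelta[has])
  new("AcquisitionProtocol", bval = bval, techo = techo, tdelta = tdelta,
      tsmalldel = tsmalldel, gradient = grad, ndirs = ndirs,
      lorder = lorder, riorder = max(lorder))
}

#' @export
setMethod("length", "AcquisitionProtocol", function(x) length(x@bval))

#' Shell table of a protocol as a data.frame
#' @param protocol an [AcquisitionProtocol-class]
#' @return data.frame with one row per shell record
#' @export
shellTable <- function(protocol) {
  data.frame(bval = protocol@bval, techo = protocol@techo,
             tdelta = protocol@tdelta, tsmalldel = protocol@tsmalldel,
             gradient = protocol@gradient, ndirs = protocol@ndirs,
             lorder = protocol@lorder)
}

setMethod("show", "AcquisitionProtocol", function(object) {
  cat(sprintf("AcquisitionProtocol: %d records, max RI order %d\n",
              length(object@bval), object@riorder))
  print(shellTable(object), digits = 4)
})

#' Does a protocol carry multiple echo times?
#' @param protocol an [AcquisitionProtocol-class]
#' @export
isMultiTE <- function(protocol) {
  te <- unique(protocol@techo[!is.na(protocol@techo)])
  length(te) > 1L
}

## ---------------------------------------------------------------------------
## Shell grouping
## ---------------------------------------------------------------------------

## Assign each volume a shell key; b below b0Threshold counts as b = 0 and is
## grouped per echo time. Keys round b and times to 3 decimals so that values
## written with finite precision group exactly.
.shellKeys <- function(table, b0Threshold = 0.05) {
  n <- length(table@bval)
  b <- round(table@bval, 3)
  b[table@bval < b0Threshold] <- 0
  te <- if (length(table@techo)) round(table@techo, 3) else rep(NA_real_, n)
  dd <- if (length(table@tdelta)) round(table@tdelta, 3) else rep(NA_real_, n)
  sd <- if (length(table@tsmalldel)) round(table@tsmalldel, 3) else rep(NA_real_, n)
  ## b = 0 volumes share a shell per TE regardless of pulse times
  dd[b == 0] <- NA; sd[b == 0] <- NA
  data.frame(b = b, te = te, dd = dd, sd = sd)
}

## Unique shells in canonical output order: ascending (TE, b), then times.
.uniqueShells <- function(keys) {
  u <- unique(keys)
  u[order(u$te, u$b, u$dd, u$sd, na.last = FALSE), , drop = FALSE]
}
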