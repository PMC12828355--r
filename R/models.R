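## ---------------------------------------------------------------------------
## Biophysical models: weighted compartment mixtures with links and bounds
## ---------------------------------------------------------------------------

#' Biophysical tissue model
#'
#' A mixture of tissue compartments with a simplex of signal fractions,
#' optional parameter links (derived parameters), fixed parameters, and a
#' rotational-invariant order. Parameters are addressed as
#' \code{"<compartment>.<slot>"} (e.g. \code{"axon.da"}), signal fractions
#' as \code{"f.<compartment>"}, and the fODF invariant as \code{"p2"}.
#'
#' @slot name model name
#' @slot compartments named list of compartment objects
#' @slot fractions named numeric simplex weights (sum to 1)
#' @slot fodf an FODF object (used when riorder > 0)
#' @slot freeParams character vector of free parameter names, in order; the
#'   residual fraction (1 - sum of the free ones) is derived
#' @slot bounds named list of c(lo, hi) per free parameter
#' @slot links named list: target parameter -> function(values) returning
#'   its derived value
#' @slot fixed named numeric of fixed parameter overrides
#' @slot riorder 0 (spherical mean) or 2 (rotational invariants)
#' @slot normalization "global", "perTE" or "none" (multi-TE convention)
#' @export
setClass("BiophysicalModel",
  representation(name = "character", compartments = "list",
                 fractions = "numeric", fodf = "FODF",
                 freeParams = "character", bounds = "list",
                 links = "list", fixed = "numeric", riorder = "integer",
                 normalization = "character"),
  prototype(fodf = new("FODF", p2 = 0), riorder = 0L,
            normalization = "global", fixed = numeric(0)))

setValidity("BiophysicalModel", function(object) {
  msg <- character(0)
  if (is.null(names(object@compartments)) ||
      any(!nzchar(names(object@compartments))))
    msg <- c(msg, "compartments must be named")
  if (!identical(sort(names(object@fractions)),
                 sort(names(object@compartments))))
    msg <- c(msg, "fractions must be named after the compartments")
  if (any(object@fractions < -1e-9) ||
      abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must be non-negative and sum to 1")
  if (!identical(sort(names(object@bounds)), sort(object@freeParams)))
    msg <- c(msg, "every free parameter needs bounds")
  if (!object@riorder %in% c(0L, 2L))
    msg <- c(msg, "riorder must be 0 or 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BiophysicalModel", function(object) {
  cat(sprintf("BiophysicalModel \"%s\" (RI order %d)\n", object@name,
              object@riorder))
  cat("  compartments:",
      paste(sprintf("%s=%s (f=%.3g)", names(object@compartments),
                    vapply(object@compartments, class, ""),
                    object@fractions[names(object@compartments)]),
            collapse = ", "), "\n")
  cat("  free:", paste(object@freeParams, collapse = ", "), "\n")
  if (length(object@links))
    cat("  linked:", paste(names(object@links), collapse = ", "), "\n")
  if (length(object@fixed))
    cat("  fixed:", paste(sprintf("%s=%g", names(object@fixed),
                                  object@fixed), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Parameter bookkeeping
## ---------------------------------------------------------------------------

.compParamSlots <- function(comp) {
  setdiff(slotNames(class(comp)), character(0))
}

#' Full parameter values of a model
#'
#' Named vector of every parameter: compartment slots, fractions and (for
#' riorder 2) the fODF invariant p2.
#'
#' @param model a [BiophysicalModel-class]
#' @return named numeric vector
#' @export
modelValues <- function(model) {
  vals <- numeric(0)
  for (nm in names(model@compartments)) {
    comp <- model@compartments[[nm]]
    for (s in .compParamSlots(comp))
      vals[paste0(nm, ".", s)] <- slot(comp, s)
  }
  for (nm in names(model@compartments))
    vals[paste0("f.", nm)] <- model@fractions[[nm]]
  if (model@riorder > 0) vals["p2"] <- model@fodf@p2
  vals
}

## Resolve a full value vector from free-parameter values: defaults ->
## fixed -> free -> links -> residual fraction.
.resolveValues <- function(model, free = NULL) {
  vals <- modelValues(model)
  if (length(model@fixed)) vals[names(model@fixed)] <- model@fixed
  if (!is.null(free)) {
    unknown <- setdiff(names(free), names(vals))
    if (length(unknown)) stop("unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    vals[names(free)] <- free
  }
  for (target in names(model@links))
    vals[target] <- model@links[[target]](vals)
  fnames <- paste0("f.", names(model@compartments))
  freeF <- intersect(model@freeParams, fnames)
  derived <- setdiff(fnames, freeF)
  if (length(derived) == 1L) {
    vals[derived] <- 1 - sum(vals[freeF])
  } else if (length(derived) > 1L)
    stop("at most one residual fraction is supported")
  if (any(vals[fnames] < -1e-9) || abs(sum(vals[fnames]) - 1) > 1e-9)
    stop("fraction simplex violated (fractions must be >= 0 and sum to 1)")
  vals
}

#' Free parameters and their bounds
#' @param model a [BiophysicalModel-class]
#' @return data.frame with columns name, lower, upper
#' @export
freeParameters <- function(model) {
  data.frame(name = model@freeParams,
             lower = vapply(model@bounds[model@freeParams], `[`, 0, 1),
             upper = vapply(model@bounds[model@freeParams], `[`, 0, 2),
             row.names = NULL)
}

## ---------------------------------------------------------------------------
## pack / unpack (stick-breaking simplex encoding)
## ---------------------------------------------------------------------------

#' Pack physical parameter values into an unconstrained-bounds vector
#'
#' Non-fraction parameters are passed through unchanged; the free fractions
#' are stick-breaking encoded (z_i = f_i / remaining mass) so each packed
#' coordinate has rectangular bounds [0, 1], which keeps MCMC proposals
#' simple. Inverse of [unpackParameters()].
#'
#' @param model a [BiophysicalModel-class]
#' @param values named numeric vector covering every free parameter (larger
#'   vectors, e.g. from [modelValues()], are subset)
#' @return numeric vector named by \code{freeParams}
#' @export
packParameters <- function(model, values) {
  fnames <- paste0("f.", names(model@compartments))
  out <- numeric(length(model@freeParams))
  names(out) <- model@freeParams
  remaining <- 1
  for (p in model@freeParams) {
    if (p %in% fnames) {
      f <- values[[p]]
      out[p] <- if (remaining > 0) f / remaining else 0
      remaining <- remaining - f
    } else out[p] <- values[[p]]
  }
  bad <- out < .packedLower(model) - 1e-9 | out > .packedUpper(model) + 1e-9
  if (any(bad))
    stop("parameter(s) out of bounds: ",
         paste(model@freeParams[bad], collapse = ", "))
  out
}

#' Unpack a parameter vector into full physical values
#'
#' @param model a [BiophysicalModel-class]
#' @param vec numeric vector in \code{freeParams} order
#' @return full named value vector with links and the residual fraction
#'   resolved
#' @export
unpackParameters <- function(model, vec) {
  if (length(vec) != length(model@freeParams))
    stop("parameter vector length mismatch")
  names(vec) <- model@freeParams
  fnames <- paste0("f.", names(model@compartments))
  free <- numeric(0)
  remaining <- 1
  for (p in model@freeParams) {
    if (p %in% fnames) {
      f <- vec[[p]] * remaining
      free[p] <- f
      remaining <- remaining - f
    } else free[p] <- vec[[p]]
  }
  .resolveValues(model, free)
}

.packedLower <- function(model) {
  fnames <- paste0("f.", names(model@compartments))
  vapply(model@freeParams, function(p)
    if (p %in% fnames) 0 else model@bounds[[p]][1], numeric(1))
}

.packedUpper <- function(model) {
  fnames <- paste0("f.", names(model@compartments))
  vapply(model@freeParams, function(p)
    if (p %in% fnames) 1 else model@bounds[[p]][2], numeric(1))
}

## ---------------------------------------------------------------------------
## Model factory
## ---------------------------------------------------------------------------

#' Construct a named biophysical model
#'
#' Builds one of the supported tissue models with its default compartments,
#' free parameters, links and bounds:
#' \describe{
#' \item{SMT}{Stick + Zeppelin white-matter model on spherical means. Free:
#'   \code{f.intra} (fia), \code{intra.dpara} (shared with the extra-cellular
#'   space by default), \code{extra.dperpFrac}. Option
#'   \code{tortuosity = TRUE} links the perpendicular fraction as
#'   1 - fia; option \code{sharedDpara = FALSE} frees the extra-cellular
#'   parallel diffusivity.}
#' \item{MTE_SMT}{SMT with free compartmental T2 values (multi-TE data).}
#' \item{SANDI}{Sphere (soma) + Stick (neurite) + Iso (extra-cellular);
#'   soma diffusivity fixed at 3 um^2/ms.}
#' \item{SANDIdot}{SANDI plus an immobile-water dot compartment (ex vivo).}
#' \item{MTE_SANDI}{SANDI with free compartmental T2 values.}
#' \item{ExCaliber}{Cylinder (axon) + Zeppelin + dot, for axon diameter
#'   index mapping; parallel diffusivities and the intrinsic diffusivity are
#'   linked by default (\code{equalDpara}). \code{mode = "exvivo"} (default)
#'   sets the isotropic diffusivity to 0 (immobile water), \code{"invivo"}
#'   to 3 um^2/ms (CSF).}
#' \item{SMI}{Stick/Zeppelin kernels + fODF p2 on rotational invariants up
#'   to order 2.}
#' \item{SMIfw}{SMI plus a free-water kernel with fixed d = 3 um^2/ms and
#'   T2 = 2000 ms, and free compartmental T2 values (multi-TE).}
#' }
#'
#' @param name model name (see Details)
#' @param tortuosity SMT only: link D_perp,ec = (1 - fia) D_par,ec
#' @param sharedDpara share the parallel diffusivity across compartments
#'   (SMT/ExCaliber default TRUE)
#' @param mode ExCaliber only: "exvivo" or "invivo"
#' @param daBounds ExCaliber only: bounds for the axon diameter index, um
#' @return a [BiophysicalModel-class]
#' @export
makeModel <- function(name = c("SMT", "MTE_SMT", "SANDI", "SANDIdot",
                               "MTE_SANDI", "ExCaliber", "SMI", "SMIfw"),
                      tortuosity = FALSE, sharedDpara = TRUE,
                      mode = c("exvivo", "invivo"), daBounds = c(0.1, 14)) {
  name <- match.arg(name)
  mode <- match.arg(mode)
  linkEq <- function(src) { force(src); function(v) v[[src]] }

  if (name %in% c("SMT", "MTE_SMT")) {
    comps <- list(intra = new("Stick", dpara = 2, t2 = 0),
                  extra = new("Zeppelin", dpara = 2, dperpFrac = 0.5, t2 = 0))
    free <- c("f.intra", "intra.dpara")
    bounds <- list("f.intra" = c(0, 1), "intra.dpara" = c(1, 3))
    links <- list()
    if (sharedDpara) links[["extra.dpara"]] <- linkEq("intra.dpara")
    else { free <- c(free, "extra.dpara"); bounds[["extra.dpara"]] <- c(1, 3) }
    if (tortuosity) {
      links[["extra.dperpFrac"]] <- function(v) 1 - v[["f.intra"]]
    } else {
      free <- c(free, "extra.dperpFrac")
      bounds[["extra.dperpFrac"]] <- c(0, 1)
    }
    if (name == "MTE_SMT") {
      comps$intra@t2 <- 80; comps$extra@t2 <- 60
      free <- c(free, "intra.t2", "extra.t2")
      bounds[c("intra.t2", "extra.t2")] <- list(c(40, 200), c(40, 200))
    }
    fr <- c(intra = 0.7, extra = 0.3)
    return(new("BiophysicalModel", name = name, compartments = comps,
               fractions = fr, freeParams = free, bounds = bounds,
               links = links, riorder = 0L))
  }

  if (name %in% c("SANDI", "SANDIdot", "MTE_SANDI")) {
    comps <- list(soma = new("Sphere", dis = 3, rs = 5, t2 = 0),
                  neurite = new("Stick", dpara = 2, t2 = 0),
                  ec = new("Iso", d = 1.5, t2 = 0))
    fr <- c(soma = 1 / 3, neurite = 1 / 3, ec = 1 / 3)
    free <- c("f.soma", "f.neurite", "soma.rs", "neurite.dpara", "ec.d")
    bounds <- list("f.soma" = c(0, 1), "f.neurite" = c(0, 1),
                   "soma.rs" = c(2, 12), "neurite.dpara" = c(1.5, 2.5),
                   "ec.d" = c(0.5, 3))
    fixed <- c("soma.dis" = 3)
    if (name == "SANDIdot") {
      comps$dot <- new("Iso", d = 0, t2 = 0)
      fr <- c(soma = 0.25, neurite = 0.25, ec = 0.25, dot = 0.25)
      free <- c("f.soma", "f.neurite", "f.ec", "soma.rs", "neurite.dpara",
                "ec.d")
      bounds[["f.ec"]] <- c(0, 1)
      fixed <- c(fixed, "dot.d" = 0)
    }
    if (name == "MTE_SANDI") {
      for (nm in c("soma", "neurite", "ec")) comps[[nm]]@t2 <- 80
      free <- c(free, "soma.t2", "neurite.t2", "ec.t2")
      bounds[c("soma.t2", "neurite.t2", "ec.t2")] <-
        list(c(40, 200), c(40, 200), c(40, 200))
    }
    return(new("BiophysicalModel", name = name, compartments = comps,
               fractions = fr, freeParams = free, bounds = bounds,
               links = list(), fixed = fixed, riorder = 0L))
  }

  if (name == "ExCaliber") {
    dIso <- if (mode == "exvivo") 0 else 3
    comps <- list(axon = new("Cylinder", da = 2, d0 = 0.6, dpara = 0.6),
                  dot = new("Iso", d = dIso, t2 = 0),
                  extra = new("Zeppelin", dpara = 0.6, dperpFrac = 0.3))
    fr <- c(axon = 0.7, dot = 0.15, extra = 0.15)
    free <- c("f.axon", "f.dot", "axon.da", "axon.dpara", "extra.dperpFrac")
    bounds <- list("f.axon" = c(0, 1), "f.dot" = c(0, 1),
                   "axon.da" = daBounds, "axon.dpara" = c(0.1, 2),
                   "extra.dperpFrac" = c(0, 1))
    links <- list()
    if (sharedDpara) {
      links[["axon.d0"]] <- linkEq("axon.dpara")
      links[["extra.dpara"]] <- linkEq("axon.dpara")
    } else {
      free <- c(free, "axon.d0", "extra.dpara")
      bounds[c("axon.d0", "extra.dpara")] <- list(c(0.1, 2), c(0.1, 2))
    }
    return(new("BiophysicalModel", name = name, compartments = comps,
               fractions = fr, freeParams = free, bounds = bounds,
               links = links, fixed = c("dot.d" = dIso), riorder = 0L))
  }

  ## SMI / SMIfw on rotational invariants
  comps <- list(axon = new("StickKernel", dpara = 2, t2 = 0),
                extra = new("ZeppelinKernel", dpara = 2, dperpFrac = 0.5,
                            t2 = 0))
  fr <- c(axon = 0.5, extra = 0.5)
  free <- c("f.axon", "axon.dpara", "extra.dpara", "extra.dperpFrac", "p2")
  bounds <- list("f.axon" = c(0, 1), "axon.dpara" = c(1, 3),
                 "extra.dpara" = c(1, 3), "extra.dperpFrac" = c(0, 1),
                 "p2" = c(0, 1))
  fixed <- numeric(0)
  if (name == "SMIfw") {
    comps$axon@t2 <- 80; comps$extra@t2 <- 60
    comps$fw <- new("IsoKernel", d = 3, t2 = 2000)
    fr <- c(axon = 0.4, extra = 0.4, fw = 0.2)
    free <- c("f.axon", "f.extra", "axon.dpara", "axon.t2", "extra.dpara",
              "extra.dperpFrac", "extra.t2", "p2")
    bounds <- list("f.axon" = c(0, 1), "f.extra" = c(0, 1),
                   "axon.dpara" = c(1, 3), "axon.t2" = c(40, 200),
                   "extra.dpara" = c(1, 3), "extra.dperpFrac" = c(0, 1),
                   "extra.t2" = c(40, 200), "p2" = c(0, 1))
    fixed <- c("fw.d" = 3, "fw.t2" = 2000)
  }
  new("BiophysicalModel", name = name, compartments = comps, fractions = fr,
      fodf = new("FODF", p2 = 0.5), freeParams = free, bounds = bounds,
      links = list(), fixed = fixed, riorder = 2L)
}

## ---------------------------------------------------------------------------
## Forward prediction
## ---------------------------------------------------------------------------

## Plain-function signal for one compartment given resolved values.
.compSignal <- function(comp, nm, vals, protocol, lorder = 0L, nterms = 20L) {
  g <- function(s) vals[[paste0(nm, ".", s)]]
  relax <- .relaxWeight(g("t2"), protocol@techo)
  b <- protocol@bval
  if (lorder == 0L) {
    relax * switch(class(comp)[1],
      Stick = , StickKernel = .smStick(b, g("dpara")),
      Zeppelin = , ZeppelinKernel =
        .smZeppelin(b, g("dpara"), g("dperpFrac") * g("dpara")),
      Cylinder = .smCylinder(b, g("dpara"), g("d0"), g("da"),
                             protocol@gradient, protocol@tsmalldel,
                             protocol@tdelta, nterms),
      Sphere = .smSphere(b, g("dis"), g("rs"), protocol@gradient,
                         protocol@tsmalldel, protocol@tdelta, nterms),
      Iso = , IsoKernel = .smIso(b, g("d")),
      stop("unsupported compartment class ", class(comp)[1]))
  } else {
    switch(class(comp)[1],
      StickKernel = .kernelIntegral(b, g("dpara"), 0, lorder, relax),
      ZeppelinKernel = .kernelIntegral(b, g("dpara"),
                                       g("dperpFrac") * g("dpara"),
                                       lorder, relax),
      IsoKernel = rep(0, length(b)),
      stop("order-", lorder, " invariants need kernel compartments, not ",
           class(comp)[1]))
  }
}

#' Predict the measurement vector of a biophysical model
#'
#' Computes the fraction-weighted mixture of compartment signals for every
#' record of the protocol. For riorder-2 models, order-0 records are the
#' mixture of K_0 kernels and order-2 records are p2 times the mixture of
#' K_2 kernels. With multi-TE protocols the compartmental T2 weighting makes
#' the raw prediction un-normalised; it is then divided by the predicted
#' b = 0 signal at the earliest TE (\code{normalization = "global"},
#' default), per TE (\code{"perTE"}), or left as is (\code{"none"}). The
#' convention used is recorded in the \code{"normalization"} attribute.
#'
#' @param model a [BiophysicalModel-class]
#' @param protocol an [AcquisitionProtocol-class]
#' @param values optional named vector of free-parameter values overriding
#'   the model's stored values
#' @param nterms GPD series terms
#' @return numeric vector of predicted normalised signals per record
#' @export
modelSignals <- function(model, protocol, values = NULL, nterms = 20L) {
  if (protocol@riorder > model@riorder)
    stop(sprintf("protocol requires RI order %d but model supports %d",
                 protocol@riorder, model@riorder))
  vals <- .resolveValues(model, values)
  nmc <- names(model@compartments)
  fr <- vals[paste0("f.", nmc)]
  out <- numeric(length(protocol@bval))
  orders <- unique(protocol@lorder)
  for (l in orders) {
    idx <- protocol@lorder == l
    sub <- if (length(orders) == 1L) protocol else .subsetProtocol(protocol, idx)
    sig <- 0
    for (i in seq_along(nmc))
      sig <- sig + fr[i] * .compSignal(model@compartments[[i]], nmc[i],
                                       vals, sub, lorder = l,
                                       nterms = nterms)
    if (l > 0) sig <- sig * vals[["p2"]]
    out[idx] <- sig
  }
  norm <- model@normalization
  if (isMultiTE(protocol) && any(vals[grep("\\.t2$", names(vals))] > 0)) {
    t2s <- vals[paste0(nmc, ".t2")]
    w <- function(te) sum(fr * ifelse(t2s > 0, exp(-te / t2s), 1))
    if (norm == "global") {
      out <- out / w(min(protocol@techo, na.rm = TRUE))
    } else if (norm == "perTE") {
      for (te in unique(protocol@techo))
        out[protocol@techo %in% te] <- out[protocol@techo %in% te] / w(te)
    }
  }
  attr(out, "normalization") <- norm
  out
}

.subsetProtocol <- function(p, idx) {
  new("AcquisitionProtocol", bval = p@bval[idx], techo = p@techo[idx],
      tdelta = p@tdelta[idx], tsmalldel = p@tsmalldel[idx],
      gradient = p@gradient[idx], ndirs = p@ndirs[idx],
      lorder = p@lorder[idx], riorder = max(p@lorder[idx]))
}

## Fast closure mapping a packed parameter vector to predicted signals;
## used by the MCMC estimator where the prediction sits in the innermost
## loop. Spherical-mean models get a specialised path that pre-resolves the
## parameter bookkeeping and protocol constants; anything else falls back
## to the generic modelSignals().
.signalPredictor <- function(model, protocol, nterms = 20L) {
  force(model); force(protocol); force(nterms)
  generic <- function(vec)
    modelSignals(model, protocol, values = unpackParameters(model, vec),
                 nterms = nterms)
  classes <- vapply(model@compartments, function(c) class(c)[1], "")
  if (model@riorder != 0L ||
      !all(classes %in% c("Stick", "Zeppelin", "Cylinder", "Sphere", "Iso")) ||
      length(unique(protocol@lorder)) != 1L)
    return(generic)

  nmc <- names(model@compartments)
  template <- .resolveValues(model, NULL)
  vnames <- names(template)
  fnames <- paste0("f.", nmc)
  isF <- model@freeParams %in% fnames
  freeIdx <- match(model@freeParams, vnames)
  fIdx <- match(fnames, vnames)
  derivedF <- setdiff(fnames, model@freeParams)
  derivedIdx <- match(derivedF, vnames)
  freeFidx <- match(intersect(model@freeParams, fnames), vnames)
  links <- model@links
  linkIdx <- match(names(links), vnames)
  b <- protocol@bval; te <- protocol@techo
  G <- protocol@gradient; dl <- protocol@tsmalldel; DL <- protocol@tdelta
  hasTE <- any(!is.na(te))
  pidx <- lapply(nmc, function(nm)
    match(paste0(nm, ".", .compParamSlots(model@compartments[[nm]])),
          vnames) |> stats::setNames(.compParamSlots(model@compartments[[nm]])))
  names(pidx) <- nmc

  function(vec) {
    vals <- template
    ## stick-breaking decode inline
    remaining <- 1
    for (j in seq_along(vec)) {
      if (isF[j]) {
        f <- vec[j] * remaining
        vals[freeIdx[j]] <- f
        remaining <- remaining - f
      } else vals[freeIdx[j]] <- vec[j]
    }
    if (length(derivedIdx))
      vals[derivedIdx] <- 1 - sum(vals[freeFidx])
    for (j in seq_along(links))
      vals[linkIdx[j]] <- links[[j]](vals)
    sig <- 0
    for (i in seq_along(nmc)) {
      ix <- pidx[[i]]
      t2 <- vals[ix[["t2"]]]
      relax <- if (t2 > 0 && hasTE) exp(-te / t2) else 1
      s <- switch(classes[i],
        Stick = .smFactor(b * vals[ix[["dpara"]]]),
        Zeppelin = .smZeppelin(b, vals[ix[["dpara"]]],
                               vals[ix[["dperpFrac"]]] * vals[ix[["dpara"]]]),
        Cylinder = .smCylinder(b, vals[ix[["dpara"]]], vals[ix[["d0"]]],
                               vals[ix[["da"]]], G, dl, DL, nterms),
        Sphere = .smSphere(b, vals[ix[["dis"]]], vals[ix[["rs"]]],
                           G, dl, DL, nterms),
        Iso = .smIso(b, vals[ix[["d"]]]))
      sig <- sig + vals[fIdx[i]] * relax * s
    }
    if (hasTE && isMultiTE(protocol) &&
        model@normalization != "none") {
      t2s <- vapply(pidx, function(ix) vals[ix[["t2"]]], 0)
      fr <- vals[fIdx]
      if (model@normalization == "global") {
        temin <- min(te, na.rm = TRUE)
        sig <- sig / sum(fr * ifelse(t2s > 0, exp(-temin / t2s), 1))
      } else {
        for (tt in unique(te))
          sig[te %in% tt] <- sig[te %in% tt] /
            sum(fr * ifelse(t2s > 0, exp(-tt / t2s), 1))
      }
    }
    sig
  }
}
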