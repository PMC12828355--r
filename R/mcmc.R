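## ---------------------------------------------------------------------------
## Metropolis-Hastings posterior sampling
## ---------------------------------------------------------------------------

#' MCMC sampler settings
#'
#' @slot params names of the free parameters to sample
#' @slot nsamples total number of draws
#' @slot burnin draws discarded from the front for summaries
#' @slot thinning keep every \code{thinning}-th draw for summaries
#' @slot proposal named Gaussian proposal std per sampled parameter (in
#'   packed-coordinate units); empty = 5% of the prior width
#' @slot start named numeric starting point, or empty for a random start
#'   drawn uniformly within the prior bounds
#' @export
setClass("Sampler",
  representation(params = "character", nsamples = "integer",
                 burnin = "integer", thinning = "integer",
                 proposal = "numeric", start = "numeric"))

setValidity("Sampler", function(object) {
  msg <- character(0)
  if (object@burnin >= object@nsamples)
    msg <- c(msg, "burnin must be smaller than nsamples")
  if (length(object@proposal) && any(object@proposal <= 0))
    msg <- c(msg, "proposal std must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a Sampler
#'
#' Defaults: 20,000 draws, 1,000 burn-in, thinning 100 for summaries, and
#' per-parameter proposal std equal to 5% of the prior width. The MCMC prior
#' is uniform within the model's parameter bounds.
#'
#' @param params character vector of free-parameter names to sample
#' @param nsamples,burnin,thinning chain settings
#' @param proposal optional named proposal std per parameter
#' @param start optional named starting values
#' @export
sampler <- function(params, nsamples = 20000, burnin = 1000, thinning = 100,
                    proposal = numeric(0), start = numeric(0)) {
  new("Sampler", params = params, nsamples = as.integer(nsamples),
      burnin = as.integer(burnin), thinning = as.integer(thinning),
      proposal = proposal, start = start)
}

#' Gaussian noise model for the MCMC likelihood
#'
#' @slot sigma noise std (initial value when sampled)
#' @slot sampled sample sigma jointly with the tissue parameters?
#' @slot bounds uniform prior bounds for sigma when sampled
#' @slot proposal Gaussian proposal std for sigma
#' @export
setClass("Noisemodel",
  representation(sigma = "numeric", sampled = "logical", bounds = "numeric",
                 proposal = "numeric"),
  prototype(sigma = 0.01, sampled = TRUE, bounds = c(1e-4, 0.2),
            proposal = 0.002))

setValidity("Noisemodel", function(object) {
  if (object@sigma <= 0) return("sigma must be > 0")
  if (object@bounds[1] <= 0 || object@bounds[2] <= object@bounds[1])
    return("sigma bounds must be increasing and positive")
  TRUE
})

#' Construct a Noisemodel
#' @param sigma noise level (std of Gaussian noise on normalised signals)
#' @param sampled if TRUE (default), sigma is sampled with a uniform prior
#' @param bounds prior bounds for sigma
#' @param proposal proposal std for sigma
#' @export
noisemodel <- function(sigma = 0.01, sampled = TRUE, bounds = c(1e-4, 0.2),
                       proposal = 0.002) {
  new("Noisemodel", sigma = sigma, sampled = sampled, bounds = bounds,
      proposal = proposal)
}

#' MCMC chain record
#'
#' @slot draws nsamples x nparams matrix of parameter draws (packed
#'   coordinates; fraction parameters are stick-breaking coordinates)
#' @slot logp log-likelihood of each draw
#' @slot accepted acceptance flag per iteration
#' @slot params sampled parameter names (plus "sigma" when sampled)
#' @slot stage stage label
#' @slot burnin,thinning summary defaults carried from the sampler
#' @export
setClass("Chain",
  representation(draws = "matrix", logp = "numeric", accepted = "logical",
                 params = "character", stage = "character",
                 burnin = "integer", thinning = "integer"))

setMethod("show", "Chain", function(object) {
  cat(sprintf("Chain [%s]: %d draws x %d params, acceptance %.1f%%\n",
              object@stage, nrow(object@draws), ncol(object@draws),
              100 * mean(object@accepted)))
})

#' Gaussian log-likelihood
#'
#' \eqn{-n/2 \log(2\pi\sigma^2) - \sum (y - \hat y)^2 / (2\sigma^2)}
#'
#' @param meas measured signals
#' @param pred predicted signals (same length)
#' @param sigma noise std (> 0)
#' @export
logLikelihoodGaussian <- function(meas, pred, sigma) {
  if (length(meas) != length(pred)) stop("meas and pred lengths differ")
  if (sigma <= 0) stop("sigma must be > 0")
  n <- length(meas)
  -n / 2 * log(2 * pi * sigma^2) - sum((meas - pred)^2) / (2 * sigma^2)
}

## ---------------------------------------------------------------------------
## Metropolis-Hastings core
## ---------------------------------------------------------------------------

#' Metropolis-Hastings sampling of a biophysical model posterior
#'
#' Samples the requested free parameters (in packed coordinates: fractions
#' are stick-breaking encoded with bounds [0, 1]) with symmetric Gaussian
#' proposals and uniform priors within the model bounds. Out-of-bounds
#' proposals are rejected. Non-sampled free parameters are held at
#' \code{fixedValues} (or the model defaults). The noise sigma is sampled
#' jointly when the noise model says so.
#'
#' @param model a [BiophysicalModel-class]
#' @param meas measurement vector matching the protocol
#' @param protocol an [AcquisitionProtocol-class]
#' @param smplr a [Sampler-class]
#' @param noise a [Noisemodel-class]
#' @param fixedValues named packed values for non-sampled free parameters
#' @param seed integer seed for reproducibility (NULL = current RNG state)
#' @param stage label stored in the chain
#' @return a [Chain-class]
#' @export
mhSample <- function(model, meas, protocol, smplr, noise = noisemodel(),
                     fixedValues = numeric(0), seed = NULL,
                     stage = "stage1") {
  if (!is.null(seed)) set.seed(seed)
  pnames <- model@freeParams
  if (!all(smplr@params %in% pnames))
    stop("sampler parameters must be free parameters of the model")
  if (length(meas) != length(protocol))
    stop("measurement length does not match the protocol")
  lower <- .packedLower(model); upper <- .packedUpper(model)
  theta <- packParameters(model, modelValues(model))
  if (length(fixedValues)) theta[names(fixedValues)] <- fixedValues
  sidx <- match(smplr@params, pnames)
  ## initial point
  if (length(smplr@start)) {
    theta[names(smplr@start)] <- smplr@start
  } else {
    theta[sidx] <- lower[sidx] + stats::runif(length(sidx)) *
      (upper[sidx] - lower[sidx])
  }
  prop <- if (length(smplr@proposal)) smplr@proposal[smplr@params]
          else 0.05 * (upper[sidx] - lower[sidx])
  sigma <- noise@sigma
  predict <- .signalPredictor(model, protocol)

  k <- length(sidx) + as.integer(noise@sampled)
  draws <- matrix(NA_real_, smplr@nsamples, k)
  cn <- c(smplr@params, if (noise@sampled) "sigma")
  colnames(draws) <- cn
  logp <- numeric(smplr@nsamples)
  accepted <- logical(smplr@nsamples)

  pred <- predict(theta)
  ll <- logLikelihoodGaussian(meas, pred, sigma)
  for (it in seq_len(smplr@nsamples)) {
    cand <- theta
    cand[sidx] <- theta[sidx] + stats::rnorm(length(sidx), 0, prop)
    csig <- if (noise@sampled)
      sigma + stats::rnorm(1, 0, noise@proposal) else sigma
    inb <- all(cand[sidx] >= lower[sidx]) && all(cand[sidx] <= upper[sidx]) &&
      (!noise@sampled || (csig >= noise@bounds[1] && csig <= noise@bounds[2]))
    if (inb) {
      cll <- logLikelihoodGaussian(meas, predict(cand), csig)
      if (is.finite(cll) && log(stats::runif(1)) < cll - ll) {
        theta <- cand; sigma <- csig; ll <- cll
        accepted[it] <- TRUE
      }
    }
    draws[it, ] <- c(theta[sidx], if (noise@sampled) sigma)
    logp[it] <- ll
  }
  if (!any(accepted[-seq_len(smplr@burnin)]))
    warning(sprintf(
      "no proposals accepted after burn-in (overall acceptance %.2f%%); consider smaller proposal std",
      100 * mean(accepted)))
  new("Chain", draws = draws, logp = logp, accepted = accepted,
      params = cn, stage = stage, burnin = smplr@burnin,
      thinning = smplr@thinning)
}

#' Posterior mean and std from a chain
#'
#' Moments are computed over post-burn-in, thinned draws.
#'
#' @param chain a [Chain-class]
#' @param burnin,thinning override the sampler's settings
#' @return data.frame with columns param, mean, std
#' @export
posteriorSummary <- function(chain, burnin = chain@burnin,
                             thinning = chain@thinning) {
  n <- nrow(chain@draws)
  if (burnin >= n) stop("burnin exceeds chain length")
  keep <- seq(burnin + 1L, n, by = max(1L, thinning))
  sub <- chain@draws[keep, , drop = FALSE]
  data.frame(param = chain@params,
             mean = colMeans(sub),
             std = apply(sub, 2, stats::sd),
             row.names = NULL)
}

#' Two-stage MCMC fitting
#'
#' Runs a first chain over all of \code{stage1}'s parameters, fixes the
#' parameters dropped by \code{stage2} at their stage-1 posterior means, and
#' re-samples the remaining parameters. Fixing the weakly coupled
#' diffusivities after stage 1 sharpens the posterior of the restricted
#' geometry parameters (axon diameter index, fractions).
#'
#' @param model a [BiophysicalModel-class]
#' @param meas measurement vector
#' @param protocol an [AcquisitionProtocol-class]
#' @param stage1,stage2 [Sampler-class] settings; stage2 parameters must be
#'   a subset of stage1's
#' @param noise a [Noisemodel-class]
#' @param seed integer seed
#' @return list(stage1 = Chain, stage2 = Chain, summary = data.frame with
#'   per-stage posterior mean/std)
#' @export
twoStageFit <- function(model, meas, protocol, stage1, stage2,
                        noise = noisemodel(), seed = NULL) {
  if (!all(stage2@params %in% stage1@params))
    stop("stage2 parameters must be a subset of stage1 parameters")
  c1 <- mhSample(model, meas, protocol, stage1, noise, seed = seed,
                 stage = "stage1")
  s1 <- posteriorSummary(c1)
  dropped <- setdiff(stage1@params, stage2@params)
  fixed <- stats::setNames(s1$mean[match(dropped, s1$param)], dropped)
  c2 <- mhSample(model, meas, protocol, stage2, noise, fixedValues = fixed,
                 seed = if (is.null(seed)) NULL else seed + 1L,
                 stage = "stage2")
  s2 <- posteriorSummary(c2)
  s1$stage <- "stage1"; s2$stage <- "stage2"
  list(stage1 = c1, stage2 = c2, summary = rbind(s1, s2))
}

## ---------------------------------------------------------------------------
## Chain diagnostics: split-Rhat and effective sample size
## ---------------------------------------------------------------------------

#' Split-Rhat and effective sample size
#'
#' Computes the rank-normalised split-Rhat convergence diagnostic and an
#' autocorrelation-based effective sample size per parameter, from one or
#' more chains.
#'
#' @param chains a [Chain-class], a list of chains, or a list of draw
#'   matrices with matching columns
#' @param burnin draws discarded from each chain first
#' @return data.frame with columns param, rhat, ess
#' @export
chainDiagnostics <- function(chains, burnin = 0L) {
  if (is(chains, "Chain")) chains <- list(chains)
  mats <- lapply(chains, function(ch)
    if (is(ch, "Chain")) ch@draws else as.matrix(ch))
  mats <- lapply(mats, function(m) {
    if (burnin >= nrow(m)) stop("burnin exceeds chain length")
    if (burnin > 0L) m <- m[-seq_len(burnin), , drop = FALSE]
    m
  })
  n <- min(vapply(mats, nrow, 0L))
  if (n < 4L) stop("need at least 4 post-burn-in draws per chain")
  params <- colnames(mats[[1]])
  if (is.null(params)) params <- paste0("par", seq_len(ncol(mats[[1]])))
  res <- lapply(seq_along(params), function(j) {
    ## split each chain in half
    halves <- unlist(lapply(mats, function(m) {
      x <- m[seq_len(n), j]
      h <- n %/% 2L
      list(x[seq_len(h)], x[(n - h + 1L):n])
    }), recursive = FALSE)
    c(rhat = .splitRhat(halves), ess = .essAcf(halves))
  })
  data.frame(param = params,
             rhat = vapply(res, `[[`, 0, "rhat"),
             ess = vapply(res, `[[`, 0, "ess"), row.names = NULL)
}

## rank-normalised split-Rhat over a list of (half-)chains
.splitRhat <- function(halves) {
  allx <- unlist(halves)
  if (stats::sd(allx) == 0) return(1)
  r <- rank(allx, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(allx) + 1 / 4))
  zs <- split(z, rep(seq_along(halves), lengths(halves)))
  n <- min(lengths(zs))
  m <- length(zs)
  means <- vapply(zs, mean, 0)
  vars <- vapply(zs, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## ESS via mean autocorrelation with Geyer-style truncation at the first
## negative paired sum
.essAcf <- function(halves) {
  n <- min(lengths(halves))
  m <- length(halves)
  maxlag <- min(n - 2L, 200L)
  acfs <- vapply(halves, function(x) {
    if (stats::sd(x) == 0) return(rep(0, maxlag + 1))
    stats::acf(x[seq_len(n)], lag.max = maxlag, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  }, numeric(maxlag + 1))
  rho <- rowMeans(acfs)
  s <- 0
  t <- 1
  while (t + 1 <= maxlag) {
    pair <- rho[t + 1] + rho[t + 2]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  m * n / (1 + 2 * s)
}

## ---------------------------------------------------------------------------
## Voxelwise map fitting
## ---------------------------------------------------------------------------

#' Voxelwise MCMC parameter maps
#'
#' Runs an independent MCMC fit in every voxel of the mask and returns
#' posterior mean and std maps per sampled parameter. Per-voxel seeds are
#' derived deterministically from \code{seed} and the voxel index, so
#' results are bit-identical for any thread count. Per-voxel failures are
#' recorded in the QC volume rather than aborting.
#'
#' @param volumes a [VolumeSeries-class] of shell measurements (typically
#'   normalised spherical means)
#' @param mask logical 3D array of voxels to fit
#' @param model a [BiophysicalModel-class]
#' @param protocol matching [AcquisitionProtocol-class]
#' @param smplr a [Sampler-class]
#' @param noise a [Noisemodel-class]
#' @param nthreads number of worker processes
#' @param seed base seed
#' @param twoStage optional [Sampler-class]; when given, each voxel is fit
#'   with [twoStageFit()] using this as the stage-2 sampler
#' @return list(mean, std: named lists of 3D arrays; qc: 3D array with 0 =
#'   ok, 1 = failed, NA = outside mask)
#' @export
fitMaps <- function(volumes, mask, model, protocol, smplr,
                    noise = noisemodel(), nthreads = 1L, seed = 1L,
                    twoStage = NULL) {
  stopifnot(is(volumes, "VolumeSeries"))
  d3 <- dim(volumes@data)[1:3]
  vox <- which(mask)
  if (!length(vox)) stop("mask is empty")
  set.seed(seed)
  voxSeeds <- sample.int(.Machine$integer.max - 1L, length(vox))
  flat <- matrix(volumes@data, nrow = prod(d3))
  fit1 <- function(i) {
    meas <- flat[vox[i], ]
    tryCatch({
      if (is.null(twoStage)) {
        ch <- mhSample(model, meas, protocol, smplr, noise,
                       seed = voxSeeds[i])
        s <- posteriorSummary(ch)
      } else {
        s <- twoStageFit(model, meas, protocol, smplr, twoStage, noise,
                         seed = voxSeeds[i])$summary
        s <- s[s$stage == "stage2", ]
      }
      list(ok = TRUE, params = s$param, mean = s$mean, std = s$std)
    }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
  }
  res <- if (nthreads > 1L)
    parallel::mclapply(seq_along(vox), fit1, mc.cores = nthreads)
  else lapply(seq_along(vox), fit1)

  ok <- vapply(res, function(r) isTRUE(r$ok), TRUE)
  if (!any(ok)) stop("all voxel fits failed: ", res[[1]]$msg)
  pnames <- res[[which(ok)[1]]]$params
  mkvol <- function() array(NA_real_, d3)
  means <- stats::setNames(replicate(length(pnames), mkvol(),
                                     simplify = FALSE), pnames)
  stds <- stats::setNames(replicate(length(pnames), mkvol(),
                                    simplify = FALSE), pnames)
  qc <- array(NA_real_, d3)
  for (i in seq_along(vox)) {
    qc[vox[i]] <- as.numeric(!ok[i])
    if (!ok[i]) next
    for (k in seq_along(pnames)) {
      means[[k]][vox[i]] <- res[[i]]$mean[k]
      stds[[k]][vox[i]] <- res[[i]]$std[k]
    }
  }
  list(mean = means, std = stds, qc = qc)
}
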