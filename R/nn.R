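## ---------------------------------------------------------------------------
## Monte-Carlo-dropout MLP estimator: training-set synthesis, training,
## stochastic inference, and evaluation
## ---------------------------------------------------------------------------

#' Prior specification for training-set synthesis
#'
#' Named list of per-parameter distributions used to draw tissue parameters
#' when synthesising training data. Supported entries:
#' \code{priorUniform(lo, hi)}, \code{priorGaussian(mean, sd, lo, hi)}
#' (truncated), and a single \code{priorDirichlet(alpha)} under the name
#' \code{"fractions"} for the compartment-fraction simplex.
#'
#' @slot specs named list of prior descriptors
#' @export
setClass("PriorSpec", representation(specs = "list"))

setValidity("PriorSpec", function(object) {
  msg <- character(0)
  for (nm in names(object@specs)) {
    p <- object@specs[[nm]]
    if (p$dist == "dirichlet" && any(p$alpha <= 0))
      msg <- c(msg, "Dirichlet concentrations must be > 0")
    if (p$dist %in% c("uniform", "gaussian") && p$lo >= p$hi)
      msg <- c(msg, sprintf("prior for '%s' needs lo < hi", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname PriorSpec-class
#' @export
priorUniform <- function(lo, hi) list(dist = "uniform", lo = lo, hi = hi)

#' @rdname PriorSpec-class
#' @param mean,sd Gaussian location and scale before truncation to [lo, hi]
#' @param lo,hi support bounds
#' @export
priorGaussian <- function(mean, sd, lo, hi)
  list(dist = "gaussian", mean = mean, sd = sd, lo = lo, hi = hi)

#' @rdname PriorSpec-class
#' @param alpha Dirichlet concentration parameters (one per compartment)
#' @export
priorDirichlet <- function(alpha) list(dist = "dirichlet", alpha = alpha)

#' @rdname PriorSpec-class
#' @param ... named prior descriptors
#' @export
priorSpec <- function(...) new("PriorSpec", specs = list(...))

#' Default priors of a model
#'
#' Uniform over the model bounds for each non-fraction free parameter, and a
#' flat Dirichlet over the compartment fractions.
#'
#' @param model a [BiophysicalModel-class]
#' @return a [PriorSpec-class]
#' @export
defaultPriors <- function(model) {
  fnames <- paste0("f.", names(model@compartments))
  specs <- list()
  for (p in setdiff(model@freeParams, fnames))
    specs[[p]] <- priorUniform(model@bounds[[p]][1], model@bounds[[p]][2])
  specs[["fractions"]] <- priorDirichlet(rep(1, length(model@compartments)))
  new("PriorSpec", specs = specs)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

## ---------------------------------------------------------------------------
## Training-set synthesis
## ---------------------------------------------------------------------------

#' Synthesise a supervised training set from the forward model
#'
#' Draws tissue parameters from the priors, predicts normalised signals
#' with the forward model, and adds Gaussian noise: per shell,
#' sigma = 1 / (SNR sqrt(ndirs)) when an SNR is given (the noise std of a
#' direction-averaged measurement), or a user-supplied sigma.
#'
#' @param model a [BiophysicalModel-class]
#' @param protocol an [AcquisitionProtocol-class]
#' @param priors a [PriorSpec-class] (default: [defaultPriors()])
#' @param n number of samples
#' @param snr b = 0 SNR of a single direction; the per-shell noise std is
#'   1/(snr * sqrt(ndirs)). Use \code{sigma} for a direct noise std.
#' @param sigma noise std applied to every shell (overrides \code{snr});
#'   0 gives noise-free signals
#' @param seed integer seed
#' @return list(params = n x P matrix of free-parameter values, signals =
#'   n x M matrix of noisy measurements, clean = noise-free signals)
#' @export
generateTrainingSet <- function(model, protocol, priors = defaultPriors(model),
                                n, snr = NULL, sigma = NULL, seed = 1L) {
  set.seed(seed)
  fnames <- paste0("f.", names(model@compartments))
  freeF <- intersect(model@freeParams, fnames)
  other <- setdiff(model@freeParams, fnames)
  specs <- priors@specs
  missing <- setdiff(other, names(specs))
  if (length(missing))
    stop("priors missing for: ", paste(missing, collapse = ", "))
  draws <- matrix(NA_real_, n, length(model@freeParams),
                  dimnames = list(NULL, model@freeParams))
  for (p in other) {
    s <- specs[[p]]
    bl <- model@bounds[[p]]
    if (s$dist != "dirichlet" && (s$lo < bl[1] - 1e-9 || s$hi > bl[2] + 1e-9))
      stop(sprintf("prior support of '%s' exceeds its bounds", p))
    draws[, p] <- switch(s$dist,
      uniform = stats::runif(n, s$lo, s$hi),
      gaussian = .rtruncnorm(n, s$mean, s$sd, s$lo, s$hi),
      stop("unsupported prior '", s$dist, "' for ", p))
  }
  if (length(freeF)) {
    dir <- specs[["fractions"]]
    if (is.null(dir)) stop("priors must include a 'fractions' block")
    fr <- .rdirichlet(n, dir$alpha)
    colnames(fr) <- fnames
    draws[, freeF] <- fr[, freeF]
  }
  clean <- .bulkSignals(model, protocol, draws)
  if (!is.null(sigma)) {
    sdshell <- rep(sigma, length(protocol))
  } else if (!is.null(snr)) {
    sdshell <- 1 / (snr * sqrt(protocol@ndirs))
  } else stop("provide either snr or sigma")
  noisy <- clean + matrix(stats::rnorm(length(clean)), nrow(clean)) *
    matrix(sdshell, n, length(sdshell), byrow = TRUE)
  list(params = draws, signals = noisy, clean = clean)
}

## Vectorised forward prediction over a matrix of free-parameter draws.
## Closed-form compartments are evaluated for all samples at once; GPD and
## kernel compartments fall back to a per-sample loop.
.bulkSignals <- function(model, protocol, draws) {
  n <- nrow(draws)
  M <- length(protocol)
  template <- .resolveValues(model, draws[1, ])
  vals <- matrix(NA_real_, n, length(template),
                 dimnames = list(NULL, names(template)))
  for (i in seq_len(n))
    vals[i, ] <- .resolveValues(model, draws[i, ])
  nmc <- names(model@compartments)
  classes <- vapply(model@compartments, function(c) class(c)[1], "")
  fastOK <- model@riorder == 0L &&
    all(classes %in% c("Stick", "Zeppelin", "Iso"))
  if (!fastOK) {
    out <- matrix(NA_real_, n, M)
    for (i in seq_len(n))
      out[i, ] <- modelSignals(model, protocol, values = vals[i, ])
    return(out)
  }
  b <- protocol@bval
  relaxM <- function(t2v) {
    te <- protocol@techo
    if (all(is.na(te))) return(matrix(1, n, M))
    w <- matrix(1, n, M)
    pos <- t2v > 0
    ok <- !is.na(te)
    if (any(pos) && any(ok))
      w[pos, ok] <- exp(-outer(1 / t2v[pos], te[ok]))
    w
  }
  sig <- matrix(0, n, M)
  for (i in seq_along(nmc)) {
    nm <- nmc[i]
    f <- vals[, paste0("f.", nm)]
    s <- switch(classes[i],
      Stick = .smFactor(outer(vals[, paste0(nm, ".dpara")], b)),
      Zeppelin = {
        dpa <- vals[, paste0(nm, ".dpara")]
        dpe <- vals[, paste0(nm, ".dperpFrac")] * dpa
        exp(-outer(dpe, b)) * .smFactor(outer(dpa - dpe, b))
      },
      Iso = exp(-outer(vals[, paste0(nm, ".d")], b)))
    sig <- sig + f * s * relaxM(vals[, paste0(nm, ".t2")])
  }
  if (isMultiTE(protocol) && any(vals[, grep("\\.t2$", colnames(vals))] > 0)) {
    t2m <- vals[, paste0(nmc, ".t2"), drop = FALSE]
    frm <- vals[, paste0("f.", nmc), drop = FALSE]
    temin <- min(protocol@techo, na.rm = TRUE)
    w0 <- rowSums(frm * ifelse(t2m > 0, exp(-temin / t2m), 1))
    sig <- sig / w0
  }
  sig
}

## ---------------------------------------------------------------------------
## Network / training configuration
## ---------------------------------------------------------------------------

#' MLP architecture and synthesis settings
#'
#' @slot model the [BiophysicalModel-class] to be estimated
#' @slot protocol the [AcquisitionProtocol-class] of the measurements
#' @slot hidden hidden layer sizes (default 3 x 48)
#' @slot dropout dropout rate after each hidden layer, in (0, 1)
#' @slot nsamples training-set size
#' @slot snr noise level for training-set synthesis (b = 0 SNR per
#'   direction); NA when \code{sigma} is used instead
#' @slot sigma direct noise std (NA when \code{snr} is used)
#' @slot seed synthesis/initialisation seed
#' @export
setClass("NetworkArg",
  representation(model = "BiophysicalModel", protocol = "AcquisitionProtocol",
                 hidden = "integer", dropout = "numeric",
                 nsamples = "integer", snr = "numeric", sigma = "numeric",
                 seed = "integer"),
  prototype(hidden = c(48L, 48L, 48L), dropout = 0.1, nsamples = 30000L,
            snr = NA_real_, sigma = NA_real_, seed = 1L))

setValidity("NetworkArg", function(object) {
  if (object@dropout <= 0 || object@dropout >= 1)
    return("dropout must be in (0, 1)")
  if (object@nsamples < 1) return("nsamples must be >= 1")
  TRUE
})

#' @rdname NetworkArg-class
#' @param model,protocol,hidden,dropout,nsamples,snr,sigma,seed see slots
#' @export
networkArg <- function(model, protocol, hidden = c(48, 48, 48),
                       dropout = 0.1, nsamples = 30000, snr = NA,
                       sigma = NA, seed = 1) {
  new("NetworkArg", model = model, protocol = protocol,
      hidden = as.integer(hidden), dropout = dropout,
      nsamples = as.integer(nsamples), snr = as.numeric(snr),
      sigma = as.numeric(sigma), seed = as.integer(seed))
}

#' MLP training options
#'
#' @slot epochs maximum training epochs
#' @slot batchsize minibatch size
#' @slot lr Adam learning rate
#' @slot split train fraction of the train/validation split, in (0, 1)
#' @slot loss "rmse" or "mse" over min-max-scaled parameters
#' @slot patience early-stopping patience (epochs without validation
#'   improvement)
#' @export
setClass("TrainingArg",
  representation(epochs = "integer", batchsize = "integer", lr = "numeric",
                 split = "numeric", loss = "character",
                 patience = "integer"),
  prototype(epochs = 200L, batchsize = 128L, lr = 1e-3, split = 0.8,
            loss = "rmse", patience = 30L))

setValidity("TrainingArg", function(object) {
  if (object@split <= 0 || object@split >= 1)
    return("split must be in (0, 1)")
  if (!object@loss %in% c("rmse", "mse")) return("loss must be rmse or mse")
  TRUE
})

#' @rdname TrainingArg-class
#' @param epochs,batchsize,lr,split,loss,patience see slots
#' @export
trainingArg <- function(epochs = 200, batchsize = 128, lr = 1e-3,
                        split = 0.8, loss = "rmse", patience = 30) {
  new("TrainingArg", epochs = as.integer(epochs),
      batchsize = as.integer(batchsize), lr = lr, split = split,
      loss = loss, patience = as.integer(patience))
}

#' Trained MC-dropout estimator
#'
#' @slot weights list of layer weight matrices and bias vectors
#' @slot dropout dropout rate (active at inference for MC dropout)
#' @slot paramNames names of the predicted parameters
#' @slot scaleLo,scaleHi per-parameter min-max scaling bounds
#' @slot inputDim expected measurement dimension
#' @slot valloss best validation loss reached
#' @slot provenance list with the priors, protocol, and seeds used
#' @export
setClass("TrainedEstimator",
  representation(weights = "list", dropout = "numeric",
                 paramNames = "character", scaleLo = "numeric",
                 scaleHi = "numeric", inputDim = "integer",
                 valloss = "numeric", provenance = "list"))

setMethod("show", "TrainedEstimator", function(object) {
  sizes <- vapply(object@weights, function(l) ncol(l$W), 0L)
  cat(sprintf("TrainedEstimator: %d -> %s (dropout %.2f), val loss %.4g\n",
              object@inputDim, paste(sizes, collapse = " -> "),
              object@dropout, object@valloss))
  cat("  parameters:", paste(object@paramNames, collapse = ", "), "\n")
})

#' Recommended number of training samples
#'
#' The heuristic for small MLPs: training samples = factor x number of
#' network parameters (weights + biases), with the factor between 10 and
#' 100 (default 50).
#'
#' @param netarg a [NetworkArg-class]
#' @param factor samples-per-weight factor; values outside [10, 100] warn
#' @return integer sample count
#' @export
recommendNSamples <- function(netarg, factor = 50) {
  if (factor < 10 || factor > 100)
    warning("factor outside the recommended range [10, 100]")
  dims <- c(length(netarg@protocol), netarg@hidden,
            length(netarg@model@freeParams))
  nw <- sum(dims[-length(dims)] * dims[-1] + dims[-1])
  as.integer(round(factor * nw))
}

## ---------------------------------------------------------------------------
## MLP internals (ReLU, inverted dropout, Adam)
## ---------------------------------------------------------------------------

.mlpInit <- function(dims) {
  lapply(seq_len(length(dims) - 1), function(i) {
    list(W = matrix(stats::rnorm(dims[i] * dims[i + 1],
                                 sd = sqrt(2 / dims[i])),
                    dims[i], dims[i + 1]),
         b = rep(0, dims[i + 1]))
  })
}

## Forward pass; dropout masks applied after each hidden ReLU (inverted
## dropout, so expectations match between train and plain inference).
.mlpForward <- function(X, layers, dropout, stochastic) {
  L <- length(layers)
  acts <- vector("list", L + 1)
  masks <- vector("list", L)
  acts[[1]] <- X
  for (i in seq_len(L)) {
    Z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    if (i < L) {
      A <- pmax(Z, 0)
      if (stochastic && dropout > 0) {
        m <- matrix(stats::runif(length(A)) > dropout, nrow(A)) / (1 - dropout)
        A <- A * m
        masks[[i]] <- m
      }
      acts[[i + 1]] <- A
    } else acts[[i + 1]] <- Z
  }
  list(out = acts[[L + 1]], acts = acts, masks = masks)
}

.mlpGrad <- function(fw, layers, Y, loss) {
  L <- length(layers)
  Yhat <- fw$out
  n <- length(Y)
  if (loss == "rmse") {
    r <- sqrt(mean((Yhat - Y)^2))
    delta <- (Yhat - Y) / (n * max(r, 1e-12))
  } else delta <- 2 * (Yhat - Y) / n
  grads <- vector("list", L)
  for (i in L:1) {
    A <- fw$acts[[i]]
    grads[[i]] <- list(W = crossprod(A, delta), b = colSums(delta))
    if (i > 1) {
      delta <- delta %*% t(layers[[i]]$W)
      if (!is.null(fw$masks[[i - 1]])) delta <- delta * fw$masks[[i - 1]]
      delta <- delta * (fw$acts[[i]] > 0)
    }
  }
  grads
}

.lossValue <- function(Yhat, Y, loss) {
  mse <- mean((Yhat - Y)^2)
  if (loss == "rmse") sqrt(mse) else mse
}

#' Train an MC-dropout MLP estimator
#'
#' Synthesises a training set from the forward model (unless one is given),
#' min-max scales the target parameters to [0, 1], and trains an MLP with
#' ReLU activations, dropout after each hidden layer, and Adam, minimising
#' the RMSE (default) over all scaled parameters. Early stopping monitors
#' the validation loss. Deterministic for a given seed.
#'
#' @param netarg a [NetworkArg-class]
#' @param trainarg a [TrainingArg-class]
#' @param data optional list(params, signals) from [generateTrainingSet()];
#'   synthesised from \code{netarg} when NULL
#' @param priors [PriorSpec-class] used when synthesising (and recorded as
#'   provenance)
#' @param verbose print per-epoch losses
#' @return a [TrainedEstimator-class]
#' @export
trainEstimator <- function(netarg, trainarg = trainingArg(), data = NULL,
                           priors = defaultPriors(netarg@model),
                           verbose = FALSE) {
  model <- netarg@model
  if (is.null(data))
    data <- generateTrainingSet(model, netarg@protocol, priors,
                                n = netarg@nsamples,
                                snr = if (is.na(netarg@snr)) NULL else netarg@snr,
                                sigma = if (is.na(netarg@sigma)) NULL else netarg@sigma,
                                seed = netarg@seed)
  X <- data$signals
  pn <- colnames(data$params)
  lo <- vapply(model@bounds[pn], `[`, 0, 1)
  hi <- vapply(model@bounds[pn], `[`, 0, 2)
  Y <- sweep(sweep(data$params, 2, lo, "-"), 2, hi - lo, "/")
  n <- nrow(X)
  set.seed(netarg@seed + 1L)
  idx <- sample.int(n)
  ntr <- floor(trainarg@split * n)
  tr <- idx[seq_len(ntr)]; va <- idx[-seq_len(ntr)]
  if (!length(va)) stop("validation split is empty")

  dims <- c(ncol(X), netarg@hidden, ncol(Y))
  layers <- .mlpInit(dims)
  mom <- lapply(layers, function(l)
    list(mW = 0 * l$W, vW = 0 * l$W, mb = 0 * l$b, vb = 0 * l$b))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0
  best <- Inf; bestLayers <- layers; wait <- 0
  for (ep in seq_len(trainarg@epochs)) {
    ord <- sample(tr)
    for (s in seq(1, length(ord), by = trainarg@batchsize)) {
      bi <- ord[s:min(s + trainarg@batchsize - 1, length(ord))]
      fw <- .mlpForward(X[bi, , drop = FALSE], layers, netarg@dropout, TRUE)
      gr <- .mlpGrad(fw, layers, Y[bi, , drop = FALSE], trainarg@loss)
      t <- t + 1
      for (i in seq_along(layers)) {
        m <- mom[[i]]
        m$mW <- beta1 * m$mW + (1 - beta1) * gr[[i]]$W
        m$vW <- beta2 * m$vW + (1 - beta2) * gr[[i]]$W^2
        m$mb <- beta1 * m$mb + (1 - beta1) * gr[[i]]$b
        m$vb <- beta2 * m$vb + (1 - beta2) * gr[[i]]$b^2
        mom[[i]] <- m
        cb1 <- 1 - beta1^t; cb2 <- 1 - beta2^t
        layers[[i]]$W <- layers[[i]]$W -
          trainarg@lr * (m$mW / cb1) / (sqrt(m$vW / cb2) + eps)
        layers[[i]]$b <- layers[[i]]$b -
          trainarg@lr * (m$mb / cb1) / (sqrt(m$vb / cb2) + eps)
      }
    }
    vhat <- .mlpForward(X[va, , drop = FALSE], layers, 0, FALSE)$out
    vloss <- .lossValue(vhat, Y[va, , drop = FALSE], trainarg@loss)
    if (!is.finite(vloss)) stop("NaN/Inf validation loss at epoch ", ep)
    if (verbose) message(sprintf("epoch %d: val %s %.5f", ep,
                                 trainarg@loss, vloss))
    if (vloss < best - 1e-6) {
      best <- vloss; bestLayers <- layers; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= trainarg@patience) break
    }
  }
  new("TrainedEstimator", weights = bestLayers, dropout = netarg@dropout,
      paramNames = pn, scaleLo = lo, scaleHi = hi,
      inputDim = ncol(X), valloss = best,
      provenance = list(priors = priors@specs,
                        protocol = shellTable(netarg@protocol),
                        seed = netarg@seed, hidden = netarg@hidden,
                        snr = netarg@snr, sigma = netarg@sigma,
                        model = model@name))
}

#' Monte-Carlo-dropout posterior summaries
#'
#' Performs \code{ntests} stochastic forward passes with dropout active and
#' returns the per-parameter mean and standard deviation, unscaled to
#' physical units. The dropout-induced spread approximates the posterior
#' uncertainty of each parameter.
#'
#' @param est a [TrainedEstimator-class]
#' @param meas measurement matrix (n x M) or single vector
#' @param ntests number of stochastic passes (>= 2)
#' @param seed optional seed for the dropout masks
#' @return list(mean, std): n x P matrices in physical units
#' @export
predictMC <- function(est, meas, ntests = 100, seed = NULL) {
  if (ntests < 2) stop("ntests must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(meas))) meas <- matrix(meas, nrow = 1)
  if (ncol(meas) != est@inputDim)
    stop("measurement dimension does not match the trained network")
  sumx <- 0; sumx2 <- 0
  for (i in seq_len(ntests)) {
    out <- .mlpForward(meas, est@weights, est@dropout, TRUE)$out
    sumx <- sumx + out
    sumx2 <- sumx2 + out^2
  }
  mu <- sumx / ntests
  va <- (sumx2 - ntests * mu^2) / (ntests - 1)
  va[va < 0] <- 0
  rng <- est@scaleHi - est@scaleLo
  mean_ <- sweep(sweep(mu, 2, rng, "*"), 2, est@scaleLo, "+")
  std_ <- sweep(sqrt(va), 2, rng, "*")
  colnames(mean_) <- colnames(std_) <- est@paramNames
  list(mean = mean_, std = std_)
}

#' Evaluate an estimator against ground truth
#'
#' Computes per-parameter bias, RMSE, and Pearson correlation between
#' ground truth and posterior means, the ground-truth-versus-estimate 2D
#' histogram, and the posterior std normalised by the prior range
#' (std / (hi - lo)).
#'
#' @param est a [TrainedEstimator-class]
#' @param testset list(params, signals) with ground-truth parameters
#' @param ntests MC-dropout passes
#' @param bins 2D histogram bins per axis
#' @param seed seed for the dropout masks
#' @return list with \code{stats} (data.frame: param, bias, rmse, pearson,
#'   meanNormStd), \code{hist2d} (list of bins x bins count matrices), and
#'   the raw predictions
#' @export
evaluateEstimator <- function(est, testset, ntests = 100, bins = 40,
                              seed = NULL) {
  pred <- predictMC(est, testset$signals, ntests, seed = seed)
  gt <- testset$params[, est@paramNames, drop = FALSE]
  rngs <- est@scaleHi - est@scaleLo
  stats_ <- data.frame(
    param = est@paramNames,
    bias = colMeans(pred$mean - gt),
    rmse = sqrt(colMeans((pred$mean - gt)^2)),
    pearson = vapply(seq_along(est@paramNames), function(j) {
      if (stats::sd(gt[, j]) == 0 || stats::sd(pred$mean[, j]) == 0)
        return(NA_real_)
      stats::cor(gt[, j], pred$mean[, j])
    }, 0),
    meanNormStd = colMeans(pred$std) / rngs,
    row.names = NULL)
  hist2d <- lapply(seq_along(est@paramNames), function(j) {
    br <- seq(est@scaleLo[j], est@scaleHi[j], length.out = bins + 1)
    cutg <- cut(gt[, j], br, include.lowest = TRUE)
    cute <- cut(pmin(pmax(pred$mean[, j], est@scaleLo[j]), est@scaleHi[j]),
                br, include.lowest = TRUE)
    table(gt = cutg, est = cute)
  })
  names(hist2d) <- est@paramNames
  list(stats = stats_, hist2d = hist2d, pred = pred)
}
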