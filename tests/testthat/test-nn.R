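test_that("training-set synthesis honours the forward model and priors", {
  m <- makeModel("SMT")
  p <- protocolPreset("hcp_smt")
  d <- generateTrainingSet(m, p, defaultPriors(m), n = 50, sigma = 0,
                           seed = 11)
  ## noise-free signals equal the forward model row by row
  for (i in c(1, 25, 50))
    expect_equal(d$signals[i, ],
                 as.numeric(modelSignals(m, p, values = d$params[i, ])),
                 tolerance = 1e-12)
  ## per-shell noise std follows 1/(snr sqrt(ndirs))
  dn <- generateTrainingSet(m, p, defaultPriors(m), n = 4000, snr = 50,
                            seed = 12)
  resid <- dn$signals - dn$clean
  expect_equal(apply(resid, 2, sd), 1 / (50 * sqrt(p@ndirs)),
               tolerance = 0.05)
})

test_that("Dirichlet fractions form a simplex with flat marginals", {
  m <- makeModel("SANDI")
  p <- protocolPreset("connectome_sandi")
  d <- generateTrainingSet(m, p, defaultPriors(m), n = 30000, sigma = 0,
                           seed = 13)
  fsum <- d$params[, "f.soma"] + d$params[, "f.neurite"]
  expect_true(all(fsum <= 1 + 1e-12 & fsum >= 0))
  expect_equal(mean(d$params[, "f.soma"]), 1 / 3, tolerance = 0.01)
  expect_equal(mean(d$params[, "f.neurite"]), 1 / 3, tolerance = 0.01)
})

test_that("prior draws match their specified distributions", {
  m <- makeModel("SMT")
  p <- protocolPreset("hcp_smt")
  prG <- priorSpec("intra.dpara" = priorGaussian(2, 0.5, 1, 3),
                   "extra.dperpFrac" = priorUniform(0, 1),
                   fractions = priorDirichlet(c(1, 1)))
  d <- generateTrainingSet(m, p, prG, n = 5000, sigma = 0, seed = 14)
  ## uniform marginals
  ksU <- ks.test(d$params[, "extra.dperpFrac"], "punif")
  expect_gt(ksU$p.value, 0.01)
  ## truncated-Gaussian D_par: KS shape check plus analytic moments
  ptr <- function(q) (pnorm(q, 2, 0.5) - pnorm(1, 2, 0.5)) /
    (pnorm(3, 2, 0.5) - pnorm(1, 2, 0.5))
  x <- d$params[, "intra.dpara"]
  ksG <- ks.test(x, ptr)
  expect_gt(ksG$p.value, 0.001)
  ## symmetric truncation: mean 2; var = sigma^2 (1 - 2 b phi(b)/Z)
  Z <- pnorm(2) - pnorm(-2)
  sdTr <- 0.5 * sqrt(1 - 2 * 2 * dnorm(2) / Z)
  expect_lt(abs(mean(x) - 2), 4 * sdTr / sqrt(length(x)))
  expect_equal(sd(x), sdTr, tolerance = 0.05)
  expect_true(all(x >= 1 & x <= 3))
  ## prior outside bounds is rejected
  bad <- priorSpec("intra.dpara" = priorUniform(0, 5),
                   "extra.dperpFrac" = priorUniform(0, 1),
                   fractions = priorDirichlet(c(1, 1)))
  expect_error(generateTrainingSet(m, p, bad, n = 10, sigma = 0), "bounds")
})

test_that("training-sample heuristic counts network weights", {
  m <- makeModel("SANDI")
  p <- protocolPreset("connectome_sandi")   # 8 shells in
  na <- networkArg(m, p, hidden = c(48, 48, 48))
  ## 8 -> 48 -> 48 -> 48 -> 5 weights + biases
  nw <- (8 * 48 + 48) + (48 * 48 + 48) * 2 + (48 * 5 + 5)
  expect_equal(recommendNSamples(na), 50L * nw)
  expect_equal(recommendNSamples(na, factor = 10), 10L * nw)
  expect_warning(recommendNSamples(na, factor = 5), "10, 100")
})

test_that("training converges below the prior-mean baseline and is seeded", {
  m <- makeModel("SMT")
  p <- protocolPreset("hcp_smt")
  d <- generateTrainingSet(m, p, defaultPriors(m), n = 16000, sigma = 0,
                           seed = 15)
  na <- networkArg(m, p, nsamples = 16000, sigma = 0, seed = 15)
  ta <- trainingArg(epochs = 80, patience = 80)
  est <- trainEstimator(na, ta, data = d)
  ## baseline: predicting the scaled prior mean gives RMSE ~ sd of the
  ## scaled targets
  lo <- est@scaleLo; hi <- est@scaleHi
  Ysc <- sweep(sweep(d$params, 2, lo, "-"), 2, hi - lo, "/")
  baseline <- sqrt(mean(sweep(Ysc, 2, colMeans(Ysc), "-")^2))
  expect_lt(est@valloss, 0.6 * baseline)
  ## label-shuffling destroys the signal-parameter association
  set.seed(19)
  dsh <- d; dsh$params <- d$params[sample(nrow(d$params)), ]
  estSh <- trainEstimator(na, trainingArg(epochs = 15, patience = 15),
                          data = dsh)
  expect_gt(estSh@valloss, 0.85 * baseline)
  ## determinism
  est2 <- trainEstimator(na, ta, data = d)
  expect_identical(est@valloss, est2@valloss)
})

test_that("MC dropout spread shrinks with the dropout rate", {
  m <- makeModel("SMT")
  p <- protocolPreset("hcp_smt")
  d <- generateTrainingSet(m, p, defaultPriors(m), n = 4000, sigma = 0,
                           seed = 16)
  test <- d$signals[1:200, ]
  stds <- vapply(c(0.01, 0.3), function(dr) {
    na <- networkArg(m, p, nsamples = 4000, sigma = 0, seed = 16,
                     dropout = dr)
    est <- trainEstimator(na, trainingArg(epochs = 15, patience = 15),
                          data = d)
    mean(predictMC(est, test, ntests = 60, seed = 1)$std)
  }, 0)
  expect_lt(stds[1], stds[2])
  ## MC means are stable across pass counts
  na <- networkArg(m, p, nsamples = 4000, sigma = 0, seed = 16)
  est <- trainEstimator(na, trainingArg(epochs = 15, patience = 15),
                        data = d)
  m1 <- predictMC(est, test, ntests = 300, seed = 2)$mean
  m2 <- predictMC(est, test, ntests = 1500, seed = 3)$mean
  expect_lt(max(abs(m1 - m2)), 0.05)
  expect_error(predictMC(est, test, ntests = 1), "ntests")
})

test_that("evaluation statistics match analytic values for a constant net", {
  ## A zero-weight network predicts the scaled midpoint 0.5 regardless of
  ## input or dropout: per-parameter RMSE must equal the analytic value
  ## for uniform ground truth, and the MC-dropout std must be 0.
  m <- makeModel("SMT")
  p <- protocolPreset("hcp_smt")
  d <- generateTrainingSet(m, p, defaultPriors(m), n = 6000, sigma = 0,
                           seed = 17)
  na <- networkArg(m, p, nsamples = 6000, sigma = 0, seed = 17)
  est <- trainEstimator(na, trainingArg(epochs = 1, patience = 1), data = d)
  for (i in seq_along(est@weights)) {
    est@weights[[i]]$W[] <- 0
    est@weights[[i]]$b[] <- if (i == length(est@weights)) 0.5 else 0
  }
  ev <- evaluateEstimator(est, d, ntests = 20, seed = 4)
  lo <- est@scaleLo; hi <- est@scaleHi
  mid <- (lo + hi) / 2
  for (j in seq_along(est@paramNames)) {
    gt <- d$params[, est@paramNames[j]]
    expect_equal(ev$stats$rmse[j], sqrt(mean((gt - mid[j])^2)),
                 tolerance = 1e-8)
    expect_equal(ev$stats$bias[j], mean(mid[j] - gt), tolerance = 1e-8)
  }
  expect_true(all(ev$stats$meanNormStd < 1e-12))
  ## uniform marginals: RMSE of the midpoint predictor ~ range/sqrt(12)
  expect_equal(ev$stats$rmse[ev$stats$param == "extra.dperpFrac"],
               1 / sqrt(12), tolerance = 0.05)
})

test_that("fraction estimates stay near the simplex on test data", {
  est <- cachedSMTEstimator()
  m <- makeModel("SMT")
  p <- protocolPreset("hcp_smt")
  test <- generateTrainingSet(m, p, defaultPriors(m), n = 500, snr = 50,
                              seed = 18)
  pred <- predictMC(est, test$signals, ntests = 40, seed = 5)
  f <- pred$mean[, "f.intra"]
  expect_true(all(f > -0.1 & f < 1.1))
})
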