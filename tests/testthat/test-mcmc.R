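test_that("Gaussian log-likelihood matches its closed form", {
  expect_equal(logLikelihoodGaussian(1, 1, 1), -0.5 * log(2 * pi))
  expect_equal(logLikelihoodGaussian(1, 0, 1), -0.5 * log(2 * pi) - 0.5)
  ## vectorised vs per-element accumulation
  set.seed(5)
  y <- rnorm(40); yh <- rnorm(40)
  ll <- sum(vapply(1:40, function(i)
    logLikelihoodGaussian(y[i], yh[i], 0.3), 0))
  expect_equal(ll, logLikelihoodGaussian(y, yh, 0.3), tolerance = 1e-12)
  expect_error(logLikelihoodGaussian(1, 1, 0), "sigma")
  expect_error(logLikelihoodGaussian(1:3, 1:2, 1), "length")
})

test_that("near-zero proposals leave the chain at its start point", {
  m <- toyIsoModel()
  p <- acquisitionProtocol(c(0.5, 1, 2), ndirs = 1L)
  meas <- as.numeric(modelSignals(m, p, values = c("iso.d" = 1)))
  sm <- sampler("iso.d", nsamples = 200, burnin = 50, thinning = 1,
                proposal = c("iso.d" = 1e-12), start = c("iso.d" = 1.3))
  ch <- mhSample(m, meas, p, sm, noisemodel(sigma = 0.05, sampled = FALSE),
                 seed = 1)
  expect_lt(max(abs(ch@draws[, "iso.d"] - 1.3)), 1e-8)
})

test_that("posterior of the toy model matches grid integration", {
  m <- toyIsoModel()
  p <- acquisitionProtocol(c(0.5, 1, 2, 3), ndirs = 1L)
  sigma <- 0.03
  set.seed(6)
  meas <- exp(-p@bval * 1.2) + rnorm(4, 0, sigma)
  ## oracle: posterior mean by grid integration under the uniform prior
  grid <- seq(0, 3, length.out = 4001)
  loglik <- vapply(grid, function(d)
    -sum((meas - exp(-p@bval * d))^2) / (2 * sigma^2), 0)
  w <- exp(loglik - max(loglik))
  oracleMean <- sum(grid * w) / sum(w)
  oracleSd <- sqrt(sum((grid - oracleMean)^2 * w) / sum(w))
  sm <- sampler("iso.d", nsamples = 20000, burnin = 2000, thinning = 1,
                proposal = c("iso.d" = 0.05))
  ch <- mhSample(m, meas, p, sm, noisemodel(sigma = sigma, sampled = FALSE),
                 seed = 2)
  s <- posteriorSummary(ch)
  ess <- chainDiagnostics(ch, burnin = 2000)$ess
  mcse <- oracleSd / sqrt(ess)
  expect_lt(abs(s$mean - oracleMean), 3 * mcse + 1e-4)
  expect_equal(s$std, oracleSd, tolerance = 0.15)
})

test_that("MH sampling is deterministic given a seed", {
  m <- toyIsoModel()
  p <- acquisitionProtocol(c(1, 2), ndirs = 1L)
  meas <- c(0.4, 0.2)
  sm <- sampler("iso.d", nsamples = 500, burnin = 100, thinning = 1)
  ch1 <- mhSample(m, meas, p, sm, noisemodel(sigma = 0.05), seed = 9)
  ch2 <- mhSample(m, meas, p, sm, noisemodel(sigma = 0.05), seed = 9)
  expect_identical(ch1@draws, ch2@draws)
  expect_identical(ch1@logp, ch2@logp)
})

test_that("stationary distribution matches the analytic posterior (KS)", {
  ## detailed-balance smoke test on a single-parameter problem
  m <- toyIsoModel()
  p <- acquisitionProtocol(c(0.5, 1, 2, 3), ndirs = 1L)
  sigma <- 0.05
  meas <- exp(-p@bval * 1.0)
  sm <- sampler("iso.d", nsamples = 50000, burnin = 5000, thinning = 10,
                proposal = c("iso.d" = 0.25))
  ch <- mhSample(m, meas, p, sm, noisemodel(sigma = sigma, sampled = FALSE),
                 seed = 3)
  keep <- ch@draws[seq(5001, 50000, by = 10), "iso.d"]
  grid <- seq(0, 3, length.out = 6001)
  loglik <- vapply(grid, function(d)
    -sum((meas - exp(-p@bval * d))^2) / (2 * sigma^2), 0)
  w <- exp(loglik - max(loglik)); cdf <- cumsum(w) / sum(w)
  ks <- max(abs(ecdf(keep)(grid) - cdf))
  expect_lt(ks, 0.02)
})

test_that("acceptance rate decreases as the proposal widens", {
  m <- toyIsoModel()
  p <- acquisitionProtocol(c(0.5, 1, 2, 3), ndirs = 1L)
  meas <- exp(-p@bval * 1.0)
  acc <- vapply(c(0.02, 0.08, 0.3, 1, 2.5), function(w) {
    sm <- sampler("iso.d", nsamples = 4000, burnin = 500, thinning = 1,
                  proposal = c("iso.d" = w))
    ch <- mhSample(m, meas, p, sm,
                   noisemodel(sigma = 0.02, sampled = FALSE), seed = 4)
    mean(ch@accepted)
  }, 0)
  expect_true(all(diff(acc) < 0))
})

test_that("two-stage fitting fixes dropped parameters at stage-1 means", {
  m <- makeModel("ExCaliber")
  p <- protocolPreset("excaliber_exvivo_dt15")
  meas <- synthVoxel(m, gtExcaliber, p, snr = 100, 1, seed = 12)[1, ]
  allp <- c("f.axon", "f.dot", "axon.da", "axon.dpara", "extra.dperpFrac")
  s1 <- sampler(allp, nsamples = 1500, burnin = 500, thinning = 2)
  s2 <- sampler(allp[1:3], nsamples = 1500, burnin = 500, thinning = 2)
  fit <- suppressWarnings(
    twoStageFit(m, meas, p, s1, s2, noisemodel(sigma = 0.01), seed = 5))
  expect_setequal(fit$stage2@params, c(allp[1:3], "sigma"))
  expect_equal(nrow(fit$summary), 6L + 4L)
  expect_error(twoStageFit(m, meas, p, s2, s1), "subset")
})

test_that("split-Rhat and ESS behave on converged and stuck chains", {
  set.seed(7)
  chains <- lapply(1:4, function(i)
    matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "x")))
  d <- chainDiagnostics(chains)
  expect_gt(d$rhat, 0.99); expect_lt(d$rhat, 1.01)
  expect_gt(d$ess, 0.8 * 4000); expect_lt(d$ess, 1.2 * 4000)
  ## two chains stuck at different constants are flagged
  stuck <- list(matrix(rep(0, 400), ncol = 1),
                matrix(rep(1, 400), ncol = 1))
  expect_gt(chainDiagnostics(stuck)$rhat, 1.1)
  expect_error(chainDiagnostics(list(matrix(rnorm(3), ncol = 1))),
               "at least 4")
})

test_that("posterior summaries use post-burn-in thinned moments", {
  ch <- new("Chain", draws = matrix(rep(2, 100), ncol = 1,
                                    dimnames = list(NULL, "a")),
            logp = rep(0, 100), accepted = rep(TRUE, 100), params = "a",
            stage = "s", burnin = 10L, thinning = 1L)
  s <- posteriorSummary(ch)
  expect_equal(s$mean, 2); expect_equal(s$std, 0)
  n <- 100
  ch2 <- new("Chain", draws = matrix(rep(c(0, 1), n / 2), ncol = 1,
                                     dimnames = list(NULL, "a")),
             logp = rep(0, n), accepted = rep(TRUE, n), params = "a",
             stage = "s", burnin = 0L, thinning = 1L)
  s2 <- posteriorSummary(ch2)
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$std, 0.5 * sqrt(n / (n - 1)))
})

test_that("voxelwise maps are thread-invariant and respect the mask", {
  m <- toyIsoModel()
  p <- acquisitionProtocol(c(0.5, 1, 2), ndirs = 1L)
  set.seed(8)
  nvox <- 10
  clean <- exp(-outer(rep(1.1, nvox), p@bval))
  arr <- array(clean + rnorm(length(clean), 0, 0.02), c(nvox, 1, 1, 3))
  vs <- volumeSeries(arr)
  mask <- array(TRUE, c(nvox, 1, 1)); mask[9:10, 1, 1] <- FALSE
  sm <- sampler("iso.d", nsamples = 400, burnin = 100, thinning = 2)
  nm <- noisemodel(sigma = 0.02, sampled = FALSE)
  r1 <- fitMaps(vs, mask, m, p, sm, nm, nthreads = 1L, seed = 10)
  r2 <- fitMaps(vs, mask, m, p, sm, nm, nthreads = 2L, seed = 10)
  expect_identical(r1$mean, r2$mean)
  expect_identical(r1$std, r2$std)
  expect_true(all(is.na(r1$mean[["iso.d"]][9:10, 1, 1])))
  expect_true(all(is.finite(r1$mean[["iso.d"]][1:8, 1, 1])))
  expect_true(all(r1$qc[1:8, 1, 1] == 0))
  ## estimates are in the right neighbourhood of the truth
  expect_lt(max(abs(r1$mean[["iso.d"]][1:8, 1, 1] - 1.1)), 0.3)
})
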