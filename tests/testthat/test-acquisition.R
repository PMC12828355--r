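test_that("b-value files are normalised to ms/um^2 on read", {
  f1 <- withr::local_tempfile(lines = "0 1000 2000", fileext = ".bvals")
  expect_equal(readAcquisition(f1)@bval, c(0, 1, 2))
  f2 <- withr::local_tempfile(lines = "0 1 2.5", fileext = ".bvals")
  expect_equal(readAcquisition(f2)@bval, c(0, 1, 2.5))
  f3 <- withr::local_tempfile(lines = "0 -5 10", fileext = ".bvals")
  expect_error(readAcquisition(f3), "non-negative")
  f4 <- withr::local_tempfile(lines = "10 20")
  expect_error(readAcquisition(f1, techoPath = f4), "entries")
})

test_that("bvec orientation is auto-detected and unit norms enforced", {
  dirs <- sphereDirections(12)
  fb <- withr::local_tempfile(lines = paste(rep(1, 12), collapse = " "))
  fv <- withr::local_tempfile()
  write.table(t(dirs), fv, row.names = FALSE, col.names = FALSE)  # 3 x N
  tab <- readAcquisition(fb, bvecPath = fv)
  expect_equal(dim(tab@bvec), c(12L, 3L))
  expect_true(all(abs(sqrt(rowSums(tab@bvec^2)) - 1) < 1e-3))
  expect_error(acquisitionTable(1, bvec = matrix(c(2, 0, 0), 1)),
               "unit")
})

test_that("PGSE b-value relation matches its closed form and inverts", {
  expect_equal(bFromPGSE(0, 9.6, 12), 0)
  ## preclinical shell: G = 660 mT/m, delta/Delta = 9.6/12 ms
  b <- bFromPGSE(660, 9.6, 12)
  expect_equal(b, (2.6752e-4 * 660 * 9.6)^2 * (12 - 3.2), tolerance = 1e-12)
  expect_lt(abs(b - 25.0) / 25.0, 0.02)   # nominal b = 25 within 2%
  ## inverse mode reaches the scanner's maximum gradient
  G <- gradientFromB(43.0, 11, 15.192)
  expect_lt(abs(G - 660) / 660, 0.01)
  ## round trip
  for (G0 in c(50, 300, 660))
    expect_equal(gradientFromB(bFromPGSE(G0, 11, 15.192), 11, 15.192), G0,
                 tolerance = 1e-10)
  expect_error(bFromPGSE(100, 12, 11), "delta < Delta")
})

test_that("multi-TE tables group into one shell per unique (b, TE)", {
  tes <- seq(62, 132, by = 10)
  tab <- acquisitionTable(bval = rep(c(700, 2000), times = 8),
                          techo = rep(tes, each = 2))
  dwi <- volumeSeries(array(1, c(2, 2, 1, 16)))
  sm <- sphericalMean(dwi, tab)
  expect_equal(length(sm$protocol), 16L)
  expect_equal(sort(unique(sm$protocol@techo)), tes)
  ## canonical ordering: ascending TE then b
  st <- shellTable(sm$protocol)
  expect_false(is.unsorted(st$techo))
  expect_equal(st$bval[st$techo == 62], c(0.7, 2.0))
})

test_that("spherical mean averages shells and is permutation-stable", {
  set.seed(1)
  ## 2 shells x 3 directions + 2 b0
  b <- c(0, 0, rep(1, 3), rep(2, 3))
  nvol <- length(b)
  arr <- array(runif(4 * 4 * 2 * nvol), c(4, 4, 2, nvol))
  arr[, , , 3:5] <- arr[, , , 3, drop = FALSE][, , , c(1, 1, 1)]  # identical
  tab <- acquisitionTable(b)
  sm <- sphericalMean(volumeSeries(arr), tab)
  expect_equal(length(sm$protocol), 3L)
  expect_equal(sm$protocol@ndirs, c(2L, 3L, 3L))
  ## mean of identical volumes is the volume
  expect_equal(sm$volumes@data[, , , 2], arr[, , , 3])
  ## simple two-value mean
  arr2 <- array(0, c(1, 1, 1, 2)); arr2[1, 1, 1, ] <- c(0.2, 0.4)
  sm2 <- sphericalMean(volumeSeries(arr2), acquisitionTable(c(1, 1)))
  expect_equal(as.numeric(sm2$volumes@data), 0.3)
  ## permuting volumes leaves all outputs unchanged
  perm <- sample(nvol)
  smp <- sphericalMean(volumeSeries(arr[, , , perm, drop = FALSE]),
                       acquisitionTable(b[perm]))
  expect_equal(smp$volumes@data, sm$volumes@data)
  expect_equal(shellTable(smp$protocol), shellTable(sm$protocol))
})

test_that("spherical mean of a stick phantom matches the erf closed form", {
  dirs <- sphereDirections(32)
  stick <- new("Stick", dpara = 2)
  sig <- synthDirectional(stick, bval = 1, dirs = dirs)   # 1 x 32
  arr <- array(rep(sig, each = 1), c(1, 1, 1, 32))
  tab <- acquisitionTable(rep(1, 32), bvec = dirs)
  sm <- sphericalMean(volumeSeries(arr), tab)
  closed <- sqrt(pi / (4 * 2)) * erfOracle(sqrt(2))
  expect_lt(abs(as.numeric(sm$volumes@data) - closed) / closed, 0.015)
})

test_that("SH fit: order 0 equals the spherical mean, isotropic has no l=2", {
  set.seed(2)
  dirs <- sphereDirections(30)
  b <- c(0, rep(1, 30))
  arr <- array(NA_real_, c(2, 2, 1, 31))
  arr[, , , 1] <- 1
  for (k in 1:30) arr[, , , k + 1] <- 0.5 + 0.01 * k  # shell values vary
  tab <- acquisitionTable(b, bvec = rbind(0, dirs))
  sm <- sphericalMean(volumeSeries(arr), tab)
  fit0 <- sphericalFit(volumeSeries(arr), tab, lmax = 0)
  expect_equal(fit0$volumes@data, sm$volumes@data, tolerance = 1e-9)
  ## isotropic signal: S0 = value, S2 = 0
  arr2 <- array(0.7, c(1, 1, 1, 31)); arr2[, , , 1] <- 1
  fit2 <- sphericalFit(volumeSeries(arr2), tab, lmax = 2)
  st <- shellTable(fit2$protocol)
  s0 <- fit2$volumes@data[1, 1, 1, st$lorder == 0 & st$bval > 0]
  s2 <- fit2$volumes@data[1, 1, 1, st$lorder == 2 & st$bval > 0]
  expect_equal(s0, 0.7, tolerance = 1e-8)
  expect_lt(abs(s2), 1e-10)
  ## underdetermined fit names the shell
  tab6 <- acquisitionTable(rep(1, 4), bvec = dirs[1:4, ])
  expect_error(sphericalFit(volumeSeries(arr[, , , 2:5, drop = FALSE]),
                            tab6, lmax = 2), "directions")
})

test_that("SH rotational invariants recover p2 * K_l of a dispersed fibre", {
  ## Synthesise a band-limited axially symmetric signal
  ## S(g) = sum_l (2l+1) p_l K_l P_l(g.n) with known p2, then check that
  ## the fitted invariants satisfy S2/S0 = p2 K2/K0 (quadrature oracle).
  dirs <- sphereDirections(60)
  fibre <- c(0.3, -0.5, 0.81); fibre <- fibre / sqrt(sum(fibre^2))
  kern <- new("StickKernel", dpara = 2)
  prot1 <- acquisitionProtocol(1.5, ndirs = 60L)
  K0 <- kernelInvariant(kern, prot1, 0)
  K2 <- kernelInvariant(kern, prot1, 2)
  p2 <- 0.7
  xi <- as.vector(dirs %*% fibre)
  sig <- K0 + 5 * p2 * K2 * legendreP(2, xi)
  arr <- array(rep(sig, each = 1), c(1, 1, 1, 60))
  tab <- acquisitionTable(rep(1.5, 60), bvec = dirs)
  fit <- sphericalFit(volumeSeries(arr), tab, lmax = 2)
  st <- shellTable(fit$protocol)
  s0 <- fit$volumes@data[1, 1, 1, st$lorder == 0]
  s2 <- fit$volumes@data[1, 1, 1, st$lorder == 2]
  expect_lt(abs(s2 / s0 - p2 * K2 / K0) / (p2 * K2 / K0), 0.02)
})

test_that("SNR maps are mean/std of b0 volumes per TE", {
  arr <- array(0, c(1, 1, 1, 4))
  arr[1, 1, 1, ] <- c(90, 100, 110, 50)
  tab <- acquisitionTable(c(0, 0, 0, 1))
  snr <- snrMap(volumeSeries(arr), tab)
  expect_equal(as.numeric(snr@data), 10)
  ## zero variance flagged as NA
  arrc <- array(100, c(1, 1, 1, 3))
  snrc <- snrMap(volumeSeries(arrc), acquisitionTable(c(0, 0, 0)))
  expect_true(is.na(as.numeric(snrc@data)))
  ## single b0 at a TE errors
  expect_error(snrMap(volumeSeries(arr[, , , c(1, 4), drop = FALSE]),
                      acquisitionTable(c(0, 1))), ">= 2")
  ## Monte-Carlo: sigma = 0.01 on unit signal, 18 b0s -> SNR ~ 100
  set.seed(3)
  nvox <- 1000
  a <- array(1 + rnorm(nvox * 18, 0, 0.01), c(nvox, 1, 1, 18))
  s <- snrMap(volumeSeries(a), acquisitionTable(rep(0, 18)))
  expect_lt(abs(mean(s@data) - 100) / 100, 0.1)
})
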