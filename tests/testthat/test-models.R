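test_that("model factory builds their standard compositions", {
  smt <- makeModel("SMT")
  expect_setequal(smt@freeParams,
                  c("f.intra", "intra.dpara", "extra.dperpFrac"))
  expect_true("extra.dpara" %in% names(smt@links))  # shared parallel diff.
  smifw <- makeModel("SMIfw")
  expect_equal(smifw@fixed, c("fw.d" = 3, "fw.t2" = 2000))
  expect_equal(smifw@riorder, 2L)
  expect_equal(length(smifw@freeParams), 8L)
  exv <- makeModel("ExCaliber", mode = "exvivo")
  expect_equal(unname(exv@fixed["dot.d"]), 0)
  inv <- makeModel("ExCaliber", mode = "invivo")
  expect_equal(unname(inv@fixed["dot.d"]), 3)
  sandidot <- makeModel("SANDIdot")
  expect_equal(length(sandidot@compartments), 4L)
  expect_error(makeModel("NODDI"))
})

test_that("any model predicts 1 at b = 0 with a single TE", {
  p0 <- acquisitionProtocol(0, ndirs = 1L)
  for (nm in c("SMT", "SANDI", "SANDIdot"))
    expect_equal(unname(modelSignals(makeModel(nm), p0)[1]), 1,
                 tolerance = 1e-12)
  pex <- acquisitionProtocol(0, tdelta = 15.192, tsmalldel = 11, ndirs = 1L)
  expect_equal(unname(modelSignals(makeModel("ExCaliber"), pex)[1]), 1,
               tolerance = 1e-12)
})

test_that("mixture linearity and compartment-order invariance hold", {
  p <- protocolPreset("excaliber_exvivo_dt15")
  m <- makeModel("ExCaliber")
  vals <- gtExcaliber
  mixed <- modelSignals(m, p, values = vals)
  ## fraction-weighted sum of single-compartment closed forms
  cyl <- new("Cylinder", da = 2, d0 = 0.6, dpara = 0.6)
  zep <- new("Zeppelin", dpara = 0.6, dperpFrac = 0.3)
  dot <- new("Iso", d = 0)
  manual <- 0.7 * compartmentSignals(cyl, p) +
    0.15 * compartmentSignals(dot, p) + 0.15 * compartmentSignals(zep, p)
  expect_equal(as.numeric(mixed), manual, tolerance = 1e-12)
  ## permuted compartment order
  m1 <- stickIsoModel(FALSE); m2 <- stickIsoModel(TRUE)
  pb <- acquisitionProtocol(c(0, 1, 2, 3), ndirs = 1L)
  s1 <- modelSignals(m1, pb, values = c("f.a" = 0.6))
  s2 <- modelSignals(m2, pb, values = c("f.b" = 0.4))
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-14)
})

test_that("ExCaliber approaches the dot floor at very high b", {
  m <- makeModel("ExCaliber")
  ## exact oracle at b = 200: fdot + fia * S_cyl + fec * S_zep (closed forms)
  mk <- function(b) acquisitionProtocol(b, tdelta = 15.192, tsmalldel = 11,
                                        ndirs = 1L)
  for (b in c(200, 500, 1000)) {
    G <- gradientFromB(b, 11, 15.192)
    la <- gpdOracle("cylinder", 1, 0.6, G, 11, 15.192, 50)
    dperp <- -la / b
    scyl <- zeppelinOracleQuad(b, 0.6, dperp)
    szep <- zeppelinOracleQuad(b, 0.6, 0.18)
    oracle <- 0.7 * scyl + 0.15 + 0.15 * szep
    got <- unname(modelSignals(m, mk(b), values = gtExcaliber)[1])
    expect_equal(got, oracle, tolerance = 1e-6)
  }
  ## the dot fraction is the b -> Inf floor; at b = 1000 the cylinder's
  ## 1/sqrt(b) tail is below 0.01
  s1000 <- unname(modelSignals(m, mk(1000), values = gtExcaliber)[1])
  expect_lt(abs(s1000 - 0.15), 0.01)
  ## monotone approach to the floor
  ss <- vapply(c(100, 200, 500, 1000), function(b)
    unname(modelSignals(m, mk(b), values = gtExcaliber)[1]), 0)
  expect_true(all(diff(ss) < 0) && all(ss > 0.15))
})

test_that("tortuosity link ties the perpendicular diffusivity to fia", {
  m <- makeModel("SMT", tortuosity = TRUE)
  expect_false("extra.dperpFrac" %in% m@freeParams)
  v <- unpackParameters(m, packParameters(
    m, c("f.intra" = 0.4, "intra.dpara" = 2)))
  expect_equal(unname(v["extra.dperpFrac"]), 0.6)
  ## effective D_perp,ec = (1 - fia) * D_par,ec = 1.2 um^2/ms
  expect_equal(unname(v["extra.dperpFrac"] * v["extra.dpara"]), 1.2)
})

test_that("parameter packing: stick-breaking simplex and bounds checks", {
  m <- makeModel("ExCaliber")   # fractions (0.7, 0.15, 0.15), 2 free coords
  vec <- packParameters(m, modelValues(m))
  expect_equal(length(vec), 5L)
  expect_equal(unname(vec[c("f.axon", "f.dot")]), c(0.7, 0.5))
  v <- unpackParameters(m, vec)
  expect_equal(unname(v[c("f.axon", "f.dot", "f.extra")]),
               c(0.7, 0.15, 0.15), tolerance = 1e-12)
  ## random round trips
  set.seed(4)
  widths <- c(1, 1, 13.9, 1.9, 1)
  for (i in 1:25) {
    z <- runif(5) * widths + c(0, 0, 0.1, 0.1, 0)
    v2 <- unpackParameters(m, z)
    expect_equal(unname(packParameters(m, v2)), unname(z),
                 tolerance = 1e-12)
  }
  ## fixing a parameter shortens the vector
  m2 <- makeModel("SMT", sharedDpara = FALSE)
  expect_equal(length(makeModel("SMT")@freeParams) + 1L,
               length(m2@freeParams))
  expect_error(packParameters(m, replace(modelValues(m), "axon.da", 99)),
               "axon.da")
})

test_that("SMI order-0 block equals the K0 mixture; order-2 scales with p2", {
  m <- makeModel("SMI")
  p <- protocolPreset("prisma_mte_smi")
  ## single-TE slice of the protocol to avoid relaxation weighting
  sub <- acquisitionProtocol(c(0, 0.7, 2, 0.7, 2),
                             tdelta = 25.2, tsmalldel = 15.2,
                             ndirs = c(4, 30, 30, 30, 30),
                             lorder = c(0, 0, 0, 2, 2))
  vals <- c("f.axon" = 0.6, "axon.dpara" = 2.2, "extra.dpara" = 1.8,
            "extra.dperpFrac" = 0.5, "p2" = 0.8)
  s <- modelSignals(m, sub, values = vals)
  stickK <- new("StickKernel", dpara = 2.2)
  zepK <- new("ZeppelinKernel", dpara = 1.8, dperpFrac = 0.5)
  o0 <- acquisitionProtocol(c(0, 0.7, 2), tdelta = 25.2, tsmalldel = 15.2,
                            ndirs = c(4, 30, 30))
  k0 <- 0.6 * kernelInvariant(stickK, o0, 0) +
    0.4 * kernelInvariant(zepK, o0, 0)
  o2 <- acquisitionProtocol(c(0.7, 2), tdelta = 25.2, tsmalldel = 15.2,
                            ndirs = 30)
  k2 <- 0.6 * kernelInvariant(stickK, o2, 2) +
    0.4 * kernelInvariant(zepK, o2, 2)
  expect_equal(as.numeric(s[1:3]), k0, tolerance = 1e-8)
  expect_equal(as.numeric(s[4:5]), 0.8 * k2, tolerance = 1e-8)
})

test_that("multi-TE predictions are renormalised to the earliest-TE b0", {
  m <- makeModel("MTE_SMT")
  p <- acquisitionProtocol(rep(c(0, 1, 2), 2),
                           techo = rep(c(62, 132), each = 3), ndirs = 1L)
  vals <- c("f.intra" = 0.6, "intra.dpara" = 2, "extra.dperpFrac" = 0.5,
            "intra.t2" = 80, "extra.t2" = 60)
  s <- modelSignals(m, p, values = vals)
  expect_equal(attr(s, "normalization"), "global")
  expect_equal(unname(s[1]), 1, tolerance = 1e-12)   # b0 at min TE
  expect_lt(unname(s[4]), 1)                          # b0 at later TE decays
  ## per-TE normalisation makes every b0 exactly 1
  m@normalization <- "perTE"
  s2 <- modelSignals(m, p, values = vals)
  expect_equal(unname(s2[c(1, 4)]), c(1, 1), tolerance = 1e-12)
})

test_that("fraction simplex violations are rejected", {
  m <- makeModel("ExCaliber")
  bad <- gtExcaliber; bad["f.axon"] <- 0.95  # 0.95+0.15 > 1
  expect_error(modelSignals(m, protocolPreset("excaliber_exvivo_dt15"),
                            values = bad), "simplex")
})
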