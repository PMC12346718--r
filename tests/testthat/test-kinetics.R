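test_that("predictGas evaluates the sigmoidal model and its limits", {
  p <- GrootParams(250, 10, 2)
  expect_equal(predictGas(p, 10), 125)           # half-asymptote at t = B
  expect_equal(predictGas(p, 0), 0)              # limit at t = 0
  expect_equal(predictGas(p, 30), 225)           # 250 / (1 + (10/30)^2)
  expect_error(predictGas(p, -1), ">= 0")
  expect_error(GrootParams(-1, 10, 2), "> 0")
  expect_error(GrootParams(250, 0, 2), "> 0")
})

test_that("model curve is non-decreasing, bounded by A, and half of A at t = B", {
  set.seed(42)
  for (i in 1:50) {
    p <- GrootParams(runif(1, 50, 400), runif(1, 1, 40), runif(1, 0.2, 6))
    tt <- sort(runif(40, 0, 200))
    g <- predictGas(p, tt)
    expect_true(all(diff(g) >= 0))
    expect_true(all(g <= p@A))
    expect_equal(predictGas(p, p@B), p@A / 2, tolerance = 1e-12)
  }
})

test_that("blank correction subtracts the run-wise blank mean at each time", {
  tt <- c(2, 6, 12, 24)
  bottles <- rbind(bottleRow("b1"), bottleRow("k1", "BLANK"),
                   bottleRow("k2", "BLANK", replicate = 2L))
  gas <- cbind(b1 = c(3, 40, 80, 110),
               k1 = c(5, 8, 9, 10), k2 = c(5, 8, 9, 12))
  st <- suppressWarnings(blankCorrect(handStudy(gas, tt, bottles)))
  corr <- assay(st, "corrected")
  expect_equal(unname(corr[4, "b1"]), 99)                 # 110 - mean(10, 12)
  expect_equal(unname(corr[1, "b1"]), -2)                 # negative value retained
  expect_warning(blankCorrect(handStudy(gas, tt, bottles)), "negative")
  # a bottle reading identical to the blank mean corrects to zero
  gas2 <- cbind(b1 = c(5, 8, 9, 11), k1 = c(5, 8, 9, 10),
                k2 = c(5, 8, 9, 12))
  st2 <- blankCorrect(handStudy(gas2, tt, bottles))
  expect_equal(unname(assay(st2, "corrected")[, "b1"]), rep(0, 4))
  # missing blank for a run is an error
  b3 <- rbind(bottleRow("b1"), bottleRow("b2", run = 2L),
              bottleRow("k1", "BLANK"))
  gas3 <- cbind(b1 = c(3, 40, 80, 110), b2 = c(3, 40, 80, 110),
                k1 = c(5, 8, 9, 10))
  expect_error(blankCorrect(handStudy(gas3, tt, b3)), "run 2")
})

test_that("OMCV normalization divides by incubated OM and guards its domain", {
  tt <- c(2, 6, 12, 24)
  bottles <- rbind(bottleRow("b1", om = 0.5), bottleRow("k1", "BLANK"))
  gas <- cbind(b1 = c(10, 20, 40, 50), k1 = c(0, 0, 0, 0))
  st <- toOMCV(handStudy(gas, tt, bottles))
  expect_equal(unname(assay(st, "omcv")[4, "b1"]), 100)   # 50 mL / 0.5 g
  expect_true(all(is.na(assay(st, "omcv")[, "k1"])))
  expect_error(handStudy(gas, tt, transform(bottles,
                                            incubated_om_g = c(0, 0))),
               "incubated OM")
})

test_that("closed-form Tmax/Rmax match the numerical-derivative oracle", {
  p <- GrootParams(250, 10, 2)
  expect_equal(computeTmax(p), 10 * (1 / 3)^(1 / 2), tolerance = 1e-12)
  expect_equal(computeTmax(p), 5.7735, tolerance = 1e-4)
  o <- gridRateMax(250, 10, 2)
  expect_equal(computeRmax(p), o$rmax, tolerance = 1e-6)
  expect_lt(abs(computeTmax(p) - o$tmax), 2 * o$resolution)
  # near the C = 1 boundary the maximum collapses toward t = 0
  p2 <- GrootParams(250, 10, 1.0001)
  expect_equal(computeTmax(p2), 10 * (1e-4 / 2.0001)^(1 / 1.0001),
               tolerance = 1e-9)
  expect_error(computeTmax(GrootParams(250, 10, 1)), "C <= 1")
  expect_error(computeRmax(GrootParams(250, 10, 1)), "C <= 1")
  # Rmax is linear in A
  expect_equal(computeRmax(GrootParams(500, 10, 2)), 2 * computeRmax(p))
})

test_that("noiseless synthetic curves are recovered to 1e-6 relative error", {
  tt <- c(seq(2, 24, by = 2), 30, 36, 48, 72, 96, 120)
  for (truth in list(c(250, 10, 2), c(218, 8, 1.2))) {
    p <- GrootParams(truth[1], truth[2], truth[3])
    fit <- fitGroot(GasCurve(tt, predictGas(p, tt)))
    expect_true(fit@converged)
    expect_equal(fit@params@A, truth[1], tolerance = 1e-6)
    expect_equal(fit@params@B, truth[2], tolerance = 1e-6)
    expect_equal(fit@params@C, truth[3], tolerance = 1e-6)
  }
})

test_that("fitting is invariant to the ordering of input points", {
  tt <- c(seq(2, 24, by = 2), 36, 48, 96)
  g <- predictGas(GrootParams(240, 12, 1.5), tt) + sin(seq_along(tt))
  f1 <- fitGroot(GasCurve(tt, g))
  set.seed(3)
  ord <- sample(seq_along(tt))
  f2 <- fitGroot(GasCurve(tt[ord], g[ord]))
  expect_identical(c(f1@params@A, f1@params@B, f1@params@C),
                   c(f2@params@A, f2@params@B, f2@params@C))
})

test_that("degenerate inputs are refused or flagged, never silently fitted", {
  expect_error(GasCurve(c(2, 4, 8), c(1, 2, 3)), "at least 4")
  expect_error(GasCurve(c(2, 4, 4, 8), c(1, 2, 3, 4)), "increasing")
  curve <- GasCurve(c(2, 4, 8, 16), c(10, 8, 12, 15))
  expect_true(curve@non_monotone)
  # a fit to a curve generated with C < 1 leaves Tmax/Rmax undefined
  tt <- c(seq(2, 24, by = 2), 36, 48, 96, 120)
  fit <- fitGroot(GasCurve(tt, predictGas(GrootParams(200, 15, 0.8), tt)))
  expect_true(fit@converged)
  expect_true(is.na(fit@tmax) && is.na(fit@rmax))
  expect_lt(abs(fit@params@C - 0.8), 1e-4)
})

test_that("per-bottle study fits recover the generating parameters", {
  cfg <- noiselessConfig(A = 246, B = 18.26, C = 1.126, replicates = 2L)
  fits <- fitKinetics(simulateStudy(cfg))
  expect_identical(nrow(fits), 2L)
  expect_true(all(fits$converged))
  expect_equal(fits$A, rep(246, 2), tolerance = 1e-6)
  expect_equal(fits$tmax_h,
               rep(computeTmax(GrootParams(246, 18.26, 1.126)), 2),
               tolerance = 1e-6)
})
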