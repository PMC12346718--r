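test_that("noiseless generation reproduces the sigmoidal truth exactly", {
  cfg <- noiselessConfig(A = 250, B = 10, C = 2,
                         times = c(0.01, 5, 10, 20), horizon = 24,
                         replicates = 1L)
  st <- simulateStudy(cfg)
  g <- assay(st, "gas")[, !isBlank(st)]
  expect_equal(g[[3]], 125)            # half-asymptote at t = B
  expect_lt(g[[1]], 0.001)             # model limit near t = 0
  # expected raw reading = blank mean + OM * G(t)
  cfg2 <- noiselessConfig(A = 250, B = 10, C = 2,
                          times = c(0.01, 5, 10, 20), horizon = 24,
                          replicates = 1L, blank_mean = 7)
  st2 <- simulateStudy(cfg2)
  expect_equal(assay(st2, "gas")[3, !isBlank(st2)], 132,
               ignore_attr = TRUE)
  expect_equal(assay(st2, "gas")[2, isBlank(st2)], 7, ignore_attr = TRUE)
})

test_that("generation is byte-identical for a fixed seed", {
  cfg <- exp1Config(seed = 11L)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(assay(a, "gas"), assay(b, "gas"))
  expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
  c <- simulateStudy(exp1Config(seed = 12L))
  expect_false(identical(assay(a, "gas"), assay(c, "gas")))
})

test_that("invalid configurations are rejected with the violated invariant named", {
  sub <- noiselessConfig()@substrates
  expect_error(studyConfig(transform(sub, A = -1)), "A, B, C")
  expect_error(studyConfig(transform(sub, dom = 1.2)), "dOM")
  expect_error(studyConfig(sub, times_h = c(5, 3, 8, 10)), "increasing")
  expect_error(studyConfig(sub, times_h = c(0, 3, 8, 10)), "increasing|start")
  expect_error(studyConfig(sub, times_h = c(2, 4, 8, 200),
                           horizon_h = 120), "horizon")
  expect_error(studyConfig(sub, replicates = 0), "replicates")
  expect_error(studyConfig(sub, runs = 0), "runs")
  expect_error(studyConfig(transform(sub, ac = -3)), "VFA")
})

test_that("residue OM encodes the true degradability before noise", {
  cfg <- noiselessConfig(dom = 0.63, replicates = 2L, runs = 2L)
  st <- simulateStudy(cfg)
  cd <- colData(st)[!isBlank(st), ]
  expect_equal(as.numeric(cd$residue_om_g),
               as.numeric(cd$incubated_om_g) * (1 - 0.63))
  expect_equal(domPercent(cd$incubated_om_g, cd$residue_om_g),
               rep(63, nrow(cd)))
})

test_that("mean observed dOM approaches the true dOM under noise", {
  cfg <- exp1Config(seed = 5L)
  st <- simulateStudy(cfg)
  cd <- colData(st)[!isBlank(st), ]
  dom_obs <- domPercent(cd$incubated_om_g, cd$residue_om_g)
  truth <- metadata(st)$truth
  for (i in seq_len(nrow(truth))) {
    grp <- dom_obs[cd$substrate == truth$label[i]]
    # dom_sd = 0.02 (2 percentage points), n = 6 -> se ~ 0.82
    expect_lt(abs(mean(grp) - 100 * truth$dom[i]), 3 * 2 / sqrt(length(grp)))
  }
})

test_that("VFA end-points are exactly the true means when CV = 0 and unbiased otherwise", {
  st0 <- simulateStudy(noiselessConfig())
  prof <- vfaData(st0)
  expect_equal(unname(as.numeric(prof[1, ])), c(50, 15, 1.5, 8, 3, 2))
  cfg <- noiselessConfig(replicates = 3L, runs = 2L)
  cfg@vfa_cv <- 0.3
  st <- simulateStudy(cfg)
  v <- vfaData(st)
  expect_true(all(as.matrix(v) > 0))   # log-normal keeps positivity
  # mean-preserving draw: acetate mean near 50 at CV 0.3, n = 6
  expect_lt(abs(mean(v$acetate) - 50) / 50, 0.5)
})

test_that("study CSV files round-trip at full precision", {
  dir <- withr::local_tempdir()
  st <- simulateStudy(exp1Config(seed = 2L))
  writeStudyCSV(st, dir)
  back <- readStudyCSV(dir)
  expect_identical(assay(back, "gas"), assay(st, "gas"))
  expect_identical(gasTimes(back), gasTimes(st))
  cd0 <- as.data.frame(colData(st)); cd1 <- as.data.frame(colData(back))
  expect_identical(cd1[order(cd1$bottle_id), ], cd0[order(cd0$bottle_id), ])
})

test_that("study configurations round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  cfg <- exp2Config(seed = 9L)
  writeStudyConfig(cfg, path)
  back <- readStudyConfig(path)
  expect_equal(back@substrates, cfg@substrates)
  expect_identical(back@seed, cfg@seed)
  expect_identical(back@times_h, cfg@times_h)
  expect_identical(simulateStudy(back), simulateStudy(cfg))
})

test_that("default designs match the two study layouts", {
  c1 <- exp1Config()
  expect_identical(nrow(c1@substrates), 5L)
  expect_identical(c1@replicates, 3L)
  expect_identical(c1@runs, 2L)
  expect_equal(c1@horizon_h, 120)
  expect_true(all(c1@substrates$A >= 218 & c1@substrates$A <= 250))
  c2 <- exp2Config()
  expect_identical(nrow(c2@substrates), 8L)
  expect_identical(c2@replicates, 2L)
  expect_equal(c2@horizon_h, 24)
  expect_identical(sort(unique(c2@substrates$cut)), c("C1", "C2"))
  expect_identical(length(unique(c2@substrates$part)), 4L)
  tot <- rowSums(c2@substrates[, c("ac", "pr", "ib", "bu", "iv", "va")])
  expect_true(all(tot > 29 & tot < 64.1))
})

test_that("fitted-A spread across replicates does not shrink as gas noise grows", {
  sds <- c(0.5, 2, 8)
  spread <- sapply(sds, function(s) {
    mean(sapply(1:5, function(seed) {
      cfg <- noiselessConfig(replicates = 6L, seed = seed)
      cfg@gas_sd_ml <- s
      st <- toOMCV(simulateStudy(cfg))
      fits <- fitKinetics(st)
      sd(fits$A)
    }))
  })
  expect_true(all(diff(spread) >= 0))
})
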