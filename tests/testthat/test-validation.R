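# shared small simulated populations for the driver tests
simTrainVal <- function(seed, n = 110, nExt = 20, m = 200, h2 = 0.6,
                        nQtl = 20, archetype = "MULTIFAM") {
  cfg <- simConfig(archetype, nGenotypes = as.integer(n + nExt),
                   nMarkers = as.integer(m), nChromosomes = 5,
                   nQtl = as.integer(nQtl), h2 = h2, seed = as.integer(seed))
  G <- simulatePopulation(cfg)
  sim <- simulatePhenotype(G, cfg)
  ids <- names(sim$phenotype)
  ext <- seq(n + 1, n + nExt)
  list(G = sim$genotypes[ids[1:n], ], y = sim$phenotype[1:n],
       GVal = sim$genotypes[ids[ext], ], yVal = sim$phenotype[ext],
       truth = sim$truth)
}

test_that("k-fold partitions are balanced exact partitions", {
  f <- kfoldPartition(137, 10, seed = 1)
  expect_equal(sort(unname(lengths(f))), c(rep(13, 3), rep(14, 7)))
  expect_identical(sort(unname(unlist(f))), 1:137)
  expect_equal(lengths(kfoldPartition(10, 10, seed = 2)), rep(1L, 10),
               ignore_attr = TRUE)
  expect_false(identical(kfoldPartition(50, 5, seed = 1),
                         kfoldPartition(50, 5, seed = 2)))
  expect_error(kfoldPartition(5, 10), ">= k")
})

test_that("holdout split sizes follow nearest-integer (ties down) accounting", {
  expect_equal(holdoutSplit(100, 4), c(train = 75L, validation = 25L))
  expect_equal(holdoutSplit(9, 2), c(train = 5L, validation = 4L))  # 4.5 down
  expect_error(holdoutSplit(3, 3))
})

test_that("cross-validation separates signal from noise and is deterministic", {
  # the no-signal null: dataset-level sampling noise of r_cv_mean is
  # O(1/sqrt(n)), so the +/-0.1 band is checked on three simulated datasets
  nullMeans <- vapply(1:3, function(s) {
    null <- simTrainVal(100 + s, n = 300, nExt = 10, m = 50, h2 = 0, nQtl = 5,
                        archetype = "GERMPLASM")
    runCV(null$G, null$y, k = 10, nRepetitions = 5, seed = 3)$mean
  }, numeric(1))
  expect_lt(abs(mean(nullMeans)), 0.1)
  strong <- simTrainVal(102, n = 300, nExt = 10, m = 50, h2 = 1, nQtl = 5,
                        archetype = "GERMPLASM")
  cvStrong <- runCV(strong$G, strong$y, k = 10, nRepetitions = 20, seed = 3)
  expect_gt(cvStrong$mean, 0.9)
  again <- runCV(strong$G, strong$y, k = 10, nRepetitions = 20, seed = 3)
  expect_identical(cvStrong$perFold, again$perFold)
  expect_true(all(abs(cvStrong$perFold) <= 1))
  expect_true(cvStrong$min <= cvStrong$mean && cvStrong$mean <= cvStrong$max)
})

test_that("external validation is consistent under genotype duplication", {
  dat <- simTrainVal(103, n = 100, nExt = 10, m = 60, h2 = 1, nQtl = 8,
                     archetype = "GERMPLASM")
  # validation set = exact clones of 30 training genotypes under new ids
  cl <- dosage(dat$G)[1:30, ]
  rownames(cl) <- paste0("clone", 1:30)
  GClone <- genotypeMatrix(cl, chrom = dat$G@chrom, pos = dat$G@pos)
  yClone <- stats::setNames(unname(dat$y[1:30]), rownames(cl))
  rEv <- runExternal(dat$G, dat$y, GClone, yClone)
  fit <- fitRRBLUP(dat$G, dat$y)
  rTrain <- predictionAbility(dat$y[1:30], predictGEBV(fit, dat$G[1:30, ]))
  expect_equal(as.numeric(rEv), rTrain, tolerance = 1e-12)
  # overlapping id sets are rejected
  expect_error(runExternal(dat$G, dat$y, dat$G[1:10, ], dat$y[1:10]),
               "overlap")
  # a degenerate fit surfaces as flagged NA, not as r = 0
  yConst <- stats::setNames(rep(1, 100), names(dat$y))
  expect_warning(rDeg <- runExternal(dat$G, yConst, GClone, yClone),
                 "degenerate")
  expect_true(is.na(rDeg))
})

test_that("strategy comparison table is structurally sound and re-derivable", {
  dat <- simTrainVal(104, n = 80, nExt = 15, m = 120, h2 = 0.7)
  tab <- runStrategyComparison(dat$G, dat$y, dat$GVal, dat$yVal, sizes = 30L,
                               k = 3, nRepetitions = 1, nRandomReps = 4,
                               remobReps = 4, seed = 5)
  expect_equal(sum(tab$strategy == "ALL"), 1L)
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$r_cv_min <= tab$r_cv_mean + 1e-12 &
                  tab$r_cv_mean <= tab$r_cv_max + 1e-12))
  nrer <- tab[tab$strategy == "NRE_R", ]
  expect_lt(nrer$r_cv_min, nrer$r_cv_max)
  expect_true(all(abs(tab$r_ev) <= 1, na.rm = TRUE))
  # deterministic external-validation cell reproduced from components
  fitFull <- fitRRBLUP(dat$G, dat$y)
  sub <- selectNREMB(fitFull, 30L)[[1]]
  rEv <- runExternal(dat$G, dat$y, dat$GVal, dat$yVal,
                     markers = subsetMarkers(sub))
  expect_equal(tab$r_ev[tab$strategy == "NRE_MB"], as.numeric(rEv),
               tolerance = 1e-12)
})

test_that("training-set sweep: full fraction coincides across methods, sizes match", {
  dat <- simTrainVal(105, n = 60, nExt = 12, m = 100, h2 = 0.7)
  tab <- runTSSizeSweep(dat$G, dat$y, dat$GVal, dat$yVal,
                        fractions = c(1.0, 0.5), nRandomReps = 3, k = 3,
                        nRepetitions = 1, nRestarts = 2, seed = 8)
  full <- tab[tab$fraction == 1, ]
  expect_equal(length(unique(round(full$r_ev, 12))), 1L)
  expect_equal(length(unique(round(full$r_cv_mean, 12))), 1L)
  expect_true(all(tab$core_size == vapply(tab$fraction, coreSize,
                                          integer(1), n = 60)))
})

test_that("marker-by-population grid has full dimensions and reproduces the baseline", {
  dat <- simTrainVal(106, n = 60, nExt = 12, m = 100, h2 = 0.7)
  grid <- suppressWarnings(
    runGrid(dat$G, dat$y, dat$GVal, dat$yVal, sizes = 30L,
            fractions = 0.5, k = 3, nRepetitions = 2, remobReps = 3,
            nRestarts = 2, seed = 12))
  expect_equal(nrow(grid), 4L)   # (all, 30) x (1.0, 0.5)
  base <- runStrategyComparison(dat$G, dat$y, dat$GVal, dat$yVal, sizes = 30L,
                                strategies = "NRE_MB", k = 3,
                                nRepetitions = 2, seed = 12)
  cell <- grid[grid$fraction == 1 & grid$size == nMarkers(dat$G), ]
  expect_equal(cell$r_cv_mean, base$r_cv_mean[base$strategy == "ALL"],
               tolerance = 1e-12)
  expect_equal(cell$r_ev, base$r_ev[base$strategy == "ALL"],
               tolerance = 1e-12)
  grid2 <- suppressWarnings(
    runGrid(dat$G, dat$y, dat$GVal, dat$yVal, sizes = 30L,
            fractions = 0.5, k = 3, nRepetitions = 2, remobReps = 3,
            nRestarts = 2, seed = 12))
  expect_identical(grid, grid2)
})

test_that("mean cross-validated ability rises with heritability", {
  h2s <- c(0.1, 0.3, 0.5, 0.8)
  means <- vapply(h2s, function(h) {
    rs <- vapply(1:10, function(s) {
      dat <- simTrainVal(1000 + s, n = 120, nExt = 5, m = 200, h2 = h,
                         nQtl = 30)
      runCV(dat$G, dat$y, k = 5, nRepetitions = 1, seed = s)$mean
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_gt(stats::cor(seq_along(h2s), means, method = "spearman"), 0)
  expect_gt(means[4], means[1])
})

test_that("random-core prediction ability rises with training-set size", {
  ra <- vapply(1:10, function(s) {
    dat <- simTrainVal(2000 + s, n = 120, nExt = 20, m = 150, h2 = 0.6)
    tab <- suppressWarnings(
      runTSSizeSweep(dat$G, dat$y, dat$GVal, dat$yVal,
                     fractions = c(0.75, 0.05), methods = "RANDOM",
                     nRandomReps = 5, k = 3, nRepetitions = 1,
                     seed = s))
    c(big = tab$r_cv_mean[tab$fraction == 0.75],
      small = tab$r_cv_mean[tab$fraction == 0.05])
  }, numeric(2))
  expect_gte(mean(ra["big", ]), mean(ra["small", ]))
})
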