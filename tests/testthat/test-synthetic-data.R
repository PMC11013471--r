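test_that("founder simulation: Fst = 0 collapses subpopulation frequencies", {
  cfg <- simConfig("GERMPLASM", nMarkers = 300, nChromosomes = 3, nSubpop = 3,
                   fst = 0, seed = 2)
  F <- simulateFounders(cfg, nFounders = 9)
  freq <- F@metadata$freq
  expect_equal(freq[1, ], freq[2, ])
  expect_equal(freq[1, ], freq[3, ])
})

test_that("founder simulation: Hudson FST recovers the Balding-Nichols target", {
  for (s in 1:10) {
    cfg <- simConfig("GERMPLASM", nMarkers = 2000, nChromosomes = 10,
                     nSubpop = 2, fst = 0.2, seed = s)
    F <- simulateFounders(cfg, nFounders = 100)
    sub <- F@metadata$subpop
    p1 <- colMeans(dosage(F)[sub == 1, ]) / 2
    p2 <- colMeans(dosage(F)[sub == 2, ]) / 2
    est <- hudsonFst(p1, p2, 50, 50)
    expect_lt(abs(est - 0.2), 0.05)
  }
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- simConfig("MULTIFAM", nGenotypes = 40, nMarkers = 120,
                   nChromosomes = 3, seed = 7)
  expect_identical(dosage(simulatePanel(cfg)), dosage(simulatePanel(cfg)))
  cfgG <- simConfig("GERMPLASM", nGenotypes = 30, nMarkers = 100,
                    nChromosomes = 2, seed = 7)
  expect_identical(dosage(simulatePanel(cfgG)), dosage(simulatePanel(cfgG)))
  cfgR <- simConfig("RIL", nGenotypes = 20, nMarkers = 100, nChromosomes = 2,
                    seed = 7)
  expect_identical(dosage(simulatePopulation(cfgR)),
                   dosage(simulatePopulation(cfgR)))
})

test_that("RIL simulation: identical parents breed true", {
  cfg <- simConfig("RIL", nGenotypes = 10, nMarkers = 100, nChromosomes = 2,
                   seed = 3)
  F <- simulateFounders(initialize(cfg, nSubpop = 1L, fst = 0), nFounders = 2)
  pa <- F[1, ]
  lines <- simulateRIL(pa, pa, cfg)
  for (i in 1:10)
    expect_equal(unname(dosage(lines)[i, ]), unname(dosage(pa)[1, ]))
})

test_that("RIL simulation matches F5 heterozygosity and segregation theory", {
  cfg <- simConfig("RIL", nGenotypes = 200, nMarkers = 2000, nChromosomes = 10,
                   selfingGenerations = 4, seed = 5)
  F <- simulateFounders(initialize(cfg, nSubpop = 1L, fst = 0), nFounders = 2)
  lines <- simulateRIL(F[1, ], F[2, ], cfg)
  d <- dosage(lines)
  expect_false(anyNA(d))
  expect_true(all(d %in% c(0, 1, 2)))
  poly <- which(dosage(F)[1, ] != dosage(F)[2, ])
  # expected residual heterozygosity after g selfings is (1/2)^g = 0.0625
  het <- mean(d[, poly] == 1)
  expect_lt(abs(het - 0.0625), 0.02)
  # Mendelian expectation: allele frequency 0.5 at polymorphic loci
  pbar <- mean(colMeans(d[, poly]) / 2)
  expect_lt(abs(pbar - 0.5), 0.03)
})

test_that("RIL simulation rejects mismatched or heterozygous parents", {
  cfg <- simConfig("RIL", nGenotypes = 5, nMarkers = 50, nChromosomes = 2,
                   seed = 3)
  F <- simulateFounders(initialize(cfg, nSubpop = 1L, fst = 0), nFounders = 2)
  het <- gm(matrix(1, 1, 50), chrom = F@chrom, pos = F@pos)
  expect_error(simulateRIL(F[1, ], het, cfg), "map|homozygous")
})

test_that("single-subpopulation panel is consistent with Hardy-Weinberg", {
  cfg <- simConfig("GERMPLASM", nGenotypes = 300, nMarkers = 400,
                   nChromosomes = 4, nSubpop = 1, fst = 0, seed = 13)
  G <- simulatePanel(cfg)
  d <- dosage(G)
  n <- nrow(d)
  rejections <- 0L
  tested <- 0L
  for (j in seq_len(ncol(d))) {
    p <- mean(d[, j]) / 2
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    if (min(expd) < 5) next
    obs <- tabulate(d[, j] + 1, 3)
    stat <- sum((obs - expd)^2 / expd)
    tested <- tested + 1L
    if (stats::pchisq(stat, df = 1, lower.tail = FALSE) < 0.001)
      rejections <- rejections + 1L
  }
  expect_gt(tested, 100)
  # no more alpha=0.001 rejections than plausible (99.9th binomial percentile)
  expect_lte(rejections, stats::qbinom(0.999, tested, 0.001) + 1)
})

test_that("multifamily panels show detectable family structure in PCA", {
  sil <- vapply(1:10, function(s) {
    cfg <- simConfig("MULTIFAM", nGenotypes = 150, nMarkers = 800,
                     nChromosomes = 5, nSubpop = 5, seed = s)
    G <- simulatePanel(cfg)
    pcs <- stats::prcomp(dosage(G), rank. = 2)$x
    meanSilhouette(pcs, G@metadata$family)
  }, numeric(1))
  expect_true(all(sil > 0))
})

test_that("phenotype simulation hits the heritability contract", {
  # h2 = 1: phenotype equals mu + breeding values exactly
  cfg <- simConfig("GERMPLASM", nGenotypes = 100, nMarkers = 200,
                   nChromosomes = 2, nQtl = 20, h2 = 1, mu = 3, seed = 4)
  G <- simulatePanel(cfg)
  sim <- simulatePhenotype(G, cfg)
  expect_equal(unname(sim$phenotype - 3),
               unname(sim$truth$trueBreedingValues))
  expect_equal(sim$truth$realizedH2, 1)
  # h2 = 0: pure noise, uncorrelated with the breeding values
  cors <- vapply(1:10, function(s) {
    cfg0 <- initialize(cfg, h2 = 0, nGenotypes = 500L, seed = as.integer(100 + s))
    G0 <- simulatePanel(cfg0)
    s0 <- simulatePhenotype(G0, cfg0)
    stats::cor(s0$phenotype, s0$truth$trueBreedingValues)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 2 / sqrt(500))
  # h2 = 0.5 at n = 500: unit slope of y on g, realized h2 near target
  stats_ <- vapply(1:20, function(s) {
    cfgH <- initialize(cfg, h2 = 0.5, nGenotypes = 500L, seed = as.integer(200 + s))
    GH <- simulatePanel(cfgH)
    sh <- simulatePhenotype(GH, cfgH)
    g <- sh$truth$trueBreedingValues
    c(slope = unname(stats::coef(stats::lm(sh$phenotype ~ g))[2]),
      h2 = sh$truth$realizedH2)
  }, numeric(2))
  expect_lt(abs(mean(stats_["slope", ]) - 1), 0.1)
  expect_lt(abs(mean(stats_["h2", ]) - 0.5), 0.08)
})

test_that("realized heritability converges to the target at large n", {
  cfg <- simConfig("GERMPLASM", nGenotypes = 2000, nMarkers = 400,
                   nChromosomes = 4, nQtl = 50, h2 = 0.5, seed = 17)
  G <- simulatePanel(cfg)
  sim <- simulatePhenotype(G, cfg)
  expect_lt(abs(sim$truth$realizedH2 - 0.5), 0.03)
})

test_that("hidden-QTL mode drops causal markers from the returned panel", {
  cfg <- simConfig("GERMPLASM", nGenotypes = 50, nMarkers = 100,
                   nChromosomes = 2, nQtl = 10, hiddenQtl = TRUE, seed = 6)
  G <- simulatePanel(cfg)
  sim <- simulatePhenotype(G, cfg)
  expect_equal(nMarkers(sim$genotypes), 90L)
  expect_length(intersect(sim$truth$qtlMarkerIds, markerIds(sim$genotypes)), 0)
})
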