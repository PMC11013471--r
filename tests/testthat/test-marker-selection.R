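test_that("30%-retention schedule reproduces known chains and edge cases", {
  expect_identical(scheduleSizes(20242), c(6072L, 1821L, 546L, 163L, 48L))
  expect_warning(s <- scheduleSizes(100), "below minSize")
  expect_length(s, 0)
  expect_identical(scheduleSizes(161), 48L)
  expect_error(scheduleSizes(40), "exceed")
})

test_that("schedule restriction keeps sizes attainable from a smaller panel", {
  chain <- c(6072L, 1821L, 546L, 163L, 48L)
  expect_identical(restrictSchedule(chain, 1044), c(546L, 163L, 48L))
  expect_identical(restrictSchedule(chain, 7000), chain)
  expect_identical(restrictSchedule(chain, 49), 48L)
})

makeFit <- function(beta) {
  new("RRBLUPFit", mu = 0, beta = beta,
      center = stats::setNames(numeric(length(beta)), names(beta)),
      varU = 1, varE = 1, lambda = 1, h2Hat = NA_real_, degenerate = FALSE)
}

test_that("effect-ranked selection takes top absolute effects, ties to earlier markers", {
  fit <- makeFit(c(a = 0.9, b = -0.5, c = 0.1))
  subs <- selectNREMB(fit, c(2L, 1L))
  expect_identical(subsetMarkers(subs[[1]]), c("a", "b"))
  expect_identical(subsetMarkers(subs[[2]]), "a")
  tied <- makeFit(c(x = 0.5, y = -0.5, z = 0.2))
  expect_identical(subsetMarkers(selectNREMB(tied, 1L)[[1]]), "x")
  # random vector vs independent sort oracle
  set.seed(12)
  beta <- stats::setNames(rnorm(200), sprintf("m%03d", 1:200))
  got <- subsetMarkers(selectNREMB(makeFit(beta), 25L)[[1]])
  oracle <- names(sort(abs(beta), decreasing = TRUE))[1:25]
  expect_setequal(got, oracle)
  expect_error(selectNREMB(fit, 4L), "exceeds")
})

test_that("random selection is uniform, reproducible and exhaustive at full size", {
  ids <- sprintf("m%03d", 1:100)
  full <- selectNRER(ids, 100L, nReps = 2, seed = 9)
  expect_setequal(subsetMarkers(full[[1]]), ids)
  a <- selectNRER(ids, c(20L, 10L), nReps = 3, seed = 5)
  b <- selectNRER(ids, c(20L, 10L), nReps = 3, seed = 5)
  expect_identical(lapply(a, subsetMarkers), lapply(b, subsetMarkers))
  # inclusion frequency at s = 10 of 100 over 2000 replicates
  reps <- selectNRER(ids, 10L, nReps = 2000, seed = 3)
  freq <- table(factor(unlist(lapply(reps, subsetMarkers)), levels = ids)) / 2000
  expect_true(all(abs(freq - 0.10) < 0.03))
  expect_error(selectNRER(ids, 101L, 1, 1), "exceeds")
})

test_that("re-estimated ranking keeps a clean dominant QTL down the whole chain", {
  # iid markers, exact single-marker signal: the causal marker dominates |beta|
  set.seed(14)
  X <- matrix(rbinom(100 * 40, 2, 0.5), 100, 40,
              dimnames = list(paste0("g", 1:100), sprintf("m%02d", 1:40)))
  G <- gm(X)
  q <- "m17"
  y <- stats::setNames(2 * X[, q], rownames(X))
  subs <- selectREMaB(G, y, c(20L, 8L, 3L))
  for (sub in subs) expect_true(q %in% subsetMarkers(sub))
  # nestedness by construction
  expect_true(all(subsetMarkers(subs[[2]]) %in% subsetMarkers(subs[[1]])))
  expect_true(all(subsetMarkers(subs[[3]]) %in% subsetMarkers(subs[[2]])))
  # a one-size schedule coincides with the no-re-estimation ranking
  one <- selectREMaB(G, y, 12L)
  expect_setequal(subsetMarkers(one[[1]]),
                  subsetMarkers(selectNREMB(fitRRBLUP(G, y), 12L)[[1]]))
})

test_that("best-of-random-models selection maximizes the evaluator", {
  # truth-count evaluator on a small instance: exhaustive enumeration shows
  # the maximum (all 3 QTL present) is attainable at subset size 5
  ids <- sprintf("m%02d", 1:20)
  qtl <- c("m03", "m11", "m18")
  evaluator <- function(markers) length(intersect(markers, qtl))
  combs <- utils::combn(20, 5)
  best <- max(apply(combs, 2, function(ix) evaluator(ids[ix])))
  expect_equal(best, 3)
  G <- gm(matrix(rbinom(10 * 20, 2, .5), 10, 20,
                 dimnames = list(paste0("g", 1:10), ids)))
  y <- stats::setNames(rnorm(10), paste0("g", 1:10))
  subs <- selectREMoB(G, y, 5L, nReps = 400, evaluator = evaluator, seed = 2)
  expect_true(all(qtl %in% subsetMarkers(subs[[1]])))
  expect_equal(subs[[1]]@score, 3)
})

test_that("best-of-random-models chains are nested, seeded and prefix-monotone", {
  cfg <- simConfig("GERMPLASM", nGenotypes = 60, nMarkers = 80,
                   nChromosomes = 2, nQtl = 10, h2 = 0.8, seed = 21)
  G <- simulatePanel(cfg)
  y <- simulatePhenotype(G, cfg)$phenotype
  s1 <- selectREMoB(G, y, c(30L, 10L), nReps = 8, seed = 6)
  s2 <- selectREMoB(G, y, c(30L, 10L), nReps = 8, seed = 6)
  expect_identical(lapply(s1, subsetMarkers), lapply(s2, subsetMarkers))
  expect_true(all(subsetMarkers(s1[[2]]) %in% subsetMarkers(s1[[1]])))
  # candidate draws for nReps = 8 are a prefix of the nReps = 20 stream, so
  # the winning score cannot decrease with more candidates
  w1 <- selectREMoB(G, y, 30L, nReps = 8, seed = 6)
  w2 <- selectREMoB(G, y, 30L, nReps = 20, seed = 6)
  expect_equal(attr(w2, "scores")[[1]][1:8], attr(w1, "scores")[[1]])
  expect_gte(w2[[1]]@score, w1[[1]]@score)
})
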