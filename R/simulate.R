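# Synthetic population generator. Emulates three soybean-like archetypes:
#  RIL       - biparental F5-derived recombinant inbred lines,
#  MULTIFAM  - a multifamily breeding panel (several biparental families from
#              a shared founder pool),
#  GERMPLASM - a structured germplasm collection (Balding-Nichols divergent
#              subpopulations, LD induced by founder-haplotype block mosaics).
# Phenotypes follow the additive model y = mu + sum_j x_ij beta_j + e with the
# residual variance set from the realized genetic variance and the target
# narrow-sense heritability.

#' SimConfig: parameters of the synthetic population generator
#'
#' @slot archetype "RIL", "MULTIFAM" or "GERMPLASM".
#' @slot nGenotypes,nMarkers,nChromosomes population and panel dimensions.
#' @slot chromLengthCM genetic length per chromosome (centimorgan).
#' @slot nQtl number of additive QTL (drawn among the markers).
#' @slot h2 target narrow-sense heritability in [0, 1].
#' @slot nSubpop number of subpopulations (GERMPLASM) or families (MULTIFAM).
#' @slot fst Balding-Nichols divergence among subpopulations, in [0, 0.5].
#' @slot selfingGenerations selfing rounds after the F1 (4 gives F5 lines).
#' @slot blockLength mean founder-haplotype block length in markers
#'   (GERMPLASM LD control).
#' @slot mu trait intercept.
#' @slot hiddenQtl when TRUE, QTL markers are dropped from the returned panel
#'   so prediction must work through linkage disequilibrium alone.
#' @slot seed integer seed; all generator randomness derives from it.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(archetype = "character", nGenotypes = "integer",
                 nMarkers = "integer", nChromosomes = "integer",
                 chromLengthCM = "numeric", nQtl = "integer", h2 = "numeric",
                 nSubpop = "integer", fst = "numeric",
                 selfingGenerations = "integer", blockLength = "numeric",
                 mu = "numeric", hiddenQtl = "logical", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (!object@archetype %in% c("RIL", "MULTIFAM", "GERMPLASM"))
    msgs <- c(msgs, "archetype must be RIL, MULTIFAM or GERMPLASM")
  if (object@h2 < 0 || object@h2 > 1) msgs <- c(msgs, "h2 must be in [0, 1]")
  if (object@fst < 0 || object@fst > 0.5) msgs <- c(msgs, "fst must be in [0, 0.5]")
  if (object@nQtl > object@nMarkers) msgs <- c(msgs, "nQtl must be <= nMarkers")
  for (f in c("nGenotypes", "nMarkers", "nChromosomes", "nSubpop"))
    if (slot(object, f) < 1L) msgs <- c(msgs, paste(f, "must be >= 1"))
  if (length(msgs)) msgs else TRUE
})

#' Build a simulation configuration
#'
#' Defaults mirror the three study archetypes at analysis scale: a biparental
#' RIL population of 137 F5-derived lines on a ~3k SNP panel; a multifamily
#' breeding panel of 227 lines in 5 families; and a structured germplasm
#' collection (300 accessions standing in for a much larger collection) in 3
#' subpopulations with Fst 0.15.
#'
#' @param archetype "RIL", "MULTIFAM" or "GERMPLASM".
#' @param nGenotypes,nMarkers,nChromosomes,chromLengthCM,nQtl,h2,nSubpop,fst,selfingGenerations,blockLength,mu,hiddenQtl,seed
#'   see [SimConfig-class]; any omitted value takes the archetype default.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig("RIL", nMarkers = 500, seed = 7)
#' @export
simConfig <- function(archetype = c("RIL", "MULTIFAM", "GERMPLASM"),
                      nGenotypes = NULL, nMarkers = NULL, nChromosomes = 20,
                      chromLengthCM = 120, nQtl = 100, h2 = 0.5,
                      nSubpop = NULL, fst = NULL, selfingGenerations = 4,
                      blockLength = 20, mu = 0, hiddenQtl = FALSE, seed = 1) {
  archetype <- match.arg(archetype)
  defaults <- switch(archetype,
    RIL       = list(n = 137L, m = 3088L, sub = 1L, fst = 0),
    MULTIFAM  = list(n = 227L, m = 5000L, sub = 5L, fst = 0.05),
    GERMPLASM = list(n = 300L, m = 5000L, sub = 3L, fst = 0.15))
  if (is.null(nGenotypes)) nGenotypes <- defaults$n
  if (is.null(nMarkers)) nMarkers <- defaults$m
  if (is.null(nSubpop)) nSubpop <- defaults$sub
  if (is.null(fst)) fst <- defaults$fst
  new("SimConfig", archetype = archetype, nGenotypes = as.integer(nGenotypes),
      nMarkers = as.integer(nMarkers), nChromosomes = as.integer(nChromosomes),
      chromLengthCM = chromLengthCM, nQtl = as.integer(min(nQtl, nMarkers)),
      h2 = h2, nSubpop = as.integer(nSubpop), fst = fst,
      selfingGenerations = as.integer(selfingGenerations),
      blockLength = blockLength, mu = mu, hiddenQtl = hiddenQtl,
      seed = as.integer(seed))
}

# Uniform marker placement on the genetic map: markers split evenly across
# chromosomes, positions sorted uniform in (0, L) cM; bp = round(cM * 1e6).
.simMap <- function(cfg) {
  m <- cfg@nMarkers
  nc <- cfg@nChromosomes
  per <- diff(floor(seq(0, m, length.out = nc + 1)))
  chrom <- rep(sprintf("chr%02d", seq_len(nc)), per)
  cm <- unlist(lapply(per, function(k) sort(stats::runif(k, 0, cfg@chromLengthCM))))
  list(chrom = chrom, cm = cm, pos = round(cm * 1e6) + 1)
}

#' Simulate a founder pool with Balding-Nichols population structure
#'
#' Ancestral allele frequencies are drawn Uniform(0.1, 0.9) per marker; each
#' subpopulation's frequency is Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst) (equal to
#' the ancestral frequency when Fst = 0). Founders are fully homozygous
#' (inbred) genotypes drawn from their subpopulation's frequencies and are
#' placed uniformly on the genetic map.
#'
#' @param cfg a [SimConfig-class].
#' @param nFounders total number of founders (split evenly over
#'   \code{cfg@nSubpop} subpopulations).
#' @return A [GenotypeMatrix-class] of homozygous founders; metadata carries
#'   the subpopulation assignment (\code{$subpop}), the per-subpopulation
#'   allele frequencies (\code{$freq}) and the genetic map (\code{$cm}).
#' @export
simulateFounders <- function(cfg, nFounders = 2L * cfg@nSubpop) {
  .withSeed(.substream(cfg@seed, "founders"), {
    map <- .simMap(cfg)
    m <- cfg@nMarkers
    pAnc <- stats::runif(m, 0.1, 0.9)
    freq <- matrix(NA_real_, nrow = cfg@nSubpop, ncol = m)
    for (s in seq_len(cfg@nSubpop)) {
      freq[s, ] <- if (cfg@fst == 0) pAnc else
        stats::rbeta(m, pAnc * (1 - cfg@fst) / cfg@fst,
                     (1 - pAnc) * (1 - cfg@fst) / cfg@fst)
    }
    subpop <- rep_len(seq_len(cfg@nSubpop), nFounders)
    subpop <- sort(subpop)
    hap <- matrix(NA_real_, nrow = nFounders, ncol = m)
    for (i in seq_len(nFounders))
      hap[i, ] <- stats::rbinom(m, 1, freq[subpop[i], ])
    d <- 2 * hap
    dimnames(d) <- list(sprintf("founder%03d", seq_len(nFounders)),
                        sprintf("snp%05d", seq_len(m)))
    genotypeMatrix(d, chrom = map$chrom, pos = map$pos,
                   metadata = list(cm = map$cm, subpop = subpop, freq = freq))
  })
}

# One gamete from a pair of haplotypes: crossovers as a Poisson process on the
# cM map (Haldane, no interference), independent per chromosome.
.gamete <- function(h1, h2, chromIdx, cmList) {
  out <- numeric(length(h1))
  for (c in seq_along(chromIdx)) {
    idx <- chromIdx[[c]]
    cm <- cmList[[c]]
    L <- max(cm)
    nco <- stats::rpois(1, L / 100)
    xo <- sort(stats::runif(nco, 0, L))
    phase <- (findInterval(cm, xo) + stats::rbinom(1, 1, 0.5)) %% 2
    out[idx] <- ifelse(phase == 0, h1[idx], h2[idx])
  }
  out
}

.chromIndex <- function(chrom) split(seq_along(chrom), factor(chrom, unique(chrom)))

#' Simulate F5-derived recombinant inbred lines from two homozygous parents
#'
#' Each line is an F1 followed by \code{cfg@selfingGenerations} rounds of
#' selfing (default 4, i.e. F5) with crossovers sampled as a Poisson process
#' on the centimorgan map (Haldane mapping, no interference).
#'
#' @param parentA,parentB single-genotype homozygous [GenotypeMatrix-class]
#'   objects on the same marker map (e.g. rows of [simulateFounders()]).
#' @param cfg a [SimConfig-class]; \code{nGenotypes} lines are produced.
#' @return A [GenotypeMatrix-class] of RIL dosages in \{0, 1, 2\}.
#' @export
simulateRIL <- function(parentA, parentB, cfg) {
  if (!identical(markerIds(parentA), markerIds(parentB)) ||
      !identical(parentA@pos, parentB@pos) ||
      !identical(parentA@chrom, parentB@chrom))
    stop("parents must share an identical marker map", call. = FALSE)
  da <- as.numeric(dosage(parentA)[1, ])
  db <- as.numeric(dosage(parentB)[1, ])
  if (any(da == 1) || any(db == 1))
    stop("parents must be homozygous at every marker", call. = FALSE)
  cm <- parentA@metadata$cm
  if (is.null(cm)) cm <- seq_along(da)  # fall back to index spacing
  chromIdx <- .chromIndex(if (length(parentA@chrom)) parentA@chrom
                          else rep("chr01", length(da)))
  cmList <- lapply(chromIdx, function(i) cm[i])
  .withSeed(.substream(cfg@seed, "ril"), {
    n <- cfg@nGenotypes
    d <- matrix(NA_real_, nrow = n, ncol = length(da))
    for (i in seq_len(n)) {
      h1 <- da / 2
      h2 <- db / 2
      for (g in seq_len(cfg@selfingGenerations)) {
        n1 <- .gamete(h1, h2, chromIdx, cmList)
        n2 <- .gamete(h1, h2, chromIdx, cmList)
        h1 <- n1
        h2 <- n2
      }
      d[i, ] <- h1 + h2
    }
    dimnames(d) <- list(sprintf("ril%04d", seq_len(n)), markerIds(parentA))
    genotypeMatrix(d, chrom = parentA@chrom, pos = parentA@pos,
                   metadata = list(cm = parentA@metadata$cm,
                                   parents = c(genotypeIds(parentA),
                                               genotypeIds(parentB))))
  })
}

# Two independent mosaic haplotypes per individual: block lengths geometric
# with mean cfg@blockLength markers (restarting at chromosome boundaries),
# each block copied from a random founder haplotype of the subpopulation.
.mosaicHaplotype <- function(pool, chromIdx, meanBlock) {
  m <- ncol(pool)
  out <- numeric(m)
  for (idx in chromIdx) {
    i <- 1
    k <- length(idx)
    while (i <= k) {
      len <- 1 + stats::rgeom(1, 1 / meanBlock)
      j <- min(i + len - 1, k)
      src <- sample.int(nrow(pool), 1)
      out[idx[i:j]] <- pool[src, idx[i:j]]
      i <- j + 1
    }
  }
  out
}

#' Simulate a multifamily breeding panel or structured germplasm collection
#'
#' MULTIFAM: \code{cfg@nSubpop} biparental families are bred from a shared
#' founder pool (each family an F1 between two distinct founders followed by
#' selfing, as in [simulateRIL()]); family labels are recorded in metadata.
#' GERMPLASM: accessions are drawn per subpopulation as two independent
#' founder-haplotype block mosaics (geometric block length, mean
#' \code{cfg@blockLength} markers), giving Hardy-Weinberg genotype frequencies
#' within subpopulations and tunable LD decay.
#'
#' @param cfg a [SimConfig-class] with archetype MULTIFAM or GERMPLASM.
#' @return A [GenotypeMatrix-class]; metadata carries \code{$family} or
#'   \code{$subpop}.
#' @export
simulatePanel <- function(cfg) {
  if (!cfg@archetype %in% c("MULTIFAM", "GERMPLASM"))
    stop("simulatePanel requires archetype MULTIFAM or GERMPLASM", call. = FALSE)
  if (cfg@archetype == "MULTIFAM") return(.simulateMultifam(cfg))
  .simulateGermplasm(cfg)
}

.simulateMultifam <- function(cfg) {
  nFam <- cfg@nSubpop
  poolCfg <- initialize(cfg, nSubpop = 1L, fst = 0)
  founders <- simulateFounders(poolCfg, nFounders = max(2L * nFam, 10L))
  chromIdx <- .chromIndex(founders@chrom)
  cm <- founders@metadata$cm
  cmList <- lapply(chromIdx, function(i) cm[i])
  .withSeed(.substream(cfg@seed, "multifam"), {
    n <- cfg@nGenotypes
    fam <- rep_len(seq_len(nFam), n)
    fam <- sort(fam)
    d <- matrix(NA_real_, nrow = n, ncol = cfg@nMarkers)
    pairs <- matrix(NA_integer_, nrow = nFam, ncol = 2)
    for (f in seq_len(nFam))
      pairs[f, ] <- sample.int(nGenotypes(founders), 2)
    for (i in seq_len(n)) {
      pa <- dosage(founders)[pairs[fam[i], 1], ] / 2
      pb <- dosage(founders)[pairs[fam[i], 2], ] / 2
      h1 <- pa
      h2 <- pb
      for (g in seq_len(cfg@selfingGenerations)) {
        n1 <- .gamete(h1, h2, chromIdx, cmList)
        n2 <- .gamete(h1, h2, chromIdx, cmList)
        h1 <- n1
        h2 <- n2
      }
      d[i, ] <- h1 + h2
    }
    dimnames(d) <- list(sprintf("line%04d", seq_len(n)), markerIds(founders))
    genotypeMatrix(d, chrom = founders@chrom, pos = founders@pos,
                   metadata = list(cm = cm, family = fam,
                                   founderPairs = pairs))
  })
}

.simulateGermplasm <- function(cfg) {
  nHapPerPop <- 16L
  founders <- simulateFounders(cfg, nFounders = nHapPerPop * cfg@nSubpop)
  chromIdx <- .chromIndex(founders@chrom)
  sub <- founders@metadata$subpop
  .withSeed(.substream(cfg@seed, "germplasm"), {
    n <- cfg@nGenotypes
    pop <- rep_len(seq_len(cfg@nSubpop), n)
    pop <- sort(pop)
    d <- matrix(NA_real_, nrow = n, ncol = cfg@nMarkers)
    haps <- dosage(founders) / 2
    for (i in seq_len(n)) {
      pool <- haps[sub == pop[i], , drop = FALSE]
      h1 <- .mosaicHaplotype(pool, chromIdx, cfg@blockLength)
      h2 <- .mosaicHaplotype(pool, chromIdx, cfg@blockLength)
      d[i, ] <- h1 + h2
    }
    dimnames(d) <- list(sprintf("acc%04d", seq_len(n)), markerIds(founders))
    genotypeMatrix(d, chrom = founders@chrom, pos = founders@pos,
                   metadata = list(cm = founders@metadata$cm, subpop = pop,
                                   freq = founders@metadata$freq))
  })
}

#' Simulate a population of the configured archetype
#'
#' Convenience dispatcher: RIL populations are bred from the first two
#' founders of a two-founder pool; MULTIFAM and GERMPLASM go through
#' [simulatePanel()].
#'
#' @param cfg a [SimConfig-class].
#' @return A [GenotypeMatrix-class].
#' @export
simulatePopulation <- function(cfg) {
  if (cfg@archetype == "RIL") {
    founders <- simulateFounders(initialize(cfg, nSubpop = 1L, fst = 0),
                                 nFounders = 2L)
    simulateRIL(founders[1, ], founders[2, ], cfg)
  } else {
    simulatePanel(cfg)
  }
}

#' Simulate an additive polygenic phenotype at a target heritability
#'
#' \code{cfg@nQtl} markers are chosen uniformly as QTL with effects drawn
#' Normal(0, 1). The breeding value of genotype i is the centered-dosage sum
#' \eqn{g_i = \sum_j (x_{ij} - \bar x_j)\beta_j}; the residual variance is set
#' so that var(g)/(var(g) + var(e)) equals \code{cfg@h2} on the generated
#' sample, and \eqn{y_i = \mu + g_i + e_i}. With \code{h2 = 1} the residual is
#' identically zero; with \code{h2 = 0} the phenotype is pure noise with unit
#' variance (the breeding values are still reported).
#'
#' @param G a complete (no missing data) [GenotypeMatrix-class].
#' @param cfg a [SimConfig-class]; uses \code{nQtl}, \code{h2}, \code{mu},
#'   \code{hiddenQtl} and the phenotype substream of \code{seed}.
#' @return A list with elements \code{phenotype} (named numeric vector),
#'   \code{truth} (list: qtlMarkerIds, qtlEffects, trueBreedingValues,
#'   realizedH2) and \code{genotypes} (the input panel, minus the QTL markers
#'   when \code{hiddenQtl} is set).
#' @export
simulatePhenotype <- function(G, cfg) {
  if (anyNA(dosage(G))) stop("genotypes must be complete; impute first", call. = FALSE)
  .withSeed(.substream(cfg@seed, "phenotype"), {
    m <- nMarkers(G)
    qtl <- sort(sample.int(m, cfg@nQtl))
    eff <- stats::rnorm(cfg@nQtl)
    X <- dosage(G)[, qtl, drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    g <- as.numeric(Xc %*% eff)
    varG <- stats::var(g)
    n <- length(g)
    if (cfg@h2 >= 1) {
      e <- numeric(n)
    } else if (cfg@h2 <= 0 || varG == 0) {
      g0 <- g
      g <- numeric(n)           # no genetic contribution to y
      e <- stats::rnorm(n, 0, 1)
      y <- cfg@mu + e
      truth <- list(qtlMarkerIds = markerIds(G)[qtl], qtlEffects = eff,
                    trueBreedingValues = stats::setNames(g0, genotypeIds(G)),
                    realizedH2 = 0)
      out <- if (cfg@hiddenQtl) G[, setdiff(seq_len(m), qtl)] else G
      return(list(phenotype = stats::setNames(y, genotypeIds(G)),
                  truth = truth, genotypes = out))
    } else {
      varE <- varG * (1 - cfg@h2) / cfg@h2
      e <- stats::rnorm(n, 0, sqrt(varE))
    }
    y <- cfg@mu + g + e
    realized <- if (stats::var(g + e) == 0) 1 else stats::var(g) / stats::var(g + e)
    truth <- list(qtlMarkerIds = markerIds(G)[qtl], qtlEffects = eff,
                  trueBreedingValues = stats::setNames(g, genotypeIds(G)),
                  realizedH2 = realized)
    out <- if (cfg@hiddenQtl) G[, setdiff(seq_len(m), qtl)] else G
    list(phenotype = stats::setNames(y, genotypeIds(G)), truth = truth,
         genotypes = out)
  })
}
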