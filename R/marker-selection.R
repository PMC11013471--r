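# Selective-genotyping strategies over a shrinking size schedule. Four
# strategies build low-density panels from a pruned marker set:
#   NRE_MB - rank once by |effect| from a single RR-BLUP fit, take top s;
#   NRE_R  - uniform random subsets, replicated;
#   RE_MAB - iterative: refit RR-BLUP on the current set, keep top s by
#            |effect|, repeat down the schedule;
#   RE_MOB - iterative best-of-random-models: at each size draw many random
#            subsets of the current entry set, score each by cross-validated
#            prediction ability on one fixed fold partition, keep the argmax.

#' Size schedule by iterated fractional retention
#'
#' Starting from \code{originM} markers, repeatedly keep
#' \code{floor(retentionFraction * s)} markers while the result stays at or
#' above \code{minSize}. With the defaults (30\% retention, floor, minimum
#' 48) a 20,242-marker set yields the chain 6072, 1821, 546, 163, 48.
#'
#' @param originM starting marker count (> \code{minSize}).
#' @param retentionFraction fraction retained per step (default 0.30).
#' @param minSize smallest admissible subset size (default 48).
#' @return Integer vector of strictly decreasing sizes (possibly empty, with
#'   a warning, when even the first step falls below \code{minSize}).
#' @export
scheduleSizes <- function(originM, retentionFraction = 0.30, minSize = 48) {
  .assertScalarNumber(retentionFraction, "retentionFraction", 1e-12, 1 - 1e-12)
  if (originM <= minSize)
    stop("originM must exceed minSize", call. = FALSE)
  sizes <- integer(0)
  s <- floor(retentionFraction * originM)
  while (s >= minSize) {
    sizes <- c(sizes, as.integer(s))
    s <- floor(retentionFraction * s)
  }
  if (!length(sizes))
    warning("first retention step falls below minSize; empty schedule")
  sizes
}

#' Restrict a canonical schedule to the sizes attainable from a smaller panel
#'
#' Keeps only schedule sizes strictly smaller than the available marker
#' count, so the same canonical chain can be reused across populations with
#' different pruned-panel sizes.
#'
#' @param sizes integer vector of schedule sizes.
#' @param mAvailable number of markers actually available.
#' @return The restricted size vector.
#' @export
restrictSchedule <- function(sizes, mAvailable) {
  sizes[sizes < mAvailable]
}

.newSubset <- function(strategy, ids, replicate = NA_integer_, score = NA_real_) {
  new("MarkerSubset", strategy = strategy, size = length(ids),
      markerIds = ids, replicate = as.integer(replicate), score = score)
}

#' Effect-ranked marker subsets without re-estimation (NRE-MB)
#'
#' Ranks markers once by the absolute value of their RR-BLUP effects and
#' takes the top s for every schedule size; subsets are nested by
#' construction. Ties at a cut are broken by marker order (earlier kept).
#'
#' @param fit an [RRBLUPFit-class] computed on the full (pruned) set.
#' @param sizes schedule of subset sizes (see [scheduleSizes()]).
#' @return List of [MarkerSubset-class], one per size.
#' @export
selectNREMB <- function(fit, sizes) {
  beta <- fit@beta
  if (any(sizes > length(beta)))
    stop("requested subset size exceeds the number of fitted markers", call. = FALSE)
  ord <- order(-abs(beta))   # stable: ties resolved by marker position
  ranked <- names(beta)[ord]
  lapply(sizes, function(s) .newSubset("NRE_MB", ranked[seq_len(s)]))
}

#' Random marker subsets without re-estimation (NRE-R)
#'
#' Independent uniform draws without replacement from the pruned marker set,
#' per size and replicate, on a dedicated seeded substream.
#'
#' @param markerIds character vector of available (pruned) marker ids.
#' @param sizes schedule of subset sizes.
#' @param nReps replicates per size (>= 1).
#' @param seed integer seed.
#' @return List of [MarkerSubset-class] of length \code{length(sizes) * nReps}
#'   (sizes vary slowest).
#' @export
selectNRER <- function(markerIds, sizes, nReps = 1000, seed = 1) {
  if (any(sizes > length(markerIds)))
    stop("requested subset size exceeds the available marker count", call. = FALSE)
  if (nReps < 1) stop("nReps must be >= 1", call. = FALSE)
  out <- list()
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    for (r in seq_len(nReps)) {
      ids <- .withSeed(.substream(seed, "nre_r", si * 100003L + r), {
        if (s == length(markerIds)) markerIds else sample(markerIds, s)
      })
      out[[length(out) + 1L]] <- .newSubset("NRE_R", ids, replicate = r)
    }
  }
  out
}

#' Effect-ranked marker subsets with re-estimation (RE-MaB)
#'
#' Starting from the full (pruned) set, at each schedule size the RR-BLUP
#' model is refit on the current set, markers are re-ranked by absolute
#' effect, and the top s become the new current set. Subsets are nested.
#'
#' @param G a complete [GenotypeMatrix-class] (pruned panel).
#' @param y named phenotype vector.
#' @param sizes schedule of subset sizes.
#' @param lambda optional fixed ridge parameter passed to [fitRRBLUP()].
#' @return List of [MarkerSubset-class], one per size.
#' @export
selectREMaB <- function(G, y, sizes, lambda = NULL) {
  current <- markerIds(G)
  out <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    if (s > length(current))
      stop("schedule size exceeds current marker set", call. = FALSE)
    fit <- fitRRBLUP(G[, current], y, lambda = lambda)
    if (fit@degenerate)
      stop("degenerate fit (zero phenotypic variance) during RE-MaB selection",
           call. = FALSE)
    ord <- order(-abs(fit@beta))
    current <- names(fit@beta)[ord][seq_len(s)]
    current <- current[order(match(current, markerIds(G)))]  # original order
    out[[si]] <- .newSubset("RE_MAB", current)
  }
  out
}

#' Cross-validation evaluator on one fixed fold partition
#'
#' Builds the default internal scorer used by [selectREMoB()]: mean
#' prediction ability over the folds of a single k-fold partition of the
#' training genotypes, shared by all candidate subsets so their scores are
#' comparable.
#'
#' @param G a complete [GenotypeMatrix-class].
#' @param y named phenotype vector.
#' @param k folds (default 5).
#' @param seed integer seed for the partition.
#' @param lambda optional fixed ridge parameter (speeds up scoring).
#' @return A function taking a character vector of marker ids and returning a
#'   scalar mean fold prediction ability.
#' @export
cvEvaluator <- function(G, y, k = 5, seed = 1, lambda = NULL) {
  folds <- kfoldPartition(length(y), k, seed = .substream(seed, "remob_folds"))
  ids <- names(y)
  function(markers) {
    Gs <- G[, markers]
    rs <- vapply(folds, function(fold) {
      train <- setdiff(seq_along(y), fold)
      fit <- fitRRBLUP(Gs[ids[train], ], y[train], lambda = lambda)
      predictionAbility(y[fold], predictGEBV(fit, Gs[ids[fold], ]))
    }, numeric(1))
    mean(rs)
  }
}

#' Model-based marker subsets via best-of-random-models (RE-MoB)
#'
#' The entry set starts as the full (pruned) set. For each schedule size s,
#' \code{nReps} random size-s subsets of the current entry set are drawn and
#' scored with the evaluator; the best-scoring subset (ties: first
#' encountered) becomes the new entry set. All candidate scores are kept in
#' the \code{"scores"} attribute of the result (a list of numeric vectors,
#' one per size).
#'
#' @param G a complete [GenotypeMatrix-class] (pruned panel).
#' @param y named phenotype vector.
#' @param sizes schedule of subset sizes.
#' @param nReps candidate subsets per size (default 1000, as in full-scale
#'   runs; small studies use 25-100).
#' @param evaluator function(markerIds) -> scalar score; defaults to
#'   [cvEvaluator()] with a fixed 5-fold partition.
#' @param seed integer seed (drives both the default evaluator's partition
#'   and the candidate draws).
#' @return List of [MarkerSubset-class], one per size, each carrying its
#'   winning score.
#' @export
selectREMoB <- function(G, y, sizes, nReps = 1000, evaluator = NULL, seed = 1) {
  if (is.null(evaluator)) evaluator <- cvEvaluator(G, y, seed = seed)
  entry <- markerIds(G)
  out <- vector("list", length(sizes))
  allScores <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    if (s > length(entry))
      stop("schedule size exceeds current entry set", call. = FALSE)
    cand <- lapply(seq_len(nReps), function(r)
      .withSeed(.substream(seed, "remob_draw", si * 1000003L + r),
                sample(entry, s)))
    scores <- vapply(cand, evaluator, numeric(1))
    best <- which.max(scores)   # ties: first encountered
    entry <- cand[[best]]
    entry <- entry[order(match(entry, markerIds(G)))]
    out[[si]] <- .newSubset("RE_MOB", entry, score = scores[best])
    allScores[[si]] <- scores
  }
  attr(out, "scores") <- allScores
  out
}
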