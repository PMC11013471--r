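# Cross-validation, external validation, and the three experiment drivers:
# marker-strategy comparison, training-set size sweep, and the joint
# marker-by-training-set grid. Fold-level prediction abilities are aggregated
# as mean/min/max over all k x repetitions fold values (not repetition means).
# Folds whose phenotypes or predictions are degenerate (zero variance) are
# skipped with a warning and counted, never imputed as zero.

#' Random k-fold partition
#'
#' Splits \code{1:n} into k random folds whose sizes differ by at most one.
#'
#' @param n number of items (>= k).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return List of k integer index vectors (disjoint, union = 1:n).
#' @export
kfoldPartition <- function(n, k, seed = 1) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("n must be >= k", call. = FALSE)
  perm <- .withSeed(seed, sample.int(n))
  sizes <- rep(floor(n / k), k) + (seq_len(k) <= n %% k)
  split(perm, rep(seq_len(k), times = sizes))
}

#' Training/validation sizes of a single k-fold holdout
#'
#' The validation size is the nearest integer to n/k (exact .5 ties rounded
#' down) and the training size is the remainder; this reproduces the split
#' accounting 151/76 (n = 227, k = 3) and 886/221 (n = 1107, k = 5).
#'
#' @param n population size (> k).
#' @param k folds (>= 2).
#' @return Named integer vector c(train, validation).
#' @export
holdoutSplit <- function(n, k) {
  if (k < 2 || n <= k) stop("need n > k >= 2", call. = FALSE)
  v <- as.integer(ceiling(n / k - 0.5))
  c(train = as.integer(n - v), validation = v)
}

#' Repeated k-fold cross-validated prediction ability
#'
#' For every repetition and fold, an RR-BLUP model is fit on the out-of-fold
#' genotypes restricted to \code{markers} and the fold is predicted; the
#' fold-level Pearson correlations are aggregated.
#'
#' @param G a complete [GenotypeMatrix-class].
#' @param y named phenotype vector (ids in \code{G}).
#' @param markers marker ids to use (default: all).
#' @param k folds (default 10).
#' @param nRepetitions repetitions of the k-fold scheme (default 20).
#' @param seed integer seed.
#' @param lambda optional fixed ridge parameter.
#' @return List with \code{mean}, \code{min}, \code{max}, the vector
#'   \code{perFold} of fold-level r values, and \code{skipped} (count of
#'   degenerate folds).
#' @export
runCV <- function(G, y, markers = markerIds(G), k = 10, nRepetitions = 20,
                  seed = 1, lambda = NULL) {
  Gs <- G[, markers]
  ids <- names(y)
  rs <- numeric(0)
  skipped <- 0L
  for (rep in seq_len(nRepetitions)) {
    folds <- kfoldPartition(length(y), k, seed = .substream(seed, "cv_fold", rep))
    stopifnot(identical(sort(unname(unlist(folds))), seq_along(y)))
    for (fold in folds) {
      train <- setdiff(seq_along(y), fold)
      r <- tryCatch({
        fit <- fitRRBLUP(Gs[ids[train], ], y[train], lambda = lambda)
        predictionAbility(y[fold], predictGEBV(fit, Gs[ids[fold], ]))
      }, error = function(e) NA_real_)
      if (is.na(r)) {
        skipped <- skipped + 1L
        warning("skipping degenerate fold (zero variance)")
      } else {
        rs <- c(rs, r)
      }
    }
  }
  list(mean = mean(rs), min = min(rs), max = max(rs), perFold = rs,
       skipped = skipped)
}

#' External-validation prediction ability
#'
#' One RR-BLUP fit on all training genotypes; the prediction ability is the
#' Pearson correlation between the validation phenotypes and the predicted
#' GEBVs. Training and validation genotype id sets must be disjoint. A
#' degenerate fit (zero GEBV variance) yields NA with attribute
#' \code{degenerate = TRUE} and a warning.
#'
#' @param GTrain,yTrain training genotypes and phenotypes.
#' @param GVal,yVal validation genotypes and phenotypes.
#' @param markers marker ids to use (default: all training markers).
#' @param lambda optional fixed ridge parameter.
#' @return Numeric r (or flagged NA).
#' @export
runExternal <- function(GTrain, yTrain, GVal, yVal,
                        markers = markerIds(GTrain), lambda = NULL) {
  if (length(intersect(names(yTrain), names(yVal))))
    stop("training and validation genotype sets overlap", call. = FALSE)
  fit <- fitRRBLUP(GTrain[, markers], yTrain, lambda = lambda)
  gebv <- predictGEBV(fit, GVal[, markers])[names(yVal)]
  r <- tryCatch(predictionAbility(yVal, gebv), error = function(e) {
    warning("degenerate external validation (zero variance); returning NA")
    structure(NA_real_, degenerate = TRUE)
  })
  r
}

#' Compare marker-selection strategies over a size schedule
#'
#' Runs the requested strategies at every schedule size and reports
#' cross-validated (mean/min/max over fold-level values; for the random
#' strategy, over per-replicate means) and external prediction abilities,
#' plus an all-markers baseline row.
#'
#' @param G,y pruned training genotypes and phenotypes.
#' @param GVal,yVal external validation genotypes and phenotypes.
#' @param sizes schedule of subset sizes.
#' @param strategies subset of c("NRE_MB", "NRE_R", "RE_MAB", "RE_MOB").
#' @param k,nRepetitions cross-validation design (default 10-fold, 20 reps).
#' @param nRandomReps NRE-R replicates per size.
#' @param remobReps RE-MoB candidate models per size.
#' @param seed integer seed.
#' @param populationLabel label copied into the result rows.
#' @return data.frame with columns population, strategy, size, r_cv_mean,
#'   r_cv_min, r_cv_max, r_ev, n_models.
#' @export
runStrategyComparison <- function(G, y, GVal, yVal, sizes,
                                  strategies = c("NRE_MB", "NRE_R", "RE_MAB",
                                                 "RE_MOB"),
                                  k = 10, nRepetitions = 20,
                                  nRandomReps = 100, remobReps = 100,
                                  seed = 1, populationLabel = "pop") {
  strategies <- match.arg(strategies, several.ok = TRUE)
  rows <- list()
  addRow <- function(strategy, size, cv, rEv, nModels = 1L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      population = populationLabel, strategy = strategy, size = size,
      r_cv_mean = cv$mean, r_cv_min = cv$min, r_cv_max = cv$max,
      r_ev = as.numeric(rEv), n_models = nModels, stringsAsFactors = FALSE)
  }
  cvOf <- function(markers, s) runCV(G, y, markers, k = k,
                                     nRepetitions = nRepetitions,
                                     seed = .substream(seed, "cmp_cv", s))
  # baseline: all pruned markers, on the shared "cv_all" substream so the
  # grid driver's (all markers, fraction 1) cell reproduces it exactly
  addRow("ALL", nMarkers(G),
         runCV(G, y, k = k, nRepetitions = nRepetitions,
               seed = .substream(seed, "cv_all")),
         runExternal(G, y, GVal, yVal))
  fitFull <- NULL
  if ("NRE_MB" %in% strategies) {
    fitFull <- fitRRBLUP(G, y)
    for (sub in selectNREMB(fitFull, sizes))
      addRow("NRE_MB", sub@size, cvOf(sub@markerIds, sub@size),
             runExternal(G, y, GVal, yVal, markers = sub@markerIds))
  }
  if ("NRE_R" %in% strategies) {
    subs <- selectNRER(markerIds(G), sizes, nReps = nRandomReps,
                       seed = .substream(seed, "cmp_nrer"))
    evalCv <- cvEvaluator(G, y, k = k, seed = .substream(seed, "cmp_nrer_cv"))
    for (s in sizes) {
      these <- Filter(function(x) x@size == s, subs)
      rcv <- vapply(these, function(x) evalCv(x@markerIds), numeric(1))
      rev_ <- vapply(these, function(x)
        as.numeric(runExternal(G, y, GVal, yVal, markers = x@markerIds)),
        numeric(1))
      addRow("NRE_R", s,
             list(mean = mean(rcv), min = min(rcv), max = max(rcv)),
             mean(rev_, na.rm = TRUE), nModels = length(these))
    }
  }
  if ("RE_MAB" %in% strategies) {
    for (sub in selectREMaB(G, y, sizes))
      addRow("RE_MAB", sub@size, cvOf(sub@markerIds, sub@size),
             runExternal(G, y, GVal, yVal, markers = sub@markerIds))
  }
  if ("RE_MOB" %in% strategies) {
    subs <- selectREMoB(G, y, sizes, nReps = remobReps,
                        seed = .substream(seed, "cmp_remob"))
    for (sub in subs)
      addRow("RE_MOB", sub@size, cvOf(sub@markerIds, sub@size),
             runExternal(G, y, GVal, yVal, markers = sub@markerIds))
  }
  do.call(rbind, rows)
}

#' Training-set size sweep with EN, AN and random core selection
#'
#' For each fraction, selects EN and AN cores from the IBS distance matrix
#' and draws random cores of the same size; models trained on each core are
#' evaluated by cross-validation within the core and by external validation.
#' Random cores are summarized as mean/min/max over replicates.
#'
#' @param G,y training genotypes and phenotypes.
#' @param GVal,yVal external validation genotypes and phenotypes.
#' @param fractions core fractions (default 0.75, 0.5, 0.2, 0.1, 0.05).
#' @param methods subset of c("EN", "AN", "RANDOM").
#' @param nRandomReps random cores per fraction.
#' @param k,nRepetitions cross-validation design within cores; k is reduced
#'   (with a warning) when a core is too small for k folds.
#' @param nRestarts core-optimizer restarts.
#' @param seed integer seed.
#' @param populationLabel label copied into the result rows.
#' @return data.frame with columns population, method, fraction, core_size,
#'   r_cv_mean, r_cv_min, r_cv_max, r_ev, r_ev_min, r_ev_max, n_models.
#' @export
runTSSizeSweep <- function(G, y, GVal, yVal,
                           fractions = c(0.75, 0.5, 0.2, 0.1, 0.05),
                           methods = c("EN", "AN", "RANDOM"),
                           nRandomReps = 20, k = 10, nRepetitions = 20,
                           nRestarts = 10, seed = 1,
                           populationLabel = "pop") {
  methods <- match.arg(methods, several.ok = TRUE)
  D <- ibsDistance(G)
  ids <- names(y)
  D <- D[ids, ids]
  n <- length(ids)
  evalCore <- function(coreIdx, fr) {
    yc <- y[coreIdx]
    # every fold needs >= 3 genotypes for a defined correlation
    kk <- max(2, min(k, floor(length(coreIdx) / 3)))
    if (kk < k) warning(sprintf("core of %d too small for %d folds; using %d",
                                length(coreIdx), k, kk))
    cv <- runCV(G[ids[coreIdx], ], yc, k = kk, nRepetitions = nRepetitions,
                seed = .substream(seed, "sweep_cv", round(fr * 1000)))
    rev_ <- runExternal(G[ids[coreIdx], ], yc, GVal, yVal)
    list(cv = cv, rev = as.numeric(rev_))
  }
  rows <- list()
  for (fr in fractions) {
    sz <- coreSize(fr, n)
    for (method in methods) {
      if (method %in% c("EN", "AN")) {
        core <- selectCore(D, fr, method = method, nRestarts = nRestarts,
                           seed = .substream(seed, "sweep_core",
                                             round(fr * 1000)))
        ev <- evalCore(core@indices, fr)
        rows[[length(rows) + 1L]] <- data.frame(
          population = populationLabel, method = method, fraction = fr,
          core_size = sz, r_cv_mean = ev$cv$mean, r_cv_min = ev$cv$min,
          r_cv_max = ev$cv$max, r_ev = ev$rev, r_ev_min = NA_real_,
          r_ev_max = NA_real_, n_models = 1L, stringsAsFactors = FALSE)
      } else {
        cvm <- revs <- numeric(nRandomReps)
        for (rep in seq_len(nRandomReps)) {
          idx <- .withSeed(.substream(seed, "sweep_rand",
                                      round(fr * 1000) * 1000L + rep),
                           sort(sample.int(n, sz)))
          ev <- evalCore(idx, fr)
          cvm[rep] <- ev$cv$mean
          revs[rep] <- ev$rev
        }
        rows[[length(rows) + 1L]] <- data.frame(
          population = populationLabel, method = "RANDOM", fraction = fr,
          core_size = sz, r_cv_mean = mean(cvm), r_cv_min = min(cvm),
          r_cv_max = max(cvm), r_ev = mean(revs, na.rm = TRUE),
          r_ev_min = suppressWarnings(min(revs, na.rm = TRUE)),
          r_ev_max = suppressWarnings(max(revs, na.rm = TRUE)),
          n_models = nRandomReps, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Joint marker-number by training-set-size grid
#'
#' Crosses the marker-size schedule (via RE-MoB selection) with AN-core
#' training-set fractions: for every fraction an AN core is selected, RE-MoB
#' marker selection is re-run inside that core (no information from excluded
#' genotypes leaks into marker selection), and every (size, fraction) cell is
#' evaluated by cross-validation within the core and by external validation.
#' The full marker set and fraction 1.0 are always included, so the
#' (all-markers, 1.0) cell equals the unreduced baseline.
#'
#' @param G,y pruned training genotypes and phenotypes.
#' @param GVal,yVal external validation genotypes and phenotypes.
#' @param sizes marker-size schedule.
#' @param fractions training-set fractions.
#' @param k,nRepetitions cross-validation design (reduced in small cores as
#'   in [runTSSizeSweep()]).
#' @param remobReps RE-MoB candidates per size.
#' @param nRestarts core-optimizer restarts.
#' @param seed integer seed.
#' @param populationLabel label copied into the result rows.
#' @return Long-format data.frame with columns population, fraction,
#'   core_size, size, r_cv_mean, r_cv_min, r_cv_max, r_ev.
#' @export
runGrid <- function(G, y, GVal, yVal, sizes,
                    fractions = c(0.75, 0.5, 0.2, 0.1, 0.05), k = 10,
                    nRepetitions = 20, remobReps = 100, nRestarts = 10,
                    seed = 1, populationLabel = "pop") {
  D <- ibsDistance(G)
  ids <- names(y)
  D <- D[ids, ids]
  n <- length(ids)
  fractions <- unique(c(1.0, fractions))
  rows <- list()
  for (fr in fractions) {
    if (fr >= 1) {
      coreIdx <- seq_len(n)
    } else {
      core <- selectCore(D, fr, method = "AN", nRestarts = nRestarts,
                         seed = .substream(seed, "grid_core", round(fr * 1000)))
      coreIdx <- core@indices
    }
    Gc <- G[ids[coreIdx], ]
    yc <- y[coreIdx]
    szHere <- restrictSchedule(sizes, nMarkers(G))
    subs <- selectREMoB(Gc, yc, szHere, nReps = remobReps,
                        seed = .substream(seed, "grid_remob", round(fr * 1000)))
    markerSets <- c(list(markerIds(G)), lapply(subs, function(s) s@markerIds))
    setSizes <- c(nMarkers(G), vapply(subs, function(s) s@size, integer(1)))
    kk <- max(2, min(k, floor(length(coreIdx) / 3)))
    if (kk < k) warning(sprintf("core of %d too small for %d folds; using %d",
                                length(coreIdx), k, kk))
    for (si in seq_along(markerSets)) {
      cvSeed <- if (fr >= 1 && si == 1L) .substream(seed, "cv_all") else
        .substream(seed, "grid_cv", round(fr * 1000) * 100L + si)
      cv <- runCV(Gc, yc, markerSets[[si]], k = kk,
                  nRepetitions = nRepetitions, seed = cvSeed)
      rev_ <- runExternal(Gc, yc, GVal, yVal, markers = markerSets[[si]])
      rows[[length(rows) + 1L]] <- data.frame(
        population = populationLabel, fraction = fr,
        core_size = length(coreIdx), size = setSizes[si],
        r_cv_mean = cv$mean, r_cv_min = cv$min, r_cv_max = cv$max,
        r_ev = as.numeric(rev_), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
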