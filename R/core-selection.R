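# Selective phenotyping: identity-by-state distances and core-set selection.
# Two single objectives are supported:
#   EN - average entry-to-nearest-entry distance, maximized (diverse cores);
#   AN - average accession-to-nearest-entry distance over the whole
#        collection, minimized (representative cores).
# The optimizer is a restarted steepest single-swap local search: from a
# seeded random core, the best improving swap of one selected against one
# unselected genotype is applied until no swap improves, and the best of
# n restarts is returned. Nearest-entry ties resolve to the smallest index.

#' Identity-by-state genetic distance matrix
#'
#' \eqn{d(i,j) = \mathrm{mean}_k |g_{ik} - g_{jk}| / 2} on the \{0,1,2\}
#' dosage scale: 0 for identical genotypes, 1 for opposite homozygotes at
#' every marker. The companion kinship is \code{1 - d}.
#'
#' @param G a complete [GenotypeMatrix-class].
#' @return A symmetric n x n numeric matrix with zero diagonal, dimnames set
#'   to genotype ids.
#' @export
ibsDistance <- function(G) {
  d <- dosage(G)
  if (anyNA(d)) stop("IBS distance requires complete genotypes; impute first",
                     call. = FALSE)
  D <- as.matrix(stats::dist(d, method = "manhattan")) / (2 * ncol(d))
  dimnames(D) <- list(genotypeIds(G), genotypeIds(G))
  D
}

#' Core size for a sampling fraction
#'
#' Nearest integer to \code{fraction * n}, with exact .5 ties rounded down
#' (the convention consistent with core sizes 45, 55, 111, 113 and 553 for
#' 20\%/5\%/10\%/50\%/50\% of collections of 227 and 1107).
#'
#' @param fraction sampling fraction in (0, 1].
#' @param n collection size.
#' @return Integer core size (>= 1; smaller results are an error).
#' @export
coreSize <- function(fraction, n) {
  .assertScalarNumber(fraction, "fraction", 1e-12, 1)
  k <- as.integer(ceiling(fraction * n - 0.5))
  if (k < 1) stop("core size would be < 1 at this fraction", call. = FALSE)
  min(k, as.integer(n))
}

#' Average entry-to-nearest-entry distance (EN objective)
#'
#' Mean over selected entries of the distance to the closest other selected
#' entry. Maximizing yields diverse cores. Requires >= 2 entries.
#'
#' @param D symmetric distance matrix.
#' @param subset integer indices (or ids) of the selected entries.
#' @return The EN objective value.
#' @export
objectiveEN <- function(D, subset) {
  if (is.character(subset)) subset <- match(subset, rownames(D))
  if (length(subset) < 2) stop("EN objective needs at least 2 entries", call. = FALSE)
  sub <- D[subset, subset, drop = FALSE]
  diag(sub) <- Inf
  mean(.rowMins(sub))
}

#' Average accession-to-nearest-entry distance (AN objective)
#'
#' Mean over all accessions of the distance to the closest selected entry
#' (selected accessions contribute zero). Minimizing yields cores that
#' represent every accession of the collection.
#'
#' @param D symmetric distance matrix.
#' @param subset integer indices (or ids) of the selected entries (>= 1).
#' @return The AN objective value.
#' @export
objectiveAN <- function(D, subset) {
  if (is.character(subset)) subset <- match(subset, rownames(D))
  if (length(subset) < 1) stop("AN objective needs at least 1 entry", call. = FALSE)
  mean(.rowMins(D[, subset, drop = FALSE]))
}

# One steepest-descent local search from a given starting subset.
# Returns list(subset, objective, trace). `dir` = +1 minimizes (AN),
# -1 maximizes (EN) by minimizing the negated objective.
.swapSearch <- function(D, S, method, maxIter) {
  n <- nrow(D)
  evalObj <- if (method == "EN") function(s) -objectiveEN(D, s)
             else function(s) objectiveAN(D, s)
  cur <- evalObj(S)
  trace <- if (method == "EN") -cur else cur
  for (iter in seq_len(maxIter)) {
    C <- setdiff(seq_len(n), S)
    if (!length(C)) break
    bestVal <- cur
    bestSwap <- NULL
    if (method == "AN") {
      Dsel <- D[, S, drop = FALSE]
      n1pos <- apply(Dsel, 1, which.min)          # ties -> smallest index
      n1val <- Dsel[cbind(seq_len(n), n1pos)]
      n2val <- if (length(S) == 1L) rep(Inf, n) else
        apply(Dsel, 1, function(r) sort(r, partial = 2)[2])
      DC <- D[, C, drop = FALSE]
      for (p in seq_along(S)) {
        base <- ifelse(n1pos == p, n2val, n1val)
        objs <- colMeans(pmin(DC, base))   # matrix first so dims survive pmin
        b <- which.min(objs)
        if (objs[b] < bestVal - 1e-12) {
          bestVal <- objs[b]
          bestSwap <- c(p, C[b])
        }
      }
    } else {
      k <- length(S)
      Dss <- D[S, S, drop = FALSE]
      diag(Dss) <- Inf
      for (p in seq_len(k)) {
        Sm <- S[-p]
        sub <- Dss[-p, -p, drop = FALSE]
        base <- .rowMins(sub)                     # nearest within S minus p
        DCm <- D[Sm, C, drop = FALSE]
        aOwn <- .colMins(DCm)                     # candidate's own nearest
        objs <- -(colSums(pmin(DCm, base)) + aOwn) / k
        b <- which.min(objs)
        if (objs[b] < bestVal - 1e-12) {
          bestVal <- objs[b]
          bestSwap <- c(p, C[b])
        }
      }
    }
    if (is.null(bestSwap)) break
    S[bestSwap[1]] <- bestSwap[2]
    cur <- evalObj(S)    # re-derive exactly from the updated subset
    trace <- c(trace, if (method == "EN") -cur else cur)
  }
  list(subset = sort(S), objective = if (method == "EN") -cur else cur,
       trace = trace)
}

#' Select a core set under the EN or AN objective
#'
#' Restarted steepest single-swap local search: each restart starts from a
#' seeded random subset of the target size and repeatedly applies the best
#' improving swap (one selected out, one unselected in) until a local optimum;
#' the best restart wins (EN maximized, AN minimized). Deterministic under
#' \code{seed}; on small instances the result matches exhaustive enumeration.
#'
#' @param D symmetric IBS distance matrix (see [ibsDistance()]).
#' @param fraction core fraction of the collection in (0, 1]; the realized
#'   size is [coreSize()] unless \code{size} overrides it.
#' @param method "EN" or "AN".
#' @param nRestarts independent restarts (default 10).
#' @param maxIter maximum accepted swaps per restart.
#' @param seed integer seed.
#' @param size optional explicit core size (overrides \code{fraction}).
#' @return A [CoreSet-class].
#' @export
selectCore <- function(D, fraction, method = c("EN", "AN"), nRestarts = 10,
                       maxIter = 200, seed = 1, size = NULL) {
  method <- match.arg(method)
  n <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("g", seq_len(n))
  k <- if (is.null(size)) coreSize(fraction, n) else as.integer(size)
  if (method == "EN" && k < 2) stop("EN cores need size >= 2", call. = FALSE)
  if (k > n) stop("core size exceeds collection size", call. = FALSE)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    S0 <- .withSeed(.substream(seed, paste0("core_", method), r),
                    sort(sample.int(n, k)))
    res <- if (k == n) {
      list(subset = seq_len(n),
           objective = if (method == "EN") objectiveEN(D, seq_len(n))
                       else objectiveAN(D, seq_len(n)),
           trace = numeric(0))
    } else {
      .swapSearch(D, S0, method, maxIter)
    }
    better <- is.null(best) ||
      (method == "EN" && res$objective > best$objective + 1e-15) ||
      (method == "AN" && res$objective < best$objective - 1e-15)
    if (better) best <- res
  }
  new("CoreSet", method = method, fraction = if (is.null(size)) fraction else k / n,
      size = k, ids = rownames(D)[best$subset],
      indices = as.integer(best$subset), objectiveValue = best$objective,
      trace = best$trace)
}
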