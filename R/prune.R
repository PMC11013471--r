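# Sliding-window LD pruning. A single greedy left-to-right pass per
# chromosome: a marker is removed iff its squared dosage correlation with an
# already-retained marker inside the trailing window exceeds the threshold.
# The earlier marker of a high-LD pair is always the one kept, so the result
# is deterministic and order-stable, and no retained pair within a window can
# exceed the threshold.

#' Squared dosage correlation (composite LD) between two markers
#'
#' @param G a [GenotypeMatrix-class].
#' @param i,j marker ids or column indices.
#' @return Squared Pearson correlation of the two dosage columns, in [0, 1].
#'   A zero-variance (monomorphic) marker yields 0 with a warning, so
#'   monomorphic markers never trigger pruning.
#' @export
pairwiseR2 <- function(G, i, j) {
  d <- dosage(G)
  if (is.character(i)) i <- match(i, markerIds(G))
  if (is.character(j)) j <- match(j, markerIds(G))
  x <- d[, i]
  y <- d[, j]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero-variance marker in r2 computation; returning 0")
    return(0)
  }
  stats::cor(x, y)^2
}

#' Prune markers to approximate linkage equilibrium
#'
#' Greedy single-pass sliding-window pruning at a squared-correlation
#' threshold (default 0.95). Markers are scanned in map order (input order
#' when no map is attached); a marker is dropped iff some retained marker in
#' the trailing window has r-squared with it above the threshold. The window
#' is either the previous \code{windowSize - 1} markers (unit "snps") or all
#' retained markers within \code{windowBp} base pairs (unit "bp"; requires a
#' map).
#'
#' @param G a complete [GenotypeMatrix-class].
#' @param r2Threshold squared-correlation threshold in (0, 1].
#' @param windowSize number of consecutive markers per comparison window
#'   (>= 2; used when \code{windowUnit = "snps"}).
#' @param windowUnit "snps" or "bp".
#' @param windowBp window width in base pairs (when \code{windowUnit = "bp"}).
#' @return The retained [GenotypeMatrix-class], markers in original order.
#' @export
pruneLD <- function(G, r2Threshold = 0.95, windowSize = 100,
                    windowUnit = c("snps", "bp"), windowBp = 1e6) {
  windowUnit <- match.arg(windowUnit)
  .assertScalarNumber(r2Threshold, "r2Threshold", 1e-12, 1)
  if (windowSize < 2) stop("windowSize must be >= 2", call. = FALSE)
  if (windowUnit == "bp" && !length(G@pos))
    stop("bp windows require a marker map", call. = FALSE)
  d <- dosage(G)
  if (anyNA(d)) stop("prune requires complete genotypes; impute first", call. = FALSE)
  chrom <- if (length(G@chrom)) G@chrom else rep("all", nMarkers(G))
  sds <- apply(d, 2, stats::sd)
  keep <- logical(nMarkers(G))
  for (idx in split(seq_len(nMarkers(G)), factor(chrom, unique(chrom)))) {
    retained <- integer(0)
    for (j in idx) {
      if (length(retained)) {
        inWin <- if (windowUnit == "snps") {
          retained[retained > j - windowSize]
        } else {
          retained[G@pos[retained] >= G@pos[j] - windowBp]
        }
        inWin <- inWin[sds[inWin] > 0]
        if (length(inWin) && sds[j] > 0) {
          r2 <- as.numeric(stats::cor(d[, j], d[, inWin, drop = FALSE]))^2
          if (any(r2 > r2Threshold)) next
        }
      }
      retained <- c(retained, j)
      keep[j] <- TRUE
    }
  }
  G[, which(keep)]
}
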