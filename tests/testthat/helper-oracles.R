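# Independent test-side oracles. These deliberately re-derive quantities by
# brute force (dense solves, exhaustive enumeration, double loops) and never
# call the code paths they are used to check.

# quick GenotypeMatrix from a bare matrix
gm <- function(d, ...) {
  if (is.null(rownames(d))) rownames(d) <- paste0("g", seq_len(nrow(d)))
  cn <- colnames(d)
  if (is.null(cn) || anyDuplicated(cn) || any(cn == ""))
    colnames(d) <- paste0("m", seq_len(ncol(d)))
  genotypeMatrix(d, ...)
}

# Dense ridge solution at a fixed ridge parameter: GLS intercept from the
# kernel, then a direct (X'X + lambda I) solve.
ridgeOracle <- function(X, y, lambda) {
  Xc <- sweep(X, 2, colMeans(X))
  H <- tcrossprod(Xc) + lambda * diag(nrow(X))
  Hi <- solve(H)
  mu <- sum(Hi %*% y) / sum(Hi)
  beta <- solve(crossprod(Xc) + lambda * diag(ncol(X)), crossprod(Xc, y - mu))
  list(mu = mu, beta = as.numeric(beta))
}

# Brute-force REML profile over log(lambda): dense evaluation of the
# restricted likelihood on a grid, refined by optimize() in the winning
# bracket. Returns the maximizing lambda within [1e-6, 1e6].
remlOracle <- function(X, y, nGrid = 400) {
  t <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  K <- tcrossprod(Xc)
  f <- function(logl) {
    H <- K + exp(logl) * diag(t)
    Hi <- solve(H)
    mu <- sum(Hi %*% y) / sum(Hi)
    r <- y - mu
    -((t - 1) * log(c(crossprod(r, Hi %*% r))) +
        c(determinant(H)$modulus) + log(sum(Hi)))
  }
  grid <- seq(log(1e-6), log(1e6), length.out = nGrid)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(nGrid, i + 1)]
  exp(stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum)
}

# Independent greedy sliding-window pruner (index-window, earlier kept).
pruneOracle <- function(d, chrom, r2t, win) {
  keep <- integer(0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    kept <- integer(0)
    for (j in idx) {
      drop <- FALSE
      for (k in kept) {
        if (j - k < win && stats::sd(d[, j]) > 0 && stats::sd(d[, k]) > 0 &&
            stats::cor(d[, j], d[, k])^2 > r2t) {
          drop <- TRUE
          break
        }
      }
      if (!drop) kept <- c(kept, j)
    }
    keep <- c(keep, kept)
  }
  sort(keep)
}

# Exhaustive double-loop evaluation of the core objectives.
enOracle <- function(D, subset) {
  vals <- numeric(length(subset))
  for (ii in seq_along(subset)) {
    i <- subset[ii]
    vals[ii] <- min(D[i, setdiff(subset, i)])
  }
  mean(vals)
}

anOracle <- function(D, subset) {
  vals <- numeric(nrow(D))
  for (i in seq_len(nrow(D))) vals[i] <- min(D[i, subset])
  mean(vals)
}

# Exhaustive global optimum over all size-k subsets.
coreOptimumOracle <- function(D, k, method) {
  combs <- utils::combn(nrow(D), k)
  f <- if (method == "EN") function(s) enOracle(D, s) else function(s) anOracle(D, s)
  vals <- apply(combs, 2, f)
  if (method == "EN") max(vals) else min(vals)
}

# Hudson two-population FST estimator from sample allele frequencies.
hudsonFst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Mean silhouette width of labelled points (Euclidean).
meanSilhouette <- function(X, labels) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Minimal VCF text for fixtures.
writeFixtureVCF <- function(path, records, samples = c("s1", "s2", "s3")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}
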