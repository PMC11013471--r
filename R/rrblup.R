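# Ridge-regression BLUP. Model: y = 1*mu + Xc*u + e with u ~ N(0, varU * I_m),
# e ~ N(0, varE * I_t) and Xc the column-centered dosage matrix. Writing
# lambda = varE/varU, the BLUP of the marker effects is
#   beta = Xc' (Xc Xc' + lambda I)^-1 (y - mu*1)        (kernel form, t x t)
#        = (Xc'Xc + lambda I)^-1 Xc' (y - mu*1)         (ridge form, m x m)
# and mu is the generalized-least-squares intercept. lambda is estimated by
# REML, profiled to a one-dimensional optimization over log(lambda) using the
# spectral decomposition of the intercept-projected kernel (the standard
# efficient mixed-model / EMMA formulation).

.LAMBDA_RANGE <- c(1e-6, 1e6)

# Restricted log-likelihood (up to an additive constant) at ratio
# delta = varE/varU, from the eigenvalues theta of S K S (intercept projected
# out) and the rotated data eta = U' y.
.remlLL <- function(logDelta, theta, eta2) {
  delta <- exp(logDelta)
  nq <- length(theta)
  0.5 * (-nq * log(sum(eta2 / (theta + delta))) - sum(log(theta + delta)))
}

#' Fit a ridge-regression BLUP genomic prediction model
#'
#' Marker dosages are centered per marker (no variance standardization);
#' variance components are estimated by REML via a single one-dimensional
#' optimization of the restricted likelihood over \eqn{\log\lambda},
#' \eqn{\lambda = \sigma^2_e/\sigma^2_u}, bounded to [1e-6, 1e6], using the
#' spectral decomposition of the genotype kernel \eqn{X_cX_c'}. Marker
#' effects are the BLUP solution (kernel form when m > t, ridge form
#' otherwise; the two agree to numerical precision). A constant phenotype
#' yields a flagged degenerate fit (mu = mean, beta = 0).
#'
#' @param G a complete [GenotypeMatrix-class] containing all phenotyped
#'   genotypes.
#' @param y named numeric phenotype vector; names must be genotype ids of
#'   \code{G} (length >= 3).
#' @param lambda optional fixed ridge parameter; skips REML when supplied.
#' @return An [RRBLUPFit-class].
#' @examples
#' cfg <- simConfig("RIL", nGenotypes = 40, nMarkers = 120, nChromosomes = 4,
#'                  nQtl = 10, h2 = 0.8, seed = 3)
#' G <- simulatePopulation(cfg)
#' sim <- simulatePhenotype(G, cfg)
#' fit <- fitRRBLUP(G, sim$phenotype)
#' @export
fitRRBLUP <- function(G, y, lambda = NULL) {
  if (is.null(names(y))) stop("phenotype vector must be named by genotype id",
                              call. = FALSE)
  if (!all(names(y) %in% genotypeIds(G)))
    stop("phenotyped ids missing from the genotype matrix: ",
         paste(utils::head(setdiff(names(y), genotypeIds(G))), collapse = ", "),
         call. = FALSE)
  t <- length(y)
  if (t < 3) stop("need at least 3 phenotyped genotypes", call. = FALSE)
  X <- dosage(G)[names(y), , drop = FALSE]
  if (anyNA(X)) stop("genotypes contain missing dosages; impute first", call. = FALSE)
  m <- ncol(X)
  if (m < 1) stop("need at least one marker", call. = FALSE)
  center <- colMeans(X)
  if (stats::var(y) == 0) {
    return(new("RRBLUPFit", mu = unname(y[1]),
               beta = stats::setNames(numeric(m), colnames(X)),
               center = stats::setNames(center, colnames(X)),
               varU = 0, varE = 0, lambda = Inf, h2Hat = NA_real_,
               degenerate = TRUE))
  }
  Xc <- sweep(X, 2, center)
  K <- tcrossprod(Xc)
  varU <- varE <- NA_real_
  if (is.null(lambda)) {
    # REML: project out the intercept; shift by I so the projected-out
    # direction is identifiable among zero eigenvalues.
    ones <- rep(1, t)
    SKS <- K + diag(t)
    SKS <- SKS - ones %*% crossprod(ones, SKS) / t
    SKS <- SKS - (SKS %*% ones) %*% t(ones) / t
    eg <- eigen(SKS, symmetric = TRUE)
    theta <- pmax(eg$values[seq_len(t - 1)] - 1, 0)
    U <- eg$vectors[, seq_len(t - 1), drop = FALSE]
    eta2 <- as.numeric(crossprod(U, y))^2
    opt <- stats::optimize(.remlLL, log(.LAMBDA_RANGE), theta = theta,
                           eta2 = eta2, maximum = TRUE, tol = 1e-9)
    lambda <- exp(opt$maximum)
    varU <- sum(eta2 / (theta + lambda)) / (t - 1)
    varE <- lambda * varU
  }
  Hfac <- chol(K + lambda * diag(t))
  Hi <- backsolve(Hfac, forwardsolve(t(Hfac), cbind(y, 1)))
  mu <- sum(Hi[, 1]) / sum(Hi[, 2])
  r <- y - mu
  if (m > t) {
    Hir <- backsolve(Hfac, forwardsolve(t(Hfac), r))
    beta <- as.numeric(crossprod(Xc, Hir))
  } else {
    beta <- as.numeric(solve(crossprod(Xc) + lambda * diag(m), crossprod(Xc, r)))
  }
  sumVar <- sum(apply(Xc, 2, stats::var))
  h2Hat <- if (is.na(varU)) NA_real_ else varU * sumVar / (varU * sumVar + varE)
  new("RRBLUPFit", mu = unname(mu), beta = stats::setNames(beta, colnames(X)),
      center = stats::setNames(center, colnames(X)), varU = varU, varE = varE,
      lambda = lambda, h2Hat = h2Hat, degenerate = FALSE)
}

#' Predict genomic estimated breeding values (GEBVs)
#'
#' Computes \eqn{\mu + X_1\beta} for new genotypes, centering the new dosage
#' matrix with the training-set centering constants. The new panel must
#' contain every marker of the fit (extra markers are ignored; order is
#' corrected by id).
#'
#' @param fit an [RRBLUPFit-class].
#' @param G a complete [GenotypeMatrix-class].
#' @return A named numeric vector of GEBVs.
#' @export
predictGEBV <- function(fit, G) {
  need <- names(fit@beta)
  missing <- setdiff(need, markerIds(G))
  if (length(missing))
    stop("markers absent from the new genotype matrix: ",
         paste(utils::head(missing), collapse = ", "), call. = FALSE)
  X <- dosage(G)[, need, drop = FALSE]
  if (anyNA(X)) stop("genotypes contain missing dosages; impute first", call. = FALSE)
  Xc <- sweep(X, 2, fit@center)
  stats::setNames(as.numeric(fit@mu + Xc %*% fit@beta), genotypeIds(G))
}

#' Prediction ability: Pearson correlation of observed phenotype and GEBV
#'
#' @param yObs observed phenotypes.
#' @param gebv predicted breeding values (same length, >= 3).
#' @return Pearson r in [-1, 1]. Zero variance in either vector is an error
#'   (distinct from r = 0).
#' @export
predictionAbility <- function(yObs, gebv) {
  if (length(yObs) != length(gebv)) stop("length mismatch", call. = FALSE)
  if (length(yObs) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(yObs) == 0 || stats::var(gebv) == 0)
    stop("zero variance in observed or predicted values; correlation undefined",
         call. = FALSE)
  stats::cor(yObs, gebv)
}
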