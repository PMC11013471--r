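#' @import methods
NULL

# The missing-dosage sentinel is NA throughout; writers emit "NA" in tables
# and "./." in VCF so round-trips preserve missingness.

#' GenotypeMatrix: genotypes-by-markers dosage matrix with optional marker map
#'
#' Central container for SNP dosage data: an n-genotype by m-marker numeric
#' matrix counting copies of the alternate allele (0, 1, 2; NA for a missing
#' call; fractional values only after mean imputation), plus an optional
#' marker map (chromosome label and 1-based physical position per marker).
#' When a map is present markers are kept sorted by (chromosome, position).
#' Arbitrary provenance (simulation truth, family labels, genetic map) lives
#' in the \code{metadata} list.
#'
#' @slot dosage numeric matrix; rownames are genotype ids, colnames marker ids.
#' @slot chrom character vector of length 0 or m.
#' @slot pos numeric vector of length 0 or m (bp, 1-based).
#' @slot metadata list of optional annotations.
#'
#' @seealso [genotypeMatrix()] for the user constructor, [filterMarkers()],
#'   [imputeMean()], [pruneLD()].
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosage = "matrix", chrom = "character", pos = "numeric",
                 metadata = "list"),
  prototype(chrom = character(0), pos = numeric(0), metadata = list()))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  msgs <- character(0)
  if (!is.numeric(d)) msgs <- c(msgs, "dosage must be a numeric matrix")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    return("dosage must have genotype ids as rownames and marker ids as colnames")
  if (anyDuplicated(rownames(d))) msgs <- c(msgs, "genotype ids must be unique")
  if (anyDuplicated(colnames(d))) msgs <- c(msgs, "marker ids must be unique")
  v <- d[!is.na(d)]
  if (length(v) && (min(v) < 0 || max(v) > 2))
    msgs <- c(msgs, "non-missing dosages must lie in [0, 2]")
  m <- ncol(d)
  if (!length(object@chrom) %in% c(0L, m))
    msgs <- c(msgs, "chrom must have length 0 or ncol(dosage)")
  if (!length(object@pos) %in% c(0L, m))
    msgs <- c(msgs, "pos must have length 0 or ncol(dosage)")
  if (length(object@chrom) == m && length(object@pos) == m && m > 1) {
    # contiguous chromosome blocks, non-decreasing position within each
    r <- rle(object@chrom)
    if (anyDuplicated(r$values))
      msgs <- c(msgs, "markers on the same chromosome must be contiguous")
    for (ch in unique(object@chrom)) {
      if (is.unsorted(object@pos[object@chrom == ch]))
        msgs <- c(msgs, "marker positions must be sorted within chromosome")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix (genotypes x markers) with dimnames; entries
#'   in \{0, 1, 2\} or NA (fractional entries in [0, 2] are accepted, e.g.
#'   after imputation).
#' @param chrom,pos optional per-marker chromosome labels and physical
#'   positions; when supplied, columns are reordered by (chrom, pos).
#' @param metadata optional list of annotations carried along.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' d <- matrix(c(0, 1, 2, 0, 1, 1), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("m1", "m2")))
#' genotypeMatrix(d)
#' @export
genotypeMatrix <- function(dosage, chrom = character(0), pos = numeric(0),
                           metadata = list()) {
  storage.mode(dosage) <- "double"
  if (length(chrom) && length(pos)) {
    o <- order(chrom, pos)
    dosage <- dosage[, o, drop = FALSE]
    chrom <- chrom[o]
    pos <- pos[o]
    if (length(metadata$cm) == length(o)) metadata$cm <- metadata$cm[o]
  }
  new("GenotypeMatrix", dosage = dosage, chrom = as.character(chrom),
      pos = as.numeric(pos), metadata = metadata)
}

#' @describeIn genotypeMatrix Genotype identifiers (rownames).
#' @param x a GenotypeMatrix.
#' @export
genotypeIds <- function(x) rownames(x@dosage)

#' @describeIn genotypeMatrix Marker identifiers (colnames).
#' @export
markerIds <- function(x) colnames(x@dosage)

#' @describeIn genotypeMatrix The dosage matrix.
#' @export
dosage <- function(x) x@dosage

#' @describeIn genotypeMatrix Number of genotypes.
#' @export
nGenotypes <- function(x) nrow(x@dosage)

#' @describeIn genotypeMatrix Number of markers.
#' @export
nMarkers <- function(x) ncol(x@dosage)

#' @describeIn genotypeMatrix Marker map as a data.frame (marker, chrom, pos),
#'   or NULL when no map is attached.
#' @export
markerMap <- function(x) {
  if (!length(x@chrom)) return(NULL)
  data.frame(marker = markerIds(x), chrom = x@chrom, pos = x@pos,
             stringsAsFactors = FALSE)
}

setMethod("show", "GenotypeMatrix", function(object) {
  nmiss <- sum(is.na(object@dosage))
  cat(sprintf("GenotypeMatrix: %d genotypes x %d markers", nGenotypes(object),
              nMarkers(object)))
  if (length(object@chrom))
    cat(sprintf(" on %d chromosome(s)", length(unique(object@chrom))))
  if (nmiss) cat(sprintf("; %d missing calls", nmiss))
  cat("\n")
})

#' @export
setMethod("[", signature(x = "GenotypeMatrix"),
  function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nGenotypes(x))
    if (missing(j)) j <- seq_len(nMarkers(x))
    if (is.character(j)) j <- match(j, markerIds(x))
    if (anyNA(j)) stop("unknown marker ids in subset")
    j <- sort(j)   # marker subsets keep map order
    d <- x@dosage[i, j, drop = FALSE]
    md <- x@metadata
    if (length(md$cm) == nMarkers(x)) md$cm <- md$cm[j]
    new("GenotypeMatrix", dosage = d,
        chrom = if (length(x@chrom)) x@chrom[j] else character(0),
        pos = if (length(x@pos)) x@pos[j] else numeric(0),
        metadata = md)
  })

#' RRBLUPFit: fitted ridge-regression BLUP model
#'
#' Holds the intercept, shrunken marker effects, REML variance components and
#' the per-marker centering constants of an RR-BLUP fit
#' (\eqn{y = \mu + X\beta + e}).
#'
#' @slot mu numeric(1) intercept (generalized-least-squares estimate).
#' @slot beta named numeric vector of marker effects.
#' @slot center named numeric vector of training-set column means.
#' @slot varU,varE marker-effect and residual variance components (NA when a
#'   fixed ridge parameter was supplied).
#' @slot lambda ridge parameter varE/varU.
#' @slot h2Hat genomic heritability estimate implied by the variance
#'   components and the training markers.
#' @slot degenerate TRUE when the phenotype had zero variance (mu = mean,
#'   beta = 0).
#' @seealso [fitRRBLUP()], [predictGEBV()].
#' @exportClass RRBLUPFit
setClass("RRBLUPFit",
  representation(mu = "numeric", beta = "numeric", center = "numeric",
                 varU = "numeric", varE = "numeric", lambda = "numeric",
                 h2Hat = "numeric", degenerate = "logical"))

setValidity("RRBLUPFit", function(object) {
  if (length(object@beta) != length(object@center))
    return("beta and center must have equal length")
  if (is.null(names(object@beta))) return("beta must be named by marker id")
  TRUE
})

#' @describeIn fitRRBLUP Marker effects of a fit, named by marker id.
#' @export
markerEffects <- function(fit) fit@beta

#' @describeIn fitRRBLUP Intercept of a fit.
#' @export
intercept <- function(fit) fit@mu

#' @describeIn fitRRBLUP Variance components as c(varU, varE, lambda).
#' @export
varianceComponents <- function(fit)
  c(varU = fit@varU, varE = fit@varE, lambda = fit@lambda)

setMethod("show", "RRBLUPFit", function(object) {
  cat(sprintf("RRBLUPFit: %d markers; mu = %.4g; lambda = %.4g",
              length(object@beta), object@mu, object@lambda))
  if (!is.na(object@h2Hat)) cat(sprintf("; genomic h2 = %.3f", object@h2Hat))
  if (object@degenerate) cat(" [degenerate: zero phenotypic variance]")
  cat("\n")
})

#' MarkerSubset: one selected low-density marker panel
#'
#' @slot strategy one of "NRE_MB", "NRE_R", "RE_MAB", "RE_MOB", "ALL".
#' @slot size number of markers.
#' @slot markerIds selected marker ids.
#' @slot replicate replicate index (random strategy), NA otherwise.
#' @slot score internal evaluator score (model-based strategy), NA otherwise.
#' @exportClass MarkerSubset
setClass("MarkerSubset",
  representation(strategy = "character", size = "integer",
                 markerIds = "character", replicate = "integer",
                 score = "numeric"),
  prototype(replicate = NA_integer_, score = NA_real_))

setValidity("MarkerSubset", function(object) {
  if (length(object@markerIds) != object@size)
    return("markerIds length must equal size")
  if (anyDuplicated(object@markerIds)) return("markerIds must be unique")
  TRUE
})

setMethod("show", "MarkerSubset", function(object) {
  cat(sprintf("MarkerSubset [%s] size %d", object@strategy, object@size))
  if (!is.na(object@replicate)) cat(sprintf(" replicate %d", object@replicate))
  if (!is.na(object@score)) cat(sprintf(" (score %.4f)", object@score))
  cat("\n")
})

#' @describeIn selectNREMB Marker ids of a subset.
#' @param subset a MarkerSubset.
#' @export
subsetMarkers <- function(subset) subset@markerIds

#' CoreSet: a selected core collection of genotypes
#'
#' @slot method "EN" (maximize entry-to-nearest-entry distance) or "AN"
#'   (minimize accession-to-nearest-entry distance).
#' @slot fraction requested core fraction of the collection.
#' @slot size realized core size.
#' @slot ids,indices selected genotype ids and their positions in the
#'   distance matrix.
#' @slot objectiveValue objective evaluated on the selected core.
#' @slot trace best objective value after each accepted swap (per best
#'   restart).
#' @exportClass CoreSet
setClass("CoreSet",
  representation(method = "character", fraction = "numeric", size = "integer",
                 ids = "character", indices = "integer",
                 objectiveValue = "numeric", trace = "numeric"))

setValidity("CoreSet", function(object) {
  if (anyDuplicated(object@indices)) return("core indices must be unique")
  if (length(object@indices) != object@size) return("indices length != size")
  TRUE
})

setMethod("show", "CoreSet", function(object) {
  cat(sprintf("CoreSet [%s] %d genotypes (fraction %.2f), objective %.5f\n",
              object@method, object@size, object@fraction,
              object@objectiveValue))
})

#' @describeIn selectCore Genotype ids of a core set.
#' @param core a CoreSet.
#' @export
coreIds <- function(core) core@ids

#' @describeIn selectCore Objective value of a core set.
#' @export
coreObjective <- function(core) core@objectiveValue
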