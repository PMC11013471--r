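# Reading/writing genotype and phenotype data, marker quality filters, and
# mean imputation. Dosages are stored VCF-style as alternate-allele counts
# {0,1,2}; the prediction engine centers internally.

.GT_CODES <- c("0/0" = 0, "0|0" = 0, "1/0" = 1, "0/1" = 1, "1|0" = 1,
               "0|1" = 1, "1/1" = 2, "1|1" = 2)

#' Read a biallelic SNP VCF into a GenotypeMatrix
#'
#' Parses a VCF 4.x file (optionally gzipped) and converts GT fields into
#' alternate-allele dosages. Only biallelic SNP records are accepted;
#' a multiallelic record is an error naming the offending record. Missing
#' genotypes (\code{./.} or \code{.}) become NA.
#'
#' @param path path to a VCF file.
#' @return A [GenotypeMatrix-class] with chromosome/position map.
#' @export
readGenotypesVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  bad <- grepl(",", alt) | nchar(fix[, "REF"]) != 1L | nchar(alt) != 1L
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("record %s:%s is not a biallelic SNP (REF=%s, ALT=%s)",
                 fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], fix[i, "ALT"]),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(rownames(fix), names(gt)))
  samples <- colnames(gt)
  if (anyDuplicated(samples)) stop("duplicate sample names in VCF", call. = FALSE)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  d <- matrix(NA_real_, nrow = length(samples), ncol = nrow(gt),
              dimnames = list(samples, ids))
  for (j in seq_len(nrow(gt))) {
    g <- gt[j, ]
    miss <- is.na(g) | g %in% c("./.", ".|.", ".")
    code <- .GT_CODES[g]
    if (any(!miss & is.na(code)))
      stop(sprintf("unparseable GT '%s' at record %s", g[which(!miss & is.na(code))[1]],
                   ids[j]), call. = FALSE)
    code[miss] <- NA_real_
    d[, j] <- code
  }
  genotypeMatrix(d, chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]))
}

#' Write a GenotypeMatrix as a minimal biallelic VCF 4.2
#'
#' Dosages must be integral (0/1/2 or NA); alleles are written as placeholder
#' A (reference) and T (alternate). Missing dosages become \code{./.}.
#'
#' @param G a GenotypeMatrix.
#' @param path output path.
#' @export
writeGenotypesVCF <- function(G, path) {
  d <- dosage(G)
  v <- d[!is.na(d)]
  if (length(v) && any(v != round(v)))
    stop("cannot write fractional (imputed) dosages as VCF genotypes", call. = FALSE)
  chrom <- if (length(G@chrom)) G@chrom else rep("1", nMarkers(G))
  pos <- if (length(G@pos)) G@pos else seq_len(nMarkers(G))
  gtstr <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypeIds(G)), collapse = "\t")), con)
  for (j in seq_len(nMarkers(G))) {
    g <- d[, j]
    calls <- ifelse(is.na(g), "./.", gtstr[g + 1])
    writeLines(paste(c(chrom[j], format(pos[j], scientific = FALSE),
                       markerIds(G)[j], "A", "T", ".", "PASS", ".", "GT",
                       calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a delimited dosage table into a GenotypeMatrix
#'
#' Rows are genotypes (first column holds genotype ids), remaining columns are
#' markers named in the header; entries must be 0, 1, 2 or NA. An optional
#' companion map file (columns marker, chrom, pos; tab-separated with header)
#' attaches physical positions.
#'
#' @param path path to the dosage table (tab- or comma-separated, by
#'   extension: .csv uses comma).
#' @param mapPath optional path to a marker map TSV.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypesTable <- function(path, mapPath = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("dosage table needs an id column plus >= 1 marker", call. = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids)) stop("duplicate genotype ids in dosage table", call. = FALSE)
  markers <- colnames(tab)[-1]
  d <- matrix(NA_real_, nrow = length(ids), ncol = length(markers),
              dimnames = list(ids, markers))
  for (j in seq_along(markers)) {
    x <- tab[[j + 1]]
    miss <- is.na(x) | x %in% c("NA", "")
    val <- suppressWarnings(as.numeric(x))
    ok <- miss | (!is.na(val) & val %in% c(0, 1, 2))
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("invalid dosage '%s' at genotype '%s', marker '%s'",
                   x[i], ids[i], markers[j]), call. = FALSE)
    }
    val[miss] <- NA_real_
    d[, j] <- val
  }
  chrom <- character(0); pos <- numeric(0)
  if (!is.null(mapPath)) {
    mp <- utils::read.table(mapPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    idx <- match(markers, mp$marker)
    if (anyNA(idx)) stop("map file is missing markers present in the table", call. = FALSE)
    chrom <- as.character(mp$chrom[idx])
    pos <- as.numeric(mp$pos[idx])
  }
  genotypeMatrix(d, chrom = chrom, pos = pos)
}

#' Write a GenotypeMatrix as a dosage table (and optional map file)
#'
#' @param G a GenotypeMatrix.
#' @param path output path (.csv for comma-separated, else tab-separated).
#' @param mapPath optional path for the marker map TSV.
#' @export
writeGenotypesTable <- function(G, path, mapPath = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- data.frame(id = genotypeIds(G), dosage(G), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(mapPath)) {
    mm <- markerMap(G)
    if (is.null(mm)) stop("no marker map attached to this GenotypeMatrix", call. = FALSE)
    utils::write.table(mm, mapPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a two-column phenotype TSV (genotype id, trait value)
#'
#' A header line is detected automatically (first line whose second field is
#' not numeric). Duplicate ids, non-numeric values and empty files are errors.
#'
#' @param path path to the TSV.
#' @return A named numeric vector of trait values.
#' @export
readPhenotypes <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("cannot read phenotype file: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(tab) == 0 || ncol(tab) < 2)
    stop("phenotype file must have >= 1 row and two columns (id, value)", call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(tab[1, 2])))) tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0) stop("phenotype file contains no data rows", call. = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate genotype id '%s' in phenotype file",
                 ids[duplicated(ids)][1]), call. = FALSE)
  vals <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(vals))
    stop(sprintf("non-numeric phenotype value '%s' for id '%s'",
                 tab[[2]][which(is.na(vals))[1]], ids[which(is.na(vals))[1]]),
         call. = FALSE)
  stats::setNames(vals, ids)
}

#' Write a phenotype vector as a two-column TSV
#'
#' @param y named numeric vector.
#' @param path output path.
#' @export
writePhenotypes <- function(y, path) {
  utils::write.table(data.frame(id = names(y), value = unname(y)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter markers on missingness and minor-allele frequency
#'
#' Retains exactly the markers whose proportion of missing calls is at most
#' \code{maxMissingProp} and whose minor-allele frequency (computed on
#' non-missing dosages) is at least \code{minMaf}; marker order is preserved.
#' Applying the filter twice equals applying it once.
#'
#' @param G a GenotypeMatrix.
#' @param maxMissingProp maximum tolerated proportion of missing calls per
#'   marker, in [0, 1].
#' @param minMaf minimum minor-allele frequency, in [0, 0.5).
#' @return The filtered [GenotypeMatrix-class] (possibly with zero markers).
#' @export
filterMarkers <- function(G, maxMissingProp = 0.8, minMaf = 0.05) {
  .assertScalarNumber(maxMissingProp, "maxMissingProp", 0, 1)
  .assertScalarNumber(minMaf, "minMaf", 0, 0.5 - 1e-12)
  d <- dosage(G)
  missProp <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0   # all-missing marker: fails any MAF threshold > 0
  keep <- missProp <= maxMissingProp & maf >= minMaf
  G[, which(keep)]
}

#' Impute missing dosages by the marker mean
#'
#' Each missing call is replaced by the mean of the marker's non-missing
#' dosages (fractional values allowed afterwards); the non-missing mean of
#' every marker is preserved exactly. A marker with no observed calls is an
#' error.
#'
#' @param G a GenotypeMatrix.
#' @return A complete [GenotypeMatrix-class].
#' @export
imputeMean <- function(G) {
  d <- dosage(G)
  nmiss <- colSums(is.na(d))
  if (any(nmiss == nrow(d)))
    stop(sprintf("marker '%s' has no observed dosages; cannot impute",
                 markerIds(G)[which(nmiss == nrow(d))[1]]), call. = FALSE)
  if (!any(nmiss > 0)) return(G)
  for (j in which(nmiss > 0)) {
    x <- d[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    d[, j] <- x
  }
  initialize(G, dosage = d)
}
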