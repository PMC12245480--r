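# Containers for biallelic SNP calls and the sample-to-population mapping.

#' Biallelic SNP genotype matrix
#'
#' Stores unphased diploid alternate-allele counts (0, 1, 2; `NA` = missing)
#' for biallelic SNPs, one row per site and one column per sample.
#'
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt`;
#'   positions must be strictly increasing within each chromosome.
#' @param calls integer matrix, `nrow(sites)` x n_samples, values in
#'   \{0, 1, 2, NA\}; column names are sample identifiers.
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(sites, calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
    stop_("`sites` needs columns chrom, pos, ref, alt")
  if (nrow(sites) != nrow(calls))
    stop_("`sites` and `calls` disagree on the number of sites")
  if (is.null(colnames(calls)))
    stop_("`calls` must have sample names as column names")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop_("genotype calls must be diploid allele counts in {0, 1, 2} or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop_(sprintf("positions must be strictly increasing within chrom %s", ch))
  }
  structure(list(sites = as.data.frame(sites), calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic sites x %d samples (%.2f%% missing)\n",
              nrow(x$sites), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Sample-to-population map with a designated outgroup
#'
#' @param samples character vector of sample identifiers.
#' @param populations character vector of the same length; population labels.
#' @param outgroup one of the population labels, used as O in the
#'   four-taxon site-pattern tests.
#' @return An object of class `"population_map"`: a data frame with columns
#'   `sample` and `population` and an `outgroup` attribute.
#' @export
population_map <- function(samples, populations, outgroup) {
  if (length(samples) != length(populations))
    stop_("`samples` and `populations` must have equal length")
  if (anyDuplicated(samples)) stop_("duplicated sample identifiers")
  if (length(outgroup) != 1L || !outgroup %in% populations)
    stop_("`outgroup` must name exactly one non-empty population")
  structure(data.frame(sample = as.character(samples),
                       population = as.character(populations),
                       stringsAsFactors = FALSE),
            outgroup = as.character(outgroup),
            class = c("population_map", "data.frame"))
}

#' @export
print.population_map <- function(x, ...) {
  tab <- table(x$population)
  cat(sprintf("population_map: %d samples in %d populations (outgroup: %s)\n",
              nrow(x), length(tab), attr(x, "outgroup")))
  print(tab)
  invisible(x)
}

outgroup_of <- function(pops) attr(pops, "outgroup")

# Check every matrix sample is mapped; returns the map restricted and ordered
# to the matrix columns.
match_popmap <- function(geno, pops) {
  idx <- match(colnames(geno$calls), pops$sample)
  if (anyNA(idx)) {
    missing <- colnames(geno$calls)[is.na(idx)][1:min(3, sum(is.na(idx)))]
    stop_("samples missing from population map: ",
          paste(missing, collapse = ", "))
  }
  pops[idx, , drop = FALSE]
}
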