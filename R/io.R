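# Readers and writers for the pipeline's file dialects: trait CSV, minimal
# VCF 4.2 (GT only), popmap TSV, occurrence CSV, TSV/JSON reports.

#' Read a trait table CSV
#'
#' Expects a header `individual,group,<trait columns...>`. Rows with any
#' missing trait value are dropped with a warning; trait columns must be
#' numeric; the group column must have exactly two levels when
#' `require_two_groups = TRUE` (the delimitation mode).
#'
#' @param path CSV file path.
#' @param require_two_groups enforce exactly two group levels (default TRUE).
#' @return Data frame `individual`, `group`, trait columns.
#' @export
read_traits <- function(path, require_two_groups = TRUE) {
  x <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("individual", "group") %in% names(x)))
    stop_("trait CSV needs `individual` and `group` columns: ", path)
  tr_cols <- setdiff(names(x), c("individual", "group"))
  if (!length(tr_cols)) stop_("no trait columns found in ", path)
  for (cc in tr_cols) {
    if (!is.numeric(x[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[cc]]))) & !is.na(x[[cc]]))
      stop_(sprintf("non-numeric values in trait column `%s` (e.g. row %d)",
                    cc, if (length(bad)) bad[1] else NA_integer_))
    }
  }
  complete <- stats::complete.cases(x[tr_cols])
  if (any(!complete)) {
    warning(sprintf("dropped %d row(s) with missing trait values", sum(!complete)),
            call. = FALSE)
    x <- x[complete, , drop = FALSE]
  }
  lv <- unique(x$group)
  if (require_two_groups && length(lv) != 2L)
    stop_(sprintf("group column must have exactly 2 levels, found %d: %s",
                  length(lv), paste(lv, collapse = ", ")))
  x
}

#' Write a trait table CSV
#' @param traits data frame `individual`, `group`, trait columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read biallelic SNPs from a VCF
#'
#' Parses a VCF 4.x with vcfR, keeps biallelic SNP records only
#' (multiallelic sites and indels are skipped, with counts reported via a
#' message) and converts the GT field to diploid alternate-allele counts.
#' Phased (`|`) genotypes are accepted as unphased; `./.` and `.` become
#' missing.
#'
#' @param path VCF path (plain text or gzipped).
#' @param verbose print the skip counts (default TRUE).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, verbose = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE],
                       stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  snp <- nchar(fix$REF) == 1L & nchar(ifelse(multi, "NN", fix$ALT)) == 1L
  keep <- !multi & snp
  if (verbose && any(!keep))
    message(sprintf("read_vcf: skipped %d multiallelic and %d non-SNP record(s)",
                    sum(multi), sum(!snp & !multi)))
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  rownames(gt) <- NULL
  gt <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (code in names(lut)) calls[gt == code] <- lut[[code]]
  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, calls)
}

#' Write a genotype matrix as a minimal VCF 4.2
#'
#' GT-only records (`0/0`, `0/1`, `1/1`, `./.`), one contig line per
#' chromosome. Round-trips through [read_vcf()].
#'
#' @param geno a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(geno$sites$chrom)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(geno$calls)),
                   collapse = "\t"), con)
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(geno$calls), ncol(geno$calls))
  ok <- !is.na(geno$calls)
  gt[ok] <- code[geno$calls[ok] + 1L]
  body <- paste(geno$sites$chrom, geno$sites$pos, ".", geno$sites$ref,
                geno$sites$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a sample-to-population map TSV
#'
#' Two tab-separated columns, `sample<TAB>population`, no header.
#'
#' @param path TSV path.
#' @param outgroup population label to flag as the outgroup.
#' @return A [population_map()].
#' @export
read_popmap <- function(path, outgroup) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("sample", "population"))
  population_map(x$sample, x$population, outgroup)
}

#' Write a sample-to-population map TSV
#' @param pops a [population_map()] (or data frame with `sample`,
#'   `population`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pops, path) {
  utils::write.table(pops[, c("sample", "population")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read occurrence records CSV
#'
#' Header `id,lon,lat`; coordinates in WGS84 decimal degrees, lon before lat.
#'
#' @param path CSV path.
#' @return Data frame `id`, `lon`, `lat`.
#' @export
read_occurrences <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(x)))
    stop_("occurrence CSV needs `lon` and `lat` columns (lon,lat order): ", path)
  if (!"id" %in% names(x)) x$id <- sprintf("occ_%03d", seq_len(nrow(x)))
  x[, c("id", "lon", "lat")]
}

#' Write occurrence records CSV
#' @param points data frame `id`, `lon`, `lat`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(points, path) {
  write.csv(points[, c("id", "lon", "lat")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write the trio table as a TSV mirroring the standard report layout
#'
#' Column header tokens: `P1, P2, P3, D-statistic, Z-score, p-value,
#' f4-ratio, BBAA, ABBA, BABA`.
#'
#' @param res a [dtrios()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dtrios <- function(res, path) {
  out <- data.frame(P1 = res$P1, P2 = res$P2, P3 = res$P3,
                    `D-statistic` = res$D, `Z-score` = res$Z,
                    `p-value` = res$p, `f4-ratio` = res$f4_ratio,
                    BBAA = res$BBAA, ABBA = res$ABBA, BABA = res$BABA,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON report for a morphological-gap analysis
#'
#' @param res a [morph_gap()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_morphogap_report <- function(res, path) {
  stopifnot(inherits(res, "morph_gap"))
  report <- list(
    var_fraction = res$pca$var_fraction,
    loadings = as.data.frame(res$pca$loadings),
    n_modes = res$modes$n_modes,
    mode_alpha = res$modes$mode_alpha,
    antimode_alpha = res$modes$antimode_alpha,
    beta_method = res$tolerance$method,
    gamma = res$tolerance$gamma,
    alpha = res$tolerance$alpha,
    beta1 = res$tolerance$beta1,
    beta2 = res$tolerance$beta2,
    min_joint_overlap = res$decision$min_joint_overlap,
    alpha_star = res$decision$alpha_star,
    threshold = res$decision$threshold,
    supported = res$decision$supported)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a JSON report for geographic range metrics
#' @param res a [range_metrics()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_range_report <- function(res, path) {
  stopifnot(inherits(res, "range_metrics"))
  jsonlite::write_json(unclass(res), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Run provenance sidecar: config, seed, package version, timestamp.
write_provenance <- function(path, config) {
  meta <- list(package = "crypsis",
               version = as.character(utils::packageVersion("crypsis")),
               r_version = as.character(getRversion()),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = config)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
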