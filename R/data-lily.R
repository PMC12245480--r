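#' Published ABBA-BABA trio table for the alpine lily system
#'
#' The 20 oriented trios reported for the six population units (GYD1401,
#' *L. nanum*, *L. lophophorum*, *L. pseudonanum*, pop1 = campanulate-flowered
#' relatives, pop2 = Duchartrei lineage) against the outgroup: D-statistic,
#' jackknife Z, p, f4-ratio and the weighted BBAA/ABBA/BABA pattern counts.
#' Used as a worked example and as a consistency check that [dstat()]
#' reproduces each printed D from its printed ABBA/BABA cells.
#'
#' @return Data frame with columns `P1, P2, P3, D, Z, p, f4_ratio, BBAA,
#'   ABBA, BABA`.
#' @export
lily_trio_table <- function() {
  path <- system.file("extdata", "lily_trios.tsv", package = "crypsis",
                      mustWork = TRUE)
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(x) <- c("P1", "P2", "P3", "D", "Z", "p", "f4_ratio",
                "BBAA", "ABBA", "BABA")
  x
}
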