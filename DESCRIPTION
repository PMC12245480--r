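Package: crypsis
Title: Delimitation of Cryptic Species from Morphometric, Genomic and
    Geographic Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing putative cryptic species boundaries by
    combining three independent lines of evidence: (1) morphological-gap
    analysis in a PCA morphospace, using two-component multivariate normal
    mixtures, the ridgeline manifold of Ray and Lindsay, and elliptical
    tolerance-region overlap at a fixed frequency threshold; (2) ABBA-BABA
    site-pattern tests of introgression (Patterson's D with block-jackknife
    significance and the f4-ratio admixture fraction) from biallelic SNP
    genotypes; and (3) IUCN geographic range metrics (extent of occurrence
    and area of occupancy with a criterion-B2 category suggestion). A
    synthetic-data module generates trait tables, drift-structured
    genotype matrices with a tunable introgression fraction, and clustered
    occurrence records with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    mvtnorm,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
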