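# ABBA-BABA site-pattern statistics: frequency-weighted pattern counts,
# Patterson's D, block-jackknife significance and the f4-ratio admixture
# fraction, for every population trio against a designated outgroup.

#' Per-site, per-population alternate-allele frequencies
#'
#' @param geno a [genotype_matrix()].
#' @param pops a [population_map()] covering every sample in `geno`.
#' @return List of class `"site_frequencies"`: `freq` (populations x sites
#'   matrix, `NA` where a population has no non-missing call), `n_alleles`
#'   (non-missing allele counts, same shape) and `populations`.
#' @export
site_frequencies <- function(geno, pops) {
  stopifnot(inherits(geno, "genotype_matrix"))
  pops <- match_popmap(geno, pops)
  labels <- unique(pops$population)
  freq <- matrix(NA_real_, length(labels), nrow(geno$sites),
                 dimnames = list(labels, NULL))
  n_all <- matrix(0L, length(labels), nrow(geno$sites),
                  dimnames = list(labels, NULL))
  for (pop in labels) {
    cols <- which(pops$population == pop)
    if (!length(cols)) stop_("population with zero samples: ", pop)
    m <- geno$calls[, cols, drop = FALSE]
    alt <- rowSums(m, na.rm = TRUE)
    n <- 2L * rowSums(!is.na(m))
    freq[pop, ] <- ifelse(n > 0L, alt / n, NA_real_)
    n_all[pop, ] <- n
  }
  structure(list(freq = freq, n_alleles = n_all, populations = labels,
                 outgroup = outgroup_of(pops)),
            class = "site_frequencies")
}

#' Per-site BBAA/ABBA/BABA pattern weights for one trio
#'
#' Uses the polarisation-symmetric frequency weighting: with population
#' alternate-allele frequencies `p1, p2, p3, pO`,
#' \deqn{abba = (1-p_1)p_2p_3(1-p_O) + p_1(1-p_2)(1-p_3)p_O}
#' and correspondingly for `baba` and `bbaa`, so both assignments of the
#' ancestral state are weighted and results do not depend on ref/alt
#' polarity. A single-term outgroup-derived mode (`symmetric = FALSE`) drops
#' the second term of each weight.
#'
#' @param freqs a [site_frequencies()].
#' @param trio character vector of three population labels (P1, P2, P3).
#' @param outgroup outgroup population label (defaults to the map's).
#' @param symmetric use the two-term polarisation-symmetric weights
#'   (default `TRUE`).
#' @return Data frame with per-site columns `bbaa`, `abba`, `baba` and
#'   logical `used` (all four populations have data). Rows where
#'   `used` is `FALSE` carry zero weight.
#' @export
pattern_weights <- function(freqs, trio, outgroup = NULL, symmetric = TRUE) {
  stopifnot(inherits(freqs, "site_frequencies"))
  outgroup <- outgroup %||% freqs$outgroup
  labs <- c(trio, outgroup)
  if (length(labs) != 4L || anyDuplicated(labs))
    stop_("`trio` plus outgroup must be four distinct population labels")
  miss <- setdiff(labs, rownames(freqs$freq))
  if (length(miss)) stop_("unknown population(s): ", paste(miss, collapse = ", "))
  p1 <- freqs$freq[trio[1], ]; p2 <- freqs$freq[trio[2], ]
  p3 <- freqs$freq[trio[3], ]; pO <- freqs$freq[outgroup, ]
  used <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(pO))
  p1[!used] <- 0; p2[!used] <- 0; p3[!used] <- 0; pO[!used] <- 0
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  bbaa <- p1 * p2 * (1 - p3) * (1 - pO)
  if (symmetric) {
    abba <- abba + p1 * (1 - p2) * (1 - p3) * pO
    baba <- baba + (1 - p1) * p2 * (1 - p3) * pO
    bbaa <- bbaa + (1 - p1) * (1 - p2) * p3 * pO
  }
  abba[!used] <- 0; baba[!used] <- 0; bbaa[!used] <- 0
  data.frame(bbaa = bbaa, abba = abba, baba = baba, used = used)
}

#' Patterson's D statistic from pattern totals
#'
#' @param abba,baba total (frequency-weighted) ABBA and BABA counts.
#' @return `D = (ABBA - BABA) / (ABBA + BABA)`, or `NA` when
#'   `ABBA + BABA = 0`.
#' @export
dstat <- function(abba, baba) {
  tot <- abba + baba
  ifelse(tot > 0, (abba - baba) / tot, NA_real_)
}

#' Orient a trio so BBAA is maximal and D non-negative
#'
#' Among the three arrangements of an unordered population triple, selects
#' the one whose BBAA total (P1 and P2 sharing the derived allele) is
#' largest - i.e. the most tree-like arrangement - then swaps P1 and P2 if
#' needed so that `ABBA >= BABA` and hence `D >= 0`. Ties are broken by
#' input order.
#'
#' @param freqs a [site_frequencies()].
#' @param trio three population labels in input order.
#' @param outgroup outgroup label (defaults to the map's).
#' @param symmetric passed to [pattern_weights()].
#' @return List: `trio` (oriented labels), `weights` (per-site data frame
#'   for the oriented arrangement), `totals` (named BBAA/ABBA/BABA sums).
#' @export
orient_trio <- function(freqs, trio, outgroup = NULL, symmetric = TRUE) {
  w <- pattern_weights(freqs, trio, outgroup, symmetric)
  # pair totals: S[xy] = weight that x and y share the derived allele
  s12 <- sum(w$bbaa); s23 <- sum(w$abba); s13 <- sum(w$baba)
  # arrangement maximising BBAA puts the max-sharing pair as (P1, P2)
  if (s12 >= s23 && s12 >= s13) {
    oriented <- trio
  } else if (s23 > s12 && s23 >= s13) {
    oriented <- c(trio[2], trio[3], trio[1])
  } else {
    oriented <- c(trio[1], trio[3], trio[2])
  }
  w <- pattern_weights(freqs, oriented, outgroup, symmetric)
  if (sum(w$abba) < sum(w$baba)) {
    oriented <- c(oriented[2], oriented[1], oriented[3])
    w <- pattern_weights(freqs, oriented, outgroup, symmetric)
  }
  list(trio = oriented, weights = w,
       totals = c(BBAA = sum(w$bbaa), ABBA = sum(w$abba), BABA = sum(w$baba)))
}

#' Block-jackknife standard error, Z and p for Patterson's D
#'
#' Sites are split into `n_blocks` contiguous equal-size blocks in genome
#' order; delete-one-block D estimates give the jackknife standard error
#' \deqn{SE = \sqrt{\frac{m-1}{m} \sum_j (D_{(-j)} - \bar{D})^2}.}
#'
#' @param weights per-site weight data frame from [pattern_weights()] (only
#'   rows with `used = TRUE` enter the blocks).
#' @param n_blocks number of blocks (default 20).
#' @return List: `SE`, `Z = D / SE`, `p = 2(1 - Phi(|Z|))`, `D`, `n_blocks`.
#'   A degenerate jackknife (`SE = 0`) is reported as `Z = Inf`, `p = 0`.
#' @export
block_jackknife <- function(weights, n_blocks = 20L) {
  if (n_blocks < 2L) stop_("`n_blocks` must be at least 2")
  abba <- weights$abba[weights$used]
  baba <- weights$baba[weights$used]
  n <- length(abba)
  if (n < n_blocks)
    stop_("fewer informative sites than blocks; use fewer blocks")
  tot_a <- sum(abba); tot_b <- sum(baba)
  if (tot_a + tot_b <= 0) stop_("no ABBA/BABA signal to jackknife")
  block <- ceiling(seq_len(n) / (n / n_blocks))
  a_j <- tapply(abba, block, sum)
  b_j <- tapply(baba, block, sum)
  if (any((tot_a - a_j) + (tot_b - b_j) <= 0))
    stop_("a single block contains all informative sites; use fewer blocks")
  d_del <- ((tot_a - a_j) - (tot_b - b_j)) / ((tot_a - a_j) + (tot_b - b_j))
  m <- length(d_del)
  se <- sqrt((m - 1) / m * sum((d_del - mean(d_del))^2))
  d <- dstat(tot_a, tot_b)
  if (se == 0) {
    z <- if (d == 0) 0 else Inf * sign(d)
    p <- if (d == 0) 1 else 0
  } else {
    z <- d / se
    p <- 2 * (1 - pnorm(abs(z)))
  }
  list(D = d, SE = se, Z = z, p = p, n_blocks = as.integer(m))
}

#' f4-ratio estimate of the admixture fraction
#'
#' Estimates the fraction of P2's genome derived from the P3 lineage as
#' \deqn{\hat f = \frac{\sum_s (p_2 - p_1)(p_3 - p_O)}
#'   {\sum_s (p_{3a} - p_1)(p_{3b} - p_O)},}
#' where `p3a`, `p3b` are frequencies computed from a random half-split of
#' P3's non-missing alleles at each site (so the denominator measures the
#' drift shared by two copies of the donor lineage). The estimate is
#' averaged over `n_resplits` seeded half-splits to reduce split noise.
#'
#' @param freqs a [site_frequencies()].
#' @param trio oriented trio labels (P1, P2, P3); P3 is the donor.
#' @param outgroup outgroup label (defaults to the map's).
#' @param n_resplits number of random half-splits averaged (default 10).
#' @param seed integer seed for the half-splits.
#' @return The admixture fraction estimate, or `NA` (with a warning) when
#'   the denominator is not positive.
#' @export
f4_ratio <- function(freqs, trio, outgroup = NULL, n_resplits = 10L,
                     seed = 1L) {
  stopifnot(inherits(freqs, "site_frequencies"))
  outgroup <- outgroup %||% freqs$outgroup
  p1 <- freqs$freq[trio[1], ]; p2 <- freqs$freq[trio[2], ]
  p3 <- freqs$freq[trio[3], ]; pO <- freqs$freq[outgroup, ]
  n3 <- freqs$n_alleles[trio[3], ]
  used <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(pO)) & n3 >= 2L
  if (!any(used)) stop_("no usable sites for the f4-ratio")
  p1 <- p1[used]; p2 <- p2[used]; p3 <- p3[used]; pO <- pO[used]
  n3 <- n3[used]
  num <- sum((p2 - p1) * (p3 - pO))
  k3 <- round(p3 * n3)          # alternate-allele count in P3
  na_half <- floor(n3 / 2)      # half-split sizes (na + nb = n3)
  nb_half <- n3 - na_half
  dens <- with_seed(seed, {
    vapply(seq_len(n_resplits), function(r) {
      ka <- rhyper(length(k3), k3, n3 - k3, na_half)
      p3a <- ka / na_half
      p3b <- (k3 - ka) / nb_half
      sum((p3a - p1) * (p3b - pO))
    }, numeric(1))
  })
  if (any(dens <= 0)) {
    warning("f4-ratio denominator not positive; estimate reported as NA",
            call. = FALSE)
    return(NA_real_)
  }
  mean(num / dens)
}

#' ABBA-BABA statistics for every population trio
#'
#' For each 3-subset of non-outgroup populations: orients the trio (max
#' BBAA, then `D >= 0`), computes the frequency-weighted pattern totals,
#' Patterson's D, block-jackknife Z and p, and the f4-ratio.
#'
#' @param geno a [genotype_matrix()].
#' @param pops a [population_map()] with `>= 3` non-outgroup populations.
#' @param n_blocks jackknife blocks (default 20).
#' @param n_resplits f4-ratio half-splits (default 10).
#' @param symmetric polarisation-symmetric pattern weights (default `TRUE`).
#' @param seed integer seed (f4-ratio half-splits).
#' @return Data frame of class `"dtrios_result"`, one row per trio, with
#'   columns `P1, P2, P3, D, Z, p, f4_ratio, BBAA, ABBA, BABA,
#'   n_sites_used, n_blocks`, ordered by input population order.
#' @examples
#' sim <- sim_genotypes(snp_sim_spec(n_sites = 2000, seed = 3))
#' dtrios(sim$geno, sim$popmap)
#' @export
dtrios <- function(geno, pops, n_blocks = 20L, n_resplits = 10L,
                   symmetric = TRUE, seed = 1L) {
  freqs <- site_frequencies(geno, pops)
  outgroup <- freqs$outgroup
  targets <- setdiff(freqs$populations, outgroup)
  if (length(targets) < 3L)
    stop_("need at least 3 non-outgroup populations")
  trios <- combn(targets, 3L, simplify = FALSE)
  rows <- lapply(seq_along(trios), function(i) {
    ot <- orient_trio(freqs, trios[[i]], outgroup, symmetric)
    jk <- block_jackknife(ot$weights, n_blocks = n_blocks)
    f4 <- f4_ratio(freqs, ot$trio, outgroup, n_resplits = n_resplits,
                   seed = derive_seed(seed, i))
    data.frame(P1 = ot$trio[1], P2 = ot$trio[2], P3 = ot$trio[3],
               D = jk$D, Z = jk$Z, p = jk$p, f4_ratio = f4,
               BBAA = ot$totals[["BBAA"]], ABBA = ot$totals[["ABBA"]],
               BABA = ot$totals[["BABA"]],
               n_sites_used = sum(ot$weights$used),
               n_blocks = jk$n_blocks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dtrios_result", "data.frame")
  out
}

#' @export
print.dtrios_result <- function(x, digits = 4, ...) {
  cat(sprintf("ABBA-BABA trios: %d rows\n", nrow(x)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
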