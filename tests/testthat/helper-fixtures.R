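# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A gaussian_component with sensible defaults for 2-D morphospace tests.
make_comp <- function(mu, sigma = diag(length(mu)), n = 100L, pi = 0.5,
                      label = NULL) {
  gaussian_component(mu, sigma, n = n, pi = pi, label = label)
}

# Random pair of 2-D components with anisotropic, rotated covariances and
# moderate separation; deterministic given seed.
random_component_pair <- function(seed, sep_range = c(1, 5)) {
  set.seed(seed)
  rot <- function(theta) matrix(c(cos(theta), sin(theta),
                                  -sin(theta), cos(theta)), 2, 2)
  rand_sigma <- function() {
    q <- rot(runif(1, 0, pi))
    q %*% diag(runif(2, 0.3, 2)^2) %*% t(q)
  }
  sep <- runif(1, sep_range[1], sep_range[2])
  ang <- runif(1, 0, 2 * pi)
  pi1 <- runif(1, 0.2, 0.8)
  list(make_comp(c(0, 0), rand_sigma(), n = 50L, pi = pi1),
       make_comp(sep * c(cos(ang), sin(ang)), rand_sigma(), n = 50L,
                 pi = 1 - pi1))
}

# Hand-built genotype matrix: calls is sites x samples.
make_geno <- function(calls, chrom = "1") {
  calls <- as.matrix(calls)
  genotype_matrix(
    data.frame(chrom = chrom, pos = seq_len(nrow(calls)), ref = "A",
               alt = "T", stringsAsFactors = FALSE),
    calls)
}

# site_frequencies straight from a frequency matrix (populations x sites),
# bypassing genotypes, for closed-form pattern-weight tests.
make_freqs <- function(freq, outgroup = "O", n_alleles = NULL) {
  if (is.null(n_alleles))
    n_alleles <- matrix(2L, nrow(freq), ncol(freq), dimnames = dimnames(freq))
  structure(list(freq = freq, n_alleles = n_alleles,
                 populations = rownames(freq), outgroup = outgroup),
            class = "site_frequencies")
}

# Dense-grid mode count of a two-component 2-D mixture: the independent
# oracle for the ridgeline mode detector. Finds strict 8-neighbour local
# maxima of the mixture density on a grid covering both components, then
# merges maxima whose connecting segment dips by less than the same
# prominence tolerance the ridgeline detector uses (plateau wiggles are not
# distinct modes under either method).
grid_mode_count <- function(c1, c2, n_grid = 201, pad = 4, rel_tol = 1e-4) {
  dens_at <- function(pts) {
    c1$pi * mvtnorm::dmvnorm(pts, c1$mu, c1$sigma) +
      c2$pi * mvtnorm::dmvnorm(pts, c2$mu, c2$sigma)
  }
  lim <- function(i) {
    s <- sqrt(max(c1$sigma[i, i], c2$sigma[i, i]))
    range(c1$mu[i], c2$mu[i]) + c(-pad, pad) * s
  }
  xs <- seq(lim(1)[1], lim(1)[2], length.out = n_grid)
  ys <- seq(lim(2)[1], lim(2)[2], length.out = n_grid)
  z <- matrix(dens_at(as.matrix(expand.grid(x = xs, y = ys))),
              n_grid, n_grid)
  floor_lev <- max(z) * 1e-4   # ignore far-tail ripples
  maxima <- NULL
  for (i in 2:(n_grid - 1)) {
    for (j in 2:(n_grid - 1)) {
      v <- z[i, j]
      if (v < floor_lev) next
      nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v >= max(nb) && sum(nb == v) == 1L)
        maxima <- rbind(maxima, c(xs[i], ys[j], v))
    }
  }
  if (is.null(maxima)) return(0L)
  tol <- rel_tol * (max(z) - min(z))
  k <- nrow(maxima)
  group <- seq_len(k)
  if (k > 1L) {
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      seg <- cbind(seq(maxima[a, 1], maxima[b, 1], length.out = 400),
                   seq(maxima[a, 2], maxima[b, 2], length.out = 400))
      dip <- min(maxima[a, 3], maxima[b, 3]) - min(dens_at(seg))
      if (dip < tol) group[group == group[b]] <- group[a]
    }
  }
  length(unique(group))
}
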