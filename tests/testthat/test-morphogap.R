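# Morphospace PCA, supervised mixture fit, ridgeline manifold, tolerance
# profiles and the gap decision.

test_that("PCA variance fractions: isotropy, degenerate rank, sign fixing", {
  set.seed(1)
  x <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("t1", "t2")))
  tab <- data.frame(group = rep(c("A", "B"), 100), x)
  p <- trait_pca(tab, n_components = 2)
  expect_equal(unname(p$var_fraction), c(0.5, 0.5), tolerance = 0.1)
  # each loading vector's largest-magnitude entry is positive
  expect_true(all(apply(p$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(2), ignore_attr = TRUE,
               tolerance = 1e-12)

  # rank-1: all traits perfectly correlated
  base <- rnorm(50)
  tab1 <- data.frame(group = rep(c("A", "B"), 25),
                     t1 = base, t2 = 2 * base, t3 = -base)
  p1 <- trait_pca(tab1, n_components = 1)
  expect_equal(p1$var_fraction[1], 1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCA recovers a planted two-factor correlation structure", {
  # 13 traits: two independent equicorrelated blocks of 6 plus 1 free trait.
  # The planted variance fractions are the analytic eigenvalues of the
  # constructed correlation matrix divided by 13.
  R <- diag(13)
  R[1:6, 1:6] <- 0.6; R[7:12, 7:12] <- 0.45; diag(R) <- 1
  planted <- eigen(R, symmetric = TRUE, only.values = TRUE)$values / 13
  set.seed(99)
  x <- MASS::mvrnorm(500, rep(0, 13), R)
  colnames(x) <- paste0("t", 1:13)
  tab <- data.frame(group = rep(c("A", "B"), 250), x)
  p <- trait_pca(tab, n_components = 2)
  expect_lt(max(abs(p$var_fraction[1:2] - planted[1:2])), 0.02)
})

test_that("PCA rejects constant traits by name and bad component counts", {
  tab <- data.frame(group = rep(c("A", "B"), 10), good = rnorm(20),
                    flat = 1)
  expect_error(trait_pca(tab), "flat")
  tab2 <- data.frame(group = rep(c("A", "B"), 10), t1 = rnorm(20),
                     t2 = rnorm(20))
  expect_error(trait_pca(tab2, n_components = 5), "n_components")
})

test_that("supervised component fit: means, covariances, weights", {
  set.seed(7)
  mu_a <- c(0, 0); mu_b <- c(3, 1)
  sig <- matrix(c(1, 0.5, 0.5, 2), 2)
  xa <- MASS::mvrnorm(1000, mu_a, sig)
  xb <- MASS::mvrnorm(1000, mu_b, sig)
  tab <- data.frame(group = rep(c("A", "B"), each = 1000),
                    t1 = c(xa[, 1], xb[, 1]), t2 = c(xa[, 2], xb[, 2]))
  cmp <- fit_components(tab)
  se <- sqrt(diag(sig) / 1000)
  expect_true(all(abs(cmp[[1]]$mu - mu_a) < 3 * se))
  expect_true(all(abs(cmp[[2]]$mu - mu_b) < 3 * se))
  expect_equal(cmp[[1]]$pi + cmp[[2]]$pi, 1)

  # mixing weights are the group sample proportions (8 and 47)
  tab2 <- data.frame(group = rep(c("pse", "nan"), c(8, 47)),
                     t1 = rnorm(55), t2 = rnorm(55))
  cmp2 <- fit_components(tab2)
  expect_equal(cmp2[[1]]$pi, 8 / 55)
  expect_equal(cmp2[[2]]$pi, 47 / 55)
  cmp3 <- fit_components(tab2, equal_weights = TRUE)
  expect_equal(cmp3[[1]]$pi, 0.5)

  # identical points: singular covariance is refused loudly
  tab3 <- data.frame(group = rep(c("A", "B"), each = 5),
                     t1 = rep(c(1, 2), each = 5), t2 = rep(c(1, 2), each = 5))
  expect_error(fit_components(tab3), "singular|positive-definite")
})

test_that("ridgeline endpoints and the equal-covariance straight segment", {
  c1 <- make_comp(c(0, 0)); c2 <- make_comp(c(4, 0))
  pr <- ridgeline(c1, c2, n_alpha = 201)
  expect_equal(pr$points[1, ], c1$mu)
  expect_equal(pr$points[201, ], c2$mu)
  # equal covariances: x*(alpha) = (4 alpha, 0)
  expect_equal(pr$points[, 1], 4 * pr$alpha, tolerance = 1e-12)
  expect_equal(pr$points[, 2], rep(0, 201), tolerance = 1e-12)
})

test_that("every ridgeline point satisfies the defining collinearity condition", {
  for (seed in 1:20) {
    pair <- random_component_pair(seed)
    pr <- ridgeline(pair[[1]], pair[[2]], n_alpha = 201)
    a <- pr$alpha
    v1 <- t(solve(pair[[1]]$sigma, t(pr$points) - pair[[1]]$mu))
    v2 <- t(solve(pair[[2]]$sigma, t(pr$points) - pair[[2]]$mu))
    resid <- sqrt(rowSums(((1 - a) * v1 + a * v2)^2))
    scale <- pmax(sqrt(rowSums(v1^2)), sqrt(rowSums(v2^2)), 1)
    expect_lt(max(resid / scale), 1e-8)
  }
})

test_that("ridgeline mode count equals the dense-grid mixture mode count", {
  for (seed in 1:20) {
    pair <- random_component_pair(seed)
    pr <- ridgeline(pair[[1]], pair[[2]])
    m <- count_modes(pr)
    expect_identical(m$n_modes, grid_mode_count(pair[[1]], pair[[2]]),
                     label = sprintf("seed %d ridgeline modes", seed))
  }
})

test_that("mode counting: flat, bimodal, and swamped profiles", {
  c1 <- make_comp(c(0, 0)); c2 <- make_comp(c(0, 0))
  expect_equal(count_modes(ridgeline(c1, c2))$n_modes, 1L)

  # separation 4 sigma, equal weights: bimodal with the antimode at 0.5
  b1 <- make_comp(c(0, 0)); b2 <- make_comp(c(4, 0))
  m <- count_modes(ridgeline(b1, b2))
  expect_equal(m$n_modes, 2L)
  expect_equal(m$n_antimodes, 1L)
  expect_equal(m$antimode_alpha, 0.5, tolerance = 0.01)

  # pi1 = 0.999 swamps the minor component despite 4 sigma separation;
  # 1-D oracle: the mixture density along the segment is monotone
  s1 <- make_comp(c(0, 0), pi = 0.999); s2 <- make_comp(c(4, 0), pi = 0.001)
  x <- seq(0, 4, length.out = 100000)
  dens <- 0.999 * dnorm(x, 0, 1) + 0.001 * dnorm(x, 4, 1)
  expect_false(is.unsorted(rev(dens)))          # oracle: monotone decreasing
  expect_equal(count_modes(ridgeline(s1, s2))$n_modes, 1L)

  # a 2.5 sigma separation is past the 2 sigma bimodality threshold
  t1 <- make_comp(c(0, 0)); t2 <- make_comp(c(2.5, 0))
  expect_equal(count_modes(ridgeline(t1, t2))$n_modes, 2L)
  # and 1.9 sigma is below it
  u1 <- make_comp(c(0, 0)); u2 <- make_comp(c(1.9, 0))
  expect_equal(count_modes(ridgeline(u1, u2))$n_modes, 1L)
})

test_that("tolerance profile: endpoints, chi-square mapping, monotonicity", {
  c1 <- make_comp(c(0, 0), n = 60L); c2 <- make_comp(c(6, 0), n = 60L)
  pr <- ridgeline(c1, c2)
  tp <- tolerance_profile(c1, c2, pr)
  expect_equal(tp$beta1[1], 0)                       # alpha = 0: ellipse is a point
  expect_equal(tp$beta2[length(tp$beta2)], 0)
  # plugin content through the implementation at squared radius 5.991
  expect_equal(stats::approx(tp$r1sq, tp$beta1, xout = 5.991)$y, 0.95,
               tolerance = 1e-4)
  expect_false(is.unsorted(tp$beta1))                # beta1 non-decreasing
  expect_false(is.unsorted(rev(tp$beta2)))           # beta2 non-increasing
  expect_error(tolerance_profile(c1, c2, pr, gamma = 1.2), "gamma")
})

test_that("beta curves are monotone along the ridgeline for random pairs", {
  for (seed in 21:30) {
    pair <- random_component_pair(seed)
    pr <- ridgeline(pair[[1]], pair[[2]])
    tp <- tolerance_profile(pair[[1]], pair[[2]], pr)
    expect_true(all(diff(tp$beta1) > -1e-9), label = sprintf("seed %d b1", seed))
    expect_true(all(diff(tp$beta2) < 1e-9), label = sprintf("seed %d b2", seed))
  }
})

test_that("calibrated tolerance content is below plugin content at small n", {
  c1 <- make_comp(c(0, 0), n = 10L); c2 <- make_comp(c(4, 0), n = 10L)
  pr <- ridgeline(c1, c2, n_alpha = 201)
  plug <- tolerance_profile(c1, c2, pr, method = "plugin")
  cal <- tolerance_profile(c1, c2, pr, method = "calibrated", seed = 4)
  mid <- which(plug$beta1 > 0.2 & plug$beta1 < 0.98)
  expect_true(all(cal$beta1[mid] < plug$beta1[mid]))
  # deterministic given the seed
  cal2 <- tolerance_profile(c1, c2, pr, method = "calibrated", seed = 4)
  expect_identical(cal$beta1, cal2$beta1)
})

test_that("tolerance ellipses through x*(alpha) are tangent, not crossing", {
  # at every ridgeline point the two Mahalanobis ellipses have anti-parallel
  # normals, so each ellipse stays outside the other's interior: the
  # boundary of one never penetrates the other beyond rounding error
  for (seed in 31:35) {
    pair <- random_component_pair(seed)
    c1 <- pair[[1]]; c2 <- pair[[2]]
    pr <- ridgeline(c1, c2, n_alpha = 201)
    theta <- seq(0, 2 * pi, length.out = 721)[-721]
    circ <- rbind(cos(theta), sin(theta))
    bound <- function(cc, r2) t(t(chol(cc$sigma)) %*% circ * sqrt(r2) + cc$mu)
    for (i in c(51, 101, 151)) {
      xs <- pr$points[i, ]
      b1 <- bound(c1, stats::mahalanobis(rbind(xs), c1$mu, c1$sigma))
      b2 <- bound(c2, stats::mahalanobis(rbind(xs), c2$mu, c2$sigma))
      pen1 <- stats::mahalanobis(rbind(xs), c2$mu, c2$sigma) -
        min(stats::mahalanobis(b1, c2$mu, c2$sigma))
      pen2 <- stats::mahalanobis(rbind(xs), c1$mu, c1$sigma) -
        min(stats::mahalanobis(b2, c1$mu, c1$sigma))
      expect_lt(pen1, 1e-8)
      expect_lt(pen2, 1e-8)
    }
  }
})

test_that("plugin beta is invariant under joint affine transforms", {
  pair <- random_component_pair(40)
  c1 <- pair[[1]]; c2 <- pair[[2]]
  tp <- tolerance_profile(c1, c2, ridgeline(c1, c2, n_alpha = 101))
  A <- matrix(c(2, 1, -0.5, 3), 2)
  b <- c(10, -4)
  tf <- function(cc) gaussian_component(A %*% cc$mu + b,
                                        A %*% cc$sigma %*% t(A),
                                        n = cc$n, pi = cc$pi)
  tp2 <- tolerance_profile(tf(c1), tf(c2), ridgeline(tf(c1), tf(c2), n_alpha = 101))
  expect_equal(tp$beta1, tp2$beta1, tolerance = 1e-8)
  expect_equal(tp$beta2, tp2$beta2, tolerance = 1e-8)
})

test_that("component swap maps alpha to 1 - alpha and leaves the decision unchanged", {
  pair <- random_component_pair(50)
  c1 <- pair[[1]]; c2 <- pair[[2]]
  pr12 <- ridgeline(c1, c2); pr21 <- ridgeline(c2, c1)
  expect_equal(pr12$points, pr21$points[nrow(pr21$points):1, ],
               tolerance = 1e-9)
  t12 <- tolerance_profile(c1, c2, pr12)
  t21 <- tolerance_profile(c2, c1, pr21)
  # the swap exchanges the two beta curves and reverses alpha
  expect_equal(t12$beta1, rev(t21$beta2), tolerance = 1e-9)
  expect_equal(t12$beta2, rev(t21$beta1), tolerance = 1e-9)
  d12 <- assess_gap(count_modes(pr12), t12)
  d21 <- assess_gap(count_modes(pr21), t21)
  expect_identical(d12$supported, d21$supported)
  expect_equal(d12$min_joint_overlap, d21$min_joint_overlap, tolerance = 1e-9)
})

test_that("gap decision: identical, well separated, and broadly overlapping pairs", {
  id1 <- make_comp(c(0, 0)); id2 <- make_comp(c(0, 0))
  pr <- ridgeline(id1, id2)
  dec <- assess_gap(count_modes(pr), tolerance_profile(id1, id2, pr))
  expect_false(dec$supported)
  expect_equal(dec$n_modes, 1L)

  # 8 sigma separation: both contents exceed 0.9 at the midpoint
  w1 <- make_comp(c(0, 0)); w2 <- make_comp(c(8, 0))
  prw <- ridgeline(w1, w2)
  tpw <- tolerance_profile(w1, w2, prw)
  expect_gt(min(pmin(tpw$beta1, tpw$beta2)[prw$alpha == 0.5]), 0.9)
  decw <- assess_gap(count_modes(prw), tpw)
  expect_true(decw$supported)

  # bimodal at 2.5 sigma but overlap far above the 0.1 threshold:
  # plugin content at the antimode is pchisq(1.25^2, 2) ~ 0.54 < 0.9
  n1 <- make_comp(c(0, 0)); n2 <- make_comp(c(2.5, 0))
  prn <- ridgeline(n1, n2)
  tpn <- tolerance_profile(n1, n2, prn)
  decn <- assess_gap(count_modes(prn), tpn)
  expect_equal(decn$n_modes, 2L)
  expect_false(decn$supported)
  expect_equal(decn$min_joint_overlap, 1 - pchisq(1.25^2, 2), tolerance = 0.01)
})

test_that("planted-gap recovery and identical-component specificity", {
  n_rep <- 40
  gap_ok <- id_ok <- 0L
  for (s in seq_len(n_rep)) {
    g <- morph_gap(sim_traits(planted_gap_spec(seed = 1000 + s)))
    gap_ok <- gap_ok + (g$decision$supported && g$modes$n_modes >= 2L)
    sp0 <- trait_sim_spec(c(100L, 100L), means = matrix(0, 2, 5),
                          sds = matrix(1, 2, 5), correlation = 0.3,
                          seed = 2000 + s)
    i <- morph_gap(sim_traits(sp0))
    id_ok <- id_ok + (!i$decision$supported)
  }
  expect_gte(gap_ok, ceiling(0.95 * n_rep))
  expect_gte(id_ok, ceiling(0.95 * n_rep))
})

test_that("near-singular covariances are refused rather than regularised", {
  expect_error(make_comp(c(0, 0), diag(c(1, 1e-12))),
               "ill-conditioned|positive-definite")
  expect_error(make_comp(c(0, 0), diag(c(1, 1e-11))),
               "ill-conditioned|positive-definite")
})
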