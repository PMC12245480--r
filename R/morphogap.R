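# Morphological-gap analysis: PCA morphospace, per-group multivariate normal
# components, ridgeline-manifold density profile, tolerance-region overlap
# and the frequency-threshold gap decision.

#' Project a trait table into a PCA morphospace
#'
#' Traits are z-scored over the pooled sample (correlation-matrix PCA; the
#' traits mix lengths, areas and ratios on different scales) and projected
#' onto the leading principal components. Loading signs are fixed so that
#' each component's largest-magnitude loading is positive.
#'
#' @param traits data frame with an `individual` column (optional), a `group`
#'   column and numeric trait columns; no missing values.
#' @param n_components number of components retained (default 2).
#' @param use_correlation if `FALSE`, traits are centred but not scaled
#'   (covariance-matrix PCA).
#' @return A list of class `"trait_pca"`:
#'   \describe{
#'     \item{scores}{data frame `individual`, `group`, `PC1..PCk`.}
#'     \item{loadings}{traits x components matrix of loading vectors.}
#'     \item{var_fraction}{per-component fractions of total variance
#'       (all components, not just those retained).}
#'     \item{center, scale}{per-trait standardisation constants.}
#'   }
#' @export
trait_pca <- function(traits, n_components = 2L, use_correlation = TRUE) {
  tm <- as_trait_matrix(traits)
  x <- tm$x
  if (any(table(tm$group) < 3L))
    stop_("need at least 3 individuals per group for a stable projection")
  if (n_components < 1L || n_components > min(ncol(x), nrow(x) - 1L))
    stop_("`n_components` must be between 1 and min(#traits, n - 1)")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    stop_("constant trait(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- prcomp(x, center = TRUE, scale. = use_correlation)
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2L, flip, `*`)
  pc$x <- sweep(pc$x, 2L, flip, `*`)
  vf <- setNames(pc$sdev^2 / sum(pc$sdev^2), colnames(pc$rotation))
  scores <- data.frame(individual = tm$individual, group = tm$group,
                       pc$x[, seq_len(n_components), drop = FALSE],
                       stringsAsFactors = FALSE)
  structure(list(scores = scores,
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 var_fraction = vf,
                 center = pc$center,
                 scale = if (use_correlation) pc$scale else rep(1, ncol(x)),
                 n_components = as.integer(n_components)),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("trait_pca: %d individuals, %d traits -> %d components\n",
              nrow(x$scores), nrow(x$loadings), x$n_components))
  vf <- x$var_fraction[seq_len(min(4, length(x$var_fraction)))]
  cat("variance fractions:",
      paste(sprintf("%s %.1f%%", names(vf), 100 * vf), collapse = ", "), "\n")
  invisible(x)
}

# Normalise a trait table: identify the group column, numeric trait columns
# and optional identifier column; reject missing values.
as_trait_matrix <- function(traits) {
  if (!is.data.frame(traits)) stop_("`traits` must be a data frame")
  if (!"group" %in% names(traits)) stop_("`traits` needs a `group` column")
  id <- if ("individual" %in% names(traits)) as.character(traits$individual)
        else sprintf("ind_%03d", seq_len(nrow(traits)))
  tr_cols <- setdiff(names(traits), c("individual", "group"))
  x <- traits[tr_cols]
  num <- vapply(x, is.numeric, logical(1))
  if (!all(num))
    stop_("non-numeric trait column(s): ", paste(tr_cols[!num], collapse = ", "))
  x <- as.matrix(x)
  if (anyNA(x)) stop_("missing trait values; clean the table first (see read_traits)")
  list(individual = id, group = as.character(traits$group), x = x)
}

#' One fitted multivariate normal component
#'
#' Holds the normal model of one putative species in morphospace: mean
#' vector, covariance matrix, sample size and mixing weight.
#'
#' @param mu mean vector.
#' @param sigma symmetric positive-definite covariance matrix.
#' @param n sample size the fit is based on.
#' @param pi mixing weight in (0, 1).
#' @param label optional component label.
#' @return An object of class `"gaussian_component"`.
#' @export
gaussian_component <- function(mu, sigma, n, pi, label = NULL) {
  sigma <- as.matrix(sigma)
  if (length(mu) != nrow(sigma)) stop_("`mu` and `sigma` dimensions disagree")
  if (!is_spd(sigma))
    stop_("`sigma` must be symmetric positive-definite; the group covariance ",
          "is singular - use fewer components or more samples")
  check_condition(sigma, "component covariance")
  assert_scalar_number(pi, "pi", 1e-12, 1 - 1e-12)
  structure(list(mu = as.numeric(mu), sigma = sigma, n = as.integer(n),
                 pi = pi, label = label),
            class = "gaussian_component")
}

#' Fit the two labelled components of the morphospace mixture
#'
#' The mixture is supervised: each component is fitted to its labelled group
#' (sample mean, unbiased sample covariance), and the mixing weights default
#' to the group sample proportions.
#'
#' @param projected either a `"trait_pca"` object or its `scores` data frame
#'   (`group` column plus numeric coordinates).
#' @param equal_weights use mixing weights 0.5/0.5 instead of sample
#'   proportions.
#' @return List of two [gaussian_component()]s, in order of first appearance
#'   of the group labels.
#' @export
fit_components <- function(projected, equal_weights = FALSE) {
  if (inherits(projected, "trait_pca")) projected <- projected$scores
  tm <- as_trait_matrix(projected)
  groups <- unique(tm$group)
  if (length(groups) != 2L)
    stop_("delimitation needs exactly 2 groups, got: ",
          paste(groups, collapse = ", "))
  total <- nrow(tm$x)
  lapply(groups, function(g) {
    xg <- tm$x[tm$group == g, , drop = FALSE]
    gaussian_component(colMeans(xg), cov(xg), n = nrow(xg),
                       pi = if (equal_weights) 0.5 else nrow(xg) / total,
                       label = g)
  })
}

#' Ridgeline manifold of a two-component normal mixture
#'
#' All critical points (modes, antimodes, saddles) of a two-component
#' multivariate normal mixture lie on the one-parameter ridgeline manifold
#' \deqn{x^*(\alpha) = [(1-\alpha)\Sigma_1^{-1} + \alpha\Sigma_2^{-1}]^{-1}
#'   [(1-\alpha)\Sigma_1^{-1}\mu_1 + \alpha\Sigma_2^{-1}\mu_2],}
#' for \eqn{\alpha \in [0,1]} (Ray & Lindsay 2005), so profiling the mixture
#' density along it suffices to count modes.
#'
#' @param c1,c2 [gaussian_component()]s with invertible covariances.
#' @param n_alpha number of uniform grid points on `[0, 1]` (default 501).
#' @return An object of class `"ridgeline_profile"`: list with `alpha`,
#'   `points` (n_alpha x d matrix), `density` (mixture density at each
#'   point) and the two components.
#' @references Ray, S. & Lindsay, B.G. (2005) The topography of multivariate
#'   normal mixtures. Annals of Statistics 33, 2042-2065.
#' @export
ridgeline <- function(c1, c2, n_alpha = 501L) {
  stopifnot(inherits(c1, "gaussian_component"), inherits(c2, "gaussian_component"))
  if (length(c1$mu) != length(c2$mu))
    stop_("components live in different dimensions")
  if (abs(c1$pi + c2$pi - 1) > 1e-8)
    stop_("mixing weights must sum to 1")
  alpha <- seq(0, 1, length.out = as.integer(n_alpha))
  s1i <- solve(c1$sigma)
  s2i <- solve(c2$sigma)
  d <- length(c1$mu)
  pts <- matrix(NA_real_, length(alpha), d)
  for (i in seq_along(alpha)) {
    a <- alpha[i]
    blend <- (1 - a) * s1i + a * s2i
    check_condition(blend, "ridgeline covariance blend", alpha = a)
    pts[i, ] <- solve(blend, (1 - a) * s1i %*% c1$mu + a * s2i %*% c2$mu)
  }
  dens <- c1$pi * mvtnorm::dmvnorm(pts, c1$mu, c1$sigma) +
    c2$pi * mvtnorm::dmvnorm(pts, c2$mu, c2$sigma)
  structure(list(alpha = alpha, points = pts, density = dens,
                 c1 = c1, c2 = c2),
            class = "ridgeline_profile")
}

#' Count modes and antimodes of a ridgeline density profile
#'
#' Local extrema are detected by a hysteresis scan over the density profile:
#' a direction change is registered only after the density has moved by more
#' than `rel_tol` times the density range since the last extremum, so
#' numerical wiggles are not counted as modes.
#'
#' @param profile a [ridgeline()] result with `>= 201` grid points.
#' @param rel_tol wiggle tolerance as a fraction of the density range
#'   (default 1e-4).
#' @return List of class `"mode_summary"`: `n_modes`, `mode_alpha`,
#'   `n_antimodes`, `antimode_alpha`.
#' @export
count_modes <- function(profile, rel_tol = 1e-4) {
  stopifnot(inherits(profile, "ridgeline_profile"))
  if (length(profile$alpha) < 201L)
    stop_("density must be evaluated on at least 201 grid points")
  d <- profile$density
  a <- profile$alpha
  rng <- max(d) - min(d)
  if (rng <= 0 || rng <= rel_tol * max(d)) {
    # flat profile (identical components): a single mode
    res <- list(n_modes = 1L, mode_alpha = a[which.max(d)],
                n_antimodes = 0L, antimode_alpha = numeric(0))
    class(res) <- "mode_summary"
    return(res)
  }
  tol <- rel_tol * rng
  ext_i <- integer(0)
  ext_type <- character(0)
  dir <- 0L
  hi <- 1L  # index of running max since last extremum
  lo <- 1L  # index of running min since last extremum
  for (i in 2:length(d)) {
    if (d[i] > d[hi]) hi <- i
    if (d[i] < d[lo]) lo <- i
    if (dir == 0L) {
      if (d[i] >= d[lo] + tol) {
        ext_i <- lo; ext_type <- "min"; dir <- 1L; hi <- i
      } else if (d[i] <= d[hi] - tol) {
        ext_i <- hi; ext_type <- "max"; dir <- -1L; lo <- i
      }
    } else if (dir == 1L) {
      if (d[i] <= d[hi] - tol) {
        ext_i <- c(ext_i, hi); ext_type <- c(ext_type, "max")
        dir <- -1L; lo <- i
      }
    } else {
      if (d[i] >= d[lo] + tol) {
        ext_i <- c(ext_i, lo); ext_type <- c(ext_type, "min")
        dir <- 1L; hi <- i
      }
    }
  }
  if (dir == 1L || dir == 0L) {
    ext_i <- c(ext_i, hi); ext_type <- c(ext_type, "max")
  } else {
    ext_i <- c(ext_i, lo); ext_type <- c(ext_type, "min")
  }
  max_pos <- which(ext_type == "max")
  modes <- ext_i[max_pos]
  # antimodes: minima strictly between two modes
  anti <- if (length(max_pos) >= 2L) {
    keep <- which(ext_type == "min")
    ext_i[keep[keep > min(max_pos) & keep < max(max_pos)]]
  } else integer(0)
  res <- list(n_modes = length(modes), mode_alpha = a[modes],
              n_antimodes = length(anti), antimode_alpha = a[anti])
  class(res) <- "mode_summary"
  res
}

#' @export
print.mode_summary <- function(x, ...) {
  cat(sprintf("ridgeline profile: %d mode(s) at alpha = %s",
              x$n_modes, paste(signif(x$mode_alpha, 3), collapse = ", ")))
  if (x$n_antimodes > 0)
    cat(sprintf("; %d antimode(s) at alpha = %s",
                x$n_antimodes, paste(signif(x$antimode_alpha, 3), collapse = ", ")))
  cat("\n")
  invisible(x)
}

# Lower gamma-quantile of the random content of the plug-in ellipsoid of
# squared radius r2, when mean and covariance are estimated from n draws of a
# d-variate normal. Affine invariance lets us calibrate on the standard
# normal. Shared Monte Carlo points make the curve smooth in r2.
calibrated_content <- function(r2, n, d, gamma = 0.95, n_rep = 200L,
                               n_points = 2000L, seed = 1L) {
  if (n <= d) stop_("tolerance calibration needs n > dimension")
  with_seed(seed, {
    x <- matrix(rnorm(n_points * d), n_points, d)
    content <- matrix(NA_real_, n_rep, length(r2))
    for (b in seq_len(n_rep)) {
      s <- matrix(rnorm(n * d), n, d)
      q <- sort(stats::mahalanobis(x, colMeans(s), cov(s)))
      content[b, ] <- findInterval(r2, q) / n_points
    }
    apply(content, 2L, quantile, probs = 1 - gamma, names = FALSE)
  })
}

#' Tolerance-region content profile along the ridgeline
#'
#' For each ridgeline point \eqn{x^*(\alpha)}, the elliptical tolerance
#' region of component *i* through that point has squared Mahalanobis radius
#' \eqn{r_i^2(\alpha) = (x^*-\mu_i)^T \Sigma_i^{-1} (x^*-\mu_i)}. Its content
#' \eqn{\beta_i} - the population proportion it encloses - is computed either
#' as the population ("plugin") value \eqn{\beta_i = F_{\chi^2_d}(r_i^2)} or
#' as a `gamma`-confidence calibrated content that accounts for estimating
#' \eqn{(\mu_i, \Sigma_i)} from `n_i` samples (Monte Carlo calibration; always
#' at most the plugin content).
#'
#' @param c1,c2 the fitted [gaussian_component()]s.
#' @param profile the [ridgeline()] profile computed from them.
#' @param gamma confidence level for the calibrated method (default 0.95).
#' @param method `"plugin"` (default) or `"calibrated"`.
#' @param seed seed for the Monte Carlo calibration.
#' @return List of class `"tolerance_profile"`: `alpha`, `beta1`, `beta2`,
#'   `r1sq`, `r2sq`, `gamma`, `method`.
#' @export
tolerance_profile <- function(c1, c2, profile, gamma = 0.95,
                              method = c("plugin", "calibrated"), seed = 1L) {
  stopifnot(inherits(profile, "ridgeline_profile"))
  method <- match.arg(method)
  assert_scalar_number(gamma, "gamma", 1e-6, 1 - 1e-6)
  d <- ncol(profile$points)
  r1 <- stats::mahalanobis(profile$points, c1$mu, c1$sigma)
  r2 <- stats::mahalanobis(profile$points, c2$mu, c2$sigma)
  if (method == "plugin") {
    b1 <- pchisq(r1, df = d)
    b2 <- pchisq(r2, df = d)
  } else {
    b1 <- calibrated_content(r1, n = c1$n, d = d, gamma = gamma,
                             seed = derive_seed(seed, 1L))
    b2 <- calibrated_content(r2, n = c2$n, d = d, gamma = gamma,
                             seed = derive_seed(seed, 2L))
  }
  structure(list(alpha = profile$alpha, beta1 = b1, beta2 = b2,
                 r1sq = r1, r2sq = r2, gamma = gamma, method = method),
            class = "tolerance_profile")
}

#' Decide whether the morphometric data support a species boundary
#'
#' The per-species overlap at ridgeline position alpha is `1 - beta_i(alpha)`
#' (the proportion of species *i* lying outside its tolerance ellipse through
#' that point). The boundary is supported when the density profile is
#' multimodal *and* some alpha exists at which both overlaps fall below the
#' frequency threshold, i.e. `max(1 - beta1, 1 - beta2) < threshold`.
#'
#' @param modes a [count_modes()] summary.
#' @param tol_profile a [tolerance_profile()].
#' @param threshold frequency threshold (default 0.1).
#' @return List of class `"gap_decision"`: `supported`, `n_modes`,
#'   `min_joint_overlap`, `alpha_star` (the minimising alpha), `threshold`.
#' @export
assess_gap <- function(modes, tol_profile, threshold = 0.1) {
  stopifnot(inherits(modes, "mode_summary"),
            inherits(tol_profile, "tolerance_profile"))
  assert_scalar_number(threshold, "threshold", 0, 1)
  joint <- pmax(1 - tol_profile$beta1, 1 - tol_profile$beta2)
  i <- which.min(joint)
  structure(list(supported = modes$n_modes >= 2L && joint[i] < threshold,
                 n_modes = modes$n_modes,
                 min_joint_overlap = joint[i],
                 alpha_star = tol_profile$alpha[i],
                 threshold = threshold),
            class = "gap_decision")
}

#' @export
print.gap_decision <- function(x, ...) {
  cat(sprintf(paste0("morphological gap: %s\n",
                     "  modes along ridgeline : %d\n",
                     "  min joint overlap     : %.4f (threshold %.2f, at alpha = %.3f)\n"),
              if (x$supported) "SUPPORTED" else "not supported",
              x$n_modes, x$min_joint_overlap, x$threshold, x$alpha_star))
  invisible(x)
}

#' Full morphological-gap pipeline
#'
#' Runs [trait_pca()], [fit_components()], [ridgeline()], [count_modes()],
#' [tolerance_profile()] and [assess_gap()] on a two-group trait table.
#'
#' @inheritParams trait_pca
#' @inheritParams tolerance_profile
#' @inheritParams assess_gap
#' @inheritParams count_modes
#' @param n_alpha ridgeline grid size (default 501).
#' @param equal_weights use 0.5/0.5 mixing weights instead of group sample
#'   proportions.
#' @param seed seed for the calibrated tolerance method.
#' @return List of class `"morph_gap"` with elements `pca`, `components`,
#'   `profile`, `modes`, `tolerance`, `decision`.
#' @examples
#' tab <- sim_traits(default_trait_spec(seed = 42))
#' res <- morph_gap(tab)
#' res$decision
#' @export
morph_gap <- function(traits, n_components = 2L, gamma = 0.95,
                      threshold = 0.1, method = c("plugin", "calibrated"),
                      n_alpha = 501L, rel_tol = 1e-4,
                      use_correlation = TRUE, equal_weights = FALSE,
                      seed = 1L) {
  method <- match.arg(method)
  pca <- trait_pca(traits, n_components = n_components,
                   use_correlation = use_correlation)
  comps <- fit_components(pca, equal_weights = equal_weights)
  prof <- ridgeline(comps[[1]], comps[[2]], n_alpha = n_alpha)
  modes <- count_modes(prof, rel_tol = rel_tol)
  tol <- tolerance_profile(comps[[1]], comps[[2]], prof, gamma = gamma,
                           method = method, seed = seed)
  dec <- assess_gap(modes, tol, threshold = threshold)
  structure(list(pca = pca, components = comps, profile = prof,
                 modes = modes, tolerance = tol, decision = dec),
            class = "morph_gap")
}

#' @export
print.morph_gap <- function(x, ...) {
  print(x$pca)
  print(x$modes)
  print(x$decision)
  invisible(x)
}
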