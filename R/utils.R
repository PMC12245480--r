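# Internal validation and numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper)
    stop_(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  invisible(x)
}

# Symmetric positive definite check via eigenvalues; tol relative to the
# largest eigenvalue so the test is scale-free.
is_spd <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev)))
}

# Condition number cap for covariance blends: beyond this we refuse to
# invert rather than regularise silently.
COND_CAP <- 1e10

check_condition <- function(m, what, alpha = NULL) {
  k <- kappa(m, exact = TRUE)
  if (!is.finite(k) || k > COND_CAP) {
    extra <- if (!is.null(alpha)) sprintf(" at alpha = %.4f", alpha) else ""
    stop_(sprintf("%s is ill-conditioned (condition number %.3g > %.0e)%s",
                  what, k, COND_CAP, extra))
  }
  invisible(k)
}

# Deterministic sub-seed derivation so one run seed reproduces every stage.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}

# Evaluate with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Shoelace area of a polygon given vertex coordinates (closed implicitly).
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
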