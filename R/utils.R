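`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bivariate standard normal distribution function
#'
#' `P(X <= h, Y <= k)` for a standard bivariate normal vector with
#' correlation `rho`. Vectorised over all arguments with the usual recycling.
#' Uses a Gauss-Legendre rule on the `asin(rho)` integral representation for
#' moderate correlations and a high-correlation expansion otherwise
#' (absolute error around 1e-15).
#'
#' @param h,k Upper integration limits.
#' @param rho Correlation(s) in `[-1, 1]`.
#' @return Numeric vector of probabilities.
#' @examples
#' pbvnorm(0, 0, 0.5) # 1/4 + asin(0.5) / (2 * pi)
#' @export
pbvnorm <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  rho <- if (length(rho) == 1L) as.numeric(rho) else rep_len(as.numeric(rho), n)
  if (any(abs(rho) > 1, na.rm = TRUE)) stop("|rho| must be <= 1")
  pbvnorm_cpp(h, k, rho)
}

# Gauss-Hermite rule (physicists': integrates f against exp(-z^2)).
ghq_rule <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  pracma::gaussHermite(n)
}

# Central-difference gradient of scalar f at x.
fd_gradient <- function(f, x, h = NULL) {
  h <- h %||% (1e-6 * (1 + abs(x)))
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h[i]
    g[i] <- (f(x + e) - f(x - e)) / (2 * h[i])
  }
  g
}

# Central-difference Jacobian of vector-valued f at x.
fd_jacobian <- function(f, x, h = NULL) {
  h <- h %||% (1e-5 * (1 + abs(x)))
  cols <- vector("list", length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h[i]
    cols[[i]] <- (f(x + e) - f(x - e)) / (2 * h[i])
  }
  do.call(cbind, cols)
}

# Numeric Hessian of scalar f via central differences of its gradient gr.
fd_hessian <- function(gr, x, h = NULL) {
  H <- fd_jacobian(gr, x, h)
  (H + t(H)) / 2
}

# Forward-difference variant: one gradient call per coordinate. Used where
# the gradient itself is analytic, so the truncation error is negligible for
# standard-error purposes.
fd_hessian_forward <- function(gr, x, h = NULL) {
  h <- h %||% (1e-5 * (1 + abs(x)))
  g0 <- gr(x)
  cols <- vector("list", length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h[i]
    cols[[i]] <- (gr(x + e) - g0) / h[i]
  }
  H <- do.call(cbind, cols)
  (H + t(H)) / 2
}

# Symmetric PSD square root (used for possibly singular covariances).
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards so simulation helpers do not disturb the session.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

ci_level_z <- function(level = 0.95) qnorm(1 - (1 - level) / 2)
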