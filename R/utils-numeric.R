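# Numerical differentiation helpers used for convergence checks, the
# observed-information (Hessian) matrix, and rate-of-aging fallbacks.

#' Central-difference gradient
#'
#' @param fn scalar function of a numeric vector
#' @param par evaluation point
#' @param h step size; default cube-root machine epsilon, scaled per coordinate
#' @return numeric vector of the same length as `par`
#' @keywords internal
numeric_gradient <- function(fn, par, h = .Machine$double.eps^(1/3)) {
  p <- length(par)
  g <- numeric(p)
  for (i in seq_len(p)) {
    hi <- h * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + hi
    dn <- par; dn[i] <- dn[i] - hi
    g[i] <- (fn(up) - fn(dn)) / (2 * hi)
  }
  g
}

#' Central-difference Hessian
#'
#' Symmetric second-difference scheme with per-coordinate step
#' `h * max(1, |par_i|)`.
#'
#' @inheritParams numeric_gradient
#' @return p x p symmetric matrix
#' @keywords internal
numeric_hessian <- function(fn, par, h = .Machine$double.eps^(1/4)) {
  p <- length(par)
  H <- matrix(0, p, p)
  hh <- h * pmax(1, abs(par))
  f0 <- fn(par)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- hh[i]
    H[i, i] <- (fn(par + ei) - 2 * f0 + fn(par - ei)) / hh[i]^2
    if (i < p) for (j in seq((i + 1), p)) {
      ej <- numeric(p); ej[j] <- hh[j]
      H[i, j] <- (fn(par + ei + ej) - fn(par + ei - ej) -
                    fn(par - ei + ej) + fn(par - ei - ej)) / (4 * hh[i] * hh[j])
      H[j, i] <- H[i, j]
    }
  }
  H
}

# Gauss-Hermite nodes/weights rescaled for expectations over N(mu, sd^2):
# E[f(W)] ~ sum(w * f(x)), with sum(w) = 1.
gauss_hermite_normal <- function(n, mu = 0, sd = 1) {
  gh <- pracma::gaussHermite(n)
  list(x = mu + sqrt(2) * sd * gh$x, w = gh$w / sqrt(pi))
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
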