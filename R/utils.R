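## Small shared numerical utilities.

#' Derive a child seed from a master seed
#'
#' All stochastic operations in the package take an explicit integer seed.
#' Higher-level routines that need several independent streams derive child
#' seeds from one master seed with a fixed linear-congruential step, so a
#' single `seed` argument reproduces an entire pipeline run.
#'
#' @param seed master seed, a single integer.
#' @param k stream index (non-negative integer).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647            # 2^31 - 1, Mersenne prime of the Lehmer RNG
  a <- 48271
  s <- (abs(seed) %% m)
  s <- (a * s + 2 * k + 1) %% m
  s <- (a * s + 1) %% m      # second pass decorrelates adjacent k
  as.integer(s %% (m - 1) + 1)
}

#' Gauss-Hermite quadrature for standard-normal expectations
#'
#' Nodes and weights such that `sum(w * f(x))` approximates `E[f(Z)]` for
#' `Z ~ N(0, 1)`.  Computed by the Golub-Welsch eigendecomposition of the
#' Hermite Jacobi matrix, so no external quadrature package is needed.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`, each of length `n`.
#' @export
gauss_hermite_normal <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = 1))
  ## physicists' Hermite recurrence: beta_i = i/2
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1, ]^2          # weights relative to total mass sqrt(pi)
  ord <- order(x)
  ## change of variable to the N(0,1) kernel
  list(nodes = sqrt(2) * x[ord], weights = w[ord] / sum(w))
}

## FNV-1a hash of a character scalar; stable across platforms, used to
## fingerprint pipeline configurations without external digest packages.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

## stable fingerprint of a diary dataset, used to refuse cross-dataset
## model comparisons
.data_fingerprint <- function(data) {
  fnv1a_hash(paste(nrow(data$data), sum(data$data$day),
                   sum(unlist(data$data[, paste0("i", 1:14)]))))
}

## argument checking helpers ------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop(sprintf("'%s' = %g is out of range", name, x), call. = FALSE)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

## central-difference Hessian of a scalar function on an unconstrained scale
numeric_hessian <- function(fn, par, h = 1e-4) {
  p <- length(par)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(par)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p)
      ei[i] <- h
      ej[j] <- h
      if (i == j) {
        H[i, i] <- (fn(par + ei) - 2 * f0 + fn(par - ei)) / h^2
      } else {
        fpp <- fn(par + ei + ej)
        fpm <- fn(par + ei - ej)
        fmp <- fn(par - ei + ej)
        fmm <- fn(par - ei - ej)
        H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h^2)
      }
    }
  }
  H
}

## nearest positive-semidefinite projection used before Cholesky sampling
make_psd <- function(S, eps = 1e-10) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, eps * max(abs(e$values)))  # an all-zero S stays zero
  e$vectors %*% (v * t(e$vectors))
}
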