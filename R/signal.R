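#' Precomputed spectral basis for signal statistics
#'
#' All signal statistics in this package are generalized-least-squares
#' quantities built on the phylogenetic covariance matrix `C`. For an
#' ultrametric tree `diag(C) = H`, so every lambda-rescaled matrix
#' `C_lambda = lambda C + (1 - lambda) H I` shares the eigenvectors of
#' `C`. One symmetric eigendecomposition per tree therefore serves every
#' lambda evaluation and every trait permutation, which is what keeps
#' thousand-tree experiments tractable. The basis is an optional argument
#' to all signal functions; when omitted it is computed on the fly.
#'
#' @param phy A chronogram.
#' @return An object of class `signal_basis`: eigenvectors `U`,
#'   eigenvalues `d`, the rotated unit vector `z1`, tree height `H`, tip
#'   count `n` and tip labels.
#' @examples
#' tr <- sim_pure_birth(30, seed = 1)
#' b <- signal_basis(tr)
#' x <- simulate_trait(tr, 0.5, seed = 2)
#' blomberg_k(x, tr, basis = b)
#' @export
signal_basis <- function(phy) {
  C <- vcv_matrix(phy)
  n <- nrow(C)
  h <- mean(diag(C))
  if (max(abs(diag(C) - h)) > 1e-6 * h) {
    stop("signal_basis requires an ultrametric tree", call. = FALSE)
  }
  eg <- eigen(C, symmetric = TRUE)
  structure(
    list(
      U = eg$vectors, d = eg$values, z1 = drop(crossprod(eg$vectors, rep(1, n))),
      H = h, n = n, tips = rownames(C)
    ),
    class = "signal_basis"
  )
}

# weights (eigenvalues) of C_lambda in the shared basis
lambda_weights <- function(basis, lambda) {
  lambda * basis$d + (1 - lambda) * basis$H
}

# GLS mean and weighted residual sum of squares in the rotated frame
gls_fit <- function(y, w, z1) {
  s11 <- sum(z1^2 / w)
  a <- sum(z1 * y / w) / s11
  r <- y - a * z1
  list(a = a, q = sum(r^2 / w), s11 = s11)
}

basis_or_compute <- function(phy, basis) {
  if (is.null(basis)) signal_basis(phy) else basis
}

rotate_traits <- function(x, phy, basis) {
  v <- trait_values(x, phy)
  list(v = v, y = drop(crossprod(basis$U, v)))
}

#' Phylogenetic (GLS) mean
#'
#' The generalized-least-squares estimate of the root state,
#' `(1' C^-1 x) / (1' C^-1 1)`, used as the centring constant by both
#' Blomberg's K and the lambda likelihood.
#'
#' @param x Trait input: a tibble with columns `tip` and `value`, a named
#'   numeric vector, or a bare vector in tip order.
#' @param phy A chronogram.
#' @param basis Optional [signal_basis()] for `phy`.
#' @return The scalar GLS mean.
#' @examples
#' tr <- read_chronogram("((A:1,B:1):1,C:2);")
#' phylo_mean(c(A = 1, B = 2, C = 3), tr)
#' @export
phylo_mean <- function(x, phy, basis = NULL) {
  basis <- basis_or_compute(phy, basis)
  rt <- rotate_traits(x, phy, basis)
  gls_fit(rt$y, basis$d, basis$z1)$a
}

#' Blomberg's K
#'
#' Ratio-based phylogenetic signal statistic: the observed ratio of the
#' trait's mean squared error around the GLS mean (`MSE0`) to the
#' phylogenetically corrected mean squared error
#' (`MSE = (x - a)' C^-1 (x - a) / (n - 1)`), scaled by its Brownian-motion
#' expectation `[tr(C) - n / (1' C^-1 1)] / (n - 1)`. K equals 1 for
#' traits evolving by Brownian motion on the tree that generated them,
#' values below 1 indicate weaker resemblance among relatives, values
#' above 1 stronger. The VCV formulation works unchanged on polytomic
#' trees.
#'
#' @inheritParams phylo_mean
#' @return The K statistic (non-negative scalar).
#' @examples
#' tr <- sim_pure_birth(50, seed = 1)
#' x <- simulate_trait(tr, 1, seed = 2)
#' blomberg_k(x, tr)
#' @export
blomberg_k <- function(x, phy, basis = NULL) {
  basis <- basis_or_compute(phy, basis)
  if (basis$n < 4L) stop("K requires at least 4 tips", call. = FALSE)
  rt <- rotate_traits(x, phy, basis)
  if (stats::var(rt$v) == 0) {
    stop("K is undefined for constant traits", call. = FALSE)
  }
  n <- basis$n
  fit <- gls_fit(rt$y, basis$d, basis$z1)
  mse <- fit$q / (n - 1)
  mse0 <- sum((rt$y - fit$a * basis$z1)^2) / (n - 1)
  expected <- (sum(basis$d) - n / fit$s11) / (n - 1)
  (mse0 / mse) / expected
}

#' Randomization test for Blomberg's K
#'
#' Permutation test of the null hypothesis of no phylogenetic signal. The
#' test statistic is the phylogenetically corrected mean squared error
#' `MSE`, which on binary trees equals the variance of the standardized
#' independent contrasts and extends unchanged to polytomies through the
#' VCV; smaller values mean stronger signal. Trait values are permuted
#' across tips `n_perm` times and the p-value is
#' `(1 + #\{MSE_perm <= MSE_obs\}) / (1 + n_perm)` (add-one correction, so
#' p is never 0 and the smallest attainable value is `1/(n_perm + 1)`).
#' With `stat = "k"` the K statistic itself is permuted instead (large
#' values indicate signal); the two versions are near-equivalent.
#'
#' @inheritParams phylo_mean
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @param stat Permutation statistic, `"mse"` (default) or `"k"`.
#' @return The p-value, with the observed statistic and `n_perm` as
#'   attributes.
#' @examples
#' tr <- sim_pure_birth(50, seed = 1)
#' x <- simulate_trait(tr, 0.9, seed = 2)
#' k_perm_test(x, tr, n_perm = 199, seed = 3)
#' @export
k_perm_test <- function(x, phy, n_perm = 999, seed = NULL, basis = NULL,
                        stat = c("mse", "k")) {
  stat <- match.arg(stat)
  if (!is.numeric(n_perm) || n_perm < 1) {
    stop("`n_perm` must be a positive integer", call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  basis <- basis_or_compute(phy, basis)
  rt <- rotate_traits(x, phy, basis)
  n <- basis$n
  invd <- 1 / basis$d
  z1 <- basis$z1
  s11 <- sum(z1^2 * invd)

  perm_idx <- with_seed_opt(
    seed,
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  )
  xp <- matrix(rt$v[perm_idx], nrow = n)
  yp <- crossprod(basis$U, xp)

  a_p <- colSums(yp * (z1 * invd)) / s11
  q_p <- colSums(yp^2 * invd) - a_p^2 * s11
  mse_p <- q_p / (n - 1)

  fit <- gls_fit(rt$y, basis$d, z1)
  mse_obs <- fit$q / (n - 1)

  if (stat == "mse") {
    p <- (1 + sum(mse_p <= mse_obs)) / (1 + n_perm)
    observed <- mse_obs
  } else {
    expected <- (sum(basis$d) - n / s11) / (n - 1)
    mse0_p <- (colSums(yp^2) - 2 * a_p * colSums(yp * z1) + a_p^2 * n) / (n - 1)
    k_p <- (mse0_p / mse_p) / expected
    mse0_obs <- sum((rt$y - fit$a * z1)^2) / (n - 1)
    k_obs <- (mse0_obs / mse_obs) / expected
    p <- (1 + sum(k_p >= k_obs)) / (1 + n_perm)
    observed <- k_obs
  }
  structure(p, statistic = observed, n_perm = n_perm)
}

#' Profiled log-likelihood of Pagel's lambda
#'
#' Log-likelihood of a multivariate-normal trait model with covariance
#' `sigma2 * C_lambda`, profiled over the GLS root state and the ML
#' variance (`sigma2_hat = (x - a)' C_lambda^-1 (x - a) / n`, divisor
#' `n`): `-0.5 * [n log(2 pi sigma2_hat) + log det C_lambda + n]`.
#'
#' @inheritParams phylo_mean
#' @param lambda Value of the down-weighting coefficient, in `[0, 1]`.
#' @return The log-likelihood (scalar).
#' @examples
#' tr <- sim_pure_birth(30, seed = 1)
#' x <- simulate_trait(tr, 0.5, seed = 2)
#' lambda_loglik(x, tr, 0.5) > lambda_loglik(x, tr, 0)
#' @export
lambda_loglik <- function(x, phy, lambda, basis = NULL) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    stop("`lambda` must be in [0, 1]", call. = FALSE)
  }
  basis <- basis_or_compute(phy, basis)
  rt <- rotate_traits(x, phy, basis)
  loglik_rotated(rt$y, basis, lambda)
}

loglik_rotated <- function(y, basis, lambda) {
  w <- lambda_weights(basis, lambda)
  if (any(w <= 0)) {
    stop("singular lambda-rescaled covariance", call. = FALSE)
  }
  n <- basis$n
  fit <- gls_fit(y, w, basis$z1)
  s2 <- fit$q / n
  -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Maximizes [lambda_loglik()] over `[0, 1]` by bounded scalar
#' optimization (Brent, tolerance `1e-6`) started from the best point of a
#' 21-point grid; boundary maxima are reported as exactly 0 or 1.
#'
#' @inheritParams phylo_mean
#' @return A list with `lambda_hat` and `lnL_hat`.
#' @examples
#' tr <- sim_pure_birth(100, seed = 1)
#' x <- simulate_trait(tr, 0.9, seed = 2)
#' pagel_lambda_ml(x, tr)$lambda_hat
#' @export
pagel_lambda_ml <- function(x, phy, basis = NULL) {
  basis <- basis_or_compute(phy, basis)
  rt <- rotate_traits(x, phy, basis)
  ml_rotated(rt$y, basis)
}

ml_rotated <- function(y, basis, tol = 1e-6) {
  grid <- seq(0, 1, length.out = 21L)
  ll <- vapply(grid, function(l) loglik_rotated(y, basis, l), 0)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(l) loglik_rotated(y, basis, l),
    lower = lo, upper = hi, maximum = TRUE, tol = tol
  )
  lam <- opt$maximum
  lnl <- opt$objective
  # boundary maxima are reported exactly
  for (b in c(lo, hi, 0, 1)) {
    lb <- loglik_rotated(y, basis, b)
    if (lb > lnl) {
      lam <- b
      lnl <- lb
    }
  }
  if (lam < tol) lam <- 0
  if (lam > 1 - tol) lam <- 1
  list(lambda_hat = lam, lnL_hat = loglik_rotated(y, basis, lam))
}

#' Likelihood-ratio test for Pagel's lambda
#'
#' Compares the maximized lambda model against the model of complete
#' phylogenetic independence (`lambda = 0`): `D = 2 (lnL_hat - lnL0)`
#' (clamped at 0) referred to the upper tail of a chi-square distribution
#' with one degree of freedom. Because the null value lies at the boundary
#' of the parameter space the test is conservative-to-nominal.
#'
#' @inheritParams phylo_mean
#' @return The p-value, with `lambda_hat`, `lnL_hat` and `lnL0` as
#'   attributes.
#' @examples
#' tr <- sim_pure_birth(100, seed = 1)
#' x <- simulate_trait(tr, 0.9, seed = 2)
#' lambda_lrt(x, tr)
#' @export
lambda_lrt <- function(x, phy, basis = NULL) {
  basis <- basis_or_compute(phy, basis)
  rt <- rotate_traits(x, phy, basis)
  ml <- ml_rotated(rt$y, basis)
  lnl0 <- loglik_rotated(rt$y, basis, 0)
  d <- max(0, 2 * (ml$lnL_hat - lnl0))
  p <- stats::pchisq(d, df = 1, lower.tail = FALSE)
  structure(p,
    lambda_hat = ml$lambda_hat, lnL_hat = ml$lnL_hat, lnL0 = lnl0
  )
}

#' Fit both phylogenetic signal tests to one tree-trait pair
#'
#' Convenience wrapper running Blomberg's K with its randomization test and
#' Pagel's lambda with its likelihood-ratio test on the same trait and
#' tree, sharing one spectral basis. Returns a `signal_fit` object with
#' [generics::tidy()] and [generics::glance()] methods.
#'
#' @inheritParams k_perm_test
#' @return A `signal_fit` object: `K`, `p_K`, `lambda_hat`, `lnL_hat`,
#'   `lnL0`, `p_lambda`, `n_perm`, `n_tips`.
#' @examples
#' tr <- sim_pure_birth(50, seed = 1)
#' x <- simulate_trait(tr, 0.7, seed = 2)
#' fit <- phylo_signal(tr, x, n_perm = 199, seed = 3)
#' tidy(fit)
#' @export
phylo_signal <- function(phy, x, n_perm = 999, seed = NULL, basis = NULL,
                         stat = c("mse", "k")) {
  stat <- match.arg(stat)
  basis <- basis_or_compute(phy, basis)
  k <- blomberg_k(x, phy, basis = basis)
  p_k <- k_perm_test(x, phy,
    n_perm = n_perm, seed = seed, basis = basis,
    stat = stat
  )
  p_l <- lambda_lrt(x, phy, basis = basis)
  structure(
    list(
      K = k, p_K = as.numeric(p_k),
      lambda_hat = attr(p_l, "lambda_hat"),
      lnL_hat = attr(p_l, "lnL_hat"), lnL0 = attr(p_l, "lnL0"),
      p_lambda = as.numeric(p_l),
      n_perm = as.integer(n_perm), n_tips = basis$n
    ),
    class = "signal_fit"
  )
}

#' @export
print.signal_fit <- function(x, ...) {
  cat("Phylogenetic signal fit (", x$n_tips, " tips)\n", sep = "")
  cat(sprintf(
    "  Blomberg's K: %.4f  (randomization p = %.4g, %d permutations)\n",
    x$K, x$p_K, x$n_perm
  ))
  cat(sprintf(
    "  Pagel's lambda: %.4f  (lnL = %.3f, lnL0 = %.3f, LRT p = %.4g)\n",
    x$lambda_hat, x$lnL_hat, x$lnL0, x$p_lambda
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname phylo_signal
#' @param ... Unused.
#' @method tidy signal_fit
#' @export
tidy.signal_fit <- function(x, ...) {
  tibble::tibble(
    index = c("K", "lambda"),
    estimate = c(x$K, x$lambda_hat),
    p.value = c(x$p_K, x$p_lambda)
  )
}

#' @rdname phylo_signal
#' @method glance signal_fit
#' @export
glance.signal_fit <- function(x, ...) {
  tibble::tibble(
    n_tips = x$n_tips, K = x$K, p_K = x$p_K,
    lambda_hat = x$lambda_hat, lnL_hat = x$lnL_hat, lnL0 = x$lnL0,
    p_lambda = x$p_lambda, n_perm = x$n_perm
  )
}
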