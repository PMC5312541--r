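#' Phylogenetic variance-covariance matrix
#'
#' The expected covariance structure of a Brownian trait on a chronogram:
#' `C[i, j]` is the shared root-to-tip path length of tips `i` and `j`
#' (the age of the root minus the age of their most recent common
#' ancestor) and `C[i, i]` is the root-to-tip distance, equal to the tree
#' height `H` for ultrametric trees. Polytomies are handled directly.
#'
#' @param phy A chronogram.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @examples
#' vcv_matrix(read_chronogram("((A:1,B:1):1,C:2);"))
#' @export
vcv_matrix <- function(phy) {
  ape::vcv.phylo(phy)
}

#' Rescale the off-diagonal of a VCV matrix
#'
#' Multiplies the off-diagonal elements of a phylogenetic covariance matrix
#' by a down-weighting coefficient `lambda` in `[0, 1]`, leaving the
#' diagonal unchanged. `lambda = 1` is the identity (full Brownian
#' structure); `lambda = 0` removes all covariance (a star phylogeny).
#'
#' @param C A VCV matrix, as from [vcv_matrix()].
#' @param lambda Down-weighting coefficient in `[0, 1]`.
#' @return The rescaled matrix.
#' @examples
#' C <- vcv_matrix(read_chronogram("((A:1,B:1):1,C:2);"))
#' lambda_rescale(C, 0.5)
#' @export
lambda_rescale <- function(C, lambda) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    stop("`lambda` must be in [0, 1]", call. = FALSE)
  }
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  C
}

#' Simulate a continuous trait with controlled phylogenetic signal
#'
#' Draws one tip-trait vector from a multivariate normal with mean
#' `root_value` and covariance `sigma2 * lambda_rescale(vcv_matrix(phy),
#' lambda_sim)` — distributionally identical to Brownian motion along a
#' lambda-rescaled tree, but exact for polytomic trees as well. Sampling
#' uses a Cholesky factor of the covariance, with a fallback to an
#' eigendecomposition with eigenvalues clipped at `1e-12` for
#' near-singular inputs.
#'
#' `simulate_traits()` produces the full signal grid (one trait per value
#' of `lambda_grid`) as a long tibble; traits are always simulated on the
#' true chronogram and reused unchanged when its degraded versions are
#' analysed.
#'
#' @param phy A chronogram.
#' @param lambda_sim Signal level used for the simulation, in `[0, 1]`.
#' @param sigma2 Brownian rate (variance per unit time), default 1.
#' @param root_value Trait value at the root, default 0.
#' @param seed Optional integer seed; fixed seed gives identical draws.
#' @param lambda_grid Signal levels for the grid, default `0.1..0.9`.
#' @return `simulate_trait()`: a tibble with columns `tip`, `value` and
#'   attributes `lambda_sim`, `sigma2`, `root_value`, `seed`.
#'   `simulate_traits()`: a tibble with columns `lambda_sim`, `tip`,
#'   `value`.
#' @examples
#' tr <- sim_pure_birth(20, seed = 1)
#' x <- simulate_trait(tr, lambda_sim = 0.9, seed = 2)
#' head(x)
#' @export
simulate_trait <- function(phy, lambda_sim, sigma2 = 1, root_value = 0,
                           seed = NULL) {
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop("`sigma2` must be positive", call. = FALSE)
  }
  C <- lambda_rescale(vcv_matrix(phy), lambda_sim) * sigma2
  n <- nrow(C)
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    # near-singular covariance: eigenvalue clipping keeps the draw exact to
    # numerical precision
    eg <- eigen(C, symmetric = TRUE)
    vals <- pmax(eg$values, 1e-12)
    R <- t(eg$vectors %*% (sqrt(vals) * t(eg$vectors)))
    message(sprintf(
      "Cholesky failed for a %d-tip covariance; using clipped eigendecomposition",
      n
    ))
  }
  z <- with_seed_opt(seed, stats::rnorm(n))
  x <- root_value + drop(crossprod(R, z))
  out <- tibble::tibble(tip = rownames(C), value = x)
  attr(out, "lambda_sim") <- lambda_sim
  attr(out, "sigma2") <- sigma2
  attr(out, "root_value") <- root_value
  attr(out, "seed") <- seed
  out
}

#' @rdname simulate_trait
#' @export
simulate_traits <- function(phy, lambda_grid = seq(0.1, 0.9, by = 0.1),
                            sigma2 = 1, root_value = 0, seed = NULL) {
  purrr::map_dfr(seq_along(lambda_grid), function(i) {
    s <- if (is.null(seed)) NULL else child_seed(seed, "trait", i)
    x <- simulate_trait(phy, lambda_grid[i],
      sigma2 = sigma2,
      root_value = root_value, seed = s
    )
    dplyr::mutate(x, lambda_sim = lambda_grid[i], .before = 1L)
  })
}

# Coerce a trait input (tibble with tip/value, named vector, or bare vector
# in tip order) to a numeric vector ordered like phy$tip.label.
trait_values <- function(x, phy) {
  labels <- phy$tip.label
  if (is.data.frame(x)) {
    stopifnot(all(c("tip", "value") %in% names(x)))
    v <- stats::setNames(x$value, x$tip)
  } else if (is.numeric(x)) {
    v <- x
  } else {
    stop("traits must be a data frame (tip, value) or a numeric vector",
      call. = FALSE
    )
  }
  if (!is.null(names(v))) {
    missing <- setdiff(labels, names(v))
    if (length(missing)) {
      stop(
        sprintf("traits missing for tips: %s", paste(missing, collapse = ", ")),
        call. = FALSE
      )
    }
    v <- v[labels]
  } else if (length(v) != length(labels)) {
    stop("unnamed trait vector must have one value per tip", call. = FALSE)
  }
  if (!all(is.finite(v))) stop("trait values must be finite", call. = FALSE)
  unname(v)
}
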