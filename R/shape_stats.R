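#' Tree-shape statistics
#'
#' Summaries of tree stemminess, imbalance and branch-length variability
#' used to stratify simulation results by tree shape.
#'
#' `gamma_statistic()` is the Pybus-Harvey gamma: with `g_k` the duration
#' during which exactly `k` lineages exist (`k = 2..n`),
#' `T = sum_{j} j * g_j` and `T_i = sum_{j<=i} j * g_j`, gamma is
#' `[mean(T_i, i = 2..n-1) - T/2] / [T * sqrt(1 / (12 (n - 2)))]`.
#' Under the pure-birth model it is asymptotically standard normal;
#' negative values indicate "tippy" trees (long internode intervals towards
#' the tips), positive values "stemmy" trees. Defined for binary ultrametric
#' trees with at least 3 tips.
#'
#' `colless_index()` is the sum over internal nodes of the absolute
#' difference in descendant tip counts between the two child subtrees;
#' 0 for a fully balanced tree, `(n-1)(n-2)/2` for a caterpillar. Defined
#' for binary rooted trees only.
#'
#' `branch_length_sd()` is the sample standard deviation (denominator
#' `n - 1`) of all branch lengths; any root edge is excluded. Low values are
#' the signature of evenly interpolated pseudo-chronograms.
#'
#' @param phy A chronogram (`phylo`).
#' @return A single numeric value (integer-valued for `colless_index()`).
#' @examples
#' tr <- sim_pure_birth(50, seed = 7)
#' gamma_statistic(tr)
#' colless_index(tr)
#' branch_length_sd(tr)
#' @export
gamma_statistic <- function(phy) {
  n <- ape::Ntip(phy)
  if (n < 3L) stop("gamma requires at least 3 tips", call. = FALSE)
  if (phy$Nnode != n - 1L) {
    stop("gamma is defined for binary trees only", call. = FALSE)
  }
  as_chronogram(phy)
  age <- node_ages(phy)
  a <- sort(age[(n + 1L):(2L * n - 1L)], decreasing = TRUE) # a_1 = H
  a <- c(a, 0) # tips
  g <- a[-length(a)] - a[-1L] # g_k for k = 2..n
  jg <- (2:n) * g
  tt <- sum(jg)
  t_i <- cumsum(jg) # T_i for i = 2..n
  num <- mean(t_i[seq_len(n - 2L)]) - tt / 2
  num / (tt * sqrt(1 / (12 * (n - 2L))))
}

#' @rdname gamma_statistic
#' @export
colless_index <- function(phy) {
  n <- ape::Ntip(phy)
  if (phy$Nnode != n - 1L) {
    stop("Colless index is defined for binary trees only", call. = FALSE)
  }
  phy <- ape::reorder.phylo(phy, "postorder")
  tips_below <- c(rep(1L, n), rep(0L, phy$Nnode))
  for (i in seq_len(nrow(phy$edge))) {
    tips_below[phy$edge[i, 1L]] <- tips_below[phy$edge[i, 1L]] +
      tips_below[phy$edge[i, 2L]]
  }
  per_node <- split(tips_below[phy$edge[, 2L]], phy$edge[, 1L])
  as.integer(sum(vapply(per_node, function(ch) abs(ch[1L] - ch[2L]), 0)))
}

#' @rdname gamma_statistic
#' @export
branch_length_sd <- function(phy) {
  if (nrow(phy$edge) < 2L) {
    stop("branch-length SD requires at least 2 edges", call. = FALSE)
  }
  stats::sd(phy$edge.length)
}

#' Shape statistics for a set of trees
#'
#' @param trees A list of chronograms (optionally named; names become
#'   `tree_id`).
#' @return A tibble with one row per tree: `tree_id`, `n_tips`, `gamma`,
#'   `colless`, `branch_length_sd`. `gamma` and `colless` are `NA` for
#'   non-binary trees.
#' @examples
#' trees <- lapply(1:3, function(i) sim_pure_birth(20, seed = i))
#' shape_stats(trees)
#' @export
shape_stats <- function(trees) {
  ids <- names(trees) %||% as.character(seq_along(trees))
  purrr::map2_dfr(trees, ids, function(tr, id) {
    binary <- tr$Nnode == ape::Ntip(tr) - 1L
    tibble::tibble(
      tree_id = id,
      n_tips = ape::Ntip(tr),
      gamma = if (binary) gamma_statistic(tr) else NA_real_,
      colless = if (binary) colless_index(tr) else NA_integer_,
      branch_length_sd = branch_length_sd(tr)
    )
  })
}
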