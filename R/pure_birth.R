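#' Simulate a pure-birth (Yule) chronogram
#'
#' Forward simulation of a constant-rate pure-birth process conditioned on a
#' fixed number of extant tips. Starting from the root split (two lineages),
#' the waiting time to the next birth is exponential with rate
#' `birth_rate` times the current lineage count, and the splitting lineage
#' is chosen uniformly. The simulation stops at the birth event that creates
#' the `n_tips`-th lineage and then extends all lineages by one further
#' exponential waiting time (rate `n_tips * birth_rate`), so terminal
#' branches are strictly positive and all tips are contemporaneous
#' (simple-stop conditioning). Tree heights are not rescaled.
#'
#' @param n_tips Number of extant tips (integer, at least 3).
#' @param birth_rate Speciation rate per lineage per unit time (positive).
#' @param seed Optional integer seed; a fixed seed gives a byte-identical
#'   tree. `NULL` uses the current RNG stream.
#' @return A binary ultrametric chronogram (`phylo`) with tips labelled
#'   `t1..tn`.
#' @examples
#' tr <- sim_pure_birth(10, seed = 1)
#' tree_height(tr)
#' @seealso [gamma_statistic()], [colless_index()]
#' @export
sim_pure_birth <- function(n_tips, birth_rate = 1, seed = NULL) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 3L) {
    stop("`n_tips` must be an integer >= 3", call. = FALSE)
  }
  if (!is.numeric(birth_rate) || birth_rate <= 0) {
    stop("`birth_rate` must be positive", call. = FALSE)
  }
  with_seed_opt(seed, {
    n <- n_tips
    root <- n + 1L
    # active lineages: origin node and its birth time
    origin <- c(root, root)
    start <- c(0, 0)
    next_int <- n + 2L
    node_time <- numeric(2L * n - 1L)
    edge <- matrix(0L, nrow = 2L * n - 2L, ncol = 2L)
    elen <- numeric(2L * n - 2L)
    e <- 0L
    t_now <- 0
    k <- 2L
    while (k < n) {
      t_now <- t_now + stats::rexp(1L, rate = birth_rate * k)
      j <- sample.int(k, 1L)
      v <- next_int
      next_int <- next_int + 1L
      node_time[v] <- t_now
      e <- e + 1L
      edge[e, ] <- c(origin[j], v)
      elen[e] <- t_now - start[j]
      origin[j] <- v
      start[j] <- t_now
      origin <- c(origin, v)
      start <- c(start, t_now)
      k <- k + 1L
    }
    t_end <- t_now + stats::rexp(1L, rate = birth_rate * n)
    for (j in seq_len(n)) {
      e <- e + 1L
      edge[e, ] <- c(origin[j], j)
      elen[e] <- t_end - start[j]
    }
    phy <- structure(
      list(
        edge = edge, edge.length = elen, Nnode = n - 1L,
        tip.label = paste0("t", seq_len(n))
      ),
      class = "phylo"
    )
    phy <- ape::reorder.phylo(phy, "cladewise")
    as_chronogram(phy)
  })
}
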