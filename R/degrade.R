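#' Collapse internal nodes into polytomies
#'
#' Degrades a binary chronogram into a polytomic chronogram by deleting a
#' random fraction of its internal nodes and re-attaching their children to
#' the deleted node's parent. Branch lengths are extended so that every
#' surviving node keeps its original age: the output is ultrametric with
#' the same height and tip set as the input.
#'
#' Two eligibility strategies are provided. `"shallow"` restricts collapsing
#' to the tipward half of the tree (internal non-root nodes with age below
#' half the tree height), emulating the high density of terminal polytomies
#' typical of taxonomy-grafted supertrees; `"all"` makes every internal
#' non-root node eligible. `round(fraction * |eligible|)` nodes (half away
#' from zero) are drawn uniformly without replacement. The root is never
#' collapsed.
#'
#' @param phy A binary chronogram.
#' @param fraction Fraction of eligible nodes to collapse, in `[0, 1)`.
#' @param strategy `"shallow"` (tipward half only) or `"all"`.
#' @param seed Optional integer seed for the node draw.
#' @param protect Integer vector of node ids (ape numbering) that must not
#'   be collapsed, e.g. nodes carrying age constraints.
#' @param shallow_side For the shallow strategy, which half of the height is
#'   eligible: `"tipward"` (age < H/2, the default) or `"rootward"`
#'   (age > H/2).
#' @return A chronogram, possibly polytomic, with attribute `"collapsed"`
#'   giving the number of deleted nodes.
#' @examples
#' tr <- sim_pure_birth(20, seed = 1)
#' poly <- collapse_nodes(tr, 0.6, strategy = "shallow", seed = 2)
#' ape::Nnode(poly) < ape::Nnode(tr)
#' @export
collapse_nodes <- function(phy, fraction, strategy = c("shallow", "all"),
                           seed = NULL, protect = integer(),
                           shallow_side = c("tipward", "rootward")) {
  strategy <- match.arg(strategy)
  shallow_side <- match.arg(shallow_side)
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop("`fraction` must be in [0, 1)", call. = FALSE)
  }
  phy <- as_chronogram(phy)
  n <- ape::Ntip(phy)
  age <- node_ages(phy)
  h <- age[root_node(phy)]
  internal <- setdiff((n + 1L):(n + phy$Nnode), root_node(phy))
  eligible <- switch(strategy,
    all = internal,
    shallow = if (shallow_side == "tipward") {
      internal[age[internal] < h / 2]
    } else {
      internal[age[internal] > h / 2]
    }
  )
  eligible <- setdiff(eligible, protect)
  k <- as.integer(round_half_away(fraction * length(eligible)))
  if (k == 0L) {
    attr(phy, "collapsed") <- 0L
    return(phy)
  }
  chosen <- with_seed_opt(seed, eligible[sample.int(length(eligible), k)])

  parent <- parent_vec(phy)
  keep <- setdiff(seq_len(n + phy$Nnode), chosen)
  # re-attach survivors to their nearest surviving ancestor
  dropped <- logical(n + phy$Nnode)
  dropped[chosen] <- TRUE
  new_parent <- parent
  for (v in keep) {
    p <- new_parent[v]
    while (!is.na(p) && dropped[p]) p <- parent[p]
    new_parent[v] <- p
  }
  out <- rebuild_chronogram(keep, new_parent, age, n, phy$tip.label)
  out <- as_chronogram(out)
  attr(out, "collapsed") <- k
  out
}

#' Select node-age constraints by time slice
#'
#' Chooses the subset of internal node ages that a BLADJ-style calibration
#' is allowed to keep, emulating the sparse sets of published divergence
#' times available in practice. The tree depth `[0, H]` is partitioned into
#' `n_slices` equal age intervals; the target total is
#' `m = round(fraction * #internal non-root nodes)` and per-slice quotas are
#' proportional to per-slice node counts (largest-remainder rounding),
#' raised to one for every non-empty slice, with the excess absorbed by the
#' slices holding the largest quotas. Nodes are drawn uniformly within
#' slices. The root is always included with its true age and does not count
#' towards `m`.
#'
#' @param phy A chronogram with at least `n_slices` internal nodes.
#' @param fraction Fraction of internal non-root nodes to fix, in `(0, 1]`.
#' @param n_slices Number of equal time slices (default 5).
#' @param seed Optional integer seed.
#' @return A tibble with columns `node_id` (ape node number) and `age`,
#'   root first — the fixed-age set consumed by [bladj_calibrate()].
#' @examples
#' tr <- sim_pure_birth(100, seed = 3)
#' fx <- select_fixed_nodes(tr, 0.05, seed = 4)
#' nrow(fx) # root + 5 constraints
#' @export
select_fixed_nodes <- function(phy, fraction, n_slices = 5L, seed = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  phy <- as_chronogram(phy)
  n <- ape::Ntip(phy)
  if (phy$Nnode < n_slices) {
    stop("tree must have at least `n_slices` internal nodes", call. = FALSE)
  }
  age <- node_ages(phy)
  root <- root_node(phy)
  h <- age[root]
  internal <- setdiff((n + 1L):(n + phy$Nnode), root)
  slice <- pmin(n_slices, floor(age[internal] / (h / n_slices)) + 1L)
  counts <- tabulate(slice, nbins = n_slices)
  m <- as.integer(round_half_away(fraction * length(internal)))
  m <- max(m, 0L)
  quota <- slice_quotas(counts, m)
  chosen <- with_seed_opt(seed, {
    picks <- integer(0)
    for (s in seq_len(n_slices)) {
      if (quota[s] > 0L) {
        ids <- internal[slice == s]
        picks <- c(picks, ids[sample.int(length(ids), quota[s])])
      }
    }
    picks
  })
  tibble::tibble(
    node_id = c(root, sort(chosen)),
    age = age[c(root, sort(chosen))]
  )
}

# Largest-remainder allocation of m draws over slices with the given node
# counts; every non-empty slice gets at least one draw when m allows it,
# otherwise only the m largest slices are served.
slice_quotas <- function(counts, m) {
  nonempty <- which(counts > 0L)
  if (m <= 0L) {
    return(integer(length(counts)))
  }
  if (m < length(nonempty)) {
    quota <- integer(length(counts))
    order_by_size <- nonempty[order(-counts[nonempty], nonempty)]
    quota[order_by_size[seq_len(m)]] <- 1L
    return(quota)
  }
  share <- m * counts / sum(counts)
  quota <- floor(share)
  rem <- share - quota
  short <- m - sum(quota)
  if (short > 0L) {
    extra <- order(-rem, seq_along(rem))[seq_len(short)]
    quota[extra] <- quota[extra] + 1L
  }
  quota[nonempty] <- pmax(quota[nonempty], 1L)
  while (sum(quota) > m) {
    i <- which.max(quota)
    quota[i] <- quota[i] - 1L
  }
  # never request more nodes than a slice holds
  over <- quota > counts
  while (any(over)) {
    excess <- sum(quota[over] - counts[over])
    quota[over] <- counts[over]
    spare <- which(quota < counts)
    for (i in spare[order(-counts[spare])]) {
      if (excess == 0L) break
      add <- min(excess, counts[i] - quota[i])
      quota[i] <- quota[i] + add
      excess <- excess - add
    }
    over <- quota > counts
    if (excess > 0L) break
  }
  as.integer(quota)
}

#' BLADJ-style even-age calibration
#'
#' Rebuilds the node ages of a topology from a sparse set of fixed ages by
#' spacing every undated node evenly between its nearest dated ancestor and
#' the dated node (or tip, at age 0) below it, mimicking the branch-length
#' adjustment algorithm used to calibrate supertree topologies. The result
#' is a pseudo-chronogram: ultrametric, same topology and height, but with
#' artificially homogeneous branch lengths.
#'
#' For an undated node `v`, let `A` be its nearest fixed ancestor (age
#' `t_A`, `d_A` edges above) and `B` the fixed node or tip below `v` — with
#' no other fixed node in between — lying at the end of the longest undated
#' chain (`d_B` edges, age `t_B`; ties broken towards the smallest age).
#' Then `age(v) = t_A - d_A * (t_A - t_B) / (d_A + d_B)`, which places the
#' nodes of a chain between two anchors at evenly spaced ages. A final
#' monotonicity pass enforces `age(parent) >= age(child) + eps` with
#' `eps = 1e-9 * H` by clamping undated nodes only; fixed nodes keep their
#' exact ages. The number of clamped nodes is reported in the
#' `"n_clamped"` attribute.
#'
#' @param phy The topology to recalibrate (its branch lengths are ignored
#'   except for defining node identity; tips are at age 0 by convention).
#' @param fixed A data frame with columns `node_id` and `age`, as produced
#'   by [select_fixed_nodes()]. Must contain the root. Fixed ages must be
#'   mutually compatible (every fixed ancestor strictly older than its
#'   fixed descendants).
#' @return A chronogram with the same topology and tip set, height equal to
#'   the root's fixed age.
#' @examples
#' tr <- sim_pure_birth(50, seed = 5)
#' fx <- select_fixed_nodes(tr, 0.15, seed = 6)
#' ps <- bladj_calibrate(tr, fx)
#' branch_length_sd(ps) # typically below branch_length_sd(tr)
#' @export
bladj_calibrate <- function(phy, fixed) {
  fixed <- as.data.frame(fixed)
  stopifnot(all(c("node_id", "age") %in% names(fixed)))
  n <- ape::Ntip(phy)
  n_all <- n + phy$Nnode
  root <- root_node(phy)
  if (!root %in% fixed$node_id) {
    stop("`fixed` must contain the root node", call. = FALSE)
  }
  if (any(fixed$node_id <= n | fixed$node_id > n_all)) {
    stop("fixed ids must refer to internal nodes", call. = FALSE)
  }
  fage <- rep(NA_real_, n_all)
  fage[fixed$node_id] <- fixed$age
  h <- fage[root]
  if (any(fixed$age < 0) || any(fixed$age > h)) {
    stop("fixed ages must lie in [0, root age]", call. = FALSE)
  }
  is_fixed <- !is.na(fage)

  pre <- ape::reorder.phylo(phy, "cladewise")$edge # parents before children
  post <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]

  # nearest fixed ancestor-or-self and its edge distance (preorder)
  nf_age <- rep(NA_real_, n_all)
  nf_d <- integer(n_all)
  nf_age[root] <- h
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1L]
    v <- pre[i, 2L]
    if (v > n && is_fixed[v]) {
      nf_age[v] <- fage[v]
      nf_d[v] <- 0L
    } else {
      nf_age[v] <- nf_age[p]
      nf_d[v] <- nf_d[p] + 1L
    }
  }
  # fixed-vs-fixed ordering check: a fixed node must be strictly younger
  # than its nearest fixed ancestor (nf_age of the parent)
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1L]
    v <- pre[i, 2L]
    if (v > n && is_fixed[v]) {
      anc_age <- if (is_fixed[p]) fage[p] else nf_age[p]
      if (fage[v] >= anc_age) {
        stop(
          sprintf(
            "fixed ages incompatible: node %d (age %.6g) is not younger than its fixed ancestor (age %.6g)",
            v, fage[v], anc_age
          ),
          call. = FALSE
        )
      }
    }
  }

  # longest undated chain down to the first fixed node or tip (postorder)
  dd <- integer(n_all) # d_B
  bage <- rep(NA_real_, n_all) # t_B
  bage[seq_len(n)] <- 0
  for (i in seq_len(nrow(post))) {
    p <- post[i, 1L]
    v <- post[i, 2L]
    cand_d <- if (v <= n || is_fixed[v]) 1L else 1L + dd[v]
    cand_age <- if (v <= n) 0 else if (is_fixed[v]) fage[v] else bage[v]
    if (is.na(bage[p]) || p <= n) {
      dd[p] <- cand_d
      bage[p] <- cand_age
    } else if (cand_d > dd[p] || (cand_d == dd[p] && cand_age < bage[p])) {
      dd[p] <- cand_d
      bage[p] <- cand_age
    }
  }

  age <- rep(0, n_all)
  age[is_fixed] <- fage[is_fixed]
  un <- which(!is_fixed & seq_len(n_all) > n)
  age[un] <- nf_age[un] - nf_d[un] * (nf_age[un] - bage[un]) / (nf_d[un] + dd[un])

  # monotonicity pass: eps-clamp undated nodes only
  eps <- 1e-9 * h
  clamped <- logical(n_all)
  for (i in seq_len(nrow(post))) { # raise above children
    p <- post[i, 1L]
    v <- post[i, 2L]
    if (!is_fixed[p] && age[p] < age[v] + eps) {
      age[p] <- age[v] + eps
      clamped[p] <- TRUE
    }
  }
  for (i in seq_len(nrow(pre))) { # clamp below parents
    p <- pre[i, 1L]
    v <- pre[i, 2L]
    if (v > n && !is_fixed[v] && age[v] > age[p] - eps) {
      age[v] <- age[p] - eps
      clamped[v] <- TRUE
    }
  }

  out <- phy
  out$edge.length <- age[phy$edge[, 1L]] - age[phy$edge[, 2L]]
  out <- as_chronogram(out)
  attr(out, "n_clamped") <- sum(clamped)
  out
}

#' Polytomic pseudo-chronograms
#'
#' Composition of the two degradations: first the tree is recalibrated from
#' a sparse fixed-age set ([select_fixed_nodes()] + [bladj_calibrate()]),
#' then the shallow node-collapsing strategy is applied to the resulting
#' pseudo-chronogram ([collapse_nodes()]). Nodes carrying age constraints
#' are never collapsed. Used to probe the interaction between unresolved
#' topology and interpolated branch lengths.
#'
#' @param phy A binary chronogram.
#' @param fix_fraction Fraction of internal node ages to fix, in `(0, 1]`.
#' @param collapse_fraction Fraction of eligible shallow nodes to collapse,
#'   in `[0, 1)`.
#' @param n_slices Number of time slices for constraint selection.
#' @param seed Optional integer seed (children are derived for the two
#'   stochastic stages).
#' @return A polytomic pseudo-chronogram with the input's tip set and
#'   height.
#' @examples
#' tr <- sim_pure_birth(60, seed = 8)
#' pp <- make_polytomic_pseudochronogram(tr, 0.05, 0.4, seed = 9)
#' abs(tree_height(pp) - tree_height(tr)) < 1e-8
#' @export
make_polytomic_pseudochronogram <- function(phy, fix_fraction,
                                            collapse_fraction,
                                            n_slices = 5L, seed = NULL) {
  s1 <- if (is.null(seed)) NULL else child_seed(seed, "fix")
  s2 <- if (is.null(seed)) NULL else child_seed(seed, "collapse")
  fixed <- select_fixed_nodes(phy, fix_fraction, n_slices = n_slices, seed = s1)
  pseudo <- bladj_calibrate(phy, fixed)
  collapse_nodes(pseudo, collapse_fraction,
    strategy = "shallow", seed = s2,
    protect = fixed$node_id
  )
}
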