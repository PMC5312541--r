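#' Chronograms: ultrametric time-trees
#'
#' A chronogram is a rooted phylogeny whose branch lengths are in units of
#' time, so that all extant tips are contemporaneous (age 0) and every node
#' has a well-defined age, i.e. its time before present. Trees are stored as
#' [ape::phylo] objects; node ages are the canonical quantity and branch
#' lengths are derived from them (`length = age(parent) - age(child)`), so
#' the two representations cannot drift apart. Polytomies are allowed unless
#' an operation states otherwise.
#'
#' `as_chronogram()` validates an existing `phylo` object against the
#' chronogram invariants and rejects it (rather than repairing it) on
#' failure: exactly one root, all tips at age 0 within a relative tolerance
#' of `1e-8` times the tree height, non-negative branch lengths, and
#' strictly positive terminal branches.
#'
#' @param phy A rooted `phylo` object with branch lengths.
#' @param tol Relative ultrametricity tolerance, as a fraction of tree
#'   height. Default `1e-8`.
#' @return `as_chronogram()` returns the validated tree (invisibly unchanged);
#'   `node_ages()` a numeric vector of ages indexed by ape node number
#'   (tips `1..n`, then internal nodes); `tree_height()` the root age.
#' @examples
#' tr <- read_chronogram("((A:1,B:1):1,C:2);")
#' tree_height(tr)
#' node_ages(tr)
#' @export
as_chronogram <- function(phy, tol = 1e-8) {
  if (!inherits(phy, "phylo")) {
    stop("`phy` must be a `phylo` object", call. = FALSE)
  }
  if (is.null(phy$edge.length)) {
    stop("chronograms require branch lengths", call. = FALSE)
  }
  # structural rootedness: exactly one node without a parent, every other
  # node with exactly one. (ape::is.rooted() calls trees with a basal
  # polytomy unrooted, but a collapsed chronogram keeps its root.)
  n_nodes <- ape::Ntip(phy) + phy$Nnode
  n_parents <- tabulate(phy$edge[, 2], nbins = n_nodes)
  if (sum(n_parents == 0L) != 1L || any(n_parents > 1L)) {
    stop("chronograms must be rooted with a unique root", call. = FALSE)
  }
  if (any(phy$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  n <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth[seq_len(n)])
  if (h <= 0) stop("tree height must be positive", call. = FALSE)
  tip_age <- h - depth[seq_len(n)]
  if (max(tip_age) > tol * h) {
    stop(
      sprintf(
        "tree is not ultrametric: tip age spread %.3g exceeds tolerance %.3g",
        max(tip_age), tol * h
      ),
      call. = FALSE
    )
  }
  terminal <- phy$edge[, 2] <= n
  if (any(phy$edge.length[terminal] <= 0)) {
    stop("tips must have strictly positive terminal branch lengths",
      call. = FALSE
    )
  }
  phy
}

#' @rdname as_chronogram
#' @export
node_ages <- function(phy) {
  n <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth[seq_len(n)])
  age <- h - depth
  # tips are contemporaneous by the class invariant; remove float dust
  age[seq_len(n)] <- 0
  age
}

#' @rdname as_chronogram
#' @export
tree_height <- function(phy) {
  n <- ape::Ntip(phy)
  max(ape::node.depth.edgelength(phy)[seq_len(n)])
}

#' Read and write chronograms in Newick format
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that
#' validate the chronogram invariants on the way in and write branch
#' lengths with 15 significant digits so that a write/read round trip
#' preserves topology, labels and branch lengths to better than 1e-10.
#' Polytomies are supported.
#'
#' @param x A Newick string (must contain `(` and end in `;`) or a path to
#'   a file containing one tree.
#' @param phy A chronogram.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths (default 15).
#' @return `read_chronogram()` returns a validated `phylo`;
#'   `write_chronogram()` a Newick string (invisibly when writing to file).
#' @examples
#' tr <- read_chronogram("(A:1,B:1,C:1);") # a star polytomy
#' write_chronogram(tr)
#' @export
read_chronogram <- function(x) {
  phy <- if (length(x) == 1L && grepl("\\(", x) && grepl(";", x)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(file = x)
  }
  if (is.null(phy)) stop("failed to parse Newick input", call. = FALSE)
  as_chronogram(phy)
}

#' @rdname read_chronogram
#' @export
write_chronogram <- function(phy, file = NULL, digits = 15) {
  if (is.null(file)) {
    ape::write.tree(phy, digits = digits)
  } else {
    ape::write.tree(phy, file = file, digits = digits)
    invisible(file)
  }
}

# ---- internal parent-map representation -----------------------------------
# Degradation operations edit trees as (parent pointer, age) tables keyed by
# the ape node numbers of the source tree, then rebuild a phylo. This keeps
# node ages exact under collapsing and recalibration.

# parent vector indexed by ape node number; root entry is NA
parent_vec <- function(phy) {
  m <- ape::Ntip(phy) + phy$Nnode
  parent <- rep(NA_integer_, m)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  parent
}

root_node <- function(phy) ape::Ntip(phy) + 1L

# Rebuild a phylo from a parent map restricted to surviving node ids.
# `parent` and `age` are indexed by original node id; ids absent from
# `keep` are dropped and their children must already point to surviving
# ancestors. Tips keep their labels and numbers 1..n; internal nodes are
# renumbered in preorder so the edge matrix is in cladewise order.
rebuild_chronogram <- function(keep, parent, age, n_tip, tip_label) {
  non_root <- keep[!is.na(parent[keep])]
  kids <- split(non_root, parent[non_root])
  root <- keep[is.na(parent[keep])]
  stopifnot(length(root) == 1L)
  n_int <- length(keep) - n_tip
  new_id <- integer(max(keep))
  new_id[seq_len(n_tip)] <- seq_len(n_tip)

  edge <- matrix(0L, nrow = length(keep) - 1L, ncol = 2L)
  elen <- numeric(nrow(edge))
  next_int <- n_tip + 1L
  e <- 0L
  # iterative preorder DFS, children pushed in reverse to preserve order;
  # a parent is always numbered before its children, so both edge columns
  # are final when written
  stack <- root
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v > n_tip) {
      new_id[v] <- next_int
      next_int <- next_int + 1L
    }
    if (!is.na(parent[v])) {
      e <- e + 1L
      edge[e, ] <- c(new_id[parent[v]], new_id[v])
      elen[e] <- age[parent[v]] - age[v]
    }
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, rev(ch))
  }
  structure(
    list(
      edge = edge, edge.length = elen, Nnode = n_int,
      tip.label = tip_label
    ),
    class = "phylo", order = "cladewise"
  )
}
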