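# Small fixture builders used across test files. Everything is built in
# code; no data files.

# caterpillar chronogram with given internal node ages (root first,
# decreasing); tips labelled A, B, ... from the deepest pair outwards
fixture_caterpillar <- function(ages) {
  stopifnot(length(ages) >= 2, all(diff(ages) < 0))
  k <- length(ages) # internal nodes; tips = k + 1
  tips <- LETTERS[seq_len(k + 1)]
  # innermost cherry
  nwk <- sprintf("(%s:%.10g,%s:%.10g)", tips[1], ages[k], tips[2], ages[k])
  for (i in seq(k - 1, 1)) {
    nwk <- sprintf(
      "(%s:%.10g,%s:%.10g)",
      nwk, ages[i] - ages[i + 1], tips[k + 2 - i], ages[i]
    )
  }
  read_chronogram(paste0(nwk, ";"))
}

fixture_star <- function(n, depth = 2) {
  st <- ape::stree(n, "star")
  st$edge.length <- rep(depth, n)
  st$tip.label <- paste0("t", seq_len(n))
  st
}

# fully balanced 4-tip chronogram
fixture_balanced4 <- function() {
  read_chronogram("((A:1,B:1):1,(C:1,D:1):1);")
}

expect_chronogram_invariants <- function(phy, height = NULL, tips = NULL) {
  expect_silent(as_chronogram(phy))
  if (!is.null(height)) expect_equal(tree_height(phy), height, tolerance = 1e-9)
  if (!is.null(tips)) expect_setequal(phy$tip.label, tips)
}

# root-to-tip path lengths in tip-label order (degradations must keep them)
tip_depths <- function(phy) {
  d <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  d[order(phy$tip.label)]
}
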