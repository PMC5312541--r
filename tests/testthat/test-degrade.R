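test_that("collapse with fraction 0 is the identity", {
  tr <- sim_pure_birth(20, seed = 1)
  out <- collapse_nodes(tr, 0, strategy = "all", seed = 2)
  expect_identical(write_chronogram(out), write_chronogram(tr))
})

test_that("collapsing the caterpillar's internal nodes yields a star", {
  tr <- fixture_caterpillar(c(4, 2, 1)) # root age 4, eligible ages 2 and 1
  out <- collapse_nodes(tr, 0.99, strategy = "all", seed = 3)
  expect_equal(attr(out, "collapsed"), 2L)
  expect_equal(out$Nnode, 1L) # root polytomy
  expect_chronogram_invariants(out, height = 4, tips = tr$tip.label)
  expect_true(all(node_ages(out)[seq_len(4)] == 0))
})

test_that("collapse removes exactly round(fraction * |eligible|) nodes", {
  for (i in 1:10) {
    tr <- sim_pure_birth(60, seed = 500 + i)
    age <- node_ages(tr)
    h <- tree_height(tr)
    internal <- setdiff(62:119, 61L)
    for (f in c(0.2, 0.4, 0.6, 0.8)) {
      all_out <- collapse_nodes(tr, f, strategy = "all", seed = i)
      expect_equal(
        tr$Nnode - all_out$Nnode,
        round_half_away(f * length(internal))
      )
      shallow_elig <- sum(age[internal] < h / 2)
      sh_out <- collapse_nodes(tr, f, strategy = "shallow", seed = i)
      expect_equal(
        tr$Nnode - sh_out$Nnode,
        round_half_away(f * shallow_elig)
      )
    }
  }
})

test_that("degradations preserve tips, height, ultrametricity and tip depths", {
  for (i in 1:8) {
    tr <- sim_pure_birth(50, seed = 700 + i)
    h <- tree_height(tr)
    depths <- tip_depths(tr)
    variants <- list(
      collapse_nodes(tr, 0.6, "shallow", seed = i),
      collapse_nodes(tr, 0.6, "all", seed = i),
      bladj_calibrate(tr, select_fixed_nodes(tr, 0.15, seed = i)),
      make_polytomic_pseudochronogram(tr, 0.05, 0.4, seed = i)
    )
    for (v in variants) {
      expect_chronogram_invariants(v, height = h, tips = tr$tip.label)
      expect_equal(tree_height(v), h, tolerance = 1e-9)
    }
    # collapse additionally preserves every surviving node age, hence all
    # root-to-tip path lengths exactly
    expect_equal(tip_depths(variants[[1]]), depths, tolerance = 1e-12)
    expect_equal(tip_depths(variants[[2]]), depths, tolerance = 1e-12)
  }
})

test_that("invalid collapse fractions are rejected", {
  tr <- sim_pure_birth(10, seed = 1)
  expect_error(collapse_nodes(tr, 1), "fraction")
  expect_error(collapse_nodes(tr, -0.1), "fraction")
})

test_that("fixed-node selection hits the target count with per-slice minima", {
  tr <- sim_pure_birth(100, seed = 9) # 98 internal non-root nodes
  fx <- select_fixed_nodes(tr, 0.05, seed = 10)
  expect_equal(nrow(fx), 6L) # 5 constraints + root
  expect_true(root_node(tr) %in% fx$node_id)
  # quotas sum exactly to m across random trees and fractions
  for (i in 1:40) {
    n <- sample(20:150, 1)
    tr_i <- sim_pure_birth(n, seed = 4000 + i)
    f <- sample(c(0.05, 0.15, 0.25, 0.35), 1)
    m <- round_half_away(f * (tr_i$Nnode - 1L))
    fx_i <- select_fixed_nodes(tr_i, f, seed = i)
    expect_equal(nrow(fx_i), m + 1L) # m constraints plus the root
    expect_false(anyDuplicated(fx_i$node_id) > 0)
    age <- node_ages(tr_i)
    expect_equal(fx_i$age, age[fx_i$node_id])
  }
  expect_error(select_fixed_nodes(tr, 0), "fraction")
})

test_that("fully constrained calibration reproduces the true chronogram", {
  for (i in 1:5) {
    tr <- sim_pure_birth(40, seed = 800 + i)
    out <- bladj_calibrate(tr, select_fixed_nodes(tr, 1))
    expect_lt(max(abs(out$edge.length - tr$edge.length)), 1e-12)
  }
})

test_that("calibration spaces an undated chain evenly", {
  tr <- fixture_caterpillar(c(4, 2, 1))
  out <- bladj_calibrate(tr, data.frame(node_id = 5L, age = 10))
  age <- sort(node_ages(out)[6:7], decreasing = TRUE)
  expect_equal(age, c(20 / 3, 10 / 3), tolerance = 1e-9)
  expect_equal(tree_height(out), 10)
})

test_that("incompatible fixed ages are reported with the offending node", {
  tr <- fixture_caterpillar(c(4, 2, 1))
  # v2 (node 7) fixed older than its fixed ancestor v1 (node 6)
  bad <- data.frame(node_id = c(5L, 6L, 7L), age = c(10, 4, 6))
  expect_error(bladj_calibrate(tr, bad), "incompatible")
  out_of_range <- data.frame(node_id = c(5L, 6L), age = c(3, 8))
  expect_error(bladj_calibrate(tr, out_of_range), "root age")
  expect_error(bladj_calibrate(tr, data.frame(node_id = 6L, age = 2)), "root")
})

test_that("pseudo-chronograms have more homogeneous branch lengths", {
  sd_true <- numeric(100)
  sd_pseudo <- numeric(100)
  for (i in 1:100) {
    tr <- sim_pure_birth(50, seed = 6000 + i)
    fx <- select_fixed_nodes(tr, 0.05, seed = i)
    sd_true[i] <- branch_length_sd(tr)
    sd_pseudo[i] <- branch_length_sd(bladj_calibrate(tr, fx))
  }
  expect_lt(mean(sd_pseudo), mean(sd_true))
})

test_that("combined degradation is the identity at the identity settings", {
  tr <- sim_pure_birth(25, seed = 12)
  out <- make_polytomic_pseudochronogram(tr, 1, 0, seed = 13)
  expect_equal(out$edge.length, tr$edge.length, tolerance = 1e-12)
  expect_identical(out$tip.label, tr$tip.label)
})

test_that("polytomic pseudo-chronograms are flatter than polytomic chronograms", {
  sd_poly <- numeric(100)
  sd_comb <- numeric(100)
  for (i in 1:100) {
    tr <- sim_pure_birth(40, seed = 7000 + i)
    sd_poly[i] <- branch_length_sd(collapse_nodes(tr, 0.4, "shallow", seed = i))
    sd_comb[i] <- branch_length_sd(
      make_polytomic_pseudochronogram(tr, 0.05, 0.4, seed = i)
    )
  }
  expect_lt(mean(sd_comb), mean(sd_poly))
})
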