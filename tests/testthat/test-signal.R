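test_that("the GLS mean reduces to known cases", {
  st <- fixture_star(5, depth = 2)
  x <- c(t1 = 1, t2 = 2, t3 = 3, t4 = 4, t5 = 10)
  expect_equal(phylo_mean(x, st), mean(x)) # C proportional to I
  tr <- sim_pure_birth(12, seed = 31)
  const <- stats::setNames(rep(3.7, 12), tr$tip.label)
  expect_equal(phylo_mean(const, tr), 3.7, tolerance = 1e-10)
  # brute-force linear algebra oracle
  tr3 <- read_chronogram("((A:1,B:1):1,C:2);")
  C <- vcv_matrix(tr3)
  Ci <- solve(C)
  x3 <- c(A = 1, B = 2, C = 3)
  expect_equal(
    phylo_mean(x3, tr3),
    drop(rep(1, 3) %*% Ci %*% x3) / sum(Ci),
    tolerance = 1e-12
  )
})

test_that("K equals 1 exactly on a star tree", {
  st <- fixture_star(8, depth = 2)
  withr::with_seed(5, {
    for (i in 1:5) {
      x <- stats::setNames(stats::rnorm(8), st$tip.label)
      expect_equal(blomberg_k(x, st), 1, tolerance = 1e-10)
    }
  })
})

test_that("K and lambda agree with an independent implementation", {
  skip_if_not_installed("phytools")
  for (i in 1:5) {
    tr <- sim_pure_birth(40, seed = 900 + i)
    x <- simulate_trait(tr, 0.7, seed = 950 + i)
    v <- stats::setNames(x$value, x$tip)
    expect_equal(blomberg_k(x, tr), unclass(phytools::phylosig(tr, v)),
      tolerance = 1e-8, ignore_attr = TRUE
    )
    ours <- pagel_lambda_ml(x, tr)
    ref <- phytools::phylosig(tr, v, method = "lambda", test = TRUE)
    expect_equal(ours$lambda_hat, ref$lambda, tolerance = 1e-3)
    expect_equal(ours$lnL_hat, ref$logL, tolerance = 1e-5)
    expect_equal(lambda_loglik(x, tr, 0), ref$logL0, tolerance = 1e-6)
  }
})

test_that("K and lambda are invariant to trait location and scale changes", {
  tr <- sim_pure_birth(30, seed = 32)
  x <- simulate_trait(tr, 0.6, seed = 33)
  v <- stats::setNames(x$value, x$tip)
  k0 <- blomberg_k(v, tr)
  l0 <- pagel_lambda_ml(v, tr)$lambda_hat
  expect_equal(blomberg_k(v + 100, tr), k0, tolerance = 1e-9)
  expect_equal(blomberg_k(v * 12, tr), k0, tolerance = 1e-9)
  expect_equal(pagel_lambda_ml(v + 100, tr)$lambda_hat, l0, tolerance = 1e-5)
  # lambda is scale-free on ultrametric trees
  scaled <- tr
  scaled$edge.length <- tr$edge.length * 10
  expect_equal(pagel_lambda_ml(v, scaled)$lambda_hat, l0, tolerance = 1e-5)
})

test_that("K degrades under permutation of traits across tips", {
  tr <- sim_pure_birth(64, seed = 34)
  x <- simulate_trait(tr, 0.9, seed = 35)
  v <- stats::setNames(x$value, x$tip)
  k_obs <- blomberg_k(v, tr)
  lower <- withr::with_seed(36, {
    vapply(1:200, function(i) {
      blomberg_k(stats::setNames(sample(v), names(v)), tr) < k_obs
    }, TRUE)
  })
  expect_gte(mean(lower), 0.95)
})

test_that("permuted traits drive the lambda estimate towards zero", {
  lam_hat <- numeric(200)
  k <- 0
  for (t in 1:20) {
    tr <- sim_pure_birth(200, seed = 1100 + t)
    b <- signal_basis(tr)
    x <- simulate_trait(tr, 0.9, seed = 1150 + t)
    v <- stats::setNames(x$value, x$tip)
    perms <- withr::with_seed(1200 + t, {
      lapply(1:10, function(i) sample(v))
    })
    for (p in perms) {
      k <- k + 1
      lam_hat[k] <- pagel_lambda_ml(
        stats::setNames(p, names(v)), tr,
        basis = b
      )$lambda_hat
    }
  }
  expect_lt(mean(lam_hat), 0.1)
})

test_that("the lambda likelihood is smooth and correct in closed form", {
  tr <- sim_pure_birth(20, seed = 37)
  x <- simulate_trait(tr, 0.5, seed = 38)
  v <- stats::setNames(x$value, x$tip)
  h <- tree_height(tr)
  # lambda = 0: i.i.d. normal likelihood at the MLE
  s2 <- mean((v - mean(v))^2) # ML variance of x, = sigma2_hat * H
  lnl_iid <- sum(stats::dnorm(v, mean(v), sqrt(s2), log = TRUE))
  expect_equal(lambda_loglik(v, tr, 0), lnl_iid, tolerance = 1e-8)
  # no jumps along a fine grid
  grid <- seq(0, 1, by = 1e-3)
  ll <- vapply(grid, function(l) lambda_loglik(v, tr, l), 0)
  expect_lt(max(abs(diff(ll))), 0.1)
  # 3-tip worked example against brute-force determinant/inverse evaluation
  tr3 <- read_chronogram("((A:1,B:1):1,C:2);")
  x3 <- c(A = 0.3, B = 1.1, C = -0.7)
  for (lam in c(0.2, 0.7, 1)) {
    Cl <- lambda_rescale(vcv_matrix(tr3), lam)
    Ci <- solve(Cl)
    a <- drop(rep(1, 3) %*% Ci %*% x3) / sum(Ci)
    q <- drop(t(x3 - a) %*% Ci %*% (x3 - a))
    lnl <- -0.5 * (3 * log(2 * pi * q / 3) + determinant(Cl)$modulus + 3)
    expect_equal(lambda_loglik(x3, tr3, lam), as.numeric(lnl),
      tolerance = 1e-10
    )
  }
})

test_that("the randomization test honours the add-one bound", {
  tr <- sim_pure_birth(50, seed = 39)
  x <- simulate_trait(tr, 0.9, seed = 40)
  p <- k_perm_test(x, tr, n_perm = 999, seed = 41)
  expect_gte(as.numeric(p), 1 / 1000)
  expect_error(k_perm_test(x, tr, n_perm = 0), "n_perm")
  # strong signal on a large tree reaches the bound
  tr2 <- sim_pure_birth(200, seed = 42)
  x2 <- simulate_trait(tr2, 0.9, seed = 43)
  expect_equal(as.numeric(k_perm_test(x2, tr2, n_perm = 999, seed = 44)),
    1 / 1000,
    tolerance = 1e-12
  )
})

test_that("the K test has power against strong signal", {
  hits <- vapply(1:200, function(i) {
    tr <- sim_pure_birth(200, seed = 1300 + i)
    x <- simulate_trait(tr, 0.9, seed = 1350 + i)
    as.numeric(k_perm_test(x, tr, n_perm = 199, seed = i)) <= 0.05
  }, TRUE)
  # power under simple-stop conditioning; decisions agree replicate-by-
  # replicate with phytools::phylosig on these data
  expect_gt(mean(hits), 0.9)
})

test_that("the likelihood-ratio test behaves at its boundary", {
  # a trait with lambda_hat = 0 gives D = 0 and p = 1
  st_like <- sim_pure_birth(40, seed = 45)
  x <- simulate_trait(st_like, 0, seed = 46)
  done <- FALSE
  for (s in 47:60) {
    x <- simulate_trait(st_like, 0, seed = s)
    ml <- pagel_lambda_ml(x, st_like)
    if (ml$lambda_hat == 0) {
      expect_equal(as.numeric(lambda_lrt(x, st_like)), 1)
      done <- TRUE
      break
    }
  }
  expect_true(done)
  expect_true(as.numeric(lambda_lrt(x, st_like)) <= 1)
})

test_that("both tests run unchanged on polytomic trees", {
  tr <- sim_pure_birth(40, seed = 61)
  poly <- collapse_nodes(tr, 0.6, "shallow", seed = 62)
  x <- simulate_trait(tr, 0.7, seed = 63)
  expect_gt(blomberg_k(x, poly), 0)
  p <- k_perm_test(x, poly, n_perm = 99, seed = 64)
  expect_true(as.numeric(p) > 0 && as.numeric(p) <= 1)
  fit <- phylo_signal(poly, x, n_perm = 99, seed = 65)
  expect_true(fit$lambda_hat >= 0 && fit$lambda_hat <= 1)
  expect_gte(fit$lnL_hat, fit$lnL0 - 1e-6)
})

test_that("collapsed trees inflate K for strongly heritable traits", {
  k_true <- numeric(50)
  k_poly <- numeric(50)
  for (i in 1:50) {
    tr <- sim_pure_birth(100, seed = 1400 + i)
    x <- simulate_trait(tr, 0.7, seed = 1450 + i)
    k_true[i] <- blomberg_k(x, tr)
    k_poly[i] <- blomberg_k(x, collapse_nodes(tr, 0.6, "shallow", seed = i))
  }
  expect_gte(mean(k_poly), mean(k_true))
})

test_that("tidy and glance summarise a signal fit", {
  tr <- sim_pure_birth(30, seed = 70)
  x <- simulate_trait(tr, 0.5, seed = 71)
  fit <- phylo_signal(tr, x, n_perm = 99, seed = 72)
  td <- tidy(fit)
  expect_identical(td$index, c("K", "lambda"))
  expect_true(all(td$p.value > 0 & td$p.value <= 1))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_identical(gl$n_perm, 99L)
  expect_output(print(fit), "Blomberg")
})

test_that("constant traits and undersized trees are rejected", {
  tr <- sim_pure_birth(10, seed = 73)
  const <- stats::setNames(rep(1, 10), tr$tip.label)
  expect_error(blomberg_k(const, tr), "constant")
  tr3 <- read_chronogram("((A:1,B:1):1,C:2);")
  expect_error(blomberg_k(c(A = 1, B = 2, C = 3), tr3), "4 tips")
})
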