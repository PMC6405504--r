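test_that("Yule trees are ultrametric, sized as requested, and deterministic", {
  tr <- sim_yule_tree(2, 1.0, seed = 1)
  expect_equal(length(tr$tip.label), 2L)
  expect_true(check_ultrametric(tr, 1e-12)$ultrametric)

  t1 <- sim_yule_tree(25, 0.7, seed = 42)
  t2 <- sim_yule_tree(25, 0.7, seed = 42)
  expect_identical(write_tree_text(t1), write_tree_text(t2))
  expect_false(identical(write_tree_text(t1),
                         write_tree_text(sim_yule_tree(25, 0.7, seed = 43))))
  expect_true(check_ultrametric(t1, 1e-12)$ultrametric)
})

test_that("Yule root heights match the pure-birth expectation", {
  h <- vapply(1:200, function(s)
    max(ape::node.depth.edgelength(sim_yule_tree(50, 1, seed = s))),
    numeric(1))
  target <- sum(1 / (2:50))
  expect_lt(abs(mean(h) - target) / target, 0.1)
  # birth rate scales time: lambda = 2 halves the expected height
  h2 <- vapply(1:100, function(s)
    max(ape::node.depth.edgelength(sim_yule_tree(50, 2, seed = 500 + s))),
    numeric(1))
  expect_lt(abs(mean(h2) - target / 2) / (target / 2), 0.15)
})

test_that("BM tip moments match the analytic variance and shared-path covariance", {
  expect_equal(unname(sim_bm(sim_yule_tree(5, 1, seed = 2), 0, 7, seed = 3)),
               rep(7, 5))
  expect_error(sim_bm(sim_yule_tree(5, 1, seed = 2), -1, 0, seed = 3), ">= 0")

  # star tree of depth T: tip variance = sigma2 * T, covariance 0
  star <- ape::read.tree(text = "(A:2,B:2,C:2);")
  xs <- t(vapply(1:800, function(s) sim_bm(star, 1.5, 0, seed = s), numeric(3)))
  expect_lt(abs(var(xs[, 1]) - 3) / 3, 0.1)
  expect_lt(abs(mean(diag(var(xs)) / 3) - 1), 0.1)

  # cherry nested at depth T with split at T - t: cov = sigma2 * (T - t)
  nested <- parse_tree("((A:1,B:1):2,C:3);")
  xx <- t(vapply(1:800, function(s) sim_bm(nested, 1, 0, seed = 1000 + s),
                 numeric(3)))
  expect_lt(abs(stats::cov(xx[, 1], xx[, 2]) - 2) / 2, 0.12)
  expect_lt(abs(stats::cov(xx[, 1], xx[, 3])), 0.2)
})

test_that("correlated BM reproduces the requested contrast correlation", {
  tr <- sim_yule_tree(150, 1, seed = 77)
  # diagonal rates: contrast cross-correlation near 0
  r0 <- vapply(1:25, function(s) {
    m <- sim_bm_correlated(tr, diag(c(1, 2)), c(0, 0), seed = s)
    stats::cor(compute_contrasts(tr, m[, 1])$contrast,
               compute_contrasts(tr, m[, 2])$contrast)
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.1)
  # rho = 0.8 with equal rates
  R <- matrix(c(1, 0.8, 0.8, 1), 2)
  r8 <- vapply(1:25, function(s) {
    m <- sim_bm_correlated(tr, R, c(0, 0), seed = 100 + s)
    stats::cor(compute_contrasts(tr, m[, 1])$contrast,
               compute_contrasts(tr, m[, 2])$contrast)
  }, numeric(1))
  expect_lt(abs(mean(r8) - 0.8), 0.05)
  # rank-1 (perfectly correlated) limit: y = c * x exactly
  c2 <- 2.5
  R1 <- matrix(c(1, c2, c2, c2^2), 2)
  m1 <- sim_bm_correlated(tr, R1, c(0, 0), seed = 5)
  expect_equal(m1[, 2], c2 * m1[, 1], tolerance = 1e-10)
  expect_error(sim_bm_correlated(tr, matrix(c(1, 2, 2, 1), 2), c(0, 0), seed = 1),
               "semi-definite")
})

test_that("the caste generator implements its construction guarantees", {
  # clade shift off, positive queen offset: every species female-biased
  sim0 <- sim_caste_dataset(sim_config(n_tips = 30, clade_shift = FALSE,
                                       sigma2_noise = 0, seed = 13))
  s0 <- ssdi_table(sim0$traits)
  expect_true(all(s0$ssdi > 0))

  # clade shift on, zero noise: exactly the designated clade is male-biased
  sim1 <- sim_caste_dataset(sim_config(n_tips = 44, clade_size = 12,
                                       sigma2_noise = 0, seed = 17))
  s1 <- ssdi_table(sim1$traits)
  neg <- s1$species[s1$ssdi < 0]
  expect_setequal(neg, sim1$clade_tips)
  expect_equal(s1$genus[s1$ssdi < 0], rep("cladeA", length(neg)))

  # degenerate identity: unit slopes, no offsets, no noise => all castes equal
  simd <- sim_caste_dataset(sim_config(n_tips = 20, slope_queen = 1,
                                       slope_male = 1, offset_queen = 0,
                                       offset_male = 0, sigma2_noise = 0,
                                       clade_shift = FALSE, seed = 23))
  expect_equal(simd$traits$queen_mm, simd$traits$worker_mm, tolerance = 1e-12)
  expect_equal(simd$traits$male_mm, simd$traits$worker_mm, tolerance = 1e-12)
  fitd <- rensch(simd$traits, simd$tree)
  expect_equal(unname(coef(fitd)), rep(1, 3), tolerance = 1e-10)

  expect_error(sim_config(slope_queen = -1, seed = 1), "> 0")
  # determinism of the full generator
  a <- sim_caste_dataset(sim_config(n_tips = 15, seed = 99))
  b <- sim_caste_dataset(sim_config(n_tips = 15, seed = 99))
  expect_identical(a$traits, b$traits)
  expect_identical(write_tree_text(a$tree), write_tree_text(b$tree))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(sim_caste_dataset(sim_config(n_tips = 10, seed = 4)))
  expect_identical(.Random.seed, before)
})

test_that("the pipeline recovers generator slopes and holds size at the null", {
  # queen-on-worker slope recovery at modest replication (the acceptance
  # suite runs the full-size version)
  for (b in c(0.8, 1.2)) {
    sl <- vapply(1:25, function(s) {
      sim <- sim_caste_dataset(sim_config(n_tips = 100, slope_queen = b,
                                          clade_shift = FALSE,
                                          seed = 30000 + 100 * b + s))
      fit <- rensch(sim$traits, sim$tree,
                    pairs = list(c("queen", "worker")))
      coef(fit)[[1]]
    }, numeric(1))
    expect_lt(abs(mean(sl) - b), 0.05)
  }
  # symmetric male~queen pair with equal unit slopes: isometry holds exactly,
  # so rejections should be near nominal
  rej <- vapply(1:60, function(s) {
    sim <- sim_caste_dataset(sim_config(n_tips = 100, slope_queen = 1,
                                        slope_male = 1, clade_shift = FALSE,
                                        seed = 40000 + s))
    fit <- rensch(sim$traits, sim$tree, pairs = list(c("male", "queen")))
    fit$fits[[1]]$test$p < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.15)
})
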