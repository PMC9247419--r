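# The homotopic connectivity-asymmetry statistic, its weight normalization,
# and the permutation null.

test_that("weight resampling hits the target moments and preserves ranks", {
  WL <- random_graph(25, 0.5, seed = 11) * matrix(rpois(625, 40), 25)
  WL <- (WL + t(WL)) / 2
  cn <- toy_connectome(WL, WL)
  out <- resample_weights_to_normal(cn, asymmetry_config())
  for (idx in list(1:25, 26:50)) {
    w <- out$W[idx, idx][upper.tri(out$W[idx, idx]) & cn$W[idx, idx] > 0]
    expect_gte(length(w), 100)
    expect_equal(mean(w), 1, tolerance = 0.01)
    expect_equal(sd(w), 0.2, tolerance = 0.01)
  }
  # rank order preserved within the hemisphere
  orig <- cn$W[1:25, 1:25][upper.tri(cn$W[1:25, 1:25]) & cn$W[1:25, 1:25] > 0]
  new <- out$W[1:25, 1:25][upper.tri(out$W[1:25, 1:25]) & cn$W[1:25, 1:25] > 0]
  expect_identical(order(rank(orig, ties.method = "first")),
                   order(rank(new, ties.method = "first")))
  # rank invariance: rescaling all inputs by 10 yields identical output
  cn10 <- toy_connectome(WL * 10, WL * 10)
  out10 <- resample_weights_to_normal(cn10, asymmetry_config())
  expect_equal(out10$W, out$W)
  # topology untouched
  expect_identical(out$W > 0, cn$W > 0)
})

test_that("resampling rejects hemispheres with fewer than two edges", {
  W <- wmat(3, rbind(c(1, 2, 4)))
  expect_error(resample_weights_to_normal(toy_connectome(W, W)), "fewer than 2")
})

test_that("pair asymmetry follows the stated profile comparison", {
  expect_equal(pair_asymmetry(c(1, 0.5), c(1, 0.5)), 0)
  expect_equal(pair_asymmetry(c(1.0, 0.5), c(0.8, 0.5)), 0.1)
  # target missing on one side: restricted to the shared connection
  expect_equal(pair_asymmetry(c(1.0, 0.5), c(0.8, 0)), 0.2)
  expect_true(is.na(pair_asymmetry(c(1, 0), c(0, 1))))
  # binary variant: 1 - |shared|/|union|
  expect_equal(pair_asymmetry(c(1, 1, 0), c(1, 0, 1), mode = "binary"), 2 / 3)
  expect_equal(pair_asymmetry(c(2, 3), c(5, 1), mode = "binary"), 0)
})

test_that("a mirror-symmetric connectome scores exactly zero", {
  WL <- random_graph(12, 0.5, seed = 21) * matrix(rpois(144, 30), 12)
  WL <- round((WL + t(WL)) / 2)
  res <- total_asymmetry(toy_connectome(WL, WL))
  expect_identical(res$species_mean, 0)
  expect_true(all(res$pair_scores[!is.na(res$pair_scores)] == 0))
})

test_that("species mean averages eligible homolog pairs", {
  # two regions per hemisphere with engineered profiles; resampling off so
  # the hand-computed values hold exactly
  WL <- wmat(3, rbind(c(1, 2, 1.0), c(1, 3, 0.5), c(2, 3, 0.7)))
  WR <- wmat(3, rbind(c(1, 2, 0.8), c(1, 3, 0.5), c(2, 3, 0.7)))
  res <- total_asymmetry(toy_connectome(WL, WR), resample = FALSE)
  # pair 1: |1-0.8|, |0.5-0.5| -> 0.1 ; pair 2: |1-0.8|, |0.7-0.7| -> 0.1
  # pair 3: |0.5-0.5|, |0.7-0.7| -> 0
  expect_equal(res$pair_scores, c(0.1, 0.1, 0))
  expect_equal(res$species_mean, mean(c(0.1, 0.1, 0)))
  expect_equal(res$n_eligible_pairs, 3L)
})

test_that("asymmetry is symmetric under hemisphere exchange", {
  WL <- random_graph(10, 0.6, seed = 31) * matrix(rpois(100, 20), 10)
  WL <- round((WL + t(WL)) / 2)
  WR <- random_graph(10, 0.6, seed = 32) * matrix(rpois(100, 20), 10)
  WR <- round((WR + t(WR)) / 2)
  a1 <- total_asymmetry(toy_connectome(WL, WR))
  a2 <- total_asymmetry(toy_connectome(WR, WL))
  expect_equal(a1$pair_scores, a2$pair_scores)
  expect_equal(a1$species_mean, a2$species_mean)
})

test_that("asymmetry grows monotonically with hemispheric perturbation", {
  mesh <- generate_hemisphere_mesh(200, subdivisions = 2)
  p <- random_parcellation(mesh, 15, seed = 2)
  cen <- region_centroids(mesh, p)
  means <- vapply(c(0.01, 0.05, 0.1, 0.3), function(eps) {
    vals <- vapply(1:8, function(s) {
      cn <- generate_connectome(cen, cen, ap_extent(mesh),
                                target_density = 0.5, decay_mm = 30,
                                asymmetry_level = eps, seed = s)
      total_asymmetry(cn)$species_mean
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("permutation test: formula, determinism, and null calibration", {
  tr <- simulate_tree(8, seed = 41)
  mesh <- generate_hemisphere_mesh(150, subdivisions = 2)
  p <- random_parcellation(mesh, 12, seed = 3)
  cen <- region_centroids(mesh, p)
  sizes <- 10^seq(0.5, 2.9, length.out = 8)
  conns <- lapply(1:8, function(s) {
    cn <- generate_connectome(cen, cen, ap_extent(mesh), target_density = 0.5,
                              decay_mm = 25, asymmetry_level = 0.02 + 0.06 * s,
                              species = tr$tip.label[s], seed = 50 + s)
    cn
  })
  trait <- sizes
  names(trait) <- tr$tip.label
  cfg <- asymmetry_config(n_perm = 50, seed = 5)
  r1 <- asymmetry_permutation_test(conns, trait, tr, cfg)
  r2 <- asymmetry_permutation_test(conns, trait, tr, cfg)
  expect_identical(r1$null_slopes, r2$null_slopes)
  expect_equal(r1$p_value,
               (1 + sum(r1$null_slopes >= r1$observed_slope)) / (1 + 50))
  expect_gte(r1$p_value, 1 / 51)

  # calibration: when the observed connectomes are themselves a draw from the
  # weight-shuffled null, empirical p is uniform on its lattice
  pvals <- vapply(1:40, function(rep) {
    shuffled <- connallom:::with_seed(1000 + rep,
                                     lapply(conns, connallom:::.shuffle_weights))
    cfg_r <- asymmetry_config(n_perm = 19, seed = 2000 + rep)
    asymmetry_permutation_test(shuffled, trait, tr, cfg_r)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
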