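# The PGLS fitting core: OLS equivalence, lambda estimation, intervals,
# invariances, the independent GLS cross-check, and RMA.

test_that("perfectly collinear data give the exact line with a degenerate flag", {
  tr <- read_phylo_tree("(A:1,B:1,C:1,D:1);")
  d <- data.frame(x = 0:3, y = c(1, 3, 5, 7), row.names = c("A", "B", "C", "D"))
  fit <- pgls(y ~ x, d, tr, lambda = 0)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-10)
  expect_true(fit$degenerate)
  expect_equal(unname(fit$se), c(0, 0))
  expect_true(all(is.na(fit$p.value)))
})

test_that("lambda fixed at 0 reproduces OLS estimates and SEs to 1e-8", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- sample(5:30, 1)
    tr <- simulate_tree(n, seed = s)
    x <- rnorm(n)
    y <- 0.7 * x + rnorm(n, sd = 0.3)
    names(x) <- names(y) <- tr$tip.label
    fit <- fit_pgls(y, x, tr, lambda = 0)
    ora <- ols_oracle(y, x)
    expect_equal(unname(coef(fit)), unname(ora$coef), tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(ora$se), tolerance = 1e-8)
  }
})

test_that("slope is invariant to the common log base", {
  tr <- simulate_tree(12, seed = 3)
  traits <- simulate_traits(tr, species_spec(seed = 3))
  d10 <- data.frame(y = log10(traits$surface_area_cm2),
                    x = log10(traits$cerebral_volume_cm3),
                    row.names = rownames(traits))
  dln <- data.frame(y = log(traits$surface_area_cm2),
                    x = log(traits$cerebral_volume_cm3),
                    row.names = rownames(traits))
  f10 <- pgls(y ~ x, d10, tr)
  fln <- pgls(y ~ x, dln, tr)
  expect_equal(unname(coef(f10)["x"]), unname(coef(fln)["x"]), tolerance = 1e-8)
})

test_that("fixed-lambda PGLS matches nlme::gls with a Pagel correlation", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(16, seed = 9)
  traits <- simulate_traits(tr, species_spec(seed = 9))
  d <- data.frame(y = log10(traits$wm_volume_cm3),
                  x = log10(traits$gm_volume_cm3),
                  species = rownames(traits))
  lam <- 0.6
  fit <- pgls(y ~ x, data = d, tree = tr, lambda = lam)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corPagel(lam, tr, form = ~species, fixed = TRUE))
  expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(g$varBeta))), tolerance = 1e-6)
})

test_that("ML lambda recovers the generating endpoints", {
  tr <- simulate_tree(60, seed = 21)
  lam_bm <- lam_iid <- numeric(30)
  for (r in 1:30) {
    tb <- simulate_traits(tr, species_spec(seed = 500 + r), residual_model = "bm")
    ti <- simulate_traits(tr, species_spec(seed = 900 + r), residual_model = "iid")
    fb <- fit_pgls(log10(tb$surface_area_cm2), log10(tb$cerebral_volume_cm3), tr)
    fi <- fit_pgls(log10(ti$surface_area_cm2), log10(ti$cerebral_volume_cm3), tr)
    lam_bm[r] <- fb$lambda
    lam_iid[r] <- fi$lambda
  }
  expect_gte(median(lam_bm), 0.8)
  expect_lte(median(lam_iid), 0.2)
})

test_that("95% CI covers the generating slope at close to nominal rate", {
  n_rep <- 200
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tr <- simulate_tree(14, seed = 3000 + r)
    traits <- simulate_traits(tr, species_spec(seed = 3000 + r))
    fit <- fit_pgls(log10(traits$surface_area_cm2),
                    log10(traits$cerebral_volume_cm3), tr)
    covered[r] <- fit$ci["x", "lower"] <= 0.85 && 0.85 <= fit$ci["x", "upper"]
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("species mismatches and short data are rejected", {
  tr <- simulate_tree(5, seed = 1)
  d <- data.frame(x = 1:5, y = 1:5, row.names = paste0("w", 1:5))
  expect_error(pgls(y ~ x, d, tr), "species sets")
  d2 <- data.frame(x = 1:2, y = 1:2, row.names = c("a", "b"))
  expect_error(pgls(y ~ x, d2, read_phylo_tree("(a:1,b:1);")), "at least 3")
})

test_that("pgls methods are coherent", {
  tr <- simulate_tree(10, seed = 4)
  traits <- simulate_traits(tr, species_spec(seed = 4))
  d <- data.frame(y = log10(traits$surface_area_cm2),
                  x = log10(traits$cerebral_volume_cm3),
                  row.names = rownames(traits))
  fit <- pgls(y ~ x, d, tr)
  expect_equal(fitted(fit) + residuals(fit), fit$y)
  expect_equal(unname(predict(fit, data.frame(x = d$x))), unname(fitted(fit)))
  expect_equal(dim(confint(fit)), c(2L, 2L))
  expect_lte(fit$ci["x", "lower"], coef(fit)["x"][[1]])
  expect_gte(fit$ci["x", "upper"], coef(fit)["x"][[1]])
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
  expect_lte(fit$adj.r.squared, 1)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(10L, 3L))
  expect_output(print(summary(fit)), "PGLS regression")
})

test_that("reduced major axis slope is sign(r) * SD(y)/SD(x)", {
  f <- rma_fit(c(1, 3, 5), c(1, 2, 3))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, -1)
  x <- c(1, 2, 4, 8)
  expect_equal(rma_fit(x, x)$slope, 1)
  set.seed(2)
  y <- x + rnorm(4, sd = 0.2)
  expect_equal(rma_fit(y, x)$slope, 1 / rma_fit(x, y)$slope, tolerance = 1e-12)
  expect_error(rma_fit(c(1, 1, 1), x[1:3]), "variance")
  expect_error(rma_fit(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(rma_fit(c(1, -1, 1, -1), c(1, 1, -1, -1)), "correlation")
})

test_that("z-transform standardizes and rejects constants", {
  v <- c(2, 4, 6, 8)
  expect_equal(mean(ztrans(v)), 0)
  expect_equal(sd(ztrans(v)), 1)
  expect_error(ztrans(rep(3, 5)), "constant")
})
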