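# Connectome assembly, density, density equalization, and length binning.

test_that("streamline counts and mean lengths populate the matrices", {
  regs <- data.frame(region = c("A", "B", "C"),
                     hemisphere = "left", x = c(0, 10, 20), y = 0, z = 0)
  st <- data.frame(region_a = c("A", "A", "B", "A", "unassigned", "B"),
                   region_b = c("B", "B", "A", "A", "C", "B"),
                   length_mm = c(10, 20, 30, 5, 7, 9))
  cn <- streamlines_to_connectome(st, regs, ap_extent_mm = 50)
  expect_equal(cn$W["A", "B"], 3)
  expect_equal(cn$L["A", "B"], 20)            # mean of 10, 20, 30
  expect_equal(cn$W, t(cn$W))
  expect_true(all(diag(cn$W) == 0))           # intra-region streamlines dropped
  log <- attr(cn, "discard_log")
  expect_equal(unname(log["unassigned"]), 1L)
  expect_equal(unname(log["intra_region"]), 2L)  # A-A and B-B
  expect_equal(sum(log), nrow(st))            # discard log + counted = input
})

test_that("an empty streamline table warns and yields a zero connectome", {
  regs <- data.frame(region = c("A", "B"), hemisphere = "left",
                     x = c(0, 10), y = 0, z = 0)
  expect_warning(cn <- streamlines_to_connectome(
    data.frame(region_a = character(), region_b = character(),
               length_mm = numeric()), regs, 50), "empty")
  expect_true(all(cn$W == 0))
})

test_that("network density counts observed over possible pairs", {
  expect_equal(network_density(complete_graph(4)), 1.0)
  expect_equal(network_density(path_graph(4)), 0.5)
  expect_equal(network_density(matrix(0, 3, 3)), 0)
  expect_error(network_density(matrix(0, 1, 1)), "at least 2")

  cn <- toy_connectome(path_graph(4), complete_graph(4))
  expect_equal(network_density(cn, "left"), 0.5)
  expect_equal(network_density(cn, "right"), 1.0)
})

test_that("density equalization keeps the strongest connections down to the minimum", {
  WL1 <- wmat(5, rbind(c(1, 2, 5), c(2, 3, 4), c(3, 4, 3), c(4, 5, 2),
                       c(1, 5, 1), c(1, 3, 6), c(2, 4, 7), c(3, 5, 8),
                       c(1, 4, 9), c(2, 5, 10)))   # complete: density 1
  WL2 <- wmat(5, rbind(c(1, 2, 5), c(2, 3, 4), c(3, 4, 3), c(4, 5, 2),
                       c(1, 5, 1), c(1, 3, 6)))    # 6/10 edges
  c1 <- toy_connectome(WL1, WL1, species = "dense")
  c2 <- toy_connectome(WL2, WL2, species = "sparse")
  eq <- equalize_density(list(c1, c2))
  expect_equal(network_density(eq[[1]], "left"), 0.6)
  expect_equal(network_density(eq[[2]], "left"), 0.6)
  # sparse network already at target: unchanged
  expect_equal(eq[[2]]$W, c2$W)
  # edge sets nested within the originals, weights preserved where kept
  expect_true(all(eq[[1]]$W[eq[[1]]$W > 0] == c1$W[eq[[1]]$W > 0]))
  expect_true(all(c1$W[eq[[1]]$W > 0] > 0))
  # symmetric zero-diagonal survives
  expect_equal(eq[[1]]$W, t(eq[[1]]$W))
  expect_true(all(diag(eq[[1]]$W) == 0))
})

test_that("thresholding keeps the top weights, ties broken deterministically", {
  W <- wmat(5, rbind(c(1, 2, 5), c(2, 3, 4), c(3, 4, 3), c(4, 5, 2), c(1, 5, 1)))
  cn <- toy_connectome(W, W)
  eq <- equalize_density(list(cn), target = 3 / 10)
  kept <- sort(eq[[1]]$W[1:5, 1:5][upper.tri(matrix(0, 5, 5))], decreasing = TRUE)
  expect_equal(kept[1:3], c(5, 4, 3))
  expect_equal(sum(eq[[1]]$W[1:5, 1:5] > 0) / 2, 3)
})

test_that("equalization rejects an unattainable target, naming the network", {
  cn <- toy_connectome(path_graph(4), species = "thin")  # density 0.5
  expect_error(equalize_density(list(cn), target = 0.9), "thin")
})

test_that("length bins cover 10% AP slices with overflow into bin 10", {
  n <- 5
  W <- wmat(n, rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1)))
  regions <- data.frame(region = c(paste0("L", 1:n), paste0("R", 1:n)),
                        hemisphere = rep(c("left", "right"), each = n),
                        x = 0, y = 0, z = 0)
  Wf <- matrix(0, 2 * n, 2 * n); Wf[1:n, 1:n] <- W
  L <- matrix(0, 2 * n, 2 * n)
  L[1, 2] <- L[2, 1] <- 5
  L[1, 3] <- L[3, 1] <- 15
  L[1, 4] <- L[4, 1] <- 95
  L[1, 5] <- L[5, 1] <- 120        # longer than the AP extent
  cn <- connectome(regions, Wf, L, ap_extent_mm = 100,
                   homolog = c(n + 1:n, 1:n))
  b <- length_bin_distribution(cn)
  expect_equal(b$proportions,
               c(0.25, 0.25, 0, 0, 0, 0, 0, 0, 0, 0.5))
  expect_equal(sum(b$proportions), 1, tolerance = 1e-9)
  expect_equal(length(b$proportions), 10L)
})

test_that("bins degenerate cases and the short/long contrast", {
  n <- 3
  regions <- data.frame(region = c(paste0("L", 1:n), paste0("R", 1:n)),
                        hemisphere = rep(c("left", "right"), each = n),
                        x = 0, y = 0, z = 0)
  W <- matrix(0, 2 * n, 2 * n)
  W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 1
  L <- ifelse(W > 0, 4, 0)                  # all lengths within bin 1
  cn <- connectome(regions, W, L, ap_extent_mm = 1000,
                   homolog = c(n + 1:n, 1:n))
  b <- length_bin_distribution(cn, scope = "left")
  expect_equal(b$proportions[1], 1.0)

  mk <- function(p) structure(list(proportions = p, counts = p * 100,
                                   bin_width_mm = 10, n_connections = 100),
                              class = "length_bins")
  expect_equal(short_long_contrast(mk(c(.3, .3, rep(.05, 8)))),
               c(short = 0.6, long = 0.4))
  expect_equal(short_long_contrast(mk(c(1, rep(0, 9)))),
               c(short = 1, long = 0))
  expect_equal(short_long_contrast(mk(rep(.1, 10))),
               c(short = 0.2, long = 0.8))
})

test_that("connectome invariants are enforced at construction", {
  regs <- data.frame(region = c("A", "B"), hemisphere = "left",
                     x = c(0, 1), y = 0, z = 0)
  Wb <- matrix(c(0, 1, 2, 0), 2)            # asymmetric
  expect_error(connectome(regs, Wb, Wb, 10), "symmetric")
  Wd <- matrix(c(1, 1, 1, 0), 2)            # nonzero diagonal
  expect_error(connectome(regs, Wd, Wd, 10), "diagonal")
  W <- matrix(c(0, 1, 1, 0), 2)
  L0 <- matrix(0, 2, 2)                      # zero length on an edge
  expect_error(connectome(regs, W, L0, 10), "positive")
})

test_that("connectome matrix and edge-list files round-trip", {
  cn <- toy_connectome(wmat(4, rbind(c(1, 2, 3), c(2, 3, 4), c(1, 4, 2))))
  pre <- file.path(tempdir(), "toy")
  write_connectome(cn, pre)
  cn2 <- read_connectome(pre, species = "toy")
  expect_equal(cn2$W, unname(cn$W))
  expect_equal(cn2$L, unname(cn$L), tolerance = 1e-6)
  expect_equal(cn2$ap_extent, cn$ap_extent)
  f <- tempfile(fileext = ".tsv")
  write_edge_list(cn, f)
  el <- read.delim(f)
  expect_equal(nrow(el), sum(cn$W > 0) / 2)
})
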