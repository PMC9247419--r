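# Synthetic hemisphere meshes and the random evenly-dispersed parcellation.

test_that("icosphere meshes have the closed-form vertex count and are closed surfaces", {
  m2 <- generate_hemisphere_mesh(100, subdivisions = 2)
  m3 <- generate_hemisphere_mesh(100, subdivisions = 3)
  expect_equal(nrow(m2$vertices), 10 * 4^2 + 2)   # 162
  expect_equal(nrow(m3$vertices), 10 * 4^3 + 2)   # 642
  expect_equal(euler_characteristic(m2), 2)
  expect_equal(euler_characteristic(m3), 2)
})

test_that("mesh area matches the requested surface area", {
  for (a in c(11, 300, 1555)) {
    m <- generate_hemisphere_mesh(a, subdivisions = 3)
    expect_equal(mesh_area(m), a * 100, tolerance = 0.005)  # cm^2 -> mm^2
  }
})

test_that("mirror meshes differ only in the sign of the mirror axis", {
  mL <- generate_hemisphere_mesh(200, subdivisions = 2, side = "left")
  mR <- generate_hemisphere_mesh(200, subdivisions = 2, side = "right")
  expect_equal(mR$vertices[, 1], -mL$vertices[, 1])
  expect_equal(mR$vertices[, 2:3], mL$vertices[, 2:3])
  expect_equal(mL$mirror_index, seq_len(nrow(mL$vertices)))
  expect_gt(ap_extent(mL), diff(range(mL$vertices[, 1])))  # AP axis longest
})

test_that("ASCII PLY round-trips a mesh", {
  m <- generate_hemisphere_mesh(50, subdivisions = 1)
  f <- tempfile(fileext = ".ply")
  write_ply(m, f)
  m2 <- read_ply(f)
  expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-8)
  expect_equal(m2$faces, unname(m$faces))
})

test_that("default parcellation yields 50 approximately equal, non-empty parcels", {
  mesh <- generate_hemisphere_mesh(300, subdivisions = 4)  # 2562 vertices
  p <- random_parcellation(mesh, n_regions = 50, seed = 1)
  expect_equal(p$n_regions, 50L)
  expect_equal(length(unique(p$labels)), 50L)
  expect_true(all(p$sizes > 0))
  expect_equal(sum(p$sizes), nrow(mesh$vertices))
  expect_lte(max(p$sizes) / min(p$sizes), 3)
  expect_true(all(p$labels %in% 1:50))
})

test_that("parcellation is deterministic per seed and varies across seeds", {
  mesh <- generate_hemisphere_mesh(100, subdivisions = 2)
  p1 <- random_parcellation(mesh, 10, seed = 7)
  p2 <- random_parcellation(mesh, 10, seed = 7)
  p3 <- random_parcellation(mesh, 10, seed = 8)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$centers, p2$centers)
  expect_false(identical(sort(p1$centers), sort(p3$centers)))
})

test_that("degenerate parcel counts work and overflow errors", {
  mesh <- generate_hemisphere_mesh(100, subdivisions = 1)  # 42 vertices
  p1 <- random_parcellation(mesh, 1, seed = 1)
  expect_true(all(p1$labels == 1L))
  pV <- random_parcellation(mesh, nrow(mesh$vertices), seed = 1)
  expect_equal(sort(unique(pV$labels)), seq_len(nrow(mesh$vertices)))
  expect_true(all(pV$sizes == 1L))
  expect_error(random_parcellation(mesh, nrow(mesh$vertices) + 1, seed = 1),
               "exceeds vertex count")
})

test_that("disconnected meshes are rejected with component sizes", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  fc <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  two <- surface_mesh(rbind(tet, tet + 10), rbind(fc, fc + 4L), "left")
  expect_error(random_parcellation(two, 2, seed = 1), "disconnected")
})

test_that("contralateral projection transfers labels through the mirror map", {
  mL <- generate_hemisphere_mesh(150, subdivisions = 2, side = "left")
  mR <- generate_hemisphere_mesh(150, subdivisions = 2, side = "right")
  pL <- random_parcellation(mL, 12, seed = 5)
  pR <- project_contralateral(pL, mL, mR)
  expect_equal(pR$labels[mL$mirror_index], pL$labels)
  expect_equal(pR$n_regions, pL$n_regions)
  back <- project_contralateral(pR, mR, mL)
  expect_identical(back$labels, pL$labels)

  bare <- surface_mesh(mL$vertices, mL$faces, "left")  # no correspondence
  expect_error(project_contralateral(pL, bare, mR), "correspondence")
})

test_that("region centroids are member means and mirror-symmetric", {
  mL <- generate_hemisphere_mesh(150, subdivisions = 2, side = "left")
  mR <- generate_hemisphere_mesh(150, subdivisions = 2, side = "right")
  pL <- random_parcellation(mL, 8, seed = 2)
  pR <- project_contralateral(pL, mL, mR)
  cL <- region_centroids(mL, pL)
  cR <- region_centroids(mR, pR)
  expect_equal(nrow(cL), 8L)
  expect_equal(cL$x, -cR$x, tolerance = 1e-6)
  expect_equal(cL$y, cR$y, tolerance = 1e-6)

  one <- random_parcellation(mL, 1, seed = 1)
  expect_equal(as.numeric(region_centroids(mL, one)[1, c("x", "y", "z")]),
               colMeans(mL$vertices))

  seg <- surface_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                      rbind(c(1, 2, 3)), "left")
  p <- structure(list(labels = c(1L, 1L, 2L), centers = c(1L, 3L),
                      n_regions = 2L, sizes = c(2L, 1L), hemisphere = "left",
                      seed = 1, distance = "geodesic"), class = "parcellation")
  expect_equal(as.numeric(region_centroids(seg, p)[1, c("x", "y", "z")]),
               c(1, 0, 0))
})

test_that("parcellation tables round-trip", {
  mesh <- generate_hemisphere_mesh(100, subdivisions = 1)
  p <- random_parcellation(mesh, 5, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_parcellation(p, f)
  p2 <- read_parcellation(f)
  expect_identical(p2$labels, p$labels)
  expect_equal(p2$n_regions, p$n_regions)
})
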