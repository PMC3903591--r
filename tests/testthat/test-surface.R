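voxSphere <- function(R = 0.2, h = 0.01) {
  n <- 2 * ceiling(R / h) + 9
  cc <- (n - 1) / 2 * h
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  d2 <- ((g$i - 1) * h - cc)^2 + ((g$j - 1) * h - cc)^2 +
    ((g$k - 1) * h - cc)^2
  array(d2 <= R^2, c(n, n, n))
}

voxCylinder <- function(R = 0.15, L = 1.0, h = 0.0075) {
  nxy <- 2 * ceiling(R / h) + 9
  nz <- ceiling(L / h) + 9
  cc <- (nxy - 1) / 2 * h
  g <- expand.grid(i = 1:nxy, j = 1:nxy)
  slice <- matrix(((g$i - 1) * h - cc)^2 + ((g$j - 1) * h - cc)^2 <= R^2,
                  nxy, nxy)
  m <- array(FALSE, c(nxy, nxy, nz))
  z0 <- 5; z1 <- z0 + round(L / h)
  for (k in z0:z1) m[, , k] <- slice
  list(mask = m, L = (z1 - z0) * h)
}

test_that("a voxelized sphere recovers the analytic area and volume", {
  R <- 0.2; h <- 0.01   # spacing = R/20
  mesh <- extractSurface(voxSphere(R, h), spacing = h * 1000)
  expect_true(meshIsClosed(mesh))
  expect_lt(abs(meshArea(mesh) / (4 * pi * R^2) - 1), 0.03)
  expect_lt(abs(meshVolume(mesh) / (4 / 3 * pi * R^3) - 1), 0.02)
})

test_that("a voxelized cylinder recovers the analytic volume and matches voxel counting", {
  R <- 0.15; h <- 0.0075
  cyl <- voxCylinder(R, 1.0, h)
  mesh <- extractSurface(cyl$mask, spacing = h * 1000)
  expect_true(meshIsClosed(mesh))
  expect_lt(abs(meshVolume(mesh) / (pi * R^2 * cyl$L) - 1), 0.02)
  # mesh-enclosed volume vs voxel-count volume agreement
  expect_lt(abs(meshVolume(mesh) / (sum(cyl$mask) * h^3) - 1), 0.02)
})

test_that("a single-voxel mask yields a valid closed surface", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  mesh <- extractSurface(m, spacing = 10)
  expect_true(meshIsClosed(mesh))
  expect_gt(meshVolume(mesh), 0)
})

test_that("empty masks are rejected", {
  expect_error(extractSurface(array(FALSE, c(4, 4, 4)), spacing = 10),
               "empty mask")
})

test_that("branch clipping removes the stub, caps the hole and stays watertight", {
  Rt <- 0.15; Rbr <- 0.06; L <- 1.0; h <- 0.010
  trunk <- straightSegment("descending_aorta", c(0.25, 0.25, 0.05),
                           c(0.25, 0.25, 0.05 + L), Rt)
  br <- straightSegment("innominate", c(0.25, 0.25, 0.55),
                        c(0.6, 0.25, 0.55), Rbr)
  ph <- phantomMask(vesselTree(list(trunk, br)), h * 1000)
  mesh <- extractSurface(ph$mask)
  lmk <- list(list(point = c(0.25 + Rt, 0.25, 0.55) - ph$origin,
                   normal = c(1, 0, 0), radius = 2.2 * Rbr))
  cl <- clipBranches(mesh, lmk)
  expect_true(meshIsClosed(cl))
  expect_lt(abs(meshArea(cl) / (2 * pi * Rt * L + 2 * pi * Rt^2) - 1), 0.05)
  # meshes without branches pass through unchanged
  expect_identical(clipBranches(mesh, list())@faces, mesh@faces)
  # off-surface landmarks are rejected
  expect_error(clipBranches(mesh, list(list(point = c(5, 5, 5),
                                            normal = c(1, 0, 0),
                                            radius = 0.05))),
               "not on surface")
})

test_that("clipping all branches of a three-branch arch creates exactly three caps", {
  h <- 0.012
  trunk <- straightSegment("descending_aorta", c(0.3, 0.3, 0.05),
                           c(0.3, 0.3, 1.05), 0.13)
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  zs <- c(0.3, 0.55, 0.8)
  brs <- lapply(1:3, function(i)
    straightSegment(c("innominate", "left_common_carotid",
                      "left_subclavian")[i],
                    c(0.3, 0.3, zs[i]),
                    c(0.3, 0.3, zs[i]) + 0.3 * unlist(dirs[i]), 0.05))
  ph <- phantomMask(vesselTree(c(list(trunk), brs)), h * 1000)
  mesh <- extractSurface(ph$mask)
  nf0 <- nrow(mesh@faces)
  lmks <- lapply(1:3, function(i)
    list(point = c(0.3, 0.3, zs[i]) + 0.13 * unlist(dirs[i]) - ph$origin,
         normal = unlist(dirs[i]), radius = 0.11))
  cl <- clipBranches(mesh, lmks)
  expect_true(meshIsClosed(cl))
  # each cap is a centroid fan: one added vertex per hole
  expect_equal(nrow(cl@vertices) - nrow(mesh@vertices), 3L)
})
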