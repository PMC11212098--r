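test_that("whole-tumor mask unions labels 1, 2 and 4 and rejects empties", {
  labs <- array(0L, c(4, 4, 4))
  expect_error(whole_tumor_mask(segmentation_mask(labs, c(1, 1, 1))),
               class = "empty_tumor_error")
  labs[2, 2, 2] <- 2L
  bm <- whole_tumor_mask(segmentation_mask(labs, c(1, 1, 1)))
  expect_equal(sum(bm$voxels), 1)
  labs[3, 3, 3] <- 1L; labs[1, 1, 1] <- 4L
  bm <- whole_tumor_mask(segmentation_mask(labs, c(1, 1, 1)))
  expect_equal(sum(bm$voxels), 3)
})

test_that("single voxel yields a closed mesh with sub-voxel volume", {
  vox <- array(FALSE, c(1, 1, 1)); vox[1, 1, 1] <- TRUE
  mesh <- build_surface_mesh(as_binary_mask(vox))
  expect_true(mesh_is_closed(mesh))
  mm <- mesh_measures(mesh)
  expect_gt(mm[["mesh_volume"]], 0)
  expect_lt(mm[["mesh_volume"]], 1)
})

test_that("digitized ball: closed genus-0 mesh, volume within 5% of the analytic sphere", {
  mesh <- build_surface_mesh(as_binary_mask(ball_mask(10)))
  expect_true(mesh_is_closed(mesh))
  v <- nrow(mesh$vertices); f <- nrow(mesh$faces)
  expect_equal(v - (3 * f / 2) + f, 2)  # Euler characteristic
  mm <- mesh_measures(mesh)
  analytic <- 4 / 3 * pi * 10^3
  expect_lt(abs(mm[["mesh_volume"]] - analytic) / analytic, 0.05)
  # discretization study: midpoint-vertex surfaces of binary balls land
  # around 0.92; the band below is frozen from that study
  expect_gt(mm[["sphericity"]], 0.90)
  expect_lt(mm[["sphericity"]], 1.02)
})

test_that("sphericity orders the ball above a 20:10:5 ellipsoid", {
  ball <- mesh_measures(build_surface_mesh(as_binary_mask(ball_mask(10))))
  emask <- ellipsoid_mask(c(45, 25, 15), c(22, 12, 7), c(20, 10, 5))
  ell <- mesh_measures(build_surface_mesh(as_binary_mask(emask)))
  expect_gt(ball[["sphericity"]], ell[["sphericity"]])
})

test_that("degenerate coplanar meshes are rejected", {
  flat <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               faces = rbind(c(1, 2, 3), c(2, 4, 3), c(1, 3, 2), c(2, 3, 4)),
               spacing_mm = c(1, 1, 1))
  class(flat) <- "tri_mesh"
  expect_error(mesh_measures(flat), class = "degenerate_mesh_error")
})

test_that("two-voxel diameters: 3D spans the pair, restricted planes match", {
  vox <- array(FALSE, c(10, 3, 3))
  vox[1, 2, 2] <- TRUE; vox[10, 2, 2] <- TRUE
  mesh <- build_surface_mesh(as_binary_mask(vox))
  d <- diameter_features(mesh)
  expect_equal(d[["max_3d_diameter"]], 10)   # 9 between centers + 2 * 0.5 mesh offset
  expect_equal(d[["max_2d_diameter_slice"]], 10)
  expect_equal(d[["max_2d_diameter_row"]], 10)
  expect_lte(d[["max_2d_diameter_column"]], 1.01)
})

test_that("single-voxel diameters are all equal and positive", {
  vox <- array(TRUE, c(1, 1, 1))
  d <- diameter_features(build_surface_mesh(as_binary_mask(vox)))
  expect_gt(d[["max_3d_diameter"]], 0)
  expect_equal(unname(d), rep(d[["max_3d_diameter"]], 4))
})

test_that("diameters equal the O(n^2) brute-force oracle on random phantoms", {
  set.seed(101)
  for (i in 1:25) {
    vox <- array(FALSE, c(14, 14, 14))
    for (k in seq_len(sample(1:2, 1))) {
      ctr <- runif(3, 4, 9); rad <- runif(3, 1.5, 4)
      vox <- vox | ellipsoid_mask(c(14, 14, 14), ctr, rad)
    }
    if (!any(vox)) next
    sp <- c(1, 1, 1)
    mesh <- build_surface_mesh(as_binary_mask(vox, sp))
    d <- diameter_features(mesh)
    o <- oracle_diameters(mesh$vertices, sp / 2)
    expect_equal(unname(d), o, tolerance = 1e-12)
    expect_gte(d[["max_3d_diameter"]] + 1e-12,
               max(d[["max_2d_diameter_slice"]], d[["max_2d_diameter_column"]],
                   d[["max_2d_diameter_row"]]))
    expect_true(mesh_is_closed(mesh))
  }
})

test_that("axis features recover sphere symmetry and ellipsoid axis ratios", {
  ball <- as_binary_mask(ball_mask(10))
  ax <- axis_features(ball)
  expect_lt(diff(range(ax[1:3])) / ax[["major_axis_length"]], 0.05)
  expect_gt(ax[["elongation"]], 0.95); expect_lte(ax[["elongation"]], 1)
  expect_gt(ax[["flatness"]], 0.95); expect_lte(ax[["flatness"]], 1)
  emask <- as_binary_mask(ellipsoid_mask(c(45, 25, 15), c(22, 12, 7), c(20, 10, 5)))
  ax2 <- axis_features(emask)
  r <- unname(ax2[1:3] / ax2[[3]])
  expect_equal(r, c(4, 2, 1), tolerance = 0.1)
  expect_gte(ax2[["major_axis_length"]], ax2[["minor_axis_length"]])
  expect_gte(ax2[["minor_axis_length"]], ax2[["least_axis_length"]])
})

test_that("degenerate voxel sets return zeros with a warning", {
  vox <- array(FALSE, c(3, 3, 3)); vox[2, 2, 2] <- TRUE
  expect_warning(ax <- axis_features(as_binary_mask(vox)), "degenerate|single")
  expect_equal(unname(ax), rep(0, 5))
  line <- array(FALSE, c(6, 3, 3)); line[1:5, 2, 2] <- TRUE
  expect_warning(ax2 <- axis_features(as_binary_mask(line)), "degenerate")
  expect_gt(ax2[["major_axis_length"]], 0)
  expect_equal(ax2[["least_axis_length"]], 0)
  expect_equal(ax2[["flatness"]], 0)
})

test_that("the full feature vector has 14 finite named values in fixed order", {
  labs <- array(0L, c(12, 12, 10))
  labs[4:8, 4:8, 4:7] <- 4L; labs[5:6, 5:6, 5:6] <- 1L
  sf <- extract_shape_features(segmentation_mask(labs, c(1, 1, 1)))
  expect_identical(names(sf), shape_feature_names())
  expect_true(all(is.finite(sf)))
  expect_true(all(sf >= 0))
})

test_that("voxel volume is exact count arithmetic", {
  labs <- array(0L, c(5, 5, 5)); labs[2, 2, 2] <- 2L
  sf <- suppressWarnings(extract_shape_features(segmentation_mask(labs, c(1, 1, 1))))
  expect_identical(sf[["voxel_volume"]], 1)
  labs[3, 3, 3] <- 4L; labs[4, 4, 4] <- 1L
  sf2 <- suppressWarnings(extract_shape_features(segmentation_mask(labs, c(0.5, 0.5, 2))))
  expect_identical(sf2[["voxel_volume"]], 3 * 0.5 * 0.5 * 2)
})

test_that("features scale correctly with voxel spacing", {
  labs <- array(0L, c(14, 14, 12))
  labs[4:10, 5:9, 4:9] <- 4L
  f1 <- extract_shape_features(segmentation_mask(labs, c(1, 1, 1)))
  f2 <- extract_shape_features(segmentation_mask(labs, c(2, 2, 2)))
  expect_equal(f2[["voxel_volume"]], 8 * f1[["voxel_volume"]])
  expect_equal(f2[["mesh_volume"]], 8 * f1[["mesh_volume"]], tolerance = 1e-9)
  expect_equal(f2[["surface_area"]], 4 * f1[["surface_area"]], tolerance = 1e-9)
  for (nm in c("max_3d_diameter", "major_axis_length", "least_axis_length"))
    expect_equal(f2[[nm]], 2 * f1[[nm]], tolerance = 1e-9)
  for (nm in c("sphericity", "elongation", "flatness"))
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-9)
})

test_that("90-degree lattice rotations leave the measures invariant", {
  set.seed(7)
  vox <- ellipsoid_mask(c(16, 16, 16), c(8, 7, 9), c(5, 3, 4))
  base <- mesh_measures(build_surface_mesh(as_binary_mask(vox)))
  rot <- aperm(vox, c(2, 1, 3))[dim(vox)[2]:1, , ]  # 90 deg about z
  got <- mesh_measures(build_surface_mesh(as_binary_mask(rot)))
  expect_identical(sum(vox), sum(rot))
  expect_equal(got[["mesh_volume"]], base[["mesh_volume"]], tolerance = 1e-9)
  expect_equal(got[["surface_area"]], base[["surface_area"]], tolerance = 1e-9)
})

test_that("scaling covariance holds on random phantoms", {
  set.seed(33)
  for (i in 1:10) {
    vox <- ellipsoid_mask(c(15, 15, 15), runif(3, 5, 9), runif(3, 2, 5))
    if (sum(vox) < 8) next
    s <- runif(1, 0.5, 3)
    m1 <- segmentation_mask(array(4L * vox, dim(vox)), c(1, 1, 1))
    m2 <- segmentation_mask(array(4L * vox, dim(vox)), c(s, s, s))
    f1 <- extract_shape_features(m1); f2 <- extract_shape_features(m2)
    expect_equal(f2[["mesh_volume"]], s^3 * f1[["mesh_volume"]], tolerance = 1e-9)
    expect_equal(f2[["surface_area"]], s^2 * f1[["surface_area"]], tolerance = 1e-9)
    expect_equal(f2[["max_3d_diameter"]], s * f1[["max_3d_diameter"]], tolerance = 1e-9)
    expect_equal(f2[["sphericity"]], f1[["sphericity"]], tolerance = 1e-9)
  }
})
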