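test_that("single-segment and deeper trees have the analytic branch count", {
  s1 <- generate_phantom(phantom_spec(grid_shape = c(32, 24, 24),
                                      tree_depth = 1, noise_sd = 0,
                                      seed = 2))
  expect_equal(s1$centerline_branches$n_branches, 1)
  expect_equal(s1$tree_graph$n_edges, 1)

  s3 <- generate_phantom(phantom_spec(tree_depth = 3, seed = 5))
  expect_equal(s3$tree_graph$n_edges, 7)  # 2^3 - 1 edges, binary branching
  expect_equal(s3$centerline_branches$n_branches, 7)
})

test_that("identical spec and seed give bit-identical samples", {
  sp <- phantom_spec(seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(as.array(a$image), as.array(b$image))
  expect_identical(as.array(a$mask), as.array(b$mask))
  c2 <- generate_phantom(phantom_spec(seed = 43))
  expect_false(identical(as.array(a$image), as.array(c2$image)))
})

test_that("noise-free images threshold back to the exact mask", {
  sp <- phantom_spec(tree_depth = 2, noise_sd = 0, seed = 9)
  s <- generate_phantom(sp)
  thr <- (sp$tube_intensity + sp$background_intensity) / 2
  rec <- array(as.integer(as.array(s$image) >= thr), dim(s$mask))
  expect_identical(rec, as.array(s$mask))
})

test_that("every centerline voxel lies inside the mask", {
  for (seed in c(1, 2, 3)) {
    s <- generate_phantom(phantom_spec(seed = seed))
    m <- as.array(s$mask)
    for (b in s$centerline_branches$branches)
      expect_true(all(m[b] == 1L))
  }
})

test_that("branches are pairwise disjoint", {
  s <- generate_phantom(phantom_spec(seed = 17))
  keys <- unlist(lapply(s$centerline_branches$branches, function(b)
    paste(b[, 1], b[, 2], b[, 3])))
  expect_equal(anyDuplicated(keys), 0)
})

test_that("mask volume grows monotonically with the root radius", {
  vols <- vapply(c(2, 3, 4), function(r) {
    sum(generate_phantom(phantom_spec(root_radius_vox = r, noise_sd = 0,
                                      seed = 4))$mask)
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(root_radius_vox = 0.5))
  expect_error(phantom_spec(radius_taper = 0))
  expect_error(phantom_spec(radius_taper = 1.2))
  expect_error(phantom_spec(noise_sd = -1))
  expect_error(generate_phantom(phantom_spec(grid_shape = c(4, 4, 4))),
               "degenerate")
  # a tree whose trunk radius leaves no room inside the grid
  expect_error(generate_phantom(phantom_spec(grid_shape = c(10, 10, 10),
                                             root_radius_vox = 4,
                                             tree_depth = 1)),
               "does not fit")
})

test_that("fixtures have their documented geometry", {
  sv <- make_fixture("single_voxel")
  expect_equal(sum(sv$mask), 1)

  st <- make_fixture("straight_tube")
  expect_equal(st$centerline_branches$n_branches, 1)
  expect_equal(nrow(st$centerline_branches$branches[[1]]), 20)
  # all centerline voxels on the tube axis
  expect_true(all(st$centerline_branches$branches[[1]][, 2] == 7))

  yj <- make_fixture("y_junction")
  expect_equal(yj$centerline_branches$n_branches, 3)
  expect_true(all(dim(yj$mask) <= 40))

  expect_error(make_fixture("no_such_fixture"), "unknown fixture")
})

test_that("NIfTI and JSON round trips preserve data and spacing", {
  dir <- withr::local_tempdir()
  s <- generate_phantom(phantom_spec(grid_shape = c(16, 16, 16),
                                     tree_depth = 1,
                                     spacing_mm = c(0.5, 0.7, 0.7),
                                     seed = 1))
  write_phantom(s, dir)
  img <- read_volume(file.path(dir, "image.nii.gz"), "image")
  msk <- read_volume(file.path(dir, "mask.nii.gz"), "mask")
  expect_equal(as.array(img), as.array(s$image), tolerance = 1e-6)
  expect_identical(as.array(msk), as.array(s$mask))
  expect_equal(spacing(img), c(0.5, 0.7, 0.7), tolerance = 1e-6)
  bs <- read_branchset(file.path(dir, "branches.json"))
  expect_equal(bs$n_branches, s$centerline_branches$n_branches)
  expect_equal(unname(bs$branches[[1]]),
               unname(s$centerline_branches$branches[[1]]))
})
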