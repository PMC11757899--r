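test_that("a single voxel is its own skeleton", {
  sv <- make_fixture("single_voxel")
  sk <- skeletonize(sv$mask)
  expect_identical(as.array(sk), as.array(sv$mask))
  expect_equal(nrow(find_bifurcations(sk)), 0)
})

test_that("a straight tube thins to a single endpoint-to-endpoint path", {
  st <- make_fixture("straight_tube")
  sk <- skeletonize(st$mask)
  m <- as.array(sk)
  expect_true(all(m <= as.array(st$mask)))       # subset of the mask
  expect_true(bf_is_thin(m))
  deg <- bf_degrees(m)
  expect_equal(sum(deg == 1), 2)                  # two endpoints
  expect_true(all(deg <= 2))                      # simple path, no junctions
  # endpoints near the tube caps (z ranges 5..24)
  ends <- which(m == 1, arr.ind = TRUE)
  zr <- range(ends[, 1])
  expect_lt(abs(zr[1] - 5), 4)
  expect_lt(abs(zr[2] - 24), 4)
  expect_equal(nrow(find_bifurcations(sk)), 0)
  expect_equal(decompose_branches(sk)$n_branches, 1)
})

test_that("a Y junction has 3 endpoints, one bifurcation cluster, 3 branches", {
  yj <- make_fixture("y_junction")
  sk <- skeletonize(yj$mask)
  m <- as.array(sk)
  expect_true(bf_is_thin(m))
  expect_equal(bf_count_endpoints(m), 3)
  bif <- find_bifurcations(sk)
  expect_gte(nrow(bif), 1)
  # bifurcation voxels form a single 26-connected cluster
  if (nrow(bif) > 1) {
    bm <- array(0L, dim(m)); bm[bif] <- 1L
    lab <- sgtube:::cpp_label3d(bm, dim(bm), 26L)
    expect_equal(max(lab), 1)
  }
  bs <- decompose_branches(sk)
  expect_equal(bs$n_branches, 3)
  # brute-force cross-check of the bifurcation count
  expect_equal(nrow(bif), bf_count_bifurcations(m))
})

test_that("branches plus bifurcation voxels exactly cover the skeleton", {
  for (nm in c("straight_tube", "y_junction", "two_blobs")) {
    sk <- skeletonize(make_fixture(nm)$mask)
    bs <- decompose_branches(sk)
    cover <- array(0L, dim(sk))
    for (b in bs$branches) cover[b] <- cover[b] + 1L
    if (nrow(bs$bifurcation_points) > 0)
      cover[bs$bifurcation_points] <- cover[bs$bifurcation_points] + 1L
    expect_identical(cover, array(as.integer(as.array(sk)), dim(sk)),
                     label = paste("coverage for", nm))
  }
})

test_that("skeletonization is idempotent on all fixtures", {
  for (nm in c("single_voxel", "straight_tube", "y_junction", "two_blobs")) {
    sk1 <- skeletonize(make_fixture(nm)$mask)
    sk2 <- skeletonize(sk1)
    expect_identical(as.array(sk1), as.array(sk2), label = nm)
  }
})

test_that("empty and invalid masks are handled", {
  empty <- binary_volume(array(0L, c(8, 8, 8)))
  expect_equal(sum(skeletonize(empty)), 0)
  expect_equal(nrow(find_bifurcations(skeletonize(empty))), 0)
  expect_equal(decompose_branches(skeletonize(empty))$n_branches, 0)
  expect_error(skeletonize(array(0.5, c(4, 4, 4))), "binary")
})

test_that("two separated blobs give two branches", {
  tb <- make_fixture("two_blobs")
  bs <- decompose_branches(skeletonize(tb$mask))
  expect_equal(bs$n_branches, 2)
})

test_that("phantom skeleton branch count matches the analytic tree", {
  # noise-free, well-separated branches
  s <- generate_phantom(phantom_spec(noise_sd = 0, seed = 3))
  bs <- decompose_branches(skeletonize(s$mask))
  expect_equal(bs$n_branches, s$centerline_branches$n_branches)
})
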