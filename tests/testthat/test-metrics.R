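test_that("binarize applies the >= tie rule", {
  p <- array(c(0.9, 0.5, 0.499, 0.1), c(4, 1, 1))
  b <- binarize(p, 0.5)
  expect_equal(as.vector(as.array(b)), c(1L, 1L, 0L, 0L))
  expect_true(all(as.array(binarize(array(0.9, c(2, 2, 2)), 0.5)) == 1))
  expect_true(all(as.array(binarize(array(1e-6, c(2, 2, 2)), 0.5)) == 0))
  expect_error(binarize(p, 0))
})

test_that("tree length rate counts covered skeleton voxels", {
  st <- make_fixture("straight_tube")
  sk <- skeletonize(st$mask)
  expect_equal(tree_length_rate(sk, st$mask), 1)  # mask covers its skeleton
  empty <- binary_volume(array(0L, dim(sk)))
  expect_equal(tree_length_rate(sk, empty), 0)
  # partial coverage: drop 30% of the 20 skeleton voxels
  co <- which(as.array(sk) == 1, arr.ind = TRUE)
  pred <- as.array(sk)
  pred[co[1:6, , drop = FALSE]] <- 0L
  expect_equal(tree_length_rate(sk, binary_volume(pred, spacing(sk))),
               14 / 20)
  expect_error(tree_length_rate(binary_volume(array(0L, dim(sk))), st$mask),
               "empty skeleton")
})

test_that("strict branch detection floors partial coverage to zero", {
  # 3 hand-built branches of 10 voxels in a 12^3 grid
  grid <- c(12L, 12L, 12L)
  branches <- list(cbind(1:10, 2, 2), cbind(1:10, 6, 6), cbind(1:10, 10, 10))
  bs <- branch_set(branches)
  pred <- array(0L, grid)
  pred[branches[[1]]] <- 1L
  pred[branches[[2]]] <- 1L
  pred[branches[[3]][1:9, ]] <- 1L  # 9/10 voxels only
  predv <- binary_volume(pred)
  expect_equal(branch_detection_rate(bs, predv), 2 / 3)
  # the relaxed rule at 0.8 counts the 0.9-covered branch
  expect_equal(branch_detection_rate(bs, predv, coverage = 0.8), 1)
  # full and empty predictions
  full <- binary_volume(array(1L, grid))
  expect_equal(branch_detection_rate(bs, full), 1)
  expect_equal(branch_detection_rate(bs, binary_volume(array(0L, grid))), 0)
  # relaxing the rule can only increase the rate
  for (cv in c(0.9, 0.7, 0.5))
    expect_gte(branch_detection_rate(bs, predv, coverage = cv),
               branch_detection_rate(bs, predv))
})

test_that("voxel scores reproduce hand arithmetic", {
  mk <- function(v) binary_volume(array(as.integer(v), c(length(v), 1, 1)))
  # TP=8 FP=2 FN=2
  pred <- mk(c(rep(1, 10), rep(0, 10)))
  gt <- mk(c(rep(1, 8), 0, 0, 1, 1, rep(0, 8)))
  vs <- voxel_scores(pred, gt)
  expect_equal(vs[c("precision", "recall", "f_measure")],
               list(precision = 0.8, recall = 0.8, f_measure = 0.8))
  # TP=9 FP=1 FN=3
  pred2 <- mk(c(rep(1, 10), rep(0, 10)))
  gt2 <- mk(c(rep(1, 9), 0, 1, 1, 1, rep(0, 7)))
  vs2 <- voxel_scores(pred2, gt2)
  expect_equal(vs2$precision, 0.9)
  expect_equal(vs2$recall, 0.75)
  expect_equal(vs2$f_measure, 2 * 0.9 * 0.75 / 1.65)
  # identical nonempty volumes
  vs3 <- voxel_scores(gt, gt)
  expect_equal(vs3$precision, 1); expect_equal(vs3$recall, 1)
  expect_equal(vs3$f_measure, 1)
  # degenerate zero conventions
  z <- mk(rep(0, 20))
  vs4 <- voxel_scores(z, z)
  expect_equal(vs4$f_measure, 0)
})

test_that("vectorized metrics agree exactly with brute-force recounts", {
  set.seed(21)
  for (nm in c("straight_tube", "y_junction", "two_blobs")) {
    f <- make_fixture(nm)
    sk <- skeletonize(f$mask)
    bs <- decompose_branches(sk)
    # corrupt the mask into an imperfect prediction
    pred <- as.array(f$mask)
    drop <- which(pred == 1)
    pred[sample(drop, length(drop) %/% 5)] <- 0L
    add <- which(pred == 0)
    pred[sample(add, 30)] <- 1L
    predv <- binary_volume(pred)
    expect_identical(tree_length_rate(sk, predv),
                     bf_tree_length_rate(sk, predv))
    expect_identical(branch_detection_rate(bs, predv),
                     bf_branch_detection_rate(bs, predv))
    expect_identical(branch_detection_rate(bs, predv, 0.8),
                     bf_branch_detection_rate(bs, predv, 0.8))
    vs <- voxel_scores(predv, f$mask)
    expect_identical(vs, bf_voxel_scores(predv, f$mask))
  }
})

test_that("false positives never hurt TR/BD and never help precision", {
  f <- make_fixture("y_junction")
  sk <- skeletonize(f$mask)
  bs <- decompose_branches(sk)
  pred <- as.array(sk)  # prediction = skeleton only
  pred[1:3, 1:3, 1:3] <- 1L  # add false positives far from the tree
  predfp <- binary_volume(pred)
  predbase <- binary_volume(as.array(sk))
  expect_gte(tree_length_rate(sk, predfp), tree_length_rate(sk, predbase))
  expect_gte(branch_detection_rate(bs, predfp),
             branch_detection_rate(bs, predbase))
  expect_lt(voxel_scores(predfp, f$mask)$precision,
            voxel_scores(predbase, f$mask)$precision)
})

test_that("evaluate_segmentation composes the pieces consistently", {
  f <- make_fixture("y_junction")
  rep <- evaluate_segmentation(f$mask, f$mask)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$tr, 1)
  expect_equal(rep$bd, 1)
  expect_equal(rep$f_measure, 1)
  expect_equal(rep$n_branches, 3)
  # harmonic-mean invariant
  expect_equal(rep$f_measure,
               2 * rep$precision * rep$recall / (rep$precision + rep$recall))
})
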