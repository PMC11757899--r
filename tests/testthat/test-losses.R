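test_that("hand-evaluated loss values are reproduced", {
  # direct arithmetic: 1 - 1.6/2.2
  expect_equal(dice_loss(c(0.8, 0.4), c(1, 0)), 1 - 1.6 / 2.2,
               tolerance = 1e-12)
  # 1 - 0.8 / (0.1*1.2 + 0.9*1)
  expect_equal(tversky_loss(c(0.8, 0.4), c(1, 0), stl_params(0.1, 0.9)),
               1 - 0.8 / 1.02, tolerance = 1e-12)
  # 1 - sigmoid(3) / 1.02
  expect_equal(stl_loss(c(0.8, 0.4), c(1, 0), stl_params(0.1, 0.9, 10)),
               1 - plogis(3) / 1.02, tolerance = 1e-12)
})

test_that("identity and empty-foreground limits hold", {
  p <- c(1, 1, 0, 0); g <- c(1, 1, 0, 0)
  expect_equal(dice_loss(p, g), 0, tolerance = 1e-5)
  expect_equal(tversky_loss(p, g, stl_params(0.3, 0.7)), 0, tolerance = 1e-5)
  # prediction mass with empty ground truth: loss 1
  expect_equal(dice_loss(c(0.5, 0.9), c(0, 0)), 1, tolerance = 1e-12)
  # both empty: defined as 0 with a warning
  expect_warning(l0 <- dice_loss(c(1e-9, 1e-9), c(0, 0)), "empty")
  expect_equal(l0, 0)
})

test_that("Tversky at alpha = beta = 0.5 degenerates to Dice", {
  set.seed(1)
  for (k in 1:20) {
    p <- runif(64, 0.01, 0.99)
    g <- rbinom(64, 1, 0.3)
    expect_equal(tversky_loss(p, g, stl_params(0.5, 0.5)), dice_loss(p, g),
                 tolerance = 1e-12)
  }
})

test_that("STL at a perfect prediction equals 1 - sigmoid(gamma/2)", {
  g <- c(rep(1, 10), rep(0, 54))
  p <- g  # clamped internally to (0,1)
  expect_equal(stl_loss(p, g, stl_params(0.01, 0.99, 7)), 1 - plogis(3.5),
               tolerance = 1e-4)
  # sigma(0) = 0.5: numerator is half the foreground mass at p = 0.5
  p5 <- rep(0.5, 64)
  l <- stl_loss(p5, g, stl_params(0.01, 0.99, 7))
  denom <- 0.01 * sum(p5) + 0.99 * sum(g)
  expect_equal(l, 1 - 0.5 * sum(g) / denom, tolerance = 1e-12)
})

test_that("gradient-ratio closed forms match direct substitution", {
  expect_equal(gradient_ratio_dice(0), 1)
  expect_equal(gradient_ratio_dice(0.5), 3)
  expect_equal(gradient_ratio_tversky(0.5, 0.1), 19)
  expect_equal(gradient_ratio_tversky(0.3, 0.5), gradient_ratio_dice(0.3))
  # ratio grows linearly in gamma at p_f = 0.5
  r1 <- gradient_ratio_stl(0.2, 0.5, stl_params(0.1, 0.9, 10))
  r2 <- gradient_ratio_stl(0.2, 0.5, stl_params(0.1, 0.9, 20))
  expect_equal((r2 + 1) / (r1 + 1), 2, tolerance = 1e-12)
  # sigmoid' is maximal at 0: low-confidence voxels get the larger ratio
  rlo <- gradient_ratio_stl(0.2, 0.5, stl_params(0.1, 0.9, 10))
  rhi <- gradient_ratio_stl(0.2, 0.95, stl_params(0.1, 0.9, 10))
  expect_gt(rlo, rhi)
  expect_error(gradient_ratio_dice(1))
})

test_that("closed-form ratios match finite-difference ratios of the losses", {
  set.seed(7)
  stlp <- stl_params(0.01, 0.99, 7)
  tvp <- stl_params(0.1, 0.9)
  for (k in 1:25) {
    p <- array(runif(64, 0.05, 0.95), c(4, 4, 4))
    g <- array(0, c(4, 4, 4))
    g[sample(64, sample(5:20, 1))] <- 1
    ld <- dice_loss(p, g)
    expect_equal(gradient_ratio_dice(ld),
                 fd_gradient_ratio(function(q) dice_loss(q, g), p, g),
                 tolerance = 1e-5)
    lt <- tversky_loss(p, g, tvp)
    expect_equal(gradient_ratio_tversky(lt, tvp$alpha),
                 fd_gradient_ratio(function(q) tversky_loss(q, g, tvp), p, g),
                 tolerance = 1e-5)
    ls <- stl_loss(p, g, stlp)
    pf <- p[which(g == 1)[1]]
    expect_equal(gradient_ratio_stl(ls, pf, stlp),
                 fd_gradient_ratio(function(q) stl_loss(q, g, stlp), p, g),
                 tolerance = 1e-5)
  }
})

test_that("analytic loss gradients match finite differences", {
  set.seed(3)
  stlp <- stl_params(0.1, 0.9, 7)
  p <- runif(27, 0.05, 0.95)
  g <- rbinom(27, 1, 0.4)
  for (fgs in list(
    list(an = sgtube:::dice_loss_grad(p, g),
         f = function(q) dice_loss(q, g)),
    list(an = sgtube:::tversky_loss_grad(p, g, stlp),
         f = function(q) tversky_loss(q, g, stlp)),
    list(an = sgtube:::stl_loss_grad(p, g, stlp),
         f = function(q) stl_loss(q, g, stlp)))) {
    for (i in c(1, 5, 14, 27))
      expect_equal(fgs$an$grad[i], fd_grad(fgs$f, p, i), tolerance = 1e-6)
  }
})

test_that("the Dice gradient ratio increases with the loss", {
  ls <- seq(0, 0.95, by = 0.05)
  rs <- vapply(ls, gradient_ratio_dice, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("losses stay within [0, 1] and STL keeps its positive floor", {
  set.seed(11)
  stlp <- stl_params(0.01, 0.99, 7)
  for (k in 1:20) {
    p <- runif(100, 0.01, 0.99)
    g <- rbinom(100, 1, 0.2)
    if (sum(g) == 0) g[1] <- 1
    for (l in c(dice_loss(p, g), tversky_loss(p, g, stlp),
                stl_loss(p, g, stlp))) {
      expect_gte(l, 0); expect_lte(l, 1)
    }
  }
  expect_gt(stl_loss(c(1, 0), c(1, 0), stlp), 0)  # floor 1 - sigmoid(gamma/2)
})

test_that("the overall objective is additive in its two terms", {
  p <- c(0.8, 0.4); g <- c(1, 0)
  ph <- c(0.7, 0.2); gh <- c(1, 0)
  prm <- stl_params(0.1, 0.9, 10)
  expect_equal(overall_loss(p, g, ph, gh, prm, skel_weight = 0),
               dice_loss(p, g))
  expect_equal(overall_loss(p, g, ph, gh, prm, skel_weight = 1),
               dice_loss(p, g) + stl_loss(ph, gh, prm))
  expect_equal(overall_loss(p, g, ph, gh, prm, skel_weight = 0.25),
               dice_loss(p, g) + 0.25 * stl_loss(ph, gh, prm))
  # perfect predictions: only the STL floor remains
  expect_equal(overall_loss(c(1, 0), c(1, 0), c(1, 0), c(1, 0),
                            stl_params(0.01, 0.99, 7)),
               1 - plogis(3.5), tolerance = 1e-4)
})

test_that("loss curves are monotone and STL is steepest at p = 0.5", {
  tab <- loss_curve_table(grid = seq(0.05, 0.95, by = 0.01))
  expect_true(all(diff(tab$dice) <= 1e-12))
  expect_true(all(diff(tab$tversky) <= 1e-12))
  expect_true(all(diff(tab$stl) <= 1e-12))
  slope_at <- function(col, p0 = 0.5, h = 0.01) {
    f <- function(p) col[which.min(abs(tab$p - p))]
    (f(p0 + h) - f(p0 - h)) / (2 * h)
  }
  expect_gt(abs(slope_at(tab$stl)), abs(slope_at(tab$tversky)))
  expect_error(loss_curve_table(grid = numeric(0)))
})
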