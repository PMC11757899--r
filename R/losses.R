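#' Hyper-parameters of the Tversky / sigmoid-adaptive Tversky loss family
#'
#' `alpha` weights the predicted-foreground mass and `beta` the true-
#' foreground mass in the denominator (`alpha + beta = 1` is enforced);
#' lowering `alpha` below 0.5 boosts the gradient a sparse foreground
#' receives. `gamma` is the steepness of the sigmoid remapping used by the
#' sigmoid-adaptive Tversky loss: larger `gamma` concentrates gradient on
#' voxels whose predicted likelihood is near 0.5.
#'
#' @param alpha,beta floats in (0, 1) with `alpha + beta = 1`.
#' @param gamma positive float (only used by the sigmoid-adaptive loss).
#' @return An object of class `stl_params`.
#' @export
stl_params <- function(alpha = 0.01, beta = 0.99, gamma = 7) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1, gamma > 0)
  if (abs(alpha + beta - 1) > 1e-8)
    stop("stl_params: alpha + beta must equal 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "stl_params")
}

LIK_EPS <- 1e-6

# clamp likelihoods into [eps, 1-eps] and coerce inputs to plain arrays;
# sums are accumulated in double precision
prep_pg <- function(p, g) {
  p <- as.numeric(p)
  g <- as.numeric(g)
  if (length(p) != length(g))
    stop("prediction and ground truth have mismatched shapes")
  if (!all(g %in% c(0, 1))) stop("ground truth must be binary")
  p <- pmin(pmax(p, LIK_EPS), 1 - LIK_EPS)
  list(p = p, g = g)
}

# after clamping, an "empty" prediction is one with every voxel at the
# clamp floor
degenerate_zero <- function(p, sg, what) {
  if (sg == 0 && all(p <= LIK_EPS * 1.000001)) {
    warning(sprintf("%s: empty prediction and empty ground truth; ",
                    what), "returning 0 (perfect empty match)")
    return(TRUE)
  }
  FALSE
}

#' Dice, Tversky and sigmoid-adaptive Tversky losses
#'
#' For a likelihood map `p` and binary ground truth `g`:
#' * Dice loss: `1 - 2*sum(p*g) / (sum(p) + sum(g))`.
#' * Tversky loss: `1 - sum(p*g) / (alpha*sum(p) + beta*sum(g))`; at
#'   `alpha = beta = 0.5` it equals the Dice loss.
#' * Sigmoid-adaptive Tversky loss (STL): the numerator's `p` is remapped
#'   through `sigmoid(gamma * (p - 0.5))`, i.e.
#'   `1 - sum(sigmoid(gamma*(p - 0.5))*g) / (alpha*sum(p) + beta*sum(g))`.
#'   A perfect binary prediction gives `1 - sigmoid(gamma/2) > 0`, not 0:
#'   the loss trades its floor for much steeper gradients near `p = 0.5`.
#'
#' Likelihoods are clamped to `[1e-6, 1 - 1e-6]` before evaluation so the
#' gradient-ratio diagnostics stay finite. The degenerate pair with
#' `sum(p) = sum(g) = 0` returns 0 with a warning (a perfect empty match;
#' the quotient itself would be 0/0).
#'
#' @param p likelihood volume or numeric array in (0, 1).
#' @param g binary volume or 0/1 array of the same shape.
#' @param params an [stl_params()].
#' @return Scalar loss in `[0, 1]`.
#' @examples
#' dice_loss(c(0.8, 0.4), c(1, 0))          # 1 - 1.6/2.2
#' tversky_loss(c(0.8, 0.4), c(1, 0), stl_params(0.1, 0.9))
#' stl_loss(c(0.8, 0.4), c(1, 0), stl_params(0.1, 0.9, 10))
#' @export
dice_loss <- function(p, g) {
  d <- prep_pg(p, g)
  sp <- sum(d$p); sg <- sum(d$g)
  if (degenerate_zero(d$p, sg, "dice_loss")) return(0)
  1 - 2 * sum(d$p * d$g) / (sp + sg)
}

#' @rdname dice_loss
#' @export
tversky_loss <- function(p, g, params) {
  stopifnot(inherits(params, "stl_params"))
  d <- prep_pg(p, g)
  sp <- sum(d$p); sg <- sum(d$g)
  if (degenerate_zero(d$p, sg, "tversky_loss")) return(0)
  1 - sum(d$p * d$g) / (params$alpha * sp + params$beta * sg)
}

#' @rdname dice_loss
#' @export
stl_loss <- function(p, g, params) {
  stopifnot(inherits(params, "stl_params"))
  d <- prep_pg(p, g)
  sp <- sum(d$p); sg <- sum(d$g)
  if (degenerate_zero(d$p, sg, "stl_loss")) return(0)
  s <- plogis(params$gamma * (d$p - 0.5))
  1 - sum(s * d$g) / (params$alpha * sp + params$beta * sg)
}

#' Combined training objective of the dual-stream network
#'
#' The Dice loss on the tubular-structure prediction plus the
#' sigmoid-adaptive Tversky loss on the skeleton prediction,
#' `dice_loss(p, g) + skel_weight * stl_loss(p_skel, g_skel, params)`.
#' The default `skel_weight = 1` adds the two terms unweighted; the weight
#' is exposed because down-weighting the skeleton term is a natural lever
#' against false positives.
#'
#' @param p,g segmentation likelihood and binary ground truth.
#' @param p_skel,g_skel skeleton likelihood and binary skeleton ground truth.
#' @param params an [stl_params()].
#' @param skel_weight non-negative weight of the skeleton term.
#' @return Scalar loss.
#' @export
overall_loss <- function(p, g, p_skel, g_skel, params = stl_params(),
                         skel_weight = 1) {
  stopifnot(skel_weight >= 0)
  dice_loss(p, g) + skel_weight * stl_loss(p_skel, g_skel, params)
}

#' Closed-form gradient ratios of the loss family
#'
#' The gradient ratio is the magnitude of a foreground voxel's loss gradient
#' divided by a background voxel's. When it is small, the sparse foreground's
#' gradient is eroded by the surrounding background gradients and thin
#' structures stop improving. The closed forms are:
#' * Dice: `2 / (1 - L_D) - 1` — shared by every foreground/background pair,
#'   and shrinking as the loss improves (the erosion mechanism).
#' * Tversky: `(1/alpha) / (1 - L_T) - 1` — the floor is lifted by
#'   `1/alpha`, but uniformly for all voxels.
#' * Sigmoid-adaptive Tversky: for a foreground voxel with likelihood `p_f`,
#'   `gamma * s * (1 - s) / alpha / (1 - L_ST) - 1` with
#'   `s = sigmoid(gamma * (p_f - 0.5))` — voxel-wise adaptive, largest for
#'   low-confidence voxels (`p_f` near 0.5).
#'
#' @param loss the current scalar loss value (in `[0, 1)`).
#' @param alpha the Tversky/STL `alpha`.
#' @param p_f predicted likelihood of the foreground voxel in question.
#' @param params an [stl_params()].
#' @return Scalar gradient ratio.
#' @examples
#' gradient_ratio_dice(0.5)                      # 3
#' gradient_ratio_tversky(0.5, alpha = 0.1)      # 19
#' @export
gradient_ratio_dice <- function(loss) {
  stopifnot(loss >= 0, loss < 1)
  2 / (1 - loss) - 1
}

#' @rdname gradient_ratio_dice
#' @export
gradient_ratio_tversky <- function(loss, alpha) {
  stopifnot(loss >= 0, loss < 1, alpha > 0, alpha < 1)
  (1 / alpha) / (1 - loss) - 1
}

#' @rdname gradient_ratio_dice
#' @export
gradient_ratio_stl <- function(loss, p_f, params) {
  stopifnot(loss >= 0, loss < 1, p_f > 0, p_f < 1,
            inherits(params, "stl_params"))
  s <- plogis(params$gamma * (p_f - 0.5))
  params$gamma * s * (1 - s) / params$alpha / (1 - loss) - 1
}

# --- analytic gradients (used by the training loop) ---------------------

# d dice_loss / d p, elementwise
dice_loss_grad <- function(p, g) {
  d <- prep_pg(p, g)
  sp <- sum(d$p); sg <- sum(d$g)
  a <- sum(d$p * d$g); b <- sp + sg
  if (sg == 0 && all(d$p <= LIK_EPS * 1.000001))
    return(list(loss = 0, grad = 0 * d$p))
  grad <- (2 * a - 2 * d$g * b) / b^2
  list(loss = 1 - 2 * a / b, grad = grad)
}

tversky_loss_grad <- function(p, g, params) {
  d <- prep_pg(p, g)
  sp <- sum(d$p); sg <- sum(d$g)
  a <- sum(d$p * d$g)
  b <- params$alpha * sp + params$beta * sg
  if (sg == 0 && all(d$p <= LIK_EPS * 1.000001))
    return(list(loss = 0, grad = 0 * d$p))
  grad <- (a * params$alpha - d$g * b) / b^2
  list(loss = 1 - a / b, grad = grad)
}

stl_loss_grad <- function(p, g, params) {
  d <- prep_pg(p, g)
  sp <- sum(d$p); sg <- sum(d$g)
  s <- plogis(params$gamma * (d$p - 0.5))
  a <- sum(s * d$g)
  b <- params$alpha * sp + params$beta * sg
  if (sg == 0 && all(d$p <= LIK_EPS * 1.000001))
    return(list(loss = 0, grad = 0 * d$p))
  grad <- (a * params$alpha - d$g * params$gamma * s * (1 - s) * b) / b^2
  list(loss = 1 - a / b, grad = grad)
}

#' Loss curves in the single-foreground-voxel scenario
#'
#' Evaluates the three losses on a toy map holding one foreground voxel with
#' likelihood `p` (optionally plus `n_background` background voxels at a
#' fixed likelihood) across a grid of `p` values. This isolates how each
#' loss treats one hard foreground voxel: the sigmoid-adaptive loss falls
#' much more steeply around `p = 0.5` than the Dice or Tversky losses.
#'
#' @param grid probabilities in (0, 1) at which to evaluate.
#' @param params_tversky,params_stl loss hyper-parameters; the defaults
#'   (Tversky `alpha = 0.1, beta = 0.9`; STL additionally `gamma = 10`) are
#'   the settings used for this comparison.
#' @param n_background number of fixed background voxels in the toy map.
#' @param background_p their likelihood.
#' @return A data.frame with columns `p`, `dice`, `tversky`, `stl`.
#' @export
loss_curve_table <- function(grid = seq(0.02, 0.98, by = 0.02),
                             params_tversky = stl_params(0.1, 0.9),
                             params_stl = stl_params(0.1, 0.9, 10),
                             n_background = 0,
                             background_p = 0.1) {
  stopifnot(length(grid) > 0, all(grid > 0), all(grid < 1))
  one <- function(p) {
    pv <- c(p, rep(background_p, n_background))
    gv <- c(1, rep(0, n_background))
    c(dice = dice_loss(pv, gv),
      tversky = tversky_loss(pv, gv, params_tversky),
      stl = stl_loss(pv, gv, params_stl))
  }
  out <- t(vapply(grid, one, numeric(3)))
  data.frame(p = grid, out)
}
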