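test_that("forward pass honours the shape contract on both heads", {
  net <- build_network(network_spec(base_channels = 4, n_levels = 3,
                                    seed = 1))
  x <- array(runif(16^3), c(16, 16, 16))
  fw <- sgcnn_forward(net, x)
  expect_equal(dim(fw$p), c(16, 16, 16, 1))
  expect_equal(dim(fw$p_skel), c(16, 16, 16, 1))
  expect_true(all(fw$p > 0 & fw$p < 1))
  expect_true(all(fw$p_skel > 0 & fw$p_skel < 1))
  expect_error(sgcnn_forward(net, array(0, c(12, 12, 12))), "divisible")
})

test_that("weight initialization is seed-deterministic", {
  sp <- network_spec(base_channels = 2, n_levels = 2, seed = 9)
  expect_identical(build_network(sp)$params, build_network(sp)$params)
  sp2 <- network_spec(base_channels = 2, n_levels = 2, seed = 10)
  expect_false(identical(build_network(sp)$params, build_network(sp2)$params))
})

test_that("attention map is 0.5 under zero init and bounded in [0.5, 1)", {
  cs <- 3
  t_in <- array(rnorm(4^3 * cs), c(4, 4, 4, cs))
  f_in <- array(rnorm(4^3 * cs), c(4, 4, 4, cs))
  zw <- array(0, c(1, 1, 1, cs, 1)); zb <- 0
  A0 <- attention_map(t_in, f_in, zw, zb, zw, zb)
  expect_true(all(A0 == 0.5))
  expect_equal(dim(A0)[1:3], dim(t_in)[1:3])
  set.seed(2)
  for (k in 1:10) {
    wt <- array(rnorm(cs), c(1, 1, 1, cs, 1))
    wf <- array(rnorm(cs), c(1, 1, 1, cs, 1))
    A <- attention_map(t_in, f_in, wt, rnorm(1), wf, rnorm(1))
    expect_true(all(A >= 0.5))   # sigmoid of a ReLU output
    expect_true(all(A < 1))
  }
  expect_error(attention_map(t_in, array(0, c(2, 2, 2, cs)), zw, zb, zw, zb),
               "misaligned")
})

test_that("zero-init residual block is the identity; gated output is A * t", {
  cs <- 2
  x <- array(rnorm(4^3 * cs), c(4, 4, 4, cs))
  zw3 <- array(0, c(3, 3, 3, cs, cs)); zb <- numeric(cs)
  rb <- sgtube:::res_fwd(x, zw3, zb, zw3, zb)
  expect_identical(rb$out, sgtube:::relu_(x))  # skip path passes x through
  # zero-init attention halves the stream feature
  zw1 <- array(0, c(1, 1, 1, cs, 1))
  at <- sgtube:::att_fwd(x, x, zw1, 0, zw1, 0)
  expect_equal(at$out, 0.5 * x, tolerance = 1e-15)
})

test_that("analytic gradients match finite differences through both streams", {
  set.seed(5)
  net <- build_network(network_spec(base_channels = 2, n_levels = 2,
                                    seed = 3))
  x <- array(runif(8^3), c(8, 8, 8, 1))
  fw <- sgcnn_forward(net, x, want_cache = TRUE)
  wp <- array(rnorm(length(fw$p)), dim(fw$p))
  ws <- array(rnorm(length(fw$p_skel)), dim(fw$p_skel))
  lossfun <- function(params) {
    net2 <- net; net2$params <- params
    f <- sgcnn_forward(net2, x)
    sum(f$p * wp) + sum(f$p_skel * ws)
  }
  G <- sgcnn_backward(net, fw$cache, wp, ws)
  h <- 1e-5
  for (nm in names(net$params)) {
    w <- net$params[[nm]]
    for (i in sample(length(w), min(2, length(w)))) {
      pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (lossfun(pp) - lossfun(pm)) / (2 * h)
      expect_equal(G[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad of %s[%d]", nm, i))
    }
  }
  # both attention inputs receive gradient (the gate is trainable end to end)
  expect_gt(sum(abs(G$sg1_af_w)), 0)
  expect_gt(sum(abs(G$sg1_at_w)), 0)
})

test_that("disabling the skeleton stream leaves a working encoder-decoder", {
  sp <- network_spec(base_channels = 2, n_levels = 2, use_sg = FALSE,
                     seed = 4)
  net <- build_network(sp)
  expect_false(any(grepl("^sg", names(net$params))))
  x <- array(runif(8^3), c(8, 8, 8))
  fw <- sgcnn_forward(net, x, want_cache = TRUE)
  expect_null(fw$p_skel)
  expect_equal(dim(fw$p), c(8, 8, 8, 1))
  G <- sgcnn_backward(net, fw$cache, array(1, dim(fw$p)))
  expect_setequal(names(G), names(net$params))
})
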