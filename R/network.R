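#' Specification of the dual-stream skeleton-guided network
#'
#' The network has a main encoder--decoder segmentation stream (each encoder
#' level: two 3x3x3 convolutions + ReLU followed by 2x2x2 max pooling;
#' each decoder level: 2x2x2 transpose-convolution upsampling, concatenation
#' with the matching encoder feature map and — where present — the
#' skeleton-guided feature map, then two 3x3x3 convolutions) and an
#' auxiliary skeleton-guided stream of two skeleton-guided blocks attached
#' to the two deepest encoder outputs. Each skeleton-guided block is a
#' residual block followed by a skeleton-attention block; the attention map
#' `A = sigmoid(ReLU(conv1(t) + conv1(f)))` is computed from the stream's
#' own feature map `t` and the encoder feature map `f` and multiplies `t`.
#' Both streams end in a 1x1x1 convolution and a sigmoid, producing the
#' tubular-structure likelihood and the skeleton likelihood.
#'
#' Channel widths double per level from `base_channels` (the figure-level
#' architecture does not pin exact widths, so they are configuration).
#' Normalization layers are not part of the reference architecture and are
#' not used.
#'
#' @param in_channels input image channels (1 for grayscale volumes).
#' @param base_channels width of the first level; level `i` has
#'   `base_channels * 2^(i-1)` channels.
#' @param n_levels number of encoder levels (>= 2; 3 reproduces the
#'   reference architecture of three downsampling blocks).
#' @param use_sg logical; `FALSE` drops the skeleton-guided stream entirely
#'   (the "w/o SG" ablation arm), leaving a plain encoder--decoder.
#' @param head_bias initial bias of the two prediction heads. The default -2
#'   starts both likelihood maps near `sigmoid(-2) = 0.12`, matching the
#'   sparse foreground prior of tubular structures; a zero init makes the
#'   initial maps 0.5 everywhere, and the first phase of training is then
#'   spent pushing the vast background down.
#' @param seed integer seed for weight initialization.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(in_channels = 1, base_channels = 8, n_levels = 3,
                         use_sg = TRUE, head_bias = -2, seed = 1) {
  stopifnot(in_channels >= 1, base_channels >= 1, n_levels >= 2,
            is.finite(head_bias))
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 n_levels = as.integer(n_levels),
                 use_sg = isTRUE(use_sg),
                 sg_levels = if (use_sg) c(n_levels, n_levels - 1L)
                             else integer(),
                 head_bias = head_bias,
                 seed = as.integer(seed)),
            class = "network_spec")
}

# He-normal init for conv layers followed by ReLU; smaller gain for heads
init_conv <- function(k, cin, cout, gain = 2) {
  array(rnorm(k^3 * cin * cout, 0, sqrt(gain / (k^3 * cin))),
        c(k, k, k, cin, cout))
}

#' Build a skeleton-guided network
#'
#' Allocates and seeds all weights. Two builds from the same spec (same
#' seed) are identical; the global RNG state is left untouched.
#'
#' @param spec a [network_spec()].
#' @return An object of class `sg_cnn`: a list with `params` (flat named
#'   list of weight arrays) and `spec`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  withr::with_seed(spec$seed, build_network_impl(spec))
}

build_network_impl <- function(spec) {
  n <- spec$n_levels
  ch <- spec$base_channels * 2^(seq_len(n) - 1)
  chb <- spec$base_channels * 2^n
  p <- list()
  for (i in seq_len(n)) {
    cin <- if (i == 1) spec$in_channels else ch[i - 1]
    p[[paste0("enc", i, "_w1")]] <- init_conv(3, cin, ch[i])
    p[[paste0("enc", i, "_b1")]] <- numeric(ch[i])
    p[[paste0("enc", i, "_w2")]] <- init_conv(3, ch[i], ch[i])
    p[[paste0("enc", i, "_b2")]] <- numeric(ch[i])
  }
  p$bott_w1 <- init_conv(3, ch[n], chb); p$bott_b1 <- numeric(chb)
  p$bott_w2 <- init_conv(3, chb, chb);   p$bott_b2 <- numeric(chb)
  for (i in rev(seq_len(n))) {
    cin_up <- if (i == n) chb else ch[i + 1]
    p[[paste0("up", i, "_w")]] <- init_conv(2, cin_up, ch[i], gain = 1)
    p[[paste0("up", i, "_b")]] <- numeric(ch[i])
    ccat <- 2 * ch[i] +
      if (spec$use_sg && i %in% spec$sg_levels) ch[i] else 0
    p[[paste0("dec", i, "_w1")]] <- init_conv(3, ccat, ch[i])
    p[[paste0("dec", i, "_b1")]] <- numeric(ch[i])
    p[[paste0("dec", i, "_w2")]] <- init_conv(3, ch[i], ch[i])
    p[[paste0("dec", i, "_b2")]] <- numeric(ch[i])
  }
  p$seghead_w <- init_conv(1, ch[1], 1, gain = 1)
  p$seghead_b <- spec$head_bias
  if (spec$use_sg) {
    for (j in 1:2) {
      cs <- ch[n - j + 1]  # block 1 at the deepest level, block 2 one above
      p[[paste0("sg", j, "_rw1")]] <- init_conv(3, cs, cs)
      p[[paste0("sg", j, "_rb1")]] <- numeric(cs)
      p[[paste0("sg", j, "_rw2")]] <- init_conv(3, cs, cs)
      p[[paste0("sg", j, "_rb2")]] <- numeric(cs)
      p[[paste0("sg", j, "_at_w")]] <- init_conv(1, cs, 1, gain = 1)
      p[[paste0("sg", j, "_at_b")]] <- numeric(1)
      p[[paste0("sg", j, "_af_w")]] <- init_conv(1, cs, 1, gain = 1)
      p[[paste0("sg", j, "_af_b")]] <- numeric(1)
    }
    p$sgup1_w <- init_conv(2, ch[n], ch[n - 1], gain = 1)
    p$sgup1_b <- numeric(ch[n - 1])
    if (n >= 3) {
      for (j in seq(n - 2, 1)) {
        p[[paste0("sgup0_", j, "_w")]] <- init_conv(2, ch[j + 1], ch[j],
                                                    gain = 1)
        p[[paste0("sgup0_", j, "_b")]] <- numeric(ch[j])
      }
    }
    p$skelhead_w <- init_conv(1, ch[1], 1, gain = 1)
    p$skelhead_b <- spec$head_bias
  }
  structure(list(params = p, spec = spec), class = "sg_cnn")
}

#' @export
print.sg_cnn <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(paste0("<sg_cnn> %d levels, base width %d, ",
                     "skeleton stream: %s\n  %d tensors, %s parameters\n"),
              x$spec$n_levels, x$spec$base_channels,
              if (x$spec$use_sg) "yes" else "no",
              length(x$params), format(np, big.mark = ",")))
  invisible(x)
}

# ---- layer primitives with explicit caches -----------------------------

relu_ <- function(x) pmax(x, 0)
sigmoid_ <- function(x) 1 / (1 + exp(-x))

# conv3 + ReLU, twice
cb_fwd <- function(x, w1, b1, w2, b2) {
  a1 <- cpp_conv3d_fwd(x, w1, b1, 1L); r1 <- relu_(a1)
  a2 <- cpp_conv3d_fwd(r1, w2, b2, 1L); r2 <- relu_(a2)
  list(out = r2, x = x, a1 = a1, r1 = r1, a2 = a2)
}
cb_bwd <- function(cache, w1, w2, g) {
  g2 <- g * (cache$a2 > 0)
  b2 <- cpp_conv3d_bwd(cache$r1, w2, g2, 1L)
  g1 <- b2$gx * (cache$a1 > 0)
  b1 <- cpp_conv3d_bwd(cache$x, w1, g1, 1L)
  list(gx = b1$gx, gw1 = b1$gw, gb1 = b1$gb, gw2 = b2$gw, gb2 = b2$gb)
}

# residual block: two conv3 with identity skip, ReLU on the sum
res_fwd <- function(x, w1, b1, w2, b2) {
  a1 <- cpp_conv3d_fwd(x, w1, b1, 1L); r1 <- relu_(a1)
  a2 <- cpp_conv3d_fwd(r1, w2, b2, 1L)
  pre <- a2 + x
  list(out = relu_(pre), x = x, a1 = a1, r1 = r1, pre = pre)
}
res_bwd <- function(cache, w1, w2, g) {
  g0 <- g * (cache$pre > 0)
  b2 <- cpp_conv3d_bwd(cache$r1, w2, g0, 1L)
  g1 <- b2$gx * (cache$a1 > 0)
  b1 <- cpp_conv3d_bwd(cache$x, w1, g1, 1L)
  list(gx = b1$gx + g0, gw1 = b1$gw, gb1 = b1$gb, gw2 = b2$gw, gb2 = b2$gb)
}

#' Skeleton-attention map
#'
#' `A = sigmoid(ReLU(conv1(t_in) + conv1(f_in)))` with single-channel 1x1x1
#' convolutions. Because the ReLU output is non-negative, every element of
#' `A` lies in `[0.5, 1)`; with zero-initialized convolutions `A` is exactly
#' 0.5 everywhere.
#'
#' @param t_in skeleton-stream feature map `(D, H, W, C)`.
#' @param f_in encoder feature map of the same shape.
#' @param wt,bt,wf,bf the two 1x1x1 convolution weights/biases.
#' @return The attention map, shape `(D, H, W, 1)`.
#' @export
attention_map <- function(t_in, f_in, wt, bt, wf, bf) {
  if (!identical(dim(t_in)[1:3], dim(f_in)[1:3]))
    stop("attention_map: spatially misaligned inputs")
  s <- cpp_conv3d_fwd(t_in, wt, bt, 0L) + cpp_conv3d_fwd(f_in, wf, bf, 0L)
  sigmoid_(relu_(s))
}

att_fwd <- function(t, f, wt, bt, wf, bf) {
  s <- cpp_conv3d_fwd(t, wt, bt, 0L) + cpp_conv3d_fwd(f, wf, bf, 0L)
  r <- relu_(s)
  A <- sigmoid_(r)
  out <- t * as.vector(A)  # channel-last layout broadcasts A over channels
  list(out = out, t = t, f = f, s = s, A = A)
}
att_bwd <- function(cache, wt, wf, g) {
  dm <- dim(cache$t)
  nsp <- prod(dm[1:3])
  gt_direct <- g * as.vector(cache$A)
  gA <- array(rowSums(matrix(g * cache$t, nsp, dm[4])), c(dm[1:3], 1))
  gs <- gA * cache$A * (1 - cache$A) * (cache$s > 0)
  bt <- cpp_conv3d_bwd(cache$t, wt, gs, 0L)
  bf <- cpp_conv3d_bwd(cache$f, wf, gs, 0L)
  list(gt = gt_direct + bt$gx, gf = bf$gx,
       gwt = bt$gw, gbt = bt$gb, gwf = bf$gw, gbf = bf$gb)
}

cat_channels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])[1:3]
  array(unlist(xs, use.names = FALSE),
        c(d, sum(vapply(xs, function(x) dim(x)[4], numeric(1)))))
}
slice_channels <- function(g, from, to) {
  g[, , , from:to, drop = FALSE]
}

# ---- full forward / backward -------------------------------------------

#' Forward pass of the skeleton-guided network
#'
#' @param net an `sg_cnn` from [build_network()].
#' @param x input array `(D, H, W, C)` (a bare 3D array is promoted to one
#'   channel); spatial dims must be divisible by `2^n_levels`.
#' @param want_cache keep all intermediates for a backward pass.
#' @return A list with `p` (segmentation likelihood, `(D,H,W,1)`), `p_skel`
#'   (skeleton likelihood, or `NULL` without the skeleton stream) and,
#'   if requested, `cache`.
#' @export
sgcnn_forward <- function(net, x, want_cache = FALSE) {
  spec <- net$spec; p <- net$params; n <- spec$n_levels
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  if (any(dim(x)[1:3] %% 2^n != 0))
    stop(sprintf("input spatial dims must be divisible by %d", 2^n))
  storage.mode(x) <- "double"
  K <- list()  # cache
  e <- vector("list", n); pools <- vector("list", n)
  cur <- x
  for (i in seq_len(n)) {
    cb <- cb_fwd(cur, p[[paste0("enc", i, "_w1")]], p[[paste0("enc", i, "_b1")]],
                 p[[paste0("enc", i, "_w2")]], p[[paste0("enc", i, "_b2")]])
    e[[i]] <- cb$out
    K[[paste0("enc", i)]] <- cb
    mp <- cpp_maxpool3d_fwd(cb$out)
    pools[[i]] <- mp
    cur <- mp$y
  }
  bott <- cb_fwd(cur, p$bott_w1, p$bott_b1, p$bott_w2, p$bott_b2)
  K$bott <- bott

  s_feat <- list()  # skeleton-guided features by encoder level
  p_skel <- NULL
  if (spec$use_sg) {
    r1 <- res_fwd(e[[n]], p$sg1_rw1, p$sg1_rb1, p$sg1_rw2, p$sg1_rb2)
    a1 <- att_fwd(r1$out, e[[n]], p$sg1_at_w, p$sg1_at_b,
                  p$sg1_af_w, p$sg1_af_b)
    u1 <- cpp_upconv3d_fwd(a1$out, p$sgup1_w, p$sgup1_b)
    r2 <- res_fwd(u1, p$sg2_rw1, p$sg2_rb1, p$sg2_rw2, p$sg2_rb2)
    a2 <- att_fwd(r2$out, e[[n - 1]], p$sg2_at_w, p$sg2_at_b,
                  p$sg2_af_w, p$sg2_af_b)
    s_feat[[n]] <- a1$out
    s_feat[[n - 1]] <- a2$out
    h <- a2$out
    hs <- list()
    if (n >= 3) for (j in seq(n - 2, 1)) {
      hs[[paste0("x", j)]] <- h
      h <- cpp_upconv3d_fwd(h, p[[paste0("sgup0_", j, "_w")]],
                            p[[paste0("sgup0_", j, "_b")]])
    }
    skel_pre <- cpp_conv3d_fwd(h, p$skelhead_w, p$skelhead_b, 0L)
    p_skel <- sigmoid_(skel_pre)
    K$sg <- list(r1 = r1, a1 = a1, u1 = u1, r2 = r2, a2 = a2,
                 hs = hs, h = h, p_skel = p_skel)
  }

  d <- bott$out
  for (i in rev(seq_len(n))) {
    u <- cpp_upconv3d_fwd(d, p[[paste0("up", i, "_w")]],
                          p[[paste0("up", i, "_b")]])
    parts <- list(u, e[[i]])
    if (spec$use_sg && i %in% spec$sg_levels)
      parts <- c(parts, list(s_feat[[i]]))
    ct <- do.call(cat_channels, parts)
    cb <- cb_fwd(ct, p[[paste0("dec", i, "_w1")]], p[[paste0("dec", i, "_b1")]],
                 p[[paste0("dec", i, "_w2")]], p[[paste0("dec", i, "_b2")]])
    K[[paste0("dec", i)]] <- list(cb = cb, up_in = d,
                                  widths = vapply(parts, function(x) dim(x)[4],
                                                  numeric(1)))
    d <- cb$out
  }
  seg_pre <- cpp_conv3d_fwd(d, p$seghead_w, p$seghead_b, 0L)
  pmap <- sigmoid_(seg_pre)
  K$e <- e; K$pools <- pools; K$x <- x; K$p <- pmap; K$dtop <- d

  out <- list(p = pmap, p_skel = p_skel)
  if (want_cache) out$cache <- K
  out
}

#' Backward pass of the skeleton-guided network
#'
#' Given gradients of a scalar loss with respect to the two likelihood
#' outputs, returns gradients with respect to every weight tensor (same
#' names as `net$params`). The sigmoid heads are differentiated internally.
#'
#' @param net an `sg_cnn`.
#' @param cache the cache from `sgcnn_forward(..., want_cache = TRUE)`.
#' @param gp gradient w.r.t. the segmentation likelihood `p`.
#' @param gp_skel gradient w.r.t. the skeleton likelihood (ignored without
#'   the skeleton stream).
#' @return Named list of gradient arrays.
#' @export
sgcnn_backward <- function(net, cache, gp, gp_skel = NULL) {
  spec <- net$spec; p <- net$params; n <- spec$n_levels
  G <- list()
  ge <- vector("list", n)  # accumulated grads w.r.t. encoder outputs
  gs_dec <- list()         # grads w.r.t. skeleton features from the decoder

  # seg head
  gpre <- gp * cache$p * (1 - cache$p)
  bh <- cpp_conv3d_bwd(cache$dtop, p$seghead_w, gpre, 0L)
  G$seghead_w <- bh$gw; G$seghead_b <- bh$gb
  gd <- bh$gx

  # decoder, shallow to deep
  for (i in seq_len(n)) {
    dc <- cache[[paste0("dec", i)]]
    bb <- cb_bwd(dc$cb, p[[paste0("dec", i, "_w1")]],
                 p[[paste0("dec", i, "_w2")]], gd)
    G[[paste0("dec", i, "_w1")]] <- bb$gw1; G[[paste0("dec", i, "_b1")]] <- bb$gb1
    G[[paste0("dec", i, "_w2")]] <- bb$gw2; G[[paste0("dec", i, "_b2")]] <- bb$gb2
    w <- dc$widths
    gu <- slice_channels(bb$gx, 1, w[1])
    gei <- slice_channels(bb$gx, w[1] + 1, w[1] + w[2])
    ge[[i]] <- if (is.null(ge[[i]])) gei else ge[[i]] + gei
    if (length(w) == 3)
      gs_dec[[as.character(i)]] <- slice_channels(bb$gx, w[1] + w[2] + 1,
                                                  sum(w))
    bu <- cpp_upconv3d_bwd(dc$up_in, p[[paste0("up", i, "_w")]], gu)
    G[[paste0("up", i, "_w")]] <- bu$gw; G[[paste0("up", i, "_b")]] <- bu$gb
    gd <- bu$gx  # grad w.r.t. the block below's output
  }
  g_bott <- gd

  # skeleton stream
  if (spec$use_sg) {
    sg <- cache$sg
    gh <- NULL
    if (!is.null(gp_skel)) {
      gpre_s <- gp_skel * sg$p_skel * (1 - sg$p_skel)
      bsh <- cpp_conv3d_bwd(sg$h, p$skelhead_w, gpre_s, 0L)
      G$skelhead_w <- bsh$gw; G$skelhead_b <- bsh$gb
      gh <- bsh$gx
      if (n >= 3) for (j in seq(1, n - 2)) {
        xin <- sg$hs[[paste0("x", j)]]
        bup <- cpp_upconv3d_bwd(xin, p[[paste0("sgup0_", j, "_w")]], gh)
        G[[paste0("sgup0_", j, "_w")]] <- bup$gw
        G[[paste0("sgup0_", j, "_b")]] <- bup$gb
        gh <- bup$gx
      }
    } else {
      G$skelhead_w <- 0 * p$skelhead_w; G$skelhead_b <- 0 * p$skelhead_b
      if (n >= 3) for (j in seq(1, n - 2)) {
        G[[paste0("sgup0_", j, "_w")]] <- 0 * p[[paste0("sgup0_", j, "_w")]]
        G[[paste0("sgup0_", j, "_b")]] <- 0 * p[[paste0("sgup0_", j, "_b")]]
      }
      gh <- 0 * sg$a2$out
    }
    gs2 <- gh
    if (!is.null(gs_dec[[as.character(n - 1)]]))
      gs2 <- gs2 + gs_dec[[as.character(n - 1)]]
    ba2 <- att_bwd(sg$a2, p$sg2_at_w, p$sg2_af_w, gs2)
    G$sg2_at_w <- ba2$gwt; G$sg2_at_b <- ba2$gbt
    G$sg2_af_w <- ba2$gwf; G$sg2_af_b <- ba2$gbf
    ge[[n - 1]] <- ge[[n - 1]] + ba2$gf
    br2 <- res_bwd(sg$r2, p$sg2_rw1, p$sg2_rw2, ba2$gt)
    G$sg2_rw1 <- br2$gw1; G$sg2_rb1 <- br2$gb1
    G$sg2_rw2 <- br2$gw2; G$sg2_rb2 <- br2$gb2
    bup1 <- cpp_upconv3d_bwd(sg$a1$out, p$sgup1_w, br2$gx)
    G$sgup1_w <- bup1$gw; G$sgup1_b <- bup1$gb
    gs1 <- bup1$gx
    if (!is.null(gs_dec[[as.character(n)]]))
      gs1 <- gs1 + gs_dec[[as.character(n)]]
    ba1 <- att_bwd(sg$a1, p$sg1_at_w, p$sg1_af_w, gs1)
    G$sg1_at_w <- ba1$gwt; G$sg1_at_b <- ba1$gbt
    G$sg1_af_w <- ba1$gwf; G$sg1_af_b <- ba1$gbf
    ge[[n]] <- ge[[n]] + ba1$gf
    br1 <- res_bwd(sg$r1, p$sg1_rw1, p$sg1_rw2, ba1$gt)
    G$sg1_rw1 <- br1$gw1; G$sg1_rb1 <- br1$gb1
    G$sg1_rw2 <- br1$gw2; G$sg1_rb2 <- br1$gb2
    ge[[n]] <- ge[[n]] + br1$gx
  }

  # bottleneck and encoder, deep to shallow
  bb <- cb_bwd(cache$bott, p$bott_w1, p$bott_w2, g_bott)
  G$bott_w1 <- bb$gw1; G$bott_b1 <- bb$gb1
  G$bott_w2 <- bb$gw2; G$bott_b2 <- bb$gb2
  gpool <- bb$gx
  for (i in rev(seq_len(n))) {
    gei <- cpp_maxpool3d_bwd(gpool, cache$pools[[i]]$idx,
                             dim(cache$e[[i]]))
    gei <- gei + ge[[i]]
    be <- cb_bwd(cache[[paste0("enc", i)]], p[[paste0("enc", i, "_w1")]],
                 p[[paste0("enc", i, "_w2")]], gei)
    G[[paste0("enc", i, "_w1")]] <- be$gw1; G[[paste0("enc", i, "_b1")]] <- be$gb1
    G[[paste0("enc", i, "_w2")]] <- be$gw2; G[[paste0("enc", i, "_b2")]] <- be$gb2
    gpool <- be$gx
  }
  G
}
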