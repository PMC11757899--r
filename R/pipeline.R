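#' Training configuration
#'
#' Defaults follow the reference training recipe for full-scale CT data:
#' SGD at initial learning rate 5e-4 with a decay factor of 0.5 every 20
#' epochs, 90 epochs total, patches of 128 x 128 x 64 voxels (given here in
#' `(z, y, x)` order), and skeleton-loss hyper-parameters
#' `alpha = 0.01, beta = 0.99, gamma = 7`. No data augmentation is applied.
#' Desk-scale experiments on phantoms override the patch size, epoch count
#' and learning rate (see [phantom_experiment()]).
#'
#' @param lr0 initial learning rate.
#' @param decay_factor,decay_every stepped learning-rate schedule:
#'   `lr = lr0 * decay_factor^floor(epoch / decay_every)`.
#' @param epochs number of epochs.
#' @param optimizer `"sgd"` (momentum SGD, the reference recipe) or
#'   `"adam"` (per-parameter adaptive steps; far more sample-efficient on
#'   the short desk-scale schedules, where only a few hundred updates are
#'   available).
#' @param momentum,weight_decay SGD momentum and L2 weight decay.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and epsilon;
#'   the default `adam_beta2 = 0.99` (rather than 0.999) keeps the
#'   second-moment estimate responsive, which avoids the
#'   collapse-to-background failure mode of Dice training on very
#'   imbalanced volumes.
#' @param grad_clip gradient clipping threshold (`Inf` = off).
#' @param clip_mode `"global"` rescales the whole gradient by its global
#'   norm; `"tensor"` clips each weight tensor's norm separately, which
#'   stops the large encoder/decoder tensors from starving the small
#'   prediction-head tensors of step size.
#' @param patch_size patch voxels `(D, H, W)`; must be divisible by
#'   `2^n_levels` of the network.
#' @param alpha,beta,gamma skeleton-loss hyper-parameters (see
#'   [stl_params()]).
#' @param skel_loss which loss supervises the skeleton stream: `"stl"`
#'   (default), `"tversky"` or `"dice"` (the ablation arms).
#' @param skel_weight weight of the skeleton term in the overall loss.
#' @param patches_per_case patches sampled per case per epoch.
#' @param fg_bias fraction of patches centred on a random foreground voxel
#'   (the rest have uniform origins); guarantees at least this share of
#'   patches contain mask foreground.
#' @param seed master seed; fans out to patch sampling and weight updates.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr0 = 5e-4, decay_factor = 0.5, decay_every = 20,
                         epochs = 90, optimizer = c("sgd", "adam"),
                         momentum = 0.9, weight_decay = 0,
                         adam_beta1 = 0.9, adam_beta2 = 0.99,
                         adam_eps = 1e-8, grad_clip = Inf,
                         clip_mode = c("global", "tensor"),
                         patch_size = c(64, 128, 128),
                         alpha = 0.01, beta = 0.99, gamma = 7,
                         skel_loss = c("stl", "tversky", "dice"),
                         skel_weight = 1, patches_per_case = 8,
                         fg_bias = 0.5, seed = 1) {
  skel_loss <- match.arg(skel_loss)
  optimizer <- match.arg(optimizer)
  clip_mode <- match.arg(clip_mode)
  stopifnot(lr0 > 0, epochs >= 1, decay_every >= 1, momentum >= 0,
            weight_decay >= 0, length(patch_size) == 3,
            all(patch_size >= 4), skel_weight >= 0, patches_per_case >= 1,
            fg_bias >= 0, fg_bias <= 1, grad_clip > 0,
            adam_beta1 >= 0, adam_beta1 < 1, adam_beta2 >= 0,
            adam_beta2 < 1, adam_eps > 0)
  structure(list(lr0 = lr0, decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 momentum = momentum, weight_decay = weight_decay,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, grad_clip = grad_clip,
                 clip_mode = clip_mode,
                 patch_size = as.integer(patch_size),
                 stl = stl_params(alpha, beta, gamma),
                 skel_loss = skel_loss, skel_weight = skel_weight,
                 patches_per_case = as.integer(patches_per_case),
                 fg_bias = fg_bias, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `lr0 * decay_factor^floor(epoch / decay_every)`; with the defaults the
#' rate halves after every 20 epochs (epoch 40 runs at `lr0 / 4`).
#'
#' @param config a [train_config()].
#' @param epoch epoch number (1-based).
#' @return Scalar learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr0 * config$decay_factor^(epoch %/% config$decay_every)
}

#' Min--max normalize an image volume to [0, 1]
#'
#' Per-case min--max scaling; a constant image maps to all zeros.
#'
#' @param image a [voxel_grid()] or numeric array with finite values.
#' @return A [voxel_grid()] with values in `[0, 1]`.
#' @export
normalize_volume <- function(image) {
  vals <- as.array(image)
  if (any(!is.finite(vals))) stop("normalize_volume: non-finite voxels")
  lo <- min(vals); hi <- max(vals)
  out <- if (hi - lo < 1e-12) array(0, dim(vals)) else (vals - lo) / (hi - lo)
  voxel_grid(out, spacing(image))
}

#' Prepare a training/evaluation case
#'
#' Normalizes the image and computes (once per case) the skeleton ground
#' truth of the mask and its branch decomposition; patches later crop from
#' the cached full-volume skeleton rather than re-thinning per patch, which
#' would change the supervision stochastically. With `cache_dir` set, the
#' skeleton is written as NIfTI on first call and re-read (byte-identical)
#' afterwards.
#'
#' @param image image volume.
#' @param mask binary ground-truth mask on the same grid.
#' @param id case identifier.
#' @param cache_dir optional directory for the cached skeleton.
#' @return An object of class `case_record`: a list with `id`, `image`
#'   (normalized), `mask`, `skeleton`, `branches`.
#' @export
prepare_case <- function(image, mask, id = "case", cache_dir = NULL) {
  check_same_geometry(as.array(image), as.array(mask), "image and mask")
  if (sum(mask) == 0)
    warning("prepare_case: empty mask for case ", id)
  skel <- NULL
  if (!is.null(cache_dir)) {
    if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
    cpath <- file.path(cache_dir, paste0(id, "_skeleton.nii.gz"))
    if (file.exists(cpath)) skel <- read_volume(cpath, "skeleton")
  }
  if (is.null(skel)) {
    skel <- skeletonize(mask)
    if (!is.null(cache_dir)) write_volume(skel, cpath)
  }
  structure(list(id = id, image = normalize_volume(image),
                 mask = mask, skeleton = skel,
                 branches = decompose_branches(skel)),
            class = "case_record")
}

# crop a window from a volume (plain array out)
crop3 <- function(vol, origin, size) {
  as.array(vol)[origin[1]:(origin[1] + size[1] - 1),
                origin[2]:(origin[2] + size[2] - 1),
                origin[3]:(origin[3] + size[3] - 1), drop = FALSE]
}

#' Sample aligned training patches from a case
#'
#' Draws `n` patch origins (all three channels crop the same window). With
#' probability `fg_bias` the patch is centred on a uniformly chosen mask
#' foreground voxel (clamped to the volume); otherwise the origin is
#' uniform. Sampling uses the supplied seed and leaves global RNG state
#' untouched; a fixed seed yields an identical patch sequence.
#'
#' @param case a [prepare_case()] record.
#' @param config a [train_config()] (patch size and foreground bias).
#' @param n number of patches.
#' @param seed RNG seed for this draw.
#' @return List of `n` lists with elements `image`, `mask`, `skeleton`
#'   (arrays of `patch_size`) and `origin`.
#' @export
sample_patches <- function(case, config, n = config$patches_per_case,
                           seed = config$seed) {
  withr::with_seed(seed, sample_patches_impl(case, config, n))
}

sample_patches_impl <- function(case, config, n) {
  dmv <- dim(as.array(case$mask))
  ps <- config$patch_size
  if (any(ps > dmv))
    stop(sprintf("patch (%s) larger than volume (%s)",
                 paste(ps, collapse = "x"), paste(dmv, collapse = "x")))
  fg <- which(as.array(case$mask) == 1L, arr.ind = TRUE)
  lapply(seq_len(n), function(k) {
    if (nrow(fg) > 0 && runif(1) < config$fg_bias) {
      ctr <- fg[sample.int(nrow(fg), 1), ]
      origin <- pmin(pmax(ctr - ps %/% 2, 1), dmv - ps + 1)
    } else {
      origin <- c(sample.int(dmv[1] - ps[1] + 1, 1),
                  sample.int(dmv[2] - ps[2] + 1, 1),
                  sample.int(dmv[3] - ps[3] + 1, 1))
    }
    list(image = crop3(case$image, origin, ps),
         mask = crop3(case$mask, origin, ps),
         skeleton = crop3(case$skeleton, origin, ps),
         origin = as.integer(origin))
  })
}

skel_loss_grad <- function(p, g, config) {
  switch(config$skel_loss,
         stl = stl_loss_grad(p, g, config$stl),
         tversky = tversky_loss_grad(p, g, config$stl),
         dice = dice_loss_grad(p, g))
}

#' Train the skeleton-guided network
#'
#' Patch-based SGD on the combined objective: Dice loss on the main
#' segmentation output plus (when the skeleton stream is enabled) the
#' configured skeleton loss on the skeleton output, weighted by
#' `skel_weight`. The learning rate follows the stepped schedule of
#' [lr_at_epoch()]. One master seed drives patch sampling; weight
#' initialization is governed by the network spec's own seed. A non-finite
#' loss aborts with a diagnostic.
#'
#' @param cases list of [prepare_case()] records.
#' @param config a [train_config()].
#' @param net_spec a [network_spec()]; `use_sg = FALSE` trains the plain
#'   encoder--decoder with Dice loss only (the "w/o SG" arm).
#' @param net optionally, an already-built `sg_cnn` to continue training.
#' @param verbose print one line per epoch.
#' @return An object of class `sg_checkpoint`: list with `params`,
#'   `net_spec`, `config`, `seed` and `log` (a data.frame with per-epoch
#'   mean total/segmentation/skeleton losses and the learning rate).
#' @export
train_sgcnn <- function(cases, config, net_spec, net = NULL,
                        verbose = FALSE) {
  stopifnot(length(cases) >= 1, inherits(config, "train_config"),
            inherits(net_spec, "network_spec"))
  if (any(config$patch_size %% 2^net_spec$n_levels != 0))
    stop("patch_size must be divisible by 2^n_levels")
  if (is.null(net)) net <- build_network(net_spec)
  params <- net$params
  vel <- lapply(params, function(w) 0 * w)   # SGD velocity / Adam 1st moment
  sec <- lapply(params, function(w) 0 * w)   # Adam 2nd moment
  step <- 0L
  log <- vector("list", config$epochs)

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config, epoch)
      ep_tot <- ep_seg <- ep_skel <- numeric(0)
      for (case in cases) {
        patches <- sample_patches_impl(case, config, config$patches_per_case)
        for (pt in patches) {
          fw <- sgcnn_forward(net, pt$image, want_cache = TRUE)
          dl <- dice_loss_grad(fw$p, pt$mask)
          gp <- array(dl$grad, dim(fw$p))
          l_skel <- 0; gps <- NULL
          if (net_spec$use_sg) {
            sl <- skel_loss_grad(fw$p_skel, pt$skeleton, config)
            l_skel <- sl$loss
            gps <- array(config$skel_weight * sl$grad, dim(fw$p_skel))
          }
          l_tot <- dl$loss + config$skel_weight * l_skel
          if (!is.finite(l_tot))
            stop(sprintf("training diverged (non-finite loss) at epoch %d",
                         epoch))
          G <- sgcnn_backward(net, fw$cache, gp, gps)
          if (is.finite(config$grad_clip)) {
            if (config$clip_mode == "global") {
              gn <- sqrt(sum(vapply(G, function(g) sum(g^2), numeric(1))))
              if (gn > config$grad_clip)
                G <- lapply(G, function(g) g * (config$grad_clip / gn))
            } else {
              G <- lapply(G, function(g) {
                gn <- sqrt(sum(g^2))
                if (gn > config$grad_clip) g * (config$grad_clip / gn) else g
              })
            }
          }
          step <- step + 1L
          for (nm in names(params)) {
            g <- G[[nm]]
            if (config$weight_decay > 0) g <- g + config$weight_decay *
                params[[nm]]
            if (config$optimizer == "sgd") {
              vel[[nm]] <- config$momentum * vel[[nm]] - lr * g
              params[[nm]] <- params[[nm]] + vel[[nm]]
            } else {
              vel[[nm]] <- config$adam_beta1 * vel[[nm]] +
                (1 - config$adam_beta1) * g
              sec[[nm]] <- config$adam_beta2 * sec[[nm]] +
                (1 - config$adam_beta2) * g^2
              mh <- vel[[nm]] / (1 - config$adam_beta1^step)
              vh <- sec[[nm]] / (1 - config$adam_beta2^step)
              params[[nm]] <- params[[nm]] -
                lr * mh / (sqrt(vh) + config$adam_eps)
            }
          }
          net$params <- params
          ep_tot <- c(ep_tot, l_tot); ep_seg <- c(ep_seg, dl$loss)
          ep_skel <- c(ep_skel, l_skel)
        }
      }
      log[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                 loss_total = mean(ep_tot),
                                 loss_seg = mean(ep_seg),
                                 loss_skel = mean(ep_skel))
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  loss %.4f (seg %.4f, skel %.4f)",
                        epoch, lr, mean(ep_tot), mean(ep_seg),
                        mean(ep_skel)))
    }
  })
  structure(list(params = net$params, net_spec = net_spec, config = config,
                 seed = config$seed, log = do.call(rbind, log)),
            class = "sg_checkpoint")
}

#' Save / load a checkpoint
#'
#' A checkpoint is a single archive holding the weights, the network spec,
#' the training configuration and the seed; a save--load round trip
#' reproduces predictions bit-for-bit.
#'
#' @param ckpt an `sg_checkpoint`.
#' @param path file path.
#' @return `load_checkpoint` returns the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "sg_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "sg_checkpoint"))
  ckpt
}

# reflect-pad a 3D array up to at least `size`
pad_reflect3 <- function(arr, size) {
  d <- dim(arr)
  pad <- pmax(0, size - d)
  if (all(pad == 0)) return(list(arr = arr, orig = d))
  idx <- lapply(1:3, function(ax) {
    n <- d[ax]; want <- n + pad[ax]
    base <- seq_len(n)
    refl <- if (n > 1) c(base, rev(base)[-1]) else base
    refl[((seq_len(want) - 1) %% length(refl)) + 1]
  })
  list(arr = arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], orig = d)
}

#' Sliding-window inference over a whole volume
#'
#' Tiles the (normalized) volume with the training patch size at the given
#' overlap, averages likelihoods where tiles overlap, and stitches the two
#' likelihood maps. Volumes smaller than the patch are reflect-padded and
#' the output cropped back. The result is independent of tile traversal
#' order.
#'
#' @param image image volume (raw intensities; normalized internally with
#'   [normalize_volume()]).
#' @param ckpt an `sg_checkpoint`.
#' @param overlap fractional tile overlap in `[0, 1)`; default 0.5.
#' @return A list with `seg` and `skel` ([likelihood_volume()]s; `skel` is
#'   `NULL` for a network without the skeleton stream).
#' @export
predict_sgcnn <- function(image, ckpt, overlap = 0.5) {
  stopifnot(inherits(ckpt, "sg_checkpoint"), overlap >= 0, overlap < 1)
  net <- structure(list(params = ckpt$params, spec = ckpt$net_spec),
                   class = "sg_cnn")
  img <- as.array(normalize_volume(image))
  ps <- ckpt$config$patch_size
  padded <- pad_reflect3(img, ps)
  arr <- padded$arr
  d <- dim(arr)
  stride <- pmax(1, round(ps * (1 - overlap)))
  origins <- lapply(1:3, function(ax) {
    o <- seq(1, d[ax] - ps[ax] + 1, by = stride[ax])
    sort(unique(c(o, d[ax] - ps[ax] + 1)))
  })
  acc_seg <- array(0, d); acc_skel <- array(0, d); cnt <- array(0, d)
  has_skel <- ckpt$net_spec$use_sg
  for (oz in origins[[1]]) for (oy in origins[[2]]) for (ox in origins[[3]]) {
    o <- c(oz, oy, ox)
    patch <- crop3(arr, o, ps)
    fw <- sgcnn_forward(net, patch)
    zi <- oz:(oz + ps[1] - 1); yi <- oy:(oy + ps[2] - 1)
    xi <- ox:(ox + ps[3] - 1)
    acc_seg[zi, yi, xi] <- acc_seg[zi, yi, xi] + fw$p[, , , 1]
    if (has_skel)
      acc_skel[zi, yi, xi] <- acc_skel[zi, yi, xi] + fw$p_skel[, , , 1]
    cnt[zi, yi, xi] <- cnt[zi, yi, xi] + 1
  }
  od <- padded$orig
  seg <- (acc_seg / cnt)[1:od[1], 1:od[2], 1:od[3], drop = FALSE]
  out <- list(seg = likelihood_volume(array(seg, od), spacing(image)),
              skel = NULL)
  if (has_skel) {
    sk <- (acc_skel / cnt)[1:od[1], 1:od[2], 1:od[3], drop = FALSE]
    out$skel <- likelihood_volume(array(sk, od), spacing(image))
  }
  out
}

#' Build a single-patch case from a phantom sample
#'
#' Crops one foreground-centred patch (image, mask and cached skeleton crop
#' the same window) from a prepared case and wraps it as a stand-alone
#' `case_record` whose volume equals the patch. Training on such a case
#' repeats the identical patch every iteration — the standard overfit
#' sanity check that gradients flow through both network streams.
#'
#' @param sample a `phantom_sample` from [generate_phantom()].
#' @param patch_size integer length-3 patch shape.
#' @return A `case_record` of exactly `patch_size` voxels.
#' @export
single_patch_case <- function(sample, patch_size = c(32, 32, 32)) {
  case <- prepare_case(sample$image, sample$mask, id = "patch")
  m <- as.array(case$mask)
  fg <- which(m == 1, arr.ind = TRUE)
  ctr <- round(colMeans(fg))
  org <- pmin(pmax(ctr - patch_size %/% 2, 1), dim(m) - patch_size + 1)
  structure(list(
    id = "patch",
    image = voxel_grid(crop3(case$image, org, patch_size)),
    mask = binary_volume(crop3(case$mask, org, patch_size)),
    skeleton = skeleton_volume(crop3(case$skeleton, org, patch_size)),
    branches = NULL
  ), class = "case_record")
}

#' Desk-scale phantom experiment
#'
#' The package's end-to-end study on synthetic data: generate branching-tube
#' phantoms, train the network on `n_train` of them, run sliding-window
#' inference on `n_test` held-out phantoms and evaluate against the exact
#' ground truth. Defaults use 48^3 phantoms of tree depth 3, a base-width-8
#' network with 3 levels, 32^3 patches, and a short high-learning-rate SGD
#' schedule sized so a run completes in minutes on one CPU.
#'
#' @param seed master seed; phantom generation, weight init and patch
#'   sampling all derive from it.
#' @param use_sg train the full dual-stream model (`TRUE`) or the plain
#'   encoder--decoder ablation arm (`FALSE`).
#' @param skel_loss skeleton-stream loss (`"stl"`, `"tversky"`, `"dice"`).
#' @param n_train,n_test number of training / held-out phantoms.
#' @param phantom baseline [phantom_spec()] for all cases (per-case seeds
#'   are derived from `seed`).
#' @param epochs,lr0,patches_per_case training-schedule overrides.
#' @param base_channels network width.
#' @param bd_coverage branch-detection rule for evaluation (see
#'   [branch_detection_rate()]).
#' @param verbose print progress.
#' @return A list with `mean` (named numeric: tr, bd, precision, recall,
#'   f_measure), `per_case` (list of `metrics_report`s), `checkpoint`.
#' @export
phantom_experiment <- function(seed = 1, use_sg = TRUE, skel_loss = "stl",
                               n_train = 8, n_test = 2,
                               phantom = phantom_spec(),
                               epochs = 12, lr0 = 0.1,
                               patches_per_case = 2, base_channels = 8,
                               bd_coverage = 0.8, verbose = FALSE) {
  make_case <- function(i) {
    sp <- phantom
    sp$seed <- as.integer((as.numeric(seed) * 1009 + i) %% 2147483647)
    s <- generate_phantom(sp)
    list(sample = s, case = prepare_case(s$image, s$mask,
                                         id = sprintf("phantom%02d", i)))
  }
  all_cases <- lapply(seq_len(n_train + n_test), make_case)
  train_cases <- lapply(all_cases[seq_len(n_train)], `[[`, "case")
  test_cases <- all_cases[n_train + seq_len(n_test)]

  cfg <- train_config(lr0 = lr0, decay_factor = 0.5,
                      decay_every = max(1, epochs %/% 2), epochs = epochs,
                      grad_clip = 1,
                      patch_size = c(32, 32, 32), skel_loss = skel_loss,
                      patches_per_case = patches_per_case, fg_bias = 0.7,
                      seed = seed)
  nspec <- network_spec(base_channels = base_channels, n_levels = 3,
                        use_sg = use_sg, seed = seed + 7L)
  ckpt <- train_sgcnn(train_cases, cfg, nspec, verbose = verbose)

  reports <- lapply(test_cases, function(tc) {
    pred <- predict_sgcnn(tc$case$image, ckpt)
    evaluate_segmentation(pred$seg, tc$case$mask,
                          skel_gt = tc$case$skeleton,
                          branches = tc$case$branches,
                          bd_coverage = bd_coverage)
  })
  mean_of <- function(f) mean(vapply(reports, `[[`, numeric(1), f))
  list(mean = c(tr = mean_of("tr"), bd = mean_of("bd"),
                precision = mean_of("precision"),
                recall = mean_of("recall"),
                f_measure = mean_of("f_measure")),
       per_case = reports, checkpoint = ckpt)
}
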