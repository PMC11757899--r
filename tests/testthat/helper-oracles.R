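# Independent brute-force oracles: plain R loops, no shared code with the
# package internals they check.

# number of foreground 26-neighbours of voxel (z, y, x)
bf_degree_at <- function(vol, z, y, x) {
  d <- dim(vol)
  cnt <- 0L
  for (oz in -1:1) for (oy in -1:1) for (ox in -1:1) {
    if (oz == 0 && oy == 0 && ox == 0) next
    zz <- z + oz; yy <- y + oy; xx <- x + ox
    if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3])
      next
    if (vol[zz, yy, xx] == 1) cnt <- cnt + 1L
  }
  cnt
}

# per-voxel 26-neighbour degree of every foreground voxel, by exhaustive scan
bf_degrees <- function(vol) {
  vol <- as.array(vol)
  fg <- which(vol == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) return(integer(0))
  vapply(seq_len(nrow(fg)), function(i)
    bf_degree_at(vol, fg[i, 1], fg[i, 2], fg[i, 3]), integer(1))
}

bf_count_endpoints <- function(vol) sum(bf_degrees(vol) == 1)
bf_count_bifurcations <- function(vol) sum(bf_degrees(vol) >= 3)

# thinness: no 2x2x2 all-foreground block
bf_is_thin <- function(vol) {
  vol <- as.array(vol)
  d <- dim(vol)
  for (z in 1:(d[1] - 1)) for (y in 1:(d[2] - 1)) for (x in 1:(d[3] - 1))
    if (all(vol[z:(z + 1), y:(y + 1), x:(x + 1)] == 1)) return(FALSE)
  TRUE
}

# loop-based metric recounts
bf_tree_length_rate <- function(skel, pred) {
  skel <- as.array(skel); pred <- as.array(pred)
  hit <- 0; tot <- 0
  co <- which(skel == 1, arr.ind = TRUE)
  for (i in seq_len(nrow(co))) {
    tot <- tot + 1
    if (pred[co[i, 1], co[i, 2], co[i, 3]] == 1) hit <- hit + 1
  }
  hit / tot
}

bf_branch_detection_rate <- function(branches, pred, coverage = 1) {
  pred <- as.array(pred)
  det <- 0
  for (b in branches$branches) {
    hit <- 0
    for (i in seq_len(nrow(b)))
      if (pred[b[i, 1], b[i, 2], b[i, 3]] == 1) hit <- hit + 1
    frac <- hit / nrow(b)
    if (coverage >= 1) det <- det + floor(frac)
    else if (frac >= coverage) det <- det + 1
  }
  det / length(branches$branches)
}

bf_voxel_scores <- function(pred, gt) {
  pred <- as.array(pred); gt <- as.array(gt)
  tp <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && gt[i] == 1) fn <- fn + 1L
  }
  pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  list(tp = tp, fp = fp, fn = fn, precision = pr, recall = rc, f_measure = f)
}

# central-difference gradient of a scalar function of a numeric vector
fd_grad <- function(f, x, i, h = 1e-6) {
  xp <- x; xp[i] <- xp[i] + h
  xm <- x; xm[i] <- xm[i] - h
  (f(xp) - f(xm)) / (2 * h)
}

# finite-difference foreground/background gradient-magnitude ratio of a loss
fd_gradient_ratio <- function(lossfn, p, g, h = 1e-6) {
  i_f <- which(g == 1)[1]
  i_b <- which(g == 0)[1]
  gf <- fd_grad(lossfn, p, i_f, h)
  gb <- fd_grad(lossfn, p, i_b, h)
  abs(gf / gb)
}
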