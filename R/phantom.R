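#' Specification of a synthetic branching-tube phantom
#'
#' The phantom emulates the geometry that makes tubular-structure segmentation
#' hard: a binary tree of tapering capsules (thick trunk, thin distal
#' branches) rasterized as bright tubes on a darker noisy background. Because
#' the tree is generated analytically, every sample comes with an exact
#' ground-truth mask and exact centerline branches, so the downstream
#' skeleton, loss, network and metric code can be exercised without any
#' external image data.
#'
#' @param grid_shape integer length-3, voxel counts `(D, H, W)` in
#'   `(z, y, x)` order.
#' @param spacing_mm numeric length-3 voxel size (mm).
#' @param tree_depth integer number of generations (>= 1); generation `g`
#'   holds `2^(g-1)` segments, so a depth-`d` tree has `2^d - 1` segments.
#' @param root_radius_vox trunk radius in voxels (>= 1).
#' @param radius_taper multiplicative radius factor per generation, in
#'   `(0, 1]`; effective radii are floored at 1 voxel so that every rounded
#'   centerline voxel stays inside its tube.
#' @param branch_angle_deg length-2 range (degrees) for a child's deviation
#'   from its parent's direction.
#' @param segment_length_vox length-2 range of segment lengths (voxels).
#' @param tube_intensity,background_intensity foreground / background mean
#'   image intensity; the image is clipped to `[0, 1]`.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (>= 0).
#' @param seed integer; identical spec + seed gives bit-identical samples.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [make_fixture()]
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48),
                         spacing_mm = c(1, 1, 1),
                         tree_depth = 3,
                         root_radius_vox = 3,
                         radius_taper = 0.75,
                         branch_angle_deg = c(20, 40),
                         segment_length_vox = c(10, 16),
                         tube_intensity = 0.8,
                         background_intensity = 0.2,
                         noise_sd = 0.05,
                         seed = 1) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            tree_depth >= 1, root_radius_vox >= 1,
            radius_taper > 0, radius_taper <= 1,
            length(branch_angle_deg) == 2,
            branch_angle_deg[1] <= branch_angle_deg[2],
            length(segment_length_vox) == 2,
            segment_length_vox[1] > 0,
            segment_length_vox[1] <= segment_length_vox[2],
            noise_sd >= 0)
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 tree_depth = as.integer(tree_depth),
                 root_radius_vox = root_radius_vox,
                 radius_taper = radius_taper,
                 branch_angle_deg = branch_angle_deg,
                 segment_length_vox = segment_length_vox,
                 tube_intensity = tube_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# distance-to-segment capsule rasterization: voxel centres within `radius`
# of the segment p0--p1 (continuous 1-based index coordinates) are foreground
rasterize_capsule <- function(mask, p0, p1, radius) {
  d <- dim(mask)
  lo <- pmax(1, floor(pmin(p0, p1) - radius - 1))
  hi <- pmin(d, ceiling(pmax(p0, p1) + radius + 1))
  if (any(lo > hi)) return(mask)
  co <- as.matrix(expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2],
                              x = lo[3]:hi[3]))
  v <- p1 - p0
  l2 <- sum(v^2)
  if (l2 < 1e-12) {
    d2 <- (co[, 1] - p0[1])^2 + (co[, 2] - p0[2])^2 + (co[, 3] - p0[3])^2
  } else {
    t <- ((co[, 1] - p0[1]) * v[1] + (co[, 2] - p0[2]) * v[2] +
            (co[, 3] - p0[3]) * v[3]) / l2
    t <- pmin(1, pmax(0, t))
    d2 <- (co[, 1] - (p0[1] + t * v[1]))^2 +
      (co[, 2] - (p0[2] + t * v[2]))^2 +
      (co[, 3] - (p0[3] + t * v[3]))^2
  }
  sel <- d2 <= radius^2
  if (any(sel)) mask[co[sel, , drop = FALSE]] <- 1L
  mask
}

# round the segment to an ordered, duplicate-free 26-connected voxel chain
discretize_segment <- function(p0, p1) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len * 2) + 1L)
  t <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + t * (p1[1] - p0[1]),
               p0[2] + t * (p1[2] - p0[2]),
               p0[3] + t * (p1[3] - p0[3]))
  vox <- round(pts)
  keep <- c(TRUE, rowSums(abs(diff(vox))) > 0)
  vox <- vox[keep, , drop = FALSE]
  storage.mode(vox) <- "integer"
  colnames(vox) <- c("z", "y", "x")
  vox
}

# orthonormal basis completing unit vector u
orthobasis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# longest admissible length along `dir` from `p0` keeping a margin inside the
# grid on every axis
max_fit_length <- function(p0, dir, grid, margin) {
  tmax <- Inf
  for (ax in 1:3) {
    if (abs(dir[ax]) < 1e-12) {
      if (p0[ax] < 1 + margin || p0[ax] > grid[ax] - margin) return(0)
      next
    }
    bound <- if (dir[ax] > 0) grid[ax] - margin else 1 + margin
    tmax <- min(tmax, (bound - p0[ax]) / dir[ax])
  }
  max(0, tmax)
}

#' Generate a synthetic branching-tube phantom
#'
#' Builds a binary tree of tube segments (two children per segment per
#' generation), rasterizes it as a union of capsules, and adds Gaussian
#' intensity noise. A voxel is foreground iff its centre lies within the
#' capsule of some segment, which makes the mask analytic and
#' resolution-consistent. Child directions and segment lengths are drawn from
#' the ranges in the spec using one seeded generator per call (no global RNG
#' state is perturbed); segments that would leave the grid are re-drawn and,
#' failing that, truncated — a tree that cannot be placed at all is an error.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_sample`: a list with elements `image`
#'   ([voxel_grid()]), `mask` ([binary_volume()]), `centerline_branches`
#'   ([branch_set()] with one branch per tree segment; junction voxels are
#'   assigned to the parent branch so branches stay disjoint), `tree_graph`
#'   (nodes, parent links and per-edge generation), and `spec`.
#' @examples
#' s <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
#'                                    tree_depth = 2, seed = 7))
#' s$mask
#' s$centerline_branches
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  grid <- spec$grid_shape
  if (any(grid < 8)) stop("phantom grid is degenerate (each axis must be >= 8)")
  ang <- spec$branch_angle_deg * pi / 180
  lens <- spec$segment_length_vox

  radius_of <- function(gen) max(1, spec$root_radius_vox *
                                   spec$radius_taper^(gen - 1))

  # root: starts near the low-z face, grows along +z with a small tilt
  r0 <- radius_of(1)
  p0 <- c(max(2, ceiling(r0 + 1)), grid[2] / 2, grid[3] / 2)
  tilt <- runif(1, 0, 5 * pi / 180)
  phi0 <- runif(1, 0, 2 * pi)
  dir0 <- c(cos(tilt), sin(tilt) * cos(phi0), sin(tilt) * sin(phi0))

  segments <- list()
  add_segment <- function(p0, dir, gen, parent) {
    r <- radius_of(gen)
    margin <- r + 1
    want <- runif(1, lens[1], lens[2])
    best <- NULL
    for (try in 1:50) {
      tmax <- max_fit_length(p0, dir, grid, margin)
      if (tmax >= want) { best <- list(dir = dir, len = want); break }
      if (is.null(best) || tmax > best$len) best <- list(dir = dir, len = tmax)
      # re-draw a deviation around the same parent direction
      if (gen == 1) {
        tilt <- runif(1, 0, 5 * pi / 180); phi <- runif(1, 0, 2 * pi)
        dir <- c(cos(tilt), sin(tilt) * cos(phi), sin(tilt) * sin(phi))
      } else {
        dir <- perturb_dir(attr(dir, "parent_dir") %||% dir, ang)
      }
    }
    if (best$len < 2)
      stop("phantom tree does not fit in the grid: increase grid_shape or ",
           "shorten segment_length_vox")
    p1 <- p0 + best$len * best$dir
    segments[[length(segments) + 1]] <<- list(p0 = p0, p1 = p1,
                                              dir = best$dir, radius = r,
                                              gen = gen, parent = parent)
    length(segments)
  }

  perturb_dir <- function(u, ang) {
    theta <- runif(1, ang[1], ang[2])
    phi <- runif(1, 0, 2 * pi)
    b <- orthobasis(u)
    d <- cos(theta) * u + sin(theta) * (cos(phi) * b$e1 + sin(phi) * b$e2)
    d / sqrt(sum(d^2))
  }

  root_id <- add_segment(p0, dir0, 1L, 0L)
  frontier <- root_id
  if (spec$tree_depth > 1) {
    for (gen in 2:spec$tree_depth) {
      nxt <- integer()
      for (pid in frontier) {
        par <- segments[[pid]]
        theta <- runif(1, ang[1], ang[2])
        phi <- runif(1, 0, 2 * pi)
        b <- orthobasis(par$dir)
        for (sgn in c(1, -1)) {
          # the two children deviate to roughly opposite azimuths
          ph <- phi + (if (sgn < 0) pi + runif(1, -0.5, 0.5) else 0)
          d <- cos(theta) * par$dir +
            sin(theta) * (cos(ph) * b$e1 + sin(ph) * b$e2)
          d <- d / sqrt(sum(d^2))
          attr(d, "parent_dir") <- par$dir
          nxt <- c(nxt, add_segment(par$p1, d, gen, pid))
        }
      }
      frontier <- nxt
    }
  }

  mask <- array(0L, grid)
  for (s in segments) mask <- rasterize_capsule(mask, s$p0, s$p1, s$radius)
  if (sum(mask) == 0) stop("phantom mask is empty")

  # analytic centerline branches, one per tree segment; voxels already used
  # by an earlier (parent) branch are dropped so branches are disjoint
  used <- array(FALSE, grid)
  branches <- list()
  for (s in segments) {
    vox <- discretize_segment(s$p0, s$p1)
    inside <- vox[, 1] >= 1 & vox[, 1] <= grid[1] &
      vox[, 2] >= 1 & vox[, 2] <= grid[2] &
      vox[, 3] >= 1 & vox[, 3] <= grid[3]
    vox <- vox[inside, , drop = FALSE]
    fresh <- !used[vox]
    used[vox[fresh, , drop = FALSE]] <- TRUE
    branches[[length(branches) + 1]] <- vox[fresh, , drop = FALSE]
  }

  img <- spec$background_intensity +
    (spec$tube_intensity - spec$background_intensity) * mask
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(prod(grid), 0, spec$noise_sd), grid)
  img <- pmin(1, pmax(0, img))

  nodes <- rbind(segments[[1]]$p0,
                 do.call(rbind, lapply(segments, `[[`, "p1")))
  tree_graph <- list(
    nodes = nodes,
    parent = c(0L, vapply(segments, function(s) s$parent, integer(1)) + 1L),
    edge_generation = vapply(segments, function(s) s$gen, integer(1)),
    n_edges = length(segments)
  )

  structure(list(image = voxel_grid(array(img, grid), spec$spacing_mm),
                 mask = binary_volume(mask, spec$spacing_mm),
                 centerline_branches = branch_set(branches),
                 tree_graph = tree_graph,
                 spec = spec),
            class = "phantom_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> depth %d tree, %d segments\n",
              x$spec$tree_depth, x$tree_graph$n_edges))
  print(x$mask)
  invisible(x)
}

#' Deterministic hand-specified test volumes
#'
#' Small (at most 40 voxels per axis) volumes with known geometry, used as
#' oracles across the skeleton, loss and metric modules:
#'
#' * `"single_voxel"`: one foreground voxel in a 9^3 grid.
#' * `"straight_tube"`: a 20-voxel-long tube of radius 2 along the z axis.
#' * `"y_junction"`: three tubes of radius 2 meeting at one point; the
#'   analytic branch set has 3 branches.
#' * `"two_blobs"`: two disjoint spheres; 2 single-voxel "branches".
#'
#' @param name fixture identifier.
#' @return A `phantom_sample` (noise-free, fully deterministic).
#' @export
make_fixture <- function(name) {
  build <- function(grid, segs, radii) {
    mask <- array(0L, grid)
    for (i in seq_along(segs))
      mask <- rasterize_capsule(mask, segs[[i]]$p0, segs[[i]]$p1, radii[i])
    used <- array(FALSE, grid)
    branches <- list()
    for (s in segs) {
      vox <- discretize_segment(s$p0, s$p1)
      fresh <- !used[vox]
      used[vox[fresh, , drop = FALSE]] <- TRUE
      branches[[length(branches) + 1]] <- vox[fresh, , drop = FALSE]
    }
    img <- 0.2 + 0.6 * mask
    structure(list(image = voxel_grid(array(img, grid)),
                   mask = binary_volume(mask),
                   centerline_branches = branch_set(branches),
                   tree_graph = list(n_edges = length(segs)),
                   spec = NULL),
              class = "phantom_sample")
  }
  switch(name,
    single_voxel = {
      grid <- c(9L, 9L, 9L)
      build(grid, list(list(p0 = c(5, 5, 5), p1 = c(5, 5, 5))), 0.4)
    },
    straight_tube = {
      grid <- c(28L, 13L, 13L)
      build(grid, list(list(p0 = c(5, 7, 7), p1 = c(24, 7, 7))), 2)
    },
    y_junction = {
      grid <- c(36L, 25L, 25L)
      segs <- list(list(p0 = c(4, 13, 13), p1 = c(18, 13, 13)),
                   list(p0 = c(18, 13, 13), p1 = c(30, 5, 13)),
                   list(p0 = c(18, 13, 13), p1 = c(30, 21, 13)))
      build(grid, segs, c(2, 2, 2))
    },
    two_blobs = {
      grid <- c(24L, 12L, 12L)
      segs <- list(list(p0 = c(6, 6, 6), p1 = c(6, 6, 6)),
                   list(p0 = c(18, 6, 6), p1 = c(18, 6, 6)))
      build(grid, segs, c(2.5, 2.5))
    },
    stop("unknown fixture name: ", name,
         " (available: single_voxel, straight_tube, y_junction, two_blobs)")
  )
}

#' Write a phantom sample to disk
#'
#' Writes `image.nii.gz` (float), `mask.nii.gz` (uint8) and
#' `branches.json` (0-based voxel triples) into `dir`.
#'
#' @param sample a `phantom_sample`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(sample, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(sample$image, file.path(dir, "image.nii.gz"))
  write_volume(sample$mask, file.path(dir, "mask.nii.gz"))
  write_branchset(sample$centerline_branches,
                  file.path(dir, "branches.json"))
  invisible(dir)
}
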