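#' Skeletonize a binary tubular mask
#'
#' Computes a one-voxel-thick centerline of a binary mask by iterative
#' border peeling: in six directional subiterations per pass, a foreground
#' voxel is removed when it is a simple point (its removal preserves the
#' topology of the object under 26-adjacency for the foreground and
#' 6-adjacency for the background) and not a curve endpoint (a voxel with at
#' most one foreground 26-neighbour). Voxels are re-tested sequentially in a
#' fixed scan order, so the skeleton is bit-identical across runs.
#'
#' @param mask a [binary_volume()] (or plain 0/1 array); may be empty.
#' @return A [skeleton_volume()] whose foreground is a subset of `mask`.
#' @examples
#' sk <- skeletonize(make_fixture("straight_tube")$mask)
#' sum(sk)
#' @export
skeletonize <- function(mask) {
  vals <- as.array(mask)
  if (!all(vals %in% c(0, 1))) stop("skeletonize: mask must be binary")
  storage.mode(vals) <- "integer"
  thin <- cpp_thin3d(vals, dim(vals))
  skeleton_volume(thin, spacing(mask))
}

#' Find bifurcation voxels of a skeleton
#'
#' A bifurcation voxel is a skeleton voxel with three or more foreground
#' 26-neighbours on the skeleton; these are the points where branches meet.
#'
#' @param skel a [skeleton_volume()] (or binary array).
#' @return Integer matrix of voxel coordinates (columns z, y, x; 1-based),
#'   possibly with zero rows.
#' @export
find_bifurcations <- function(skel) {
  vals <- as.array(skel)
  storage.mode(vals) <- "integer"
  cnt <- cpp_neighbor_count26(vals, dim(vals))
  co <- which(vals == 1L & cnt >= 3L, arr.ind = TRUE)
  colnames(co) <- c("z", "y", "x")
  storage.mode(co) <- "integer"
  co
}

#' Decompose a skeleton into branches
#'
#' Adjacent bifurcation voxels are first merged into clusters (thinning can
#' leave a 2-voxel junction at a "Y"); the clusters are removed and the
#' 26-connected components of the remainder are the branches. Bifurcation
#' voxels belong to no branch, which keeps branches pairwise disjoint and
#' the branch detection rate well defined.
#'
#' @param skel a [skeleton_volume()] (or binary array).
#' @return A [branch_set()]; the union of branch voxels and bifurcation
#'   voxels is exactly the skeleton foreground.
#' @examples
#' decompose_branches(skeletonize(make_fixture("y_junction")$mask))
#' @export
decompose_branches <- function(skel) {
  vals <- as.array(skel)
  storage.mode(vals) <- "integer"
  d <- dim(vals)
  bif <- find_bifurcations(vals)
  rest <- vals
  if (nrow(bif) > 0) rest[bif] <- 0L
  lab <- cpp_label3d(rest, d, 26L)
  n <- max(lab)
  branches <- vector("list", n)
  if (n > 0) {
    co <- which(lab > 0, arr.ind = TRUE)
    grp <- lab[co]
    for (j in seq_len(n)) {
      b <- co[grp == j, , drop = FALSE]
      colnames(b) <- c("z", "y", "x")
      branches[[j]] <- b
    }
  }
  branch_set(branches, bif)
}

#' Count skeleton endpoints
#'
#' Endpoints are skeleton voxels with exactly one foreground 26-neighbour.
#' Useful as a structural check (a straight tube has 2, a "Y" has 3).
#'
#' @param skel a skeleton volume or binary array.
#' @return Integer count.
#' @export
count_endpoints <- function(skel) {
  vals <- as.array(skel)
  storage.mode(vals) <- "integer"
  cnt <- cpp_neighbor_count26(vals, dim(vals))
  sum(vals == 1L & cnt == 1L)
}
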