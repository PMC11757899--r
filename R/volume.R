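#' Voxel volume containers
#'
#' Volumes are plain 3D numeric arrays in `(z, y, x)` index order carrying a
#' `spacing` attribute (per-axis voxel size in millimetres). Four thin S3
#' classes mark what a volume holds: a grayscale image (`voxel_grid`), a
#' `{0,1}` mask (`binary_volume`), a thin centerline mask (`skeleton_volume`)
#' and a per-voxel likelihood in `(0,1)` (`likelihood_volume`). All functions
#' in the package also accept plain arrays where the meaning is unambiguous.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, voxel size per axis (mm).
#' @return The array with class and `spacing` attribute set.
#' @examples
#' v <- voxel_grid(array(0, c(4, 4, 4)))
#' spacing(v)
#' @name volumes
NULL

new_volume <- function(values, spacing, class) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  structure(values, spacing = spacing, class = class)
}

#' @rdname volumes
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1)) {
  if (any(!is.finite(values))) stop("voxel_grid: non-finite voxel values")
  new_volume(values, spacing, "voxel_grid")
}

#' @rdname volumes
#' @export
binary_volume <- function(values, spacing = c(1, 1, 1)) {
  if (!all(values %in% c(0, 1))) stop("binary_volume: values must be 0 or 1")
  storage.mode(values) <- "integer"
  new_volume(values, spacing, c("binary_volume", "voxel_grid"))
}

#' @rdname volumes
#' @export
skeleton_volume <- function(values, spacing = c(1, 1, 1)) {
  v <- binary_volume(values, spacing)
  class(v) <- c("skeleton_volume", class(v))
  v
}

#' @rdname volumes
#' @param eps likelihoods are clamped to `[eps, 1 - eps]` so that loss
#'   gradients and gradient ratios stay finite.
#' @export
likelihood_volume <- function(values, spacing = c(1, 1, 1), eps = 1e-6) {
  if (any(!is.finite(values))) stop("likelihood_volume: non-finite values")
  values[] <- pmin(pmax(values, eps), 1 - eps)
  new_volume(values, spacing, c("likelihood_volume", "voxel_grid"))
}

#' @rdname volumes
#' @param x a volume.
#' @export
spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) c(1, 1, 1) else s
}

#' @export
as.array.voxel_grid <- function(x, ...) {
  array(as.vector(x), dim(x))
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %s mm\n", class(x)[1],
              d[1], d[2], d[3], paste(signif(spacing(x), 4), collapse = " x ")))
  if (inherits(x, "binary_volume")) {
    cat(sprintf("  foreground voxels: %d (%.3f%%)\n", sum(x),
                100 * mean(x)))
  } else {
    cat(sprintf("  value range: [%.4g, %.4g]\n", min(x), max(x)))
  }
  invisible(x)
}

# strip class/attrs down to a plain numeric array
as_plain_array <- function(x) {
  array(as.numeric(x), dim = dim(x))
}

check_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s have mismatched shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

#' Read and write volumes as NIfTI
#'
#' Images are written as float32 and masks/skeletons as uint8, with the voxel
#' spacing recorded in the NIfTI header.
#'
#' @param vol a volume object.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   volume of the requested kind.
#' @export
write_volume <- function(vol, path) {
  datatype <- if (inherits(vol, "binary_volume")) "uint8" else "float"
  arr <- as_plain_array(vol)
  attr(arr, "pixdim") <- spacing(vol)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = datatype), path)
  invisible(path)
}

#' @rdname write_volume
#' @param kind one of `"image"`, `"mask"`, `"skeleton"`, `"likelihood"`.
#' @export
read_volume <- function(path, kind = c("image", "mask", "skeleton",
                                       "likelihood")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img))
  switch(kind,
         image = voxel_grid(arr, sp),
         mask = binary_volume(arr, sp),
         skeleton = skeleton_volume(arr, sp),
         likelihood = likelihood_volume(arr, sp))
}

#' Branch sets
#'
#' A branch set is the decomposition of a centerline into branches: maximal
#' skeleton segments delimited by bifurcation points and endpoints. Branch
#' voxel coordinates are stored 1-based in `(z, y, x)` index order; the JSON
#' interchange format uses 0-based triples.
#'
#' @param branches list of integer matrices (one per branch, columns z, y, x).
#' @param bifurcation_points integer matrix of bifurcation voxels (may have
#'   zero rows).
#' @return An object of class `branch_set`.
#' @export
branch_set <- function(branches,
                       bifurcation_points = matrix(integer(), 0, 3)) {
  branches <- lapply(branches, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "integer"
    stopifnot(ncol(b) == 3, nrow(b) >= 1)
    colnames(b) <- c("z", "y", "x")
    b
  })
  bifurcation_points <- as.matrix(bifurcation_points)
  storage.mode(bifurcation_points) <- "integer"
  structure(list(branches = branches,
                 bifurcation_points = bifurcation_points,
                 n_branches = length(branches)),
            class = "branch_set")
}

#' @export
print.branch_set <- function(x, ...) {
  sizes <- vapply(x$branches, nrow, integer(1))
  cat(sprintf("<branch_set> %d branches (%d voxels), %d bifurcation voxels\n",
              x$n_branches, sum(sizes), nrow(x$bifurcation_points)))
  invisible(x)
}

#' @rdname branch_set
#' @param bs a `branch_set`.
#' @param path output JSON path.
#' @export
write_branchset <- function(bs, path) {
  out <- list(
    branches = lapply(bs$branches, function(b) unname(b) - 1L),
    bifurcation_points = unname(bs$bifurcation_points) - 1L,
    n_branches = bs$n_branches
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname branch_set
#' @export
read_branchset <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  triples <- function(lst) {
    if (length(lst) == 0) return(matrix(integer(), 0, 3))
    do.call(rbind, lapply(lst, function(v) as.integer(unlist(v)))) + 1L
  }
  branch_set(lapply(raw$branches, triples), triples(raw$bifurcation_points))
}
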