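#' Mean time series of a spherical ROI
#'
#' Averages, per volume, the voxels whose world-space centers lie within
#' `radius_mm` (inclusive) of a center coordinate. Coordinates are in the
#' volume's own world space as given by its affine (voxel indices are
#' 0-based in the affine convention); no template-space conversion is
#' attempted.
#'
#' @param volume A 3D or 4D numeric array, or an `RNifti` image (in which
#'   case the affine is taken from the image unless supplied).
#' @param center_mm Numeric length-3 world-space center.
#' @param radius_mm Sphere radius in millimeters; default 3.
#' @param affine 4 x 4 voxel-to-world affine; required for plain arrays.
#' @return Numeric vector with one mean per volume (length 1 for 3D input).
#' @export
extract_sphere_roi <- function(volume, center_mm, radius_mm = 3,
                               affine = NULL) {
  if (is.null(affine)) {
    if (requireNamespace("RNifti", quietly = TRUE) &&
        inherits(volume, "niftiImage")) {
      affine <- structure(RNifti::xform(volume), class = NULL)
    } else {
      stop("supply a 4 x 4 affine for plain array input")
    }
  }
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)), length(center_mm) == 3L,
            radius_mm > 0)
  arr <- as.array(volume)
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L)) stop("volume must be 3D or 4D")
  d <- dim(arr)[1:3]
  idx <- as.matrix(expand.grid(i = seq_len(d[1L]) - 1L,
                               j = seq_len(d[2L]) - 1L,
                               k = seq_len(d[3L]) - 1L))
  world <- cbind(idx, 1) %*% t(affine)
  dist2 <- (world[, 1L] - center_mm[1L])^2 + (world[, 2L] - center_mm[2L])^2 +
    (world[, 3L] - center_mm[3L])^2
  inside <- dist2 <= radius_mm^2 + 1e-9
  if (!any(inside))
    stop("empty sphere at (", paste(center_mm, collapse = ", "),
         ") mm with radius ", radius_mm, " mm")
  vox <- idx[inside, , drop = FALSE] + 1L
  if (nd == 3L) {
    return(mean(arr[vox]))
  }
  n_vol <- dim(arr)[4L]
  vapply(seq_len(n_vol), function(v) {
    mean(arr[cbind(vox, v)])
  }, numeric(1))
}

#' Scale signals by the per-time-point global mean
#'
#' Divides every value by the global mean of its time point, removing
#' whole-volume fluctuations: for a T x N matrix, each row is divided by its
#' row mean; for a 4D array, each volume is divided by its mean over all
#' voxels. After scaling, every time point's global mean is exactly 1.
#'
#' @param x A T x N matrix (rows = time) or a 4D array (4th dim = time).
#' @return Same shape as `x`.
#' @export
scale_by_global_mean <- function(x) {
  if (is.matrix(x)) {
    gm <- rowMeans(x)
    if (any(gm == 0)) stop("zero global mean at time point(s): ",
                           paste(utils::head(which(gm == 0)), collapse = ", "))
    return(x / gm)
  }
  arr <- as.array(x)
  if (length(dim(arr)) != 4L) stop("expected a matrix or 4D array")
  n_vol <- dim(arr)[4L]
  for (v in seq_len(n_vol)) {
    gm <- mean(arr[, , , v])
    if (gm == 0) stop("zero global mean at time point ", v)
    arr[, , , v] <- arr[, , , v] / gm
  }
  arr
}
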