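#' In-plane affine transform
#'
#' A 2D similarity transform (translation, rotation, isotropic scale) applied
#' identically to every axial slice of a volume, about a fixed in-plane
#' center. Units are pixels for the translation and degrees for the rotation.
#' Applying the transform to an image `I` produces `I'(x) = I(A(x))` with
#' `A(x) = s * R * (x - c) + c + t`, i.e. the transform maps output pixel
#' coordinates into the source image.
#'
#' @param tx,ty Translation in pixels.
#' @param rot Rotation in degrees (counter-clockwise).
#' @param scale Isotropic scale factor, `> 0`.
#' @param center In-plane center of rotation/scaling `(cx, cy)` in pixel
#'   coordinates; defaults to the image center when applied.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(tx = 0, ty = 0, rot = 0, scale = 1, center = NULL) {
  if (scale <= 0) stop("scale must be positive")
  structure(list(tx = tx, ty = ty, rot = rot, scale = scale, center = center),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d> t = (%.3f, %.3f) px, rot = %.3f deg, scale = %.4f\n",
              x$tx, x$ty, x$rot, x$scale))
  invisible(x)
}

is_identity_affine <- function(tf, tol = 1e-12) {
  abs(tf$tx) < tol && abs(tf$ty) < tol && abs(tf$rot) < tol &&
    abs(tf$scale - 1) < tol
}

#' Invert an in-plane affine transform
#' @param tf An [affine2d()].
#' @return The inverse [affine2d()] (about the same center).
#' @export
invert_affine <- function(tf) {
  th <- -tf$rot * pi / 180
  s <- 1 / tf$scale
  # inverse of x -> s R (x - c) + c + t is x -> (1/s) R^-1 (x - c - t) + c
  tr <- -s * rot_mat(th) %*% c(tf$tx, tf$ty)
  affine2d(tx = tr[1], ty = tr[2], rot = -tf$rot, scale = s, center = tf$center)
}

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Map output pixel coordinates (xi, yi vectors) through tf into source coords.
affine_map <- function(tf, xi, yi, dims) {
  c0 <- tf$center
  if (is.null(c0)) c0 <- (dims[1:2] + 1) / 2
  th <- tf$rot * pi / 180
  R <- rot_mat(th)
  dx <- xi - c0[1]; dy <- yi - c0[2]
  sx <- tf$scale * (R[1, 1] * dx + R[1, 2] * dy) + c0[1] + tf$tx
  sy <- tf$scale * (R[2, 1] * dx + R[2, 2] * dy) + c0[2] + tf$ty
  list(x = sx, y = sy)
}

# Bilinear sampling of a 3D volume at in-plane coordinates (sx, sy) on slice
# zi (all vectors of equal length). Out-of-grid points get `fill`.
bilinear_sample <- function(vol, sx, sy, zi, fill) {
  d <- dim(vol)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- x0 >= 1 & sx <= d[1] & y0 >= 1 & sy <= d[2]
  out <- rep(fill, length(sx))
  if (!any(inside)) return(out)
  x0 <- x0[inside]; y0 <- y0[inside]; fx <- fx[inside]; fy <- fy[inside]
  z <- zi[inside]
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2])  # upper edge: weight 0
  zoff <- (z - 1L) * d[1] * d[2]
  v00 <- vol[x0 + (y0 - 1L) * d[1] + zoff]
  v10 <- vol[x1 + (y0 - 1L) * d[1] + zoff]
  v01 <- vol[x0 + (y1 - 1L) * d[1] + zoff]
  v11 <- vol[x1 + (y1 - 1L) * d[1] + zoff]
  out[inside] <- v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
  out
}

#' Resample a 3D frame through an in-plane affine transform
#'
#' Linear interpolation; voxels mapping outside the grid are filled with the
#' frame minimum. Integer translations reproduce source voxel values exactly.
#'
#' @param frame 3D numeric array.
#' @param tf An [affine2d()].
#' @return The resampled 3D array.
#' @export
resample_frame <- function(frame, tf) {
  d <- dim(frame)
  if (is_identity_affine(tf)) return(frame)
  xi <- rep(seq_len(d[1]), times = d[2])
  yi <- rep(seq_len(d[2]), each = d[1])
  src <- affine_map(tf, xi, yi, d)
  fill <- min(frame)
  out <- array(0, d)
  for (z in seq_len(d[3])) {
    out[, , z] <- bilinear_sample(frame, src$x, src$y, rep(z, length(src$x)), fill)
  }
  out
}
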