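#' @useDynLib lungmech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor dnorm qnorm
NULL

# ---- containers ------------------------------------------------------------

#' Create a 3D volume
#'
#' A volume is a 3D numeric array on a regular axis-aligned grid with voxel
#' spacing and origin in millimetres. Voxel (i,j,k) is centred at
#' `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @param origin numeric length-3, mm position of the first voxel centre.
#' @param semantics free-text label for the value semantics ("HU", "density",
#'   "probability", "label", "map").
#' @return An object of class `lm_volume`.
#' @export
lm_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      semantics = "map") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(data = data, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L),
                 semantics = semantics),
            class = "lm_volume")
}

#' @export
print.lm_volume <- function(x, ...) {
  cat(sprintf("<lm_volume %s> %s, spacing %s mm, range [%.4g, %.4g]\n",
              x$semantics, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              suppressWarnings(min(x$data, na.rm = TRUE)),
              suppressWarnings(max(x$data, na.rm = TRUE))))
  invisible(x)
}

#' Create a displacement vector field
#'
#' Stores the per-voxel displacement u(x) in mm on the fixed-image grid. The
#' associated spatial transform is `phi(x) = x + u(x)`, mapping fixed-grid
#' positions into the moving image; the deformation gradient is F = I + grad u.
#'
#' @param data 4D numeric array `[nx, ny, nz, 3]`, components in mm.
#' @param spacing,origin grid geometry as in [lm_volume()].
#' @param direction label recording the anatomical direction convention,
#'   e.g. "expiration_to_inspiration".
#' @return An object of class `lm_dvf`.
#' @export
lm_dvf <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = "fixed_to_moving") {
  data <- as.array(data)
  d <- dim(data)
  if (length(d) != 4L || d[4] != 3L)
    stop("DVF data must be a 4D array with 3 components on the last axis")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(data = data, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L),
                 direction = direction),
            class = "lm_dvf")
}

#' @export
print.lm_dvf <- function(x, ...) {
  cat(sprintf("<lm_dvf> %s, spacing %s mm, max |u| = %.4g mm, %s\n",
              paste(dim(x$data)[1:3], collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sqrt(max(rowSums(matrix(x$data, ncol = 3L)^2))),
              x$direction))
  invisible(x)
}

vol_dim <- function(v) dim(v$data)
dvf_dim <- function(d) dim(d$data)[1:3]

#' Grid voxel-centre coordinates (mm)
#'
#' @param shape integer length-3 grid shape.
#' @param spacing,origin grid geometry.
#' @return list with vectors `x`, `y`, `z` of per-axis coordinates.
#' @export
grid_coords <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  spacing <- rep_len(spacing, 3L); origin <- rep_len(origin, 3L)
  list(x = origin[1] + (seq_len(shape[1]) - 1) * spacing[1],
       y = origin[2] + (seq_len(shape[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(shape[3]) - 1) * spacing[3])
}

# Dense nx*ny*nz x 3 matrix of voxel-centre coordinates, column-major order
# matching as.vector() of an array of that shape.
grid_points <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  co <- grid_coords(shape, spacing, origin)
  cbind(rep(co$x, times = shape[2] * shape[3]),
        rep(rep(co$y, each = shape[1]), times = shape[3]),
        rep(co$z, each = shape[1] * shape[2]))
}

# ---- interpolation ---------------------------------------------------------

# Trilinear interpolation of a 3D array at arbitrary mm coordinates.
# pts: n x 3 matrix in mm. Out-of-domain points are clamped to the boundary
# (replicate padding) unless fill is given, in which case they take `fill`.
interp_trilinear <- function(arr, spacing, origin, pts, fill = NULL) {
  d <- dim(arr)
  gx <- (pts[, 1] - origin[1]) / spacing[1] + 1
  gy <- (pts[, 2] - origin[2]) / spacing[2] + 1
  gz <- (pts[, 3] - origin[3]) / spacing[3] + 1
  outside <- gx < 1 | gx > d[1] | gy < 1 | gy > d[2] | gz < 1 | gz > d[3]
  cx <- pmin(pmax(gx, 1), d[1]); cy <- pmin(pmax(gy, 1), d[2])
  cz <- pmin(pmax(gz, 1), d[3])
  i0 <- pmin(floor(cx), d[1] - 1L); j0 <- pmin(floor(cy), d[2] - 1L)
  k0 <- pmin(floor(cz), d[3] - 1L)
  if (d[1] == 1L) i0 <- rep(1, length(cx))
  if (d[2] == 1L) j0 <- rep(1, length(cy))
  if (d[3] == 1L) k0 <- rep(1, length(cz))
  fx <- cx - i0; fy <- cy - j0; fz <- cz - k0
  n1 <- d[1]; n12 <- d[1] * d[2]
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  idx <- function(i, j, k) (k - 1) * n12 + (j - 1) * n1 + i
  a <- as.vector(arr)
  v <- a[idx(i0, j0, k0)] * (1 - fx) * (1 - fy) * (1 - fz) +
       a[idx(i1, j0, k0)] * fx       * (1 - fy) * (1 - fz) +
       a[idx(i0, j1, k0)] * (1 - fx) * fy       * (1 - fz) +
       a[idx(i1, j1, k0)] * fx       * fy       * (1 - fz) +
       a[idx(i0, j0, k1)] * (1 - fx) * (1 - fy) * fz +
       a[idx(i1, j0, k1)] * fx       * (1 - fy) * fz +
       a[idx(i0, j1, k1)] * (1 - fx) * fy       * fz +
       a[idx(i1, j1, k1)] * fx       * fy       * fz
  if (!is.null(fill)) v[outside] <- fill
  v
}

# Nearest-neighbour interpolation (for label maps).
interp_nearest <- function(arr, spacing, origin, pts, fill = 0) {
  d <- dim(arr)
  i <- round((pts[, 1] - origin[1]) / spacing[1]) + 1
  j <- round((pts[, 2] - origin[2]) / spacing[2]) + 1
  k <- round((pts[, 3] - origin[3]) / spacing[3]) + 1
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(fill, nrow(pts))
  out[ok] <- as.vector(arr)[(k[ok] - 1) * d[1] * d[2] + (j[ok] - 1) * d[1] + i[ok]]
  out
}

# ---- separable convolution -------------------------------------------------

# Convolve a 3D array along one axis with a 1D kernel, replicate padding.
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, d)
  for (t in seq_along(kernel)) {
    off <- t - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)
    sl <- switch(axis,
                 arr[src, , , drop = FALSE],
                 arr[, src, , drop = FALSE],
                 arr[, , src, drop = FALSE])
    out <- out + kernel[t] * sl
  }
  out
}

gauss_kernel <- function(sigma_vox, order = 0L, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma_vox))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) return(-x / sigma_vox^2 * g)
  if (order == 2L) {
    k <- (x^2 - sigma_vox^2) / sigma_vox^4 * g
    return(k - mean(k)) # zero DC response: constants have zero 2nd derivative
  }
  stop("order must be 0, 1 or 2")
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels (scalar or 3).
gauss_smooth <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0)
      arr <- conv_axis(arr, gauss_kernel(sigma_vox[ax]), ax)
  }
  arr
}
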