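# Volume standardization and vessel enhancement: isotropic resampling,
# union bounding-box cropping, multiscale Hessian vesselness, Otsu threshold.

#' Resample a volume onto an isotropic grid
#'
#' Trilinear interpolation (nearest-neighbour for label volumes) onto a grid
#' with the requested isotropic spacing covering the input extent.
#'
#' @param v an [lm_volume()].
#' @param spacing target isotropic spacing (mm), scalar.
#' @param method "linear" or "nearest" (use "nearest" for label maps).
#' @return resampled [lm_volume()].
#' @export
resample_isotropic <- function(v, spacing = 1, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (spacing <= 0) stop("spacing must be positive")
  d <- vol_dim(v)
  extent <- (d - 1) * v$spacing
  nshape <- pmax(floor(extent / spacing) + 1, 1)
  pts <- grid_points(nshape, rep(spacing, 3), v$origin)
  vals <- if (method == "linear")
    interp_trilinear(v$data, v$spacing, v$origin, pts)
  else
    interp_nearest(v$data, v$spacing, v$origin, pts)
  lm_volume(array(vals, nshape), rep(spacing, 3), v$origin, v$semantics)
}

#' Crop volumes to the union bounding box of two masks
#'
#' Finds the 3D bounding box of `maskA | maskB`, grows it by `margin` voxels
#' (clipped to the domain), and crops every payload volume to it.
#'
#' @param maskA,maskB binary [lm_volume()]s on a common grid.
#' @param margin margin in voxels added on every side.
#' @param payloads list of [lm_volume()]s (and/or [lm_dvf()]s) to crop;
#'   defaults to the two masks themselves.
#' @return list of cropped payloads (same order/names), with the crop box
#'   in attribute `bbox` (2 x 3 voxel index matrix).
#' @export
union_crop <- function(maskA, maskB, margin = 0L,
                       payloads = list(maskA = maskA, maskB = maskB)) {
  u <- (maskA$data > 0.5) | (maskB$data > 0.5)
  if (!any(u)) stop("union of masks is empty; nothing to crop to")
  idx <- which(u, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1)
  hi <- pmin(apply(idx, 2, max) + margin, dim(u))
  out <- lapply(payloads, function(p) {
    if (inherits(p, "lm_dvf")) {
      lm_dvf(p$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], , drop = FALSE],
             p$spacing, p$origin + (lo - 1) * p$spacing, p$direction)
    } else {
      lm_volume(p$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
                p$spacing, p$origin + (lo - 1) * p$spacing, p$semantics)
    }
  })
  attr(out, "bbox") <- rbind(lo, hi)
  out
}

# scale-normalized (gamma = 1) Gaussian-derivative Hessian entries at one
# scale; sigma in mm, converted per-axis to voxels
hessian_at_scale <- function(arr, spacing, sigma_mm) {
  sv <- sigma_mm / spacing
  k0 <- lapply(1:3, function(ax) gauss_kernel(sv[ax], 0L))
  k1 <- lapply(1:3, function(ax) gauss_kernel(sv[ax], 1L) / spacing[ax])
  k2 <- lapply(1:3, function(ax) gauss_kernel(sv[ax], 2L) / spacing[ax]^2)
  conv3 <- function(a, kx, ky, kz)
    conv_axis(conv_axis(conv_axis(a, kx, 1L), ky, 2L), kz, 3L)
  s2 <- sigma_mm^2
  list(h11 = s2 * conv3(arr, k2[[1]], k0[[2]], k0[[3]]),
       h22 = s2 * conv3(arr, k0[[1]], k2[[2]], k0[[3]]),
       h33 = s2 * conv3(arr, k0[[1]], k0[[2]], k2[[3]]),
       h12 = s2 * conv3(arr, k1[[1]], k1[[2]], k0[[3]]),
       h13 = s2 * conv3(arr, k1[[1]], k0[[2]], k1[[3]]),
       h23 = s2 * conv3(arr, k0[[1]], k1[[2]], k1[[3]]))
}

#' Multiscale Hessian vesselness (bright tubular structures)
#'
#' At each scale the image is convolved with scale-normalized Gaussian
#' derivatives and the Hessian eigenvalues are sorted by magnitude
#' |e1| <= |e2| <= |e3|. A bright tube has e2, e3 strongly negative and of
#' similar magnitude with e1 near zero; the tubularness functional
#' (Frangi-style, with plate/blob ratio terms and a structure-norm term)
#' maps this to [0, 1]. The final map is the voxelwise maximum over scales.
#'
#' @param v an [lm_volume()].
#' @param scales vector of Gaussian scales (mm).
#' @param alpha,beta sensitivity of the plate/blob ratio terms.
#' @param c_frac structure-norm sensitivity as a fraction of the maximum
#'   Hessian norm at each scale (NULL uses half the maximum).
#' @return [lm_volume()] with semantics "probability".
#' @export
vesselness <- function(v, scales = c(1, 2, 3), alpha = 0.5, beta = 0.5,
                       c_frac = 0.5) {
  if (length(scales) < 1 || any(scales <= 0)) stop("scales must be positive")
  d <- vol_dim(v)
  best <- array(0, d)
  for (s in scales) {
    H <- hessian_at_scale(v$data, v$spacing, s)
    ev <- eig_sym3(as.vector(H$h11), as.vector(H$h22), as.vector(H$h33),
                   as.vector(H$h12), as.vector(H$h13), as.vector(H$h23))
    # vectorized magnitude sort of the three eigenvalues
    a1 <- ev$e1; a2 <- ev$e2; a3 <- ev$e3
    abs1 <- abs(a1); abs2 <- abs(a2); abs3 <- abs(a3)
    # build sorted-by-|.| triples (l1s smallest)
    l1s <- a1; l2s <- a2; l3s <- a3
    # bubble sort by magnitude, 3 elements
    sw <- abs1 > abs2
    t1 <- ifelse(sw, l2s, l1s); t2 <- ifelse(sw, l1s, l2s)
    l1s <- t1; l2s <- t2
    abs1 <- abs(l1s); abs2 <- abs(l2s)
    sw <- abs2 > abs3
    t2 <- ifelse(sw, l3s, l2s); t3 <- ifelse(sw, l2s, l3s)
    l2s <- t2; l3s <- t3
    abs2 <- abs(l2s); abs3 <- abs(l3s)
    sw <- abs1 > abs2
    t1 <- ifelse(sw, l2s, l1s); t2 <- ifelse(sw, l1s, l2s)
    l1s <- t1; l2s <- t2
    Ra <- abs(l2s) / pmax(abs(l3s), 1e-12)       # tube vs plate
    Rb <- abs(l1s) / pmax(sqrt(abs(l2s * l3s)), 1e-12) # blob deviation
    S <- sqrt(l1s^2 + l2s^2 + l3s^2)
    cc <- if (is.null(c_frac)) 0.5 * max(S) else c_frac * max(S)
    if (cc <= 0) cc <- 1
    resp <- (1 - exp(-Ra^2 / (2 * alpha^2))) *
      exp(-Rb^2 / (2 * beta^2)) *
      (1 - exp(-S^2 / (2 * cc^2)))
    resp[l2s > 0 | l3s > 0] <- 0 # bright structures only
    best <- pmax(best, array(resp, d))
  }
  lm_volume(best, v$spacing, v$origin, "probability")
}

#' Otsu threshold of a volume
#'
#' Builds a 256-bin histogram over the value range and selects the cut that
#' maximizes between-class variance; returns the binarized volume
#' (value >= threshold) with the threshold as an attribute.
#'
#' @param v an [lm_volume()] or numeric array with non-constant values.
#' @param n_bins histogram resolution (default 256).
#' @return binary [lm_volume()]; attributes `threshold` (mm value on the
#'   input scale) and `n_bins`.
#' @export
otsu <- function(v, n_bins = 256L) {
  vol <- if (inherits(v, "lm_volume")) v else lm_volume(as.array(v))
  x <- as.vector(vol$data)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("Otsu threshold undefined for constant input")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  total <- w[n_bins]; mu_t <- mu[n_bins]
  w0 <- w[-n_bins]; mu0 <- mu[-n_bins]
  w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  # between-class variance w0*w1*(m0 - m1)^2 with class means m0, m1
  m0 <- mu0 / pmax(w0, 1); m1 <- (mu_t - mu0) / pmax(w1, 1)
  between[valid] <- (w0[valid] / total) * (w1[valid] / total) *
    (m0[valid] - m1[valid])^2
  cut <- which.max(between)
  thr <- br[cut + 1L] # threshold at the upper edge of the last class-0 bin
  out <- array(as.numeric(vol$data >= thr), vol_dim(vol))
  structure(lm_volume(out, vol$spacing, vol$origin, "label"),
            threshold = thr, n_bins = n_bins)
}
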