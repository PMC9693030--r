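# Registration-quality metrics: lobe Dice coefficient (LDC), worst-10%
# surface error (W10SE), vessel-tree position error (VTPE) and symmetric
# closest-skeleton error (SCSE), plus the surface/skeleton extraction and
# label warping they rely on.

as_mask_array <- function(x) {
  if (inherits(x, "lm_volume")) x$data > 0.5 else as.array(x) > 0.5
}

mask_points_mm <- function(x) {
  v <- if (inherits(x, "lm_volume")) x else lm_volume(x)
  idx <- which(v$data > 0.5, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, v$spacing, "*"), 2, v$origin, "+")
}

#' Dice overlap coefficient of two binary regions
#'
#' DC = 2 |L1 and L2| / (|L1| + |L2|).
#'
#' @param L1,L2 binary volumes (logical arrays or [lm_volume()]s).
#' @return fraction in [0, 1].
#' @export
dice <- function(L1, L2) {
  a <- as_mask_array(L1); b <- as_mask_array(L2)
  stopifnot(all(dim(a) == dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("Dice undefined: both regions are empty")
  2 * sum(a & b) / (na + nb)
}

#' Lobe Dice coefficient: mean Dice over the five lung lobes
#'
#' The five lobes (1 = RUL, 2 = RML, 3 = RLL, 4 = LUL, 5 = LLL) are compared
#' label by label; the LDC is their unweighted mean Dice.
#'
#' @param A,B lobe label maps (integer arrays or [lm_volume()]s, labels 0-5).
#' @return fraction in [0, 1]; attribute `per_lobe` carries the 5 values.
#' @export
lobe_dice <- function(A, B) {
  a <- if (inherits(A, "lm_volume")) A$data else as.array(A)
  b <- if (inherits(B, "lm_volume")) B$data else as.array(B)
  per <- vapply(1:5, function(l) {
    la <- a == l; lb <- b == l
    if (sum(la) + sum(lb) == 0)
      stop(sprintf("lobe label %d empty in both maps", l))
    2 * sum(la & lb) / (sum(la) + sum(lb))
  }, numeric(1))
  structure(mean(per), per_lobe = per)
}

#' Triangulated iso-surface of a binary mask
#'
#' Extracts the 0.5 iso-surface of the (optionally Gaussian pre-smoothed)
#' mask by marching tetrahedra, merges duplicate vertices and removes
#' degenerate triangles. Smoothing (default sigma of 0.65 voxels) turns the
#' staircase voxel boundary into a sub-voxel-accurate surface whose area is
#' close to the underlying smooth shape.
#'
#' @param mask binary [lm_volume()] (or logical array, unit spacing assumed).
#' @param smooth_sigma Gaussian pre-smoothing sigma in voxels (0 disables).
#' @return object of class `lm_mesh`: `vertices` (N x 3, mm) and
#'   `triangles` (M x 3 vertex indices).
#' @export
extract_surface <- function(mask, smooth_sigma = 0.65) {
  v <- if (inherits(mask, "lm_volume")) mask else lm_volume(mask)
  m <- as.numeric(v$data > 0.5)
  if (sum(m) == 0) stop("cannot extract a surface from an empty mask")
  arr <- array(m, dim(v$data))
  if (smooth_sigma > 0) arr <- gauss_smooth(arr, smooth_sigma)
  # pad with background so the surface is closed at the domain boundary
  d <- dim(arr)
  p <- array(0, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  res <- cpp_march_tets(as.vector(p), dim(p), 0.5, v$spacing,
                        v$origin - v$spacing)
  V <- res$vertices; Fm <- res$triangles
  if (nrow(V) == 0) stop("iso-surface is empty after smoothing")
  key <- paste(round(V[, 1], 6), round(V[, 2], 6), round(V[, 3], 6))
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  V2 <- V[uk, , drop = FALSE]
  F2 <- matrix(map[Fm], ncol = 3)
  # drop degenerate triangles (repeated vertex or zero area)
  e1 <- V2[F2[, 2], ] - V2[F2[, 1], ]
  e2 <- V2[F2[, 3], ] - V2[F2[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  keep <- area2 > 1e-12
  F2 <- F2[keep, , drop = FALSE]
  # drop vertices orphaned by triangle cleaning and reindex
  vkeep <- sort(unique(as.vector(F2)))
  remap <- integer(nrow(V2)); remap[vkeep] <- seq_along(vkeep)
  structure(list(vertices = V2[vkeep, , drop = FALSE],
                 triangles = matrix(remap[F2], ncol = 3)),
            class = "lm_mesh")
}

#' @export
print.lm_mesh <- function(x, ...) {
  cat(sprintf("<lm_mesh> %d vertices, %d triangles, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a triangle mesh (mm^2)
#' @param mesh an `lm_mesh`.
#' @return numeric scalar.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; Fm <- mesh$triangles
  e1 <- V[Fm[, 2], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  e2 <- V[Fm[, 3], , drop = FALSE] - V[Fm[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# distances from each vertex of `from` to the closest surface point of `to`
# (closest point may lie in a triangle interior, not only at vertices)
surface_vertex_dists <- function(from, to) {
  if (nrow(to$triangles) == 0) stop("target mesh has no triangles")
  cpp_point_mesh_dists(from$vertices, to$vertices, to$triangles)
}

#' Worst-10% surface error between two meshes (mm)
#'
#' For every vertex of S1 the exact point-to-surface distance to S2 is
#' computed (the closest point may lie on a triangle face); the mean of the
#' largest ceil(0.1 N) distances is W10(S1->S2). The metric is the average
#' of the two directions: W10SE = (W10(S1->S2) + W10(S2->S1)) / 2.
#'
#' @param S1,S2 `lm_mesh` objects.
#' @param frac worst fraction to average (default 0.10).
#' @return mm value; attributes `w10_12` and `w10_21` carry the directions.
#' @export
worst10_surface_error <- function(S1, S2, frac = 0.10) {
  if (nrow(S1$triangles) == 0 || nrow(S2$triangles) == 0)
    stop("both meshes must contain triangles")
  w10 <- function(a, b) {
    d <- sort(surface_vertex_dists(a, b), decreasing = TRUE)
    mean(d[seq_len(ceiling(frac * length(d)))])
  }
  w12 <- w10(S1, S2); w21 <- w10(S2, S1)
  structure((w12 + w21) / 2, w10_12 = w12, w10_21 = w21)
}

#' Vessel-tree position error (mm)
#'
#' Mean closest-point distance from every voxel of M1 to M2 and from every
#' voxel of M2 to M1, averaged: VTPE = (mean d(M1->M2) + mean d(M2->M1)) / 2.
#'
#' @param M1,M2 binary vessel masks ([lm_volume()] or logical array).
#' @return mm value.
#' @export
vessel_tree_position_error <- function(M1, M2) {
  p1 <- mask_points_mm(M1); p2 <- mask_points_mm(M2)
  if (nrow(p1) == 0 || nrow(p2) == 0) stop("vessel masks must be nonempty")
  (mean(cpp_min_dists(p1, p2)) + mean(cpp_min_dists(p2, p1))) / 2
}

#' Curve skeleton of a binary mask by topology-preserving thinning
#'
#' Six-subiteration border thinning deleting simple, non-endpoint voxels
#' (simple-point criterion: one 26-connected foreground component in the
#' 26-neighbourhood and one 6-connected background component in the
#' 18-neighbourhood). Preserves the connected-component count of the input.
#'
#' @param mask binary [lm_volume()] or logical array.
#' @return object of class `lm_skeleton`: `points` (K x 3, mm), plus the
#'   binary `mask` volume of skeletal voxels.
#' @export
skeletonize <- function(mask) {
  v <- if (inherits(mask, "lm_volume")) mask else lm_volume(mask)
  m <- v$data > 0.5
  if (!any(m)) stop("cannot skeletonize an empty mask")
  sk <- cpp_thin3d(as.vector(m), dim(m))
  skv <- lm_volume(array(as.numeric(sk), dim(m)), v$spacing, v$origin, "label")
  structure(list(points = mask_points_mm(skv), mask = skv),
            class = "lm_skeleton")
}

#' Symmetric closest-skeleton error (mm)
#'
#' Symmetric mean closest-point distance between two skeleton point sets —
#' the skeleton counterpart of [vessel_tree_position_error()].
#'
#' @param K1,K2 `lm_skeleton` objects (or K x 3 point matrices).
#' @return mm value.
#' @export
skeleton_error <- function(K1, K2) {
  p1 <- if (inherits(K1, "lm_skeleton")) K1$points else as.matrix(K1)
  p2 <- if (inherits(K2, "lm_skeleton")) K2$points else as.matrix(K2)
  if (nrow(p1) == 0 || nrow(p2) == 0) stop("skeletons must be nonempty")
  (mean(cpp_min_dists(p1, p2)) + mean(cpp_min_dists(p2, p1))) / 2
}

#' Warp a label map through a displacement field
#'
#' Pull-back nearest-neighbour resampling: warped(x) = labels(x + u(x)).
#' With u the fixed-to-moving field, this carries the moving-image labels
#' onto the fixed grid for overlap evaluation against the fixed labels.
#'
#' @param labels label map ([lm_volume()]).
#' @param dvf an [lm_dvf()] on the same grid.
#' @return warped label map ([lm_volume()]).
#' @export
warp_labels <- function(labels, dvf) {
  shape <- vol_dim(labels)
  if (!all(shape == dvf_dim(dvf))) stop("label map and DVF grids differ")
  pts <- grid_points(shape, dvf$spacing, dvf$origin)
  u <- matrix(dvf$data, ncol = 3L)
  w <- interp_nearest(labels$data, labels$spacing, labels$origin, pts + u,
                      fill = 0)
  lm_volume(array(w, shape), labels$spacing, labels$origin, "label")
}

#' Warp a scalar volume through a displacement field (trilinear pull-back)
#'
#' warped(x) = v(x + u(x)); out-of-domain samples take `fill`.
#'
#' @param v an [lm_volume()].
#' @param dvf an [lm_dvf()] on the same grid.
#' @param fill value for samples outside the moving image domain.
#' @return warped [lm_volume()].
#' @export
warp_volume <- function(v, dvf, fill = NULL) {
  shape <- vol_dim(v)
  if (!all(shape == dvf_dim(dvf))) stop("volume and DVF grids differ")
  pts <- grid_points(shape, dvf$spacing, dvf$origin)
  u <- matrix(dvf$data, ncol = 3L)
  w <- interp_trilinear(v$data, v$spacing, v$origin, pts + u, fill = fill)
  lm_volume(array(w, shape), v$spacing, v$origin, v$semantics)
}

#' All four registration-quality metrics for one evaluation pair
#'
#' Computes LDC, W10SE (on whole-lung surfaces), VTPE and SCSE between fixed
#' structures and (typically warped) moving structures.
#'
#' @param fixed_lobes,moving_lobes lobe label maps on the fixed grid.
#' @param fixed_vessels,moving_vessels binary vessel masks on the fixed grid.
#' @param smooth_sigma surface pre-smoothing passed to [extract_surface()].
#' @return data.frame with columns metric, value, units.
#' @export
registration_qa <- function(fixed_lobes, moving_lobes, fixed_vessels,
                            moving_vessels, smooth_sigma = 0.65) {
  ldc <- as.numeric(lobe_dice(fixed_lobes, moving_lobes))
  sf <- extract_surface(lm_volume(array(as.numeric(fixed_lobes$data > 0),
                                        vol_dim(fixed_lobes)),
                                  fixed_lobes$spacing, fixed_lobes$origin),
                        smooth_sigma)
  sm <- extract_surface(lm_volume(array(as.numeric(moving_lobes$data > 0),
                                        vol_dim(moving_lobes)),
                                  moving_lobes$spacing, moving_lobes$origin),
                        smooth_sigma)
  w10 <- as.numeric(worst10_surface_error(sf, sm))
  vtpe <- vessel_tree_position_error(fixed_vessels, moving_vessels)
  scse <- skeleton_error(skeletonize(fixed_vessels), skeletonize(moving_vessels))
  data.frame(metric = c("LDC", "W10SE", "VTPE", "SCSE"),
             value = c(ldc, w10, vtpe, scse),
             units = c("fraction", "mm", "mm", "mm"))
}
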