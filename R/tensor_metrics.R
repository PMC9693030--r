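# Deformation-gradient tensor field and derived biomechanical maps.
#
# Convention: for a displacement field u on the fixed grid the transform is
# phi(x) = x + u(x) and F = I + grad u. det F = J > 1 means local volume
# expansion under phi. For expiration->inspiration fields J > 1 marks
# regions of large local inflation.

#' Deformation gradient tensor field from a displacement field
#'
#' Computes F = I + grad u with spacing-aware finite differences: central
#' differences at interior voxels (second-order accurate), one-sided
#' differences on the one-voxel boundary shell. The boundary shell should be
#' excluded from regional statistics (see [interior_mask()]).
#'
#' @param dvf an [lm_dvf()].
#' @return An object of class `lm_tensor_field`: a 5D array `F[i,j,k,r,c]`
#'   plus grid geometry.
#' @export
deformation_gradient <- function(dvf) {
  stopifnot(inherits(dvf, "lm_dvf"))
  d <- dvf_dim(dvf)
  if (any(d < 3L)) stop("grid must be at least 3 voxels along every axis")
  h <- dvf$spacing
  F <- array(0, c(d, 3L, 3L))
  for (comp in 1:3) {
    u <- dvf$data[, , , comp]
    for (ax in 1:3) {
      F[, , , comp, ax] <- diff_axis(u, h[ax], ax) + (comp == ax)
    }
  }
  structure(list(F = F, spacing = dvf$spacing, origin = dvf$origin),
            class = "lm_tensor_field")
}

# d/dx along one axis: central interior, one-sided first/last slice.
diff_axis <- function(u, h, axis) {
  d <- dim(u)
  n <- d[axis]
  ip <- c(2:n, n)   # forward neighbour (clamped)
  im <- c(1, 1:(n - 1))  # backward neighbour (clamped)
  # denominator: 2h interior, h where clamped (one-sided)
  den <- rep(2 * h, n); den[1] <- h; den[n] <- h
  g <- switch(axis,
              (u[ip, , , drop = FALSE] - u[im, , , drop = FALSE]),
              (u[, ip, , drop = FALSE] - u[, im, , drop = FALSE]),
              (u[, , ip, drop = FALSE] - u[, , im, drop = FALSE]))
  sweep_den <- switch(axis,
                      array(rep(den, times = prod(d[2:3])), d),
                      aperm(array(rep(den, times = prod(d[c(1, 3)])),
                                  d[c(2, 1, 3)]), c(2, 1, 3)),
                      aperm(array(rep(den, times = prod(d[1:2])),
                                  d[c(3, 1, 2)]), c(2, 3, 1)))
  array(g, d) / sweep_den
}

#' Logical mask of interior voxels (boundary shell removed)
#'
#' @param shape integer length-3 grid shape.
#' @param shell number of boundary voxels to strip (default 1, matching the
#'   one-sided-difference shell of [deformation_gradient()]).
#' @return logical 3D array.
#' @export
interior_mask <- function(shape, shell = 1L) {
  m <- array(FALSE, shape)
  i <- (1L + shell):(shape[1] - shell)
  j <- (1L + shell):(shape[2] - shell)
  k <- (1L + shell):(shape[3] - shell)
  m[i, j, k] <- TRUE
  m
}

# Vectorized eigenvalues of symmetric 3x3 matrices (descending), analytic
# trigonometric method. Inputs are parallel vectors of the unique entries.
eig_sym3 <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  # snap numerically isotropic tensors (eigenvalue spread at rounding level)
  # to exact isotropy so derived anisotropy indices vanish identically
  scale <- pmax(abs(a11), abs(a22), abs(a33), 1)
  p[p < 1e-12 * scale] <- 0
  nz <- p > 0
  b11 <- (a11 - q); b22 <- (a22 - q); b33 <- (a33 - q)
  detB <- b11 * (b22 * b33 - a23^2) -
    a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- rep(0, length(a11))
  r[nz] <- detB[nz] / (2 * p[nz]^3)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!nz] <- q[!nz]; e2[!nz] <- q[!nz]; e3[!nz] <- q[!nz]
  list(e1 = e1, e2 = e2, e3 = e3)
}

# Vectorized determinant of general 3x3 matrices given as 9 parallel vectors.
det3 <- function(f11, f12, f13, f21, f22, f23, f31, f32, f33) {
  f11 * (f22 * f33 - f23 * f32) -
    f12 * (f21 * f33 - f23 * f31) +
    f13 * (f21 * f32 - f22 * f31)
}

#' Principal stretches of the right Cauchy-Green tensor
#'
#' Forms C = F'F per voxel and returns the square roots of its eigenvalues
#' sorted descending: lambda1 >= lambda2 >= lambda3 > 0 where valid. Voxels
#' with det F <= 0 or non-finite entries are marked invalid; eigenvalues that
#' would fall below 1e-12 are floored there and the voxel invalidated.
#'
#' @param tf an `lm_tensor_field` from [deformation_gradient()].
#' @return An object of class `lm_stretch_field`: arrays `l1`, `l2`, `l3`,
#'   logical `valid`, the determinant map `detF`, and grid geometry.
#' @export
principal_stretches <- function(tf) {
  stopifnot(inherits(tf, "lm_tensor_field"))
  d <- dim(tf$F)[1:3]
  f <- lapply(1:3, function(r) lapply(1:3, function(c) as.vector(tf$F[, , , r, c])))
  # C = F'F entries
  c11 <- f[[1]][[1]]^2 + f[[2]][[1]]^2 + f[[3]][[1]]^2
  c22 <- f[[1]][[2]]^2 + f[[2]][[2]]^2 + f[[3]][[2]]^2
  c33 <- f[[1]][[3]]^2 + f[[2]][[3]]^2 + f[[3]][[3]]^2
  c12 <- f[[1]][[1]] * f[[1]][[2]] + f[[2]][[1]] * f[[2]][[2]] + f[[3]][[1]] * f[[3]][[2]]
  c13 <- f[[1]][[1]] * f[[1]][[3]] + f[[2]][[1]] * f[[2]][[3]] + f[[3]][[1]] * f[[3]][[3]]
  c23 <- f[[1]][[2]] * f[[1]][[3]] + f[[2]][[2]] * f[[2]][[3]] + f[[3]][[2]] * f[[3]][[3]]
  ev <- eig_sym3(c11, c22, c33, c12, c13, c23)
  detF <- det3(f[[1]][[1]], f[[1]][[2]], f[[1]][[3]],
               f[[2]][[1]], f[[2]][[2]], f[[2]][[3]],
               f[[3]][[1]], f[[3]][[2]], f[[3]][[3]])
  finite <- is.finite(c11) & is.finite(c22) & is.finite(c33) &
    is.finite(c12) & is.finite(c13) & is.finite(c23)
  floor_hit <- !is.na(ev$e3) & ev$e3 < 1e-12
  valid <- finite & !is.na(detF) & detF > 0 & !floor_hit
  l1 <- sqrt(pmax(ev$e1, 1e-12)); l2 <- sqrt(pmax(ev$e2, 1e-12))
  l3 <- sqrt(pmax(ev$e3, 1e-12))
  structure(list(l1 = array(l1, d), l2 = array(l2, d), l3 = array(l3, d),
                 valid = array(valid, d), detF = array(detF, d),
                 spacing = tf$spacing, origin = tf$origin),
            class = "lm_stretch_field")
}

#' Jacobian determinant map J = lambda1 * lambda2 * lambda3
#'
#' J > 1 is local volume expansion, J < 1 contraction. Invalid voxels are NA.
#'
#' @param sf an `lm_stretch_field`.
#' @return [lm_volume()] with semantics "J".
#' @export
jacobian_map <- function(sf) {
  stopifnot(inherits(sf, "lm_stretch_field"))
  J <- sf$l1 * sf$l2 * sf$l3
  J[!sf$valid] <- NA_real_
  lm_volume(J, sf$spacing, sf$origin, semantics = "J")
}

#' Anisotropic deformation index map
#'
#' ADI = sqrt(((lambda1 - lambda2)/lambda2)^2 + ((lambda2 - lambda3)/lambda3)^2).
#' Zero iff the stretch is isotropic (lambda1 = lambda2 = lambda3); larger
#' values mean more direction-dependent deformation.
#'
#' @param sf an `lm_stretch_field`.
#' @return [lm_volume()] with semantics "ADI"; invalid voxels NA.
#' @export
adi_map <- function(sf) {
  stopifnot(inherits(sf, "lm_stretch_field"))
  adi <- sqrt(((sf$l1 - sf$l2) / sf$l2)^2 + ((sf$l2 - sf$l3) / sf$l3)^2)
  adi[!sf$valid] <- NA_real_
  lm_volume(adi, sf$spacing, sf$origin, semantics = "ADI")
}

#' Slab-rod index map
#'
#' SRI = atan( lambda3 (lambda1 - lambda2) / (lambda2 (lambda2 - lambda3)) ) / (pi/2),
#' in [0, 1]: 0 for slab-like anisotropy (stretch along two directions,
#' lambda1 = lambda2 > lambda3), 1 for rod-like (stretch along one direction,
#' lambda1 > lambda2 = lambda3, taken as the arctan limit). SRI is undefined
#' where ADI = 0 (isotropic voxels); those voxels are masked.
#'
#' @param sf an `lm_stretch_field`.
#' @param adi the ADI map from [adi_map()] (used only for the validity mask).
#' @return list with `sri` ([lm_volume()], NA where undefined) and logical
#'   array `sri_valid`.
#' @export
sri_map <- function(sf, adi = adi_map(sf)) {
  stopifnot(inherits(sf, "lm_stretch_field"))
  num <- sf$l3 * (sf$l1 - sf$l2)
  den <- sf$l2 * (sf$l2 - sf$l3)
  sri <- atan2(num, den) / (pi / 2)
  # atan2 handles den = 0: rod-like (num > 0, den = 0) -> pi/2 -> SRI = 1
  isotropic <- !is.na(adi$data) & adi$data == 0
  sri_valid <- sf$valid & !isotropic
  sri[!sri_valid] <- NA_real_
  list(sri = lm_volume(sri, sf$spacing, sf$origin, semantics = "SRI"),
       sri_valid = sri_valid)
}

#' Anisotropy shape coordinates alpha and beta
#'
#' alpha = sign(J - 1) * (lambda2/lambda3 - 1) and
#' beta = sign(J - 1) * (lambda1/lambda2 - 1). The parenthesised ratios are
#' always >= 0 by the eigenvalue ordering, so alpha and beta share the sign
#' of J - 1: both positive under expansion, both negative under contraction.
#' Voxels with J = 1 have an undefined sign factor and are masked.
#'
#' @param sf an `lm_stretch_field`.
#' @param J the Jacobian map from [jacobian_map()].
#' @return list of two [lm_volume()]s `alpha` and `beta` (NA where masked).
#' @export
alpha_beta_map <- function(sf, J = jacobian_map(sf)) {
  stopifnot(inherits(sf, "lm_stretch_field"))
  s <- sign(J$data - 1)
  s[!is.na(s) & s == 0] <- NA_real_
  alpha <- s * (sf$l2 / sf$l3 - 1)
  beta <- s * (sf$l1 / sf$l2 - 1)
  alpha[!sf$valid] <- NA_real_
  beta[!sf$valid] <- NA_real_
  list(alpha = lm_volume(alpha, sf$spacing, sf$origin, semantics = "alpha"),
       beta = lm_volume(beta, sf$spacing, sf$origin, semantics = "beta"))
}

#' Compute all biomechanical maps from a displacement field
#'
#' Convenience wrapper chaining [deformation_gradient()],
#' [principal_stretches()] and the individual map constructors.
#'
#' @param dvf an [lm_dvf()].
#' @return list with `J`, `ADI`, `SRI`, `sri_valid`, `alpha`, `beta`,
#'   `stretches`, and `direction` (copied from the input DVF).
#' @export
biomech_maps <- function(dvf) {
  sf <- principal_stretches(deformation_gradient(dvf))
  J <- jacobian_map(sf)
  adi <- adi_map(sf)
  sri <- sri_map(sf, adi)
  ab <- alpha_beta_map(sf, J)
  list(J = J, ADI = adi, SRI = sri$sri, sri_valid = sri$sri_valid,
       alpha = ab$alpha, beta = ab$beta, stretches = sf,
       direction = dvf$direction)
}
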