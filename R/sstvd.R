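# Tissue-volume-preserving B-spline registration.
#
# Minimizes  gamma1 * SSTVD + gamma2 * SSVMD + gamma3 * elastic  over a
# cubic-B-spline-parameterized displacement field, coarse to fine:
#   SSTVD  = mean_Omega ( If(x) - J(x) * Im(x + u(x)) )^2
#   SSVMD  = mean_Omega ( Fv(x) - Mv(x + u(x)) )^2
#   elastic = mean ||L u||^2,  L = -0.75 laplacian - 0.25 grad(div)
# with J = det(I + grad u) computed analytically from the B-spline basis
# derivatives. The Jacobian factor makes the intensity term compare tissue
# *volumes*, the model under which lung tissue is conserved across breathing.

#' Convert CT Hounsfield units to a tissue-density (fraction) image
#'
#' Linear air/tissue mixture: density = clamp((HU - HU_air) /
#' (HU_tissue - HU_air), 0, 1) with HU_air = -1000 and HU_tissue = 55.
#'
#' @param ct an [lm_volume()] in HU.
#' @param hu_air,hu_tissue mixture endpoints.
#' @return [lm_volume()] with semantics "density", values in [0, 1].
#' @export
hu_to_density <- function(ct, hu_air = -1000, hu_tissue = 55) {
  f <- pmin(pmax((ct$data - hu_air) / (hu_tissue - hu_air), 0), 1)
  lm_volume(f, ct$spacing, ct$origin, "density")
}

# ---- cubic B-spline machinery ----------------------------------------------

# cardinal cubic B-spline and its derivative, support (-2, 2)
bspline3 <- function(t) {
  at <- abs(t)
  ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
         ifelse(at < 2, (2 - at)^3 / 6, 0))
}
bspline3_d <- function(t) {
  at <- abs(t); s <- sign(t)
  ifelse(at < 1, s * (-12 * at + 9 * at^2) / 6,
         ifelse(at < 2, s * (-3 * (2 - at)^2) / 6, 0))
}

# per-axis basis matrices: value W and spatial derivative D (n x ncp)
basis_matrices <- function(coords, cp0, knot, ncp) {
  cp <- cp0 + (seq_len(ncp) - 1) * knot
  t <- outer(coords, cp, function(x, p) (x - p) / knot)
  list(W = bspline3(t), D = bspline3_d(t) / knot)
}

# C [m1,m2,m3] contracted with matrices Mx (n1 x m1), My, Mz
tensor3_mult <- function(C, Mx, My, Mz) {
  d <- dim(C)
  A <- Mx %*% matrix(C, d[1], d[2] * d[3])           # n1 x (m2 m3)
  A <- array(A, c(nrow(Mx), d[2], d[3]))
  B <- My %*% matrix(aperm(A, c(2, 1, 3)), d[2], nrow(Mx) * d[3])
  B <- aperm(array(B, c(nrow(My), nrow(Mx), d[3])), c(2, 1, 3))
  E <- Mz %*% matrix(aperm(B, c(3, 1, 2)), d[3], nrow(Mx) * nrow(My))
  aperm(array(E, c(nrow(Mz), nrow(Mx), nrow(My))), c(2, 3, 1))
}

#' Create an identity cubic B-spline transform
#'
#' Control points on a lattice with the given knot spacing, extended two
#' knots beyond the image domain so the cubic basis fully covers it.
#'
#' @param shape,spacing,origin fixed-image grid geometry.
#' @param knot knot spacing in mm (scalar or length 3).
#' @return object of class `lm_bspline`: zero coefficient lattice
#'   `coef[i,j,k,comp]` (mm) plus lattice and grid geometry.
#' @export
bspline_identity <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             knot = 8) {
  knot <- rep_len(knot, 3L)
  extent <- (shape - 1) * spacing
  ncp <- ceiling(extent / knot) + 5L
  cp0 <- origin - 2 * knot
  structure(list(coef = array(0, c(ncp, 3L)), knot = knot, cp0 = cp0,
                 ncp = ncp, shape = shape, spacing = spacing, origin = origin),
            class = "lm_bspline")
}

bspline_bases <- function(T) {
  co <- grid_coords(T$shape, T$spacing, T$origin)
  list(x = basis_matrices(co$x, T$cp0[1], T$knot[1], T$ncp[1]),
       y = basis_matrices(co$y, T$cp0[2], T$knot[2], T$ncp[2]),
       z = basis_matrices(co$z, T$cp0[3], T$knot[3], T$ncp[3]))
}

#' Dense displacement field of a B-spline transform
#'
#' @param T an `lm_bspline`.
#' @return an [lm_dvf()] on the transform's image grid.
#' @export
bspline_dvf <- function(T) {
  B <- bspline_bases(T)
  u <- array(0, c(T$shape, 3L))
  for (c in 1:3)
    u[, , , c] <- tensor3_mult(T$coef[, , , c, drop = FALSE][, , , 1],
                               B$x$W, B$y$W, B$z$W)
  lm_dvf(u, T$spacing, T$origin, direction = "fixed_to_moving")
}

# dense u plus analytic grad u (list G[[comp]][[axis]]) from the basis
bspline_dvf_grad <- function(T, B = bspline_bases(T)) {
  u <- vector("list", 3L); G <- vector("list", 3L)
  for (c in 1:3) {
    Cc <- T$coef[, , , c, drop = FALSE][, , , 1]
    u[[c]] <- tensor3_mult(Cc, B$x$W, B$y$W, B$z$W)
    G[[c]] <- list(tensor3_mult(Cc, B$x$D, B$y$W, B$z$W),
                   tensor3_mult(Cc, B$x$W, B$y$D, B$z$W),
                   tensor3_mult(Cc, B$x$W, B$y$W, B$z$D))
  }
  list(u = u, G = G)
}

# analytic det(I + grad u) and cofactor matrix entries from grad-u arrays
jac_and_cof <- function(G) {
  F <- function(r, c) G[[r]][[c]] + (r == c)
  f11 <- F(1, 1); f12 <- F(1, 2); f13 <- F(1, 3)
  f21 <- F(2, 1); f22 <- F(2, 2); f23 <- F(2, 3)
  f31 <- F(3, 1); f32 <- F(3, 2); f33 <- F(3, 3)
  J <- f11 * (f22 * f33 - f23 * f32) - f12 * (f21 * f33 - f23 * f31) +
    f13 * (f21 * f32 - f22 * f31)
  # cofactor C[r,c] = dJ/dF[r,c]
  cof <- list(
    list(f22 * f33 - f23 * f32, -(f21 * f33 - f23 * f31), f21 * f32 - f22 * f31),
    list(-(f12 * f33 - f13 * f32), f11 * f33 - f13 * f31, -(f11 * f32 - f12 * f31)),
    list(f12 * f23 - f13 * f22, -(f11 * f23 - f13 * f21), f11 * f22 - f12 * f21))
  list(J = J, cof = cof)
}

# ---- individual cost terms (exported for testing/inspection) ----------------

#' Tissue-volume-difference similarity cost
#'
#' mean over the evaluation mask of (If - J * Im(x + u))^2 with J the
#' analytic B-spline Jacobian. Folding voxels (J <= 0 in the mask) are
#' counted and reported but the cost is still returned.
#'
#' @param If,Im fixed/moving tissue-density [lm_volume()]s.
#' @param T an `lm_bspline`.
#' @param mask optional logical array / [lm_volume()]; defaults to the whole
#'   domain.
#' @return cost value; attribute `n_folded` counts J <= 0 voxels in the mask.
#' @export
sstvd_cost <- function(If, Im, T, mask = NULL) {
  B <- bspline_bases(T)
  ug <- bspline_dvf_grad(T, B)
  jc <- jac_and_cof(ug$G)
  pts <- grid_points(T$shape, T$spacing, T$origin)
  wp <- pts + cbind(as.vector(ug$u[[1]]), as.vector(ug$u[[2]]),
                    as.vector(ug$u[[3]]))
  Imw <- interp_trilinear(Im$data, Im$spacing, Im$origin, wp)
  m <- if (is.null(mask)) rep(TRUE, nrow(pts)) else as.vector(as_mask_array(mask))
  r <- as.vector(If$data) - as.vector(jc$J) * Imw
  structure(mean(r[m]^2), n_folded = sum(as.vector(jc$J)[m] <= 0))
}

#' Vesselness-difference similarity cost
#'
#' mean over the mask of (Fv - Mv(x + u))^2 (no Jacobian weighting).
#'
#' @param Fv,Mv fixed/moving vesselness [lm_volume()]s.
#' @inheritParams sstvd_cost
#' @return cost value.
#' @export
ssvmd_cost <- function(Fv, Mv, T, mask = NULL) {
  ug <- bspline_dvf_grad(T)
  pts <- grid_points(T$shape, T$spacing, T$origin)
  wp <- pts + cbind(as.vector(ug$u[[1]]), as.vector(ug$u[[2]]),
                    as.vector(ug$u[[3]]))
  Mvw <- interp_trilinear(Mv$data, Mv$spacing, Mv$origin, wp)
  m <- if (is.null(mask)) rep(TRUE, nrow(pts)) else as.vector(as_mask_array(mask))
  mean((as.vector(Fv$data) - Mvw)[m]^2)
}

# second difference along an axis, spacing-aware, replicate boundary
diff2_axis <- function(u, h, axis) {
  d <- dim(u); n <- d[axis]
  ip <- c(2:n, n); im <- c(1, 1:(n - 1))
  g <- switch(axis,
              u[ip, , , drop = FALSE] + u[im, , , drop = FALSE] - 2 * u,
              u[, ip, , drop = FALSE] + u[, im, , drop = FALSE] - 2 * u,
              u[, , ip, drop = FALSE] + u[, , im, drop = FALSE] - 2 * u)
  array(g, d) / h^2
}

# mixed second derivative d^2 u / dx_a dx_b (a != b) via nested first diffs
diffm_axis <- function(u, ha, hb, a, b) diff_axis(diff_axis(u, ha, a), hb, b)

# apply L = -0.75 laplacian - 0.25 grad(div) to a displacement field given
# as a list of three component arrays; returns a list of three arrays
apply_elastic_L <- function(ul, h) {
  out <- vector("list", 3L)
  for (i in 1:3) {
    lap <- diff2_axis(ul[[i]], h[1], 1L) + diff2_axis(ul[[i]], h[2], 2L) +
      diff2_axis(ul[[i]], h[3], 3L)
    gd <- 0
    for (j in 1:3) {
      gd <- gd + if (i == j) diff2_axis(ul[[j]], h[j], j)
      else diffm_axis(ul[[j]], h[j], h[i], j, i)
    }
    out[[i]] <- -0.75 * lap - 0.25 * gd
  }
  out
}

#' Linear-elastic regularization cost
#'
#' mean over the domain of ||L u||^2 with the linear elasticity operator
#' L = -0.75 laplacian - 0.25 grad(div) applied to the dense displacement
#' field by finite differences. Zero for the identity and for any constant
#' translation.
#'
#' @param T an `lm_bspline`.
#' @return cost value.
#' @export
elastic_cost <- function(T) {
  ug <- bspline_dvf_grad(T)
  Lu <- apply_elastic_L(ug$u, T$spacing)
  mean(Lu[[1]]^2 + Lu[[2]]^2 + Lu[[3]]^2)
}

# ---- total cost and analytic gradient ---------------------------------------

reg_cost_grad <- function(T, If, Im, Fv, Mv, mask_vec, weights, B,
                          grad = TRUE) {
  ug <- bspline_dvf_grad(T, B)
  jc <- jac_and_cof(ug$G)
  pts <- grid_points(T$shape, T$spacing, T$origin)
  wp <- pts + cbind(as.vector(ug$u[[1]]), as.vector(ug$u[[2]]),
                    as.vector(ug$u[[3]]))
  N <- sum(mask_vec)
  Ntot <- length(mask_vec)

  Imw <- interp_trilinear(Im$vol$data, Im$vol$spacing, Im$vol$origin, wp)
  r1 <- (as.vector(If$data) - as.vector(jc$J) * Imw) * mask_vec
  c_sstvd <- sum(r1^2) / N

  Mvw <- interp_trilinear(Mv$vol$data, Mv$vol$spacing, Mv$vol$origin, wp)
  r2 <- (as.vector(Fv$data) - Mvw) * mask_vec
  c_ssvmd <- sum(r2^2) / N

  Lu <- apply_elastic_L(ug$u, T$spacing)
  c_el <- mean(Lu[[1]]^2 + Lu[[2]]^2 + Lu[[3]]^2)

  total <- weights[1] * c_sstvd + weights[2] * c_ssvmd + weights[3] * c_el
  out <- list(total = total, sstvd = c_sstvd, ssvmd = c_ssvmd,
              elastic = c_el,
              n_folded = sum(as.vector(jc$J)[mask_vec > 0] <= 0))
  if (!grad) return(out)

  d <- T$shape
  # moving-image gradients sampled at warped points
  g_u <- vector("list", 3L)
  for (k in 1:3) {
    gIm <- interp_trilinear(Im$grad[[k]], Im$vol$spacing, Im$vol$origin, wp)
    gMv <- interp_trilinear(Mv$grad[[k]], Mv$vol$spacing, Mv$vol$origin, wp)
    g_u[[k]] <- array(weights[1] * (2 / N) * r1 * (-as.vector(jc$J) * gIm) +
                        weights[2] * (2 / N) * r2 * (-gMv), d)
  }
  # elastic term: L is (to boundary terms) self-adjoint
  LLu <- apply_elastic_L(Lu, T$spacing)
  for (k in 1:3)
    g_u[[k]] <- g_u[[k]] + weights[3] * (2 / Ntot) * LLu[[k]]

  # derivative-of-J term: dC1/d(grad u)[k][j] = -(2/N) r1 Imw cof[k][j]
  g_G <- vector("list", 3L)
  for (k in 1:3) {
    g_G[[k]] <- vector("list", 3L)
    for (j in 1:3)
      g_G[[k]][[j]] <- array(weights[1] * (2 / N) * r1 *
                               (-Imw * as.vector(jc$cof[[k]][[j]])), d)
  }

  grad_c <- array(0, c(T$ncp, 3L))
  tWx <- t(B$x$W); tWy <- t(B$y$W); tWz <- t(B$z$W)
  tDx <- t(B$x$D); tDy <- t(B$y$D); tDz <- t(B$z$D)
  for (k in 1:3) {
    g <- tensor3_mult(g_u[[k]], tWx, tWy, tWz) +
      tensor3_mult(g_G[[k]][[1]], tDx, tWy, tWz) +
      tensor3_mult(g_G[[k]][[2]], tWx, tDy, tWz) +
      tensor3_mult(g_G[[k]][[3]], tWx, tWy, tDz)
    grad_c[, , , k] <- g
  }
  out$grad <- grad_c
  out
}

# precompute a moving image with its spatial gradient (central differences)
moving_with_grad <- function(v) {
  list(vol = v,
       grad = lapply(1:3, function(ax) diff_axis(v$data, v$spacing[ax], ax)))
}

# ---- multiresolution driver -------------------------------------------------

downsample_volume <- function(v, factor, method = "linear") {
  if (factor >= 1) return(v)
  sm <- if (method == "linear")
    lm_volume(gauss_smooth(v$data, 0.5 / factor), v$spacing, v$origin,
              v$semantics)
  else v
  target <- v$spacing[1] / factor
  resample_isotropic(sm, target, method = method)
}

dilate_mask <- function(m, r) {
  k <- rep(1, 2 * r + 1)
  a <- m * 1
  for (ax in 1:3) a <- conv_axis(a, k, ax)
  a > 0.5
}

#' Default desk-scale registration configuration
#'
#' Three resolution levels (1/4, 1/2, 1 of the input resolution) with
#' B-spline knot spacings 8, 8 and 4 mm and decreasing iteration counts —
#' the same coarse-to-fine structure as full-scale tissue-volume
#' registration, sized for 64^3 volumes. Weights: intensity and vesselness
#' terms at 1, elastic regularization at 0.05.
#'
#' @param levels list of lists with `factor`, `knot`, `iters`.
#' @param weights length-3 weights (gamma1, gamma2, gamma3).
#' @param step0 initial control-point step length (mm).
#' @param tol relative cost-decrease convergence tolerance per level.
#' @return config list.
#' @export
reg_config <- function(levels = list(list(factor = 0.25, knot = 8, iters = 60),
                                     list(factor = 0.5, knot = 8, iters = 40),
                                     list(factor = 1, knot = 4, iters = 30)),
                       weights = c(1, 1, 0.05), step0 = 2, tol = 1e-6) {
  stopifnot(all(weights >= 0), length(weights) == 3)
  list(levels = levels, weights = weights, step0 = step0, tol = tol)
}

# separable least-squares fit of a dense field to a B-spline lattice
fit_bspline_to_field <- function(u_arr, shape, spacing, origin, knot) {
  T <- bspline_identity(shape, spacing, origin, knot)
  B <- bspline_bases(T)
  pinv <- function(W) {
    WtW <- crossprod(W)
    solve(WtW + diag(1e-8, ncol(W)), t(W))
  }
  Px <- pinv(B$x$W); Py <- pinv(B$y$W); Pz <- pinv(B$z$W)
  for (c in 1:3)
    T$coef[, , , c] <- tensor3_mult(u_arr[, , , c], Px, Py, Pz)
  T
}

#' B-spline registration of a moving to a fixed image
#'
#' Gradient descent with Armijo backtracking on the total cost
#' gamma1 * SSTVD + gamma2 * SSVMD + gamma3 * elastic, coarse-to-fine.
#' The accepted-cost trace is monotone non-increasing within each level.
#'
#' @param fixed,moving tissue-density [lm_volume()]s (same grid).
#' @param fixed_vesselness,moving_vesselness vesselness [lm_volume()]s; pass
#'   constant-zero volumes to disable the SSVMD term.
#' @param mask evaluation mask (fixed lung), dilated by 2 voxels internally.
#' @param cfg configuration from [reg_config()].
#' @param verbose print per-level progress.
#' @return list with `transform` (`lm_bspline` at full resolution), `dvf`
#'   (dense [lm_dvf()]), `trace` (data.frame level/iter/cost/fold count).
#' @export
register_sstvd <- function(fixed, moving, fixed_vesselness, moving_vesselness,
                           mask, cfg = reg_config(), verbose = FALSE) {
  stopifnot(all(vol_dim(fixed) == vol_dim(moving)))
  mask_full <- dilate_mask(as_mask_array(mask), 2L)
  trace <- list()
  T_prev <- NULL
  for (li in seq_along(cfg$levels)) {
    lv <- cfg$levels[[li]]
    f <- downsample_volume(fixed, lv$factor)
    m <- downsample_volume(moving, lv$factor)
    fv <- downsample_volume(fixed_vesselness, lv$factor)
    mv <- downsample_volume(moving_vesselness, lv$factor)
    mk <- downsample_volume(lm_volume(mask_full * 1, fixed$spacing,
                                      fixed$origin), lv$factor,
                            method = "nearest")
    mask_vec <- as.numeric(as.vector(mk$data) > 0.5)
    if (sum(mask_vec) == 0) mask_vec <- rep(1, prod(vol_dim(f)))
    shape <- vol_dim(f)

    T <- if (is.null(T_prev)) {
      bspline_identity(shape, f$spacing, f$origin, lv$knot)
    } else {
      # carry the previous level's dense field onto this level's lattice
      prev_dvf <- bspline_dvf(T_prev)
      pts <- grid_points(shape, f$spacing, f$origin)
      u_arr <- array(0, c(shape, 3L))
      for (c in 1:3)
        u_arr[, , , c] <- array(
          interp_trilinear(prev_dvf$data[, , , c], prev_dvf$spacing,
                           prev_dvf$origin, pts), shape)
      fit_bspline_to_field(u_arr, shape, f$spacing, f$origin, lv$knot)
    }
    B <- bspline_bases(T)
    Im <- moving_with_grad(m)
    Mv <- moving_with_grad(mv)

    cg <- reg_cost_grad(T, f, Im, fv, Mv, mask_vec, cfg$weights, B)
    cost <- cg$total
    step <- cfg$step0 * lv$knot / 8
    trace[[length(trace) + 1L]] <- data.frame(level = li, iter = 0L,
                                              cost = cost,
                                              n_folded = cg$n_folded)
    for (it in seq_len(lv$iters)) {
      gmax <- max(abs(cg$grad))
      if (!is.finite(cost)) stop("non-finite registration cost")
      if (gmax == 0) break
      dir <- -cg$grad / gmax # step in mm units of control displacement
      accepted <- FALSE
      s <- step
      for (bt in 1:12) {
        T_try <- T
        T_try$coef <- T$coef + s * dir
        cg_try <- reg_cost_grad(T_try, f, Im, fv, Mv, mask_vec, cfg$weights,
                                B, grad = FALSE)
        if (is.finite(cg_try$total) && cg_try$total < cost) {
          accepted <- TRUE
          break
        }
        s <- s / 2
      }
      if (!accepted) break
      rel <- (cost - cg_try$total) / max(cost, 1e-12)
      T <- T_try
      cg <- reg_cost_grad(T, f, Im, fv, Mv, mask_vec, cfg$weights, B)
      cost <- cg$total
      step <- min(s * 1.5, cfg$step0 * lv$knot / 2)
      trace[[length(trace) + 1L]] <- data.frame(level = li, iter = it,
                                                cost = cost,
                                                n_folded = cg$n_folded)
      if (rel < cfg$tol) break
    }
    if (verbose)
      message(sprintf("level %d (factor %.2g): cost %.6g after %d iters",
                      li, lv$factor, cost, nrow(do.call(rbind, trace))))
    T_prev <- T
  }
  # resample final transform onto the full-resolution grid
  final <- if (all(T_prev$shape == vol_dim(fixed))) T_prev else {
    prev_dvf <- bspline_dvf(T_prev)
    shape <- vol_dim(fixed)
    pts <- grid_points(shape, fixed$spacing, fixed$origin)
    u_arr <- array(0, c(shape, 3L))
    for (c in 1:3)
      u_arr[, , , c] <- array(
        interp_trilinear(prev_dvf$data[, , , c], prev_dvf$spacing,
                         prev_dvf$origin, pts), shape)
    fit_bspline_to_field(u_arr, shape, fixed$spacing, fixed$origin,
                         cfg$levels[[length(cfg$levels)]]$knot)
  }
  dvf <- bspline_dvf(final)
  dvf$direction <- "fixed_to_moving"
  tr <- do.call(rbind, trace)
  fold_frac <- tr$n_folded[nrow(tr)] / max(sum(mask_full), 1)
  if (fold_frac > 0.1)
    warning(sprintf("fold fraction %.1f%% inside the mask", 100 * fold_frac))
  list(transform = final, dvf = dvf, trace = tr)
}
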