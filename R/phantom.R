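# Synthetic phantom generator: analytic deformation fields with closed-form
# deformation gradients, lobe-labelled two-lung geometry with a branching
# vessel tree, tissue-volume-conserving expiration/inspiration image pairs,
# and staged cohorts with a controllable regional-expansion trend.

# run expr with a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Affine displacement field u(x) = (A - I) x
#'
#' The deformation gradient of the resulting field equals `A` at every
#' interior voxel, so downstream maps have closed forms (J = det A).
#'
#' @param A 3x3 matrix with positive determinant.
#' @param shape integer length-3 grid shape.
#' @param spacing,origin grid geometry (mm).
#' @return an [lm_dvf()].
#' @export
make_affine_dvf <- function(A, shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  if (det(A) <= 0) stop("det(A) must be positive (invertible deformation)")
  pts <- grid_points(shape, spacing, origin)
  u <- pts %*% t(A - diag(3))
  lm_dvf(array(u, c(shape, 3L)), spacing, origin, direction = "affine")
}

#' Sinusoidal displacement field along one axis
#'
#' u has the single nonzero component `u_axis(x) = a * sin(k * x_axis)`, so
#' analytically F = I + a k cos(k x_axis) e_axis e_axis' and
#' J(x) = 1 + a k cos(k x_axis). Invertibility requires |a k| < 1.
#'
#' @param a amplitude (mm).
#' @param k wavenumber (1/mm).
#' @param axis axis index 1..3 along which the wave runs (and displaces).
#' @param shape,spacing,origin grid geometry.
#' @return an [lm_dvf()].
#' @export
make_sinusoidal_dvf <- function(a, k, axis, shape, spacing = c(1, 1, 1),
                                origin = c(0, 0, 0)) {
  if (abs(a * k) >= 1) stop("|a*k| must be < 1 for an invertible deformation")
  stopifnot(axis %in% 1:3)
  pts <- grid_points(shape, spacing, origin)
  u <- matrix(0, nrow(pts), 3)
  u[, axis] <- a * sin(k * pts[, axis])
  lm_dvf(array(u, c(shape, 3L)), spacing, origin, direction = "sinusoidal")
}

#' Analytic Jacobian of a sinusoidal field
#'
#' Closed form J(x) = 1 + a k cos(k x_axis) on the same grid, for use as
#' ground truth in convergence studies.
#'
#' @inheritParams make_sinusoidal_dvf
#' @return an [lm_volume()].
#' @export
sinusoidal_jacobian_analytic <- function(a, k, axis, shape, spacing = c(1, 1, 1),
                                         origin = c(0, 0, 0)) {
  pts <- grid_points(shape, spacing, origin)
  J <- 1 + a * k * cos(k * pts[, axis])
  lm_volume(array(J, shape), spacing, origin, semantics = "J")
}

#' Smooth radial expansion/contraction field with low-frequency modulation
#'
#' A global scaling about `center` (`u = g (x - c)`, giving J near (1+g)^3)
#' plus a divergence-oscillating sinusoidal perturbation that creates spatial
#' J heterogeneity while leaving the domain-mean J approximately unchanged.
#'
#' @param scale linear scale factor g; the bulk Jacobian is (1+g)^3.
#' @param center mm coordinates of the expansion centre.
#' @param mod_amp amplitude (mm) of the modulation; keep small relative to
#'   1/mod_k so the field stays invertible.
#' @param mod_k modulation wavenumber (1/mm).
#' @param phase length-3 phase offsets for the modulation.
#' @param shape,spacing,origin grid geometry.
#' @return an [lm_dvf()].
#' @export
make_radial_dvf <- function(scale, center, shape, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0), mod_amp = 0, mod_k = 0.1,
                            phase = c(0, 0, 0)) {
  pts <- grid_points(shape, spacing, origin)
  u <- sweep(pts, 2, center) * scale
  if (mod_amp != 0) {
    u[, 1] <- u[, 1] + mod_amp * sin(mod_k * pts[, 2] + phase[1])
    u[, 2] <- u[, 2] + mod_amp * sin(mod_k * pts[, 3] + phase[2])
    u[, 3] <- u[, 3] + mod_amp * sin(mod_k * pts[, 1] + phase[3])
  }
  lm_dvf(array(u, c(shape, 3L)), spacing, origin,
         direction = "expiration_to_inspiration")
}

#' Two-lung lobe-labelled phantom with a branching vessel tree
#'
#' Builds two disjoint ellipsoidal "lungs"; the right lung is split by two
#' oblique planes into upper/middle/lower lobes (labels 1 = RUL, 2 = RML,
#' 3 = RLL) and the left by one plane (4 = LUL, 5 = LLL). A three-generation
#' binary-branching tube tree (radius decay 0.7 per generation) inside each
#' lung provides the vessel mask. Deterministic for a given seed.
#'
#' @param shape integer length-3 grid shape (48^3 or larger recommended).
#' @param spacing voxel spacing in mm.
#' @param seed integer RNG seed controlling branch angles.
#' @return list with `lobes` ([lm_volume()], labels 0..5), `vessel_mask`,
#'   `lung_mask` (binary [lm_volume()]s), and `centers` (2x3 mm matrix of
#'   lung centroids, right then left).
#' @export
make_lung_phantom <- function(shape, spacing = c(1, 1, 1), seed = 1L) {
  shape <- rep_len(as.integer(shape), 3L)
  if (any(shape < 32L))
    stop("grid too small for a five-lobe phantom: need at least 32 voxels per axis")
  spacing <- rep_len(spacing, 3L)
  ext <- shape * spacing
  pts <- grid_points(shape, spacing, c(0, 0, 0))
  # right lung centred left-of-midline on axis 1 (radiological convention
  # is irrelevant for the phantom; labels are what matters)
  cR <- ext * c(0.30, 0.50, 0.50)
  cL <- ext * c(0.70, 0.50, 0.50)
  semi <- ext * c(0.155, 0.26, 0.33)
  inside <- function(ctr) {
    ((pts[, 1] - ctr[1]) / semi[1])^2 + ((pts[, 2] - ctr[2]) / semi[2])^2 +
      ((pts[, 3] - ctr[3]) / semi[3])^2 <= 1
  }
  inR <- inside(cR); inL <- inside(cL)
  lobes <- numeric(nrow(pts))
  # oblique split planes: score increases with z, tilted in x and y
  n1 <- c(0.25, 0.15, 1); n1 <- n1 / sqrt(sum(n1^2))
  sR <- (pts[, 1] - cR[1]) * n1[1] + (pts[, 2] - cR[2]) * n1[2] +
    (pts[, 3] - cR[3]) * n1[3]
  lobes[inR & sR > 0.30 * semi[3]] <- 1 # RUL
  lobes[inR & sR <= 0.30 * semi[3] & sR > -0.15 * semi[3]] <- 2 # RML
  lobes[inR & sR <= -0.15 * semi[3]] <- 3 # RLL
  n2 <- c(-0.2, 0.1, 1); n2 <- n2 / sqrt(sum(n2^2))
  sL <- (pts[, 1] - cL[1]) * n2[1] + (pts[, 2] - cL[2]) * n2[2] +
    (pts[, 3] - cL[3]) * n2[3]
  lobes[inL & sL > 0.05 * semi[3]] <- 4 # LUL
  lobes[inL & sL <= 0.05 * semi[3]] <- 5 # LLL
  if (any(tabulate(lobes[lobes > 0], 5L) == 0))
    stop("grid too small: an empty lobe was produced; use a larger shape")
  lung <- inR | inL

  # vessel tree: recursive binary branching from each lung apex region
  segs <- with_seed(seed, {
    out <- list()
    for (ctr in list(cR, cL)) {
      root <- ctr + c(0, 0, 0.55 * semi[3])
      dir0 <- c(0, 0, -1)
      len0 <- 0.55 * semi[3]
      r0 <- max(1.6 * max(spacing), 0.035 * ext[3])
      queue <- list(list(p = root, d = dir0, len = len0, r = r0, gen = 1L))
      while (length(queue)) {
        s <- queue[[1]]; queue <- queue[-1]
        q <- s$p + s$d * s$len
        out[[length(out) + 1L]] <- c(s$p, q, s$r)
        if (s$gen < 3L) {
          for (b in 1:2) {
            ang <- runif(1, 25, 50) * pi / 180
            az <- runif(1, 0, 2 * pi)
            # rotate parent direction by ang about a random azimuth
            d <- s$d
            perp1 <- c(d[2] - d[3], d[3] - d[1], d[1] - d[2])
            perp1 <- perp1 / sqrt(sum(perp1^2))
            perp2 <- c(d[2] * perp1[3] - d[3] * perp1[2],
                       d[3] * perp1[1] - d[1] * perp1[3],
                       d[1] * perp1[2] - d[2] * perp1[1])
            nd <- cos(ang) * d + sin(ang) * (cos(az) * perp1 + sin(az) * perp2)
            nd <- nd / sqrt(sum(nd^2))
            queue[[length(queue) + 1L]] <-
              list(p = q, d = nd, len = 0.72 * s$len, r = 0.7 * s$r,
                   gen = s$gen + 1L)
          }
        }
      }
    }
    out
  })
  vessel <- rasterize_tubes(segs, shape, spacing)
  vessel <- vessel & array(lung, shape)

  list(lobes = lm_volume(array(lobes, shape), spacing, semantics = "label"),
       vessel_mask = lm_volume(array(as.numeric(vessel), shape), spacing,
                               semantics = "label"),
       lung_mask = lm_volume(array(as.numeric(lung), shape), spacing,
                             semantics = "label"),
       centers = rbind(cR, cL))
}

# mark voxels within radius of any line segment; segs are c(p, q, r) vectors
rasterize_tubes <- function(segs, shape, spacing) {
  out <- array(FALSE, shape)
  for (s in segs) {
    p <- s[1:3]; q <- s[4:6]; r <- s[7]
    lo <- pmax(floor((pmin(p, q) - r) / spacing) + 1, 1)
    hi <- pmin(ceiling((pmax(p, q) + r) / spacing) + 1, shape)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    px <- (ii - 1) * spacing[1]; py <- (jj - 1) * spacing[2]
    pz <- (kk - 1) * spacing[3]
    g <- as.matrix(expand.grid(x = px, y = py, z = pz))
    v <- q - p; L2 <- sum(v^2)
    t <- if (L2 > 0) pmin(pmax(((g[, 1] - p[1]) * v[1] + (g[, 2] - p[2]) * v[2] +
                                  (g[, 3] - p[3]) * v[3]) / L2, 0), 1) else 0
    dx <- g[, 1] - (p[1] + t * v[1]); dy <- g[, 2] - (p[2] + t * v[2])
    dz <- g[, 3] - (p[3] + t * v[3])
    hit <- dx^2 + dy^2 + dz^2 <= r^2
    sub <- array(FALSE, c(length(ii), length(jj), length(kk)))
    sub[hit] <- TRUE
    out[ii, jj, kk] <- out[ii, jj, kk] | sub
  }
  out
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves x = y - u(x) for every grid point y, i.e. computes phi^-1 for
#' phi(x) = x + u(x). Iterates until the maximum update falls below `tol`
#' voxels or `max_iter` iterations.
#'
#' @param dvf an [lm_dvf()].
#' @param tol convergence tolerance in voxels (default 1e-3).
#' @param max_iter iteration cap (default 50).
#' @return n x 3 matrix of phi^-1 evaluated at every grid point (mm),
#'   in column-major voxel order.
#' @export
invert_dvf_points <- function(dvf, tol = 1e-3, max_iter = 50L) {
  shape <- dvf_dim(dvf)
  y <- grid_points(shape, dvf$spacing, dvf$origin)
  x <- y
  hmin <- min(dvf$spacing)
  for (it in seq_len(max_iter)) {
    ux <- vapply(1:3, function(c)
      interp_trilinear(dvf$data[, , , c], dvf$spacing, dvf$origin, x),
      numeric(nrow(x)))
    xn <- y - ux
    step <- max(abs(xn - x)) / hmin
    x <- xn
    if (step < tol) break
  }
  x
}

#' Synthesize a tissue-volume-conserving expiration/inspiration image pair
#'
#' The expiration tissue-fraction image takes fixed values per region
#' (parenchyma 0.2, vessels 1.0, soft tissue outside the lung 1.0). The
#' inspiration image is the expiration image carried through the deformation
#' with its tissue fraction divided by the local Jacobian, so total lung
#' tissue volume is conserved — the intensity model under which the
#' tissue-volume-difference registration cost is zero at the true transform.
#' HU values follow the linear air/tissue mixture
#' HU = hu_air + fraction * (hu_tissue - hu_air).
#'
#' @param lung_mask,vessel_mask binary [lm_volume()]s on a common grid.
#' @param dvf the expiration-to-inspiration [lm_dvf()] on the same grid.
#' @param hu_air,hu_tissue HU endpoints of the mixture model.
#' @param frac_parenchyma,frac_vessel expiration tissue fractions.
#' @return list with `ct_expiration`, `ct_inspiration` (HU [lm_volume()]s),
#'   `frac_expiration`, `frac_inspiration` (fraction volumes), and
#'   `insp_lung_mask` (the lung region in inspiration geometry).
#' @export
synthesize_image_pair <- function(lung_mask, vessel_mask, dvf,
                                  hu_air = -1000, hu_tissue = 55,
                                  frac_parenchyma = 0.2, frac_vessel = 1.0) {
  shape <- vol_dim(lung_mask)
  stopifnot(all(shape == dvf_dim(dvf)))
  lung <- lung_mask$data > 0.5
  vessel <- vessel_mask$data > 0.5
  f_exp <- array(1.0, shape) # soft tissue background
  f_exp[lung] <- frac_parenchyma
  f_exp[vessel & lung] <- frac_vessel

  J <- jacobian_map(principal_stretches(deformation_gradient(dvf)))$data
  if (any(!is.finite(J[lung])) || any(J[lung] <= 0))
    stop("deformation folds inside the lung (J <= 0); cannot conserve tissue")

  xinv <- invert_dvf_points(dvf)
  # sample a lung-extended fraction field: outside-lung voxels take the
  # parenchyma value so interpolation does not blur the bright soft-tissue
  # background across the lung boundary (which would break conservation)
  f_ext <- f_exp
  f_ext[!lung] <- frac_parenchyma
  f_at <- interp_trilinear(f_ext, dvf$spacing, dvf$origin, xinv)
  J_at <- interp_trilinear(J, dvf$spacing, dvf$origin, xinv)
  lung_at <- interp_trilinear(array(as.numeric(lung), shape), dvf$spacing,
                              dvf$origin, xinv)
  f_insp <- array(1.0, shape)
  inl <- lung_at > 0.5
  f_insp[inl] <- f_at[inl] / pmax(J_at[inl], 1e-6)
  f_insp <- pmin(pmax(f_insp, 0), 1)

  to_hu <- function(f) hu_air + f * (hu_tissue - hu_air)
  sp <- lung_mask$spacing; or <- lung_mask$origin
  list(ct_expiration = lm_volume(to_hu(f_exp), sp, or, "HU"),
       ct_inspiration = lm_volume(to_hu(f_insp), sp, or, "HU"),
       frac_expiration = lm_volume(f_exp, sp, or, "density"),
       frac_inspiration = lm_volume(f_insp, sp, or, "density"),
       insp_lung_mask = lm_volume(array(as.numeric(inl), shape), sp, or,
                                  "label"))
}

#' Generate a staged synthetic cohort with a decreasing expansion trend
#'
#' Each subject in stage s (0-indexed, emulating disease-severity groups 0-4)
#' receives a smooth expansion field whose lung-mean Jacobian is drawn from
#' Normal(stage_expansion_means[s+1], noise_sd^2). Stage means must be
#' strictly decreasing and all > 1 — the regional-trend structure under test.
#' Deterministic for a given seed.
#'
#' @param n_per_stage subjects per stage.
#' @param stage_expansion_means 5 strictly decreasing lung-mean J targets.
#' @param noise_sd between-subject SD of the target mean J.
#' @param seed integer seed.
#' @param shape,spacing phantom grid geometry.
#' @param images if FALSE, skip the (expensive) image-pair synthesis and
#'   return geometry + true DVF only.
#' @return list of subjects; each has `id`, `stage`, `target_J`, `lobes`,
#'   `vessel_mask`, `lung_mask`, `true_dvf`, and (if `images`) the CT pair.
#' @export
make_cohort <- function(n_per_stage, stage_expansion_means =
                          c(1.8, 1.6, 1.4, 1.2, 1.05),
                        noise_sd = 0.05, seed = 1L, shape = c(64, 64, 64),
                        spacing = c(1, 1, 1), images = TRUE) {
  m <- stage_expansion_means
  if (any(diff(m) >= 0)) stop("stage_expansion_means must be strictly decreasing")
  if (any(m <= 1)) stop("stage_expansion_means must all exceed 1")
  n_stages <- length(m)
  targets <- with_seed(seed, {
    matrix(rnorm(n_stages * n_per_stage, rep(m, each = n_per_stage), noise_sd),
           nrow = n_per_stage)
  })
  targets <- pmax(targets, 1.01)
  subjects <- list()
  for (s in seq_len(n_stages)) {
    for (i in seq_len(n_per_stage)) {
      sid <- sprintf("S%d_%02d", s - 1, i)
      subj_seed <- (seed * 131L + s * 17L + i) %% .Machine$integer.max
      ph <- make_lung_phantom(shape, spacing, seed = subj_seed)
      tgt <- targets[i, s]
      g <- tgt^(1 / 3) - 1
      ctr <- colMeans(ph$centers)
      dvf <- make_radial_dvf(g, ctr, shape, spacing,
                             mod_amp = 0.25 * min(shape * spacing) * g * 0.15,
                             mod_k = 2 * pi / (shape[1] * spacing[1]),
                             phase = with_seed(subj_seed + 1L, runif(3, 0, 2 * pi)))
      subj <- list(id = sid, stage = s - 1L, target_J = tgt,
                   lobes = ph$lobes, vessel_mask = ph$vessel_mask,
                   lung_mask = ph$lung_mask, true_dvf = dvf)
      if (images) {
        pair <- synthesize_image_pair(ph$lung_mask, ph$vessel_mask, dvf)
        subj$ct_expiration <- pair$ct_expiration
        subj$ct_inspiration <- pair$ct_inspiration
      }
      subjects[[length(subjects) + 1L]] <- subj
    }
  }
  subjects
}
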