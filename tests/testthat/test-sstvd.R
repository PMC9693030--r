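test_that("HU-to-density conversion is the clamped linear air/tissue mixture", {
  ct <- lm_volume(array(c(-1000, 55, -472.5, -2000, 500), c(5, 1, 1)))
  d <- hu_to_density(lm_volume(array(c(-1000, 55, -472.5, -2000, 500),
                                     c(5, 1, 1))))
  expect_equal(as.vector(d$data), c(0, 1, 0.5, 0, 1))
})

test_that("similarity costs vanish at perfect alignment and match closed forms", {
  n <- 16
  T <- bspline_identity(c(n, n, n), knot = 4)
  img <- lm_volume(array(stats::runif(n^3), c(n, n, n)))
  expect_equal(as.numeric(sstvd_cost(img, img, T)), 0)
  expect_equal(ssvmd_cost(img, img, T), 0)
  # uniform images: mean (0.2 - 0.4)^2 = 0.04
  If <- lm_volume(array(0.2, c(n, n, n)))
  Im <- lm_volume(array(0.4, c(n, n, n)))
  expect_equal(as.numeric(sstvd_cost(If, Im, T)), 0.04, tolerance = 1e-12)
  # constant vesselness difference c -> cost c^2
  Fv <- lm_volume(array(0.3, c(n, n, n)))
  Mv <- lm_volume(array(0.1, c(n, n, n)))
  expect_equal(ssvmd_cost(Fv, Mv, T), 0.04, tolerance = 1e-12)
  # translation recovers a translated vesselness image
  mvt <- lm_volume(array(0, c(n, n, n)))
  fv <- lm_volume(array(0, c(n, n, n)))
  fv$data[6:10, 6:10, 6:10] <- 1
  mvt$data[8:12, 6:10, 6:10] <- 1
  Ttr <- T; Ttr$coef[, , , 1] <- 2 # u = +2 mm along x everywhere
  expect_lt(ssvmd_cost(fv, mvt, Ttr), 1e-10)
})

test_that("volume-preserving uniform stretch leaves the tissue-volume cost unchanged", {
  # uniform density images and a volume-preserving affine transform: the
  # Jacobian factor exactly compensates the intensity
  n <- 24
  If <- lm_volume(array(0.3, c(n, n, n)))
  Im <- lm_volume(array(0.3, c(n, n, n)))
  A <- diag(c(1.25, 0.8, 1)) # det = 1
  u <- grid_points(c(n, n, n)) %*% t(A - diag(3))
  Tfit <- lungmech:::fit_bspline_to_field(array(u, c(n, n, n, 3)),
                                          c(n, n, n), c(1, 1, 1), c(0, 0, 0),
                                          4)
  # evaluate away from the boundary where warped samples stay inside
  mask <- interior_mask(c(n, n, n), 6L)
  c_id <- as.numeric(sstvd_cost(If, Im, bspline_identity(c(n, n, n), knot = 4),
                                mask))
  c_vp <- as.numeric(sstvd_cost(If, Im, Tfit, mask))
  expect_equal(c_id, 0)
  expect_lt(c_vp, 1e-6)
})

test_that("elastic regularization is zero for rigid shifts and matches the quadratic closed form", {
  n <- 16
  T <- bspline_identity(c(n, n, n), knot = 4)
  expect_equal(elastic_cost(T), 0)
  Ttr <- T; Ttr$coef[, , , 2] <- 3 # constant translation
  expect_lt(elastic_cost(Ttr), 1e-18)
  # u_x = x^2: L u_x = -0.75 * 2 - 0.25 * 2 = -2, so ||Lu||^2 = 4
  co <- grid_coords(c(n, n, n))
  ux <- array(rep(co$x^2, n * n), c(n, n, n))
  ul <- list(ux, array(0, c(n, n, n)), array(0, c(n, n, n)))
  Lu <- lungmech:::apply_elastic_L(ul, c(1, 1, 1))
  int <- interior_mask(c(n, n, n))
  expect_lt(max(abs(Lu[[1]][int] + 2)), 1e-9)
  expect_equal(max(abs(Lu[[2]][int])), 0)
})

test_that("the analytic cost gradient agrees with finite differences", {
  set.seed(4)
  n <- 12
  gs <- lungmech:::gauss_smooth
  f <- lm_volume(gs(array(stats::runif(n^3), c(n, n, n)), 2))
  m <- lm_volume(gs(array(stats::runif(n^3), c(n, n, n)), 2))
  fv <- lm_volume(gs(array(stats::runif(n^3), c(n, n, n)), 2))
  mv <- lm_volume(gs(array(stats::runif(n^3), c(n, n, n)), 2))
  T <- bspline_identity(c(n, n, n), knot = 4)
  T$coef <- T$coef + array(stats::rnorm(length(T$coef), 0, 0.2), dim(T$coef))
  B <- lungmech:::bspline_bases(T)
  Im <- lungmech:::moving_with_grad(m); Mv <- lungmech:::moving_with_grad(mv)
  mask <- rep(1, n^3); w <- c(1, 1, 0.05)
  cg <- lungmech:::reg_cost_grad(T, f, Im, fv, Mv, mask, w, B)
  idx <- order(-abs(cg$grad))[1:6] # check the largest-gradient coefficients
  eps <- 1e-5
  for (i in idx) {
    Tp <- T; Tp$coef[i] <- Tp$coef[i] + eps
    Tm <- T; Tm$coef[i] <- Tm$coef[i] - eps
    fd <- (lungmech:::reg_cost_grad(Tp, f, Im, fv, Mv, mask, w, B,
                                    grad = FALSE)$total -
             lungmech:::reg_cost_grad(Tm, f, Im, fv, Mv, mask, w, B,
                                      grad = FALSE)$total) / (2 * eps)
    expect_lt(abs(fd - cg$grad[i]) / max(abs(fd), 1e-8), 0.15)
  }
})

test_that("registering an image to itself stays near the identity with a non-increasing trace", {
  set.seed(6)
  n <- 24
  gs <- lungmech:::gauss_smooth
  img <- lm_volume(gs(array(stats::runif(n^3), c(n, n, n)), 1.5))
  zero_v <- lm_volume(array(0, c(n, n, n)))
  mask <- lm_volume(array(1, c(n, n, n)))
  cfg <- reg_config(levels = list(list(factor = 0.5, knot = 8, iters = 10),
                                  list(factor = 1, knot = 8, iters = 10)))
  res <- register_sstvd(img, img, zero_v, zero_v, mask, cfg)
  expect_lt(max(abs(res$dvf$data)), 0.1) # < 0.1 voxel at 1 mm spacing
  for (lv in split(res$trace$cost, res$trace$level))
    expect_true(all(diff(lv) <= 1e-12))
})

test_that("registration recovers a known smooth deformation on a small phantom pair", {
  ph <- small_phantom()
  ctr <- colMeans(ph$centers)
  dvf <- make_radial_dvf(0.1, ctr, c(48, 48, 48), mod_amp = 0.6,
                         mod_k = 2 * pi / 48, phase = c(1, 2, 3))
  pair <- synthesize_image_pair(ph$lung_mask, ph$vessel_mask, dvf)
  If <- hu_to_density(pair$ct_expiration)
  Im <- hu_to_density(pair$ct_inspiration)
  fv <- vesselness(If, scales = c(1, 2))
  mv <- vesselness(Im, scales = c(1, 2))
  cfg <- reg_config(levels = list(list(factor = 0.25, knot = 8, iters = 40),
                                  list(factor = 0.5, knot = 8, iters = 30),
                                  list(factor = 1, knot = 4, iters = 15)))
  res <- register_sstvd(If, Im, fv, mv, ph$lung_mask, cfg)
  lung <- ph$lung_mask$data > 0.5
  err <- sqrt(apply((res$dvf$data - dvf$data)^2, 1:3, sum))
  u0 <- sqrt(apply(dvf$data^2, 1:3, sum))
  expect_lt(mean(err[lung]), 1) # sub-voxel mean recovery
  expect_lt(mean(err[lung]), 0.5 * mean(u0[lung])) # clear improvement
  # final cost at most the identity-transform cost
  c_id <- as.numeric(sstvd_cost(If, Im,
                                bspline_identity(c(48, 48, 48), knot = 4),
                                lungmech:::dilate_mask(lung, 2L))) +
    0.05 * 0 # elastic at identity is zero
  expect_lt(utils::tail(res$trace$cost, 1), c_id)
})
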