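test_that("affine fields reproduce their generating matrix exactly at interior voxels", {
  A <- diag(c(1.2, 1.1, 0.9))
  dvf <- make_affine_dvf(A, c(10, 10, 10))
  tf <- deformation_gradient(dvf)
  int <- interior_mask(c(10, 10, 10))
  for (r in 1:3) for (c in 1:3) {
    Frc <- tf$F[, , , r, c]
    expect_lt(max(abs(Frc[int] - A[r, c])), 1e-12)
  }
  J <- jacobian_map(principal_stretches(tf))
  expect_lt(max(abs(J$data[int] - prod(diag(A)))), 1e-10)

  # identity and uniform doubling
  z <- lm_dvf(array(0, c(6, 6, 6, 3)))
  tfz <- deformation_gradient(z)
  expect_equal(tfz$F[3, 3, 3, , ], diag(3))
  J2 <- jacobian_map(principal_stretches(deformation_gradient(
    make_affine_dvf(2 * diag(3), c(8, 8, 8)))))
  expect_lt(max(abs(J2$data[interior_mask(c(8, 8, 8))] - 8)), 1e-10)
})

test_that("degenerate deformations are rejected, tiny grids error", {
  expect_error(make_affine_dvf(diag(c(-1, 1, 1)), c(6, 6, 6)), "det")
  expect_error(make_sinusoidal_dvf(a = 2, k = 0.6, axis = 1, c(8, 8, 8)),
               "invertible")
  expect_error(deformation_gradient(lm_dvf(array(0, c(2, 5, 5, 3)))),
               "at least 3")
})

test_that("principal stretches match eigen() and satisfy the determinant identity", {
  set.seed(42)
  for (rep in 1:20) {
    F1 <- matrix(rnorm(9, sd = 0.4), 3, 3) + diag(3)
    if (det(F1) <= 0) next
    dvf <- make_affine_dvf(F1, c(6, 6, 6))
    sf <- principal_stretches(deformation_gradient(dvf))
    lam <- c(sf$l1[3, 3, 3], sf$l2[3, 3, 3], sf$l3[3, 3, 3])
    # independent route: base eigen on F'F
    ev <- sqrt(sort(eigen(t(F1) %*% F1, symmetric = TRUE)$values,
                    decreasing = TRUE))
    expect_equal(lam, ev, tolerance = 1e-10)
    expect_true(all(diff(lam) <= 1e-12))
    # lambda1*lambda2*lambda3 == det F
    expect_lt(abs(prod(lam) - det(F1)), 1e-10)
    expect_lt(max(abs(jacobian_map(sf)$data - sf$detF), na.rm = TRUE), 1e-8)
  }
})

test_that("stretch-derived maps are rotation invariant", {
  set.seed(7)
  A <- diag(c(1.5, 1.2, 0.8))
  for (rep in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    sA <- principal_stretches(deformation_gradient(
      make_affine_dvf(A, c(6, 6, 6))))
    sRA <- principal_stretches(deformation_gradient(
      make_affine_dvf(R %*% A, c(6, 6, 6))))
    i <- c(3, 3, 3)
    expect_equal(c(sA$l1[3, 3, 3], sA$l2[3, 3, 3], sA$l3[3, 3, 3]),
                 c(sRA$l1[3, 3, 3], sRA$l2[3, 3, 3], sRA$l3[3, 3, 3]),
                 tolerance = 1e-10)
  }
  # pure rotation: all stretches are 1
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sR <- principal_stretches(deformation_gradient(make_affine_dvf(R, c(6, 6, 6))))
  expect_equal(c(sR$l1[3, 3, 3], sR$l2[3, 3, 3], sR$l3[3, 3, 3]),
               c(1, 1, 1), tolerance = 1e-10)
})

test_that("ADI and SRI take their defining values on canonical stretch patterns", {
  cases <- list(
    list(A = 2 * diag(3), adi = 0, sri = NA_real_), # isotropic: SRI undefined
    list(A = diag(c(2, 1, 1)), adi = 1, sri = 1),   # rod
    list(A = diag(c(2, 2, 1)), adi = 1, sri = 0))   # slab
  for (cs in cases) {
    m <- biomech_maps(make_affine_dvf(cs$A, c(8, 8, 8)))
    i <- 4
    expect_equal(m$ADI$data[i, i, i], cs$adi, tolerance = 1e-12)
    if (is.na(cs$sri)) {
      expect_true(is.na(m$SRI$data[i, i, i]))
      expect_false(m$sri_valid[i, i, i])
    } else {
      expect_equal(m$SRI$data[i, i, i], cs$sri, tolerance = 1e-12)
    }
  }
})

test_that("SRI stays in [0,1] and ADI nonnegative over random deformations", {
  set.seed(11)
  for (rep in 1:10) {
    F1 <- diag(3) + matrix(rnorm(9, sd = 0.3), 3, 3)
    if (det(F1) <= 0) next
    m <- biomech_maps(make_affine_dvf(F1, c(6, 6, 6)))
    sri <- m$SRI$data[m$sri_valid]
    expect_true(all(sri >= -1e-12 & sri <= 1 + 1e-12))
    expect_true(all(m$ADI$data[!is.na(m$ADI$data)] >= 0))
  }
})

test_that("alpha/beta share the sign of J - 1 and hit closed-form values", {
  m <- biomech_maps(make_affine_dvf(diag(c(2, 1, 1)), c(8, 8, 8)))
  expect_equal(m$alpha$data[4, 4, 4], 0, tolerance = 1e-12)
  expect_equal(m$beta$data[4, 4, 4], 1, tolerance = 1e-12)
  m2 <- biomech_maps(make_affine_dvf(diag(c(2, 2, 1)), c(8, 8, 8)))
  expect_equal(m2$alpha$data[4, 4, 4], 1, tolerance = 1e-12)
  expect_equal(m2$beta$data[4, 4, 4], 0, tolerance = 1e-12)
  # isotropic contraction: ratios are 1, so alpha = beta = 0
  m3 <- biomech_maps(make_affine_dvf(0.5 * diag(3), c(8, 8, 8)))
  expect_equal(m3$alpha$data[4, 4, 4], 0, tolerance = 1e-12)
  expect_equal(m3$beta$data[4, 4, 4], 0, tolerance = 1e-12)
  # contraction with anisotropy: both negative
  m4 <- biomech_maps(make_affine_dvf(diag(c(0.9, 0.7, 0.5)), c(8, 8, 8)))
  expect_lt(m4$alpha$data[4, 4, 4], 0)
  expect_lt(m4$beta$data[4, 4, 4], 0)
})

test_that("numerical J converges to the sinusoidal closed form at O(h^2)", {
  a <- 3; k <- 0.1
  errs <- vapply(c(1, 0.5, 0.25), function(h) {
    n <- round(20 / h) + 1
    shape <- c(n, 9, 9); sp <- c(h, 1, 1)
    dv <- make_sinusoidal_dvf(a, k, 1, shape, sp)
    Ja <- sinusoidal_jacobian_analytic(a, k, 1, shape, sp)
    J <- jacobian_map(principal_stretches(deformation_gradient(dv)))
    int <- interior_mask(shape)
    max(abs(J$data[int] - Ja$data[int]))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3.3)
  expect_gt(errs[2] / errs[3], 3.3)
  # at 1 mm and a*k = 0.3 the voxelwise error is below 1e-3
  dv <- make_sinusoidal_dvf(3, 0.1, 1, c(41, 9, 9))
  Ja <- sinusoidal_jacobian_analytic(3, 0.1, 1, c(41, 9, 9))
  J <- jacobian_map(principal_stretches(deformation_gradient(dv)))
  int <- interior_mask(c(41, 9, 9))
  expect_lt(max(abs(J$data[int] - Ja$data[int])), 1e-3)
  # amplitude zero: J identically 1
  dv0 <- make_sinusoidal_dvf(0, 0.1, 1, c(9, 9, 9))
  expect_equal(max(abs(dv0$data)), 0)
})
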