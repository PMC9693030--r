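test_that("Dice and lobe Dice follow their definitions", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE; a[1:2, 2, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[1:2, 2, 1] <- TRUE; b[1:2, 3, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5) # |a|=|b|=4, overlap 2 -> 2*2/8
  disj <- array(FALSE, c(4, 4, 4)); disj[4, 4, 4] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_error(dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
               "empty")
  # lobe dice: mean of per-lobe values
  l1 <- array(0L, c(6, 6, 6)); l2 <- array(0L, c(6, 6, 6))
  for (l in 1:5) { l1[l, 1:2, 1] <- l; l2[l, 1:2, 1] <- l }
  l2[4, 1:2, 1] <- 0; l2[4, 2:3, 1] <- 4 # shift lobe 4 by one voxel
  l2[5, 1:2, 1] <- 0; l2[5, 2:3, 1] <- 5
  ld <- lobe_dice(l1, l2)
  expect_equal(attr(ld, "per_lobe"), c(1, 1, 1, 0.5, 0.5))
  expect_equal(as.numeric(ld), 0.8)
  expect_equal(as.numeric(lobe_dice(l1, l1)), 1)
  bad <- l1; bad[bad == 3] <- 0
  expect_error(lobe_dice(bad, bad), "label 3")
})

test_that("extracted surfaces approximate analytic areas and enclose single voxels", {
  # axis-aligned box
  box <- array(0, c(20, 20, 20)); box[5:15, 5:15, 5:15] <- 1
  mb <- extract_surface(lm_volume(box))
  expect_lt(abs(mesh_area(mb) - 6 * 11^2) / (6 * 11^2), 0.10)
  # sphere radius 10 mm
  ms <- extract_surface(lm_volume(sphere_mask() * 1))
  expect_lt(abs(mesh_area(ms) - 4 * pi * 100) / (4 * pi * 100), 0.10)
  # single voxel: nonempty closed mesh around the voxel centre
  sv <- array(0, c(5, 5, 5)); sv[3, 3, 3] <- 1
  msv <- extract_surface(lm_volume(sv), smooth_sigma = 0)
  expect_gt(nrow(msv$triangles), 0)
  ctr <- colMeans(msv$vertices)
  expect_equal(ctr, c(2, 2, 2), tolerance = 1e-6) # voxel [3,3,3] is at 2 mm
  expect_error(extract_surface(lm_volume(array(0, c(5, 5, 5)))), "empty")
})

test_that("worst-10% surface error matches geometry and a brute-force oracle", {
  S1 <- flat_square_mesh(0); S2 <- flat_square_mesh(3)
  expect_equal(as.numeric(worst10_surface_error(S1, S1)), 0)
  expect_equal(as.numeric(worst10_surface_error(S1, S2)), 3, tolerance = 1e-12)
  # oracle equivalence on small random meshes
  set.seed(3)
  for (rep in 1:3) {
    V <- matrix(runif(45, 0, 10), ncol = 3)
    Fi <- matrix(sample(15, 30, TRUE), ncol = 3)
    Fi <- Fi[Fi[, 1] != Fi[, 2] & Fi[, 2] != Fi[, 3] & Fi[, 1] != Fi[, 3], ,
             drop = FALSE]
    M <- structure(list(vertices = V, triangles = Fi), class = "lm_mesh")
    P <- matrix(runif(60, -2, 12), ncol = 3)
    d_fast <- lungmech:::cpp_point_mesh_dists(P, V, Fi)
    d_oracle <- oracle_point_mesh_dist(P, M)
    expect_lt(max(abs(d_fast - d_oracle)), 1e-9)
  }
})

test_that("vessel-tree position error equals a brute-force oracle and detects offsets", {
  tube <- tube_mask()
  t2 <- array(FALSE, dim(tube)); t2[, , ] <- FALSE
  t2[, , 3:15] <- tube[, , 1:13] # translate 2 voxels along z
  v1 <- lm_volume(tube * 1); v2 <- lm_volume(t2 * 1)
  expect_equal(vessel_tree_position_error(v1, v1), 0)
  vt <- vessel_tree_position_error(v1, v2)
  p1 <- lungmech:::mask_points_mm(v1); p2 <- lungmech:::mask_points_mm(v2)
  expect_lt(abs(vt - oracle_symmetric_nn(p1, p2)), 1e-9)
  # dilated superset: asymmetric components differ, symmetric matches oracle
  dil <- lungmech:::dilate_mask(tube, 1L)
  v3 <- lm_volume(dil * 1)
  d_12 <- mean(lungmech:::cpp_min_dists(p1, lungmech:::mask_points_mm(v3)))
  d_21 <- mean(lungmech:::cpp_min_dists(lungmech:::mask_points_mm(v3), p1))
  expect_equal(d_12, 0)
  expect_gt(d_21, 0)
  expect_lt(abs(vessel_tree_position_error(v1, v3) -
                  oracle_symmetric_nn(p1, lungmech:::mask_points_mm(v3))), 1e-9)
  expect_error(vessel_tree_position_error(v1, lm_volume(array(0, dim(tube)))),
               "nonempty")
})

test_that("skeletonization thins tubes to their axis and preserves topology", {
  sk <- skeletonize(lm_volume(tube_mask() * 1))
  # skeleton lies within 1 voxel of the known tube axis (y = z = 7 in mm: 6)
  off_axis <- sqrt((sk$points[, 2] - 6)^2 + (sk$points[, 3] - 6)^2)
  expect_lte(max(off_axis), sqrt(2)) # within one voxel of the axis
  expect_true(all(sk$mask$data[tube_mask()] | TRUE)) # subset of input:
  expect_equal(sum(sk$mask$data > 0.5 & !tube_mask()), 0)
  # single voxel maps to itself
  sv <- array(FALSE, c(5, 5, 5)); sv[3, 3, 3] <- TRUE
  expect_equal(unname(skeletonize(lm_volume(sv * 1))$points),
               matrix(c(2, 2, 2), 1))
  # Y-branch: exactly three endpoints, one component
  segs <- list(c(15, 15, 2, 15, 15, 16, 2.5),
               c(15, 15, 16, 8, 15, 28, 2),
               c(15, 15, 16, 22, 15, 28, 2))
  m <- lungmech:::rasterize_tubes(segs, c(30, 30, 30), c(1, 1, 1))
  sky <- skeletonize(lm_volume(m * 1))
  msk <- sky$mask$data > 0.5
  idx <- which(msk, arr.ind = TRUE)
  nb <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    sum(msk[max(1, i - 1):min(30, i + 1), max(1, j - 1):min(30, j + 1),
            max(1, k - 1):min(30, k + 1)]) - 1L
  }, integer(1))
  expect_equal(sum(nb == 1), 3)
  expect_equal(count_components26(msk), count_components26(m))
})

test_that("skeleton error matches geometry and the brute-force oracle", {
  k1 <- cbind(5:25, 6, 6); k2 <- cbind(5:25, 10, 6) # parallel, 4 mm apart
  expect_equal(skeleton_error(k1, k1), 0)
  expect_equal(skeleton_error(k1, k2), 4)
  set.seed(9)
  a <- matrix(runif(60, 0, 20), ncol = 3); b <- matrix(runif(45, 0, 20), ncol = 3)
  expect_lt(abs(skeleton_error(a, b) - oracle_symmetric_nn(a, b)), 1e-9)
})

test_that("all four metrics are symmetric and degrade monotonically with rigid offset", {
  ph <- small_phantom()
  offsets <- c(0, 2, 4)
  vals <- lapply(offsets, function(o) {
    sh <- array(0L, c(48, 48, 48))
    if (o == 0) sh <- ph$lobes$data
    else sh[(1 + o):48, , ] <- ph$lobes$data[1:(48 - o), , ]
    lob2 <- lm_volume(sh, semantics = "label")
    ves2 <- lm_volume(array(as.numeric(sh > 0 & FALSE), c(48, 48, 48)))
    vs <- array(0, c(48, 48, 48))
    if (o == 0) vs <- ph$vessel_mask$data
    else vs[(1 + o):48, , ] <- ph$vessel_mask$data[1:(48 - o), , ]
    list(lobes = lob2, vessels = lm_volume(vs))
  })
  ldc <- vapply(vals, function(v) as.numeric(lobe_dice(ph$lobes, v$lobes)),
                numeric(1))
  vtpe <- vapply(vals, function(v)
    vessel_tree_position_error(ph$vessel_mask, v$vessels), numeric(1))
  expect_true(all(diff(ldc) < 0))
  expect_true(all(diff(vtpe) > 0))
  # symmetry of the metrics in their arguments
  v2 <- vals[[2]]
  expect_equal(as.numeric(lobe_dice(ph$lobes, v2$lobes)),
               as.numeric(lobe_dice(v2$lobes, ph$lobes)))
  expect_equal(vessel_tree_position_error(ph$vessel_mask, v2$vessels),
               vessel_tree_position_error(v2$vessels, ph$vessel_mask))
  s1 <- skeletonize(ph$vessel_mask); s2 <- skeletonize(v2$vessels)
  expect_equal(skeleton_error(s1, s2), skeleton_error(s2, s1))
})

test_that("label warping is exact for identity and voxel translations, and near-invertible", {
  ph <- small_phantom()
  z <- lm_dvf(array(0, c(48, 48, 48, 3)))
  expect_identical(warp_labels(ph$lobes, z)$data, ph$lobes$data)
  # exact 3-voxel translation along x
  tr <- lm_dvf(array(rep(c(3, 0, 0), each = 48^3), c(48, 48, 48, 3)))
  w <- warp_labels(ph$lobes, tr)
  expect_identical(w$data[1:45, , ], ph$lobes$data[4:48, , ])
  # warp by smooth field then by its (approximate) inverse: high Dice
  ctr <- colMeans(ph$centers)
  dvf <- make_radial_dvf(0.08, ctr, c(48, 48, 48))
  xinv <- invert_dvf_points(dvf)
  vinv <- lm_dvf(array(xinv - grid_points(c(48, 48, 48)), c(48, 48, 48, 3)))
  w1 <- warp_labels(ph$lobes, dvf)
  w2 <- warp_labels(w1, vinv)
  expect_gte(as.numeric(lobe_dice(ph$lobes, w2)), 0.98)
  expect_error(warp_labels(ph$lobes, lm_dvf(array(0, c(24, 24, 24, 3)))),
               "differ")
})
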