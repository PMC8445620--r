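# Displacement-field application and registration-evaluation metrics.

test_that("the identity field is a no-op for volumes and points", {
  vol <- intensity_volume(array(rnorm(5^3), c(5, 5, 5)))
  f0 <- make_displacement_field("identity", grid = vol)
  out <- apply_displacement_volume(vol, f0, interp = "nearest")
  expect_identical(out$data, vol$data)

  pts <- fiducial_set(c("a", "b"), rbind(c(1, 2, 3), c(2, 2, 2)))
  moved <- transform_points(pts, f0)
  expect_equal(moved$points, pts$points)
})

test_that("a one-voxel translation shifts the array under nearest sampling", {
  a <- array(rnorm(4^3), c(4, 4, 4))
  vol <- intensity_volume(a, background = 0)
  f <- make_displacement_field("translation", list(t = c(1, 0, 0)),
                               grid = vol)
  out <- apply_displacement_volume(vol, f, interp = "nearest")
  # pull-back: output voxel i samples input at i+1
  expect_equal(out$data[1:3, , ], a[2:4, , ])
  expect_true(all(out$data[4, , ] == 0))
})

test_that("trilinear warping is exact on an affine intensity ramp", {
  dm <- c(12, 12, 12)
  idx <- as.matrix(expand.grid(0:11, 0:11, 0:11))
  ramp <- array(idx[, 1] + 2 * idx[, 2] + 3 * idx[, 3], dm)
  vol <- intensity_volume(ramp)
  f <- make_displacement_field("smooth_random",
                               list(max_disp = 1.5, sigma_vox = 2),
                               grid = vol, seed = 6)
  out <- apply_displacement_volume(vol, f, interp = "trilinear")
  pts <- as.matrix(expand.grid(0:11, 0:11, 0:11))
  d <- matrix(f$vectors, ncol = 3)
  target <- pts + d
  inside <- target[, 1] >= 0 & target[, 1] <= 11 &
    target[, 2] >= 0 & target[, 2] <= 11 &
    target[, 3] >= 0 & target[, 3] <= 11
  analytic <- target[, 1] + 2 * target[, 2] + 3 * target[, 3]
  expect_equal(as.vector(out$data)[inside], analytic[inside],
               tolerance = 1e-6)
})

test_that("point transforms follow constant and linear analytic fields", {
  pts <- fiducial_set(letters[1:4],
                      rbind(c(1, 1, 1), c(2, 3, 1), c(4, 4, 4), c(3, 1, 2)))
  ft <- make_displacement_field("translation", list(t = c(3, 4, 0)),
                                grid = c(6, 6, 6))
  moved <- transform_points(pts, ft)
  expect_equal(moved$points, pts$points + matrix(c(3, 4, 0), 4, 3,
                                                 byrow = TRUE))

  A <- matrix(c(0.05, 0.01, 0, 0, -0.03, 0.02, 0.01, 0, 0.04), 3, 3)
  fl <- make_displacement_field("polynomial", list(lin = A),
                                grid = c(6, 6, 6))
  movedl <- transform_points(pts, fl)
  expect_equal(movedl$points, pts$points + pts$points %*% t(A),
               tolerance = 1e-9)

  # out-of-grid points are flagged, not raised
  far <- fiducial_set("far", rbind(c(100, 0, 0)))
  mf <- transform_points(far, ft)
  expect_true(attr(mf, "outside"))
  expect_equal(mf$points, far$points)
})

test_that("Jacobian determinants match analytic fields", {
  f0 <- make_displacement_field("identity", grid = c(6, 6, 6))
  expect_equal(jacobian_determinant(f0)$data, array(1, c(6, 6, 6)))

  fs <- make_displacement_field("scale", list(s = 1.2), grid = c(8, 8, 8))
  j <- jacobian_determinant(fs)$data
  expect_equal(j[2:7, 2:7, 2:7], array(1.2^3, c(6, 6, 6)),
               tolerance = 1e-6)

  # polynomial field with a hand-differentiated Jacobian: central
  # differences are O(h^2)-exact, and exact for quadratics
  quad <- c(0.002, -0.001, 0.0015)
  A <- matrix(c(0.01, 0.002, 0, -0.003, 0.02, 0.001, 0, 0.004, -0.01), 3, 3,
              byrow = TRUE)
  fp <- make_displacement_field("polynomial", list(quad = quad, lin = A),
                                grid = c(7, 7, 7))
  jp <- jacobian_determinant(fp)$data
  idx <- as.matrix(expand.grid(1:5, 1:5, 1:5))  # interior, 0-based
  for (r in sample(nrow(idx), 20)) {
    pvox <- idx[r, ]
    Jan <- A + diag(2 * quad * pvox) + diag(3)
    expect_equal(jp[pvox[1] + 1, pvox[2] + 1, pvox[3] + 1], det(Jan),
                 tolerance = 1e-9)
  }
})

test_that("mean Jacobian over a warped box matches voxel-counted volume change", {
  # uniform scale about the grid centre; compare mean interior det with the
  # voxel-counting volume ratio of a warped binary mask
  s <- 1.15
  dm <- c(24, 24, 24)
  centre <- (dm - 1) / 2
  f <- make_displacement_field("scale", list(s = s, centre = centre),
                               grid = dm)
  mask <- array(0, dm)
  mask[9:16, 9:16, 9:16] <- 1
  vol <- intensity_volume(mask)
  # trilinear occupancy: voxel counting with fractional boundary voxels
  warped <- apply_displacement_volume(vol, f, interp = "trilinear")
  ratio <- sum(mask) / sum(warped$data)   # pull-back shrinks the mask by s^3
  j <- jacobian_determinant(f)$data
  expect_equal(mean(j[2:23, 2:23, 2:23]), ratio, tolerance = 0.02 * ratio)
})

test_that("Dice overlap follows the formula and is symmetric", {
  a <- array(0L, c(4, 4, 4))
  b <- array(0L, c(4, 4, 4))
  a[1:5] <- 1L       # |A| = 5
  b[4:6] <- 1L       # |B| = 3, overlap {4,5} = 2
  la <- label_volume(a)
  lb <- label_volume(b)
  expect_equal(unname(dice_overlap(la, lb)), 0.5)
  expect_identical(dice_overlap(la, lb), dice_overlap(lb, la))

  expect_equal(unname(dice_overlap(la, la)), 1)
  disj_a <- label_volume(array(c(1L, rep(0L, 63)), c(4, 4, 4)))
  disj_b <- label_volume(array(c(0L, 1L, rep(0L, 62)), c(4, 4, 4)))
  expect_equal(unname(dice_overlap(disj_a, disj_b)), 0)

  # label missing from one volume: undefined, reported NA
  c1 <- array(0L, c(4, 4, 4)); c1[1] <- 2L
  expect_true(is.na(dice_overlap(label_volume(c1), lb)["2"]))
  expect_error(dice_overlap(la, label_volume(array(0L, c(3, 3, 3)))),
               "grid")
})

test_that("fiducial misregistration distances are Euclidean with summary", {
  ref <- fiducial_set(c("ac", "pc", "t"),
                      rbind(c(0, 0, 0), c(1, 1, 1), c(5, 5, 5)))
  same <- fiducial_misregistration(ref, ref)
  expect_equal(unname(same$distances), c(0, 0, 0))

  shifted <- fiducial_set(ref$names, ref$points +
                            matrix(c(3, 4, 0), 3, 3, byrow = TRUE))
  mis <- fiducial_misregistration(ref, shifted)
  expect_equal(unname(mis$distances), c(5, 5, 5))
  expect_equal(unname(mis$summary["mean"]), 5)
  expect_equal(unname(mis$summary["sd"]), 0)

  # order-free matching + brute-force norm oracle
  set.seed(3)
  p2 <- ref$points + matrix(rnorm(9), 3, 3)
  perm <- c(2, 3, 1)
  tr <- fiducial_set(ref$names[perm], p2[perm, ])
  mis2 <- fiducial_misregistration(ref, tr)
  expect_equal(unname(mis2$distances),
               sqrt(rowSums((ref$points - p2)^2)))
  expect_error(fiducial_misregistration(
    ref, fiducial_set(c("ac", "pc", "x"), p2)), "unmatched")
})

test_that("stratified summaries equal a brute-force group-by", {
  set.seed(17)
  dm <- c(6, 6, 6)
  metric <- intensity_volume(array(rnorm(prod(dm)), dm))
  lab <- label_volume(array(sample(0:3, prod(dm), TRUE), dm))
  groups <- list(g1 = c(1L, 2L), g2 = 3L)
  s <- stratified_summary(metric, lab, groups)
  for (g in names(groups)) {
    sel <- lab$data %in% groups[[g]]
    expect_equal(s$mean[s$group == g], mean(metric$data[sel]))
    expect_equal(s$n[s$group == g], sum(sel))
    expect_equal(s[s$group == g, "q50"],
                 unname(quantile(metric$data[sel], 0.5)))
  }
  # constant metric: SD 0
  cst <- intensity_volume(array(2, dm))
  sc <- stratified_summary(cst, lab, groups)
  expect_equal(sc$sd, c(0, 0))
})

test_that("inverse-field composition returns fiducials within discretisation error", {
  s <- 1.1
  f <- make_displacement_field("scale", list(s = s), grid = c(10, 10, 10))
  finv <- make_displacement_field("scale", list(s = 1 / s),
                                  grid = c(10, 10, 10))
  pts <- fiducial_set(c("p1", "p2"), rbind(c(2, 3, 4), c(5, 5, 5)))
  there <- transform_points(pts, f)
  back <- transform_points(there, finv)
  expect_equal(back$points, pts$points, tolerance = 1e-6)
})
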