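# Iso-to-allocortical axis: geodesics, ribbon volumetrisation, binned rsFC.

test_that("the axis is zero at bridgeheads and equals arclength on a strip", {
  mesh <- flat_strip(12, 3, spacing = 1)
  bridge <- c(1L, 13L, 25L)  # first column
  ax <- compute_axis(mesh, bridge)
  expect_equal(ax$axis[bridge], c(0, 0, 0))
  # middle-row vertices: distance along the strip equals x coordinate
  middle <- 13:24
  expect_equal(ax$axis[middle], mesh$vertices[middle, 1], tolerance = 1e-10)
  expect_error(compute_axis(mesh, integer(0)), "non-empty")
  expect_error(compute_axis(mesh, 99L), "out of range")
})

test_that("the axis matches a dense shortest-path oracle on a C-shaped sheet", {
  # bent strip: a curved (C-shaped) band in the plane
  n <- 30
  theta <- seq(0, 4, length.out = n)
  inner <- cbind(5 * cos(theta), 5 * sin(theta), 0)
  outer_ <- cbind(7 * cos(theta), 7 * sin(theta), 0)
  v <- rbind(inner, outer_)
  i <- seq_len(n - 1)
  f <- rbind(cbind(i, i + 1L, i + n), cbind(i + 1L, i + n + 1L, i + n))
  mesh <- triangle_mesh(v, f)
  oracle <- floyd_warshall(mesh)
  ax <- compute_axis(mesh, c(1L, n + 1L))
  expect_equal(ax$axis, pmin(oracle[1, ], oracle[n + 1, ]), tolerance = 1e-10)
})

test_that("the axis is 1-Lipschitz along mesh edges", {
  mesh <- small_sheet()$pial
  g <- adjacency_graph(mesh)
  ax <- compute_axis(mesh, 1L, graph = g)
  el <- igraph::as_edgelist(g, names = FALSE)
  len <- igraph::E(g)$weight
  expect_true(all(abs(ax$axis[el[, 1]] - ax$axis[el[, 2]]) <= len + 1e-9))
})

test_that("signed axes negate the isocortical side", {
  mesh <- flat_strip(10, 2)
  bridge <- c(5L, 15L)
  iso <- which(mesh$vertices[, 1] < 4)
  ax <- compute_axis(mesh, bridge, signed = TRUE, iso_side = iso)
  expect_true(all(ax$axis[iso] <= 0))
  expect_true(all(ax$axis[setdiff(seq_len(20), c(iso, bridge))] >= 0))
})

test_that("ribbon volumetrisation reproduces an analytic slab", {
  # flat slab: pial z = 0, white z = -2, over a 10 x 6 mm footprint
  pial <- flat_strip(21, 13, spacing = 0.5)
  white <- triangle_mesh(pial$vertices + matrix(c(0, 0, -2),
                                                21 * 13, 3, byrow = TRUE),
                         pial$faces)
  sheet <- cortical_sheet(pial, white)
  ax <- compute_axis(pial, which(pial$vertices[, 1] == 0))
  vsz <- 0.25
  dm <- ceiling(c(10, 6, 4) / vsz) + 8L
  aff <- diag(c(vsz, vsz, vsz, 1))
  # half-voxel offset keeps voxel centres off the slab boundary planes,
  # so centre counting is unbiased
  aff[1:3, 4] <- c(-1.125, -1.125, -3.125)
  grid <- intensity_volume(array(0, dm), aff, background = -1)
  rib <- axis_to_ribbon(sheet, ax, grid)

  filled <- rib$data != -1
  idx <- which(filled, arr.ind = TRUE) - 1L
  centres <- voxel_to_world(idx, aff)
  # analytic slab membership: all filled voxels lie in the slab
  expect_true(all(centres[, 3] >= -2 - 1e-9 & centres[, 3] <= 1e-9))
  expect_true(all(centres[, 1] >= -0.5 & centres[, 1] <= 10.5))
  # volume conservation within 5%
  slab_vol <- 10 * 6 * 2
  expect_lt(abs(sum(filled) * vsz^3 - slab_vol) / slab_vol, 0.05)
  # values equal the axis of the nearest column (axis = x coordinate),
  # so they differ from the clamped x by at most half the column pitch
  expect_lt(max(abs(rib$data[filled] -
                      pmin(pmax(centres[, 1], 0), 10))), 0.3)

  # constant axis fills the ribbon with the constant
  axc <- structure(list(axis = rep(7, 21 * 13), bridgeheads = 1L),
                   class = "axis_model")
  ribc <- axis_to_ribbon(sheet, axc, grid)
  expect_true(all(ribc$data[ribc$data != -1] == 7))

  # disjoint grid: warning and empty volume
  far <- intensity_volume(array(0, c(4, 4, 4)),
                          {
                            a <- diag(4); a[1:3, 4] <- c(100, 100, 100); a
                          }, background = -1)
  expect_warning(ribf <- axis_to_ribbon(sheet, ax, far), "empty ribbon")
  expect_true(all(ribf$data == -1))
})

test_that("binned connectivity recovers planted couplings and flags degeneracy", {
  set.seed(31)
  v <- 1200
  axis <- runif(v, 0, 30)
  b <- make_axis_bold(axis, n_parcels = 4, T_len = 250,
                      coupling = c(0.3, 0, 0, 0), noise_sd = 1, seed = 5)
  res <- binned_axis_connectivity(b$voxel_ts, axis, b$parcel_ts, n_bins = 30)
  expect_gt(res$trend_r[1], 0.9)
  # uncoupled parcels never reach the coupled parcel's rsFC strength
  expect_lt(max(abs(res$rsfc[, 2:4])), max(res$rsfc[, 1]))

  # a parcel timeseries built as one bin's mean timeseries gives rsFC ~ 1
  parcel_same <- matrix(colMeans(b$voxel_ts[axis <= 1, , drop = FALSE]),
                        nrow = 1)
  res2 <- binned_axis_connectivity(b$voxel_ts, axis,
                                   rbind(parcel_same, b$parcel_ts),
                                   n_bins = 30)
  # the first parcel is exactly the mean of low-axis voxels: rsFC with the
  # lowest bin must be very high (identical construction up to binning)
  expect_gt(res2$rsfc[1, 1], 0.9)

  # constant timeseries produce NA rsFC
  const_parcel <- matrix(1, 1, 250)
  res3 <- binned_axis_connectivity(b$voxel_ts, axis, const_parcel,
                                   n_bins = 10)
  expect_true(all(is.na(res3$rsfc)))
  expect_error(binned_axis_connectivity(b$voxel_ts, axis,
                                        b$parcel_ts[, 1:10], n_bins = 10),
               "disagree on T")

  # trend r is invariant to monotone bin relabelling by construction:
  # correlation against rank-preserved positions is what is computed
  expect_equal(length(res$trend_r), 4)
})
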