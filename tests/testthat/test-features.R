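# Moment features, parcel averaging, partial correlation, stratification.

# independent textbook evaluation of the 10 moment features
moments_oracle <- function(p, alpha) {
  pop <- function(x) {
    m <- sum(x) / length(x)
    m2 <- sum((x - m)^2) / length(x)
    m3 <- sum((x - m)^3) / length(x)
    m4 <- sum((x - m)^4) / length(x)
    c(mean = m, sd = sqrt(m2),
      skewness = if (m2 > 0) m3 / m2^(3 / 2) else 0,
      kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
  }
  k <- length(p)
  d <- (p[-1] - p[-k]) / (alpha[-1] - alpha[-k])
  amid <- (alpha[-1] + alpha[-k]) / 2
  mp <- pop(p)
  md <- pop(d)
  c(mean = unname(mp["mean"]), cog = sum(alpha * p) / sum(p),
    sd = unname(mp["sd"]), skewness = unname(mp["skewness"]),
    kurtosis = unname(mp["kurtosis"]),
    d_mean = unname(md["mean"]), d_cog = sum(amid * abs(d)) / sum(abs(d)),
    d_sd = unname(md["sd"]), d_skewness = unname(md["skewness"]),
    d_kurtosis = unname(md["kurtosis"]))
}

test_that("all 10 moment features match the textbook formulas", {
  set.seed(5)
  alpha <- seq(0, 1, length.out = 50)
  for (i in 1:100) {
    p <- runif(50, 0.5, 10)
    got <- central_moments(matrix(p, ncol = 1), alpha)[1, ]
    expect_equal(got, moments_oracle(p, alpha), tolerance = 1e-10)
  }
})

test_that("constant and symmetric profiles have the expected moments", {
  alpha <- seq(0, 1, length.out = 21)
  cst <- central_moments(matrix(4, 21, 1), alpha)[1, ]
  expect_equal(unname(cst["mean"]), 4)
  expect_equal(unname(cst["sd"]), 0)
  expect_equal(unname(cst["cog"]), 0.5)

  sym <- 1 + exp(-(alpha - 0.5)^2 / 0.02)  # symmetric bump about mid-depth
  m <- central_moments(matrix(sym, 21, 1), alpha)[1, ]
  expect_equal(unname(m["cog"]), 0.5, tolerance = 1e-12)

  # a profile whose intensity values are symmetric about their mean has
  # exactly zero Fisher skewness
  set.seed(2)
  v <- runif(10)
  p_sym <- c(5 + v, 5 - v)
  ms <- central_moments(matrix(p_sym, ncol = 1),
                        seq(0, 1, length.out = 20))[1, ]
  expect_lt(abs(ms["skewness"]), 1e-12)

  # zero-sum profile: centre of gravity flagged missing
  z <- rep(c(1, -1), length.out = 20)  # sums to exactly zero
  mz <- central_moments(matrix(z, ncol = 1),
                        seq(0, 1, length.out = 20))[1, ]
  expect_true(is.na(mz["cog"]))
})

test_that("parcel averaging equals the brute-force group-by mean", {
  set.seed(8)
  mesh <- flat_strip(8, 5)
  prof <- profile_set(matrix(rnorm(10 * 40), 10, 40),
                      seq(0, 1, length.out = 10))
  pm <- decimate_and_parcellate(mesh, 7, seed = 3)
  got <- parcel_average_profiles(prof, pm)
  expect_equal(dim(got), c(7, 10))
  for (p in 1:7) {
    members <- which(pm$assignment == p)
    expect_equal(got[p, ],
                 rowMeans(prof$values[, members, drop = FALSE]),
                 tolerance = 1e-12)
  }
  # singleton parcels -> identity
  pmN <- decimate_and_parcellate(mesh, 40, seed = 1)
  gotN <- parcel_average_profiles(prof, pmN)
  expect_equal(gotN[pmN$assignment, ], t(prof$values), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("partial correlation obeys the closed-form identity", {
  set.seed(13)
  k <- 30
  control <- rnorm(k)
  x <- rbind(rnorm(k), rnorm(k), rnorm(k) + 0.5 * control)
  got <- partial_correlation_matrix(x, control = control)
  r <- function(a, b) cor(a, b)
  for (i in 1:3) for (j in 1:3) {
    rij <- r(x[i, ], x[j, ])
    ric <- r(x[i, ], control)
    rjc <- r(x[j, ], control)
    expected <- (rij - ric * rjc) / sqrt((1 - ric^2) * (1 - rjc^2))
    if (i == j) expected <- 1
    expect_equal(got[i, j], expected, tolerance = 1e-10)
  }

  # equal profiles orthogonal to the control correlate at exactly 1
  o <- rnorm(k)
  o <- o - mean(o)
  o <- o - control * sum(o * control) / sum(control^2)
  # o is orthogonal to control after centring; duplicate rows
  two <- rbind(o, o)
  got2 <- partial_correlation_matrix(two, control = control)
  expect_equal(got2[1, 2], 1, tolerance = 1e-10)

  # zero residual variance is flagged missing
  degenerate <- rbind(2 + 3 * control, rnorm(k))
  got3 <- partial_correlation_matrix(degenerate, control = control)
  expect_true(is.na(got3[1, 2]))
})

test_that("normalised angle maps correlations onto [0, 1] monotonically", {
  expect_equal(normalised_angle(c(-1, 0, 1)), c(0, 0.5, 1))
  r <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(normalised_angle(r)) > 0))
  expect_error(normalised_angle(1.01), "\\[-1, 1\\]")
  expect_equal(normalised_angle(1 + 1e-12), 1)  # clipped within tolerance
})

test_that("label stratification matches a brute-force boundary filter", {
  mesh <- flat_strip(20, 5)
  labels <- ifelse(mesh$vertices[, 1] < 9.5, 1L, 2L)
  feats <- cbind(a = mesh$vertices[, 1], b = rnorm(100))

  s0 <- stratify_features_by_label(feats, labels)
  expect_equal(s0$n[s0$label == 1][1], sum(labels == 1))
  expect_equal(s0$mean[s0$label == 1 & s0$feature == "a"],
               mean(feats[labels == 1, 1]))

  margin <- 3
  s1 <- stratify_features_by_label(feats, labels, mesh,
                                   exclude_margin = margin)
  kept <- attr(s1, "kept")
  # oracle: geodesic distance to the nearest cross-label vertex
  g <- adjacency_graph(mesh)
  d <- floyd_warshall(mesh)
  el <- igraph::as_edgelist(g, names = FALSE)
  bnd <- sort(unique(as.vector(el[labels[el[, 1]] != labels[el[, 2]], ])))
  dist_b <- apply(d[, bnd, drop = FALSE], 1, min)
  expect_equal(kept, dist_b >= margin)

  # single label: summaries equal global summaries
  sG <- stratify_features_by_label(feats, rep(1L, 100))
  expect_equal(sG$mean[sG$feature == "b"], mean(feats[, 2]))
})
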