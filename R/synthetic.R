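# Deterministic synthetic fixtures: folded cortical sheets, laminar
# "staining" volumes with equivolumetric ground truth, analytic displacement
# fields, and axis-graded BOLD timeseries. All generators are pure
# functions of (parameters, seed).

#' Laminar specification for synthetic staining volumes
#'
#' The default emulates a six-layer isocortical profile with a thin
#' high-density band at volume fractions 0.4-0.5 (a "layer IV" peak) and a
#' secondary superficial peak ("layer II"), so the default profile has
#' exactly two peaks.
#'
#' @param boundaries strictly increasing layer lower..upper volume-fraction
#'   boundaries in (0, 1], last exactly 1 (pial to white).
#' @param densities per-layer staining intensity.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed integer seed for the noise.
#' @return an object of class \code{laminar_spec}.
#' @export
laminar_spec <- function(boundaries = c(0.1, 0.25, 0.4, 0.5, 0.75, 1.0),
                         densities = c(30, 90, 60, 120, 70, 50),
                         noise_sd = 0, seed = 1L) {
  if (length(boundaries) != length(densities))
    stop("boundaries and densities must have equal length")
  if (any(diff(boundaries) <= 0) || boundaries[1] <= 0 ||
        abs(boundaries[length(boundaries)] - 1) > 1e-12)
    stop("boundaries must be strictly increasing in (0, 1] with last = 1")
  if (!all(is.finite(densities))) stop("densities must be finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(boundaries = boundaries, densities = densities,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "laminar_spec")
}

#' Generate a folded two-surface cortical sheet
#'
#' The pial surface is a sinusoidally folded rectangular grid
#' (\code{z = fold_amp * sin(fold_freq * x)}); the white surface is offset
#' from it along the local surface normal by \code{thickness}, giving a
#' vertex-correspondent pial/white pair with one shared face table. At
#' gyral crowns the pial area exceeds the white area; at fundi the
#' reverse.
#'
#' @param n_x,n_y grid dimensions (vertices).
#' @param fold_amp fold amplitude in mm (0 = two parallel planes).
#' @param fold_freq fold spatial frequency in 1/mm.
#' @param thickness cortical thickness in mm.
#' @param spacing grid spacing in mm (default 0.5).
#' @return a \code{cortical_sheet}.
#' @export
make_folded_sheet <- function(n_x = 40, n_y = 20, fold_amp = 2,
                              fold_freq = 0.4, thickness = 2,
                              spacing = 0.5) {
  if (n_x < 2 || n_y < 2) stop("grid must be at least 2 x 2")
  if (thickness <= 0) stop("thickness must be positive")
  x <- (seq_len(n_x) - 1) * spacing
  y <- (seq_len(n_y) - 1) * spacing
  # self-intersection: offset distance must stay below the minimum radius
  # of curvature of the fold
  if (fold_amp > 0) {
    max_curv <- fold_amp * fold_freq^2  # max |z''| / (1 + z'^2)^{3/2} bound
    if (thickness * max_curv >= 1)
      stop("thickness >= fold radius of curvature: the white surface would ",
           "self-intersect")
  }
  xv <- rep(x, times = n_y)
  yv <- rep(y, each = n_x)
  z <- fold_amp * sin(fold_freq * xv)
  dz <- fold_amp * fold_freq * cos(fold_freq * xv)
  nrm <- cbind(-dz, 0, 1) / sqrt(1 + dz^2)
  pial_v <- cbind(xv, yv, z)
  white_v <- pial_v - thickness * nrm
  faces <- grid_faces(n_x, n_y)
  cortical_sheet(triangle_mesh(pial_v, faces),
                 triangle_mesh(white_v, faces))
}

grid_faces <- function(n_x, n_y) {
  i <- rep(seq_len(n_x - 1), times = n_y - 1)
  j <- rep(seq_len(n_y - 1), each = n_x - 1)
  v00 <- (j - 1) * n_x + i
  v10 <- v00 + 1L
  v01 <- v00 + n_x
  v11 <- v01 + 1L
  rbind(cbind(v00, v10, v01), cbind(v10, v11, v01))
}

#' Generate a laminar staining volume over a cortical sheet
#'
#' Each voxel centre inside the ribbon is assigned the density of the layer
#' containing its true volume-fraction depth. The depth is converted from
#' the distance fraction along the local pial-white segment through the
#' inverse of the equivolumetric model (using the sheet's own vertex
#' areas), so the planted laminar structure is equivolumetric by
#' construction. Gaussian noise is added from the spec's seed.
#'
#' @param sheet a \code{cortical_sheet}.
#' @param spec a \code{laminar_spec}.
#' @param voxel_size isotropic voxel size in mm; must resolve the thinnest
#'   layer with at least 2 voxels across the cortical thickness.
#' @param background fill value outside the ribbon (default 0).
#' @return an \code{intensity_volume}; attributes \code{"layer"} (integer
#'   ground-truth layer per voxel, 0 outside) and \code{"alpha"}
#'   (ground-truth volume-fraction depth, NA outside) support
#'   parameter-recovery tests.
#' @export
make_laminar_volume <- function(sheet, spec, voxel_size = 0.2,
                                background = 0) {
  stopifnot(inherits(sheet, "cortical_sheet"), inherits(spec, "laminar_spec"))
  p <- sheet$pial$vertices
  w <- sheet$white$vertices
  thick <- sqrt(rowSums((p - w)^2))
  min_frac <- min(diff(c(0, spec$boundaries)))
  if (min_frac * mean(thick) < 2 * voxel_size - 1e-9)
    stop("voxel_size too coarse: the thinnest layer (",
         signif(min_frac * mean(thick), 3), " mm) needs >= 2 voxels")
  lo <- pmin(apply(p, 2, min), apply(w, 2, min)) - 2 * voxel_size
  hi <- pmax(apply(p, 2, max), apply(w, 2, max)) + 2 * voxel_size
  dm <- pmax(ceiling((hi - lo) / voxel_size) + 1L, 3L)
  affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  affine[1:3, 4] <- lo
  idx <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1),
                               k = 0:(dm[3] - 1)))
  centres <- voxel_to_world(idx, affine)

  mid <- (p + w) / 2
  nn <- nearest_vertex(mid, centres)
  seg <- w - p
  seg_len2 <- rowSums(seg^2)
  spacing <- local_spacing(sheet$pial)
  rel <- centres - p[nn, , drop = FALSE]
  t_par <- rowSums(rel * seg[nn, , drop = FALSE]) / seg_len2[nn]
  perp2 <- rowSums(rel^2) - t_par^2 * seg_len2[nn]
  inside <- t_par >= 0 & t_par <= 1 & perp2 <= (0.75 * spacing[nn])^2

  ap <- vertex_areas(sheet$pial)
  aw <- vertex_areas(sheet$white)
  # inverse equivolumetric map: distance fraction t -> volume fraction alpha
  tin <- t_par[inside]
  apv <- ap[nn[inside]]
  awv <- aw[nn[inside]]
  alpha_in <- (apv * tin + (awv - apv) * tin^2 / 2) / ((apv + awv) / 2)
  alpha_in <- pmin(pmax(alpha_in, 0), 1)
  nb <- length(spec$boundaries)
  layer_in <- 1L + findInterval(alpha_in, spec$boundaries[-nb])

  vals <- rep(background, nrow(centres))
  vals[inside] <- spec$densities[layer_in] +
    with_seed(spec$seed, stats::rnorm(sum(inside), 0, spec$noise_sd))
  layer <- integer(nrow(centres))
  layer[inside] <- layer_in
  alpha <- rep(NA_real_, nrow(centres))
  alpha[inside] <- alpha_in

  vol <- intensity_volume(array(vals, dm), affine, background = background)
  attr(vol, "layer") <- array(layer, dm)
  attr(vol, "alpha") <- array(alpha, dm)
  vol
}

#' Generate an analytic displacement field
#'
#' Families: \code{identity} (zero vectors), \code{translation}
#' (\code{params$t}, mm), \code{scale} (\code{d(p) = (s - 1)(p - centre)}
#' with \code{params$s} and optional \code{params$centre}),
#' \code{polynomial} (\code{d_c(p) = quad_c p_c^2 + (A p)_c} with
#' \code{params$quad} length-3 and \code{params$lin} 3x3) and
#' \code{smooth_random} (Gaussian-filtered white noise rescaled to
#' \code{params$max_disp} mm; \code{params$sigma_vox} sets the filter
#' width in voxels).
#'
#' @param kind one of \code{"identity"}, \code{"translation"},
#'   \code{"scale"}, \code{"polynomial"}, \code{"smooth_random"}.
#' @param params named list of family parameters (see above).
#' @param grid an \code{intensity_volume} supplying grid and affine, or an
#'   integer vector of grid dimensions (unit spacing at the origin).
#' @param seed integer seed (used by \code{smooth_random}).
#' @return a \code{displacement_field}.
#' @export
make_displacement_field <- function(kind, params = list(), grid = c(8, 8, 8),
                                    seed = 1L) {
  kind <- match.arg(kind, c("identity", "translation", "scale",
                            "polynomial", "smooth_random"))
  if (inherits(grid, "intensity_volume")) {
    dm <- dim(grid$data)
    affine <- grid$affine
  } else {
    dm <- as.integer(grid)
    affine <- diag(4)
  }
  idx <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1),
                               k = 0:(dm[3] - 1)))
  pts <- voxel_to_world(idx, affine)
  d <- switch(kind,
    identity = matrix(0, nrow(pts), 3),
    translation = {
      t3 <- params$t
      if (length(t3) != 3) stop("translation needs params$t of length 3")
      matrix(t3, nrow(pts), 3, byrow = TRUE)
    },
    scale = {
      s <- params$s
      if (is.null(s)) stop("scale needs params$s")
      centre <- if (is.null(params$centre)) c(0, 0, 0) else params$centre
      (s - 1) * sweep(pts, 2, centre)
    },
    polynomial = {
      quad <- if (is.null(params$quad)) c(0, 0, 0) else params$quad
      lin <- if (is.null(params$lin)) matrix(0, 3, 3) else params$lin
      sweep(pts^2, 2, quad, `*`) + pts %*% t(lin)
    },
    smooth_random = {
      sigma <- if (is.null(params$sigma_vox)) 2 else params$sigma_vox
      max_disp <- if (is.null(params$max_disp)) 1 else params$max_disp
      noise <- with_seed(seed, array(stats::rnorm(prod(dm) * 3), c(dm, 3)))
      for (c3 in 1:3) noise[, , , c3] <- gauss_smooth_3d(noise[, , , c3], sigma)
      noise <- noise / max(abs(noise)) * max_disp
      matrix(noise, ncol = 3)
    })
  displacement_field(array(d, c(dm, 3)), affine)
}

# separable Gaussian filter with replicated borders
gauss_smooth_3d <- function(v, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  dm <- dim(v)
  for (ax in 1:3) {
    n <- dm[ax]
    acc <- array(0, dm)
    for (o in -r:r) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      shifted <- switch(ax,
                        v[idx, , , drop = FALSE],
                        v[, idx, , drop = FALSE],
                        v[, , idx, drop = FALSE])
      acc <- acc + k[o + r + 1] * shifted
    }
    v <- acc
  }
  v
}

#' Generate axis-graded synthetic BOLD timeseries
#'
#' Parcel timeseries are i.i.d. standard Gaussian; each voxel timeseries
#' couples to parcel r with strength \code{coupling[r]} scaled by the
#' voxel's normalised axis position, plus Gaussian noise:
#' \code{voxel_v = sum_r coupling_r * anorm_v * parcel_r + noise}. The
#' planted trend (rsFC increasing along the axis for positively coupled
#' parcels) is recoverable by \code{\link{binned_axis_connectivity}}.
#'
#' @param axis_values length-V axis values (mm).
#' @param n_parcels number of parcels R.
#' @param T_len number of time points (>= 10).
#' @param coupling per-parcel coupling slope (recycled to length R).
#' @param noise_sd voxel noise SD.
#' @param seed integer seed.
#' @return list with \code{voxel_ts} (V x T) and \code{parcel_ts} (R x T).
#' @export
make_axis_bold <- function(axis_values, n_parcels = 10, T_len = 300,
                           coupling = 0, noise_sd = 1, seed = 1L) {
  if (T_len < 10) stop("T_len must be >= 10")
  v <- length(axis_values)
  coupling <- rep_len(coupling, n_parcels)
  rng <- range(axis_values)
  anorm <- if (diff(rng) > 0) (axis_values - rng[1]) / diff(rng) else
    rep(0.5, v)
  with_seed(seed, {
    parcel_ts <- matrix(stats::rnorm(n_parcels * T_len), n_parcels, T_len)
    signal <- (anorm %o% coupling) %*% parcel_ts  # V x T
    voxel_ts <- signal + matrix(stats::rnorm(v * T_len, 0, noise_sd), v, T_len)
    list(voxel_ts = voxel_ts, parcel_ts = parcel_ts)
  })
}
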