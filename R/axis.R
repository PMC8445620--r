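# Iso-to-allocortical axis: geodesic distance from bridgehead vertices on a
# confluent cortical surface, its volumetrisation into the cortical ribbon,
# and axis-binned functional-connectivity profiling.

#' Compute the iso-to-allocortical axis
#'
#' Geodesic distance (mm) of every vertex from the nearest bridgehead — the
#' vertices where the isocortical and allocortical surface constructions
#' meet. With \code{signed = TRUE}, distances on the designated isocortical
#' side are negated so the axis increases monotonically from isocortex to
#' allocortex.
#'
#' @param mesh a \code{triangle_mesh} (the confluent surface).
#' @param bridgeheads non-empty vector of 1-based vertex indices.
#' @param signed negate the isocortical side? (default FALSE)
#' @param iso_side vertex indices of the isocortical side (required when
#'   \code{signed}).
#' @param graph optional precomputed adjacency graph.
#' @return an object of class \code{axis_model}: list with \code{axis}
#'   (per-vertex mm) and \code{bridgeheads}.
#' @export
compute_axis <- function(mesh, bridgeheads, signed = FALSE, iso_side = NULL,
                         graph = NULL) {
  n <- n_vertices(mesh)
  if (length(bridgeheads) == 0) stop("bridgeheads must be non-empty")
  if (any(bridgeheads < 1 | bridgeheads > n))
    stop("bridgehead index out of range [1, ", n, "]")
  if (is.null(graph)) graph <- adjacency_graph(mesh)
  axis <- weighted_geodesic(graph, bridgeheads)
  if (signed) {
    if (is.null(iso_side)) stop("signed axis needs iso_side vertex indices")
    axis[iso_side] <- -axis[iso_side]
  }
  structure(list(axis = axis, bridgeheads = sort(unique(bridgeheads))),
            class = "axis_model")
}

#' @export
print.axis_model <- function(x, ...) {
  cat("<axis_model> ", length(x$axis), " vertices, ",
      length(x$bridgeheads), " bridgeheads, range [",
      signif(min(x$axis), 3), ", ", signif(max(x$axis), 3), "] mm\n", sep = "")
  invisible(x)
}

#' Volumetrise an axis into the cortical ribbon
#'
#' Fills every voxel of the template grid whose centre lies inside the
#' cortical ribbon (between pial and white) with the axis value of its
#' nearest surface vertex; everything else gets the template background.
#' Ribbon membership is decided by nearest mid-surface vertex: the voxel
#' centre is projected onto that vertex's pial-white segment and must fall
#' within the segment (with a small longitudinal tolerance) and within a
#' thickness-scaled lateral radius of it.
#'
#' @param sheet a \code{cortical_sheet}.
#' @param axis an \code{axis_model} on the sheet's mesh.
#' @param grid an \code{intensity_volume} providing the output grid and
#'   affine (its data are ignored).
#' @param lateral_scale lateral acceptance radius as a multiple of the
#'   surface sample spacing (default 0.75, a Voronoi-cell radius).
#' @param oversample surface samples per voxel edge (default 2): faces are
#'   subdivided until samples are spaced about \code{voxel/oversample},
#'   which bounds the lateral quantisation error of the ribbon mask.
#' @return an \code{intensity_volume} of axis values over the ribbon.
#' @export
axis_to_ribbon <- function(sheet, axis, grid, lateral_scale = 0.75,
                           oversample = 2) {
  stopifnot(inherits(sheet, "cortical_sheet"), inherits(axis, "axis_model"),
            inherits(grid, "intensity_volume"))
  dm <- dim(grid$data)
  idx <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1),
                               k = 0:(dm[3] - 1)))
  centres <- voxel_to_world(idx, grid$affine)
  h <- min(voxel_size(grid$affine)) / oversample
  samp <- supersample_sheet(sheet, h)
  mid <- (samp$pial + samp$white) / 2

  # coarse prefilter: a voxel can only be in the ribbon if it is within
  # half the local thickness (plus a margin) of some mid-surface vertex
  vmid <- (sheet$pial$vertices + sheet$white$vertices) / 2
  thick <- sqrt(rowSums((sheet$pial$vertices - sheet$white$vertices)^2))
  vspace <- local_spacing(sheet$pial)
  cn <- nearest_vertex(vmid, centres)
  cd2 <- rowSums((centres - vmid[cn, , drop = FALSE])^2)
  margin <- (thick[cn] / 2 + vspace[cn] + h)^2
  cand <- which(cd2 <= margin)

  inside <- logical(nrow(centres))
  val <- numeric(nrow(centres))
  if (length(cand) > 0) {
    cc <- centres[cand, , drop = FALSE]
    nn <- nearest_vertex(mid, cc)
    seg <- samp$white - samp$pial
    seg_len2 <- rowSums(seg^2)
    rel <- cc - samp$pial[nn, , drop = FALSE]
    t_par <- rowSums(rel * seg[nn, , drop = FALSE]) / seg_len2[nn]
    perp2 <- rowSums(rel^2) - t_par^2 * seg_len2[nn]
    ok <- t_par >= -1e-9 & t_par <= 1 + 1e-9 &
      perp2 <= (lateral_scale * samp$spacing[nn])^2
    inside[cand] <- ok
    val[cand] <- axis$axis[samp$vertex[nn]]
  }
  out <- array(grid$background, dm)
  if (!any(inside)) {
    warning("empty ribbon: no voxel centre falls between pial and white")
  } else {
    out[idx[inside, , drop = FALSE] + 1L] <- val[inside]
  }
  intensity_volume(out, grid$affine, background = grid$background)
}

# barycentric supersampling of a cortical sheet: sample points on every
# face at spacing <= h, carrying the interpolated pial/white positions,
# the owning (nearest) face vertex, and the local sample spacing
supersample_sheet <- function(sheet, h) {
  pv <- sheet$pial$vertices
  wv <- sheet$white$vertices
  f <- sheet$pial$faces
  e1 <- sqrt(rowSums((pv[f[, 1], ] - pv[f[, 2], ])^2))
  e2 <- sqrt(rowSums((pv[f[, 2], ] - pv[f[, 3], ])^2))
  e3 <- sqrt(rowSums((pv[f[, 1], ] - pv[f[, 3], ])^2))
  max_edge <- pmax(e1, e2, e3)
  n_sub <- pmax(1L, as.integer(ceiling(max_edge / h)))
  out_p <- list(); out_w <- list(); out_v <- list(); out_s <- list()
  for (n in sort(unique(n_sub))) {
    faces <- which(n_sub == n)
    bary <- as.matrix(expand.grid(i = 0:n, j = 0:n))
    bary <- bary[rowSums(bary) <= n, , drop = FALSE]
    b <- cbind(bary[, 1], bary[, 2], n - rowSums(bary)) / n
    # owner vertex: largest barycentric weight (ties to the first)
    owner <- max.col(b, ties.method = "first")
    fp <- f[faces, , drop = FALSE]
    np <- nrow(b)
    p1 <- pv[fp[, 1], , drop = FALSE]; p2 <- pv[fp[, 2], , drop = FALSE]
    p3 <- pv[fp[, 3], , drop = FALSE]
    w1 <- wv[fp[, 1], , drop = FALSE]; w2 <- wv[fp[, 2], , drop = FALSE]
    w3 <- wv[fp[, 3], , drop = FALSE]
    for (s in seq_len(np)) {
      out_p[[length(out_p) + 1]] <-
        b[s, 1] * p1 + b[s, 2] * p2 + b[s, 3] * p3
      out_w[[length(out_w) + 1]] <-
        b[s, 1] * w1 + b[s, 2] * w2 + b[s, 3] * w3
      out_v[[length(out_v) + 1]] <- fp[, owner[s]]
      out_s[[length(out_s) + 1]] <- max_edge[faces] / n
    }
  }
  list(pial = do.call(rbind, out_p), white = do.call(rbind, out_w),
       vertex = unlist(out_v), spacing = unlist(out_s))
}

# shortest incident-edge length per vertex (the lateral Voronoi scale)
local_spacing <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- unique(t(apply(e, 1, sort)))
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  out <- rep(Inf, n_vertices(mesh))
  for (j in 1:2) {
    s <- tapply(len, e[, j], min)
    ii <- as.integer(names(s))
    out[ii] <- pmin(out[ii], s)
  }
  out
}

#' Axis-binned functional connectivity profiling
#'
#' Averages voxel-wise BOLD timeseries within equal-width bins of the axis
#' (default 100), correlates each bin with each isocortical parcel
#' timeseries (rsFC), and per parcel correlates rsFC strength against bin
#' position (the trend r). Bins with no voxels are dropped and their
#' indices reported; bins or parcels with zero temporal variance give
#' \code{NA} rsFC.
#'
#' @param voxel_ts V x T matrix of BOLD timeseries (grey-matter voxels,
#'   pre-filtered by the caller).
#' @param voxel_axis length-V axis values.
#' @param parcel_ts R x T matrix of parcel timeseries (default 1000
#'   parcels upstream).
#' @param n_bins number of equal-width axis bins (default 100).
#' @return list with \code{rsfc} (bins x parcels), \code{trend_r} (per
#'   parcel), \code{bin_centres}, \code{dropped_bins}.
#' @export
binned_axis_connectivity <- function(voxel_ts, voxel_axis, parcel_ts,
                                     n_bins = 100) {
  voxel_ts <- as.matrix(voxel_ts)
  parcel_ts <- as.matrix(parcel_ts)
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (length(voxel_axis) != nrow(voxel_ts))
    stop("voxel_axis must have one value per voxel timeseries")
  if (ncol(voxel_ts) != ncol(parcel_ts))
    stop("voxel and parcel timeseries disagree on T (",
         ncol(voxel_ts), " vs ", ncol(parcel_ts), ")")
  rng <- range(voxel_axis)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(voxel_axis, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, n_bins)
  keep <- which(counts > 0)
  bin_ts <- t(vapply(keep, function(b)
    colMeans(voxel_ts[bin == b, , drop = FALSE]), numeric(ncol(voxel_ts))))
  rsfc <- suppressWarnings(stats::cor(t(bin_ts), t(parcel_ts)))
  pos <- keep  # bin position index
  trend <- apply(rsfc, 2, function(col) {
    ok <- is.finite(col)
    if (sum(ok) < 3 || stats::sd(col[ok]) == 0) return(NA_real_)
    stats::cor(col[ok], pos[ok])
  })
  list(rsfc = rsfc,
       trend_r = trend,
       bin_centres = (edges[keep] + edges[keep + 1]) / 2,
       dropped_bins = setdiff(seq_len(n_bins), keep))
}
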