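# Staining-intensity depth profiles: sampling, inversion, smoothing, and
# the profile quality metrics (peak count, spatial autocorrelation).

#' Invert image intensities
#'
#' Cell-body stains digitise with dark (dense) tissue as low numbers; the
#' common convention flips them so intensity increases with cell-body
#' density: \code{out = max_value - in}. Applying the operation twice with
#' the same \code{max_value} restores the input.
#'
#' @param volume an \code{intensity_volume}.
#' @param max_value scalar >= the data maximum (255 for 8-bit data).
#' @return the inverted \code{intensity_volume} (background also inverted).
#' @export
invert_intensity <- function(volume, max_value) {
  stopifnot(inherits(volume, "intensity_volume"))
  if (max_value < max(volume$data))
    stop("max_value (", max_value, ") is below the data maximum (",
         max(volume$data), ")")
  intensity_volume(max_value - volume$data, volume$affine,
                   background = max_value - volume$background)
}

#' Sample staining-intensity profiles along a surface stack
#'
#' Interpolates the volume at every stack coordinate, giving a K x N
#' profile matrix (depths x vertices). Coordinates outside the volume
#' receive the background value and are flagged in the validity mask.
#'
#' @param stack a \code{surface_stack}.
#' @param volume an \code{intensity_volume}.
#' @param interp interpolation method: \code{"trilinear"} (default),
#'   \code{"tricubic"}, \code{"nearest"} or \code{"sinc"}.
#' @param mesh_ref identifier stored with the profiles.
#' @return a \code{profile_set}.
#' @export
sample_profiles <- function(stack, volume, interp = "trilinear",
                            mesh_ref = "") {
  stopifnot(inherits(stack, "surface_stack"),
            inherits(volume, "intensity_volume"))
  interp <- match.arg(interp, interp_methods)
  k <- dim(stack$coords)[1]
  n <- dim(stack$coords)[2]
  pts <- matrix(stack$coords, ncol = 3)  # (k,n) pairs in column-major order
  res <- interp_volume(volume, pts, method = interp)
  profile_set(matrix(res$values, nrow = k, ncol = n), stack$alpha,
              mesh_ref = mesh_ref,
              mask = matrix(res$inside, nrow = k, ncol = n))
}

#' Depth-wise profile smoothing (shrink-minimising)
#'
#' Per profile, applies Taubin two-step smoothing along the depth axis:
#' \code{v <- v + lambda L(v)} then \code{v <- v + mu L(v)}, where L is the
#' 1-D umbrella operator (neighbour mean minus value) and the endpoints are
#' held fixed. The lambda/mu pair (0.5, -0.53) is the classic shrink-free
#' choice; only the iteration count is exposed.
#'
#' @param profiles a \code{profile_set}.
#' @param iterations number of lambda+mu passes (>= 0; default 2).
#' @param lambda,mu Taubin coefficients.
#' @return the smoothed \code{profile_set}.
#' @export
smooth_profiles_depthwise <- function(profiles, iterations = 2,
                                      lambda = 0.5, mu = -0.53) {
  stopifnot(inherits(profiles, "profile_set"))
  if (iterations < 0) stop("iterations must be >= 0")
  v <- profiles$values
  k <- nrow(v)
  if (k < 3) {
    warning("fewer than 3 depths; depth-wise smoothing is a no-op")
    return(profiles)
  }
  umbrella_step <- function(v, coef) {
    l <- (v[1:(k - 2), , drop = FALSE] + v[3:k, , drop = FALSE]) / 2 -
      v[2:(k - 1), , drop = FALSE]
    v[2:(k - 1), ] <- v[2:(k - 1), , drop = FALSE] + coef * l
    v
  }
  for (i in seq_len(iterations)) {
    v <- umbrella_step(v, lambda)
    v <- umbrella_step(v, mu)
  }
  profile_set(v, profiles$alpha, mesh_ref = profiles$mesh_ref,
              mask = profiles$mask)
}

#' Surface-wise profile smoothing
#'
#' Applies geodesic Gaussian smoothing (\code{\link{surface_gaussian_smooth}})
#' at each depth independently.
#'
#' @param profiles a \code{profile_set}.
#' @param mesh the \code{triangle_mesh} the profile columns live on.
#' @param fwhm kernel FWHM in mm (default 2).
#' @param graph optional precomputed adjacency graph.
#' @return the smoothed \code{profile_set}.
#' @export
smooth_profiles_surface <- function(profiles, mesh, fwhm = 2, graph = NULL) {
  stopifnot(inherits(profiles, "profile_set"))
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(profiles)
  if (is.null(graph)) graph <- adjacency_graph(mesh)
  W <- smoothing_weights(mesh, fwhm, graph)
  v <- t(as.matrix(Matrix::tcrossprod(W, Matrix::Matrix(profiles$values))))
  profile_set(v, profiles$alpha, mesh_ref = profiles$mesh_ref,
              mask = profiles$mask)
}

#' Count the peaks of a depth profile
#'
#' A peak is an interior depth strictly greater than both neighbours.
#' Plateaus (runs of equal values) count once, at the leftmost plateau
#' index, iff the profile is strictly greater on both plateau flanks.
#' Endpoints are never peaks.
#'
#' @param profile numeric vector of length K >= 3.
#' @return integer peak count.
#' @export
count_profile_peaks <- function(profile) {
  k <- length(profile)
  if (k < 3) stop("a profile needs at least 3 depths")
  # collapse plateaus to single samples, remembering nothing but order
  r <- rle(profile)$values
  m <- length(r)
  if (m < 3) return(0L)
  sum(r[2:(m - 1)] > r[1:(m - 2)] & r[2:(m - 1)] > r[3:m])
}

#' Spatial autocorrelation of profiles along the mesh
#'
#' For each hop distance d = 1..max_steps, the mean product-moment
#' correlation between the depth profiles of vertex pairs exactly d steps
#' apart on the mesh graph. Pairs are drawn from a budgeted sample of
#' source vertices (deterministic given \code{seed}).
#'
#' @param profiles a \code{profile_set}.
#' @param graph adjacency graph of the profile mesh.
#' @param max_steps largest hop distance (default 50).
#' @param n_sources number of source vertices sampled (budget).
#' @param max_pairs_per_step per-distance cap on correlated pairs.
#' @param seed integer seed for the pair sampling.
#' @return numeric vector of length \code{max_steps}; \code{NA} where no
#'   pair at that distance exists.
#' @export
spatial_autocorrelation <- function(profiles, graph, max_steps = 50,
                                    n_sources = 200, max_pairs_per_step = 500,
                                    seed = 1L) {
  stopifnot(inherits(profiles, "profile_set"))
  if (max_steps < 1) stop("max_steps must be >= 1")
  n <- ncol(profiles$values)
  with_seed(seed, {
    src <- if (n_sources >= n) seq_len(n) else sort(sample.int(n, n_sources))
    hops <- igraph::distances(graph, v = src, weights = NA)
    out <- rep(NA_real_, max_steps)
    for (d in seq_len(max_steps)) {
      idx <- which(hops == d, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      if (nrow(idx) > max_pairs_per_step)
        idx <- idx[sample.int(nrow(idx), max_pairs_per_step), , drop = FALSE]
      a <- profiles$values[, src[idx[, 1]], drop = FALSE]
      b <- profiles$values[, idx[, 2], drop = FALSE]
      cors <- colsums_cor(a, b)
      out[d] <- mean(cors, na.rm = TRUE)
    }
    out
  })
}

# columnwise Pearson correlation between paired matrices
colsums_cor <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  den <- sqrt(colSums(a^2) * colSums(b^2))
  out <- colSums(a * b) / den
  out[den == 0] <- NA_real_
  out
}
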