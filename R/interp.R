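# Separable-kernel interpolation of 3D volumes at arbitrary world points.
# All methods share the same out-of-volume rule: a point whose continuous
# voxel coordinate falls outside [0, dim-1] on any axis receives the volume's
# background value and inside = FALSE. Kernel taps that protrude past the
# border are clamped (border replication), so wide kernels stay defined up to
# the edge.

interp_methods <- c("trilinear", "tricubic", "nearest", "sinc")

kernel_taps <- list(trilinear = 0:1, tricubic = -1:2, sinc = -3:4)

# Keys cubic-convolution kernel, a = -0.5 (weights sum to 1 exactly)
keys_cubic <- function(t) {
  t <- abs(t)
  a <- -0.5
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- a * (t[i2]^3 - 5 * t[i2]^2 + 8 * t[i2] - 4)
  w
}

# Lanczos-windowed sinc, radius 4 voxels
lanczos4 <- function(t) {
  w <- numeric(length(t))
  inr <- abs(t) < 4
  tt <- t[inr]
  s <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  w[inr] <- s(tt) * s(tt / 4)
  w
}

axis_weights <- function(frac, method) {
  taps <- kernel_taps[[method]]
  w <- switch(method,
    trilinear = cbind(1 - frac, frac),
    tricubic = vapply(taps, function(o) keys_cubic(o - frac),
                      numeric(length(frac))),
    sinc = vapply(taps, function(o) lanczos4(o - frac),
                  numeric(length(frac))))
  if (!is.matrix(w)) w <- matrix(w, nrow = length(frac))
  if (method == "sinc") w <- w / rowSums(w)  # windowed sinc: renormalise
  w
}

#' Interpolate a volume at world coordinates
#'
#' @param volume an \code{intensity_volume}.
#' @param points n x 3 matrix of world coordinates (mm).
#' @param method one of \code{"trilinear"}, \code{"tricubic"},
#'   \code{"nearest"}, \code{"sinc"} (Lanczos window, radius 4 voxels).
#' @return list with \code{values} (length n; background where outside) and
#'   \code{inside} (logical validity mask).
#' @export
interp_volume <- function(volume, points, method = "trilinear") {
  stopifnot(inherits(volume, "intensity_volume"))
  method <- match.arg(method, interp_methods)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  v <- world_to_voxel(points, volume$affine)
  d <- dim(volume$data)
  inside <- v[, 1] >= 0 & v[, 1] <= d[1] - 1 &
    v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
    v[, 3] >= 0 & v[, 3] <= d[3] - 1
  inside[!is.finite(rowSums(v))] <- FALSE
  values <- rep(volume$background, nrow(points))
  if (!any(inside)) return(list(values = values, inside = inside))
  vi <- v[inside, , drop = FALSE]

  if (method == "nearest") {
    idx <- round(vi)
    values[inside] <- volume$data[cbind(idx[, 1], idx[, 2], idx[, 3]) + 1L]
    return(list(values = values, inside = inside))
  }

  taps <- kernel_taps[[method]]
  base <- floor(vi)
  frac <- vi - base
  wx <- axis_weights(frac[, 1], method)
  wy <- axis_weights(frac[, 2], method)
  wz <- axis_weights(frac[, 3], method)
  acc <- numeric(nrow(vi))
  dat <- volume$data
  for (a in seq_along(taps)) {
    ix <- pmin(pmax(base[, 1] + taps[a], 0), d[1] - 1) + 1L
    for (b in seq_along(taps)) {
      iy <- pmin(pmax(base[, 2] + taps[b], 0), d[2] - 1) + 1L
      wxy <- wx[, a] * wy[, b]
      for (cc in seq_along(taps)) {
        iz <- pmin(pmax(base[, 3] + taps[cc], 0), d[3] - 1) + 1L
        w <- wxy * wz[, cc]
        nz <- w != 0
        if (any(nz))
          acc[nz] <- acc[nz] + w[nz] * dat[cbind(ix[nz], iy[nz], iz[nz])]
      }
    }
  }
  values[inside] <- acc
  list(values = values, inside = inside)
}
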