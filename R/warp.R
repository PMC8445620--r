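# Applying and evaluating dense displacement fields. The convention is
# pull-back resampling: the field lives on the output (fixed) grid and
# output voxel v samples the input at world(v) + d(v).

field_world_points <- function(field) {
  dm <- dim(field$vectors)[1:3]
  idx <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1),
                               k = 0:(dm[3] - 1)))
  voxel_to_world(idx, field$affine)
}

#' Apply a displacement field to a volume
#'
#' Resamples \code{volume} onto the field grid: each output voxel at world
#' position x receives the input interpolated at \code{x + d(x)}.
#' Out-of-range samples get the background value.
#'
#' @param volume input \code{intensity_volume}.
#' @param field a \code{displacement_field} on the output grid.
#' @param interp \code{"trilinear"} (default), \code{"tricubic"},
#'   \code{"nearest"} or \code{"sinc"}.
#' @return the resampled \code{intensity_volume} on the field grid.
#' @export
apply_displacement_volume <- function(volume, field, interp = "trilinear") {
  stopifnot(inherits(volume, "intensity_volume"),
            inherits(field, "displacement_field"))
  interp <- match.arg(interp, interp_methods)
  dm <- dim(field$vectors)[1:3]
  pts <- field_world_points(field)
  d <- matrix(field$vectors, ncol = 3)
  res <- interp_volume(volume, pts + d, method = interp)
  intensity_volume(array(res$values, dm), field$affine,
                   background = volume$background)
}

#' Transform fiducial points through a displacement field
#'
#' Each point maps to \code{p + d(p)} with d interpolated trilinearly from
#' the vector grid. Points outside the grid are passed through unmoved and
#' flagged in the \code{"outside"} attribute.
#'
#' @param points a \code{fiducial_set}.
#' @param field a \code{displacement_field}.
#' @return the transformed \code{fiducial_set} with an \code{"outside"}
#'   logical attribute.
#' @export
transform_points <- function(points, field) {
  stopifnot(inherits(points, "fiducial_set"),
            inherits(field, "displacement_field"))
  dm <- dim(field$vectors)[1:3]
  disp <- matrix(NA_real_, nrow(points$points), 3)
  inside <- rep(TRUE, nrow(points$points))
  for (c3 in 1:3) {
    comp <- intensity_volume(field$vectors[, , , c3], field$affine)
    res <- interp_volume(comp, points$points, method = "trilinear")
    disp[, c3] <- res$values
    inside <- inside & res$inside
  }
  disp[!inside, ] <- 0
  out <- fiducial_set(points$names, points$points + disp)
  attr(out, "outside") <- !inside
  out
}

#' Jacobian determinant map of a displacement field
#'
#' \code{det(I + dd/dx)} per voxel, with spatial gradients taken by central
#' differences in world mm (one-sided at grid borders). Values above 1 mark
#' local expansion, below 1 compression.
#'
#' @param field a \code{displacement_field} with at least 3 voxels per axis.
#' @return an \code{intensity_volume} of determinants on the field grid.
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  dm <- dim(field$vectors)[1:3]
  if (any(dm < 3)) stop("the field grid needs >= 3 voxels per axis")
  ainv <- solve(field$affine[1:3, 1:3])  # d(index)/d(world)
  # gradient of each displacement component along each index axis
  g <- array(NA_real_, c(dm, 3, 3))  # [x,y,z, component, index-axis]
  for (comp in 1:3) {
    v <- field$vectors[, , , comp]
    for (ax in 1:3) {
      g[, , , comp, ax] <- index_gradient(v, ax)
    }
  }
  det_map <- array(NA_real_, dm)
  # J_world = I + (dd/dindex) %*% d(index)/d(world), evaluated voxel-wise
  gi <- matrix(aperm(g, c(4, 5, 1, 2, 3)), nrow = 9)  # 9 x nvox, comp fastest
  nvox <- prod(dm)
  a11 <- ainv[1, ]; a21 <- ainv[2, ]; a31 <- ainv[3, ]
  # dd_c/dx_w = sum_ax g[c,ax] * ainv[ax,w]
  J <- array(0, c(3, 3, nvox))
  for (w in 1:3) {
    for (cc in 1:3) {
      J[cc, w, ] <- gi[cc, ] * ainv[1, w] + gi[cc + 3, ] * ainv[2, w] +
        gi[cc + 6, ] * ainv[3, w]
    }
    J[w, w, ] <- J[w, w, ] + 1
  }
  det_map[] <- J[1, 1, ] * (J[2, 2, ] * J[3, 3, ] - J[2, 3, ] * J[3, 2, ]) -
    J[1, 2, ] * (J[2, 1, ] * J[3, 3, ] - J[2, 3, ] * J[3, 1, ]) +
    J[1, 3, ] * (J[2, 1, ] * J[3, 2, ] - J[2, 2, ] * J[3, 1, ])
  intensity_volume(det_map, field$affine, background = 1)
}

# central differences along index axis `ax`, one-sided at borders
index_gradient <- function(v, ax) {
  dm <- dim(v)
  n <- dm[ax]
  shift <- function(off) {
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    switch(ax,
           v[idx, , , drop = FALSE],
           v[, idx, , drop = FALSE],
           v[, , idx, drop = FALSE])
  }
  denom <- array(2, dm)
  edge1 <- function(arr, val) {
    switch(ax,
           arr[c(1, n), , ] <- val,
           arr[, c(1, n), ] <- val,
           arr[, , c(1, n)] <- val)
    arr
  }
  denom <- edge1(denom, 1)
  (shift(1L) - shift(-1L)) / denom
}

#' Dice overlap per label
#'
#' \code{2 |A n B| / (|A| + |B|)} for every label code present in either
#' volume; a label absent from one of the two has undefined Dice and is
#' reported as \code{NA}.
#'
#' @param a,b \code{label_volume}s on the same grid and affine.
#' @return named numeric vector of Dice coefficients, one per label code
#'   (background 0 excluded).
#' @export
dice_overlap <- function(a, b) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!all(dim(a$data) == dim(b$data)) ||
        max(abs(a$affine - b$affine)) > 1e-6)
    stop("label volumes must share grid and affine")
  codes <- setdiff(sort(unique(c(a$data, b$data))), 0L)
  out <- vapply(codes, function(l) {
    na <- sum(a$data == l)
    nb <- sum(b$data == l)
    if (na == 0 || nb == 0) return(NA_real_)
    2 * sum(a$data == l & b$data == l) / (na + nb)
  }, numeric(1))
  names(out) <- codes
  out
}

#' Fiducial misregistration distances
#'
#' Euclidean distance per matched landmark name, with the summary reported
#' as mean, SD and maximum (the conventional "mean +/- SD, max" form).
#'
#' @param reference,transformed \code{fiducial_set}s with matching names
#'   (order-free).
#' @return list with \code{distances} (named, mm) and \code{summary}
#'   (mean, sd, max).
#' @export
fiducial_misregistration <- function(reference, transformed) {
  stopifnot(inherits(reference, "fiducial_set"),
            inherits(transformed, "fiducial_set"))
  missing_names <- c(setdiff(reference$names, transformed$names),
                     setdiff(transformed$names, reference$names))
  if (length(missing_names) > 0)
    stop("unmatched fiducial names: ",
         paste(unique(missing_names), collapse = ", "))
  m <- match(reference$names, transformed$names)
  d <- sqrt(rowSums((reference$points -
                       transformed$points[m, , drop = FALSE])^2))
  names(d) <- reference$names
  list(distances = d,
       summary = c(mean = mean(d), sd = stats::sd(d), max = max(d)))
}

#' Region-stratified summary of a metric volume
#'
#' Summarises metric values (e.g. a Jacobian map) over the voxels of each
#' region group (e.g. lobes built from an atlas).
#'
#' @param metric_volume an \code{intensity_volume}.
#' @param regions a \code{label_volume} on the same grid.
#' @param groups named list mapping group name -> vector of label codes;
#'   default one group per label code.
#' @param probs quantiles reported (default quartiles).
#' @return data.frame with one row per group: n, mean, sd and quantiles.
#' @export
stratified_summary <- function(metric_volume, regions, groups = NULL,
                               probs = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(metric_volume, "intensity_volume"),
            inherits(regions, "label_volume"))
  if (!all(dim(metric_volume$data) == dim(regions$data)))
    stop("metric and region volumes must share the grid")
  if (is.null(groups)) {
    codes <- setdiff(sort(unique(as.vector(regions$data))), 0L)
    groups <- stats::setNames(as.list(codes), paste0("label_", codes))
  }
  do.call(rbind, lapply(names(groups), function(gname) {
    sel <- regions$data %in% groups[[gname]]
    x <- metric_volume$data[sel]
    qs <- if (length(x)) stats::quantile(x, probs) else
      stats::setNames(rep(NA_real_, length(probs)),
                      paste0(100 * probs, "%"))
    cbind(data.frame(group = gname, n = length(x),
                     mean = if (length(x)) mean(x) else NA_real_,
                     sd = if (length(x) > 1) stats::sd(x) else NA_real_),
          as.data.frame(as.list(qs), check.names = FALSE,
                        col.names = paste0("q", 100 * probs)))
  }))
}
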