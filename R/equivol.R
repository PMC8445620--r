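# Equivolumetric intracortical surface placement. Surfaces are initialised
# at equidistant depths and modulated by cortical curvature through the
# local pial/white area ratio, so equal tissue-volume fractions (not equal
# distances) separate consecutive surfaces.

#' Equivolumetric depth fraction
#'
#' For a cortical column modelled as a frustum whose cross-sectional area
#' varies linearly from \code{area_pial} at depth 0 to \code{area_white} at
#' depth 1, returns the distance fraction rho (from the pial surface) below
#' which a fraction \code{alpha} of the column volume lies:
#' \deqn{\rho = \frac{-A_p + \sqrt{(1-\alpha) A_p^2 + \alpha A_w^2}}{A_w - A_p}}
#' with the equidistant limit \code{rho = alpha} when the areas are equal.
#'
#' @param area_pial,area_white positive local areas (mm^2); vectors recycle.
#' @param alpha volume fraction(s) in [0, 1] (0 = pial, 1 = white).
#' @return distance fraction(s) in [0, 1].
#' @export
equivolumetric_fraction <- function(area_pial, area_white, alpha) {
  if (any(area_pial <= 0) || any(area_white <= 0))
    stop("areas must be positive")
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  n <- max(length(area_pial), length(area_white), length(alpha))
  ap <- rep_len(area_pial, n)
  aw <- rep_len(area_white, n)
  al <- rep_len(alpha, n)
  rho <- al
  neq <- abs(aw - ap) > 1e-12 * pmax(ap, aw)
  rho[neq] <- (-ap[neq] + sqrt((1 - al[neq]) * ap[neq]^2 +
                                 al[neq] * aw[neq]^2)) / (aw[neq] - ap[neq])
  pmin(pmax(rho, 0), 1)
}

#' Build an equivolumetric (or equidistant) surface stack
#'
#' Computes per-vertex pial and white areas with \code{\link{vertex_areas}}
#' and places surface k (volume fraction \code{alpha_k = (k-1)/(K-1)}) at
#' \code{pial + rho(A_p, A_w, alpha_k) * (white - pial)} along the straight
#' segment joining corresponding vertices. With
#' \code{method = "equidistant"} the curvature modulation is skipped and
#' \code{rho = alpha} everywhere (useful as a baseline).
#'
#' @param sheet a \code{cortical_sheet}.
#' @param n_surfaces number of surfaces K (>= 2; default 50).
#' @param method \code{"equivolumetric"} (default) or \code{"equidistant"}.
#' @param area_fwhm optional geodesic FWHM (mm) for pre-smoothing the pial
#'   and white area maps before computing rho; 0 disables (default).
#' @return a \code{surface_stack}.
#' @export
build_surface_stack <- function(sheet, n_surfaces = 50,
                                method = c("equivolumetric", "equidistant"),
                                area_fwhm = 0) {
  stopifnot(inherits(sheet, "cortical_sheet"))
  method <- match.arg(method)
  if (n_surfaces < 2) stop("n_surfaces must be >= 2")
  n <- n_vertices(sheet$pial)
  alpha <- seq(0, 1, length.out = n_surfaces)
  p <- sheet$pial$vertices
  w <- sheet$white$vertices
  if (method == "equivolumetric") {
    ap <- vertex_areas(sheet$pial)
    aw <- vertex_areas(sheet$white)
    if (area_fwhm > 0) {
      g <- adjacency_graph(sheet$pial)
      ap <- surface_gaussian_smooth(sheet$pial, ap, area_fwhm, graph = g)
      aw <- surface_gaussian_smooth(sheet$pial, aw, area_fwhm, graph = g)
    }
    rho <- vapply(alpha, function(a) equivolumetric_fraction(ap, aw, a),
                  numeric(n))
  } else {
    rho <- matrix(alpha, nrow = n, ncol = n_surfaces, byrow = TRUE)
  }
  degenerate <- rowSums((p - w)^2) == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-thickness vertices; rho set to alpha there")
    rho[degenerate, ] <- matrix(alpha, nrow = sum(degenerate),
                                ncol = n_surfaces, byrow = TRUE)
  }
  coords <- array(NA_real_, c(n_surfaces, n, 3))
  for (k in seq_len(n_surfaces)) {
    coords[k, , ] <- p + rho[, k] * (w - p)
  }
  surface_stack(coords, alpha, t(rho))
}
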