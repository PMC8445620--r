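# Moment-based profile parameterisation and label-stratified summaries.
# The five classic observer-independent features (mean, centre of gravity,
# SD, skewness, kurtosis) are computed for the profile and for its
# finite-difference derivative: 10 features per vertex.

moment_feature_names <- c("mean", "cog", "sd", "skewness", "kurtosis",
                          "d_mean", "d_cog", "d_sd", "d_skewness",
                          "d_kurtosis")

profile_moments_one <- function(p, alpha) {
  m <- mean(p)
  m2 <- mean((p - m)^2)
  s <- sqrt(m2)
  skew <- if (m2 > 0) mean((p - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((p - m)^4) / m2^2 - 3 else 0
  tot <- sum(p)
  cog <- if (abs(tot) > 0) sum(alpha * p) / tot else NA_real_
  c(mean = m, cog = cog, sd = s, skewness = skew, kurtosis = kurt)
}

#' Central-moment features of staining-intensity profiles
#'
#' Per profile: mean, centre of gravity (intensity-weighted mean depth
#' fraction), SD, Fisher skewness and excess kurtosis of the intensity
#' values across depth; and the same five for the finite-difference
#' derivative profile (centre of gravity taken on the absolute derivative,
#' at the mid-depth grid). Zero-sum profiles get \code{NA} centre of
#' gravity.
#'
#' @param profiles a \code{profile_set} (or a single numeric profile plus
#'   \code{alpha}).
#' @param alpha depth fractions; taken from the profile set when omitted.
#' @return N x 10 matrix with columns \code{mean, cog, sd, skewness,
#'   kurtosis, d_mean, d_cog, d_sd, d_skewness, d_kurtosis}.
#' @export
central_moments <- function(profiles, alpha = NULL) {
  if (inherits(profiles, "profile_set")) {
    v <- profiles$values
    alpha <- profiles$alpha
  } else {
    v <- as.matrix(profiles)
    if (is.null(alpha)) stop("alpha is required for raw profile input")
  }
  k <- nrow(v)
  if (k < 4) stop("moment features need K >= 4 depths")
  dal <- diff(alpha)
  amid <- (alpha[-1] + alpha[-k]) / 2
  out <- t(apply(v, 2, function(p) {
    d <- diff(p) / dal
    c(profile_moments_one(p, alpha),
      {
        md <- profile_moments_one(d, amid)
        ad <- abs(d)
        md["cog"] <- if (sum(ad) > 0) sum(amid * ad) / sum(ad) else NA_real_
        md
      })
  }))
  colnames(out) <- moment_feature_names
  out
}

#' Average profiles within parcels
#'
#' @param profiles a \code{profile_set} (columns = vertices).
#' @param parcels a \code{parcel_map} covering every column.
#' @return P x K matrix of parcel-average profiles (row p is the mean
#'   profile of parcel p).
#' @export
parcel_average_profiles <- function(profiles, parcels) {
  stopifnot(inherits(profiles, "profile_set"),
            inherits(parcels, "parcel_map"))
  if (length(parcels$assignment) != ncol(profiles$values))
    stop("parcel map and profile set disagree on vertex count")
  grp <- factor(parcels$assignment, levels = seq_along(parcels$selected))
  out <- apply(profiles$values, 1, function(row) tapply(row, grp, mean))
  matrix(out, nrow = length(parcels$selected),
         dimnames = NULL)  # P x K (apply stacks per-depth results as columns)
}

#' Partial-correlation matrix of parcel profiles
#'
#' Entry (i, j) is the Pearson correlation across depth of the residuals of
#' profiles i and j after least-squares regression (with intercept) on the
#' control profile — by default the global mean profile. Equals the
#' standard partial-correlation identity
#' \code{(r_ij - r_ic r_jc) / sqrt((1 - r_ic^2)(1 - r_jc^2))}.
#'
#' @param parcel_profiles P x K matrix (rows = parcels).
#' @param control length-K control profile; default the column mean of
#'   \code{parcel_profiles}.
#' @return P x P symmetric matrix, diagonal 1; entries with zero residual
#'   variance are \code{NA}.
#' @export
partial_correlation_matrix <- function(parcel_profiles, control = NULL) {
  x <- as.matrix(parcel_profiles)
  k <- ncol(x)
  if (k <= 3) stop("need K > 3 depths")
  if (is.null(control)) control <- colMeans(x)
  if (length(control) != k) stop("control profile length must equal K")
  cc <- control - mean(control)
  xc <- sweep(x, 1, rowMeans(x))
  denom <- sum(cc^2)
  resid <- if (denom > 0) {
    beta <- as.numeric(xc %*% cc) / denom
    xc - outer(beta, cc)
  } else xc
  rv <- rowSums(resid^2)
  r <- tcrossprod(resid) / sqrt(outer(rv, rv))
  diag(r) <- 1
  # residual variance at floating-point noise level counts as zero
  degen <- rv <= 1e-12 * pmax(rowSums(xc^2), .Machine$double.eps)
  r[degen, ] <- NA_real_
  r[, degen] <- NA_real_
  r
}

#' Normalised-angle affinity
#'
#' Maps correlations to affinities in [0, 1]:
#' \code{a = 1 - acos(r) / pi}, so r = 1, 0, -1 give 1, 0.5, 0.
#'
#' @param corr matrix (or vector) of correlations in [-1, 1]; values within
#'   1e-9 past the bounds are clipped, anything further is an error.
#' @return affinity of the same shape.
#' @export
normalised_angle <- function(corr) {
  if (any(abs(corr) > 1 + 1e-9, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  r <- pmin(pmax(corr, -1), 1)
  out <- 1 - acos(r) / pi
  if (is.matrix(corr)) dim(out) <- dim(corr)
  out
}

#' Stratify per-vertex features by surface labels
#'
#' Summarises each feature within each label: count, mean, SD. Vertices
#' within \code{exclude_margin} mm (geodesic) of a label boundary (a vertex
#' with a differently-labelled neighbour) can be excluded before
#' summarising.
#'
#' @param features N x F numeric matrix (rows = vertices).
#' @param labels integer per-vertex label codes.
#' @param mesh a \code{triangle_mesh}; required when \code{exclude_margin > 0}.
#' @param exclude_margin geodesic boundary margin in mm (default 0 = keep all).
#' @param graph optional precomputed adjacency graph.
#' @return a data.frame with columns \code{label, feature, n, mean, sd}.
#' @export
stratify_features_by_label <- function(features, labels, mesh = NULL,
                                       exclude_margin = 0, graph = NULL) {
  features <- as.matrix(features)
  if (length(labels) != nrow(features))
    stop("labels must align with feature rows")
  keep <- rep(TRUE, length(labels))
  if (exclude_margin > 0) {
    if (is.null(mesh)) stop("mesh is required for boundary exclusion")
    if (is.null(graph)) graph <- adjacency_graph(mesh)
    bnd <- boundary_vertices(graph, labels)
    if (length(bnd) > 0) {
      d <- weighted_geodesic(graph, bnd)
      keep <- d >= exclude_margin
    }
  }
  fn <- colnames(features)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(features)))
  out <- do.call(rbind, lapply(sort(unique(labels)), function(l) {
    rows <- which(labels == l & keep)
    do.call(rbind, lapply(seq_along(fn), function(j) {
      x <- features[rows, j]
      data.frame(label = l, feature = fn[j], n = length(rows),
                 mean = if (length(rows)) mean(x) else NA_real_,
                 sd = if (length(rows) > 1) stats::sd(x) else NA_real_)
    }))
  }))
  attr(out, "kept") <- keep
  out
}

boundary_vertices <- function(graph, labels) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  mixed <- labels[el[, 1]] != labels[el[, 2]]
  sort(unique(c(el[mixed, 1], el[mixed, 2])))
}
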