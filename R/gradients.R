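# Diffusion map embedding of profile-similarity matrices. Nontrivial
# eigenvectors of the anisotropic diffusion operator form the large-scale
# gradients of cytoarchitectural differentiation.

#' Diffusion map embedding of an affinity matrix
#'
#' Row-wise sparsifies the affinity (keeping the top \code{1 - sparsity}
#' fraction of each row), symmetrises by averaging, forms the anisotropic
#' kernel \code{W' = D^-a W D^-a} (density normalisation, default
#' \code{a = 0.5}), row-normalises to the diffusion operator and returns
#' its nontrivial right eigenvectors scaled by their eigenvalues
#' (diffusion time 0 convention). Variance explained is each nontrivial
#' eigenvalue over the nontrivial eigenvalue sum. The sign of each
#' component is fixed so its correlation with parcel index is nonnegative.
#'
#' @param affinity P x P symmetric nonnegative matrix (e.g. from
#'   \code{\link{normalised_angle}}).
#' @param n_components number of gradients to return (default 10).
#' @param diffusion_alpha density-normalisation exponent in [0, 1]
#'   (default 0.5).
#' @param sparsity fraction of each row zeroed before embedding, in [0, 1)
#'   (default 0.9).
#' @return an object of class \code{gradient_result}: list with
#'   \code{eigenvectors} (P x C), \code{eigenvalues} (nonincreasing),
#'   \code{variance_explained}.
#' @export
diffusion_embedding <- function(affinity, n_components = 10,
                                diffusion_alpha = 0.5, sparsity = 0.9) {
  a <- as.matrix(affinity)
  p <- nrow(a)
  if (p != ncol(a)) stop("affinity must be square")
  if (max(abs(a - t(a))) > 1e-8) stop("affinity must be symmetric")
  if (any(a < -1e-12)) stop("affinity must be nonnegative")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must lie in [0, 1)")

  w <- a
  if (sparsity > 0) {
    keep <- max(1L, ceiling((1 - sparsity) * p))
    for (i in seq_len(p)) {
      thr <- sort(w[i, ], decreasing = TRUE)[keep]
      w[i, w[i, ] < thr] <- 0
    }
    w <- (w + t(w)) / 2
  }

  comps <- igraph::components(
    igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected"))
  if (comps$no > 1)
    stop("affinity graph is disconnected (", comps$no, " components of sizes ",
         paste(comps$csize, collapse = ", "), ")")

  d <- rowSums(w)
  w2 <- w / outer(d^diffusion_alpha, d^diffusion_alpha)
  d2 <- rowSums(w2)
  # symmetric conjugate of the row-normalised operator
  s <- w2 / outer(sqrt(d2), sqrt(d2))
  es <- eigen(s, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  lam <- es$values[ord]
  psi <- es$vectors[, ord, drop = FALSE] / sqrt(d2)  # right eigenvectors
  nc <- min(n_components, p - 1)
  lam_nt <- lam[-1]
  lam_pos <- pmax(lam_nt, 0)
  ev <- sweep(psi[, 1 + seq_len(nc), drop = FALSE], 2, lam_nt[seq_len(nc)],
              `*`)
  # deterministic sign: correlate with parcel index
  idx <- seq_len(p)
  for (j in seq_len(nc)) {
    if (stats::sd(ev[, j]) > 0 && stats::cor(ev[, j], idx) < 0)
      ev[, j] <- -ev[, j]
  }
  structure(list(eigenvectors = ev,
                 eigenvalues = lam_nt[seq_len(nc)],
                 variance_explained = lam_pos[seq_len(nc)] / sum(lam_pos)),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat("<gradient_result> ", nrow(x$eigenvectors), " parcels x ",
      ncol(x$eigenvectors), " components; variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$variance_explained[
        seq_len(min(3, length(x$variance_explained)))]), collapse = ", "),
      " ...\n", sep = "")
  invisible(x)
}

#' Full histological-gradient pipeline
#'
#' The four stages in one call: (1) parcel-average profiles, (2) partial
#' correlation controlling for the global mean profile, (3) normalised
#' angle, (4) diffusion map embedding.
#'
#' @param profiles a \code{profile_set}.
#' @param parcels a \code{parcel_map}.
#' @param n_components,diffusion_alpha,sparsity passed to
#'   \code{\link{diffusion_embedding}}.
#' @return a \code{gradient_result} with the parcel-average profiles and
#'   affinity attached as attributes.
#' @export
profile_gradients <- function(profiles, parcels, n_components = 10,
                              diffusion_alpha = 0.5, sparsity = 0.9) {
  pp <- parcel_average_profiles(profiles, parcels)
  r <- partial_correlation_matrix(pp)
  aff <- normalised_angle(r)
  g <- diffusion_embedding(aff, n_components = n_components,
                           diffusion_alpha = diffusion_alpha,
                           sparsity = sparsity)
  attr(g, "parcel_profiles") <- pp
  attr(g, "affinity") <- aff
  g
}
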