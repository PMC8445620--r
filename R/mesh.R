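# Mesh graph and geometry primitives. Geodesics are graph geodesics along
# triangle edges (the convention used for surface-mesh spatial statistics),
# not exact polyhedral geodesics.

#' Build the vertex adjacency graph of a mesh
#'
#' Vertices u and v are adjacent iff they share a face; each edge carries its
#' Euclidean length in mm as the \code{weight} attribute.
#'
#' @param mesh a \code{triangle_mesh}.
#' @return an \code{igraph} undirected graph with N vertices and a
#'   \code{weight} edge attribute (mm).
#' @export
adjacency_graph <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, n_vertices(mesh) - igraph::vcount(g))
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  igraph::E(g)$weight <- len
  g
}

#' Breadth-first hop distance from a source set
#'
#' The number of steps is the shortest path along the surface mesh treating
#' edges as a graph.
#'
#' @param graph adjacency graph from \code{\link{adjacency_graph}}.
#' @param sources non-empty vector of source vertex indices (1-based).
#' @param max_steps hop radius; vertices further away are returned as
#'   \code{NA} (unreached).
#' @return numeric vector of per-vertex hop counts (\code{NA} = unreached).
#' @export
step_distance <- function(graph, sources, max_steps = Inf) {
  if (length(sources) == 0) stop("sources must be non-empty")
  d <- igraph::distances(graph, v = sources, weights = NA)
  d <- apply(d, 2, min)
  d[!is.finite(d) | d > max_steps] <- NA_real_
  d
}

#' Edge-weighted geodesic distance from a source set
#'
#' Dijkstra shortest-path distance along mesh edges, in mm. Vertices in
#' components that contain no source come back as \code{Inf} (reported, not
#' raised).
#'
#' @param graph adjacency graph with mm edge weights.
#' @param sources non-empty vector of source vertex indices.
#' @return numeric vector of per-vertex distances in mm.
#' @export
weighted_geodesic <- function(graph, sources) {
  if (length(sources) == 0) stop("sources must be non-empty")
  d <- igraph::distances(graph, v = sources,
                         weights = igraph::E(graph)$weight)
  apply(d, 2, min)
}

#' Per-vertex surface area
#'
#' Each vertex receives one third of the summed areas of its incident faces,
#' so the vertex areas partition the total surface area.
#'
#' @param mesh a \code{triangle_mesh}.
#' @return numeric vector of per-vertex areas in mm^2.
#' @export
vertex_areas <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  face_area <- 0.5 * sqrt(rowSums(cr^2))
  out <- numeric(n_vertices(mesh))
  for (j in 1:3) {
    s <- tapply(face_area, f[, j], sum)
    idx <- as.integer(names(s))
    out[idx] <- out[idx] + s
  }
  out / 3
}

#' Geodesic Gaussian smoothing of a per-vertex field
#'
#' Weighted vertex averaging with Gaussian weights
#' \code{exp(-d^2 / (2 sigma^2))} on the edge-weighted geodesic distance d,
#' truncated at 3 sigma and renormalised to sum 1 per vertex
#' (\code{sigma = fwhm / 2.3548}). \code{fwhm = 0} is the identity.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param field per-vertex numeric vector (finite).
#' @param fwhm kernel full width at half maximum, mm (>= 0).
#' @param graph optional precomputed adjacency graph (saves recomputation
#'   when smoothing many fields on one mesh).
#' @return smoothed per-vertex vector.
#' @export
surface_gaussian_smooth <- function(mesh, field, fwhm, graph = NULL) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (length(field) != n_vertices(mesh))
    stop("field length must equal the vertex count")
  if (!all(is.finite(field))) stop("field must be finite")
  if (fwhm == 0) return(field)
  W <- smoothing_weights(mesh, fwhm, graph)
  as.numeric(W %*% field)
}

smoothing_weights <- function(mesh, fwhm, graph = NULL) {
  if (is.null(graph)) graph <- adjacency_graph(mesh)
  sigma <- fwhm / 2.3548
  d <- igraph::distances(graph, weights = igraph::E(graph)$weight)
  w <- exp(-d^2 / (2 * sigma^2))
  w[d > 3 * sigma] <- 0
  w <- Matrix::Matrix(w, sparse = TRUE)
  Matrix::Diagonal(x = 1 / Matrix::rowSums(w)) %*% w
}

#' Decimate a mesh into parcels
#'
#' Selects \code{n_target} vertices by farthest-point sampling on the
#' edge-weighted graph (the first vertex drawn deterministically from
#' \code{seed}) and assigns every vertex to the nearest selected vertex by
#' hop distance; ties are broken by smallest Euclidean distance, remaining
#' ties by lowest selected-vertex index. Every selected vertex is assigned
#' to itself, so the assignment is a partition into \code{n_target} parcels.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param n_target number of parcels, in [1, N].
#' @param seed integer seed for the initial farthest-point vertex.
#' @param graph optional precomputed adjacency graph.
#' @return an object of class \code{parcel_map}: list with
#'   \code{assignment} (per-vertex parcel id, 1..n_target) and
#'   \code{selected} (selected vertex indices; parcel k is centred on
#'   \code{selected[k]}).
#' @export
decimate_and_parcellate <- function(mesh, n_target, seed = 1L, graph = NULL) {
  n <- n_vertices(mesh)
  if (n_target < 1 || n_target > n)
    stop("n_target must lie in [1, ", n, "]")
  if (is.null(graph)) graph <- adjacency_graph(mesh)
  w <- igraph::E(graph)$weight
  selected <- integer(n_target)
  selected[1] <- with_seed(seed, sample.int(n, 1L))
  mind <- as.numeric(igraph::distances(graph, v = selected[1], weights = w))
  if (n_target > 1) {
    for (k in 2:n_target) {
      nxt <- which.max(mind)  # which.max takes the lowest index on ties
      selected[k] <- nxt
      dk <- as.numeric(igraph::distances(graph, v = nxt, weights = w))
      mind <- pmin(mind, dk)
    }
  }
  hops <- igraph::distances(graph, v = selected, weights = NA)
  assignment <- vapply(seq_len(n), function(v) {
    h <- hops[, v]
    cand <- which(h == min(h))
    if (length(cand) > 1) {
      e <- sqrt(rowSums((mesh$vertices[selected[cand], , drop = FALSE] -
                           matrix(mesh$vertices[v, ], length(cand), 3,
                                  byrow = TRUE))^2))
      cand <- cand[e == min(e)]
    }
    cand[which.min(selected[cand])]  # final tie-break: lowest vertex index
  }, integer(1))
  structure(list(assignment = assignment, selected = selected),
            class = "parcel_map")
}

#' @export
print.parcel_map <- function(x, ...) {
  cat("<parcel_map> ", length(x$assignment), " vertices in ",
      length(x$selected), " parcels\n", sep = "")
  invisible(x)
}

#' Re-index faces over the selected vertices of a parcellation
#'
#' The decimated render mesh: faces whose three vertices map to three
#' distinct parcels, re-indexed over the selected vertices.
#'
#' @param mesh the original \code{triangle_mesh}.
#' @param parcels a \code{parcel_map} from \code{\link{decimate_and_parcellate}}.
#' @return a \code{triangle_mesh} over the selected vertices.
#' @export
retriangulate <- function(mesh, parcels) {
  f <- matrix(parcels$assignment[mesh$faces], ncol = 3)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- unique(t(apply(f[keep, , drop = FALSE], 1, sort)))
  triangle_mesh(mesh$vertices[parcels$selected, , drop = FALSE], f,
                allow_unreferenced = TRUE)
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
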