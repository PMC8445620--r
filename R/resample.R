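# Surface-to-surface resampling through registered spheres: per destination
# vertex, the containing source triangle is found by radial (gnomonic)
# projection and the value is interpolated barycentrically (or copied from
# the nearest source vertex, mandatory for label data).

#' Resample per-vertex data between registered spheres
#'
#' @param values per-vertex vector on the source mesh.
#' @param sphere_src,sphere_dst \code{triangle_mesh} spheres sharing one
#'   registration frame (approximately common centre and radius).
#' @param method \code{"barycentric"} (default) or \code{"nearest"}; use
#'   nearest for label data.
#' @return vector of length \code{n_vertices(sphere_dst)}, with a logical
#'   \code{"fallback"} attribute marking destination vertices that needed
#'   the nearest-triangle fallback.
#' @export
surface_resample <- function(values, sphere_src, sphere_dst,
                             method = c("barycentric", "nearest")) {
  method <- match.arg(method)
  if (length(values) != n_vertices(sphere_src))
    stop("values must have one entry per source vertex")
  src <- sphere_src$vertices
  dst <- sphere_dst$vertices
  centre <- colMeans(src)
  srcc <- sweep(src, 2, centre)
  dstc <- sweep(dst, 2, centre)

  nn <- nearest_vertex(srcc, dstc)
  if (method == "nearest") {
    out <- values[nn]
    attr(out, "fallback") <- rep(FALSE, length(out))
    return(out)
  }

  # candidate triangles: those incident to the nearest source vertex (and
  # its neighbours' triangles as a second ring if needed)
  f <- sphere_src$faces
  incident <- split(rep(seq_len(nrow(f)), 3), as.vector(f))
  out <- numeric(nrow(dst))
  fallback <- rep(FALSE, nrow(dst))
  for (v in seq_len(nrow(dst))) {
    p <- dstc[v, ]
    ring1 <- incident[[as.character(nn[v])]]
    ring_verts <- unique(as.vector(f[ring1, , drop = FALSE]))
    tris <- unique(unlist(incident[as.character(ring_verts)]))
    best <- NULL
    best_min_b <- -Inf
    for (tr in tris) {
      vi <- f[tr, ]
      b <- radial_barycentric(p, srcc[vi[1], ], srcc[vi[2], ], srcc[vi[3], ])
      if (is.null(b)) next
      mb <- min(b)
      if (mb > best_min_b) {
        best_min_b <- mb
        best <- list(vi = vi, b = b)
      }
      if (mb >= -1e-9) break
    }
    if (is.null(best)) {  # degenerate projection; copy nearest vertex
      out[v] <- values[nn[v]]
      fallback[v] <- TRUE
      next
    }
    if (best_min_b < -1e-9) fallback[v] <- TRUE
    b <- pmax(best$b, 0)
    b <- b / sum(b)
    out[v] <- sum(b * values[best$vi])
  }
  attr(out, "fallback") <- fallback
  out
}

# barycentric coordinates of the ray through p (from the sphere centre)
# within triangle (v1, v2, v3); NULL when the ray is parallel to the plane
# or hits it on the opposite side of the sphere (sum(b) <= 0)
radial_barycentric <- function(p, v1, v2, v3) {
  m <- cbind(v1, v2, v3)
  b <- tryCatch(solve(m, p), error = function(e) NULL)
  if (is.null(b)) return(NULL)
  s <- sum(b)
  if (s < 1e-12) return(NULL)
  as.numeric(b / s)
}

nearest_vertex <- function(src, query, chunk = NULL) {
  n <- nrow(query)
  if (is.null(chunk)) chunk <- max(16L, as.integer(2e7 / max(nrow(src), 1)))
  out <- integer(n)
  s2 <- rowSums(src^2)
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    q <- query[i0:i1, , drop = FALSE]
    d <- outer(rowSums(q^2), s2, "+") - 2 * q %*% t(src)
    out[i0:i1] <- max.col(-d, ties.method = "first")
  }
  out
}
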