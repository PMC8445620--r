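# Shared in-code fixtures and independent oracles.

# regular tetrahedron (unit edge length)
tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8)
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  triangle_mesh(v, f)
}

# flat strip of n_x by n_y grid vertices at z = 0, given spacing
flat_strip <- function(n_x, n_y, spacing = 1) {
  x <- (seq_len(n_x) - 1) * spacing
  y <- (seq_len(n_y) - 1) * spacing
  v <- cbind(rep(x, times = n_y), rep(y, each = n_x), 0)
  i <- rep(seq_len(n_x - 1), times = n_y - 1)
  j <- rep(seq_len(n_y - 1), each = n_x - 1)
  v00 <- (j - 1) * n_x + i
  f <- rbind(cbind(v00, v00 + 1L, v00 + n_x),
             cbind(v00 + 1L, v00 + n_x + 1L, v00 + n_x))
  triangle_mesh(v, f)
}

# icosphere: subdivided icosahedron projected onto a sphere
icosphere <- function(subdiv = 2, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "_")
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  triangle_mesh(v, f)
}

# dense Floyd-Warshall all-pairs shortest paths (independent of igraph)
floyd_warshall <- function(mesh) {
  n <- nrow(mesh$vertices)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)])
  len <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  for (i in seq_len(nrow(e))) {
    d[e[i, 1], e[i, 2]] <- min(d[e[i, 1], e[i, 2]], len[i])
    d[e[i, 2], e[i, 1]] <- d[e[i, 1], e[i, 2]]
  }
  for (k in seq_len(n)) {
    dk <- d[, k]
    d <- pmin(d, outer(dk, d[k, ], `+`))
  }
  d
}

# small default-parameter sheet shared by several tests
small_sheet <- function() make_folded_sheet(n_x = 24, n_y = 8)

expect_equal_tol <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
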