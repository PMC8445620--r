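# Text-format readers/writers and the format-dispatching surface reader.

#' Read a surface mesh (GIFTI or text)
#'
#' GIFTI surfaces (\code{.surf.gii}/\code{.gii}) carry vertices and faces in
#' one file. The text encoding is a pair of whitespace tables: \code{path}
#' holds N rows of x y z world coordinates and \code{faces_path} M rows of
#' three 0-based vertex indices (the GIFTI index convention; indices are
#' 1-based inside R).
#'
#' @param path GIFTI surface file, or vertex coordinate table.
#' @param faces_path face index table; required for the text encoding.
#' @return a \code{triangle_mesh}.
#' @export
read_surface <- function(path, faces_path = NULL) {
  if (is_gifti_path(path)) return(read_gifti_surface(path))
  if (is.null(faces_path))
    stop("text surfaces need both a vertex table and a face table")
  vertices <- as.matrix(utils::read.table(path))
  faces <- as.matrix(utils::read.table(faces_path))
  triangle_mesh(vertices, faces + 1L)
}

#' Write a surface mesh (GIFTI or text)
#'
#' @param mesh a \code{triangle_mesh}.
#' @param path output GIFTI path, or vertex table path for text.
#' @param faces_path face table path for the text encoding (0-based indices).
#' @return the path, invisibly.
#' @export
write_surface <- function(mesh, path, faces_path = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (is_gifti_path(path)) {
    write_gifti_surface(mesh, path)
  } else {
    if (is.null(faces_path))
      stop("text surfaces need both a vertex table and a face table path")
    utils::write.table(format(mesh$vertices, digits = 17), path,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(mesh$faces - 1L, faces_path,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read per-vertex data (text or GIFTI func/label)
#'
#' @param path whitespace text (one value per line) or a GIFTI
#'   \code{.func.gii}/\code{.shape.gii}/\code{.label.gii} file.
#' @param n_vertices expected number of vertices; the read length must match.
#' @return numeric (or integer, for label files) vector of length
#'   \code{n_vertices}. Label tables travel in the \code{"labels"} attribute.
#' @export
read_vertex_data <- function(path, n_vertices) {
  vals <- if (is_gifti_path(path)) {
    read_gifti_vertex_data(path)
  } else {
    v <- scan(path, what = numeric(), quiet = TRUE)
    if (all(v == round(v))) storage.mode(v) <- "integer"
    v
  }
  if (length(vals) != n_vertices)
    stop("per-vertex data has ", length(vals), " values but the mesh has ",
         n_vertices, " vertices")
  vals
}

#' Write per-vertex data (text or GIFTI)
#'
#' @param values per-vertex vector; integer vectors are written as label
#'   arrays in GIFTI.
#' @param path output path (\code{.gii} for GIFTI, anything else for text).
#' @return the path, invisibly.
#' @export
write_vertex_data <- function(values, path) {
  if (is_gifti_path(path)) {
    write_gifti_vertex_data(values, path)
  } else {
    writeLines(format(values, digits = 17, trim = TRUE, scientific = FALSE),
               path)
  }
  invisible(path)
}

#' Read anatomical fiducials from CSV
#'
#' Expects columns \code{name,x,y,z} in world mm (RAS assumed). Leading
#' comment lines starting with \code{#} are tolerated, so Slicer-flavoured
#' exports with a header comment block parse too.
#'
#' @param path CSV path.
#' @return a \code{fiducial_set}.
#' @export
read_fiducials <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("fiducial CSV must have columns name,x,y,z; got: ",
         paste(names(df), collapse = ","))
  fiducial_set(df$name, as.matrix(df[, c("x", "y", "z")]))
}

#' Write anatomical fiducials as CSV
#'
#' @param fiducials a \code{fiducial_set}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_fiducials <- function(fiducials, path) {
  stopifnot(inherits(fiducials, "fiducial_set"))
  df <- data.frame(name = fiducials$names,
                   x = fiducials$points[, 1],
                   y = fiducials$points[, 2],
                   z = fiducials$points[, 3])
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
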