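#' Construct an intensity volume
#'
#' A 3D scalar image with a voxel-index-to-world affine. Voxel indices are
#' 0-based and the affine maps index to world mm (NIfTI convention), so voxel
#' \code{(i,j,k)} sits at world position \code{affine \%*\% c(i,j,k,1)}.
#'
#' @param data 3D numeric array. A 4D array with a single fourth dimension is
#'   squeezed to 3D.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world mm.
#' @param background scalar fill value used for out-of-volume samples.
#' @return An object of class \code{intensity_volume} with fields
#'   \code{data}, \code{affine}, \code{background}.
#' @export
intensity_volume <- function(data, affine = diag(4), background = 0) {
  if (length(dim(data)) == 4L) {
    if (dim(data)[4] != 1L)
      stop("volume data must be 3D (or 4D with a single frame)")
    data <- array(data, dim(data)[1:3])
  }
  if (length(dim(data)) != 3L)
    stop("volume data must be 3D, got ", length(dim(data)), " dimensions")
  affine <- as_affine(affine)
  structure(list(data = data, affine = affine, background = background),
            class = "intensity_volume")
}

as_affine <- function(affine) {
  affine <- unclass(affine)
  attributes(affine) <- list(dim = dim(affine))
  if (!is.matrix(affine) || any(dim(affine) != c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  storage.mode(affine) <- "double"
  d <- det(affine)
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    stop("affine must be invertible")
  affine
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat("<intensity_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ",
      paste(signif(voxel_size(x$affine), 4), collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Construct a triangle mesh
#'
#' @param vertices N x 3 numeric matrix of world coordinates (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param allow_unreferenced keep vertices no face uses? (default FALSE;
#'   decimated render meshes may need TRUE)
#' @return An object of class \code{triangle_mesh}.
#' @export
triangle_mesh <- function(vertices, faces, allow_unreferenced = FALSE) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be N x 3")
  if (ncol(faces) != 3L) stop("faces must be M x 3")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n))
    stop("face index out of range [1, ", n, "]")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
    stop("degenerate face with a repeated vertex index")
  if (!allow_unreferenced && !all(seq_len(n) %in% faces))
    stop("every vertex must be referenced by at least one face")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Construct a fiducial point set
#'
#' Named anatomical landmarks in world mm (RAS orientation assumed).
#'
#' @param names character vector of unique landmark names.
#' @param points P x 3 numeric matrix of world coordinates (mm).
#' @return An object of class \code{fiducial_set}.
#' @export
fiducial_set <- function(names, points) {
  points <- as.matrix(points)
  dimnames(points) <- NULL
  storage.mode(points) <- "double"
  names <- as.character(names)
  if (nrow(points) != length(names)) stop("names and points disagree in length")
  if (ncol(points) != 3L) stop("points must be P x 3")
  if (anyDuplicated(names))
    stop("duplicate fiducial names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  if (!all(is.finite(points))) stop("fiducial coordinates must be finite")
  structure(list(names = names, points = points), class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("<fiducial_set> ", length(x$names), " landmarks\n", sep = "")
  invisible(x)
}

#' Construct a cortical sheet (vertex-correspondent pial/white pair)
#'
#' Vertex i of the pial mesh corresponds to vertex i of the white mesh and
#' both share one face table; the pair is the scaffold for intracortical
#' surface construction.
#'
#' @param pial,white \code{triangle_mesh} objects with identical vertex count
#'   and face table.
#' @return An object of class \code{cortical_sheet}.
#' @export
cortical_sheet <- function(pial, white) {
  stopifnot(inherits(pial, "triangle_mesh"), inherits(white, "triangle_mesh"))
  if (n_vertices(pial) != n_vertices(white))
    stop("pial and white must have the same vertex count")
  if (!identical(pial$faces, white$faces))
    stop("pial and white must share one face table")
  if (all(pial$vertices == white$vertices))
    stop("pial and white coincide everywhere (zero thickness sheet)")
  structure(list(pial = pial, white = white), class = "cortical_sheet")
}

#' @export
print.cortical_sheet <- function(x, ...) {
  th <- sqrt(rowSums((x$pial$vertices - x$white$vertices)^2))
  cat("<cortical_sheet> ", n_vertices(x$pial), " vertices, thickness ",
      signif(mean(th), 3), " mm (mean)\n", sep = "")
  invisible(x)
}

#' Construct a surface stack
#'
#' K intracortical surfaces sharing one vertex correspondence: \code{coords}
#' is K x N x 3 (world mm), \code{alpha} the K volume fractions (0 = pial,
#' 1 = white) and \code{rho} the K x N per-vertex distance fractions.
#'
#' @param coords K x N x 3 array of world coordinates.
#' @param alpha length-K strictly increasing volume fractions in [0, 1].
#' @param rho K x N matrix of distance fractions in [0, 1].
#' @return An object of class \code{surface_stack}.
#' @export
surface_stack <- function(coords, alpha, rho) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (length(alpha) != dim(coords)[1]) stop("alpha length must equal K")
  if (any(diff(alpha) <= 0)) stop("alpha must be strictly increasing")
  if (alpha[1] < 0 || alpha[length(alpha)] > 1) stop("alpha must lie in [0, 1]")
  if (!all(dim(rho) == dim(coords)[1:2])) stop("rho must be K x N")
  structure(list(coords = coords, alpha = as.numeric(alpha), rho = rho),
            class = "surface_stack")
}

#' @export
print.surface_stack <- function(x, ...) {
  cat("<surface_stack> ", dim(x$coords)[1], " surfaces x ",
      dim(x$coords)[2], " vertices\n", sep = "")
  invisible(x)
}

#' Construct a profile set
#'
#' K (depths) x N (vertices) staining-intensity matrix with its depth
#' fractions; the central object of the toolkit.
#'
#' @param values K x N numeric matrix of intensities.
#' @param alpha length-K volume fractions (pial to white).
#' @param mesh_ref identifier of the source mesh (free-form string).
#' @param mask optional K x N logical matrix, TRUE where the sample fell
#'   inside the volume.
#' @return An object of class \code{profile_set}.
#' @export
profile_set <- function(values, alpha, mesh_ref = "", mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("a profile set needs K >= 2 depths")
  if (length(alpha) != nrow(values)) stop("alpha length must equal K")
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  structure(list(values = values, alpha = as.numeric(alpha),
                 mesh_ref = mesh_ref, mask = mask),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("<profile_set> ", nrow(x$values), " depths x ", ncol(x$values),
      " vertices\n", sep = "")
  invisible(x)
}

#' Construct a displacement field
#'
#' @param vectors X x Y x Z x 3 array of displacement vectors in world mm,
#'   defined on the output (fixed) grid.
#' @param affine 4x4 grid-index-to-world affine.
#' @return An object of class \code{displacement_field}.
#' @export
displacement_field <- function(vectors, affine = diag(4)) {
  stopifnot(length(dim(vectors)) == 4L, dim(vectors)[4] == 3L)
  if (!all(is.finite(vectors))) stop("displacement vectors must be finite")
  structure(list(vectors = vectors, affine = as_affine(affine)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("<displacement_field> grid ", paste(dim(x$vectors)[1:3], collapse = " x "),
      ", max |d| = ", signif(max(abs(x$vectors)), 4), " mm\n", sep = "")
  invisible(x)
}

#' Construct a label volume
#'
#' @param data 3D integer array of nonnegative label codes; 0 is background.
#' @param affine 4x4 voxel-index-to-world affine.
#' @param labels optional named integer vector or data.frame mapping codes to
#'   names.
#' @return An object of class \code{label_volume}.
#' @export
label_volume <- function(data, affine = diag(4), labels = NULL) {
  if (length(dim(data)) != 3L) stop("label data must be 3D")
  if (any(data < 0)) stop("label codes must be nonnegative")
  if (max(abs(data - round(data))) > 0) stop("label codes must be integers")
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = as_affine(affine), labels = labels),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  codes <- setdiff(sort(unique(as.vector(x$data))), 0L)
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      length(codes), " labels\n", sep = "")
  invisible(x)
}

# world <-> 0-based voxel index conversion (points as n x 3 matrices)
world_to_voxel <- function(points, affine) {
  points <- rbind(t(as.matrix(points)), 1)
  t(solve(affine) %*% points)[, 1:3, drop = FALSE]
}

voxel_to_world <- function(indices, affine) {
  indices <- rbind(t(as.matrix(indices)), 1)
  t(affine %*% indices)[, 1:3, drop = FALSE]
}
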