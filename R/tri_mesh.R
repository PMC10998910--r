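#' Triangulated spine mesh
#'
#' A `tri_mesh` holds the triangulated surface of a single dendritic spine:
#' an `N x 3` matrix of vertex coordinates in micrometers and an `f x 3`
#' integer matrix of faces, each row indexing three vertices (1-based).
#' Meshes cut from a dendrite are open at the base; closed meshes are
#' watertight.
#'
#' @param vertices numeric matrix, `N x 3`, vertex coordinates in um.
#' @param faces integer matrix, `f x 3`, vertex indices per triangle.
#' @param validate check structural invariants (`N >= 4`, `f >= 1`, indices
#'   in range)? Disable only for intermediate states inside the repair loop.
#' @return An object of class `tri_mesh`.
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'               rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
#' n_vertices(m)
#' @export
tri_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  m <- structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
  if (validate) validate_tri_mesh(m)
  m
}

validate_tri_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) < 4L || nrow(f) < 1L)
    stop("malformed mesh: need at least 4 vertices and 1 face")
  if (anyNA(v) || anyNA(f)) stop("malformed mesh: NA entries")
  if (min(f) < 1L || max(f) > nrow(v))
    stop("malformed mesh: face index out of range")
  invisible(mesh)
}

#' @rdname tri_mesh
#' @param x,mesh a `tri_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname tri_mesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d faces>\n",
              n_vertices(x), n_faces(x)))
  ext <- apply(x$vertices, 2L, range)
  cat(sprintf("  extent (um): x [%.3g, %.3g]  y [%.3g, %.3g]  z [%.3g, %.3g]\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m * m))

# Face corner coordinate matrices (list of A, B, C).
face_corners <- function(mesh) {
  list(A = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       B = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       C = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

#' Per-face triangle areas
#'
#' Area of each face, `s_i = |AB x AC| / 2`, in um^2.
#'
#' @param mesh a `tri_mesh`.
#' @return numeric vector of length `n_faces(mesh)`.
#' @export
face_areas <- function(mesh) {
  co <- face_corners(mesh)
  0.5 * row_norms(cross3(co$B - co$A, co$C - co$A))
}

# Undirected edge list as a 2-column matrix of sorted vertex-index pairs,
# one row per half-edge occurrence (not deduplicated).
half_edges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

# Unique undirected edges with multiplicities.
edge_table <- function(faces) {
  he <- half_edges(faces)
  key <- paste(he[, 1], he[, 2])
  tab <- table(key)
  first <- !duplicated(key)
  edges <- he[first, , drop = FALSE]
  mult <- as.integer(tab[paste(edges[, 1], edges[, 2])])
  list(edges = edges, mult = mult)
}

#' Vertex neighbor counts
#'
#' For each vertex, the number of distinct vertices sharing an edge with it.
#' Boundary vertices at the spine's dendrite cut typically have the smallest
#' counts, which is how the spine base is located.
#'
#' @param mesh a `tri_mesh`.
#' @return integer vector of length `n_vertices(mesh)`.
#' @export
vertex_neighbor_counts <- function(mesh) {
  et <- edge_table(mesh$faces)
  counts <- tabulate(c(et$edges[, 1], et$edges[, 2]), nbins = n_vertices(mesh))
  as.integer(counts)
}

# Boundary edges: undirected edges used by exactly one face.
boundary_edges <- function(mesh) {
  et <- edge_table(mesh$faces)
  et$edges[et$mult == 1L, , drop = FALSE]
}

#' Mesh integrity flags
#'
#' Assesses whether a mesh is watertight (every edge shared by exactly two
#' faces), edge-manifold (no edge shared by more than two faces), and whether
#' a convex hull with positive volume can be computed from its vertices.
#'
#' @param mesh a `tri_mesh`.
#' @return list with logical fields `is_watertight`, `is_manifold`,
#'   `hull_computable`.
#' @export
integrity <- function(mesh) {
  et <- edge_table(mesh$faces)
  hull_ok <- tryCatch(convex_hull_volume(mesh$vertices) > 0,
                      error = function(e) FALSE)
  list(is_watertight = all(et$mult == 2L),
       is_manifold = all(et$mult <= 2L),
       hull_computable = isTRUE(hull_ok))
}
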