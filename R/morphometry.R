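#' Locate the spine base center
#'
#' A spine cut from its dendrite is left with an open hole; the rim vertices
#' of that hole have the fewest edge neighbors in the whole mesh. The base
#' center is the mean coordinate of all vertices whose neighbor count equals
#' the mesh-wide minimum.
#'
#' @param mesh an open (non-watertight) [tri_mesh].
#' @return numeric length-3 point (um).
#' @export
find_base_center <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0L)
    stop("no base: mesh is watertight (no boundary hole)")
  counts <- vertex_neighbor_counts(mesh)
  sel <- counts == min(counts)
  colMeans(mesh$vertices[sel, , drop = FALSE])
}

#' Spine geometry scaffold
#'
#' Precomputes the quantities shared by the morphometric descriptors:
#' base center `S_bc`, gravity center `G_c` (the unweighted vertex centroid,
#' also used as the volume apex), per-vertex displacement vectors from the
#' base center and their magnitudes, the 5%-subset size `n`, per-face areas
#' and signed tetrahedron volumes.
#'
#' @param mesh a [tri_mesh] with a detectable base (open at the dendrite
#'   cut), or any mesh if `base_center` is supplied.
#' @param base_center optional precomputed base center.
#' @return object of class `spine_geometry`.
#' @export
spine_geometry <- function(mesh, base_center = NULL) {
  if (is.null(base_center)) base_center <- find_base_center(mesh)
  v <- mesh$vertices
  l <- sweep(v, 2, base_center)
  co <- face_corners(mesh)
  gc <- colMeans(v)
  vol_signed <- rowSums(cross3(co$B - co$A, co$C - co$A) *
                          sweep(co$A, 2, gc)) / 6
  structure(list(S_bc = base_center, G_c = gc, l = l,
                 distances = row_norms(l),
                 N = nrow(v), f = n_faces(mesh),
                 n = max(1L, as.integer(ceiling(0.05 * nrow(v)))),
                 s = face_areas(mesh), v = vol_signed),
            class = "spine_geometry")
}

#' Morphometric descriptors of a spine mesh
#'
#' The ten descriptors: Length `L` (mean of the 5% largest vertex-to-base
#' distances), Surface `S`, Volume `V`, Hull Volume `HV`, Hull Ratio
#' `HR = (HV - V)/V`, Average Distance `AD`, Coefficient of Variation in
#' Distance `CVD`, Open Angle `OA`, Mean Curvature `MC` and Mean Gaussian
#' Curvature `GC`.
#'
#' @param geom a [spine_geometry].
#' @name spine_features
NULL

#' @rdname spine_features
#' @export
feature_length <- function(geom) {
  d <- sort(geom$distances, decreasing = TRUE)
  cutoff <- d[geom$n]
  mean(d[d >= cutoff])
}

#' @rdname spine_features
#' @param mesh a [tri_mesh].
#' @export
feature_surface <- function(mesh) sum(face_areas(mesh))

#' @rdname spine_features
#'
#' @details For meshes open at the base hole, `feature_volume` first caps
#' the single boundary loop by fan triangulation to the base center, which
#' makes the signed-tetrahedra sum independent of the reference point.
#' @export
feature_volume <- function(mesh, geom = NULL) {
  closed <- close_base(mesh, geom)
  g <- spine_geometry(closed$mesh, base_center = closed$base)
  abs(sum(g$v))
}

# Cap the base hole (if any) by a triangle fan to the base center, keeping
# the surface orientation consistent. Errors on multiple boundary loops.
close_base <- function(mesh, geom = NULL) {
  f <- mesh$faces
  dir_e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(dir_e[, 1], dir_e[, 2])
  rev_key <- paste(dir_e[, 2], dir_e[, 1])
  open_idx <- which(!(key %in% rev_key))
  if (length(open_idx) == 0L)
    return(list(mesh = mesh, base = if (!is.null(geom)) geom$S_bc else
      colMeans(mesh$vertices), capped = FALSE))
  be <- dir_e[open_idx, , drop = FALSE]
  if (n_boundary_loops(be) > 1L)
    stop("cannot cap base: mesh has multiple boundary loops")
  base <- if (!is.null(geom)) geom$S_bc else find_base_center(mesh)
  bi <- n_vertices(mesh) + 1L
  cap <- cbind(rep(bi, nrow(be)), be[, 2], be[, 1])
  m <- tri_mesh(rbind(mesh$vertices, base), rbind(mesh$faces, cap),
                validate = FALSE)
  list(mesh = m, base = base, capped = TRUE)
}

n_boundary_loops <- function(directed_edges) {
  verts <- unique(as.vector(directed_edges))
  parent <- seq_along(verts)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  a <- match(directed_edges[, 1], verts)
  b <- match(directed_edges[, 2], verts)
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_along(verts), find, 1L)))
}

#' @rdname spine_features
#' @export
feature_hull <- function(mesh, geom = NULL) {
  hull <- convex_hull(mesh$vertices)
  V <- feature_volume(mesh, geom)
  list(HV = hull$volume, HR = (hull$volume - V) / V)
}

#' @rdname spine_features
#' @export
feature_distance_stats <- function(geom) {
  d <- geom$distances
  if (length(d) < 2L) stop("need at least 2 vertices for distance stats")
  AD <- mean(d)
  if (AD == 0) stop("undefined CVD: all vertices coincide with the base center")
  list(AD = AD, CVD = sqrt(mean((d - AD)^2)) / AD)
}

#' @rdname spine_features
#' @export
feature_open_angle <- function(mesh, geom = NULL) {
  if (is.null(geom)) geom <- spine_geometry(mesh)
  axis <- geom$G_c - geom$S_bc
  an <- sqrt(sum(axis^2))
  if (an == 0) stop("undefined spine axis: gravity center equals base center")
  axis <- axis / an
  keep <- geom$distances > 0
  u <- geom$l[keep, , drop = FALSE] / geom$distances[keep]
  mean(acos(pmin(pmax(as.vector(u %*% axis), -1), 1)))
}

#' @rdname spine_features
#'
#' @details Curvatures use the discrete estimators on the (base-capped)
#' closed surface: total integral mean curvature from edge lengths and
#' signed dihedral angles, total Gaussian curvature from vertex angle
#' defects (whose sum is exactly `4*pi` on a closed genus-0 surface), each
#' normalized by the closed surface area.
#' @export
feature_curvatures <- function(mesh, geom = NULL) {
  closed <- close_base(mesh, geom)
  m <- closed$mesh
  et <- edge_table(m$faces)
  if (any(et$mult > 2L)) stop("non-manifold edges: curvature undefined")
  S <- sum(face_areas(m))

  # signed dihedral angles over interior edges
  co <- face_corners(m)
  nrm <- cross3(co$B - co$A, co$C - co$A)
  nlen <- row_norms(nrm)
  nrm <- nrm / pmax(nlen, 1e-300)
  he <- half_edges(m$faces)
  fid <- rep(seq_len(n_faces(m)), 3L)
  key <- paste(he[, 1], he[, 2])
  o <- order(key)
  key_s <- key[o]; fid_s <- fid[o]; he_s <- he[o, , drop = FALSE]
  pair_first <- which(key_s == c(key_s[-1], "")) # first of each shared pair
  f1 <- fid_s[pair_first]; f2 <- fid_s[pair_first + 1L]
  ev <- m$vertices[he_s[pair_first, 2], , drop = FALSE] -
    m$vertices[he_s[pair_first, 1], , drop = FALSE]
  elen <- row_norms(ev)
  ehat <- ev / pmax(elen, 1e-300)
  n1 <- nrm[f1, , drop = FALSE]; n2 <- nrm[f2, , drop = FALSE]
  # convexity sign from the face winding: edge direction as traversed in f1
  sinb <- rowSums(cross3(n1, n2) * ehat)
  cosb <- rowSums(n1 * n2)
  # match sign convention to the traversal direction of the edge within f1
  dir1 <- edge_direction_in_face(m$faces, f1, he_s[pair_first, , drop = FALSE])
  beta <- atan2(sinb, pmin(pmax(cosb, -1), 1)) * dir1
  total_mc <- 0.5 * sum(elen * beta)

  total_gc <- sum(angle_defects(m))
  list(MC = abs(total_mc) / S, GC = total_gc / S, closed_area = S)
}

# +1 if the undirected edge (a,b) (a<b) is traversed a->b in the face, else -1
edge_direction_in_face <- function(faces, fidx, edges) {
  fa <- faces[fidx, , drop = FALSE]
  d <- integer(nrow(edges))
  for (k in 1:3) {
    a <- fa[, k]; b <- fa[, k %% 3L + 1L]
    hit <- a == edges[, 1] & b == edges[, 2]
    d[hit] <- 1L
    hit2 <- a == edges[, 2] & b == edges[, 1]
    d[hit2] <- -1L
  }
  d
}

angle_defects <- function(mesh) {
  co <- face_corners(mesh)
  ang <- function(p, q, r) {
    u <- q - p; v <- r - p
    cosv <- rowSums(u * v) / pmax(row_norms(u) * row_norms(v), 1e-300)
    acos(pmin(pmax(cosv, -1), 1))
  }
  aA <- ang(co$A, co$B, co$C)
  aB <- ang(co$B, co$C, co$A)
  aC <- ang(co$C, co$A, co$B)
  sums <- numeric(n_vertices(mesh))
  sums_add <- function(idx, val) {
    t <- tapply(val, idx, sum)
    sums[as.integer(names(t))] <<- sums[as.integer(names(t))] + t
  }
  sums_add(mesh$faces[, 1], aA)
  sums_add(mesh$faces[, 2], aB)
  sums_add(mesh$faces[, 3], aC)
  2 * pi - sums
}

#' Compute all ten morphometric features of one spine
#'
#' @param mesh a repaired [tri_mesh], open at the dendrite cut so the base
#'   is detectable (watertight meshes raise a no-base error unless
#'   `base_center` is supplied).
#' @param base_center optional precomputed base center.
#' @return named list with entries `L`, `S`, `V`, `HV`, `HR`, `AD`, `CVD`,
#'   `OA`, `MC`, `GC`.
#' @examples
#' sp <- make_spine_mesh(spine_params("stubby", head_radius = 0.5))
#' unlist(compute_features(sp$mesh))
#' @export
compute_features <- function(mesh, base_center = NULL) {
  geom <- spine_geometry(mesh, base_center = base_center)
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("feature %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  L <- wrap("L", feature_length(geom))
  S <- wrap("S", feature_surface(mesh))
  V <- wrap("V", feature_volume(mesh, geom))
  hull <- wrap("HV/HR", feature_hull(mesh, geom))
  ds <- wrap("AD/CVD", feature_distance_stats(geom))
  OA <- wrap("OA", feature_open_angle(mesh, geom))
  curv <- wrap("MC/GC", feature_curvatures(mesh, geom))
  list(L = L, S = S, V = V, HV = hull$HV, HR = hull$HR,
       AD = ds$AD, CVD = ds$CVD, OA = OA, MC = curv$MC, GC = curv$GC)
}

#' Feature table for a set of spine meshes
#'
#' Applies [compute_features()] to a list of meshes and binds the results
#' with per-spine metadata into the feature table consumed by the
#' dimension-reduction and clustering stages.
#'
#' @param meshes list of [tri_mesh] objects.
#' @param metadata optional data.frame with one row per mesh (e.g.
#'   `spine_id`, `mouse_id`, `cell_id`, `group`).
#' @return data.frame of metadata plus the ten feature columns.
#' @export
feature_table <- function(meshes, metadata = NULL) {
  feats <- do.call(rbind, lapply(meshes, function(m)
    as.data.frame(compute_features(m))))
  if (is.null(metadata))
    metadata <- data.frame(spine_id = seq_along(meshes))
  stopifnot(nrow(metadata) == length(meshes))
  cbind(metadata, feats)
}
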