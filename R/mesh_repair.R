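#' Mesh optimization and repair loop
#'
#' Cleans a reconstructed spine mesh before morphometry. The steps run in a
#' fixed order: the mesh bounding box is measured and a target edge length
#' derived from its diagonal (recorded with the chosen level of detail);
#' collinear (zero-area) triangles are removed; isolated vertices are
#' dropped; self-intersecting faces are eliminated; duplicated faces are
#' removed; isolated vertices are dropped again; the outer hull volume is
#' computed as an integrity probe; triangles with an interior angle greater
#' than 179 degrees are removed; duplicated faces and duplicated vertices
#' are removed once more; finally mesh integrity is assessed. If the
#' integrity check fails the loop restarts at the collinear-removal step at
#' reduced detail (one retry), then errors.
#'
#' @param mesh a [tri_mesh].
#' @param detail `"normal"` (target edge length = box diagonal / 100) or
#'   `"reduced"` (diagonal / 50).
#' @param detail_divisors named numeric vector giving the diagonal divisor
#'   per detail level.
#' @param eps tolerance (um) for the self-intersection test.
#' @return list with `mesh` (repaired [tri_mesh]) and `report`, a
#'   `repair_report` with removal counts, the detail level used and the
#'   number of passes.
#' @export
repair_mesh <- function(mesh, detail = c("normal", "reduced"),
                        detail_divisors = c(normal = 100, reduced = 50),
                        eps = 1e-9) {
  detail <- match.arg(detail)
  counts <- c(removed_degenerate = 0L, removed_isolated_vertices = 0L,
              removed_self_intersections = 0L, removed_duplicate_faces = 0L,
              removed_obtuse = 0L, removed_duplicate_vertices = 0L)
  passes <- 0L
  levels <- if (detail == "normal") c("normal", "reduced") else "reduced"
  for (lvl in levels) {
    passes <- passes + 1L
    res <- repair_pass(mesh, eps = eps)
    counts <- counts + res$counts
    ok <- tryCatch({
      validate_tri_mesh(res$mesh)
      flags <- integrity(res$mesh)
      flags$is_manifold && flags$hull_computable
    }, error = function(e) FALSE)
    if (ok) {
      box <- apply(res$mesh$vertices, 2, range)
      target_len <- sqrt(sum((box[2, ] - box[1, ])^2)) / detail_divisors[[lvl]]
      report <- structure(c(as.list(counts),
                            list(level_of_detail_used = lvl,
                                 target_edge_length = target_len,
                                 passes = passes)),
                          class = "repair_report")
      return(list(mesh = res$mesh, report = report))
    }
    mesh <- res$mesh  # retry at reduced detail on the already-cleaned mesh
  }
  stop("repair failure: mesh integrity could not be restored ",
       "after reduced-detail retry")
}

repair_pass <- function(mesh, eps = 1e-9) {
  counts <- c(removed_degenerate = 0L, removed_isolated_vertices = 0L,
              removed_self_intersections = 0L, removed_duplicate_faces = 0L,
              removed_obtuse = 0L, removed_duplicate_vertices = 0L)

  # collinear / zero-area triangles
  areas <- face_areas(mesh)
  scale2 <- max(areas, 1e-300)
  bad <- areas <= 1e-12 * scale2 | mesh$faces[, 1] == mesh$faces[, 2] |
    mesh$faces[, 2] == mesh$faces[, 3] | mesh$faces[, 1] == mesh$faces[, 3]
  counts["removed_degenerate"] <- sum(bad)
  mesh <- drop_faces(mesh, which(bad))

  r <- drop_isolated_vertices(mesh)
  counts["removed_isolated_vertices"] <- r$removed
  mesh <- r$mesh

  si <- self_intersecting_faces(mesh, eps = eps)
  counts["removed_self_intersections"] <- length(si)
  mesh <- drop_faces(mesh, si)

  dup <- duplicated_face_rows(mesh$faces)
  counts["removed_duplicate_faces"] <- sum(dup)
  mesh <- drop_faces(mesh, which(dup))

  r <- drop_isolated_vertices(mesh)
  counts["removed_isolated_vertices"] <-
    counts["removed_isolated_vertices"] + r$removed
  mesh <- r$mesh

  # integrity probe: outer hull volume (result unused, failure tolerated
  # here; the final integrity assessment decides)
  tryCatch(convex_hull_volume(mesh$vertices), error = function(e) NULL)

  ang <- max_face_angles(mesh)
  obtuse <- ang > 179 * pi / 180
  counts["removed_obtuse"] <- sum(obtuse)
  mesh <- drop_faces(mesh, which(obtuse))

  dup <- duplicated_face_rows(mesh$faces)
  counts["removed_duplicate_faces"] <-
    counts["removed_duplicate_faces"] + sum(dup)
  mesh <- drop_faces(mesh, which(dup))

  r <- merge_duplicate_vertices(mesh)
  counts["removed_duplicate_vertices"] <- r$removed
  mesh <- r$mesh

  list(mesh = mesh, counts = counts)
}

#' @export
print.repair_report <- function(x, ...) {
  cat("<repair_report>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

drop_faces <- function(mesh, idx) {
  if (length(idx) == 0L) return(mesh)
  tri_mesh(mesh$vertices, mesh$faces[-idx, , drop = FALSE], validate = FALSE)
}

drop_isolated_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  removed <- n_vertices(mesh) - length(used)
  if (removed == 0L) return(list(mesh = mesh, removed = 0L))
  remap <- integer(n_vertices(mesh))
  remap[used] <- seq_along(used)
  mesh <- tri_mesh(mesh$vertices[used, , drop = FALSE],
                   matrix(remap[mesh$faces], ncol = 3L), validate = FALSE)
  list(mesh = mesh, removed = removed)
}

duplicated_face_rows <- function(faces) {
  key <- apply(faces, 1L, function(r) paste(sort(r), collapse = " "))
  duplicated(key)
}

merge_duplicate_vertices <- function(mesh) {
  key <- apply(mesh$vertices, 1L, paste, collapse = " ")
  first <- !duplicated(key)
  removed <- sum(!first)
  if (removed == 0L) return(list(mesh = mesh, removed = 0L))
  idx <- match(key, key[first])
  faces <- matrix(idx[mesh$faces], ncol = 3L)
  # merging can collapse faces to degenerate ones; drop them silently
  deg <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  mesh <- tri_mesh(mesh$vertices[first, , drop = FALSE],
                   faces[!deg, , drop = FALSE], validate = FALSE)
  r <- drop_isolated_vertices(mesh)
  list(mesh = r$mesh, removed = removed)
}

max_face_angles <- function(mesh) {
  co <- face_corners(mesh)
  ang <- function(p, q, r) {
    u <- q - p; v <- r - p
    cosv <- rowSums(u * v) / pmax(row_norms(u) * row_norms(v), 1e-300)
    acos(pmin(pmax(cosv, -1), 1))
  }
  pmax(ang(co$A, co$B, co$C), ang(co$B, co$C, co$A), ang(co$C, co$A, co$B))
}

# Indices of faces that intersect another face they share no vertex with.
# Bounding boxes prune candidate pairs; actual crossing is detected by
# testing each edge of one triangle against the interior of the other.
self_intersecting_faces <- function(mesh, eps = 1e-9) {
  f <- mesh$faces
  nf <- nrow(f)
  if (nf < 2L) return(integer(0))
  co <- face_corners(mesh)
  lo <- pmin(co$A, co$B, co$C)
  hi <- pmax(co$A, co$B, co$C)
  ord <- order(lo[, 1])
  bad <- logical(nf)
  for (ii in seq_len(nf - 1L)) {
    i <- ord[ii]
    jj <- ii + 1L
    cand <- integer(0)
    while (jj <= nf && lo[ord[jj], 1] <= hi[i, 1] + eps) {
      cand <- c(cand, ord[jj]); jj <- jj + 1L
    }
    if (length(cand) == 0L) next
    keep <- lo[cand, 2] <= hi[i, 2] + eps & hi[cand, 2] >= lo[i, 2] - eps &
      lo[cand, 3] <= hi[i, 3] + eps & hi[cand, 3] >= lo[i, 3] - eps
    for (j in cand[keep]) {
      if (any(f[i, ] %in% f[j, ])) next
      if (triangles_cross(co$A[i, ], co$B[i, ], co$C[i, ],
                          co$A[j, ], co$B[j, ], co$C[j, ], eps)) {
        bad[i] <- TRUE; bad[j] <- TRUE
      }
    }
  }
  which(bad)
}

triangles_cross <- function(a1, b1, c1, a2, b2, c2, eps = 1e-9) {
  seg_hits <- function(p, q, ta, tb, tc) {
    segment_hits_triangle(p, q, ta, tb, tc, eps)
  }
  seg_hits(a1, b1, a2, b2, c2) || seg_hits(b1, c1, a2, b2, c2) ||
    seg_hits(c1, a1, a2, b2, c2) || seg_hits(a2, b2, a1, b1, c1) ||
    seg_hits(b2, c2, a1, b1, c1) || seg_hits(c2, a2, a1, b1, c1)
}

# Moller-Trumbore segment/triangle test, strict interior hits only.
segment_hits_triangle <- function(p, q, a, b, c, eps = 1e-9) {
  d <- q - p
  e1 <- b - a
  e2 <- c - a
  h <- c(d[2] * e2[3] - d[3] * e2[2],
         d[3] * e2[1] - d[1] * e2[3],
         d[1] * e2[2] - d[2] * e2[1])
  det <- sum(e1 * h)
  if (abs(det) < 1e-14) return(FALSE)  # parallel or coplanar
  s <- p - a
  u <- sum(s * h) / det
  if (u <= eps || u >= 1 - eps) return(FALSE)
  qv <- c(s[2] * e1[3] - s[3] * e1[2],
          s[3] * e1[1] - s[1] * e1[3],
          s[1] * e1[2] - s[2] * e1[1])
  v <- sum(d * qv) / det
  if (v <= eps || u + v >= 1 - eps) return(FALSE)
  t <- sum(e2 * qv) / det
  t > eps && t < 1 - eps
}
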