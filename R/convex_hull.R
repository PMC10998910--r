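#' Convex hull of a 3D point set
#'
#' Quickhull-style incremental construction: an initial tetrahedron of
#' extreme points is grown by repeatedly lifting the farthest outside point
#' onto the hull, deleting the faces it sees and stitching new faces along
#' the horizon. Used for the Hull Volume descriptor and as the integrity
#' probe of the mesh repair loop.
#'
#' @param points numeric matrix `n x 3`.
#' @param tol points within `tol` (times the bounding-box diagonal) of a face
#'   plane are treated as on the plane.
#' @return list with `faces` (`m x 3` integer matrix of indices into
#'   `points`, outward-oriented), `volume` and `area` of the hull.
#' @export
convex_hull <- function(points, tol = 1e-10) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 4L) stop("degenerate hull: need at least 4 points")
  diag_len <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  if (diag_len == 0) stop("degenerate hull: all points coincide")
  eps <- tol * diag_len

  ## initial simplex: two farthest extreme points, then max-distance point
  ## from the line, then from the plane
  ext <- c(apply(pts, 2, which.min), apply(pts, 2, which.max))
  d2 <- as.matrix(stats::dist(pts[ext, , drop = FALSE]))
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  i1 <- ext[ij[1]]; i2 <- ext[ij[2]]
  if (i1 == i2) stop("degenerate hull: all points coincide")
  ab <- pts[i2, ] - pts[i1, ]
  dline <- row_norms(cross3(sweep(pts, 2, pts[i1, ]),
                            matrix(ab, n, 3, byrow = TRUE))) / sqrt(sum(ab^2))
  i3 <- which.max(dline)
  if (dline[i3] <= eps) stop("degenerate hull: points are collinear")
  nrm <- cross3(matrix(ab, 1), matrix(pts[i3, ] - pts[i1, ], 1))[1, ]
  nrm <- nrm / sqrt(sum(nrm^2))
  dplane <- abs(as.vector(sweep(pts, 2, pts[i1, ]) %*% nrm))
  i4 <- which.max(dplane)
  if (dplane[i4] <= eps) stop("degenerate hull: points are coplanar")

  interior <- colMeans(pts[c(i1, i2, i3, i4), , drop = FALSE])
  mk_face <- function(a, b, c) {
    nv <- cross3(matrix(pts[b, ] - pts[a, ], 1),
                 matrix(pts[c, ] - pts[a, ], 1))[1, ]
    nn <- sqrt(sum(nv^2))
    if (nn == 0) return(NULL)
    nv <- nv / nn
    if (sum(nv * (interior - pts[a, ])) > 0) { tmp <- b; b <- c; c <- tmp; nv <- -nv }
    list(v = c(a, b, c), n = nv, off = sum(nv * pts[a, ]))
  }
  faces <- list(mk_face(i1, i2, i3), mk_face(i1, i2, i4),
                mk_face(i1, i3, i4), mk_face(i2, i3, i4))
  alive <- rep(TRUE, 4L)

  dist_to <- function(f, idx) as.vector(pts[idx, , drop = FALSE] %*% f$n) - f$off
  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  outside <- lapply(faces, function(f) {
    d <- dist_to(f, remaining)
    remaining[d > eps]
  })

  repeat {
    fi <- which(alive & lengths(outside) > 0L)
    if (length(fi) == 0L) break
    fi <- fi[1]
    cand <- outside[[fi]]
    d <- dist_to(faces[[fi]], cand)
    p <- cand[which.max(d)]
    ## visible faces: all alive faces that see p
    vis <- which(alive)
    vis <- vis[vapply(vis, function(j) dist_to(faces[[j]], p) > eps, TRUE)]
    if (length(vis) == 0L) { outside[[fi]] <- setdiff(outside[[fi]], p); next }
    ## horizon: edges of visible faces not shared with another visible face
    ve <- do.call(rbind, lapply(vis, function(j) {
      v <- faces[[j]]$v
      rbind(v[c(1, 2)], v[c(2, 3)], v[c(3, 1)])
    }))
    key <- paste(pmin(ve[, 1], ve[, 2]), pmax(ve[, 1], ve[, 2]))
    horiz <- ve[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    pool <- unique(c(unlist(outside[vis]), p))
    alive[vis] <- FALSE
    for (k in seq_len(nrow(horiz))) {
      f <- mk_face(horiz[k, 1], horiz[k, 2], p)
      if (is.null(f)) next
      faces[[length(faces) + 1L]] <- f
      alive[length(faces)] <- TRUE
      d <- dist_to(f, pool)
      outside[[length(faces)]] <- pool[d > eps]
      pool <- pool[d <= eps]  # assign each point to the first face seeing it
    }
  }

  fm <- do.call(rbind, lapply(faces[alive], function(f) f$v))
  a <- pts[fm[, 1], , drop = FALSE]
  b <- pts[fm[, 2], , drop = FALSE]
  cc <- pts[fm[, 3], , drop = FALSE]
  vol <- abs(sum((cross3(b - a, cc - a) *
                  sweep(a, 2, interior)) %*% rep(1, 3)) / 6)
  area <- 0.5 * sum(row_norms(cross3(b - a, cc - a)))
  list(faces = fm, volume = vol, area = area)
}

#' @rdname convex_hull
#' @export
convex_hull_volume <- function(points, tol = 1e-10) {
  convex_hull(points, tol = tol)$volume
}
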