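# Small reference solids and brute-force oracles used across tests.

cube_mesh <- function(edge = 1) {
  corners <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge),
                                   z = c(0, edge)))
  hull <- convex_hull(corners)
  tri_mesh(corners, hull$faces)
}

regular_tetrahedron <- function(edge = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v <- v / sqrt(8) * edge   # edge length |v1 - v2| = edge
  hull <- convex_hull(v)
  tri_mesh(v, hull$faces)
}

# cylinder closed by a top fan, open at the bottom ring (centered at origin)
capped_cylinder <- function(radius = 1, height = 2, m = 24, rings = 8) {
  theta <- 2 * pi * (seq_len(m) - 1) / m
  zs <- seq(0, height, length.out = rings)
  v <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(theta), radius * sin(theta), z)))
  v <- rbind(v, c(0, 0, height))
  apex <- nrow(v)
  rid <- function(i) (i - 1) * m + seq_len(m)
  m2 <- c(2:m, 1)
  f <- do.call(rbind, lapply(seq_len(rings - 1), function(i) {
    lo <- rid(i); hi <- rid(i + 1)
    rbind(cbind(lo, lo[m2], hi[m2]), cbind(lo, hi[m2], hi))
  }))
  top <- rid(rings)
  f <- rbind(f, cbind(top, top[m2], apex))
  tri_mesh(v, f)
}

# icosphere with the polar cap removed (open boundary)
open_icosphere <- function(subdivisions = 2, zcut = 0.8) {
  ic <- icosphere(subdivisions)
  cap_verts <- which(ic$vertices[, 3] > zcut)
  drop <- which(apply(ic$faces, 1, function(r) any(r %in% cap_verts)))
  m <- spinemorph:::drop_faces(ic, drop)
  spinemorph:::drop_isolated_vertices(m)$mesh
}

# brute-force per-vertex neighbor counts by full edge enumeration
bf_neighbor_counts <- function(mesh) {
  n <- n_vertices(mesh)
  adj <- vector("list", n)
  for (i in seq_len(n_faces(mesh))) {
    f <- mesh$faces[i, ]
    adj[[f[1]]] <- c(adj[[f[1]]], f[2], f[3])
    adj[[f[2]]] <- c(adj[[f[2]]], f[1], f[3])
    adj[[f[3]]] <- c(adj[[f[3]]], f[1], f[2])
  }
  vapply(adj, function(a) length(unique(a)), 1L)
}

# brute-force convex hull volume by facet-plane enumeration (small n only):
# every unique supporting plane contributes its polygon area times the
# distance to the interior point
bf_hull_volume <- function(pts, eps = 1e-9) {
  n <- nrow(pts)
  centroid <- colMeans(pts)
  planes <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    nv <- spinemorph:::cross3(matrix(pts[j, ] - pts[i, ], 1),
                              matrix(pts[k, ] - pts[i, ], 1))[1, ]
    nn <- sqrt(sum(nv^2))
    if (nn < eps) next
    nv <- nv / nn
    dd <- as.vector(sweep(pts, 2, pts[i, ]) %*% nv)
    if (all(dd <= eps)) {
      planes[[length(planes) + 1]] <- c(nv, sum(nv * pts[i, ]))
    } else if (all(dd >= -eps)) {
      planes[[length(planes) + 1]] <- c(-nv, -sum(nv * pts[i, ]))
    }
  }
  pl <- unique(round(do.call(rbind, planes), 7))
  vol <- 0
  for (r in seq_len(nrow(pl))) {
    nv <- pl[r, 1:3]; off <- pl[r, 4]
    on_plane <- abs(as.vector(pts %*% nv) - off) <= 1e-6
    face_pts <- pts[on_plane, , drop = FALSE]
    if (nrow(face_pts) < 3) next
    # 2D polygon area of the hull of the on-plane points
    b1 <- face_pts[2, ] - face_pts[1, ]
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- spinemorph:::cross3(matrix(nv, 1), matrix(b1, 1))[1, ]
    uv <- cbind(sweep(face_pts, 2, face_pts[1, ]) %*% b1,
                sweep(face_pts, 2, face_pts[1, ]) %*% b2)
    h <- grDevices::chull(uv)
    poly <- uv[h, , drop = FALSE]
    m <- nrow(poly)
    area <- abs(sum(poly[, 1] * poly[c(2:m, 1), 2] -
                      poly[c(2:m, 1), 1] * poly[, 2])) / 2
    vol <- vol + area * abs(off - sum(nv * centroid)) / 3
  }
  vol
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_res <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

transform_mesh <- function(mesh, scale = 1, rotation = diag(3),
                           translation = c(0, 0, 0)) {
  m <- mesh
  m$vertices <- sweep(scale * (mesh$vertices %*% t(rotation)), 2,
                      translation, `+`)
  m
}

# voxelized ball mask (z, y, x) with margin voxels of background
ball_mask <- function(radius, spacing, margin = 4) {
  rv <- radius / spacing   # per-axis radius in voxels, spacing = (z, y, x)
  d <- 2 * ceiling(rv) + 2 * margin + 1
  ctr <- (d + 1) / 2
  iz <- ((seq_len(d[1]) - ctr[1]) / rv[1])^2
  iy <- ((seq_len(d[2]) - ctr[2]) / rv[2])^2
  ix <- ((seq_len(d[3]) - ctr[3]) / rv[3])^2
  arr <- outer(outer(iz, iy, `+`), ix, `+`)
  array(arr <= 1, dim = d)
}
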