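#' Icosphere test solid
#'
#' Subdivided icosahedron projected onto a sphere: a closed genus-0 mesh
#' with near-uniform triangles, handy as an analytic reference surface
#' (area `4 pi r^2`, volume `4/3 pi r^3`, mean curvature `1/r`, Gaussian
#' curvature `1/r^2`).
#'
#' @param subdivisions number of 4-way refinement rounds (0 = icosahedron).
#' @param radius sphere radius (um).
#' @param center sphere center.
#' @return a [tri_mesh].
#' @export
icosphere <- function(subdivisions = 2L, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      verts <<- rbind(verts, (verts[a, ] + verts[b, ]) / 2)
      mid_cache[[key]] <- nrow(verts)
      nrow(verts)
    }
    nf <- matrix(0L, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  v <- v / row_norms(v) * radius
  v <- sweep(v, 2, center, `+`)
  tri_mesh(v, f)
}
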