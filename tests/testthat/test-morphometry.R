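test_that("base center sits at the centroid of the cut rim", {
  cyl <- capped_cylinder(radius = 1, height = 2)
  expect_equal(find_base_center(cyl), c(0, 0, 0), tolerance = 1e-6,
               ignore_attr = TRUE)

  # icosphere with the polar cap removed: compare to the brute-force
  # centroid of the boundary-edge vertices (tolerance relative to scale)
  m <- open_icosphere(2, zcut = 0.8)
  bc <- find_base_center(m)
  be <- spinemorph:::boundary_edges(m)
  ref <- colMeans(m$vertices[unique(as.vector(be)), , drop = FALSE])
  expect_lt(sqrt(sum((bc - ref)^2)), 0.02 * 2)   # within 2% of the diameter

  expect_error(find_base_center(icosphere(1)), "no base")
})

test_that("length averages the 5% farthest vertices", {
  # all vertices at distance r = 2: L = 2
  g <- list(distances = rep(2, 40), n = 2L)
  class(g) <- "spine_geometry"
  expect_equal(feature_length(g), 2)

  g2 <- list(distances = 1:20, n = 1L)
  class(g2) <- "spine_geometry"
  expect_equal(feature_length(g2), 20)

  set.seed(9)
  d <- stats::runif(137, 0.1, 5)
  n <- ceiling(0.05 * 137)
  g3 <- list(distances = d, n = as.integer(n))
  class(g3) <- "spine_geometry"
  expect_equal(feature_length(g3),
               mean(sort(d, decreasing = TRUE)[seq_len(n)]))
})

test_that("surface area matches closed forms", {
  expect_equal(feature_surface(cube_mesh()), 6)
  expect_equal(feature_surface(regular_tetrahedron()), sqrt(3),
               tolerance = 1e-12)
  expect_equal(feature_surface(icosphere(3)), 4 * pi, tolerance = 0.01)
})

test_that("volume matches closed forms", {
  expect_equal(feature_volume(cube_mesh()), 1, tolerance = 1e-12)
  expect_equal(feature_volume(regular_tetrahedron()), 1 / (6 * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(feature_volume(icosphere(3)), 4 * pi / 3, tolerance = 0.02)
})

test_that("hull volume and ratio are exact for convex shapes", {
  h <- feature_hull(cube_mesh())
  expect_equal(h$HV, 1, tolerance = 1e-12)
  expect_equal(h$HR, 0, tolerance = 1e-9)

  hi <- feature_hull(icosphere(2))
  expect_lte(hi$HR, 0.02)
  expect_gte(hi$HR, -1e-9)
})

test_that("hull volume matches brute-force facet enumeration on an L-prism", {
  # two unit cubes sharing a face, one shifted: a concave L-shaped solid
  pts <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)),
               as.matrix(expand.grid(1:2, 0:1, 0:1 + 0.5)))
  pts <- unique(pts)
  expect_equal(convex_hull_volume(pts), bf_hull_volume(pts),
               tolerance = 1e-6)   # oracle rounds facet planes to 1e-7
})

test_that("random point clouds agree with brute-force hull volume", {
  for (seed in 1:3) {
    set.seed(seed)
    pts <- matrix(stats::rnorm(3 * 12), ncol = 3)
    expect_equal(convex_hull_volume(pts), bf_hull_volume(pts),
                 tolerance = 1e-6)
  }
})

test_that("distance statistics follow the population formulas", {
  g <- list(distances = rep(3, 10)); class(g) <- "spine_geometry"
  ds <- feature_distance_stats(g)
  expect_equal(ds$AD, 3)
  expect_equal(ds$CVD, 0)

  g2 <- list(distances = rep(c(1, 3), 8)); class(g2) <- "spine_geometry"
  ds2 <- feature_distance_stats(g2)
  expect_equal(ds2$AD, 2)
  expect_equal(ds2$CVD, 0.5)

  set.seed(5)
  d <- stats::rlnorm(101)
  g3 <- list(distances = d); class(g3) <- "spine_geometry"
  ds3 <- feature_distance_stats(g3)
  expect_equal(ds3$AD, mean(d))
  expect_equal(ds3$CVD, sqrt(mean((d - mean(d))^2)) / mean(d))
})

test_that("open angle handles axial, planar and hemispheric cases", {
  # vertices strictly along the axis beyond the base: OA = 0
  g <- list(S_bc = c(0, 0, 0), G_c = c(0, 0, 1),
            l = cbind(0, 0, c(1, 2, 3)), distances = c(1, 2, 3))
  class(g) <- "spine_geometry"
  expect_equal(feature_open_angle(NULL, g), 0)

  # vertices in the plane perpendicular to the axis: OA = pi/2
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  g2 <- list(S_bc = c(0, 0, 0), G_c = c(0, 0, 1),
             l = cbind(cos(th), sin(th), 0), distances = rep(1, 8))
  class(g2) <- "spine_geometry"
  expect_equal(feature_open_angle(NULL, g2), pi / 2)

  # hemisphere: matches the brute-force per-vertex average
  m <- make_spine_mesh(spine_params("stubby", head_radius = 1))$mesh
  geom <- spine_geometry(m)
  oa <- feature_open_angle(m, geom)
  axis <- (geom$G_c - geom$S_bc) / sqrt(sum((geom$G_c - geom$S_bc)^2))
  keep <- geom$distances > 0
  ang <- acos(pmin(pmax(
    (geom$l[keep, ] / geom$distances[keep]) %*% axis, -1), 1))
  expect_equal(oa, mean(ang))

  g3 <- list(S_bc = c(0, 0, 0), G_c = c(0, 0, 0),
             l = cbind(1, 0, 0), distances = 1)
  class(g3) <- "spine_geometry"
  expect_error(feature_open_angle(NULL, g3), "axis")
})

test_that("curvatures satisfy Gauss-Bonnet and sphere closed forms", {
  for (m in list(icosphere(1), icosphere(2, radius = 3), cube_mesh(),
                 regular_tetrahedron())) {
    cv <- feature_curvatures(m)
    expect_equal(cv$GC * cv$closed_area, 4 * pi, tolerance = 1e-6)
  }
  ic1 <- icosphere(3, radius = 1)
  ic2 <- icosphere(3, radius = 2)
  expect_equal(feature_curvatures(ic1)$GC, 1, tolerance = 0.02)
  expect_equal(feature_curvatures(ic2)$GC, 0.25, tolerance = 0.02)
  expect_equal(feature_curvatures(ic2)$MC, 0.5, tolerance = 0.1)
})

test_that("compute_features is deterministic and mutually consistent", {
  m <- make_spine_mesh(spine_params("mushroom", mesh_resolution = 2L))$mesh
  f1 <- compute_features(m)
  f2 <- compute_features(m)
  expect_identical(f1, f2)
  geom <- spine_geometry(m)
  expect_equal(f1$AD, feature_distance_stats(geom)$AD)
  expect_gte(f1$HV, f1$V)
})

test_that("equidistant spines have CVD 0 and L = AD", {
  # a hemisphere's vertices all sit one radius from its base center
  m <- make_spine_mesh(spine_params("stubby", head_radius = 0.8))$mesh
  f <- compute_features(m)
  expect_equal(f$CVD, 0, tolerance = 1e-6)
  expect_equal(f$L, f$AD, tolerance = 1e-6)
  expect_equal(f$AD, 0.8, tolerance = 1e-6)
})

test_that("features scale with the documented powers of c", {
  m <- make_spine_mesh(spine_params("mushroom", mesh_resolution = 1L))$mesh
  f <- unlist(compute_features(m))
  cscale <- 2.5
  fs <- unlist(compute_features(transform_mesh(m, scale = cscale)))
  powers <- c(L = 1, S = 2, V = 3, HV = 3, HR = 0, AD = 1, CVD = 0, OA = 0,
              MC = -1, GC = -2)
  expect_equal(fs[names(powers)], f[names(powers)] * cscale^powers,
               tolerance = 1e-6)
})

test_that("features are invariant to rigid motion", {
  m <- make_spine_mesh(spine_params("thin", mesh_resolution = 1L))$mesh
  f <- unlist(compute_features(m))
  mt <- transform_mesh(m, rotation = random_rotation(3),
                       translation = c(5, -2, 1.5))
  ft <- unlist(compute_features(mt))
  expect_equal(ft, f, tolerance = 1e-6)
})

test_that("volume errors on meshes with multiple boundary loops", {
  # tube open at both ends: two boundary loops
  th <- 2 * pi * (0:11) / 12
  v <- rbind(cbind(cos(th), sin(th), 0), cbind(cos(th), sin(th), 1))
  m2 <- c(2:12, 1)
  f <- rbind(cbind(1:12, m2, m2 + 12), cbind(1:12, m2 + 12, 13:24))
  tube <- tri_mesh(v, f)
  expect_error(feature_volume(tube), "boundary loops")
})
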