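test_that("meshes round-trip through PLY, OBJ and STL", {
  m <- icosphere(2, radius = 0.7)
  td <- withr::local_tempdir()

  for (ext in c("ply", "obj")) {
    p <- file.path(td, paste0("m.", ext))
    save_mesh(m, p)
    m2 <- load_mesh(p)
    expect_identical(n_vertices(m2), n_vertices(m))
    expect_identical(n_faces(m2), n_faces(m))
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(m2$faces, m$faces)
  }

  pb <- file.path(td, "bin.ply")
  save_mesh(m, pb, binary = TRUE)
  mb <- load_mesh(pb)
  expect_equal(mb$vertices, m$vertices, tolerance = 1e-12,
               ignore_attr = TRUE)

  # STL is a triangle soup in float32: welding restores the topology and
  # coordinates up to single-precision round-off, but not vertex order
  ps <- file.path(td, "m.stl")
  save_mesh(m, ps)
  ms <- load_mesh(ps)
  expect_identical(n_vertices(ms), n_vertices(m))
  expect_identical(n_faces(ms), n_faces(m))
  d2 <- outer(rowSums(ms$vertices^2), rowSums(m$vertices^2), `+`) -
    2 * ms$vertices %*% t(m$vertices)
  expect_lt(max(sqrt(pmax(apply(d2, 1, min), 0))), 1e-6)
})

test_that("a unit cube loads with 8 vertices and 12 triangles", {
  td <- withr::local_tempdir()
  p <- file.path(td, "cube.ply")
  save_mesh(cube_mesh(), p)
  m <- load_mesh(p)
  expect_identical(n_vertices(m), 8L)
  expect_identical(n_faces(m), 12L)
})

test_that("malformed mesh files are rejected", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), p)
  expect_error(load_mesh(p), "malformed")
  expect_error(load_mesh(file.path(td, "missing.ply")), "no such file")
  p2 <- file.path(td, "empty.obj")
  writeLines("# nothing", p2)
  expect_error(load_mesh(p2), "malformed")
})

test_that("vertex neighbor counts match brute-force adjacency", {
  tet <- regular_tetrahedron()
  expect_identical(vertex_neighbor_counts(tet), rep(3L, 4))
  ico <- icosphere(0)
  expect_identical(vertex_neighbor_counts(ico), rep(5L, 12))

  m <- make_spine_mesh(spine_params("mushroom", mesh_resolution = 1L))$mesh
  expect_identical(vertex_neighbor_counts(m), bf_neighbor_counts(m))

  # handshake: counts sum to twice the number of undirected edges
  et <- spinemorph:::edge_table(m$faces)
  expect_identical(sum(vertex_neighbor_counts(m)), 2L * nrow(et$edges))
})

test_that("integrity flags watertightness, manifoldness and hull", {
  ic <- icosphere(1)
  fl <- integrity(ic)
  expect_true(fl$is_watertight)
  expect_true(fl$is_manifold)
  expect_true(fl$hull_computable)

  holed <- spinemorph:::drop_faces(ic, 1L)
  expect_false(integrity(holed)$is_watertight)
  expect_true(integrity(holed)$is_manifold)

  flat <- tri_mesh(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0),
                   rbind(c(1, 2, 3), c(2, 4, 3)))
  expect_false(integrity(flat)$hull_computable)
})

test_that("repair removes duplicated faces, degenerate triangles and leftovers", {
  m <- icosphere(2)

  dup <- m
  dup$faces <- rbind(dup$faces, dup$faces[c(1, 5), ])
  r <- repair_mesh(dup)
  expect_identical(r$report$removed_duplicate_faces, 2L)
  expect_identical(n_faces(r$mesh), n_faces(m))

  deg <- m
  nv <- n_vertices(m)
  deg$vertices <- rbind(deg$vertices, c(0, 0, 2), c(0, 0, 2.5), c(0, 0, 3))
  deg$faces <- rbind(deg$faces, c(nv + 1L, nv + 2L, nv + 3L))
  r2 <- repair_mesh(deg)
  expect_identical(r2$report$removed_degenerate, 1L)
  expect_identical(r2$report$removed_isolated_vertices, 3L)
  expect_identical(n_vertices(r2$mesh), nv)
})

test_that("duplicate-vertex injection is cleaned to the de-duplicated set", {
  set.seed(4)
  m <- icosphere(2)
  n <- n_vertices(m)
  picks <- sample.int(n, ceiling(0.05 * n))
  m2 <- m
  # re-point some faces at duplicated copies of existing vertices
  for (p in picks) {
    m2$vertices <- rbind(m2$vertices, m2$vertices[p, ])
    hit <- which(m2$faces == p)[1]
    m2$faces[hit] <- nrow(m2$vertices)
  }
  r <- repair_mesh(m2)
  expect_identical(r$report$removed_duplicate_vertices, length(picks))
  # brute-force duplicate scan: surviving vertex set equals the unique set
  key_out <- apply(r$mesh$vertices, 1, paste, collapse = " ")
  key_in <- unique(apply(m2$vertices, 1, paste, collapse = " "))
  expect_setequal(key_out, key_in)
})

test_that("repair is idempotent", {
  m <- make_spine_mesh(spine_params("mushroom", mesh_resolution = 1L))$mesh
  r1 <- repair_mesh(m)
  r2 <- repair_mesh(r1$mesh)
  removals <- unlist(r2$report[c("removed_degenerate",
                                 "removed_isolated_vertices",
                                 "removed_self_intersections",
                                 "removed_duplicate_faces",
                                 "removed_obtuse",
                                 "removed_duplicate_vertices")])
  expect_true(all(removals == 0L))
  expect_identical(r2$report$level_of_detail_used, "normal")
})

test_that("self-intersecting faces are detected and eliminated", {
  m <- icosphere(1, radius = 1)
  # a rogue triangle slicing through the sphere wall, sharing no vertex
  nv <- n_vertices(m)
  m$vertices <- rbind(m$vertices,
                      c(0.5, -2, 0), c(0.5, 2, 0), c(1.5, 0, 0.1))
  m$faces <- rbind(m$faces, c(nv + 1L, nv + 2L, nv + 3L))
  bad <- spinemorph:::self_intersecting_faces(m)
  expect_true((n_faces(m)) %in% bad)      # the rogue face is flagged
  expect_true(length(bad) >= 2L)          # together with the wall it pierces
  r <- repair_mesh(m)
  expect_gte(r$report$removed_self_intersections, 2L)
})

test_that("synthetic spine meshes pass repair untouched", {
  for (fam in c("stubby", "mushroom", "thin")) {
    m <- make_spine_mesh(spine_params(fam, mesh_resolution = 1L))$mesh
    r <- repair_mesh(m)
    expect_identical(n_faces(r$mesh), n_faces(m))
    expect_identical(n_vertices(r$mesh), n_vertices(m))
  }
})
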