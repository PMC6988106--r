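# Surface extraction, normals, geodesic distances and label projection.

test_that("digitized spheres reconstruct radius, topology and area", {
  for (r in c(6, 10)) {
    sp <- sphere_mask(r)
    mesh <- extract_surface(sp$mask, sp$spacing, c(0, 0, 0))
    rad <- sqrt(rowSums(sweep(mesh$vertices, 2, sp$center)^2))
    expect_lt(abs(mean(rad) - r), 0.5)
    expect_equal(nrow(mesh$vertices) - nrow(mesh$edges) + nrow(mesh$faces), 2)
    expect_lt(abs(mesh_area(mesh) / (4 * pi * r^2) - 1), 0.1)
    # unit normals
    expect_equal(max(abs(sqrt(rowSums(mesh$normals^2)) - 1)), 0,
                 tolerance = 1e-6)
  }
})

test_that("mesh is denser than the image resolution", {
  sp <- sphere_mask(8)
  mesh <- extract_surface(sp$mask, sp$spacing, c(0, 0, 0))
  el <- sqrt(rowSums((mesh$vertices[mesh$edges[, 1], ] -
                      mesh$vertices[mesh$edges[, 2], ])^2))
  expect_lt(mean(el), min(sp$spacing))
})

test_that("single voxel yields a closed mesh inside its bounding box", {
  seg <- array(FALSE, c(5, 5, 5))
  seg[3, 3, 3] <- TRUE
  mesh <- extract_surface(seg, c(1, 1, 1), c(0, 0, 0))
  expect_equal(nrow(mesh$vertices) - nrow(mesh$edges) + nrow(mesh$faces), 2)
  # voxel centre (0-based index 2) spans [1.5, 2.5] mm per axis
  expect_true(all(mesh$vertices >= 1.5 - 1e-9 & mesh$vertices <= 2.5 + 1e-9))
})

test_that("empty and multi-component segmentations are handled", {
  expect_error(extract_surface(array(FALSE, c(5, 5, 5))), "empty")
  seg <- array(FALSE, c(12, 12, 12))
  seg[3:5, 3:5, 3:5] <- TRUE      # 27 voxels
  seg[9, 9, 9] <- TRUE            # separate single voxel
  expect_warning(mesh <- extract_surface(seg), "largest")
  expect_true(all(mesh$vertices <= 6))   # kept the big block only
})

test_that("vertex normals point outward, whatever the face winding", {
  sp <- sphere_mask(9)
  mesh <- extract_surface(sp$mask, sp$spacing, c(0, 0, 0))
  dirs <- sweep(mesh$vertices, 2, sp$center)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_gt(min(rowSums(mesh$normals * dirs)), 0.9)
  # flipping all faces must not flip the normals (interior test fixes sign)
  flipped <- mesh
  flipped$faces <- mesh$faces[, c(1, 3, 2)]
  n2 <- vertex_normals(flipped)
  expect_gt(min(rowSums(n2 * dirs)), 0.9)
})

test_that("normals of a flat triangle fan equal the plane normal", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 3, 4))
  mesh <- structure(list(vertices = v, faces = f,
                         edges = atrialscar:::faces_to_edges(f)),
                    class = "surface_mesh")
  n <- vertex_normals(mesh)
  expect_equal(abs(n[, 3]), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(n[, 1:2], matrix(0, 4, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("geodesic distances satisfy the basic identities", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0))
  f <- rbind(c(1, 2, 3))
  mesh <- surface_mesh(v, f)
  expect_equal(geodesic_distance(mesh, 1, 1), 0)
  expect_equal(geodesic_distance(mesh, 1, 2), 1)      # adjacent: edge length
  # path graph with edge lengths 1 and 2: direct edge removed
  mesh2 <- mesh
  mesh2$edges <- rbind(c(1L, 2L), c(2L, 3L))
  expect_equal(geodesic_distance(mesh2, 1, 3), 3)
})

test_that("geodesics match a brute-force shortest-path oracle", {
  seg <- array(FALSE, c(9, 9, 9))
  seg[4:6, 4:6, 4:6] <- TRUE
  mesh <- extract_surface(seg, smooth_sigma = 0)   # small blocky mesh
  expect_lte(nrow(mesh$vertices), 200)
  from <- c(1, 7, nrow(mesh$vertices))
  for (s in from) {
    oracle <- brute_force_geodesic(mesh, s)
    got <- geodesic_distance(mesh, s, seq_len(nrow(mesh$vertices)))
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("label projection follows the normal corridor", {
  sp <- sphere_mask(8)
  mesh <- extract_surface(sp$mask, sp$spacing, c(0, 0, 0))
  dims <- sp$dims
  empty <- array(0, dims)
  expect_true(all(project_labels(empty, mesh, spacing = sp$spacing) == 0))

  # scar voxel ~1 mm outside a node along its normal -> labelled
  node <- 1L
  p_in <- mesh$vertices[node, ] + 1 * mesh$normals[node, ]
  scar <- array(0, dims)
  ijk <- round(p_in / sp$spacing)
  scar[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] <- 1
  lab <- project_labels(scar, mesh, depth_out_mm = 4, depth_in_mm = 1,
                        spacing = sp$spacing)
  expect_equal(lab[node], 1L)

  # voxel ~6 mm outside is beyond the 4 mm corridor of that node
  p_out <- mesh$vertices[node, ] + 6 * mesh$normals[node, ]
  scar2 <- array(0, dims)
  ijk2 <- round(p_out / sp$spacing)
  scar2[ijk2[1] + 1, ijk2[2] + 1, ijk2[3] + 1] <- 1
  lab2 <- project_labels(scar2, mesh, depth_out_mm = 4, depth_in_mm = 1,
                         spacing = sp$spacing)
  expect_equal(lab2[node], 0L)
})

test_that("projection is monotone in the corridor depth", {
  ph <- make_phantom(small_phantom_config(seed = 8))
  mesh <- extract_surface(ph$la_seg, ph$spacing, ph$origin)
  l_short <- project_labels(ph$scar_seg * 1, mesh, depth_out_mm = 2,
                            spacing = ph$spacing)
  l_long <- project_labels(ph$scar_seg * 1, mesh, depth_out_mm = 5,
                           spacing = ph$spacing)
  expect_true(all(l_long >= l_short))
  expect_gt(sum(l_short), 0)
})

test_that("meshes with point scalars round-trip through PLY and export to VTK", {
  sp <- sphere_mask(5)
  mesh <- extract_surface(sp$mask, sp$spacing, c(0, 0, 0))
  lab <- as.numeric(seq_len(nrow(mesh$vertices)) %% 2)
  ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(mesh, ply, scalars = list(scar = lab))
  back <- read_ply(ply)
  expect_equal(unname(back$mesh$vertices), unname(mesh$vertices),
               tolerance = 1e-5)
  expect_identical(back$mesh$faces, mesh$faces)
  expect_equal(back$scalars$scar, lab)
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(mesh, vtk, scalars = list(scar = lab))
  txt <- readLines(vtk)
  expect_true(any(grepl("POLYGONS", txt)))
  expect_true(any(grepl("SCALARS scar", txt)))
})

test_that("cap removal opens the mesh only inside the requested cone", {
  sp <- sphere_mask(8)
  mesh <- extract_surface(sp$mask, sp$spacing, c(0, 0, 0))
  open <- remove_mesh_cap(mesh, direction = c(0, 0, 1), angle_deg = 30)
  expect_lt(nrow(open$vertices), nrow(mesh$vertices))
  # an open mesh no longer has Euler characteristic 2
  expect_lt(nrow(open$vertices) - nrow(open$edges) + nrow(open$faces), 2)
  # removed vertices all sit in the +z cone; survivors elsewhere intact
  d <- sweep(open$vertices, 2, sp$center)
  cosang <- d[, 3] / sqrt(rowSums(d^2))
  expect_lt(sum(cosang > cos(20 * pi / 180)), 10)
  expect_identical(nrow(open$normals), nrow(open$vertices))
})
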