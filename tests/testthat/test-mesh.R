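test_that("mesh and CFL rules follow their closed forms", {
  expect_equal(hmax_rule(343, 150e3), 343 / (6 * 150e3))
  expect_equal(round(hmax_rule(343, 150e3), 8), 3.8111e-4, tolerance = 1e-7)
  expect_equal(hmax_rule(343, 57166.7), 1e-3, tolerance = 1e-5)
  expect_error(hmax_rule(343, 0), "positive")
  expect_equal(cfl_number(343, 1 / (60 * 150e3), hmax_rule(343, 150e3)), 0.1)
  expect_equal(cfl_number(343, 1e-3 / 343, 1e-3), 1)
  expect_equal(cfl_number(343, 0, 1e-3), 0)
  expect_error(cfl_number(343, 1e-7, 0), "positive")
})

test_that("ball meshes are positively oriented, watertight volumes", {
  m <- build_ball_mesh(radius = 1.5e-3, target_h = 4e-4)
  vols <- resonear:::tet_volumes(m$nodes, m$tets)
  expect_true(all(vols > 0))
  # polyhedral volume a little under the sphere volume, converging with h
  expect_equal(sum(vols), 4 / 3 * pi * (1.5e-3)^3, tolerance = 0.05)
  m2 <- build_ball_mesh(radius = 1.5e-3, target_h = 2e-4)
  err1 <- abs(sum(vols) - 4 / 3 * pi * (1.5e-3)^3)
  err2 <- abs(sum(resonear:::tet_volumes(m2$nodes, m2$tets)) - 4 / 3 * pi * (1.5e-3)^3)
  expect_lt(err2, err1)
  # every interior triangular face is shared by exactly two tets
  tets <- m$tets
  faces <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
                 tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "-")
  cnt <- table(table(key))
  expect_true(all(names(cnt) %in% c("1", "2")))
  # boundary faces (count 1) all lie on the outer sphere
  bkey <- names(table(key))[table(key) == 1]
  bnodes <- unique(as.integer(unlist(strsplit(bkey, "-"))))
  r <- sqrt(rowSums(m$nodes[bnodes, ]^2))
  expect_true(all(abs(r - 1.5e-3) < 1e-9))
})

test_that("parametric ears meet their geometric contract", {
  mesh <- build_parametric_ear(slit_area = 0.16e-6, cavity_volume = 0.14e-9,
                               sphere_radius = 1.8e-3, target_h = 4.5e-4)
  expect_equal(mesh$meta$realized_volume_m3, 0.14e-9, tolerance = 0.02)
  expect_true(mesh$meta$realized_volume_m3 >= 0.137e-9 &&
                mesh$meta$realized_volume_m3 <= 0.143e-9)
  expect_equal(mesh$meta$realized_slit_area_m2, 0.16e-6, tolerance = 0.02)
  expect_gt(nrow(mesh$node_pairs), 0)
  # determinism
  mesh2 <- build_parametric_ear(slit_area = 0.16e-6, cavity_volume = 0.14e-9,
                                sphere_radius = 1.8e-3, target_h = 4.5e-4)
  expect_identical(mesh$nodes, mesh2$nodes)
  expect_identical(mesh$tets, mesh2$tets)
  # impossible proportions: slit wider than the cavity can accommodate
  expect_error(build_parametric_ear(slit_area = 2e-6, cavity_volume = 0.05e-9,
                                    sphere_radius = 1.8e-3, target_h = 4.5e-4),
               "too large|Slit radius")
})

test_that("cavity wall disconnects interior from exterior except the slit", {
  mesh <- build_parametric_ear(slit_area = 0.16e-6, cavity_volume = 0.14e-9,
                               sphere_radius = 1.8e-3, target_h = 4.5e-4)
  # wall nodes are duplicated: inside and outside copies share coordinates
  np <- mesh$node_pairs
  expect_equal(mesh$nodes[np[, "inside"], ], mesh$nodes[np[, "outside"], ])
  # no tet contains both an inside and an outside copy
  ins <- np[, "inside"]; outs <- np[, "outside"]
  has_in <- matrix(mesh$tets %in% ins, ncol = 4)
  has_out <- matrix(mesh$tets %in% outs, ncol = 4)
  expect_false(any(rowSums(has_in) > 0 & rowSums(has_out) > 0))
})

test_that("STL surfaces load, validate and measure volumes", {
  sphere_path <- tempfile(fileext = ".stl")
  write_ascii_stl_sphere(sphere_path, radius_mm = 1, n = 32)
  g <- load_stl_geometry(sphere_path, units = "mm")
  expect_equal(g$meta$enclosed_volume_m3, 4 / 3 * pi * 1e-9, tolerance = 0.02)
  cube_path <- tempfile(fileext = ".stl")
  write_ascii_stl_cube(cube_path, side_mm = 1)
  gc <- load_stl_geometry(cube_path, units = "mm")
  expect_equal(gc$meta$enclosed_volume_m3, 1e-9, tolerance = 1e-6)
  # declared mm units produce a 1e-3 m bounding box
  bb <- apply(gc$meta$surface_vertices, 2, function(x) diff(range(x)))
  expect_equal(unname(bb), rep(1e-3, 3), tolerance = 1e-9)
  # interior tetrahedralisation approximates the enclosed volume
  vol_tets <- sum(resonear:::tet_volumes(gc$nodes, gc$tets))
  expect_equal(vol_tets, 1e-9, tolerance = 0.35)
  # non-watertight surface fails loudly
  open_path <- tempfile(fileext = ".stl")
  write_ascii_stl_cube(open_path, side_mm = 1, drop_last = TRUE)
  expect_error(load_stl_geometry(open_path, units = "mm"), "watertight")
})
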