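# square ring of side s centred at (cx, cy)
square_ring <- function(s = 1, cx = 0, cy = 0) {
  h <- s / 2
  cbind(cx + c(-h, h, h, -h), cy + c(-h, -h, h, h))
}

unit_cube_mesh <- function() {
  sq <- square_ring(1, 0.5, 0.5)
  cs <- suppressWarnings(contour_set(list(
    list(z = 0, polygons = list(sq)),
    list(z = 1, polygons = list(sq))
  )))
  suppressWarnings(contours_to_mesh(cs))
}

test_that("a stitched and capped cuboid has exact area and volume", {
  mesh <- unit_cube_mesh()
  expect_true(mesh$watertight)
  expect_equal(as.numeric(mesh_surface_area(mesh)), 6, tolerance = 1e-12)
  expect_equal(mesh_volume(mesh), 1, tolerance = 1e-12)
})

test_that("sphere meshes converge monotonically to the analytic sphere", {
  levels <- list(c(0.2, 16), c(0.1, 32), c(0.05, 64))
  v_err <- sa_err <- numeric(0)
  for (lv in levels) {
    cs <- make_structure(fixture_spec("sphere", r = 1, slice_spacing = lv[1],
                                      points_per_ring = lv[2]))
    mesh <- contours_to_mesh(cs)
    expect_true(mesh$watertight)
    v_err <- c(v_err, abs(mesh_volume(mesh) - 4 * pi / 3) / (4 * pi / 3))
    sa_err <- c(sa_err, abs(as.numeric(mesh_surface_area(mesh)) - 4 * pi) / (4 * pi))
  }
  expect_true(all(diff(v_err) < 0))
  expect_true(all(diff(sa_err) < 0))
  expect_lt(v_err[2], 0.02)   # 1 mm slicing within 2% of 4pi/3
  expect_lt(sa_err[2], 0.02)
})

test_that("no valid closed mesh undercuts the sphere bound of its own volume", {
  # isoperimetric property: the diagnostic can only fire against an external
  # reference volume, never against the mesh's own enclosed volume
  specs <- list(
    fixture_spec("sphere", r = 0.6, slice_spacing = 0.1),
    fixture_spec("ellipsoid", a = 1, b = 0.6, c = 1.4, slice_spacing = 0.1),
    fixture_spec("two_lobe", r1 = 0.6, r2 = 0.4, separation = 1.7,
                 slice_spacing = 0.05),
    sphere_fixture(0.011, slice_spacing = 0.1, pixel_quantum = 0.1)
  )
  for (spec in specs) {
    mesh <- suppressWarnings(contours_to_mesh(make_structure(spec)))
    sa <- expect_silent(mesh_surface_area(mesh))
    expect_false(attr(sa, "nonphysical_sa"))
    expect_gte(as.numeric(sa), attr(sa, "sphere_bound"))
  }
})

test_that("coarse pixelated tiny structure reproduces the non-physical area pathology", {
  # a 0.011 cm^3 target contoured on a 1 mm grid: the mesh understates both
  # area and volume, so its area falls below the 0.24 cm^2 sphere bound of
  # the planning-system volume
  cs <- make_structure(sphere_fixture(0.011, slice_spacing = 0.1,
                                      pixel_quantum = 0.1))
  mesh <- suppressWarnings(contours_to_mesh(cs))
  expect_true(attr(mesh, "resolution_warning"))
  expect_warning(
    sa <- mesh_surface_area(mesh, reference_volume = 0.011),
    "non-physical"
  )
  expect_true(attr(sa, "nonphysical_sa"))
  expect_lt(as.numeric(sa), sphere_surface_area_from_volume(0.011))
  expect_lt(as.numeric(sa), 0.24)
})

test_that("ellipsoid mesh area exceeds the equal-volume sphere area", {
  cs <- make_structure(fixture_spec("ellipsoid", a = 1, b = 0.7, c = 1.3,
                                    slice_spacing = 0.05, points_per_ring = 96))
  mesh <- contours_to_mesh(cs)
  v <- mesh_volume(mesh)
  sa <- as.numeric(mesh_surface_area(mesh))
  expect_gt(sa, sphere_surface_area_from_volume(v))
  # and tracks the analytic oracle of the ideal shape to a few percent
  expect_equal(v, attr(cs, "analytic_volume"), tolerance = 0.01)
  expect_equal(sa, attr(cs, "analytic_area"), tolerance = 0.01)
})

test_that("two-lobe fixtures exercise multi-ring matching and capping", {
  cs <- make_structure(fixture_spec("two_lobe", r1 = 0.6, r2 = 0.35,
                                    separation = 1.6, slice_spacing = 0.05))
  mesh <- contours_to_mesh(cs)
  expect_true(mesh$watertight)
  expect_equal(mesh_volume(mesh), attr(cs, "analytic_volume"), tolerance = 0.02)
  expect_equal(as.numeric(mesh_surface_area(mesh)), attr(cs, "analytic_area"),
               tolerance = 0.02)
})

test_that("volume is orientation-independent and needs watertightness", {
  mesh <- unit_cube_mesh()
  flipped <- gk_mesh(mesh$vertices, mesh$triangles[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), mesh_volume(mesh), tolerance = 1e-12)
  open_mesh <- suppressWarnings(
    gk_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), matrix(1:3, 1))
  )
  expect_false(open_mesh$watertight)
  expect_error(mesh_volume(open_mesh), "not watertight")
})

test_that("single-slice structures are extruded to a slab and flagged", {
  cs <- suppressWarnings(contour_set(
    list(list(z = 0.05, polygons = list(square_ring(0.5)))),
    spacing = c(NA, 0.1)
  ))
  expect_true(cs$degenerate)
  mesh <- suppressWarnings(contours_to_mesh(cs))
  expect_true(attr(mesh, "degenerate"))
  expect_equal(mesh_volume(mesh), 0.5 * 0.5 * 0.1, tolerance = 1e-12)
  # without any thickness information the extrusion cannot be sized
  cs2 <- suppressWarnings(contour_set(
    list(list(z = 0, polygons = list(square_ring(0.5))))
  ))
  expect_error(suppressWarnings(contours_to_mesh(cs2)), "slab_thickness")
})

test_that("mesh quantities scale correctly under unit rescaling", {
  # the same geometry built 10x larger (mm magnitudes) scales SA by 100 and
  # volume by 1000, so a mm-read structure converted to cm is consistent
  sq <- square_ring(1, 0.5, 0.5)
  cs_cm <- suppressWarnings(contour_set(list(list(z = 0, polygons = list(sq)),
                                             list(z = 1, polygons = list(sq)))))
  cs_mm <- suppressWarnings(contour_set(list(list(z = 0, polygons = list(sq * 10)),
                                             list(z = 10, polygons = list(sq * 10)))))
  m_cm <- suppressWarnings(contours_to_mesh(cs_cm))
  m_mm <- suppressWarnings(contours_to_mesh(cs_mm))
  expect_equal(as.numeric(mesh_surface_area(m_mm)),
               100 * as.numeric(mesh_surface_area(m_cm)), tolerance = 1e-12)
  expect_equal(mesh_volume(m_mm), 1000 * mesh_volume(m_cm), tolerance = 1e-12)
})

test_that("mesh exports are well-formed text", {
  mesh <- unit_cube_mesh()
  stl <- withr::local_tempfile(fileext = ".stl")
  off <- withr::local_tempfile(fileext = ".off")
  write_stl(mesh, stl)
  write_off(mesh, off)
  stl_lines <- readLines(stl)
  expect_identical(stl_lines[1], "solid gkr50")
  expect_identical(tail(stl_lines, 1), "endsolid gkr50")
  expect_equal(sum(grepl("^  facet", stl_lines)), nrow(mesh$triangles))
  off_lines <- readLines(off)
  expect_identical(off_lines[1], "OFF")
  expect_equal(off_lines[2],
               sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)))
})

test_that("50%-isodose volume extraction matches analytic dose phantoms", {
  # uniform grid entirely above threshold returns the whole grid volume
  g <- array(10, c(5, 5, 5))
  expect_equal(vidc50_from_dose_grid(g, c(0.1, 0.1, 0.1), 10), 0.125)
  # all-zero grid: zero volume with a warning
  expect_warning(v0 <- vidc50_from_dose_grid(array(0, c(4, 4, 4)),
                                             c(0.1, 0.1, 0.1), 20),
                 "V_IDC50% = 0")
  expect_equal(v0, 0)
  # radially decreasing dose with known 50% radius rho = 1 cm
  gx <- seq(-2, 2, by = 0.05)
  rr <- sqrt(outer(outer(gx^2, gx^2, "+"), gx^2, "+"))
  dose <- array(pmax(0, 20 * (1 - rr / 2)), dim = rep(length(gx), 3))
  v <- vidc50_from_dose_grid(dose, rep(0.05, 3), 20)
  shell <- 4 * pi * 1^2 * 0.05  # one voxel-shell at the 50% surface
  expect_lt(abs(v - 4 * pi / 3), shell)
  # sub-voxel refinement gets closer on a coarser grid
  gx2 <- seq(-2, 2, by = 0.2)
  rr2 <- sqrt(outer(outer(gx2^2, gx2^2, "+"), gx2^2, "+"))
  dose2 <- array(pmax(0, 20 * (1 - rr2 / 2)), dim = rep(length(gx2), 3))
  v_plain <- vidc50_from_dose_grid(dose2, rep(0.2, 3), 20)
  v_ref <- vidc50_from_dose_grid(dose2, rep(0.2, 3), 20, refine = 4)
  expect_lt(abs(v_ref - 4 * pi / 3), abs(v_plain - 4 * pi / 3) + 1e-9)
})
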