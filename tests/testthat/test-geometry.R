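# Scenario builders and fiber patterns: voxelized volumes against exact
# constructive-solid-geometry oracles, tagging, determinism, unit fibers.

test_that("slab myocardial volume matches the slab-minus-capsule oracle", {
  cfg <- reduced_config()
  mesh <- suppressWarnings(build_slab_scenario(cfg))
  r <- cfg$catheter_diameter / 2
  L <- 2 * cfg$electrode_length + cfg$insulator_length
  exact <- cfg$lateral_extent^2 * cfg$wall_thickness -
    capsule_slab_overlap(r, L, cfg$insertion_depth)
  expect_equal(myocardial_volume(mesh), exact, tolerance = 0.01)
  # refinement halves the voxelization error budget comfortably
  cfg4 <- suppressWarnings(scenario_config(lateral_extent = 26.4e-3,
                                           blood_depth = 4.8e-3,
                                           resolution = 0.4e-3))
  mesh4 <- build_slab_scenario(cfg4)
  expect_equal(myocardial_volume(mesh4), exact, tolerance = 0.005)
})

test_that("tangent catheter (zero insertion) leaves the slab volume exact", {
  cfg <- reduced_config(insertion_depth = 0)
  mesh <- suppressWarnings(build_slab_scenario(cfg))
  expect_equal(myocardial_volume(mesh),
               cfg$lateral_extent^2 * cfg$wall_thickness, tolerance = 1e-12)
})

test_that("invalid scenario configurations are rejected", {
  expect_error(reduced_config(insertion_depth = 3e-3), "geometry error")
  expect_error(reduced_config(resolution = 1.2e-3), "resolution error")
  expect_error(suppressWarnings(scenario_config(lateral_extent = 20e-3,
                                                resolution = 0.8e-3)),
               "lateral_extent")
  expect_error(reduced_config(wall_thickness = -1), "positive")
  # reference-resolution warning fires when building on a coarse grid
  expect_warning(build_slab_scenario(scenario_config(resolution = 0.95e-3)),
                 "400")
})

test_that("scenario meshes tag every region and are deterministic", {
  mesh1 <- reduced_slab()
  mesh2 <- reduced_slab()
  expect_identical(mesh1$nodes, mesh2$nodes)
  expect_identical(mesh1$elems, mesh2$elems)
  expect_identical(mesh1$region, mesh2$region)
  expect_setequal(unique(as.character(mesh1$region)),
                  c("MYOCARDIUM", "BLOOD", "ELECTRODE_LEFT",
                    "ELECTRODE_RIGHT", "INSULATOR"))
  expect_false(anyNA(mesh1$region))
  fc <- boundary_facets(mesh1)
  expect_gt(nrow(fc$ENDOCARDIAL), 0)
  expect_gt(nrow(fc$ELECTRODE_LEFT_SURFACE), 0)
  expect_gt(nrow(fc$EPICARDIAL), 0)
})

test_that("ostium scenario removes the hole cylinder; zero diameter is a no-op", {
  cfg <- reduced_config()
  slab <- suppressWarnings(build_slab_scenario(cfg))
  same <- suppressWarnings(build_ostium_scenario(cfg, 0))
  expect_identical(same$region, slab$region)
  mesh <- suppressWarnings(build_ostium_scenario(cfg, 8e-3))
  r <- cfg$catheter_diameter / 2
  L <- 2 * cfg$electrode_length + cfg$insulator_length
  exact <- cfg$lateral_extent^2 * cfg$wall_thickness -
    capsule_slab_overlap(r, L, cfg$insertion_depth) -
    pi * (4e-3)^2 * cfg$wall_thickness
  expect_equal(myocardial_volume(mesh), exact, tolerance = 0.01)
  expect_error(suppressWarnings(build_ostium_scenario(cfg, 14e-3)),
               "geometry error")
})

test_that("ostium wall facets lie on the hole cylinder", {
  cfg <- reduced_config()
  mesh <- suppressWarnings(build_ostium_scenario(cfg, 8e-3))
  yc <- mesh$ostium$center_y
  fc <- interface_facets(mesh, "MYOCARDIUM", "BLOOD")
  lateral <- fc[fc$dir %in% c("x-", "x+", "y-", "y+"), ]
  expect_gt(nrow(lateral), 0)
  mid <- (mesh$nodes[lateral$n1, ] + mesh$nodes[lateral$n3, ]) / 2
  radii <- sqrt(mid[, 1]^2 + (mid[, 2] - yc)^2)
  # lateral myocardium-blood faces are either on the hole wall or on the
  # catheter indentation; the hole-wall ones sit within a cell of the radius
  on_hole <- abs(mid[, 2] - yc) < 4e-3 + 2 * cfg$resolution &
    mid[, 2] > cfg$catheter_diameter
  expect_gt(sum(on_hole), 0)
  expect_true(all(abs(radii[on_hole] - 4e-3) <= 1.5 * cfg$resolution))
})

test_that("uniform and circumferential fiber patterns have the right geometry", {
  mesh <- reduced_slab()
  fib <- make_fiber_field(mesh, "UNIFORM", list(theta = 0))
  expect_equal(nrow(fib$dir), sum(mesh$region == "MYOCARDIUM"))
  expect_true(all(fib$dir[, 1] == 1 & fib$dir[, 2] == 0 & fib$dir[, 3] == 0))
  th <- pi / 3
  fib <- make_fiber_field(mesh, "UNIFORM", list(theta = th))
  expect_equal(fib$dir[1, ], c(cos(th), sin(th), 0))

  ctr <- c(1.2e-3, 2e-3)
  fib <- make_fiber_field(mesh, "CIRCUMFERENTIAL", list(center = ctr))
  expect_equal(max(abs(sqrt(rowSums(fib$dir^2)) - 1)), 0, tolerance = 1e-12)
  # element nearest ctr + (r, 0): tangent is (0, 1, 0) up to sign
  cen <- element_centroids(mesh)[fib$elements, ]
  probe <- which.min((cen[, 1] - (ctr[1] + 6e-3))^2 + (cen[, 2] - ctr[2])^2)
  d <- fib$dir[probe, ]
  expect_equal(abs(d[2]), 1, tolerance = 0.12)
  expect_lt(abs(d[1]), 0.12)
})

test_that("crossing bundles blend with unit norm and match uniform far away", {
  mesh <- reduced_slab()
  fib <- make_fiber_field(mesh, "CROSSING_BUNDLES",
                          list(theta1 = pi / 4, theta2 = -pi / 4,
                               divide_y = 0, blend_width = 2e-3))
  expect_equal(max(abs(sqrt(rowSums(fib$dir^2)) - 1)), 0, tolerance = 1e-12)
  cen <- element_centroids(mesh)[fib$elements, ]
  up <- cen[, 2] > 1.1e-3
  dn <- cen[, 2] < -1.1e-3
  expect_true(all(abs(fib$dir[up, 1] - cos(-pi / 4)) < 1e-12))
  expect_true(all(abs(fib$dir[up, 2] - sin(-pi / 4)) < 1e-12))
  expect_true(all(abs(fib$dir[dn, 1] - cos(pi / 4)) < 1e-12))
  expect_true(all(abs(fib$dir[dn, 2] - sin(pi / 4)) < 1e-12))
  # antiparallel bundles cancel on the divide line
  expect_error(make_fiber_field(mesh, "CROSSING_BUNDLES",
                                list(theta1 = 0, theta2 = pi)),
               "degenerate-fiber")
})

test_that("VTK export writes a well-formed ASCII file", {
  mesh <- box_mesh(c(0, 0, 0), rep(2e-3, 3), rep(2L, 3))
  f <- tempfile(fileext = ".vtu")
  write_vtu(mesh, f, point_data = list(V = seq_len(nrow(mesh$nodes))),
            cell_data = list(E = matrix(1, nrow(mesh$elems), 3)))
  txt <- readLines(f)
  expect_true(any(grepl("UnstructuredGrid", txt)))
  expect_true(any(grepl('Name="V"', txt)))
  expect_true(any(grepl('Name="E" NumberOfComponents="3"', txt)))
  doc <- xml2::read_xml(f)  # parses as XML
  expect_equal(xml2::xml_name(doc), "VTKFile")
})
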