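# Threshold lesion metrics: partial-volume integration, surface area,
# marching-tetrahedra isosurface, extents, paired differences.

# two-layer box: myocardium below z = 2 mm, blood above; endocardial
# interface is the 10 x 10 mm plane at z = 2 mm
layered_box <- function() {
  mesh <- box_mesh(c(0, 0, 0), c(10e-3, 10e-3, 4e-3), c(10, 10, 4))
  cen <- element_centroids(mesh)
  mesh$region <- factor(ifelse(cen[, 3] < 2e-3, "MYOCARDIUM", "BLOOD"),
                        levels = levels(mesh$region))
  mesh
}

test_that("tetrahedron partial volumes match a Monte-Carlo oracle", {
  set.seed(11)
  n_mc <- 2e5
  # barycentric sampling of the reference tetrahedron
  w <- matrix(stats::rexp(4 * n_mc), ncol = 4)
  w <- w / rowSums(w)
  for (rep in 1:12) {
    v <- stats::rnorm(4)
    f_exact <- pfasim:::tet_fraction_above(matrix(v, 1))
    f_mc <- mean(w %*% v > 0)
    expect_lt(abs(f_exact - f_mc), 6 / sqrt(n_mc))
  }
  # degenerate/tied cases
  expect_equal(pfasim:::tet_fraction_above(matrix(c(1, 1, 1, 1), 1)), 1)
  expect_equal(pfasim:::tet_fraction_above(matrix(c(-1, -1, -1, -1), 1)), 0)
  expect_equal(pfasim:::tet_fraction_above(matrix(c(1, 1, -1, -1), 1)), 0.5,
               tolerance = 1e-6)
})

test_that("triangle area fractions match a Monte-Carlo oracle", {
  set.seed(12)
  n_mc <- 2e5
  w <- matrix(stats::rexp(3 * n_mc), ncol = 3)
  w <- w / rowSums(w)
  for (rep in 1:12) {
    v <- stats::rnorm(3)
    f_exact <- pfasim:::tri_fraction_above(matrix(v, 1))
    f_mc <- mean(w %*% v > 0)
    expect_lt(abs(f_exact - f_mc), 6 / sqrt(n_mc))
  }
})

test_that("uniform fields give all-or-nothing ablation volume", {
  mesh <- layered_box()
  ne <- nrow(mesh$elems)
  expect_equal(ablation_volume(mesh, rep(2e5, ne)), 200)  # 10x10x2 mm myo
  expect_equal(ablation_volume(mesh, rep(0.5e5, ne)), 0)
  expect_error(ablation_volume(mesh, rep(1e5, ne), threshold = -1),
               "domain error")
})

test_that("point-source field yields the analytic ball volume and extents", {
  mesh <- box_mesh(c(0, 0, 0), rep(24e-3, 3), rep(40L, 3))
  cen <- element_centroids(mesh)
  ctr <- rep(12e-3, 3)
  r2 <- colSums((t(cen) - ctr)^2)
  thr <- 1e5
  r_star <- 6e-3
  e_mag <- thr * r_star^2 / r2
  vol <- ablation_volume(mesh, e_mag, thr)
  expect_equal(vol, 4 / 3 * pi * (r_star * 1e3)^3, tolerance = 0.02)
  iso <- extract_isosurface(mesh, e_mag, thr)
  expect_gt(nrow(iso$triangles), 100)
  # vertex radii close to the threshold radius
  vr <- sqrt(rowSums((iso$triangles[, 1:3] - 12)^2))
  expect_lt(max(abs(vr - r_star * 1e3)) / (r_star * 1e3), 0.02)
  ext <- isosurface_extents(iso)
  expect_equal(unname(ext), rep(2 * r_star * 1e3, 3), tolerance = 0.02)
})

test_that("ablation volume is monotone non-increasing in the threshold", {
  mesh <- box_mesh(c(0, 0, 0), rep(12e-3, 3), rep(12L, 3))
  cen <- element_centroids(mesh)
  r2 <- colSums((t(cen) - rep(6e-3, 3))^2)
  e_mag <- 1e5 * (3e-3)^2 / r2
  vols <- vapply(seq(0.5e5, 3e5, length.out = 12),
                 function(th) ablation_volume(mesh, e_mag, th), numeric(1))
  expect_true(all(diff(vols) <= 1e-9))
})

test_that("surface ablation area handles uniform, half, and radial fields", {
  mesh <- layered_box()
  ne <- nrow(mesh$elems)
  expect_equal(surface_ablation_area(mesh, rep(2e5, ne)), 100)
  expect_equal(surface_ablation_area(mesh, rep(0.5e5, ne)), 0)
  # supra-threshold on exactly half the patch: step at the midline puts the
  # midline nodes at the threshold
  cen <- element_centroids(mesh)
  e_half <- ifelse(cen[, 1] < 5e-3, 2e5, 0)
  expect_equal(surface_ablation_area(mesh, e_half), 50, tolerance = 1e-6)
  expect_error(surface_ablation_area(mesh, rep(2e5, ne), surface = "NOPE"),
               "tag error")
})

test_that("smooth radial fall-off reproduces the analytic disc area", {
  mesh <- box_mesh(c(0, 0, 0), c(20e-3, 20e-3, 4e-3), c(40, 40, 8))
  cen <- element_centroids(mesh)
  mesh$region <- factor(ifelse(cen[, 3] < 2e-3, "MYOCARDIUM", "BLOOD"),
                        levels = levels(mesh$region))
  # in-plane radial decay centred on the patch; threshold radius 6 mm
  r2 <- (cen[, 1] - 10e-3)^2 + (cen[, 2] - 10e-3)^2
  e_mag <- 1e5 * (6e-3)^2 / pmax(r2, 1e-12)
  area <- surface_ablation_area(mesh, e_mag)
  expect_equal(area, pi * 36, tolerance = 0.02)
})

test_that("isosurface of a linear ramp is planar at the crossing", {
  mesh <- box_mesh(c(0, 0, 0), rep(10e-3, 3), rep(10L, 3))
  cen <- element_centroids(mesh)
  e_mag <- 2e4 + cen[, 1] * 2e7  # crosses 1e5 V/m at x = 4 mm
  iso <- extract_isosurface(mesh, e_mag)
  expect_gt(nrow(iso$triangles), 0)
  xs <- c(iso$triangles[, 1], iso$triangles[, 4], iso$triangles[, 7])
  expect_lt(max(abs(xs - 4)), 1e-6)
  # field below threshold everywhere: empty surface, zero metrics
  iso0 <- extract_isosurface(mesh, rep(1e4, nrow(mesh$elems)))
  expect_equal(nrow(iso0$triangles), 0)
  ext <- isosurface_extents(iso0)
  expect_equal(unname(ext), c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(ext, "empty"))
  expect_error(extract_isosurface(mesh, rep(1e5, nrow(mesh$elems))),
               "degenerate-isosurface")
})

test_that("isosurface extents never exceed the mesh bounding box", {
  mesh <- box_mesh(c(0, 0, 0), rep(10e-3, 3), rep(10L, 3))
  set.seed(3)
  e_mag <- stats::runif(nrow(mesh$elems), 0, 2e5)
  ext <- isosurface_extents(extract_isosurface(mesh, e_mag))
  expect_true(all(ext <= 10 + 1e-9))
})

test_that("paired differences carry the significance conventions", {
  pd <- paired_difference(2.0, 1.0, "volume")
  expect_equal(pd$percent, 100)
  expect_true(pd$significant)
  pd <- paired_difference(1.04, 1.0, "volume")
  expect_equal(pd$percent, 4, tolerance = 1e-9)
  expect_false(pd$significant)
  pd <- paired_difference(5, 5, "area")
  expect_equal(pd$absolute, 0)
  expect_false(pd$significant)
  expect_false(paired_difference(10.9, 10.0, "extent")$significant)
  expect_true(paired_difference(11.1, 10.0, "extent")$significant)
  expect_true(paired_difference(43.5, 39.0, "temperature")$significant)
  expect_false(paired_difference(40.0, 39.0, "temperature")$significant)
  expect_error(paired_difference(1, 0, "volume"), "undefined-percent")
})

test_that("aggregate stats match the two-pass formula", {
  expect_equal(aggregate_stats(c(1, 2, 3)), c(mean = 2, sd = 1))
  expect_error(aggregate_stats(5), "insufficient-data")
  set.seed(5)
  x <- stats::rnorm(31)
  s <- aggregate_stats(x)
  m <- sum(x) / length(x)
  expect_equal(unname(s["mean"]), m, tolerance = 1e-12)
  expect_equal(unname(s["sd"]),
               sqrt(sum((x - m)^2) / (length(x) - 1)), tolerance = 1e-12)
})
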