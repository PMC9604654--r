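# Potential solver verification against closed-form oracles: parallel
# plates, anisotropic coordinate stretching, conservation and scaling laws.

# fixed-conductivity models for linear verification solves
iso_fixed <- conductivity_model(mode = "IC", field_dependent = FALSE)

plate_solve <- function(mesh, model, fibers = NULL, amplitude = 10) {
  left <- boundary_nodes(mesh, "xmin")
  right <- boundary_nodes(mesh, "xmax")
  solve_potential(mesh, fibers, model, amplitude,
                  dirichlet = list(nodes = c(left, right),
                                   values = c(rep(amplitude, length(left)),
                                              rep(0, length(right))),
                                   left = left, right = right))
}

test_that("parallel plates reproduce the 1-D field and Ohmic current", {
  d <- 8e-3
  mesh <- box_mesh(c(0, 0, 0), c(d, 6e-3, 4e-3), c(8, 6, 4))
  amp <- 10
  sol <- plate_solve(mesh, iso_fixed, amplitude = amp)
  expect_equal(sol$e_mag, rep(amp / d, nrow(mesh$elems)), tolerance = 1e-10)
  expect_equal(sol$E[, 1], rep(amp / d, nrow(mesh$elems)), tolerance = 1e-10)
  # V attains its extrema on the electrodes
  expect_true(all(sol$V >= -1e-9 & sol$V <= amp + 1e-9))
  area <- 6e-3 * 4e-3
  I_exact <- 0.0537 * amp / d * area
  I_left <- total_electrode_current(sol, sol$dirichlet$left)
  I_right <- total_electrode_current(sol, sol$dirichlet$right)
  expect_equal(I_left, I_exact, tolerance = 1e-8)
  expect_equal(I_left + I_right, 0, tolerance = 1e-10 * abs(I_left))
})

test_that("axis-aligned anisotropy leaves the 1-D field unchanged and scales current", {
  d <- 8e-3
  mesh <- box_mesh(c(0, 0, 0), c(d, 6e-3, 4e-3), c(8, 6, 4))
  fib <- make_fiber_field(mesh, "UNIFORM", list(theta = 0))
  mac <- conductivity_model(group = 2, field_dependent = FALSE)
  amp <- 10
  sol <- plate_solve(mesh, mac, fib, amplitude = amp)
  expect_equal(sol$e_mag, rep(amp / d, nrow(mesh$elems)), tolerance = 1e-10)
  sl <- unname(split_conductivity(0.0537, 3.75)["sigma_l"])
  I_iso <- total_electrode_current(plate_solve(mesh, iso_fixed, amplitude = amp),
                                   boundary_nodes(mesh, "xmin"))
  I_ani <- total_electrode_current(sol, sol$dirichlet$left)
  expect_equal(I_ani / I_iso, sl / 0.0537, tolerance = 1e-9)
})

test_that("anisotropic solve equals the coordinate-stretched isotropic solve", {
  # diag(sl, st, st) on a cubic grid == isotropic problem on a grid with
  # spacings h/sqrt(sigma_k); same lattice, same constrained nodes
  n <- c(12L, 12L, 12L)
  sp <- split_conductivity(0.0537, 4.98)
  sl <- unname(sp["sigma_l"]); st <- unname(sp["sigma_t"])
  h <- 1e-3
  mesh_a <- box_mesh(c(0, 0, 0), n * h, n)
  mesh_i <- box_mesh(c(0, 0, 0), n * h / sqrt(c(sl, st, st)), n)
  fib <- make_fiber_field(mesh_a, "UNIFORM", list(theta = 0))
  mac <- conductivity_model(ratio_R = sl / st, sigma_i = (sl + st) / 2,
                            mode = "AC", field_dependent = FALSE)
  # interior source patch at the centre, outer boundary grounded
  ctr <- which(rowSums(abs(t(t(mesh_a$nodes) - c(6e-3, 6e-3, 6e-3))) ) < 1.6e-3)
  outer <- unique(unlist(lapply(c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax"),
                                boundary_nodes, mesh = mesh_a)))
  ctr <- setdiff(ctr, outer)
  dir_a <- list(nodes = c(ctr, outer),
                values = c(rep(5, length(ctr)), rep(0, length(outer))))
  sol_a <- solve_potential(mesh_a, fib, mac, 5, dirichlet = dir_a)
  sol_i <- solve_potential(mesh_i, NULL, iso_fixed, 5, dirichlet = dir_a)
  expect_equal(sol_a$V, sol_i$V, tolerance = 1e-8)
})

test_that("with fixed conductivity the solution scales linearly in amplitude", {
  mesh <- reduced_slab()
  fib <- make_fiber_field(mesh, "UNIFORM", list(theta = 0))
  mac <- conductivity_model(group = 4, field_dependent = FALSE)
  s1 <- cached("slab_g4_fixed_1000", solve_potential(mesh, fib, mac, 1000))
  s2 <- solve_potential(mesh, fib, mac, 2000)
  expect_equal(s2$V, 2 * s1$V, tolerance = 1e-9)
  expect_equal(s2$Q, 4 * s1$Q, tolerance = 1e-9)
  expect_equal(total_electrode_current(s2, "ELECTRODE_LEFT"),
               2 * total_electrode_current(s1, "ELECTRODE_LEFT"),
               tolerance = 1e-9)
})

test_that("scenario solves conserve current and respect the maximum principle", {
  mesh <- reduced_slab()
  fib <- make_fiber_field(mesh, "UNIFORM", list(theta = 0))
  sol <- cached("slab_g4_sigmoid_1000",
                solve_potential(mesh, fib, conductivity_model(group = 4), 1000))
  I_l <- total_electrode_current(sol, "ELECTRODE_LEFT")
  I_r <- total_electrode_current(sol, "ELECTRODE_RIGHT")
  expect_lt(abs(I_l + I_r), 0.005 * abs(I_l))
  expect_true(all(sol$V >= -1e-6 * 1000 & sol$V <= 1000 * (1 + 1e-6)))
  expect_error(total_electrode_current(sol, "ELECTRODE_TOP"), "tag error")
})

test_that("power density matches the quadratic form oracle", {
  # isotropic: Q = sigma |E|^2
  fake <- list(E = matrix(c(1e5, 0, 0), 1),
               sigma6 = matrix(c(0.0537, 0.0537, 0.0537, 0, 0, 0), 1))
  expect_equal(compute_power_density(fake), 5.37e8)
  # field aligned with the fiber: Q = sigma_l |E|^2
  sp <- split_conductivity(0.0537, 3.75)
  f <- c(1, 0, 0)
  S6 <- matrix(0, 1, 6)
  S6[1, 1:3] <- unname(sp["sigma_t"]) + (sp["sigma_l"] - sp["sigma_t"]) * f^2
  fake <- list(E = matrix(c(2e5, 0, 0), 1), sigma6 = S6)
  expect_equal(compute_power_density(fake), unname(sp["sigma_l"]) * 4e10)
  # random tensors against an explicit matrix product
  set.seed(21)
  for (rep in 1:10) {
    f <- stats::rnorm(3); f <- f / sqrt(sum(f^2))
    S <- conductivity_tensor(f, 0.09, 0.02)
    E <- stats::rnorm(3) * 1e5
    fake <- list(E = matrix(E, 1),
                 sigma6 = matrix(c(S[1, 1], S[2, 2], S[3, 3],
                                   S[1, 2], S[1, 3], S[2, 3]), 1))
    expect_equal(compute_power_density(fake),
                 as.numeric(t(E) %*% S %*% E), tolerance = 1e-12)
  }
})

test_that("solver errors are raised for missing tags and non-convergence", {
  mesh <- box_mesh(c(0, 0, 0), rep(4e-3, 3), rep(4L, 3))
  expect_error(solve_potential(mesh, NULL, iso_fixed, 10), "boundary error")
  slab <- reduced_slab()
  fib <- make_fiber_field(slab, "UNIFORM", list(theta = 0))
  expect_error(
    solve_potential(slab, fib, conductivity_model(group = 4), 1000,
                    solver_settings(max_picard_iterations = 2)),
    "convergence error")
  expect_error(solve_potential(slab, fib, conductivity_model(group = 4), -5),
               "amplitude")
})
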