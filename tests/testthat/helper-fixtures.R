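# Shared fixtures: reduced-size scenario meshes so the suite stays fast.
# The reduced slab uses a 0.8 mm grid (the reference resolution is 0.4 mm);
# builders warn about this, which the helper silences.

reduced_config <- function(...) {
  args <- utils::modifyList(
    list(lateral_extent = 26.4e-3, blood_depth = 4.8e-3,
         resolution = 0.8e-3),
    list(...))
  suppressWarnings(do.call(scenario_config, args))
}

reduced_slab <- function(...) {
  suppressWarnings(build_slab_scenario(reduced_config(...)))
}

# cache expensive shared solves across test files within one run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# analytic volume removed from the slab by a capsule (cylinder of radius r,
# axial length L, hemispherical caps) whose lowest point sits depth d below
# the tissue surface: circular-segment prism plus a full spherical cap
capsule_slab_overlap <- function(r, L, d) {
  if (d <= 0) return(0)
  seg <- r^2 * acos((r - d) / r) - (r - d) * sqrt(2 * r * d - d^2)
  cap <- pi * d^2 * (3 * r - d) / 3
  seg * L + cap
}
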