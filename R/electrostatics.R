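# Nonlinear quasi-static potential solve: div(sigma(E) grad V) = 0 with
# electrode Dirichlet surfaces and natural zero-flux boundaries, discretized
# with trilinear hexahedra and solved by Picard (fixed-point) iteration on
# the field-dependent conductivity.

#' Solver settings
#'
#' @param picard_tolerance relative change in V (scaled by the applied
#'   amplitude) below which the Picard loop stops.
#' @param max_picard_iterations iteration cap; exceeding it is an error.
#' @param relaxation under-relaxation factor in (0, 1] applied to the
#'   conductivity update between Picard steps.
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(picard_tolerance = 1e-6,
                            max_picard_iterations = 100L,
                            relaxation = 0.7) {
  stopifnot(picard_tolerance > 0, max_picard_iterations >= 1,
            relaxation > 0, relaxation <= 1)
  structure(list(picard_tolerance = picard_tolerance,
                 max_picard_iterations = as.integer(max_picard_iterations),
                 relaxation = relaxation),
            class = "solver_settings")
}

# 8x8 component stiffness matrices K^(ab)_ij = int dNi/dxa dNj/dxb dV for a
# trilinear hexahedron with spacings h, by 2x2x2 Gauss quadrature (exact for
# these integrands). Returns the six matrices paired with the packed
# symmetric conductivity layout; off-diagonal components are pre-symmetrized.
hex_stiffness_components <- function(h) {
  sgn <- cbind(c(-1, 1, 1, -1, -1, 1, 1, -1),
               c(-1, -1, 1, 1, -1, -1, 1, 1),
               c(-1, -1, -1, -1, 1, 1, 1, 1))
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  detJ <- prod(h) / 8
  comp <- array(0, dim = c(8, 8, 3, 3))
  for (q in seq_len(nrow(gp))) {
    xi <- gp[q, ]
    # dN/dx_a at this Gauss point (chain rule factor 2/h_a)
    dN <- sapply(1:3, function(a) {
      oth <- setdiff(1:3, a)
      sgn[, a] / 8 *
        (1 + sgn[, oth[1]] * xi[oth[1]]) * (1 + sgn[, oth[2]] * xi[oth[2]]) *
        (2 / h[a])
    })
    for (a in 1:3) for (b in 1:3)
      comp[, , a, b] <- comp[, , a, b] + tcrossprod(dN[, a], dN[, b]) * detJ
  }
  list(xx = comp[, , 1, 1], yy = comp[, , 2, 2], zz = comp[, , 3, 3],
       xy = comp[, , 1, 2] + comp[, , 2, 1],
       xz = comp[, , 1, 3] + comp[, , 3, 1],
       yz = comp[, , 2, 3] + comp[, , 3, 2])
}

# Assemble the global sparse stiffness matrix from packed per-element
# conductivities (E x 6). Elements with all-zero conductivity contribute
# nothing. Returns a dgCMatrix over all nodes.
assemble_stiffness <- function(mesh, sigma6) {
  comps <- hex_stiffness_components(mesh$h)
  active <- which(rowSums(abs(sigma6)) > 0)
  el <- mesh$elems[active, , drop = FALSE]
  rows <- el[, rep(1:8, times = 8)]
  cols <- el[, rep(1:8, each = 8)]
  vals <- matrix(0, length(active), 64)
  for (ci in seq_along(comps)) {  # packed order xx, yy, zz, xy, xz, yz
    s <- sigma6[active, ci]
    if (any(s != 0))
      vals <- vals + outer(s, as.vector(comps[[ci]]))
  }
  Matrix::sparseMatrix(i = as.vector(rows), j = as.vector(cols),
                       x = as.vector(vals),
                       dims = c(n_nodes(mesh), n_nodes(mesh)))
}

# Piecewise-constant element field E = -grad V at cell centroids: for the
# trilinear interpolant on an axis-aligned hex this is the difference of
# opposite-face averages over the spacing.
element_field <- function(mesh, V) {
  Vm <- matrix(V[mesh$elems], ncol = 8)
  Ex <- -(rowMeans(Vm[, c(2, 3, 6, 7)]) - rowMeans(Vm[, c(1, 4, 5, 8)])) / mesh$h[1]
  Ey <- -(rowMeans(Vm[, c(3, 4, 7, 8)]) - rowMeans(Vm[, c(1, 2, 5, 6)])) / mesh$h[2]
  Ez <- -(rowMeans(Vm[, c(5, 6, 7, 8)]) - rowMeans(Vm[, c(1, 2, 3, 4)])) / mesh$h[3]
  cbind(Ex, Ey, Ez, deparse.level = 0)
}

sigma_times_vec <- function(sigma6, E) {
  cbind(sigma6[, 1] * E[, 1] + sigma6[, 4] * E[, 2] + sigma6[, 5] * E[, 3],
        sigma6[, 4] * E[, 1] + sigma6[, 2] * E[, 2] + sigma6[, 6] * E[, 3],
        sigma6[, 5] * E[, 1] + sigma6[, 6] * E[, 2] + sigma6[, 3] * E[, 3])
}

default_electrode_dirichlet <- function(mesh, amplitude) {
  left <- unique(as.vector(mesh$elems[mesh$region == "ELECTRODE_LEFT", ]))
  right <- unique(as.vector(mesh$elems[mesh$region == "ELECTRODE_RIGHT", ]))
  if (!length(left) || !length(right))
    stop("boundary error: mesh must contain both electrode regions")
  list(nodes = c(left, right),
       values = c(rep(amplitude, length(left)), rep(0, length(right))),
       left = left, right = right)
}

#' Solve the quasi-static potential problem
#'
#' Solves `div(sigma(E) grad V) = 0` with the pulse amplitude applied as a
#' Dirichlet value on the left electrode, ground on the right electrode, and
#' natural zero-flux conditions on all outer boundaries. The field-dependent
#' conductivity is handled by Picard iteration: solve the linear system with
#' the current conductivity, recompute the element fields, update the
#' conductivity through the electroporation sigmoid with under-relaxation,
#' and repeat until the scaled change in V falls below tolerance. Electrode
#' metal is treated as equipotential (all its nodes are constrained), which
#' is the appropriate limit for a conductivity seven orders above tissue.
#'
#' @param mesh a `tissue_mesh` (scenario meshes carry electrode regions;
#'   verification meshes may instead pass explicit `dirichlet` constraints).
#' @param fibers a `fiber_field` (required for AC mode).
#' @param model a [conductivity_model()].
#' @param amplitude applied pulse amplitude (V), positive.
#' @param settings a [solver_settings()].
#' @param dirichlet optional explicit constraints: list with `nodes` and
#'   `values` overriding the electrode defaults.
#' @return object of class `field_solution`: nodal `V` (volts), per-element
#'   `E` (V/m), `e_mag`, packed conductivity `sigma6` (S/m), current density
#'   `J` (A/m^2), power density `Q` (W/m^3), `picard_iterations`, `residual`,
#'   the assembled stiffness matrix `K`, and the constraint sets.
#' @export
solve_potential <- function(mesh, fibers = NULL, model, amplitude = 1000,
                            settings = solver_settings(), dirichlet = NULL) {
  if (amplitude <= 0) stop("amplitude must be positive")
  if (is.null(dirichlet)) dirichlet <- default_electrode_dirichlet(mesh, amplitude)
  fixed <- dirichlet$nodes
  if (anyDuplicated(fixed)) {
    keep <- !duplicated(fixed)
    dirichlet$values <- dirichlet$values[keep]
    fixed <- fixed[keep]
    dirichlet$nodes <- fixed
  }
  nn <- n_nodes(mesh)
  free <- setdiff(seq_len(nn), fixed)
  V <- numeric(nn)
  V[fixed] <- dirichlet$values

  e_mag <- rep(0, n_elems(mesh))
  sigma6 <- element_conductivity(mesh, fibers, model, e_mag)
  omega <- settings$relaxation
  residual <- Inf
  prev_residual <- Inf
  iters <- 0L
  nonlinear <- model$field_dependent && any(mesh$region == "MYOCARDIUM")
  chol_cache <- NULL
  repeat {
    iters <- iters + 1L
    K <- assemble_stiffness(mesh, sigma6)
    Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
    b <- -K[free, fixed, drop = FALSE] %*% V[fixed]
    # reuse the symbolic factorization across Picard iterations (the
    # sparsity pattern is fixed; only the conductivities change)
    Vf <- tryCatch({
      chol_cache <- if (is.null(chol_cache)) Matrix::Cholesky(Kff)
                    else Matrix::update(chol_cache, Kff)
      as.vector(Matrix::solve(chol_cache, b))
    }, error = function(e) as.vector(Matrix::solve(Kff, b)))
    Vnew <- V
    Vnew[free] <- Vf
    residual <- max(abs(Vnew - V)) / max(abs(dirichlet$values), amplitude)
    V <- Vnew
    if (!nonlinear) break
    # adaptive damping: the sigmoid is steep, and a fixed relaxation can
    # limit-cycle; halve it whenever the contraction stalls
    if (iters > 2L && residual > 0.9 * prev_residual)
      omega <- max(omega / 2, 0.05)
    prev_residual <- residual
    E <- element_field(mesh, V)
    e_mag <- sqrt(rowSums(E^2))
    sigma_target <- element_conductivity(mesh, fibers, model, e_mag)
    sigma6 <- (1 - omega) * sigma6 + omega * sigma_target
    if (iters > 1L && residual < settings$picard_tolerance) break
    if (iters >= settings$max_picard_iterations)
      stop("convergence error: Picard iteration did not converge within ",
           settings$max_picard_iterations, " iterations (last residual ",
           signif(residual, 3), ")")
  }
  # final consistent fields with the conductivity actually used in K
  K <- assemble_stiffness(mesh, sigma6)
  E <- element_field(mesh, V)
  e_mag <- sqrt(rowSums(E^2))
  J <- sigma_times_vec(sigma6, E)
  Q <- rowSums(E * J)
  sol <- list(V = V, E = E, e_mag = e_mag, sigma6 = sigma6, J = J, Q = Q,
              picard_iterations = iters, residual = residual, K = K,
              dirichlet = dirichlet, mesh = mesh, amplitude = amplitude,
              model = model)
  class(sol) <- "field_solution"
  sol
}

#' @export
print.field_solution <- function(x, ...) {
  cat("field_solution: amplitude", x$amplitude, "V,",
      x$picard_iterations, "Picard iterations, residual",
      signif(x$residual, 3), "\n")
  cat("  max |E| =", signif(max(x$e_mag), 4), "V/m; max Q =",
      signif(max(x$Q), 4), "W/m^3\n")
  invisible(x)
}

#' Joule power density
#'
#' Per-element power density `Q = E^T sigma E` (W/m^3), reducing to
#' `sigma |E|^2` for isotropic conductivity. Blood and insulator carry their
#' constant conductivities, so their (small) dissipation is included.
#'
#' @param solution a `field_solution`.
#' @return numeric vector, W/m^3 per element.
#' @export
compute_power_density <- function(solution) {
  rowSums(solution$E * sigma_times_vec(solution$sigma6, solution$E))
}

#' Total current through an electrode
#'
#' Discrete surface integral of `J . n` over an electrode, evaluated as the
#' stiffness-matrix reaction sum over that electrode's constrained nodes
#' (the consistent-flux form of the boundary integral; it satisfies discrete
#' conservation exactly).
#'
#' @param solution a `field_solution`.
#' @param electrode `"ELECTRODE_LEFT"` or `"ELECTRODE_RIGHT"`, or an integer
#'   vector of constrained node indices.
#' @return current in amperes (positive = out of the electrode into tissue
#'   for the driven electrode).
#' @export
total_electrode_current <- function(solution,
                                    electrode = "ELECTRODE_LEFT") {
  if (is.character(electrode)) {
    nodes <- switch(electrode,
                    ELECTRODE_LEFT = solution$dirichlet$left,
                    ELECTRODE_RIGHT = solution$dirichlet$right,
                    stop("tag error: unknown electrode tag '", electrode, "'"))
    if (is.null(nodes))
      stop("tag error: solution has no '", electrode, "' constraint set")
  } else nodes <- electrode
  r <- as.vector(solution$K %*% solution$V)
  sum(r[nodes])
}
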