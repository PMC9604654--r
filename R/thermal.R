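# Transient Pennes bioheat stepping: implicit Euler diffusion with the gated
# Joule source and first-order upwind advection by a prescribed blood
# velocity field. Perfusion and metabolic heat are omitted (negligible next
# to the pulsed Joule source); temperatures are in degrees Celsius (offsets
# cancel in every retained term).

#' Material properties of the ablation model
#'
#' Density, specific heat, thermal conductivity and (for the non-myocardial
#' regions) electrical conductivity of the four materials, plus the blood
#' viscosity used in the Reynolds-number check.
#'
#' @return data frame with columns `material`, `rho` (kg/m^3), `c` (J/kg/K),
#'   `k` (W/m/K), `sigma` (S/m; NA for myocardium, whose conductivity is the
#'   field-dependent model), `mu` (kg/m/s; blood only).
#' @export
material_properties <- function() {
  data.frame(
    material = c("electrode", "catheter", "blood", "myocardium"),
    rho = c(21500, 70, 1000, 1200),
    c = c(132, 1045, 4180, 3200),
    k = c(71, 0.026, 0.54, 0.53),
    sigma = c(4.6e6, 1e-5, 0.99, NA),
    mu = c(NA, NA, 2.1e-3, NA)
  )
}

region_material <- function(region) {
  c(MYOCARDIUM = "myocardium", BLOOD = "blood", ELECTRODE_LEFT = "electrode",
    ELECTRODE_RIGHT = "electrode", INSULATOR = "catheter")[as.character(region)]
}

#' Reynolds number and laminar-flow check
#'
#' `Re = rho u D / mu` for a channel of diameter `D`; flow is flagged
#' laminar below 2000.
#'
#' @param rho fluid density (kg/m^3).
#' @param u flow speed (m/s).
#' @param D characteristic diameter (m).
#' @param mu dynamic viscosity (kg/m/s).
#' @return list with `Re` and logical `laminar`.
#' @export
reynolds_number <- function(rho, u, D, mu) {
  if (any(c(rho, u, D, mu) <= 0) || any(!is.finite(c(rho, u, D, mu))))
    stop("domain error: all inputs must be positive and finite")
  Re <- rho * u * D / mu
  list(Re = Re, laminar = Re < 2000)
}

#' Prescribed blood velocity field
#'
#' Analytic stand-in for the intracardiac flow: zero outside the blood
#' region, and inside it either a uniform plug along +x or a channel
#' (Poiseuille) profile vanishing at the endocardium and the outer roof.
#' Both profiles are divergence-free by construction.
#'
#' @param mesh a `tissue_mesh`.
#' @param profile `"plug"` or `"poiseuille"`.
#' @param u_max peak speed (m/s).
#' @return E x 3 matrix of element velocities (m/s), class `velocity_field`.
#' @export
velocity_field <- function(mesh, profile = c("plug", "poiseuille"),
                           u_max = 0.1) {
  profile <- match.arg(profile)
  u <- matrix(0, n_elems(mesh), 3)
  blood <- mesh$region == "BLOOD"
  if (any(blood)) {
    if (profile == "plug") {
      u[blood, 1] <- u_max
    } else {
      z <- element_centroids(mesh)[, 3]
      H <- mesh$origin[3] + mesh$dims[3] * mesh$h[3]
      s <- pmin(pmax(z / H, 0), 1)
      u[blood, 1] <- u_max * 4 * s[blood] * (1 - s[blood])
    }
  }
  class(u) <- c("velocity_field", class(u))
  u
}

node_ijk <- function(mesh, nodes) {
  nxp <- mesh$dims[1] + 1L
  nyp <- mesh$dims[2] + 1L
  id0 <- nodes - 1L
  cbind(i = id0 %% nxp,
        j = (id0 %/% nxp) %% nyp,
        k = id0 %/% (nxp * nyp))
}

# upwind advection matrix rho_c * u . grad on the node lattice; rows only at
# nodes with non-zero velocity. Returns list(C = dgCMatrix, needs_fix =
# nodes whose upwind neighbour is outside the mesh).
advection_matrix <- function(mesh, velocity, rho_c_blood) {
  nn <- n_nodes(mesh)
  # nodal velocity: mean of adjacent element velocities (zero outside blood,
  # so interface nodes are slowed, approximating no-slip)
  cnt <- tabulate(as.vector(mesh$elems), nn)
  acc <- function(col) {
    a <- numeric(nn)
    for (c8 in 1:8) {
      t <- tapply(velocity[, col], mesh$elems[, c8], sum)
      a[as.integer(names(t))] <- a[as.integer(names(t))] + as.vector(t)
    }
    a / pmax(cnt, 1L)
  }
  ux <- acc(1); uy <- acc(2); uz <- acc(3)
  active <- which(abs(ux) + abs(uy) + abs(uz) > 0)
  ii <- jj <- integer(0); xx <- numeric(0)
  needs_fix <- integer(0)
  ijk <- node_ijk(mesh, active)
  nxp <- mesh$dims[1] + 1L
  nyp <- mesh$dims[2] + 1L
  strides <- c(1L, nxp, nxp * nyp)
  uu <- cbind(ux, uy, uz)
  for (ax in 1:3) {
    u_ax <- uu[active, ax]
    nz <- which(u_ax != 0)
    if (!length(nz)) next
    upstep <- ifelse(u_ax[nz] > 0, -1L, 1L)
    pos <- ijk[nz, ax] + upstep
    inside <- pos >= 0L & pos <= mesh$dims[ax]
    nb <- active[nz] + upstep * strides[ax]
    coef <- rho_c_blood * abs(u_ax[nz]) / mesh$h[ax]
    ok <- which(inside)
    ii <- c(ii, active[nz][ok], active[nz][ok])
    jj <- c(jj, active[nz][ok], nb[ok])
    xx <- c(xx, coef[ok], -coef[ok])
    needs_fix <- c(needs_fix, active[nz][!inside])
  }
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
  list(C = C, needs_fix = unique(needs_fix), max_u = max(abs(uu)))
}

#' Run the thermal protocol
#'
#' Steps `rho c dT/dt = div(k grad T) + Q g(t) - rho c u . grad T` with
#' implicit (backward) Euler in time, lumped mass, trilinear-hexahedron
#' diffusion, and first-order upwind advection. Outer boundaries are
#' zero-flux; when a velocity field is supplied, blood nodes whose upwind
#' neighbour leaves the mesh (the inflow face) are held at the inflow
#' temperature. In `GATED` mode the exact pulse on/off schedule gates the
#' Joule source with step `dt_on` inside trains and `dt_off` during train
#' intervals; `DUTY_AVERAGED` applies the source scaled by the protocol duty
#' factor continuously with step `dt_off`.
#'
#' @param mesh a `tissue_mesh`.
#' @param field a `field_solution` on the same mesh (its `Q` is the on-state
#'   source), or a numeric per-element power density (W/m^3).
#' @param protocol a [pulse_protocol()].
#' @param materials material table (see [material_properties()]).
#' @param velocity optional [velocity_field()] (E x 3, m/s).
#' @param mode `"GATED"` or `"DUTY_AVERAGED"`.
#' @param dt_on,dt_off time steps (s) during trains / between trains.
#' @param T0 initial temperature (deg C).
#' @param inflow_temp inflow blood temperature (deg C).
#' @return object of class `thermal_state`: nodal `T` (deg C), final time
#'   `t`, and `max_T_trace` (data frame `t`, `T_max` over the myocardium).
#' @export
run_thermal_protocol <- function(mesh, field, protocol,
                                 materials = material_properties(),
                                 velocity = NULL,
                                 mode = c("GATED", "DUTY_AVERAGED"),
                                 dt_on = 25e-6, dt_off = 2e-3,
                                 T0 = 37, inflow_temp = 37) {
  mode <- match.arg(mode)
  Q <- if (is.numeric(field)) field else field$Q
  if (length(Q) != n_elems(mesh))
    stop("field must supply one power density per element")
  if (mode == "GATED" && dt_on > protocol$pulse_width)
    stop("dt_on must not exceed the pulse width in GATED mode")
  sched <- gating_schedule(protocol)

  mat <- materials[match(region_material(mesh$region), materials$material), ]
  rho_c <- mat$rho * mat$c
  kth <- mat$k
  vol <- cell_volume(mesh)
  nn <- n_nodes(mesh)

  # lumped nodal heat capacity and nodal source (on-state)
  lump <- function(x_elem) {
    a <- numeric(nn)
    for (c8 in 1:8) {
      t <- tapply(x_elem, mesh$elems[, c8], sum)
      a[as.integer(names(t))] <- a[as.integer(names(t))] + as.vector(t)
    }
    a
  }
  M <- lump(rho_c * vol / 8)
  q_on <- lump(Q * vol / 8)

  sigma6_k <- cbind(kth, kth, kth, 0, 0, 0)
  K <- assemble_stiffness(mesh, sigma6_k)

  fixed <- integer(0)
  C <- NULL
  if (!is.null(velocity)) {
    rc_blood <- materials$rho[materials$material == "blood"] *
      materials$c[materials$material == "blood"]
    adv <- advection_matrix(mesh, velocity, rc_blood)
    C <- adv$C
    fixed <- adv$needs_fix
    cfl <- adv$max_u * max(dt_on, dt_off) / min(mesh$h)
    if (cfl > 100)
      stop("stability error: advective Courant number ", signif(cfl, 3),
           " too large; reduce the time step or refine the grid")
  }
  free <- setdiff(seq_len(nn), fixed)
  A_base <- if (is.null(C)) K else K + C

  myo_nodes <- unique(as.vector(mesh$elems[mesh$region == "MYOCARDIUM", ]))
  if (!length(myo_nodes)) myo_nodes <- seq_len(nn)

  Tn <- rep(T0, nn)
  Tn[fixed] <- inflow_temp
  tcur <- 0
  trace_t <- numeric(0)
  trace_T <- numeric(0)

  factor_cache <- new.env(parent = emptyenv())
  get_solver <- function(dt) {
    key <- sprintf("%.12e", dt)
    if (!is.null(factor_cache[[key]])) return(factor_cache[[key]])
    A <- A_base + Matrix::Diagonal(nn, M / dt)
    Aff <- A[free, free, drop = FALSE]
    Afd <- A[free, fixed, drop = FALSE]
    lu <- Matrix::lu(Aff)
    sv <- list(lu = lu, Afd = Afd, dt = dt)
    factor_cache[[key]] <- sv
    sv
  }
  step_segment <- function(duration, g, dt_target) {
    nstep <- max(1L, ceiling(duration / dt_target - 1e-9))
    dt <- duration / nstep
    sv <- get_solver(dt)
    for (s in seq_len(nstep)) {
      rhs <- (M / dt) * Tn + g * q_on
      rhs_f <- rhs[free]
      if (length(fixed))
        rhs_f <- rhs_f - as.vector(sv$Afd %*% Tn[fixed])
      Tn[free] <<- as.vector(Matrix::solve(sv$lu, rhs_f))
      tcur <<- tcur + dt
      trace_t[length(trace_t) + 1L] <<- tcur
      trace_T[length(trace_T) + 1L] <<- max(Tn[myo_nodes])
    }
  }

  if (mode == "DUTY_AVERAGED") {
    duty <- sched$total_on_time / sched$total_duration
    step_segment(sched$total_duration, duty, dt_off)
  } else {
    p <- protocol
    for (tr in seq_len(p$n_trains)) {
      for (pl in seq_len(p$pulses_per_train)) {
        step_segment(p$pulse_width, 1, dt_on)
        step_segment(p$pulse_interval, 0, dt_on)
      }
      step_segment(p$train_interval, 0, dt_off)
    }
  }
  out <- list(T = Tn, t = tcur,
              max_T_trace = data.frame(t = trace_t, T_max = trace_T),
              mode = mode, myo_nodes = myo_nodes)
  class(out) <- "thermal_state"
  out
}

#' @export
print.thermal_state <- function(x, ...) {
  cat("thermal_state (", x$mode, "): t = ", signif(x$t, 6), " s, max myocardial T = ",
      signif(max(x$max_T_trace$T_max), 5), " deg C\n", sep = "")
  invisible(x)
}
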