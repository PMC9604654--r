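# Myocardial electrical conductivity: the anisotropy split, the fiber-aligned
# conductivity tensor, and the field-dependent electroporation sigmoid.

#' Reference conductivity groups
#'
#' The four anisotropy groups used throughout: groups 1-2 span the
#' longitudinal-to-transverse ratio reported for normal myocardium, groups
#' 3-4 the larger ratios reported for fibrillating (fibrotic) myocardium.
#' All share the isotropic baseline 0.0537 S/m; the anisotropic values
#' follow from [split_conductivity()].
#'
#' @return data frame with columns `group`, `ratio_R`, `sigma_i`, `sigma_l`,
#'   `sigma_t` (S/m).
#' @export
conductivity_groups <- function() {
  ratio <- c(1.429, 3.75, 4.98, 6.25)
  sigma_i <- 0.0537
  sp <- vapply(ratio, function(R) split_conductivity(sigma_i, R), numeric(2))
  data.frame(group = 1:4, ratio_R = ratio, sigma_i = sigma_i,
             sigma_l = sp[1, ], sigma_t = sp[2, ])
}

#' Split an isotropic conductivity into anisotropic components
#'
#' Solves the pair of constraints sigma_l / sigma_t = R and
#' (sigma_l + sigma_t) / 2 = sigma_i, i.e. the anisotropic pair whose
#' arithmetic mean is the isotropic value and whose ratio is the anisotropy
#' ratio:
#' sigma_l = 2 R sigma_i / (R + 1), sigma_t = 2 sigma_i / (R + 1).
#'
#' @param sigma_i isotropic conductivity (S/m), positive.
#' @param ratio_R anisotropy ratio sigma_l / sigma_t, at least 1.
#' @return named numeric vector `c(sigma_l, sigma_t)` in S/m.
#' @export
split_conductivity <- function(sigma_i, ratio_R) {
  if (!is.finite(sigma_i) || sigma_i <= 0)
    stop("sigma_i must be positive")
  if (!is.finite(ratio_R) || ratio_R < 1)
    stop("domain error: ratio_R must be >= 1 (longitudinal dominates)")
  c(sigma_l = 2 * ratio_R * sigma_i / (ratio_R + 1),
    sigma_t = 2 * sigma_i / (ratio_R + 1))
}

#' Conductivity model
#'
#' Bundles the myocardial conductivity parameters: the baseline isotropic
#' value and anisotropy ratio (from which the longitudinal/transverse
#' baselines follow), the electroporation sigmoid parameters, and the mode
#' (`"AC"` anisotropic tensor, `"IC"` isotropic scalar).
#'
#' The sigmoid raises conductivity from its pre-electroporation baseline
#' toward the single post-electroporation value `sigma_post` as membrane
#' pores form with increasing field magnitude. In AC mode the sigmoid is
#' applied independently to the longitudinal and transverse baselines, so
#' both principal values converge to `sigma_post` at high field and the
#' tissue loses its anisotropy once fully electroporated.
#'
#' @param group reference group 1-4 (see [conductivity_groups()]); sets
#'   `ratio_R`. Ignored when `ratio_R` is given directly.
#' @param sigma_i isotropic baseline (S/m); also the pre-electroporation
#'   conductivity `sigma_pre`.
#' @param ratio_R anisotropy ratio (>= 1).
#' @param mode `"AC"` or `"IC"`.
#' @param sigma_post post-electroporation conductivity (S/m).
#' @param e_center,e_slope sigmoid center and slope (V/m).
#' @param shift_factor dimensionless factor multiplying the exponential.
#' @param field_dependent set `FALSE` to freeze conductivity at its
#'   zero-field baseline (linear solves for verification).
#' @return object of class `conductivity_model`.
#' @export
conductivity_model <- function(group = NULL, sigma_i = 0.0537, ratio_R = NULL,
                               mode = c("AC", "IC"), sigma_post = 0.281,
                               e_center = 58e3, e_slope = 3e3,
                               shift_factor = 10, field_dependent = TRUE) {
  mode <- match.arg(mode)
  if (is.null(ratio_R)) {
    ratio_R <- if (is.null(group)) 1
               else conductivity_groups()$ratio_R[match(group, 1:4)]
    if (is.na(ratio_R)) stop("group must be one of 1, 2, 3, 4")
  }
  sp <- split_conductivity(sigma_i, ratio_R)
  if (sigma_i >= sigma_post)
    stop("sigma_i must be below sigma_post")
  m <- list(sigma_i = sigma_i, ratio_R = ratio_R,
            sigma_l0 = unname(sp["sigma_l"]), sigma_t0 = unname(sp["sigma_t"]),
            sigma_pre = sigma_i, sigma_post = sigma_post,
            e_center = e_center, e_slope = e_slope,
            shift_factor = shift_factor, mode = mode,
            field_dependent = isTRUE(field_dependent), group = group)
  class(m) <- "conductivity_model"
  m
}

#' @export
print.conductivity_model <- function(x, ...) {
  cat("conductivity_model (", x$mode, "): sigma_i = ", x$sigma_i,
      " S/m, R = ", x$ratio_R, "\n", sep = "")
  cat("  baselines sigma_l0 = ", signif(x$sigma_l0, 4), ", sigma_t0 = ",
      signif(x$sigma_t0, 4), " S/m; sigma_post = ", x$sigma_post, " S/m\n",
      sep = "")
  if (!x$field_dependent) cat("  field dependence disabled\n")
  invisible(x)
}

#' Electroporation conductivity sigmoid
#'
#' Field-dependent conductivity
#' `sigma(E) = sigma_lo + (sigma_post - sigma_lo) /
#'   (1 + shift * exp(-(|E| - e_center) / e_slope))`,
#' a smooth rise from the pre-electroporation baseline `sigma_lo` toward the
#' post-electroporation plateau as pores form in the cell membranes. With the
#' default parameters the value at zero field is the baseline to within
#' ~1e-10 S/m (the shift factor suppresses the increment) and the high-field
#' limit is `sigma_post`.
#'
#' @param e_mag field magnitude(s), V/m, non-negative.
#' @param sigma_lo baseline conductivity (S/m), below `model$sigma_post`.
#' @param model a [conductivity_model()] supplying the sigmoid parameters.
#' @return conductivity in S/m, same length as `e_mag`; strictly increasing
#'   in `e_mag`.
#' @export
electroporation_sigmoid <- function(e_mag, sigma_lo, model) {
  if (any(e_mag < 0)) stop("e_mag must be non-negative")
  if (any(sigma_lo >= model$sigma_post))
    stop("domain error: sigma_lo must be below sigma_post")
  sigma_lo + (model$sigma_post - sigma_lo) /
    (1 + model$shift_factor * exp(-(e_mag - model$e_center) / model$e_slope))
}

#' Fiber-aligned conductivity tensor
#'
#' Rank-one anisotropic tensor `sigma_t I + (sigma_l - sigma_t) A A^T` for a
#' unit fiber direction A: conduction at `sigma_l` along the fiber and
#' `sigma_t` across it. Symmetric positive definite with eigenvalues
#' `{sigma_l, sigma_t, sigma_t}`.
#'
#' @param fiber unit 3-vector (direction cosines of the fiber).
#' @param sigma_l,sigma_t longitudinal and transverse conductivities (S/m).
#' @return 3 x 3 symmetric matrix (S/m).
#' @export
conductivity_tensor <- function(fiber, sigma_l, sigma_t) {
  if (abs(sqrt(sum(fiber^2)) - 1) > 1e-9)
    stop("normalization error: fiber direction must be a unit vector")
  sigma_t * diag(3) + (sigma_l - sigma_t) * tcrossprod(fiber)
}

#' Effective (field-dependent) conductivity
#'
#' Evaluates the conductivity at a given field magnitude. In IC mode the
#' scalar sigmoid from the isotropic baseline is returned. In AC mode the
#' sigmoid is applied independently to the longitudinal and transverse
#' baselines and the tensor is assembled from the fiber direction; both
#' principal values converge to the single post-electroporation conductivity
#' at high field.
#'
#' @param model a [conductivity_model()].
#' @param e_mag field magnitude (V/m).
#' @param fiber unit fiber direction (required in AC mode).
#' @return scalar (IC) or 3 x 3 tensor (AC), S/m.
#' @export
effective_conductivity <- function(model, e_mag, fiber = NULL) {
  if (!model$field_dependent) e_mag <- 0
  if (model$mode == "IC")
    return(unname(electroporation_sigmoid(e_mag, model$sigma_i, model)))
  if (is.null(fiber))
    stop("missing-fiber error: AC mode requires a fiber direction")
  sl <- electroporation_sigmoid(e_mag, model$sigma_l0, model)
  st <- electroporation_sigmoid(e_mag, model$sigma_t0, model)
  conductivity_tensor(fiber, sl, st)
}

# Vectorized per-element conductivity in packed symmetric form
# (columns xx, yy, zz, xy, xz, yz) for the solver. Non-myocardial regions get
# their constant isotropic values; electrode metal is excluded from assembly
# (handled as an equipotential Dirichlet region) and left at zero.
element_conductivity <- function(mesh, fibers, model, e_mag,
                                 materials = material_properties()) {
  ne <- n_elems(mesh)
  sig <- matrix(0, ne, 6,
                dimnames = list(NULL, c("xx", "yy", "zz", "xy", "xz", "yz")))
  reg <- mesh$region
  blood_sigma <- materials$sigma[materials$material == "blood"]
  ins_sigma <- materials$sigma[materials$material == "catheter"]
  sig[reg == "BLOOD", 1:3] <- blood_sigma
  sig[reg == "INSULATOR", 1:3] <- ins_sigma
  myo <- which(reg == "MYOCARDIUM")
  if (length(myo)) {
    e_myo <- if (length(e_mag) == 1) rep(e_mag, length(myo)) else e_mag[myo]
    if (!model$field_dependent) e_myo[] <- 0
    if (model$mode == "IC") {
      s <- electroporation_sigmoid(e_myo, model$sigma_i, model)
      sig[myo, 1] <- s; sig[myo, 2] <- s; sig[myo, 3] <- s
    } else {
      if (is.null(fibers))
        stop("missing-fiber error: AC mode requires a fiber field")
      if (!identical(fibers$elements, myo))
        fib <- fibers$dir[match(myo, fibers$elements), , drop = FALSE]
      else fib <- fibers$dir
      if (anyNA(fib))
        stop("fiber field does not cover all myocardial elements")
      sl <- electroporation_sigmoid(e_myo, model$sigma_l0, model)
      st <- electroporation_sigmoid(e_myo, model$sigma_t0, model)
      d <- sl - st
      a <- fib[, 1]; b <- fib[, 2]; g <- fib[, 3]
      sig[myo, 1] <- st + d * a * a
      sig[myo, 2] <- st + d * b * b
      sig[myo, 3] <- st + d * g * g
      sig[myo, 4] <- d * a * b
      sig[myo, 5] <- d * a * g
      sig[myo, 6] <- d * b * g
    }
  }
  sig
}
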