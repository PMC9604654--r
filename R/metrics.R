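# Lesion metrics from a field solution: the 1000 V/cm (1e5 V/m) irreversible
# electroporation threshold applied to |E|, integrated with sub-element
# resolution. Element fields are volume-averaged to nodes; each hexahedron is
# split into the six Kuhn tetrahedra (equal volume), on which the linear
# interpolant gives closed-form partial volumes, surface-area fractions and
# marching-tetrahedra isosurface triangles.

# Kuhn decomposition of the VTK hexahedron: six tetrahedra, each 1/6 of the
# cell volume, sharing the main diagonal node1-node7.
KUHN_TETS <- rbind(
  c(1L, 2L, 3L, 7L), c(1L, 2L, 6L, 7L), c(1L, 4L, 3L, 7L),
  c(1L, 4L, 8L, 7L), c(1L, 5L, 6L, 7L), c(1L, 5L, 8L, 7L)
)

#' Average an element field to the nodes of a region
#'
#' Volume-weighted (here: uniform-cell, so arithmetic) average of an
#' element-wise quantity over the region's elements adjacent to each node.
#' Nodes with no adjacent element of the region get `NA`.
#'
#' @param mesh a `tissue_mesh`.
#' @param x numeric per-element values.
#' @param region region tag whose elements contribute, default myocardium.
#' @return numeric per-node vector.
#' @export
nodal_field <- function(mesh, x, region = "MYOCARDIUM") {
  if (length(x) != n_elems(mesh))
    stop("x must have one value per element")
  nn <- n_nodes(mesh)
  sel <- mesh$region == region
  el <- mesh$elems[sel, , drop = FALSE]
  xv <- x[sel]
  acc <- numeric(nn)
  cnt <- numeric(nn)
  for (c8 in 1:8) {
    t <- tapply(xv, el[, c8], sum)
    ids <- as.integer(names(t))
    acc[ids] <- acc[ids] + as.vector(t)
    n <- tapply(rep(1, length(xv)), el[, c8], sum)
    cnt[ids] <- cnt[ids] + as.vector(n)
  }
  out <- rep(NA_real_, nn)
  has <- cnt > 0
  out[has] <- acc[has] / cnt[has]
  out
}

# deterministic tie-breaking jitter so the divided-difference formulas below
# see distinct vertex values; relative magnitude 1e-9 of the local scale
jitter_ties <- function(d) {
  scale <- pmax(apply(abs(d), 1, max), 1e-300)
  for (c in seq_len(ncol(d))) d[, c] <- d[, c] - scale * 1e-9 * c
  d
}

# Fraction of a tetrahedron where the linear interpolant of the vertex
# offsets d = value - threshold is positive. Closed form via divided
# differences: sum over positive vertices of d_i^3 / prod_{j!=i}(d_i - d_j).
tet_fraction_above <- function(d) {
  f <- numeric(nrow(d))
  npos <- rowSums(d > 0)
  f[npos == 4L] <- 1
  mid <- which(npos >= 1L & npos <= 3L)
  if (length(mid)) {
    dm <- jitter_ties(d[mid, , drop = FALSE])
    fm <- numeric(length(mid))
    for (i in 1:4) {
      oth <- setdiff(1:4, i)
      pos <- dm[, i] > 0
      if (any(pos)) {
        di <- dm[pos, i]
        fm[pos] <- fm[pos] + di^3 /
          ((di - dm[pos, oth[1]]) * (di - dm[pos, oth[2]]) *
           (di - dm[pos, oth[3]]))
      }
    }
    f[mid] <- pmin(pmax(fm, 0), 1)
  }
  f
}

# 2-D analogue on a triangle: sum over positive vertices of
# d_i^2 / prod_{j!=i}(d_i - d_j).
tri_fraction_above <- function(d) {
  f <- numeric(nrow(d))
  npos <- rowSums(d > 0)
  f[npos == 3L] <- 1
  mid <- which(npos == 1L | npos == 2L)
  if (length(mid)) {
    dm <- jitter_ties(d[mid, , drop = FALSE])
    fm <- numeric(length(mid))
    for (i in 1:3) {
      oth <- setdiff(1:3, i)
      pos <- dm[, i] > 0
      if (any(pos)) {
        di <- dm[pos, i]
        fm[pos] <- fm[pos] + di^2 /
          ((di - dm[pos, oth[1]]) * (di - dm[pos, oth[2]]))
      }
    }
    f[mid] <- pmin(pmax(fm, 0), 1)
  }
  f
}

#' Ablation volume above a field threshold
#'
#' Volume of the myocardium where the nodal-interpolated field magnitude
#' exceeds the irreversible-electroporation threshold, integrated with
#' sub-element resolution (closed-form partial volumes on the Kuhn
#' tetrahedra of each cell).
#'
#' @param mesh a `tissue_mesh`.
#' @param e_mag per-element field magnitude (V/m), e.g. `solution$e_mag`.
#' @param threshold field threshold (V/m), default 1e5 (= 1000 V/cm).
#' @return ablation volume in mm^3.
#' @export
ablation_volume <- function(mesh, e_mag, threshold = 1e5) {
  if (threshold <= 0) stop("domain error: threshold must be positive")
  myo <- which(mesh$region == "MYOCARDIUM")
  if (!length(myo)) return(0)
  vn <- nodal_field(mesh, e_mag, "MYOCARDIUM")
  el <- mesh$elems[myo, , drop = FALSE]
  total <- 0
  for (t in seq_len(nrow(KUHN_TETS))) {
    d <- matrix(vn[el[, KUHN_TETS[t, ]]], ncol = 4) - threshold
    total <- total + sum(tet_fraction_above(d))
  }
  total * cell_volume(mesh) / 6 * 1e9
}

#' Surface ablation area above a field threshold
#'
#' Area of a tagged interface where the nodal-interpolated field magnitude
#' exceeds the threshold. The default surface is the endocardial
#' myocardium-blood interface (the visible tissue surface of the scenario).
#' Each quadrilateral facet is split into two triangles on which the
#' supra-threshold area fraction has a closed form.
#'
#' @param mesh a `tissue_mesh`.
#' @param e_mag per-element field magnitude (V/m).
#' @param threshold field threshold (V/m), default 1e5.
#' @param surface facet tag from [boundary_facets()], default `"ENDOCARDIAL"`.
#' @return area in mm^2.
#' @export
surface_ablation_area <- function(mesh, e_mag, threshold = 1e5,
                                  surface = "ENDOCARDIAL") {
  if (threshold <= 0) stop("domain error: threshold must be positive")
  facets <- boundary_facets(mesh)
  if (is.null(facets[[surface]]))
    stop("tag error: unknown surface tag '", surface, "'")
  fc <- facets[[surface]]
  if (!nrow(fc)) return(0)
  vn <- nodal_field(mesh, e_mag, "MYOCARDIUM")
  # facet area from the two spacings orthogonal to the face direction
  ax <- match(substr(fc$dir, 1, 1), c("x", "y", "z"))
  face_area <- prod(mesh$h) / mesh$h[ax]
  v <- cbind(vn[fc$n1], vn[fc$n2], vn[fc$n3], vn[fc$n4]) - threshold
  f1 <- tri_fraction_above(v[, c(1, 2, 3), drop = FALSE])
  f2 <- tri_fraction_above(v[, c(1, 3, 4), drop = FALSE])
  sum((f1 + f2) / 2 * face_area) * 1e6
}

#' Extract the threshold isosurface inside the myocardium
#'
#' Marching tetrahedra on the Kuhn decomposition of the myocardial cells,
#' applied to the nodal-interpolated field magnitude. Returns the triangle
#' soup of the `|E| = threshold` surface (watertight up to the domain
#' boundary).
#'
#' @param mesh a `tissue_mesh`.
#' @param e_mag per-element field magnitude (V/m).
#' @param threshold field threshold (V/m), default 1e5.
#' @return object of class `iso_surface`: list with `triangles` (n x 9
#'   matrix; each row one triangle as v1 xyz, v2 xyz, v3 xyz, in mm) and
#'   `threshold`.
#' @export
extract_isosurface <- function(mesh, e_mag, threshold = 1e5) {
  if (threshold <= 0) stop("domain error: threshold must be positive")
  myo <- which(mesh$region == "MYOCARDIUM")
  vn <- nodal_field(mesh, e_mag, "MYOCARDIUM")
  vals <- vn[unique(as.vector(mesh$elems[myo, ]))]
  if (length(vals) && all(abs(vals - threshold) < .Machine$double.eps * 100))
    stop("degenerate-isosurface error: field is constant at the threshold")
  el <- mesh$elems[myo, , drop = FALSE]
  tris <- list()
  for (t in seq_len(nrow(KUHN_TETS))) {
    ids <- matrix(el[, KUHN_TETS[t, ]], ncol = 4)
    d <- matrix(vn[ids], ncol = 4) - threshold
    d <- jitter_ties(d)
    npos <- rowSums(d > 0)
    # edge intersection points for rows `rows` between vertex columns a, b
    ipt <- function(rows, a, b) {
      pa <- mesh$nodes[ids[rows, a], , drop = FALSE]
      pb <- mesh$nodes[ids[rows, b], , drop = FALSE]
      s <- d[rows, a] / (d[rows, a] - d[rows, b])
      pa + s * (pb - pa)
    }
    # one vertex on one side, three on the other: one triangle
    for (v in 1:4) {
      oth <- setdiff(1:4, v)
      for (side in c(1L, 3L)) {
        rows <- which(npos == side &
                        (if (side == 1L) d[, v] > 0 else d[, v] <= 0))
        if (!length(rows)) next
        p1 <- ipt(rows, v, oth[1]); p2 <- ipt(rows, v, oth[2])
        p3 <- ipt(rows, v, oth[3])
        tris[[length(tris) + 1L]] <- cbind(p1, p2, p3)
      }
    }
    # two-two split: quad -> two triangles
    pairs <- utils::combn(4, 2)
    for (pc in seq_len(ncol(pairs))) {
      v1 <- pairs[1, pc]; v2 <- pairs[2, pc]
      w <- setdiff(1:4, c(v1, v2))
      rows <- which(npos == 2L & d[, v1] > 0 & d[, v2] > 0)
      if (!length(rows)) next
      ac <- ipt(rows, v1, w[1]); ad <- ipt(rows, v1, w[2])
      bd <- ipt(rows, v2, w[2]); bc <- ipt(rows, v2, w[1])
      tris[[length(tris) + 1L]] <- cbind(ac, ad, bd)
      tris[[length(tris) + 1L]] <- cbind(ac, bd, bc)
    }
  }
  triangles <- if (length(tris)) do.call(rbind, tris) * 1e3
               else matrix(numeric(0), 0, 9)
  dimnames(triangles) <- NULL
  structure(list(triangles = triangles, threshold = threshold),
            class = "iso_surface")
}

#' @export
print.iso_surface <- function(x, ...) {
  cat("iso_surface:", nrow(x$triangles), "triangles at", x$threshold, "V/m\n")
  invisible(x)
}

#' Per-axis extents of an isosurface
#'
#' Maximum minus minimum of the isosurface vertex coordinates along each
#' scenario axis — the lesion-size measure used for threshold isosurfaces.
#' An empty surface yields zero extents flagged with `attr(, "empty")`.
#'
#' @param isosurface an `iso_surface`.
#' @return named numeric `c(extent_x, extent_y, extent_z)` in mm.
#' @export
isosurface_extents <- function(isosurface) {
  tr <- isosurface$triangles
  if (!nrow(tr)) {
    out <- c(extent_x = 0, extent_y = 0, extent_z = 0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  vx <- c(tr[, 1], tr[, 4], tr[, 7])
  vy <- c(tr[, 2], tr[, 5], tr[, 8])
  vz <- c(tr[, 3], tr[, 6], tr[, 9])
  c(extent_x = max(vx) - min(vx), extent_y = max(vy) - min(vy),
    extent_z = max(vz) - min(vz))
}

#' All lesion metrics of a field solution
#'
#' Convenience wrapper: supra-threshold surface ablation area, ablation
#' volume, isosurface and its per-axis extents.
#'
#' @param mesh a `tissue_mesh`.
#' @param field a `field_solution` or per-element |E| (V/m).
#' @param threshold field threshold (V/m), default 1e5.
#' @return list of class `ablation_metrics` with `area_mm2`, `volume_mm3`,
#'   `extents_mm`, `isosurface`, `threshold`.
#' @export
ablation_metrics <- function(mesh, field, threshold = 1e5) {
  e_mag <- if (is.numeric(field)) field else field$e_mag
  iso <- extract_isosurface(mesh, e_mag, threshold)
  out <- list(area_mm2 = surface_ablation_area(mesh, e_mag, threshold),
              volume_mm3 = ablation_volume(mesh, e_mag, threshold),
              extents_mm = isosurface_extents(iso),
              isosurface = iso, threshold = threshold)
  class(out) <- "ablation_metrics"
  out
}

#' @export
print.ablation_metrics <- function(x, ...) {
  cat("ablation_metrics (threshold", x$threshold, "V/m):\n")
  cat("  surface area:", signif(x$area_mm2, 5), "mm^2\n")
  cat("  volume:      ", signif(x$volume_mm3, 5), "mm^3\n")
  cat("  extents:     ", paste(signif(x$extents_mm, 5), collapse = " / "),
      "mm (x/y/z)\n")
  invisible(x)
}

#' Paired anisotropic-vs-isotropic difference
#'
#' Difference statistics between a metric under anisotropic (AC) and
#' isotropic (IC) conductivity, with the significance conventions used for
#' lesion comparisons: isosurface extents are compared absolutely
#' (significant at >= 1 mm), areas and volumes as percentages
#' (significant at >= 5%), temperatures absolutely (significant at >= 4 degC).
#'
#' @param metric_ac,metric_ic the paired metric values (same units).
#' @param kind one of `"extent"`, `"area"`, `"volume"`, `"temperature"`.
#' @return list of class `paired_difference` with `absolute`, `percent`
#'   (`(AC - IC)/IC * 100`; `NA` when not applicable) and `significant`.
#' @export
paired_difference <- function(metric_ac, metric_ic,
                              kind = c("extent", "area", "volume",
                                       "temperature")) {
  kind <- match.arg(kind)
  absolute <- metric_ac - metric_ic
  percent <- if (metric_ic != 0) absolute / metric_ic * 100 else NA_real_
  if (kind %in% c("area", "volume") && metric_ic == 0)
    stop("undefined-percent error: IC metric is zero")
  significant <- switch(kind,
    extent = abs(absolute) >= 1,
    area = abs(percent) >= 5,
    volume = abs(percent) >= 5,
    temperature = abs(absolute) >= 4)
  structure(list(absolute = absolute, percent = percent,
                 significant = significant, kind = kind),
            class = "paired_difference")
}

#' @export
print.paired_difference <- function(x, ...) {
  cat("paired_difference (", x$kind, "): AC - IC = ", signif(x$absolute, 5),
      if (!is.na(x$percent)) paste0(" (", signif(x$percent, 4), "%)") else "",
      if (x$significant) " [significant]" else " [not significant]", "\n",
      sep = "")
  invisible(x)
}

#' Mean and sample standard deviation
#'
#' @param values numeric vector, length at least 2.
#' @return named numeric `c(mean, sd)`.
#' @export
aggregate_stats <- function(values) {
  if (length(values) < 2)
    stop("insufficient-data error: need at least 2 values")
  c(mean = mean(values), sd = stats::sd(values))
}
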