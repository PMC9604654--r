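# Structured hexahedral grids with region tags. Node/element numbering is
# lattice order: node id = i + (nx+1)*(j + (ny+1)*k) + 1, cell id =
# i + nx*(j + ny*k) + 1, with (i, j, k) zero-based along (x, y, z).

REGION_LEVELS <- c("MYOCARDIUM", "BLOOD", "ELECTRODE_LEFT", "ELECTRODE_RIGHT",
                   "INSULATOR")

#' Structured hexahedral box mesh
#'
#' Builds an axis-aligned box discretized into identical hexahedral cells.
#' This is the background grid used by the scenario builders and directly by
#' verification problems (parallel plates, point sources).
#'
#' @param lower,upper numeric length-3, opposite box corners in meters.
#' @param n integer length-3, number of cells along each axis.
#' @param region region tag assigned to every cell (may be reassigned later).
#' @return An object of class `tissue_mesh`: list with `nodes` (N x 3 m),
#'   `elems` (E x 8 node indices, VTK hexahedron ordering), `region` (factor
#'   per element), `dims`, `h` (cell spacings, m), `origin`.
#' @export
box_mesh <- function(lower, upper, n, region = "MYOCARDIUM") {
  stopifnot(length(lower) == 3, length(upper) == 3, length(n) == 3,
            all(upper > lower), all(n >= 1))
  n <- as.integer(n)
  h <- (upper - lower) / n
  xs <- lower[1] + h[1] * 0:n[1]
  ys <- lower[2] + h[2] * 0:n[2]
  zs <- lower[3] + h[3] * 0:n[3]
  nodes <- cbind(
    x = rep(xs, times = (n[2] + 1L) * (n[3] + 1L)),
    y = rep(rep(ys, each = n[1] + 1L), times = n[3] + 1L),
    z = rep(zs, each = (n[1] + 1L) * (n[2] + 1L))
  )
  nxp <- n[1] + 1L
  dy <- nxp
  dz <- nxp * (n[2] + 1L)
  i <- rep(0:(n[1] - 1L), times = n[2] * n[3])
  j <- rep(rep(0:(n[2] - 1L), each = n[1]), times = n[3])
  k <- rep(0:(n[3] - 1L), each = n[1] * n[2])
  n0 <- i + nxp * (j + (n[2] + 1L) * k) + 1L
  elems <- cbind(n0, n0 + 1L, n0 + 1L + dy, n0 + dy,
                 n0 + dz, n0 + 1L + dz, n0 + 1L + dy + dz, n0 + dy + dz)
  dimnames(elems) <- NULL
  mesh <- list(
    nodes = nodes,
    elems = elems,
    region = factor(rep(region, nrow(elems)), levels = REGION_LEVELS),
    dims = n,
    h = h,
    origin = lower
  )
  class(mesh) <- "tissue_mesh"
  mesh
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat("tissue_mesh:", nrow(x$nodes), "nodes,", nrow(x$elems), "hex cells\n")
  cat("  grid", paste(x$dims, collapse = " x "),
      " spacing (mm):", paste(signif(x$h * 1e3, 4), collapse = " x "), "\n")
  print(table(x$region))
  invisible(x)
}

n_nodes <- function(mesh) nrow(mesh$nodes)
n_elems <- function(mesh) nrow(mesh$elems)
cell_volume <- function(mesh) prod(mesh$h)

#' Element centroids
#'
#' @param mesh a `tissue_mesh`.
#' @return E x 3 matrix of cell centroids (m).
#' @export
element_centroids <- function(mesh) {
  n <- mesh$dims
  i <- rep(0:(n[1] - 1L), times = n[2] * n[3])
  j <- rep(rep(0:(n[2] - 1L), each = n[1]), times = n[3])
  k <- rep(0:(n[3] - 1L), each = n[1] * n[2])
  cbind(mesh$origin[1] + (i + 0.5) * mesh$h[1],
        mesh$origin[2] + (j + 0.5) * mesh$h[2],
        mesh$origin[3] + (k + 0.5) * mesh$h[3])
}

# cell lattice coordinates (zero-based i, j, k) for every element
cell_ijk <- function(mesh) {
  n <- mesh$dims
  cbind(i = rep(0:(n[1] - 1L), times = n[2] * n[3]),
        j = rep(rep(0:(n[2] - 1L), each = n[1]), times = n[3]),
        k = rep(0:(n[3] - 1L), each = n[1] * n[2]))
}

#' Total volume of a tagged region
#'
#' @param mesh a `tissue_mesh`.
#' @param region region tag, default `"MYOCARDIUM"`.
#' @return volume in cubic meters.
#' @export
region_volume <- function(mesh, region = "MYOCARDIUM") {
  sum(mesh$region == region) * cell_volume(mesh)
}

#' Myocardial volume of a scenario mesh
#'
#' @param mesh a `tissue_mesh`.
#' @return myocardial volume in cubic meters.
#' @export
myocardial_volume <- function(mesh) region_volume(mesh, "MYOCARDIUM")

#' Nodes on an outer face of the mesh box
#'
#' @param mesh a `tissue_mesh`.
#' @param face one of `"xmin"`, `"xmax"`, `"ymin"`, `"ymax"`, `"zmin"`, `"zmax"`.
#' @return integer vector of node indices.
#' @export
boundary_nodes <- function(mesh,
                           face = c("xmin", "xmax", "ymin", "ymax",
                                    "zmin", "zmax")) {
  face <- match.arg(face)
  ax <- match(substr(face, 1, 1), c("x", "y", "z"))
  lim <- if (endsWith(face, "min")) mesh$origin[ax]
         else mesh$origin[ax] + mesh$dims[ax] * mesh$h[ax]
  which(abs(mesh$nodes[, ax] - lim) < 1e-9 * max(mesh$h))
}

# Local node subsets of the VTK hexahedron forming each face, keyed by the
# outward direction of the face.
HEX_FACE_NODES <- list(
  "x-" = c(1L, 4L, 8L, 5L), "x+" = c(2L, 3L, 7L, 6L),
  "y-" = c(1L, 2L, 6L, 5L), "y+" = c(4L, 3L, 7L, 8L),
  "z-" = c(1L, 2L, 3L, 4L), "z+" = c(5L, 6L, 7L, 8L)
)

# neighbour cell ids in a given lattice direction; 0 where out of range
neighbor_cells <- function(mesh, dir) {
  n <- mesh$dims
  ijk <- cell_ijk(mesh)
  step <- switch(dir,
    "x-" = c(-1L, 0L, 0L), "x+" = c(1L, 0L, 0L),
    "y-" = c(0L, -1L, 0L), "y+" = c(0L, 1L, 0L),
    "z-" = c(0L, 0L, -1L), "z+" = c(0L, 0L, 1L))
  i <- ijk[, 1] + step[1]; j <- ijk[, 2] + step[2]; k <- ijk[, 3] + step[3]
  ok <- i >= 0L & i < n[1] & j >= 0L & j < n[2] & k >= 0L & k < n[3]
  out <- integer(nrow(ijk))
  out[ok] <- i[ok] + n[1] * (j[ok] + n[2] * k[ok]) + 1L
  out
}

#' Facets on the interface between two regions
#'
#' Enumerates the quadrilateral cell faces whose owner cell is tagged
#' `region_a` and whose lattice neighbour is tagged `region_b`. The
#' endocardial surface, for example, is `interface_facets(mesh, "MYOCARDIUM",
#' "BLOOD")`.
#'
#' @param mesh a `tissue_mesh`.
#' @param region_a,region_b region tags (`region_b` may be a vector of tags).
#' @return data frame with owner element `elem`, face direction `dir`, and
#'   the four corner node indices `n1..n4`.
#' @export
interface_facets <- function(mesh, region_a, region_b) {
  out <- vector("list", 6)
  names(out) <- names(HEX_FACE_NODES)
  owner_ok <- mesh$region == region_a
  for (dir in names(HEX_FACE_NODES)) {
    nb <- neighbor_cells(mesh, dir)
    sel <- which(owner_ok & nb > 0L & (mesh$region[pmax(nb, 1L)] %in% region_b))
    if (!length(sel)) next
    fn <- HEX_FACE_NODES[[dir]]
    out[[dir]] <- data.frame(elem = sel, dir = dir,
                             n1 = mesh$elems[sel, fn[1]],
                             n2 = mesh$elems[sel, fn[2]],
                             n3 = mesh$elems[sel, fn[3]],
                             n4 = mesh$elems[sel, fn[4]])
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(elem = integer(), dir = character(), n1 = integer(),
                      n2 = integer(), n3 = integer(), n4 = integer())
  rownames(out) <- NULL
  out
}

#' Tagged boundary and interface facets of a scenario mesh
#'
#' Returns the facet groups the solvers and metrics refer to:
#' `ENDOCARDIAL` (myocardium-blood interface), `EPICARDIAL` (bottom face of
#' the myocardium), `ELECTRODE_LEFT_SURFACE` / `ELECTRODE_RIGHT_SURFACE`
#' (metal in contact with conductive tissue or blood), `BLOOD_INFLOW` /
#' `BLOOD_OUTFLOW` (blood cells on the x-extremes), and `OUTER` (remaining
#' outer box faces).
#'
#' @param mesh a `tissue_mesh`.
#' @return named list of facet data frames (see [interface_facets()]).
#' @export
boundary_facets <- function(mesh) {
  conductive <- c("MYOCARDIUM", "BLOOD", "INSULATOR")
  res <- list(
    ENDOCARDIAL = interface_facets(mesh, "MYOCARDIUM", "BLOOD"),
    ELECTRODE_LEFT_SURFACE = interface_facets(mesh, "ELECTRODE_LEFT", conductive),
    ELECTRODE_RIGHT_SURFACE = interface_facets(mesh, "ELECTRODE_RIGHT", conductive)
  )
  outer <- vector("list", 6)
  names(outer) <- names(HEX_FACE_NODES)
  epi <- inflow <- outflow <- NULL
  for (dir in names(HEX_FACE_NODES)) {
    nb <- neighbor_cells(mesh, dir)
    sel <- which(nb == 0L)
    if (!length(sel)) next
    fn <- HEX_FACE_NODES[[dir]]
    df <- data.frame(elem = sel, dir = dir,
                     n1 = mesh$elems[sel, fn[1]], n2 = mesh$elems[sel, fn[2]],
                     n3 = mesh$elems[sel, fn[3]], n4 = mesh$elems[sel, fn[4]])
    reg <- mesh$region[sel]
    if (dir == "z-") {
      epi <- rbind(epi, df[reg == "MYOCARDIUM", ])
      df <- df[reg != "MYOCARDIUM", ]
    } else if (dir == "x-") {
      inflow <- rbind(inflow, df[reg == "BLOOD", ])
      df <- df[reg != "BLOOD", ]
    } else if (dir == "x+") {
      outflow <- rbind(outflow, df[reg == "BLOOD", ])
      df <- df[reg != "BLOOD", ]
    }
    outer[[dir]] <- df
  }
  empty <- data.frame(elem = integer(), dir = character(), n1 = integer(),
                      n2 = integer(), n3 = integer(), n4 = integer())
  res$EPICARDIAL <- if (is.null(epi)) empty else epi
  res$BLOOD_INFLOW <- if (is.null(inflow)) empty else inflow
  res$BLOOD_OUTFLOW <- if (is.null(outflow)) empty else outflow
  res$OUTER <- do.call(rbind, outer[!vapply(outer, is.null, logical(1))])
  res <- lapply(res, function(d) { rownames(d) <- NULL; d })
  res
}

#' Export a mesh (with optional fields) as an ASCII VTK unstructured grid
#'
#' Writes a `.vtu` XML file with the hexahedral cells, the `region` tag as
#' cell data, and any additional point/cell data arrays supplied. Vector
#' arrays are passed as matrices with 3 columns.
#'
#' @param mesh a `tissue_mesh`.
#' @param file output path (conventionally `.vtu`).
#' @param point_data named list of per-node vectors/3-column matrices.
#' @param cell_data named list of per-element vectors/3-column matrices.
#' @return `file`, invisibly.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  np <- n_nodes(mesh); ne <- n_elems(mesh)
  cell_data <- c(list(region = as.integer(mesh$region)), cell_data)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(x) paste(formatC(as.vector(x), format = "g", digits = 9),
                           collapse = " ")
  arr <- function(name, x) {
    ncomp <- if (is.matrix(x)) ncol(x) else 1L
    vals <- if (is.matrix(x)) as.vector(t(x)) else x
    w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              name, ncomp))
    w(num(vals))
    w("</DataArray>")
  }
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w("<UnstructuredGrid>")
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', np, ne))
  w("<Points>")
  arr("Points", mesh$nodes)
  w("</Points>")
  w("<Cells>")
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(as.vector(t(mesh$elems)) - 1L, collapse = " "))
  w("</DataArray>")
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(8L * seq_len(ne), collapse = " "))
  w("</DataArray>")
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(12L, ne), collapse = " "))
  w("</DataArray>")
  w("</Cells>")
  if (length(point_data)) {
    w("<PointData>")
    for (nm in names(point_data)) arr(nm, point_data[[nm]])
    w("</PointData>")
  }
  if (length(cell_data)) {
    w("<CellData>")
    for (nm in names(cell_data)) arr(nm, cell_data[[nm]])
    w("</CellData>")
  }
  w("</Piece>")
  w("</UnstructuredGrid>")
  w("</VTKFile>")
  invisible(file)
}
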