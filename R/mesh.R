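#' Construct a shared-vertex tissue mesh
#'
#' A mesh is the model's vertex set \eqn{V} and cell set \eqn{C}: an
#' \eqn{n \times 2} matrix of vertex positions (x = anterior-posterior,
#' y = basoapical) and an \eqn{m \times 4} matrix of vertex indices per
#' quadrilateral cell in the fixed cyclic order anterior-basal,
#' posterior-basal, posterior-apical, anterior-apical. Adjacent cells share
#' the two vertices of their common lateral edge. Each tissue carries an
#' \emph{ECM frame}: a basal reference line \code{basal_y} and an apical
#' direction \code{apical_sign} (+1 apical above the line, -1 mirrored), so
#' the adhesion/repulsion distances are basoapical distances from that line.
#'
#' @param vertices numeric n x 2 matrix of vertex coordinates.
#' @param cells integer m x 4 matrix of 1-based vertex indices.
#' @param fixed integer vector of vertex indices whose x coordinate is
#'   immobilized (the anterior-most vertices).
#' @param tissue character vector, length m: tissue label per cell.
#' @param frames named list, one entry per tissue label:
#'   \code{list(basal_y =, apical_sign =, V0 =)} (\code{V0} optional,
#'   overriding the mechanical target area for that tissue).
#' @param validate check mesh invariants (default TRUE).
#' @return An object of class \code{tissue_mesh}.
#' @export
tissue_mesh <- function(vertices, cells, fixed = integer(0),
                        tissue = rep("tissue", nrow(cells)),
                        frames = list(tissue = list(basal_y = 0, apical_sign = 1)),
                        validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  dimnames(cells) <- NULL
  if (ncol(vertices) != 2) stop("vertices must be an n x 2 matrix")
  if (ncol(cells) != 4) stop("cells must be an m x 4 matrix")
  mesh <- structure(list(vertices = vertices, cells = cells,
                         fixed = as.integer(fixed),
                         tissue = as.character(tissue), frames = frames),
                    class = "tissue_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate tissue-mesh invariants
#'
#' Checks finite coordinates, index ranges, four distinct vertices per cell,
#' simple (non-self-intersecting) cell polygons with positive oriented area
#' in their tissue frame, and that every tissue label has a frame.
#'
#' @param mesh a \code{tissue_mesh}.
#' @return The mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  if (any(!is.finite(v))) stop("geometry error: non-finite vertex coordinates")
  n <- nrow(v)
  if (any(mesh$cells < 1L) || any(mesh$cells > n))
    stop("lookup error: cell refers to a missing vertex")
  if (length(mesh$fixed) && (any(mesh$fixed < 1L) || any(mesh$fixed > n)))
    stop("lookup error: fixed vertex id out of range")
  if (length(mesh$tissue) != nrow(mesh$cells))
    stop("tissue labels must have one entry per cell")
  missing_fr <- setdiff(unique(mesh$tissue), names(mesh$frames))
  if (length(missing_fr))
    stop("no ecm_frame for tissue(s): ", paste(missing_fr, collapse = ", "))
  for (i in seq_len(nrow(mesh$cells))) {
    ids <- mesh$cells[i, ]
    if (length(unique(ids)) != 4L)
      stop("geometry error: cell ", i, " has repeated vertex indices")
    cell_area(mesh, i)  # errors on degenerate or self-intersecting quads
  }
  invisible(mesh)
}

.cell_coords <- function(mesh, cell_id) {
  if (length(cell_id) != 1L || is.na(cell_id) ||
      cell_id < 1L || cell_id > nrow(mesh$cells))
    stop("lookup error: unknown cell_id ", cell_id)
  mesh$vertices[mesh$cells[cell_id, ], , drop = FALSE]
}

.frame_of_cell <- function(mesh, cell_id) {
  mesh$frames[[mesh$tissue[cell_id]]]
}

# proper intersection test of segments p1-p2 and p3-p4 (interiors crossing)
.segments_cross <- function(p1, p2, p3, p4) {
  cp <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  d1 <- cp(p3, p4, p1); d2 <- cp(p3, p4, p2)
  d3 <- cp(p1, p2, p3); d4 <- cp(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

#' Area of one cell
#'
#' Shoelace area of the cell's quadrilateral, oriented by the tissue frame so
#' that a valid cell has positive area. Degenerate (zero-area) and
#' self-intersecting quads raise a geometry error: they signal a parameter
#' regime outside model validity.
#'
#' @param mesh a \code{tissue_mesh}.
#' @param cell_id cell index.
#' @return Cell area (model units squared).
#' @export
cell_area <- function(mesh, cell_id) {
  p <- .cell_coords(mesh, cell_id)
  fr <- .frame_of_cell(mesh, cell_id)
  idx <- c(2L, 3L, 4L, 1L)
  # shoelace: sum(x_k * y_{k+1} - x_{k+1} * y_k) / 2
  a_signed <- 0.5 * sum(p[, 1] * p[idx, 2] - p[idx, 1] * p[, 2])
  if (.segments_cross(p[1, ], p[2, ], p[3, ], p[4, ]) ||
      .segments_cross(p[2, ], p[3, ], p[4, ], p[1, ]))
    stop("geometry error: cell ", cell_id, " is self-intersecting")
  area <- fr$apical_sign * a_signed
  if (area <= 0)
    stop("geometry error: cell ", cell_id, " has non-positive oriented area (",
         signif(area, 6), ")")
  area
}

#' Perimeter of one cell
#'
#' Sum of the four edge lengths in cyclic order.
#'
#' @inheritParams cell_area
#' @return Cell perimeter (model units).
#' @export
cell_perimeter <- function(mesh, cell_id) {
  p <- .cell_coords(mesh, cell_id)
  idx <- c(2L, 3L, 4L, 1L)
  sum(sqrt(rowSums((p[idx, , drop = FALSE] - p)^2)))
}

#' Edge elastic energy of one cell
#'
#' The stretch readout driving division:
#' \eqn{U_i = b (L_{i,apical}^2 + L_{i,basal}^2)/2}, with the basal edge
#' joining the first two vertices of the cell and the apical edge the last
#' two.
#'
#' @inheritParams cell_area
#' @param b perimeter-contraction coefficient.
#' @return Elastic energy of the apical and basal edges.
#' @export
edge_elastic_energy <- function(mesh, cell_id, b) {
  p <- .cell_coords(mesh, cell_id)
  basal2 <- sum((p[2, ] - p[1, ])^2)
  apical2 <- sum((p[4, ] - p[3, ])^2)
  0.5 * b * (apical2 + basal2)
}

# Assemble the per-tissue spec list handed to the compiled core.
# `behavior` is a named list per tissue: list(migrate=, strain_div=, clock_mode=)
.tissue_spec <- function(mesh, params, behavior = NULL) {
  nm <- names(mesh$frames)
  lapply(nm, function(t) {
    fr <- mesh$frames[[t]]
    bh <- if (!is.null(behavior) && !is.null(behavior[[t]])) behavior[[t]] else list()
    list(basal_y = fr$basal_y,
         apical_sign = fr$apical_sign,
         migrate = isTRUE(bh$migrate),
         strain_div = isTRUE(bh$strain_div),
         clock_mode = if (is.null(bh$clock_mode)) 0L else as.integer(bh$clock_mode),
         V0 = if (!is.null(fr$V0)) fr$V0 else params$V0)
  })
}

.cell_tissue_index <- function(mesh) {
  match(mesh$tissue, names(mesh$frames))
}

#' Total tissue energy
#'
#' Evaluates the four-term vertex-model energy (area conservation, perimeter
#' contraction, basal-ECM adhesion, apical repulsion) over all cells, with
#' adhesion/repulsion distances measured from each tissue's basal reference
#' line.
#'
#' @param mesh a \code{tissue_mesh}.
#' @param params a \code{mechanical_params}.
#' @return Scalar energy.
#' @export
tissue_energy <- function(mesh, params) {
  stopifnot(inherits(params, "mechanical_params"))
  energy_cpp(mesh$vertices, mesh$cells, .cell_tissue_index(mesh),
             .tissue_spec(mesh, params), unclass(params))
}

#' Analytic force field
#'
#' Per-vertex force \eqn{F_j = -\partial U/\partial r_j}, the exact gradient
#' of \code{\link{tissue_energy}}. Entries are reported for every vertex
#' including those with fixed x coordinates; the integrator masks the latter.
#'
#' @inheritParams tissue_energy
#' @return n x 2 matrix of force components.
#' @export
tissue_forces <- function(mesh, params) {
  stopifnot(inherits(params, "mechanical_params"))
  f <- forces_cpp(mesh$vertices, mesh$cells, .cell_tissue_index(mesh),
                  .tissue_spec(mesh, params), unclass(params))
  colnames(f) <- c("fx", "fy")
  f
}

#' Basal adhesion potential f
#'
#' Piecewise-quadratic well describing adhesion between the basal surface and
#' the ECM: \eqn{f(x) = (x-h)^2/2 - (h_{th}-h)^2/4} for
#' \eqn{x < (h_{th}+h)/2}, \eqn{f(x) = -(x-h_{th})^2/2} for
#' \eqn{(h_{th}+h)/2 \le x < h_{th}}, and 0 beyond the cutoff; continuous and
#' once-differentiable at both breakpoints, with minimum
#' \eqn{-(h_{th}-h)^2/4} at \eqn{x = h}.
#'
#' @param dist basoapical distance(s) from the basal reference line.
#' @param h ECM position (adhesion minimum).
#' @param h_th adhesion cutoff; must exceed \code{h}.
#' @return Potential value(s).
#' @export
basal_potential_f <- function(dist, h, h_th) {
  if (!is.finite(h) || !is.finite(h_th) || h < 0 || h >= h_th)
    stop("parameter error: need 0 <= h < h_th")
  mid <- 0.5 * (h + h_th)
  ifelse(dist < mid, 0.5 * (dist - h)^2 - 0.25 * (h_th - h)^2,
         ifelse(dist < h_th, -0.5 * (dist - h_th)^2, 0))
}

#' Apical repulsion potential g
#'
#' Zero below the confinement distance \eqn{\ell}, half-quadratic
#' \eqn{(x-\ell)^2/2} beyond it.
#'
#' @param dist basoapical distance(s) from the basal reference line.
#' @param ell confinement distance (> 0).
#' @return Potential value(s).
#' @export
apical_potential_g <- function(dist, ell) {
  if (!is.finite(ell) || ell <= 0) stop("parameter error: ell must be positive")
  ifelse(dist < ell, 0, 0.5 * (dist - ell)^2)
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat("tissue_mesh:", nrow(x$vertices), "vertices,", nrow(x$cells), "cells (",
      paste(sprintf("%s: %d", names(table(x$tissue)), table(x$tissue)),
            collapse = ", "),
      "),", length(x$fixed), "x-fixed vertices\n")
  invisible(x)
}
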