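#' Create a simulation state
#'
#' Bundles a mesh with per-cell dynamic state: migration force \code{v},
#' activity \code{w}, age since birth, latch time \code{T_latch} (NA when the
#' edge elastic energy has not yet exceeded the division threshold), and the
#' clock period \code{D}.
#'
#' @param mesh a \code{tissue_mesh}.
#' @param t current time.
#' @param D clock period assigned to every cell (NA for tissues without
#'   clocked division).
#' @return An object of class \code{sim_state}.
#' @export
sim_state <- function(mesh, t = 0, D = NA_real_) {
  m <- nrow(mesh$cells)
  structure(list(
    mesh = mesh,
    cell_state = data.frame(v = numeric(m), w = numeric(m), age = numeric(m),
                            T_latch = rep(NA_real_, m), D = rep(D, m)),
    t = t), class = "sim_state")
}

#' Graded migration activity
#'
#' \eqn{w_i = v_{max}\,((x_i - x_{min})/(x_{max} - x_{min}))^\alpha} for
#' cell-centroid positions \eqn{x_i}, where \eqn{x_{min}}/\eqn{x_{max}} are
#' the extreme centroids. The posterior-most cell receives \eqn{v_{max}} and
#' the anterior-most 0; when all centroids coincide (single cell) every cell
#' receives \eqn{v_{max}} by convention, since the degenerate gradient has no
#' anterior-posterior information.
#'
#' @param centroid_xs numeric vector of cell-centroid x positions.
#' @param params a \code{migration_params}.
#' @return Vector of activities in \code{[0, vmax]}.
#' @export
migration_activity <- function(centroid_xs, params) {
  stopifnot(inherits(params, "migration_params"))
  if (length(centroid_xs) == 0) stop("input error: no centroids")
  rng <- range(centroid_xs)
  if (diff(rng) <= 0) return(rep(params$vmax, length(centroid_xs)))
  s <- (centroid_xs - rng[1]) / diff(rng)
  params$vmax * s^params$exponent
}

.cell_centroids <- function(mesh) {
  rowMeans(matrix(mesh$vertices[t(mesh$cells), 1], ncol = 4, byrow = TRUE))
}

# One classical RK4 step of eta dv/dt = -v + w with w frozen (vectorized).
.rk4_relax <- function(v, w, eta, dt) {
  k1 <- (w - v) / eta
  k2 <- (w - (v + 0.5 * dt * k1)) / eta
  k3 <- (w - (v + 0.5 * dt * k2)) / eta
  k4 <- (w - (v + dt * k3)) / eta
  v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Advance migration forces by one step
#'
#' Recomputes the activity \eqn{w_i} from current centroids, then performs
#' one classical fourth-order Runge-Kutta step of the relaxation ODE
#' \eqn{\eta\, dv_i/dt = -v_i + w_i} with \eqn{w_i} frozen within the step.
#'
#' @param state a \code{sim_state}.
#' @param params a \code{migration_params}.
#' @param dt time step (> 0).
#' @return The state with updated \code{v} and \code{w}.
#' @export
advance_migration_forces <- function(state, params, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  w <- migration_activity(.cell_centroids(state$mesh), params)
  state$cell_state$w <- w
  state$cell_state$v <- .rk4_relax(state$cell_state$v, w, params$eta, dt)
  state
}

#' Advance vertex positions by one Euler-Maruyama step
#'
#' \eqn{r_j \leftarrow r_j + ((F_j + F^{applied}_j)/\tau)\,dt +
#' (\sigma/\tau)\sqrt{dt}\,N(0, I)} per free coordinate; the x coordinate of
#' fixed vertices is left untouched (no drift, no noise), their y remains
#' free.
#'
#' @param state a \code{sim_state}.
#' @param params a \code{mechanical_params}.
#' @param integ an \code{integrator_spec}.
#' @param applied_forces optional n x 2 matrix of extra per-vertex forces
#'   (e.g. migration forces), aligned with the vertex table.
#' @return The state with updated vertex positions and time.
#' @export
advance_vertices <- function(state, params, integ, applied_forces = NULL) {
  mesh <- state$mesh
  n <- nrow(mesh$vertices)
  f <- tissue_forces(mesh, params)
  if (!is.null(applied_forces)) {
    applied_forces <- as.matrix(applied_forces)
    if (!identical(dim(applied_forces), dim(f)))
      stop("applied_forces must be an n x 2 matrix aligned with the vertex table")
    f <- f + applied_forces
  }
  dt <- integ$dt
  noise <- if (params$sigma > 0)
    matrix(rnorm(2 * n, sd = params$sigma / params$tau * sqrt(dt)), n, 2)
  else matrix(0, n, 2)
  newv <- mesh$vertices + f / params$tau * dt + noise
  dimnames(newv) <- NULL
  if (length(mesh$fixed)) newv[mesh$fixed, 1] <- mesh$vertices[mesh$fixed, 1]
  if (any(!is.finite(newv)))
    stop("integration blow-up: non-finite vertex positions at t=", state$t)
  state$mesh$vertices <- newv
  state$t <- state$t + dt
  state
}

#' Stretch-triggered division bookkeeping
#'
#' Latches \code{T_latch} at the first time a cell's edge elastic energy
#' \eqn{U_i} exceeds \code{U_th}; once the latency has elapsed
#' (\eqn{t > T_i + S_i}), returns the cell as due if \eqn{U_i} is still above
#' threshold (default \code{"latch-and-recheck"}; cells that relaxed below
#' threshold are re-armed) or unconditionally under \code{"latch-and-fire"}.
#'
#' @param state a \code{sim_state}.
#' @param dparams a \code{division_params}.
#' @param b perimeter-contraction coefficient entering \eqn{U_i}.
#' @return List with \code{state} (updated latches) and \code{due}
#'   (indices of cells to divide this step, ascending).
#' @export
strain_division_update <- function(state, dparams, b) {
  stopifnot(inherits(dparams, "division_params"))
  m <- nrow(state$mesh$cells)
  Ui <- vapply(seq_len(m), function(i) edge_elastic_energy(state$mesh, i, b),
               numeric(1))
  tl <- state$cell_state$T_latch
  t <- state$t
  newly <- is.na(tl) & Ui > dparams$U_th
  tl[newly] <- t
  expired <- !is.na(tl) & t > tl + dparams$S_default
  fire <- expired & (dparams$rearm_policy == "latch-and-fire" | Ui > dparams$U_th)
  rearm <- expired & !fire
  tl[rearm] <- NA_real_
  state$cell_state$T_latch <- tl
  list(state = state, due = which(fire))
}

#' Clocked division bookkeeping
#'
#' Under \code{mode = "all"}, returns every cell whose age has reached its
#' period \code{D}. Under \code{mode = "posterior"} only the posterior-most
#' cell (largest centroid x) is eligible, emulating elongation by posterior
#' addition.
#'
#' @param state a \code{sim_state}.
#' @param spec a \code{clock_division_spec}.
#' @return Indices of cells due to divide (ascending).
#' @export
clock_division_update <- function(state, spec) {
  stopifnot(inherits(spec, "clock_division_spec"))
  D <- ifelse(is.na(state$cell_state$D), spec$D, state$cell_state$D)
  due <- which(state$cell_state$age >= D)
  if (spec$mode == "posterior" && length(due)) {
    post <- which.max(.cell_centroids(state$mesh))
    due <- intersect(due, post)
  }
  sort(due)
}

#' Divide one cell at its edge midpoints
#'
#' Inserts two new vertices at the exact midpoints of the cell's apical and
#' basal edges and replaces the parent with two daughter quadrilaterals (the
#' anterior daughter reuses the parent's row; the posterior daughter is
#' appended). No pre-existing vertex moves. Both daughters start with
#' migration force 0, age 0, an unset latch, and inherit the parent's clock
#' period.
#'
#' @param mesh a \code{tissue_mesh}.
#' @param cell_id index of the cell to divide.
#' @param states optional per-cell state data frame (columns v, w, age,
#'   T_latch, D) to update alongside the mesh.
#' @return List with the new \code{mesh} and (if given) updated
#'   \code{states}.
#' @export
divide_cell <- function(mesh, cell_id, states = NULL) {
  p <- .cell_coords(mesh, cell_id)
  ids <- mesh$cells[cell_id, ]
  if (sum((p[2, ] - p[1, ])^2) == 0 || sum((p[4, ] - p[3, ])^2) == 0)
    stop("geometry error: zero-length apical or basal edge in cell ", cell_id)
  mb <- 0.5 * (p[1, ] + p[2, ])
  ma <- 0.5 * (p[3, ] + p[4, ])
  n <- nrow(mesh$vertices)
  mesh$vertices <- rbind(mesh$vertices, rbind(mb, ma, deparse.level = 0),
                         deparse.level = 0)
  dimnames(mesh$vertices) <- NULL
  id_mb <- n + 1L
  id_ma <- n + 2L
  mesh$cells[cell_id, ] <- c(ids[1], id_mb, id_ma, ids[4])
  mesh$cells <- rbind(mesh$cells, c(id_mb, ids[2], ids[3], id_ma),
                      deparse.level = 0)
  mesh$tissue <- c(mesh$tissue, mesh$tissue[cell_id])
  if (is.null(states)) return(list(mesh = mesh, states = NULL))
  daughter <- states[cell_id, , drop = FALSE]
  daughter$v <- 0; daughter$age <- 0; daughter$T_latch <- NA_real_
  states[cell_id, c("v", "age")] <- 0
  states[cell_id, "T_latch"] <- NA_real_
  states <- rbind(states, daughter)
  rownames(states) <- NULL
  list(mesh = mesh, states = states)
}

.frame_label_tissue <- function(frame, frame_names) {
  frame$tissue <- frame_names[frame$tissue]
  frame
}

# Convert one engine frame into a tissue_mesh (fixed ids from the run config).
#' Rebuild a tissue mesh from a recorded trace frame
#'
#' @param trace a \code{sim_trace}.
#' @param k frame index (1-based; \code{length(trace$frames)} is the final
#'   frame).
#' @return A \code{tissue_mesh}.
#' @export
frame_mesh <- function(trace, k) {
  fr <- trace$frames[[k]]
  tissue_mesh(fr$vertices, fr$cells, fixed = trace$fixed,
              tissue = fr$tissue, frames = trace$ecm_frames, validate = FALSE)
}

# Shared driver over the compiled engine.
.run_engine <- function(mesh, params, migration, division, integ, behavior,
                        t_end, record_every, seed, t0 = 0,
                        init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(mesh$cells)
  if (is.null(init))
    init <- list(v = numeric(m), age = numeric(m), T_latch = rep(NA_real_, m),
                 D = rep(NA_real_, m))
  div <- if (is.null(division)) division_params() else division
  mig <- if (is.null(migration)) migration_params(vmax = 0) else migration
  res <- run_engine_cpp(mesh$vertices, mesh$cells, .cell_tissue_index(mesh),
                        seq_len(nrow(mesh$vertices)) %in% mesh$fixed,
                        .tissue_spec(mesh, params, behavior), unclass(params),
                        unclass(mig), unclass(div),
                        integ$dt, t0, t_end, record_every,
                        init$v, init$age, init$T_latch, init$D)
  nm <- names(mesh$frames)
  frames <- lapply(res$frames, .frame_label_tissue, frame_names = nm)
  events <- as.data.frame(res$events)
  events$tissue <- nm[events$tissue]
  structure(list(
    frames = frames, frame_times = res$frame_times,
    energy_series = res$energy_series,
    events = events,
    final = c(res$final, list(tissue_labels = nm[res$final$tissue])),
    fixed = mesh$fixed, ecm_frames = mesh$frames,
    config_echo = list(mech = params, migration = mig, division = div,
                       integrator = integ, behavior = behavior,
                       t_end = t_end, record_every = record_every),
    seed = seed), class = "sim_trace")
}

#' Run a single migrating tissue
#'
#' Time-evolves one cell chain under the full model: graded migration forces
#' (RK4-relaxed, applied at each cell's posterior basal vertex),
#' Euler-Maruyama vertex dynamics on the analytic force field, and
#' stretch-triggered division, interleaved each step. Snapshots are recorded
#' at a fixed cadence and every division event is logged with its time and
#' position.
#'
#' @param mesh a \code{tissue_mesh}; typically from
#'   \code{\link{make_initial_mesh}}.
#' @param params a \code{mechanical_params}.
#' @param migration a \code{migration_params}, or NULL for no migration.
#' @param division a \code{division_params}, or NULL to disable division.
#' @param integ an \code{integrator_spec}.
#' @param t_end end time.
#' @param record_every snapshot cadence (time units).
#' @param seed RNG seed; identical seeds give bit-identical traces.
#' @return A \code{sim_trace}: frames, per-step energy series, division
#'   events, final state, config echo.
#' @export
run_single_tissue <- function(mesh, params = mechanical_params(),
                              migration = migration_params(preset = "graded"),
                              division = division_params(),
                              integ = integrator_spec(),
                              t_end = 100, record_every = 1, seed = NULL) {
  behavior <- stats::setNames(
    rep(list(list(migrate = !is.null(migration) && migration$vmax > 0,
                  strain_div = !is.null(division), clock_mode = 0L)),
        length(mesh$frames)),
    names(mesh$frames))
  .run_engine(mesh, params, migration, division, integ, behavior,
              t_end, record_every, seed)
}

#' @export
print.sim_trace <- function(x, ...) {
  fin <- x$final
  cat("sim_trace: t in [", x$frame_times[1], ",", fin$t, "],",
      length(x$frames), "frames,", nrow(x$events), "division events,",
      nrow(fin$vertices), "vertices /", nrow(fin$cells), "cells at end\n")
  invisible(x)
}
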