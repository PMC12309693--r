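#' Specification of a three-tissue midline assembly
#'
#' Floorplate (FP) above, notochord central, hypochord (HC) below, each a
#' shared-vertex cell chain in its own ECM frame. The notochord starts with
#' twice as many cells as each follower, at half the cell width, so all
#' three tissues have equal initial extent. When \code{tethered}, the
#' posterior basal vertex of the posterior-most FP (resp. HC) cell is merged
#' with the apical (resp. basal) posterior vertex of the posterior-most
#' notochord cell into a single shared vertex.
#'
#' @param n_follower initial FP (and HC) cell count (>= 2).
#' @param tethered bond the posterior ends (default TRUE).
#' @param noto_D notochord clock period.
#' @param noto_clock_mode \code{"posterior"} (one division per period at the
#'   posterior end, steady elongation) or \code{"all"} (every cell ages).
#' @param follower_migration \code{migration_params} shared by FP and HC.
#' @param follower_division \code{division_params} for stretch-triggered
#'   follower division.
#' @param cell_width follower cell width (notochord cells are half as
#'   wide).
#' @param cell_height cell height for all tissues.
#' @return An object of class \code{assembly_spec}.
#' @export
assembly_spec <- function(n_follower = 8, tethered = TRUE, noto_D = 0.8,
                          noto_clock_mode = c("posterior", "all"),
                          follower_migration = migration_params(
                            preset = "graded", vmax = 0.5),
                          follower_division = division_params(),
                          cell_width = 1, cell_height = 1) {
  noto_clock_mode <- match.arg(noto_clock_mode)
  if (n_follower < 2) stop("n_follower must be >= 2")
  structure(list(n_follower = as.integer(n_follower), tethered = tethered,
                 noto_D = noto_D, noto_clock_mode = noto_clock_mode,
                 follower_migration = follower_migration,
                 follower_division = follower_division,
                 cell_width = cell_width, cell_height = cell_height),
            class = "assembly_spec")
}

# Concatenate meshes, offsetting vertex indices.
.combine_meshes <- function(meshes) {
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices),
                              integer(1))))
  vertices <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  cells <- do.call(rbind, lapply(seq_along(meshes), function(k)
    meshes[[k]]$cells + offs[k]))
  fixed <- unlist(lapply(seq_along(meshes), function(k)
    meshes[[k]]$fixed + offs[k]))
  tissue <- unlist(lapply(meshes, `[[`, "tissue"))
  frames <- do.call(c, lapply(meshes, `[[`, "frames"))
  tissue_mesh(vertices, cells, fixed = fixed, tissue = tissue,
              frames = frames)
}

.posterior_cell <- function(mesh, tissue) {
  sel <- which(mesh$tissue == tissue)
  cx <- .cell_centroids(mesh)[sel]
  sel[which.max(cx)]
}

#' Locate the posterior tether bonds of an assembly
#'
#' @param mesh a three-tissue assembly mesh.
#' @return List of two bonds (FP-notochord, HC-notochord), each
#'   \code{list(follower_vertex =, leader_vertex =)}.
#' @export
find_tether_bonds <- function(mesh) {
  fp <- .posterior_cell(mesh, "floorplate")
  hc <- .posterior_cell(mesh, "hypochord")
  nt <- .posterior_cell(mesh, "notochord")
  list(
    # FP basal posterior vertex <-> notochord upper (apical) posterior vertex
    list(follower_vertex = mesh$cells[fp, 2], leader_vertex = mesh$cells[nt, 3]),
    # HC basal posterior vertex <-> notochord lower (basal) posterior vertex
    list(follower_vertex = mesh$cells[hc, 2], leader_vertex = mesh$cells[nt, 2]))
}

#' Merge a tether bond into one shared vertex
#'
#' The two vertices become one (placed at their midpoint): every cell
#' reference to the follower vertex is rewritten to the leader vertex, the
#' orphan row is removed and indices are compacted, so the global vertex
#' count drops by one. Forces on the merged vertex are then automatically
#' the sum of both tissues' energy gradients. Because division inserts
#' daughters at edge midpoints and never moves existing vertices, the merged
#' vertex remains the posterior-most vertex of both chains after posterior
#' divisions -- the bond re-attaches itself. Merging an already-merged bond
#' (identical ids) is a no-op with a warning; unmerging is not supported.
#'
#' @param mesh a \code{tissue_mesh}.
#' @param bond \code{list(follower_vertex =, leader_vertex =)}.
#' @return The merged mesh.
#' @export
merge_tether_vertices <- function(mesh, bond) {
  fv <- bond$follower_vertex
  lv <- bond$leader_vertex
  n <- nrow(mesh$vertices)
  if (fv < 1 || fv > n || lv < 1 || lv > n)
    stop("lookup error: bond vertex out of range")
  if (fv == lv) {
    warning("vertices already merged; no-op")
    return(mesh)
  }
  mesh$vertices[lv, ] <- 0.5 * (mesh$vertices[lv, ] + mesh$vertices[fv, ])
  cells <- mesh$cells
  cells[cells == fv] <- lv
  remap <- function(i) ifelse(i > fv, i - 1L, i)
  mesh$cells <- matrix(remap(cells), nrow = nrow(cells))
  mesh$vertices <- mesh$vertices[-fv, , drop = FALSE]
  mesh$fixed <- remap(setdiff(mesh$fixed, fv))
  validate_mesh(mesh)
  mesh
}

#' Build a three-tissue midline assembly
#'
#' Notochord central (basal line at the bottom of its band), FP above with
#' its basal line at the notochord's apical level, HC mirrored below. All
#' three chains start at the same anterior position with equal extent; each
#' tissue's two anterior-most vertices are x-fixed. With
#' \code{spec$tethered} the two posterior tether bonds are merged.
#'
#' @param spec an \code{assembly_spec}.
#' @param basal_offset distance of basal edges from each basal line (the
#'   ECM position).
#' @return A \code{sim_state} whose mesh covers the three tissues; the
#'   applied bonds (if any) are stored in the \code{bonds} attribute of the
#'   mesh.
#' @export
build_assembly <- function(spec, basal_offset = 0.05) {
  stopifnot(inherits(spec, "assembly_spec"))
  w <- spec$cell_width
  hgt <- spec$cell_height
  gap <- 2 * basal_offset  # clearance between adjacent tissue bands
  noto <- make_initial_mesh(2L * spec$n_follower, cell_width = w / 2,
                            cell_height = hgt,
                            frame = list(basal_y = 0, apical_sign = 1,
                                         V0 = w / 2 * hgt),
                            tissue = "notochord", basal_offset = basal_offset)
  fp_base <- basal_offset + hgt + gap
  fp <- make_initial_mesh(spec$n_follower, cell_width = w, cell_height = hgt,
                          frame = list(basal_y = fp_base, apical_sign = 1,
                                       V0 = w * hgt),
                          tissue = "floorplate", basal_offset = basal_offset)
  hc <- make_initial_mesh(spec$n_follower, cell_width = w, cell_height = hgt,
                          frame = list(basal_y = -gap, apical_sign = -1,
                                       V0 = w * hgt),
                          tissue = "hypochord", basal_offset = basal_offset)
  mesh <- .combine_meshes(list(noto, fp, hc))
  if (spec$tethered) {
    bonds <- find_tether_bonds(mesh)
    # merge one bond at a time; indices shift after each compaction
    mesh <- merge_tether_vertices(mesh, bonds[[1]])
    bonds2 <- find_tether_bonds(mesh)
    mesh <- merge_tether_vertices(mesh, bonds2[[2]])
    attr(mesh, "bonds") <- find_tether_bonds(mesh)
  }
  st <- sim_state(mesh)
  st$cell_state$D <- ifelse(mesh$tissue == "notochord", spec$noto_D, Inf)
  st
}

#' Run a three-tissue assembly
#'
#' Co-evolves the tethered (or untethered) assembly: the notochord elongates
#' by clocked division, the followers by migration plus stretch-triggered
#' division; all tissues share the stochastic vertex dynamics. Division
#' events and per-frame snapshots are recorded as in
#' \code{\link{run_single_tissue}}.
#'
#' @param spec an \code{assembly_spec}.
#' @param t_end end time.
#' @param seed RNG seed.
#' @param params a \code{mechanical_params}.
#' @param integ an \code{integrator_spec}.
#' @param record_every snapshot cadence.
#' @return A \code{sim_trace}.
#' @export
run_assembly <- function(spec, t_end = 60, seed = NULL,
                         params = mechanical_params(),
                         integ = integrator_spec(), record_every = 1) {
  st <- build_assembly(spec)
  mesh <- st$mesh
  clock_mode <- if (spec$noto_clock_mode == "posterior") 2L else 1L
  behavior <- list(
    notochord = list(migrate = FALSE, strain_div = FALSE,
                     clock_mode = clock_mode),
    floorplate = list(migrate = TRUE, strain_div = TRUE, clock_mode = 0L),
    hypochord = list(migrate = TRUE, strain_div = TRUE, clock_mode = 0L))
  init <- list(v = st$cell_state$v, age = st$cell_state$age,
               T_latch = st$cell_state$T_latch, D = st$cell_state$D)
  .run_engine(mesh, params, spec$follower_migration, spec$follower_division,
              integ, behavior, t_end, record_every, seed, init = init)
}

# Canonical migration strength for the single-tissue scenarios.
.single_tissue_vmax <- 2

#' Run a canonical scenario preset
#'
#' Single-tissue presets reproduce the three migration phenotypes at
#' \code{m = 32} initial cells: \code{"posterior_only"} (activity confined
#' to the posterior-most cell; proliferation restricted to the posterior),
#' \code{"uniform"} (all cells maximally active; the anchored anterior
#' end overstretches, producing anterior gap flags), and
#' \code{"graded"} (linear activity gradient; spatially unbiased
#' proliferation). Assembly presets pair graded-migration followers with a
#' fast (\code{"fast_leader"}, clock period D = 0.8) or slow
#' (\code{"slow_leader"}, D = 1.2) notochord, tethered or not.
#'
#' @param name preset id: one of \code{"posterior_only"},
#'   \code{"uniform"}, \code{"graded"}, \code{"fast_leader"},
#'   \code{"slow_leader"}.
#' @param tethered tether the posterior ends (assembly presets only).
#' @param seed RNG seed.
#' @param t_end end time; defaults to 100 for single-tissue presets and 60
#'   for assembly presets.
#' @param overrides named list patching scenario knobs: \code{vmax},
#'   \code{exponent}, \code{eta}, \code{U_th}, \code{S_default},
#'   \code{n_follower}, \code{m}, \code{record_every}.
#' @return List with the \code{trace} and a \code{report} (preset, key
#'   observables).
#' @export
scenario <- function(name = c("posterior_only", "uniform", "graded",
                              "fast_leader", "slow_leader"),
                     tethered = TRUE, seed = 1, t_end = NULL,
                     overrides = list()) {
  name <- match.arg(name)
  ov <- function(key, default) if (!is.null(overrides[[key]])) overrides[[key]] else default
  rec <- ov("record_every", 1)
  if (name %in% c("posterior_only", "uniform", "graded")) {
    preset <- name
    if (is.null(t_end)) t_end <- 100
    mig <- migration_params(eta = ov("eta", 1), vmax = ov("vmax", .single_tissue_vmax),
                            exponent = ov("exponent",
                                          migration_params(preset = preset)$exponent))
    div <- division_params(U_th = ov("U_th", division_params()$U_th),
                           S_default = ov("S_default",
                                          division_params()$S_default))
    mesh <- make_initial_mesh(ov("m", 32), tissue = "floorplate",
                              frame = list(basal_y = 0, apical_sign = 1))
    trace <- run_single_tissue(mesh, migration = mig, division = div,
                               t_end = t_end, record_every = rec, seed = seed)
    final <- trace$frames[[length(trace$frames)]]
    flags <- gap_flag(final, "floorplate")
    report <- list(
      name = name, seed = seed, t_end = t_end,
      n_divisions = nrow(trace$events),
      uniformity = if (nrow(trace$events)) uniformity_statistic(trace$events)
                   else NA_real_,
      posterior_quartile_fraction =
        if (nrow(trace$events)) mean(trace$events$relative_position >= 0.75)
        else NA_real_,
      final_length = tissue_length(final, "floorplate"),
      gap_flags = as.integer(flags),
      gap_flag_positions = attr(flags, "centroid_x"))
  } else {
    if (is.null(t_end)) t_end <- 60
    D <- if (name == "fast_leader") 0.8 else 1.2
    spec <- assembly_spec(
      n_follower = ov("n_follower", 8), tethered = tethered, noto_D = D,
      follower_migration = migration_params(
        eta = ov("eta", 1),
        vmax = ov("vmax", assembly_spec()$follower_migration$vmax),
        exponent = ov("exponent", 1)),
      follower_division = division_params(
        U_th = ov("U_th", division_params()$U_th),
        S_default = ov("S_default", division_params()$S_default)))
    trace <- run_assembly(spec, t_end = t_end, seed = seed,
                          record_every = rec)
    mm <- length_mismatch_series(trace)
    report <- list(
      name = name, seed = seed, t_end = t_end, tethered = tethered,
      noto_D = D,
      n_divisions = nrow(trace$events),
      n_follower_divisions = sum(trace$events$tissue != "notochord"),
      posterior_quartile_follower_divisions =
        sum(trace$events$tissue != "notochord" &
              trace$events$relative_position >= 0.75),
      max_mismatch = max(mm$mismatch),
      final_mismatch = max(mm$mismatch[mm$t == max(mm$t)]))
  }
  list(trace = trace, report = report)
}

#' Sweep the gradient exponent of the graded preset
#'
#' Runs the graded single-tissue scenario over a grid of gradient exponents
#' and seeds and reports the division-position uniformity statistic for each
#' run.
#'
#' @param exponents numeric vector of gradient exponents.
#' @param seeds integer vector of seeds per exponent.
#' @param t_end end time per run.
#' @param ... passed to \code{\link{scenario}} as overrides.
#' @return Data frame with \code{exponent}, \code{seed},
#'   \code{uniformity}, \code{n_divisions}.
#' @export
sweep_alpha <- function(exponents = c(0.85, 1, 1.2, 1.5), seeds = 1:3,
                        t_end = 100, ...) {
  grid <- expand.grid(exponent = exponents, seed = seeds)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    sc <- scenario("graded", seed = grid$seed[k], t_end = t_end,
                   overrides = list(exponent = grid$exponent[k], ...))
    data.frame(exponent = grid$exponent[k], seed = grid$seed[k],
               uniformity = sc$report$uniformity,
               n_divisions = sc$report$n_divisions)
  })
  do.call(rbind, res)
}
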