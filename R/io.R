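# Plain-text serialization. No domain-standard format exists for vertex
# meshes, so the dialect is fixed here and covered by round-trip tests:
#   vertices CSV: id,x,y,fixed      cells CSV: id,v0,v1,v2,v3,tissue
# A JSON document carries the same tables plus the ECM frames in one file.

#' Write a mesh as a pair of CSV tables
#'
#' @param mesh a \code{tissue_mesh}.
#' @param vertices_file,cells_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_mesh_csv <- function(mesh, vertices_file, cells_file) {
  v <- data.frame(id = seq_len(nrow(mesh$vertices)),
                  x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                  fixed = seq_len(nrow(mesh$vertices)) %in% mesh$fixed)
  cl <- data.frame(id = seq_len(nrow(mesh$cells)),
                   v0 = mesh$cells[, 1], v1 = mesh$cells[, 2],
                   v2 = mesh$cells[, 3], v3 = mesh$cells[, 4],
                   tissue = mesh$tissue)
  write.csv(v, vertices_file, row.names = FALSE)
  write.csv(cl, cells_file, row.names = FALSE)
  invisible(c(vertices_file, cells_file))
}

#' Read a mesh from the CSV pair
#'
#' @param vertices_file,cells_file paths written by
#'   \code{\link{write_mesh_csv}}.
#' @param frames ECM frames (not stored in the CSV dialect; supply the ones
#'   the mesh was built with).
#' @return A \code{tissue_mesh}.
#' @export
read_mesh_csv <- function(vertices_file, cells_file, frames) {
  v <- read.csv(vertices_file)
  cl <- read.csv(cells_file)
  tissue_mesh(cbind(v$x, v$y), as.matrix(cl[, c("v0", "v1", "v2", "v3")]),
              fixed = v$id[v$fixed], tissue = cl$tissue, frames = frames)
}

#' Serialize a mesh to a single JSON document
#'
#' @param mesh a \code{tissue_mesh}.
#' @param file output path; if NULL, the JSON string is returned.
#' @return The path (or JSON string), invisibly.
#' @export
write_mesh_json <- function(mesh, file = NULL) {
  doc <- list(vertices = unname(apply(mesh$vertices, 1, as.list)),
              cells = unname(apply(mesh$cells, 1, as.list)),
              fixed = mesh$fixed, tissue = mesh$tissue,
              frames = mesh$frames)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(invisible(js))
  writeLines(js, file)
  invisible(file)
}

#' Read a mesh from its JSON document
#'
#' @param file path written by \code{\link{write_mesh_json}}.
#' @return A \code{tissue_mesh}.
#' @export
read_mesh_json <- function(file) {
  doc <- jsonlite::fromJSON(file, simplifyMatrix = TRUE)
  frames <- lapply(doc$frames, function(fr) lapply(fr, as.numeric))
  tissue_mesh(doc$vertices, doc$cells, fixed = doc$fixed,
              tissue = doc$tissue, frames = frames)
}

#' Write a simulation trace to a directory
#'
#' Emits \code{frames.csv} (long format: frame, t, vertex, x, y),
#' \code{cells.csv} (frame, t, cell, v0..v3, tissue), \code{divisions.csv}
#' (the event log) and \code{summary.json} (config echo, seed, counts,
#' final lengths).
#'
#' @param trace a \code{sim_trace}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_trace <- function(trace, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  frames <- do.call(rbind, lapply(seq_along(trace$frames), function(k) {
    fr <- trace$frames[[k]]
    data.frame(frame = k, t = fr$t, vertex = seq_len(nrow(fr$vertices)),
               x = fr$vertices[, 1], y = fr$vertices[, 2])
  }))
  cells <- do.call(rbind, lapply(seq_along(trace$frames), function(k) {
    fr <- trace$frames[[k]]
    data.frame(frame = k, t = fr$t, cell = seq_len(nrow(fr$cells)),
               v0 = fr$cells[, 1], v1 = fr$cells[, 2], v2 = fr$cells[, 3],
               v3 = fr$cells[, 4], tissue = fr$tissue)
  }))
  write.csv(frames, file.path(dir, "frames.csv"), row.names = FALSE)
  write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(trace$events, file.path(dir, "divisions.csv"), row.names = FALSE)
  final <- trace$frames[[length(trace$frames)]]
  summary <- list(
    seed = trace$seed,
    t_final = final$t,
    n_frames = length(trace$frames),
    n_divisions = nrow(trace$events),
    tissues = lapply(stats::setNames(nm = names(trace$ecm_frames)),
                     function(tn) list(
                       n_cells = sum(final$tissue == tn),
                       length = tissue_length(final, tn))),
    config = list(
      mech = unclass(trace$config_echo$mech),
      migration = unclass(trace$config_echo$migration),
      division = unclass(trace$config_echo$division),
      dt = trace$config_echo$integrator$dt,
      t_end = trace$config_echo$t_end,
      record_every = trace$config_echo$record_every))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Write an intensity profile (or paired profile) as CSV
#'
#' Two columns (\code{position}, \code{value}) for a plain profile, three
#' (\code{position}, \code{value}, \code{reference}) for a paired profile.
#'
#' @param profile an \code{intensity_profile} or \code{paired_profile}.
#' @param file output path.
#' @return Invisibly, the path.
#' @export
write_profile_csv <- function(profile, file) {
  df <- if (inherits(profile, "paired_profile"))
    data.frame(position = profile$signal$positions,
               value = profile$signal$values,
               reference = profile$reference$values)
  else data.frame(position = profile$positions, value = profile$values)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read an intensity profile (or paired profile) from CSV
#'
#' @param file path written by \code{\link{write_profile_csv}}; a
#'   \code{reference} column makes the result a \code{paired_profile}.
#' @return An \code{intensity_profile} or \code{paired_profile}.
#' @export
read_profile_csv <- function(file) {
  df <- read.csv(file)
  if ("reference" %in% names(df))
    paired_profile(df$position, df$value, df$reference)
  else intensity_profile(df$position, df$value)
}
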