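.frame_tissue_xs <- function(frame, tissue) {
  sel <- frame$tissue == tissue
  if (!any(sel)) stop("lookup error: unknown tissue '", tissue, "'")
  ids <- unique(as.vector(frame$cells[sel, , drop = FALSE]))
  frame$vertices[ids, 1]
}

.as_frame <- function(x) {
  if (inherits(x, "tissue_mesh"))
    list(vertices = x$vertices, cells = x$cells, tissue = x$tissue)
  else x
}

#' Anterior-posterior extent of a tissue
#'
#' Posterior-most minus anterior-most vertex x position of the tissue in one
#' snapshot.
#'
#' @param frame a trace frame (element of \code{trace$frames}) or a
#'   \code{tissue_mesh}.
#' @param tissue tissue label.
#' @return Length along the anterior-posterior axis.
#' @export
tissue_length <- function(frame, tissue) {
  xs <- .frame_tissue_xs(.as_frame(frame), tissue)
  max(xs) - min(xs)
}

#' Spatial uniformity of division positions
#'
#' Kolmogorov-Smirnov distance between the empirical distribution of
#' relative division positions (cell centroid normalized by tissue extent at
#' division time, in \code{[0, 1]}) and the uniform distribution on
#' \code{[0, 1]}. 0 means perfectly unbiased proliferation; 1 means all
#' divisions at one end. Depends only on relative positions, so it is
#' invariant to affine rescaling of the axis.
#'
#' @param events division-event data frame (columns \code{t},
#'   \code{relative_position}), e.g. \code{trace$events}.
#' @param t_min discard events at or before this time (e.g. an initial
#'   transient).
#' @return KS distance in \code{[0, 1]}; \code{NA} with a warning when no
#'   events remain.
#' @export
uniformity_statistic <- function(events, t_min = 0) {
  x <- events$relative_position[events$t > t_min]
  n <- length(x)
  if (n == 0) {
    warning("no division events after t_min; uniformity undefined")
    return(NA_real_)
  }
  x <- sort(x)
  i <- seq_len(n)
  max(pmax(i / n - x, x - (i - 1) / n))
}

#' Flag over-stretched (rupture-proxy) cells
#'
#' A shared-vertex chain cannot physically open a gap, so rupture is proxied
#' by basal-edge overextension: cells whose basal edge exceeds
#' \code{rupture_factor} times the initial basal length are flagged.
#'
#' @param frame a trace frame or \code{tissue_mesh}.
#' @param tissue tissue label.
#' @param rupture_factor overextension ratio (> 1), default 3.
#' @param initial_basal basal edge length of a freshly built cell (the
#'   generator's \code{cell_width}), default 1.
#' @return Integer ids (cell rows within the frame) of flagged cells, with
#'   their centroid x positions as the \code{centroid_x} attribute.
#' @export
gap_flag <- function(frame, tissue, rupture_factor = 3, initial_basal = 1) {
  if (rupture_factor <= 1) stop("rupture_factor must exceed 1")
  frame <- .as_frame(frame)
  sel <- which(frame$tissue == tissue)
  if (!length(sel)) stop("lookup error: unknown tissue '", tissue, "'")
  v <- frame$vertices
  c1 <- frame$cells[sel, 1]
  c2 <- frame$cells[sel, 2]
  basal <- sqrt((v[c2, 1] - v[c1, 1])^2 + (v[c2, 2] - v[c1, 2])^2)
  hit <- basal > rupture_factor * initial_basal
  out <- sel[hit]
  attr(out, "centroid_x") <- (v[c1, 1][hit] + v[c2, 1][hit]) / 2
  out
}

#' Relative length mismatch between follower tissues and the leader
#'
#' Per-frame \eqn{|L_{follower} - L_{leader}| / L_{leader}} for each
#' follower tissue in the trace.
#'
#' @param trace a \code{sim_trace} containing the leader and at least one
#'   follower tissue.
#' @param leader leader tissue label (default \code{"notochord"}).
#' @param followers follower tissue labels; defaults to all other tissues in
#'   the trace.
#' @return Data frame with columns \code{t}, \code{tissue},
#'   \code{mismatch}.
#' @export
length_mismatch_series <- function(trace, leader = "notochord",
                                   followers = NULL) {
  tissues <- names(trace$ecm_frames)
  if (!leader %in% tissues) stop("lookup error: leader tissue not in trace")
  if (is.null(followers)) followers <- setdiff(tissues, leader)
  out <- do.call(rbind, lapply(seq_along(trace$frames), function(k) {
    fr <- trace$frames[[k]]
    Ln <- tissue_length(fr, leader)
    if (Ln <= 0) stop("division-by-zero guard: leader length is zero at t=",
                      fr$t)
    data.frame(t = fr$t, tissue = followers,
               mismatch = vapply(followers, function(f)
                 abs(tissue_length(fr, f) - Ln) / Ln, numeric(1)))
  }))
  rownames(out) <- NULL
  out
}

#' Simulated kymograph of cell boundaries
#'
#' Rasterizes the lateral cell-boundary positions (the shared basal vertices
#' of the chain) of one tissue over time: rows are recorded frames, columns
#' are spatial bins over the union extent of the whole trace, and each
#' boundary deposits unit mass split linearly between its two neighboring
#' bins. Constant-velocity motion appears as slanted lines whose slope is
#' recoverable with \code{\link{estimate_kymograph_angle}} +
#' \code{\link{kymograph_velocity}}.
#'
#' @param trace a \code{sim_trace} with at least two frames.
#' @param tissue tissue label.
#' @param n_bins number of spatial bins (default 256).
#' @return Matrix (rows = time, cols = bins) with attributes
#'   \code{space_per_px} (bin width), \code{time_per_row} (median frame
#'   spacing), \code{bin_centers} and \code{times}.
#' @export
export_kymograph <- function(trace, tissue, n_bins = 256) {
  if (length(trace$frames) < 2) stop("need at least 2 frames")
  xs_list <- lapply(trace$frames, function(fr) {
    sel <- fr$tissue == tissue
    if (!any(sel)) stop("lookup error: unknown tissue '", tissue, "'")
    sort(unique(fr$vertices[unique(as.vector(fr$cells[sel, 1:2])), 1]))
  })
  rng <- range(unlist(xs_list))
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  width <- diff(rng) / n_bins
  img <- matrix(0, length(xs_list), n_bins)
  for (r in seq_along(xs_list)) {
    u <- (xs_list[[r]] - rng[1]) / width + 0.5  # bin-center coordinates
    lo <- pmin(pmax(floor(u), 1), n_bins)
    f <- pmin(pmax(u - lo, 0), 1)
    hi <- pmin(lo + 1, n_bins)
    for (j in seq_along(u)) {
      img[r, lo[j]] <- img[r, lo[j]] + (1 - f[j])
      img[r, hi[j]] <- img[r, hi[j]] + f[j]
    }
  }
  structure(img,
            space_per_px = width,
            time_per_row = median(diff(trace$frame_times)),
            bin_centers = rng[1] + (seq_len(n_bins) - 0.5) * width,
            times = trace$frame_times)
}
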