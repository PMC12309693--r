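#' One-dimensional intensity profile
#'
#' Positional fluorescence samples along a drawn line: strictly increasing
#' positions and non-negative intensities.
#'
#' @param positions monotone increasing coordinates (micrometers or pixels).
#' @param values intensities, same length.
#' @return An object of class \code{intensity_profile}.
#' @export
intensity_profile <- function(positions, values) {
  if (length(positions) != length(values))
    stop("positions and values must have equal length")
  if (any(!is.finite(positions)) || any(diff(positions) <= 0))
    stop("positions must be finite and strictly increasing")
  structure(list(positions = as.numeric(positions),
                 values = as.numeric(values)),
            class = "intensity_profile")
}

#' Paired signal/reference profile
#'
#' A signal channel (e.g. an HCR probe) and a reference channel (e.g. a
#' ubiquitously expressed membrane marker) sampled on a shared position
#' grid.
#'
#' @param positions shared position grid.
#' @param signal signal-channel intensities.
#' @param reference reference-channel intensities.
#' @return An object of class \code{paired_profile}.
#' @export
paired_profile <- function(positions, signal, reference) {
  if (length(signal) != length(reference))
    stop("signal and reference must share the position grid")
  structure(list(signal = intensity_profile(positions, signal),
                 reference = intensity_profile(positions, reference)),
            class = "paired_profile")
}

#' Relative Golgi position along the anterior-posterior axis
#'
#' For a cell of apical length \code{L} with the Golgi spanning offsets
#' \code{a} (anterior edge) to \code{b} (posterior edge) from the anterior
#' cell end, the index is \eqn{(a + b) / 2L}: 0 at the anterior extreme, 1 at
#' the posterior extreme, larger meaning a more posterior Golgi.
#'
#' @param L apical surface length (> 0), micrometers.
#' @param a distance from the anterior cell end to the anterior Golgi edge.
#' @param b distance from the anterior cell end to the posterior Golgi edge.
#' @return Index in \code{[0, 1]} (vectorized).
#' @export
golgi_position_index <- function(L, a, b) {
  if (any(!is.finite(L)) || any(L <= 0))
    stop("measurement error: L must be positive")
  if (any(a < 0) || any(a > b) || any(b > L))
    stop("measurement error: need 0 <= a <= b <= L")
  (a + b) / (2 * L)
}

#' Apical/basal signal ratio of a membrane profile
#'
#' Sums the intensities over the first and last \code{fraction} of the
#' profile's arc length (apical end first by convention) and returns
#' apical sum / basal sum.
#'
#' @param profile an \code{intensity_profile} along the membrane, apical end
#'   first.
#' @param fraction fraction of arc length summed at each end, in
#'   \code{(0, 0.5]}.
#' @return Apical/basal ratio.
#' @export
apical_basal_signal_ratio <- function(profile, fraction = 0.30) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  p <- profile$positions
  v <- profile$values
  if (length(p) < 4) stop("need at least 4 samples")
  span <- p[length(p)] - p[1]
  apical_sum <- sum(v[p <= p[1] + fraction * span])
  basal_sum <- sum(v[p >= p[length(p)] - fraction * span])
  if (basal_sum == 0) stop("undefined-ratio error: basal sum is zero")
  apical_sum / basal_sum
}

#' Cell velocity from a kymograph line angle
#'
#' Converts a manually measured line angle into a velocity. The angle is
#' measured from the time axis (rows), so 0 degrees is a stationary
#' (vertical) line: \eqn{v = \tan(\theta) \cdot s_{px} / t_{row}}.
#'
#' @param angle_deg line angle in degrees from the time axis,
#'   \code{|angle| < 90}.
#' @param space_per_px spatial calibration (micrometers/pixel).
#' @param time_per_row temporal calibration (min/row).
#' @return Velocity (micrometers/min), vectorized over angles.
#' @export
kymograph_velocity <- function(angle_deg, space_per_px, time_per_row) {
  if (any(abs(angle_deg) >= 90)) stop("angle must satisfy |angle| < 90")
  if (space_per_px <= 0 || time_per_row <= 0)
    stop("calibration scales must be positive")
  tan(angle_deg * pi / 180) * space_per_px / time_per_row
}

#' Estimate the line angle of a kymograph
#'
#' Fits the per-row intensity centroid against row index (background is
#' suppressed by subtracting each row's median and clamping at zero) and
#' returns the line angle from the time axis, in degrees and in pixel
#' units, suitable for \code{\link{kymograph_velocity}}.
#'
#' @param image kymograph matrix, rows = time, columns = position.
#' @return Angle in degrees from the time axis.
#' @export
estimate_kymograph_angle <- function(image) {
  if (!is.matrix(image) || nrow(image) < 2)
    stop("need a kymograph with at least 2 rows")
  cols <- seq_len(ncol(image))
  centroids <- apply(image, 1, function(row) {
    # suppress the noise floor: keep only pixels well above the row's
    # background level (median + 3 robust SDs)
    w <- pmax(row - median(row) - 3 * stats::mad(row), 0)
    if (sum(w) == 0) return(NA_real_)
    sum(w * cols) / sum(w)
  })
  rows <- seq_len(nrow(image))
  ok <- is.finite(centroids)
  if (sum(ok) < 2) stop("kymograph has no usable rows")
  slope_px_per_row <- unname(stats::coef(stats::lm(centroids[ok] ~ rows[ok]))[2])
  atan(slope_px_per_row) * 180 / pi
}

#' Positive fraction of a manual count
#'
#' E.g. the EdU-positive rate: positives over total.
#'
#' @param n_pos number of positive cells, \code{0 <= n_pos <= n_total}.
#' @param n_total total cells counted (> 0).
#' @return Fraction in \code{[0, 1]}.
#' @export
positive_fraction <- function(n_pos, n_total) {
  if (any(n_total == 0)) stop("undefined-rate error: n_total is zero")
  if (any(n_pos < 0) || any(n_pos > n_total))
    stop("need 0 <= n_pos <= n_total")
  n_pos / n_total
}

#' Nuclear/cytoplasmic intensity ratio
#'
#' @param nuc_mean mean intensity of the nuclear ROI (>= 0).
#' @param cyt_mean mean intensity of the cytoplasmic ROI (> 0).
#' @return Ratio \code{nuc_mean / cyt_mean}, vectorized.
#' @export
nuclear_cytoplasmic_ratio <- function(nuc_mean, cyt_mean) {
  if (any(cyt_mean <= 0)) stop("cytoplasmic mean must be positive")
  if (any(nuc_mean < 0)) stop("nuclear mean must be non-negative")
  nuc_mean / cyt_mean
}

#' Normalize a paired profile into axis bins
#'
#' Implements the depth-corrected gradient readout: (1) a running-minimum
#' filter over the reference channel removes narrow membrane-localized peaks
#' and extracts the baseline; (2) the signal is divided by that baseline
#' pointwise; (3) positions are partitioned into \code{n_bins} equal-width
#' bins along the anterior-posterior axis (half-open intervals, last bin
#' closed); (4) the per-bin mean is taken; (5) all bins are rescaled by the
#' maximum bin so the largest value is exactly 1.
#'
#' @param pp a \code{paired_profile}.
#' @param filter_window running-minimum window (odd, >= 1, in samples);
#'   windows are truncated symmetrically at the profile ends.
#' @param n_bins number of equal-width bins (>= 2).
#' @return Data frame with \code{bin}, \code{center} (bin center position)
#'   and \code{value} (normalized mean, max exactly 1).
#' @export
normalize_paired_profile <- function(pp, filter_window = 11, n_bins = 20) {
  stopifnot(inherits(pp, "paired_profile"))
  if (filter_window < 1 || filter_window %% 2 != 1)
    stop("filter_window must be odd and >= 1")
  if (n_bins < 2) stop("n_bins must be >= 2")
  pos <- pp$signal$positions
  baseline <- zoo::rollapply(zoo::zoo(pp$reference$values), filter_window,
                             min, partial = TRUE, align = "center")
  baseline <- as.numeric(baseline)
  if (any(baseline <= 0))
    stop("normalization error: non-positive baseline after filtering")
  norm <- pp$signal$values / baseline
  breaks <- seq(min(pos), max(pos), length.out = n_bins + 1)
  idx <- findInterval(pos, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  if (any(counts == 0)) stop("bin-coverage error: empty bin")
  means <- vapply(seq_len(n_bins), function(k) mean(norm[idx == k]), numeric(1))
  mx <- max(means)
  if (mx <= 0) stop("normalization error: non-positive bin maximum")
  data.frame(bin = seq_len(n_bins),
             center = 0.5 * (breaks[-1] + breaks[-(n_bins + 1)]),
             value = means / mx)
}
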