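#' Build an initial chain mesh
#'
#' Chain of \code{m} identical axis-aligned quadrilateral cells with shared
#' vertices: \code{m + 1} basal and \code{m + 1} apical vertices, so a fresh
#' chain has \code{2 (m + 1)} vertices. The basal edge sits at distance
#' \code{basal_offset} from the frame's basal reference line (the ECM
#' position), and the x coordinates of the two anterior-most vertices are
#' fixed.
#'
#' @param m number of cells (>= 1).
#' @param cell_width,cell_height cell dimensions (model units, > 0).
#' @param frame ECM frame: \code{list(basal_y =, apical_sign =, V0 =)}
#'   (\code{V0} optional per-tissue target area).
#' @param tissue tissue label.
#' @param basal_offset distance of the basal edge from the basal reference
#'   line; defaults to the default ECM position \code{h}.
#' @param x0 anterior end position.
#' @return A \code{tissue_mesh}.
#' @export
make_initial_mesh <- function(m, cell_width = 1, cell_height = 1,
                              frame = list(basal_y = 0, apical_sign = 1),
                              tissue = "tissue", basal_offset = 0.05, x0 = 0) {
  if (!is.finite(m) || m < 1) stop("m must be >= 1")
  if (cell_width <= 0 || cell_height <= 0)
    stop("cell dimensions must be positive")
  m <- as.integer(m)
  xs <- x0 + cell_width * (0:m)
  s <- frame$apical_sign
  yb <- frame$basal_y + s * basal_offset
  ya <- frame$basal_y + s * (basal_offset + cell_height)
  vertices <- rbind(cbind(xs, yb), cbind(xs, ya))
  b <- seq_len(m + 1)          # basal vertex ids
  a <- m + 1 + seq_len(m + 1)  # apical vertex ids
  cells <- cbind(b[1:m], b[2:(m + 1)], a[2:(m + 1)], a[1:m])
  fr <- stats::setNames(list(frame), tissue)
  tissue_mesh(vertices, cells, fixed = c(b[1], a[1]),
              tissue = rep(tissue, m), frames = fr)
}

#' Synthetic kymograph with known front velocity
#'
#' Position-time raster containing one bright line of slope
#' \code{velocity}: at row \eqn{r} (time \eqn{r \cdot} \code{time_per_row})
#' the line sits at \eqn{x_0 + v t}, rendered as a narrow Gaussian stripe
#' plus i.i.d. Gaussian pixel noise. The generating velocity is returned
#' alongside so estimators can be closed-loop tested.
#'
#' @param velocity front velocity (micrometers/min).
#' @param duration total time (min, > 0).
#' @param noise_sd pixel noise standard deviation (intensity units; stripe
#'   peak is 1).
#' @param seed RNG seed (same seed, same image).
#' @param space_per_px spatial calibration (micrometers/pixel).
#' @param time_per_row temporal calibration (min/row).
#' @param n_px raster width in pixels.
#' @param stripe_sd stripe width (pixels).
#' @return List: \code{image} (rows = time, cols = position), \code{velocity}
#'   (ground truth), \code{space_per_px}, \code{time_per_row}.
#' @export
make_kymograph <- function(velocity, duration, noise_sd = 0.05, seed = 1,
                           space_per_px = 1, time_per_row = 1,
                           n_px = 256, stripe_sd = 1.5) {
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  set.seed(seed)
  times <- seq(0, duration, by = time_per_row)
  n_rows <- length(times)
  # start the line so it stays inside the raster
  x_start <- if (velocity >= 0) 0.15 * n_px * space_per_px
             else 0.85 * n_px * space_per_px
  img <- matrix(0, n_rows, n_px)
  px <- (seq_len(n_px) - 0.5) * space_per_px
  for (r in seq_len(n_rows)) {
    center <- x_start + velocity * times[r]
    img[r, ] <- exp(-(px - center)^2 / (2 * (stripe_sd * space_per_px)^2))
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(length(img), sd = noise_sd),
                                        n_rows, n_px)
  list(image = img, velocity = velocity,
       space_per_px = space_per_px, time_per_row = time_per_row)
}

#' Synthetic paired HCR/reference profile with known gradient
#'
#' Emulates a two-channel intensity profile along the anterior-posterior
#' axis: the signal channel is a power-law gradient
#' \eqn{s^{\gamma}} (anterior \eqn{s = 0} to posterior \eqn{s = 1})
#' multiplied by a shared depth-dependent exponential baseline; the reference
#' channel is the same baseline plus narrow membrane-localized peaks. The
#' generating gradient is returned for recovery tests of
#' \code{\link{normalize_paired_profile}}.
#'
#' @param gradient_exponent gradient shape \eqn{\gamma} (0 = flat).
#' @param baseline_decay exponential decay rate of the shared baseline per
#'   unit position.
#' @param peak_density expected membrane peaks per unit position.
#' @param noise_sd additive Gaussian noise sd (both channels).
#' @param seed RNG seed.
#' @param n number of samples.
#' @param length_ap profile length (position units).
#' @param peak_width peak half-width in samples (must stay below the
#'   baseline filter window).
#' @return List: \code{profile} (a \code{paired_profile}),
#'   \code{gradient} (ground-truth gradient at the sample positions),
#'   \code{baseline}.
#' @export
make_paired_profile <- function(gradient_exponent = 1, baseline_decay = 0.005,
                                peak_density = 0.05, noise_sd = 0,
                                seed = 1, n = 400, length_ap = 200,
                                peak_width = 1) {
  set.seed(seed)
  pos <- seq(0, length_ap, length.out = n)
  s <- pos / length_ap
  gradient <- s^gradient_exponent
  baseline <- 100 * exp(-baseline_decay * pos)
  signal <- gradient * baseline
  reference <- baseline
  n_peaks <- rbinom(1, n, min(1, peak_density * length_ap / n))
  if (n_peaks > 0) {
    centers <- sample(seq_len(n), n_peaks)
    for (ct in centers) {
      idx <- max(1, ct - peak_width):min(n, ct + peak_width)
      reference[idx] <- reference[idx] + 2.5 * baseline[idx]
    }
  }
  if (noise_sd > 0) {
    signal <- signal + rnorm(n, sd = noise_sd)
    reference <- reference + rnorm(n, sd = noise_sd)
  }
  list(profile = paired_profile(pos, signal, reference),
       gradient = gradient, baseline = baseline)
}

#' Synthetic ROI measurement table with known ground truth
#'
#' Per-cell nuclear and cytoplasmic mean intensities drawn around a stated
#' nuclear/cytoplasmic ratio, plus Bernoulli EdU calls at a stated positive
#' rate.
#'
#' @param n_cells number of cells.
#' @param true_nc_ratio generating nuclear/cytoplasmic ratio.
#' @param true_edu_rate generating EdU-positive rate, in \code{[0, 1]}.
#' @param noise_sd multiplicative noise sd on intensities (0 = exact).
#' @param seed RNG seed.
#' @return List: \code{table} (data frame with columns \code{cell},
#'   \code{nuc_mean}, \code{cyt_mean}, \code{edu_positive}) and
#'   \code{truth}.
#' @export
make_roi_table <- function(n_cells, true_nc_ratio = 1.5, true_edu_rate = 0.3,
                           noise_sd = 0, seed = 1) {
  if (true_edu_rate < 0 || true_edu_rate > 1)
    stop("true_edu_rate must be in [0, 1]")
  set.seed(seed)
  cyt <- 100 * exp(if (noise_sd > 0) rnorm(n_cells, sd = noise_sd) else 0)
  nuc <- cyt * true_nc_ratio *
    exp(if (noise_sd > 0) rnorm(n_cells, sd = noise_sd) else 0)
  edu <- rbinom(n_cells, 1, true_edu_rate)
  list(table = data.frame(cell = seq_len(n_cells), nuc_mean = nuc,
                          cyt_mean = cyt, edu_positive = edu),
       truth = list(nc_ratio = true_nc_ratio, edu_rate = true_edu_rate))
}
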