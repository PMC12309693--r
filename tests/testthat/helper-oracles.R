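# Shared oracles and fixture builders.

# Central finite-difference gradient of tissue_energy; the independent
# oracle for the analytic force field.
fd_forces <- function(mesh, params, eps = 1e-5) {
  g <- mesh$vertices * 0
  for (j in seq_len(nrow(mesh$vertices))) {
    for (k in 1:2) {
      m1 <- mesh; m1$vertices[j, k] <- m1$vertices[j, k] + eps
      m2 <- mesh; m2$vertices[j, k] <- m2$vertices[j, k] - eps
      g[j, k] <- -(tissue_energy(m1, params) - tissue_energy(m2, params)) /
        (2 * eps)
    }
  }
  g
}

# Randomly jittered cell chain: valid but away from equilibrium.
random_chain_mesh <- function(n_cells, jitter = 0.12, tissue = "tissue",
                              apical_sign = 1) {
  mesh <- make_initial_mesh(n_cells, tissue = tissue,
                            frame = list(basal_y = 0,
                                         apical_sign = apical_sign))
  mesh$vertices <- mesh$vertices +
    matrix(runif(length(mesh$vertices), -jitter, jitter),
           ncol = 2)
  validate_mesh(mesh)
  mesh
}

# First time any flagged cell sits in the anterior half of the tissue.
first_anterior_flag_time <- function(trace, tissue, anterior_fraction = 0.5) {
  for (k in seq_along(trace$frames)) {
    fr <- trace$frames[[k]]
    fl <- gap_flag(fr, tissue)
    if (length(fl)) {
      ext <- range(.frame_xs_helper(fr, tissue))
      rel <- (attr(fl, "centroid_x") - ext[1]) / diff(ext)
      if (any(rel <= anterior_fraction)) return(fr$t)
    }
  }
  Inf
}

.frame_xs_helper <- function(fr, tissue) {
  sel <- fr$tissue == tissue
  fr$vertices[unique(as.vector(fr$cells[sel, , drop = FALSE])), 1]
}

# Brute-force running minimum (independent of zoo), truncated at the ends.
brute_running_min <- function(x, window) {
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    min(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

# Empirical KS distance against U(0,1) by direct ECDF comparison.
brute_ks_uniform <- function(x) {
  x <- sort(x)
  n <- length(x)
  max(pmax(seq_len(n) / n - x, x - (seq_len(n) - 1) / n))
}

# Richardson estimate of a value jump at a breakpoint: for a piecewise-smooth
# function, d(e) = f(x+e) - f(x-e) = J + 2 e f' + O(e^2); the combination
# d(e) - 2 d(e/2) cancels the slope term and leaves -J + O(e^2).
numeric_jump <- function(fun, x, e = 1e-7) {
  d1 <- fun(x + e) - fun(x - e)
  d2 <- fun(x + e / 2) - fun(x - e / 2)
  abs(d1 - 2 * d2)
}

# One-sided derivative mismatch across a breakpoint.
derivative_jump <- function(fun, x, e = 1e-6) {
  left <- (fun(x - e) - fun(x - 2 * e)) / e
  right <- (fun(x + 2 * e) - fun(x + e)) / e
  abs(left - right)
}
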