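#' Mechanical parameters of the vertex model
#'
#' Coefficients of the tissue energy
#' \deqn{U = \frac{a}{2}\sum_i (V_i - V_0)^2 + \frac{b}{2}\sum_i L_i^2 +
#'       c \sum_i \sum_{r_j \in B_i} f(|r_j - p_j|) +
#'       d \sum_i \sum_{r_j \in A_i} g(|r_j - p_j|)}
#' where \eqn{V_i} is the area of cell \eqn{i}, \eqn{L_i} its perimeter,
#' \eqn{B_i}/\eqn{A_i} its basal/apical vertex pairs and \eqn{|r_j - p_j|} the
#' basoapical distance of a vertex from the tissue's basal reference line.
#' The basal adhesion well \eqn{f} has its minimum at distance \code{h} (the
#' ECM position) and vanishes beyond the cutoff \code{h_th}; the apical
#' repulsion \eqn{g} switches on beyond the confinement distance \code{ell}.
#'
#' The defaults of \code{a} and \code{b} are a joint calibration: for a
#' square cell of side \eqn{s}, stationarity of the area + perimeter terms
#' gives a rest shape \eqn{s^2 = V_0 - 8b/a}, so \eqn{8b < aV_0} is required
#' for a stable rest cell at all, and \eqn{8b/a \ll V_0} keeps the rest area
#' near the target. The area stiffness also sets how fast a freshly divided
#' daughter re-expands toward \eqn{V_0}, which must outpace the notochord
#' division clock for elongation to be clock-limited rather than
#' growth-limited.
#'
#' @param a area-conservation stiffness.
#' @param b perimeter-contraction coefficient (also scales the edge elastic
#'   energy that triggers stretch-induced division).
#' @param c basal-adhesion strength.
#' @param d apical-repulsion strength.
#' @param V0 target cell area.
#' @param h ECM position: distance of the adhesion minimum from the basal
#'   reference line.
#' @param h_th adhesion cutoff distance (must exceed \code{h}).
#' @param ell apical confinement distance.
#' @param tau viscosity (drag) coefficient of the overdamped vertex dynamics.
#' @param sigma amplitude of the white noise acting on vertices.
#' @return An object of class \code{mechanical_params}.
#' @export
mechanical_params <- function(a = 5, b = 0.02, c = 5, d = 5, V0 = 1,
                              h = 0.05, h_th = 0.5, ell = 1.2,
                              tau = 1, sigma = 0.01) {
  vals <- c(a = a, b = b, c = c, d = d, tau = tau, sigma = sigma)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("a, b, c, d, tau and sigma must be finite and non-negative")
  if (!is.finite(V0) || V0 <= 0) stop("V0 must be positive")
  if (!is.finite(h) || !is.finite(h_th) || h < 0 || h >= h_th)
    stop("parameter error: need 0 <= h < h_th")
  if (!is.finite(ell) || ell <= 0) stop("parameter error: ell must be positive")
  structure(list(a = a, b = b, c = c, d = d, V0 = V0, h = h, h_th = h_th,
                 ell = ell, tau = tau, sigma = sigma),
            class = "mechanical_params")
}

#' Migration-force parameters
#'
#' The migration force \eqn{v_i} of cell \eqn{i} relaxes toward the activity
#' \eqn{w_i} with time constant \code{eta}:
#' \eqn{\eta\, dv_i/dt = -v_i + w_i(t)}. The activity is graded along the
#' anterior-posterior axis,
#' \eqn{w_i = v_{max} ((x_i - x_{min})/(x_{max} - x_{min}))^\alpha},
#' with \eqn{x_i} the cell-centroid position and \eqn{\alpha =}
#' \code{exponent} controlling the gradient shape. Presets are named by the
#' migration phenotype they produce: \code{"posterior_only"} (large exponent,
#' activity confined to the posterior-most cells), \code{"uniform"} (exponent
#' near zero, all cells at \eqn{v_{max}}), and \code{"graded"} (exponent 1, a
#' linear gradient).
#'
#' @param eta relaxation time constant (> 0).
#' @param vmax maximum migration force.
#' @param exponent gradient-shape exponent \eqn{\alpha > 0}; ignored when a
#'   non-custom \code{preset} is given.
#' @param preset one of \code{"custom"}, \code{"posterior_only"},
#'   \code{"uniform"}, \code{"graded"}.
#' @return An object of class \code{migration_params}.
#' @export
migration_params <- function(eta = 1, vmax = 2, exponent = 1,
                             preset = c("custom", "posterior_only",
                                        "uniform", "graded")) {
  preset <- match.arg(preset)
  exponent <- switch(preset,
    posterior_only = 100,
    uniform = 0.01,
    graded = 1,
    custom = exponent)
  if (!is.finite(eta) || eta <= 0) stop("eta must be positive")
  if (!is.finite(vmax) || vmax < 0) stop("vmax must be non-negative")
  if (!is.finite(exponent) || exponent <= 0) stop("exponent must be positive")
  structure(list(eta = eta, vmax = vmax, exponent = exponent, preset = preset),
            class = "migration_params")
}

#' Stretch-triggered division parameters
#'
#' A cell's edge elastic energy is \eqn{U_i = b(L_{i,apical}^2 +
#' L_{i,basal}^2)/2}. When \eqn{U_i} first exceeds the threshold \code{U_th}
#' at time \eqn{T_i}, the cell latches; once the latency \code{S_default} has
#' elapsed (\eqn{t > T_i + S_i}) the cell divides at the midpoints of its
#' apical and basal edges. Under the default \code{"latch-and-recheck"}
#' policy a cell whose \eqn{U_i} has relaxed back below threshold by the time
#' the latency expires does not divide (and may latch again later);
#' \code{"latch-and-fire"} divides regardless.
#'
#' @param U_th elastic-energy threshold (> 0).
#' @param S_default latency between latching and division.
#' @param rearm_policy \code{"latch-and-recheck"} or \code{"latch-and-fire"}.
#' @return An object of class \code{division_params}.
#' @export
division_params <- function(U_th = 0.15, S_default = 0.05,
                            rearm_policy = c("latch-and-recheck",
                                             "latch-and-fire")) {
  rearm_policy <- match.arg(rearm_policy)
  if (!is.finite(U_th) || U_th <= 0) stop("U_th must be positive")
  if (!is.finite(S_default) || S_default < 0) stop("S_default must be >= 0")
  structure(list(U_th = U_th, S_default = S_default,
                 rearm_policy = rearm_policy),
            class = "division_params")
}

#' Clocked-division specification (notochord)
#'
#' @param D division period per cell (> 0); cells divide when their age
#'   reaches \code{D} and both daughters restart at age 0 inheriting \code{D}.
#' @param mode \code{"all"}: every cell ages and divides (the literal
#'   per-cell rule, suitable for short horizons); \code{"posterior"}: only
#'   the posterior-most cell of the tissue divides, one division per period
#'   \code{D} -- this emulates elongation by posterior addition from the
#'   chordoneural hinge and yields steady leader growth at long horizons.
#' @return An object of class \code{clock_division_spec}.
#' @export
clock_division_spec <- function(D = 0.8, mode = c("posterior", "all")) {
  mode <- match.arg(mode)
  if (!is.finite(D) || D <= 0) stop("D must be positive")
  structure(list(D = D, mode = mode), class = "clock_division_spec")
}

#' Integrator specification
#'
#' Vertex positions follow \eqn{\tau\, dr_j/dt = F_j + \sigma \xi(t)},
#' integrated by Euler-Maruyama with increments
#' \eqn{(F_j/\tau)\,dt + (\sigma/\tau)\sqrt{dt}\, N(0,1)} per free
#' coordinate; migration forces are integrated by classical RK4.
#'
#' @param dt time step.
#' @param seed optional RNG seed applied before a run; identical seeds give
#'   bit-identical trajectories.
#' @return An object of class \code{integrator_spec}.
#' @export
integrator_spec <- function(dt = 0.001, seed = NULL) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  structure(list(dt = dt, seed = seed,
                 noise_convention = "sqrt(dt)-scaled Gaussian increments"),
            class = "integrator_spec")
}
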