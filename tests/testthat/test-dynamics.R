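test_that("migration activity implements the graded power law", {
  mp <- function(al) migration_params(vmax = 1, exponent = al)
  expect_equal(migration_activity(c(0, 1, 2), mp(1)), c(0, 0.5, 1))
  expect_equal(migration_activity(c(0, 1, 2), mp(2)), c(0, 0.25, 1))
  # degenerate range: every cell at vmax by documented convention
  expect_equal(migration_activity(3, mp(1)), 1)
  expect_equal(migration_activity(c(2, 2, 2), mp(5)), c(1, 1, 1))
  expect_error(migration_activity(numeric(0), mp(1)), "input error")
  # monotone non-decreasing in centroid x for any exponent
  xs <- sort(runif(20))
  for (al in c(0.01, 0.5, 1, 3, 100))
    expect_true(all(diff(migration_activity(xs, mp(al))) >= 0))
})

test_that("phenotype presets map onto the printed formula", {
  # as printed, s^alpha with small alpha is ~1 everywhere (uniform activity)
  # and with large alpha is ~0 except at the posterior-most cell
  u <- migration_activity(0:4, migration_params(vmax = 1, preset = "uniform"))
  p <- migration_activity(0:4, migration_params(vmax = 1, preset = "posterior_only"))
  expect_true(all(u[-1] > 0.95))
  expect_true(all(p[2:4] < 1e-10) && p[5] == 1)
})

test_that("RK4 migration-force relaxation matches the closed form", {
  mesh <- make_initial_mesh(1)
  st <- sim_state(mesh)
  mp <- migration_params(eta = 1, vmax = 1, exponent = 1)
  # single cell => degenerate gradient => w = vmax = 1 throughout
  dt <- 0.001
  for (i in 1:1000) st <- advance_migration_forces(st, mp, dt)
  expect_lt(abs(st$cell_state$v[1] - (1 - exp(-1))), 1e-6)

  # halving dt changes the t = 1 value below the RK4 convergence floor
  st2 <- sim_state(mesh)
  for (i in 1:2000) st2 <- advance_migration_forces(st2, mp, dt / 2)
  expect_lt(abs(st2$cell_state$v[1] - st$cell_state$v[1]), 1e-8)

  # fixed point: w = 0, v = 0 stays 0
  st0 <- sim_state(mesh)
  st0$cell_state$v <- 0
  mp0 <- migration_params(eta = 1, vmax = 0)
  st0 <- advance_migration_forces(st0, mp0, dt)
  expect_identical(st0$cell_state$v, 0)
})

test_that("Euler-Maruyama step honours drift, masking and noise off", {
  mesh <- make_initial_mesh(2)
  p0 <- mechanical_params(a = 0, b = 0, c = 0, d = 0, sigma = 0)
  st <- sim_state(mesh)
  integ <- integrator_spec(dt = 0.001)
  st1 <- advance_vertices(st, p0, integ)
  expect_identical(st1$mesh$vertices, mesh$vertices)

  # constant applied force (tau, 0) on one free vertex moves x by exactly dt
  ap <- mesh$vertices * 0
  free_v <- setdiff(seq_len(nrow(mesh$vertices)), mesh$fixed)[1]
  ap[free_v, 1] <- p0$tau
  st2 <- advance_vertices(st, p0, integ, applied_forces = ap)
  expect_equal(st2$mesh$vertices[free_v, 1] - mesh$vertices[free_v, 1], 0.001)

  # fixed vertices never move in x, even when pushed
  ap2 <- mesh$vertices * 0
  ap2[mesh$fixed, 1] <- 100
  st3 <- advance_vertices(st, p0, integ, applied_forces = ap2)
  expect_identical(st3$mesh$vertices[mesh$fixed, 1], mesh$vertices[mesh$fixed, 1])
})

test_that("driftless displacement variance follows (sigma/tau)^2 t", {
  # zero all mechanics so vertices are independent Brownian walkers; pool
  # free coordinates of a long chain across replicate runs
  p <- mechanical_params(a = 0, b = 0, c = 0, d = 0, sigma = 0.2, tau = 2)
  t_end <- 0.05
  mesh <- make_initial_mesh(300)
  disp <- c()
  set.seed(99)
  for (rep in 1:9) {
    tr <- run_single_tissue(mesh, params = p, migration = NULL,
                            division = NULL,
                            integ = integrator_spec(dt = 0.001),
                            t_end = t_end, record_every = t_end)
    fin <- tr$frames[[length(tr$frames)]]
    d <- fin$vertices - mesh$vertices
    free <- setdiff(seq_len(nrow(mesh$vertices)), mesh$fixed)
    disp <- c(disp, d[free, 1], d[, 2])
  }
  n <- length(disp)
  expect_gt(n, 1e4)
  v_hat <- mean(disp^2)
  v_true <- (p$sigma / p$tau)^2 * t_end
  se <- v_true * sqrt(2 / n)
  expect_lt(abs(v_hat - v_true), 3 * se)
})

test_that("strain-triggered division latches, waits and rechecks", {
  b <- 0.02
  dp <- division_params(U_th = 0.15, S_default = 0.5)
  # scripted U_i trajectory: stretch the basal+apical edges of cell 1 by
  # moving its posterior lateral edge, then relax it again
  base <- make_initial_mesh(2)
  stretch <- function(mesh, len) {
    # widen cell 1 to basal/apical length `len` without moving cell 2's far edge
    mesh$vertices[2, 1] <- len
    mesh$vertices[5, 1] <- len
    mesh
  }
  st <- sim_state(base)
  st$t <- 2
  st$mesh <- stretch(st$mesh, 3)   # U_1 = 0.02 * 9 = 0.18 > U_th, latch at t=2
  r <- strain_division_update(st, dp, b)
  expect_length(r$due, 0)
  expect_equal(r$state$cell_state$T_latch[1], 2)
  expect_true(is.na(r$state$cell_state$T_latch[2]))

  # latency not yet elapsed at t = 2.4
  r$state$t <- 2.4
  r2 <- strain_division_update(r$state, dp, b)
  expect_length(r2$due, 0)

  # first step past t = 2.5 with U_i still high: cell divides
  r2$state$t <- 2.6
  r3 <- strain_division_update(r2$state, dp, b)
  expect_equal(r3$due, 1L)

  # relaxed below threshold before expiry: recheck policy spares it, re-arms
  st_relax <- r$state
  st_relax$t <- 2.6
  st_relax$mesh <- stretch(st_relax$mesh, 1)
  r4 <- strain_division_update(st_relax, dp, b)
  expect_length(r4$due, 0)
  expect_true(is.na(r4$state$cell_state$T_latch[1]))

  # latch-and-fire divides regardless of relaxation
  dp_fire <- division_params(U_th = 0.15, S_default = 0.5,
                             rearm_policy = "latch-and-fire")
  st_relax2 <- r$state
  st_relax2$t <- 2.6
  st_relax2$mesh <- stretch(st_relax2$mesh, 1)
  r5 <- strain_division_update(st_relax2, dp_fire, b)
  expect_equal(r5$due, 1L)
})

test_that("clocked division fires on age under both modes", {
  mesh <- make_initial_mesh(3)
  st <- sim_state(mesh, D = 0.8)
  st$cell_state$age <- c(0.81, 0.5, 0.9)
  spec_all <- clock_division_spec(D = 0.8, mode = "all")
  expect_equal(clock_division_update(st, spec_all), c(1L, 3L))
  # posterior mode: only the posterior-most cell (cell 3) is eligible
  spec_post <- clock_division_spec(D = 0.8, mode = "posterior")
  expect_equal(clock_division_update(st, spec_post), 3L)
  # run shorter than the period: no divisions
  st$cell_state$age <- rep(0.5, 3)
  expect_length(clock_division_update(st, spec_all), 0)
})

test_that("division inserts exact midpoints and preserves the neighborhood", {
  mesh <- make_initial_mesh(3)
  states <- sim_state(mesh)$cell_state
  states$v <- c(0.3, 0.7, 0.1)
  a_parent <- cell_area(mesh, 2)
  v_before <- mesh$vertices
  r <- divide_cell(mesh, 2, states)
  expect_equal(nrow(r$mesh$cells), 4)
  expect_equal(nrow(r$mesh$vertices), nrow(v_before) + 2)
  # no pre-existing vertex moved (bit-identical)
  expect_identical(r$mesh$vertices[seq_len(nrow(v_before)), ], v_before)
  # new vertices at the exact edge midpoints
  p <- v_before[mesh$cells[2, ], ]
  expect_identical(r$mesh$vertices[nrow(v_before) + 1, ],
                   (p[1, ] + p[2, ]) / 2)
  expect_identical(r$mesh$vertices[nrow(v_before) + 2, ],
                   (p[3, ] + p[4, ]) / 2)
  # daughters' areas sum to the parent's
  expect_equal(cell_area(r$mesh, 2) + cell_area(r$mesh, 4), a_parent,
               tolerance = 1e-12)
  expect_equal(cell_area(r$mesh, 2), a_parent / 2, tolerance = 1e-12)
  # neighbors untouched, daughters reset
  expect_identical(r$states$v[c(1, 3)], c(0.3, 0.1))
  expect_identical(r$states$v[c(2, 4)], c(0, 0))
  expect_true(all(is.na(r$states$T_latch[c(2, 4)])))
  # degenerate edge refuses to divide
  bad <- mesh
  bad$vertices[2, ] <- bad$vertices[1, ]
  expect_error(divide_cell(bad, 1), "geometry error")
})

test_that("single-tissue runs are deterministic and obey the chain census", {
  mesh <- make_initial_mesh(32)
  expect_equal(nrow(mesh$vertices), 66)  # (m + 1) * 2 shared-vertex chain
  tr1 <- run_single_tissue(make_initial_mesh(8), t_end = 1, seed = 123)
  tr2 <- run_single_tissue(make_initial_mesh(8), t_end = 1, seed = 123)
  expect_identical(tr1$frames, tr2$frames)
  expect_identical(tr1$events, tr2$events)

  # quiescent run: no migration, no noise, no divisions -> no events and
  # energy only decreases
  p <- mechanical_params(sigma = 0)
  trq <- run_single_tissue(make_initial_mesh(6), params = p,
                           migration = NULL, division = NULL,
                           t_end = 5)
  expect_equal(nrow(trq$events), 0)
  expect_true(all(diff(trq$energy_series) <= 1e-10))
})
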