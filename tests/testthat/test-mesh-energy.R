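test_that("cell area and perimeter match hand-derived values", {
  sq <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                    matrix(1:4, 1))
  expect_equal(cell_area(sq, 1), 1)
  expect_equal(cell_perimeter(sq, 1), 4)

  rect <- tissue_mesh(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)),
                      matrix(1:4, 1))
  expect_equal(cell_perimeter(rect, 1), 6)

  # parallelogram, shoelace and edge lengths evaluated by hand
  par <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(1.5, 1), c(0.5, 1)),
                     matrix(1:4, 1))
  expect_equal(cell_area(par, 1), 1)
  expect_equal(cell_perimeter(par, 1), 2 + 2 * sqrt(1.25))
})

test_that("degenerate and invalid cells raise geometry/lookup errors", {
  collinear <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0)),
                           matrix(1:4, 1), validate = FALSE)
  expect_error(cell_area(collinear, 1), "geometry error")
  bowtie <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                        matrix(1:4, 1), validate = FALSE)
  expect_error(cell_area(bowtie, 1), "self-intersecting")
  ok <- make_initial_mesh(2)
  expect_error(cell_area(ok, 99), "lookup error")
  expect_error(cell_perimeter(ok, 0), "lookup error")
})

test_that("area and perimeter are invariant under cyclic index rotation", {
  base <- rbind(c(0, 0), c(1.1, -0.05), c(1.2, 0.9), c(-0.1, 1))
  ref <- tissue_mesh(base, matrix(1:4, 1))
  a0 <- cell_area(ref, 1)
  p0 <- cell_perimeter(ref, 1)
  for (r in 1:3) {
    rot <- tissue_mesh(base, matrix(c(1:4, 1:4)[(r + 1):(r + 4)], 1),
                       validate = FALSE)
    expect_equal(cell_area(rot, 1), a0)
    expect_equal(cell_perimeter(rot, 1), p0)
  }
})

test_that("basal potential f matches its printed piecewise form", {
  # minimum at x = h, depth -(h_th - h)^2 / 4
  expect_equal(basal_potential_f(1, 1, 2), -0.25)
  # both branches agree at the midpoint breakpoint
  expect_equal(basal_potential_f(1.5, 1, 2), -0.125)
  expect_equal(-0.5 * (1.5 - 2)^2, -0.125)
  # zero beyond the cutoff
  expect_equal(basal_potential_f(2.7, 1, 2), 0)
  expect_error(basal_potential_f(1, 2, 2), "parameter error")
})

test_that("apical potential g is zero below ell and quadratic beyond", {
  expect_equal(apical_potential_g(0.5, 1), 0)
  expect_equal(apical_potential_g(1, 1), 0)
  expect_equal(apical_potential_g(2, 1), 0.5)
  expect_error(apical_potential_g(1, 0), "parameter error")
})

test_that("f and g are C1 at their breakpoints across a parameter grid", {
  for (h in c(0, 0.05, 0.3, 0.8)) {
    for (h_th in c(h + 0.1, h + 0.5, h + 1.5)) {
      f <- function(x) basal_potential_f(x, h, h_th)
      for (bp in c((h + h_th) / 2, h_th)) {
        expect_lt(numeric_jump(f, bp), 1e-10)
        expect_lt(derivative_jump(f, bp), 1e-5)
      }
    }
  }
  for (ell in c(0.5, 1.2, 3)) {
    g <- function(x) apical_potential_g(x, ell)
    expect_lt(numeric_jump(g, ell), 1e-10)
    expect_lt(derivative_jump(g, ell), 1e-5)
  }
})

test_that("tissue energy evaluates the printed four-term sum", {
  sq <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                    matrix(1:4, 1))
  p <- mechanical_params(a = 1, b = 1, c = 0, d = 0, V0 = 1)
  # area term 0, perimeter term 16/2
  expect_equal(tissue_energy(sq, p), 8)

  # adding the basal term: two basal vertices at distance 0 from the line
  p2 <- mechanical_params(a = 1, b = 1, c = 2, d = 0, V0 = 1,
                          h = 0.05, h_th = 0.5)
  expect_equal(tissue_energy(sq, p2), 8 + 2 * 2 * basal_potential_f(0, 0.05, 0.5))

  # apical term: apical vertices at distance 1 with ell = 0.4
  p3 <- mechanical_params(a = 1, b = 1, c = 0, d = 3, V0 = 1, ell = 0.4)
  expect_equal(tissue_energy(sq, p3), 8 + 3 * 2 * apical_potential_g(1, 0.4))
})

test_that("energy is invariant under rigid x-translation", {
  set.seed(42)
  mesh <- random_chain_mesh(5)
  p <- mechanical_params()
  u0 <- tissue_energy(mesh, p)
  shifted <- mesh
  shifted$vertices[, 1] <- shifted$vertices[, 1] + 13.7
  expect_equal(tissue_energy(shifted, p), u0, tolerance = 1e-12)
  # y-translation is broken only by the adhesion/repulsion terms
  p_free <- mechanical_params(c = 0, d = 0)
  yshift <- mesh
  yshift$vertices[, 2] <- yshift$vertices[, 2] + 2.1
  expect_equal(tissue_energy(yshift, p_free), tissue_energy(mesh, p_free),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(tissue_energy(yshift, p), u0)))
})

test_that("analytic forces equal the finite-difference gradient", {
  set.seed(7)
  for (rep in 1:5) {
    mesh <- random_chain_mesh(sample(1:12, 1))
    p <- mechanical_params()
    f <- tissue_forces(mesh, p)
    fd <- fd_forces(mesh, p)
    expect_lt(max(abs(f - fd)) / max(1, max(abs(f))), 1e-6)
  }
})

test_that("forces on a shared vertex sum both cells' contributions", {
  set.seed(11)
  mesh <- random_chain_mesh(2)
  p <- mechanical_params()
  f <- tissue_forces(mesh, p)
  # per-cell finite differences: evaluate each single-cell mesh separately
  single <- function(cell) {
    tissue_mesh(mesh$vertices, mesh$cells[cell, , drop = FALSE],
                tissue = mesh$tissue[cell], frames = mesh$frames)
  }
  fd_sum <- fd_forces(single(1), p) + fd_forces(single(2), p)
  expect_lt(max(abs(f - fd_sum)), 1e-6)
})

test_that("forces vanish at a relaxed configuration", {
  mesh <- make_initial_mesh(3)
  p <- mechanical_params(sigma = 0)
  tr <- run_single_tissue(mesh, params = p, migration = NULL, division = NULL,
                          t_end = 100, record_every = 100)
  relaxed <- frame_mesh(tr, length(tr$frames))
  expect_lt(max(abs(tissue_forces(relaxed, p))), 1e-3)
})

test_that("edge elastic energy uses the apical and basal pairs", {
  sq <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), matrix(1:4, 1))
  expect_equal(edge_elastic_energy(sq, 1, b = 1), 1)
  wide <- tissue_mesh(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)), matrix(1:4, 1))
  expect_equal(edge_elastic_energy(wide, 1, b = 1), 4)
  expect_equal(edge_elastic_energy(wide, 1, b = 0), 0)
  expect_error(edge_elastic_energy(sq, 5, b = 1), "lookup error")
})
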