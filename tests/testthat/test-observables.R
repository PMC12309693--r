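test_that("tissue length reads the anterior-posterior extent", {
  mesh <- make_initial_mesh(32, tissue = "floorplate")
  expect_equal(tissue_length(mesh, "floorplate"), 32)
  expect_equal(tissue_length(make_initial_mesh(1), "tissue"), 1)
  # midpoint insertion adds no extent
  d <- divide_cell(mesh, 7)
  expect_equal(tissue_length(d$mesh, "floorplate"), 32)
  expect_error(tissue_length(mesh, "notochord"), "lookup error")
})

test_that("uniformity statistic is the KS distance to U(0,1)", {
  ev <- function(x) data.frame(t = seq_along(x), relative_position = x)
  # all divisions at the posterior extreme
  expect_equal(uniformity_statistic(ev(rep(1, 12))), 1)
  # uniform quantiles k/(n+1) stay within 1/(n+1)
  n <- 19
  q <- (1:n) / (n + 1)
  expect_lte(uniformity_statistic(ev(q)), 1 / (n + 1) + 1e-12)
  # agreement with the brute-force ECDF comparison on random draws
  set.seed(3)
  for (rep in 1:5) {
    x <- runif(40)
    expect_equal(uniformity_statistic(ev(x)), brute_ks_uniform(x))
  }
  # t_min filters events; empty remainder warns and returns NA
  e <- ev(c(0.2, 0.8)); e$t <- c(1, 2)
  expect_warning(out <- uniformity_statistic(e, t_min = 10))
  expect_true(is.na(out))
})

test_that("gap flags fire on basal overextension only", {
  mesh <- make_initial_mesh(5, tissue = "floorplate")
  expect_length(gap_flag(mesh, "floorplate"), 0)
  stretched <- mesh
  # stretch cell 3's basal edge to 4x by moving one basal vertex
  stretched$vertices[4, 1] <- stretched$vertices[3, 1] + 4
  fl <- gap_flag(stretched, "floorplate", rupture_factor = 3,
                 initial_basal = 1)
  expect_equal(as.integer(fl), 3L)
  expect_error(gap_flag(mesh, "floorplate", rupture_factor = 1), "exceed")
})

test_that("mismatch series tracks |L_f - L_n| / L_n per frame", {
  # constructed two-frame trace: static follower, growing leader
  mk_frame <- function(t, noto_len) {
    noto <- make_initial_mesh(2, cell_width = noto_len / 2,
                              tissue = "notochord")
    fp <- make_initial_mesh(2, cell_width = 1, tissue = "floorplate",
                            frame = list(basal_y = 1.2, apical_sign = 1))
    v <- rbind(noto$vertices, fp$vertices)
    cl <- rbind(noto$cells, fp$cells + nrow(noto$vertices))
    list(t = t, vertices = v, cells = cl,
         tissue = c(noto$tissue, fp$tissue))
  }
  trace <- list(frames = list(mk_frame(0, 2), mk_frame(1, 3), mk_frame(2, 4)),
                frame_times = 0:2,
                ecm_frames = list(notochord = list(basal_y = 0, apical_sign = 1),
                                  floorplate = list(basal_y = 1.2, apical_sign = 1)))
  mm <- length_mismatch_series(trace)
  expect_equal(mm$mismatch, c(0, 1 / 3, 1 / 2))
  expect_true(all(diff(mm$mismatch) >= 0))
  # identical tissues give all-zero mismatch
  tr0 <- list(frames = list(mk_frame(0, 2)), frame_times = 0,
              ecm_frames = trace$ecm_frames)
  tr0$frames[[1]]$tissue <- c("notochord", "notochord",
                              "floorplate", "floorplate")
  expect_error(length_mismatch_series(list(frames = list(), frame_times = c(),
                                           ecm_frames = list(a = 1)),
                                      leader = "notochord"), "lookup error")
})

test_that("kymograph export encodes boundary motion recoverably", {
  # uniform translation at known speed: rigid drift of a relaxed chain
  mk <- make_initial_mesh(6, tissue = "floorplate")
  v <- 0.8
  frames <- lapply(0:20, function(t) {
    m <- mk
    m$vertices[, 1] <- m$vertices[, 1] + v * t
    list(t = t, vertices = m$vertices, cells = m$cells, tissue = m$tissue)
  })
  trace <- list(frames = frames, frame_times = 0:20,
                ecm_frames = list(floorplate = list(basal_y = 0, apical_sign = 1)))
  ky <- export_kymograph(trace, "floorplate")
  ang <- estimate_kymograph_angle(ky)
  v_hat <- kymograph_velocity(ang, attr(ky, "space_per_px"),
                              attr(ky, "time_per_row"))
  expect_lt(abs(v_hat - v) / v, 0.05)

  # static mesh: strictly vertical lines (every row identical)
  static <- trace
  static$frames <- lapply(static$frames, function(f) {
    f$vertices <- mk$vertices; f
  })
  ks <- export_kymograph(static, "floorplate")
  expect_true(all(apply(ks, 2, function(col) length(unique(col)) == 1)))

  expect_error(export_kymograph(trace, "no-such-tissue"), "lookup error")
  expect_error(export_kymograph(list(frames = frames[1],
                                     frame_times = 0), "floorplate"),
               "at least 2 frames")
})
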