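test_that("multi-frame XYZ files round-trip", {
  cfg <- generator_config(n_traj = 1, traj_dt_fs = 2, traj_t_max_fs = 100)
  tr <- generate_trajectory_ensemble(cfg, seed = 3)$trajectories[[1]]
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(tr, path, digits = 8)
  back <- read_xyz_trajectory(path, dt_fs = 2)
  expect_equal(n_frames(back), n_frames(tr))
  expect_equal(time_span_fs(back), 100)
  expect_equal(back$frames, tr$frames, tolerance = 1e-7)
  expect_equal(back$elements, tr$elements)
})

test_that("malformed XYZ input is reported with a frame index", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "ok", "H 0 0 0", "H 1 0 0", "O 0 1 0",
               "3", "bad", "H 0 0 0", "O 1 0 0", "H 0 1 0"), path)
  expect_error(read_xyz_trajectory(path, 1), "frame 2")
  writeLines(c("2", "x", "H 0 0 0", "Zz 1 0 0"), path)
  expect_error(read_xyz_trajectory(path, 1), "element")
})

test_that("migration detection is exact to one frame", {
  for (dt in c(0.1, 0.5)) {
    tr <- make_migration_traj(dt_fs = dt, cross_at = 50)
    rec <- migration_times(tr)
    expect_equal(rec$t_mig1_fs, 51 * dt, tolerance = 1e-9)
    expect_equal(rec$origin1, "beta")
    expect_true(is.na(rec$t_mig2_fs))
  }
  # fine-timestep case: crossing between frames 1233 and 1234 at 0.1 fs
  tr <- make_migration_traj(dt_fs = 0.1, cross_at = 1233, n_frames = 1300)
  expect_equal(migration_times(tr)$t_mig1_fs, 123.4, tolerance = 1e-9)
})

test_that("only the first threshold crossing counts for a re-crossing H", {
  tr <- make_migration_traj(dt_fs = 0.1, cross_at = 40, recross_at = 60,
                            n_frames = 120)
  rec <- migration_times(tr)
  expect_equal(rec$t_mig1_fs, 41 * 0.1, tolerance = 1e-9)
  expect_equal(nrow(rec$crossings), 1)
})

test_that("a bound trajectory reports no migration and no bond break", {
  geom <- ethanol_geometry()
  frames <- array(geom$xyz, c(9, 3, 50))
  tr <- trajectory(geom$elements, frames, 1)
  rec <- migration_times(tr)
  expect_true(is.na(rec$t_mig1_fs) && is.na(rec$t_mig2_fs))
  expect_true(is.na(co_break_time(tr)))
  expect_equal(as.character(final_fragments(tr)), "unfragmented")
})

test_that("C-O break detection is exact to one frame", {
  tr <- make_cobreak_traj(dt_fs = 0.1, cross_at = 5000, n_frames = 5200)
  expect_equal(co_break_time(tr), 500.0, tolerance = 0.1 + 1e-9)
  tr2 <- make_cobreak_traj(dt_fs = 0.5, cross_at = 80, n_frames = 200)
  expect_equal(co_break_time(tr2), 81 * 0.5, tolerance = 1e-9)
})

test_that("migration and break criteria are frame-invariant under rigid motion", {
  tr <- make_migration_traj(dt_fs = 0.2, cross_at = 30, n_frames = 80)
  set.seed(10)
  rot <- random_rotation()
  shift <- c(5, -3, 12)
  tr_rot <- tr
  for (f in seq_len(n_frames(tr))) {
    tr_rot$frames[, , f] <- tr$frames[, , f] %*% t(rot) +
      matrix(shift, 9, 3, byrow = TRUE)
  }
  expect_equal(migration_times(tr_rot)$t_mig1_fs,
               migration_times(tr)$t_mig1_fs)
  tr2 <- make_cobreak_traj(dt_fs = 0.2, cross_at = 60, n_frames = 150)
  tr2_rot <- tr2
  for (f in seq_len(n_frames(tr2))) {
    tr2_rot$frames[, , f] <- tr2$frames[, , f] %*% t(rot) +
      matrix(shift, 9, 3, byrow = TRUE)
  }
  expect_equal(co_break_time(tr2_rot), co_break_time(tr2))
})

test_that("final-frame classification recovers constructed channels", {
  geom <- ethanol_geometry()
  # H3O unit displaced 10 angstrom from the C2H3 remainder
  xyz <- geom$xyz
  h3o <- channel_fragment_atoms("DHM")[["H3O+"]]
  o <- geom$xyz[3, ]
  # park the two migrated H at O-H bond distance before displacing
  for (a in setdiff(h3o, c(3L, 4L))) {
    u <- (geom$xyz[a, ] - o) / sqrt(sum((geom$xyz[a, ] - o)^2))
    xyz[a, ] <- o + 0.97 * u
  }
  xyz[h3o, ] <- xyz[h3o, ] + matrix(c(10, 0, 0), length(h3o), 3, byrow = TRUE)
  tr <- trajectory(geom$elements, array(xyz, c(9, 3, 1)), 1)
  lab <- final_fragments(tr)
  expect_equal(as.character(lab), "DHM")
  expect_setequal(attr(lab, "fragments"), c("H3O", "C2H3"))
})

test_that("cumulative yields count defining times and never decrease", {
  rec <- data.frame(channel = c("DHM", "DHM", "DHM", "SHM"),
                    t_event_fs = c(100, 200, 300, 50))
  grid <- seq(0, 400, 50)
  y <- cumulative_yield(rec, "DHM", grid)
  expect_equal(y$value[match(c(100, 200, 300), y$t_fs)], c(1, 2, 3))
  expect_true(all(diff(y$value) >= 0))
  y0 <- cumulative_yield(rec, "NHM", grid)
  expect_true(all(y0$value == 0))
})

test_that("theory curves scale onto experiment at the reference time", {
  grid <- seq(0, 1200, 100)
  theory <- cumulative_yield(
    data.frame(channel = "DHM", t_event_fs = c(100, 400, 900)), "DHM", grid)
  experiment <- theory
  experiment$value <- c(rep(0.005, 5), rep(0.02, 8))
  sc <- scale_to_experiment(theory, experiment, t_ref_fs = 1000)
  i <- which.min(abs(grid - 1000))
  expect_equal(sc$value[i], experiment$value[i])
  expect_equal(attr(sc, "scale_factor"), 0.02 / 3)
  sc2 <- scale_to_experiment(sc, experiment, t_ref_fs = 1000)
  expect_equal(sc2$value, sc$value)
  empty <- theory; empty$value <- 0
  expect_error(scale_to_experiment(empty, experiment), "zero")
})

test_that("degenerate correlations are reported absent", {
  rec <- data.frame(t_mig1_fs = c(1, 2), t_mig2_fs = c(3, 4),
                    t_co_break_fs = c(5, 6),
                    origin2 = c("alpha", "beta"))
  cc <- migration_correlations(rec)
  expect_false(cc$t2_vs_t1$present)  # fewer than 3 pairs
  rec3 <- data.frame(t_mig1_fs = c(1, 2, 3), t_mig2_fs = c(7, 7, 7),
                     t_co_break_fs = c(5, 6, 7),
                     origin2 = c("alpha", "beta", "beta"))
  cc3 <- migration_correlations(rec3)
  expect_false(cc3$t2_vs_t1$present)  # zero variance in t2
  expect_equal(cc3$origin_counts, c(alpha = 1L, beta = 2L))
})
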