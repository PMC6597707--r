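small_cfg <- function(...) {
  generator_config(n_pulse_pairs = 200,
                   delay_breaks_fs = seq(-400, 400, 100), ...)
}

test_that("event streams are reproducible from (config, seed)", {
  g1 <- generate_event_stream(small_cfg(), seed = 5, include_triple = FALSE)
  g2 <- generate_event_stream(small_cfg(), seed = 5, include_triple = FALSE)
  expect_identical(g1, g2)
  g3 <- generate_event_stream(small_cfg(), seed = 6, include_triple = FALSE)
  expect_false(identical(g1$truth, g3$truth))
})

test_that("generated events conserve momentum before the detector", {
  gen <- generate_event_stream(small_cfg(), seed = 7)
  sums <- vapply(gen$events, function(e) sqrt(sum(colSums(e$p)^2)), 0)
  expect_lt(max(sums), 1e-6)
})

test_that("the generator's true KER is recovered end-to-end", {
  gen <- generate_event_stream(small_cfg(background_fraction = 0), seed = 8,
                               include_triple = FALSE)
  asg <- assign_channels(gen$hits)
  ok <- !is.na(asg$channel)
  tr_chan <- gen$truth$channel[match(asg$shot_id[ok], gen$truth$shot_id)]
  expect_true(all(asg$channel[ok] == tr_chan, na.rm = TRUE))
  kers <- vapply(asg$events, ker, 0)
  true_ker <- gen$truth$ker_eV[match(
    vapply(asg$events, function(e) e$shot_id, 0L), gen$truth$shot_id)]
  expect_lt(max(abs(kers - true_ker) / true_ker), 1e-6)
})

test_that("invalid branching fractions are rejected", {
  expect_error(generator_config(branching = c(NHM = 0.9, SHM = 0.3,
                                              DHM = 0, TRIPLE = 0)),
               "branching")
  expect_error(generator_config(traj_channel_fractions = c(NHM = 0.5,
                                                           SHM = 0.2,
                                                           DHM = 0.2)),
               "sum to 1")
})

test_that("trajectory ensembles are reproducible and carry valid truth", {
  cfg <- generator_config(n_traj = 8, traj_dt_fs = 2, traj_t_max_fs = 600)
  g1 <- generate_trajectory_ensemble(cfg, seed = 4)
  g2 <- generate_trajectory_ensemble(cfg, seed = 4)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$truth), 8)
  both <- !is.na(g1$truth$t_mig1_fs) & !is.na(g1$truth$t_mig2_fs)
  expect_true(all(g1$truth$t_mig2_fs[both] >= g1$truth$t_mig1_fs[both]))
})

test_that("scripted trajectories reproduce their scripted event times", {
  cfg <- generator_config(n_traj = 40, traj_dt_fs = 1, traj_t_max_fs = 2500,
                          traj_channel_fractions = c(NHM = 0.3, SHM = 0.3,
                                                     DHM = 0.4))
  gen <- generate_trajectory_ensemble(cfg, seed = 2)
  rec <- migration_records(gen$trajectories)
  done <- gen$truth$channel == rec$channel
  # every completed trajectory is classified as its true channel
  completed <- !is.na(gen$truth$t_co_break3_fs)
  expect_true(all(done[completed]))
  i <- which(completed & gen$truth$channel == "DHM")
  expect_true(all(abs(rec$t_mig2_fs[i] - gen$truth$t_mig2_fs[i]) <=
                    cfg$traj_dt_fs))
  expect_true(all(abs(rec$t_co_break_fs[i] - gen$truth$t_co_break3_fs[i]) <=
                    cfg$traj_dt_fs))
  # origin labels recovered exactly
  expect_equal(rec$origin1[i], gen$truth$origin1[i])
  expect_equal(rec$origin2[i], gen$truth$origin2[i])
})

test_that("migration is faster at higher internal energy", {
  cfg_lo <- generator_config(n_traj = 60, traj_dt_fs = 2,
                             traj_t_max_fs = 1000, energy_eV = 5,
                             traj_channel_fractions = c(NHM = 0, SHM = 1,
                                                        DHM = 0))
  cfg_hi <- generator_config(n_traj = 60, traj_dt_fs = 2,
                             traj_t_max_fs = 1000, energy_eV = 10,
                             traj_channel_fractions = c(NHM = 0, SHM = 1,
                                                        DHM = 0))
  t_lo <- generate_trajectory_ensemble(cfg_lo, seed = 3)$truth$t_mig1_fs
  t_hi <- generate_trajectory_ensemble(cfg_hi, seed = 3)$truth$t_mig1_fs
  expect_gt(mean(t_lo, na.rm = TRUE), mean(t_hi, na.rm = TRUE))
})
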