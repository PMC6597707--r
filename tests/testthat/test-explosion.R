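test_that("zero-charge bodies drift freely", {
  b <- charged_bodies(c("OH+", "C2H5+"), rbind(c(0, 0, 0), c(3, 0, 0)),
                      velocity = rbind(c(0.1, 0, 0), c(0, 0.05, 0)),
                      charge = c(0, 0))
  out <- coulomb_propagate(b, 100, dt_fs = 0.5)
  expect_equal(out$x, c(10, 3), tolerance = 1e-9)
  expect_equal(out$y, c(0, 5), tolerance = 1e-9)
  expect_equal(unlist(out[, c("vx", "vy", "vz")]),
               unlist(b[, c("vx", "vy", "vz")]), ignore_attr = TRUE)
})

test_that("coincident bodies are rejected", {
  b <- charged_bodies(c("H+", "H+"), rbind(c(0, 0, 0), c(0.01, 0, 0)))
  expect_error(coulomb_propagate(b, 10), "degenerate")
})

test_that("equilateral three-charge explosion is symmetric", {
  r <- 2
  pos <- r * rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                   c(-0.5, -sqrt(3) / 2, 0))
  b <- charged_bodies(rep("H3O+", 3), pos, charge = rep(1, 3))
  out <- coulomb_propagate(b, 5e4, to_asymptote = TRUE)
  v <- sqrt(rowSums(as.matrix(out[, c("vx", "vy", "vz")])^2))
  expect_lt(diff(range(v)) / mean(v), 1e-6)
})

test_that("two-body propagation matches the analytic Coulomb energy", {
  # KER = k q1 q2 / R for charges released from rest
  for (R in c(2, 5)) {
    b <- charged_bodies(c("OH+", "C2H5+"), rbind(c(0, 0, 0), c(R, 0, 0)),
                        charge = c(1, 1))
    out <- coulomb_propagate(b, 5e4, to_asymptote = TRUE)
    d <- attr(out, "diagnostics")
    expect_equal(d$kinetic_eV, k_coul / R, tolerance = 5e-3)
    expect_lt(d$energy_drift_eV, 1e-3 * d$e0_eV)
  }
})

test_that("propagation is rotation-equivariant", {
  set.seed(7)
  rot <- random_rotation()
  expect_equal(crossprod(rot), diag(3), tolerance = 1e-12)
  expect_equal(det(rot), 1, tolerance = 1e-12)
  pos <- rbind(c(0, 0, 0), c(1.2, 0.8, -0.5), c(-0.9, 1.1, 0.4))
  sp <- c("H+", "H2O+", "C2H3+")
  r1 <- coulomb_propagate(charged_bodies(sp, pos, charge = rep(1, 3)),
                          5e4, to_asymptote = TRUE)
  r2 <- coulomb_propagate(charged_bodies(sp, pos %*% t(rot),
                                         charge = rep(1, 3)),
                          5e4, to_asymptote = TRUE)
  p_rot <- body_momenta_au(r1) %*% t(rot)
  expect_lt(max(abs(p_rot - body_momenta_au(r2))) /
              max(abs(body_momenta_au(r2))), 1e-9)
})

test_that("concerted two-body momenta are exactly back-to-back", {
  ev <- simulate_concerted("NHM", seed = 11)
  expect_equal(ev$p[1, ], -ev$p[2, ],
               tolerance = 1e-9 * sqrt(sum(ev$p[1, ]^2)))
  ev2 <- simulate_concerted("DHM", seed = 12)
  expect_equal(sqrt(sum(ev2$p[1, ]^2)), sqrt(sum(ev2$p[2, ]^2)),
               tolerance = 1e-9)
  expect_error(simulate_concerted("BOGUS"), "unknown channel")
})

test_that("concerted KER is orientation-independent", {
  kers <- vapply(1:5, function(s)
    attr(simulate_concerted("TRIPLE", seed = s), "ker_eV"), 0)
  expect_lt(diff(range(kers)) / mean(kers), 1e-3)
})

test_that("sequential breakup conserves momentum and bookkeeps charge", {
  defs <- process_defs()
  for (pr in names(defs)) {
    d <- defs[[pr]]
    expect_equal(sum(species_mass(d$daughters)),
                 species_mass(d$intermediate), tolerance = 1e-6)
    ev <- simulate_sequential(pr, t_ionize_fs = 150, seed = 21)
    expect_setequal(ev$species, c("H+", "H2O+", "C2H3+"))
    expect_lt(sqrt(sum(colSums(ev$p)^2)), 1e-6)
    expect_gt(attr(ev, "ker_eV"), 0)
  }
})

test_that("deprotonation-first energy sharing approaches the two-step limit", {
  # at late second ionization the proton keeps its step-1 share
  # (45/46) KER1 and the heavy daughters split KER2 between themselves
  g <- ethanol_geometry()
  d <- process_defs()$seq_iii
  r1 <- sqrt(sum((atom_com(g, d$first_atoms) -
                    atom_com(g, d$intermediate_atoms))^2))
  ker1 <- k_coul / r1
  ker2 <- k_coul / d$daughter_sep_A
  expected <- (45 / 46) * ker1 / (ker1 + ker2)
  ev <- simulate_sequential("seq_iii", t_ionize_fs = 5000, seed = 31)
  e_h <- kinetic_energy(ev$p[ev$species == "H+", ], species_mass("H+"))
  expect_equal(e_h / attr(ev, "ker_eV"), expected, tolerance = 0.03)
})

test_that("sequential KER decreases toward the late-ionization limit", {
  kers <- vapply(c(0, 50, 200, 800), function(ti)
    attr(simulate_sequential("seq_i", ti, seed = 5,
                             daughter_placement = "geometry"), "ker_eV"), 0)
  expect_true(all(diff(kers) < 0))
})

test_that("process ensembles are reproducible from their seed", {
  e1 <- simulate_process_ensemble("seq_ii", 4, seed = 42)
  e2 <- simulate_process_ensemble("seq_ii", 4, seed = 42)
  expect_identical(e1, e2)
  e3 <- simulate_process_ensemble("seq_ii", 4, seed = 43)
  expect_false(identical(e1, e3))
})
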