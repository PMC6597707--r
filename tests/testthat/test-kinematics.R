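test_that("kinetic energy follows E = p^2/2m in eV", {
  # independent SI-route oracle: (p hbar/a0)^2 / (2 m) in joule -> eV
  p_si <- 20 * 1.054571817e-34 / 0.529177210903e-10
  e_si <- p_si^2 / (2 * 1.00782503 * 1.66053906660e-27) / 1.602176634e-19
  expect_equal(kinetic_energy(c(20, 0, 0), 1.00782503), e_si,
               tolerance = 1e-7)
  expect_equal(e_si, 2.962, tolerance = 1e-3)
  expect_equal(kinetic_energy(c(0, 0, 0), 18), 0)
  expect_equal(kinetic_energy(c(0, 24, 0), 17),
               4 * kinetic_energy(c(0, 12, 0), 17))
  expect_error(kinetic_energy(c(1, 0, 0), -1), "positive")
})

test_that("KER sums fragment energies and is rotation-invariant", {
  ev <- make_triple_event()
  m <- species_mass(ev$species)
  expect_equal(ker(ev), sum(kinetic_energy(ev$p, m)))
  set.seed(3)
  rot <- random_rotation()
  ev_rot <- coincidence_event(ev$species, ev$p %*% t(rot))
  expect_equal(ker(ev_rot), ker(ev), tolerance = 1e-12)
  ev0 <- coincidence_event(c("OH+", "C2H5+"), matrix(0, 2, 3))
  expect_equal(ker(ev0), 0)
})

test_that("Dalitz coordinates reproduce the defining worked examples", {
  expect_equal(unlist(dalitz_coordinates(2, 2, 2)), c(x_d = 0, y_d = 0))
  expect_equal(unlist(dalitz_coordinates(3, 3, 0)),
               c(x_d = 0, y_d = -1 / 3))
  d <- dalitz_coordinates(2, 1, 3)
  expect_equal(d$x_d, (2 - 1) / (sqrt(3) * 6), tolerance = 1e-10)
  expect_equal(d$x_d, 0.09623, tolerance = 1e-4)
  expect_equal(d$y_d, 1 / 6, tolerance = 1e-10)
  expect_error(dalitz_coordinates(0, 0, 0), "KER")
  expect_error(dalitz_coordinates(-1, 1, 1), "non-negative")
})

test_that("Dalitz map is scale-invariant and stays in the allowed region", {
  set.seed(14)
  for (i in 1:200) {
    e <- stats::rexp(3)
    d1 <- dalitz_coordinates(e[1], e[2], e[3])
    d2 <- dalitz_coordinates(7.3 * e[1], 7.3 * e[2], 7.3 * e[3])
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_gte(d1$y_d, -1 / 3); expect_lte(d1$y_d, 2 / 3)
    expect_lte(abs(d1$x_d), 1 / sqrt(3) + 1e-12)
  }
})

test_that("Newton transform fixes the reference axis and the half-planes", {
  ev <- make_triple_event(p_h = c(4, -3, 2), p_h2o = c(-28, 21, -5))
  nt <- newton_transform(ev)
  expect_equal(nt$species, c("C2H3+", "H2O+", "H+"))
  expect_equal(nt$p_perp[1], 0)
  expect_gt(nt$p_parallel[1], 0)
  expect_gte(nt$p_perp[2], 0)
  expect_lte(nt$p_perp[3], 0)
  # magnitudes preserved
  idx <- match(nt$species, ev$species)
  expect_equal(nt$p, sqrt(rowSums(ev$p[idx, ]^2)), tolerance = 1e-12)
  # reference (3,4,0) -> (5, 0)
  ev2 <- make_triple_event(p_h = c(0, 0, 10), p_h2o = c(-3, -4, -5))
  # C2H3+ momentum is -(pH + pH2O) = (3, 4, -5); use H2O+ as reference
  nt2 <- newton_transform(ev2, reference = "H2O+", upper = "C2H3+",
                          lower = "H+")
  expect_equal(nt2$p_parallel[1], sqrt(50), tolerance = 1e-12)
})

test_that("Newton transform preserves pairwise angles and is idempotent", {
  ev <- make_triple_event(p_h = c(7, -11, 3), p_h2o = c(-40, 12, 6))
  nt <- newton_transform(ev)
  ang <- function(a, b) acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  p3 <- cbind(nt$p_parallel, nt$p_perp, 0)
  idx <- match(nt$species, ev$species)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(ang(p3[i, ], p3[j, ]), ang(ev$p[idx[i], ], ev$p[idx[j], ]),
                 tolerance = 1e-9)
  }
  # applying the transform to its own output changes nothing
  ev_t <- coincidence_event(nt$species, p3)
  nt2 <- newton_transform(ev_t)
  expect_equal(nt2$p_parallel, nt$p_parallel, tolerance = 1e-12)
  expect_equal(nt2$p_perp, nt$p_perp, tolerance = 1e-12)
})

test_that("Newton transform rejects unusable events", {
  ev <- make_triple_event()
  ev$species <- c("H+", "OH+", "C2H5+")
  expect_error(newton_transform(ev), "does not contain")
  ev2 <- coincidence_event(c("C2H3+", "H2O+", "H+"),
                           rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)))
  expect_error(newton_transform(ev2), "undefined")
})

test_that("proton-momentum split uses the half-open boundary at 20 au", {
  mk <- function(p) coincidence_event(
    c("H+", "H2O+", "C2H3+"), rbind(p, c(-30, 0, 0), c(30 - p[1], -p[2], -p[3])))
  evs <- list(mk(c(19.9, 0, 0)), mk(c(20.0, 0, 0)), mk(c(45, 0, 0)))
  out <- split_by_proton_momentum(evs)
  expect_length(out$low, 1)
  expect_length(out$high, 2)
  expect_equal(out$n_skipped, 0L)
  out0 <- split_by_proton_momentum(list())
  expect_length(out0$low, 0); expect_length(out0$high, 0)
  no_h <- coincidence_event(c("OH+", "C2H5+"), rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_warning(out2 <- split_by_proton_momentum(list(no_h)), "skipped")
  expect_equal(out2$n_skipped, 1L)
})

test_that("event tables round-trip through the long format", {
  evs <- list(make_triple_event(),
              coincidence_event(c("OH+", "C2H5+"),
                                rbind(c(5, 1, 2), c(-5, -1, -2)),
                                delay_fs = 250, shot_id = 7L))
  tab <- events_to_table(evs)
  expect_equal(nrow(tab), 5)
  back <- events_from_table(tab)
  expect_equal(back[[1]]$p, evs[[1]]$p)
  expect_equal(back[[2]]$delay_fs, 250)
})
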