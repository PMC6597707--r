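.mk_events <- function(delay, ker_eV) {
  lapply(seq_along(delay), function(i) {
    pm <- ceimig:::.two_body_p_au("DHM", ker_eV[i])
    coincidence_event(c("H3O+", "C2H3+"),
                      rbind(c(pm, 0, 0), c(-pm, 0, 0)),
                      delay_fs = delay[i], shot_id = i)
  })
}

test_that("KER-delay maps bin events and keep totals", {
  m0 <- ker_delay_map(list())
  expect_true(all(m0$counts == 0))
  set.seed(2)
  evs <- .mk_events(runif(300, -900, 900), runif(300, 0.2, 14))
  m <- ker_delay_map(evs)
  expect_equal(sum(m$counts), 300)
})

test_that("mean gated KER decreases with delay for a separating stream", {
  cfg <- generator_config(n_pulse_pairs = 3000, p_event = 0.05,
                          branching = c(NHM = 0, SHM = 0, DHM = 1,
                                        TRIPLE = 0),
                          background_fraction = 0, tau_mig_fs = 100)
  gen <- generate_event_stream(cfg, seed = 2, include_triple = FALSE)
  tr <- gen$truth
  d <- tr[tr$channel == "DHM" & tr$delay_fs > 200, ]
  mean_ker <- tapply(d$ker_eV, cut(d$delay_fs, seq(200, 1000, 200)), mean)
  expect_true(all(diff(mean_ker) < 0))
})

test_that("yields normalize by pulse pairs and respect the gate", {
  evs <- .mk_events(rep(125, 10), rep(2, 10))
  scan <- yield_vs_delay(evs, c(0.5, 3.6), pulse_pairs = rep(1000, 40))
  expect_equal(scan$yield[scan$delay_fs == 125], 0.01)
  expect_equal(sum(scan$n_events), 10)
  scan2 <- yield_vs_delay(evs, c(0.5, 3.6), pulse_pairs = rep(2000, 40))
  expect_equal(scan2$yield[scan2$delay_fs == 125], 0.005)
  # out-of-gate events are not counted
  scan3 <- yield_vs_delay(.mk_events(rep(125, 5), rep(5, 5)), c(0.5, 3.6),
                          rep(1000, 40))
  expect_equal(sum(scan3$n_events), 0)
  # overlap flag
  expect_true(all(scan$overlap[abs(scan$delay_fs) < 30]))
  expect_false(any(scan$overlap[abs(scan$delay_fs) > 30]))
})

test_that("gated counts are preserved when adjacent bins merge", {
  set.seed(5)
  evs <- .mk_events(runif(400, -1000, 1000), runif(400, 0.2, 4))
  fine <- yield_vs_delay(evs, c(0.5, 3.6), rep(500, 40),
                         delay_breaks_fs = seq(-1000, 1000, 50))
  coarse <- yield_vs_delay(evs, c(0.5, 3.6), rep(1000, 20),
                           delay_breaks_fs = seq(-1000, 1000, 100))
  expect_equal(sum(fine$n_events), sum(coarse$n_events))
  merged <- tapply(fine$n_events, rep(seq_len(20), each = 2), sum)
  expect_equal(as.vector(merged), coarse$n_events)
  expect_equal(fine$yield[1] , fine$n_events[1] / 500)
})

test_that("channel ratios propagate counting uncertainty", {
  evs <- .mk_events(rep(c(225, 275), each = 20), rep(2, 40))
  a <- yield_vs_delay(evs, c(0.5, 3.6), rep(1000, 40))
  r <- channel_ratio(a, a)
  expect_true(all(r$ratio == 1))
  expect_equal(r$sigma, r$ratio * sqrt(2 / 20)[1] *
                 rep(1, nrow(r)), tolerance = 1e-12)
  b <- a; b$delay_fs <- b$delay_fs + 1
  expect_error(channel_ratio(a, b), "binning")
})

test_that("saturating-exponential fits recover clean curves exactly", {
  t <- seq(25, 1975, 50)
  y <- 0.02 * (1 - exp(-pmax(t - 80, 0) / 350))
  scan <- data.frame(delay_fs = t, n_events = round(y * 5e4),
                     pulse_pairs = 5e4, yield = y, overlap = abs(t) < 30)
  class(scan) <- c("cei_delayscan", "data.frame")
  fit <- fit_saturating_yield(scan)
  expect_equal(fit$tau_fs, 350, tolerance = 0.02)
  expect_equal(fit$t0_fs, 80, tolerance = 0.1)
  fit0 <- fit_saturating_yield(scan, fit_t0 = FALSE)
  expect_gt(fit0$tau_fs, 0)
})
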