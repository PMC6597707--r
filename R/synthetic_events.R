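#' Synthetic-data generator configuration
#'
#' Conditions emulating the pump-probe coincidence experiment and the
#' molecular-dynamics trajectory ensembles: two 730 nm, 9 fs pulses
#' (intensities 4.2e14 / 6.7e14 W/cm2 -- carried as provenance only), a
#' delay scan, delay-independent channel branching, exponential migration
#' completion times whose mean scales inversely with the internal energy,
#' an uncorrelated first/second migration, and a second migration driving
#' the C-O bond break after a fixed short lag.
#'
#' @param n_pulse_pairs pulse pairs per delay bin.
#' @param delay_breaks_fs delay bin edges (fs).
#' @param p_event probability that a pulse pair yields one analyzable
#'   coincidence event.
#' @param branching intended-channel branching fractions (delay
#'   independent), named NHM/SHM/DHM/TRIPLE, summing to <= 1.
#' @param tau_mig_fs mean migration (channel-completion) time at the
#'   reference internal energy (fs); one shared value keeps the channel
#'   ratios flat.
#' @param energy_eV internal energy (eV); migration is faster at higher
#'   energy: the effective mean is `tau_mig_fs * energy_ref_eV / energy_eV`.
#' @param energy_ref_eV reference internal energy for `tau_mig_fs`.
#' @param e_drift_eV kinetic energy already carried by the separating
#'   cation fragments when the probe arrives (eV).
#' @param v_sep_A_fs separation speed of the dissociating cation fragments
#'   (angstrom/fs).
#' @param background_fraction fraction of events caused by a single pulse
#'   (delay-independent KER bands).
#' @param bg_ker_two_body_eV,bg_ker_triple_eV centre/sd of the
#'   single-pulse KER bands (eV).
#' @param false_pair_fraction fraction of event-bearing shots worth of
#'   extra shots carrying an uncorrelated random hit pair.
#' @param tau_mig1_fs,t2_offset_fs,tau_mig2_fs first-migration mean, and
#'   offset + mean of the (independent) second-migration time (fs).
#' @param co_delta_fs,co_sigma_fs lag and Gaussian jitter of the C-O break
#'   after the migration completing the channel (fs).
#' @param traj_channel_fractions trajectory-ensemble channel fractions.
#' @param n_traj,traj_dt_fs,traj_t_max_fs trajectory ensemble size,
#'   frame spacing and maximum propagation time (3 ps).
#' @param jitter_A thermal position jitter on the starting geometry
#'   (angstrom).
#' @param charge precursor charge of the trajectory ensemble.
#' @return list of class `cei_genconfig`.
#' @export
generator_config <- function(n_pulse_pairs = 300,
                             delay_breaks_fs = delay_binning_defaults()$breaks_fs,
                             p_event = 0.05,
                             branching = c(NHM = 0.30, SHM = 0.25,
                                           DHM = 0.25, TRIPLE = 0.20),
                             tau_mig_fs = 300,
                             energy_eV = 5,
                             energy_ref_eV = 5,
                             e_drift_eV = 1.0,
                             v_sep_A_fs = 0.04,
                             background_fraction = 0.10,
                             bg_ker_two_body_eV = c(5, 0.3),
                             bg_ker_triple_eV = c(13, 1),
                             false_pair_fraction = 0.05,
                             tau_mig1_fs = 150,
                             t2_offset_fs = 200,
                             tau_mig2_fs = 600,
                             co_delta_fs = 40,
                             co_sigma_fs = 5,
                             traj_channel_fractions = c(NHM = 0.2, SHM = 0.3,
                                                        DHM = 0.5),
                             n_traj = 1000,
                             traj_dt_fs = 0.5,
                             traj_t_max_fs = 3000,
                             jitter_A = 0.02,
                             charge = 2L) {
  if (any(branching < 0) || sum(branching) > 1 + 1e-12) {
    stop("branching fractions must be non-negative and sum to <= 1")
  }
  if (any(traj_channel_fractions < 0) ||
      abs(sum(traj_channel_fractions) - 1) > 1e-12) {
    stop("trajectory channel fractions must be non-negative and sum to 1")
  }
  structure(c(as.list(environment()),
              list(pulse = list(wavelength_nm = 730, duration_fs = 9,
                                intensity_Wcm2 = c(pump = 4.2e14,
                                                   probe = 6.7e14)))),
            class = "cei_genconfig")
}

# equilibrium charge-site separation (angstrom) of a two-body channel
.channel_r_eq <- function(channel, geometry = ethanol_geometry()) {
  frag <- channel_fragment_atoms(channel)
  com <- t(vapply(frag, function(idx) atom_com(geometry, idx), numeric(3)))
  sqrt(sum((com[1, ] - com[2, ])^2))
}

# back-to-back momentum magnitudes (a.u.) for two-body channels, vectorized
.two_body_p_au <- function(channel, ker_eV) {
  u <- unit_system()
  m <- species_mass(channel_defs()[[channel]]$species)
  mu_au <- (m[1] * m[2] / sum(m)) * u$amu_to_au_mass
  sqrt(2 * (ker_eV / u$hartree_to_eV) * mu_au)
}

# n random unit 3-vectors (rows)
.random_directions <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# three momenta summing to zero with the given total kinetic energy
.random_triple_momenta <- function(species, ker_eV) {
  m <- species_mass(species)
  p <- rbind(stats::rnorm(3, sd = 10), stats::rnorm(3, sd = 30))
  p <- rbind(p, -colSums(p))
  e <- sum(kinetic_energy(p, m))
  p * sqrt(ker_eV / e)
}

#' Generate a synthetic pump-probe coincidence event stream
#'
#' For every pulse pair an event occurs with probability `p_event`; its
#' intended channel is drawn from the branching fractions and its migration
#' completion time T from an exponential. If the probe arrives before T the
#' probe projects the still-unmigrated cation and the event lands in the
#' no-migration (precursor) channel at the prompt equilibrium KER;
#' otherwise the event lands in its migrated channel with the fragments
#' separated to R(t) = R_eq + v_sep (|t| - T), so the Coulomb part of the
#' KER decreases with delay. Triple-coincidence events are produced by the
#' two-step sequential simulator with the second ionization at |t| - T.
#' Single-pulse background events populate delay-independent KER bands.
#' All momenta are passed through the spectrometer forward model to yield
#' detector hit tables; uncorrelated false hit pairs are mixed in.
#'
#' @param config a `cei_genconfig`.
#' @param seed integer seed; the output is reproducible from
#'   (config, seed).
#' @param spect a `cei_spectrometer`.
#' @param include_triple set `FALSE` to skip the (propagation-heavy)
#'   sequential triple events.
#' @return list: `hits` (data.frame `shot_id`, `delay_fs`, `tof_ns`,
#'   `x_mm`, `y_mm`), `events` (list of true `cei_event`s), `truth`
#'   (data.frame: `event_id`, `shot_id`, `delay_fs`, `source`, `intended`,
#'   `channel`, `t_complete_fs`, `process`, `ker_eV`), `pulse_pairs`
#'   (integer per delay bin), `delay_breaks_fs`.
#' @export
generate_event_stream <- function(config = generator_config(), seed = 1,
                                  spect = spectrometer_config(),
                                  include_triple = TRUE) {
  set.seed(seed)
  br <- config$branching
  tau_eff <- config$tau_mig_fs * config$energy_ref_eV / config$energy_eV
  breaks <- config$delay_breaks_fs
  nbin <- length(breaks) - 1
  pulse_pairs <- rep(config$n_pulse_pairs, nbin)
  geom <- ethanol_geometry()
  r_eq <- vapply(c(NHM = "NHM", SHM = "SHM", DHM = "DHM"), .channel_r_eq, 0,
                 geometry = geom)
  k <- unit_system()$coulomb_constant_eV_angstrom
  procs <- names(process_defs())
  chans <- channel_defs()

  # per-bin event counts and delays, flattened
  n_ev <- stats::rbinom(nbin, pulse_pairs, config$p_event)
  delay <- unlist(lapply(seq_len(nbin), function(b)
    stats::runif(n_ev[b], breaks[b], breaks[b + 1])))
  n <- length(delay)
  t_abs <- abs(delay)
  is_bg <- stats::runif(n) < config$background_fraction
  intended <- sample(names(br), n, replace = TRUE, prob = br)
  t_complete <- stats::rexp(n, rate = 1 / tau_eff)
  t_complete[is_bg] <- NA_real_

  # realized channel + true KER per event
  channel <- character(n)
  ker_ev <- numeric(n)
  migrated <- !is_bg & t_abs >= t_complete
  precursor <- !is_bg & !migrated
  channel[precursor] <- "NHM"
  ker_ev[precursor] <- k / (r_eq["NHM"] +
                              stats::rnorm(sum(precursor), 0, 0.05))
  channel[is_bg] <- intended[is_bg]
  two_bg <- is_bg & intended != "TRIPLE"
  ker_ev[two_bg] <- pmax(stats::rnorm(sum(two_bg), config$bg_ker_two_body_eV[1],
                                      config$bg_ker_two_body_eV[2]), 0.5)
  tri_bg <- is_bg & intended == "TRIPLE"
  ker_ev[tri_bg] <- pmax(stats::rnorm(sum(tri_bg), config$bg_ker_triple_eV[1],
                                      config$bg_ker_triple_eV[2]), 0.5)
  for (ch in c("NHM", "SHM", "DHM")) {
    i <- migrated & intended == ch
    channel[i] <- ch
    r_t <- r_eq[ch] + config$v_sep_A_fs * (t_abs[i] - t_complete[i])
    ker_ev[i] <- config$e_drift_eV + k / r_t
  }
  tri <- migrated & intended == "TRIPLE"
  if (!include_triple) {
    keep <- !tri
    delay <- delay[keep]; t_abs <- t_abs[keep]; is_bg <- is_bg[keep]
    intended <- intended[keep]; t_complete <- t_complete[keep]
    channel <- channel[keep]; ker_ev <- ker_ev[keep]
    two_bg <- two_bg[keep]; tri_bg <- tri_bg[keep]
    precursor <- precursor[keep]; migrated <- migrated[keep]
    tri <- tri[keep]
    n <- length(delay)
  }
  channel[tri] <- "TRIPLE"
  process <- rep(NA_character_, n)
  process[tri] <- sample(procs, sum(tri), replace = TRUE)

  # momenta: vectorized for two-body events, simulated for triples
  dirs <- .random_directions(n)
  events <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- channel[i]
    src <- if (is_bg[i]) "single_pulse" else "pump_probe"
    if (ch == "TRIPLE" && !is_bg[i]) {
      ev <- simulate_sequential(process[i],
                                t_ionize_fs = t_abs[i] - t_complete[i])
      ev$delay_fs <- delay[i]; ev$shot_id <- i; ev$source <- src
      ker_ev[i] <- attr(ev, "ker_eV")
    } else if (ch == "TRIPLE") {
      ev <- coincidence_event(chans$TRIPLE$species,
                              .random_triple_momenta(chans$TRIPLE$species,
                                                     ker_ev[i]),
                              delay_fs = delay[i], shot_id = i, source = src)
    } else {
      pm <- .two_body_p_au(ch, ker_ev[i])
      ev <- coincidence_event(chans[[ch]]$species,
                              rbind(pm * dirs[i, ], -pm * dirs[i, ]),
                              delay_fs = delay[i], shot_id = i, source = src)
    }
    events[[i]] <- ev
  }

  truth <- data.frame(event_id = seq_len(n), shot_id = seq_len(n),
                      delay_fs = delay,
                      source = ifelse(is_bg, "single_pulse", "pump_probe"),
                      intended = intended, channel = channel,
                      t_complete_fs = t_complete, process = process,
                      ker_eV = ker_ev, stringsAsFactors = FALSE)

  # hit table: all fragments at once through the forward model
  frag_n <- vapply(events, function(e) length(e$species), 0L)
  all_p <- do.call(rbind, lapply(events, function(e) e$p))
  all_sp <- unlist(lapply(events, function(e) e$species))
  hits <- forward_model(all_p, all_sp, spect)
  hits <- cbind(data.frame(shot_id = rep(seq_len(n), frag_n),
                           delay_fs = rep(delay, frag_n)), hits)

  # uncorrelated false hit pairs on extra shots
  n_false <- stats::rbinom(1, n, config$false_pair_fraction)
  if (n_false > 0) {
    f_delay <- stats::runif(n_false, breaks[1], breaks[nbin + 1])
    f_sp <- sample(species_catalog()$name[1:7], 2 * n_false, replace = TRUE)
    f_p <- matrix(stats::rnorm(6 * n_false, sd = 40), 2 * n_false, 3)
    f_hits <- forward_model(f_p, f_sp, spect)
    f_hits <- cbind(data.frame(shot_id = rep(n + seq_len(n_false), each = 2),
                               delay_fs = rep(f_delay, each = 2)), f_hits)
    hits <- rbind(hits, f_hits)
  }

  list(hits = hits, events = events, truth = truth,
       pulse_pairs = pulse_pairs, delay_breaks_fs = breaks)
}
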