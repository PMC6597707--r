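.unit <- function(v) v / sqrt(sum(v^2))

# piecewise-linear O-H distance path: approach from d0 so that the
# threshold (1 angstrom) is crossed exactly at t_mig, then settle to the
# 0.97 angstrom O-H bond length; the transfer never starts before frame 0
# so the H is still at its donor carbon when origins are assigned
.mig_distance <- function(t, t_mig, d0, transfer_fs = 30, settle_fs = 5) {
  t_start <- max(t_mig - transfer_fs, 0)
  ramp_fs <- t_mig - t_start
  d <- rep(d0, length(t))
  ramp <- t > t_start & t <= t_mig
  d[ramp] <- d0 + (t[ramp] - t_start) / ramp_fs * (1.0 - d0)
  settle <- t > t_mig & t <= t_mig + settle_fs
  d[settle] <- 1.0 - (t[settle] - t_mig) / settle_fs * 0.03
  d[t > t_mig + settle_fs] <- 0.97
  d
}

# build one scripted trajectory; times may be NA (event absent)
.script_trajectory <- function(config, id, channel, t_mig1, t_mig2,
                               mig_atoms, t_co) {
  geom <- ethanol_geometry()
  base <- geom$xyz + matrix(stats::rnorm(27, sd = config$jitter_A), 9, 3)
  dt <- config$traj_dt_fs
  nf <- as.integer(floor(config$traj_t_max_fs / dt)) + 1L
  t <- (seq_len(nf) - 1) * dt
  frames <- array(base, c(9, 3, nf))

  o_pos0 <- base[3, ]
  e_sep <- .unit(o_pos0 - base[2, ])  # O departs from C_alpha
  d0_co <- sqrt(sum((o_pos0 - base[2, ])^2))

  if (!is.na(t_co)) {
    s <- config$v_sep_A_fs * pmax(0, t - t_co) / 2
    o_side <- c(3L, 4L)
    for (a in seq_len(9)) {
      sgn <- if (a %in% o_side) 1 else -1
      for (d in 1:3) frames[a, d, ] <- frames[a, d, ] + sgn * e_sep[d] * s
    }
  }

  migs <- list()
  if (!is.na(t_mig1)) migs <- c(migs, list(list(atom = mig_atoms[1], t = t_mig1)))
  if (!is.na(t_mig2)) migs <- c(migs, list(list(atom = mig_atoms[2], t = t_mig2)))
  for (mg in migs) {
    u <- .unit(base[mg$atom, ] - o_pos0)
    d0 <- sqrt(sum((base[mg$atom, ] - o_pos0)^2))
    dist_t <- .mig_distance(t, mg$t, d0)
    for (d in 1:3) frames[mg$atom, d, ] <- frames[3, d, ] + u[d] * dist_t
  }

  list(traj = trajectory(geom$elements, frames, dt, charge = config$charge,
                         energy_eV = config$energy_eV, id = id),
       d0_co = d0_co)
}

#' Generate a scripted trajectory ensemble
#'
#' Kinematically scripted ethanol-ion trajectories emulating the
#' statistical structure of molecular-dynamics ensembles: each trajectory
#' starts at the jittered equilibrium geometry; hydrogens migrate to the
#' oxygen along smooth interpolated paths at sampled times; for the double
#' migration the first and second migration times are drawn independently,
#' while the C-O bond separation is initiated a fixed short lag (plus
#' Gaussian jitter) after the migration completing the channel -- the
#' concerted second-migration / bond-break mechanism. Migration origins
#' (alpha vs beta carbon) are sampled 50/50. Times falling beyond the
#' propagation window leave the trajectory unfragmented.
#'
#' @param config a `cei_genconfig`; the relevant fields are
#'   `traj_channel_fractions`, `tau_mig1_fs`, `t2_offset_fs`,
#'   `tau_mig2_fs`, `co_delta_fs`, `co_sigma_fs`, `v_sep_A_fs`,
#'   `energy_eV` (migration means scale with `energy_ref_eV / energy_eV`),
#'   `n_traj`, `traj_dt_fs`, `traj_t_max_fs`, `jitter_A`.
#' @param seed integer seed; output reproducible from (config, seed).
#' @param n_traj optional override of `config$n_traj`.
#' @return list: `trajectories` (list of `cei_trajectory`), `truth`
#'   (data.frame: `id`, `channel`, `t_mig1_fs`, `t_mig2_fs`, `origin1`,
#'   `origin2`, `t_co_init_fs`, `t_co_break3_fs` -- the time the O-C
#'   distance truly crosses 3 angstrom).
#' @export
generate_trajectory_ensemble <- function(config = generator_config(),
                                         seed = 1, n_traj = config$n_traj) {
  set.seed(seed)
  esc <- config$energy_ref_eV / config$energy_eV  # faster at higher energy
  tau1 <- config$tau_mig1_fs * esc
  off2 <- config$t2_offset_fs * esc
  tau2 <- config$tau_mig2_fs * esc
  alpha_h <- c(5L, 6L)
  beta_h <- c(7L, 8L, 9L)
  chan_names <- names(config$traj_channel_fractions)

  trajs <- vector("list", n_traj)
  truth <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    channel <- sample(chan_names, 1, prob = config$traj_channel_fractions)
    t1 <- t2 <- t_co <- NA_real_
    org1 <- org2 <- NA_character_
    atoms <- c(NA_integer_, NA_integer_)
    dt <- config$traj_dt_fs
    if (channel == "NHM") {
      t_co <- stats::rexp(1, 1 / (config$tau_mig_fs * esc))
    } else {
      org1 <- sample(c("alpha", "beta"), 1)
      atoms[1] <- if (org1 == "alpha") sample(alpha_h, 1) else sample(beta_h, 1)
      t1 <- max(stats::rexp(1, 1 / tau1), 2 * dt)
      if (channel == "SHM") {
        t_co <- t1 + config$co_delta_fs +
          stats::rnorm(1, 0, config$co_sigma_fs)
      } else {  # DHM: independent second migration drives the C-O break
        org2 <- sample(c("alpha", "beta"), 1)
        pool <- setdiff(if (org2 == "alpha") alpha_h else beta_h, atoms[1])
        atoms[2] <- if (length(pool) == 1) pool else sample(pool, 1)
        repeat {
          t2 <- off2 + stats::rexp(1, 1 / tau2)
          if (t2 > t1 + 2 * dt) break
        }
        t_co <- t2 + config$co_delta_fs +
          stats::rnorm(1, 0, config$co_sigma_fs)
      }
    }
    # events beyond the propagation window do not happen
    horizon <- config$traj_t_max_fs
    if (!is.na(t1) && t1 > horizon) { t1 <- t2 <- t_co <- NA; org1 <- org2 <- NA }
    if (!is.na(t2) && t2 > horizon) { t2 <- t_co <- NA; org2 <- NA }
    if (!is.na(t_co) && t_co > horizon) t_co <- NA

    st <- .script_trajectory(config, i, channel, t1, t2, atoms, t_co)
    trajs[[i]] <- st$traj
    t_break3 <- if (is.na(t_co)) NA_real_ else
      t_co + (3 - st$d0_co) / config$v_sep_A_fs
    if (!is.na(t_break3) && t_break3 > horizon) t_break3 <- NA_real_
    truth[[i]] <- data.frame(
      id = i, channel = channel, t_mig1_fs = t1, t_mig2_fs = t2,
      origin1 = org1, origin2 = org2, t_co_init_fs = t_co,
      t_co_break3_fs = t_break3, stringsAsFactors = FALSE)
  }
  list(trajectories = trajs, truth = do.call(rbind, truth))
}
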