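# shared fixtures built in code

k_coul <- ceimig::unit_system()$coulomb_constant_eV_angstrom

# an ethanol-based scripted trajectory in which one beta hydrogen moves
# linearly toward the oxygen so that d(H, O) first drops below `threshold`
# between frames cross_at and cross_at + 1 (0-based), and optionally
# recrosses outward and back
make_migration_traj <- function(dt_fs = 0.1, cross_at = 50, n_frames = 120,
                                threshold = 1.0, atom = 7L,
                                recross_at = NA) {
  geom <- ceimig::ethanol_geometry()
  o <- geom$xyz[3, ]
  h0 <- geom$xyz[atom, ]
  u <- (h0 - o) / sqrt(sum((h0 - o)^2))
  d0 <- sqrt(sum((h0 - o)^2))
  # distance crosses threshold midway between the two frames
  t_cross <- (cross_at + 0.5) * dt_fs
  tt <- (seq_len(n_frames) - 1) * dt_fs
  slope <- (threshold - d0) / t_cross
  d <- pmax(d0 + slope * tt, 0.8)
  if (!is.na(recross_at)) {
    # pop back above threshold and dip below again
    i <- tt >= recross_at * dt_fs & tt < (recross_at + 10) * dt_fs
    d[i] <- threshold + 0.3
  }
  frames <- array(geom$xyz, c(9, 3, n_frames))
  for (f in seq_len(n_frames)) frames[atom, , f] <- o + u * d[f]
  ceimig::trajectory(geom$elements, frames, dt_fs, id = 1L)
}

# trajectory in which the O(H) group separates from the alpha carbon at
# constant speed so that d(O, C_alpha) crosses `threshold` between frames
# cross_at and cross_at + 1 (0-based)
make_cobreak_traj <- function(dt_fs = 0.1, cross_at = 50, n_frames = 120,
                              threshold = 3.0, speed = NULL) {
  geom <- ceimig::ethanol_geometry()
  d0 <- sqrt(sum((geom$xyz[3, ] - geom$xyz[2, ])^2))
  e <- (geom$xyz[3, ] - geom$xyz[2, ]) / d0
  t_cross <- (cross_at + 0.5) * dt_fs
  if (is.null(speed)) speed <- (threshold - d0) / t_cross
  tt <- (seq_len(n_frames) - 1) * dt_fs
  frames <- array(geom$xyz, c(9, 3, n_frames))
  for (f in seq_len(n_frames)) {
    for (a in c(3L, 4L)) frames[a, , f] <- geom$xyz[a, ] + e * speed * tt[f]
  }
  ceimig::trajectory(geom$elements, frames, dt_fs, id = 1L)
}

# a momentum-conserving triple event (H+ + H2O+ + C2H3+)
make_triple_event <- function(p_h = c(5, -18, 0), p_h2o = c(-30, 25, 4)) {
  p <- rbind(p_h, p_h2o, -(p_h + p_h2o))
  ceimig::coincidence_event(c("H+", "H2O+", "C2H3+"), p)
}
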