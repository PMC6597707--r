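#' Default propagation settings for the point-charge simulator
#'
#' Velocity-Verlet step `dt_fs` (fs), simulated-time cap `t_cap_fs` (fs),
#' asymptote criterion `resid_frac` (terminate once the residual pairwise
#' Coulomb potential is below this fraction of the accumulated kinetic
#' energy), and the far-field step adaptation: beyond `r_adapt_A` angstrom of
#' closest pair separation the step grows proportionally to that separation,
#' capped at `dt_max_fs`.
#'
#' @return named list of settings.
#' @export
propagation_defaults <- function() {
  list(dt_fs = 0.05, t_cap_fs = 5e4, resid_frac = 1e-3,
       r_adapt_A = 50, dt_max_fs = 25)
}

#' Construct a table of charged bodies
#'
#' @param species character vector of species labels (catalogue names).
#' @param position n x 3 matrix, angstrom.
#' @param velocity n x 3 matrix, angstrom/fs (default: at rest).
#' @param charge elementary charges (default: catalogue charge).
#' @param mass amu (default: catalogue mass).
#' @return data.frame of class `cei_bodies`.
#' @export
charged_bodies <- function(species, position, velocity = NULL,
                           charge = NULL, mass = NULL) {
  position <- rbind(position)
  n <- nrow(position)
  if (is.null(velocity)) velocity <- matrix(0, n, 3)
  velocity <- rbind(velocity)
  if (is.null(mass)) mass <- species_mass(species)
  if (is.null(charge)) charge <- species_lookup(species)$charge
  stopifnot(length(species) == n, length(mass) == n, length(charge) == n,
            all(mass > 0), all(is.finite(position)), all(is.finite(velocity)))
  out <- data.frame(species = species, mass = mass, charge = as.numeric(charge),
                    x = position[, 1], y = position[, 2], z = position[, 3],
                    vx = velocity[, 1], vy = velocity[, 2], vz = velocity[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("cei_bodies", "data.frame")
  out
}

.check_separations <- function(pos, min_sep = 0.05) {
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  if (any(d < min_sep)) {
    stop("degenerate configuration: bodies closer than ", min_sep, " angstrom")
  }
}

#' Propagate charged point bodies under mutual Coulomb repulsion
#'
#' Velocity-Verlet integration of the classical equations of motion with
#' pairwise Coulomb forces; total momentum is conserved exactly (antisymmetric
#' pairwise forces) and total energy to the integration tolerance.
#'
#' @param bodies a `cei_bodies` table (see [charged_bodies()]).
#' @param t_end_fs simulated time to propagate (fs). With
#'   `to_asymptote = TRUE` this is a cap and propagation stops earlier once
#'   the asymptote criterion holds.
#' @param dt_fs base integration step (fs).
#' @param to_asymptote stop when the residual potential is below
#'   `settings$resid_frac` of the accumulated kinetic energy.
#' @param settings see [propagation_defaults()].
#' @return the propagated `cei_bodies` table, with attribute `diagnostics`
#'   (list: `t_fs`, `n_steps`, `kinetic_eV`, `potential_eV`,
#'   `energy_drift_eV`, `e0_eV`, `converged`).
#' @export
coulomb_propagate <- function(bodies, t_end_fs, dt_fs = propagation_defaults()$dt_fs,
                              to_asymptote = FALSE,
                              settings = propagation_defaults()) {
  stopifnot(nrow(bodies) >= 2, dt_fs > 0, t_end_fs >= 0)
  pos <- as.matrix(bodies[, c("x", "y", "z")])
  vel <- as.matrix(bodies[, c("vx", "vy", "vz")])
  .check_separations(pos)
  u <- unit_system()
  res <- propagate_coulomb_cpp(pos, vel, bodies$mass, bodies$charge,
                               dt_fs, t_end_fs, to_asymptote,
                               settings$resid_frac, settings$r_adapt_A,
                               settings$dt_max_fs,
                               u$coulomb_constant_eV_angstrom,
                               u$amu_angfs2_to_eV)
  out <- bodies
  out[, c("x", "y", "z")] <- res$pos
  out[, c("vx", "vy", "vz")] <- res$vel
  attr(out, "diagnostics") <- res[c("t", "n_steps", "kinetic_eV", "potential_eV",
                                    "energy_drift_eV", "e0_eV", "converged")]
  names(attr(out, "diagnostics"))[1] <- "t_fs"
  out
}

#' Momenta (a.u.) of a propagated body table
#'
#' @param bodies a `cei_bodies` table.
#' @return n x 3 matrix of momenta in atomic units.
#' @export
body_momenta_au <- function(bodies) {
  u <- unit_system()
  as.matrix(bodies[, c("vx", "vy", "vz")]) * bodies$mass *
    u$amu_angfs_to_au_momentum
}

#' Uniform random rotation matrix
#'
#' Uniform over SO(3) via a normalized Gaussian quaternion drawn from the
#' current RNG stream.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

.event_from_bodies <- function(bodies, diag_list, process = "concerted",
                               t_ionize_fs = NA_real_) {
  p <- body_momenta_au(bodies)
  ke <- diag_list[[length(diag_list)]]$kinetic_eV
  ev <- coincidence_event(bodies$species, p, delay_fs = NA_real_,
                          source = "simulated")
  attr(ev, "ker_eV") <- ke
  attr(ev, "process") <- process
  attr(ev, "t_ionize_fs") <- t_ionize_fs
  attr(ev, "energy_drift_eV") <- max(vapply(diag_list, function(d)
    d$energy_drift_eV, 0))
  attr(ev, "e0_eV") <- diag_list[[1]]$e0_eV
  ev
}

#' Concerted Coulomb explosion of one fragmentation channel
#'
#' Unit point charges are placed at the centres of mass of the channel's
#' fragments within the intact ethanol geometry, a uniform random orientation
#' is applied, and the bodies are propagated from rest to the Coulomb
#' asymptote. Momenta are returned in the parent rest frame.
#'
#' @param channel channel name (`"NHM"`, `"SHM"`, `"DHM"`, `"TRIPLE"`).
#' @param geometry a `cei_geometry` (default [ethanol_geometry()]).
#' @param seed optional integer seed (`NULL`: use current RNG stream).
#' @param settings propagation settings.
#' @return a `cei_event` (see [coincidence_event()]) with attributes
#'   `ker_eV`, `process`, `energy_drift_eV`.
#' @export
simulate_concerted <- function(channel, geometry = ethanol_geometry(),
                               seed = NULL, settings = propagation_defaults()) {
  if (!is.null(seed)) set.seed(seed)
  frag <- channel_fragment_atoms(channel)
  com <- t(vapply(frag, function(idx) atom_com(geometry, idx), numeric(3)))
  rot <- random_rotation()
  com <- com %*% t(rot)
  bodies <- charged_bodies(names(frag), com, charge = rep(1, nrow(com)))
  bodies <- coulomb_propagate(bodies, settings$t_cap_fs, settings$dt_fs,
                              to_asymptote = TRUE, settings = settings)
  .event_from_bodies(bodies, list(attr(bodies, "diagnostics")),
                     process = "concerted")
}

#' Sequential breakup process definitions
#'
#' The three sequential pathways feeding the triple coincidence channel
#' H+ + H2O+ + C2H3+: process i ejects C2H3+ first (leaving H3O+), process
#' ii ejects H2O+ first (leaving C2H4+), process iii ejects H+ first
#' (deprotonation, leaving C2H5O+). In the second step the intermediate is
#' ionized once more and splits into its two daughters.
#'
#' @details The daughter separation of the proton-releasing second steps is
#'   a charge-separation distance (3 angstrom), not the covalent bond
#'   length: treating the fragments as point charges already at the
#'   equilibrium bond length would release the full bare-Coulomb energy
#'   (~15 eV for O-H), far above the few-eV kinetic energy releases such
#'   two-body proton eliminations produce; the heavy-pair split of the
#'   deprotonation pathway uses the centre-of-mass distance of its
#'   daughters within the intact geometry.
#' @return named list (`seq_i`, `seq_ii`, `seq_iii`); each entry lists the
#'   first ejected species, the intermediate, the daughters, the atom-index
#'   sets within [ethanol_geometry()], and the daughter centre-of-mass
#'   separation (angstrom) used for isotropic step-2 placement.
#' @export
process_defs <- function() {
  list(
    seq_i = list(
      id = "seq_i", first = "C2H3+", intermediate = "H3O+",
      daughters = c("H+", "H2O+"),
      first_atoms = c(1L, 2L, 6L, 8L, 9L),
      intermediate_atoms = c(3L, 4L, 5L, 7L),
      daughter_atoms = list(7L, c(3L, 4L, 5L)),
      daughter_sep_A = 3.0),
    seq_ii = list(
      id = "seq_ii", first = "H2O+", intermediate = "C2H4+",
      daughters = c("H+", "C2H3+"),
      first_atoms = c(3L, 4L, 5L),
      intermediate_atoms = c(1L, 2L, 6L, 7L, 8L, 9L),
      daughter_atoms = list(7L, c(1L, 2L, 6L, 8L, 9L)),
      daughter_sep_A = 3.0),
    seq_iii = list(
      id = "seq_iii", first = "H+", intermediate = "C2H5O+",
      daughters = c("H2O+", "C2H3+"),
      first_atoms = 7L,
      intermediate_atoms = c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 9L),
      daughter_atoms = list(c(3L, 4L, 5L), c(1L, 2L, 6L, 8L, 9L)),
      daughter_sep_A = 2.30)
  )
}

#' Two-step sequential Coulomb explosion
#'
#' Step 1: the dication (two unit charges at the centres of mass of the first
#' fragment and the intermediate) explodes from rest for `t_ionize_fs`.
#' Step 2: the intermediate is ionized once more (+1) and split into its two
#' daughters -- placed around the intermediate's centre of mass with its
#' velocity (zero internal velocity), either along a uniformly random
#' direction at the equilibrium daughter separation (`"isotropic"`) or at
#' the daughters' centres of mass within the intact geometry (`"geometry"`,
#' which at `t_ionize_fs = 0` reduces to the concerted three-body explosion).
#' The three bodies are then propagated to the Coulomb asymptote.
#'
#' @param process a process id (`"seq_i"`, `"seq_ii"`, `"seq_iii"`) or an
#'   entry of [process_defs()].
#' @param t_ionize_fs delay of the second ionization step (fs, >= 0).
#' @param seed optional integer seed.
#' @param daughter_placement `"isotropic"` or `"geometry"`.
#' @param geometry a `cei_geometry`.
#' @param settings propagation settings.
#' @return a `cei_event` with attributes `ker_eV`, `process`,
#'   `t_ionize_fs`, `energy_drift_eV`.
#' @export
simulate_sequential <- function(process, t_ionize_fs, seed = NULL,
                                daughter_placement = c("isotropic", "geometry"),
                                geometry = ethanol_geometry(),
                                settings = propagation_defaults()) {
  if (!is.null(seed)) set.seed(seed)
  daughter_placement <- match.arg(daughter_placement)
  if (is.character(process)) {
    defs <- process_defs()
    if (!process %in% names(defs)) {
      stop("unknown process: ", process, "; known: ",
           paste(names(defs), collapse = ", "))
    }
    process <- defs[[process]]
  }
  stopifnot(t_ionize_fs >= 0)

  rot <- random_rotation()
  geom_rot <- geometry
  geom_rot$xyz <- geometry$xyz %*% t(rot)

  com_first <- atom_com(geom_rot, process$first_atoms)
  com_inter <- atom_com(geom_rot, process$intermediate_atoms)
  bodies1 <- charged_bodies(c(process$first, process$intermediate),
                            rbind(com_first, com_inter),
                            charge = c(1, 1))
  diags <- list()
  if (t_ionize_fs > 0) {
    bodies1 <- coulomb_propagate(bodies1, t_ionize_fs, settings$dt_fs,
                                 to_asymptote = FALSE, settings = settings)
    diags <- c(diags, list(attr(bodies1, "diagnostics")))
  }

  md <- species_mass(process$daughters)
  inter_pos <- as.numeric(bodies1[2, c("x", "y", "z")])
  inter_vel <- as.numeric(bodies1[2, c("vx", "vy", "vz")])
  first_pos <- as.numeric(bodies1[1, c("x", "y", "z")])

  place <- function() {
    if (daughter_placement == "geometry") {
      dp <- t(vapply(process$daughter_atoms,
                     function(idx) atom_com(geom_rot, idx), numeric(3)))
      com0 <- drop(md %*% dp) / sum(md)
      dp + matrix(inter_pos - com0, 2, 3, byrow = TRUE)
    } else {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      d <- process$daughter_sep_A
      rbind(inter_pos + u * d * md[2] / sum(md),
            inter_pos - u * d * md[1] / sum(md))
    }
  }
  dpos <- place()
  tries <- 0
  while (min(sqrt(colSums((t(dpos) - first_pos)^2))) < 0.05) {
    tries <- tries + 1
    if (tries >= 10 || daughter_placement == "geometry") {
      stop("step-2 daughters overlap the first fragment after ", tries,
           " retries")
    }
    dpos <- place()
  }

  bodies2 <- charged_bodies(
    c(process$first, process$daughters),
    rbind(first_pos, dpos),
    velocity = rbind(as.numeric(bodies1[1, c("vx", "vy", "vz")]),
                     inter_vel, inter_vel),
    charge = c(1, 1, 1))
  bodies2 <- coulomb_propagate(bodies2, settings$t_cap_fs, settings$dt_fs,
                               to_asymptote = TRUE, settings = settings)
  diags <- c(diags, list(attr(bodies2, "diagnostics")))
  .event_from_bodies(bodies2, diags, process = process$id,
                     t_ionize_fs = t_ionize_fs)
}

#' Ensemble of sequential-breakup events
#'
#' `n` independent events with random orientation and second-step ionization
#' delays drawn from an exponential distribution (memoryless stand-in for the
#' probe arrival), reproducible from `seed`.
#'
#' @param process process id or definition (see [simulate_sequential()]).
#' @param n number of events.
#' @param seed integer seed.
#' @param t_ionize_mean_fs mean of the exponential ionization-delay
#'   distribution (fs); or pass fixed delays via `t_ionize_fs`.
#' @param t_ionize_fs optional vector of fixed delays (length 1 or n),
#'   overriding the exponential draw.
#' @param ... further arguments to [simulate_sequential()].
#' @return list of `cei_event`s.
#' @export
simulate_process_ensemble <- function(process, n, seed = 1,
                                      t_ionize_mean_fs = 300,
                                      t_ionize_fs = NULL, ...) {
  stopifnot(n >= 1)
  set.seed(seed)
  tt <- if (is.null(t_ionize_fs)) {
    stats::rexp(n, rate = 1 / t_ionize_mean_fs)
  } else {
    rep_len(t_ionize_fs, n)
  }
  lapply(seq_len(n), function(i) {
    simulate_sequential(process, t_ionize_fs = tt[i], seed = NULL, ...)
  })
}
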