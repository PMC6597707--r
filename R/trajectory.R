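#' Construct a trajectory object
#'
#' Element labels plus per-frame Cartesian coordinates at a fixed timestep,
#' as produced by molecular-dynamics propagation of an ethanol ion.
#'
#' @param elements character vector of element symbols (H, C, O).
#' @param frames 3D array `[atoms, 3, frames]` of coordinates (angstrom).
#' @param dt_fs timestep between frames (fs), > 0.
#' @param charge precursor charge state (1 or 2).
#' @param energy_eV internal (vibrational) excitation energy metadata (eV).
#' @param id trajectory identifier.
#' @return list of class `cei_trajectory`.
#' @export
trajectory <- function(elements, frames, dt_fs, charge = 2L,
                       energy_eV = NA_real_, id = NA_integer_) {
  stopifnot(dt_fs > 0, length(dim(frames)) == 3,
            dim(frames)[1] == length(elements), dim(frames)[2] == 3)
  bad <- setdiff(unique(elements), c("H", "C", "O"))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  structure(list(elements = elements, frames = frames, dt_fs = dt_fs,
                 charge = charge, energy_eV = energy_eV, id = id),
            class = "cei_trajectory")
}

#' Number of frames / time span of a trajectory
#' @param traj a `cei_trajectory`.
#' @return integer frame count / time spanned (fs, `(n-1) * dt`).
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' @rdname n_frames
#' @export
time_span_fs <- function(traj) (n_frames(traj) - 1) * traj$dt_fs

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ dialect: per frame an atom-count line, a comment line, then
#' one `element x y z` line per atom. All frames must have the same atom
#' count and element ordering.
#'
#' @param path file path.
#' @param dt_fs timestep between frames (fs).
#' @param ... further metadata passed to [trajectory()].
#' @return a `cei_trajectory`.
#' @export
read_xyz_trajectory <- function(path, dt_fs, ...) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0) stop("empty XYZ file: ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat) || nat < 1) stop("malformed atom-count line in ", path)
  per <- nat + 2L
  nframe <- length(lines) / per
  if (nframe != floor(nframe)) {
    stop("file length is not a whole number of ", per, "-line frames")
  }
  nframe <- as.integer(nframe)
  counts <- suppressWarnings(as.integer(trimws(lines[(seq_len(nframe) - 1) * per + 1])))
  if (any(is.na(counts) | counts != nat)) {
    stop("inconsistent atom count at frame ",
         which(is.na(counts) | counts != nat)[1])
  }
  body <- lines[-(rep((seq_len(nframe) - 1) * per, each = 2) + c(1L, 2L))]
  fields <- strsplit(trimws(body), "[[:space:]]+")
  elements <- vapply(fields[seq_len(nat)], `[[`, "", 1)
  coords <- matrix(as.numeric(unlist(lapply(fields, `[`, 2:4))), ncol = 3,
                   byrow = TRUE)
  if (anyNA(coords)) stop("non-numeric coordinates in ", path)
  frames <- array(NA_real_, c(nat, 3, nframe))
  for (f in seq_len(nframe)) {
    el <- vapply(fields[(f - 1) * nat + seq_len(nat)], `[[`, "", 1)
    if (!identical(el, elements)) stop("element ordering differs at frame ", f)
    frames[, , f] <- coords[(f - 1) * nat + seq_len(nat), ]
  }
  trajectory(elements, frames, dt_fs, ...)
}

#' Write a trajectory as a multi-frame XYZ file
#'
#' @param traj a `cei_trajectory`.
#' @param path output path.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 6) {
  nat <- length(traj$elements)
  nf <- n_frames(traj)
  fmt <- sprintf("%%-2s %%.%df %%.%df %%.%df", digits, digits, digits)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(as.character(nat),
                 sprintf("frame %d t= %g fs", f - 1, (f - 1) * traj$dt_fs),
                 sprintf(fmt, traj$elements, traj$frames[, 1, f],
                         traj$frames[, 2, f], traj$frames[, 3, f])), con)
  }
  invisible(path)
}

# per-frame distance between atoms i and j: vector over frames
.pair_distance <- function(traj, i, j) {
  d <- traj$frames[i, , , drop = FALSE] - traj$frames[j, , , drop = FALSE]
  sqrt(colSums(matrix(d, nrow = 3)^2))
}

.oxygen_index <- function(traj) {
  o <- which(traj$elements == "O")
  if (length(o) != 1) stop("expected exactly one O atom, found ", length(o))
  o
}

#' Hydrogen migration times of a trajectory
#'
#' A non-hydroxyl hydrogen counts as migrated at the first frame where its
#' distance to the oxygen atom drops below `threshold_A` (1 angstrom by
#' default); later re-crossings are ignored. The hydrogen already within the
#' threshold at frame 0 (the original hydroxyl H) is excluded, so a single
#' migration marks H2O+ formation and two mark H3O+. Each migrating H is
#' labelled by its origin -- the carbon nearest to it at frame 0, alpha
#' (adjacent to O) or beta (terminal).
#'
#' @param traj a `cei_trajectory` (one O atom).
#' @param threshold_A O-H distance threshold (angstrom).
#' @return list: `t_mig1_fs`, `t_mig2_fs` (fs, `NA` if absent),
#'   `origin1`, `origin2` (`"alpha"`/`"beta"`/`NA`), and `crossings`
#'   (data.frame of all migrating H atoms: `atom`, `t_fs`, `origin`).
#' @export
migration_times <- function(traj, threshold_A = 1.0) {
  o <- .oxygen_index(traj)
  cs <- which(traj$elements == "C")
  hs <- which(traj$elements == "H")
  # alpha carbon = carbon closest to O at frame 0
  d_oc0 <- sqrt(colSums((t(traj$frames[cs, , 1]) - traj$frames[o, , 1])^2))
  alpha_c <- cs[which.min(d_oc0)]
  atom <- integer(0); t_fs <- numeric(0); origin <- character(0)
  for (h in hs) {
    d <- .pair_distance(traj, h, o)
    if (d[1] < threshold_A) next  # original hydroxyl H
    k <- which(d < threshold_A)
    if (length(k) == 0) next
    d_hc0 <- sqrt(colSums((t(traj$frames[cs, , 1]) - traj$frames[h, , 1])^2))
    atom <- c(atom, h)
    t_fs <- c(t_fs, (min(k) - 1) * traj$dt_fs)
    origin <- c(origin,
                if (cs[which.min(d_hc0)] == alpha_c) "alpha" else "beta")
  }
  ord <- order(t_fs, atom)  # same-frame ties broken by atom index
  crossings <- data.frame(atom = atom[ord], t_fs = t_fs[ord],
                          origin = origin[ord], stringsAsFactors = FALSE)
  list(t_mig1_fs = if (nrow(crossings) >= 1) crossings$t_fs[1] else NA_real_,
       t_mig2_fs = if (nrow(crossings) >= 2) crossings$t_fs[2] else NA_real_,
       origin1 = if (nrow(crossings) >= 1) crossings$origin[1] else NA_character_,
       origin2 = if (nrow(crossings) >= 2) crossings$origin[2] else NA_character_,
       crossings = crossings)
}

#' Carbon-oxygen bond-break time
#'
#' First frame where the distance between the oxygen and the carbon it
#' departs from (the carbon nearest O at frame 0) exceeds `threshold_A`
#' (3 angstrom by default).
#'
#' @param traj a `cei_trajectory` (one O, two C atoms).
#' @param threshold_A O-C distance threshold (angstrom).
#' @return break time (fs) or `NA` if the bond never opens.
#' @export
co_break_time <- function(traj, threshold_A = 3.0) {
  o <- .oxygen_index(traj)
  cs <- which(traj$elements == "C")
  if (length(cs) != 2) stop("expected exactly two C atoms")
  d0 <- sqrt(colSums((t(traj$frames[cs, , 1]) - traj$frames[o, , 1])^2))
  ca <- cs[which.min(d0)]
  d <- .pair_distance(traj, o, ca)
  k <- which(d > threshold_A)
  if (length(k) == 0) NA_real_ else (min(k) - 1) * traj$dt_fs
}

#' Classify the final frame into a fragmentation channel
#'
#' Builds the bond graph of the last frame (bond iff distance <
#' `bond_scale` x sum of covalent radii; H 0.31, C 0.76, O 0.66 angstrom),
#' takes connected components, maps their compositions to species, and
#' matches the resulting fragment set against the channel definitions.
#'
#' @param traj a `cei_trajectory`.
#' @param bond_scale dimensionless scale on the covalent-radius sum.
#' @return channel label (`"NHM"`, `"SHM"`, `"DHM"`, `"TRIPLE"`),
#'   `"unfragmented"`, or `"other"`; attribute `fragments` holds the
#'   component compositions as formula strings.
#' @export
final_fragments <- function(traj, bond_scale = 1.2) {
  nat <- length(traj$elements)
  xyz <- traj$frames[, , n_frames(traj)]
  r <- .covalent_radius[traj$elements]
  d <- as.matrix(stats::dist(xyz))
  bonded <- d < bond_scale * outer(r, r, `+`)
  comp <- .connected_components(bonded)
  formula <- function(idx) {
    cc <- table(factor(traj$elements[idx], levels = c("C", "H", "O")))
    paste0(ifelse(cc > 0, paste0(names(cc), ifelse(cc > 1, cc, "")), ""),
           collapse = "")
  }
  frags <- sort(unname(vapply(comp, formula, "")))
  # formulas follow C, H, O element order (e.g. OH prints as "HO")
  label <- if (length(frags) == 1) "unfragmented"
  else if (identical(frags, sort(c("HO", "C2H5")))) "NHM"
  else if (identical(frags, sort(c("H2O", "C2H4")))) "SHM"
  else if (identical(frags, sort(c("H3O", "C2H3")))) "DHM"
  else if (identical(frags, sort(c("H", "H2O", "C2H3")))) "TRIPLE"
  else "other"
  structure(label, fragments = frags)
}

.connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  split(seq_len(n), comp)
}

#' Full migration record of one trajectory
#'
#' Applies [migration_times()], [co_break_time()] and [final_fragments()]
#' and assembles the per-trajectory record row. The channel-defining event
#' time is the migration completing the species (first migration for SHM,
#' second for DHM) and the C-O break time for NHM.
#'
#' @param traj a `cei_trajectory`.
#' @param migration_threshold_A,co_threshold_A,bond_scale see the
#'   underlying operations.
#' @return one-row data.frame: `id`, `charge`, `energy_eV`, `t_mig1_fs`,
#'   `t_mig2_fs`, `origin1`, `origin2`, `t_co_break_fs`, `channel`,
#'   `t_event_fs`.
#' @export
migration_record <- function(traj, migration_threshold_A = 1.0,
                             co_threshold_A = 3.0, bond_scale = 1.2) {
  mig <- migration_times(traj, migration_threshold_A)
  tco <- co_break_time(traj, co_threshold_A)
  chan <- as.character(final_fragments(traj, bond_scale))
  t_event <- switch(chan,
                    NHM = tco,
                    SHM = mig$t_mig1_fs,
                    DHM = mig$t_mig2_fs,
                    TRIPLE = mig$t_mig2_fs,
                    NA_real_)
  data.frame(id = traj$id, charge = traj$charge, energy_eV = traj$energy_eV,
             t_mig1_fs = mig$t_mig1_fs, t_mig2_fs = mig$t_mig2_fs,
             origin1 = mig$origin1, origin2 = mig$origin2,
             t_co_break_fs = tco, channel = chan, t_event_fs = t_event,
             stringsAsFactors = FALSE)
}

#' Migration records for a trajectory ensemble
#'
#' @param trajs list of `cei_trajectory`s.
#' @param ... passed to [migration_record()].
#' @return data.frame, one row per trajectory.
#' @export
migration_records <- function(trajs, ...) {
  do.call(rbind, lapply(trajs, migration_record, ...))
}
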