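#' Construct a coincidence event
#'
#' One detected (or simulated) fragmentation: an ordered set of fragments
#' with species labels and momentum 3-vectors in atomic units, plus the
#' pump-probe delay and provenance.
#'
#' @param species character vector of fragment species labels.
#' @param momenta n x 3 matrix of momenta (a.u.).
#' @param delay_fs pump-probe delay (fs; signed, negative = the stronger
#'   pulse arrives first).
#' @param shot_id integer laser shot-pair id.
#' @param source one of `"pump_probe"`, `"single_pulse"`, `"simulated"`.
#' @return list of class `cei_event` with elements `species`, `p` (matrix),
#'   `delay_fs`, `shot_id`, `source`.
#' @export
coincidence_event <- function(species, momenta, delay_fs = NA_real_,
                              shot_id = NA_integer_, source = "pump_probe") {
  momenta <- rbind(momenta)
  stopifnot(length(species) == nrow(momenta), nrow(momenta) >= 2,
            all(is.finite(momenta)))
  structure(list(species = species, p = unname(momenta), delay_fs = delay_fs,
                 shot_id = shot_id, source = source),
            class = "cei_event")
}

#' Non-relativistic kinetic energy from momentum
#'
#' E = |p|^2 / (2 m), with p in atomic units of momentum and m in amu,
#' returned in eV.
#'
#' @param momentum 3-vector or n x 3 matrix of momenta (a.u.).
#' @param mass_amu mass in amu (> 0), scalar or length n.
#' @return energy (eV), scalar or length n.
#' @export
kinetic_energy <- function(momentum, mass_amu) {
  if (any(mass_amu <= 0)) stop("mass must be positive")
  momentum <- rbind(momentum)
  u <- unit_system()
  p2 <- unname(rowSums(momentum^2))              # a.u.^2
  (p2 / (2 * mass_amu * u$amu_to_au_mass)) * u$hartree_to_eV
}

#' Kinetic energy release of an event
#'
#' Sum of the fragments' kinetic energies; fragment masses come from the
#' species catalogue.
#'
#' @param event a `cei_event`.
#' @return KER in eV.
#' @export
ker <- function(event) {
  sum(kinetic_energy(event$p, species_mass(event$species)))
}

#' Newton-frame transformation of a three-fragment event
#'
#' Rotates (and if needed reflects) the three momenta into the molecular
#' frame fixed by the reference fragment: the reference momentum lies along
#' the positive parallel axis (p_perp = 0), the `upper` species has
#' p_perp >= 0 and the `lower` species p_perp <= 0. The event plane is
#' spanned by the reference and upper momenta; the lower fragment's
#' out-of-plane component is folded into its signed transverse component so
#' that every momentum magnitude is preserved (for momentum-conserving
#' events all three momenta are coplanar and the fold is exact).
#'
#' @param event a `cei_event` with exactly three fragments.
#' @param reference,upper,lower species labels present in the event
#'   (defaults: the triple coincidence convention with C2H3+ as reference,
#'   H2O+ upper, H+ lower).
#' @return data.frame with columns `species`, `p_parallel`, `p_perp`, `p`
#'   (all a.u.), rows ordered reference, upper, lower.
#' @export
newton_transform <- function(event, reference = "C2H3+", upper = "H2O+",
                             lower = "H+") {
  stopifnot(length(event$species) == 3)
  idx <- match(c(reference, upper, lower), event$species)
  if (any(is.na(idx))) {
    stop("event does not contain the three species ",
         paste(c(reference, upper, lower), collapse = ", "))
  }
  pr <- event$p[idx[1], ]
  pu <- event$p[idx[2], ]
  pl <- event$p[idx[3], ]
  nr <- sqrt(sum(pr^2))
  if (nr < 1e-9) stop("reference momentum vanishes; Newton frame undefined")
  ex <- pr / nr
  yv <- pu - sum(pu * ex) * ex
  ny <- sqrt(sum(yv^2))
  ey <- if (ny < 1e-12) {
    # upper parallel to reference: any transverse axis serves
    v <- if (abs(ex[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- v - sum(v * ex) * ex
    v / sqrt(sum(v^2))
  } else {
    yv / ny
  }
  comp <- function(p) {
    ppar <- sum(p * ex)
    pperp2 <- max(sum(p^2) - ppar^2, 0)
    s <- sum(p * ey)
    c(ppar, sign(if (s == 0) 1 else s) * sqrt(pperp2))
  }
  m <- rbind(c(nr, 0), comp(pu), comp(pl))
  # lower-half convention for the lower species
  if (m[3, 2] > 0) m[3, 2] <- -m[3, 2]
  data.frame(species = c(reference, upper, lower),
             p_parallel = m[, 1], p_perp = m[, 2],
             p = sqrt(m[, 1]^2 + m[, 2]^2),
             stringsAsFactors = FALSE)
}

#' Dalitz coordinates of a three-body energy sharing
#'
#' x_d = (E_C2H3 - E_H2O) / (sqrt(3) * KER), y_d = E_H / KER - 1/3, with
#' KER the sum of the three fragment energies. Every physical
#' (momentum-conserving) event falls inside y_d in [-1/3, 2/3],
#' |x_d| <= 1/sqrt(3).
#'
#' @param e_c2h3,e_h2o,e_h fragment kinetic energies (eV, >= 0); vectorized.
#' @return data.frame with columns `x_d`, `y_d`.
#' @export
dalitz_coordinates <- function(e_c2h3, e_h2o, e_h) {
  if (any(c(e_c2h3, e_h2o, e_h) < 0)) stop("energies must be non-negative")
  tot <- e_c2h3 + e_h2o + e_h
  if (any(tot <= 0)) stop("KER must be positive")
  data.frame(x_d = (e_c2h3 - e_h2o) / (sqrt(3) * tot),
             y_d = e_h / tot - 1 / 3)
}

#' Dalitz coordinates of a triple coincidence event
#'
#' @param event a `cei_event` containing H+, H2O+ and C2H3+.
#' @return one-row data.frame with `x_d`, `y_d`.
#' @export
dalitz_from_event <- function(event) {
  idx <- match(c("C2H3+", "H2O+", "H+"), event$species)
  if (any(is.na(idx))) stop("event is not a H+ + H2O+ + C2H3+ triple")
  e <- kinetic_energy(event$p[idx, ], species_mass(event$species[idx]))
  dalitz_coordinates(e[1], e[2], e[3])
}

#' Split triple events by proton momentum magnitude
#'
#' Partition of events by |p(H+)| against a split value (half-open
#' convention: the boundary value goes to the high list), mirroring the
#' separation of the Newton-plot inner and outer arches at 20 a.u.
#'
#' @param events list of `cei_event`s, each containing an H+ fragment
#'   (events without one are skipped and counted).
#' @param p_split_au split value (a.u.).
#' @return list with elements `low`, `high` (event lists) and `n_skipped`.
#' @export
split_by_proton_momentum <- function(events, p_split_au = 20) {
  low <- list(); high <- list(); skipped <- 0L
  for (ev in events) {
    i <- match("H+", ev$species)
    if (is.na(i)) { skipped <- skipped + 1L; next }
    pm <- sqrt(sum(ev$p[i, ]^2))
    if (pm < p_split_au) low[[length(low) + 1L]] <- ev
    else high[[length(high) + 1L]] <- ev
  }
  if (skipped > 0) warning(skipped, " events without an H+ fragment skipped")
  list(low = low, high = high, n_skipped = skipped)
}

#' Convert between event lists and long event tables
#'
#' The long table has one row per fragment: `event_id`, `shot_id`,
#' `delay_fs`, `source`, `species`, `px_au`, `py_au`, `pz_au`.
#'
#' @param events list of `cei_event`s.
#' @return data.frame (long format).
#' @export
events_to_table <- function(events) {
  if (length(events) == 0) {
    return(data.frame(event_id = integer(), shot_id = integer(),
                      delay_fs = numeric(), source = character(),
                      species = character(), px_au = numeric(),
                      py_au = numeric(), pz_au = numeric()))
  }
  do.call(rbind, lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    data.frame(event_id = i, shot_id = ev$shot_id, delay_fs = ev$delay_fs,
               source = ev$source, species = ev$species,
               px_au = ev$p[, 1], py_au = ev$p[, 2], pz_au = ev$p[, 3],
               stringsAsFactors = FALSE)
  }))
}

#' @rdname events_to_table
#' @param table a long event table.
#' @export
events_from_table <- function(table) {
  lapply(split(table, table$event_id), function(d) {
    coincidence_event(d$species, as.matrix(d[, c("px_au", "py_au", "pz_au")]),
                      delay_fs = d$delay_fs[1], shot_id = d$shot_id[1],
                      source = d$source[1])
  })
}
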