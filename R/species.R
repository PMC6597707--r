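.atomic_mass <- c(H = 1.00782503, C = 12.0, O = 15.99491462)

# covalent radii (angstrom) used for bond detection throughout
.covalent_radius <- c(H = 0.31, C = 0.76, O = 0.66)

#' Fragment species catalogue
#'
#' All ionic fragments appearing in the two-body channels (no / single /
#' double hydrogen migration: OH+ + C2H5+, H2O+ + C2H4+, H3O+ + C2H3+), the
#' triple coincidence channel H+ + H2O+ + C2H3+, and the sequential-breakup
#' intermediates. Masses are sums of isotopic atomic masses (amu); species
#' separation is by nominal (integer) mass over charge.
#'
#' @return A data.frame with one row per species: `name`, `mass` (amu),
#'   `nominal_mass` (integer amu), `charge` (elementary charges), and a
#'   `composition` list column of element counts.
#' @export
species_catalog <- function() {
  comp <- list(
    "H+"      = c(H = 1),
    "OH+"     = c(O = 1, H = 1),
    "H2O+"    = c(O = 1, H = 2),
    "H3O+"    = c(O = 1, H = 3),
    "C2H3+"   = c(C = 2, H = 3),
    "C2H4+"   = c(C = 2, H = 4),
    "C2H5+"   = c(C = 2, H = 5),
    "C2H5O+"  = c(C = 2, H = 5, O = 1)
  )
  mass <- vapply(comp, function(cc) sum(.atomic_mass[names(cc)] * cc), 0)
  data.frame(
    name         = names(comp),
    mass         = unname(mass),
    nominal_mass = as.integer(round(unname(mass))),
    charge       = 1L,
    composition  = I(unname(comp)),
    stringsAsFactors = FALSE
  )
}

#' Look up one species in the catalogue
#'
#' @param name species label, e.g. `"H3O+"`.
#' @return A one-row data.frame (see [species_catalog()]).
#' @export
species_lookup <- function(name) {
  cat <- species_catalog()
  i <- match(name, cat$name)
  if (any(is.na(i))) {
    stop("unknown species: ", paste(name[is.na(i)], collapse = ", "),
         "; known: ", paste(cat$name, collapse = ", "))
  }
  cat[i, , drop = FALSE]
}

#' Species masses in amu
#'
#' @param name character vector of species labels.
#' @return numeric vector of masses (amu).
#' @export
species_mass <- function(name) species_lookup(name)$mass

#' Equilibrium geometry of ethanol (anti conformer)
#'
#' Hard-coded gas-phase equilibrium geometry of the anti (trans) conformer of
#' ethanol, CH3-CH2-OH, built from standard bond lengths (C-C 1.52, C-O 1.43,
#' C-H 1.09, O-H 0.97 angstrom) and tetrahedral angles. Atom roles
#' distinguish the carbon adjacent to oxygen (C_alpha) from the terminal
#' methyl carbon (C_beta), and the hydroxyl / alpha / beta hydrogens.
#'
#' @param conformer only `"anti"` is implemented; the gauche conformer is a
#'   placeholder option.
#' @return A list of class `cei_geometry`: `elements` (character),
#'   `xyz` (9 x 3 matrix, angstrom), `roles` (character).
#' @export
ethanol_geometry <- function(conformer = c("anti", "gauche")) {
  conformer <- match.arg(conformer)
  if (conformer == "gauche") {
    stop("only the anti conformer geometry is implemented")
  }
  xyz <- rbind(
    c(-1.5200,  0.0000,  0.0000),  # C_beta
    c( 0.0000,  0.0000,  0.0000),  # C_alpha
    c( 0.4419,  1.3599,  0.0000),  # O
    c( 1.4119,  1.3687,  0.0000),  # hydroxyl H (anti to C_beta)
    c( 0.3698, -0.5089,  0.8901),  # alpha H
    c( 0.3698, -0.5089, -0.8901),  # alpha H
    c(-1.8838, -1.0274,  0.0000),  # beta H (anti to O)
    c(-1.8838,  0.5137,  0.8898),  # beta H
    c(-1.8838,  0.5137, -0.8898)   # beta H
  )
  structure(list(
    elements = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    xyz      = xyz,
    roles    = c("C_beta", "C_alpha", "O", "hydroxyl-H",
                 "alpha-H", "alpha-H", "beta-H", "beta-H", "beta-H")
  ), class = "cei_geometry")
}

#' Atom-index partition of ethanol into the fragments of each channel
#'
#' Maps each fragmentation channel to the atom indices (into
#' [ethanol_geometry()]) making up each fragment, in the channel's species
#' order. The migrated hydrogens are one alpha H for the single migration and
#' one alpha plus one beta H for the double migration; the ejected proton of
#' the triple channel is a beta H.
#'
#' @param channel one of `"NHM"`, `"SHM"`, `"DHM"`, `"TRIPLE"`.
#' @return named list of integer vectors (names = species labels).
#' @keywords internal
channel_fragment_atoms <- function(channel) {
  switch(channel,
    NHM    = list("OH+"   = c(3L, 4L),
                  "C2H5+" = c(1L, 2L, 5L, 6L, 7L, 8L, 9L)),
    SHM    = list("H2O+"  = c(3L, 4L, 5L),
                  "C2H4+" = c(1L, 2L, 6L, 7L, 8L, 9L)),
    DHM    = list("H3O+"  = c(3L, 4L, 5L, 7L),
                  "C2H3+" = c(1L, 2L, 6L, 8L, 9L)),
    TRIPLE = list("H+"    = 7L,
                  "H2O+"  = c(3L, 4L, 5L),
                  "C2H3+" = c(1L, 2L, 6L, 8L, 9L)),
    stop("unknown channel: ", channel,
         "; known: NHM, SHM, DHM, TRIPLE")
  )
}

#' Coincidence channel definitions
#'
#' The four analysis channels with their species lists, default KER gates
#' (half-open, eV) and the default momentum-conservation threshold used by
#' the coincidence gate.
#'
#' @return named list of channel definitions; each has `name`, `species`,
#'   `ker_gate` (two-element numeric, `[low, high)` eV; for the triple
#'   channel the low/high KER sub-gates are in `ker_subgates`), and
#'   `momentum_sum_threshold` (a.u.).
#' @export
channel_defs <- function() {
  thr <- 10
  list(
    TRIPLE = list(name = "TRIPLE",
                  species = c("H+", "H2O+", "C2H3+"),
                  ker_gate = c(0, 13),
                  ker_subgates = list(low = c(0, 5), high = c(5, 13)),
                  momentum_sum_threshold = thr),
    DHM    = list(name = "DHM", species = c("H3O+", "C2H3+"),
                  ker_gate = c(0.5, 3.6), momentum_sum_threshold = thr),
    SHM    = list(name = "SHM", species = c("H2O+", "C2H4+"),
                  ker_gate = c(0.5, 3.6), momentum_sum_threshold = thr),
    NHM    = list(name = "NHM", species = c("OH+", "C2H5+"),
                  ker_gate = c(0, 4), momentum_sum_threshold = thr)
  )
}

#' Centre of mass of a subset of atoms
#'
#' @param geom a `cei_geometry`.
#' @param idx integer atom indices.
#' @return length-3 numeric (angstrom).
#' @keywords internal
atom_com <- function(geom, idx) {
  m <- .atomic_mass[geom$elements[idx]]
  drop(m %*% geom$xyz[idx, , drop = FALSE]) / sum(m)
}

#' Write a geometry as a single-frame XYZ file
#'
#' @param geom a `cei_geometry`.
#' @param path output file path.
#' @param comment comment line.
#' @return `path`, invisibly.
#' @export
write_xyz_geometry <- function(geom, path, comment = "ethanol") {
  lines <- c(
    length(geom$elements), comment,
    sprintf("%-2s %14.8f %14.8f %14.8f",
            geom$elements, geom$xyz[, 1], geom$xyz[, 2], geom$xyz[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}
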