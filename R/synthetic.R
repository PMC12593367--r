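#' Toy molecule templates
#'
#' Builds small reference molecules with known ground-truth symmetry for
#' testing and synthetic landscapes:
#' \itemize{
#'   \item `asymmetric_triatomic`: bent C-N-O chain, point group C1 (Q = 1).
#'   \item `symmetric_AB2`: water-like O-H2, one mirror swap (Q = 2).
#'   \item `square_AB4`: square-planar C-F4; the point group acts on the
#'     atoms as the 8 permutations of the 4-fold dihedral group (Q = 8).
#'   \item `asymmetric_chain4`: C-N-O-S chain with a configurable
#'     S-O-N-C dihedral, point group C1 (Q = 1); the template used for
#'     planted-torsion landscapes.
#' }
#'
#' @param template Template name.
#' @param torsion Dihedral angle in degrees for `asymmetric_chain4`
#'   (default 150).
#' @return A [molecule()].
#' @export
make_molecule <- function(template = c("asymmetric_triatomic", "symmetric_AB2",
                                       "square_AB4", "asymmetric_chain4"),
                          torsion = 150) {
  template <- match.arg(template)
  switch(template,
    asymmetric_triatomic = molecule(
      c("C", "N", "O"),
      rbind(c(1, 2), c(2, 3)),
      rbind(c(0, 0, 0), c(1.40, 0, 0), c(2.10, 1.05, 0))),
    symmetric_AB2 = molecule(
      c("O", "H", "H"),
      rbind(c(1, 2), c(1, 3)),
      rbind(c(0, 0, 0), c(0.757, 0.586, 0), c(-0.757, 0.586, 0))),
    square_AB4 = molecule(
      c("C", "F", "F", "F", "F"),
      rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)),
      rbind(c(0, 0, 0), c(1.30, 0, 0), c(0, 1.30, 0),
            c(-1.30, 0, 0), c(0, -1.30, 0))),
    asymmetric_chain4 = {
      coords <- rbind(c(0, 0, 0), c(1.45, 0, 0), c(1.95, 1.25, 0),
                      c(3.30, 1.80, 0.95))
      coords <- set_torsion(coords, 1:4, torsion)
      molecule(c("C", "N", "O", "S"),
               rbind(c(1, 2), c(2, 3), c(3, 4)), coords)
    })
}

#' Set a dihedral angle by rotating the terminal atom
#'
#' Rotates atom `atoms[4]` about the `atoms[2]`-`atoms[3]` bond so the
#' dihedral over `atoms` equals `angle` (degrees).
#'
#' @param coords N x 3 coordinate matrix.
#' @param atoms Four atom indices defining the dihedral chain.
#' @param angle Target dihedral in degrees.
#' @return The modified coordinate matrix.
#' @export
set_torsion <- function(coords, atoms, angle) {
  cur <- dihedral_angle(coords[atoms[1], ], coords[atoms[2], ],
                        coords[atoms[3], ], coords[atoms[4], ])
  # rotating atom 4 by +delta about the 2->3 axis decreases the signed
  # dihedral by delta under the atan2 convention used in dihedral_angle()
  delta <- (cur - angle) * pi / 180
  axis <- coords[atoms[3], ] - coords[atoms[2], ]
  axis <- axis / sqrt(sum(axis^2))
  v <- coords[atoms[4], ] - coords[atoms[3], ]
  # Rodrigues rotation about the bond axis
  vrot <- v * cos(delta) + .cross3(axis, v) * sin(delta) +
    axis * sum(axis * v) * (1 - cos(delta))
  coords[atoms[4], ] <- coords[atoms[3], ] + vrot
  coords
}

.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Smallest intermolecular (or self-image) contact margin in a cubic cell:
# the minimum over contacts of dist - floor_ij, where floor_ij is the larger
# of the hard clash floor (1.5 A) and the bond-perception cutoff
# r_i + r_j + bond_tol + 0.05. A nonnegative margin guarantees both no
# clashes and that bond perception recovers exactly the intramolecular
# bonds, so generated structures always satisfy the partition invariant.
.contact_margin <- function(coords, mol_id, elements, lattice,
                            bond_tol = 0.4) {
  n <- nrow(coords)
  radii <- covalent_radius(elements)
  floor_ <- pmax(outer(radii, radii, "+") + bond_tol + 0.05, 1.5)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- Inf
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ]
    disp <- as.numeric(sh %*% lattice)
    for (i in seq_len(n)) {
      d <- sweep(coords, 2, coords[i, ] - disp)  # coords_j + sh - coords_i
      dist <- sqrt(rowSums(d^2))
      same_cell <- all(sh == 0)
      excl <- if (same_cell) mol_id == mol_id[i] else rep(FALSE, n)
      excl[i] <- excl[i] || same_cell
      dist[excl] <- Inf
      best <- min(best, min(dist - floor_[i, ]))
    }
  }
  best
}

#' Generate a synthetic crystal landscape
#'
#' Produces random molecular packings in cubic P1 cells with planted,
#' controllable density-descriptor and energy-descriptor relationships, so
#' kernel, hull, interpretability and regression machinery can be exercised
#' end to end without external datasets. Cells are scaled isotropically to
#' hit target densities drawn uniformly from `density_range`; molecular
#' conformation (a terminal-atom torsion) is planted per `torsion_rule`;
#' energies come from `energy_model` plus Gaussian noise. Landscapes are
#' random packings, not physical lattice-energy minima.
#'
#' @param n_structures Number of structures (>= 4).
#' @param template Molecule template, see [make_molecule()].
#' @param density_range Density range in g/cm^3 (default 0.8-1.25, feasible
#'   packings for the hydrogen-free toy molecules).
#' @param torsion_rule Optional list: `atoms` (4 indices, default 1:4),
#'   `ranges` (list of absolute-angle intervals in degrees, one per class),
#'   `prob` (class probabilities). Angles are drawn uniformly in the chosen
#'   class interval with random sign. Only meaningful for
#'   `asymmetric_chain4`.
#' @param energy_model Function `f(density, torsion)` returning the
#'   noiseless energy in kJ/mol; default `35 * (max(density_range) -
#'   density)` (denser packings more stable, ~15 kJ/mol per landscape).
#' @param noise_sd Gaussian energy-noise standard deviation in kJ/mol
#'   (default 0).
#' @param zprime_choices Candidate molecule counts per cell (default 1).
#' @param seed RNG seed; output is deterministic given the seed.
#' @param max_retries Packing retries per structure before a clash error
#'   (intermolecular contact floor 1.5 Angstrom).
#' @return List with `structures` (partitioned [crystal()] objects),
#'   `energies`, `densities`, `torsions`, `classes` (when a torsion rule is
#'   set), `labels`, `molecule`.
#' @export
make_landscape <- function(n_structures, template = "asymmetric_triatomic",
                           density_range = c(0.8, 1.25), torsion_rule = NULL,
                           energy_model = NULL, noise_sd = 0,
                           zprime_choices = 1L, seed = 1L,
                           max_retries = 80L) {
  stopifnot(n_structures >= 4, noise_sd >= 0)
  set.seed(seed)
  mol <- make_molecule(template)
  if (is.null(energy_model)) {
    energy_model <- function(density, torsion) {
      35 * (max(density_range) - density)
    }
  }
  structures <- vector("list", n_structures)
  densities <- stats::runif(n_structures, density_range[1], density_range[2])
  torsions <- rep(NA_real_, n_structures)
  classes <- NULL
  if (!is.null(torsion_rule)) {
    if (template != "asymmetric_chain4") {
      stop("torsion_rule requires the asymmetric_chain4 template ",
           "(symmetric molecules must stay rigid)")
    }
    atoms <- if (is.null(torsion_rule$atoms)) 1:4 else torsion_rule$atoms
    prob <- if (is.null(torsion_rule$prob)) {
      rep(1 / length(torsion_rule$ranges), length(torsion_rule$ranges))
    } else torsion_rule$prob
    cls <- sample(seq_along(torsion_rule$ranges), n_structures,
                  replace = TRUE, prob = prob)
    mag <- vapply(cls, function(k) {
      stats::runif(1, torsion_rule$ranges[[k]][1], torsion_rule$ranges[[k]][2])
    }, numeric(1))
    torsions <- mag * sample(c(-1, 1), n_structures, replace = TRUE)
    classes <- cls - 1L
  }
  labels <- sprintf("s%04d", seq_len(n_structures))
  mass <- sum(atomic_mass(mol$elements))
  for (i in seq_len(n_structures)) {
    z <- if (length(zprime_choices) == 1) zprime_choices
         else sample(zprime_choices, 1)
    vol <- z * mass / (densities[i] * 0.602214076)
    a <- vol^(1 / 3)
    lattice <- diag(a, 3)
    ref <- mol$coords
    if (!is.na(torsions[i])) ref <- set_torsion(ref, 1:4, torsions[i])
    ref <- sweep(ref, 2, colMeans(ref))
    placed <- NULL
    for (try_ in seq_len(max_retries)) {
      coords <- NULL; mol_id <- integer(0)
      frac_centers <- if (z == 1) matrix(stats::runif(3), 1, 3) else {
        base <- as.matrix(expand.grid(c(0.25, 0.75), c(0.25, 0.75),
                                      c(0.25, 0.75)))[seq_len(z), , drop = FALSE]
        base + matrix(stats::runif(3 * z, -0.05, 0.05), z, 3)
      }
      for (m in seq_len(z)) {
        R <- .random_rotation()
        pos <- ref %*% R +
          matrix(frac_centers[m, ] %*% lattice, nrow(ref), 3, byrow = TRUE)
        coords <- rbind(coords, pos)
        mol_id <- c(mol_id, rep(m, nrow(ref)))
      }
      if (.contact_margin(coords, mol_id, rep(mol$elements, z),
                          lattice) >= 0) {
        placed <- coords
        break
      }
    }
    if (is.null(placed)) {
      stop("packing failure for structure ", labels[i], ": could not avoid ",
           "atom clashes below 1.5 A at density ", signif(densities[i], 3),
           " g/cm^3 after ", max_retries, " retries")
    }
    cr <- crystal(lattice, placed, rep(mol$elements, z), label = labels[i])
    cr <- partition_molecules(cr, mol)
    structures[[i]] <- cr
  }
  energies <- vapply(seq_len(n_structures), function(i) {
    energy_model(densities[i], torsions[i])
  }, numeric(1))
  if (noise_sd > 0) energies <- energies + stats::rnorm(n_structures, 0, noise_sd)
  for (i in seq_len(n_structures)) {
    structures[[i]]$energy <- energies[i]
    if (!is.null(classes)) structures[[i]]$class_label <- classes[i]
  }
  list(structures = structures, energies = energies, densities = densities,
       torsions = torsions, classes = classes, labels = labels,
       molecule = mol)
}

#' Write a landscape to extended-XYZ files plus a sidecar CSV
#'
#' @param landscape A [make_landscape()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in landscape$structures) {
    write_crystal(s, file.path(dir, paste0(s$label, ".xyz")))
  }
  tab <- data.frame(label = landscape$labels,
                    energy_kjmol = landscape$energies,
                    density_gcm3 = landscape$densities,
                    class = if (is.null(landscape$classes)) NA
                            else landscape$classes)
  utils::write.csv(tab, file.path(dir, "properties.csv"), row.names = FALSE)
  invisible(dir)
}
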