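#' Periodic molecular crystal structure
#'
#' A `crystal` holds a periodic structure: a 3x3 lattice matrix (rows are the
#' cell vectors, Angstrom), Cartesian atomic coordinates, element symbols, and
#' optional annotations (lattice energy in kJ/mol, density in g/cm^3, a label,
#' a binary class). After [partition_molecules()] the atoms are grouped into
#' molecule copies with a consistent intramolecular indexing; `zprime` is then
#' the number of molecules treated as the asymmetric unit (for P1 /
#' symmetry-expanded cells this is all molecules in the cell) and
#' `n_asym_copies` the number of copies of that unit in the cell.
#'
#' @param lattice 3x3 numeric matrix of row cell vectors (Angstrom).
#' @param coords n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param elements Character vector of element symbols, length n.
#' @param energy Optional lattice energy (kJ/mol).
#' @param density Optional density (g/cm^3); computed from the cell when `NA`.
#' @param label Structure identifier.
#' @param class_label Optional binary class (0/1) annotation.
#' @return Object of class `crystal`.
#' @export
crystal <- function(lattice, coords, elements, energy = NA_real_,
                    density = NA_real_, label = "crystal",
                    class_label = NA_integer_) {
  lattice <- matrix(as.numeric(lattice), 3, 3)
  if (abs(det(lattice)) < 1e-10) stop("lattice is not invertible")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  elements <- as.character(elements)
  covalent_radius(elements)
  if (nrow(coords) != length(elements) || ncol(coords) != 3) {
    stop("coords must be n x 3 with one row per element")
  }
  if (is.na(density)) {
    density <- sum(atomic_mass(elements)) / abs(det(lattice)) * .g_per_cm3_factor
  }
  structure(list(lattice = lattice, coords = coords, elements = elements,
                 molecule_partition = NULL, zprime = NA_integer_,
                 n_asym_copies = 1L, energy = as.numeric(energy),
                 density = as.numeric(density), label = as.character(label),
                 class_label = class_label),
            class = "crystal")
}

#' @export
print.crystal <- function(x, ...) {
  cat("crystal '", x$label, "': ", nrow(x$coords), " atoms",
      if (!is.na(x$zprime)) paste0(", Z' = ", x$zprime), ", density ",
      signif(x$density, 4), " g/cm^3",
      if (!is.na(x$energy)) paste0(", E = ", signif(x$energy, 6), " kJ/mol"),
      "\n", sep = "")
  invisible(x)
}

.frac_coords <- function(crystal) crystal$coords %*% solve(crystal$lattice)

## ---- extended XYZ -------------------------------------------------------

#' Read a crystal structure from file
#'
#' Supports extended-XYZ (with a `Lattice="..."` comment field) and minimal
#' core-dictionary CIF restricted to P1 or symmetry-expanded atom lists
#' (cell parameters plus an `_atom_site` loop with fractional coordinates).
#' Fractional coordinates are converted to Cartesian; atoms are not wrapped
#' into the cell, so molecules written whole stay whole.
#'
#' @param path File path.
#' @param format `"extxyz"` or `"cif"`; guessed from the extension by default.
#' @return A [crystal()] object.
#' @export
read_crystal <- function(path, format = c("auto", "extxyz", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "extxyz"
  }
  if (format == "extxyz") .read_extxyz(path) else .read_cif(path)
}

#' Write a crystal structure to file
#'
#' @param x A [crystal()] object.
#' @param path Output file path.
#' @param format `"extxyz"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_crystal <- function(x, path, format = c("auto", "extxyz", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "extxyz"
  }
  if (format == "extxyz") .write_extxyz(x, path) else .write_cif(x, path)
  invisible(path)
}

.read_extxyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("extxyz parse error: file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("extxyz parse error: first line must be the atom count")
  comment <- lines[2]
  lat_match <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (length(lat_match) == 0) stop("extxyz format error: missing Lattice field")
  lat_vals <- as.numeric(strsplit(trimws(gsub('Lattice="|"', "", lat_match)),
                                  "\\s+")[[1]])
  if (length(lat_vals) != 9) stop("extxyz format error: Lattice needs 9 numbers")
  lattice <- matrix(lat_vals, 3, 3, byrow = TRUE)
  get_field <- function(key) {
    m <- regmatches(comment, regexpr(paste0(key, '=("[^"]*"|\\S+)'), comment))
    if (length(m) == 0) return(NA_character_)
    gsub('^"|"$', "", sub(paste0(key, "="), "", m))
  }
  atom_lines <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  elements <- vapply(atom_lines, `[`, "", 1)
  coords <- t(vapply(atom_lines, function(f) as.numeric(f[2:4]), numeric(3)))
  crystal(lattice, coords, elements,
          energy = suppressWarnings(as.numeric(get_field("energy_kjmol"))),
          density = suppressWarnings(as.numeric(get_field("density_gcm3"))),
          label = if (is.na(get_field("label"))) basename(path) else get_field("label"),
          class_label = suppressWarnings(as.integer(get_field("class"))))
}

.write_extxyz <- function(x, path) {
  lat <- paste(sprintf("%.10f", as.vector(t(x$lattice))), collapse = " ")
  extras <- sprintf('label="%s"', x$label)
  if (!is.na(x$energy)) extras <- paste(extras, sprintf("energy_kjmol=%.10f", x$energy))
  if (!is.na(x$density)) extras <- paste(extras, sprintf("density_gcm3=%.10f", x$density))
  if (!is.na(x$class_label)) extras <- paste(extras, sprintf("class=%d", x$class_label))
  header <- sprintf('Lattice="%s" Properties=species:S:1:pos:R:3 %s', lat, extras)
  body <- sprintf("%-2s %18.10f %18.10f %18.10f", x$elements,
                  x$coords[, 1], x$coords[, 2], x$coords[, 3])
  writeLines(c(nrow(x$coords), header, body), path)
}

## ---- minimal core CIF ---------------------------------------------------

.read_cif <- function(path) {
  lines <- readLines(path)
  getnum <- function(tag) {
    ln <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (length(ln) == 0) stop("CIF format error: missing ", tag)
    as.numeric(sub("\\(.*", "", strsplit(trimws(ln[1]), "\\s+")[[1]][2]))
  }
  a <- getnum("_cell_length_a"); b <- getnum("_cell_length_b")
  cc <- getnum("_cell_length_c")
  al <- getnum("_cell_angle_alpha") * pi / 180
  be <- getnum("_cell_angle_beta") * pi / 180
  ga <- getnum("_cell_angle_gamma") * pi / 180
  # standard crystallographic cell matrix (a along x, b in xy plane)
  v1 <- c(a, 0, 0)
  v2 <- c(b * cos(ga), b * sin(ga), 0)
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(cc^2 - cx^2 - cy^2, 0))
  lattice <- rbind(v1, v2, c(cx, cy, cz))
  # locate the atom_site loop
  loop_starts <- grep("^\\s*loop_", lines)
  site <- NULL
  for (ls in loop_starts) {
    tags <- character(); i <- ls + 1
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (any(grepl("^_atom_site_fract_x", tags))) {
      rows <- list()
      while (i <= length(lines) && !grepl("^\\s*(loop_|_|#|$)", lines[i])) {
        rows[[length(rows) + 1]] <- strsplit(trimws(lines[i]), "\\s+")[[1]]
        i <- i + 1
      }
      site <- list(tags = tags, rows = rows)
      break
    }
  }
  if (is.null(site)) stop("CIF parse error: no _atom_site loop")
  col <- function(tag) match(tag, site$tags)
  ic <- col("_atom_site_type_symbol")
  if (is.na(ic)) ic <- col("_atom_site_label")
  ix <- col("_atom_site_fract_x"); iy <- col("_atom_site_fract_y")
  iz <- col("_atom_site_fract_z")
  elements <- vapply(site$rows, function(r) gsub("[0-9].*$", "", r[ic]), "")
  frac <- t(vapply(site$rows, function(r)
    as.numeric(sub("\\(.*", "", r[c(ix, iy, iz)])), numeric(3)))
  crystal(lattice, frac %*% lattice, elements, label = basename(path))
}

.write_cif <- function(x, path) {
  lat <- x$lattice
  a <- sqrt(sum(lat[1, ]^2)); b <- sqrt(sum(lat[2, ]^2)); cc <- sqrt(sum(lat[3, ]^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  frac <- .frac_coords(x)
  lines <- c(
    sprintf("data_%s", gsub("\\s", "_", x$label)),
    "_symmetry_space_group_name_H-M   'P 1'",
    sprintf("_cell_length_a   %.8f", a),
    sprintf("_cell_length_b   %.8f", b),
    sprintf("_cell_length_c   %.8f", cc),
    sprintf("_cell_angle_alpha   %.8f", ang(lat[2, ], lat[3, ])),
    sprintf("_cell_angle_beta   %.8f", ang(lat[1, ], lat[3, ])),
    sprintf("_cell_angle_gamma   %.8f", ang(lat[1, ], lat[2, ])),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    sprintf("%s%d %s %.10f %.10f %.10f", x$elements, seq_along(x$elements),
            x$elements, frac[, 1], frac[, 2], frac[, 3])
  )
  writeLines(lines, path)
}

## ---- molecule partitioning ---------------------------------------------

# Minimum-image displacement of points y relative to x under lattice L (rows).
.min_image_shift <- function(dfrac) dfrac - round(dfrac)

#' Partition crystal atoms into molecule copies
#'
#' Groups atoms by covalent connectivity across periodic boundaries (two atoms
#' bond when their minimum-image distance is below the sum of covalent radii
#' plus `bond_tolerance`), unwraps each group so molecules are spatially
#' contiguous, and reorders each group onto the reference intramolecular
#' indexing of `mol` via element-labelled graph isomorphism. When the
#' reference bond graph has automorphisms the lexicographically smallest
#' mapping is taken; the residual ambiguity is exactly the molecular symmetry
#' handled by [find_mappings()] and the adapted kernel.
#'
#' @param x A [crystal()].
#' @param mol The reference [molecule()].
#' @param bond_tolerance Bond-detection tolerance in Angstrom (default 0.4).
#' @return The crystal with `molecule_partition` (list of integer index
#'   vectors ordered by intramolecular index), unwrapped coordinates, and
#'   `zprime` filled.
#' @export
partition_molecules <- function(x, mol, bond_tolerance = 0.4) {
  stopifnot(inherits(x, "crystal"), inherits(mol, "molecule"))
  n_at <- nrow(x$coords)
  if (n_at %% mol$n != 0) {
    stop("inconsistent molecule: ", n_at, " atoms is not a multiple of N = ", mol$n)
  }
  frac <- .frac_coords(x)
  radii <- covalent_radius(x$elements)
  # pairwise min-image distances and bond list
  bonds <- matrix(integer(0), 0, 2)
  shifts <- list()
  for (i in seq_len(n_at - 1L)) {
    dfrac <- frac[(i + 1L):n_at, , drop = FALSE] -
      matrix(frac[i, ], n_at - i, 3, byrow = TRUE)
    img <- round(dfrac)
    dcart <- (dfrac - img) %*% x$lattice
    dist <- sqrt(rowSums(dcart^2))
    cut <- radii[i] + radii[(i + 1L):n_at] + bond_tolerance
    hit <- which(dist < cut)
    if (length(hit)) {
      j <- i + hit
      bonds <- rbind(bonds, cbind(i, j))
      for (k in seq_along(hit)) {
        shifts[[paste(i, j[k])]] <- img[hit[k], ]   # frac shift: pos_j - shift ~ near i
      }
    }
  }
  g <- igraph::make_empty_graph(n = n_at, directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, t(bonds))
  comp <- igraph::components(g)
  if (any(comp$csize != mol$n)) {
    stop("inconsistent molecule: connected group sizes ",
         paste(unique(comp$csize), collapse = ", "), " do not all equal N = ", mol$n)
  }
  # unwrap: BFS within each component, placing each atom at the image nearest
  # its BFS parent
  coords <- x$coords
  adj <- lapply(seq_len(n_at), function(i) integer(0))
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  ref_graph <- .molecule_graph(mol$elements, mol$bonds)
  partition <- vector("list", comp$no)
  elem_levels <- sort(unique(c(x$elements, mol$elements)))
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    root <- members[1]
    seen <- c(root); queue <- root
    pos <- list(); pos[[as.character(root)]] <- frac[root, ]
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in adj[[i]]) {
        if (j %in% seen) next
        key <- if (i < j) paste(i, j) else paste(j, i)
        img <- shifts[[key]]
        if (i > j) img <- -img
        # frac position of j contiguous with i's unwrapped position
        pos[[as.character(j)]] <- pos[[as.character(i)]] + (frac[j, ] - img - frac[i, ])
        seen <- c(seen, j); queue <- c(queue, j)
      }
    }
    for (m in members) coords[m, ] <- pos[[as.character(m)]] %*% x$lattice
    # map onto reference indexing
    sub_bonds <- bonds[bonds[, 1] %in% members & bonds[, 2] %in% members, , drop = FALSE]
    local <- match(sub_bonds, members)
    dim(local) <- dim(sub_bonds)
    gg <- igraph::make_empty_graph(n = mol$n, directed = FALSE)
    if (nrow(local)) gg <- igraph::add_edges(gg, t(local))
    if (nrow(local) != nrow(mol$bonds)) {
      stop("different molecule: group of atoms (",
           paste(members, collapse = ","), ") has ", nrow(local),
           " perceived bonds but the reference has ", nrow(mol$bonds))
    }
    col_ref <- as.integer(factor(mol$elements, levels = elem_levels))
    col_sub <- as.integer(factor(x$elements[members], levels = elem_levels))
    isos <- igraph::subgraph_isomorphisms(ref_graph, gg, method = "vf2",
                                          vertex.color1 = col_ref,
                                          vertex.color2 = col_sub)
    if (length(isos) == 0) {
      stop("different molecule: group of atoms (",
           paste(members, collapse = ","),
           ") is not isomorphic to the reference molecule")
    }
    maps <- matrix(vapply(isos, as.integer, integer(mol$n)),
                   nrow = mol$n)  # maps[i, ] image of ref atom i
    best <- do.call(order, as.data.frame(t(maps)))[1]
    partition[[cid]] <- members[maps[, best]]
  }
  # deterministic copy order: by first atom index of each copy
  partition <- partition[order(vapply(partition, min, 1L))]
  x$coords <- coords
  x$molecule_partition <- partition
  x$zprime <- length(partition)
  x$n_asym_copies <- 1L
  x
}

#' Validate a structure set for the adapted kernel
#'
#' The adapted analogous-atom kernel applies to structure sets of consistent
#' Z' or to any set whose underlying molecule is asymmetric (identity-only
#' point group); with a symmetric molecule and mixed Z' positive
#' semidefiniteness of the kernel is not guaranteed, so such sets are flagged
#' invalid. When the molecule is symmetric the conformations of all molecule
#' copies are also checked against the reference (the mapping set is only
#' meaningful for a rigid conformation).
#'
#' @param structures List of partitioned [crystal()] objects.
#' @param mol The reference [molecule()].
#' @param symmetric Logical: does the molecule have point-group symmetry
#'   beyond the identity (Q > 1)?
#' @param conformer_tolerance Max deviation (Angstrom) of intramolecular
#'   distances from the reference before a symmetric molecule is deemed
#'   flexible (default 0.25).
#' @return List with `valid`, `zprimes`, `mixed_zprime`, `reason`.
#' @export
validate_set <- function(structures, mol, symmetric,
                         conformer_tolerance = 0.25) {
  zp <- vapply(structures, function(s) {
    if (is.null(s$molecule_partition)) stop("partition not filled for '", s$label, "'")
    s$zprime
  }, integer(1))
  mixed <- length(unique(zp)) > 1
  valid <- TRUE; reason <- "ok"
  if (symmetric && mixed) {
    valid <- FALSE
    reason <- "mixed Z' with a symmetric molecule: adapted kernel PSD not guaranteed"
  }
  if (symmetric && valid) {
    dref <- as.matrix(stats::dist(mol$coords))
    for (s in structures) {
      for (cp in s$molecule_partition) {
        d <- as.matrix(stats::dist(s$coords[cp, , drop = FALSE]))
        if (max(abs(d - dref)) > conformer_tolerance) {
          valid <- FALSE
          reason <- paste0("symmetric molecule with varying conformation ('",
                           s$label, "'): mapping set from one reference ",
                           "conformation is not applicable")
          break
        }
      }
      if (!valid) break
    }
  }
  list(valid = valid, zprimes = zp, mixed_zprime = mixed, reason = reason)
}

#' Read structure annotations from a sidecar CSV
#'
#' Columns: `label`, `energy_kjmol`, optional `density_gcm3`, optional
#' `class`. Values are attached to the matching crystals by label.
#'
#' @param structures List of [crystal()] objects.
#' @param path CSV file path.
#' @return The structure list with annotations filled.
#' @export
annotate_structures <- function(structures, path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- vapply(structures, function(s) s$label, "")
  idx <- match(labels, tab$label)
  for (i in seq_along(structures)) {
    if (is.na(idx[i])) next
    row <- tab[idx[i], ]
    if (!is.null(row$energy_kjmol)) structures[[i]]$energy <- row$energy_kjmol
    if (!is.null(row$density_gcm3) && !is.na(row$density_gcm3)) {
      structures[[i]]$density <- row$density_gcm3
    }
    if (!is.null(row$class) && !is.na(row$class)) {
      structures[[i]]$class_label <- as.integer(row$class)
    }
  }
  structures
}
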