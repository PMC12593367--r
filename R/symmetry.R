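#' Point-group atom mappings of a molecule
#'
#' Finds the set Q of "analogous atom" mappings used by the adapted kernel:
#' element-preserving automorphisms of the covalent bond graph whose
#' permutation is realizable by a rigid proper or improper rotation of the
#' reference conformation. Realizability is tested by best-fit orthogonal
#' superposition (Kabsch with reflections allowed) of the permuted onto the
#' original coordinates after centroid alignment; a permutation is accepted
#' when the RMSD falls below `rmsd_tolerance`. The identity is always
#' included; an asymmetric molecule therefore returns the identity-only set.
#'
#' @param mol A [molecule()] with reference coordinates.
#' @param rmsd_tolerance Acceptance RMSD in Angstrom (default 0.1).
#' @return Object of class `mapping_set`: list with `perms` (list of 1-based
#'   permutation vectors, identity first), `labels`, and `Q`.
#' @export
find_mappings <- function(mol, rmsd_tolerance = 0.1) {
  g <- .molecule_graph(mol$elements, mol$bonds)
  cols <- igraph::V(g)$color_code
  autos <- igraph::subgraph_isomorphisms(g, g, method = "vf2",
                                         vertex.color1 = cols,
                                         vertex.color2 = cols)
  X <- scale(mol$coords, center = TRUE, scale = FALSE)
  keep <- list()
  for (a in autos) {
    p <- as.integer(a)
    # permuted configuration: atom i moved to the site of atom p[i]
    Y <- X[p, , drop = FALSE]
    rmsd <- .orthogonal_fit_rmsd(X, Y)
    if (rmsd < rmsd_tolerance) keep[[length(keep) + 1]] <- p
  }
  keep <- unique(keep)
  ident <- seq_len(mol$n)
  is_id <- vapply(keep, function(p) all(p == ident), logical(1))
  keep <- c(list(ident), keep[!is_id])
  labels <- c("E", if (length(keep) > 1) paste0("op", seq_len(length(keep) - 1)))
  structure(list(perms = keep, labels = labels, Q = length(keep)),
            class = "mapping_set")
}

# RMSD of best orthogonal (proper or improper) superposition of Y onto X.
.orthogonal_fit_rmsd <- function(X, Y) {
  s <- svd(crossprod(Y, X))
  R <- s$u %*% t(s$v)        # orthogonal, reflections permitted
  sqrt(mean(rowSums((Y %*% R - X)^2)))
}

#' @export
print.mapping_set <- function(x, ...) {
  cat("mapping_set: Q =", x$Q, "atom mappings (",
    paste(x$labels, collapse = " "), ")\n")
  invisible(x)
}

#' Verify group closure of a mapping set
#'
#' True iff the composition of any two member permutations is a member and
#' every member's inverse is present (with the identity this makes the set a
#' permutation group, as required for the operator-averaged kernel).
#'
#' @param mset A `mapping_set`.
#' @return Logical flag.
#' @export
verify_closure <- function(mset) {
  key <- function(p) paste(p, collapse = ",")
  members <- vapply(mset$perms, key, "")
  for (p in mset$perms) {
    if (!key(order(p)) %in% members) return(FALSE)  # inverse
    for (q in mset$perms) {
      if (!key(p[q]) %in% members) return(FALSE)    # composition (p after q)
    }
  }
  TRUE
}

#' Write atom mappings as a plain-text permutation list
#'
#' One line per mapping: space-separated images of atoms 0..N-1 (0-based, so
#' files interoperate with other tooling).
#'
#' @param mset A `mapping_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mappings <- function(mset, path) {
  writeLines(vapply(mset$perms, function(p) paste(p - 1L, collapse = " "), ""),
             path)
  invisible(path)
}

#' Read atom mappings from a plain-text permutation list
#'
#' @param path File of 0-based permutation lines (see [write_mappings()]).
#' @return A `mapping_set`.
#' @export
read_mappings <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  perms <- lapply(lines, function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]]) + 1L)
  n <- length(perms[[1]])
  for (p in perms) {
    if (length(p) != n || !setequal(p, seq_len(n))) {
      stop("invalid permutation line in ", path)
    }
  }
  ident <- seq_len(n)
  is_id <- vapply(perms, function(p) all(p == ident), logical(1))
  perms <- c(list(ident), unique(perms[!is_id]))
  structure(list(perms = perms,
                 labels = c("E", if (length(perms) > 1)
                   paste0("op", seq_len(length(perms) - 1))),
                 Q = length(perms)),
            class = "mapping_set")
}
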