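#' Molecular topology and reference geometry
#'
#' A `molecule` bundles the covalent topology (element list plus bond list)
#' of the molecule underlying a crystal landscape with one representative
#' conformation. The reference geometry anchors two things: the canonical
#' intramolecular atom indexing that every crystal in a structure set is
#' mapped onto, and the detection of point-group atom mappings (see
#' [find_mappings()]).
#'
#' @param elements Character vector of element symbols, length `N`.
#' @param bonds Two-column integer matrix (or list of pairs) of 1-based atom
#'   indices forming the covalent bond graph. The graph must be connected.
#' @param coords `N x 3` numeric matrix of Cartesian coordinates (Angstrom)
#'   of one representative conformation.
#' @return An object of class `molecule` with fields `elements`, `bonds`,
#'   `coords` and `n`.
#' @export
molecule <- function(elements, bonds, coords) {
  elements <- as.character(elements)
  n <- length(elements)
  covalent_radius(elements)  # validates symbols
  if (is.list(bonds)) bonds <- do.call(rbind, bonds)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0 && (min(bonds) < 1 || max(bonds) > n)) {
    stop("bond indices must lie in [1, N]")
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!identical(dim(coords), c(n, 3L)) && !identical(dim(coords), as.integer(c(n, 3)))) {
    stop("coords must be an N x 3 matrix")
  }
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  if (n > 1 && igraph::count_components(g) != 1) {
    stop("bond graph must be connected")
  }
  structure(list(elements = elements, bonds = bonds, coords = coords, n = n),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("molecule:", x$n, "atoms (", paste(x$elements, collapse = " "), "),",
      nrow(x$bonds), "bonds\n")
  invisible(x)
}

# igraph bond graph with element labels attached as vertex colours.
.molecule_graph <- function(elements, bonds) {
  n <- length(elements)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0) g <- igraph::add_edges(g, t(bonds))
  igraph::V(g)$color_code <- as.integer(factor(elements, levels = sort(unique(elements))))
  g
}
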