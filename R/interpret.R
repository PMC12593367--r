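#' Dihedral angle of four points
#'
#' Signed dihedral (degrees, in (-180, 180]) of the chain p1-p2-p3-p4.
#'
#' @param p1,p2,p3,p4 Numeric length-3 Cartesian coordinates.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("undefined-angle: collinear atoms give a degenerate dihedral")
  }
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Binary class labels from an intramolecular torsion
#'
#' For each structure the dihedral over the four given intramolecular atom
#' indices is computed per molecule copy and averaged over the copies of the
#' asymmetric unit (the Z' > 1 rule); the structure is assigned class 1 when
#' the absolute value of the average meets or exceeds the threshold, else
#' class 0.
#'
#' @param structures List of partitioned [crystal()] objects.
#' @param atoms Integer vector of four intramolecular (reference) indices.
#' @param threshold Threshold angle in degrees (default 90).
#' @return Object of class `class_labels`: integer vector of 0/1 with
#'   attributes `definition` and `torsion` (the per-structure averages).
#' @export
torsion_class <- function(structures, atoms, threshold = 90) {
  stopifnot(length(atoms) == 4)
  avg <- vapply(structures, function(s) {
    if (is.null(s$molecule_partition)) stop("partition not filled for '", s$label, "'")
    angs <- vapply(s$molecule_partition, function(cp) {
      xyz <- s$coords[cp[atoms], , drop = FALSE]
      dihedral_angle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
    }, numeric(1))
    mean(angs)
  }, numeric(1))
  # ties at the threshold belong to class 1; the 1e-9 guard keeps exact-tie
  # averages (e.g. copies at +100 and +80 deg) from flipping on rounding
  labels <- as.integer(abs(avg) >= threshold - 1e-9)
  structure(labels,
            definition = sprintf(
              "|mean dihedral(%s)| >= %g deg (averaged over molecule copies)",
              paste(atoms, collapse = "-"), threshold),
            torsion = avg, class = "class_labels")
}

#' Strongest linear density-descriptor relationship
#'
#' Ordinary least-squares R^2 of density regressed on each of the first
#' `n_components` kPCA components individually; the strongest correlation
#' and its (1-based) component index are returned.
#'
#' @param pc A [kpca()] result.
#' @param densities Per-structure densities (g/cm^3).
#' @param n_components Number of leading components scanned (default 32).
#' @return List with `r2` (best R^2), `component`, `r2_all`.
#' @export
density_r2 <- function(pc, densities, n_components = 32L) {
  if (stats::sd(densities) == 0) {
    stop("constant density: R^2 is undefined")
  }
  m <- min(n_components, ncol(pc$coords))
  r2 <- vapply(seq_len(m), function(j) {
    x <- pc$coords[, j]
    if (stats::sd(x) == 0) return(0)
    stats::cor(x, densities)^2
  }, numeric(1))
  list(r2 = max(r2), component = which.max(r2), r2_all = r2)
}

# stratified k-fold assignment (per-class round robin on shuffled order)
.stratified_folds <- function(y, k, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.balanced_accuracy <- function(truth, pred) {
  mean(vapply(unique(truth), function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

#' Linear SVC accuracy of class labels from kPCA descriptors
#'
#' Trains linear soft-margin support-vector classifiers to predict a binary
#' structural class from kPCA descriptor values and reports the maximum
#' balanced accuracy over the feature-set/C search space, estimated by
#' stratified k-fold cross-validation.
#'
#' Modes: `"single_best_of_32"` assesses each of the first 32 components
#' individually; `"best_subset_of_top5"` assesses every nonempty subset of
#' the five top-ranked components.
#'
#' @param pc A [kpca()] result.
#' @param labels Binary class labels (0/1), e.g. from [torsion_class()].
#' @param mode Search mode (see above).
#' @param C_grid Hinge-loss weights searched (default 0.01, 0.1, 1, 10, 100).
#' @param folds Number of stratified CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `balanced_accuracy` (the maximum), `features` (winning
#'   component set), `C` (winning weight), `results` (full search table).
#' @export
svc_accuracy <- function(pc, labels,
                         mode = c("single_best_of_32", "best_subset_of_top5"),
                         C_grid = c(0.01, 0.1, 1, 10, 100), folds = 5L,
                         seed = 1L) {
  mode <- match.arg(mode)
  y <- factor(as.integer(labels), levels = c(0, 1))
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("both classes must be present")
  }
  m <- ncol(pc$coords)
  feature_sets <- if (mode == "single_best_of_32") {
    as.list(seq_len(min(32L, m)))
  } else {
    top <- seq_len(min(5L, m))
    unlist(lapply(seq_along(top), function(k)
      utils::combn(top, k, simplify = FALSE)), recursive = FALSE)
  }
  fold <- .stratified_folds(as.integer(as.character(y)), folds, seed = seed)
  results <- data.frame()
  best <- list(balanced_accuracy = -Inf)
  for (fs in feature_sets) {
    X <- pc$coords[, fs, drop = FALSE]
    for (C in C_grid) {
      pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
      for (f in seq_len(folds)) {
        tr <- fold != f; te <- fold == f
        if (length(unique(y[tr])) < 2 || !any(te)) next
        fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                          cost = C, scale = FALSE, type = "C-classification")
        pred[te] <- stats::predict(fit, X[te, , drop = FALSE])
      }
      ok <- !is.na(pred)
      ba <- .balanced_accuracy(as.character(y[ok]), as.character(pred[ok]))
      results <- rbind(results,
                       data.frame(features = paste(fs, collapse = "+"),
                                  C = C, balanced_accuracy = ba))
      if (ba > best$balanced_accuracy) {
        best <- list(balanced_accuracy = ba, features = fs, C = C)
      }
    }
  }
  c(best, list(results = results))
}

#' Geometric intermolecular hydrogen-bond class (approximate)
#'
#' Convenience detector assigning class 1 when the given acceptor atom of
#' any molecule copy accepts an intermolecular hydrogen bond: an H atom of
#' another molecule (bonded to N, O or F) lies within `ha_max` of the
#' acceptor with a D-H...A angle above `angle_min`. This is a simple
#' geometric criterion, not a crystallographic motif search, and is
#' approximate by construction.
#'
#' @param structures List of partitioned [crystal()] objects.
#' @param acceptor Intramolecular index of the acceptor atom.
#' @param mol The reference [molecule()] (for donor-H connectivity).
#' @param ha_max Maximum H...A distance in Angstrom (default 2.5).
#' @param angle_min Minimum D-H...A angle in degrees (default 120).
#' @return `class_labels` vector of 0/1.
#' @export
hbond_class <- function(structures, acceptor, mol, ha_max = 2.5,
                        angle_min = 120) {
  donors <- c("N", "O", "F")
  h_idx <- which(mol$elements == "H")
  dh <- do.call(rbind, lapply(h_idx, function(h) {
    nb <- unique(c(mol$bonds[mol$bonds[, 1] == h, 2],
                   mol$bonds[mol$bonds[, 2] == h, 1]))
    nb <- nb[mol$elements[nb] %in% donors]
    if (length(nb)) cbind(d = nb[1], h = h) else NULL
  }))
  labels <- vapply(structures, function(s) {
    frac <- .frac_coords(s)
    for (ca in seq_along(s$molecule_partition)) {
      acc <- s$molecule_partition[[ca]][acceptor]
      for (cb in seq_along(s$molecule_partition)) {
        if (is.null(dh)) next
        for (r in seq_len(nrow(dh))) {
          d_at <- s$molecule_partition[[cb]][dh[r, "d"]]
          h_at <- s$molecule_partition[[cb]][dh[r, "h"]]
          same_mol <- cb == ca
          # H...A min-image displacement
          dfrac <- frac[acc, ] - frac[h_at, ]
          img <- round(dfrac)
          dvec <- (dfrac - img) %*% s$lattice
          if (same_mol && all(img == 0)) next  # intramolecular contact
          dist <- sqrt(sum(dvec^2))
          if (dist > ha_max || dist < 1e-6) next
          hd <- s$coords[d_at, ] - s$coords[h_at, ]  # H -> D
          cosang <- sum(hd * dvec) / (sqrt(sum(hd^2)) * dist)
          ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi  # D-H...A angle at H
          if (ang > angle_min) return(1L)
        }
      }
    }
    0L
  }, integer(1))
  structure(labels, definition = sprintf(
    "acceptor atom %d accepts an intermolecular H bond (H...A < %g A, D-H...A > %g deg)",
    acceptor, ha_max, angle_min), class = "class_labels")
}
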