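#' Kernel principal component analysis of a similarity kernel
#'
#' Double-centers the (normalized) kernel matrix, eigendecomposes it, and
#' returns descriptor coordinates `coords[, j] = eigvec_j * sqrt(eigval_j)`
#' ordered by descending eigenvalue. Eigenvalues below `-1e-8 * lambda_max`
#' raise a kernel-integrity error; tiny negatives are clipped to zero and
#' their components dropped. The Gram matrix of the coordinates reproduces
#' the centered kernel. Coordinates are unique up to per-component sign.
#'
#' @param K Symmetric (normalized) `kernel_matrix`.
#' @return Object of class `kpca_result`: `eigenvalues` (all, descending),
#'   `coords` (n x m), `centering` (row means and grand mean of K),
#'   `labels`.
#' @export
kpca <- function(K) {
  Km <- unclass(K)
  n <- nrow(Km)
  if (max(abs(Km - t(Km))) > 1e-8) stop("kernel matrix must be symmetric")
  rm_ <- rowMeans(Km)
  gm <- mean(Km)
  Kc <- Km - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  es <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  lmax <- max(es$values, 0)
  if (min(es$values) < -1e-8 * max(lmax, 1)) {
    stop("kernel-integrity error: centered kernel has eigenvalue ",
         format(min(es$values)), " (not positive semidefinite)")
  }
  vals <- pmax(es$values, 0)
  keep <- which(vals > 1e-12 * max(lmax, 1))
  coords <- es$vectors[, keep, drop = FALSE] %*% diag(sqrt(vals[keep]),
                                                      length(keep))
  labels <- attr(K, "labels")
  if (is.null(labels)) labels <- rownames(Km)
  structure(list(eigenvalues = vals, coords = coords,
                 centering = list(row_means = rm_, grand_mean = gm),
                 labels = labels),
            class = "kpca_result")
}

#' @export
print.kpca_result <- function(x, ...) {
  cat("kpca_result:", nrow(x$coords), "structures,", ncol(x$coords),
      "components; leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = " "), "\n")
  invisible(x)
}

## ---- lower convex envelope ---------------------------------------------

# Lower convex envelope of points (coords, energy) evaluated at the points
# themselves. coords: n x d. Returns envelope values (<= energies).
.lower_envelope <- function(coords, energies) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  # reduce to an affinely independent coordinate basis (degenerate-geometry
  # fallback: hull taken in the d' < d subspace actually spanned)
  ctr <- colMeans(coords)
  Xc <- sweep(coords, 2, ctr)
  sv <- svd(Xc)
  rank_keep <- which(sv$d > 1e-9 * max(sv$d[1], 1))
  if (length(rank_keep) < ncol(coords)) {
    warning("degenerate descriptor geometry: hull built in ",
            length(rank_keep), "-dimensional affine subspace")
  }
  if (length(rank_keep) == 0) return(rep(min(energies), n))
  X <- Xc %*% sv$v[, rank_keep, drop = FALSE]
  if (length(rank_keep) == 1) {
    return(.lower_envelope_1d(X[, 1], energies))
  }
  d <- ncol(X)
  A3 <- rbind(t(X), rep(1, n))
  env <- numeric(n)
  for (i in seq_len(n)) {
    b3 <- c(X[i, ], 1)
    sgn <- ifelse(b3 < 0, -1, 1)
    sol <- boot::simplex(a = energies, A3 = sweep(A3, 1, sgn, "*"),
                         b3 = b3 * sgn)
    env[i] <- if (sol$solved == 1) sol$value else energies[i]
  }
  pmin(env, energies)
}

# exact monotone-chain lower hull + piecewise-linear interpolation
.lower_envelope_1d <- function(x, energies) {
  ord <- order(x, energies)
  xs <- x[ord]; es <- energies[ord]
  # for duplicate abscissae only the lowest energy can support the hull
  first <- !duplicated(xs)
  hx <- xs[first]; he <- es[first]
  # (duplicates keep the minimum energy at that abscissa)
  if (any(!first)) {
    he <- vapply(hx, function(v) min(es[xs == v]), numeric(1))
  }
  stack <- integer(0)
  for (i in seq_along(hx)) {
    while (length(stack) >= 2) {
      a <- stack[length(stack) - 1]; b <- stack[length(stack)]
      cross <- (hx[b] - hx[a]) * (he[i] - he[a]) -
        (he[b] - he[a]) * (hx[i] - hx[a])
      if (cross <= 0) stack <- stack[-length(stack)] else break
    }
    stack <- c(stack, i)
  }
  env_at <- function(v) {
    j <- findInterval(v, hx[stack], all.inside = TRUE)
    a <- stack[j]; b <- stack[j + 1]
    ifelse(hx[b] > hx[a],
           he[a] + (he[b] - he[a]) * (v - hx[a]) / (hx[b] - hx[a]),
           pmin(he[a], he[b]))
  }
  if (length(stack) == 1) return(pmin(rep(he[stack], length(x)), energies))
  pmin(env_at(x), energies)
}

#' Build a generalized convex hull model
#'
#' Computes the lower convex envelope over (descriptor coordinates, energy)
#' and each structure's dressed energy: its vertical energy distance above
#' the envelope at its own descriptor coordinates. Energies are handled
#' relative to the set minimum; the global-minimum structure always lies on
#' the hull (dressed energy 0).
#'
#' @param coords n x d matrix of descriptor coordinates (e.g. leading kPCA
#'   components, raw scale).
#' @param energies Numeric energies (kJ/mol), length n.
#' @param labels Optional structure labels.
#' @return Object of class `hull_model`: `dim`, `coords`,
#'   `energies` (relative to the set minimum), `dressed_energy`,
#'   `vertices` (indices with dressed energy ~ 0), `labels`.
#' @export
build_hull <- function(coords, energies, labels = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(energies) != n) stop("energies must match coords rows")
  if (anyNA(energies)) stop("energies present for all structures required")
  if (n < ncol(coords) + 2) {
    stop("need at least d + 2 structures for a ", ncol(coords), "-descriptor hull")
  }
  e_rel <- energies - min(energies)
  env <- .lower_envelope(coords, e_rel)
  dressed <- e_rel - env
  dressed[dressed < 1e-9] <- 0
  if (is.null(labels)) labels <- as.character(seq_len(n))
  structure(list(dim = ncol(coords), coords = coords, energies = e_rel,
                 dressed_energy = dressed,
                 vertices = which(dressed <= 1e-8), labels = labels),
            class = "hull_model")
}

#' @export
print.hull_model <- function(x, ...) {
  cat("hull_model: d =", x$dim, ",", length(x$labels), "structures,",
      length(x$vertices), "hull vertices\n")
  invisible(x)
}

#' Candidate pool from known polymorphs
#'
#' The candidate pool is the set of structures inside the smallest dressed
#' energy window that contains all currently known polymorphs: the window is
#' the largest dressed energy among the known structures, and every
#' structure with dressed energy at or below the window (ties included) is a
#' member.
#'
#' @param hull A [build_hull()] model.
#' @param known Character labels (or integer indices) of known structures.
#' @return Object of class `candidate_pool`: `window` (kJ/mol), `members`
#'   (labels), `size`.
#' @export
candidate_pool_from_known <- function(hull, known) {
  idx <- .known_idx(hull$labels, known)
  window <- max(hull$dressed_energy[idx])
  sel <- hull$dressed_energy <= window + 1e-12
  structure(list(window = window, members = hull$labels[sel],
                 size = sum(sel)),
            class = "candidate_pool")
}

.known_idx <- function(labels, known) {
  if (length(known) == 0) stop("empty set of known structures")
  if (is.numeric(known)) return(as.integer(known))
  idx <- match(known, labels)
  if (anyNA(idx)) {
    stop("unknown structure label(s): ", paste(known[is.na(idx)], collapse = ", "))
  }
  idx
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat("candidate_pool:", x$size, "structures within dressed-energy window",
      signif(x$window, 5), "kJ/mol\n")
  invisible(x)
}

#' Baseline candidate pools from traditional landscape analysis
#'
#' Two baselines against which GCH pools are compared: (i) the smallest
#' relative-energy cutoff above the global minimum containing all known
#' structures, and (ii) the candidate pool from a convex hull built on a
#' single intuitive descriptor (density by default; any user-supplied
#' per-structure descriptor such as a torsion angle may be substituted).
#'
#' @param energies Numeric energies (kJ/mol).
#' @param known Labels or indices of known structures.
#' @param labels Structure labels.
#' @param descriptor Per-structure intuitive descriptor for the hull
#'   baseline; defaults to `densities`.
#' @param densities Densities in g/cm^3 (optional; the hull baseline is
#'   skipped with a warning when absent).
#' @return List with `energy_cutoff` and `energy_density` candidate pools
#'   (the latter `NULL` when no descriptor is available).
#' @export
baseline_pools <- function(energies, known, labels = as.character(seq_along(energies)),
                           densities = NULL, descriptor = densities) {
  idx <- .known_idx(labels, known)
  e_rel <- energies - min(energies)
  window <- max(e_rel[idx])
  sel <- e_rel <= window + 1e-12
  cutoff_pool <- structure(list(window = window, members = labels[sel],
                                size = sum(sel)),
                           class = "candidate_pool")
  density_pool <- NULL
  if (is.null(descriptor) || all(is.na(descriptor))) {
    warning("no density/descriptor available: skipping the descriptor-hull baseline")
  } else {
    hull <- build_hull(matrix(descriptor, ncol = 1), energies, labels = labels)
    density_pool <- candidate_pool_from_known(hull, known)
  }
  list(energy_cutoff = cutoff_pool, energy_density = density_pool)
}

#' Candidate-pool distribution under energy noise
#'
#' Measures the sensitivity of GCH candidate pools to random errors in the
#' calculated energies: the hull and pool are rebuilt `iterations` times,
#' each time with i.i.d. noise added to every energy, drawn from a uniform
#' distribution centred on zero whose standard deviation equals `noise_sd`
#' (half-width `noise_sd * sqrt(3)`). Descriptor coordinates come from a
#' single kPCA of the noiseless kernel (energies do not enter the kPCA).
#'
#' @param K Normalized `kernel_matrix`.
#' @param energies Energies in kJ/mol.
#' @param known Labels or indices of known structures.
#' @param noise_sd Standard deviation of the energy noise (kJ/mol).
#' @param iterations Number of resampling iterations (default 250).
#' @param seed RNG seed (noise is drawn structure-by-structure in a fixed
#'   order, so runs are bitwise reproducible).
#' @param d Hull dimensionality: number of leading kPCA components.
#' @return Object of class `noise_ensemble`: `iterations`, `noise_sd`,
#'   `seed`, `pool_sizes`, `noise_sd_empirical`.
#' @export
resample_pools <- function(K, energies, known, noise_sd, iterations = 250L,
                           seed = 1L, d = 2L) {
  stopifnot(iterations >= 1)
  pc <- kpca(K)
  coords <- pc$coords[, seq_len(min(d, ncol(pc$coords))), drop = FALSE]
  labels <- pc$labels
  if (is.null(labels)) labels <- as.character(seq_along(energies))
  idx <- .known_idx(labels, known)
  half <- noise_sd * sqrt(3)
  set.seed(seed)
  sizes <- integer(iterations)
  ssq <- 0; nn <- 0
  for (it in seq_len(iterations)) {
    noise <- if (half > 0) stats::runif(length(energies), -half, half)
             else numeric(length(energies))
    ssq <- ssq + sum(noise^2); nn <- nn + length(noise)
    hull <- build_hull(coords, energies + noise, labels = labels)
    sizes[it] <- candidate_pool_from_known(hull, idx)$size
  }
  structure(list(iterations = iterations, noise_sd = noise_sd, seed = seed,
                 pool_sizes = sizes,
                 noise_sd_empirical = sqrt(ssq / max(nn, 1))),
            class = "noise_ensemble")
}

#' Compare two noise ensembles (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test with tie correction on the per-iteration
#' candidate-pool sizes of two ensembles.
#'
#' @param e1,e2 `noise_ensemble` objects (or plain numeric samples).
#' @return List with `U` and `p_value`.
#' @export
compare_ensembles <- function(e1, e2) {
  x <- if (inherits(e1, "noise_ensemble")) e1$pool_sizes else e1
  y <- if (inherits(e2, "noise_ensemble")) e2$pool_sizes else e2
  if (length(x) == 0 || length(y) == 0) stop("both ensembles must be nonempty")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Rank correlation between hull-based and energetic rankings
#'
#' Kendall tau between the known structures' ranking by dressed energy and
#' their ranking by relative lattice energy.
#'
#' @param hull A [build_hull()] model.
#' @param known Labels or indices of at least three known structures.
#' @return List with `tau` and `p_value`.
#' @export
rank_correlation <- function(hull, known) {
  idx <- .known_idx(hull$labels, known)
  if (length(idx) < 3) stop("need at least 3 known structures for a rank correlation")
  ct <- suppressWarnings(stats::cor.test(hull$dressed_energy[idx],
                                         hull$energies[idx],
                                         method = "kendall"))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}
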