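#' SOAP descriptor parameters
#'
#' Parameters of the atomic-environment power-spectrum descriptor: the
#' neighbour density of each species within `r_cut` of a central atom is a
#' sum of Gaussians of width `sigma_atom` placed on the neighbouring atoms
#' (periodic images included, the central atom included in its own species
#' channel). The density is expanded in `n_max` orthonormalized spherical
#' Gaussian radial functions and spherical harmonics up to `l_max`, and
#' contracted to the rotationally invariant power spectrum.
#'
#' @param r_cut Cutoff radius in Angstrom (> 0). The study cutoffs of
#'   interest are typically 4-10 Angstrom.
#' @param n_max Radial basis size (default 8).
#' @param l_max Angular band limit (default 6).
#' @param sigma_atom Gaussian smearing width in Angstrom (default 0.5).
#' @param species Ordered character vector of element symbols the descriptor
#'   accounts for; every element in the structures must be listed.
#' @param n_quad Gauss-Legendre radial quadrature size (default 60).
#' @return Object of class `soap_params`.
#' @export
soap_params <- function(r_cut, n_max = 8L, l_max = 6L, sigma_atom = 0.5,
                        species, n_quad = 60L) {
  stopifnot(r_cut > 0, n_max >= 1, l_max >= 0, sigma_atom > 0,
            length(species) >= 1)
  structure(list(r_cut = r_cut, n_max = as.integer(n_max),
                 l_max = as.integer(l_max), sigma_atom = sigma_atom,
                 species = as.character(species), n_quad = as.integer(n_quad)),
            class = "soap_params")
}

#' @export
print.soap_params <- function(x, ...) {
  cat("soap_params: r_cut =", x$r_cut, "A, n_max =", x$n_max, ", l_max =",
      x$l_max, ", sigma =", x$sigma_atom, "A, species:",
      paste(x$species, collapse = " "), "\n")
  invisible(x)
}

.params_hash <- function(params) {
  paste0("soap-", paste(c(params$r_cut, params$n_max, params$l_max,
                          params$sigma_atom, params$species), collapse = "_"))
}

## ---- radial basis -------------------------------------------------------

# Orthonormalized spherical-Gaussian radial basis evaluated on a
# Gauss-Legendre grid over [0, r_cut]. Returns nodes, weights and the
# n_quad x n_max matrix of orthonormal basis values.
.radial_basis <- function(params) {
  gl <- pracma::gaussLegendre(params$n_quad, 0, params$r_cut)
  r <- gl$x; w <- gl$w
  n_max <- params$n_max
  centers <- if (n_max == 1) 0 else seq(0, params$r_cut, length.out = n_max)
  width <- params$r_cut / max(n_max, 2)
  phi <- exp(-outer(r, centers, "-")^2 / (2 * width^2))  # n_quad x n_max
  S <- crossprod(phi, phi * (w * r^2))
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-12 * max(es$values)) {
    stop("radial basis overlap is numerically singular; lower n_max")
  }
  S_inv_sqrt <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  list(nodes = r, weights = w, basis = phi %*% S_inv_sqrt,
       centers = centers, width = width)
}

## ---- real spherical harmonics ------------------------------------------

# (2l+1) x n matrix of orthonormal real spherical harmonics for unit
# directions `u` (n x 3). Row order: m = 0, then (cos, sin) pairs for
# m = 1..l.
.real_sph_harm <- function(l, u) {
  n <- nrow(u)
  ct <- pmin(pmax(u[, 3], -1), 1)
  phi <- atan2(u[, 2], u[, 1])
  P <- pracma::legendre(l, ct)                 # (l+1) x n, m = 0..l
  if (l == 0) P <- matrix(P, 1, n)
  out <- matrix(0, 2 * l + 1, n)
  out[1, ] <- sqrt((2 * l + 1) / (4 * pi)) * P[1, ]
  if (l > 0) {
    for (m in 1:l) {
      nrm <- sqrt((2 * l + 1) / (2 * pi) *
                    exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      out[2 * m, ] <- nrm * P[m + 1, ] * cos(m * phi)
      out[2 * m + 1, ] <- nrm * P[m + 1, ] * sin(m * phi)
    }
  }
  out
}

# exp(-x) * i_l(x) for x >= 0 (scaled modified spherical Bessel, first kind)
.scaled_mod_sph_bessel <- function(l, x) {
  out <- numeric(length(x))
  small <- x < 1e-6
  if (any(small)) {
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    out[small] <- x[small]^l / dfact * exp(-x[small])
  }
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- sqrt(pi / (2 * xs)) * besselI(xs, l + 0.5, expon.scaled = TRUE)
  }
  out
}

## ---- expansion + power spectrum ----------------------------------------

# Expansion coefficients c[[l]]: n_max x (2l+1) for one species channel.
# neighbors: distances R (may include 0 for the central atom) and unit
# directions U (n x 3; rows with R ~ 0 are ignored for l > 0).
.species_coefficients <- function(R, U, params, rad) {
  n_max <- params$n_max; l_max <- params$l_max; sig <- params$sigma_atom
  cl <- lapply(0:l_max, function(l) matrix(0, n_max, 2 * l + 1))
  at_center <- R < 1e-10
  if (any(at_center)) {
    # only the l = 0 channel survives for a Gaussian centred on the origin
    integ <- crossprod(rad$basis,
                       rad$weights * rad$nodes^2 *
                         exp(-rad$nodes^2 / (2 * sig^2)))
    cl[[1]][, 1] <- cl[[1]][, 1] +
      sum(at_center) * sqrt(4 * pi) * as.numeric(integ)
  }
  if (any(!at_center)) {
    Rn <- R[!at_center]
    Un <- U[!at_center, , drop = FALSE]
    r <- rad$nodes
    gauss <- exp(-(outer(r, Rn, "-"))^2 / (2 * sig^2))  # n_quad x n_nb
    xarg <- outer(r, Rn) / sig^2
    W <- rad$weights * r^2
    for (l in 0:l_max) {
      Sl <- matrix(.scaled_mod_sph_bessel(l, as.numeric(xarg)), nrow = length(r))
      Il <- crossprod(rad$basis, (gauss * Sl) * W)      # n_max x n_nb
      Y <- .real_sph_harm(l, Un)                        # (2l+1) x n_nb
      cl[[l + 1]] <- cl[[l + 1]] + 4 * pi * tcrossprod(Il, Y)
    }
  }
  cl
}

# Contract per-species coefficient lists into the flat power-spectrum vector.
# Blocks ordered by species pair (alpha <= beta in params$species order),
# then l = 0..l_max; within a block b1 <= b2 for alpha == beta (off-diagonal
# weighted sqrt(2)) and the full b1 x b2 grid (weighted sqrt(2)) for
# alpha < beta, so that the plain dot product of two vectors equals the full
# unrestricted sum over species and radial indices.
.power_spectrum <- function(coeffs, params) {
  n_species <- length(params$species)
  n_max <- params$n_max
  out <- c()
  upper <- upper.tri(matrix(0, n_max, n_max), diag = TRUE)
  offdiag <- upper.tri(matrix(0, n_max, n_max))
  for (a in seq_len(n_species)) {
    for (b in a:n_species) {
      for (l in 0:params$l_max) {
        pref <- pi * sqrt(8 / (2 * l + 1))
        block <- pref * tcrossprod(coeffs[[a]][[l + 1]], coeffs[[b]][[l + 1]])
        if (a == b) {
          block[offdiag] <- block[offdiag] * sqrt(2)
          out <- c(out, block[upper])
        } else {
          out <- c(out, sqrt(2) * as.numeric(block))
        }
      }
    }
  }
  out
}

# Periodic neighbour list: positions and species codes of all atoms (with
# images) within r_cut of `center`.
.neighbour_env <- function(center, images_pos, images_species, r_cut) {
  d <- images_pos - matrix(center, nrow(images_pos), 3, byrow = TRUE)
  dist <- sqrt(rowSums(d^2))
  keep <- dist <= r_cut
  list(R = dist[keep],
       U = d[keep, , drop = FALSE] /
         pmax(dist[keep], 1e-300),
       species = images_species[keep])
}

#' Compute per-atom SOAP power spectra for a crystal
#'
#' Expands the Gaussian-smeared neighbour density (periodic images within the
#' cutoff included, central atom included) of every atom of the asymmetric
#' unit's molecule copies and contracts it to the invariant power spectrum.
#' Rows are ordered copy-major: copy 1 atoms 1..N, copy 2 atoms 1..N, ...
#'
#' @param x A partitioned [crystal()] (see [partition_molecules()]).
#' @param params A [soap_params()] object.
#' @return Object of class `environments`: list with `spectra` (matrix,
#'   one row per atom), `copy`, `index` (intramolecular index per row),
#'   `n_index` (atoms per molecule), `label`, `params`.
#' @export
compute_environments <- function(x, params) {
  stopifnot(inherits(x, "crystal"), inherits(params, "soap_params"))
  if (is.null(x$molecule_partition)) {
    stop("partition not filled; run partition_molecules() first")
  }
  if (!all(x$elements %in% params$species)) {
    stop("configuration error: element(s) ",
         paste(setdiff(unique(x$elements), params$species), collapse = ", "),
         " not in params$species")
  }
  rad <- .radial_basis(params)
  # replicate enough periodic images to cover r_cut around any (possibly
  # unwrapped) atom position
  inv <- solve(x$lattice)
  spacing <- 1 / sqrt(colSums(inv^2))
  frac <- .frac_coords(x)
  reps <- ceiling(params$r_cut / spacing) +
    ceiling(pmax(apply(frac, 2, max) - 1, 0 - apply(frac, 2, min), 0)) + 1L
  grid <- as.matrix(expand.grid(-reps[1]:reps[1], -reps[2]:reps[2],
                                -reps[3]:reps[3]))
  shifts <- grid %*% x$lattice
  n_at <- nrow(x$coords)
  images_pos <- shifts[rep(seq_len(nrow(shifts)), each = n_at), ] +
    x$coords[rep(seq_len(n_at), nrow(shifts)), ]
  images_species <- rep(x$elements, nrow(shifts))
  species_code <- match(images_species, params$species)

  centers <- unlist(x$molecule_partition)
  n_copy <- length(x$molecule_partition)
  n_index <- length(x$molecule_partition[[1]])
  spectra <- NULL
  for (ci in seq_along(centers)) {
    env <- .neighbour_env(x$coords[centers[ci], ], images_pos, species_code,
                          params$r_cut)
    coeffs <- lapply(seq_along(params$species), function(s) {
      sel <- env$species == s
      .species_coefficients(env$R[sel], env$U[sel, , drop = FALSE], params, rad)
    })
    v <- .power_spectrum(coeffs, params)
    if (is.null(spectra)) spectra <- matrix(0, length(centers), length(v))
    spectra[ci, ] <- v
  }
  structure(list(spectra = spectra,
                 copy = rep(seq_len(n_copy), each = n_index),
                 index = rep(seq_len(n_index), n_copy),
                 n_index = n_index, label = x$label,
                 params_hash = .params_hash(params)),
            class = "environments")
}

#' Local SOAP kernel between two atomic environments
#'
#' The similarity of two atomic environments is the plain dot product of
#' their power-spectrum vectors.
#'
#' @param a,b Numeric power-spectrum vectors from identical [soap_params()].
#' @return Similarity scalar.
#' @export
local_kernel <- function(a, b) {
  if (length(a) != length(b)) {
    stop("parameter mismatch: power spectra have different lengths")
  }
  sum(a * b)
}
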