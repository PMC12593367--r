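## Shared fixtures and independent oracles. Fixtures are generated in code
## and memoised so each is built at most once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fix)) assign(name, force(expr), envir = .fix)
  get(name, envir = .fix)
}

tri_params <- function(r_cut = 4) {
  soap_params(r_cut, n_max = 4, l_max = 3, species = c("C", "N", "O"))
}

tri_landscape <- function() {
  memo("tri_landscape", make_landscape(30, template = "asymmetric_triatomic",
                                       seed = 101))
}

tri_envs <- function() {
  memo("tri_envs", lapply(tri_landscape()$structures, compute_environments,
                          params = tri_params()))
}

tri_mset <- function() memo("tri_mset", find_mappings(tri_landscape()$molecule))

tri_kernel <- function(type = "adapted") {
  memo(paste0("tri_kernel_", type),
       normalize_kernel(build_kernel_matrix(tri_envs(), type,
                                            mset = tri_mset())))
}

ab2_landscape <- function() {
  memo("ab2_landscape", make_landscape(10, template = "symmetric_AB2",
                                       density_range = c(0.55, 0.8),
                                       seed = 7))
}

ab2_params <- function() soap_params(4, n_max = 3, l_max = 2,
                                     species = c("H", "O"))

ab2_envs <- function() {
  memo("ab2_envs", lapply(ab2_landscape()$structures, compute_environments,
                          params = ab2_params()))
}

## ---- independent kernel oracles ----------------------------------------

# Brute-force adapted kernel: explicit enumeration of mappings, molecule-copy
# pairs and atoms, built only on local_kernel().
brute_force_adapted <- function(env_a, env_b, mset) {
  N <- env_a$n_index
  S <- max(env_a$copy); T_ <- max(env_b$copy)
  total <- 0
  for (p in mset$perms) {
    kq <- 0
    for (a in seq_len(S)) {
      for (b in seq_len(T_)) {
        for (i in seq_len(N)) {
          ra <- which(env_a$copy == a & env_a$index == i)
          rb <- which(env_b$copy == b & env_b$index == p[i])
          kq <- kq + local_kernel(env_a$spectra[ra, ], env_b$spectra[rb, ])
        }
      }
    }
    total <- total + kq / (N * S * T_)
  }
  total / mset$Q
}

# Brute-force average kernel: mean over every atom pair.
brute_force_average <- function(env_a, env_b) {
  acc <- 0
  for (i in seq_len(nrow(env_a$spectra))) {
    for (j in seq_len(nrow(env_b$spectra))) {
      acc <- acc + local_kernel(env_a$spectra[i, ], env_b$spectra[j, ])
    }
  }
  acc / (nrow(env_a$spectra) * nrow(env_b$spectra))
}

# Hand-built environments object (for arithmetic examples).
fake_env <- function(spectra, n_index, n_copy = nrow(spectra) / n_index,
                     label = "fake") {
  structure(list(spectra = spectra,
                 copy = rep(seq_len(n_copy), each = n_index),
                 index = rep(seq_len(n_index), n_copy),
                 n_index = n_index, label = label, params_hash = "fake"),
            class = "environments")
}

## ---- lower-envelope oracle ---------------------------------------------

# Exhaustive lower convex envelope at the data points: minimum over all
# affinely independent (d+1)-point subsets whose descriptor simplex contains
# the query, of the linear interpolation; by Caratheodory this equals the
# convex envelope. d = 1 or 2.
envelope_oracle <- function(coords, energies) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- ncol(coords)
  env <- energies
  if (d == 1) {
    x <- coords[, 1]
    for (q in seq_len(n)) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (abs(x[j] - x[i]) < 1e-12) next
          t_ <- (x[q] - x[i]) / (x[j] - x[i])
          if (t_ < -1e-12 || t_ > 1 + 1e-12) next
          val <- energies[i] + t_ * (energies[j] - energies[i])
          env[q] <- min(env[q], val)
        }
      }
    }
    return(env)
  }
  trip <- utils::combn(n, 3)
  a <- coords[trip[1, ], , drop = FALSE]
  b <- coords[trip[2, ], , drop = FALSE]
  cc <- coords[trip[3, ], , drop = FALSE]
  den <- (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  ok <- abs(den) > 1e-12
  for (q in seq_len(n)) {
    px <- coords[q, 1] - a[, 1]; py <- coords[q, 2] - a[, 2]
    l2 <- ((cc[, 2] - a[, 2]) * px - (cc[, 1] - a[, 1]) * py) / den
    l3 <- (-(b[, 2] - a[, 2]) * px + (b[, 1] - a[, 1]) * py) / den
    l1 <- 1 - l2 - l3
    inside <- ok & l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (any(inside)) {
      vals <- l1[inside] * energies[trip[1, inside]] +
        l2[inside] * energies[trip[2, inside]] +
        l3[inside] * energies[trip[3, inside]]
      env[q] <- min(env[q], min(vals))
    }
  }
  env
}

## ---- SOAP grid-integration oracle --------------------------------------

# Expansion coefficients by direct 3D numerical integration of the neighbour
# density against basis x harmonic, with the density evaluated pointwise as
# a sum of Gaussians (no Bessel-expansion identity involved).
grid_coefficients <- function(R_list, U_list, params, n_r = 100, n_t = 48,
                              n_p = 72) {
  rad <- crystalgch:::.radial_basis(params)
  glr <- pracma::gaussLegendre(n_r, 0, params$r_cut)
  glt <- pracma::gaussLegendre(n_t, -1, 1)
  phis <- 2 * pi * (seq_len(n_p) - 1) / n_p
  wp <- 2 * pi / n_p
  centers_cart <- U_list * R_list  # n_nb x 3, rows R * u
  # grid points
  pts <- expand.grid(r = glr$x, ct = glt$x, phi = phis)
  st <- sqrt(1 - pts$ct^2)
  xyz <- cbind(pts$r * st * cos(pts$phi), pts$r * st * sin(pts$phi),
               pts$r * pts$ct)
  dens <- rep(0, nrow(xyz))
  for (k in seq_len(nrow(centers_cart))) {
    d2 <- rowSums(sweep(xyz, 2, centers_cart[k, ])^2)
    dens <- dens + exp(-d2 / (2 * params$sigma_atom^2))
  }
  wgt <- rep(glr$w * glr$x^2, times = n_t * n_p) *
    rep(rep(glt$w, each = n_r), times = n_p) * wp
  # radial basis values on the grid (interpolate: basis defined on GL nodes)
  width <- rad$width
  centers <- rad$centers
  phi_raw <- exp(-outer(glr$x, centers, "-")^2 / (2 * width^2))
  # orthonormalization transform recovered from the node values
  Sh <- crossprod(exp(-outer(rad$nodes, centers, "-")^2 / (2 * width^2)))
  # use the same transform as the implementation: solve for it
  trans <- qr.solve(exp(-outer(rad$nodes, centers, "-")^2 / (2 * width^2)),
                    rad$basis)
  gvals <- phi_raw %*% trans                       # n_r x n_max
  out <- lapply(0:params$l_max, function(l) matrix(0, params$n_max, 2 * l + 1))
  u_grid <- xyz / pmax(sqrt(rowSums(xyz^2)), 1e-300)
  for (l in 0:params$l_max) {
    Y <- crystalgch:::.real_sph_harm(l, u_grid)    # (2l+1) x n_pts
    for (n_ in seq_len(params$n_max)) {
      gn <- rep(gvals[, n_], times = n_t * n_p)
      out[[l + 1]][n_, ] <- as.numeric(Y %*% (gn * dens * wgt))
    }
  }
  out
}

## ---- misc helpers -------------------------------------------------------

# all permutations of a small vector (for brute-force symmetry enumeration)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# hand-built hull_model for rank-correlation arithmetic
fake_hull <- function(dressed, energies, labels = as.character(seq_along(dressed))) {
  structure(list(dim = 1L, coords = matrix(seq_along(dressed)),
                 energies = energies - min(energies),
                 dressed_energy = dressed,
                 vertices = which(dressed <= 1e-8), labels = labels),
            class = "hull_model")
}

# hand-built kpca_result around a given coordinate matrix
fake_kpca <- function(coords) {
  structure(list(eigenvalues = rep(1, ncol(coords)), coords = as.matrix(coords),
                 centering = list(row_means = rep(0, nrow(coords)),
                                  grand_mean = 0),
                 labels = as.character(seq_len(nrow(coords)))),
            class = "kpca_result")
}
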