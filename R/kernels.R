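#' Global structure-structure kernels
#'
#' Two global kernels over a set of molecular crystal structures are
#' supported. The *average* kernel is the arithmetic mean of all atom-atom
#' local similarities between the compared cell contents. The *adapted*
#' (analogous-atom) kernel restricts comparisons to atoms sharing the same
#' intramolecular index up to a molecular point-group mapping: for each
#' mapping q the per-operator kernel averages k(A_i, B_q(i)) over atoms and
#' over all molecule-copy pairs of the two asymmetric units, and the final
#' kernel is the mean of the per-operator kernels over the mapping group
#' (mean rather than maximum, which preserves positive semidefiniteness).
#'
#' @name kernels
NULL

# copy-averaged per-intramolecular-index feature matrix (N x F)
.index_features <- function(env) {
  N <- env$n_index
  out <- matrix(0, N, ncol(env$spectra))
  for (i in seq_len(N)) {
    rows <- which(env$index == i)
    out[i, ] <- colMeans(env$spectra[rows, , drop = FALSE])
  }
  out
}

#' Average-kernel similarity of two structures
#'
#' Mean of the local kernels over all atom pairs between the compared cell
#' contents.
#'
#' @param env_a,env_b `environments` objects from [compute_environments()]
#'   with identical parameters.
#' @return Similarity scalar.
#' @export
average_pair <- function(env_a, env_b) {
  .check_env_pair(env_a, env_b)
  as.numeric(tcrossprod(rbind(colMeans(env_a$spectra)),
                        rbind(colMeans(env_b$spectra))))
}

.check_env_pair <- function(env_a, env_b) {
  if (!identical(env_a$params_hash, env_b$params_hash) ||
      ncol(env_a$spectra) != ncol(env_b$spectra)) {
    stop("parameter mismatch: environments computed with different SOAP parameters")
  }
}

#' Adapted (analogous-atom) kernel similarity of two structures
#'
#' For every point-group mapping q, sums k(A_i, B_q(i)) over intramolecular
#' indices i, averaged over all molecule-copy pairs of the asymmetric units
#' and over atoms; the result is the mean over all Q mappings.
#'
#' @param env_a,env_b `environments` objects sharing SOAP parameters and a
#'   consistent intramolecular indexing (see [partition_molecules()]).
#' @param mset [find_mappings()] result for the shared molecule.
#' @param allow_mixed_zprime Permit comparisons between structures of
#'   different Z' for a symmetric molecule (Q > 1). Disallowed by default:
#'   such sets are outside the kernel's stated applicability.
#' @return Similarity scalar, symmetric in its arguments.
#' @export
adapted_pair <- function(env_a, env_b, mset, allow_mixed_zprime = FALSE) {
  .check_env_pair(env_a, env_b)
  N <- env_a$n_index
  if (env_b$n_index != N) stop("structures contain different molecules")
  for (p in mset$perms) {
    if (length(p) != N) stop("mapping length ", length(p), " does not match N = ", N)
  }
  if (mset$Q > 1 && !allow_mixed_zprime &&
      max(env_a$copy) != max(env_b$copy)) {
    stop("invalid comparison: mixed Z' (", max(env_a$copy), " vs ",
         max(env_b$copy), ") with a symmetric molecule; the adapted kernel ",
         "requires consistent Z' unless the molecule is asymmetric")
  }
  phi_a <- .index_features(env_a)
  phi_b <- .index_features(env_b)
  M <- tcrossprod(phi_a, phi_b)
  kq <- vapply(mset$perms, function(p) {
    mean(M[cbind(seq_len(N), p)])
  }, numeric(1))
  mean(kq)
}

#' Build a kernel matrix over a structure set
#'
#' Computes the raw pairwise similarity matrix for a list of structures.
#' For the adapted kernel the group-symmetrized feature construction is
#' used: per-index features are averaged over molecule copies and over the
#' mapping group, and the kernel is their Gram matrix, which is exactly
#' symmetric and positive semidefinite by construction and coincides with
#' the pairwise operator-averaged definition.
#'
#' @param structures List of partitioned [crystal()] objects, or a list of
#'   precomputed `environments`.
#' @param kernel_type `"average"` or `"adapted"`.
#' @param params [soap_params()]; required when crystals (not environments)
#'   are supplied.
#' @param mset [find_mappings()] result; required for the adapted kernel.
#' @return Object of class `kernel_matrix`: the similarity matrix with
#'   attributes `labels`, `kernel_type`, `normalized`, `params_hash`.
#' @export
build_kernel_matrix <- function(structures, kernel_type = c("adapted", "average"),
                                params = NULL, mset = NULL) {
  kernel_type <- match.arg(kernel_type)
  envs <- .as_environments(structures, params)
  labels <- vapply(envs, function(e) e$label, "")
  n <- length(envs)
  if (kernel_type == "average") {
    X <- t(vapply(envs, function(e) colMeans(e$spectra),
                  numeric(ncol(envs[[1]]$spectra))))
    K <- tcrossprod(X)
  } else {
    if (is.null(mset)) stop("adapted kernel requires a mapping set")
    N <- envs[[1]]$n_index
    zp <- vapply(envs, function(e) max(e$copy), integer(1))
    if (mset$Q > 1 && length(unique(zp)) > 1) {
      stop("invalid set: mixed Z' (", paste(sort(unique(zp)), collapse = ", "),
           ") with a symmetric molecule (Q = ", mset$Q, "); see validate_set()")
    }
    X <- matrix(0, n, N * ncol(envs[[1]]$spectra))
    for (s in seq_len(n)) {
      phi <- .index_features(envs[[s]])
      if (envs[[s]]$n_index != N) {
        stop("structure '", labels[s], "' contains a different molecule")
      }
      psi <- matrix(0, N, ncol(phi))
      for (p in mset$perms) psi <- psi + phi[p, , drop = FALSE]
      X[s, ] <- as.numeric(psi / mset$Q)
    }
    K <- tcrossprod(X) / N
  }
  dimnames(K) <- list(labels, labels)
  structure(K, labels = labels, kernel_type = kernel_type,
            normalized = FALSE,
            params_hash = envs[[1]]$params_hash,
            class = c("kernel_matrix", "matrix", "array"))
}

.as_environments <- function(structures, params) {
  if (inherits(structures[[1]], "environments")) return(structures)
  if (is.null(params)) stop("params required to compute environments")
  lapply(structures, compute_environments, params = params)
}

#' Normalize a kernel matrix to unit self-similarity
#'
#' K'(A, B) = K(A, B) / sqrt(K(A, A) K(B, B)); the diagonal becomes exactly 1.
#'
#' @param K A `kernel_matrix` (or plain symmetric matrix) with strictly
#'   positive diagonal.
#' @return The normalized `kernel_matrix`.
#' @export
normalize_kernel <- function(K) {
  d <- diag(K)
  if (any(d <= 0)) {
    stop("degenerate structure: nonpositive kernel self-similarity")
  }
  s <- sqrt(d)
  Kn <- unclass(K) / tcrossprod(s)
  diag(Kn) <- 1
  dimnames(Kn) <- dimnames(K)
  structure(Kn, labels = attr(K, "labels"),
            kernel_type = attr(K, "kernel_type"), normalized = TRUE,
            params_hash = attr(K, "params_hash"),
            class = c("kernel_matrix", "matrix", "array"))
}

#' Check positive semidefiniteness of a kernel matrix
#'
#' @param K Symmetric matrix.
#' @param tol Relative tolerance: pass iff the smallest eigenvalue is at
#'   least `-tol` times the largest (default 1e-8).
#' @return List with `min_eigenvalue`, `max_eigenvalue`, `pass`.
#' @export
check_psd <- function(K, tol = 1e-8) {
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  list(min_eigenvalue = min(ev), max_eigenvalue = max(ev),
       pass = min(ev) >= -tol * max(abs(ev)))
}

#' Save a kernel matrix (dense text + JSON sidecar)
#'
#' @param K A `kernel_matrix`.
#' @param prefix Path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
save_kernel <- function(K, prefix) {
  utils::write.table(unclass(K), paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(labels = attr(K, "labels"), kernel_type = attr(K, "kernel_type"),
         normalized = attr(K, "normalized"),
         params_hash = attr(K, "params_hash")),
    paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Load a kernel matrix written by [save_kernel()]
#'
#' @param prefix Path prefix used at save time.
#' @return A `kernel_matrix`.
#' @export
load_kernel <- function(prefix) {
  vals <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  dimnames(vals) <- list(meta$labels, meta$labels)
  structure(vals, labels = meta$labels, kernel_type = meta$kernel_type,
            normalized = meta$normalized, params_hash = meta$params_hash,
            class = c("kernel_matrix", "matrix", "array"))
}
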