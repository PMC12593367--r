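#' Load and validate a run configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), fills defaults,
#' and validates values before any computation. The configuration drives the
#' three workflows: kernel construction (SOAP parameters + kernel type),
#' hull analysis (dimensionality, resampling), interpretability and GPR.
#'
#' @param config Path to a YAML file or a named list.
#' @return Validated configuration list of class `run_config` (with a
#'   provenance `hash` field recorded in every output).
#' @export
run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(
    paths = list(structures_dir = "structures", kernel_prefix = "kernel",
                 out_dir = "out"),
    molecule = list(template = "asymmetric_triatomic"),
    soap = list(r_cut = 4, n_max = 6, l_max = 4, sigma_atom = 0.5),
    kernel_type = "adapted",
    synth = list(n_structures = 40, noise_sd = 0, seed = 1),
    gch = list(d = 2, iterations = 250, noise_sd = 0.5, seed = 1,
               known = NULL),
    interpret = list(n_components = 32, folds = 5),
    gpr = list(folds = 5, alpha = 1e-6, seed = 1, block_size = 500)
  )
  cfg <- utils::modifyList(defaults, cfg)
  if (cfg$soap$r_cut <= 0) stop("config validation error: soap r_cut must be > 0")
  if (cfg$soap$n_max < 1 || cfg$soap$l_max < 0 || cfg$soap$sigma_atom <= 0) {
    stop("config validation error: invalid SOAP parameters")
  }
  if (!cfg$kernel_type %in% c("adapted", "average")) {
    stop("config validation error: kernel_type must be adapted or average")
  }
  if (cfg$gch$d < 1 || cfg$gch$iterations < 1) {
    stop("config validation error: invalid gch options")
  }
  cfg$hash <- substr(.config_hash(cfg), 1, 12)
  class(cfg) <- "run_config"
  cfg
}

.config_hash <- function(cfg) {
  cfg$hash <- NULL
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
  # small stable polynomial rolling hash; no external digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(txt))) h <- (h * 131 + b) %% 1e12
  sprintf("%012.0f", h)
}

.atomic_write_json <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
}

.read_structure_dir <- function(dir, mol) {
  files <- sort(list.files(dir, pattern = "\\.(xyz|extxyz|cif)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no structure files in ", dir)
  structures <- lapply(files, read_crystal)
  structures <- lapply(structures, partition_molecules, mol = mol)
  csv <- file.path(dir, "properties.csv")
  if (file.exists(csv)) structures <- annotate_structures(structures, csv)
  structures
}

#' Run a configured workflow
#'
#' Wires the package modules into end-to-end workflows:
#' \describe{
#'   \item{synth}{generate a synthetic landscape into the structures dir.}
#'   \item{kernel}{read structures, build + normalize the configured kernel,
#'     save it.}
#'   \item{gch}{kPCA, hull, candidate pools, baselines, noise resampling and
#'     rank statistics; writes pool/ensemble CSVs and a JSON summary.}
#'   \item{interpret}{density regression and (when class labels exist)
#'     SVC accuracies; writes a JSON report.}
#'   \item{gpr}{cross-validated energy-prediction errors; writes a JSON
#'     report.}
#' }
#' Outputs are written atomically and stamped with the configuration hash.
#'
#' @param config A [run_config()] (or path / list accepted by it).
#' @param workflow One of `"synth"`, `"kernel"`, `"gch"`, `"interpret"`,
#'   `"gpr"`.
#' @return Invisibly, a list of the main results of the workflow.
#' @export
run_workflow <- function(config,
                         workflow = c("kernel", "gch", "interpret", "gpr",
                                      "synth")) {
  workflow <- match.arg(workflow)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  mol <- do.call(make_molecule, cfg$molecule)

  if (workflow == "synth") {
    args <- cfg$synth
    args$template <- cfg$molecule$template
    land <- do.call(make_landscape, args)
    write_landscape(land, cfg$paths$structures_dir)
    return(invisible(list(landscape = land)))
  }

  if (workflow == "kernel") {
    structures <- .read_structure_dir(cfg$paths$structures_dir, mol)
    params <- do.call(soap_params,
                      c(cfg$soap, list(species = sort(unique(mol$elements)))))
    mset <- find_mappings(mol)
    vs <- validate_set(structures, mol, symmetric = mset$Q > 1)
    if (!vs$valid && cfg$kernel_type == "adapted") {
      stop("structures: ", vs$reason)
    }
    K <- build_kernel_matrix(structures, cfg$kernel_type, params = params,
                             mset = mset)
    K <- normalize_kernel(K)
    save_kernel(K, cfg$paths$kernel_prefix)
    return(invisible(list(kernel = K)))
  }

  K <- load_kernel(cfg$paths$kernel_prefix)
  props <- utils::read.csv(file.path(cfg$paths$structures_dir,
                                     "properties.csv"))
  props <- props[match(attr(K, "labels"), props$label), ]
  energies <- props$energy_kjmol

  if (workflow == "gch") {
    known <- cfg$gch$known
    if (is.null(known)) known <- props$label[which.min(energies)]
    pc <- kpca(K)
    d <- min(cfg$gch$d, ncol(pc$coords))
    hull <- build_hull(pc$coords[, seq_len(d), drop = FALSE], energies,
                       labels = pc$labels)
    pool <- candidate_pool_from_known(hull, known)
    base <- baseline_pools(energies, known, labels = props$label,
                           densities = props$density_gcm3)
    ens <- resample_pools(K, energies, known, noise_sd = cfg$gch$noise_sd,
                          iterations = cfg$gch$iterations,
                          seed = cfg$gch$seed, d = d)
    tau <- if (length(known) >= 3) rank_correlation(hull, known) else NULL
    utils::write.csv(data.frame(label = hull$labels,
                                dressed_energy = hull$dressed_energy,
                                in_pool = hull$labels %in% pool$members),
                     file.path(cfg$paths$out_dir, "pool.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(iteration = seq_along(ens$pool_sizes),
                                pool_size = ens$pool_sizes),
                     file.path(cfg$paths$out_dir, "ensemble.csv"),
                     row.names = FALSE)
    summary <- list(config_hash = cfg$hash, d = d, window = pool$window,
                    pool_size = pool$size,
                    energy_cutoff_pool = base$energy_cutoff$size,
                    energy_density_pool =
                      if (is.null(base$energy_density)) NA
                      else base$energy_density$size,
                    median_noise_pool = stats::median(ens$pool_sizes),
                    tau = if (is.null(tau)) NA else tau$tau)
    .atomic_write_json(summary, file.path(cfg$paths$out_dir, "gch.json"))
    return(invisible(list(hull = hull, pool = pool, baselines = base,
                          ensemble = ens, summary = summary)))
  }

  if (workflow == "interpret") {
    pc <- kpca(K)
    res <- list(config_hash = cfg$hash)
    if (!is.null(props$density_gcm3) && !all(is.na(props$density_gcm3))) {
      dr <- density_r2(pc, props$density_gcm3,
                       n_components = cfg$interpret$n_components)
      res$best_r2 <- dr$r2
      res$best_component <- dr$component
    }
    if (!is.null(props$class) && !all(is.na(props$class)) &&
        length(unique(stats::na.omit(props$class))) == 2) {
      res$svc_single <- svc_accuracy(pc, props$class,
                                     mode = "single_best_of_32",
                                     folds = cfg$interpret$folds)[
                                       c("balanced_accuracy", "C")]
      res$svc_subset <- svc_accuracy(pc, props$class,
                                     mode = "best_subset_of_top5",
                                     folds = cfg$interpret$folds)[
                                       c("balanced_accuracy", "C")]
    }
    .atomic_write_json(res, file.path(cfg$paths$out_dir, "interpret.json"))
    return(invisible(res))
  }

  # gpr
  cv <- cross_validate(K, energies, folds = cfg$gpr$folds,
                       alpha = cfg$gpr$alpha, seed = cfg$gpr$seed)
  res <- list(config_hash = cfg$hash, rmse_mean = cv$rmse_mean,
              rmse_sd = cv$rmse_sd, mae_mean = cv$mae_mean,
              mae_sd = cv$mae_sd)
  .atomic_write_json(res, file.path(cfg$paths$out_dir, "gpr.json"))
  utils::write.csv(cv$per_fold, file.path(cfg$paths$out_dir, "gpr_folds.csv"),
                   row.names = FALSE)
  invisible(c(res, list(per_fold = cv$per_fold)))
}
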