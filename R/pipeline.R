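## End-to-end orchestration: bond perception -> typing -> ring/UB adjustments
## -> pruning -> classification -> scans -> mode projection/smart selection ->
## design matrices -> bounded weighted LASSO -> lambda_best -> statistics.

#' Pipeline configuration
#'
#' Collects every tolerance and switch of the protocol with its default:
#' stretch-typing window 1 percent, angle/dihedral rounding 0.01 rad, linear
#' tolerance 0.03 rad, CADT/ADDT case threshold 130 degrees, smart-selection
#' cutoff |c| > 0.1, scan step 10 degrees, 100 lambda values spanning a 1e-5
#' ratio, coordinate-descent threshold 1e-10, individual equilibrium values,
#' cross terms off, linear-dihedral modes on. One seed governs pruning ties,
#' scan-instance draws and the synthetic sampler. The configuration is
#' serialized into every report.
#'
#' @param stretch_tol relative stretch-typing window
#' @param round_digits decimal digits (radians) for angle/dihedral rounding
#' @param eps_linear linear-dihedral tolerance (radians)
#' @param case_threshold_deg bond-angle threshold switching CADT to ADDT
#' @param smart_threshold smart-selection cutoff on |c_m|
#' @param step_deg torsion-scan increment (degrees)
#' @param n_lambda,lambda_ratio,thresh LASSO path controls
#' @param eq_mode `"individual"` or `"average"` equilibrium values
#' @param cross_terms include bond-bond cross terms
#' @param addt_linear include linear-dihedral torsion modes
#' @param seed pipeline seed
#' @param tolerance_scale bond-perception radius scale
#' @param radii per-element typing radii
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(stretch_tol = 0.01, round_digits = 2L,
                            eps_linear = 0.03, case_threshold_deg = 130,
                            smart_threshold = 0.1, step_deg = 10,
                            n_lambda = 100L, lambda_ratio = 1e-5,
                            thresh = 1e-10, eq_mode = c("individual", "average"),
                            cross_terms = FALSE, addt_linear = TRUE,
                            seed = 1L, tolerance_scale = 1.0,
                            radii = default_typing_radii()) {
  eq_mode <- match.arg(eq_mode)
  stopifnot(stretch_tol > 0, eps_linear > 0, case_threshold_deg > 0,
            smart_threshold > 0, step_deg > 0, n_lambda >= 2L,
            lambda_ratio > 0, thresh > 0)
  structure(list(stretch_tol = stretch_tol, round_digits = round_digits,
                 eps_linear = eps_linear,
                 case_threshold_deg = case_threshold_deg,
                 smart_threshold = smart_threshold, step_deg = step_deg,
                 n_lambda = n_lambda, lambda_ratio = lambda_ratio,
                 thresh = thresh, eq_mode = eq_mode,
                 cross_terms = cross_terms, addt_linear = addt_linear,
                 seed = as.integer(seed), tolerance_scale = tolerance_scale,
                 radii = radii),
            class = "pipeline_config")
}

#' Type, classify, prune and scan a structure
#'
#' The structure-side front end of the pipeline: bond perception, unit-cell
#' validation, internal-coordinate typing, dihedral classification, coupled
#' dihedral-type pruning and hindered-rotor resolution (which generates the
#' rigid torsion scans reused downstream).
#' @param structure a `periodic_structure`
#' @param config a `pipeline_config`
#' @return list with `icset`, `scans`, `prune_report`
#' @export
prepare_icset <- function(structure, config = pipeline_config()) {
  graph <- detect_bonds(structure, radii = config$radii,
                        tolerance_scale = config$tolerance_scale)
  val <- validate_unit_cell(structure, graph)
  if (!val$ok) {
    stop("unit cell too small: atom pair(s) bonded through multiple images (",
         paste(sprintf("%d-%d", val$offending$a, val$offending$b),
               collapse = ", "),
         "); expand to a supercell")
  }
  icset <- type_internal_coords(structure, graph,
                                stretch_tol = config$stretch_tol,
                                round_digits = config$round_digits)
  icset <- classify_dihedral_types(icset, eps_linear = config$eps_linear)
  pr <- prune_dihedral_types(icset, seed = config$seed)
  hd <- detect_hindered(pr$icset, seed = config$seed,
                        step_deg = config$step_deg, radii = config$radii,
                        tolerance_scale = config$tolerance_scale)
  list(icset = hd$icset, scans = hd$scans, prune_report = pr$report)
}

#' Run the full flexibility-parameterization pipeline
#'
#' @param structure a `periodic_structure` (or a fixture name)
#' @param reference one of: an `oracle_spec` (its hidden model generates the
#'   reference data), a `reference_dataset`, or a CSV path prefix accepted by
#'   [read_reference_csv()]
#' @param config a `pipeline_config`; when `reference` is an `oracle_spec`
#'   its own configuration is used so typing and scans agree
#' @param out_dir optional directory for artifacts (parameter JSON,
#'   statistics JSON, inventory CSVs, scan manifests, pruning report)
#' @param ... passed to [generate_reference_data()] when `reference` is an
#'   `oracle_spec`
#' @return object of class `flex_fit`: list with the fitted `model`,
#'   `icset`, `coeffs` and `selected_modes` per rotatable type, the lasso
#'   `path` and `selection`, `stats` (training/validation/per-atom), the
#'   pruning report, a stage-count `log`, and the `config`
#' @export
run_pipeline <- function(structure, reference, config = pipeline_config(),
                         out_dir = NULL, ...) {
  if (is.character(structure) && length(structure) == 1L &&
      !file.exists(structure)) {
    structure <- make_fixture(structure)
  }
  if (inherits(reference, "oracle_spec")) {
    config <- reference$config
    prep <- list(icset = reference$icset, scans = reference$scans,
                 prune_report = reference$prune_report)
    dataset <- generate_reference_data(reference, ...)
  } else {
    prep <- prepare_icset(structure, config)
    dataset <- if (inherits(reference, "reference_dataset")) reference
      else read_reference_csv(reference, structure)
  }
  fit_pipeline(prep, dataset, config, out_dir = out_dir)
}

#' Fit force constants given a prepared structure and reference data
#'
#' The fitting back end of [run_pipeline()]: attaches scan energies to the
#' prepared scans, projects each rotatable type's curve onto the mode basis,
#' smart-selects modes, assembles the flexibility terms and design matrices,
#' runs the bounded weighted LASSO path, selects `lambda_best`, and computes
#' training and validation statistics.
#' @param prep result of [prepare_icset()]
#' @param dataset a `reference_dataset` (scan energies keyed by dihedral type)
#' @param config a `pipeline_config`
#' @param out_dir optional artifact directory
#' @return a `flex_fit` (see [run_pipeline()])
#' @export
fit_pipeline <- function(prep, dataset, config = pipeline_config(),
                         out_dir = NULL) {
  icset <- prep$icset
  scans <- prep$scans
  ## attach scan energies by dihedral type
  energy_by_type <- list()
  for (s in dataset$scans) {
    energy_by_type[[as.character(s$type)]] <- s
  }
  coeffs <- list()
  selected_modes <- list()
  for (nm in names(scans)) {
    src <- energy_by_type[[nm]]
    if (is.null(src)) {
      stop("reference data carry no scan energies for rotatable dihedral type ",
           nm)
    }
    if (length(src$phi_deg) != length(scans[[nm]]$phi_deg) ||
        max(abs(sort(src$phi_deg) - sort(scans[[nm]]$phi_deg))) > 1e-9) {
      stop("scan grid in reference data does not match the generated scan ",
           "for type ", nm)
    }
    scans[[nm]]$energies <- src$energies[order(src$phi_deg)][
      order(order(scans[[nm]]$phi_deg))]
    co <- project_torsion_modes(scans[[nm]])
    coeffs[[nm]] <- co
    selected_modes[[nm]] <- smart_select(co, threshold = config$smart_threshold)
  }
  eq_icset <- if (config$eq_mode == "average") {
    average_equilibrium_values(icset)
  } else icset
  model <- assign_term_kinds(eq_icset, selected_modes = selected_modes,
                             cross_terms = config$cross_terms,
                             addt_linear = config$addt_linear,
                             case_threshold_deg = config$case_threshold_deg)
  bounds <- assign_bounds(model)
  ## training design: optimized + finite-displacement + training dynamics
  ## forces, plus the centered scan-energy block
  dataset_fit <- dataset
  dataset_fit$scans <- unname(scans)
  design <- build_design(model, dataset_fit, icset = eq_icset)
  w <- observation_weights(design$Y, design$part)
  nu <- penalty_factors(design$M, w)
  path <- lasso_path(design$M, design$Y, w, nu, bounds$lb, bounds$ub,
                     n_lambda = config$n_lambda,
                     lambda_ratio = config$lambda_ratio,
                     thresh = config$thresh)
  selection <- select_lambda_best(path, design$M, design$Y, design$part,
                                  n_atoms(icset$structure))
  model$k <- pmax(selection$beta, bounds$lb)  # clamp -0 style leakage
  model$k[abs(model$k) < .Machine$double.xmin] <- 0
  stats_train <- compute_statistics(model$k, design, per_atom = TRUE)
  design_valid <- build_design(model, dataset, icset = eq_icset,
                               tags = c("optimized", "aimd_validation"),
                               include_scans = FALSE)
  stats_valid <- compute_statistics(model$k, design_valid, per_atom = TRUE)
  kinds <- vapply(model$terms, `[[`, character(1L), "kind")
  log <- list(
    n_atoms = n_atoms(icset$structure),
    stretch_instances = length(unique(icset$stretch_instances$edge)),
    stretch_types = nrow(icset$stretch_types),
    angle_instances = nrow(icset$angle_instances),
    angle_types = nrow(icset$angle_types),
    dihedral_instances = if (nrow(icset$dihedral_instances))
      length(unique(icset$dihedral_instances$phys_id)) else 0L,
    dihedral_types = nrow(icset$dihedral_types),
    dihedral_types_active = sum(icset$dihedral_active),
    pruned_fraction = if (nrow(icset$dihedral_types))
      1 - sum(icset$dihedral_active) / nrow(icset$dihedral_types) else 0,
    icr_percent = compute_icr(icset),
    n_attempted_k = length(model$k),
    n_k_remaining = sum(model$k != 0),
    eliminated_by_kind = as.list(table(kinds[model$k == 0])),
    classification = as.list(table(icset$dihedral_types$classification)))
  fit <- structure(list(model = model, icset = icset, scans = scans,
                        coeffs = coeffs, selected_modes = selected_modes,
                        bounds = bounds, path = path, selection = selection,
                        design_train = design, stats_train = stats_train,
                        stats_valid = stats_valid,
                        prune_report = prep$prune_report,
                        log = log, config = config),
                   class = "flex_fit")
  if (!is.null(out_dir)) write_fit_artifacts(fit, out_dir)
  fit
}

#' @export
print.flex_fit <- function(x, ...) {
  cat("flex_fit\n")
  cat(sprintf("  terms attempted: %d, remaining at lambda_best: %d\n",
              x$log$n_attempted_k, x$log$n_k_remaining))
  cat(sprintf("  internal coordinate redundancy: %.1f%%\n", x$log$icr_percent))
  tr <- x$stats_train
  cat(sprintf("  training   %-14s R2 = %.4f  RMSE = %.4f\n", tr$part, tr$R2,
              tr$RMSE), sep = "")
  va <- x$stats_valid
  cat(sprintf("  validation %-14s R2 = %.4f  RMSE = %.4f\n", va$part, va$R2,
              va$RMSE), sep = "")
  invisible(x)
}

#' Write pipeline artifacts
#' @param fit a `flex_fit`
#' @param out_dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_fit_artifacts <- function(fit, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_flex_model(fit$model, file.path(out_dir, "parameters.json"))
  write_icoords_csv(fit$icset, file.path(out_dir, "icoords"))
  if (nrow(fit$prune_report)) {
    utils::write.csv(fit$prune_report, file.path(out_dir, "pruning_report.csv"),
                     row.names = FALSE)
  }
  for (nm in names(fit$scans)) {
    write_torsion_scan(fit$scans[[nm]],
                       file.path(out_dir, paste0("scan_type_", nm)))
  }
  stats <- list(
    config = fit$config[setdiff(names(fit$config), "radii")],
    log = fit$log,
    lambda_best = fit$selection$lambda_best,
    training = fit$stats_train,
    validation = fit$stats_valid,
    per_atom_training = attr(fit$stats_train, "per_atom"),
    per_atom_validation = attr(fit$stats_valid, "per_atom"),
    mode_coefficients = lapply(fit$coeffs, function(co)
      list(c = co$c, E_avg = co$E_avg, r2_full = co$r2_full)),
    selected_modes = fit$selected_modes)
  jsonlite::write_json(stats, file.path(out_dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  txt <- utils::capture.output(print(fit))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
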