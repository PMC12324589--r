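## End-to-end orchestration: configuration, stage sequencing, artifact
## writing, and a miniature demo dataset.

#' Build a validated pipeline run configuration
#'
#' Collects the tunable parameters of every stage with the conventional
#' defaults (1000 permutations, 1000 bootstraps, component-wise alpha
#' 0.001, scan alpha 0.05, 5-95 percentile loading intervals). Either
#' `synth` (generator parameters) or `inputs` (file paths) must describe
#' the data source. One master `seed` fans out to deterministic per-stage
#' child seeds so stages are independently reproducible.
#'
#' @param seed master seed.
#' @param out_dir artifact directory.
#' @param synth list of [mode_truth()] / [simulate_cohort()] parameters
#'   (plus optional `phenome` and `transfer` sublists), or `NULL` when
#'   reading files.
#' @param inputs named list of file paths (`participants`, `features`,
#'   `confounds`, optional `phenome`, `phenome_meta`,
#'   `transfer_features`, `transfer_covariates`), or `NULL` when
#'   simulating.
#' @param n_components components fitted.
#' @param n_perm,n_boot permutation and bootstrap iterations.
#' @param alpha_mode component-wise significance threshold.
#' @param alpha_scan family-wise scan level.
#' @param percentiles bootstrap CI percentile pair.
#' @param centering projection centering mode (see [project_cohort()]).
#' @param shared_block block carried to the transfer cohort.
#' @param brackets,transfer_brackets age-bracket breakpoints for the two
#'   cohorts (years and months respectively).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 7, out_dir = tempfile("plsmodes_run_"),
                       synth = list(), inputs = NULL,
                       n_components = 10, n_perm = 1000, n_boot = 1000,
                       alpha_mode = 0.001, alpha_scan = 0.05,
                       percentiles = c(5, 95),
                       centering = "target", shared_block = "GMV",
                       brackets = c(40, 50, 55, 60, 65, 70),
                       transfer_brackets = c(100, 110, 120, 130, 140)) {
  check_scalar(seed, "seed", integer = TRUE)
  check_scalar(n_components, "n_components", lower = 1, integer = TRUE)
  check_scalar(n_perm, "n_perm", lower = 1, integer = TRUE)
  check_scalar(n_boot, "n_boot", lower = 2, integer = TRUE)
  check_scalar(alpha_mode, "alpha_mode", lower = 1e-12, upper = 1)
  check_scalar(alpha_scan, "alpha_scan", lower = 1e-12, upper = 1)
  if (is.null(synth) && is.null(inputs)) {
    abort("either `synth` parameters or `inputs` paths must be given.")
  }
  if (!is.null(inputs)) {
    needed <- c("participants", "features", "confounds")
    missing_keys <- setdiff(needed, names(inputs))
    if (length(missing_keys) > 0) {
      abort(sprintf("`inputs` lacks required path(s): %s",
                    paste(missing_keys, collapse = ", ")))
    }
    for (nm in names(inputs)) {
      if (!file.exists(inputs[[nm]])) {
        abort(sprintf("input path for `%s` does not exist: %s", nm, inputs[[nm]]))
      }
    }
  }
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, synth = synth,
              inputs = inputs, n_components = n_components, n_perm = n_perm,
              n_boot = n_boot, alpha_mode = alpha_mode,
              alpha_scan = alpha_scan, percentiles = percentiles,
              centering = centering, shared_block = shared_block,
              brackets = brackets, transfer_brackets = transfer_brackets)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys as in [run_config()]. Relative input paths
#'   are resolved against the file's directory.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$inputs)) {
    raw$inputs <- lapply(raw$inputs, function(p) {
      if (!grepl("^(/|[A-Za-z]:)", p)) file.path(dirname(path), p) else p
    })
  }
  if (!is.null(raw$synth) && !is.null(raw$synth$block_sizes)) {
    raw$synth$block_sizes <- unlist(raw$synth$block_sizes)
  }
  allowed <- names(formals(run_config))
  do.call(run_config, raw[intersect(names(raw), allowed)])
}

## build the synthetic data bundle described by config$synth
simulate_from_config <- function(cfg) {
  sy <- cfg$synth %||% list()
  truth_args <- sy[intersect(names(sy), names(formals(mode_truth)))]
  truth_args$seed <- truth_args$seed %||% child_seed(cfg$seed, 1L)
  truth <- do.call(mode_truth, truth_args)
  n <- sy$n %||% 1000
  cohort <- simulate_cohort(n = n, truth = truth, seed = cfg$seed)
  participants <- simulate_participants(cohort, seed = cfg$seed)
  phenome <- NULL
  if (!identical(sy$phenome, FALSE)) {
    ph_args <- if (is.list(sy$phenome)) sy$phenome else list()
    phenome <- do.call(simulate_phenome,
                       c(list(cohort = cohort, seed = cfg$seed), ph_args))
  }
  transfer <- NULL
  if (!identical(sy$transfer, FALSE)) {
    tr_args <- if (is.list(sy$transfer)) sy$transfer else list()
    tr_args$shared_block <- tr_args$shared_block %||% cfg$shared_block
    transfer <- do.call(simulate_transfer_cohort,
                        c(list(truth = cohort$truth, seed = cfg$seed), tr_args))
  }
  list(participants = participants, features = cohort$features,
       confounds = cohort$confounds, phenome = phenome, transfer = transfer,
       cohort = cohort)
}

## load the file-based data bundle described by config$inputs
load_from_config <- function(cfg) {
  inp <- cfg$inputs
  phenome <- NULL
  if (!is.null(inp$phenome)) {
    values <- read_participant_table(inp$phenome)
    meta <- if (!is.null(inp$phenome_meta)) {
      read_participant_table(inp$phenome_meta)
    } else NULL
    phenome <- structure(list(values = values, meta = meta),
                         class = "synthetic_phenome")
  }
  transfer <- NULL
  if (!is.null(inp$transfer_features)) {
    transfer <- list(
      features = read_participant_table(inp$transfer_features),
      covariates = if (!is.null(inp$transfer_covariates)) {
        read_participant_table(inp$transfer_covariates)
      } else NULL
    )
  }
  list(participants = read_participant_table(inp$participants),
       features = read_participant_table(inp$features),
       confounds = read_participant_table(inp$confounds),
       phenome = phenome, transfer = transfer, cohort = NULL)
}

#' Run the full subtyping pipeline
#'
#' Executes the stages in order: data acquisition (simulation or file
#' input), cohort preparation (recoding, exclusion filters,
#' residualization), PLS fit, permutation significance, bootstrap
#' loading stability (on the significant components), phenome scan,
#' transfer-cohort projection through the shared block, and age-bracket
#' stratification of both cohorts. All artifacts are written under
#' `config$out_dir` with provenance headers; a machine-readable
#' `report.json` summarizes the run. Rerunning with the same
#' configuration reproduces identical outputs (timestamps aside).
#'
#' @param config a `run_config` or the path to a YAML config file.
#' @return the report, invisibly, as a list; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(
    package = "plsmodes",
    version = as.character(utils::packageVersion("plsmodes")),
    config_hash = config$hash,
    seed = config$seed
  )

  data <- if (!is.null(config$inputs)) load_from_config(config) else
    simulate_from_config(config)

  prepped <- prep_cohort(data$participants, data$features, data$confounds)
  model <- pls_fit(prepped$features, prepped$trait,
                   n_components = min(config$n_components,
                                      nrow(prepped$features) - 1))
  latent <- latent_correlation(model)

  perm <- pls_permutation_test(prepped$features, prepped$trait,
                               n_components = model$n_components,
                               n_perm = config$n_perm,
                               alpha = config$alpha_mode,
                               seed = child_seed(config$seed, "permute"))
  k_sig <- sum(perm$result$significant)
  k_boot <- max(1, k_sig)
  boot <- pls_bootstrap_loadings(prepped$features, prepped$trait,
                                 n_components = k_boot,
                                 n_boot = config$n_boot,
                                 percentiles = config$percentiles,
                                 seed = child_seed(config$seed, "boot"))

  scores <- pls_transform(model, prepped$features)
  scan_res <- NULL
  if (!is.null(data$phenome)) {
    scan_res <- phenome_scan(scores, data$phenome, alpha = config$alpha_scan)
  }

  transfer_scores <- NULL
  strat_transfer <- NULL
  if (!is.null(data$transfer)) {
    rmodel <- restrict_model(model, config$shared_block)
    transfer_scores <- project_cohort(rmodel, data$transfer$features,
                                      centering = config$centering)
    if (!is.null(data$transfer$covariates)) {
      strat_transfer <- stratify_age(transfer_scores,
                                     data$transfer$covariates$age,
                                     brackets = config$transfer_brackets)
    }
  }
  ages <- data$participants$age[match(prepped$trait$participant_id,
                                      data$participants$participant_id)]
  strat_source <- stratify_age(scores, ages, brackets = config$brackets)

  ## artifacts
  p <- function(f) file.path(config$out_dir, f)
  write_pls_model(model, p("model.json"), provenance = prov)
  write_table_prov(perm$result, p("mode_significance.tsv"), prov)
  write_table_prov(boot$ci, p("loading_stability.tsv"), prov)
  write_table_prov(scores, p("scores.tsv"), prov)
  write_table_prov(strat_source, p("age_brackets_source.tsv"), prov)
  if (!is.null(scan_res)) {
    write_table_prov(tibble::as_tibble(scan_res), p("associations_behavior.tsv"), prov)
  }
  if (!is.null(transfer_scores)) {
    write_table_prov(transfer_scores, p("transfer_scores.tsv"), prov)
  }
  if (!is.null(strat_transfer)) {
    write_table_prov(strat_transfer, p("age_brackets_transfer.tsv"), prov)
  }

  top_assoc <- NULL
  if (!is.null(scan_res)) {
    top_assoc <- scan_res |>
      dplyr::filter(.data$passes_bonferroni) |>
      dplyr::arrange(.data$p) |>
      head(10) |>
      dplyr::select("component", "phenotype", "r", "p")
  }
  report <- list(
    provenance = prov,
    prep = prepped$report,
    n_components_fitted = model$n_components,
    latent_correlations = as.list(setNames(latent$r, latent$component)),
    n_significant_modes = k_sig,
    significant_modes = perm$result$component[perm$result$significant],
    bootstrap = list(n_boot = boot$n_boot, n_redraws = boot$n_redraws,
                     stable_loadings = sum(boot$ci$significant)),
    scan = if (!is.null(scan_res)) list(
      family_size = attr(scan_res, "family_size"),
      threshold = attr(scan_res, "threshold"),
      n_pass = sum(scan_res$passes_bonferroni),
      top = top_assoc
    ),
    transfer = if (!is.null(transfer_scores)) list(
      n_projected = nrow(transfer_scores),
      shared_block = config$shared_block,
      centering = config$centering
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(report, p("report.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(report)
}

#' Write a ready-to-run miniature demo dataset
#'
#' Simulates a small two-cohort dataset at the full default feature
#' layout (GMV 139 / FA 48 / FC 210), writes every table as TSV plus the
#' ground-truth sidecar, and emits a `config.yaml` that [run_pipeline()]
#' can consume directly. Note that at demo sample sizes the feature
#' count far exceeds what permutation testing can resolve, so the demo
#' config is set up for a fast smoke run rather than mode discovery.
#'
#' @param seed integer seed.
#' @param out_dir writable output directory.
#' @param n,n2 source and transfer cohort sizes.
#' @return invisibly, the named vector of paths written.
#' @export
make_demo <- function(seed = 7, out_dir, n = 400, n2 = 200) {
  if (missing(out_dir)) abort("`out_dir` is required.")
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory: %s", out_dir))
  truth <- mode_truth(seed = child_seed(seed, 1L))
  cohort <- simulate_cohort(n = n, truth = truth, seed = seed)
  participants <- simulate_participants(cohort, seed = seed)
  phenome <- simulate_phenome(cohort, n_pheno = 120, seed = seed)
  transfer <- simulate_transfer_cohort(cohort$truth, n2 = n2, seed = seed)

  paths <- write_cohort(cohort, out_dir)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(participants, p("participants.tsv"))
  readr::write_tsv(phenome$values, p("phenome.tsv"))
  readr::write_tsv(phenome$meta, p("phenome_meta.tsv"))
  readr::write_tsv(transfer$features, p("transfer_features.tsv"))
  readr::write_tsv(transfer$covariates, p("transfer_covariates.tsv"))
  cfg <- list(
    seed = seed,
    out_dir = file.path(out_dir, "run"),
    inputs = list(
      participants = "participants.tsv", features = "features.tsv",
      confounds = "confounds.tsv", phenome = "phenome.tsv",
      phenome_meta = "phenome_meta.tsv",
      transfer_features = "transfer_features.tsv",
      transfer_covariates = "transfer_covariates.tsv"
    ),
    n_components = 5, n_perm = 199, n_boot = 100,
    alpha_mode = 0.001, alpha_scan = 0.05,
    transfer_brackets = c(100, 110, 120, 130, 140)
  )
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(c(paths,
              participants = p("participants.tsv"),
              phenome = p("phenome.tsv"),
              phenome_meta = p("phenome_meta.tsv"),
              transfer_features = p("transfer_features.tsv"),
              transfer_covariates = p("transfer_covariates.tsv"),
              config = p("config.yaml")))
}
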