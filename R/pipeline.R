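#' Benchmark configurations across simulated grid datasets
#'
#' Runs [outer_cv()] for every (dataset, configuration) pair and collects
#' one row per pair with the grid cell tags and the mean outer-CV score —
#' the table [rank_algorithms()] consumes.
#'
#' @param datasets list of `multimodal_dataset` built by [build_grid()]
#'   (each carries its cell in `meta$cell`).
#' @param configs list of `algorithm_config`, or a list of
#'   [ensemble_search_spec()] (named), to evaluate.
#' @param task,cv,integration,imputation,inner_folds,n_opt_iters passed to
#'   [outer_cv()].
#' @return data.frame with columns `config_id`, `snr_db`, `variant`, `seed`,
#'   `score` (mean over replications), `ci_lo`, `ci_hi`.
#' @export
benchmark_grid <- function(datasets, configs,
                           task = c("classification", "regression"),
                           cv = outer_cv_spec(),
                           integration = "mean", imputation = "median",
                           inner_folds = 3L, n_opt_iters = 25L) {
  task <- match.arg(task)
  rows <- list()
  for (ds in datasets) {
    cell <- ds$meta$cell %||% list(snr_db = NA_real_, variant = NA_character_,
                                   seed = NA_integer_)
    for (ci in seq_along(configs)) {
      config <- configs[[ci]]
      res <- outer_cv(ds, config, task = task, cv = cv,
                      integration = integration, imputation = imputation,
                      inner_folds = inner_folds, n_opt_iters = n_opt_iters)
      rows[[length(rows) + 1L]] <- data.frame(
        config_id = res$model_id,
        snr_db = cell$snr_db, variant = cell$variant, seed = cell$seed,
        score = res$summary$mean,
        ci_lo = res$summary$ci[1L], ci_hi = res$summary$ci[2L],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulation grid to disk
#'
#' One manifest + CSV set per grid cell, plus a `grid_index.json` tying the
#' cells to their files.
#'
#' @param grid a [grid_spec()].
#' @param out_dir output directory.
#' @param loadings,mask optional shared loading model and missingness
#'   template (see [build_grid()]).
#' @return the index path, invisibly.
#' @export
simulate_grid_to_dir <- function(grid, out_dir, loadings = NULL,
                                 mask = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  datasets <- build_grid(grid, loadings = loadings, mask = mask)
  cells <- grid_cells(grid)
  index <- lapply(seq_along(datasets), function(i) {
    name <- sprintf("cell_%s_%+03d_s%02d", cells$variant[i],
                    as.integer(cells$snr_db[i]), cells$seed[i])
    manifest <- write_dataset(datasets[[i]], file.path(out_dir, name),
                              name = name)
    list(snr_db = cells$snr_db[i], variant = cells$variant[i],
         seed = cells$seed[i],
         manifest = file.path(name, basename(manifest)))
  })
  index_path <- file.path(out_dir, "grid_index.json")
  jsonlite::write_json(index, index_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(index_path)
}

#' Write the reference fixture dataset to disk
#'
#' Generates the 289-subject, five-modality synthetic reference cohort with
#' grafted block-wise + random missingness, writes it as manifest + CSVs
#' (loadable by [load_dataset()]) together with a JSON summary of the
#' per-block missing fractions.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @param snr_db SNR of the generated cohort (default 0 dB).
#' @param variant latent-variable variant (default `"cluster"`).
#' @return the manifest path, invisibly.
#' @export
make_fixture <- function(seed = 1L, dir, snr_db = 0, variant = "cluster") {
  fx <- reference_fixture(seed)
  spec <- latent_cohort_spec(
    variant = variant, n_subjects = fx$layout$n_subjects, snr_db = snr_db,
    layout = fx$layout, outcome_link = "cluster_label", seed = seed)
  ds <- generate_cohort(spec, fx$loadings)
  ds <- apply_missing_pattern(ds, fx$mask, seed = seed)
  manifest <- write_dataset(ds, dir, name = "fixture")
  jsonlite::write_json(
    list(seed = seed,
         missing_fractions = as.list(extract_missing_mask(ds)$fractions)),
    file.path(dir, "fixture_mask_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Assemble a run configuration
#'
#' A fully serializable description of one end-to-end run: the simulation
#' grid, the approach (single-algorithm registry subset or auto-ensemble),
#' the outer CV settings, the integration and imputation choices, and one
#' master seed that deterministically expands to every stage seed.
#'
#' @param task `"classification"` or `"regression"`.
#' @param approach `"single"` or `"ensemble"`.
#' @param n_subjects subjects per simulated dataset.
#' @param snr_values,variants,seeds simulation grid axes.
#' @param config_ids registry configuration ids to benchmark (single
#'   approach); default a small defaults-mode subset.
#' @param budget,max_ensemble_size auto-ensemble knobs (ensemble approach).
#' @param n_replications,test_fraction,stratify_by outer CV settings.
#' @param integration,imputation pipeline choices.
#' @param inner_folds,n_opt_iters inner-loop settings.
#' @param snr_window SNR selection window for ranking.
#' @param master_seed single integer behind all randomness.
#' @return object of class `run_config`.
#' @export
run_config <- function(task = "classification", approach = "single",
                       n_subjects = 120L,
                       snr_values = c(-20, 0, 20),
                       variants = c("cluster", "spectrum"),
                       seeds = 1:2,
                       config_ids = c("logreg_default", "cart_default",
                                      "svm_rbf_default"),
                       budget = 20, max_ensemble_size = 4L,
                       n_replications = 10L, test_fraction = 0.25,
                       stratify_by = "outcome",
                       integration = "mean", imputation = "median",
                       inner_folds = 3L, n_opt_iters = 25L,
                       snr_window = c(-20, 0), master_seed = 1L) {
  structure(
    list(task = task, approach = approach, n_subjects = as.integer(n_subjects),
         snr_values = snr_values, variants = variants, seeds = seeds,
         config_ids = config_ids, budget = budget,
         max_ensemble_size = as.integer(max_ensemble_size),
         n_replications = as.integer(n_replications),
         test_fraction = test_fraction, stratify_by = stratify_by,
         integration = integration, imputation = imputation,
         inner_folds = as.integer(inner_folds),
         n_opt_iters = as.integer(n_opt_iters),
         snr_window = snr_window, master_seed = as.integer(master_seed)),
    class = "run_config"
  )
}

write_jsonl <- function(records, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                             digits = NA)), con)
  }
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Simulate the configured grid, benchmark the configured approach on every
#' grid dataset, rank configurations inside the SNR window, and write the
#' run directory: `grid_index.json` (if requested), `results.csv` (one row
#' per configuration per grid cell), `ranking.json`, `summary.json`, and a
#' `log.jsonl` with one structured record per stage including
#' fitted-parameter digests for the leakage audit.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created).
#' @param write_grid also write every simulated dataset as manifest + CSVs.
#' @return the parsed summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, write_grid = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  stamp <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }

  outcome_link <- if (config$task == "classification") "cluster_label"
                  else "linear_response"
  layout <- demo_layout(config$master_seed)
  base <- latent_cohort_spec(
    variant = config$variants[1L], n_subjects = config$n_subjects,
    snr_db = 0, layout = layout, outcome_link = outcome_link,
    seed = derive_seed(config$master_seed, "base"))
  grid <- grid_spec(base, snr_values = config$snr_values,
                    variants = config$variants, seeds = config$seeds)
  loadings <- random_loadings(layout, derive_seed(config$master_seed,
                                                  "loadings"))
  datasets <- build_grid(grid, loadings = loadings)
  stamp("simulate", n_datasets = length(datasets))
  if (write_grid) {
    simulate_grid_to_dir(grid, file.path(out_dir, "grid"),
                         loadings = loadings)
  }

  cvspec <- outer_cv_spec(test_fraction = config$test_fraction,
                          n_replications = config$n_replications,
                          stratify_by = config$stratify_by,
                          seed = derive_seed(config$master_seed, "cv"))
  if (config$approach == "single") {
    reg <- registry(config$task)
    configs <- reg[config$config_ids]
  } else {
    configs <- list(auto_ensemble = ensemble_search_spec(
      budget = config$budget,
      max_ensemble_size = config$max_ensemble_size,
      seed = derive_seed(config$master_seed, "ensemble")))
  }
  results <- benchmark_grid(
    datasets, configs, task = config$task, cv = cvspec,
    integration = config$integration, imputation = config$imputation,
    inner_folds = config$inner_folds, n_opt_iters = config$n_opt_iters)
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  stamp("benchmark", n_rows = nrow(results),
        digest = param_digest(results$score))

  better <- if (config$task == "classification") "higher" else "lower"
  ranking <- rank_algorithms(results, snr_window = config$snr_window,
                             better = better)
  jsonlite::write_json(
    list(table = ranking$table, best = ranking$best,
         median = ranking$median, poorest = ranking$poorest,
         snr_window = ranking$snr_window),
    file.path(out_dir, "ranking.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stamp("select", best = ranking$best, median = ranking$median,
        poorest = ranking$poorest)

  summary <- list(
    config = unclass(config),
    n_datasets = length(datasets),
    mean_score = mean(results$score),
    ranking = list(best = ranking$best, median = ranking$median,
                   poorest = ranking$poorest),
    results_digest = param_digest(results$score)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_jsonl(log, file.path(out_dir, "log.jsonl"))
  invisible(summary)
}

#' Compact demonstration layout
#'
#' Three modalities split into five submodalities with a handful of features
#' each — the shape used by the worked examples and the scaled-down
#' benchmark experiments.
#'
#' @param seed unused placeholder kept for interface symmetry.
#' @param features_per_submodality features per submodality (default 4).
#' @return a [dataset_layout()].
#' @export
demo_layout <- function(seed = 1L, features_per_submodality = 4L) {
  k <- features_per_submodality
  feat <- function(stub) paste0(stub, "_", seq_len(k))
  dataset_layout(
    list(
      cognition = list(memory = feat("mem"), attention = feat("att")),
      imaging = list(cortical = feat("ctx"), subcortical = feat("sub")),
      clinical = list(symptoms = feat("sym"))
    ),
    n_subjects = 100L
  )
}
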