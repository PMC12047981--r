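#' Configuration for a full benchmark run
#'
#' Bundles the simulation settings with every analysis knob of the pipeline.
#' Each stage has its own seed (derived from `seed` by small fixed offsets)
#' so stages can be re-run independently; all seeds and parameters are
#' recorded in the run manifest.
#'
#' @param seed Base integer seed. Stage seeds: cohort = seed,
#'   split = seed + 1, submissions = seed + 2, embedding = seed + 3,
#'   permutations = seed + 4 (+ a per-score offset).
#' @param simulation A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param recipes Planted recipe table, or `NULL` to plant one from the
#'   cohort seed with [plant_recipes()].
#' @param scores Scores to map; `NULL` (default) maps all 13.
#' @param grid_size,n_neighbors,min_dist,metric Embedding parameters, see
#'   [embed_morphospace()].
#' @param sigma Presence-map kernel width in cells, see
#'   [build_signal_maps()].
#' @param n_perm,alpha Permutation test parameters, see
#'   [permutation_tmap()].
#' @param threshold Feature-field binarization threshold, see
#'   [inverse_feature_maps()].
#' @param k_inverse Inverse-transform neighbors.
#' @param split_tolerance,split_attempts Pseudorandomization control, see
#'   [split_cohort()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 42L,
                       simulation = sim_config(seed = seed),
                       recipes = NULL,
                       scores = NULL,
                       grid_size = 60L, n_neighbors = 15L, min_dist = 0.1,
                       metric = "hamming", sigma = 2,
                       n_perm = 5000L, alpha = 0.05,
                       threshold = 0.5, k_inverse = 5L,
                       split_tolerance = 0.1, split_attempts = 1000L) {
  stopifnot(grid_size >= 2L, sigma >= 0, n_perm >= 1L,
            alpha > 0, alpha <= 1, threshold >= 0, threshold <= 1)
  structure(
    list(seed = as.integer(seed), simulation = simulation,
         recipes = recipes, scores = scores,
         grid_size = as.integer(grid_size),
         n_neighbors = as.integer(n_neighbors), min_dist = min_dist,
         metric = metric, sigma = sigma,
         n_perm = as.integer(n_perm), alpha = alpha,
         threshold = threshold, k_inverse = as.integer(k_inverse),
         split_tolerance = split_tolerance,
         split_attempts = as.integer(split_attempts),
         seeds = list(cohort = as.integer(seed),
                      split = as.integer(seed) + 1L,
                      submissions = as.integer(seed) + 2L,
                      embedding = as.integer(seed) + 3L,
                      permutation = as.integer(seed) + 4L)),
    class = "run_config"
  )
}

#' Run the full benchmark pipeline in memory
#'
#' Simulate (or reuse) a cohort and submissions, evaluate and rank them,
#' embed the feature combinations into the discretized morphospace, compute
#' a permutation t-map per score, invert the space into binarized feature
#' fields, read recipes at every significant local maximum, and aggregate a
#' per-domain recipe table. Deterministic given the config's seeds.
#'
#' @param config A [run_config()].
#' @param cohort,submissions Optional pre-built cohort (with roles) and
#'   `submission_set`; when supplied the simulation stages are skipped and
#'   predictions are evaluated as given.
#' @return A list with elements `catalog`, `recipes_planted`, `cohort`,
#'   `submissions`, `evaluation`, `ranking`, `space`, `statmaps` (named
#'   list), `fields`, `recipes`, `domain_recipes`, `config`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL,
                         submissions = NULL) {
  stopifnot(inherits(config, "run_config"))
  catalog <- score_catalog()
  sim <- config$simulation
  recipes_planted <- config$recipes
  if (is.null(recipes_planted)) {
    recipes_planted <- plant_recipes(config$seeds$cohort)
  }
  if (is.null(cohort)) {
    cohort <- generate_cohort(sim, catalog)
    cohort <- split_cohort(cohort, sim$n_train, sim$n_val,
                           seed = config$seeds$split,
                           tolerance = config$split_tolerance,
                           max_attempts = config$split_attempts,
                           catalog = catalog)
  }
  if (is.null(submissions)) {
    submissions <- generate_submissions(cohort, recipes_planted, sim,
                                        catalog,
                                        seed = config$seeds$submissions)
  }
  evaluation <- evaluate_submissions(submissions, cohort, catalog)
  ranking <- rank_submissions(evaluation, catalog)

  space <- embed_morphospace(submissions, grid_size = config$grid_size,
                             n_neighbors = config$n_neighbors,
                             min_dist = config$min_dist,
                             metric = config$metric,
                             seed = config$seeds$embedding,
                             k_inverse = config$k_inverse)
  presence <- build_signal_maps(space$coords, config$grid_size,
                                config$sigma)
  fields <- inverse_feature_maps(space, config$threshold)

  score_set <- config$scores
  if (is.null(score_set)) score_set <- catalog$score
  sub_order <- rownames(space$features)
  statmaps <- list()
  all_recipes <- list()
  for (si in seq_along(score_set)) {
    sc <- score_set[si]
    ev <- evaluation[evaluation$score == sc, ]
    r2 <- ev$r2[match(sub_order, ev$submission_id)]
    if (anyNA(r2)) {
      stop("Missing R2 for score ", sc, " in some submissions",
           call. = FALSE)
    }
    sm <- permutation_tmap(presence, r2, n_perm = config$n_perm,
                           alpha = config$alpha,
                           seed = config$seeds$permutation + si,
                           score_name = sc)
    statmaps[[sc]] <- sm
    all_recipes[[sc]] <- recipes_for_score(sm, fields)
  }
  recipes <- dplyr::bind_rows(all_recipes)
  domain_recipes <- aggregate_domain_recipes(recipes, catalog)

  list(catalog = catalog, recipes_planted = recipes_planted,
       cohort = cohort, submissions = submissions,
       evaluation = evaluation, ranking = ranking,
       space = space, statmaps = statmaps, fields = fields,
       recipes = recipes, domain_recipes = domain_recipes,
       config = config)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Run the pipeline and write a reproducible artifact directory
#'
#' Executes [run_pipeline()] and writes six artifact families: evaluation
#' tables (`evaluation.csv`, `ranking.csv`), simulated data (`cohort.csv`,
#' `submission_features.csv`, `submission_predictions.csv`), the morphospace
#' (`morphospace/coords.csv`, `morphospace/meta.json`), per-score stat maps
#' (`statmaps/<score>.csv`, `statmaps/summary.csv`), feature fields
#' (`fields/continuous.csv`, `fields/binary.csv`), and recipes
#' (`recipes.csv`, `domain_recipes.csv`, `recipes.json`), plus a
#' `manifest.json` recording every seed and parameter. Re-running with the
#' same config reproduces the numeric outputs byte-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [run_pipeline()].
#' @return Invisibly, the [run_pipeline()] result with `$paths` appended.
#' @export
run_full <- function(config = run_config(), out_dir, ...) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  res <- run_pipeline(config, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("morphospace", "statmaps", "fields")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  p <- function(...) file.path(out_dir, ...)

  readr::write_csv(res$cohort, p("cohort.csv"))
  readr::write_csv(res$submissions$features, p("submission_features.csv"))
  readr::write_csv(res$submissions$predictions,
                   p("submission_predictions.csv"))
  readr::write_csv(res$evaluation, p("evaluation.csv"))
  readr::write_csv(res$ranking, p("ranking.csv"))
  readr::write_csv(tidy(res$space), p("morphospace", "coords.csv"))
  write_json_file(
    list(grid_size = res$space$grid_size,
         bounds = as.data.frame(res$space$bounds),
         seed = res$space$seed, metric = res$space$metric,
         n_neighbors = res$space$n_neighbors,
         min_dist = res$space$min_dist,
         k_inverse = res$space$k_inverse),
    p("morphospace", "meta.json")
  )
  for (sc in names(res$statmaps)) {
    readr::write_csv(tidy(res$statmaps[[sc]]), p("statmaps",
                                                 paste0(sc, ".csv")))
  }
  readr::write_csv(dplyr::bind_rows(lapply(res$statmaps, glance)),
                   p("statmaps", "summary.csv"))
  g <- res$fields$grid_size
  cells <- grid_cells_xy(g)
  cont <- matrix(res$fields$continuous, g * g, n_features())
  bin <- matrix(res$fields$binary, g * g, n_features())
  colnames(cont) <- colnames(bin) <- res$fields$features
  base_tbl <- tibble::tibble(gx = cells$gx, gy = cells$gy)
  readr::write_csv(dplyr::bind_cols(base_tbl, tibble::as_tibble(cont)),
                   p("fields", "continuous.csv"))
  readr::write_csv(dplyr::bind_cols(base_tbl, tibble::as_tibble(bin)),
                   p("fields", "binary.csv"))
  readr::write_csv(res$recipes, p("recipes.csv"))
  readr::write_csv(res$domain_recipes, p("domain_recipes.csv"))
  write_json_file(
    list(recipes = res$recipes,
         domain_recipes = res$domain_recipes,
         absent_domains = attr(res$domain_recipes, "absent_domains"),
         sources = attr(res$domain_recipes, "sources")),
    p("recipes.json")
  )
  cfg <- res$config
  write_json_file(
    list(package = "morphobench",
         version = as.character(utils::packageVersion("morphobench")),
         seed = cfg$seed, seeds = cfg$seeds,
         simulation = unclass(cfg$simulation)[
           setdiff(names(cfg$simulation), "score_params")],
         score_params = cfg$simulation$score_params,
         grid_size = cfg$grid_size, n_neighbors = cfg$n_neighbors,
         min_dist = cfg$min_dist, metric = cfg$metric, sigma = cfg$sigma,
         n_perm = cfg$n_perm, alpha = cfg$alpha,
         threshold = cfg$threshold, k_inverse = cfg$k_inverse,
         split_tolerance = cfg$split_tolerance,
         split_attempts = cfg$split_attempts,
         scores = names(res$statmaps)),
    p("manifest.json")
  )
  res$paths <- list(
    root = out_dir,
    evaluation = p("evaluation.csv"), ranking = p("ranking.csv"),
    domain_recipes = p("domain_recipes.csv"),
    manifest = p("manifest.json")
  )
  invisible(res)
}

#' Read a cohort table written by [run_full()]
#'
#' @param path Path to a cohort CSV.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read a submission set from its two CSV tables
#'
#' @param features_path CSV with `submission_id`, `team_id` and the 17
#'   canonical feature columns.
#' @param predictions_path Long CSV with `submission_id`, `patient_id`,
#'   `score`, `predicted`.
#' @return A `submission_set`.
#' @export
read_submissions <- function(features_path, predictions_path) {
  features <- readr::read_csv(features_path, show_col_types = FALSE)
  build_feature_matrix(features)  # validates columns
  predictions <- readr::read_csv(predictions_path, show_col_types = FALSE)
  stopifnot(all(c("submission_id", "patient_id", "score", "predicted")
                %in% names(predictions)))
  structure(list(features = features, predictions = predictions),
            class = "submission_set")
}

#' Export a grid as a NIfTI volume
#'
#' Embeds a morphospace grid (a matrix, or the t-map of a `statmap`) into a
#' grid_size x grid_size x 1 NIfTI-1 volume with identity orientation, so
#' maps can be inspected in neuroimaging viewers. Requires the RNifti
#' package.
#'
#' @param x A grid matrix or a `statmap`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
export_grid_nifti <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("export_grid_nifti() requires the RNifti package", call. = FALSE)
  }
  grid <- if (inherits(x, "statmap")) x$t else as.matrix(x)
  vol <- array(grid, dim = c(dim(grid), 1L))
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
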