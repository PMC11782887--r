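#' Run configuration for the end-to-end pipeline
#'
#' Defaults follow the analysis conventions used throughout the package:
#' restart probability 0.15, modified-Z cutoff 5, missingness thresholds
#' 150 (donors) / 740 (proteins), 7:3 split with 10-fold CV repeated 5
#' times, cell-line clusters of at least 3 lines with mean correlation
#' over 0.4, and 100 random communicator sets.
#'
#' @param network,pathways,itc_catalog,disease_genes Input paths (edge TSV,
#'   GMT, catalog TSV, GMT).
#' @param out Output directory.
#' @param restart_prob,modz_cutoff,rng_seed Core analysis settings.
#' @param threshold Optional precomputed significance threshold; when
#'   `NULL` it is calibrated from `pathways`.
#' @param n_random_draws Random draws per pathway set during calibration.
#' @param direction_policy,dangling_policy Network assembly policies.
#' @param max_missing_per_donor,max_missing_per_protein,split_ratio,folds,repeats
#'   Diagnostic-validation settings.
#' @param min_cluster,min_avg_corr,n_random_sets Perturbation-validation
#'   settings.
#' @return A list of class `run_config`.
#' @export
run_config <- function(network = NULL, pathways = NULL, itc_catalog = NULL,
                       disease_genes = NULL, out = "itcrank_run",
                       restart_prob = 0.15, modz_cutoff = 5, rng_seed = 1,
                       threshold = NULL, n_random_draws = 1,
                       direction_policy = "undirected_all",
                       dangling_policy = "uniform_jump",
                       max_missing_per_donor = 150,
                       max_missing_per_protein = 740,
                       split_ratio = 0.7, folds = 10, repeats = 5,
                       min_cluster = 3, min_avg_corr = 0.4,
                       n_random_sets = 100) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

run_log <- function(dir, lines) {
  msg <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), lines)
  cat(paste0(msg, "\n"), file = file.path(dir, "run.log"), append = TRUE)
  invisible(msg)
}

#' Run the core pipeline: build, calibrate, score, select
#'
#' Chains network assembly, significance calibration, communicator scoring
#' and disease-specific selection, writing `score_matrix.tsv`,
#' `specific_itcs.tsv`, `calibration.json` and a manifest into the output
#' directory. Reruns with the same config and seed are bit-identical.
#'
#' @param config A [run_config()] with `network`, `pathways`,
#'   `itc_catalog`, `disease_genes` and `out` set.
#' @return Invisibly, a list with the `itc_score_matrix`, the
#'   `specific_itc_result`, the `calibration_result` and the resolved
#'   config.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c("network", "pathways", "itc_catalog", "disease_genes")) {
    if (is.null(config[[p]]) || !file.exists(config[[p]])) {
      abort(sprintf("input path `%s` is missing or does not exist: %s", p,
                    config[[p]] %||% "<null>"))
    }
  }
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  run_log(config$out, "pipeline start")

  edges <- load_edge_table(config$network)
  network <- assemble_network(edges, config$direction_policy)
  W <- column_normalize(network, config$dangling_policy)
  run_log(config$out, sprintf("network: %d nodes", nrow(network$nodes)))

  cfg_rwr <- rwr_config(restart_prob = config$restart_prob)
  calib <- NULL
  threshold <- config$threshold
  if (is.null(threshold)) {
    calib <- calibrate_threshold(W, read_gmt(config$pathways),
                                 n_random_draws = config$n_random_draws,
                                 rng_seed = config$rng_seed, config = cfg_rwr)
    export_calibration(calib, config$out)
    threshold <- calib$threshold
    run_log(config$out, sprintf("calibrated threshold: %.6g", threshold))
  }

  scores <- score_all(W, read_itc_catalog(config$itc_catalog),
                      read_gmt(config$disease_genes), threshold,
                      rng_seed = config$rng_seed, config = cfg_rwr)
  specific <- select_specific(scores, config$modz_cutoff)
  export_scores(scores, specific, config$out)
  run_log(config$out, sprintf("selected %d (disease, communicator) pair(s)",
                              nrow(specific)))

  manifest <- c(list(stage = "all"),
                config[setdiff(names(config), c("threshold"))],
                list(threshold_used = threshold))
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  jsonlite::write_json(manifest, file.path(config$out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scores = scores, specific = specific, calibration = calib,
                 config = config))
}

#' Dispatch one pipeline subcommand
#'
#' Thin programmatic entry point behind the command-line script. Supported
#' names: `simulate` (write a complete synthetic fixture directory),
#' `build-network`, `calibrate`, `score`, `select`, and `all` (the chained
#' core pipeline). The two validation harnesses are exposed through their
#' functions ([run_diagnosis()], [fold_vs_random()]) and the fixture
#' generators.
#'
#' @param name Subcommand name.
#' @param config A [run_config()].
#' @return Invisibly, the subcommand's primary result.
#' @export
run_subcommand <- function(name, config) {
  name <- match.arg(name, c("simulate", "build-network", "calibrate",
                            "score", "select", "all"))
  stopifnot(inherits(config, "run_config"))
  if (name == "simulate") {
    fx <- make_network_fixture(rng_seed = config$rng_seed)
    write_fixture_dir(fx, config$out)
    return(invisible(fx))
  }
  if (name == "build-network") {
    edges <- load_edge_table(config$network)
    network <- assemble_network(edges, config$direction_policy)
    export_network(network, config$out)
    return(invisible(network))
  }
  if (name == "calibrate") {
    edges <- load_edge_table(config$network)
    W <- column_normalize(assemble_network(edges, config$direction_policy),
                          config$dangling_policy)
    calib <- calibrate_threshold(W, read_gmt(config$pathways),
                                 n_random_draws = config$n_random_draws,
                                 rng_seed = config$rng_seed,
                                 config = rwr_config(restart_prob = config$restart_prob))
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    export_calibration(calib, config$out)
    return(invisible(calib))
  }
  if (name %in% c("score", "select", "all")) {
    res <- run_pipeline(config)
    return(invisible(res))
  }
}
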