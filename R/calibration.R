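#' Pairwise walk probabilities within a gene set
#'
#' For every ordered pair `(s, t)` of distinct set members present in the
#' network, records the walk probability at `t` when seeding at `s`. These
#' within-set values quantify how tightly a functional gene set hangs
#' together under network propagation.
#'
#' @param W A `transition_matrix`.
#' @param members Character vector of member ids (intersected with the
#'   network; members absent from it are ignored).
#' @param config An [rwr_config()].
#' @param profiles Optional precomputed named list of `rwr_profile`s to
#'   reuse (one per member); computed if missing.
#' @return Numeric vector of length `m * (m - 1)` for `m` mapped members;
#'   `numeric(0)` (with a log entry) when fewer than 2 members map.
#' @export
within_set_rwr_values <- function(W, members, config = rwr_config(),
                                  profiles = NULL) {
  ids <- colnames(as_walk_matrix(W))
  mapped <- intersect(unique(members), ids)
  if (length(mapped) < 2) {
    itc_log("gene set skipped: fewer than 2 members map to the network")
    return(numeric(0))
  }
  if (is.null(profiles)) profiles <- batch_rwr(W, mapped, config)
  vals <- lapply(mapped, function(s) {
    unname(profiles[[s]]$p[setdiff(mapped, s)])
  })
  unlist(vals, use.names = FALSE)
}

#' Calibrate the minimum walk probability with biological significance
#'
#' For each pathway set, records the median of its within-set pairwise walk
#' values; for each pathway set and each random draw, draws a size-matched
#' uniform random node set (without replacement) and records its median.
#' The calibrated threshold is the exact maximum over all random-set
#' medians: walk probabilities below it are indistinguishable from what
#' random gene sets achieve by topology alone.
#'
#' @param W A `transition_matrix`.
#' @param pathway_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param n_random_draws Number of size-matched random sets per pathway set.
#' @param rng_seed Integer seed controlling the random draws.
#' @param config An [rwr_config()].
#' @return An object of class `calibration_result`: list with
#'   `pathway_medians` (tibble: set, n_members, median), `random_medians`
#'   (tibble: draw, set, n_members, median), `threshold`, `rng_seed`,
#'   `config`.
#' @export
calibrate_threshold <- function(W, pathway_sets, n_random_draws = 1,
                                rng_seed = 1, config = rwr_config()) {
  stopifnot(is.list(pathway_sets), length(pathway_sets) >= 1,
            n_random_draws >= 1)
  ids <- colnames(as_walk_matrix(W))
  mapped_sets <- lapply(pathway_sets, function(m) intersect(unique(m), ids))
  usable <- vapply(mapped_sets, length, integer(1)) >= 2
  if (!any(usable)) abort("no pathway set has at least 2 members in the network")
  if (any(!usable)) {
    itc_log("skipped %d pathway set(s) with fewer than 2 mapped members", sum(!usable))
  }
  mapped_sets <- mapped_sets[usable]
  sizes <- vapply(mapped_sets, length, integer(1))
  if (max(sizes) > length(ids)) abort("network is smaller than the largest pathway set")

  random_sets <- withr::with_seed(rng_seed, {
    lapply(seq_len(n_random_draws), function(d) {
      lapply(sizes, function(sz) sample(ids, sz, replace = FALSE))
    })
  })

  all_seeds <- unique(c(unlist(mapped_sets, use.names = FALSE),
                        unlist(random_sets, use.names = FALSE)))
  profiles <- batch_rwr(W, all_seeds, config)

  set_median <- function(members) {
    median(within_set_rwr_values(W, members, config, profiles = profiles))
  }
  pathway_medians <- tibble::tibble(
    set = names(mapped_sets),
    n_members = unname(sizes),
    median = unname(vapply(mapped_sets, set_median, numeric(1)))
  )
  random_medians <- dplyr::bind_rows(lapply(seq_len(n_random_draws), function(d) {
    tibble::tibble(
      draw = d,
      set = names(mapped_sets),
      n_members = unname(sizes),
      median = unname(vapply(random_sets[[d]], set_median, numeric(1)))
    )
  }))

  structure(
    list(pathway_medians = pathway_medians,
         random_medians = random_medians,
         threshold = max(random_medians$median),
         rng_seed = rng_seed,
         config = config),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d pathway set(s), %d random median(s); threshold = %.6g\n",
              nrow(x$pathway_medians), nrow(x$random_medians), x$threshold))
  invisible(x)
}

#' Tidy a calibration result into one row per set median
#'
#' @param x A `calibration_result`.
#' @param ... Unused.
#' @return Tibble with columns `group` (`pathway`/`random`), `set`,
#'   `n_members`, `median`.
#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pathway_medians, group = "pathway", .before = 1),
    dplyr::mutate(dplyr::select(x$random_medians, -"draw"), group = "random",
                  .before = 1)
  )
}

#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    n_pathway_sets = nrow(x$pathway_medians),
    n_random_medians = nrow(x$random_medians),
    median_pathway_median = median(x$pathway_medians$median),
    rng_seed = x$rng_seed
  )
}

#' Box plot of pathway versus random within-set medians
#'
#' @param object A `calibration_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calibration_result
#' @export
autoplot.calibration_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$median)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "within-set median walk probability",
                  title = "Significance calibration",
                  subtitle = sprintf("threshold = max(random medians) = %.3g",
                                     object$threshold)) +
    ggplot2::theme_minimal()
}

#' Write a calibration result (JSON summary + TSV of medians)
#'
#' @param result A `calibration_result`.
#' @param dir Output directory.
#' @return Invisibly, the JSON summary list.
#' @export
export_calibration <- function(result, dir) {
  stopifnot(inherits(result, "calibration_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tidy(result), file.path(dir, "calibration_medians.tsv"))
  summary <- list(
    threshold = result$threshold,
    rng_seed = result$rng_seed,
    restart_prob = result$config$restart_prob,
    pathway_medians = as.list(setNames(result$pathway_medians$median,
                                       result$pathway_medians$set))
  )
  jsonlite::write_json(summary, file.path(dir, "calibration.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
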