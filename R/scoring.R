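#' Thresholded influence of one seed on a disease gene set
#'
#' Walk probabilities at disease genes below the significance threshold are
#' treated as zero (no influence); the rest are summed.
#'
#' @param profile An `rwr_profile`.
#' @param disease_genes Character vector of disease gene ids.
#' @param threshold Nonnegative significance threshold; probabilities must
#'   strictly exceed it to count.
#' @return A tibble row with `seed`, `raw_sum`, `n_dg_hit`, `n_dg_in_network`.
#' @export
thresholded_influence <- function(profile, disease_genes, threshold) {
  stopifnot(inherits(profile, "rwr_profile"))
  assert_scalar_number(threshold, "threshold", lower = 0)
  dg <- intersect(unique(disease_genes), names(profile$p))
  if (length(dg) == 0) {
    warn("no disease genes map to the network; raw influence is 0")
    return(tibble::tibble(seed = profile$seed_id, raw_sum = 0,
                          n_dg_hit = 0L, n_dg_in_network = 0L))
  }
  v <- profile$p[dg]
  hit <- v > threshold
  tibble::tibble(seed = profile$seed_id, raw_sum = sum(v[hit]),
                 n_dg_hit = sum(hit), n_dg_in_network = length(dg))
}

# vectorized raw influence for a matrix of profiles (nodes x seeds)
.raw_sums <- function(P, dg, threshold) {
  V <- P[dg, , drop = FALSE]
  V[V <= threshold] <- 0
  list(raw = colSums(V), hits = colSums(V > 0))
}

#' Random-gene baseline influence on a disease gene set
#'
#' Draws `n_random` network nodes uniformly without replacement, computes
#' each one's thresholded influence on the disease genes as a walk seed, and
#' returns the arithmetic mean. This baseline corrects for hubness: highly
#' connected disease genes receive large walk probabilities from any seed.
#'
#' @param W A `transition_matrix`.
#' @param disease_genes Character vector of disease gene ids.
#' @param n_random Number of random seeds (the analysis default is the
#'   communicator catalog size).
#' @param threshold Significance threshold passed to the influence sum.
#' @param rng_seed Integer seed for the draw.
#' @param config An [rwr_config()].
#' @param exclude Optional node ids excluded from the draw pool.
#' @return List with `mean` (the baseline), `sums` (per random seed),
#'   `genes` (the drawn seeds).
#' @export
random_gene_baseline <- function(W, disease_genes, n_random, threshold,
                                 rng_seed = 1, config = rwr_config(),
                                 exclude = NULL) {
  ids <- colnames(as_walk_matrix(W))
  pool <- setdiff(ids, exclude)
  if (n_random < 1) abort("`n_random` must be at least 1")
  if (n_random > length(pool)) {
    abort(sprintf("cannot draw %d random genes from a pool of %d", n_random,
                  length(pool)))
  }
  genes <- withr::with_seed(rng_seed, sample(pool, n_random, replace = FALSE))
  profiles <- batch_rwr(W, genes, config)
  sums <- vapply(profiles, function(pr) {
    thresholded_influence(pr, disease_genes, threshold)$raw_sum
  }, numeric(1))
  list(mean = mean(sums), sums = unname(sums), genes = genes)
}

#' Score every communicator against every disease
#'
#' Runs a restart walk from every catalog entry, sums the thresholded walk
#' probabilities over each disease's genes, and divides by the mean of the
#' same quantity over size-matched random seeds (the hub-correction
#' baseline). Diseases with fewer than `min_disease_genes` genes in the
#' network are excluded with a log entry.
#'
#' @param W A `transition_matrix`.
#' @param itc_catalog Tibble with an `id` column (see [read_itc_catalog()]),
#'   or a character vector of ids.
#' @param disease_gene_sets Named list of character vectors.
#' @param threshold Significance threshold from [calibrate_threshold()].
#' @param rng_seed Integer seed; per-disease baseline draws are derived from
#'   it deterministically.
#' @param config An [rwr_config()].
#' @param n_random Random seeds per disease baseline; defaults to the number
#'   of mapped catalog entries.
#' @param n_baseline_repeats Number of baseline draws averaged per disease.
#' @param exclude_itcs_from_baseline If `TRUE`, catalog entries are removed
#'   from the random-draw pool.
#' @param min_disease_genes Disease admission rule: minimum mapped genes.
#' @return An object of class `itc_score_matrix`: list with `scores`
#'   (communicators x diseases, normalized), `raw`, `hits`, `baselines`
#'   (tibble), `threshold`, `rng_seed`, `config`, `dropped_diseases`,
#'   `unmapped_itcs`.
#' @export
score_all <- function(W, itc_catalog, disease_gene_sets, threshold,
                      rng_seed = 1, config = rwr_config(), n_random = NULL,
                      n_baseline_repeats = 1,
                      exclude_itcs_from_baseline = FALSE,
                      min_disease_genes = 10) {
  Wm <- as_walk_matrix(W)
  ids <- colnames(Wm)
  itc_ids <- if (is.data.frame(itc_catalog)) itc_catalog$id else itc_catalog
  if (length(itc_ids) == 0) abort("the communicator catalog is empty")
  if (anyDuplicated(itc_ids)) abort("communicator catalog ids must be unique")
  mapped_itcs <- intersect(itc_ids, ids)
  unmapped <- setdiff(itc_ids, ids)
  if (length(unmapped) > 0) {
    itc_log("%d catalog entr(ies) not in the network were dropped", length(unmapped))
  }
  if (length(mapped_itcs) == 0) abort("no communicator catalog entry maps to the network")

  stopifnot(is.list(disease_gene_sets), !is.null(names(disease_gene_sets)))
  mapped_dgs <- lapply(disease_gene_sets, function(g) intersect(unique(g), ids))
  eligible <- vapply(mapped_dgs, length, integer(1)) >= min_disease_genes
  dropped <- names(mapped_dgs)[!eligible]
  if (length(dropped) > 0) {
    itc_log("excluded %d disease(s) with fewer than %d mapped genes",
            length(dropped), min_disease_genes)
  }
  mapped_dgs <- mapped_dgs[eligible]
  if (length(mapped_dgs) == 0) {
    abort(sprintf("no disease has at least %d genes in the network", min_disease_genes))
  }
  if (is.null(n_random)) n_random <- length(mapped_itcs)

  profiles <- batch_rwr(W, mapped_itcs, config)
  P <- vapply(profiles, function(pr) pr$p, numeric(length(ids)))
  rownames(P) <- ids

  diseases <- names(mapped_dgs)
  raw <- matrix(0, length(mapped_itcs), length(diseases),
                dimnames = list(mapped_itcs, diseases))
  hits <- raw
  normalized <- raw
  baselines <- vector("list", length(diseases))
  unusable <- character(0)

  for (d in seq_along(diseases)) {
    dg <- mapped_dgs[[d]]
    rs <- .raw_sums(P, dg, threshold)
    raw[, d] <- rs$raw
    hits[, d] <- rs$hits
    draw_seeds <- rng_seed + 1000L * d + seq_len(n_baseline_repeats) - 1L
    draws <- lapply(draw_seeds, function(s) {
      random_gene_baseline(W, dg, n_random, threshold, rng_seed = s,
                           config = config,
                           exclude = if (exclude_itcs_from_baseline) mapped_itcs)
    })
    all_sums <- unlist(lapply(draws, `[[`, "sums"))
    base <- mean(all_sums)
    if (base == 0) {
      pos <- all_sums[all_sums > 0]
      if (length(pos) > 0) {
        base <- min(pos)
        itc_log("zero baseline for disease '%s'; using smallest positive random sum",
                diseases[d])
      } else {
        unusable <- c(unusable, diseases[d])
        base <- NA_real_
        itc_log("disease '%s' flagged unusable: all random baseline sums are zero",
                diseases[d])
      }
    }
    baselines[[d]] <- tibble::tibble(disease = diseases[d], baseline = base,
                                     n_random = n_random,
                                     n_repeats = n_baseline_repeats)
    normalized[, d] <- if (is.na(base)) NA_real_ else raw[, d] / base
  }

  keep <- !diseases %in% unusable
  structure(
    list(scores = normalized[, keep, drop = FALSE],
         raw = raw[, keep, drop = FALSE],
         hits = hits[, keep, drop = FALSE],
         baselines = dplyr::bind_rows(baselines),
         threshold = threshold, rng_seed = rng_seed, config = config,
         dropped_diseases = dropped, unusable_diseases = unusable,
         unmapped_itcs = unmapped),
    class = "itc_score_matrix"
  )
}

#' @export
print.itc_score_matrix <- function(x, ...) {
  cat(sprintf("<itc_score_matrix> %d communicators x %d diseases (threshold %.3g)\n",
              nrow(x$scores), ncol(x$scores), x$threshold))
  invisible(x)
}

#' Tidy normalized communicator scores into long form
#'
#' @param x An `itc_score_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `itc`, `disease`, `score`, `raw_sum`,
#'   `n_dg_hit`.
#' @method tidy itc_score_matrix
#' @export
tidy.itc_score_matrix <- function(x, ...) {
  M <- x$scores
  out <- tibble::tibble(itc = rep(rownames(M), times = ncol(M)),
                        disease = rep(colnames(M), each = nrow(M)),
                        score = as.numeric(M))
  out$raw_sum <- as.numeric(x$raw)
  out$n_dg_hit <- as.integer(x$hits)
  out
}

#' Heatmap of normalized communicator-by-disease scores
#'
#' @param object An `itc_score_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot itc_score_matrix
#' @export
autoplot.itc_score_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$disease, y = .data$itc,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "normalized\ninfluence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Modified Z-scores (median/MAD outlier scores)
#'
#' `modZ_i = 0.6745 * (x_i - median(x)) / MAD` with
#' `MAD = median(|x - median(x)|)`. When the MAD is zero (common for
#' zero-heavy score rows) the mean absolute deviation takes its place with
#' the constant 1.2533 in the denominator:
#' `modZ_i = 0.6745 * (x_i - median(x)) / (1.2533 * meanAD)`. If that is
#' also zero the vector is constant and all scores are 0.
#'
#' @param values Numeric vector of at least 3 values.
#' @return Numeric vector of modified Z-scores (names preserved).
#' @export
modified_z <- function(values) {
  if (!is.numeric(values) || length(values) < 3) {
    abort("modified_z() needs at least 3 numeric values")
  }
  med <- median(values)
  dev <- values - med
  mad0 <- median(abs(dev))
  if (mad0 > 0) return(0.6745 * dev / mad0)
  meanad <- mean(abs(dev))
  if (meanad > 0) return(0.6745 * dev / (1.2533 * meanad))
  setNames(rep(0, length(values)), names(values))
}

#' Select disease-specific communicators by cross-disease modified Z-score
#'
#' For each communicator, modified Z-scores are computed across its per-
#' disease normalized scores; a (communicator, disease) pair is kept iff its
#' modZ strictly exceeds the cutoff, marking the disease as an outlier
#' within that communicator's profile.
#'
#' @param scores An `itc_score_matrix` or a numeric matrix
#'   (communicators x diseases) with dimnames.
#' @param modz_cutoff Selection cutoff (default 5).
#' @return An object of class `specific_itc_result`: tibble with columns
#'   `disease`, `itc`, `modz`, sorted by disease then descending modZ;
#'   attribute `modz_cutoff`.
#' @export
select_specific <- function(scores, modz_cutoff = 5) {
  M <- if (inherits(scores, "itc_score_matrix")) scores$scores else scores
  if (!is.matrix(M)) abort("`scores` must be an itc_score_matrix or a matrix")
  if (ncol(M) < 3) {
    abort("at least 3 diseases are required to form a modified Z-score distribution")
  }
  rows <- lapply(seq_len(nrow(M)), function(i) {
    mz <- modified_z(M[i, ])
    keep <- which(mz > modz_cutoff)
    if (length(keep) == 0) return(NULL)
    tibble::tibble(disease = colnames(M)[keep], itc = rownames(M)[i],
                   modz = unname(mz[keep]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(disease = character(0), itc = character(0),
                          modz = numeric(0))
  }
  out <- dplyr::arrange(out, .data$disease, dplyr::desc(.data$modz))
  attr(out, "modz_cutoff") <- modz_cutoff
  class(out) <- c("specific_itc_result", class(out))
  out
}

#' @method glance specific_itc_result
#' @export
glance.specific_itc_result <- function(x, ...) {
  per_disease <- dplyr::count(tibble::as_tibble(x), .data$disease)
  per_itc <- dplyr::count(tibble::as_tibble(x), .data$itc)
  tibble::tibble(
    n_pairs = nrow(x),
    n_diseases = nrow(per_disease),
    n_itcs = nrow(per_itc),
    median_itcs_per_disease = if (nrow(per_disease)) median(per_disease$n) else NA_real_,
    median_diseases_per_itc = if (nrow(per_itc)) median(per_itc$n) else NA_real_,
    modz_cutoff = attr(x, "modz_cutoff")
  )
}

#' Export a score matrix and specific-communicator lists
#'
#' Writes the normalized score matrix as TSV (communicators as rows), the
#' selected pairs as `disease  itc  modz` TSV, and a run manifest JSON.
#'
#' @param scores An `itc_score_matrix`.
#' @param specific A `specific_itc_result`.
#' @param dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
export_scores <- function(scores, specific, dir) {
  stopifnot(inherits(scores, "itc_score_matrix"),
            inherits(specific, "specific_itc_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sm <- tibble::as_tibble(scores$scores, rownames = "itc")
  readr::write_tsv(sm, file.path(dir, "score_matrix.tsv"))
  readr::write_tsv(tibble::as_tibble(specific), file.path(dir, "specific_itcs.tsv"))
  manifest <- list(
    threshold = scores$threshold,
    rng_seed = scores$rng_seed,
    restart_prob = scores$config$restart_prob,
    modz_cutoff = attr(specific, "modz_cutoff"),
    n_itcs = nrow(scores$scores),
    n_diseases = ncol(scores$scores),
    dropped_diseases = scores$dropped_diseases,
    unusable_diseases = scores$unusable_diseases,
    unmapped_itcs = scores$unmapped_itcs
  )
  jsonlite::write_json(manifest, file.path(dir, "score_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
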