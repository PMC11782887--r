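#' Construct a perturbation signature matrix
#'
#' @param values Numeric matrix, genes as rows (rownames required),
#'   signatures as columns.
#' @param meta Tibble with one row per column: `signature_id`, `cell_line`,
#'   `perturbagen`, `ptype` (`"OX"` over-expression / `"KD"` knock-down),
#'   `time`, `exemplar` (logical), `tas` (transcriptional activity score).
#' @return An object of class `signature_matrix`.
#' @export
signature_matrix <- function(values, meta) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            is.data.frame(meta), nrow(meta) == ncol(values))
  need <- c("signature_id", "cell_line", "perturbagen", "ptype", "time",
            "exemplar", "tas")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(sprintf("signature metadata is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (is.null(colnames(values))) colnames(values) <- meta$signature_id
  stopifnot(identical(colnames(values), meta$signature_id))
  structure(list(values = values, meta = tibble::as_tibble(meta)),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d genes x %d signatures (%d cell lines)\n",
              nrow(x$values), ncol(x$values), length(unique(x$meta$cell_line))))
  invisible(x)
}

#' Read a signature matrix from a values TSV plus metadata sidecar TSV
#'
#' @param values_path TSV with a `gene` column then one column per
#'   signature id.
#' @param meta_path TSV with the metadata columns of [signature_matrix()].
#' @return A `signature_matrix`.
#' @export
read_signature_matrix <- function(values_path, meta_path) {
  vals <- readr::read_tsv(values_path, show_col_types = FALSE, progress = FALSE)
  stopifnot("gene" %in% names(vals))
  M <- as.matrix(vals[, setdiff(names(vals), "gene"), drop = FALSE])
  rownames(M) <- vals$gene
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  meta$exemplar <- as.logical(meta$exemplar)
  signature_matrix(M, meta[match(colnames(M), meta$signature_id), ])
}

#' Quality/condition filtering of perturbation signatures
#'
#' Applies, in order: keep exemplar-flagged signatures; among duplicates of
#' the same (perturbagen, cell line, perturbation type) keep the highest-
#' TAS column; keep only allowed perturbation types; keep only the required
#' perturbation time; drop excluded cell lines. Per-rule drop counts are
#' logged and attached.
#'
#' @param sig A `signature_matrix`.
#' @param require_exemplar Keep only exemplar signatures (default `TRUE`).
#' @param allowed_ptypes Perturbation types kept (default over-expression
#'   and knock-down).
#' @param required_time Perturbation time kept (default `"96 h"`); `NULL`
#'   keeps all.
#' @param excluded_cell_lines Cell lines dropped entirely.
#' @return The filtered `signature_matrix` with attribute `drop_counts`.
#' @export
filter_signatures <- function(sig, require_exemplar = TRUE,
                              allowed_ptypes = c("OX", "KD"),
                              required_time = "96 h",
                              excluded_cell_lines = character(0)) {
  stopifnot(inherits(sig, "signature_matrix"))
  meta <- sig$meta
  keep <- rep(TRUE, nrow(meta))
  drops <- list()

  if (require_exemplar) {
    bad <- keep & !meta$exemplar
    drops$not_exemplar <- sum(bad)
    keep[bad] <- FALSE
  }
  # max-TAS de-duplication within (perturbagen, cell_line, ptype)
  grp <- paste(meta$perturbagen, meta$cell_line, meta$ptype, sep = "\r")
  dup_drop <- rep(FALSE, nrow(meta))
  for (g in unique(grp[keep])) {
    members <- which(keep & grp == g)
    if (length(members) > 1) {
      best <- members[which.max(meta$tas[members])]
      dup_drop[setdiff(members, best)] <- TRUE
    }
  }
  drops$duplicate_lower_tas <- sum(dup_drop)
  keep[dup_drop] <- FALSE

  bad <- keep & !meta$ptype %in% allowed_ptypes
  drops$ptype <- sum(bad); keep[bad] <- FALSE
  if (!is.null(required_time)) {
    bad <- keep & meta$time != required_time
    drops$time <- sum(bad); keep[bad] <- FALSE
  }
  bad <- keep & meta$cell_line %in% excluded_cell_lines
  drops$excluded_cell_line <- sum(bad); keep[bad] <- FALSE

  if (!any(keep)) {
    abort(sprintf("no signature survives filtering (drops: %s)",
                  paste(sprintf("%s=%d", names(drops), unlist(drops)),
                        collapse = ", ")))
  }
  itc_log("signature filtering kept %d of %d columns", sum(keep), nrow(meta))
  out <- signature_matrix(sig$values[, keep, drop = FALSE], meta[keep, ])
  attr(out, "drop_counts") <- drops
  out
}

#' Map communicators to their downstream transcription factors
#'
#' A receptor maps to every transcription factor reachable from it by a
#' directed path in the pathway graph; a ligand inherits the union of its
#' paired receptors' TF sets.
#'
#' @param pathway_graph A directed igraph object or an edge data frame
#'   (columns `from`, `to`).
#' @param receptors Character vector of receptor ids.
#' @param ligand_receptor_pairs Optional tibble with columns `ligand`,
#'   `receptor`.
#' @param tfs Character vector of transcription-factor ids (nonempty).
#' @return An object of class `itc_tf_map`: list with `map` (named list id
#'   -> TF character vector) and `unmapped` (ids with no downstream TF or
#'   absent from the graph).
#' @export
map_itcs_to_tfs <- function(pathway_graph, receptors,
                            ligand_receptor_pairs = NULL, tfs) {
  if (is.data.frame(pathway_graph)) {
    pathway_graph <- igraph::graph_from_data_frame(pathway_graph, directed = TRUE)
  }
  stopifnot(igraph::is_directed(pathway_graph), length(tfs) > 0)
  vnames <- igraph::V(pathway_graph)$name
  map <- list()
  unmapped <- character(0)
  for (r in unique(receptors)) {
    if (!r %in% vnames) {
      itc_log("receptor '%s' absent from the pathway graph", r)
      unmapped <- c(unmapped, r)
      next
    }
    reach <- names(igraph::subcomponent(pathway_graph, r, mode = "out"))
    tf_set <- setdiff(intersect(reach, tfs), r)
    if (length(tf_set) == 0) unmapped <- c(unmapped, r)
    else map[[r]] <- sort(tf_set)
  }
  if (!is.null(ligand_receptor_pairs)) {
    stopifnot(all(c("ligand", "receptor") %in% names(ligand_receptor_pairs)))
    for (l in unique(ligand_receptor_pairs$ligand)) {
      recs <- ligand_receptor_pairs$receptor[ligand_receptor_pairs$ligand == l]
      tf_set <- sort(unique(unlist(map[intersect(recs, names(map))])))
      if (length(tf_set) == 0) unmapped <- c(unmapped, l)
      else map[[l]] <- tf_set
    }
  }
  structure(list(map = map, unmapped = unique(unmapped)), class = "itc_tf_map")
}

#' Inferred signature of one communicator in one cell line
#'
#' The communicator's perturbation signature is the elementwise sum of its
#' downstream TFs' signatures in the given cell line and perturbation type;
#' TFs without a signature there are skipped and counted.
#'
#' @param sig A filtered `signature_matrix`.
#' @param tf_set Character vector of TF perturbagen ids.
#' @param cell_line Cell-line id.
#' @param ptype `"OX"` or `"KD"`.
#' @return Named numeric vector over genes, or `NULL` (logged) when no TF
#'   of the set has a signature in that cell line/ptype.
#' @export
itc_signature <- function(sig, tf_set, cell_line, ptype) {
  stopifnot(inherits(sig, "signature_matrix"))
  sel <- sig$meta$perturbagen %in% tf_set &
    sig$meta$cell_line == cell_line & sig$meta$ptype == ptype
  if (!any(sel)) {
    itc_log("no %s signature in cell line %s for the given TF set", ptype, cell_line)
    return(NULL)
  }
  n_missing <- length(setdiff(tf_set, sig$meta$perturbagen[sel]))
  v <- rowSums(sig$values[, sel, drop = FALSE])
  attr(v, "n_tfs_missing") <- n_missing
  v
}

#' Select a correlated cell-line cluster at the disease genes
#'
#' Pearson correlations between cell lines are computed on signature values
#' restricted to disease-gene rows, pairing matched (perturbagen, ptype)
#' columns; cell lines are clustered by average-linkage hierarchical
#' clustering on `1 - correlation`, and the largest cluster of at least
#' `min_cluster` lines whose mean pairwise correlation exceeds
#' `min_avg_corr` is returned (ties broken by higher mean correlation). An
#' empty vector means the disease must be discarded.
#'
#' @param sig A filtered `signature_matrix`.
#' @param disease_genes Character vector of disease-gene ids (rows).
#' @param min_cluster Minimum cluster size (default 3).
#' @param min_avg_corr Minimum mean pairwise correlation (default 0.4).
#' @return Character vector of selected cell lines (possibly empty), with
#'   attribute `correlations` (the cell-line correlation matrix).
#' @export
select_cell_lines <- function(sig, disease_genes, min_cluster = 3,
                              min_avg_corr = 0.4) {
  stopifnot(inherits(sig, "signature_matrix"))
  lines <- sort(unique(sig$meta$cell_line))
  if (length(lines) < min_cluster) {
    itc_log("only %d cell line(s); no cluster possible", length(lines))
    return(character(0))
  }
  dg <- intersect(unique(disease_genes), rownames(sig$values))
  if (length(dg) < 2) abort("fewer than 2 disease genes have signature rows")

  key <- paste(sig$meta$perturbagen, sig$meta$ptype, sep = "\r")
  C <- matrix(NA_real_, length(lines), length(lines),
              dimnames = list(lines, lines))
  diag(C) <- 1
  for (a in seq_along(lines)) {
    for (b in seq_len(a - 1L)) {
      ca <- which(sig$meta$cell_line == lines[a])
      cb <- which(sig$meta$cell_line == lines[b])
      common <- intersect(key[ca], key[cb])
      if (length(common) == 0) { C[a, b] <- C[b, a] <- 0; next }
      ia <- ca[match(common, key[ca])]
      ib <- cb[match(common, key[cb])]
      va <- as.vector(sig$values[dg, ia, drop = FALSE])
      vb <- as.vector(sig$values[dg, ib, drop = FALSE])
      C[a, b] <- C[b, a] <- cor(va, vb)
    }
  }
  C[is.na(C)] <- 0

  hc <- hclust(as.dist(1 - C), method = "average")
  best <- character(0)
  best_size <- 0L
  best_corr <- -Inf
  for (k in seq_along(lines)) {
    grp <- cutree(hc, k = k)
    for (g in unique(grp)) {
      members <- lines[grp == g]
      if (length(members) < min_cluster) next
      sub <- C[members, members]
      avg <- mean(sub[lower.tri(sub)])
      if (avg <= min_avg_corr) next
      if (length(members) > best_size ||
          (length(members) == best_size && avg > best_corr)) {
        best <- members
        best_size <- length(members)
        best_corr <- avg
      }
    }
  }
  if (length(best) == 0) itc_log("no cell-line cluster meets the correlation criterion")
  attr(best, "correlations") <- C
  best
}

#' Overall inferred perturbation of a communicator set on disease genes
#'
#' Per communicator and selected cell line the downstream-TF signature sum
#' is computed; absolute values are averaged elementwise across cell lines;
#' the per-gene values at disease genes are summed across the communicator
#' set into a perturbation profile, whose mean over disease genes is
#' returned.
#'
#' @param sig A filtered `signature_matrix`.
#' @param itc_set Character vector of communicator ids.
#' @param tf_map An `itc_tf_map`.
#' @param cell_lines Selected cell lines (from [select_cell_lines()]).
#' @param disease_genes Character vector of disease-gene ids.
#' @param ptype `"OX"` or `"KD"`.
#' @return Scalar perturbation score (nonnegative), with attribute
#'   `n_usable_itcs`.
#' @export
disease_perturbation_score <- function(sig, itc_set, tf_map, cell_lines,
                                       disease_genes, ptype) {
  stopifnot(inherits(sig, "signature_matrix"), inherits(tf_map, "itc_tf_map"),
            length(cell_lines) > 0)
  dg <- intersect(unique(disease_genes), rownames(sig$values))
  if (length(dg) == 0) abort("no disease gene has a signature row")
  profile <- setNames(numeric(length(dg)), dg)
  usable <- 0L
  for (itc in itc_set) {
    tfs <- tf_map$map[[itc]]
    if (is.null(tfs)) next
    mats <- list()
    for (cl in cell_lines) {
      v <- suppressMessages(itc_signature(sig, tfs, cl, ptype))
      if (!is.null(v)) mats[[length(mats) + 1]] <- abs(v)
    }
    if (length(mats) == 0) next
    avg_abs <- Reduce(`+`, mats) / length(mats)
    profile <- profile + avg_abs[dg]
    usable <- usable + 1L
  }
  if (usable == 0) abort("no usable communicator in the set (no mapped TFs with signatures)")
  out <- mean(profile)
  attr(out, "n_usable_itcs") <- usable
  out
}

#' Fold increase of disease-communicator perturbation over random sets
#'
#' The disease set's perturbation score is divided by the score of each of
#' `n_sets` seeded, size-matched random communicator sets drawn from the
#' pool (excluding the disease set itself); the fold values are tested
#' against 1 by a one-sample t-test. Random sets scoring 0 are redrawn (up
#' to 10 times) and otherwise excluded with a log entry.
#'
#' @inheritParams disease_perturbation_score
#' @param disease_itcs The disease-specific communicator set.
#' @param itc_pool Pool of communicator ids to draw random sets from.
#' @param n_sets Number of random sets (default 100).
#' @param rng_seed Integer seed.
#' @param alternative t-test sidedness (default `"two.sided"`; use
#'   `"greater"` for a one-sided test of fold > 1).
#' @return An object of class `perturbation_result`: list with
#'   `disease_score`, `random_scores`, `fold_values`, `mean_fold`,
#'   `t_stat`, `p_value`, `cell_lines_used`, `ptype`, `n_excluded_sets`.
#' @export
fold_vs_random <- function(sig, disease_itcs, itc_pool, tf_map, cell_lines,
                           disease_genes, ptype, n_sets = 100, rng_seed = 1,
                           alternative = "two.sided") {
  ds <- disease_perturbation_score(sig, disease_itcs, tf_map, cell_lines,
                                   disease_genes, ptype)
  pool <- setdiff(unique(itc_pool), disease_itcs)
  k <- length(disease_itcs)
  if (length(pool) < k) abort("communicator pool too small for size-matched random sets")
  score_one <- function(set) {
    tryCatch(as.numeric(disease_perturbation_score(sig, set, tf_map, cell_lines,
                                                   disease_genes, ptype)),
             error = function(e) 0)
  }
  res <- withr::with_seed(rng_seed, {
    random_scores <- numeric(0)
    n_excluded <- 0L
    for (i in seq_len(n_sets)) {
      sc <- 0
      for (try in seq_len(10L)) {
        sc <- score_one(sample(pool, k, replace = FALSE))
        if (sc > 0) break
      }
      if (sc > 0) random_scores <- c(random_scores, sc)
      else {
        n_excluded <- n_excluded + 1L
        itc_log("random set %d excluded after 10 zero-score draws", i)
      }
    }
    list(random_scores = random_scores, n_excluded = n_excluded)
  })
  folds <- as.numeric(ds) / res$random_scores
  if (sd(folds) == 0) {
    # degenerate case: every random set scores exactly like the disease set
    tt <- list(statistic = c(t = if (folds[1] == 1) 0 else sign(folds[1] - 1) * Inf),
               p.value = if (folds[1] == 1) 1 else 0)
  } else {
    tt <- t.test(folds, mu = 1, alternative = alternative)
  }
  structure(
    list(disease_score = as.numeric(ds), random_scores = res$random_scores,
         fold_values = folds, mean_fold = mean(folds),
         t_stat = unname(tt$statistic), p_value = tt$p.value,
         cell_lines_used = cell_lines, ptype = ptype,
         n_excluded_sets = res$n_excluded, rng_seed = rng_seed),
    class = "perturbation_result"
  )
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("<perturbation_result> %s: mean fold %.3f over %d random sets (t = %.2f, p = %.3g)\n",
              x$ptype, x$mean_fold, length(x$random_scores), x$t_stat, x$p_value))
  invisible(x)
}

#' @method glance perturbation_result
#' @export
glance.perturbation_result <- function(x, ...) {
  tibble::tibble(ptype = x$ptype, disease_score = x$disease_score,
                 mean_fold = x$mean_fold, t_stat = x$t_stat,
                 p_value = x$p_value, n_random_sets = length(x$random_scores),
                 n_excluded_sets = x$n_excluded_sets,
                 n_cell_lines = length(x$cell_lines_used))
}

#' Histogram of fold-increase values against the null value 1
#'
#' @param object A `perturbation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perturbation_result
#' @export
autoplot.perturbation_result <- function(object, ...) {
  df <- tibble::tibble(fold = object$fold_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold)) +
    ggplot2::geom_histogram(bins = 25, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$mean_fold, colour = "red") +
    ggplot2::labs(x = "disease / random perturbation fold",
                  y = "random sets",
                  subtitle = sprintf("mean fold %.2f, p = %.3g (%s)",
                                     object$mean_fold, object$p_value,
                                     object$ptype)) +
    ggplot2::theme_minimal()
}
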