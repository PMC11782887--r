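# proteome tables are tibbles: a `donor_id` column plus one numeric column
# per protein; NA marks a missing measurement.

proteome_matrix <- function(table) {
  stopifnot(is.data.frame(table), "donor_id" %in% names(table))
  M <- as.matrix(table[, setdiff(names(table), "donor_id"), drop = FALSE])
  rownames(M) <- table$donor_id
  storage.mode(M) <- "double"
  M
}

matrix_to_proteome <- function(M) {
  tibble::as_tibble(M, rownames = "donor_id")
}

#' Filter a proteome table by missingness and impute the remainder
#'
#' Donors with more missing proteins than `max_missing_per_donor` are
#' dropped first; then proteins missing in more than
#' `max_missing_per_protein` of the *remaining* donors are dropped; the
#' remaining missing cells are filled with the per-protein median over the
#' surviving donors. The order matters and is fixed (donors, then proteins,
#' then imputation).
#'
#' @param table Tibble with a `donor_id` column and one numeric column per
#'   protein; `NA` = missing.
#' @param max_missing_per_donor Drop a donor when its missing-protein count
#'   strictly exceeds this (default 150).
#' @param max_missing_per_protein Drop a protein when its missing-donor
#'   count strictly exceeds this (default 740).
#' @return The filtered, imputed tibble with attributes `n_donors_dropped`,
#'   `n_proteins_dropped`, `n_imputed`.
#' @export
filter_missing <- function(table, max_missing_per_donor = 150,
                           max_missing_per_protein = 740) {
  assert_scalar_number(max_missing_per_donor, "max_missing_per_donor", lower = 0)
  assert_scalar_number(max_missing_per_protein, "max_missing_per_protein", lower = 0)
  M <- proteome_matrix(table)
  donor_miss <- rowSums(is.na(M))
  keep_donor <- donor_miss <= max_missing_per_donor
  if (!any(keep_donor)) abort("all donors exceed the missingness threshold")
  M <- M[keep_donor, , drop = FALSE]
  prot_miss <- colSums(is.na(M))
  keep_prot <- prot_miss <= max_missing_per_protein
  if (!any(keep_prot)) abort("all proteins exceed the missingness threshold")
  M <- M[, keep_prot, drop = FALSE]
  n_imputed <- sum(is.na(M))
  if (n_imputed > 0) {
    for (j in seq_len(ncol(M))) {
      miss <- is.na(M[, j])
      if (any(miss)) M[miss, j] <- median(M[!miss, j])
    }
  }
  out <- matrix_to_proteome(M)
  attr(out, "n_donors_dropped") <- sum(!keep_donor)
  attr(out, "n_proteins_dropped") <- sum(!keep_prot)
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Assemble a feature matrix for one diagnostic condition
#'
#' Three feature conditions are compared in the validation: the disease's
#' specific communicators, an equal number of random measured proteins, and
#' the disease's raw known genes. Requested ids are intersected with the
#' measured proteins; a condition with zero measured features is marked
#' baseline-only (its prediction scores are fixed at chance level).
#'
#' @param table A filtered proteome tibble (see [filter_missing()]).
#' @param feature_ids Requested ids (ignored for `random_proteins`).
#' @param condition One of `"specific_itcs"`, `"random_proteins"`,
#'   `"raw_disease_genes"`.
#' @param rng_seed Seed for the random-protein draw.
#' @param n_features Required for `random_proteins`: how many proteins to
#'   draw (match the specific-communicator count).
#' @param exclude_ids For `random_proteins`: ids excluded from the pool
#'   (the disease's specific communicators).
#' @return List with `features` (tibble: `donor_id` + used columns),
#'   `used_ids`, `condition`, `baseline_only`.
#' @export
assemble_features <- function(table, feature_ids,
                              condition = c("specific_itcs", "random_proteins",
                                            "raw_disease_genes"),
                              rng_seed = 1, n_features = NULL,
                              exclude_ids = NULL) {
  condition <- match.arg(condition)
  measured <- setdiff(names(table), "donor_id")
  if (condition == "random_proteins") {
    if (is.null(n_features)) {
      abort("`n_features` (the specific-communicator count) is required for random_proteins")
    }
    pool <- setdiff(measured, exclude_ids)
    if (n_features > length(pool)) abort("random-protein pool is too small")
    used <- withr::with_seed(rng_seed, sample(pool, n_features, replace = FALSE))
  } else {
    used <- intersect(unique(feature_ids), measured)
  }
  baseline_only <- length(used) == 0
  if (baseline_only) {
    itc_log("condition '%s': no requested feature is measured; baseline-only",
            condition)
  }
  list(features = table[, c("donor_id", used), drop = FALSE],
       used_ids = used, condition = condition, baseline_only = baseline_only)
}

# AUROC by the rank (Mann-Whitney) relation, via pROC
auroc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision estimator: scores are ranked descending and precision
#' is accumulated at each positive, `AP = (1/P) * sum_k prec(k) * 1[y_k = 1]`.
#' Ties are broken by original order after a stable sort.
#'
#' @param labels Logical (or 0/1) outcome vector.
#' @param scores Numeric prediction scores, larger = more positive.
#' @return The average precision in \[0, 1\].
#' @export
auprc <- function(labels, scores) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores), any(labels), !all(labels))
  o <- order(scores, decreasing = TRUE)
  l <- labels[o]
  prec <- cumsum(l) / seq_along(l)
  sum(prec[l]) / sum(l)
}

#' Diagnostic prediction harness (stratified split + repeated CV)
#'
#' Donors are split 7:3 into training and held-out test sets by stratified
#' random sampling. On the training set, `folds`-fold cross-validation
#' repeated `repeats` times trains one gradient-boosted tree model
#' (xgboost, binary logistic, positive-class weight = n_negative /
#' n_positive) per fold; every model is evaluated on the same held-out test
#' set, recording AUROC and AUPRC. The AUPRC baseline is the test-set case
#' prevalence.
#'
#' @param features Tibble with `donor_id` plus numeric feature columns, or
#'   the list returned by [assemble_features()].
#' @param labels Logical vector of case status aligned with the feature
#'   rows, or a tibble with `donor_id` and `case` columns.
#' @param split_ratio Training fraction (default 0.7).
#' @param folds,repeats Cross-validation geometry (defaults 10 and 5).
#' @param rng_seed Integer seed (split, folds, and tree training).
#' @param nrounds Boosting rounds per model (library default elsewhere).
#' @param params Extra xgboost parameters overriding the defaults.
#' @return An object of class `diagnosis_result`: tibble with one row per
#'   CV model (`rep`, `fold`, `auroc`, `auprc`) and attributes
#'   `auprc_baseline`, `n_features`, `baseline_only`, `config`.
#' @export
run_diagnosis <- function(features, labels, split_ratio = 0.7, folds = 10,
                          repeats = 5, rng_seed = 1, nrounds = 100,
                          params = list()) {
  baseline_only <- FALSE
  if (is.list(features) && !is.data.frame(features) &&
      !is.null(features$features)) {
    baseline_only <- isTRUE(features$baseline_only)
    features <- features$features
  }
  stopifnot(is.data.frame(features), "donor_id" %in% names(features))
  if (is.data.frame(labels)) {
    stopifnot(all(c("donor_id", "case") %in% names(labels)))
    labels <- labels$case[match(features$donor_id, labels$donor_id)]
  }
  y <- as.logical(labels)
  stopifnot(length(y) == nrow(features), !anyNA(y))
  if (length(unique(y)) < 2) abort("both classes must be present")

  X <- as.matrix(features[, setdiff(names(features), "donor_id"), drop = FALSE])
  n_feat <- ncol(X)
  if (n_feat == 0) baseline_only <- TRUE

  n_models <- folds * repeats
  res <- withr::with_seed(rng_seed, {
    test_idx <- unlist(lapply(c(FALSE, TRUE), function(cls) {
      idx <- which(y == cls)
      sample(idx, round((1 - split_ratio) * length(idx)))
    }))
    train_idx <- setdiff(seq_along(y), test_idx)
    if (length(unique(y[test_idx])) < 2 || length(unique(y[train_idx])) < 2) {
      abort("stratified split left a side with a single class")
    }
    prevalence <- mean(y[test_idx])
    if (baseline_only) {
      metrics <- tibble::tibble(rep = rep(seq_len(repeats), each = folds),
                                fold = rep(seq_len(folds), times = repeats),
                                auroc = 0.5, auprc = prevalence)
      list(metrics = metrics, prevalence = prevalence)
    } else {
      y_tr <- y[train_idx]
      rows <- vector("list", n_models)
      m <- 0L
      for (rp in seq_len(repeats)) {
        fold_id <- stratified_folds(y_tr, folds)
        for (fd in seq_len(folds)) {
          m <- m + 1L
          fit_rows <- train_idx[fold_id != fd]
          y_fit <- y[fit_rows]
          if (length(unique(y_fit)) < 2) {
            warn(sprintf("fold %d of repeat %d has a single class; skipped", fd, rp))
            next
          }
          spw <- sum(!y_fit) / sum(y_fit)
          par <- modifyList(list(objective = "binary:logistic",
                                 eval_metric = "logloss",
                                 scale_pos_weight = spw,
                                 nthread = 1,
                                 seed = rng_seed + m), params)
          dtrain <- xgboost::xgb.DMatrix(X[fit_rows, , drop = FALSE],
                                         label = as.numeric(y_fit))
          fit <- xgboost::xgb.train(params = par, data = dtrain,
                                    nrounds = nrounds, verbose = 0)
          pred <- stats::predict(fit, X[test_idx, , drop = FALSE])
          rows[[m]] <- tibble::tibble(rep = rp, fold = fd,
                                      auroc = auroc(y[test_idx], pred),
                                      auprc = auprc(y[test_idx], pred))
        }
      }
      list(metrics = dplyr::bind_rows(rows), prevalence = prevalence)
    }
  })

  out <- res$metrics
  attr(out, "auprc_baseline") <- res$prevalence
  attr(out, "n_features") <- n_feat
  attr(out, "baseline_only") <- baseline_only
  attr(out, "config") <- list(split_ratio = split_ratio, folds = folds,
                              repeats = repeats, rng_seed = rng_seed,
                              nrounds = nrounds)
  class(out) <- c("diagnosis_result", class(out))
  out
}

#' @method glance diagnosis_result
#' @export
glance.diagnosis_result <- function(x, ...) {
  tibble::tibble(
    median_auroc = median(x$auroc),
    median_auprc = median(x$auprc),
    auprc_baseline = attr(x, "auprc_baseline"),
    n_models = nrow(x),
    n_features = attr(x, "n_features"),
    baseline_only = attr(x, "baseline_only")
  )
}

#' Paired comparison of feature conditions across diseases
#'
#' Per-disease median metrics are compared between feature conditions by a
#' one-sided paired Wilcoxon signed-rank test (condition A greater than
#' condition B). For AUPRC the per-disease baseline is subtracted first,
#' since each disease has its own prevalence. With fewer than 5 paired
#' diseases only the per-disease deltas are reported.
#'
#' @param results Tibble with columns `disease`, `condition`,
#'   `median_auroc`, `median_auprc`, `auprc_baseline` (one row per disease
#'   and condition, e.g. built from [glance.diagnosis_result()] rows).
#' @return List with `summary` (tibble: metric, condition_a, condition_b,
#'   n_pairs, statistic, p_value) and `deltas` (per-disease differences).
#' @export
compare_conditions <- function(results) {
  need <- c("disease", "condition", "median_auroc", "median_auprc",
            "auprc_baseline")
  stopifnot(all(need %in% names(results)))
  results <- dplyr::mutate(results,
                           auprc_over_baseline = .data$median_auprc - .data$auprc_baseline)
  conditions <- unique(results$condition)
  pairs <- utils::combn(conditions, 2, simplify = FALSE)
  metrics <- c(auroc = "median_auroc", auprc = "auprc_over_baseline")

  summary_rows <- list()
  delta_rows <- list()
  for (pr in pairs) {
    a <- results[results$condition == pr[1], ]
    b <- results[results$condition == pr[2], ]
    common <- intersect(a$disease, b$disease)
    for (mn in names(metrics)) {
      va <- a[[metrics[[mn]]]][match(common, a$disease)]
      vb <- b[[metrics[[mn]]]][match(common, b$disease)]
      delta_rows[[length(delta_rows) + 1]] <- tibble::tibble(
        metric = mn, condition_a = pr[1], condition_b = pr[2],
        disease = common, delta = va - vb)
      if (length(common) >= 5) {
        wt <- suppressWarnings(wilcox.test(va, vb, paired = TRUE,
                                           alternative = "greater"))
        stat <- unname(wt$statistic); pv <- wt$p.value
      } else {
        stat <- NA_real_; pv <- NA_real_
      }
      summary_rows[[length(summary_rows) + 1]] <- tibble::tibble(
        metric = mn, condition_a = pr[1], condition_b = pr[2],
        n_pairs = length(common), statistic = stat, p_value = pv)
    }
  }
  list(summary = dplyr::bind_rows(summary_rows),
       deltas = dplyr::bind_rows(delta_rows))
}

#' Box plot of CV metric distributions
#'
#' @param object A `diagnosis_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diagnosis_result
#' @export
autoplot.diagnosis_result <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("auroc", "auprc"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = attr(object, "auprc_baseline"),
                        linetype = 2, colour = "grey40") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "held-out test metric",
                  subtitle = "dashed line: AUPRC baseline (test prevalence)") +
    ggplot2::theme_minimal()
}
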