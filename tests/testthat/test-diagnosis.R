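toy_proteome <- function() {
  # 4 donors x 3 proteins; donor D4 misses everything, protein P3 is sparse
  tibble::tibble(
    donor_id = paste0("D", 1:4),
    P1 = c(1, 2, 3, NA),
    P2 = c(4, NA, 6, NA),
    P3 = c(NA, NA, NA, NA))
}

test_that("missingness filtering drops donors first, then proteins, then imputes", {
  out <- filter_missing(toy_proteome(), max_missing_per_donor = 2,
                        max_missing_per_protein = 2)
  expect_equal(out$donor_id, paste0("D", 1:3))       # D4 (3 missing) dropped
  expect_setequal(setdiff(names(out), "donor_id"), c("P1", "P2"))
  expect_equal(out$P2, c(4, 5, 6))                    # median of 4, 6 imputed
  expect_equal(attr(out, "n_donors_dropped"), 1)
  expect_equal(attr(out, "n_proteins_dropped"), 1)
})

test_that("the donor-then-protein order is what rescues the sparse protein's donors", {
  # P3 is missing for all 4 donors; with the donor pass first, D4 leaves and
  # P3's count drops to 3 which still exceeds 2 -> dropped. Under a
  # protein-first order P1/P2 would each count 2 <= 2 and D4 would survive
  # on 2 remaining proteins. The fixed order must drop D4.
  out <- filter_missing(toy_proteome(), max_missing_per_donor = 2,
                        max_missing_per_protein = 2)
  expect_false("D4" %in% out$donor_id)
  expect_error(filter_missing(toy_proteome(), 0, 0), "all donors")
})

test_that("surviving dimensions match the fixture manifest exactly", {
  fx <- make_proteome_fixture(rng_seed = 6)
  th <- fx$manifest$parameters
  out <- filter_missing(fx$table, th$donor_miss_threshold,
                        th$protein_miss_threshold)
  expect_equal(nrow(out), fx$manifest$expected_n_donors)
  expect_equal(ncol(out) - 1, fx$manifest$expected_n_proteins)
  expect_identical(out$donor_id, fx$manifest$expected_donor_ids)
  expect_identical(setdiff(names(out), "donor_id"),
                   fx$manifest$expected_protein_ids)
  expect_false(fx$manifest$planted_donor %in% out$donor_id)
  expect_false(fx$manifest$planted_protein %in% names(out))
  expect_false(anyNA(out))
})

test_that("feature assembly intersects, samples reproducibly, and flags baseline-only", {
  tab <- tibble::tibble(donor_id = paste0("D", 1:5),
                        A = 1:5, B = 6:10, C = 11:15)
  got <- assemble_features(tab, c("A", "C", "ZZ"), "specific_itcs")
  expect_setequal(got$used_ids, c("A", "C"))
  expect_false(got$baseline_only)

  none <- assemble_features(tab, "ZZ", "raw_disease_genes")
  expect_true(none$baseline_only)

  r1 <- assemble_features(tab, NULL, "random_proteins", rng_seed = 3,
                          n_features = 2, exclude_ids = "A")
  r2 <- assemble_features(tab, NULL, "random_proteins", rng_seed = 3,
                          n_features = 2, exclude_ids = "A")
  expect_identical(r1$used_ids, r2$used_ids)
  expect_false("A" %in% r1$used_ids)
  expect_error(assemble_features(tab, NULL, "random_proteins", n_features = 9),
               "pool")
})

test_that("average precision agrees with an independent threshold sweep", {
  withr::with_seed(12, {
    for (i in 1:20) {
      n <- 50
      y <- runif(n) < 0.3
      if (!any(y) || all(y)) next
      s <- rnorm(n) + y
      expect_equal(auprc(y, s), oracle_auprc(y, s), tolerance = 1e-12)
    }
  })
  # perfect separation gives 1; the baseline equals prevalence for a flat score
  expect_equal(auprc(c(TRUE, TRUE, FALSE, FALSE), c(4, 3, 2, 1)), 1)
})

test_that("a separable proteome is classified nearly perfectly", {
  fx <- make_proteome_fixture(n_donors = 150, n_cases = 50, effect_size = 3,
                              rng_seed = 8)
  th <- fx$manifest$parameters
  tab <- filter_missing(fx$table, th$donor_miss_threshold,
                        th$protein_miss_threshold)
  feats <- assemble_features(tab, fx$manifest$informative_proteins,
                             "specific_itcs")
  labels <- fx$labels[match(tab$donor_id, fx$labels$donor_id), ]
  res <- run_diagnosis(feats, labels, folds = 5, repeats = 2, rng_seed = 8)
  expect_gt(median(res$auroc), 0.95)
  expect_true(all(res$auprc >= attr(res, "auprc_baseline")))
  # the AUPRC baseline is exactly the held-out test prevalence
  n_test <- round(0.3 * sum(labels$case)) + round(0.3 * sum(!labels$case))
  expect_equal(attr(res, "auprc_baseline") * n_test,
               round(attr(res, "auprc_baseline") * n_test))
})

test_that("label-independent features hover at chance and runs are reproducible", {
  fx <- make_proteome_fixture(n_donors = 150, n_cases = 50, effect_size = 0,
                              rng_seed = 9)
  th <- fx$manifest$parameters
  tab <- filter_missing(fx$table, th$donor_miss_threshold,
                        th$protein_miss_threshold)
  feats <- assemble_features(tab, fx$manifest$informative_proteins,
                             "specific_itcs")
  labels <- fx$labels[match(tab$donor_id, fx$labels$donor_id), ]
  r1 <- run_diagnosis(feats, labels, folds = 5, repeats = 2, rng_seed = 2)
  r2 <- run_diagnosis(feats, labels, folds = 5, repeats = 2, rng_seed = 2)
  expect_identical(r1$auroc, r2$auroc)
  expect_gt(median(r1$auroc), 0.3)
  expect_lt(median(r1$auroc), 0.7)
})

test_that("baseline-only conditions report chance AUROC and prevalence AUPRC", {
  fx <- make_proteome_fixture(n_donors = 100, n_cases = 30, rng_seed = 3)
  th <- fx$manifest$parameters
  tab <- filter_missing(fx$table, th$donor_miss_threshold,
                        th$protein_miss_threshold)
  feats <- assemble_features(tab, "NOT_MEASURED", "raw_disease_genes")
  labels <- fx$labels[match(tab$donor_id, fx$labels$donor_id), ]
  res <- run_diagnosis(feats, labels, folds = 5, repeats = 2, rng_seed = 1)
  expect_true(all(res$auroc == 0.5))
  expect_true(all(res$auprc == attr(res, "auprc_baseline")))
  expect_true(attr(res, "baseline_only"))
  g <- glance(res)
  expect_equal(g$median_auroc, 0.5)
})

test_that("condition comparison detects constructed dominance and handles few pairs", {
  base <- tibble::tibble(disease = paste0("dis", 1:8),
                         condition = "specific_itcs",
                         median_auroc = seq(0.6, 0.74, length.out = 8),
                         median_auprc = seq(0.3, 0.44, length.out = 8),
                         auprc_baseline = 0.1)
  worse <- dplyr::mutate(base, condition = "random_proteins",
                         median_auroc = .data$median_auroc - 0.1,
                         median_auprc = .data$median_auprc - 0.1)
  cmp <- compare_conditions(dplyr::bind_rows(base, worse))
  row <- cmp$summary[cmp$summary$metric == "auroc", ]
  expect_lt(row$p_value, 0.05)
  expect_equal(cmp$deltas$delta[cmp$deltas$metric == "auroc"], rep(0.1, 8))

  same <- dplyr::mutate(base, condition = "random_proteins")
  cmp0 <- compare_conditions(dplyr::bind_rows(base, same))
  expect_true(all(cmp0$deltas$delta == 0))

  few <- dplyr::bind_rows(base[1:3, ], worse[1:3, ])
  cmpf <- compare_conditions(few)
  expect_true(all(is.na(cmpf$summary$p_value)))
  expect_equal(nrow(cmpf$deltas), 6)
})
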