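toy_signatures <- function() {
  V <- matrix(seq_len(12), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  meta <- tibble::tibble(
    signature_id = paste0("s", 1:3),
    cell_line = c("CL1", "CL1", "CL2"),
    perturbagen = c("TF1", "TF1", "TF1"),
    ptype = "OX", time = "96 h", exemplar = TRUE,
    tas = c(0.2, 0.7, 0.5))
  signature_matrix(V, meta)
}

test_that("filtering keeps the max-TAS duplicate and is the identity when idle", {
  sig <- toy_signatures()
  out <- filter_signatures(sig)
  expect_setequal(out$meta$signature_id, c("s2", "s3"))  # s1 loses on TAS
  expect_equal(attr(out, "drop_counts")$duplicate_lower_tas, 1)

  idle <- filter_signatures(out)  # already clean: nothing more to drop
  expect_identical(idle$values, out$values)

  expect_error(filter_signatures(sig, excluded_cell_lines = c("CL1", "CL2")),
               "no signature survives")
})

test_that("fixture filtering survivors match the manifest bookkeeping", {
  fx <- make_signature_fixture(rng_seed = 10)
  filt <- filter_signatures(
    fx$signatures,
    excluded_cell_lines = fx$manifest$excluded_cell_line)
  expect_equal(ncol(filt$values), fx$manifest$expected_surviving_columns)
  expect_false(fx$manifest$excluded_cell_line %in% filt$meta$cell_line)
  expect_true(all(filt$meta$time == "96 h"))
  expect_true(all(filt$meta$exemplar))
  expect_equal(anyDuplicated(filt$meta[, c("perturbagen", "cell_line",
                                           "ptype")]), 0)
})

test_that("receptors map to reachable TFs and ligands inherit them", {
  edges <- tibble::tibble(from = c("R1", "X", "L_ignored"),
                          to = c("X", "TF1", "R1"))
  map <- map_itcs_to_tfs(edges, receptors = c("R1", "R_missing"),
                         ligand_receptor_pairs = tibble::tibble(
                           ligand = c("L1", "L2"),
                           receptor = c("R1", "R_missing")),
                         tfs = c("TF1", "TF2"))
  expect_equal(map$map$R1, "TF1")
  expect_equal(map$map$L1, "TF1")
  expect_setequal(map$unmapped, c("R_missing", "L2"))
})

test_that("reachability matches a brute-force closure on random DAGs", {
  for (seed in 1:5) {
    edges <- withr::with_seed(seed, {
      n <- 60
      ids <- sprintf("V%02d", seq_len(n))
      from <- sample(n - 1, 150, replace = TRUE)
      to <- from + sapply(from, function(f) sample(n - f, 1))
      unique(tibble::tibble(from = ids[from], to = ids[to]))
    })
    tfs <- sprintf("V%02d", 41:60)
    receptors <- sprintf("V%02d", 1:10)
    map <- map_itcs_to_tfs(edges, receptors, tfs = tfs)
    for (r in receptors) {
      expect_identical(map$map[[r]] %||% character(0),
                       oracle_tf_closure(edges, r, tfs))
    }
  }
})

test_that("communicator signatures are TF column sums with cancellation", {
  V <- cbind(a = c(1, 2, -1), b = c(-1, -2, 1), c = c(3, 0, 1))
  rownames(V) <- paste0("g", 1:3)
  meta <- tibble::tibble(signature_id = c("a", "b", "c"),
                         cell_line = "CL1",
                         perturbagen = c("TF1", "TF2", "TF3"),
                         ptype = "KD", time = "96 h", exemplar = TRUE,
                         tas = 0.5)
  sig <- signature_matrix(V, meta)
  expect_equal(itc_signature(sig, "TF3", "CL1", "KD"),
               c(g1 = 3, g2 = 0, g3 = 1), ignore_attr = TRUE)
  expect_equal(unname(itc_signature(sig, c("TF1", "TF2"), "CL1", "KD")),
               c(0, 0, 0), ignore_attr = TRUE)
  three <- itc_signature(sig, c("TF1", "TF2", "TF3"), "CL1", "KD")
  expect_equal(unname(three), unname(rowSums(V)), ignore_attr = TRUE)
  expect_null(suppressMessages(itc_signature(sig, "TF9", "CL1", "KD")))
})

test_that("identical cell-line blocks are all selected", {
  base <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(
    sprintf("g%02d", 1:40), NULL))
  V <- cbind(base, base, base)
  meta <- tibble::tibble(
    signature_id = sprintf("s%02d", 1:18),
    cell_line = rep(c("CL1", "CL2", "CL3"), each = 6),
    perturbagen = rep(paste0("TF", 1:6), 3),
    ptype = "OX", time = "96 h", exemplar = TRUE, tas = 0.5)
  colnames(V) <- meta$signature_id
  sig <- signature_matrix(V, meta)
  sel <- select_cell_lines(sig, sprintf("g%02d", 1:20))
  expect_setequal(as.character(sel), c("CL1", "CL2", "CL3"))
})

test_that("the planted correlated block is recovered exactly and the null is empty", {
  fx <- make_signature_fixture(rng_seed = 14)
  filt <- filter_signatures(fx$signatures,
                            excluded_cell_lines = fx$manifest$excluded_cell_line)
  sel <- select_cell_lines(filt, fx$manifest$disease_genes)
  expect_setequal(as.character(sel), fx$manifest$corr_block)

  for (seed in c(4, 5)) {
    nul <- make_signature_fixture(corr_block = NULL, dg_inflation = 1,
                                  rng_seed = seed)
    nfilt <- filter_signatures(nul$signatures,
                               excluded_cell_lines = nul$manifest$excluded_cell_line)
    expect_length(select_cell_lines(nfilt, nul$manifest$disease_genes), 0)
  }
})

test_that("perturbation scores reduce to the unit field and scale linearly", {
  V <- matrix(1, nrow = 4, ncol = 1, dimnames = list(paste0("g", 1:4), "s1"))
  meta <- tibble::tibble(signature_id = "s1", cell_line = "CL1",
                         perturbagen = "TF1", ptype = "KD", time = "96 h",
                         exemplar = TRUE, tas = 0.5)
  sig <- signature_matrix(V, meta)
  tf_map <- structure(list(map = list(R1 = "TF1"), unmapped = character(0)),
                      class = "itc_tf_map")
  sc <- disease_perturbation_score(sig, "R1", tf_map, "CL1",
                                   paste0("g", 1:4), "KD")
  expect_equal(as.numeric(sc), 1)

  sig2 <- signature_matrix(V * 2, meta)
  sc2 <- disease_perturbation_score(sig2, "R1", tf_map, "CL1",
                                    paste0("g", 1:4), "KD")
  expect_equal(as.numeric(sc2), 2 * as.numeric(sc))
  expect_error(disease_perturbation_score(sig, "R_unmapped", tf_map, "CL1",
                                          paste0("g", 1:4), "KD"),
               "no usable")
})

test_that("the score equals a from-scratch recomputation on the fixture", {
  fx <- make_signature_fixture(rng_seed = 20)
  filt <- filter_signatures(fx$signatures,
                            excluded_cell_lines = fx$manifest$excluded_cell_line)
  tf_map <- map_itcs_to_tfs(fx$pathway_graph, fx$receptors, fx$lr_pairs,
                            fx$tfs)
  lines <- fx$manifest$corr_block
  itcs <- fx$manifest$disease_itcs
  got <- disease_perturbation_score(filt, itcs, tf_map, lines,
                                    fx$manifest$disease_genes, "KD")
  # independent recomputation straight from the matrix and metadata
  dg <- fx$manifest$disease_genes
  profile <- setNames(numeric(length(dg)), dg)
  for (itc in itcs) {
    tfs <- tf_map$map[[itc]]
    per_line <- list()
    for (cl in lines) {
      cols <- filt$meta$signature_id[filt$meta$perturbagen %in% tfs &
                                       filt$meta$cell_line == cl &
                                       filt$meta$ptype == "KD"]
      if (length(cols) == 0) next
      per_line[[cl]] <- abs(rowSums(filt$values[, cols, drop = FALSE]))[dg]
    }
    profile <- profile + Reduce(`+`, per_line) / length(per_line)
  }
  expect_equal(as.numeric(got), mean(profile), tolerance = 1e-12)
})

test_that("planted disease communicators show a strong fold increase", {
  fx <- make_signature_fixture(dg_inflation = 3, rng_seed = 30)
  filt <- filter_signatures(fx$signatures,
                            excluded_cell_lines = fx$manifest$excluded_cell_line)
  tf_map <- map_itcs_to_tfs(fx$pathway_graph, fx$receptors, fx$lr_pairs,
                            fx$tfs)
  lines <- select_cell_lines(filt, fx$manifest$disease_genes)
  res <- fold_vs_random(filt, fx$manifest$disease_itcs,
                        fx$manifest$itc_pool, tf_map, lines,
                        fx$manifest$disease_genes, "KD", n_sets = 50,
                        rng_seed = 30)
  expect_gt(res$mean_fold, 1.5)
  expect_lt(res$p_value, 0.01)
  res2 <- fold_vs_random(filt, fx$manifest$disease_itcs,
                         fx$manifest$itc_pool, tf_map, lines,
                         fx$manifest$disease_genes, "KD", n_sets = 50,
                         rng_seed = 30)
  expect_identical(res$fold_values, res2$fold_values)
  g <- glance(res)
  expect_equal(g$mean_fold, res$mean_fold)
})

test_that("random sets identical to the disease set give unit folds", {
  # pool of exactly the disease set's size forces every draw to be the same
  V <- matrix(rnorm(20), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2")))
  meta <- tibble::tibble(signature_id = c("s1", "s2"), cell_line = "CL1",
                         perturbagen = c("TF1", "TF2"), ptype = "KD",
                         time = "96 h", exemplar = TRUE, tas = 0.5)
  sig <- signature_matrix(V, meta)
  tf_map <- structure(list(map = list(R1 = c("TF1", "TF2"),
                                      R2 = c("TF1", "TF2")),
                           unmapped = character(0)), class = "itc_tf_map")
  res <- fold_vs_random(sig, "R1", c("R1", "R2"), tf_map, "CL1",
                        sprintf("g%02d", 1:10), "KD", n_sets = 10,
                        rng_seed = 1)
  expect_true(all(res$fold_values == 1))
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
})
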