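test_that("thresholded influence censors below-threshold probabilities", {
  theta <- 1e-4
  pr <- fake_profile(c(g1 = 2 * theta, g2 = theta / 2, g3 = 3 * theta,
                       other = 0.9))
  inf <- thresholded_influence(pr, c("g1", "g2", "g3"), theta)
  expect_equal(inf$raw_sum, 5 * theta)
  expect_equal(inf$n_dg_hit, 2)

  expect_equal(thresholded_influence(pr, c("g1", "g2", "g3"), 0)$raw_sum,
               5.5 * theta)  # no censoring at threshold zero
  all_below <- thresholded_influence(pr, c("g1", "g2", "g3"), 1)
  expect_equal(all_below$raw_sum, 0)
  expect_equal(all_below$n_dg_hit, 0)
  expect_warning(thresholded_influence(pr, "absent", 0), "no disease genes")
})

test_that("the random baseline is the mean of per-seed sums and is seeded", {
  W <- random_transition(40, seed = 8)
  dg <- sprintf("N%03d", 1:8)
  b1 <- random_gene_baseline(W, dg, n_random = 10, threshold = 0, rng_seed = 3)
  b2 <- random_gene_baseline(W, dg, n_random = 10, threshold = 0, rng_seed = 3)
  expect_identical(b1, b2)
  expect_equal(b1$mean, mean(b1$sums))
  expect_length(b1$genes, 10)
  expect_error(random_gene_baseline(W, dg, n_random = 1000, threshold = 0),
               "pool")
})

test_that("hub-attached disease genes attract a larger baseline than peripheral ones", {
  fx <- make_network_fixture(rng_seed = 13)
  W <- column_normalize(fx$network)
  A <- fx$network$adjacency
  deg <- Matrix::colSums(A)
  hubs <- names(sort(deg, decreasing = TRUE))[1:10]
  periphery <- names(sort(deg))[1:10]
  bh <- random_gene_baseline(W, hubs, n_random = 30, threshold = 0, rng_seed = 1)
  bp <- random_gene_baseline(W, periphery, n_random = 30, threshold = 0, rng_seed = 1)
  expect_gt(bh$mean, bp$mean)
})

test_that("scores are raw sums over the per-disease baseline", {
  fx <- make_network_fixture(rng_seed = 4)
  W <- column_normalize(fx$network)
  dgs <- list(d1 = fx$manifest$disease_genes,
              d2 = fx$manifest$modules[[2]],
              d3 = fx$manifest$modules[[3]])
  sc <- score_all(W, fx$itc_catalog, dgs, threshold = 0, rng_seed = 7,
                  n_random = 25)
  for (d in colnames(sc$scores)) {
    base <- sc$baselines$baseline[sc$baselines$disease == d]
    expect_equal(sc$scores[, d], sc$raw[, d] / base)
    # baseline is a per-disease constant, so ranking matches the raw ranking
    expect_identical(order(sc$scores[, d]), order(sc$raw[, d]))
  }
  expect_true(all(sc$scores >= 0))
})

test_that("a communicator disconnected from the disease component scores zero", {
  edges <- dplyr::bind_rows(
    random_edges(30, p = 0.15, seed = 2),
    tibble::tibble(source = "ISO1", target = "ISO2", layer = "ppi",
                   directed = FALSE, provenance = "t"))
  W <- column_normalize(assemble_network(edges))
  dgs <- list(d1 = sprintf("N%03d", 1:12), d2 = sprintf("N%03d", 13:24),
              d3 = sprintf("N%03d", c(1:6, 25:30)))
  sc <- score_all(W, c("ISO1", "N002", "N015"), dgs, threshold = 0,
                  rng_seed = 1, n_random = 10, min_disease_genes = 5)
  expect_equal(unname(sc$scores["ISO1", ]), rep(0, 3))
  specific <- select_specific(sc, modz_cutoff = 5)
  expect_false("ISO1" %in% specific$itc)
})

test_that("diseases below the gene-count admission rule are excluded", {
  fx <- make_network_fixture(rng_seed = 4)
  W <- column_normalize(fx$network)
  dgs <- list(big = fx$manifest$disease_genes, tiny = fx$network$nodes$id[1:3])
  sc <- score_all(W, fx$itc_catalog, dgs, threshold = 0, rng_seed = 1,
                  n_random = 10)
  expect_equal(colnames(sc$scores), "big")
  expect_equal(sc$dropped_diseases, "tiny")
  expect_error(score_all(W, character(0), dgs, 0), "empty")
})

test_that("modified Z-scores match the direct formula on random vectors", {
  withr::with_seed(99, {
    for (i in 1:100) {
      x <- switch(1 + i %% 4,
                  rnorm(sample(3:40, 1)),
                  rexp(sample(3:40, 1)),
                  c(rep(0, sample(3:20, 1)), runif(3)),
                  round(rnorm(sample(3:40, 1)), 1))  # ties exercise MAD = 0 less often
      expect_equal(modified_z(x), oracle_modz(x), tolerance = 1e-12)
    }
  })
})

test_that("modified Z-scores handle degenerate spreads as documented", {
  expect_equal(modified_z(rep(2, 5)), rep(0, 5))
  x <- c(rep(1, 9), 10)
  mz <- modified_z(x)
  expect_equal(mz[10], 0.6745 * 9 / (1.2533 * 0.9), tolerance = 1e-12)
  expect_gt(mz[10], 5)
  sym <- modified_z(c(-3, 0, 3))
  expect_equal(sym, -rev(sym))
  expect_error(modified_z(c(1, 2)), "at least 3")
})

test_that("specific-communicator selection keeps only outlier diseases", {
  M <- rbind(
    flat = c(1, 1.1, 0.9, 1, 1.05, 0.95, 1.02),
    spike = c(1, 1.1, 0.9, 8, 1.05, 0.95, 1.02),
    zero = rep(0, 7))
  colnames(M) <- paste0("d", 1:7)
  res <- select_specific(M, modz_cutoff = 5)
  expect_equal(unique(res$itc), "spike")
  expect_equal(res$disease, "d4")
  expect_equal(res$modz[1], unname(oracle_modz(M["spike", ])["d4"]))
  expect_equal(nrow(select_specific(M, modz_cutoff = Inf)), 0)
  expect_error(select_specific(M[, 1:2]), "3 diseases")
})

test_that("selection commutes with inversion and sorts by modZ within disease", {
  withr::with_seed(31, {
    M <- matrix(rexp(20 * 6), 20, 6,
                dimnames = list(paste0("itc", 1:20), paste0("d", 1:6)))
    M[3, 2] <- 40
    M[7, 5] <- 60
  })
  res <- select_specific(M, modz_cutoff = 5)
  # row-wise selection assembled independently must give the same pair set
  manual <- list()
  for (i in seq_len(nrow(M))) {
    mz <- oracle_modz(M[i, ])
    for (j in which(mz > 5)) {
      manual[[length(manual) + 1]] <- paste(colnames(M)[j], rownames(M)[i])
    }
  }
  expect_setequal(paste(res$disease, res$itc), unlist(manual))
  for (d in unique(res$disease)) {
    expect_true(all(diff(res$modz[res$disease == d]) <= 0))
  }
})

test_that("planted communicators take the top normalized ranks", {
  fx <- make_network_fixture(rng_seed = 17)
  W <- column_normalize(fx$network)
  dgs <- list(disease = fx$manifest$disease_genes)
  sc <- score_all(W, fx$itc_catalog, dgs, threshold = 0, rng_seed = 17,
                  min_disease_genes = 10)
  top5 <- rownames(sc$scores)[order(sc$scores[, 1], decreasing = TRUE)][1:5]
  expect_setequal(top5, fx$manifest$planted_itcs)
})

test_that("score matrices tidy and export round-trip", {
  fx <- make_network_fixture(rng_seed = 4)
  W <- column_normalize(fx$network)
  dgs <- list(d1 = fx$manifest$disease_genes, d2 = fx$manifest$modules[[2]],
              d3 = fx$manifest$modules[[3]])
  sc <- score_all(W, fx$itc_catalog, dgs, threshold = 0, rng_seed = 7,
                  n_random = 20)
  td <- tidy(sc)
  expect_equal(nrow(td), prod(dim(sc$scores)))
  expect_equal(td$score[td$itc == rownames(sc$scores)[1] & td$disease == "d1"],
               sc$scores[1, "d1"])
  specific <- select_specific(sc)
  dir <- withr::local_tempdir()
  export_scores(sc, specific, dir)
  back <- readr::read_tsv(file.path(dir, "score_matrix.tsv"),
                          show_col_types = FALSE)
  expect_equal(back$itc, rownames(sc$scores))
  expect_equal(back$d1, unname(sc$scores[, "d1"]))
})
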