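# Seeded synthetic-fixture generators. Each returns its inputs in the same
# shapes the analysis functions consume, plus a manifest recording the
# planted ground truth so tests can assert parameter recovery. All
# randomness flows from the single rng_seed argument (restored on exit).

node_ids <- function(n, prefix = "G") sprintf("%s%04d", prefix, seq_len(n))

#' Synthetic modular network with planted communicators
#'
#' Generates a preferential-attachment backbone overlaid with planted
#' stochastic-block modules; one module is designated the disease-gene
#' module. `n_itcs` planted "communicator" nodes each receive
#' `wiring_strength` extra edges into the disease module, while `n_decoys`
#' decoy communicators receive the same number of uniformly placed extra
#' edges, so planted and decoy nodes have matched extra degree and differ
#' only in where their edges point.
#'
#' @param n_nodes Total nodes (default 500).
#' @param n_modules,module_size Planted module geometry (default 5 x 20).
#' @param p_within,p_between Within-/between-module edge probabilities
#'   among module nodes (defaults 0.25 / 0.01).
#' @param n_itcs Planted communicators wired to the disease module
#'   (default 5).
#' @param n_decoys Decoy communicators wired uniformly (default 45).
#' @param n_dg Disease-gene count, at most `module_size` (default all of
#'   the disease module).
#' @param wiring_strength Extra edges per communicator (default 8); 0 makes
#'   planted and decoy nodes indistinguishable (a negative control).
#' @param rng_seed Integer seed.
#' @return List of class `network_fixture`: `network` (a
#'   `hetero_network`), `edges` (the edge tibble), `itc_catalog` (tibble
#'   `id`, `role`), `manifest` (ground truth).
#' @export
make_network_fixture <- function(n_nodes = 500, n_modules = 5,
                                 module_size = 20, p_within = 0.25,
                                 p_between = 0.01, n_itcs = 5,
                                 n_decoys = 45, n_dg = module_size,
                                 wiring_strength = 8, rng_seed = 1) {
  stopifnot(n_modules * module_size + n_itcs + n_decoys <= n_nodes,
            p_within > 0, p_within < 1, p_between > 0, p_between < 1,
            n_dg <= module_size, wiring_strength >= 0)
  ids <- node_ids(n_nodes)
  out <- withr::with_seed(rng_seed, {
    g <- igraph::sample_pa(n_nodes, power = 1, m = 2, directed = FALSE)
    backbone <- igraph::as_edgelist(g, names = FALSE)
    edges <- tibble::tibble(source = ids[backbone[, 1]],
                            target = ids[backbone[, 2]])

    perm <- sample(n_nodes)
    module_nodes <- lapply(seq_len(n_modules), function(m) {
      ids[perm[((m - 1) * module_size + 1):(m * module_size)]]
    })
    names(module_nodes) <- sprintf("module_%02d", seq_len(n_modules))
    off <- n_modules * module_size
    itcs <- ids[perm[(off + 1):(off + n_itcs)]]
    decoys <- ids[perm[(off + n_itcs + 1):(off + n_itcs + n_decoys)]]
    dg <- module_nodes[[1]][seq_len(n_dg)]

    sbm_edges <- list()
    for (m in seq_len(n_modules)) {
      pr <- t(utils::combn(module_nodes[[m]], 2))
      keep <- stats::runif(nrow(pr)) < p_within
      sbm_edges[[m]] <- tibble::tibble(source = pr[keep, 1], target = pr[keep, 2])
    }
    cross <- t(utils::combn(seq_len(n_modules), 2))
    for (i in seq_len(nrow(cross))) {
      a <- module_nodes[[cross[i, 1]]]
      b <- module_nodes[[cross[i, 2]]]
      pr <- expand.grid(source = a, target = b, stringsAsFactors = FALSE)
      keep <- stats::runif(nrow(pr)) < p_between
      sbm_edges[[n_modules + i]] <- tibble::as_tibble(pr[keep, , drop = FALSE])
    }

    wire <- list()
    if (wiring_strength > 0) {
      for (v in itcs) {
        wire[[length(wire) + 1]] <- tibble::tibble(
          source = v, target = sample(dg, min(wiring_strength, length(dg))))
      }
      for (v in decoys) {
        wire[[length(wire) + 1]] <- tibble::tibble(
          source = v, target = sample(setdiff(ids, v), wiring_strength))
      }
    }
    dplyr::bind_rows(c(list(edges), sbm_edges, wire)) |>
      dplyr::mutate(layer = "ppi", directed = FALSE, provenance = "synthetic") |>
      dplyr::distinct(.data$source, .data$target, .keep_all = TRUE) |>
      list(module_nodes = module_nodes, itcs = itcs, decoys = decoys, dg = dg)
  })
  edge_tbl <- out[[1]]
  network <- suppressMessages(assemble_network(edge_tbl, "undirected_all"))
  catalog <- tibble::tibble(
    id = c(out$itcs, out$decoys),
    role = rep(c("receptor", "ligand"), length.out = n_itcs + n_decoys))
  manifest <- list(
    generator = "network_fixture", rng_seed = rng_seed,
    parameters = list(n_nodes = n_nodes, n_modules = n_modules,
                      module_size = module_size, p_within = p_within,
                      p_between = p_between, n_itcs = n_itcs,
                      n_decoys = n_decoys, n_dg = n_dg,
                      wiring_strength = wiring_strength),
    modules = out$module_nodes,
    disease_genes = out$dg,
    planted_itcs = out$itcs,
    decoy_itcs = out$decoys,
    n_edges = nrow(edge_tbl)
  )
  structure(list(network = network, edges = edge_tbl, itc_catalog = catalog,
                 manifest = manifest),
            class = "network_fixture")
}

#' Pathway-like gene sets drawn from a network fixture's planted modules
#'
#' Each set is a uniform subset of one planted module, emulating a curated
#' pathway collection whose members are topologically cohesive.
#'
#' @param fixture A `network_fixture`.
#' @param n_sets Number of sets (default 20).
#' @param set_size Members per set (default 8).
#' @param rng_seed Integer seed.
#' @return Named list of character vectors.
#' @export
fixture_pathway_sets <- function(fixture, n_sets = 20, set_size = 8,
                                 rng_seed = 1) {
  stopifnot(inherits(fixture, "network_fixture"))
  modules <- fixture$manifest$modules
  withr::with_seed(rng_seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      m <- modules[[(i - 1) %% length(modules) + 1]]
      sample(m, min(set_size, length(m)))
    })
    names(sets) <- sprintf("pathway_%02d", seq_len(n_sets))
    sets
  })
}

#' Synthetic donor-by-protein proteome table with planted structure
#'
#' Gaussian measurements per protein; case donors are shifted by
#' `effect_size` standard deviations on the informative proteins; cells go
#' missing i.i.d. at `missing_rate`. One planted donor and one planted
#' (non-informative) protein exceed the given missingness thresholds so the
#' filter path is exercised, and the manifest records the post-filter
#' dimensions computed directly from the missingness mask.
#'
#' @param n_donors,n_proteins Table dimensions (defaults 200 x 50).
#' @param n_cases Case donors (default 60).
#' @param n_informative Proteins carrying case signal (default 5).
#' @param effect_size Case shift in SD units (default 3; 0 gives a null
#'   fixture).
#' @param missing_rate Background i.i.d. missingness (default 0.02).
#' @param donor_miss_threshold,protein_miss_threshold Thresholds the
#'   planted donor/protein are built to exceed (defaults 10 / 20).
#' @param rng_seed Integer seed.
#' @return List of class `proteome_fixture`: `table` (tibble with NAs),
#'   `labels` (tibble `donor_id`, `case`), `manifest`.
#' @export
make_proteome_fixture <- function(n_donors = 200, n_proteins = 50,
                                  n_cases = 60, n_informative = 5,
                                  effect_size = 3, missing_rate = 0.02,
                                  donor_miss_threshold = 10,
                                  protein_miss_threshold = 20,
                                  rng_seed = 1) {
  stopifnot(n_cases < n_donors, n_informative <= n_proteins,
            missing_rate >= 0, missing_rate < 1)
  donors <- node_ids(n_donors, "D")
  proteins <- node_ids(n_proteins, "P")
  out <- withr::with_seed(rng_seed, {
    cases <- sample(donors, n_cases)
    informative <- sample(proteins, n_informative)
    mu <- rnorm(n_proteins, mean = 10, sd = 2)
    X <- matrix(rnorm(n_donors * n_proteins), n_donors, n_proteins,
                dimnames = list(donors, proteins))
    X <- sweep(X, 2, mu, `+`)
    X[donors %in% cases, informative] <- X[donors %in% cases, informative] + effect_size

    mask <- matrix(runif(n_donors * n_proteins) < missing_rate,
                   n_donors, n_proteins)
    planted_donor <- donors[1]
    planted_protein <- setdiff(proteins, informative)[1]
    mask[1, sample(n_proteins, min(donor_miss_threshold + 5, n_proteins))] <- TRUE
    victim_rows <- sample(2:n_donors, min(protein_miss_threshold + 5, n_donors - 1))
    mask[victim_rows, match(planted_protein, proteins)] <- TRUE
    X[mask] <- NA_real_
    list(X = X, cases = cases, informative = informative, mask = mask,
         planted_donor = planted_donor, planted_protein = planted_protein)
  })
  # post-filter dimensions from mask arithmetic (independent of the filter
  # implementation): donors first, then proteins on the surviving donors
  keep_donor <- rowSums(out$mask) <= donor_miss_threshold
  keep_protein <- colSums(out$mask[keep_donor, , drop = FALSE]) <= protein_miss_threshold
  manifest <- list(
    generator = "proteome_fixture", rng_seed = rng_seed,
    parameters = list(n_donors = n_donors, n_proteins = n_proteins,
                      n_cases = n_cases, n_informative = n_informative,
                      effect_size = effect_size, missing_rate = missing_rate,
                      donor_miss_threshold = donor_miss_threshold,
                      protein_miss_threshold = protein_miss_threshold),
    informative_proteins = out$informative,
    planted_donor = out$planted_donor,
    planted_protein = out$planted_protein,
    expected_n_donors = sum(keep_donor),
    expected_n_proteins = sum(keep_protein),
    expected_donor_ids = donors[keep_donor],
    expected_protein_ids = proteins[keep_protein]
  )
  structure(
    list(table = matrix_to_proteome(out$X),
         labels = tibble::tibble(donor_id = donors,
                                 case = donors %in% out$cases),
         manifest = manifest),
    class = "proteome_fixture"
  )
}

#' Synthetic perturbation-signature fixture with planted structure
#'
#' Builds a gene-by-signature effect matrix over several cell lines with:
#' a correlated cell-line block sharing a latent factor at the disease-gene
#' rows (pairwise correlation about `rho`); transcription factors
#' downstream of designated disease receptors whose disease-gene effects
#' are inflated by `dg_inflation`; and metadata decoys for the filter path
#' (a non-exemplar column, a lower-TAS duplicate, an off-time column, and
#' an excluded cell line). A small directed pathway graph (receptor ->
#' intermediate -> TFs) and ligand-receptor pairs accompany the matrix.
#'
#' @param n_genes,n_dg Measured genes and disease genes (defaults 300 / 30).
#' @param cell_lines Cell-line ids (default `CL1`..`CL8`).
#' @param corr_block Subset of `cell_lines` sharing the latent factor
#'   (default the first 4); `NULL` or empty plants no correlation.
#' @param n_tfs TF perturbagens (default 12).
#' @param n_receptors,n_ligands Communicator pool composition (defaults
#'   30 / 20).
#' @param n_disease_receptors Receptors routed to the inflated TFs
#'   (default 3).
#' @param dg_inflation Multiplier on disease-gene rows of disease-TF
#'   signatures (default 3; 1 gives the null fixture).
#' @param rho Latent-factor variance share within the correlated block
#'   (default 0.6).
#' @param rng_seed Integer seed.
#' @return List of class `signature_fixture`: `signatures` (unfiltered
#'   `signature_matrix`), `pathway_graph` (edge tibble `from`, `to`),
#'   `lr_pairs`, `receptors`, `ligands`, `tfs`, `manifest`.
#' @export
make_signature_fixture <- function(n_genes = 300, n_dg = 30,
                                   cell_lines = paste0("CL", 1:8),
                                   corr_block = paste0("CL", 1:4),
                                   n_tfs = 12, n_receptors = 30,
                                   n_ligands = 20, n_disease_receptors = 3,
                                   dg_inflation = 3, rho = 0.55,
                                   rng_seed = 1) {
  stopifnot(all(corr_block %in% cell_lines), n_dg <= n_genes,
            n_disease_receptors < n_receptors, rho >= 0, rho < 1,
            dg_inflation > 0)
  genes <- node_ids(n_genes)
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  receptors <- sprintf("R%02d", seq_len(n_receptors))
  ligands <- sprintf("L%02d", seq_len(n_ligands))
  excluded_line <- "EXCL"
  ptypes <- c("OX", "KD")

  out <- withr::with_seed(rng_seed, {
    dg <- sample(genes, n_dg)
    disease_receptors <- receptors[seq_len(n_disease_receptors)]
    n_disease_tfs <- max(2L, n_tfs %/% 4L)
    disease_tfs <- tfs[seq_len(n_disease_tfs)]
    other_tfs <- setdiff(tfs, disease_tfs)

    graph_rows <- list()
    tf_sets <- list()
    for (r in receptors) {
      pool <- if (r %in% disease_receptors) disease_tfs else other_tfs
      tf_sets[[r]] <- sort(sample(pool, sample(2:min(3, length(pool)), 1)))
      mid <- paste0("X_", r)
      graph_rows[[r]] <- tibble::tibble(
        from = c(r, rep(mid, length(tf_sets[[r]]))),
        to = c(mid, tf_sets[[r]]))
    }
    pathway_graph <- dplyr::bind_rows(graph_rows)
    lr_pairs <- tibble::tibble(
      ligand = ligands,
      receptor = c(
        sample(disease_receptors, 2, replace = TRUE),          # disease ligands
        sample(setdiff(receptors, disease_receptors),
               n_ligands - 2, replace = TRUE)))
    disease_itcs <- c(disease_receptors, ligands[1:2])

    all_lines <- c(cell_lines, excluded_line)
    cols <- expand.grid(perturbagen = tfs, cell_line = all_lines,
                        ptype = ptypes, stringsAsFactors = FALSE)
    cols <- tibble::as_tibble(cols)
    cols$time <- "96 h"
    cols$exemplar <- TRUE
    cols$tas <- round(runif(nrow(cols), 0.3, 1), 4)

    V <- matrix(rnorm(n_genes * nrow(cols)), n_genes, nrow(cols),
                dimnames = list(genes, NULL))
    if (length(corr_block) >= 2 && rho > 0) {
      for (tf in tfs) {
        for (pt in ptypes) {
          z <- rnorm(n_dg)
          sel <- which(cols$perturbagen == tf & cols$ptype == pt &
                         cols$cell_line %in% corr_block)
          for (j in sel) {
            V[dg, j] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n_dg)
          }
        }
      }
    }
    if (dg_inflation != 1) {
      sel <- which(cols$perturbagen %in% disease_tfs)
      V[dg, sel] <- V[dg, sel] * dg_inflation
    }

    # metadata decoys for the filter path
    decoy_vals <- matrix(rnorm(n_genes * 3), n_genes, 3)
    decoys <- tibble::tibble(
      perturbagen = rep(tfs[1], 3), cell_line = rep(cell_lines[1], 3),
      ptype = rep("OX", 3),
      time = c("96 h", "96 h", "24 h"),
      exemplar = c(TRUE, FALSE, TRUE),
      tas = c(0.01, 0.99, 0.5))  # lower-TAS duplicate, non-exemplar, off-time
    cols <- dplyr::bind_rows(cols, decoys)
    V <- cbind(V, decoy_vals)
    cols$signature_id <- sprintf("SIG%04d", seq_len(nrow(cols)))
    colnames(V) <- cols$signature_id
    list(V = V, cols = cols, dg = dg, tf_sets = tf_sets,
         disease_receptors = disease_receptors, disease_tfs = disease_tfs,
         lr_pairs = lr_pairs, disease_itcs = disease_itcs,
         pathway_graph = pathway_graph)
  })

  meta <- out$cols[, c("signature_id", "cell_line", "perturbagen", "ptype",
                       "time", "exemplar", "tas")]
  sig <- signature_matrix(out$V, meta)

  # expected survivors of the default filter, from metadata arithmetic
  m <- meta[meta$exemplar & meta$time == "96 h" &
              meta$ptype %in% ptypes & meta$cell_line != excluded_line, ]
  m <- m[order(-m$tas), ]
  m <- m[!duplicated(m[, c("perturbagen", "cell_line", "ptype")]), ]

  manifest <- list(
    generator = "signature_fixture", rng_seed = rng_seed,
    parameters = list(n_genes = n_genes, n_dg = n_dg,
                      cell_lines = cell_lines, corr_block = corr_block,
                      n_tfs = n_tfs, n_receptors = n_receptors,
                      n_ligands = n_ligands,
                      n_disease_receptors = n_disease_receptors,
                      dg_inflation = dg_inflation, rho = rho),
    disease_genes = out$dg,
    disease_receptors = out$disease_receptors,
    disease_tfs = out$disease_tfs,
    disease_itcs = out$disease_itcs,
    itc_pool = c(receptors, ligands),
    receptor_tf_sets = out$tf_sets,
    corr_block = corr_block,
    excluded_cell_line = excluded_line,
    expected_surviving_columns = nrow(m)
  )
  structure(
    list(signatures = sig, pathway_graph = out$pathway_graph,
         lr_pairs = out$lr_pairs, receptors = receptors, ligands = ligands,
         tfs = tfs, manifest = manifest),
    class = "signature_fixture"
  )
}

#' Write a network fixture as a pipeline-ready input directory
#'
#' Emits `edges.tsv`, `itc_catalog.tsv`, `pathways.gmt`,
#' `disease_genes.gmt` and `fixture_manifest.json` in the formats the
#' pipeline reads, so tests exercise the real I/O paths.
#'
#' @param fixture A `network_fixture`.
#' @param dir Output directory (created if needed).
#' @param n_diseases Number of disease gene sets to emit; the first is the
#'   planted disease module, the rest are uniform random sets of the same
#'   size (default 6, giving the cross-disease distribution the selection
#'   step needs).
#' @param n_pathways,pathway_size Passed to [fixture_pathway_sets()].
#' @return Invisibly, the directory path.
#' @export
write_fixture_dir <- function(fixture, dir, n_diseases = 6, n_pathways = 20,
                              pathway_size = 8) {
  stopifnot(inherits(fixture, "network_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(fixture$edges, file.path(dir, "edges.tsv"))
  readr::write_tsv(fixture$itc_catalog, file.path(dir, "itc_catalog.tsv"))
  write_gmt(fixture_pathway_sets(fixture, n_pathways, pathway_size,
                                 rng_seed = fixture$manifest$rng_seed),
            file.path(dir, "pathways.gmt"))
  ids <- fixture$network$nodes$id
  dg0 <- fixture$manifest$disease_genes
  dgs <- withr::with_seed(fixture$manifest$rng_seed + 17, {
    sets <- c(list(disease_01 = dg0),
              lapply(seq_len(max(0, n_diseases - 1)), function(i) {
                sample(ids, length(dg0))
              }))
    names(sets) <- sprintf("disease_%02d", seq_along(sets))
    sets
  })
  write_gmt(dgs, file.path(dir, "disease_genes.gmt"))
  jsonlite::write_json(fixture$manifest, file.path(dir, "fixture_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
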