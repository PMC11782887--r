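# Shared helpers: tiny networks, file writers and independent oracles.
# Everything is generated in code; no stored fixtures.

options(itcrank.quiet = TRUE)

write_edge_tsv <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                            .local_envir = parent.frame())) {
  readr::write_tsv(df, path)
  path
}

# undirected edge tibble for an Erdos-Renyi-ish random graph, connected-ish
random_edges <- function(n = 50, p = 0.08, seed = 1) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    # tether isolated vertices so the walk matrix has no dangling columns
    iso <- which(igraph::degree(g) == 0)
    el <- igraph::as_edgelist(g)
    ids <- sprintf("N%03d", seq_len(n))
    out <- tibble::tibble(source = ids[el[, 1]], target = ids[el[, 2]])
    if (length(iso) > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        source = ids[iso], target = ids[(iso %% n) + 1]))
    }
    out$layer <- "ppi"
    out$directed <- FALSE
    out$provenance <- "test"
    out
  })
}

random_transition <- function(n = 50, p = 0.08, seed = 1,
                              dangling_policy = "uniform_jump") {
  column_normalize(assemble_network(random_edges(n, p, seed)), dangling_policy)
}

path_transition <- function(n = 5) {
  ids <- LETTERS[seq_len(n)]
  edges <- tibble::tibble(source = ids[-n], target = ids[-1],
                          layer = "ppi", directed = FALSE, provenance = "t")
  column_normalize(assemble_network(edges))
}

# independent stationary-solution oracle: dense solve written from scratch,
# no calls into the package's walk code
oracle_rwr <- function(W, seed_id, r) {
  Wd <- as.matrix(if (inherits(W, "transition_matrix")) W$W else W)
  ids <- colnames(Wd)
  e <- as.numeric(ids == seed_id)
  p <- solve(diag(length(ids)) - (1 - r) * Wd, r * e)
  setNames(p, ids)
}

# independent modified-Z oracle: direct transcription of the formula
oracle_modz <- function(x) {
  med <- median(x)
  mad0 <- median(abs(x - med))
  if (mad0 > 0) return(0.6745 * (x - med) / mad0)
  meanad <- mean(abs(x - med))
  if (meanad > 0) return(0.6745 * (x - med) / (1.2533 * meanad))
  rep(0, length(x))
}

# independent average-precision oracle: precision accumulated by explicit
# loop over distinct score cutoffs
oracle_auprc <- function(labels, scores) {
  labels <- as.logical(labels)
  cuts <- sort(unique(scores), decreasing = TRUE)
  total_pos <- sum(labels)
  ap <- 0
  prev_tp <- 0
  for (cut in cuts) {
    sel <- scores >= cut
    tp <- sum(labels[sel])
    prec <- tp / sum(sel)
    ap <- ap + (tp - prev_tp) * prec
    prev_tp <- tp
  }
  ap / total_pos
}

# independent reachability oracle: BFS transitive closure restricted to TFs
oracle_tf_closure <- function(edges, receptor, tfs) {
  adj <- split(edges$to, edges$from)
  seen <- character(0)
  frontier <- receptor
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(setdiff(intersect(seen, tfs), receptor))
}

# artificial walk profile with prescribed probabilities (for influence tests)
fake_profile <- function(p) {
  structure(list(seed_id = "S", p = p, iterations = 1L, converged = TRUE,
                 config = rwr_config()), class = "rwr_profile")
}
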