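#' Read a typed edge table
#'
#' Reads a tab-separated edge table with a header and at least `source` and
#' `target` columns. Optional `layer`, `directed` and `provenance` columns are
#' honoured; the `layer`/`directed` arguments, when given, override the file.
#' Rows with an empty source or target, or with an unknown layer tag, are
#' counted and skipped; duplicate (source, target, layer) triples collapse to
#' a single record.
#'
#' @param path Path to a TSV file with a header row.
#' @param layer Optional layer tag applied to every row: one of `"ppi"`,
#'   `"tf_target"`, `"mirna_target"`.
#' @param directed Optional logical applied to every row; by default
#'   regulatory layers (`tf_target`, `mirna_target`) are directed and `ppi`
#'   is not.
#' @return A tibble with columns `source`, `target`, `layer`, `directed`,
#'   `provenance` and attributes `n_skipped` (malformed rows) and
#'   `n_duplicates` (collapsed records).
#' @export
load_edge_table <- function(path, layer = NULL, directed = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("edge table file not found: %s", paste(path, collapse = ", ")))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(c("source", "target"), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("edge table is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  valid_layers <- c("ppi", "tf_target", "mirna_target")
  if (!is.null(layer)) {
    layer <- match.arg(layer, valid_layers)
    df$layer <- layer
  } else if (!"layer" %in% names(df)) {
    df$layer <- "ppi"
  }
  if (!is.null(directed)) {
    df$directed <- directed
  } else if ("directed" %in% names(df)) {
    df$directed <- tolower(trimws(df$directed)) %in% c("true", "t", "1", "yes")
  } else {
    df$directed <- df$layer %in% c("tf_target", "mirna_target")
  }
  if (!"provenance" %in% names(df)) df$provenance <- ""
  df$provenance <- dplyr::coalesce(df$provenance, "")

  bad <- is.na(df$source) | df$source == "" |
    is.na(df$target) | df$target == "" |
    is.na(df$layer) | !df$layer %in% valid_layers
  n_skipped <- sum(bad)
  if (n_skipped > 0) itc_log("skipped %d malformed edge row(s) in %s", n_skipped, path)
  df <- df[!bad, c("source", "target", "layer", "directed", "provenance")]

  n_before <- nrow(df)
  df <- dplyr::distinct(df, .data$source, .data$target, .data$layer, .keep_all = TRUE)
  n_dup <- n_before - nrow(df)
  if (n_dup > 0) itc_log("collapsed %d duplicate edge record(s)", n_dup)

  out <- tibble::as_tibble(df)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Assemble a heterogeneous molecular network from edge records
#'
#' Builds the node set as the union of edge endpoints and a sparse adjacency
#' matrix `A` with `A[i, j] > 0` iff an edge `j -> i` exists under the chosen
#' direction policy. Self-loops are removed (with a logged count). Under
#' `"undirected_all"` every layer is symmetrized; under `"as_declared"` edges
#' flagged directed (typically TF-target and miRNA-target regulation) keep
#' their direction and the rest are symmetrized. Multi-layer duplicates of
#' the same node pair count once; all edges carry weight 1.
#'
#' @param edges A tibble of edge records (as from [load_edge_table()]) or a
#'   list of such tibbles, which are concatenated.
#' @param direction_policy `"undirected_all"` (default) or `"as_declared"`.
#' @return An object of class `hetero_network`: a list with `nodes` (tibble
#'   of `id`, `kind`), `edges` (cleaned records), `adjacency` (sparse
#'   matrix), and `direction_policy`.
#' @export
assemble_network <- function(edges, direction_policy = c("undirected_all", "as_declared")) {
  direction_policy <- match.arg(direction_policy)
  if (is.data.frame(edges)) edges <- list(edges)
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) == 0) abort("cannot assemble a network from an empty edge union")

  n_loops <- sum(edges$source == edges$target)
  if (n_loops > 0) itc_log("removed %d self-loop(s)", n_loops)
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  if (nrow(edges) == 0) abort("no edges remain after self-loop removal")

  ids <- sort(unique(c(edges$source, edges$target)))
  n <- length(ids)
  mirna_ids <- unique(edges$source[edges$layer == "mirna_target"])
  kind <- ifelse(grepl("::", ids, fixed = TRUE), "complex",
                 ifelse(ids %in% mirna_ids, "mirna", "protein"))
  nodes <- tibble::tibble(id = ids, kind = kind)
  idx <- setNames(seq_len(n), ids)

  si <- idx[edges$source]
  ti <- idx[edges$target]
  if (direction_policy == "undirected_all") {
    und <- rep(TRUE, nrow(edges))
  } else {
    und <- !edges$directed
  }
  # pairs contributing both directions (symmetrized) and one direction
  from <- c(si, ti[und])
  to <- c(ti, si[und])
  key <- unique((as.numeric(from) - 1) * n + to)  # j -> i stored as A[to, from]
  from_u <- key %/% n + 1
  to_u <- key %% n
  wrap <- to_u == 0
  to_u[wrap] <- n
  from_u[wrap] <- from_u[wrap] - 1
  A <- Matrix::sparseMatrix(i = to_u, j = from_u, x = 1, dims = c(n, n),
                            dimnames = list(ids, ids))

  structure(
    list(nodes = nodes, edges = tibble::as_tibble(edges), adjacency = A,
         direction_policy = direction_policy, n_self_loops_removed = n_loops),
    class = "hetero_network"
  )
}

#' @export
print.hetero_network <- function(x, ...) {
  cat(sprintf("<hetero_network> %d nodes, %d stored edge entries (%s)\n",
              nrow(x$nodes), Matrix::nnzero(x$adjacency), x$direction_policy))
  invisible(x)
}

.col_normalize <- function(A, dangling_policy, n) {
  if (any(A@x < 0)) abort("adjacency has negative entries; cannot column-normalize")
  cs <- Matrix::colSums(A)
  nz <- cs > 0
  scale <- ifelse(nz, 1 / cs, 0)
  W <- A %*% Matrix::Diagonal(x = scale)
  dangling <- which(!nz)
  if (length(dangling) > 0) {
    if (dangling_policy == "uniform_jump") {
      fill <- Matrix::sparseMatrix(
        i = rep(seq_len(n), length(dangling)),
        j = rep(dangling, each = n),
        x = 1 / n, dims = c(n, n))
      W <- W + fill
    } else {
      fill <- Matrix::sparseMatrix(i = dangling, j = dangling, x = 1,
                                   dims = c(n, n))
      W <- W + fill
    }
  }
  W <- methods::as(W, "CsparseMatrix")
  dimnames(W) <- dimnames(A)
  err <- max(abs(Matrix::colSums(W) - 1))
  if (err > 1e-12) abort(sprintf("column normalization failed (max |colsum - 1| = %.3g)", err))
  list(W = W, n_dangling = length(dangling))
}

#' Column-normalize an adjacency matrix into a walk transition matrix
#'
#' Divides each column with nonzero out-mass by its sum; columns with no
#' out-edges (dangling nodes) are filled per policy: `"uniform_jump"` puts
#' `1/|V|` everywhere in the column, `"self_loop"` puts 1 on the diagonal.
#' Column sums are verified to 1e-12.
#'
#' @param x A `hetero_network` or a nonnegative (sparse) matrix with
#'   dimnames.
#' @param dangling_policy `"uniform_jump"` (default) or `"self_loop"`.
#' @return An object of class `transition_matrix`: list with the sparse
#'   column-stochastic matrix `W`, the `dangling_policy`, the number of
#'   dangling columns handled, and a checksum of the source adjacency.
#' @export
column_normalize <- function(x, dangling_policy = c("uniform_jump", "self_loop")) {
  dangling_policy <- match.arg(dangling_policy)
  if (inherits(x, "hetero_network")) {
    A <- x$adjacency
  } else if (inherits(x, "Matrix") || is.matrix(x)) {
    A <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
    if (is.null(dimnames(A)) || is.null(colnames(A))) {
      dimnames(A) <- list(as.character(seq_len(nrow(A))), as.character(seq_len(ncol(A))))
    }
  } else {
    abort("`x` must be a hetero_network or a matrix")
  }
  n <- ncol(A)
  res <- .col_normalize(A, dangling_policy, n)
  structure(
    list(W = res$W, dangling_policy = dangling_policy,
         n_dangling = res$n_dangling, source_network_hash = object_hash(A)),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d nodes, %d nonzeros, dangling policy '%s'\n",
              ncol(x$W), Matrix::nnzero(x$W), x$dangling_policy))
  invisible(x)
}

# resolve a transition_matrix or bare matrix into the stochastic matrix
as_walk_matrix <- function(W) {
  if (inherits(W, "transition_matrix")) return(W$W)
  if (inherits(W, "Matrix") || is.matrix(W)) return(W)
  abort("`W` must be a transition_matrix (see column_normalize())")
}

#' Export a network as an edge list with a JSON manifest
#'
#' @param network A `hetero_network`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
export_network <- function(network, dir) {
  stopifnot(inherits(network, "hetero_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(network$edges, file.path(dir, "edges.tsv"))
  readr::write_tsv(network$nodes, file.path(dir, "nodes.tsv"))
  manifest <- list(
    n_nodes = nrow(network$nodes),
    n_edges = nrow(network$edges),
    direction_policy = network$direction_policy,
    adjacency_checksum = object_hash(network$adjacency)
  )
  jsonlite::write_json(manifest, file.path(dir, "network_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
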