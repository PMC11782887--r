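#' Read gene sets from a GMT file
#'
#' Thin wrapper around `fgsea::gmtPathways()`; each line of a GMT file is a
#' set name, a description, and tab-separated member ids.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of member ids (duplicates
#'   within a set removed).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (second GMT column); recycled.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an inter-tissue communicator catalog
#'
#' Reads a TSV with columns `id` and `role` (one of `ligand`, `receptor`,
#' `both`). Ids must be unique.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `id` and `role`.
#' @export
read_itc_catalog <- function(path) {
  if (!file.exists(path)) abort(sprintf("ITC catalog not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(c("id", "role"), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("ITC catalog is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$id)) abort("ITC catalog ids must be unique")
  bad_role <- !df$role %in% c("ligand", "receptor", "both")
  if (any(bad_role)) {
    abort(sprintf("unknown ITC role(s): %s",
                  paste(unique(df$role[bad_role]), collapse = ", ")))
  }
  tibble::as_tibble(df[, c("id", "role")])
}
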