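# internal helpers shared across modules

# level-tagged progress messages; suppressible via options(itcrank.quiet = TRUE)
itc_log <- function(fmt, ...) {
  if (isTRUE(getOption("itcrank.quiet", FALSE))) return(invisible(NULL))
  inform(paste0("[itcrank] ", sprintf(fmt, ...)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort(sprintf("`%s` = %s is outside its allowed range", name, format(x)))
  }
  invisible(x)
}

# stratified assignment of k fold ids, balanced within each class
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# deterministic checksum of an R object (for manifests / provenance)
object_hash <- function(x) rlang::hash(x)
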