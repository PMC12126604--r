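# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local random seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so stochastic routines never leak global state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed derivation; stays inside 32-bit integer range
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# write a data.frame as deterministic TSV (used by run_pipeline and examples)
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
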