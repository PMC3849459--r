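#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames median ave
#' @importFrom graphics matplot legend
#' @importFrom utils head read.table write.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Diagnostic messages (skipped rows, probability floors) are emitted only when
# options(labrec.verbose = TRUE); counts are always attached as attributes.
labrec_log <- function(...) {
  if (isTRUE(getOption("labrec.verbose", FALSE))) message(...)
  invisible(NULL)
}
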