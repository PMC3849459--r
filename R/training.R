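#' Build the symmetric co-occurrence training matrix
#'
#' Counts, over a set of training cases, how often each pair of laboratory
#' tests is taken together: if a case contains `test_a` and `test_b`, one is
#' added to the (a, b) and (b, a) cells. Counts are case-level and binary —
#' a pair co-occurring within one case contributes exactly 1 regardless of
#' how many records produced it. The diagonal stores the marginal count (the
#' number of cases containing the test), so a single structure carries both
#' the joint and the marginal frequencies; all ranking probabilities are
#' ratios of these counts to the number of cases.
#'
#' Internally the matrix is the cross-product of a sparse case-by-test
#' incidence matrix, densified because test universes here are small.
#'
#' @param cs a [case_set()] of training cases.
#' @param universe optional test universe (character); defaults to
#'   `cs$universe`. Candidate tests at ranking time are drawn from this
#'   universe, so pass the full universe when the training split may miss
#'   some codes. Every code used by `cs` must be covered.
#' @return An object of class `training_matrix`: list with `universe`,
#'   `n_cases` and `joint` (an M-by-M symmetric integer matrix with the
#'   marginals on the diagonal, dimnames = universe).
#' @examples
#' cs <- case_set(list(v1 = c("A", "B"), v2 = c("A", "B"), v3 = c("A", "C"), v4 = "C"))
#' tm <- build_training_matrix(cs)
#' counts(tm, "A")       # cases containing A
#' counts(tm, "A", "B")  # cases containing both A and B
#' @export
build_training_matrix <- function(cs, universe = NULL) {
  stopifnot(inherits(cs, "case_set"))
  if (is.null(universe)) universe <- cs$universe
  universe <- sort(unique(as.character(universe)))
  outside <- setdiff(unique(unlist(cs$cases, use.names = FALSE)), universe)
  if (length(outside) > 0L)
    stop("case contains test(s) outside universe: ",
         paste(outside, collapse = ", "), call. = FALSE)
  M <- length(universe)
  n <- length(cs)
  codes <- unlist(cs$cases, use.names = FALSE)
  i <- rep.int(seq_len(n), lengths(cs$cases))
  j <- match(codes, universe)
  inc <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, M))
  joint <- as.matrix(Matrix::crossprod(inc))
  storage.mode(joint) <- "integer"
  dimnames(joint) <- list(universe, universe)
  structure(list(universe = universe, n_cases = n, joint = joint),
            class = "training_matrix")
}

#' Look up training counts
#'
#' @param tm a [build_training_matrix()] result.
#' @param i test code; with `j` absent, returns the marginal count of `i`.
#' @param j optional second test code; returns the joint count of `i` and `j`.
#' @return A non-negative integer count.
#' @export
counts <- function(tm, i, j = NULL) {
  stopifnot(inherits(tm, "training_matrix"))
  for (code in c(i, j)) {
    if (!code %in% tm$universe)
      stop("unknown test code: ", code, call. = FALSE)
  }
  if (is.null(j)) tm$joint[i, i] else tm$joint[i, j]
}

#' @export
print.training_matrix <- function(x, ...) {
  cat(sprintf("<training_matrix> %d test(s), %d training case(s)\n",
              length(x$universe), x$n_cases))
  invisible(x)
}

#' Serialize a training matrix as plain text
#'
#' Line 1 holds M and the number of training cases, line 2 the tab-separated
#' test codes, then M lines of tab-separated integer counts (full symmetric
#' matrix, marginals on the diagonal). The round trip through
#' [read_training_matrix()] is bit-exact, so evaluation can run off this
#' sidecar instead of re-reading the raw records.
#'
#' @param tm a `training_matrix`.
#' @param file path to write to / read from.
#' @return `write_training_matrix()` returns `file` invisibly;
#'   `read_training_matrix()` returns the `training_matrix`.
#' @export
write_training_matrix <- function(tm, file) {
  stopifnot(inherits(tm, "training_matrix"))
  lines <- c(
    paste(length(tm$universe), tm$n_cases, sep = "\t"),
    paste(tm$universe, collapse = "\t"),
    apply(tm$joint, 1L, paste, collapse = "\t")
  )
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_training_matrix
#' @export
read_training_matrix <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) < 2L) stop("malformed training-matrix file", call. = FALSE)
  hdr <- as.integer(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop("malformed training-matrix header", call. = FALSE)
  M <- hdr[1L]; n <- hdr[2L]
  universe <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (length(universe) != M || length(lines) != 2L + M)
    stop("malformed training-matrix body", call. = FALSE)
  joint <- do.call(rbind, lapply(lines[-(1:2)], function(l)
    as.integer(strsplit(l, "\t", fixed = TRUE)[[1L]])))
  if (!is.matrix(joint) || ncol(joint) != M || anyNA(joint))
    stop("malformed training-matrix counts", call. = FALSE)
  dimnames(joint) <- list(universe, universe)
  structure(list(universe = universe, n_cases = n, joint = joint),
            class = "training_matrix")
}
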