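#' Weighting configuration
#'
#' Bundles everything that shapes the log-odds weight of a candidate test:
#' the smoothing configuration, the algebraic form of the score
#' (`evidence_mode`), and the epsilon floor applied inside logarithms.
#'
#' Two forms of the score are provided. `"exact"` is the posterior log-odds
#' of the candidate being taken, derived without approximation from the
#' naive-Bayes classifier over the case's taken tests: a prior term
#' `log((alpha + theta) / (1 - alpha + theta))` plus, per taken test,
#' `log(beta (1 - alpha) / (gamma - alpha beta))`. `"literal"` is the widely
#' quoted simplified form `(k - 1) log((1 - alpha) / alpha) +
#' sum log(beta / (gamma - beta))`, whose prior coefficient and denominator
#' differ from the exact derivation; its denominator goes negative precisely
#' for positively associated test pairs, which the epsilon floor absorbs.
#' Both produce a full ranking; only `"exact"` is guaranteed to equal the
#' brute-force Bayesian posterior odds.
#'
#' @param smoothing a [smoothing_config()]; default Jelinek-Mercer with
#'   `lambda = 0.2` and `theta = 0.5`, the usual sweet spot on co-occurrence
#'   data of this kind.
#' @param evidence_mode `"exact"` (default) or `"literal"`.
#' @param epsilon positive floor applied to log numerators/denominators so
#'   every weight is finite; default `1e-12`. Floor events are counted on the
#'   returned ranking and reported when `options(labrec.verbose = TRUE)`.
#' @return An object of class `weight_config`.
#' @export
weight_config <- function(smoothing = smoothing_config("jelinek_mercer", 0.2, 0.5),
                          evidence_mode = c("exact", "literal"),
                          epsilon = 1e-12) {
  stopifnot(inherits(smoothing, "smoothing_config"))
  evidence_mode <- match.arg(evidence_mode)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon <= 0)
    stop("`epsilon` must be a single positive value", call. = FALSE)
  structure(list(smoothing = smoothing, evidence_mode = evidence_mode,
                 epsilon = epsilon),
            class = "weight_config")
}

#' @export
print.weight_config <- function(x, ...) {
  cat(sprintf("<weight_config> mode = %s, smoothing = %s (param %g, theta %g), epsilon = %g\n",
              x$evidence_mode, x$smoothing$method, x$smoothing$param,
              x$smoothing$theta, x$epsilon))
  invisible(x)
}

#' Count-ratio probability estimates
#'
#' The three probabilities behind the weight, each a ratio of training
#' counts: `estimate_alpha()` is the prior probability of the candidate test
#' (cases containing it over all cases); `estimate_gamma()` is the same
#' marginal for a taken test; `estimate_beta()` is the conditional
#' probability of a taken test given the candidate (their joint count over
#' the candidate's marginal count).
#'
#' @param tm a [build_training_matrix()] result with `n_cases > 0`.
#' @param test0 candidate (conditioning) test code.
#' @param testi taken test code.
#' @return A probability in `[0, 1]`.
#' @export
estimate_alpha <- function(tm, test0) {
  counts(tm, test0) / positive_n(tm)
}

#' @rdname estimate_alpha
#' @export
estimate_gamma <- function(tm, testi) {
  counts(tm, testi) / positive_n(tm)
}

#' @rdname estimate_alpha
#' @export
estimate_beta <- function(tm, testi, test0) {
  base <- counts(tm, test0)
  if (base == 0L)
    stop("conditioning test ", test0,
         " unseen in training; smooth or skip", call. = FALSE)
  counts(tm, testi, test0) / base
}

positive_n <- function(tm) {
  stopifnot(inherits(tm, "training_matrix"))
  if (tm$n_cases <= 0L) stop("training matrix has no cases", call. = FALSE)
  tm$n_cases
}

#' Prior term of the literal weight form
#'
#' `(k - 1) * log((1 - alpha + theta) / (alpha + theta))`: minus `(k - 1)`
#' times the Laplace-smoothed log-odds ([smooth_log_odds_laplace()]), where
#' `k` is the number of tests the case has taken. This is the prior term of
#' the literal (simplified) weight form; the exact form uses the smoothed
#' log-odds itself with coefficient +1.
#'
#' @param alpha prior probability of the candidate test (vectorized).
#' @param theta Laplace parameter in `[0, 1]`; `theta = 0` requires
#'   `0 < alpha < 1`.
#' @param k number of taken tests (non-negative integer).
#' @return Natural-log prior term; 0 whenever `k = 1`.
#' @export
prior_term <- function(alpha, theta, k) {
  stopifnot(k >= 0)
  -(k - 1) * smooth_log_odds_laplace(alpha, theta)
}

#' Per-test evidence term of the weight
#'
#' The contribution of one taken test to the candidate's log-odds.
#' `"exact"` mode returns `log(beta (1 - alpha) / (gamma - beta alpha))` —
#' the log ratio of the probability of the taken test under "candidate
#' taken" vs "candidate not taken"; `"literal"` mode returns
#' `log(beta / (gamma - beta))` as in the simplified weight form. Any
#' non-positive numerator or denominator is floored at `epsilon` before the
#' log, so the result is always finite; floor events are counted in the
#' `"n_floored"` attribute.
#'
#' @param beta conditional probability of the taken test given the candidate
#'   (already smoothed, see [apply_smoothing()]); vectorized.
#' @param gamma marginal probability of the taken test.
#' @param alpha prior probability of the candidate; required in exact mode.
#' @param mode `"exact"` or `"literal"`.
#' @param epsilon positive floor.
#' @return Numeric vector of log terms with attribute `n_floored`.
#' @export
evidence_term <- function(beta, gamma, alpha = NULL,
                          mode = c("exact", "literal"), epsilon = 1e-12) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    if (is.null(alpha)) stop("exact mode needs `alpha`", call. = FALSE)
    num <- beta * (1 - alpha)
    den <- gamma - beta * alpha
  } else {
    num <- beta
    den <- gamma - beta
  }
  n_floored <- sum(num < epsilon) + sum(den < epsilon)
  if (n_floored > 0L)
    labrec_log("evidence term floored at epsilon in ", n_floored, " place(s)")
  out <- log(pmax(num, epsilon)) - log(pmax(den, epsilon))
  attr(out, "n_floored") <- n_floored
  out
}

# Weights of every candidate test for one case, vectorized over candidates.
# Returns a named numeric vector (candidates in universe order) with
# attributes n_floored and skipped_tests.
case_weights <- function(taken, tm, config) {
  stopifnot(inherits(tm, "training_matrix"), inherits(config, "weight_config"))
  n <- positive_n(tm)
  universe <- tm$universe
  taken <- unique(as.character(taken))
  unknown <- setdiff(taken, universe)
  if (length(unknown) > 0L)
    stop("taken test(s) outside universe: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cand <- setdiff(universe, taken)
  if (length(cand) == 0L)
    stop("no candidate tests: case already contains the whole universe",
         call. = FALSE)
  k <- length(taken)
  marg <- diag(tm$joint)
  theta <- config$smoothing$theta
  eps <- config$epsilon

  alpha <- marg[cand] / n
  prior <- if (config$evidence_mode == "exact")
    smooth_log_odds_laplace(alpha, theta)
  else
    prior_term(alpha, theta, k)

  gamma_t <- marg[taken] / n
  skipped <- taken[gamma_t == 0]
  if (length(skipped) > 0L)
    labrec_log("taken test(s) unseen in training skipped: ",
               paste(skipped, collapse = ", "))
  use <- taken[gamma_t > 0]
  n_floored <- 0L
  evidence <- numeric(length(cand))
  if (length(use) > 0L) {
    J <- tm$joint[use, cand, drop = FALSE]
    base <- matrix(marg[cand], nrow = length(use), ncol = length(cand),
                   byrow = TRUE)
    G <- matrix(marg[use] / n, nrow = length(use), ncol = length(cand))
    beta_raw <- J / pmax(base, 1L)  # joint <= marginal, so base 0 => joint 0
    beta_s <- apply_smoothing(config$smoothing, beta_raw, G,
                              joint_count = J, base_count = base)
    terms <- evidence_term(beta_s, G,
                           alpha = matrix(alpha, nrow = length(use),
                                          ncol = length(cand), byrow = TRUE),
                           mode = config$evidence_mode, epsilon = eps)
    n_floored <- attr(terms, "n_floored")
    evidence <- colSums(matrix(terms, nrow = length(use)))
  }
  w <- prior + evidence
  names(w) <- cand
  attr(w, "n_floored") <- n_floored
  attr(w, "skipped_tests") <- skipped
  w
}

#' Weight of one candidate test for a case
#'
#' The log-odds score of `test0` being taken by a case that has already
#' taken `taken`, under the configured form and smoothing. Higher is a
#' stronger recommendation.
#'
#' @param test0 candidate test code; must not be among `taken`.
#' @param taken character vector of the case's taken test codes (or a
#'   single-case [case_set()] element).
#' @param tm a [build_training_matrix()] result.
#' @param config a [weight_config()].
#' @return A single finite numeric weight.
#' @examples
#' cs <- case_set(list(v1 = c("A", "B"), v2 = c("A", "B"), v3 = c("A", "C"), v4 = "C"))
#' tm <- build_training_matrix(cs)
#' cfg <- weight_config(smoothing_config("none", theta = 0), "exact")
#' test_weight("B", "A", tm, cfg)  # log 2: B co-occurs with A in half the A-cases
#' @export
test_weight <- function(test0, taken, tm, config = weight_config()) {
  taken <- unique(as.character(taken))
  if (test0 %in% taken)
    stop("candidate ", test0, " already taken by this case", call. = FALSE)
  if (!test0 %in% tm$universe)
    stop("unknown test code: ", test0, call. = FALSE)
  w <- case_weights(taken, tm, config)
  unname(w[[test0]])
}

#' Rank all candidate tests for a case
#'
#' Scores every test in the training universe not already taken by the case
#' and returns them sorted by weight, descending; exact ties are broken by
#' test code, ascending, so the ranking is fully deterministic.
#'
#' @param taken character vector of taken test codes.
#' @param tm a [build_training_matrix()] result.
#' @param config a [weight_config()].
#' @param case_id identifier carried into the output.
#' @return A data frame of class `recommendation` with columns `case_id`,
#'   `rank`, `test_code`, `weight`, and attributes `n_floored` and
#'   `skipped_tests`.
#' @examples
#' cs <- case_set(list(v1 = c("A", "B"), v2 = c("A", "B"), v3 = c("A", "C"), v4 = "C"))
#' tm <- build_training_matrix(cs)
#' cfg <- weight_config(smoothing_config("none", theta = 0), "exact")
#' rank_candidates("A", tm, cfg)   # B above C
#' @export
rank_candidates <- function(taken, tm, config = weight_config(),
                            case_id = "case") {
  w <- case_weights(taken, tm, config)
  ord <- order(-w, names(w), method = "radix")
  out <- data.frame(
    case_id = case_id,
    rank = seq_along(w),
    test_code = names(w)[ord],
    weight = unname(w[ord]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("recommendation", "data.frame")
  attr(out, "n_floored") <- attr(w, "n_floored")
  attr(out, "skipped_tests") <- attr(w, "skipped_tests")
  out
}

#' Write rankings as TSV
#'
#' Columns `case_id`, `rank`, `test_code`, `weight` (6 decimals). Several
#' recommendations may be concatenated with `rbind()` first.
#'
#' @param rec a `recommendation` data frame (or rbind of several).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_recommendations <- function(rec, file) {
  stopifnot(is.data.frame(rec),
            all(c("case_id", "rank", "test_code", "weight") %in% names(rec)))
  out <- rec[, c("case_id", "rank", "test_code", "weight")]
  out$weight <- sprintf("%.6f", out$weight)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
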