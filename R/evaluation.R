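#' Split cases into training and validation sets
#'
#' Random, seeded partition of a [case_set()]. The split is performed on
#' patients, never on cases, so with visit-level cases all visits of one
#' patient land on the same side. The training side is sized as close as
#' possible to `round(train_fraction * N)` cases (exactly that when every
#' patient contributes one case): patients are shuffled under the seed and
#' the cut point minimizing the distance to the target size is taken.
#'
#' @param cs a [case_set()] with at least 2 cases.
#' @param train_fraction fraction of cases for training, in (0, 1).
#' @param seed integer seed; the same seed always yields the same partition.
#' @return List with elements `train` and `validation`, both `case_set`s
#'   sharing the universe of `cs`.
#' @export
split_cases <- function(cs, train_fraction, seed) {
  stopifnot(inherits(cs, "case_set"))
  if (length(cs) < 2L) stop("need at least 2 cases to split", call. = FALSE)
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      is.na(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  target <- round(train_fraction * length(cs))
  patients <- unique(cs$patient_id)
  shuffled <- with_seed(seed, sample(patients))
  sizes <- table(cs$patient_id)[shuffled]
  cum <- cumsum(as.integer(sizes))
  # cut after the prefix of patients whose case count is closest to target
  cut <- which.min(abs(cum - target))
  if (cum[cut] == length(cs)) cut <- cut - 1L   # keep validation non-empty
  if (cut < 1L) cut <- 1L
  train_patients <- shuffled[seq_len(cut)]
  in_train <- cs$patient_id %in% train_patients
  list(train = cs[in_train], validation = cs[!in_train])
}

#' Remove one test per case as the evaluation label
#'
#' For each validation case with at least two tests, one test is chosen
#' uniformly at random (under the seed) as the *golden standard* label; the
#' remaining tests form the validation input the ranking must work from.
#' Cases with fewer than two tests are excluded — removal would leave no
#' evidence — and counted.
#'
#' @param cs a [case_set()] of validation cases.
#' @param seed integer seed.
#' @return List with `inputs` (a `case_set` of the reduced cases), `labels`
#'   (named character vector of removed test codes, aligned with `inputs`),
#'   and `n_excluded`.
#' @export
remove_labels <- function(cs, seed) {
  stopifnot(inherits(cs, "case_set"))
  k <- case_sizes(cs)
  keep <- k >= 2L
  n_excluded <- sum(!keep)
  if (!any(keep))
    stop("no validation case has 2 or more tests", call. = FALSE)
  kept <- cs[keep]
  picks <- with_seed(seed,
    vapply(kept$cases, function(tests) sample(tests, 1L), ""))
  inputs <- kept
  inputs$cases <- Map(setdiff, kept$cases, picks)
  list(inputs = inputs, labels = picks, n_excluded = n_excluded)
}

#' Top-X hit rate of a set of rankings (CorrectRate_X)
#'
#' The fraction of validation cases whose golden-standard test appears among
#' the first `X` entries of the system's ranked list. Since the top 3
#' positions contain the top 1, `correct_rate(r, l, 1) <= correct_rate(r, l, 3)`
#' always.
#'
#' @param rankings list of rankings, one per case: either character vectors
#'   of test codes in rank order or `recommendation` data frames from
#'   [rank_candidates()].
#' @param labels character vector of golden-standard test codes, aligned
#'   with `rankings`.
#' @param X number of top positions compared to the label (`X >= 1`).
#' @return The hit rate, a value in `[0, 1]`.
#' @examples
#' r <- list(c("A", "B"), c("B", "A"))
#' correct_rate(r, c("A", "A"), X = 1)  # 0.5
#' correct_rate(r, c("A", "A"), X = 2)  # 1
#' @export
correct_rate <- function(rankings, labels, X) {
  stopifnot(is.list(rankings), X >= 1)
  if (length(rankings) != length(labels))
    stop("rankings and labels differ in length", call. = FALSE)
  if (length(rankings) == 0L) stop("no rankings to score", call. = FALSE)
  hit <- mapply(function(r, lab) {
    codes <- if (is.data.frame(r)) r$test_code else as.character(r)
    lab %in% head(codes, X)
  }, rankings, labels)
  mean(hit)
}

#' Run the full split / remove-label / rank / score experiment
#'
#' One end-to-end evaluation round: the cases are split by patient into
#' training and validation sides, one test per validation case is removed as
#' its label, the co-occurrence matrix is built from the training side over
#' the full universe, every validation input is ranked, and the top-X hit
#' rates are computed. Candidates are always the universe minus the input's
#' taken tests, so the removed test is always a candidate. Fully reproducible
#' from the two seeds.
#'
#' @param cs a [case_set()].
#' @param config a [weight_config()].
#' @param train_fraction fraction of cases used for training (default 0.6).
#' @param split_seed,label_seed integer seeds for the partition and the label
#'   choice, separately reproducible.
#' @param X integer vector of top-list depths to score (default `c(1, 3)`).
#' @return An object of class `eval_result`: list with `correct_rate` (named
#'   numeric, one entry per `X`), `per_case` (data frame: `case_id`, `label`,
#'   `k_input`, `rank_of_label`, and a `top_X` 0/1 column per `X`), `n`,
#'   `n_excluded`, `n_train`, and the configuration used.
#' @examples
#' sim <- generate_cases(synthetic_config(n_cases = 80, seed = 42))
#' run_experiment(sim$cases, weight_config(), split_seed = 1, label_seed = 2)
#' @export
run_experiment <- function(cs, config = weight_config(), train_fraction = 0.6,
                           split_seed, label_seed, X = c(1L, 3L)) {
  stopifnot(inherits(cs, "case_set"), all(X >= 1))
  halves <- split_cases(cs, train_fraction, split_seed)
  if (length(halves$train) == 0L || length(halves$validation) == 0L)
    stop("experiment stage split: a side is empty", call. = FALSE)
  pairs <- remove_labels(halves$validation, label_seed)
  tm <- build_training_matrix(halves$train, universe = cs$universe)

  ids <- names(pairs$inputs$cases)
  rank_of_label <- vapply(seq_along(ids), function(j) {
    rec <- rank_candidates(pairs$inputs$cases[[j]], tm, config,
                           case_id = ids[j])
    match(pairs$labels[[j]], rec$test_code)
  }, integer(1))

  per_case <- data.frame(
    case_id = ids,
    label = unname(pairs$labels),
    k_input = unname(case_sizes(pairs$inputs)),
    rank_of_label = rank_of_label,
    stringsAsFactors = FALSE
  )
  cr <- setNames(numeric(length(X)), as.character(X))
  for (x in X) {
    per_case[[paste0("top_", x)]] <- as.integer(rank_of_label <= x)
    cr[[as.character(x)]] <- mean(rank_of_label <= x)
  }
  structure(
    list(correct_rate = cr, per_case = per_case, n = length(ids),
         n_excluded = pairs$n_excluded, n_train = length(halves$train),
         train_fraction = train_fraction, config = config,
         seeds = c(split = split_seed, label = label_seed)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d validation case(s) (%d excluded), %d training case(s)\n",
              x$n, x$n_excluded, x$n_train))
  for (nm in names(x$correct_rate))
    cat(sprintf("  CorrectRate_%s = %.4f\n", nm, x$correct_rate[[nm]]))
  invisible(x)
}

#' Sweep a smoothing parameter over a grid
#'
#' Re-runs [run_experiment()] once per grid value of the chosen smoother's
#' parameter, holding the seeds (hence the split and the labels) fixed so
#' that only the parameter varies across rows.
#'
#' @param cs a [case_set()].
#' @param method beta smoother to sweep (see [smoothing_config()]).
#' @param grid numeric vector of parameter values in `[0, 1]`.
#' @param theta Laplace parameter held fixed.
#' @param evidence_mode passed to [weight_config()].
#' @param train_fraction,split_seed,label_seed,X as in [run_experiment()].
#' @return A data frame of class `sweep_result` with columns `method`,
#'   `param`, `correct_rate_1`, `correct_rate_3`, ... (one column per `X`).
#' @export
parameter_sweep <- function(cs, method, grid, theta = 0.5,
                            evidence_mode = "exact", train_fraction = 0.6,
                            split_seed, label_seed, X = c(1L, 3L)) {
  stopifnot(all(grid >= 0 & grid <= 1))
  rows <- lapply(grid, function(p) {
    cfg <- weight_config(smoothing_config(method, p, theta), evidence_mode)
    res <- run_experiment(cs, cfg, train_fraction, split_seed, label_seed, X)
    out <- data.frame(method = method, param = p, stringsAsFactors = FALSE)
    for (x in X) out[[paste0("correct_rate_", x)]] <- res$correct_rate[[as.character(x)]]
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @export
plot.sweep_result <- function(x, ...) {
  crs <- grep("^correct_rate_", names(x), value = TRUE)
  graphics::matplot(x$param, as.matrix(x[crs]), type = "b",
                    pch = seq_along(crs), lty = 1,
                    xlab = sprintf("%s parameter", x$method[1L]),
                    ylab = "CorrectRate", ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = sub("correct_rate_", "X = ", crs),
                   pch = seq_along(crs), lty = 1, col = seq_along(crs))
  invisible(x)
}

#' Write evaluation outputs as TSV
#'
#' `write_metrics()` emits one row per scored depth: `X`, `correct_rate`,
#' `n`, `excluded_count`. `write_per_case()` emits the per-case table.
#'
#' @param res an [run_experiment()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_metrics <- function(res, file) {
  stopifnot(inherits(res, "eval_result"))
  out <- data.frame(
    X = names(res$correct_rate),
    correct_rate = sprintf("%.6f", res$correct_rate),
    n = res$n,
    excluded_count = res$n_excluded,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_metrics
#' @export
write_per_case <- function(res, file) {
  stopifnot(inherits(res, "eval_result"))
  utils::write.table(res$per_case, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
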