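#' Configuration of the synthetic patient-visit generator
#'
#' The generator emulates the structure that makes laboratory-test
#' recommendation possible at all: tests that are ordered together because a
#' latent *condition* couples them (the classic example being an HbA1c and a
#' fasting-glucose test both ordered on suspicion of diabetes). Each
#' condition owns a disjoint *panel* of tests. Per visit, each condition is
#' present independently with `p_condition`; each test of a present
#' condition's panel is ordered with `p_panel_test`; every other test is
#' ordered independently with `noise_rate`. Setting `n_conditions = 0`
#' yields pure-noise (independence) data, the calibration baseline.
#'
#' @param n_cases number of visits to generate (default 500).
#' @param M number of tests in the universe (default 20).
#' @param n_conditions number of latent conditions (default 4).
#' @param panel_size tests per condition panel (default 5);
#'   `n_conditions * panel_size <= M`.
#' @param p_condition probability a visit carries each condition (default 0.5).
#' @param p_panel_test probability a panel test fires given its condition
#'   (default 0.9).
#' @param noise_rate independent firing probability of all other tests
#'   (default 0.02).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 500, M = 20, n_conditions = 4,
                             panel_size = 5, p_condition = 0.5,
                             p_panel_test = 0.9, noise_rate = 0.02,
                             seed = 1) {
  stopifnot(n_cases >= 1, M >= 1, n_conditions >= 0, panel_size >= 1)
  if (n_conditions * panel_size > M)
    stop("panels must fit in the universe: n_conditions * panel_size <= M",
         call. = FALSE)
  for (p in c(p_condition, p_panel_test, noise_rate))
    stopifnot(is.numeric(p), length(p) == 1L, !is.na(p), p >= 0, p <= 1)
  structure(list(n_cases = as.integer(n_cases), M = as.integer(M),
                 n_conditions = as.integer(n_conditions),
                 panel_size = as.integer(panel_size),
                 p_condition = p_condition, p_panel_test = p_panel_test,
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate synthetic patient cases
#'
#' Draws `n_cases` visits under the latent-condition model of
#' [synthetic_config()]. Test codes are `T001 ... T<M>` (zero-padded so the
#' lexicographic universe order matches the numeric one); panel `c` owns the
#' `panel_size` consecutive codes starting at `(c-1) * panel_size + 1`.
#' Visits with zero tests are redrawn (a case without tests carries no
#' information), within a bounded retry budget.
#'
#' @param config a [synthetic_config()].
#' @param max_retries redraw rounds allowed for empty visits (default 100).
#' @return List with `cases` (a [case_set()], one visit per synthetic
#'   patient), `ground_truth` (logical `n_cases x n_conditions` matrix of
#'   condition assignments) and `panels` (list of panel code vectors).
#' @examples
#' sim <- generate_cases(synthetic_config(n_cases = 5, seed = 7))
#' sim$cases
#' @export
generate_cases <- function(config, max_retries = 100L) {
  stopifnot(inherits(config, "synthetic_config"))
  codes <- sprintf("T%03d", seq_len(config$M))
  panels <- if (config$n_conditions > 0)
    split(codes[seq_len(config$n_conditions * config$panel_size)],
          rep(seq_len(config$n_conditions), each = config$panel_size))
  else list()

  with_seed(config$seed, {
    n <- config$n_cases
    Z <- matrix(runif(n * config$n_conditions) < config$p_condition,
                nrow = n)
    draw <- function(rows) {
      # per-test firing probability for each requested visit
      prob <- matrix(config$noise_rate, nrow = length(rows), ncol = config$M)
      for (c_idx in seq_len(config$n_conditions)) {
        on <- Z[rows, c_idx]
        cols <- (c_idx - 1L) * config$panel_size + seq_len(config$panel_size)
        prob[on, cols] <- config$p_panel_test
      }
      matrix(runif(length(rows) * config$M), nrow = length(rows)) < prob
    }
    occ <- draw(seq_len(n))
    tries <- 0L
    repeat {
      empty <- which(rowSums(occ) == 0L)
      if (length(empty) == 0L) break
      tries <- tries + 1L
      if (tries > max_retries)
        stop("generation error: retry budget exhausted while resampling ",
             "empty visits (degenerate configuration?)", call. = FALSE)
      occ[empty, ] <- draw(empty)
    }
    ids <- sprintf("P%04d", seq_len(n))
    tests <- lapply(seq_len(n), function(r) codes[occ[r, ]])
    names(tests) <- ids
    list(
      cases = case_set(tests, patient_id = ids, universe = codes,
                       unit = "visit"),
      ground_truth = Z,
      panels = panels
    )
  })
}

#' Hit rate of a uniformly random ranking
#'
#' The probability that a uniformly random ordering of the `M - k` candidate
#' tests places the single true label within the top `X`: `X / (M - k)`.
#' Used as the uninformative baseline against which rankings are calibrated.
#'
#' @param M universe size.
#' @param k number of taken tests in the validation input (`k < M`).
#' @param X top-list depth, `1 <= X <= M - k`.
#' @return A probability.
#' @export
random_baseline <- function(M, k, X) {
  stopifnot(k < M, X >= 1)
  if (X > M - k)
    stop("X exceeds the number of candidates (M - k)", call. = FALSE)
  X / (M - k)
}

#' Write cases as a raw laboratory-record CSV
#'
#' Emits one row per (case, test) in the standard thirteen-column laboratory
#' export layout (SDTE, REQ#, PNUM, PNAM, PSEX, BDTE, TSEQ, TEST, DESC,
#' RSLT, NORM, REXP, EXRS), with only the service date, patient number and
#' test code filled, so synthetic data flows through [read_lab_records()]
#' exactly like real exports. Each case becomes one visit on its own date.
#'
#' @param cs a [case_set()].
#' @param file output path.
#' @param start_date service date of the first case; subsequent cases of the
#'   same patient advance by one day.
#' @return `file`, invisibly.
#' @export
write_lab_records <- function(cs, file, start_date = as.Date("2024-01-01")) {
  stopifnot(inherits(cs, "case_set"))
  visit_no <- stats::ave(seq_along(cs$patient_id), cs$patient_id,
                         FUN = seq_along)
  dates <- format(start_date + visit_no - 1L)
  k <- case_sizes(cs)
  df <- data.frame(
    SDTE = rep(dates, k),
    `REQ#` = "",
    PNUM = rep(cs$patient_id, k),
    PNAM = "", PSEX = "", BDTE = "",
    TSEQ = unlist(lapply(k, seq_len), use.names = FALSE),
    TEST = unlist(cs$cases, use.names = FALSE),
    DESC = "", RSLT = "", NORM = "", REXP = "", EXRS = "",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}
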