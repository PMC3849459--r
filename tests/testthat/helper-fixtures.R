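# Shared fixtures and independent oracles. Everything here is deliberately
# naive (loops, products of probabilities) so it cannot share a defect with
# the vectorized implementation it checks.

# Four-case fixture used throughout: marginals A=3 B=2 C=2, joints AB=2,
# AC=1, BC=0.
fixture_cases <- function() {
  case_set(list(v1 = c("A", "B"), v2 = c("A", "B"), v3 = c("A", "C"),
                v4 = "C"))
}

# Brute-force posterior log-odds of "candidate taken" vs "not taken" for one
# case, from the Bayesian classifier: prior odds times, per taken test, the
# ratio of its conditional probability under each class. All probabilities
# are plain count ratios read off the training matrix.
oracle_log_odds <- function(test0, taken, tm) {
  n <- tm$n_cases
  a <- tm$joint[test0, test0] / n
  num <- a
  den <- 1 - a
  for (ti in taken) {
    b <- tm$joint[ti, test0] / tm$joint[test0, test0]
    g <- tm$joint[ti, ti] / n
    num <- num * b
    den <- den * (g - a * b) / (1 - a)
  }
  log(num / den)
}

# TRUE when no epsilon floor can trigger for any candidate of `taken`:
# candidate seen but not universal, every (taken, candidate) pair seen, and
# no taken test fully contained in a candidate's cases.
floor_free <- function(taken, tm) {
  n <- tm$n_cases
  cand <- setdiff(tm$universe, taken)
  for (t0 in cand) {
    m0 <- tm$joint[t0, t0]
    if (m0 == 0 || m0 == n) return(FALSE)
    for (ti in taken) {
      if (tm$joint[ti, t0] == 0) return(FALSE)
      if (tm$joint[ti, ti] <= tm$joint[ti, t0]) return(FALSE)
    }
  }
  length(cand) >= 2
}

# Small random instance: M tests, up to 10 cases of random subsets, plus a
# query case. Returns NULL unless the instance is floor-free.
random_small_instance <- function(seed) {
  set.seed(seed)
  M <- sample(3:6, 1)
  universe <- LETTERS[seq_len(M)]
  n <- sample(4:10, 1)
  tests <- replicate(n, {
    k <- sample(seq_len(M), 1)
    sample(universe, k)
  }, simplify = FALSE)
  cs <- case_set(tests, universe = universe)
  tm <- build_training_matrix(cs)
  k_taken <- sample(seq_len(max(1, M - 2)), 1)
  taken <- sample(universe, k_taken)
  if (!floor_free(taken, tm)) return(NULL)
  list(tm = tm, taken = taken)
}

# Independent top-X rescan of rankings vs labels, with explicit loops.
brute_force_correct_rate <- function(rankings, labels, X) {
  hits <- 0
  for (j in seq_along(rankings)) {
    codes <- if (is.data.frame(rankings[[j]])) rankings[[j]]$test_code
             else rankings[[j]]
    top <- codes[seq_len(min(X, length(codes)))]
    if (labels[[j]] %in% top) hits <- hits + 1
  }
  hits / length(rankings)
}

# The five printed validation patients used as the worked hit-rate example:
# golden-standard test and the visible head of each recommendation list.
table1_rankings <- function() {
  list(
    p1 = c("test_104", "test_5", "test_40"),
    p2 = c("test_30", "test_3", "test_18"),
    p3 = c("test_95", "test_2", "test_34"),
    p4 = c("test_78", "test_19", "test_58"),
    p5 = c("test_92", "test_134", "test_198")
  )
}

table1_labels <- function() {
  c("test_104", "test_30", "test_2", "test_95", "test_198")
}

# Raw-record CSV fragment in the standard export layout.
write_records_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
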