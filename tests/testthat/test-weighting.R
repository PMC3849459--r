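nosmooth_exact <- weight_config(smoothing_config("none", theta = 0), "exact")

test_that("probability estimates are the count ratios off the matrix", {
  tm <- build_training_matrix(fixture_cases())
  expect_equal(estimate_alpha(tm, "A"), 0.75)
  expect_equal(estimate_alpha(tm, "B"), 0.5)
  expect_equal(estimate_gamma(tm, "A"), 0.75)
  expect_equal(estimate_beta(tm, "A", "B"), 1.0)   # every B-case has A
  expect_equal(estimate_beta(tm, "B", "A"), 2 / 3)
  expect_equal(estimate_beta(tm, "C", "B"), 0)
  expect_error(estimate_alpha(tm, "Z"), "unknown test code")
})

test_that("an unseen conditioning test cannot be conditioned on raw", {
  tm <- build_training_matrix(fixture_cases(),
                              universe = c("A", "B", "C", "D"))
  expect_equal(estimate_alpha(tm, "D"), 0)
  expect_error(estimate_beta(tm, "A", "D"), "unseen in training")
})

test_that("literal prior term matches its closed form", {
  expect_equal(prior_term(0.3, 0.2, 1), 0)
  expect_equal(prior_term(0.5, 0, 3), 0)
  expect_equal(prior_term(0.2, 0, 2), log(0.8 / 0.2))
  expect_error(prior_term(0, 0, 2), "degenerate")
  expect_error(prior_term(1, 0, 3), "degenerate")
})

test_that("evidence terms match forced arithmetic in both modes", {
  # independence: beta equals gamma makes the exact term vanish
  for (a in c(0.2, 0.5, 0.8)) {
    expect_equal(evidence_term(0.4, 0.4, alpha = a, mode = "exact"), 0,
                 ignore_attr = TRUE)
  }
  expect_equal(evidence_term(0.6, 0.4, alpha = 0.5, mode = "exact"),
               log(3), ignore_attr = TRUE)
  expect_equal(evidence_term(0.2, 0.5, mode = "literal"),
               log(0.2 / 0.3), ignore_attr = TRUE)
})

test_that("non-positive numerators and denominators are floored, not infinite", {
  # literal denominator gamma - beta < 0 for positively associated pairs
  v <- evidence_term(0.6, 0.4, mode = "literal", epsilon = 1e-12)
  expect_true(is.finite(v))
  expect_equal(attr(v, "n_floored"), 1L)
  v2 <- evidence_term(0, 0.4, alpha = 0.5, mode = "exact", epsilon = 1e-12)
  expect_true(is.finite(v2))
  expect_gte(attr(v2, "n_floored"), 1L)
})

test_that("weights on the worked fixture equal their hand-derived values", {
  tm <- build_training_matrix(fixture_cases())
  expect_equal(test_weight("B", "A", tm, nosmooth_exact), log(2))
  expect_equal(test_weight("C", "A", tm, nosmooth_exact), -log(2))
  rec <- rank_candidates("A", tm, nosmooth_exact)
  expect_equal(rec$test_code, c("B", "C"))
  expect_equal(rec$rank, 1:2)
})

test_that("full Jelinek-Mercer smoothing collapses evidence to independence", {
  tm <- build_training_matrix(fixture_cases())
  cfg <- weight_config(smoothing_config("jelinek_mercer", 1, theta = 0.5),
                       "exact")
  # with lambda = 1, beta becomes gamma and every exact evidence term is 0,
  # so the weight reduces to the smoothed prior log-odds alone
  for (t0 in c("B", "C"))
    expect_equal(test_weight(t0, "A", tm, cfg),
                 smooth_log_odds_laplace(estimate_alpha(tm, t0), 0.5))
  # the literal form decomposes into prior_term plus literal evidence terms
  # (here beta -> gamma makes the literal denominator zero, hence floored)
  cfg_lit <- weight_config(smoothing_config("jelinek_mercer", 1, theta = 0.5),
                           "literal")
  w_lit <- test_weight("B", "A", tm, cfg_lit)
  expect_equal(w_lit,
               prior_term(0.5, 0.5, 1) +
                 as.numeric(evidence_term(0.75, 0.75, mode = "literal")))
})

test_that("candidate already taken and exhausted universes are domain errors", {
  tm <- build_training_matrix(fixture_cases())
  expect_error(test_weight("A", c("A", "B"), tm, nosmooth_exact),
               "already taken")
  expect_error(rank_candidates(c("A", "B", "C"), tm, nosmooth_exact),
               "no candidate")
  rec <- rank_candidates(c("A", "B"), tm, nosmooth_exact)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$test_code, "C")
})

test_that("exact ties are broken by test code, ascending", {
  # B and C are exchangeable given A: identical counts
  cs <- case_set(list(v1 = c("A", "B"), v2 = c("A", "C")))
  tm <- build_training_matrix(cs)
  cfg <- weight_config(smoothing_config("none", theta = 0.5), "exact")
  rec <- rank_candidates("A", tm, cfg)
  expect_equal(rec$weight[1], rec$weight[2])
  expect_equal(rec$test_code, c("B", "C"))
})

test_that("ranking does not depend on the order taken tests are listed", {
  set.seed(21)
  universe <- LETTERS[1:6]
  tests <- replicate(15, sample(universe, sample(2:5, 1)), simplify = FALSE)
  tm <- build_training_matrix(case_set(tests, universe = universe))
  cfg <- weight_config(smoothing_config("jelinek_mercer", 0.2, 0.5), "exact")
  taken <- c("A", "C", "E")
  r1 <- rank_candidates(taken, tm, cfg)
  r2 <- rank_candidates(rev(taken), tm, cfg)
  expect_identical(r1$test_code, r2$test_code)
  expect_equal(r1$weight, r2$weight)
})

test_that("raising a joint count with a taken test never lowers the exact weight", {
  tm <- build_training_matrix(fixture_cases())
  w0 <- test_weight("C", "B", tm, nosmooth_exact)
  tm2 <- tm
  tm2$joint["B", "C"] <- tm2$joint["C", "B"] <- 1L  # was 0; still <= marginals
  w1 <- test_weight("C", "B", tm2, nosmooth_exact)
  expect_gt(w1, w0)
})

test_that("weights stay finite for every smoother with positive parameters", {
  tm <- build_training_matrix(fixture_cases(),
                              universe = c("A", "B", "C", "D"))
  for (method in c("jelinek_mercer", "dirichlet", "absolute_discounting")) {
    for (mode in c("exact", "literal")) {
      cfg <- weight_config(smoothing_config(method, 0.2, theta = 0.5), mode)
      rec <- rank_candidates("A", tm, cfg)
      expect_true(all(is.finite(rec$weight)), info = paste(method, mode))
      expect_setequal(rec$test_code, c("B", "C", "D"))  # unseen D is a candidate
    }
  }
})

test_that("taken tests unseen in training are skipped and change nothing", {
  tm <- build_training_matrix(fixture_cases(),
                              universe = c("A", "B", "C", "D"))
  cfg <- weight_config(smoothing_config("jelinek_mercer", 0.2, 0.5), "exact")
  with_d <- rank_candidates(c("A", "D"), tm, cfg)
  without_d <- rank_candidates("A", tm, cfg)
  expect_identical(attr(with_d, "skipped_tests"), "D")
  merged <- merge(with_d, without_d, by = "test_code")
  expect_equal(merged$weight.x, merged$weight.y)
})

test_that("exact-mode weights equal the brute-force posterior log-odds", {
  found <- 0L
  seed <- 0L
  while (found < 20L && seed < 4000L) {
    seed <- seed + 1L
    inst <- random_small_instance(seed)
    if (is.null(inst)) next
    found <- found + 1L
    cand <- setdiff(inst$tm$universe, inst$taken)
    rec <- rank_candidates(inst$taken, inst$tm, nosmooth_exact)
    oracle <- vapply(cand, oracle_log_odds, numeric(1),
                     taken = inst$taken, tm = inst$tm)
    expect_equal(rec$weight,
                 unname(oracle[rec$test_code]), tolerance = 1e-9)
    # identical rankings up to exact mathematical ties: the package order
    # must be non-increasing under the oracle scores and vice versa
    expect_true(all(diff(unname(oracle[rec$test_code])) <= 1e-9))
    ord <- order(-oracle, names(oracle), method = "radix")
    w <- setNames(rec$weight, rec$test_code)
    expect_true(all(diff(unname(w[names(oracle)[ord]])) <= 1e-9))
  }
  expect_gte(found, 20L)
})

test_that("rankings serialize as a six-decimal TSV", {
  tm <- build_training_matrix(fixture_cases())
  rec <- rank_candidates("A", tm, nosmooth_exact, case_id = "v9")
  f <- tempfile(fileext = ".tsv")
  write_recommendations(rec, f)
  lines <- readLines(f)
  expect_equal(lines[1], "case_id\trank\ttest_code\tweight")
  expect_equal(lines[2], "v9\t1\tB\t0.693147")
})
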