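#' Smoothing configuration
#'
#' The conditional probability beta = Pr(taken test | candidate test) is a
#' ratio of small counts and is zero whenever a pair was never observed
#' together in training; smoothing mixes it with the taken test's marginal
#' probability gamma so unseen pairs keep non-zero mass. Three standard
#' language-model smoothers are available for beta, plus additive (Laplace)
#' smoothing of the prior log-odds of the candidate test.
#'
#' @param method one of `"none"`, `"jelinek_mercer"`, `"dirichlet"`,
#'   `"absolute_discounting"`.
#' @param param the smoother's parameter (lambda, mu or delta respectively),
#'   in `[0, 1]`; ignored for `"none"`. At 0 every method returns the raw
#'   beta.
#' @param theta Laplace parameter for the prior log-odds, in `[0, 1]`;
#'   `theta > 0` keeps the prior finite for tests unseen (or always seen) in
#'   training. Default 0.5, past which top-X accuracy is typically stable.
#' @return An object of class `smoothing_config`.
#' @seealso [apply_smoothing()], [weight_config()]
#' @export
smoothing_config <- function(method = c("none", "jelinek_mercer", "dirichlet",
                                        "absolute_discounting"),
                             param = 0, theta = 0.5) {
  method <- match.arg(method)
  if (method != "none") {
    if (!is.numeric(param) || length(param) != 1L || is.na(param) ||
        param < 0 || param > 1)
      stop("smoothing `param` must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1)
    stop("`theta` must be a single value in [0, 1]", call. = FALSE)
  structure(list(method = method, param = if (method == "none") 0 else param,
                 theta = theta),
            class = "smoothing_config")
}

#' @export
print.smoothing_config <- function(x, ...) {
  cat(sprintf("<smoothing_config> method = %s, param = %g, theta = %g\n",
              x$method, x$param, x$theta))
  invisible(x)
}

#' Jelinek-Mercer smoothing of a conditional probability
#'
#' Linear interpolation between the conditional probability `beta` and the
#' marginal `gamma`: `(1 - lambda) * beta + lambda * gamma`.
#'
#' @param beta,gamma probabilities in `[0, 1]` (vectorized).
#' @param lambda mixing weight in `[0, 1]`; 0 returns `beta`, 1 returns
#'   `gamma`.
#' @return Smoothed probability, between `min(beta, gamma)` and
#'   `max(beta, gamma)` elementwise.
#' @export
smooth_beta_jelinek_mercer <- function(beta, gamma, lambda) {
  check_unit_param(lambda, "lambda")
  (1 - lambda) * beta + lambda * gamma
}

#' Dirichlet-prior smoothing of a conditional probability
#'
#' `(beta + mu * gamma) / (1 + mu)`, the Dirichlet-prior smoother with its
#' pseudocount normalized by the conditioning count so `mu` lives on
#' `[0, 1]`. Approaches `gamma` monotonically as `mu` grows.
#'
#' @inheritParams smooth_beta_jelinek_mercer
#' @param mu normalized pseudocount weight, `mu >= 0` (here `[0, 1]`).
#' @return Smoothed probability.
#' @export
smooth_beta_dirichlet <- function(beta, gamma, mu) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    stop("`mu` must be a single non-negative value", call. = FALSE)
  (beta + mu * gamma) / (1 + mu)
}

#' Absolute-discounting smoothing of a conditional probability
#'
#' Subtracts a constant discount `delta` from the raw joint count and adds
#' back `delta * gamma`: `max(joint_count - delta, 0) / base_count +
#' delta * gamma`. When the conditioning test was never seen
#' (`base_count = 0`) the discounted term is dropped and `delta * gamma` is
#' returned as the pure fallback. The result is not renormalized and may
#' slightly exceed 1; only the induced ranking is meaningful downstream.
#'
#' @param joint_count co-occurrence count of the taken and candidate tests
#'   (vectorized).
#' @param base_count marginal count of the candidate (conditioning) test.
#' @param delta discount in `[0, 1]`; 0 recovers the raw ratio.
#' @param gamma marginal probability of the taken test.
#' @return Non-negative smoothed value.
#' @export
smooth_beta_absolute_discounting <- function(joint_count, base_count, delta, gamma) {
  check_unit_param(delta, "delta")
  out <- delta * gamma
  pos <- base_count > 0
  out <- out + ifelse(pos, pmax(joint_count - delta, 0) / ifelse(pos, base_count, 1), 0)
  out
}

#' Laplace-smoothed prior log-odds
#'
#' `log((alpha + theta) / (1 - alpha + theta))`, the additive-smoothed
#' log-odds of a candidate test's prior probability `alpha`. Finite for
#' `alpha` in `{0, 1}` whenever `theta > 0`.
#'
#' @param alpha prior probability in `[0, 1]` (vectorized).
#' @param theta additive parameter in `[0, 1]`.
#' @return Natural-log odds; 0 at `alpha = 0.5` for any `theta`.
#' @export
smooth_log_odds_laplace <- function(alpha, theta) {
  check_unit_param(theta, "theta")
  if (theta == 0 && any(alpha <= 0 | alpha >= 1))
    stop("degenerate prior: alpha in {0, 1} requires theta > 0", call. = FALSE)
  log((alpha + theta) / (1 - alpha + theta))
}

#' Apply the configured smoother to a conditional probability
#'
#' Dispatcher over the beta smoothers: `"none"` returns `beta` unchanged
#' (downstream epsilon flooring handles zeros), the other methods apply their
#' formula. Absolute discounting works on the raw counts, which must then be
#' supplied.
#'
#' @param config a [smoothing_config()].
#' @param beta,gamma probabilities (vectorized).
#' @param joint_count,base_count raw counts backing `beta`; required for
#'   `method = "absolute_discounting"`.
#' @return Smoothed beta values.
#' @export
apply_smoothing <- function(config, beta, gamma,
                            joint_count = NULL, base_count = NULL) {
  stopifnot(inherits(config, "smoothing_config"))
  switch(config$method,
    none = beta,
    jelinek_mercer = smooth_beta_jelinek_mercer(beta, gamma, config$param),
    dirichlet = smooth_beta_dirichlet(beta, gamma, config$param),
    absolute_discounting = {
      if (is.null(joint_count) || is.null(base_count))
        stop("absolute discounting needs `joint_count` and `base_count`",
             call. = FALSE)
      smooth_beta_absolute_discounting(joint_count, base_count,
                                       config$param, gamma)
    }
  )
}

check_unit_param <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("`", name, "` must be a single value in [0, 1]", call. = FALSE)
  invisible(x)
}
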