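#' Exact binomial probability mass function
#'
#' Validated wrapper around [stats::dbinom()] exposing the pmf
#' \eqn{b(k, n, p) = \binom{n}{k} p^k (1-p)^{n-k}} used throughout the
#' two-stage calculations.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p Success probability.
#' @return `P(X = k)` for `X ~ Binomial(n, p)`.
#' @examples
#' binom_pmf(2, 2, 0.5)   # 0.25
#' @export
binom_pmf <- function(k, n, p) {
  n <- check_count(n, "n", min = 0L)
  k <- check_count(k, "k", min = 0L)
  p <- check_probability(p, "p")
  if (k > n) stop_argument("`k` = %d exceeds `n` = %d.", k, n)
  stats::dbinom(k, n, p)
}

#' Exact cumulative binomial distribution function
#'
#' \eqn{B(k, n, p) = \sum_{i=0}^{k} b(i, n, p)}; `k = -1` denotes the empty
#' sum and returns 0.
#'
#' @param k Upper summation limit, `-1 <= k <= n`.
#' @inheritParams binom_pmf
#' @return `P(X <= k)` for `X ~ Binomial(n, p)`.
#' @examples
#' binom_cdf(-1, 10, 0.3)  # 0
#' binom_cdf(0, 1, 0.5)    # 0.5
#' @export
binom_cdf <- function(k, n, p) {
  n <- check_count(n, "n", min = 0L)
  k <- check_count(k, "k", min = -1L)
  p <- check_probability(p, "p")
  if (k > n) stop_argument("`k` = %d exceeds `n` = %d.", k, n)
  stats::pbinom(k, n, p)
}

#' Probability of early termination
#'
#' PET(p) = `B(r1, n1, p)`: the probability that the trial stops for futility
#' at the interim analysis when the true response rate is `p`.  Evaluated at
#' `p0` it is the probability of *correctly* stopping, at `pa` of *wrongly*
#' stopping.
#'
#' @param design A [two_stage_design()].
#' @param p True response probability.
#' @return A probability.
#' @examples
#' d <- two_stage_design(16, 51, 20, 60)
#' pet(d, 0.65)
#' @export
pet <- function(design, p) {
  stopifnot(inherits(design, "two_stage_design"))
  p <- check_probability(p, "p")
  stats::pbinom(design$r1, design$n1, p)
}

#' Probability of rejecting the null under the two-stage rule
#'
#' The probability of the rejection event \{x1 > r1 and x > r\} when the true
#' response rate is `p`, with the futility rule enforced:
#' \deqn{\sum_{i=r_1+1}^{n_1} b(i, n_1, p)\, P(X_2 > r - i),}
#' where \eqn{P(X_2 > r - i) = 1 - B(r-i, n_2, p)} and equals 1 whenever
#' `i > r` (stage-1 responses alone already exceed the critical value, so
#' rejection is certain).  Evaluated at `pa` this is the design's actual
#' power; at `p0` it coincides with [type1_error()].
#'
#' @inheritParams pet
#' @return A probability.
#' @examples
#' reject_probability(two_stage_design(5, 20, 23, 71), 0.40)  # actual power
#' @export
reject_probability <- function(design, p) {
  stopifnot(inherits(design, "two_stage_design"))
  p <- check_probability(p, "p")
  r1 <- design$r1; n1 <- design$n1; r <- design$r; n2 <- design$n - design$n1
  if (r1 >= n1) return(0)
  i <- (r1 + 1L):n1
  # pbinom(r - i, ..., lower.tail = FALSE) is 1 for r - i < 0, as required
  sum(stats::dbinom(i, n1, p) *
        stats::pbinom(r - i, n2, p, lower.tail = FALSE))
}

#' Actual type I error of a two-stage design
#'
#' The attained one-sided type I error with the futility rule enforced,
#' \deqn{1 - \Big[B(r_1, n_1, p_0) +
#'   \sum_{i=r_1+1}^{\min(n_1, r)} b(i, n_1, p_0) B(r-i, n_2, p_0)\Big],}
#' i.e. one minus the probability of accepting the null either at the interim
#' or at the final analysis.  Algebraically identical to
#' [reject_probability()] evaluated at `p0`.
#'
#' @param design A [two_stage_design()].
#' @param p0 Null response probability.
#' @return A probability.
#' @export
type1_error <- function(design, p0) {
  stopifnot(inherits(design, "two_stage_design"))
  p0 <- check_probability(p0, "p0")
  r1 <- design$r1; n1 <- design$n1; r <- design$r; n2 <- design$n - design$n1
  top <- min(n1, r)
  s <- if (top >= r1 + 1L) {
    i <- (r1 + 1L):top
    sum(stats::dbinom(i, n1, p0) * stats::pbinom(r - i, n2, p0))
  } else 0
  1 - (stats::pbinom(r1, n1, p0) + s)
}

#' Expected sample size of a two-stage design
#'
#' EN(p) = `n1 + (1 - PET(p)) * (n - n1)`.
#'
#' @inheritParams pet
#' @return Expected number of patients (a real number in `[n1, n]`).
#' @export
expected_sample_size <- function(design, p) {
  stopifnot(inherits(design, "two_stage_design"))
  p <- check_probability(p, "p")
  design$n1 + (1 - pet(design, p)) * (design$n - design$n1)
}

#' Type I error when the futility rule is ignored
#'
#' The rejection probability of the final exact test `x > r` when the trial
#' always proceeds to stage 2, `1 - B(r, n, p0)`.  For a non-binding futility
#' rule this is the quantity that must stay below the nominal level: ignoring
#' a stop can only *add* rejection events, so
#' `type1_error(design, p0) <= alpha_no_stop(design, p0)` always.
#'
#' @inheritParams type1_error
#' @return A probability.
#' @export
alpha_no_stop <- function(design, p0) {
  stopifnot(inherits(design, "two_stage_design"))
  p0 <- check_probability(p0, "p0")
  stats::pbinom(design$r, design$n, p0, lower.tail = FALSE)
}

#' The six operating characteristics of a two-stage design
#'
#' Computes, for a design and a test problem: the interim fraction `n1/n`;
#' PET(pa) and PET(p0) (probabilities of wrongly and correctly stopping for
#' futility); the attained type I error with (`alpha_d`) and without
#' (`alpha_no_stop`) adherence to the stopping rule; the attained power
#' (`power_d`); and the expected sample sizes EN(p0) and EN(pa) together with
#' the maximum sample size `n`.
#'
#' @param design A [two_stage_design()].
#' @param params A [design_params()].
#' @return An object of class `"op_chars"`: a list with elements `ratio`,
#'   `pet_pa`, `pet_p0`, `alpha_d`, `alpha_no_stop`, `power_d`, `en_p0`,
#'   `en_pa`, `n_max`.
#' @examples
#' pars <- design_params(0.25, 0.40)
#' operating_characteristics(two_stage_design(5, 20, 23, 71), pars)
#' @export
operating_characteristics <- function(design, params) {
  stopifnot(inherits(design, "two_stage_design"),
            inherits(params, "design_params"))
  structure(list(
    ratio         = design$n1 / design$n,
    pet_pa        = pet(design, params$pa),
    pet_p0        = pet(design, params$p0),
    alpha_d       = type1_error(design, params$p0),
    alpha_no_stop = alpha_no_stop(design, params$p0),
    power_d       = reject_probability(design, params$pa),
    en_p0         = expected_sample_size(design, params$p0),
    en_pa         = expected_sample_size(design, params$pa),
    n_max         = design$n
  ), class = "op_chars")
}

#' @export
print.op_chars <- function(x, ...) {
  cat(sprintf("  n1/n = %.2f, n = %d\n", x$ratio, x$n_max))
  cat(sprintf("  PET(p0) = %.3f (correct stop), PET(pa) = %.3f (wrong stop)\n",
              x$pet_p0, x$pet_pa))
  cat(sprintf("  alpha_d = %.4f, alpha_no_stop = %.4f, power = %.4f\n",
              x$alpha_d, x$alpha_no_stop, x$power_d))
  cat(sprintf("  EN(p0) = %.2f, EN(pa) = %.2f\n", x$en_p0, x$en_pa))
  invisible(x)
}

#' Futility boundary on the p-value scale
#'
#' Converts the count rule "stop if `x1 <= r1`" into the equivalent p-value
#' threshold `alpha0` of the rule "stop if `p_interim > alpha0`", where the
#' interim p-value for observed `x1` is the one-sided upper-tail exact
#' binomial p-value `P(X1 >= x1 | p0) = 1 - B(x1 - 1, n1, p0)`.  The returned
#' `alpha0` is the p-value of the smallest continuation outcome
#' `x1 = r1 + 1`, i.e. `1 - B(r1, n1, p0)`, so that
#' `p_interim > alpha0` holds exactly when `x1 <= r1`.
#'
#' The upper-tail p-value convention is a documented package choice; the two
#' formalizations of the stopping rule are interconvertible under it (the
#' interim p-value is strictly decreasing in `x1` for `0 < p0 < 1`).
#'
#' @inheritParams type1_error
#' @return The p-value-scale futility boundary `alpha0`.  For the degenerate
#'   rule `r1 = n1` (stopping certain) a warning is issued and 0 is returned
#'   (no continuation outcome exists).
#' @examples
#' interim_pvalue_threshold(two_stage_design(10, 39, 21, 62), 0.25)
#' @export
interim_pvalue_threshold <- function(design, p0) {
  stopifnot(inherits(design, "two_stage_design"))
  p0 <- check_probability(p0, "p0")
  if (design$r1 >= design$n1)
    warning(warningCondition(
      "r1 = n1: the futility rule is degenerate (stopping is certain).",
      class = "optifut_degenerate_rule"))
  stats::pbinom(design$r1, design$n1, p0, lower.tail = FALSE)
}
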