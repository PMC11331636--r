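#' @keywords internal
stop_argument <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("optifut_argument_error", "optifut_error")))
}

#' @keywords internal
stop_infeasible <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("optifut_infeasible", "optifut_error")))
}

check_probability <- function(x, name, lower = 0, upper = 1,
                              open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_argument("`%s` must be a single finite number, got %s.",
                  name, deparse(substitute(x)))
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_argument("`%s` = %g is outside %s%g, %g%s.", name, x,
                  if (open_lower) "(" else "[", lower, upper,
                  if (open_upper) ")" else "]")
  as.numeric(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      abs(x - round(x)) > 1e-8)
    stop_argument("`%s` must be a single integer.", name)
  x <- as.integer(round(x))
  if (x < min)
    stop_argument("`%s` = %d must be >= %d.", name, x, min)
  x
}

#' Test-problem parameters for a single-arm binary endpoint
#'
#' Bundles the null and alternative response probabilities and the targeted
#' one-sided error rates of the exact binomial test problem
#' \eqn{H_0: p \le p_0} versus \eqn{H_1: p > p_0}.  `p0` is the highest
#' response rate at which the treatment would be considered unsuccessful and
#' `pa` the lowest rate warranting further study.
#'
#' @param p0 Null response probability, `0 < p0 < pa`.
#' @param pa Alternative response probability, `p0 < pa < 1`.
#' @param alpha One-sided targeted nominal significance level in (0, 1).
#' @param beta Targeted type II error rate in (0, 1); targeted power is
#'   `1 - beta`.
#'
#' @return An object of class `"design_params"`.
#' @examples
#' design_params(p0 = 0.25, pa = 0.40, alpha = 0.05, beta = 0.20)
#' @export
design_params <- function(p0, pa, alpha = 0.05, beta = 0.20) {
  p0    <- check_probability(p0, "p0", open_lower = TRUE, open_upper = TRUE)
  pa    <- check_probability(pa, "pa", open_lower = TRUE, open_upper = TRUE)
  alpha <- check_probability(alpha, "alpha", open_lower = TRUE, open_upper = TRUE)
  beta  <- check_probability(beta, "beta", open_lower = TRUE, open_upper = TRUE)
  if (p0 >= pa)
    stop_argument("`p0` (%g) must be strictly smaller than `pa` (%g).", p0, pa)
  structure(list(p0 = p0, pa = pa, alpha = alpha, beta = beta),
            class = "design_params")
}

#' @export
print.design_params <- function(x, ...) {
  cat(sprintf("Test problem: H0 p <= %g vs H1 p > %g (pa = %g)\n",
              x$p0, x$p0, x$pa))
  cat(sprintf("One-sided alpha = %g, targeted power = %g\n",
              x$alpha, 1 - x$beta))
  invisible(x)
}

#' Two-stage design tuple (r1, n1, r, n)
#'
#' A two-stage single-arm design: evaluate `n1` patients, stop for futility if
#' the number of responses `x1 <= r1`; otherwise evaluate `n - n1` more and
#' reject the null hypothesis if the total number of responses `x > r`.
#'
#' @param r1 Futility threshold at the interim, `0 <= r1 <= n1`.  `r1 = n1` is
#'   a degenerate rule that always stops.
#' @param n1 Stage-1 sample size, `1 <= n1 < n`.
#' @param r Final rejection threshold (reject if `x > r`), `r1 <= r <= n`.
#' @param n Total sample size.
#'
#' @return An object of class `"two_stage_design"`.
#' @examples
#' two_stage_design(r1 = 5, n1 = 20, r = 23, n = 71)
#' @export
two_stage_design <- function(r1, n1, r, n) {
  n1 <- check_count(n1, "n1", min = 1L)
  n  <- check_count(n,  "n",  min = 2L)
  r1 <- check_count(r1, "r1", min = 0L)
  r  <- check_count(r,  "r",  min = 0L)
  if (n1 >= n)
    stop_argument("`n1` = %d must be strictly smaller than `n` = %d.", n1, n)
  if (r1 > n1)
    stop_argument("`r1` = %d must not exceed `n1` = %d.", r1, n1)
  if (r < r1 || r > n)
    stop_argument("`r` = %d must satisfy r1 <= r <= n (r1 = %d, n = %d).",
                  r, r1, n)
  structure(list(r1 = r1, n1 = n1, r = r, n = n), class = "two_stage_design")
}

#' @export
print.two_stage_design <- function(x, ...) {
  cat(sprintf("Two-stage design (r1, n1, r, n) = (%d, %d, %d, %d)\n",
              x$r1, x$n1, x$r, x$n))
  cat(sprintf("  stage 1: stop for futility if x1 <= %d of %d\n", x$r1, x$n1))
  cat(sprintf("  stage 2: %d further patients; reject H0 if x > %d of %d\n",
              x$n - x$n1, x$r, x$n))
  invisible(x)
}

#' Admissibility constraints for futility-boundary searches
#'
#' Bounds used by [optimized_futility_design()] and [kim_modified()]:
#' the acceptable overall power loss `pow_loss`, the upper bound `pi_wrong` on
#' the probability of wrongly stopping for futility PET(pa), the allowed range
#' for the interim timing n1/n, and the looser PET(pa) bound used by Kim's
#' modified designs (0.1 by default).
#'
#' @param pow_loss Acceptable overall power loss caused by the futility stop
#'   (the optimized design must keep power `>= 1 - beta - pow_loss`).
#' @param pi_wrong Upper bound on PET(pa) for the optimized design.
#' @param ratio_lower,ratio_upper Inclusive bounds on the interim fraction
#'   n1/n, with `0 < ratio_lower < ratio_upper < 1`.
#' @param pet_pa_bound_kim PET(pa) bound applied by Kim's modified designs.
#'
#' @return An object of class `"admissible_constraints"`.
#' @examples
#' admissible_constraints()  # the default planning constraints
#' @export
admissible_constraints <- function(pow_loss = 0.05, pi_wrong = 0.05,
                                   ratio_lower = 1 / 3, ratio_upper = 2 / 3,
                                   pet_pa_bound_kim = 0.1) {
  pow_loss <- check_probability(pow_loss, "pow_loss", open_upper = TRUE)
  pi_wrong <- check_probability(pi_wrong, "pi_wrong")
  ratio_lower <- check_probability(ratio_lower, "ratio_lower",
                                   open_lower = TRUE, open_upper = TRUE)
  ratio_upper <- check_probability(ratio_upper, "ratio_upper",
                                   open_lower = TRUE, open_upper = TRUE)
  pet_pa_bound_kim <- check_probability(pet_pa_bound_kim, "pet_pa_bound_kim")
  if (ratio_lower >= ratio_upper)
    stop_argument("`ratio_lower` (%g) must be < `ratio_upper` (%g).",
                  ratio_lower, ratio_upper)
  structure(list(pow_loss = pow_loss, pi_wrong = pi_wrong,
                 ratio_lower = ratio_lower, ratio_upper = ratio_upper,
                 pet_pa_bound_kim = pet_pa_bound_kim),
            class = "admissible_constraints")
}

#' @export
print.admissible_constraints <- function(x, ...) {
  cat(sprintf(paste0("Admissible constraints: Pow_loss <= %g, PET(pa) <= %g,",
                     " %g <= n1/n <= %g (Kim PET(pa) bound %g)\n"),
              x$pow_loss, x$pi_wrong, x$ratio_lower, x$ratio_upper,
              x$pet_pa_bound_kim))
  invisible(x)
}

#' Search configuration for design enumeration
#'
#' @param n_max Upper bound on the total sample size for the Simon/Kim
#'   enumeration.  `NULL` (default) resolves, per test problem, to
#'   `max(100, 2 * n_single_stage)`, an envelope that contains all published
#'   designs for the default scenario grid.  Note that feasible two-stage
#'   designs can have a total n *below* the single-stage minimum (the interim
#'   constraint changes the attained error rates), so no lower bound is
#'   enforced; searches simply signal infeasibility when the set is empty.
#' @param tie_break_policy Only `"default"` is implemented: Simon optimal
#'   breaks ties by minimal EN(p0), then n, n1, r1; Simon minimax by minimal
#'   n, then EN(p0), n1; the optimized design by maximal PET(p0), then minimal
#'   n1, then minimal r1.  For a fixed admissible (r1, n1, n), `r` is the
#'   smallest value meeting the alpha constraint (which maximizes power).
#'
#' @return An object of class `"search_config"`.
#' @export
search_config <- function(n_max = NULL, tie_break_policy = "default") {
  if (!is.null(n_max)) n_max <- check_count(n_max, "n_max", min = 2L)
  if (!identical(tie_break_policy, "default"))
    stop_argument("Unknown tie_break_policy '%s' (only \"default\").",
                  tie_break_policy)
  structure(list(n_max = n_max, tie_break_policy = tie_break_policy),
            class = "search_config")
}

resolve_n_max <- function(params, config) {
  if (!is.null(config$n_max)) return(config$n_max)
  ss <- single_stage_design(params)
  max(100L, 2L * ss$n)
}
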