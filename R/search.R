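#' Single-stage exact binomial design
#'
#' Smallest sample size `n` for which some critical value `r` gives a
#' one-sided exact binomial test `reject if x > r` with attained level
#' `1 - B(r, n, p0) <= alpha` and power `1 - B(r, n, pa) >= 1 - beta`.
#' At that `n`, `r` is the smallest integer meeting the alpha condition
#' (which maximizes power among valid critical values).
#'
#' @param params A [design_params()].
#' @param cap Hard upper bound on the scan over `n` (default 1000).
#' @return A list of class `"single_stage_design"` with integer elements
#'   `n` and `r`.
#' @examples
#' single_stage_design(design_params(0.25, 0.40))  # n = 62, r = 21
#' @export
single_stage_design <- function(params, cap = 1000L) {
  stopifnot(inherits(params, "design_params"))
  cap <- check_count(cap, "cap", min = 1L)
  p0 <- params$p0; pa <- params$pa
  # feasibility comparisons carry a 1e-12 slack so that constraints attained
  # exactly (e.g. 1 - B(0, 1, 0.05) = alpha) are not lost to rounding
  for (n in seq_len(cap)) {
    # smallest r with 1 - B(r, n, p0) <= alpha
    r <- stats::qbinom(1 - params$alpha, n, p0)
    while (stats::pbinom(r, n, p0) < 1 - params$alpha - 1e-12) r <- r + 1L
    while (r > 0L && stats::pbinom(r - 1L, n, p0) >= 1 - params$alpha - 1e-12)
      r <- r - 1L
    if (stats::pbinom(r, n, pa, lower.tail = FALSE) >= 1 - params$beta - 1e-12)
      return(structure(list(n = as.integer(n), r = as.integer(r)),
                       class = "single_stage_design"))
  }
  stop_infeasible(
    "No single-stage design with n <= %d attains alpha = %g and power %g.",
    cap, params$alpha, 1 - params$beta)
}

#' @export
print.single_stage_design <- function(x, ...) {
  cat(sprintf("Single-stage exact binomial design: n = %d, reject if x > %d\n",
              x$n, x$r))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Vectorized scan of the two-stage design space.
#
# For each (n1, n) pair the attained type I error and power of every (r1, r)
# combination are obtained from one cumulative-sum matrix per hypothesis:
#   M[i+1, r+1] = b(i, n1, p) * B(r - i, n2, p)   (0 for r < i),
# so that column-cumulative sums give the Eq.-style acceptance sum for any r1
# as CS[n1+1, ] - CS[r1+1, ].  The minimal critical value r attaining the
# alpha constraint is then a row count, and the design's power is read off
# the same construction under pa.  Only that minimal r is retained: for fixed
# (r1, n1, n) it maximizes power, and no selection criterion (EN, n, PET,
# interim ratio) depends on r beyond feasibility.
# ---------------------------------------------------------------------------

.optifut_cache <- new.env(parent = emptyenv())

scan_cache_key <- function(params, n_max) {
  sprintf("%.17g|%.17g|%.17g|%.17g|%d",
          params$p0, params$pa, params$alpha, params$beta, n_max)
}

#' @keywords internal
feasible_design_table <- function(params, n_max, use_cache = TRUE) {
  key <- scan_cache_key(params, n_max)
  if (use_cache && !is.null(.optifut_cache[[key]]))
    return(.optifut_cache[[key]])

  p0 <- params$p0; pa <- params$pa
  alpha <- params$alpha; beta <- params$beta
  # shift index matrix: entry (i+1, r+1) maps r - i to position r - i + 2 in a
  # CDF lookup vector prefixed with 0 (so r - i < 0 yields 0)
  shift <- outer(0:n_max, 0:n_max, function(i, r) pmax(r - i, -1L) + 2L)
  acc <- list()
  for (n1 in seq_len(n_max - 1L)) {
    b0 <- stats::dbinom(0:n1, n1, p0); B0 <- stats::pbinom(0:n1, n1, p0)
    ba <- stats::dbinom(0:n1, n1, pa); Ba <- stats::pbinom(0:n1, n1, pa)
    # r1 candidates: continuation probability 1 - Ba[r1+1] must allow the
    # power requirement, i.e. PET(pa) = Ba[r1+1] <= beta
    r1s <- which(Ba[seq_len(n1)] <= beta) - 1L
    if (!length(r1s)) next
    rows <- seq_along(r1s)
    for (n in (n1 + 1L):n_max) {
      n2 <- n - n1
      idx <- shift[1:(n1 + 1L), 1:(n + 1L), drop = FALSE]
      B20e <- c(0, stats::pbinom(0:n, n2, p0))
      B2ae <- c(0, stats::pbinom(0:n, n2, pa))
      M0 <- b0 * matrix(B20e[idx], n1 + 1L)     # b0 recycles down columns
      Ma <- ba * matrix(B2ae[idx], n1 + 1L)
      CS0 <- apply(M0, 2L, cumsum)
      CSa <- apply(Ma, 2L, cumsum)
      top0 <- matrix(CS0[n1 + 1L, ], length(r1s), n + 1L, byrow = TRUE)
      topa <- matrix(CSa[n1 + 1L, ], length(r1s), n + 1L, byrow = TRUE)
      T1  <- (1 - B0[r1s + 1L]) - (top0 - CS0[r1s + 1L, , drop = FALSE])
      POW <- (1 - Ba[r1s + 1L]) - (topa - CSa[r1s + 1L, , drop = FALSE])
      # T1 is non-increasing along r; minimal feasible r = number of columns
      # still above alpha (r = n always attains 0)
      rmin <- as.integer(rowSums(T1 > alpha + 1e-12))
      r <- pmax(rmin, r1s)                      # enforce r >= r1
      at <- cbind(rows, r + 1L)
      powr <- POW[at]
      keep <- powr >= 1 - beta - 1e-12
      if (!any(keep)) next
      k1 <- r1s[keep]
      acc[[length(acc) + 1L]] <- data.frame(
        r1 = k1, n1 = n1, r = r[keep], n = n,
        pet_p0 = B0[k1 + 1L], pet_pa = Ba[k1 + 1L],
        en_p0 = n1 + (1 - B0[k1 + 1L]) * n2,
        en_pa = n1 + (1 - Ba[k1 + 1L]) * n2,
        alpha_d = T1[at][keep], power_d = powr[keep],
        alpha_no_stop = stats::pbinom(r[keep], n, p0, lower.tail = FALSE))
    }
  }
  out <- if (length(acc)) do.call(rbind, acc) else
    data.frame(r1 = integer(), n1 = integer(), r = integer(), n = integer(),
               pet_p0 = numeric(), pet_pa = numeric(), en_p0 = numeric(),
               en_pa = numeric(), alpha_d = numeric(), power_d = numeric(),
               alpha_no_stop = numeric())
  out <- out[order(out$n, out$n1, out$r1, out$r), , drop = FALSE]
  rownames(out) <- NULL
  if (use_cache) .optifut_cache[[key]] <- out
  out
}

#' Enumerate all feasible two-stage designs
#'
#' Literal enumeration of every tuple `(r1, n1, r, n)` with `n <= n_max`,
#' `1 <= n1 < n`, `0 <= r1 <= n1`, `r1 <= r <= n` whose attained type I error
#' is at most `alpha` and whose attained power is at least `1 - beta`.  Rows
#' are emitted in a fixed deterministic order (`n`, then `n1`, `r1`, `r`
#' ascending).  Intended for small `n_max` (certification, auditing); the
#' design searches use an equivalent vectorized scan that retains only the
#' minimal critical value per `(r1, n1, n)`.
#'
#' An empty result is valid.  Note that feasibility below the single-stage
#' minimum sample size is possible: enforcing the interim stop changes the
#' attained error rates, so e.g. the Simon minimax design can have a smaller
#' total `n` than the single-stage design.
#'
#' @param params A [design_params()].
#' @param n_max Upper bound on the total sample size (`>= 2`).
#' @return A data frame with columns `r1`, `n1`, `r`, `n`, `alpha_d`,
#'   `power_d`, `pet_p0`, `pet_pa`, `en_p0`.
#' @examples
#' nrow(enumerate_feasible_designs(design_params(0.05, 0.25), n_max = 25))
#' @export
enumerate_feasible_designs <- function(params, n_max) {
  stopifnot(inherits(params, "design_params"))
  n_max <- check_count(n_max, "n_max", min = 2L)
  p0 <- params$p0; pa <- params$pa
  acc <- list()
  for (n in 2:n_max) for (n1 in seq_len(n - 1L)) {
    n2 <- n - n1
    B0 <- stats::pbinom(0:n1, n1, p0); b0 <- stats::dbinom(0:n1, n1, p0)
    Ba <- stats::pbinom(0:n1, n1, pa); ba <- stats::dbinom(0:n1, n1, pa)
    for (r1 in 0:(n1 - 1L)) {
      if (Ba[r1 + 1L] > params$beta) break
      i <- (r1 + 1L):n1
      rs <- r1:n
      # acceptance CDF lookups over all r at once
      S0 <- stats::pbinom(outer(rs, i, "-"), n2, p0) %*% b0[i + 1L]
      Sa <- stats::pbinom(outer(rs, i, "-"), n2, pa) %*% ba[i + 1L]
      a_d <- 1 - (B0[r1 + 1L] + as.numeric(S0))
      pow <- 1 - (Ba[r1 + 1L] + as.numeric(Sa))
      ok <- a_d <= params$alpha + 1e-12 & pow >= 1 - params$beta - 1e-12
      if (!any(ok)) next
      acc[[length(acc) + 1L]] <- data.frame(
        r1 = r1, n1 = n1, r = rs[ok], n = n,
        alpha_d = a_d[ok], power_d = pow[ok],
        pet_p0 = B0[r1 + 1L], pet_pa = Ba[r1 + 1L],
        en_p0 = n1 + (1 - B0[r1 + 1L]) * n2)
    }
  }
  out <- if (length(acc)) do.call(rbind, acc) else
    data.frame(r1 = integer(), n1 = integer(), r = integer(), n = integer(),
               alpha_d = numeric(), power_d = numeric(), pet_p0 = numeric(),
               pet_pa = numeric(), en_p0 = numeric())
  rownames(out) <- NULL
  out
}

design_from_row <- function(row) {
  two_stage_design(r1 = row$r1, n1 = row$n1, r = row$r, n = row$n)
}

#' Simon's optimal two-stage design
#'
#' Among all feasible tuples under `n_max`, returns the design minimizing the
#' expected sample size under the null hypothesis EN(p0).  Ties are broken by
#' minimal `n`, then `n1`, then `r1`; the critical value `r` is the smallest
#' attaining the alpha constraint.
#'
#' @param params A [design_params()].
#' @param config A [search_config()].
#' @return A [two_stage_design()].
#' @examples
#' \donttest{
#' simon_optimal(design_params(0.25, 0.40))  # (5, 20, 23, 71)
#' }
#' @export
simon_optimal <- function(params, config = search_config()) {
  stopifnot(inherits(params, "design_params"), inherits(config, "search_config"))
  n_max <- resolve_n_max(params, config)
  tab <- feasible_design_table(params, n_max)
  if (!nrow(tab))
    stop_infeasible(paste0(
      "No two-stage design with n <= %d attains alpha <= %g and power >= %g."),
      n_max, params$alpha, 1 - params$beta)
  best <- tab[order(tab$en_p0, tab$n, tab$n1, tab$r1), ][1L, ]
  design_from_row(best)
}

#' Simon's minimax two-stage design
#'
#' Among all feasible tuples under `n_max`, returns the design with minimal
#' total sample size `n`; ties are broken by minimal EN(p0), then `n1`.
#'
#' @inheritParams simon_optimal
#' @return A [two_stage_design()].
#' @examples
#' \donttest{
#' simon_minimax(design_params(0.25, 0.40))  # (16, 51, 20, 60)
#' }
#' @export
simon_minimax <- function(params, config = search_config()) {
  stopifnot(inherits(params, "design_params"), inherits(config, "search_config"))
  n_max <- resolve_n_max(params, config)
  tab <- feasible_design_table(params, n_max)
  if (!nrow(tab))
    stop_infeasible(paste0(
      "No two-stage design with n <= %d attains alpha <= %g and power >= %g."),
      n_max, params$alpha, 1 - params$beta)
  best <- tab[order(tab$n, tab$en_p0, tab$n1, tab$r1), ][1L, ]
  design_from_row(best)
}

# inclusive interim-ratio test with a tolerance that cannot misclassify
# rational ratios at trial-size denominators (|n1/n - bound| >= 1/(3n) when
# the bound is a third and the ratio differs)
ratio_within <- function(n1, n, lower, upper, tol = 1e-9) {
  n1 >= lower * n - tol & n1 <= upper * n + tol
}

#' Kim's modified Simon designs
#'
#' Applies Simon's selection criteria (optimal: minimal EN(p0); minimax:
#' minimal `n`) after two additional feasibility constraints: the probability
#' of wrongly stopping for futility `PET(pa) <= pet_pa_bound_kim` (0.1 by
#' default) and an interim fraction `ratio_lower <= n1/n <= ratio_upper`
#' (inclusive).
#'
#' @inheritParams simon_optimal
#' @param constraints An [admissible_constraints()].
#' @param variant `"optimal"` or `"minimax"`.
#' @return A [two_stage_design()].
#' @examples
#' \donttest{
#' pars <- design_params(0.25, 0.40)
#' kim_modified(pars, variant = "optimal")   # (6, 24, 22, 67)
#' kim_modified(pars, variant = "minimax")   # (10, 40, 21, 62)
#' }
#' @export
kim_modified <- function(params, constraints = admissible_constraints(),
                         config = search_config(),
                         variant = c("optimal", "minimax")) {
  stopifnot(inherits(params, "design_params"),
            inherits(constraints, "admissible_constraints"),
            inherits(config, "search_config"))
  variant <- match.arg(variant)
  n_max <- resolve_n_max(params, config)
  tab <- feasible_design_table(params, n_max)
  if (!nrow(tab))
    stop_infeasible(paste0(
      "No two-stage design with n <= %d attains alpha <= %g and power >= %g."),
      n_max, params$alpha, 1 - params$beta)
  tab1 <- tab[tab$pet_pa <= constraints$pet_pa_bound_kim + 1e-12, ,
              drop = FALSE]
  if (!nrow(tab1))
    stop_infeasible("The PET(pa) <= %g constraint empties the feasible set.",
                    constraints$pet_pa_bound_kim)
  tab2 <- tab1[ratio_within(tab1$n1, tab1$n, constraints$ratio_lower,
                            constraints$ratio_upper), , drop = FALSE]
  if (!nrow(tab2))
    stop_infeasible(
      "The interim ratio constraint %g <= n1/n <= %g empties the feasible set.",
      constraints$ratio_lower, constraints$ratio_upper)
  best <- if (variant == "optimal")
    tab2[order(tab2$en_p0, tab2$n, tab2$n1, tab2$r1), ][1L, ]
  else
    tab2[order(tab2$n, tab2$en_p0, tab2$n1, tab2$r1), ][1L, ]
  design_from_row(best)
}

#' Optimized non-binding futility boundary design
#'
#' Derives the futility boundary of this package's optimized design.  The
#' total sample size `n` and critical value `r` are fixed at the
#' [single_stage_design()] values and are *not* adjusted for the interim
#' look, so the attained type I error never exceeds the nominal level even if
#' the stopping rule is ignored (non-binding validity).  Over all admissible
#' interim rules `(r1, n1)` with
#' \itemize{
#'   \item `ratio_lower <= n1/n <= ratio_upper` (inclusive),
#'   \item `PET(pa) = B(r1, n1, pa) <= pi_wrong`, and
#'   \item two-stage power (with the fixed `r`, `n`) `>= 1 - beta - pow_loss`,
#' }
#' the pair maximizing the probability of correctly stopping for futility
#' PET(p0) is returned (ties: minimal `n1`, then minimal `r1`).  For fixed
#' `n1` only the largest admissible `r1` can be optimal, since PET(p0)
#' increases with `r1` while both constraints tighten, which the search
#' exploits.
#'
#' @inheritParams kim_modified
#' @return A [two_stage_design()] whose `(r, n)` equal the single-stage
#'   design's.
#' @examples
#' optimized_futility_design(design_params(0.25, 0.40))  # (10, 39, 21, 62)
#' @export
optimized_futility_design <- function(params,
                                      constraints = admissible_constraints()) {
  stopifnot(inherits(params, "design_params"),
            inherits(constraints, "admissible_constraints"))
  if (constraints$pow_loss >= 1 - params$beta)
    stop_argument("`pow_loss` (%g) must be smaller than the targeted power %g.",
                  constraints$pow_loss, 1 - params$beta)
  ss <- single_stage_design(params)
  n <- ss$n; r <- ss$r
  n1s <- seq_len(n - 1L)
  n1s <- n1s[ratio_within(n1s, n, constraints$ratio_lower,
                          constraints$ratio_upper)]
  if (!length(n1s))
    stop_infeasible(
      "No stage-1 size n1 < n = %d lies within the interim ratio bounds [%g, %g].",
      n, constraints$ratio_lower, constraints$ratio_upper)
  pow_min <- 1 - params$beta - constraints$pow_loss
  best <- NULL
  any_pet_ok <- FALSE
  for (n1 in n1s) {
    peta <- stats::pbinom(0:n1, n1, params$pa)
    ok <- which(peta <= constraints$pi_wrong + 1e-12)
    if (!length(ok)) next
    any_pet_ok <- TRUE
    # scan r1 downward from the largest PET(pa)-admissible value; power
    # increases as r1 decreases, so the first power-admissible r1 is the
    # per-n1 optimum
    for (r1 in rev(ok - 1L)) {
      d <- two_stage_design(r1 = r1, n1 = n1, r = r, n = n)
      if (reject_probability(d, params$pa) >= pow_min) {
        p0stop <- pet(d, params$p0)
        if (is.null(best) || p0stop > best$pet_p0)
          best <- list(design = d, pet_p0 = p0stop)
        break
      }
    }
  }
  if (is.null(best)) {
    if (!any_pet_ok)
      stop_infeasible(
        "PET(pa) <= %g admits no interim rule within the ratio bounds.",
        constraints$pi_wrong)
    stop_infeasible(
      "The power condition >= %g (pow_loss %g) admits no interim rule.",
      pow_min, constraints$pow_loss)
  }
  best$design
}
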