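#' Scenario grid for design comparison
#'
#' A sequence of test problems sharing a fixed effect `delta = pa - p0` and
#' error rates, plus the admissibility constraints applied to the constrained
#' designs.  The default grid runs `p0` from 0.05 to 0.75 in steps of 0.05
#' with `delta = 0.15`, `alpha = 0.05`, `beta = 0.2`.
#'
#' @param p0_values Strictly increasing vector of null response rates.
#' @param delta Assumed effect `pa - p0` (every `p0 + delta` must be < 1).
#' @param alpha,beta Targeted one-sided error rates.
#' @param constraints An [admissible_constraints()].
#' @return An object of class `"scenario_grid"`.
#' @export
scenario_grid <- function(p0_values = seq(0.05, 0.75, by = 0.05),
                          delta = 0.15, alpha = 0.05, beta = 0.2,
                          constraints = admissible_constraints()) {
  if (!is.numeric(p0_values) || !length(p0_values) || anyNA(p0_values))
    stop_argument("`p0_values` must be a non-empty numeric vector.")
  if (any(diff(p0_values) <= 0))
    stop_argument("`p0_values` must be strictly increasing.")
  delta <- check_probability(delta, "delta", open_lower = TRUE,
                             open_upper = TRUE)
  if (any(p0_values <= 0) || any(p0_values + delta >= 1))
    stop_argument("Every p0 must satisfy 0 < p0 and p0 + delta < 1.")
  alpha <- check_probability(alpha, "alpha", open_lower = TRUE,
                             open_upper = TRUE)
  beta <- check_probability(beta, "beta", open_lower = TRUE, open_upper = TRUE)
  stopifnot(inherits(constraints, "admissible_constraints"))
  structure(list(p0_values = as.numeric(p0_values), delta = delta,
                 alpha = alpha, beta = beta, constraints = constraints),
            class = "scenario_grid")
}

#' The default planning grid as a ready-to-run fixture
#'
#' Returns the package's canonical comparison grid: `delta = 0.15`,
#' `alpha = 0.05`, `beta = 0.2`, `p0` from 0.05 to 0.75 in steps of 0.05 and
#' the default constraints (`pi_wrong = 0.05`, `pow_loss = 0.05`, interim
#' ratio within \[1/3, 2/3\], Kim PET(pa) bound 0.1).
#'
#' @return A [scenario_grid()].
#' @export
load_fixture_scenarios <- function() scenario_grid()

design_families <- c("single_stage", "simon_optimal", "simon_minimax",
                     "kim_optimal", "kim_minimax", "optimized")

compared_families <- setdiff(design_families, "single_stage")

oc_columns <- c("ratio", "pet_p0", "pet_pa", "alpha_d", "alpha_no_stop",
                "power_d", "en_p0", "en_pa")

comparison_row <- function(p0, pa, alpha, beta, family, design, params,
                           status = "ok") {
  base <- data.frame(p0 = p0, pa = pa, alpha = alpha, beta = beta,
                     design = family, r1 = NA_integer_, n1 = NA_integer_,
                     r = NA_integer_, n = NA_integer_,
                     ratio = NA_real_, pet_p0 = NA_real_, pet_pa = NA_real_,
                     alpha_d = NA_real_, alpha_no_stop = NA_real_,
                     power_d = NA_real_, en_p0 = NA_real_, en_pa = NA_real_,
                     status = status, stringsAsFactors = FALSE)
  if (!is.null(design)) {
    oc <- operating_characteristics(design, params)
    base$r1 <- design$r1; base$n1 <- design$n1
    base$r <- design$r; base$n <- design$n
    for (col in oc_columns) base[[col]] <- oc[[col]]
  }
  base
}

#' Run the five design families over a scenario grid
#'
#' For each `p0` in the grid computes the single-stage design, Simon's
#' optimal and minimax designs, Kim's modified optimal and minimax designs,
#' and the optimized non-binding futility design, together with all operating
#' characteristics.  Infeasible cells are recorded with an explanatory
#' `status` and `NA` fields rather than dropped.
#'
#' The single-stage design is reported as a two-stage row with a degenerate
#' stage split only in its tuple columns: `r1 = NA`, `n1 = NA`, and its
#' characteristics are those of the fixed test (`pet_* = NA`,
#' `alpha_d = alpha_no_stop`, `en = n`).
#'
#' @param grid A [scenario_grid()].
#' @param config A [search_config()].
#' @param families Subset of
#'   `c("single_stage", "simon_optimal", "simon_minimax", "kim_optimal",
#'   "kim_minimax", "optimized")` to compute.  The default is the five
#'   compared two-stage families; `"single_stage"` can be requested
#'   explicitly (its row carries the fixed-design characteristics with
#'   `r1 = n1 = NA`).
#' @return A data frame of class `"comparison_table"`, one row per
#'   (scenario, family), with attributes `grid` and `meta` (software version
#'   and timestamp; the data payload itself is deterministic).
#' @examples
#' \donttest{
#' g <- scenario_grid(p0_values = 0.25)
#' run_scenario_grid(g)
#' }
#' @export
run_scenario_grid <- function(grid, config = search_config(),
                              families = compared_families) {
  stopifnot(inherits(grid, "scenario_grid"),
            inherits(config, "search_config"))
  families <- match.arg(families, design_families, several.ok = TRUE)
  cn <- grid$constraints
  rows <- list()
  for (p0 in grid$p0_values) {
    pa <- p0 + grid$delta
    params <- design_params(p0, pa, grid$alpha, grid$beta)
    for (family in families) {
      row <- tryCatch({
        if (family == "single_stage") {
          ss <- single_stage_design(params)
          base <- comparison_row(p0, pa, grid$alpha, grid$beta, family,
                                 NULL, params)
          base$r <- ss$r; base$n <- ss$n
          base$alpha_d <- stats::pbinom(ss$r, ss$n, p0, lower.tail = FALSE)
          base$alpha_no_stop <- base$alpha_d
          base$power_d <- stats::pbinom(ss$r, ss$n, pa, lower.tail = FALSE)
          base$en_p0 <- base$en_pa <- as.numeric(ss$n)
          base
        } else {
          design <- switch(family,
            simon_optimal = simon_optimal(params, config),
            simon_minimax = simon_minimax(params, config),
            kim_optimal   = kim_modified(params, cn, config, "optimal"),
            kim_minimax   = kim_modified(params, cn, config, "minimax"),
            optimized     = optimized_futility_design(params, cn))
          comparison_row(p0, pa, grid$alpha, grid$beta, family, design, params)
        }
      }, optifut_infeasible = function(e) {
        comparison_row(p0, pa, grid$alpha, grid$beta, family, NULL, params,
                       status = paste0("infeasible: ", conditionMessage(e)))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            grid = grid,
            meta = list(package = "optifut",
                        version = as.character(utils::packageVersion("optifut")),
                        timestamp = format(Sys.time(), tz = "UTC")),
            class = c("comparison_table", "data.frame"))
}

higher_is_better <- c(pet_p0 = TRUE, power_d = TRUE,
                      ratio = FALSE, pet_pa = FALSE, alpha_d = FALSE,
                      alpha_no_stop = FALSE, en_p0 = FALSE, en_pa = FALSE,
                      n = FALSE, n_max = FALSE)

#' Rank designs on one operating characteristic
#'
#' Per scenario, ranks the available design families on the chosen
#' characteristic and reports all pairwise differences.  Orientation follows
#' the planning intuition: larger is better for `pet_p0` and `power_d`
#' (rank 1 = largest); smaller is better for the sample-size, wrong-stop and
#' error-rate measures (rank 1 = smallest).  `"n_max"` is accepted as an
#' alias for the total sample size column `n`.
#'
#' @param table A `"comparison_table"` from [run_scenario_grid()].
#' @param characteristic One of `"ratio"`, `"pet_p0"`, `"pet_pa"`,
#'   `"alpha_d"`, `"alpha_no_stop"`, `"power_d"`, `"en_p0"`, `"en_pa"`,
#'   `"n"`/`"n_max"`.
#' @return A list with elements `characteristic`, `ranking` (data frame with
#'   `p0`, `design`, `value`, `rank`) and `differences` (data frame of
#'   pairwise `value` differences `design_a - design_b` per scenario).
#' @export
compare_designs <- function(table, characteristic) {
  stopifnot(inherits(table, "comparison_table"))
  if (identical(characteristic, "n_max")) characteristic <- "n"
  allowed <- c(oc_columns, "n")
  if (!is.character(characteristic) || length(characteristic) != 1L ||
      !characteristic %in% allowed)
    stop_argument("`characteristic` must be one of: %s.",
                  paste(c(allowed, "n_max"), collapse = ", "))
  asc <- !higher_is_better[[characteristic]]
  ok <- table[table$status == "ok" & !is.na(table[[characteristic]]), ,
              drop = FALSE]
  rank_rows <- list(); diff_rows <- list()
  for (p0 in unique(ok$p0)) {
    sub <- ok[ok$p0 == p0, , drop = FALSE]
    v <- sub[[characteristic]]
    rk <- rank(if (asc) v else -v, ties.method = "min")
    rank_rows[[length(rank_rows) + 1L]] <-
      data.frame(p0 = p0, design = sub$design, value = v, rank = rk)
    if (nrow(sub) > 1L) {
      pairs <- utils::combn(seq_len(nrow(sub)), 2L)
      diff_rows[[length(diff_rows) + 1L]] <- data.frame(
        p0 = p0,
        design_a = sub$design[pairs[1L, ]],
        design_b = sub$design[pairs[2L, ]],
        difference = v[pairs[1L, ]] - v[pairs[2L, ]])
    }
  }
  list(characteristic = characteristic,
       ranking = do.call(rbind, c(rank_rows,
                                  list(make.row.names = FALSE))),
       differences = if (length(diff_rows))
         do.call(rbind, c(diff_rows, list(make.row.names = FALSE)))
       else NULL)
}

round_payload <- function(df) {
  # documented output precision: tuples exact, probabilities 4 decimals,
  # expected sample sizes 2 decimals
  for (col in c("ratio", "pet_p0", "pet_pa", "alpha_d", "alpha_no_stop",
                "power_d"))
    df[[col]] <- round(df[[col]], 4)
  for (col in c("en_p0", "en_pa")) df[[col]] <- round(df[[col]], 2)
  df
}

#' Write a comparison table as CSV
#'
#' One row per (scenario, design family), fixed column order
#' `p0, pa, alpha, beta, design, r1, n1, r, n, ratio, pet_p0, pet_pa,
#' alpha_d, alpha_no_stop, power_d, en_p0, en_pa, status`.  Probabilities are
#' written with 4 decimals and expected sample sizes with 2; the payload
#' carries no timestamp, so output for a fixed input is byte-identical.
#'
#' @param table A `"comparison_table"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(table, path) {
  stopifnot(inherits(table, "comparison_table"))
  utils::write.csv(round_payload(as.data.frame(table)), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a comparison table as JSON, nested by scenario
#'
#' @inheritParams write_comparison_csv
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(table, path) {
  stopifnot(inherits(table, "comparison_table"))
  df <- round_payload(as.data.frame(table))
  scenarios <- lapply(unique(df$p0), function(p0) {
    sub <- df[df$p0 == p0, , drop = FALSE]
    list(p0 = p0, pa = sub$pa[1L], alpha = sub$alpha[1L], beta = sub$beta[1L],
         designs = lapply(seq_len(nrow(sub)), function(i)
           as.list(sub[i, setdiff(names(sub),
                                  c("p0", "pa", "alpha", "beta"))])))
  })
  jsonlite::write_json(scenarios, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
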