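test_that("single_stage_design reproduces known sizes and a brute-force
           oracle", {
  ss <- single_stage_design(worked_params())
  expect_equal(ss$n, 62)
  expect_equal(ss$r, 21)

  # extreme separation, checked against an exhaustive (n, r) scan
  pars <- design_params(0.05, 0.80)
  o <- oracle_single_stage(0.05, 0.80, 0.05, 0.20)
  ss2 <- single_stage_design(pars)
  expect_equal(ss2$n, o$n)
  expect_equal(ss2$r, o$r)

  # tightening the power requirement never shrinks n
  n_loose <- single_stage_design(design_params(0.2, 0.35, beta = 0.2))$n
  n_tight <- single_stage_design(design_params(0.2, 0.35, beta = 0.1))$n
  expect_gte(n_tight, n_loose)

  expect_error(single_stage_design(design_params(0.50, 0.51), cap = 100),
               class = "optifut_infeasible")
})

test_that("enumerate_feasible_designs yields exactly the feasible tuples", {
  pars <- design_params(0.05, 0.25)
  tab <- enumerate_feasible_designs(pars, n_max = 25)
  expect_gt(nrow(tab), 0)

  # spot-check rows against the independent joint-enumeration oracle
  set.seed(5)
  idx <- sample(nrow(tab), min(25, nrow(tab)))
  for (i in idx) {
    row <- tab[i, ]
    o0 <- oracle_joint(row$r1, row$n1, row$r, row$n, pars$p0)
    oa <- oracle_joint(row$r1, row$n1, row$r, row$n, pars$pa)
    expect_lt(abs(row$alpha_d - o0$reject), 1e-10)
    expect_lt(abs(row$power_d - oa$reject), 1e-10)
    expect_lte(row$alpha_d, pars$alpha + 1e-12)
    expect_gte(row$power_d, 1 - pars$beta - 1e-12)
  }

  # completeness on a tiny space: no feasible tuple is missed
  missed <- 0L
  for (n in 2:12) for (n1 in 1:(n - 1)) for (r1 in 0:n1) for (r in r1:n) {
    o0 <- oracle_joint(r1, n1, r, n, pars$p0)
    oa <- oracle_joint(r1, n1, r, n, pars$pa)
    feasible <- o0$reject <= pars$alpha && oa$reject >= 1 - pars$beta
    listed <- any(tab$r1 == r1 & tab$n1 == n1 & tab$r == r & tab$n == n)
    if (feasible != listed) missed <- missed + 1L
  }
  expect_identical(missed, 0L)
})

test_that("the feasible stream contains the published minimax tuple and is
           empty below the minimax n", {
  tab60 <- enumerate_feasible_designs(worked_params(), n_max = 60)
  expect_true(any(tab60$r1 == 16 & tab60$n1 == 51 &
                    tab60$r == 20 & tab60$n == 60))
  # 60 is the minimal feasible total n for this problem, so any smaller
  # envelope leaves the stream empty (note: the single-stage n is 62 -- a
  # feasible two-stage design may undercut it)
  expect_identical(nrow(enumerate_feasible_designs(worked_params(),
                                                   n_max = 45)), 0L)
})

test_that("Simon searches match the published designs and certify on a
           reduced problem", {
  pars <- worked_params()
  opt <- simon_optimal(pars)
  expect_identical(unlist(opt), c(r1 = 5L, n1 = 20L, r = 23L, n = 71L))
  mm <- simon_minimax(pars)
  expect_identical(unlist(mm), c(r1 = 16L, n1 = 51L, r = 20L, n = 60L))
  expect_lte(mm$n, opt$n)

  # exhaustive certification on a reduced problem
  red <- design_params(0.05, 0.25)
  cfg <- search_config(n_max = 30)
  all30 <- enumerate_feasible_designs(red, 30)
  ropt <- simon_optimal(red, cfg)
  expect_equal(expected_sample_size(ropt, red$p0), min(all30$en_p0),
               tolerance = 1e-12)
  rmm <- simon_minimax(red, cfg)
  expect_identical(rmm$n, min(all30$n))

  expect_error(simon_optimal(red, search_config(n_max = 5)),
               class = "optifut_infeasible")
})

test_that("kim_modified applies its two constraints and collapses to Simon
           when they are vacuous", {
  pars <- worked_params()
  cn <- admissible_constraints()
  ko <- kim_modified(pars, cn, variant = "optimal")
  expect_identical(unlist(ko), c(r1 = 6L, n1 = 24L, r = 22L, n = 67L))
  km <- kim_modified(pars, cn, variant = "minimax")
  expect_identical(unlist(km), c(r1 = 10L, n1 = 40L, r = 21L, n = 62L))
  for (d in list(ko, km)) {
    expect_lte(pet(d, pars$pa), 0.1)
    expect_gte(d$n1 / d$n, 1 / 3 - 1e-9)
    expect_lte(d$n1 / d$n, 2 / 3 + 1e-9)
  }

  vacuous <- admissible_constraints(pet_pa_bound_kim = 1,
                                    ratio_lower = 1e-9,
                                    ratio_upper = 1 - 1e-9)
  red <- design_params(0.05, 0.25)
  cfg <- search_config(n_max = 30)
  expect_identical(unlist(kim_modified(red, vacuous, cfg, "optimal")),
                   unlist(simon_optimal(red, cfg)))
  expect_identical(unlist(kim_modified(red, vacuous, cfg, "minimax")),
                   unlist(simon_minimax(red, cfg)))

  # under n_max = 30 the smallest attainable PET(pa) is 0.75^29 ~ 2e-4, so a
  # 1e-5 bound empties the set and the error must name it
  err <- tryCatch(
    kim_modified(red, admissible_constraints(pet_pa_bound_kim = 1e-5), cfg),
    optifut_infeasible = function(e) conditionMessage(e))
  expect_match(err, "PET\\(pa\\)")
  # a ratio band above the largest attainable interim fraction (29/30)
  err2 <- tryCatch(
    kim_modified(red, admissible_constraints(ratio_lower = 0.97,
                                             ratio_upper = 0.99), cfg),
    optifut_infeasible = function(e) conditionMessage(e))
  expect_match(err2, "ratio")
})

test_that("optimized_futility_design fixes (r, n) at the single-stage values
           and maximizes PET(p0) subject to its constraints", {
  pars <- worked_params()
  cn <- admissible_constraints()
  d <- optimized_futility_design(pars, cn)
  expect_identical(unlist(d), c(r1 = 10L, n1 = 39L, r = 21L, n = 62L))

  oc <- operating_characteristics(d, pars)
  expect_lte(oc$pet_pa, cn$pi_wrong + 1e-12)
  expect_gte(oc$power_d, 1 - pars$beta - cn$pow_loss)
  expect_lte(oc$alpha_no_stop, pars$alpha)

  # certification: no admissible (n1, r1) pair beats the returned PET(p0),
  # using the independent oracle for the constraint probabilities
  ss <- single_stage_design(pars)
  best_pet <- pet(d, pars$p0)
  for (n1 in seq_len(ss$n - 1)) {
    if (n1 / ss$n < 1 / 3 - 1e-9 || n1 / ss$n > 2 / 3 + 1e-9) next
    for (r1 in 0:n1) {
      if (pbinom(r1, n1, pars$pa) > cn$pi_wrong + 1e-12) break
      cand <- two_stage_design(r1, n1, ss$r, ss$n)
      if (reject_probability(cand, pars$pa) <
            1 - pars$beta - cn$pow_loss) next
      expect_lte(pet(cand, pars$p0), best_pet + 1e-12)
    }
  }
})

test_that("optimized search reports which constraint bound an empty set", {
  pars <- worked_params()
  msg_pet <- tryCatch(
    optimized_futility_design(pars, admissible_constraints(pi_wrong = 1e-12)),
    optifut_infeasible = function(e) conditionMessage(e))
  expect_match(msg_pet, "PET\\(pa\\)")

  msg_ratio <- tryCatch(
    optimized_futility_design(pars,
      admissible_constraints(ratio_lower = 0.985, ratio_upper = 0.995)),
    optifut_infeasible = function(e) conditionMessage(e))
  expect_match(msg_ratio, "ratio")

  expect_error(
    optimized_futility_design(pars, admissible_constraints(pow_loss = 0.9)),
    class = "optifut_argument_error")
})

test_that("tightening pi_wrong/pow_loss changes only (r1, n1) and never
           raises PET(p0)", {
  pars <- worked_params()
  ladder <- c(0.05, 0.025, 0.0125)
  prev_pet <- Inf
  for (v in ladder) {
    d <- optimized_futility_design(
      pars, admissible_constraints(pow_loss = v, pi_wrong = v))
    expect_identical(c(d$r, d$n), c(21L, 62L))
    p <- pet(d, pars$p0)
    expect_lte(p, prev_pet + 1e-12)
    prev_pet <- p
  }
})
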