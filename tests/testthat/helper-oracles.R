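# Independent oracles: plain double-loop enumeration of the joint stage-1 /
# stage-2 outcome space.  Deliberately naive -- these must not share code
# with the package's vectorized paths.

oracle_joint <- function(r1, n1, r, n, p) {
  n2 <- n - n1
  pet <- sum(dbinom(0:r1, n1, p))
  rej <- 0
  acc <- 0
  if (r1 < n1) {
    for (x1 in (r1 + 1L):n1) {
      for (x2 in 0:n2) {
        pr <- dbinom(x1, n1, p) * dbinom(x2, n2, p)
        if (x1 + x2 > r) rej <- rej + pr else acc <- acc + pr
      }
    }
  }
  list(pet = pet, reject = rej, accept = acc)
}

random_small_design <- function(n_cap = 25L) {
  n <- sample(2:n_cap, 1L)
  n1 <- sample(seq_len(n - 1L), 1L)
  r1 <- sample(0:n1, 1L)
  r <- sample(r1:n, 1L)
  two_stage_design(r1 = r1, n1 = n1, r = r, n = n)
}

# brute-force single-stage oracle: scan every (n, r) pair in order (same
# 1e-12 boundary slack as the package so exactly-attained constraints do not
# flip on rounding)
oracle_single_stage <- function(p0, pa, alpha, beta, cap = 200L) {
  for (n in 1:cap) {
    for (r in 0:n) {
      if (pbinom(r, n, p0, lower.tail = FALSE) <= alpha + 1e-12 &&
          pbinom(r, n, pa, lower.tail = FALSE) >= 1 - beta - 1e-12)
        return(list(n = n, r = r))
    }
  }
  NULL
}

worked_params <- function() design_params(0.25, 0.40, 0.05, 0.20)
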