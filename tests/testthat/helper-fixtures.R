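## Shared fixtures and independent oracles used across the suite.

## Small deterministic cohort for I/O and QC tests.
tiny_cohort <- function(seed = 1, n = 60, m = 30, blocks = 6, ...) {
  cfg <- sim_config(n_samples = n, n_variants = m, n_blocks = blocks,
                    seed = seed, ...)
  simulate_cohort(cfg)
}

binary_outcome_of <- function(sim) {
  classify_response(compute_alda_total(
    sim$phenos$alda_a, sim$phenos[, paste0("alda_b", 1:5)]))
}

## Independent HWE oracle: enumerate every heterozygote count compatible
## with the observed allele totals and sum the exact conditional
## probabilities (direct factorial formula, no recurrences, no shortcuts).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_A <- 2 * n_AA + n_Aa
  if (min(n_a, n_A) == 0) return(1)
  hets <- seq(min(n_a, n_A) %% 2, min(n_a, n_A), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    AA <- (n_A - h) / 2
    exp(lfactorial(n) - lfactorial(AA) - lfactorial(h) - lfactorial(aa) +
          h * log(2) + lfactorial(n_A) + lfactorial(n_a) -
          lfactorial(2 * n))
  }, numeric(1))
  p_obs <- pr[hets == n_Aa]
  sum(pr[pr <= p_obs * (1 + 1e-10)])
}

## Independent hypergeometric enrichment oracle: direct summation of the
## upper tail.
fisher_oracle <- function(k_in, K_set, n_in, N_ref) {
  xs <- k_in:min(K_set, n_in)
  sum(vapply(xs, function(x) {
    exp(lchoose(K_set, x) + lchoose(N_ref - K_set, n_in - x) -
          lchoose(N_ref, n_in))
  }, numeric(1)))
}
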