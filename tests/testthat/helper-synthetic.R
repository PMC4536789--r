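# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except in the explicit I/O round-trip tests.

# A small two-class genome with TADs large enough that many anchors pass
# the in-TAD filter, plus its sampled map.
two_class_pipeline <- function(chrom_len = 4e6, sigma_log = 0.1,
                               seed_genome = 42, seed_map = 43,
                               S1 = 4.15, S4 = 5.296) {
  sp <- genome_spec(
    chromosome_length_bp = chrom_len,
    tad_median_kb = 110, tad_sdlog = 0.2,
    class_proportions = c(D1 = 0.5, D4 = 0.5),
    class_params = list(
      D1 = c(K = 0.852e-9, L = 10.81, S = S1),
      D4 = c(K = 2.405e-9, L = 10.32, S = S4)
    )
  )
  genome <- simulate_genome(sp, seed = seed_genome)
  map <- simulate_contact_map(genome, sigma_log = sigma_log, seed = seed_map)
  list(spec = sp, genome = genome, map = map)
}

# Exhaustive-enumeration Mann-Whitney oracle (no ties): distribution of U
# over all choose(n_a + n_b, n_a) assignments of ranks to the first
# sample; two-sided p doubles the smaller tail (capped at 1).
enumerate_mw_p <- function(x, y) {
  n_a <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, function(idx) sum(seq_along(pooled)[idx]) -
                n_a * (n_a + 1) / 2)
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}
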