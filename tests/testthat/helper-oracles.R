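# Independent oracles, deliberately naive: these re-derive expected values by
# brute force and must never share code with the implementation under test.

# translate-and-compare consequence oracle over the standard genetic code
oracle_consequence <- function(codon, pos, alt) {
  code <- Biostrings::GENETIC_CODE
  mut <- codon
  substr(mut, pos, pos) <- alt
  aa0 <- code[[codon]]
  aa1 <- code[[mut]]
  if (aa0 == "*" && aa1 == "*") return("excluded_other")
  if (aa0 == "*") return("stop_lost")
  if (aa1 == "*") return("stop_gained")
  if (aa0 == aa1) "synonymous" else "missense"
}

# loop-summation window oracle
oracle_window_sum <- function(x, i, w, L) {
  half <- (w - 1) / 2
  lo <- max(1, i - half); hi <- min(L, i + half)
  s <- 0
  for (j in lo:hi) s <- s + x[j]
  s
}

# one-term-per-outcome enumeration of the minimum-likelihood two-sided test
oracle_two_sided_binom <- function(x, n, p) {
  if (n == 0) return(1)
  pmf <- stats::dbinom(0:n, n, p)
  sum(pmf[pmf <= pmf[x + 1] * (1 + 1e-7)])
}

# independently coded BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# a tiny fixed transcript: Met-Lys-Trp-Leu-stop
toy_transcript <- function(id = "TOY1") {
  transcript(id, "ATGAAATGGCTTTAA")
}

# neutral or depleted simulated exome scored end to end; returns profiles,
# regions, truth, and per-transcript codon counts
run_sim_pipeline <- function(scenario, w = 31, fdr = 0.1) {
  sim <- simulate_exome(scenario)
  profs <- lapply(names(sim$transcripts), function(id)
    test_profile(compute_profile(sim$transcripts[[id]], sim$observed[[id]],
                                 sim$possible[[id]], w = w)))
  profs <- adjust_profiles(profs, fdr_threshold = fdr)
  names(profs) <- names(sim$transcripts)
  regions <- call_regions(profs, fdr_threshold = fdr)
  n_codons <- vapply(sim$transcripts, function(t) t$n_codons, integer(1))
  list(sim = sim, profiles = profs, regions = regions,
       truth = sim$truth, n_codons = n_codons)
}

# depleted-region scenario used by the recovery and direction checks:
# one 60-codon region per 400-codon transcript, missense retention rho
depleted_scenario <- function(seed, n_transcripts = 20, rho = 0.2,
                              region_len = 60, len = 400, pi_obs = 0.6) {
  set.seed(seed)
  starts <- sample(seq_len(len - region_len + 1), n_transcripts, replace = TRUE)
  simulation_scenario(
    seed = seed, n_transcripts = n_transcripts,
    length_range = c(len, len), pi_obs = pi_obs,
    depleted_regions = data.frame(
      transcript = seq_len(n_transcripts), start_codon = starts,
      end_codon = starts + region_len - 1L, rho = rho))
}
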