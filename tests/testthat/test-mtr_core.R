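test_that("window_bounds matches the truncated-window arithmetic", {
  expect_equal(window_bounds(16, 31, 100), list(lo = 1L, hi = 31L))
  expect_equal(window_bounds(1, 31, 100), list(lo = 1L, hi = 16L))
  expect_equal(window_bounds(100, 41, 100), list(lo = 80L, hi = 100L))
  expect_error(window_bounds(5, 30, 100), "invalid-parameter")
  expect_error(window_bounds(5, -3, 100), "invalid-parameter")
  expect_error(window_bounds(0, 31, 100), "invalid-parameter")
})

test_that("aggregate_window equals loop summation on random tallies", {
  set.seed(42)
  for (rep in 1:100) {
    L <- sample(5:120, 1)
    counts <- data.frame(
      codon_index = 1:L,
      mis_obs = rpois(L, 2), syn_obs = rpois(L, 1),
      mis_exp = rep(7L, L), syn_exp = rep(2L, L))
    i <- sample(L, 1)
    w <- sample(c(3, 5, 21, 31, 41), 1)
    wc <- aggregate_window(counts, i, w)
    for (col in c("mis_obs", "syn_obs", "mis_exp", "syn_exp")) {
      expect_equal(wc[[col]], oracle_window_sum(counts[[col]], i, w, L),
                   label = paste(col, "i =", i, "w =", w, "L =", L))
    }
  }
})

test_that("aggregate_window handles degenerate tallies", {
  counts <- data.frame(codon_index = 1:10, mis_obs = 0L, syn_obs = 0L,
                       mis_exp = 0L, syn_exp = 0L)
  wc <- aggregate_window(counts, 5, 5)
  expect_equal(wc$mis_obs + wc$syn_obs + wc$mis_exp + wc$syn_exp, 0L)
  counts$mis_obs[7] <- 4L
  expect_equal(aggregate_window(counts, 5, 5)$mis_obs, 4L)
  expect_equal(aggregate_window(counts, 2, 5)$mis_obs, 0L)
})

test_that("compute_mtr reproduces the ratio-of-proportions arithmetic", {
  expect_equal(compute_mtr(list(mis_obs = 10, syn_obs = 5,
                                mis_exp = 210, syn_exp = 70)),
               (10 / 15) / (210 / 280))
  expect_equal(compute_mtr(list(mis_obs = 21, syn_obs = 7,
                                mis_exp = 210, syn_exp = 70)), 1.0)
  expect_equal(compute_mtr(list(mis_obs = 0, syn_obs = 8,
                                mis_exp = 210, syn_exp = 70)), 0.0)
  expect_true(is.na(compute_mtr(list(mis_obs = 0, syn_obs = 0,
                                     mis_exp = 210, syn_exp = 70))))
  expect_error(compute_mtr(list(mis_obs = 1, syn_obs = 1,
                                mis_exp = 0, syn_exp = 0)),
               "degenerate-window")
})

test_that("MTR is invariant under scaling all four window tallies", {
  set.seed(7)
  for (rep in 1:50) {
    wc <- list(mis_obs = sample(1:50, 1), syn_obs = sample(0:20, 1),
               mis_exp = sample(50:300, 1), syn_exp = sample(10:100, 1))
    k <- sample(2:9, 1)
    scaled <- lapply(wc, function(v) v * k)
    expect_equal(compute_mtr(scaled), compute_mtr(wc))
  }
})

test_that("profiles are all-NA with no observed variants and exactly 1 at saturation", {
  t <- generate_transcript(50, 11)
  pv <- enumerate_possible_variants(t)
  empty <- compute_profile(t, data.frame(), pv, w = 31)
  expect_equal(nrow(empty), 50L)
  expect_true(all(is.na(empty$mtr)))
  # observed = all possible -> proportions identical by construction
  sat <- pv; sat$origin <- "observed"
  prof <- compute_profile(t, sat, pv, w = 31)
  expect_true(all(prof$mtr == 1.0))
})

test_that("duplicate observed records count once", {
  t <- transcript("T", "ATGAAATGGCTTTAA")
  obs1 <- annotate_observed(t, data.frame(pos = 6, ref = "A", alt = "G"),
                            mode = "cds")
  obs2 <- annotate_observed(t, data.frame(pos = c(6, 6), ref = "A",
                                          alt = "G"), mode = "cds")
  p1 <- compute_profile(t, obs1, w = 31)
  p2 <- compute_profile(t, obs2, w = 31)
  expect_equal(p1$mtr, p2$mtr)
  expect_equal(p2$syn_obs[1], 1L)
})

test_that("interior MTR is translation-invariant for uniform counts", {
  # transcript of identical codons: every interior window sees the same tallies
  t <- transcript("T", paste(rep("AAG", 61), collapse = ""))
  pv <- enumerate_possible_variants(t)
  # same two missense + one synonymous change in every codon
  obs <- pv[(pv$cds_pos %% 3 == 1 & pv$alt %in% c("C", "G")) |
              (pv$cds_pos %% 3 == 0 & pv$alt == "A"), ]
  obs$origin <- "observed"
  prof <- compute_profile(t, obs, pv, w = 21)
  interior <- prof$mtr[11:51]
  expect_true(all(abs(interior - interior[1]) < 1e-12))
})

test_that("population filter equals no filter when every record shares the label", {
  t <- generate_transcript(40, 23)
  pv <- enumerate_possible_variants(t)
  sc <- simulation_scenario(seed = 23, n_transcripts = 1,
                            length_range = c(40, 40), pi_obs = 0.7)
  obs <- sample_observed(t, pv, sc)
  obs$population <- "ALL"
  p_all <- compute_profile(t, obs, pv, w = 31, population = "ALL")
  p_none <- compute_profile(t, obs, pv, w = 31)
  expect_equal(p_all$mtr, p_none$mtr)
  # absent label warns and yields an all-NA profile
  expect_warning(p_empty <- compute_profile(t, obs, pv, w = 31,
                                            population = "nope"),
                 "empty-population")
  expect_true(all(is.na(p_empty$mtr)))
})

test_that("ethnicity_profiles enforces the sample-size and window rules", {
  t <- generate_transcript(30, 31)
  pv <- enumerate_possible_variants(t)
  sc <- simulation_scenario(seed = 31, n_transcripts = 1,
                            length_range = c(30, 30), pi_obs = 0.8,
                            populations = c(A = 0.7, B = 0.3))
  obs <- sample_observed(t, pv, sc)
  res <- suppressMessages(
    ethnicity_profiles(t, obs, pv, populations = c(A = 20000, B = 1000)))
  expect_setequal(names(res), c("A.w31", "A.w41"))
  # 21-codon windows are refused for stratified profiles under defaults
  expect_error(
    ethnicity_profiles(t, obs, pv, populations = c(A = 20000), w_set = 21),
    "invalid-parameter")
  # threshold overridden to 0 stratifies every label
  res0 <- ethnicity_profiles(t, obs, pv,
                             populations = c(A = 20000, B = 1000),
                             min_exomes = 0)
  expect_equal(length(res0), 4L)
})
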