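#' Exact binomial probability mass
#'
#' Computed in log space (`lchoose`), so it is stable for large `n`.
#'
#' @param n Number of trials (scalar).
#' @param x Number of successes (scalar or vector).
#' @param p Success probability.
#' @return `P(X = x)` for `X ~ Binomial(n, p)`.
#' @export
binom_pmf <- function(n, x, p) {
  if (length(n) != 1L || length(p) != 1L || is.na(n) || is.na(p) ||
      n < 0 || p < 0 || p > 1 || any(x < 0 | x > n)) {
    stop("invalid-parameter error: need 0 <= x <= n and 0 <= p <= 1",
         call. = FALSE)
  }
  if (p == 0) return(as.numeric(x == 0))
  if (p == 1) return(as.numeric(x == n))
  exp(lchoose(n, x) + x * log(p) + (n - x) * log1p(-p))
}

#' Two-sided exact binomial test (minimum-likelihood method)
#'
#' The two-sided p-value is the sum of `P(X = k)` over every outcome `k` whose
#' probability does not exceed that of the observed outcome (up to a relative
#' tolerance of 1e-7 guarding against floating-point ties). `n = 0` returns 1.
#'
#' @param x Observed successes.
#' @param n Trials.
#' @param p Null success probability.
#' @return Two-sided p-value in (0, 1].
#' @export
binom_exact_test <- function(x, n, p) {
  if (n == 0) return(1)
  pmf <- binom_pmf(n, 0:n, p)
  obs <- pmf[x + 1L]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `NA` entries are excluded from the ranking (the family size `m` counts
#' non-`NA` tests only) and returned as `NA`.
#'
#' @param raw_p Vector of raw p-values in (0, 1], possibly with `NA`s.
#' @return Vector of BH q-values, same length and order as the input.
#' @export
bh_adjust <- function(raw_p) {
  q <- rep(NA_real_, length(raw_p))
  ok <- !is.na(raw_p)
  if (any(ok)) q[ok] <- stats::p.adjust(raw_p[ok], method = "BH")
  q
}

#' Fill per-codon raw p-values in an MTR profile
#'
#' At each codon the test uses the window tallies: `n = mis_obs + syn_obs`
#' observed variants, `x = mis_obs` missense among them, against the null
#' proportion `p = mis_exp / (mis_exp + syn_exp)` from the possible variants
#' of the same window. Windows with no observed variants get `raw_p = NA`.
#'
#' @param profile An `mtr_profile`.
#' @return The profile with `raw_p` filled.
#' @export
test_profile <- function(profile) {
  stopifnot(inherits(profile, "mtr_profile"))
  n <- profile$mis_obs + profile$syn_obs
  x <- profile$mis_obs
  p0 <- profile$mis_exp / (profile$mis_exp + profile$syn_exp)
  raw <- rep(NA_real_, nrow(profile))
  todo <- which(n > 0)
  if (length(todo)) {
    # adjacent windows often share tallies; test each distinct triple once
    key <- paste(x[todo], n[todo], signif(p0[todo], 12))
    first <- !duplicated(key)
    pv <- vapply(todo[first],
                 function(i) binom_exact_test(x[i], n[i], p0[i]), numeric(1))
    raw[todo] <- pv[match(key, key[first])]
  }
  profile$raw_p <- raw
  profile
}

#' Apply the FDR adjustment across a set of profiles
#'
#' Joint scope ranks every non-`NA` codon test of every profile in one
#' Benjamini-Hochberg family (exome-wide semantics); per-transcript scope
#' adjusts each profile separately. Sets `fdr_q` and the `significant` flag
#' (`fdr_q < fdr_threshold` and `mtr < 1`).
#'
#' @param profiles A single `mtr_profile` or a list of them (tested with
#'   [test_profile()]).
#' @param fdr_threshold Significance threshold on the q-value (default 0.1).
#' @param scope `"joint"` (default) or `"per_transcript"`.
#' @return A list of profiles with `fdr_q` and `significant` filled (a list of
#'   length one if a single profile was given).
#' @export
adjust_profiles <- function(profiles, fdr_threshold = 0.1,
                            scope = c("joint", "per_transcript")) {
  scope <- match.arg(scope)
  if (inherits(profiles, "mtr_profile")) profiles <- list(profiles)
  if (scope == "per_transcript") {
    return(lapply(profiles, function(pr) {
      pr$fdr_q <- bh_adjust(pr$raw_p)
      pr$significant <- !is.na(pr$fdr_q) & pr$fdr_q < fdr_threshold & pr$mtr < 1
      pr
    }))
  }
  all_p <- unlist(lapply(profiles, function(pr) pr$raw_p), use.names = FALSE)
  all_q <- bh_adjust(all_p)
  off <- 0L
  for (k in seq_along(profiles)) {
    nr <- nrow(profiles[[k]])
    q <- all_q[off + seq_len(nr)]
    profiles[[k]]$fdr_q <- q
    profiles[[k]]$significant <-
      !is.na(q) & q < fdr_threshold & profiles[[k]]$mtr < 1
    off <- off + nr
  }
  profiles
}

#' Call intolerant regions from adjusted profiles
#'
#' A region is a maximal run of consecutive codons with `fdr_q` below the
#' threshold and `MTR < 1`. Codons that are significant but with `MTR >= 1`
#' are tolerant-significant: they are reported in the `tolerant_significant`
#' attribute, never as intolerant regions.
#'
#' @param profiles A single `mtr_profile` or list of them, with `fdr_q` filled
#'   (see [adjust_profiles()]).
#' @param fdr_threshold q-value threshold (default 0.1).
#' @return data.frame with one row per region: `transcript_id`, `population`,
#'   `window_size`, `start_codon`, `end_codon`, `n_codons`, `min_mtr`,
#'   `mean_mtr`, `min_fdr_q`.
#' @export
call_regions <- function(profiles, fdr_threshold = 0.1) {
  if (inherits(profiles, "mtr_profile")) profiles <- list(profiles)
  out <- list()
  tol <- list()
  for (pr in profiles) {
    sig <- !is.na(pr$fdr_q) & pr$fdr_q < fdr_threshold
    dep <- sig & !is.na(pr$mtr) & pr$mtr < 1
    tol_idx <- which(sig & !is.na(pr$mtr) & pr$mtr >= 1)
    if (length(tol_idx)) {
      tol[[length(tol) + 1L]] <- data.frame(
        transcript_id = attr(pr, "transcript_id"), codon_index = tol_idx)
    }
    if (!any(dep)) next
    r <- rle(dep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (k in keep) {
      idx <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = attr(pr, "transcript_id"),
        population = attr(pr, "population"),
        window_size = attr(pr, "window_size"),
        start_codon = starts[k], end_codon = ends[k],
        n_codons = length(idx),
        min_mtr = min(pr$mtr[idx]),
        mean_mtr = mean(pr$mtr[idx]),
        min_fdr_q = min(pr$fdr_q[idx]),
        stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(out)) do.call(rbind, out) else data.frame(
    transcript_id = character(), population = character(),
    window_size = integer(), start_codon = integer(), end_codon = integer(),
    n_codons = integer(), min_mtr = numeric(), mean_mtr = numeric(),
    min_fdr_q = numeric(), stringsAsFactors = FALSE)
  attr(regions, "tolerant_significant") <-
    if (length(tol)) do.call(rbind, tol) else
      data.frame(transcript_id = character(), codon_index = integer())
  regions
}

#' Mann-Whitney rank-sum comparison of two score distributions
#'
#' Exact enumeration when both groups have at most 12 observations and no
#' ties; the tie-corrected normal approximation otherwise. The one-sided
#' alternative `"less"` tests for lower scores in group `a`.
#'
#' @param scores_a,scores_b Non-empty numeric vectors (e.g. per-variant MTR).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A list with `U` (the Mann-Whitney statistic for `a` vs `b`) and
#'   `p.value`.
#' @export
rank_sum_compare <- function(scores_a, scores_b,
                             alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(scores_a) == 0L || length(scores_b) == 0L ||
      anyNA(scores_a) || anyNA(scores_b)) {
    stop("invalid-input error: both score vectors must be non-empty and free of NA",
         call. = FALSE)
  }
  small <- length(scores_a) <= 12L && length(scores_b) <= 12L
  ties <- anyDuplicated(c(scores_a, scores_b)) > 0L
  wt <- suppressWarnings(stats::wilcox.test(
    scores_a, scores_b, alternative = alternative,
    exact = small && !ties, correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value)
}

#' Enrichment of low scores in cases versus controls
#'
#' For each cutoff, builds the 2x2 table of below-cutoff versus at-or-above
#' cutoff counts in cases and controls, reports the odds ratio (with a Haldane
#' 0.5 continuity correction when any cell is zero), the two-sided Fisher
#' exact p-value, and the percentage of each group below the cutoff.
#'
#' @param scores_case,scores_control Non-empty numeric score vectors.
#' @param cutoffs Score cutoffs (default `c(0.25, 0.5)`).
#' @return data.frame with one row per cutoff: `cutoff`, `odds_ratio`,
#'   `fisher_p`, `case_pct`, `control_pct` and the four cell counts.
#' @export
low_mtr_enrichment <- function(scores_case, scores_control,
                               cutoffs = c(0.25, 0.5)) {
  if (length(scores_case) == 0L || length(scores_control) == 0L) {
    stop("invalid-input error: empty score vector", call. = FALSE)
  }
  rows <- lapply(cutoffs, function(cut) {
    a <- sum(scores_case < cut);    b <- sum(scores_case >= cut)
    cc <- sum(scores_control < cut); d <- sum(scores_control >= cut)
    if (any(c(a, b, cc, d) == 0)) {
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      or <- (a * d) / (b * cc)
    }
    fp <- stats::fisher.test(matrix(c(a, cc, b, d), nrow = 2))$p.value
    data.frame(cutoff = cut, odds_ratio = or, fisher_p = fp,
               case_pct = 100 * a / (a + b), control_pct = 100 * cc / (cc + d),
               n_case_below = a, n_case_above = b,
               n_control_below = cc, n_control_above = d)
  })
  do.call(rbind, rows)
}
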