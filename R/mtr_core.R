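#' Truncated sliding-window bounds
#'
#' The window centred at codon `i` spans `[H, J]` with
#' `H = max(1, i - (w-1)/2)` and `J = min(L, i + (w-1)/2)`, i.e. it is
#' truncated at the transcript termini rather than shrunk symmetrically.
#'
#' @param i Codon index (may be a vector), 1-based.
#' @param w Odd window size in codons (>= 3).
#' @param L Transcript length in codons.
#' @return A list with integer vectors `lo` (H) and `hi` (J).
#' @export
window_bounds <- function(i, w, L) {
  w <- as.integer(w)
  if (length(w) != 1L || is.na(w) || w < 3L || w %% 2L == 0L) {
    stop("invalid-parameter error: window size must be an odd integer >= 3",
         call. = FALSE)
  }
  i <- as.integer(i)
  if (any(i < 1L | i > L)) {
    stop("invalid-parameter error: codon index out of range 1..", L, call. = FALSE)
  }
  half <- (w - 1L) %/% 2L
  list(lo = pmax(1L, i - half), hi = pmin(as.integer(L), i + half))
}

#' Per-codon observed/expected missense and synonymous tallies
#'
#' Counts distinct (cds_pos, alt) variant alleles per codon. Only missense and
#' synonymous consequences contribute; stop-type and excluded labels are
#' dropped from both the observed and the expected tallies.
#'
#' @param possible Site-variant data.frame from [enumerate_possible_variants()].
#' @param observed Site-variant data.frame from [annotate_observed()] (may be
#'   empty).
#' @param n_codons Transcript length in codons.
#' @return data.frame with columns `codon_index`, `mis_obs`, `syn_obs`,
#'   `mis_exp`, `syn_exp` (one row per codon).
#' @export
site_counts <- function(possible, observed, n_codons) {
  tally <- function(v, what) {
    if (nrow(v) == 0L || is.null(v$consequence)) {
      return(tabulate(integer(0), nbins = n_codons))
    }
    keep <- v$consequence == what
    tabulate(v$codon_index[keep], nbins = n_codons)
  }
  if (nrow(observed) > 0L) {
    observed <- observed[!duplicated(paste(observed$cds_pos, observed$alt)), ,
                         drop = FALSE]
  }
  data.frame(
    codon_index = seq_len(n_codons),
    mis_obs = tally(observed, "missense"),
    syn_obs = tally(observed, "synonymous"),
    mis_exp = tally(possible, "missense"),
    syn_exp = tally(possible, "synonymous")
  )
}

#' Sum per-codon tallies over one sliding window
#'
#' @param counts Per-codon tallies from [site_counts()].
#' @param i Window centre (codon index).
#' @param w Odd window size.
#' @return One-row data.frame with `center`, `lo`, `hi`, `window_size` and the
#'   four summed tallies.
#' @export
aggregate_window <- function(counts, i, w) {
  L <- nrow(counts)
  b <- window_bounds(i, w, L)
  idx <- b$lo:b$hi
  data.frame(
    center = as.integer(i), lo = b$lo, hi = b$hi, window_size = as.integer(w),
    mis_obs = sum(counts$mis_obs[idx]), syn_obs = sum(counts$syn_obs[idx]),
    mis_exp = sum(counts$mis_exp[idx]), syn_exp = sum(counts$syn_exp[idx])
  )
}

# windowed sums for all centres at once via cumulative sums
window_sums <- function(x, lo, hi) {
  cs <- cumsum(x)
  cs[hi] - ifelse(lo > 1L, cs[lo - 1L], 0)
}

#' Missense tolerance ratio of one window
#'
#' `MTR = [mis_obs / (mis_obs + syn_obs)] / [mis_exp / (mis_exp + syn_exp)]`.
#' Windows with no observed variants yield `NA`; a window with no possible
#' missense variants is degenerate and raises an error (cannot occur for a
#' non-empty coding window).
#'
#' @param wc One-row window-counts data.frame from [aggregate_window()], or any
#'   list with the four tallies.
#' @return MTR value, or `NA` when `mis_obs + syn_obs == 0`.
#' @export
compute_mtr <- function(wc) {
  obs_tot <- wc$mis_obs + wc$syn_obs
  exp_tot <- wc$mis_exp + wc$syn_exp
  if (exp_tot == 0 || wc$mis_exp == 0) {
    stop("degenerate-window error: no expected missense variation in window",
         call. = FALSE)
  }
  if (obs_tot == 0) return(NA_real_)
  (wc$mis_obs / obs_tot) / (wc$mis_exp / exp_tot)
}

#' Compute a per-codon MTR profile for a transcript
#'
#' Builds per-codon observed/expected tallies from distinct variant alleles,
#' sums them over the truncated sliding window at every codon, and forms the
#' MTR ratio. `raw_p`, `fdr_q` and `significant` are left `NA` here; they are
#' filled by [test_profile()] and [adjust_profiles()].
#'
#' @param t An `mtr_transcript`.
#' @param observed Observed site variants (from [annotate_observed()]).
#' @param possible Possible site variants (from
#'   [enumerate_possible_variants()]); computed when `NULL`.
#' @param w Odd window size in codons (default 31).
#' @param population Optional population label; observed variants are
#'   restricted to that label. If no observed record carries the label a
#'   warning is raised and an all-`NA` profile returned.
#' @return An `mtr_profile`: a data.frame with one row per codon
#'   (`codon_index`, `lo`, `hi`, the four window tallies, `mtr`, `raw_p`,
#'   `fdr_q`, `significant`) and attributes `transcript_id`, `window_size`,
#'   `population`.
#' @export
compute_profile <- function(t, observed, possible = NULL, w = 31L,
                            population = NULL) {
  stopifnot(inherits(t, "mtr_transcript"))
  if (is.null(possible)) possible <- enumerate_possible_variants(t)
  observed <- as.data.frame(observed)
  if (!is.null(population) && nrow(observed) > 0L) {
    keep <- !is.na(observed$population) & observed$population == population
    if (!any(keep)) {
      warning("empty-population warning: no observed variants labelled '",
              population, "'", call. = FALSE)
    }
    observed <- observed[keep, , drop = FALSE]
  }
  L <- t$n_codons
  counts <- site_counts(possible, observed, L)
  b <- window_bounds(seq_len(L), w, L)
  mis_obs <- window_sums(counts$mis_obs, b$lo, b$hi)
  syn_obs <- window_sums(counts$syn_obs, b$lo, b$hi)
  mis_exp <- window_sums(counts$mis_exp, b$lo, b$hi)
  syn_exp <- window_sums(counts$syn_exp, b$lo, b$hi)
  if (any(mis_exp == 0)) {
    stop("degenerate-window error: window with no possible missense variants",
         call. = FALSE)
  }
  obs_tot <- mis_obs + syn_obs
  mtr <- ifelse(obs_tot == 0, NA_real_,
                (mis_obs / obs_tot) / (mis_exp / (mis_exp + syn_exp)))
  prof <- data.frame(
    codon_index = seq_len(L), lo = b$lo, hi = b$hi,
    mis_obs = mis_obs, syn_obs = syn_obs,
    mis_exp = mis_exp, syn_exp = syn_exp,
    mtr = mtr, raw_p = NA_real_, fdr_q = NA_real_, significant = NA
  )
  structure(prof,
            transcript_id = t$transcript_id,
            window_size = as.integer(w),
            population = if (is.null(population)) NA_character_ else population,
            class = c("mtr_profile", "data.frame"))
}

#' Population-stratified MTR profiles
#'
#' One profile per population whose exome sample size reaches the minimum
#' threshold, for each allowed window size. The defaults mirror the published
#' stratification rule: at least 15 000 exomes, windows 31 and 41 only.
#'
#' @param t An `mtr_transcript`.
#' @param observed Observed site variants with a `population` column.
#' @param possible Possible site variants (computed when `NULL`).
#' @param populations Named numeric vector of per-population exome counts.
#' @param w_set Allowed window sizes (default `c(31, 41)`).
#' @param min_exomes Minimum exome count (default 15000; set 0 to stratify on
#'   every label).
#' @param allowed_windows Window sizes permitted for stratified profiles;
#'   requesting a window outside this set is an error.
#' @return Named list of `mtr_profile` objects, names `"<population>.w<w>"`.
#'   Populations below the threshold are skipped with a message.
#' @export
ethnicity_profiles <- function(t, observed, possible = NULL, populations,
                               w_set = c(31L, 41L), min_exomes = 15000,
                               allowed_windows = c(31L, 41L)) {
  if (is.null(names(populations)) || any(!nzchar(names(populations)))) {
    stop("populations must be a named vector of exome counts", call. = FALSE)
  }
  if (!all(w_set %in% allowed_windows)) {
    stop("invalid-parameter error: stratified profiles allow windows {",
         paste(allowed_windows, collapse = ", "), "} only", call. = FALSE)
  }
  if (is.null(possible)) possible <- enumerate_possible_variants(t)
  out <- list()
  for (pop in names(populations)) {
    if (populations[[pop]] < min_exomes) {
      message("skipping population '", pop, "': ", populations[[pop]],
              " exomes < threshold ", min_exomes)
      next
    }
    for (w in w_set) {
      out[[paste0(pop, ".w", w)]] <-
        compute_profile(t, observed, possible, w = w, population = pop)
    }
  }
  out
}

#' @export
print.mtr_profile <- function(x, ...) {
  cat("mtr_profile:", attr(x, "transcript_id"),
      "| window", attr(x, "window_size"),
      "| population", attr(x, "population"), "\n")
  cat(" ", nrow(x), "codons;", sum(!is.na(x$mtr)), "with defined MTR;",
      sum(x$significant %in% TRUE), "significant\n")
  invisible(x)
}
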