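#' Define a simulation scenario
#'
#' A scenario states the world a synthetic exome is drawn from: how many
#' transcripts, their codon-length range, the per-variant observation
#' probability, optional regions under purifying selection (where possible
#' missense variants are observed at a reduced rate), and an optional
#' population mixture. The same seed always yields bit-identical output;
#' per-transcript random streams are split from the scenario seed, so results
#' do not depend on transcript order.
#'
#' @param seed Integer seed.
#' @param n_transcripts Number of transcripts (>= 1).
#' @param length_range Two-element integer vector, codon-length range
#'   (uniform draw; both ends >= 10).
#' @param pi_obs Per-variant observation probability in (0, 1]: each possible
#'   synonymous variant is observed independently with probability `pi_obs`,
#'   each possible missense variant with `pi_obs * rho` of its codon.
#' @param depleted_regions `NULL`, or data.frame with columns
#'   `transcript` (1-based index), `start_codon`, `end_codon`, `rho`
#'   (missense retention in `[0, 1]`; `rho = 1` means neutral).
#' @param populations Optional named numeric vector of mixture proportions
#'   (summing to 1) used to label observed variants.
#' @return A `sim_scenario` list.
#' @export
simulation_scenario <- function(seed = 1L, n_transcripts = 20L,
                                length_range = c(400L, 400L), pi_obs = 0.6,
                                depleted_regions = NULL, populations = NULL) {
  stopifnot(length(length_range) == 2L)
  if (n_transcripts < 1L) stop("schema error: n_transcripts must be >= 1",
                               call. = FALSE)
  if (any(length_range < 10L)) stop("schema error: transcript length must be >= 10 codons",
                                    call. = FALSE)
  if (!(pi_obs > 0 && pi_obs <= 1)) stop("schema error: pi_obs must be in (0, 1]",
                                         call. = FALSE)
  if (!is.null(depleted_regions)) {
    depleted_regions <- as.data.frame(depleted_regions)
    need <- c("transcript", "start_codon", "end_codon", "rho")
    if (!all(need %in% names(depleted_regions))) {
      stop("schema error: depleted_regions needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (any(depleted_regions$rho < 0 | depleted_regions$rho > 1)) {
      stop("schema error: rho must lie in [0, 1]", call. = FALSE)
    }
    if (any(depleted_regions$start_codon > depleted_regions$end_codon) ||
        any(depleted_regions$start_codon < 1L)) {
      stop("schema error: bad region bounds", call. = FALSE)
    }
  }
  if (!is.null(populations)) {
    if (is.null(names(populations)) ||
        abs(sum(populations) - 1) > 1e-8 || any(populations < 0)) {
      stop("schema error: populations must be named proportions summing to 1",
           call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed),
                 n_transcripts = as.integer(n_transcripts),
                 length_range = as.integer(length_range),
                 pi_obs = pi_obs,
                 depleted_regions = depleted_regions,
                 populations = populations),
            class = "sim_scenario")
}

# deterministic per-transcript substream seed, kept within 32-bit range
.sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a random transcript with no internal stop codons
#'
#' Starts with ATG, continues with codons drawn uniformly from the 61
#' sense codons, and ends with a uniformly drawn stop codon (excluded from
#' `n_codons`). Deterministic under the seed.
#'
#' @param length_codons Number of amino-acid codons (>= 10).
#' @param seed Integer seed.
#' @param transcript_id Identifier (default derived from the seed).
#' @return An `mtr_transcript` with `n_codons == length_codons`.
#' @export
generate_transcript <- function(length_codons, seed,
                                transcript_id = sprintf("SYN%08d", seed %% 1e8)) {
  if (length_codons < 10L) stop("schema error: length must be >= 10 codons",
                                call. = FALSE)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- setdiff(codons, .STOP_CODONS)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  body <- sample(sense, length_codons - 1L, replace = TRUE)
  stopc <- sample(.STOP_CODONS, 1L)
  transcript(transcript_id, paste0("ATG", paste(body, collapse = ""), stopc))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Sample observed variants from the possible variants of a transcript
#'
#' Independent Bernoulli draw per possible variant: synonymous variants are
#' observed with probability `pi_obs`, missense variants with
#' `pi_obs * rho(codon)` where `rho` comes from the scenario's depleted
#' regions (1 outside them). Stop-type possible variants are never observed
#' (they would be excluded from the tallies regardless). Population labels,
#' when the scenario has a mixture, are drawn per observed variant.
#'
#' @param t An `mtr_transcript`.
#' @param possible Its possible variants ([enumerate_possible_variants()]).
#' @param scenario A `sim_scenario`.
#' @param transcript_index 1-based index of `t` in the scenario (selects the
#'   depleted regions and the random substream).
#' @return data.frame of observed site variants (`origin = "observed"`).
#' @export
sample_observed <- function(t, possible, scenario, transcript_index = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(scenario$seed, transcript_index))

  rho <- rep(1, t$n_codons)
  dr <- scenario$depleted_regions
  if (!is.null(dr)) {
    dr <- dr[dr$transcript == transcript_index, , drop = FALSE]
    for (j in seq_len(nrow(dr))) {
      hi <- min(dr$end_codon[j], t$n_codons)
      rho[dr$start_codon[j]:hi] <- dr$rho[j]
    }
  }
  p <- numeric(nrow(possible))
  mis <- possible$consequence == "missense"
  syn <- possible$consequence == "synonymous"
  p[syn] <- scenario$pi_obs
  p[mis] <- scenario$pi_obs * rho[possible$codon_index[mis]]
  take <- stats::runif(nrow(possible)) < p
  obs <- possible[take, , drop = FALSE]
  obs$origin <- "observed"
  if (!is.null(scenario$populations) && nrow(obs) > 0L) {
    obs$population <- sample(names(scenario$populations), nrow(obs),
                             replace = TRUE, prob = scenario$populations)
  }
  rownames(obs) <- NULL
  obs
}

#' Draw a full synthetic exome
#'
#' Generates every transcript of the scenario and samples its observed
#' variants.
#'
#' @param scenario A `sim_scenario`.
#' @return A list with `transcripts` (named list), `possible` and `observed`
#'   (named lists of site-variant data.frames), and `truth` (data.frame of
#'   depleted-region codons: `transcript_id`, `start_codon`, `end_codon`,
#'   `rho`; empty when the scenario is fully neutral).
#' @export
simulate_exome <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(scenario$seed)
  lens <- if (scenario$length_range[1] == scenario$length_range[2]) {
    rep(scenario$length_range[1], scenario$n_transcripts)
  } else {
    sample(seq.int(scenario$length_range[1], scenario$length_range[2]),
           scenario$n_transcripts, replace = TRUE)
  }
  transcripts <- list(); possible <- list(); observed <- list()
  truth <- list()
  for (k in seq_len(scenario$n_transcripts)) {
    t <- generate_transcript(lens[k], .sub_seed(scenario$seed, 100000L + k),
                             transcript_id = sprintf("SYNT%04d", k))
    pos <- enumerate_possible_variants(t)
    obs <- sample_observed(t, pos, scenario, transcript_index = k)
    transcripts[[t$transcript_id]] <- t
    possible[[t$transcript_id]] <- pos
    observed[[t$transcript_id]] <- obs
    dr <- scenario$depleted_regions
    if (!is.null(dr)) {
      dr <- dr[dr$transcript == k & dr$rho < 1, , drop = FALSE]
      if (nrow(dr)) {
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = t$transcript_id,
          start_codon = dr$start_codon,
          end_codon = pmin(dr$end_codon, t$n_codons),
          rho = dr$rho, stringsAsFactors = FALSE)
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    transcript_id = character(), start_codon = integer(),
    end_codon = integer(), rho = numeric(), stringsAsFactors = FALSE)
  list(transcripts = transcripts, possible = possible, observed = observed,
       truth = truth)
}

#' Score called regions against simulation truth
#'
#' Per-codon confusion counts (a codon is truth-positive when it lies in a
#' depleted region of its transcript, call-positive when inside a called
#' region) and the region Jaccard index in codon units,
#' `|called intersect true| / |called union true|`.
#'
#' @param called data.frame from [call_regions()].
#' @param truth Truth data.frame (`transcript_id`, `start_codon`, `end_codon`).
#' @param n_codons Named integer vector: codons per transcript.
#' @return A list with `tp`, `fp`, `fn`, `tn` and `jaccard` (`NA` when both
#'   called and truth are empty; 0 when exactly one side is empty).
#' @export
truth_evaluation <- function(called, truth, n_codons) {
  tp <- fp <- fn <- tn <- 0L
  inter <- 0L; uni <- 0L
  for (id in names(n_codons)) {
    L <- n_codons[[id]]
    is_true <- rep(FALSE, L)
    tt <- truth[truth$transcript_id == id, , drop = FALSE]
    for (j in seq_len(nrow(tt)))
      is_true[tt$start_codon[j]:tt$end_codon[j]] <- TRUE
    is_call <- rep(FALSE, L)
    cc <- called[called$transcript_id == id, , drop = FALSE]
    for (j in seq_len(nrow(cc)))
      is_call[cc$start_codon[j]:cc$end_codon[j]] <- TRUE
    tp <- tp + sum(is_call & is_true)
    fp <- fp + sum(is_call & !is_true)
    fn <- fn + sum(!is_call & is_true)
    tn <- tn + sum(!is_call & !is_true)
    inter <- inter + sum(is_call & is_true)
    uni <- uni + sum(is_call | is_true)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       jaccard = if (uni == 0L) NA_real_ else inter / uni)
}
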