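#' Run configuration
#'
#' Central defaults of the pipeline: 31-codon window (presets 21/31/41),
#' FDR threshold 0.1 applied jointly across all transcripts of a run,
#' PASS-only variant filtering, population stratification restricted to
#' populations with at least 15 000 exomes and windows 31/41, and the GRCh37
#' assembly label (echoed to outputs; the code itself is assembly-agnostic).
#'
#' @param window_size Odd sliding-window size in codons (default 31).
#' @param window_size_set Preset window sizes (documentation of the published
#'   choices; any odd size is accepted by `window_size`).
#' @param fdr_threshold FDR significance threshold in (0, 1) (default 0.1).
#' @param fdr_scope `"joint"` (one BH family across transcripts, default) or
#'   `"per_transcript"`.
#' @param min_population_exomes Minimum exome count for stratified profiles.
#' @param population_windows Window sizes allowed for stratified profiles.
#' @param pass_only Keep only FILTER = PASS variants.
#' @param dot_is_pass Treat missing FILTER as PASS.
#' @param assembly Assembly label echoed to run summaries.
#' @param seed Integer seed for any randomised step.
#' @return An `mtr_config` list.
#' @export
mtr_config <- function(window_size = 31L,
                       window_size_set = c(21L, 31L, 41L),
                       fdr_threshold = 0.1,
                       fdr_scope = c("joint", "per_transcript"),
                       min_population_exomes = 15000,
                       population_windows = c(31L, 41L),
                       pass_only = TRUE,
                       dot_is_pass = FALSE,
                       assembly = "GRCh37",
                       seed = 1L) {
  fdr_scope <- match.arg(fdr_scope)
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 3L || window_size %% 2L == 0L) {
    stop("invalid-parameter error: window_size must be an odd integer >= 3",
         call. = FALSE)
  }
  if (any(window_size_set %% 2L == 0L)) {
    stop("invalid-parameter error: window sizes must be odd", call. = FALSE)
  }
  if (!(fdr_threshold > 0 && fdr_threshold < 1)) {
    stop("invalid-parameter error: fdr_threshold must lie in (0, 1)",
         call. = FALSE)
  }
  structure(list(window_size = window_size,
                 window_size_set = as.integer(window_size_set),
                 fdr_threshold = fdr_threshold,
                 fdr_scope = fdr_scope,
                 min_population_exomes = min_population_exomes,
                 population_windows = as.integer(population_windows),
                 pass_only = isTRUE(pass_only),
                 dot_is_pass = isTRUE(dot_is_pass),
                 assembly = assembly,
                 seed = as.integer(seed)),
            class = "mtr_config")
}
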