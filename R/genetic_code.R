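# package-level cache (consequence lookup table, built lazily)
.mtr_env <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")
.STOP <- "*"

#' Translate a codon with the standard nuclear genetic code
#'
#' @param codon A 3-character string over `{A,C,G,T}` (case-insensitive).
#' @return A single-letter amino-acid symbol, or `"*"` for a stop codon.
#' @examples
#' translate_codon("ATG") # "M"
#' translate_codon("TAA") # "*"
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon)) {
    stop("invalid-sequence error: codon must be 3 characters over {A,C,G,T}, got '",
         codon, "'", call. = FALSE)
  }
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Classify the protein consequence of a single-base change in a codon
#'
#' Compares the translation of the reference codon with the translation of the
#' codon carrying `alt` at `pos_in_codon`.
#'
#' @param codon Reference 3-base codon.
#' @param pos_in_codon Position of the change within the codon (1, 2 or 3).
#' @param alt Alternate base, different from the reference base at that
#'   position.
#' @return One of `"synonymous"`, `"missense"`, `"stop_gained"`, `"stop_lost"`
#'   or `"excluded_other"` (stop-to-stop changes).
#' @examples
#' classify_consequence("AAA", 3, "G") # synonymous (AAG, Lys)
#' classify_consequence("AAA", 1, "C") # missense  (CAA, Gln)
#' classify_consequence("TAC", 3, "A") # stop_gained (TAA)
#' @export
classify_consequence <- function(codon, pos_in_codon, alt) {
  codon <- toupper(codon)
  alt <- toupper(alt)
  if (!pos_in_codon %in% 1:3) {
    stop("invalid-parameter error: pos_in_codon must be 1, 2 or 3", call. = FALSE)
  }
  if (!alt %in% .BASES) {
    stop("invalid-sequence error: alt must be a single base in {A,C,G,T}",
         call. = FALSE)
  }
  ref_base <- substr(codon, pos_in_codon, pos_in_codon)
  if (identical(alt, ref_base)) {
    stop("invalid-variant error: alt equals the reference base", call. = FALSE)
  }
  aa_ref <- translate_codon(codon)
  mut <- codon
  substr(mut, pos_in_codon, pos_in_codon) <- alt
  aa_alt <- translate_codon(mut)
  if (aa_ref == .STOP && aa_alt == .STOP) return("excluded_other")
  if (aa_ref == .STOP) return("stop_lost")
  if (aa_alt == .STOP) return("stop_gained")
  if (aa_ref == aa_alt) "synonymous" else "missense"
}

# Named lookup over all 64 x 3 x 3 (codon, position, alt) combinations.
# Keys are paste0(codon, pos, alt); values are consequence labels.
consequence_table <- function() {
  if (!is.null(.mtr_env$cons_tab)) return(.mtr_env$cons_tab)
  codons <- names(Biostrings::GENETIC_CODE)
  keys <- character(64L * 9L)
  vals <- character(64L * 9L)
  k <- 0L
  for (cod in codons) {
    for (pos in 1:3) {
      ref <- substr(cod, pos, pos)
      for (alt in setdiff(.BASES, ref)) {
        k <- k + 1L
        keys[k] <- paste0(cod, pos, alt)
        vals[k] <- classify_consequence(cod, pos, alt)
      }
    }
  }
  tab <- vals[seq_len(k)]
  names(tab) <- keys[seq_len(k)]
  .mtr_env$cons_tab <- tab
  tab
}

revcomp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}
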