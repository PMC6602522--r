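#' Construct a transcript from an in-frame coding sequence
#'
#' A transcript holds one in-frame CDS. The terminal stop codon, when present,
#' is kept in the sequence but excluded from `n_codons` (the number of
#' amino-acid positions). Ambiguous bases are rejected.
#'
#' @param transcript_id Identifier string.
#' @param cds_seq Nucleotide string over `{A,C,G,T}`, length a multiple of 3
#'   and at least 6.
#' @param gene_symbol Optional gene symbol.
#' @param genomic_map Optional data.frame with columns `cds_pos`, `chrom`,
#'   `genomic_pos` and optionally `strand` ("+" default). Must cover every CDS
#'   position exactly once, with unique genomic coordinates.
#' @return An object of class `mtr_transcript`.
#' @export
transcript <- function(transcript_id, cds_seq, gene_symbol = NA_character_,
                       genomic_map = NULL) {
  cds_seq <- toupper(as.character(cds_seq))
  if (grepl("[^ACGT]", cds_seq)) {
    stop("invalid-sequence error: transcript '", transcript_id,
         "' contains ambiguous or non-ACGT bases", call. = FALSE)
  }
  len <- nchar(cds_seq)
  if (len < 6L || len %% 3L != 0L) {
    stop("invalid-sequence error: CDS length must be a multiple of 3 and >= 6",
         call. = FALSE)
  }
  last_codon <- substr(cds_seq, len - 2L, len)
  has_stop <- translate_codon(last_codon) == .STOP
  n_codons <- len %/% 3L - as.integer(has_stop)
  if (n_codons < 1L) {
    stop("invalid-sequence error: transcript has no coding codons", call. = FALSE)
  }
  if (!is.null(genomic_map)) {
    genomic_map <- validate_genomic_map(genomic_map, len)
  }
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_symbol = gene_symbol,
         cds_seq = cds_seq,
         n_codons = n_codons,
         has_terminal_stop = has_stop,
         genomic_map = genomic_map),
    class = "mtr_transcript"
  )
}

validate_genomic_map <- function(map, cds_len) {
  map <- as.data.frame(map)
  need <- c("cds_pos", "chrom", "genomic_pos")
  if (!all(need %in% names(map))) {
    stop("genomic_map must have columns cds_pos, chrom, genomic_pos", call. = FALSE)
  }
  if (is.null(map$strand)) map$strand <- "+"
  map$cds_pos <- as.integer(map$cds_pos)
  map$genomic_pos <- as.integer(map$genomic_pos)
  map$chrom <- as.character(map$chrom)
  if (!setequal(map$cds_pos, seq_len(cds_len))) {
    stop("genomic_map must cover every CDS position exactly once", call. = FALSE)
  }
  key <- paste(map$chrom, map$genomic_pos)
  if (anyDuplicated(key)) {
    stop("genomic_map is not injective: duplicated genomic coordinates",
         call. = FALSE)
  }
  map[order(map$cds_pos), , drop = FALSE]
}

#' @export
print.mtr_transcript <- function(x, ...) {
  cat("mtr_transcript", x$transcript_id,
      if (!is.na(x$gene_symbol)) paste0("(", x$gene_symbol, ")") else "",
      "\n  CDS length:", nchar(x$cds_seq), "nt;",
      x$n_codons, "codons",
      if (x$has_terminal_stop) "(terminal stop excluded)" else "",
      "\n  genomic map:", if (is.null(x$genomic_map)) "none" else "present", "\n")
  invisible(x)
}

#' Read transcripts from a FASTA file of coding sequences
#'
#' One record per transcript; the header is `transcript_id` optionally
#' followed by `|gene_symbol`.
#'
#' @param path FASTA file path.
#' @return A named list of `mtr_transcript` objects.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- vector("list", length(seqs))
  ids <- character(length(seqs))
  for (i in seq_along(seqs)) {
    hdr <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1]]
    id <- trimws(hdr[1])
    sym <- if (length(hdr) > 1L) trimws(hdr[2]) else NA_character_
    out[[i]] <- transcript(id, as.character(seqs[[i]]), gene_symbol = sym)
    ids[i] <- id
  }
  names(out) <- ids
  out
}

#' Read a genomic coordinate map for transcripts
#'
#' TSV with columns `transcript_id`, `cds_pos`, `chrom`, `genomic_pos` and
#' optional `strand`; `#` lines are comments. Minus-strand rows mean the
#' coding strand is the reverse complement of the reference at that position.
#'
#' @param path TSV file path.
#' @return A named list of per-transcript map data.frames.
#' @export
read_genomic_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  split(df[setdiff(names(df), "transcript_id")], df$transcript_id)
}

codon_of <- function(cds_pos) as.integer(ceiling(cds_pos / 3))

codon_string <- function(t, codon_index) {
  substr(t$cds_seq, 3L * (codon_index - 1L) + 1L, 3L * codon_index)
}

#' Enumerate all possible single-nucleotide variants of a transcript
#'
#' Every CDS position within the first `n_codons` codons has exactly three
#' alternate alleles; each is classified by protein consequence. The terminal
#' stop codon, when present, is not enumerated.
#'
#' @param t An `mtr_transcript`.
#' @return A data.frame of site variants (`origin = "possible"`), ordered by
#'   (`cds_pos`, `alt`), with `9 * n_codons` rows.
#' @export
enumerate_possible_variants <- function(t) {
  stopifnot(inherits(t, "mtr_transcript"))
  npos <- 3L * t$n_codons
  refs <- strsplit(substr(t$cds_seq, 1L, npos), "")[[1]]
  # 3 alternates per position; setdiff() keeps them in A<C<G<T order
  alt_list <- lapply(refs, function(b) setdiff(.BASES, b))
  cds_pos <- rep(seq_len(npos), each = 3L)
  alt <- unlist(alt_list, use.names = FALSE)
  ref <- rep(refs, each = 3L)
  ci <- codon_of(cds_pos)
  pic <- cds_pos - 3L * (ci - 1L)
  codons <- substring(t$cds_seq, 3L * (ci - 1L) + 1L, 3L * ci)
  cons <- unname(consequence_table()[paste0(codons, pic, alt)])
  data.frame(
    transcript_id = t$transcript_id,
    cds_pos = cds_pos,
    codon_index = ci,
    ref = ref,
    alt = alt,
    consequence = cons,
    origin = "possible",
    population = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Annotate observed variant records against a transcript
#'
#' Maps records to CDS coordinates (through the transcript's genomic map when
#' `mode = "genomic"`), checks the reference allele against the CDS, and
#' labels each accepted record with its protein consequence. Records are never
#' fatal: failures are returned with a reason.
#'
#' @param t An `mtr_transcript`.
#' @param records data.frame with columns `pos`, `ref`, `alt` and optionally
#'   `chrom` and `population`. `pos` is a CDS position (`mode = "cds"`) or a
#'   genomic position (`mode = "genomic"`).
#' @param mode Coordinate mode of `records$pos`.
#' @return A data.frame of accepted site variants (`origin = "observed"`),
#'   with the rejected records (and a `reason` column: `"unmappable"`,
#'   `"out_of_range"`, `"ref_mismatch"`) in `attr(, "rejected")`.
#' @export
annotate_observed <- function(t, records, mode = c("cds", "genomic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "mtr_transcript"))
  records <- as.data.frame(records)
  empty <- data.frame(
    transcript_id = character(), cds_pos = integer(), codon_index = integer(),
    ref = character(), alt = character(), consequence = character(),
    origin = character(), population = character(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    attr(empty, "rejected") <- cbind(records, reason = character(0))
    return(empty)
  }
  if (is.null(records$population)) records$population <- NA_character_
  ref <- toupper(as.character(records$ref))
  alt <- toupper(as.character(records$alt))
  pos <- as.integer(records$pos)
  reason <- rep(NA_character_, nrow(records))
  cds_pos <- rep(NA_integer_, nrow(records))

  if (mode == "genomic") {
    if (is.null(t$genomic_map)) {
      stop("transcript '", t$transcript_id,
           "' has no genomic_map; cannot annotate genomic records", call. = FALSE)
    }
    map <- t$genomic_map
    key <- paste(map$chrom, map$genomic_pos)
    qchrom <- if (is.null(records$chrom)) rep(NA_character_, nrow(records))
              else as.character(records$chrom)
    idx <- match(paste(qchrom, pos), key)
    reason[is.na(idx)] <- "unmappable"
    hit <- !is.na(idx)
    cds_pos[hit] <- map$cds_pos[idx[hit]]
    minus <- hit & map$strand[idx] == "-"
    ref[minus] <- unname(revcomp_base(ref[minus]))
    alt[minus] <- unname(revcomp_base(alt[minus]))
  } else {
    cds_pos <- pos
    bad <- is.na(cds_pos) | cds_pos < 1L | cds_pos > nchar(t$cds_seq)
    reason[bad] <- "out_of_range"
    cds_pos[bad] <- NA_integer_
  }

  ok <- is.na(reason)
  bad_base <- ok & !(ref %in% .BASES & alt %in% .BASES)
  reason[bad_base] <- "invalid_base"
  ok <- is.na(reason)
  same <- ok & ref == alt
  reason[same] <- "not_variant"
  ok <- is.na(reason)
  cds_base <- substring(t$cds_seq, cds_pos, cds_pos)
  mismatch <- ok & cds_base != ref
  reason[mismatch] <- "ref_mismatch"
  ok <- is.na(reason)

  ci <- codon_of(cds_pos)
  pic <- cds_pos - 3L * (ci - 1L)
  cons <- rep(NA_character_, nrow(records))
  in_coding <- ok & ci <= t$n_codons
  if (any(in_coding)) {
    codons <- substring(t$cds_seq, 3L * (ci[in_coding] - 1L) + 1L,
                        3L * ci[in_coding])
    cons[in_coding] <- unname(consequence_table()[
      paste0(codons, pic[in_coding], alt[in_coding])])
  }
  # variants falling in a terminal stop codon are labelled but excluded
  cons[ok & ci > t$n_codons] <- "excluded_other"

  if (!any(ok)) {
    attr(empty, "rejected") <- cbind(records, reason = reason)
    return(empty)
  }
  accepted <- data.frame(
    transcript_id = t$transcript_id,
    cds_pos = cds_pos[ok],
    codon_index = ci[ok],
    ref = ref[ok],
    alt = alt[ok],
    consequence = cons[ok],
    origin = "observed",
    population = as.character(records$population)[ok],
    stringsAsFactors = FALSE
  )
  rejected <- cbind(records[!ok, , drop = FALSE], reason = reason[!ok])
  attr(accepted, "rejected") <- rejected
  accepted
}
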