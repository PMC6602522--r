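#' Read observed variants and apply the single-nucleotide PASS filter
#'
#' Reads a VCF (4.x, multi-allelic records split one row per alternate allele)
#' or the package's TSV dialect (columns `chrom`, `pos`, `ref`, `alt`,
#' `filter`, optional `population`; `#` lines are comments). Records are kept
#' only when the FILTER is `PASS` and both alleles are single `ACGT` bases.
#' Dropped records are tallied by reason and attached as an attribute; nothing
#' here is fatal except an unreadable file.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension when `NULL`.
#' @param mode Whether `pos` is a `"genomic"` or a `"cds"` coordinate (in CDS
#'   mode the chrom column carries the transcript id). Recorded on the output,
#'   not used for filtering.
#' @param pass_only Keep only PASS records (default TRUE).
#' @param dot_is_pass Treat a missing FILTER (`"."`) as PASS (default FALSE:
#'   missing filter fails).
#' @param population Optional per-file population label, used when the input
#'   has no population column.
#' @return data.frame of retained records (`chrom`, `pos`, `ref`, `alt`,
#'   `filter`, `population`, `source`), with attributes `rejections` (a named
#'   count per reason), `n_input_rows` and `n_records` (rows after
#'   multi-allelic splitting), and `mode`.
#' @export
read_observed <- function(path, format = NULL, mode = c("genomic", "cds"),
                          pass_only = TRUE, dot_is_pass = FALSE,
                          population = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  format <- match.arg(format, c("vcf", "tsv"))
  raw <- if (format == "vcf") .read_vcf_records(path) else .read_tsv_records(path)
  rec <- raw$records
  if (is.null(rec$population) || all(is.na(rec$population))) {
    rec$population <- if (is.null(population)) NA_character_ else population
  }
  rec$source <- basename(path)

  reason <- rep(NA_character_, nrow(rec))
  rec$ref <- toupper(rec$ref)
  rec$alt <- toupper(rec$alt)
  is_pass <- toupper(rec$filter) == "PASS" |
    (dot_is_pass & rec$filter %in% c(".", ""))
  if (pass_only) reason[!is_pass] <- "not_pass"
  snv <- nchar(rec$ref) == 1L & nchar(rec$alt) == 1L
  reason[is.na(reason) & !snv] <- "not_snv"
  goodbase <- rec$ref %in% .BASES & rec$alt %in% .BASES
  reason[is.na(reason) & !goodbase] <- "invalid_base"

  kept <- rec[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  rej <- table(reason[!is.na(reason)])
  if (raw$n_malformed > 0L) {
    rej <- c(rej, malformed = raw$n_malformed)
  }
  attr(kept, "rejections") <- rej
  attr(kept, "n_input_rows") <- raw$n_rows
  attr(kept, "n_records") <- nrow(rec) + raw$n_malformed
  attr(kept, "mode") <- mode
  message("read_observed: ", raw$n_rows, " rows -> ", nrow(rec) + raw$n_malformed,
          " allele records; kept ", nrow(kept),
          if (length(rej)) paste0("; dropped ",
            paste(paste0(names(rej), "=", as.integer(rej)), collapse = ", "))
          else "")
  kept
}

.read_vcf_records <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  n_rows <- length(vcf)
  e <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(e)
  data_alt <- as.character(VariantAnnotation::alt(e))
  list(records = data.frame(
         chrom = as.character(GenomeInfoDb::seqnames(rr)),
         pos = BiocGenerics::start(rr),
         ref = as.character(VariantAnnotation::ref(e)),
         alt = data_alt,
         filter = VariantAnnotation::filt(e),
         population = NA_character_,
         stringsAsFactors = FALSE),
       n_rows = n_rows, n_malformed = 0L)
}

.read_tsv_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  n_rows <- length(body)
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok <- lengths(fields) == length(header)
  mat <- do.call(rbind, fields[ok])
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("TSV variant file must have columns chrom, pos, ref, alt", call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(df$pos))
  badpos <- is.na(pos)
  n_malformed <- sum(!ok) + sum(badpos)
  df <- df[!badpos, , drop = FALSE]
  pos <- pos[!badpos]
  # multi-allelic alt like "G,T" splits into one record per allele
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  rep_idx <- rep(seq_len(nrow(df)), lengths(alts))
  records <- data.frame(
    chrom = df$chrom[rep_idx],
    pos = pos[rep_idx],
    ref = df$ref[rep_idx],
    alt = unlist(alts, use.names = FALSE),
    filter = if (is.null(df$filter)) "PASS" else df$filter[rep_idx],
    population = if (is.null(df$population)) NA_character_
                 else df$population[rep_idx],
    stringsAsFactors = FALSE)
  list(records = records, n_rows = n_rows, n_malformed = n_malformed)
}

#' Parse one variant-query line
#'
#' Three accepted forms, split on `-` or `:` (case-insensitive):
#' `chrom-pos-ref-alt`, `chrom-pos`, and `transcript:protein_pos` (either
#' separator). Four fields with single-base third and fourth tokens take
#' precedence over the two-field forms. Unparseable lines are returned with
#' `ok = FALSE` and a reason, never an error.
#'
#' @param q A query string.
#' @return A list with `form` (`"chrom_pos_ref_alt"`, `"chrom_pos"`,
#'   `"transcript_protein_pos"` or `NA`), the populated fields of that form,
#'   `ok` and `raw`.
#' @export
parse_variant_query <- function(q) {
  raw <- q
  q <- trimws(q)
  bad <- function(reason) list(form = NA_character_, ok = FALSE,
                               reason = reason, raw = raw)
  if (!nzchar(q)) return(bad("empty"))
  tok <- strsplit(q, "[-:]")[[1]]
  tok <- tok[nzchar(tok)]
  if (length(tok) == 4L) {
    ref <- toupper(tok[3]); alt <- toupper(tok[4])
    posn <- suppressWarnings(as.integer(tok[2]))
    if (ref %in% .BASES && alt %in% .BASES && !is.na(posn)) {
      return(list(form = "chrom_pos_ref_alt", chromosome = .norm_chrom(tok[1]),
                  position = posn, ref = ref, alt = alt, ok = TRUE, raw = raw))
    }
    return(bad("unrecognized_4_field"))
  }
  if (length(tok) == 2L) {
    posn <- suppressWarnings(as.integer(tok[2]))
    if (is.na(posn) || posn < 1L) return(bad("bad_position"))
    if (grepl("^(chr)?([0-9]{1,2}|[XYM]|MT)$", tok[1], ignore.case = TRUE)) {
      return(list(form = "chrom_pos", chromosome = .norm_chrom(tok[1]),
                  position = posn, ok = TRUE, raw = raw))
    }
    return(list(form = "transcript_protein_pos",
                transcript_id = tok[1], protein_pos = posn, ok = TRUE, raw = raw))
  }
  bad("unrecognized_format")
}

.norm_chrom <- function(x) sub("^chr", "", x, ignore.case = TRUE)

#' Write the per-variant flat file
#'
#' One row per possible variant of each transcript, joined with the per-codon
#' MTR profile (tab-separated, `NA` for undefined values). Genomic coordinates
#' are used when the transcript carries a genomic map, otherwise the position
#' column holds the CDS position and the chromosome the transcript id.
#'
#' @param flat data.frame from [flat_file_table()] (or a list of them).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_flat_file <- function(flat, path) {
  if (is.list(flat) && !is.data.frame(flat)) flat <- do.call(rbind, flat)
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Build the per-variant flat table for one transcript
#'
#' @param t An `mtr_transcript`.
#' @param possible Possible site variants; computed when `NULL`.
#' @param profile An `mtr_profile` for `t` (tested/adjusted or not).
#' @return data.frame with columns `transcript_id`, `chromosome`, `position`,
#'   `ref`, `alt`, `codon_index`, `consequence`, `mtr`, `raw_p`, `fdr_q`.
#' @export
flat_file_table <- function(t, possible = NULL, profile) {
  stopifnot(inherits(profile, "mtr_profile"))
  if (is.null(possible)) possible <- enumerate_possible_variants(t)
  if (!is.null(t$genomic_map)) {
    m <- t$genomic_map
    idx <- match(possible$cds_pos, m$cds_pos)
    chromosome <- m$chrom[idx]
    position <- m$genomic_pos[idx]
  } else {
    chromosome <- rep(t$transcript_id, nrow(possible))
    position <- possible$cds_pos
  }
  ci <- possible$codon_index
  data.frame(
    transcript_id = t$transcript_id,
    chromosome = chromosome,
    position = position,
    ref = possible$ref,
    alt = possible$alt,
    codon_index = ci,
    consequence = possible$consequence,
    mtr = profile$mtr[ci],
    raw_p = profile$raw_p[ci],
    fdr_q = profile$fdr_q[ci],
    stringsAsFactors = FALSE
  )
}

#' Write the per-residue MTR table
#'
#' One row per codon: `transcript_id`, `codon_index`, `mtr`, `obs_mis`,
#' `obs_syn`, `exp_mis`, `exp_syn`, `raw_p`, `fdr_q`, `significant`
#' (tab-separated; `NA` for undefined values).
#'
#' @param profiles An `mtr_profile` or list of them.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_mtr_table <- function(profiles, path) {
  if (inherits(profiles, "mtr_profile")) profiles <- list(profiles)
  tabs <- lapply(profiles, function(pr) data.frame(
    transcript_id = attr(pr, "transcript_id"),
    codon_index = pr$codon_index,
    mtr = pr$mtr,
    obs_mis = pr$mis_obs, obs_syn = pr$syn_obs,
    exp_mis = pr$mis_exp, exp_syn = pr$syn_exp,
    raw_p = pr$raw_p, fdr_q = pr$fdr_q, significant = pr$significant,
    stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a written MTR table
#'
#' @param path File written by [write_mtr_table()].
#' @return data.frame with the table columns.
#' @export
read_mtr_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE)
}

#' Write called regions as BED
#'
#' Protein-coordinate BED (0-based half-open: `transcript_id`, `start_codon-1`,
#' `end_codon`) by default; genomic BED when the transcript carries a genomic
#' map. Adjacent regions are written as-is, never merged.
#'
#' @param regions data.frame from [call_regions()].
#' @param transcripts Named list of `mtr_transcript` (needed for genomic BED;
#'   may be `NULL` for protein-space output).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(regions, transcripts = NULL, path) {
  lines <- character(0)
  if (nrow(regions) > 0L) {
    lines <- vapply(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      t <- if (!is.null(transcripts)) transcripts[[r$transcript_id]] else NULL
      if (!is.null(t) && !is.null(t$genomic_map)) {
        cds <- (3L * (r$start_codon - 1L) + 1L):(3L * r$end_codon)
        m <- t$genomic_map
        g <- m$genomic_pos[m$cds_pos %in% cds]
        paste(m$chrom[1], min(g) - 1L, max(g), r$transcript_id, sep = "\t")
      } else {
        paste(r$transcript_id, r$start_codon - 1L, r$end_codon, sep = "\t")
      }
    }, character(1))
  }
  writeLines(lines, path)
  invisible(path)
}
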