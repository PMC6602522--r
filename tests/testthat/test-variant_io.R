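write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=lowq,Description=\"low quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.",
    "chr1\t105\t.\tA\tG,T\t.\tPASS\t.",
    "chr1\t110\t.\tAT\tA\t.\tPASS\t.",
    "chr1\t115\t.\tC\tT\t.\tlowq\t.",
    "chr1\t120\t.\tG\tA\t.\t.\t."), path)
  path
}

test_that("read_observed applies the PASS + SNV filter to VCF input", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"))
  suppressMessages(rec <- read_observed(f, mode = "genomic"))
  # kept: 100 A>G, and the split 105 A>G / A>T; dropped: indel, lowq, '.'
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$pos, c(100L, 105L, 105L))
  expect_setequal(rec$alt[rec$pos == 105], c("G", "T"))
  rej <- attr(rec, "rejections")
  expect_equal(unname(rej[["not_pass"]]), 2L)
  expect_equal(unname(rej[["not_snv"]]), 1L)
  # accounting: retained + rejected = allele records after splitting
  expect_equal(nrow(rec) + sum(rej), attr(rec, "n_records"))
  expect_equal(attr(rec, "n_input_rows"), 5L)
})

test_that("'.' FILTER can be configured to pass", {
  f <- write_test_vcf(tempfile(fileext = ".vcf"))
  suppressMessages(rec <- read_observed(f, mode = "genomic", dot_is_pass = TRUE))
  expect_true(any(rec$pos == 120))
})

test_that("read_observed handles the TSV dialect and is idempotent", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "# synthetic observed variants",
    "chrom\tpos\tref\talt\tfilter\tpopulation",
    "T1\t4\tA\tG\tPASS\tEUR",
    "T1\t5\tA\tG,T\tPASS\tEUR",
    "T1\t6\tAT\tA\tPASS\tSAS",
    "T1\t7\tC\tT\tfail\tSAS",
    "T1\tnotanumber\tA\tG\tPASS\tEUR"), f)
  suppressMessages(rec <- read_observed(f, mode = "cds"))
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$population, c("EUR", "EUR", "EUR"))
  rej <- attr(rec, "rejections")
  expect_equal(unname(rej[["malformed"]]), 1L)
  expect_equal(nrow(rec) + sum(rej), attr(rec, "n_records"))
  # idempotence: write the kept records back out, filter again, nothing changes
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(rec[c("chrom", "pos", "ref", "alt", "filter", "population")],
                     f2, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressMessages(rec2 <- read_observed(f2, mode = "cds"))
  expect_equal(rec2[c("chrom", "pos", "ref", "alt")],
               rec[c("chrom", "pos", "ref", "alt")])
  expect_equal(length(attr(rec2, "rejections")), 0L)
})

test_that("parse_variant_query recognizes the three forms", {
  q1 <- parse_variant_query("7-140453136-A-T")
  expect_equal(q1$form, "chrom_pos_ref_alt")
  expect_equal(q1$chromosome, "7")
  expect_equal(q1$position, 140453136L)
  expect_equal(q1$ref, "A"); expect_equal(q1$alt, "T")

  q2 <- parse_variant_query("7-140453136")
  expect_equal(q2$form, "chrom_pos")

  q3 <- parse_variant_query("ENST00000288602:600")
  expect_equal(q3$form, "transcript_protein_pos")
  expect_equal(q3$protein_pos, 600L)
  # '-' separator and case-insensitive alleles also accepted
  expect_equal(parse_variant_query("ENST00000288602-600")$form,
               "transcript_protein_pos")
  expect_equal(parse_variant_query("chr7-1000-a-t")$ref, "A")
  # unparseable lines report, never error
  expect_false(parse_variant_query("not a query at all")$ok)
  expect_false(parse_variant_query("")$ok)
  expect_false(parse_variant_query("7-12-XX-YY")$ok)
})

test_that("flat file has one row per possible variant with NA-safe MTR", {
  t <- transcript("T1", "ATGAAATAA")
  prof <- compute_profile(t, data.frame(), w = 31) # no observed: all-NA MTR
  flat <- flat_file_table(t, profile = prof)
  expect_equal(nrow(flat), 18L)
  expect_true(all(is.na(flat$mtr)))
  f <- tempfile(fileext = ".tsv")
  write_flat_file(flat, f)
  lines <- readLines(f)
  expect_equal(length(lines), 19L) # header + 18 rows
  expect_match(lines[2], "\tNA", fixed = TRUE)
  # empty transcript set gives a header-only file
  f2 <- tempfile(fileext = ".tsv")
  write_flat_file(flat[0, ], f2)
  expect_equal(length(readLines(f2)), 1L)
})

test_that("MTR table writes one row per codon and round-trips to 6 decimals", {
  t <- generate_transcript(30, 5)
  sc <- simulation_scenario(seed = 5, n_transcripts = 1,
                            length_range = c(30, 30), pi_obs = 0.9)
  pv <- enumerate_possible_variants(t)
  obs <- sample_observed(t, pv, sc)
  prof <- adjust_profiles(test_profile(compute_profile(t, obs, pv, w = 21)))[[1]]
  f <- tempfile(fileext = ".tsv")
  write_mtr_table(prof, f)
  back <- read_mtr_table(f)
  expect_equal(nrow(back), t$n_codons)
  expect_equal(back$mtr, prof$mtr, tolerance = 1e-6)
  expect_equal(back$raw_p, prof$raw_p, tolerance = 1e-6)
  expect_equal(back$fdr_q, prof$fdr_q, tolerance = 1e-6)
})

test_that("all-NA profiles serialize with NA fields", {
  t <- transcript("T1", "ATGAAATAA")
  prof <- compute_profile(t, data.frame(), w = 31)
  f <- tempfile(fileext = ".tsv")
  write_mtr_table(prof, f)
  back <- read_mtr_table(f)
  expect_equal(nrow(back), 2L)
  expect_true(all(is.na(back$mtr)))
  expect_true(all(is.na(back$fdr_q)))
})

test_that("regions BED uses 0-based half-open coordinates and never merges", {
  regions <- data.frame(
    transcript_id = c("T1", "T1"), population = NA, window_size = 31L,
    start_codon = c(5L, 11L), end_codon = c(10L, 12L), n_codons = c(6L, 2L),
    min_mtr = 0.5, mean_mtr = 0.6, min_fdr_q = 0.01)
  f <- tempfile(fileext = ".bed")
  write_regions_bed(regions, NULL, f)
  lines <- readLines(f)
  expect_equal(lines[1], "T1\t4\t10")
  expect_equal(lines[2], "T1\t10\t12") # adjacent regions stay separate
  # empty input -> empty file
  write_regions_bed(regions[0, ], NULL, f)
  expect_equal(length(readLines(f)), 0L)
  # genomic BED when a map is present
  map <- data.frame(cds_pos = 1:36, chrom = "9", genomic_pos = 1001:1036)
  t <- transcript("T1", paste(rep("ATGAAAGGGCTTTCACCA", 2), collapse = ""),
                  genomic_map = map)
  write_regions_bed(regions[1, ], list(T1 = t), f)
  expect_equal(readLines(f), "9\t1012\t1030\tT1") # cds 13..30 -> 1013..1030
})
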