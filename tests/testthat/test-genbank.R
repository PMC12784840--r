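test_that("synthetic genomes round-trip through the flat-file writer", {
  gb <- withr::local_tempfile(fileext = ".gb")
  out <- synthesize_genome(synthetic_spec(seed = 3), gb)
  rec <- parse_genbank(gb)
  expect_s3_class(rec, "genome_record")
  expect_equal(rec$accession, out$record$accession)
  expect_equal(rec$sequence, out$record$sequence)
  expect_equal(rec$length, nchar(out$record$sequence))
  expect_equal(rec$topology, "circular")
  counts <- table(rec$features$kind)
  expect_equal(unname(counts[["CDS"]]), 13)
  expect_equal(unname(counts[["tRNA"]]), 22)
  expect_equal(unname(counts[["rRNA"]]), 2)
  cds <- rec$features[rec$features$kind == "CDS", ]
  ref <- out$record$features[out$record$features$kind == "CDS", ]
  expect_equal(cds$start, ref$start)
  expect_equal(cds$end, ref$end)
  expect_equal(cds$strand, ref$strand)
  expect_equal(cds$codon_start, ref$codon_start)
  expect_equal(cds$transl_table, rep(5L, 13))
})

test_that("multi-record files split correctly", {
  f1 <- withr::local_tempfile(fileext = ".gb")
  f2 <- withr::local_tempfile(fileext = ".gb")
  specs <- synthetic_cohort(seed = 5)[1:2]
  synthesize_genome(specs[[1]], f1)
  synthesize_genome(specs[[2]], f2)
  both <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(readLines(f1), readLines(f2)), both)
  recs <- read_genbank(both)
  expect_length(recs, 2)
  expect_equal(vapply(recs, `[[`, character(1), "organism"),
               vapply(specs, `[[`, character(1), "species"),
               ignore_attr = TRUE)
  expect_error(parse_genbank(both), "single-record")
})

test_that("degenerate inputs raise parse errors", {
  empty <- withr::local_tempfile(fileext = ".gb")
  writeLines(character(0), empty)
  expect_error(parse_genbank(empty), "parse error")
  expect_error(parse_genbank(file.path(tempdir(), "absent.gb")),
               "cannot read")
  # a record with features but no CDS is rejected by parse_genbank
  lines <- toy_genbank(paste(rep("ACGT", 30), collapse = ""),
                       c("     tRNA            1..60",
                         "                     /gene=\"trnA\""))
  norc <- withr::local_tempfile(fileext = ".gb")
  writeLines(lines, norc)
  expect_error(parse_genbank(norc), "no protein-coding genes")
})

test_that("locations parse: complement, join across the origin, codon_start", {
  # genome: cox1 = ATG AAA TTT TAA at 11..22 on minus strand (stored as
  # its reverse complement), preceded by 10 spacer bases
  gene_sense <- "ATGAAATTTTAA"
  seq <- paste0("TTTTTTTTTT", revcomp_chr(gene_sense), "AAAAAAAA")
  lines <- toy_genbank(seq, c(
    "     CDS             complement(11..22)",
    "                     /gene=\"COX1\"",
    "                     /codon_start=1",
    "                     /transl_table=5"))
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(lines, f)
  rec <- parse_genbank(f)
  expect_equal(rec$features$strand, "-")
  genes <- extract_pcgs(rec)
  expect_equal(genes[[1]]$codons, c("ATG", "AAA", "TTT"))
  expect_equal(genes[[1]]$stop_note, "complete_TAA")

  # origin-wrapping feature: last 6 bases + first 6 bases form the CDS
  wrap_seq <- paste0("AATTTTTA", paste(rep("T", 14), collapse = ""), "ATGAAA")
  lines2 <- toy_genbank(wrap_seq, c(
    "     CDS             join(23..28,1..8)",
    "                     /gene=\"nad2\"",
    "                     /codon_start=1"))
  f2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(lines2, f2)
  genes2 <- extract_pcgs(parse_genbank(f2))
  expect_equal(genes2[[1]]$codons, c("ATG", "AAA", "AAT", "TTT"))
  expect_equal(genes2[[1]]$stop_note, "incomplete_TA")

  # codon_start=2 shifts the frame before codonization
  cs_seq <- paste0("C", "ATGAAATTTTAA")
  lines3 <- toy_genbank(cs_seq, c(
    "     CDS             1..13",
    "                     /gene=\"ND3\"",
    "                     /codon_start=2"))
  f3 <- withr::local_tempfile(fileext = ".gb")
  writeLines(lines3, f3)
  genes3 <- extract_pcgs(parse_genbank(f3))
  expect_equal(genes3[[1]]$codons, c("ATG", "AAA", "TTT"))
})

test_that("writer output is byte-identical under a fixed seed", {
  f1 <- withr::local_tempfile(fileext = ".gb")
  f2 <- withr::local_tempfile(fileext = ".gb")
  synthesize_genome(synthetic_spec(seed = 9), f1)
  synthesize_genome(synthetic_spec(seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
})
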