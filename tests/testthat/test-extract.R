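toy_record_with_cds <- function(cds_genomic, features) {
  seq <- paste0("TTTTTTTTTT", cds_genomic, "AAAAAAAA")
  f <- withr::local_tempfile(fileext = ".gb", .local_envir = parent.frame())
  writeLines(toy_genbank(seq, features), f)
  parse_genbank(f)
}

test_that("gene labels normalize across annotation styles", {
  expect_equal(
    normalize_gene(c("COI", "COX1", "cox1", "cytochrome c oxidase subunit I",
                     "ND2", "NADH dehydrogenase subunit 4L", "nad4L",
                     "ATP8", "ATPase6", "ATP synthase F0 subunit 6",
                     "CYTB", "cob", "cytochrome b")),
    c("cox1", "cox1", "cox1", "cox1", "nad2", "nad4L", "nad4L",
      "atp8", "atp6", "atp6", "cytb", "cytb", "cytb"))
  expect_true(is.na(normalize_gene("trnK")))
  expect_true(is.na(normalize_gene("16S ribosomal RNA")))
})

test_that("minus-strand CDS are extracted in sense orientation", {
  rec <- toy_record_with_cds(
    revcomp_chr("ATGAAATAA"),
    c("     CDS             complement(11..19)",
      "                     /gene=\"nad1\"",
      "                     /codon_start=1"))
  g <- extract_pcgs(rec)[[1]]
  expect_equal(g$codons, c("ATG", "AAA"))
  expect_equal(g$stop_note, "complete_TAA")
  expect_equal(g$strand, "-")
  expect_equal(g$start_codon, "ATG")
})

test_that("incomplete stops (T / TA) are trimmed and recorded", {
  rec_t <- toy_record_with_cds(
    "ATTAAATTTT",
    c("     CDS             11..20",
      "                     /gene=\"cox2\"",
      "                     /codon_start=1"))
  g <- extract_pcgs(rec_t)[[1]]
  expect_equal(g$codons, c("ATT", "AAA", "TTT"))
  expect_equal(g$stop_note, "incomplete_T")

  rec_ta <- toy_record_with_cds(
    "ATAAAATTTTA",
    c("     CDS             11..21",
      "                     /gene=\"nad4\"",
      "                     /codon_start=1"))
  g2 <- extract_pcgs(rec_ta)[[1]]
  expect_equal(g2$codons, c("ATA", "AAA", "TTT"))
  expect_equal(g2$stop_note, "incomplete_TA")
})

test_that("frame, internal-stop, unknown-gene and ambiguity handling", {
  rec_frame <- toy_record_with_cds(
    "ATGAAATTTTG", # length 11, ends G: neither codon multiple nor T/TA
    c("     CDS             11..21",
      "                     /gene=\"cox3\""))
  expect_error(extract_pcgs(rec_frame), "frame error.*cox3")

  rec_stop <- toy_record_with_cds(
    "ATGTAAAAATAA",
    c("     CDS             11..22",
      "                     /gene=\"atp6\""))
  expect_error(extract_pcgs(rec_stop),
               "internal stop codon at codon index 2")

  rec_unknown <- toy_record_with_cds(
    "ATGAAATAA",
    c("     CDS             11..19",
      "                     /gene=\"orf1234\""))
  expect_error(extract_pcgs(rec_unknown), "unknown gene label")

  rec_amb <- toy_record_with_cds(
    "ATGANATAA",
    c("     CDS             11..19",
      "                     /gene=\"nad6\""))
  expect_warning(genes <- extract_pcgs(rec_amb), "ambiguity")
  expect_length(genes, 0)
})

test_that("strand invariance: minus-strand gene equals plus-strand gene of the reverse-complemented genome", {
  gb <- withr::local_tempfile(fileext = ".gb")
  out <- synthesize_genome(synthetic_spec(seed = 21), gb)
  rec <- parse_genbank(gb)
  minus <- rec$features[rec$features$kind == "CDS" &
                          rec$features$strand == "-", ]
  expect_gt(nrow(minus), 0)
  i <- 1
  # build the reverse-complemented genome with the same gene on plus strand
  n <- rec$length
  flipped <- rec
  flipped$sequence <- revcomp_chr(rec$sequence)
  new_start <- n - minus$end[i] + 1L
  new_end <- n - minus$start[i] + 1L
  flipped$features <- data.frame(
    kind = "CDS", start = new_start, end = new_end, strand = "+",
    gene = minus$gene[i], codon_start = 1L, transl_table = 5L,
    stringsAsFactors = FALSE)
  flipped$features$segments <- list(matrix(c(new_start, new_end), nrow = 1))
  g_orig <- Filter(function(g) g$gene == minus$gene[i], extract_pcgs(rec))[[1]]
  g_flip <- extract_pcgs(flipped)[[1]]
  expect_identical(g_flip$codons, g_orig$codons)
  expect_identical(g_flip$stop_note, g_orig$stop_note)
})

test_that("frame property: codons plus stop suffix account for the full CDS span", {
  gb <- withr::local_tempfile(fileext = ".gb")
  synthesize_genome(synthetic_spec(seed = 22), gb)
  genes <- extract_pcgs(parse_genbank(gb))
  suffix <- c(complete_TAA = 3L, complete_TAG = 3L,
              incomplete_T = 1L, incomplete_TA = 2L, none = 0L)
  for (g in genes) {
    expect_equal(3L * length(g$codons) + suffix[[g$stop_note]],
                 g$span_length)
  }
})

test_that("gene inventory and FASTA export cover the extracted set", {
  gb <- withr::local_tempfile(fileext = ".gb")
  synthesize_genome(synthetic_spec(seed = 23), gb)
  genes <- extract_pcgs(parse_genbank(gb))
  inv <- gene_inventory(genes)
  expect_equal(nrow(inv), 13)
  expect_setequal(inv$gene, PCG_NAMES)
  expect_true(all(inv$start_codon %in% c("ATG", "ATT", "ATA", "TTG")))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_pcg_fasta(genes, fa)
  lines <- readLines(fa)
  expect_equal(sum(startsWith(lines, ">")), 13)
  first_len <- sum(nchar(lines[2:(which(startsWith(lines, ">"))[2] - 1)]))
  expect_equal(first_len, 3L * inv$length_codons[1])
})
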