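test_that("gene sampling is deterministic and honors the layout", {
  sp <- one_gene_spec(200, theta = 0.3)
  set.seed(41); a <- sample_gene(sp, "g1")
  set.seed(41); b <- sample_gene(sp, "g1")
  expect_identical(a$gene$codons, b$gene$codons)
  expect_equal(length(a$gene$codons), 200)
  expect_equal(a$gene$codons[1], "ATG")
  # no in-frame stop can ever be emitted
  expect_false(any(a$gene$codons %in% c("TAA", "TAG")))
  expect_error(sample_gene(sp, "nope"), "not in spec layout")
})

test_that("concentrated codon weights force RSCU to the family size", {
  tab <- codon_table5()
  w <- lapply(tab$families, function(f) {
    stats::setNames(c(1, rep(0, length(f) - 1)), f)
  })
  sp <- synthetic_spec(codon_weights = w, genes = one_gene_spec(500)$genes)
  set.seed(42)
  g <- sample_gene(sp, "g1")$gene
  prof <- compute_rscu(count_codons(list(g), "per_gene")[[1]], tab)
  used <- vapply(tab$families, `[[`, character(1), 1)
  hit <- prof[!is.na(prof$rscu) & prof$count > 0, ]
  expect_true(all(hit$codon %in% used))
  expect_equal(hit$rscu, hit$family_size[match(hit$codon, hit$codon)])
  # implied ground truth agrees
  truth <- ground_truth_stats(sp)
  ir <- truth$implied_rscu[hit$codon]
  expect_equal(unname(ir), as.numeric(hit$family_size))
  # all-zero weights in a family are a spec error
  w$F <- stats::setNames(c(0, 0), tab$families$F)
  expect_error(synthetic_spec(codon_weights = w,
                              genes = one_gene_spec(500)$genes),
               "degenerate codon weights")
})

test_that("theta is recovered as GC3s and uniform weights imply RSCU 1", {
  sp <- one_gene_spec(10000, theta = 0.5)
  truth <- ground_truth_stats(sp)
  expect_equal(truth$implied_gc3s, 0.5, tolerance = 1e-12)
  expect_true(all(abs(stats::na.omit(truth$implied_rscu) - 1) < 1e-12))
  set.seed(43)
  g <- sample_gene(sp, "g1")$gene
  comp <- positional_composition(g$codons)
  expect_lt(abs(comp$gc3s - 0.5), 0.02)

  truth25 <- ground_truth_stats(one_gene_spec(100, theta = 0.25))
  expect_equal(truth25$implied_gc3s, 0.25, tolerance = 1e-12)
  # emission probabilities are a distribution; implied RSCU sums to family size
  expect_equal(sum(truth25$codon_probs), 1, tolerance = 1e-12)
  tab <- codon_table5()
  fam <- tab$families[["G"]]
  expect_equal(sum(truth25$implied_rscu[fam]), 4, tolerance = 1e-12)
})

test_that("a synthetic cohort orders estimated GC3s exactly as theta", {
  specs <- synthetic_cohort(seed = 2)
  dir <- withr::local_tempdir()
  gc3s_mean <- vapply(specs, function(sp) {
    gb <- file.path(dir, paste0(sp$accession, ".gb"))
    synthesize_genome(sp, gb)
    genes <- extract_pcgs(parse_genbank(gb))
    mean(composition_table(genes)$gc3s)
  }, numeric(1))
  thetas <- vapply(specs, `[[`, numeric(1), "theta")
  expect_equal(order(gc3s_mean), order(thetas))
  expect_true(all(abs(gc3s_mean - thetas) < 0.03))
})

test_that("RSCU estimates converge to the generator's implied values", {
  # 250,000 codons give every per-codon sampling sd below ~0.03, so the
  # 0.1 bound is a sharp convergence check even for the rarest families
  sp <- one_gene_spec(250000, theta = 0.265, seed = 51)
  set.seed(51)
  g <- sample_gene(sp, "g1")$gene
  est <- compute_rscu(count_codons(list(g), "per_gene")[[1]])
  implied <- ground_truth_stats(sp)$implied_rscu
  v <- stats::setNames(est$rscu, est$codon)[names(implied)]
  expect_lt(max(abs(v - implied), na.rm = TRUE), 0.1)
})

test_that("neutrality scenarios produce the expected slope regimes", {
  mut <- neutrality_scenario("mutation", seed = 11)
  sel <- neutrality_scenario("selection", seed = 12)
  fit_mut <- fit_neutrality(mut$gc3, mut$gc12, "mutation")
  fit_sel <- fit_neutrality(sel$gc3, sel$gc12, "selection")
  expect_lt(abs(fit_mut$slope - 1), 0.15)
  expect_lt(abs(fit_sel$slope), 0.15)
  expect_gt(fit_mut$pearson_r, 0.9)
})

test_that("ground-truth JSON is written alongside the genome", {
  gb <- withr::local_tempfile(fileext = ".gb")
  tr <- withr::local_tempfile(fileext = ".json")
  out <- synthesize_genome(synthetic_spec(seed = 44), gb, truth_path = tr)
  truth <- jsonlite::read_json(tr, simplifyVector = TRUE)
  expect_equal(truth$theta, 0.265)
  expect_equal(sort(names(truth$tallies)), sort(PCG_NAMES))
  expect_equal(truth$tallies$cox1, unname(out$tallies$cox1))
})
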