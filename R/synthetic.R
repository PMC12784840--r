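#' Default gene layout for a synthetic mitogenome
#'
#' Thirteen protein-coding genes with arthropod-like lengths, a mix of
#' strands, atypical start codons (ATT/ATA/TTG alongside ATG) and all
#' four terminator variants, including the incomplete stops (single T
#' or TA) completed by polyadenylation in real mitochondria.
#'
#' @return data.frame: `gene`, `length_codons`, `strand`, `start_codon`,
#'   `stop_variant` (one of TAA, TAG, T, TA).
#' @export
default_gene_layout <- function() {
  data.frame(
    gene = c("cox1", "cox2", "cox3", "atp6", "atp8", "nad1", "nad2",
             "nad3", "nad4", "nad4L", "nad5", "nad6", "cytb"),
    length_codons = c(512L, 227L, 261L, 224L, 52L, 310L, 324L,
                      117L, 445L, 95L, 572L, 160L, 379L),
    strand = c("+", "+", "+", "+", "+", "-", "+",
               "+", "-", "-", "-", "+", "+"),
    start_codon = c("ATT", "ATG", "ATG", "ATG", "ATT", "TTG", "ATA",
                    "ATT", "ATG", "ATA", "ATT", "ATA", "ATG"),
    stop_variant = c("TAA", "T", "TA", "TAA", "TAA", "TAG", "TAA",
                     "TAG", "TA", "TAA", "T", "TAA", "TAA"),
    stringsAsFactors = FALSE
  )
}

#' Default amino-acid composition of an AT-rich mitochondrial proteome
#'
#' Elevated Leu/Ile/Phe/Ser/Met, as in arthropod mitochondrial
#' proteins, keeping synthetic genes in the compositional regime of
#' real AT-rich mitogenomes.
#'
#' @return Named probability vector over the 20 amino acids
#'   (one-letter codes), summing to 1.
#' @export
default_aa_freqs <- function() {
  w <- c(L = 15, S = 10, I = 10, F = 9, M = 5.5, V = 6, G = 6, N = 5,
         T = 5, A = 5, K = 4, Y = 4, P = 4, E = 3, W = 2, H = 2,
         Q = 2, R = 2, D = 2, C = 1.5)
  w / sum(w)
}

#' Within-family codon probabilities under a GC3 bias parameter
#'
#' The scalar codon-weight model: every G/C-ending codon of a family
#' gets weight `theta`, every A/T-ending codon weight `1 - theta`,
#' normalized within the family. Because every synonymous family under
#' table 5 splits evenly between G/C- and A/T-ending codons, the
#' implied GC fraction at third positions is exactly `theta`, which
#' makes `theta` the generator's direct handle on GC3s.
#'
#' @param theta GC3 bias in (0, 1).
#' @param table a [codon_table5()] object.
#' @return Named list: amino acid -> named probability vector over its
#'   codons.
#' @export
codon_probs_from_theta <- function(theta, table = codon_table5()) {
  stopifnot(theta > 0, theta < 1)
  lapply(table$families, function(cods) {
    w <- ifelse(substr(cods, 3, 3) %in% c("G", "C"), theta, 1 - theta)
    names(w) <- cods
    w / sum(w)
  })
}

#' Specification of a synthetic mitogenome
#'
#' Bundles everything [synthesize_genome()] needs: the gene layout, the
#' amino-acid composition, the within-family codon usage model (either
#' the scalar GC3 bias `theta` or explicit per-family weights) and the
#' random seed. With a fixed seed the emitted genome is byte-identical
#' across runs.
#'
#' The defaults emulate the compositional regime of mygalomorph
#' mitogenomes: 13 PCGs on both strands with atypical starts and
#' incomplete stops, an AT-rich amino-acid palette, and `theta = 0.265`
#' so that synonymous third positions are about 26.5% GC.
#'
#' @param species species label.
#' @param seed integer random seed.
#' @param theta scalar GC3 bias in (0, 1); ignored when `codon_weights`
#'   is supplied.
#' @param codon_weights optional named list (amino acid -> named
#'   non-negative weights over its codons) overriding the theta model.
#' @param aa_freqs named probability vector over the 20 amino acids;
#'   defaults to [default_aa_freqs()].
#' @param genes gene layout data.frame as in [default_gene_layout()].
#' @param accession accession string for the emitted record.
#' @param table a [codon_table5()] object.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(species = "Synthomygale exemplaris",
                           seed = 1L, theta = 0.265,
                           codon_weights = NULL, aa_freqs = NULL,
                           genes = default_gene_layout(),
                           accession = NULL,
                           table = codon_table5()) {
  if (is.null(aa_freqs)) aa_freqs <- default_aa_freqs()
  stopifnot(abs(sum(aa_freqs) - 1) < 1e-8, all(aa_freqs >= 0))
  stopifnot(all(genes$length_codons >= 10),
            all(genes$strand %in% c("+", "-")),
            all(genes$start_codon %in% c("ATG", "ATT", "ATA", "TTG")),
            all(genes$stop_variant %in% c("TAA", "TAG", "T", "TA")))
  if (is.null(codon_weights)) {
    probs <- codon_probs_from_theta(theta, table)
  } else {
    probs <- lapply(names(table$families), function(a) {
      w <- codon_weights[[a]]
      if (is.null(w)) {
        w <- rep(1, length(table$families[[a]]))
        names(w) <- table$families[[a]]
      }
      w <- w[table$families[[a]]]
      if (anyNA(w) || all(w == 0)) {
        stop("degenerate codon weights for amino acid ", a)
      }
      w / sum(w)
    })
    names(probs) <- names(table$families)
  }
  if (is.null(accession)) {
    accession <- sprintf("SYN_%06d", abs(seed) %% 1000000L)
  }
  structure(
    list(species = species, seed = as.integer(seed), theta = theta,
         codon_probs = probs, aa_freqs = aa_freqs, genes = genes,
         accession = accession, table = table),
    class = "synthetic_spec"
  )
}

#' Sample one synthetic gene
#'
#' Codons are drawn i.i.d.: an amino acid from the composition vector,
#' then a codon within its family from the codon-usage model. The start
#' codon is placed first as-is; no stop can be emitted in frame because
#' stops belong to no family.
#'
#' @param spec a `synthetic_spec`.
#' @param gene gene name, a row of `spec$genes`.
#' @return A list: `gene` (a `gene_seq` with the sampled codons,
#'   terminator noted but not included) and `tally` (named emission
#'   counts over the sampled codons). Uses the current RNG state; seed
#'   control happens in [synthesize_genome()].
#' @export
sample_gene <- function(spec, gene) {
  row <- spec$genes[spec$genes$gene == gene, ]
  if (nrow(row) != 1) stop("gene not in spec layout: ", gene)
  n <- row$length_codons - 1L
  aas <- sample(names(spec$aa_freqs), n, replace = TRUE,
                prob = spec$aa_freqs)
  codons <- c(row$start_codon, vapply(aas, function(a) {
    p <- spec$codon_probs[[a]]
    sample(names(p), 1L, prob = p)
  }, character(1), USE.NAMES = FALSE))
  g <- structure(
    list(gene = gene, species = spec$species, accession = spec$accession,
         strand = row$strand, codons = codons, start_codon = codons[1],
         stop_note = switch(row$stop_variant,
                            TAA = "complete_TAA", TAG = "complete_TAG",
                            T = "incomplete_T", TA = "incomplete_TA"),
         span_length = 3L * length(codons) + nchar(row$stop_variant)),
    class = "gene_seq"
  )
  tally <- table(factor(codons,
                        levels = setdiff(names(spec$table$aa),
                                         spec$table$stop_codons)))
  list(gene = g, tally = stats::setNames(as.integer(tally), names(tally)))
}

rand_at_seq <- function(n, at = 0.75) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

#' Synthesize a GenBank-format mitogenome
#'
#' Emits a single circular record carrying the 13 CDS of the spec on
#' their strands (codon_start 1, transl_table 5, incomplete-stop genes
#' annotated with correspondingly truncated spans), AT-rich intergenic
#' spacers, placeholder tRNA/rRNA features (22 + 2, completing the
#' standard 37-gene metazoan complement) and a control region. The file
#' round-trips through [parse_genbank()] and [extract_pcgs()] with
#' byte-exact recovery of the sampled codon lists.
#'
#' @param spec a [synthetic_spec()].
#' @param path output path for the GenBank flat file.
#' @param truth_path optional path for the ground-truth JSON (emission
#'   tallies plus the analytic expectations of [ground_truth_stats()]);
#'   `NULL` (default) skips it.
#' @return Invisibly, a list: `path`, `record` (the `genome_record`
#'   written), `genes` (list of sampled `gene_seq`), `tallies` (per-gene
#'   emission counts), `truth` ([ground_truth_stats()] output).
#' @examples
#' gb <- tempfile(fileext = ".gb")
#' out <- synthesize_genome(synthetic_spec(seed = 42), gb)
#' out$record
#' @export
synthesize_genome <- function(spec, path, truth_path = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  genes <- list()
  tallies <- list()
  segments <- character(0)
  feats <- list()
  pos <- 0L

  add_feature <- function(kind, len, strand = "+", gene = NA_character_,
                          seq = NULL) {
    if (is.null(seq)) seq <- rand_at_seq(len)
    segments[[length(segments) + 1L]] <<- seq
    feats[[length(feats) + 1L]] <<- list(
      kind = kind, start = pos + 1L, end = pos + nchar(seq),
      strand = strand, gene = gene)
    pos <<- pos + nchar(seq)
  }
  add_spacer <- function() {
    len <- sample(5:20, 1)
    segments[[length(segments) + 1L]] <<- rand_at_seq(len)
    pos <<- pos + len
  }

  for (i in seq_len(nrow(spec$genes))) {
    row <- spec$genes[i, ]
    add_spacer()
    drawn <- sample_gene(spec, row$gene)
    genes[[row$gene]] <- drawn$gene
    tallies[[row$gene]] <- drawn$tally
    sense <- paste0(paste(drawn$gene$codons, collapse = ""),
                    row$stop_variant)
    genomic <- if (row$strand == "-") revcomp(sense) else sense
    add_feature("CDS", strand = row$strand, gene = row$gene, seq = genomic)
  }
  # placeholder structural RNAs and control region
  trna_names <- paste0("trn", LETTERS[1:22])
  for (k in 1:22) {
    add_spacer()
    add_feature("tRNA", len = sample(60:72, 1), gene = trna_names[k],
                strand = sample(c("+", "-"), 1))
  }
  add_spacer()
  add_feature("rRNA", len = 1050L, gene = "rrnL")
  add_spacer()
  add_feature("rRNA", len = 740L, gene = "rrnS")
  add_spacer()
  add_feature("D-loop", len = 320L)

  features <- data.frame(
    kind = vapply(feats, `[[`, character(1), "kind"),
    start = vapply(feats, `[[`, integer(1), "start"),
    end = vapply(feats, `[[`, integer(1), "end"),
    strand = vapply(feats, `[[`, character(1), "strand"),
    gene = vapply(feats, `[[`, character(1), "gene"),
    codon_start = 1L,
    transl_table = 5L,
    stringsAsFactors = FALSE
  )
  features$transl_table[features$kind != "CDS"] <- NA_integer_
  features$segments <- lapply(seq_len(nrow(features)), function(i) {
    matrix(c(features$start[i], features$end[i]), nrow = 1)
  })

  record <- structure(
    list(accession = spec$accession, organism = spec$species,
         length = pos, topology = "circular",
         sequence = paste(segments, collapse = ""), features = features),
    class = "genome_record"
  )
  write_genbank(record, path)
  truth <- ground_truth_stats(spec)
  truth$tallies <- tallies
  if (!is.null(truth_path)) {
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(path = path, record = record, genes = genes,
                 tallies = tallies, truth = truth))
}

#' Analytic expectations implied by a synthetic spec
#'
#' The closed-form ground truth of the generator's codon model, used as
#' the oracle in parameter-recovery tests: per-codon emission
#' probabilities, the RSCU implied by them (within-family probability
#' times family size), and the expected GC fractions by codon position,
#' including GC3s over synonymous families.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `species`, `theta`, `codon_probs` (overall emission
#'   probability of each sense codon), `implied_rscu` (named vector,
#'   `NA` for Met/Trp codons), `implied_gc3s`, `implied_gc12`,
#'   `implied_gc3`.
#' @export
ground_truth_stats <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tab <- spec$table
  fam <- tab$families
  p_codon <- unlist(lapply(names(fam), function(a) {
    p_a <- if (a %in% names(spec$aa_freqs)) spec$aa_freqs[[a]] else 0
    spec$codon_probs[[a]] * p_a
  }))
  implied_rscu <- unlist(lapply(names(fam), function(a) {
    v <- spec$codon_probs[[a]] * length(fam[[a]])
    if (a %in% tab$excluded_aa) v[] <- NA_real_
    v
  }))
  syn_aa <- setdiff(names(fam), tab$excluded_aa)
  gc_at <- function(codons, k) substr(codons, k, k) %in% c("G", "C")
  pos_gc <- function(k, aa_set) {
    num <- sum(unlist(lapply(aa_set, function(a) {
      spec$aa_freqs[[a]] * sum(spec$codon_probs[[a]][gc_at(fam[[a]], k)])
    })))
    den <- sum(unlist(spec$aa_freqs[aa_set]))
    num / den
  }
  all_aa <- names(fam)
  gc1 <- pos_gc(1, all_aa); gc2 <- pos_gc(2, all_aa)
  list(species = spec$species, theta = spec$theta,
       codon_probs = p_codon, implied_rscu = implied_rscu,
       implied_gc3s = pos_gc(3, syn_aa),
       implied_gc3 = pos_gc(3, all_aa),
       implied_gc12 = (gc1 + gc2) / 2)
}

#' A seven-species synthetic cohort
#'
#' Builds specs for a cohort of synthetic mitogenomes with distinct
#' per-species GC3 bias, spanning the range of synonymous GC content
#' observed across mygalomorph mitogenomes (roughly 0.17 to 0.46, mean
#' near 0.27).
#'
#' @param seed integer master seed; per-species seeds are `seed + 1:n`.
#' @param thetas per-species GC3 bias values (length defines cohort
#'   size).
#' @return Named list of [synthetic_spec()] objects.
#' @export
synthetic_cohort <- function(seed = 1L,
                             thetas = c(0.18, 0.20, 0.23, 0.26,
                                        0.29, 0.33, 0.44)) {
  n <- length(thetas)
  species <- paste("Synthomygale",
                   c("alpha", "beta", "gamma", "delta", "epsilon",
                     "zeta", "eta", "theta", "iota", "kappa")[seq_len(n)])
  specs <- lapply(seq_len(n), function(i) {
    synthetic_spec(species = species[i], seed = as.integer(seed) + i,
                   theta = thetas[i],
                   accession = sprintf("SYN_%03d%03d", abs(seed) %% 1000, i))
  })
  names(specs) <- species
  specs
}

#' Synthetic gene-level data for neutrality-plot scenarios
#'
#' Generates per-gene (GC3, GC12) pairs under two evolutionary
#' scenarios. In the `mutation` scenario each gene gets its own GC3
#' bias and the amino-acid composition is coupled to it (interpolating
#' between an AT-rich and a GC-rich palette at a rate chosen
#' analytically so expected GC12 rises one-for-one with GC3): mutation
#' pressure drives all positions together and the neutrality slope is
#' near 1. In the `selection` scenario the amino-acid composition is
#' held fixed while the per-gene GC3 bias varies, so GC12 is flat in
#' expectation and the slope is near 0.
#'
#' @param scenario `"mutation"` or `"selection"`.
#' @param n_genes number of genes to simulate.
#' @param codons_per_gene codons per simulated gene.
#' @param theta_range range of the per-gene GC3 bias.
#' @param seed integer seed.
#' @return data.frame: `theta`, `gc3`, `gc12`, one row per gene.
#' @export
neutrality_scenario <- function(scenario = c("mutation", "selection"),
                                n_genes = 40, codons_per_gene = 500,
                                theta_range = c(0.15, 0.5), seed = 1L) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  tab <- codon_table5()
  at_palette <- default_aa_freqs()
  gc_w <- c(A = 20, G = 20, P = 15, R = 10, T = 10, V = 10, S = 5,
            L = 5, E = 5, I = 1, F = 1, M = 1, N = 1, K = 1, Y = 1,
            W = 1, H = 1, Q = 1, D = 1, C = 1)
  gc_palette <- gc_w[names(at_palette)] / sum(gc_w)
  gc12_of <- function(aa) {
    s <- synthetic_spec(aa_freqs = aa, theta = 0.5, genes = minimal_layout())
    ground_truth_stats(s)$implied_gc12
  }
  g_at <- gc12_of(at_palette)
  g_gc <- gc12_of(gc_palette)
  span <- g_gc - g_at
  if (diff(theta_range) > span) {
    stop("theta_range wider than the attainable GC12 span (", round(span, 3),
         "); narrow the range")
  }
  thetas <- stats::runif(n_genes, theta_range[1], theta_range[2])
  out <- do.call(rbind, lapply(thetas, function(th) {
    aa <- if (scenario == "mutation") {
      m <- (th - theta_range[1]) / span
      v <- (1 - m) * at_palette + m * gc_palette
      v / sum(v)
    } else at_palette
    sp <- synthetic_spec(aa_freqs = aa, theta = th,
                         genes = minimal_layout(codons_per_gene))
    codons <- sample_gene(sp, "g1")$gene$codons
    comp <- positional_composition(codons, tab)
    data.frame(theta = th, gc3 = comp$gc3, gc12 = comp$gc12)
  }))
  rownames(out) <- NULL
  out
}

minimal_layout <- function(len = 100L) {
  data.frame(gene = "g1", length_codons = as.integer(len), strand = "+",
             start_codon = "ATG", stop_variant = "TAA",
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec:", x$species, "(", x$accession, ")\n")
  cat("  ", nrow(x$genes), "genes,",
      sum(x$genes$length_codons), "codons, theta =", x$theta,
      ", seed =", x$seed, "\n")
  invisible(x)
}
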