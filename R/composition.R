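#' Positional nucleotide composition of a coding sequence
#'
#' Computes the GC fraction at each codon position over all retained
#' codons (GC1, GC2, GC3, and GC12 = (GC1 + GC2)/2), plus
#' synonymous-site quantities restricted to codons whose amino acid has
#' two or more interchangeable codons (Met and Trp excluded by
#' convention): GC3s and the third-position base tallies A3s/T3s/G3s/C3s.
#' Third-position tallies over fourfold-degenerate families only
#' (Val, Pro, Thr, Ala, Gly, Arg under table 5) are also returned for
#' parity-rule-2 analysis, where fourfold sites are the cleanest signal
#' because the base at position 3 is free of amino-acid constraint.
#'
#' @param gene a `gene_seq`, or a bare character vector of codons.
#' @param table a [codon_table5()] object.
#' @return A one-row data.frame: `gc1`, `gc2`, `gc3`, `gc12`, `gc3s`,
#'   `at` (overall A+T fraction), synonymous third-position counts
#'   `a3s`, `t3s`, `g3s`, `c3s`, and fourfold-only counts `a3f`, `t3f`,
#'   `g3f`, `c3f`. `gc3s` is `NA` (with a warning) when the gene has no
#'   synonymous codons, never silently 0.
#' @examples
#' positional_composition(c("GGG", "GGG"))[, c("gc3", "gc3s")]
#' @export
positional_composition <- function(gene, table = codon_table5()) {
  codons <- if (inherits(gene, "gene_seq")) gene$codons else gene
  stopifnot(length(codons) >= 1, all(grepl("^[ACGT]{3}$", codons)))
  p1 <- substr(codons, 1, 1)
  p2 <- substr(codons, 2, 2)
  p3 <- substr(codons, 3, 3)
  gc <- function(b) mean(b %in% c("G", "C"))
  gc1 <- gc(p1); gc2 <- gc(p2); gc3 <- gc(p3)

  aa <- unname(table$aa[codons])
  syn <- !(aa %in% table$excluded_aa) # every table-5 family has >= 2 codons
  four <- aa %in% table$classes[["4"]]
  base_counts <- function(b) {
    n <- table(factor(b, levels = c("A", "T", "G", "C")))
    as.integer(n)
  }
  s3 <- base_counts(p3[syn])
  f3 <- base_counts(p3[four])
  gc3s <- if (any(syn)) gc(p3[syn]) else {
    warning("gene has no synonymous codons; GC3s undefined")
    NA_real_
  }
  data.frame(
    gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2,
    gc3s = gc3s, at = mean(c(p1, p2, p3) %in% c("A", "T")),
    a3s = s3[1], t3s = s3[2], g3s = s3[3], c3s = s3[4],
    a3f = f3[1], t3f = f3[2], g3f = f3[3], c3f = f3[4]
  )
}

#' Per-gene composition table for a gene set
#'
#' @param genes a `gene_set` from [extract_pcgs()].
#' @param table a [codon_table5()] object.
#' @return data.frame with one row per gene: species, gene, then the
#'   columns of [positional_composition()].
#' @export
composition_table <- function(genes, table = codon_table5()) {
  out <- do.call(rbind, lapply(genes, function(g) {
    cbind(species = g$species, gene = g$gene,
          positional_composition(g, table), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
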