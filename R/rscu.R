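#' Tally codon usage per gene or per species
#'
#' @param genes a `gene_set` (or list of `gene_seq`) from
#'   [extract_pcgs()] or [sample_gene()].
#' @param scope `"per_gene"` for one tally per gene, or `"per_species"`
#'   to pool all protein-coding genes of each species into one tally
#'   (the unit on which species-level RSCU profiles are computed).
#' @param table a [codon_table5()] object.
#' @return A named list of `codon_counts` objects: named integer vectors
#'   over the 62 sense codons, with attributes `label`, `species` and
#'   `total`. Stop codons are never counted (they are removed at
#'   extraction).
#' @examples
#' gb <- tempfile(fileext = ".gb")
#' synthesize_genome(synthetic_spec(seed = 1), gb)
#' genes <- extract_pcgs(parse_genbank(gb))
#' counts <- count_codons(genes, "per_species")
#' attr(counts[[1]], "total")
#' @export
count_codons <- function(genes, scope = c("per_gene", "per_species"),
                         table = codon_table5()) {
  scope <- match.arg(scope)
  if (length(genes) == 0) stop("empty gene list")
  sense <- setdiff(names(table$aa), table$stop_codons)
  tally <- function(codon_vec, label, species) {
    counts <- table(factor(codon_vec, levels = sense))
    out <- as.integer(counts)
    names(out) <- sense
    structure(out, label = label, species = species, total = sum(out),
              class = "codon_counts")
  }
  if (scope == "per_gene") {
    out <- lapply(genes, function(g) {
      tally(g$codons, paste(g$species, g$gene, sep = "|"), g$species)
    })
    names(out) <- vapply(out, attr, character(1), "label")
  } else {
    species <- vapply(genes, `[[`, character(1), "species")
    out <- lapply(split(genes, species), function(gs) {
      tally(unlist(lapply(gs, `[[`, "codons")), gs[[1]]$species,
            gs[[1]]$species)
    })
  }
  out
}

#' Relative synonymous codon usage
#'
#' RSCU is the observed count of a codon divided by the count expected
#' if all synonymous codons for its amino acid were used equally: for a
#' codon `c` in a family of `n` synonymous codons with family total `N`,
#' `RSCU(c) = count(c) * n / N`. A value of 1 means no bias; values sum
#' to the family size within each observed family. Stop codons and the
#' single-codon-treated amino acids Met and Trp are excluded; their
#' codons get class `undefined`, as do codons of families absent from
#' the tally (`RSCU = NA`, distinguishing "family absent" from "unused
#' codon in a present family", which is RSCU 0).
#'
#' @param counts a `codon_counts` object from [count_codons()].
#' @param table a [codon_table5()] object.
#' @return data.frame of class `rscu_profile` with one row per sense
#'   codon: `codon`, `aa`, `family_size`, `count`, `rscu`, `class`
#'   (preferred / neutral / rare / undefined) plus attributes `label`
#'   and `species` carried over from the tally.
#' @examples
#' g <- list(list(gene = "toy", species = "sp", codons =
#'   c("TTT", "TTT", "TTT", "TTC")))
#' compute_rscu(count_codons(g, "per_gene")[[1]])[1:2, ]
#' @export
compute_rscu <- function(counts, table = codon_table5()) {
  stopifnot(inherits(counts, "codon_counts"))
  syn_aa <- setdiff(names(table$families), table$excluded_aa)
  codon <- names(counts)
  aa <- unname(table$aa[codon])
  fam_size <- unname(table$degeneracy[aa])
  cnt <- as.integer(counts)
  fam_tot <- tapply(cnt, aa, sum)[aa]
  rscu <- ifelse(aa %in% syn_aa & fam_tot > 0,
                 cnt * fam_size / fam_tot, NA_real_)
  cls <- rep("undefined", length(codon))
  ok <- !is.na(rscu)
  cls[ok] <- classify_rscu(rscu[ok])
  out <- data.frame(codon = codon, aa = aa, family_size = fam_size,
                    count = cnt, rscu = unname(rscu), class = cls,
                    stringsAsFactors = FALSE)
  out <- out[order(out$aa, out$codon), ]
  rownames(out) <- NULL
  structure(out, label = attr(counts, "label"),
            species = attr(counts, "species"),
            class = c("rscu_profile", "data.frame"))
}

#' Classify RSCU values into preference classes
#'
#' Thresholds standard in codon usage studies: strongly preferred when
#' RSCU > 1.6, rarely used when RSCU < 0.6, neutral in between
#' (boundaries inclusive on the neutral side).
#'
#' @param rscu numeric vector of non-negative RSCU values.
#' @return Character vector: `"preferred"`, `"neutral"` or `"rare"`.
#' @examples
#' classify_rscu(c(0, 0.6, 1.6, 3.5))
#' @export
classify_rscu <- function(rscu) {
  if (any(is.na(rscu)) || any(rscu < 0)) {
    stop("RSCU values must be non-negative and non-missing")
  }
  ifelse(rscu > 1.6, "preferred", ifelse(rscu < 0.6, "rare", "neutral"))
}

#' Long-format RSCU table across units
#'
#' Convenience wrapper running [compute_rscu()] over every tally in a
#' [count_codons()] result and stacking the profiles.
#'
#' @inheritParams count_codons
#' @return data.frame: `species`, `unit` (gene label or species for
#'   pooled tallies), `codon`, `aa`, `count`, `rscu`, `class`.
#' @export
rscu_table <- function(genes, scope = c("per_species", "per_gene"),
                       table = codon_table5()) {
  scope <- match.arg(scope)
  counts <- count_codons(genes, scope, table)
  out <- do.call(rbind, lapply(counts, function(ct) {
    prof <- compute_rscu(ct, table)
    cbind(species = attr(ct, "species"), unit = attr(ct, "label"),
          as.data.frame(prof), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
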