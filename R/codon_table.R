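#' The invertebrate mitochondrial genetic code (translation table 5)
#'
#' Builds the codon table used throughout the package: NCBI translation
#' table 5, under which AGA/AGG encode serine, ATA encodes methionine and
#' TGA encodes tryptophan. Only TAA and TAG are stop codons, leaving 62
#' sense codons. Methionine and tryptophan (two codons each under this
#' code) are excluded from all synonymous-site statistics, so 58 codons
#' enter RSCU and related analyses.
#'
#' @return An object of class `codon_table`: a list with
#'   \describe{
#'     \item{aa}{named character vector mapping all 64 codons to one-letter
#'       amino acids (`*` for stop).}
#'     \item{families}{named list mapping each amino acid to its synonymous
#'       codon set.}
#'     \item{stop_codons}{`c("TAA", "TAG")`.}
#'     \item{start_codons}{permitted initiation codons
#'       (ATG, ATT, ATA, TTG, GTG).}
#'     \item{excluded_aa}{amino acids excluded from synonymous statistics
#'       (`M`, `W`).}
#'     \item{syn_codons}{the 58 codons used in synonymous-site analyses.}
#'     \item{degeneracy}{named integer vector: synonymous family size for
#'       each amino acid.}
#'     \item{classes}{list mapping degeneracy class ("2", "4", "6", "8") to
#'       the amino acids in it; under table 5 the sizes are 10, 6, 1 (Leu)
#'       and 1 (the eightfold Ser family TCN + AGN).}
#'   }
#' @examples
#' tab <- codon_table5()
#' tab$aa[c("ATA", "TGA", "AGA")] # M, W, S
#' @export
codon_table5 <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- paste0(
    rep(bases, each = 16),
    rep(rep(bases, each = 4), 4),
    rep(bases, 16)
  )
  # standard-table amino acids in TCAG order, then the table-5 reassignments
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CCWW", # TTT..TGG block ordered T,C,A,G at pos3
    "LLLLPPPPHHQQRRRR",
    "IIMMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  names(aa) <- codons
  aa["TGA"] <- "W" # opal read-through
  aa["ATA"] <- "M"
  aa[c("AGA", "AGG")] <- "S"

  stop_codons <- c("TAA", "TAG")
  sense <- aa[!aa %in% "*"]
  families <- split(names(sense), sense)
  excluded_aa <- c("M", "W")
  syn_aa <- setdiff(names(families), excluded_aa)
  degeneracy <- vapply(families, length, integer(1))
  classes <- split(syn_aa, as.character(degeneracy[syn_aa]))

  structure(
    list(
      aa = aa,
      families = families,
      stop_codons = stop_codons,
      start_codons = c("ATG", "ATT", "ATA", "TTG", "GTG"),
      excluded_aa = excluded_aa,
      syn_codons = sort(unname(unlist(families[syn_aa]))),
      degeneracy = degeneracy,
      classes = classes
    ),
    class = "codon_table"
  )
}

#' Translate codons under translation table 5
#'
#' @param codon character vector of trinucleotides over A/C/G/T
#'   (case-insensitive; U is accepted as T).
#' @param table a [codon_table5()] object.
#' @return Character vector of one-letter amino acids; `"*"` for TAA/TAG.
#'   Codons containing ambiguity codes (N etc.) translate to `NA`, the
#'   signal by which genes are excluded from codon statistics.
#' @examples
#' translate_codon(c("ATA", "TGA", "AGA", "TTT"))
#' @export
translate_codon <- function(codon, table = codon_table5()) {
  codon <- chartr("u", "T", chartr("U", "T", toupper(codon)))
  bad <- nchar(codon) != 3L
  if (any(bad)) {
    stop("not a trinucleotide: ", paste(codon[bad], collapse = ", "))
  }
  out <- unname(table$aa[codon])
  out # NA for non-ACGT codons
}

#' @export
print.codon_table <- function(x, ...) {
  cat("Invertebrate mitochondrial genetic code (table 5)\n")
  cat("  sense codons:", length(x$aa) - length(x$stop_codons),
      " stops:", paste(x$stop_codons, collapse = "/"), "\n")
  cat("  degeneracy classes:",
      paste(sprintf("%s-fold x%d", names(x$classes),
                    lengths(x$classes)), collapse = ", "), "\n")
  invisible(x)
}

# reverse complement of an ACGT string (vectorised over strings)
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
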