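#' Canonical mitochondrial protein-coding gene names
#'
#' The 13 protein-coding genes (PCGs) of the standard metazoan
#' mitochondrial gene complement, in conventional order.
#' @export
PCG_NAMES <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cytb",
               "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")

#' Normalize a GenBank gene label to its canonical PCG name
#'
#' GenBank annotation of mitogenomes labels the same gene many ways
#' (COX1 / COI / CO1 / "cytochrome c oxidase subunit I"; ND4L / nad4L;
#' CYTB / cob / "cytochrome b"; ...). This maps any of the common
#' variants onto the canonical lowercase set in [PCG_NAMES].
#'
#' @param label character vector of gene or product labels.
#' @return Character vector of canonical names; `NA` where the label is
#'   not a recognized protein-coding gene.
#' @examples
#' normalize_gene(c("COI", "ND4L", "cytochrome b", "ATPase6", "trnK"))
#' @export
normalize_gene <- function(label) {
  vapply(label, function(x) {
    if (is.na(x)) return(NA_character_)
    s <- tolower(gsub("[^a-z0-9]", "", tolower(x)))
    roman <- c(i = "1", ii = "2", iii = "3")
    # cytochrome c oxidase
    m <- regmatches(s, regexec("^(?:cytochromecoxidasesubunit|cox?|mtco)(i{1,3}|[123])$", s))[[1]]
    if (length(m)) {
      d <- if (m[2] %in% names(roman)) roman[[m[2]]] else m[2]
      return(paste0("cox", d))
    }
    # NADH dehydrogenase, nad4L before nad4
    m <- regmatches(s, regexec("^(?:nadhdehydrogenasesubunit|nadh?|nd)(4l|[1-6])$", s))[[1]]
    if (length(m)) {
      return(if (m[2] == "4l") "nad4L" else paste0("nad", m[2]))
    }
    # ATP synthase
    m <- regmatches(s, regexec("^(?:atpsynthasef0subunit|atpsynthasesubunit|atpase|atp)([68])$", s))[[1]]
    if (length(m)) return(paste0("atp", m[2]))
    if (s %in% c("cytb", "cob", "cyb", "cytochromeb", "mtcyb")) return("cytb")
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Extract and codonize protein-coding genes from a genome record
#'
#' Cuts every CDS feature out of the genome, reverse-complements
#' minus-strand genes to sense orientation, applies the `codon_start`
#' reading-frame offset, strips the terminator, and splits the coding
#' region into codons. Complete stops (TAA/TAG) and incomplete stops
#' (a trailing T or TA, completed to TAA by polyadenylation — the
#' standard arthropod mitogenome convention) are removed and recorded in
#' `stop_note`; start codons, including the atypical ATT/ATA/TTG starts
#' of invertebrate mitochondria, are retained as ordinary codons.
#'
#' Genes containing ambiguity codes (N etc.) are dropped with a warning
#' rather than guessed. A post-trim length that is not a multiple of 3
#' is a frame error; an internal TAA/TAG is an annotation-inconsistency
#' error; a CDS label that cannot be mapped by [normalize_gene()] is an
#' unknown-gene error.
#'
#' @param record a `genome_record` from [parse_genbank()].
#' @param table a [codon_table5()] object.
#' @return An object of class `gene_set`: a list of `gene_seq` objects,
#'   each with fields `gene`, `species`, `accession`, `strand`, `codons`
#'   (character vector of sense-strand trinucleotides, stop removed),
#'   `start_codon`, `stop_note` (one of `complete_TAA`, `complete_TAG`,
#'   `incomplete_T`, `incomplete_TA`, `none`) and `span_length` (the
#'   annotated CDS span in bp).
#' @examples
#' gb <- tempfile(fileext = ".gb")
#' synthesize_genome(synthetic_spec(seed = 1), gb)
#' genes <- extract_pcgs(parse_genbank(gb))
#' gene_inventory(genes)
#' @export
extract_pcgs <- function(record, table = codon_table5()) {
  stopifnot(inherits(record, "genome_record"))
  cds <- record$features[record$features$kind == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) {
    stop("no protein-coding genes: record ", record$accession,
         " has no CDS feature")
  }
  genes <- list()
  for (i in seq_len(nrow(cds))) {
    canon <- normalize_gene(cds$gene[i])
    if (is.na(canon)) {
      stop("unknown gene label in ", record$accession, ": ",
           if (is.na(cds$gene[i])) "<unlabelled CDS>" else cds$gene[i])
    }
    segs <- cds$segments[[i]]
    raw <- paste(apply(segs, 1, function(s) {
      substr(record$sequence, s[1], s[2])
    }), collapse = "")
    sense <- if (cds$strand[i] == "-") revcomp(raw) else raw
    offset <- cds$codon_start[i] - 1L
    if (offset > 0) sense <- substr(sense, offset + 1, nchar(sense))

    n <- nchar(sense)
    phase <- n %% 3L
    stop_note <- "none"
    if (phase == 1L) {
      tail1 <- substr(sense, n, n)
      if (tail1 != "T") {
        stop("frame error in ", record$accession, " ", canon,
             ": CDS length ", n, " is not a codon multiple and does not ",
             "end in an incomplete stop")
      }
      sense <- substr(sense, 1, n - 1L)
      stop_note <- "incomplete_T"
    } else if (phase == 2L) {
      tail2 <- substr(sense, n - 1L, n)
      if (tail2 != "TA") {
        stop("frame error in ", record$accession, " ", canon,
             ": CDS length ", n, " is not a codon multiple and does not ",
             "end in an incomplete stop")
      }
      sense <- substr(sense, 1, n - 2L)
      stop_note <- "incomplete_TA"
    } else {
      tail3 <- substr(sense, n - 2L, n)
      if (tail3 %in% table$stop_codons) {
        sense <- substr(sense, 1, n - 3L)
        stop_note <- paste0("complete_", tail3)
      }
    }
    if (nchar(sense) == 0 || nchar(sense) %% 3L != 0L) {
      stop("frame error in ", record$accession, " ", canon,
           ": post-trim length ", nchar(sense), " is not a multiple of 3")
    }
    codons <- substring(sense, seq(1, nchar(sense), 3), seq(3, nchar(sense), 3))
    internal_stop <- which(codons %in% table$stop_codons)
    if (length(internal_stop)) {
      stop("annotation inconsistency in ", record$accession, " ", canon,
           ": internal stop codon at codon index ", internal_stop[1])
    }
    if (any(!grepl("^[ACGT]{3}$", codons))) {
      warning("dropping ", record$accession, " ", canon,
              ": contains ambiguity codes")
      next
    }
    genes[[length(genes) + 1L]] <- structure(
      list(gene = canon, species = record$organism,
           accession = record$accession, strand = cds$strand[i],
           codons = codons, start_codon = codons[1],
           stop_note = stop_note,
           span_length = sum(segs[, 2] - segs[, 1] + 1L)),
      class = "gene_seq"
    )
  }
  structure(genes, class = "gene_set")
}

#' Tabulate an extracted gene set
#'
#' @param genes a `gene_set` from [extract_pcgs()], or a plain list of
#'   `gene_seq` objects (e.g. pooled across species).
#' @return data.frame with one row per gene: species, accession, gene,
#'   strand, length in codons, start codon and stop note.
#' @export
gene_inventory <- function(genes) {
  data.frame(
    species = vapply(genes, `[[`, character(1), "species"),
    accession = vapply(genes, `[[`, character(1), "accession"),
    gene = vapply(genes, `[[`, character(1), "gene"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    length_codons = vapply(genes, function(g) length(g$codons), integer(1)),
    start_codon = vapply(genes, `[[`, character(1), "start_codon"),
    stop_note = vapply(genes, `[[`, character(1), "stop_note"),
    stringsAsFactors = FALSE
  )
}

#' Write extracted coding sequences as FASTA
#'
#' @param genes a `gene_set` from [extract_pcgs()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_pcg_fasta <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genes) {
    writeLines(paste0(">", gsub(" ", "_", g$species), "|", g$gene), con)
    seq <- paste(g$codons, collapse = "")
    starts <- seq(1, nchar(seq), 70)
    writeLines(substring(seq, starts, pmin(starts + 69, nchar(seq))), con)
  }
  invisible(path)
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", length(x), "protein-coding genes from",
      length(unique(vapply(x, `[[`, character(1), "species"))), "species\n")
  print(utils::head(gene_inventory(x), 15))
  if (length(x) > 15) cat("  ...\n")
  invisible(x)
}
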