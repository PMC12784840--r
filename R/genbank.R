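#' Read GenBank flat files of mitochondrial genomes
#'
#' A reader for the GenBank flat-file dialect produced by NCBI for
#' mitogenome records (and by [synthesize_genome()]): LOCUS line,
#' ORGANISM, a FEATURES table with CDS/tRNA/rRNA/D-loop entries, and an
#' ORIGIN sequence block. Feature locations may be `a..b`,
#' `complement(...)` or `join(...)` (the latter covering a single
#' origin-spanning feature on a circular molecule); `<`/`>` partial
#' markers are stripped. Coordinates are kept 1-based inclusive, exactly
#' as annotated.
#'
#' @param path path to a GenBank flat file (single- or multi-record).
#' @return A named list of `genome_record` objects (named by accession).
#'   Each record is a list with `accession`, `organism`, `length`,
#'   `topology`, `sequence` (uppercase string) and `features`, a
#'   data.frame with columns `kind`, `start`, `end`, `strand` ("+"/"-"),
#'   `gene`, `codon_start`, `transl_table` and a `segments` list-column
#'   holding the 1-based inclusive span(s) of each feature.
#' @seealso [parse_genbank()] for the single-record convenience wrapper,
#'   [extract_pcgs()] for gene extraction.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !any(nzchar(lines))) {
    stop("GenBank parse error at line 1: empty file (", path, ")")
  }
  # split into records on the '//' terminator
  ends <- grep("^//", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  records <- list()
  for (i in seq_along(ends)) {
    chunk <- lines[starts[i]:ends[i]]
    offset <- starts[i] - 1L
    if (!any(grepl("^LOCUS", chunk))) next # trailing blank block
    rec <- parse_gb_record(chunk, offset, path)
    records[[rec$accession]] <- rec
  }
  if (length(records) == 0) {
    stop("GenBank parse error at line 1: no LOCUS line found (", path, ")")
  }
  records
}

#' Parse a single-record GenBank flat file
#'
#' @inheritParams read_genbank
#' @return A single `genome_record` (see [read_genbank()]). Errors if the
#'   file holds more than one record or the record has no CDS feature.
#' @examples
#' spec <- synthetic_spec(seed = 1)
#' gb <- tempfile(fileext = ".gb")
#' synthesize_genome(spec, gb)
#' rec <- parse_genbank(gb)
#' table(rec$features$kind)
#' @export
parse_genbank <- function(path) {
  recs <- read_genbank(path)
  if (length(recs) != 1) {
    stop("expected a single-record GenBank file, found ", length(recs),
         " records in ", path)
  }
  rec <- recs[[1]]
  if (!any(rec$features$kind == "CDS")) {
    stop("no protein-coding genes: record ", rec$accession,
         " has no CDS feature")
  }
  rec
}

parse_gb_record <- function(chunk, offset, path) {
  locus_i <- grep("^LOCUS", chunk)[1]
  locus <- chunk[locus_i]
  toks <- strsplit(trimws(locus), "[[:space:]]+")[[1]]
  declared_len <- suppressWarnings(as.integer(toks[which(toks == "bp") - 1]))
  topology <- if (any(toks == "circular")) "circular" else "linear"
  name <- toks[2]

  acc_i <- grep("^ACCESSION", chunk)
  accession <- if (length(acc_i)) {
    strsplit(trimws(chunk[acc_i[1]]), "[[:space:]]+")[[1]][2]
  } else name
  if (is.na(accession)) accession <- name

  org_i <- grep("^[[:space:]]+ORGANISM", chunk)
  organism <- if (length(org_i)) {
    sub("^[[:space:]]+ORGANISM[[:space:]]+", "", chunk[org_i[1]])
  } else NA_character_

  feat_i <- grep("^FEATURES", chunk)
  origin_i <- grep("^ORIGIN", chunk)
  if (length(origin_i) == 0) {
    stop("GenBank parse error at line ", offset + length(chunk),
         ": no ORIGIN block (", path, ")")
  }
  origin_i <- origin_i[1]

  seq_lines <- chunk[(origin_i + 1):length(chunk)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) {
    stop("GenBank parse error at line ", offset + origin_i,
         ": empty ORIGIN block (", path, ")")
  }
  if (!is.na(declared_len) && nchar(sequence) != declared_len) {
    warning("record ", accession, ": LOCUS declares ", declared_len,
            " bp but ORIGIN holds ", nchar(sequence), " bp")
  }

  features <- if (length(feat_i)) {
    parse_gb_features(chunk[(feat_i[1] + 1):(origin_i - 1)],
                      offset + feat_i[1], nchar(sequence), path)
  } else empty_features()

  structure(
    list(accession = accession, organism = organism,
         length = nchar(sequence), topology = topology,
         sequence = sequence, features = features),
    class = "genome_record"
  )
}

empty_features <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             strand = character(), gene = character(),
             codon_start = integer(), transl_table = integer(),
             stringsAsFactors = FALSE)
}

parse_gb_features <- function(lines, offset, seq_len, path) {
  # feature keys start in column 6; qualifiers/continuations in column 22
  is_key <- grepl("^ {5}[A-Za-z]", lines)
  key_idx <- which(is_key)
  out <- list()
  for (j in seq_along(key_idx)) {
    i <- key_idx[j]
    last <- if (j < length(key_idx)) key_idx[j + 1] - 1L else length(lines)
    block <- lines[i:last]
    kind <- sub("^ {5}([^ ]+).*", "\\1", block[1])
    # location may continue over lines until the first qualifier
    qual_start <- grep("^ {21}/", block)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
    loc <- gsub("[[:space:]]", "",
                paste(c(sub("^ {5}[^ ]+ +", "", block[1]),
                        trimws(block[seq_len(loc_end)[-1]])), collapse = ""))
    parsed <- tryCatch(
      parse_gb_location(loc),
      error = function(e) {
        stop("GenBank parse error at line ", offset + i, ": ",
             conditionMessage(e), " (", path, ")")
      }
    )
    quals <- paste(block[seq_len(length(block)) >= loc_end + 1], collapse = "\n")
    gene <- gb_qualifier(quals, "gene")
    if (is.na(gene)) gene <- gb_qualifier(quals, "product")
    cs <- suppressWarnings(as.integer(gb_qualifier(quals, "codon_start")))
    tt <- suppressWarnings(as.integer(gb_qualifier(quals, "transl_table")))
    out[[j]] <- list(kind = kind, segments = parsed$segments,
                     strand = parsed$strand, gene = gene,
                     codon_start = if (is.na(cs)) 1L else cs,
                     transl_table = tt)
  }
  out <- out[!vapply(out, function(x) x$kind %in% c("source"), logical(1))]
  if (length(out) == 0) return(empty_features())
  feats <- data.frame(
    kind = vapply(out, `[[`, character(1), "kind"),
    start = vapply(out, function(x) x$segments[1, 1], integer(1)),
    end = vapply(out, function(x) x$segments[nrow(x$segments), 2], integer(1)),
    strand = vapply(out, `[[`, character(1), "strand"),
    gene = vapply(out, `[[`, character(1), "gene"),
    codon_start = vapply(out, `[[`, integer(1), "codon_start"),
    transl_table = vapply(out, `[[`, integer(1), "transl_table"),
    stringsAsFactors = FALSE
  )
  feats$segments <- lapply(out, `[[`, "segments")
  bad <- feats$start < 1 | vapply(feats$segments, max, integer(1)) > seq_len
  if (any(bad)) {
    stop("feature interval outside [1, ", seq_len, "]: ",
         paste(feats$kind[bad], feats$gene[bad], collapse = ", "))
  }
  feats
}

gb_qualifier <- function(quals, name) {
  pat <- paste0("/", name, "=(\"([^\"]*)\"|([^\\s/\"]+))")
  m <- regmatches(quals, regexpr(pat, quals, perl = TRUE))
  if (length(m) == 0) return(NA_character_)
  gsub("^\"|\"$", "", sub(paste0("/", name, "="), "", m, fixed = TRUE))
}

parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  while (grepl("^complement\\(", loc)) {
    strand <- if (strand == "+") "-" else "+"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",")[[1]]
  if (length(parts) == 0) stop("empty location")
  segs <- t(vapply(parts, function(p) {
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      as.integer(strsplit(p, "\\.\\.")[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      rep(as.integer(p), 2)
    } else {
      stop("unsupported location syntax: ", p)
    }
  }, integer(2)))
  dimnames(segs) <- NULL
  if (any(segs[, 2] < segs[, 1])) stop("reversed interval in location: ", loc)
  list(segments = segs, strand = strand)
}

#' Write a genome record as a GenBank flat file
#'
#' Emits the minimal legal dialect (LOCUS, ACCESSION, ORGANISM, FEATURES,
#' ORIGIN with 60-base lines in blocks of 10) that [read_genbank()]
#' parses back losslessly.
#'
#' @param record a `genome_record` (see [read_genbank()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "genome_record"))
  n <- nchar(record$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %-16s %11d bp    DNA     %-8s INV 01-JAN-2026",
            record$accession, n, record$topology))
  w("DEFINITION  ", record$organism, " mitochondrion, complete genome.")
  w("ACCESSION   ", record$accession)
  w("SOURCE      mitochondrion ", record$organism)
  w("  ORGANISM  ", record$organism)
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     %-16s%s", "source", paste0("1..", n)))
  w("                     /organism=\"", record$organism, "\"")
  w("                     /organelle=\"mitochondrion\"")
  feats <- record$features
  for (i in seq_len(nrow(feats))) {
    segs <- feats$segments[[i]]
    loc <- paste(apply(segs, 1, function(s) {
      if (s[1] == s[2]) as.character(s[1]) else paste0(s[1], "..", s[2])
    }), collapse = ",")
    if (nrow(segs) > 1) loc <- paste0("join(", loc, ")")
    if (feats$strand[i] == "-") loc <- paste0("complement(", loc, ")")
    w(sprintf("     %-16s%s", feats$kind[i], loc))
    if (!is.na(feats$gene[i])) {
      w("                     /gene=\"", feats$gene[i], "\"")
    }
    if (feats$kind[i] == "CDS") {
      w("                     /codon_start=", feats$codon_start[i])
      if (!is.na(feats$transl_table[i])) {
        w("                     /transl_table=", feats$transl_table[i])
      }
    }
  }
  w("ORIGIN")
  s <- tolower(record$sequence)
  starts <- seq(1, n, by = 60)
  for (st in starts) {
    line <- substr(s, st, min(st + 59, n))
    grp <- substring(line, seq(1, nchar(line), 10),
                     pmin(seq(10, nchar(line) + 9, 10), nchar(line)))
    w(sprintf("%9d %s", st, paste(grp, collapse = " ")))
  }
  w("//")
  invisible(path)
}

#' @export
print.genome_record <- function(x, ...) {
  cat("genome_record ", x$accession, " (", x$organism, ")\n", sep = "")
  cat("  ", x$length, " bp, ", x$topology, "\n", sep = "")
  tab <- table(x$features$kind)
  cat("  features:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
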