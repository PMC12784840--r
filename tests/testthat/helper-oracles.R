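# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately re-derive quantities from first principles (loops,
# closed forms) rather than calling the package's vectorized paths.

make_gene <- function(codons, gene = "toy", species = "Testozoa minima",
                      strand = "+", stop_note = "complete_TAA") {
  structure(
    list(gene = gene, species = species, accession = "TEST_000001",
         strand = strand, codons = codons, start_codon = codons[1],
         stop_note = stop_note, span_length = 3L * length(codons) + 3L),
    class = "gene_seq"
  )
}

make_counts <- function(counts, table = codon_table5()) {
  sense <- setdiff(names(table$aa), table$stop_codons)
  full <- stats::setNames(integer(length(sense)), sense)
  full[names(counts)] <- as.integer(counts)
  structure(full, label = "oracle", species = "oracle", total = sum(full),
            class = "codon_counts")
}

one_gene_spec <- function(len, theta = 0.5, aa_freqs = NULL, seed = 1L) {
  synthetic_spec(
    theta = theta, aa_freqs = aa_freqs, seed = seed,
    genes = data.frame(gene = "g1", length_codons = as.integer(len),
                       strand = "+", start_codon = "ATG",
                       stop_variant = "TAA", stringsAsFactors = FALSE)
  )
}

# Wright homozygosity / ENC evaluated by explicit loops over amino acids,
# sharing only the documented conventions (n_a >= 2; positive F kept;
# class mean; cross-class mean imputation; clip at 61).
enc_oracle <- function(counts, table = codon_table5()) {
  class_of_aa <- list()
  for (k in names(table$classes)) {
    for (a in table$classes[[k]]) class_of_aa[[a]] <- k
  }
  f_by_class <- list(`2` = c(), `4` = c(), `6` = c(), `8` = c())
  for (a in names(class_of_aa)) {
    n_a <- 0
    for (cod in table$families[[a]]) n_a <- n_a + counts[[cod]]
    if (n_a < 2) next
    sum_p2 <- 0
    for (cod in table$families[[a]]) {
      sum_p2 <- sum_p2 + (counts[[cod]] / n_a)^2
    }
    f <- (n_a * sum_p2 - 1) / (n_a - 1)
    if (f > 0) {
      k <- class_of_aa[[a]]
      f_by_class[[k]] <- c(f_by_class[[k]], f)
    }
  }
  f_k <- vapply(f_by_class, function(v) {
    if (length(v)) sum(v) / length(v) else NA_real_
  }, numeric(1))
  if (all(is.na(f_k))) return(NA_real_)
  f_k[is.na(f_k)] <- mean(f_k, na.rm = TRUE)
  enc <- 2 + 10 / f_k[["2"]] + 6 / f_k[["4"]] + 1 / f_k[["6"]] + 1 / f_k[["8"]]
  min(enc, 61)
}

# Reverse complement, re-derived for test independence.
revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Closed-form simple OLS of y on x.
ols_oracle <- function(x, y) {
  n <- length(x)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  resid <- y - alpha - beta * x
  se <- sqrt(sum(resid^2) / (n - 2) / sum((x - mean(x))^2))
  list(slope = beta, intercept = alpha, se = se,
       r2 = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

# Central-moment summary statistics by direct accumulation.
moments_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  list(mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)),
       skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# Random small codon-count table (<= ~500 codons) over the sense codons.
random_count_table <- function(table = codon_table5()) {
  sense <- setdiff(names(table$aa), table$stop_codons)
  k <- sample(10:length(sense), 1)
  picked <- sample(sense, k)
  counts <- stats::setNames(stats::rpois(k, lambda = sample(1:8, 1)) + 1L,
                            picked)
  make_counts(counts, table)
}

# Minimal hand-written GenBank text for parser edge cases.
toy_genbank <- function(sequence, features_text, accession = "TOY_000001",
                        topology = "circular") {
  n <- nchar(sequence)
  starts <- seq(1, n, by = 60)
  origin <- vapply(starts, function(st) {
    line <- substr(tolower(sequence), st, min(st + 59, n))
    grp <- substring(line, seq(1, nchar(line), 10),
                     pmin(seq(10, nchar(line) + 9, 10), nchar(line)))
    sprintf("%9d %s", st, paste(grp, collapse = " "))
  }, character(1))
  c(sprintf("LOCUS       %s %d bp    DNA     %s INV 01-JAN-2026",
            accession, n, topology),
    paste0("ACCESSION   ", accession),
    "  ORGANISM  Testozoa minima",
    "FEATURES             Location/Qualifiers",
    features_text,
    "ORIGIN", origin, "//")
}
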