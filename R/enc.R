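#' Wright's effective number of codons (ENC)
#'
#' ENC summarizes how far a gene's codon usage departs from uniform use
#' of synonymous codons: it equals the number of amino acids (20, here
#' realized as 2 + 10 + 6 + 1 + 1 over the table-5 degeneracy layout)
#' under maximal bias and rises toward the number of sense codons when
#' all synonymous codons are used equally.
#'
#' For each amino acid `a` with `n_a >= 2` observed codons and usage
#' fractions `p_i`, the codon homozygosity is
#' `F_a = (n_a * sum(p_i^2) - 1) / (n_a - 1)`. Amino acids are pooled by
#' degeneracy class `k` (under table 5: ten 2-fold, six 4-fold, Leu as
#' the one 6-fold, Ser as the one 8-fold family), `F_k` is the mean of
#' the `F_a` in class `k`, and
#' `ENC = 2 + sum_k N_k / F_k` with `N_2 = 10, N_4 = 6, N_6 = 1,
#' N_8 = 1`; the leading 2 accounts for Met and Trp. A class with no
#' computable (positive) `F_a` is imputed as the mean of the available
#' class homozygosities. Values above 61 are clipped to 61, the ceiling
#' fixed by the ENC-ratio convention.
#'
#' @param counts a `codon_counts` object from [count_codons()].
#' @param table a [codon_table5()] object.
#' @param clip clip the result to at most 61 (default TRUE).
#' @return A list of class `enc_result`: `enc` (observed ENC), `f_hat`
#'   (named vector of class homozygosities), `n_class` (codon counts per
#'   class), `imputed` (classes whose homozygosity was imputed), `label`.
#'   `enc` is `NA` (signaled by warning) when no class homozygosity is
#'   computable.
#' @examples
#' g <- list(list(gene = "toy", species = "sp",
#'   codons = c("TTT", "TTT", "TTC", "TTC",
#'              "GGA", "GGC", "GGG", "GGT")))
#' compute_enc(count_codons(g, "per_gene")[[1]])$enc
#' @export
compute_enc <- function(counts, table = codon_table5(), clip = TRUE) {
  stopifnot(inherits(counts, "codon_counts"))
  if (sum(counts) < 1) stop("codon counts are empty")
  f_a <- numeric(0)
  for (a in setdiff(names(table$families), table$excluded_aa)) {
    cnt <- as.integer(counts[table$families[[a]]])
    n_a <- sum(cnt)
    if (n_a < 2) next # F_a divides by n_a - 1
    p <- cnt / n_a
    f_a[[a]] <- (n_a * sum(p^2) - 1) / (n_a - 1)
  }
  n_k <- c(`2` = 10, `4` = 6, `6` = 1, `8` = 1)
  f_k <- sapply(names(n_k), function(k) {
    vals <- f_a[intersect(names(f_a), table$classes[[k]])]
    vals <- vals[vals > 0]
    if (length(vals)) mean(vals) else NA_real_
  })
  imputed <- names(f_k)[is.na(f_k)]
  if (all(is.na(f_k))) {
    warning("ENC undefined: no degeneracy class has a computable homozygosity")
    enc <- NA_real_
  } else {
    f_k[is.na(f_k)] <- mean(f_k, na.rm = TRUE)
    enc <- 2 + sum(n_k / f_k)
    if (clip && enc > 61) enc <- 61
  }
  structure(list(enc = enc, f_hat = f_k, n_class = n_k, imputed = imputed,
                 label = attr(counts, "label")),
            class = "enc_result")
}

#' Expected ENC under mutation pressure alone
#'
#' The null curve of the ENC-vs-GC3s plot: the ENC a gene would have if
#' codon usage were shaped solely by the GC content at synonymous third
#' positions, `ENC_expected = 2 + GC3s + 29 / (GC3s^2 + (1 - GC3s)^2)`.
#' Genes falling well below this curve are candidates for selection on
#' codon usage.
#'
#' @param gc3s numeric vector in \[0, 1\].
#' @return Expected ENC values (31 at GC3s 0, maximum 60.5 at 0.5).
#' @examples
#' expected_enc(c(0, 0.5, 1))
#' @export
expected_enc <- function(gc3s) {
  if (any(is.na(gc3s)) || any(gc3s < 0 | gc3s > 1)) {
    stop("gc3s must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC ratio
#'
#' Normalized deviation of observed from expected ENC,
#' `(ENC_obs - ENC_exp) / (61 - ENC_exp)`. Zero means the gene sits on
#' the mutation-only curve; negative values indicate usage more biased
#' than mutation pressure alone predicts.
#'
#' @param enc_observed,enc_expected numeric vectors.
#' @return Numeric vector; `NA` with a warning where `enc_expected` is 61
#'   (the ratio is undefined there).
#' @export
enc_ratio <- function(enc_observed, enc_expected) {
  undef <- enc_expected == 61
  if (any(undef, na.rm = TRUE)) {
    warning("ENC ratio undefined where expected ENC equals 61")
  }
  ifelse(undef, NA_real_,
         (enc_observed - enc_expected) / (61 - enc_expected))
}

#' Per-gene ENC table for the ENC-GC3s plot
#'
#' Runs [compute_enc()] and [positional_composition()] over every gene
#' and assembles the plot-ready table with the expected-ENC curve value
#' and the ENC ratio.
#'
#' @param genes a `gene_set` from [extract_pcgs()].
#' @param table a [codon_table5()] object.
#' @param clip passed to [compute_enc()].
#' @return data.frame: species, gene, `enc`, `gc3s`, `enc_expected`,
#'   `enc_ratio`.
#' @export
enc_table <- function(genes, table = codon_table5(), clip = TRUE) {
  counts <- count_codons(genes, "per_gene", table)
  out <- do.call(rbind, lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    enc <- compute_enc(counts[[i]], table, clip = clip)$enc
    gc3s <- positional_composition(g, table)$gc3s
    exp_enc <- if (is.na(gc3s)) NA_real_ else expected_enc(gc3s)
    data.frame(species = g$species, gene = g$gene, enc = enc, gc3s = gc3s,
               enc_expected = exp_enc,
               enc_ratio = if (is.na(exp_enc)) NA_real_ else
                 enc_ratio(enc, exp_enc),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
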