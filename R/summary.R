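#' Descriptive statistics with distribution shape
#'
#' Mean, sample standard deviation (n - 1), coefficient of variation,
#' range, median, and the moment-based shape measures: skewness
#' `g1 = m3 / m2^(3/2)` and excess kurtosis `g2 = m4 / m2^2 - 3`, where
#' `m_k` are central moments with divisor n (no small-sample
#' adjustment).
#'
#' @param values numeric vector (NAs dropped).
#' @param label optional variable label.
#' @return One-row data.frame: `variable`, `n`, `mean`, `sd`, `cv`,
#'   `min`, `max`, `median`, `skewness`, `kurtosis`. With n < 2 the
#'   spread and shape measures are `NA`; `cv` is `NA` when the mean
#'   is 0.
#' @examples
#' summarize_values(c(1, 1, 1, 7))
#' @export
summarize_values <- function(values, label = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("no non-missing values to summarize")
  m <- mean(values)
  if (n >= 2) {
    s <- stats::sd(values)
    m2 <- mean((values - m)^2)
    skew <- if (m2 > 0) mean((values - m)^3) / m2^1.5 else NA_real_
    kurt <- if (m2 > 0) mean((values - m)^4) / m2^2 - 3 else NA_real_
  } else {
    s <- skew <- kurt <- NA_real_
  }
  data.frame(
    variable = label, n = n, mean = m, sd = s,
    cv = if (!is.na(s) && m != 0) s / m else NA_real_,
    min = min(values), max = max(values), median = stats::median(values),
    skewness = skew, kurtosis = kurt, stringsAsFactors = FALSE
  )
}

#' Assemble an RSCU matrix across species
#'
#' Aligns RSCU profiles into a units-by-codons matrix, the input for
#' codon-usage heatmaps. Columns are the codons analyzed for synonymous
#' usage (stops and the Met/Trp codons excluded), ordered by amino acid
#' and then codon. Undefined RSCU (the codon's whole family absent from
#' a unit) stays `NA`.
#'
#' @param profiles a list of `rscu_profile` objects from
#'   [compute_rscu()], or the output of [rscu_table()].
#' @param table a [codon_table5()] object.
#' @return Numeric matrix, rows named by unit label, columns by codon.
#' @export
build_rscu_matrix <- function(profiles, table = codon_table5()) {
  if (is.data.frame(profiles)) {
    profiles <- split(profiles, profiles$unit)
    labels <- names(profiles)
  } else {
    labels <- vapply(profiles, function(p) {
      lb <- attr(p, "label")
      if (is.null(lb)) NA_character_ else lb
    }, character(1))
  }
  if (length(profiles) < 1) stop("no profiles")
  if (anyDuplicated(labels)) {
    stop("duplicate row labels: ", paste(unique(labels[duplicated(labels)]),
                                         collapse = ", "))
  }
  aa <- table$aa[table$syn_codons]
  cols <- table$syn_codons[order(aa, table$syn_codons)]
  mat <- t(vapply(profiles, function(p) {
    v <- p$rscu
    names(v) <- p$codon
    unname(v[cols])
  }, numeric(length(cols))))
  dimnames(mat) <- list(labels, cols)
  mat
}

#' Hierarchical clustering of a codon-usage matrix
#'
#' Agglomerative clustering with Euclidean distance and complete
#' linkage, the scheme used to order heatmap rows. Rows may be species
#' (default) or, with `rows = "codons"`, the transposed matrix to
#' cluster codons instead. Missing cells are imputed as 0 for the
#' distance computation only (with a warning); a single-row matrix
#' yields a trivial single-leaf tree.
#'
#' @param matrix numeric matrix from [build_rscu_matrix()].
#' @param rows cluster the matrix rows as given (`"units"`) or cluster
#'   codons (`"codons"`, transposes first).
#' @return An object of class `hclust` (see [stats::hclust()]), or for
#'   a single row a list of class `single_leaf` with the label. Convert
#'   to Newick with [cluster_newick()].
#' @export
cluster_codon_matrix <- function(matrix, rows = c("units", "codons")) {
  rows <- match.arg(rows)
  if (rows == "codons") matrix <- t(matrix)
  if (anyNA(matrix)) {
    warning("imputing ", sum(is.na(matrix)), " missing cell(s) as 0 for ",
            "clustering")
    matrix[is.na(matrix)] <- 0
  }
  if (nrow(matrix) == 1) {
    return(structure(list(label = rownames(matrix)), class = "single_leaf"))
  }
  matrix <- matrix[order(rownames(matrix)), , drop = FALSE] # tie-break order
  stats::hclust(stats::dist(matrix, method = "euclidean"),
                method = "complete")
}

#' Newick text for a clustering tree
#'
#' @param tree an `hclust` from [cluster_codon_matrix()] (or its
#'   `single_leaf` result).
#' @return A Newick string (with branch lengths from merge heights),
#'   suitable for recording heatmap row order.
#' @export
cluster_newick <- function(tree) {
  if (inherits(tree, "single_leaf")) return(paste0("(", tree$label, ");"))
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy)
}

#' Cross-variable summary table
#'
#' [summarize_values()] applied to the main per-gene diagnostics (ENC,
#' GC3s, GC12, GC3) and, optionally, to each codon's RSCU across units.
#'
#' @param enc data.frame from [enc_table()].
#' @param composition data.frame from [composition_table()].
#' @param rscu optional data.frame from [rscu_table()]; adds one row per
#'   codon summarizing RSCU across units.
#' @return data.frame of stacked [summarize_values()] rows.
#' @export
summary_table <- function(enc, composition, rscu = NULL) {
  out <- rbind(
    summarize_values(enc$enc, "ENC"),
    summarize_values(enc$gc3s, "GC3s"),
    summarize_values(composition$gc12, "GC12"),
    summarize_values(composition$gc3, "GC3")
  )
  if (!is.null(rscu)) {
    per_codon <- do.call(rbind, lapply(split(rscu, rscu$codon), function(d) {
      vals <- d$rscu[!is.na(d$rscu)]
      if (length(vals) == 0) return(NULL)
      summarize_values(vals, paste0("RSCU_", d$codon[1]))
    }))
    out <- rbind(out, per_codon)
  }
  rownames(out) <- NULL
  out
}
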