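#' Neutrality regression of GC12 on GC3
#'
#' Fits the neutrality plot for one species: ordinary least squares of
#' GC12 (mean GC at codon positions 1 and 2, dominated by amino-acid
#' constraint) on GC3 (position 3, largely synonymous) across its
#' protein-coding genes. Under pure mutation pressure both respond
#' equally and the slope approaches 1; selection on the protein
#' decouples them and pulls the slope toward 0. The verdict compares
#' the 95% slope confidence interval (t distribution, n - 2 df)
#' against 1: intervals containing 1 are `neutral-compatible`,
#' entirely below 1 `selection-constrained`, entirely above 1
#' `positive/relaxed`.
#'
#' @param gc3,gc12 numeric vectors of per-gene GC3 and GC12 fractions
#'   (same length, at least 3 points).
#' @param species label carried into the result.
#' @return One-row data.frame of class `neutrality_fit`: `species`,
#'   `n_genes`, `slope`, `intercept`, `r_squared`, `p_value` (two-sided
#'   t test of slope = 0), `ci_low`, `ci_high`, `pearson_r`, `verdict`.
#' @examples
#' fit_neutrality(c(0.2, 0.3, 0.4, 0.5), c(0.25, 0.30, 0.36, 0.40))
#' @export
fit_neutrality <- function(gc3, gc12, species = NA_character_) {
  stopifnot(length(gc3) == length(gc12))
  keep <- stats::complete.cases(gc3, gc12)
  gc3 <- gc3[keep]; gc12 <- gc12[keep]
  if (length(gc3) < 3) stop("neutrality fit needs at least 3 genes")
  if (stats::var(gc3) == 0) {
    stop("degenerate fit: GC3 has zero variance across genes")
  }
  fit <- stats::lm(gc12 ~ gc3)
  sm <- summary(fit)
  ci <- stats::confint(fit, "gc3", level = 0.95)
  slope <- unname(stats::coef(fit)["gc3"])
  verdict <- if (ci[1] <= 1 && ci[2] >= 1) {
    "neutral-compatible"
  } else if (ci[2] < 1) "selection-constrained" else "positive/relaxed"
  out <- data.frame(
    species = species, n_genes = length(gc3), slope = slope,
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients["gc3", "Pr(>|t|)"],
    ci_low = ci[1], ci_high = ci[2],
    pearson_r = stats::cor(gc3, gc12),
    verdict = verdict, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("neutrality_fit", "data.frame")
  out
}

#' Per-species neutrality fits from a composition table
#'
#' @param composition data.frame from [composition_table()] (columns
#'   `species`, `gc3`, `gc12`).
#' @return data.frame with one [fit_neutrality()] row per species.
#' @export
neutrality_table <- function(composition) {
  out <- do.call(rbind, lapply(split(composition, composition$species),
                               function(d) {
    fit_neutrality(d$gc3, d$gc12, species = d$species[1])
  }))
  rownames(out) <- NULL
  out
}

#' Parity rule 2 (PR2) coordinates
#'
#' Within-strand parity rule 2 predicts A = T and G = C at sites free of
#' selection; the PR2 plot places each gene at
#' (G3/(G3 + C3), A3/(A3 + T3)) computed from third-position bases, with
#' (0.5, 0.5) the parity point. By default only third positions of
#' fourfold-degenerate families (Val, Pro, Thr, Ala, Gly, Arg) are
#' used, where the third base carries no amino-acid information; set
#' `sites = "synonymous"` to use all synonymous third positions as a
#' sensitivity analysis.
#'
#' @param composition data.frame from [composition_table()] or a single
#'   row from [positional_composition()].
#' @param sites `"fourfold"` (default) or `"synonymous"`.
#' @return The input with columns `a3_ratio` (A3/(A3+T3)), `g3_ratio`
#'   (G3/(G3+C3)) and `pr2_n` (third-position sites used) appended.
#'   Ratios with a zero denominator are `NA` (flagged by warning) and
#'   should be excluded from species means.
#' @examples
#' comp <- positional_composition(c("GCA", "GCA", "GCA", "GCT", "GCG", "GCC"))
#' pr2_coordinates(comp)[, c("a3_ratio", "g3_ratio")]
#' @export
pr2_coordinates <- function(composition, sites = c("fourfold", "synonymous")) {
  sites <- match.arg(sites)
  cols <- if (sites == "fourfold") c("a3f", "t3f", "g3f", "c3f") else
    c("a3s", "t3s", "g3s", "c3s")
  a <- composition[[cols[1]]]; t <- composition[[cols[2]]]
  g <- composition[[cols[3]]]; c <- composition[[cols[4]]]
  if (any(a + t == 0 | g + c == 0)) {
    warning("PR2 coordinate undefined for ", sum(a + t == 0 | g + c == 0),
            " gene(s) with no usable third-position sites")
  }
  composition$a3_ratio <- ifelse(a + t > 0, a / (a + t), NA_real_)
  composition$g3_ratio <- ifelse(g + c > 0, g / (g + c), NA_real_)
  composition$pr2_n <- a + t + g + c
  composition
}
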