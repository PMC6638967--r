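# Analytic power for the sibship linkage design: non-central F-test with a
# noncentrality parameter driven by allele frequency, effect size and
# residual familial correlation.

#' Pointwise significance level of a LOD threshold
#'
#' One-sided convention: `alpha = 0.5 * P(chisq_1 > 2 ln(10) * lod)`.
#' Inverse of [p_to_lod()]; LOD 0 maps to 0.5 and LOD 3.6 to ~2e-5.
#'
#' @param lod LOD score(s) >= 0.
#' @return significance level(s) in `(0, 0.5]`.
#' @export
lod_alpha <- function(lod) {
  if (any(lod < 0)) stop("lod must be non-negative")
  0.5 * stats::pchisq(2 * log(10) * lod, df = 1, lower.tail = FALSE)
}

#' Analytic power of the sibship contrast-test linkage design
#'
#' Non-centrality parameter
#' `lambda = f n (MAF - MAF^2) beta^2 / (1 - 0.5 (h2 - 2 (MAF - MAF^2) beta^2))`
#' for `f` families of `n` siblings, a biallelic QTL of frequency `MAF` and
#' additive effect `beta` (phenotype SDs per allele) against a polygenic
#' background of heritability `h2`.  Power is the upper tail of the
#' noncentral `F(df1, df2, lambda)` distribution at the central-F critical
#' value for significance level `alpha`, with `df1 = 2 f` and
#' `df2 = f n - 3`.  At `beta = 0` power equals `alpha` exactly.
#'
#' @param f number of families.
#' @param n siblings per family.
#' @param maf minor allele frequency in (0, 0.5].
#' @param beta effect size in phenotype SD per allele.
#' @param h2 heritability in `[0, 1)`.
#' @param lod_threshold LOD detection threshold; converted to `alpha` via
#'   [lod_alpha()] unless `alpha` is given directly.
#' @param alpha significance level overriding `lod_threshold`.
#' @return power in `[alpha, 1]`, with the design parameters as attributes.
#' @export
linkage_power <- function(f, n, maf, beta, h2 = 0.8, lod_threshold = 3.6,
                          alpha = NULL) {
  stopifnot(f >= 1, n >= 1, maf > 0, maf <= 0.5, h2 >= 0, h2 < 1)
  if (f * n - 3 <= 0) stop("df2 = f*n - 3 must be positive")
  if (is.null(alpha)) alpha <- lod_alpha(lod_threshold)
  v <- maf - maf^2
  denom <- 1 - 0.5 * (h2 - 2 * v * beta^2)
  if (denom <= 0) stop("pathological beta/h2 combination: denominator <= 0")
  lambda <- f * n * v * beta^2 / denom
  df1 <- 2 * f; df2 <- f * n - 3
  crit <- stats::qf(1 - alpha, df1, df2)
  pw <- stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
  structure(pw, lambda = lambda, df1 = df1, df2 = df2, alpha = alpha)
}
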