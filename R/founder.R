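# Founder haplotype pool: the population the synthetic cohort's parents are
# drawn from.  A finite pool emulates the small effective population size of a
# founder population: globally rare alleles can be common in the pool, and
# unrelated parents share background haplotypes.

#' Simulate a founder haplotype pool
#'
#' Draws a pool of phased haplotypes over the SNPs of a map.  Most SNP
#' frequencies follow `freq_spectrum`; `n_elevated` SNPs are marked
#' "founder-elevated": rare in a large cosmopolitan reference
#' (frequency < `rare_cut`) but common in the pool (>= `common_cut`), the
#' signature of genetic drift after a founder event.  Elevated (and
#' explicitly forced) SNPs get exact allele counts so the flag invariant holds
#' by construction; all other SNPs are binomial draws from their target
#' frequency.
#'
#' @param snps SNP map from [place_snps()].
#' @param n_haplotypes pool size (>= 4).
#' @param freq_spectrum function `n -> n` frequencies in (0, 1); default
#'   uniform on (0.05, 0.5).
#' @param n_elevated number of founder-elevated SNPs.
#' @param seed integer seed; mandatory, reproducibility is part of the
#'   contract.
#' @param forced_freq optional numeric vector (length = number of SNPs, NA =
#'   unforced) of pool frequencies realized as exact counts.
#' @param rare_cut,common_cut frequency cutoffs defining "rare in the
#'   reference" and "common in the pool".
#' @return list of class `founder_pool`: `haplotypes` (0/1 matrix, haplotype
#'   x SNP), `pool_freq`, `cosmopolitan_freq`, `elevated` (logical), `snps`.
#' @export
simulate_founder_pool <- function(snps, n_haplotypes,
                                  freq_spectrum = function(n) stats::runif(n, 0.05, 0.5),
                                  n_elevated = 0, seed, forced_freq = NULL,
                                  rare_cut = 0.01, common_cut = 0.05) {
  if (missing(seed)) stop("'seed' is required: founder pools must be reproducible")
  m <- nrow(snps)
  if (n_haplotypes < 4) stop("n_haplotypes must be >= 4 (two diploid founders)")
  if (n_elevated < 0 || m < 1) stop("counts must be non-negative")
  if (n_elevated > m) stop("n_elevated exceeds the number of SNPs")
  set.seed(seed)

  target <- freq_spectrum(m)
  stopifnot(length(target) == m, all(target > 0 & target < 1))
  cosmo <- target
  elevated <- rep(FALSE, m)
  if (n_elevated > 0) {
    idx <- sample.int(m, n_elevated)
    elevated[idx] <- TRUE
    cosmo[idx] <- stats::runif(n_elevated, 0, rare_cut * 0.99)
    target[idx] <- stats::runif(n_elevated, common_cut, 0.3)
  }
  exact <- if (is.null(forced_freq)) rep(NA_real_, m) else forced_freq
  exact[elevated] <- pmax(target[elevated], ceiling(common_cut * n_haplotypes) / n_haplotypes)

  hap <- matrix(0L, nrow = n_haplotypes, ncol = m,
                dimnames = list(NULL, snps$snp))
  is_exact <- !is.na(exact)
  if (any(!is_exact)) {
    hap[, !is_exact] <- matrix(
      stats::rbinom(n_haplotypes * sum(!is_exact), 1L,
                    rep(target[!is_exact], each = n_haplotypes)),
      nrow = n_haplotypes
    )
  }
  for (j in which(is_exact)) {
    k <- round(exact[j] * n_haplotypes)
    k <- min(max(k, 0L), n_haplotypes)
    hap[sample.int(n_haplotypes, k), j] <- 1L
  }
  pool_freq <- colMeans(hap)
  structure(
    list(haplotypes = hap, pool_freq = pool_freq, cosmopolitan_freq = cosmo,
         elevated = elevated, snps = snps,
         rare_cut = rare_cut, common_cut = common_cut),
    class = "founder_pool"
  )
}

#' Founder-population allele frequency contrast
#'
#' Counts SNPs that are rare (< `rare_cut`) in population A yet common
#' (>= `common_cut`) in population B, and contrasts that count with a
#' sampling-noise control in which B is replaced by a binomial subsample of
#' A's frequencies at B's sample size.  A large observed count with a control
#' count near zero is the frequency signature of a founder event rather than
#' of small-sample noise.
#'
#' @param freq_a,freq_b per-SNP allele frequencies in populations A and B.
#' @param n_a,n_b diploid sample sizes behind the two frequency tables.
#' @param rare_cut,common_cut cutoffs in (0, 1).
#' @param seed integer seed for the subsampling control.
#' @param n_control number of control subsamples to draw.
#' @return list: `observed` count, `control` (integer vector, length
#'   `n_control`), `n_rare_a`, and the cutoffs.
#' @export
founder_frequency_contrast <- function(freq_a, freq_b, n_a, n_b,
                                       rare_cut = 0.01, common_cut = 0.05,
                                       seed, n_control = 1) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(length(freq_a) == length(freq_b),
            all(freq_a >= 0 & freq_a <= 1), all(freq_b >= 0 & freq_b <= 1))
  if (rare_cut <= 0 || rare_cut >= 1 || common_cut <= 0 || common_cut >= 1) {
    stop("cutoffs must lie in (0, 1)")
  }
  set.seed(seed)
  rare_a <- freq_a < rare_cut
  observed <- sum(rare_a & freq_b >= common_cut)
  m <- length(freq_a)
  control <- integer(n_control)
  for (r in seq_len(n_control)) {
    sub <- stats::rbinom(m, 2L * n_b, freq_a) / (2 * n_b)
    control[r] <- sum(rare_a & sub >= common_cut)
  }
  list(observed = observed, control = control, n_rare_a = sum(rare_a),
       rare_cut = rare_cut, common_cut = common_cut, n_b = n_b)
}
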