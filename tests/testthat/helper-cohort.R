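# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code under fixed seeds; no data files.

# small synthetic cohort: genotypes + truth + (optionally) phenotypes
tiny_cohort <- function(n_families = 4, sibs = c(10, 12), mean_sibs = 11,
                        total_bp = 6e7, total_morgans = 6, n_chrom = 4,
                        n_snps = 6000, n_hap = 200, n_elevated = 0,
                        seed = 1, noise = FALSE) {
  map <- scaled_genome(total_bp, total_morgans, n_chrom)
  snps <- place_snps(map, n_snps)
  pool <- simulate_founder_pool(snps, n_hap, n_elevated = n_elevated,
                                seed = seed)
  ped <- make_cohort_pedigree(n_families, sibs, mean_sibs, seed = seed + 1)
  fam <- simulate_families(ped, pool, map, seed = seed + 2)
  geno <- if (noise) {
    apply_genotyping_noise(fam$geno, noise_model(), seed = seed + 3)
  } else fam$geno
  list(map = map, snps = snps, pool = pool, ped = ped,
       geno = geno, geno_clean = fam$geno, truth = fam$truth)
}

# exact per-SNP IBD state of a pair, looked up from a called track
state_at <- function(track, chrom, pos) {
  t <- track[track$chrom == chrom, ]
  t$state[findInterval(pos, t$start)]
}

# brute force: minimal number of corrected pair states over *all* pairs of
# bipartitions (full double enumeration; feasible for small sibships only)
oracle_min_corrections <- function(M) {
  s_n <- nrow(M)
  pr <- which(upper.tri(M), arr.ind = TRUE)
  pi <- pr[, 1]; pj <- pr[, 2]
  mvec <- M[upper.tri(M)]
  best <- Inf
  for (g in 0:(2^(s_n - 1) - 1)) {
    bm <- c(0L, as.integer(intToBits(g))[seq_len(s_n - 1)])
    for (h in 0:(2^(s_n - 1) - 1)) {
      bp <- c(0L, as.integer(intToBits(h))[seq_len(s_n - 1)])
      cost <- sum(((bm[pi] == bm[pj]) + (bp[pi] == bp[pj])) != mvec)
      if (cost < best) best <- cost
    }
  }
  best
}

# pairwise-state matrix implied by two bipartitions
config_matrix <- function(bm, bp) {
  M <- outer(bm, bm, "==") + outer(bp, bp, "==")
  diag(M) <- 2L
  M
}

# Haseman-Elston style regression oracle for a single relatedness component:
# regress cross products of centered phenotypes on relatedness
he_regression_h2 <- function(y, A) {
  yc <- y - mean(y)
  cp <- tcrossprod(yc)
  ut <- upper.tri(A)
  fit <- stats::lm(cp[ut] ~ A[ut])
  unname(stats::coef(fit)[2] / stats::var(y))
}

# truth genome-sharing fractions of one family (SNP-weighted)
truth_sharing <- function(cohort, fid) {
  sibs <- family_sibs(cohort$ped, fid)
  acc <- c(0, 0, 0)
  for (a in seq_len(length(sibs) - 1)) {
    for (b in (a + 1):length(sibs)) {
      t12 <- truth_pair_ibd(cohort$truth, fid, sibs[a], sibs[b])
      acc <- acc + tabulate(t12 + 1, 3)
    }
  }
  acc / sum(acc)
}

# corrected z-scores for a cohort under a given phenotype model
cohort_heights <- function(cohort, model = phenotype_model(), seed = 99) {
  ph <- simulate_phenotypes(cohort$ped, cohort$geno_clean, model, seed = seed,
                            freqs = cohort$pool$pool_freq)
  corr <- correct_heights(ph)
  stats::setNames(corr$z, corr$iid)
}

# inheritance vectors straight from simulation truth, for every family
truth_vectors_list <- function(cohort) {
  lapply(stats::setNames(nm = family_ids(cohort$ped)), function(f) {
    truth_inheritance_vectors(cohort$truth, f, cohort$map, cohort$snps)
  })
}
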