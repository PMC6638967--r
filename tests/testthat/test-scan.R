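# Permutation contrast-test linkage scan, LOD conversion, QTL calling,
# separation distance and the FDR threshold sweep.

test_that("contrast R-squared equals the ANOVA decomposition", {
  # SSB = 4, SST = 5 -> R2 = 0.8
  expect_equal(contrast_r2(c(1, 2, 3, 4), c(0, 0, 1, 1)), 0.8)
  # equal group means
  expect_equal(contrast_r2(c(1, 3, 1, 3), c(0, 0, 1, 1)), 0)
  # perfectly separated, zero within-group variance
  expect_equal(contrast_r2(c(5, 5, 9, 9), c("a", "a", "b", "b")), 1)
  # one group empty
  expect_true(is.na(contrast_r2(c(1, 2, 3), c(1, 1, 1))))
})

test_that("LOD and pointwise significance are a one-sided chi-square pair", {
  expect_equal(p_to_lod(0.5), 0)
  expect_equal(p_to_lod(1), 0)
  # p ~ 0.016 -> LOD ~ 1 (chi-square quantile 4.605 over 2 ln 10)
  expect_equal(p_to_lod(0.016), qchisq(0.032, 1, lower.tail = FALSE) / (2 * log(10)))
  expect_lt(abs(p_to_lod(0.016) - 1), 0.01)
  # the classical genome-wide threshold: LOD 3.6 <-> p ~ 2e-5
  expect_lt(abs(lod_alpha(3.6) / 2e-5 - 1), 0.2)
  expect_equal(lod_alpha(0), 0.5)
  # inverse pair on (0, 0.5)
  for (p in c(1e-6, 1e-4, 0.01, 0.2, 0.49)) {
    expect_equal(lod_alpha(p_to_lod(p)), p, tolerance = 1e-9)
  }
  expect_error(p_to_lod(1.5), "0, 1")
  expect_error(lod_alpha(-1), "non-negative")
})

test_that("family scans calibrate local P by within-family permutations", {
  co <- tiny_cohort(n_families = 2, n_snps = 1500, seed = 81)
  vl <- truth_vectors_list(co)
  grid <- scan_grid(co$map, 1e5)

  # constant heights: R2 undefined -> all local P 1
  h_const <- stats::setNames(rep(1.7, 12), family_sibs(co$ped, "F01"))
  fs <- family_scan(vl[["F01"]], h_const[vl[["F01"]]$sibs], grid, n_perm = 50,
                    seed = 1)
  expect_true(all(fs$local_p == 1))

  # under the null the rank of the real contrast R2 among permuted R2s is
  # exchangeable: the per-parent local P is (discretely) uniform
  set.seed(2)
  G <- rep(c(0, 1), each = 6)
  reals <- vapply(1:300, function(r) {
    h <- rnorm(12)
    r2 <- contrast_r2(h, G)
    perm <- vapply(1:60, function(j) contrast_r2(sample(h), G), numeric(1))
    mean(perm >= r2)
  }, numeric(1))
  expect_lt(suppressWarnings(stats::ks.test(reals, "punif")$statistic),
            1.63 / sqrt(300) + 1 / 60)   # alpha = 0.01 + discreteness slack

  # fewer than 4 phenotyped siblings: skipped with a warning
  h_small <- stats::setNames(rnorm(length(vl[["F01"]]$sibs)), vl[["F01"]]$sibs)
  h_small[-(1:3)] <- NA
  expect_warning(out <- family_scan(vl[["F01"]], h_small, grid, 10, seed = 1),
                 "fewer than 4")
  expect_null(out)
})

test_that("combining families calibrates genome-wide P and LOD", {
  co <- tiny_cohort(n_families = 4, n_snps = 2000, seed = 83)
  vl <- truth_vectors_list(co)
  h <- cohort_heights(co, phenotype_model(h2_total = 0.3), seed = 5)
  scan <- cohort_scan(vl, h, co$map, grid_step = 1e5, n_perm = 100, seed = 7)

  expect_true(all(scan$gw_p >= 0 & scan$gw_p <= 1))
  expect_true(all(scan$lod >= 0))
  # a score at the permutation median maps to gw P ~ 0.5 and LOD ~ 0
  med <- stats::median(scan$perm_score)
  i_med <- which.min(abs(scan$score - med))
  expect_gt(scan$gw_p[i_med], 0.25)
  expect_lt(scan$lod[i_med], 0.05)
  # determinism
  scan2 <- cohort_scan(vl, h, co$map, grid_step = 1e5, n_perm = 100, seed = 7)
  expect_identical(scan$lod, scan2$lod)
})

test_that("a planted QTL is localized by the scan", {
  hits <- 0
  for (s in 1:5) {
    co <- tiny_cohort(n_families = 10, sibs = c(10, 14), mean_sibs = 12,
                      n_snps = 2000, n_elevated = 20, seed = 200 + 13 * s)
    csnp <- co$snps$snp[co$pool$elevated][which.max(co$pool$pool_freq[co$pool$elevated])]
    mod <- phenotype_model(h2_total = 0.86,
                           causal = data.frame(snp = csnp, beta = 0.85))
    h <- cohort_heights(co, mod, seed = 300 + s)
    vl <- truth_vectors_list(co)
    scan <- cohort_scan(vl, h, co$map, grid_step = 1e5, n_perm = 150,
                        seed = 400 + s)
    true_chrom <- co$snps$chrom[co$snps$snp == csnp]
    true_pos <- co$snps$pos[co$snps$snp == csnp]
    peak <- which.max(scan$lod)
    if (scan$grid$chrom[peak] == true_chrom &&
        abs(scan$grid$pos[peak] - true_pos) < 4e6) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 4)
})

test_that("QTL calling merges nearby peaks and draws 1-LOD intervals", {
  # constructed LOD track on two chromosomes
  grid <- data.frame(chrom = rep(1:2, each = 100),
                     pos = rep(seq(1e6, 100e6, by = 1e6), 2))
  lod <- numeric(200)
  # two peaks 10 Mb apart (same QTL), interval by 1-LOD drop
  lod[grid$chrom == 1] <- pmax(4 - abs(seq(-49, 50)) * 0.1, 0)     # peak at 50e6
  lod[grid$chrom == 1][60] <- 3.4                                   # shoulder peak
  q1 <- call_qtls(list(grid = grid, lod = lod), threshold = 3, merge_distance = 33e6)
  expect_identical(nrow(q1), 1L)
  expect_equal(q1$peak_pos, 50e6)
  expect_equal(q1$peak_lod, 4)
  # monotone decay: endpoints at the furthest grid points above peak - 1
  expect_equal(q1$start, 41e6)
  expect_equal(q1$end, 60e6)

  # two peaks 50 Mb apart are two QTLs
  lod2 <- numeric(200)
  lod2[grid$chrom == 2] <- pmax(4 - abs(seq(-24, 75)) * 0.5, 0) +
    pmax(4 - abs(seq(-74, 25)) * 0.5, 0)
  q2 <- call_qtls(list(grid = grid, lod = lod2), threshold = 3, merge_distance = 33e6)
  expect_identical(nrow(q2), 2L)

  # nothing above threshold: empty table
  q0 <- call_qtls(list(grid = grid, lod = rep(0.1, 200)), threshold = 3,
                  merge_distance = 33e6)
  expect_identical(nrow(q0), 0L)
})

test_that("separation distance tracks the LOD autocorrelation length", {
  grid <- data.frame(chrom = rep(1:4, each = 200),
                     pos = rep(seq(5e5, 1e8, by = 5e5), 4))
  # white noise: decorrelates within about one grid step
  set.seed(9)
  lodw <- abs(rnorm(800))
  sw <- estimate_qtl_separation(list(grid = grid, lod = lodw), bin_width = 1e6)
  expect_lte(sw$distance, 3e6)

  # smoothed track with a known correlation length
  L <- 20  # grid steps of 5e5 -> 10 Mb
  sm <- stats::filter(rnorm(900), rep(1 / L, L), sides = 1)
  lods <- abs(as.numeric(sm)[!is.na(sm)])[1:800]
  ss <- estimate_qtl_separation(list(grid = grid, lod = lods), bin_width = 1e6)
  expect_gt(ss$distance, L * 5e5 / 3)
  expect_lt(ss$distance, L * 5e5 * 3)

  # identical LOD everywhere: flat curve, maximum distance with a warning
  expect_warning(
    sf <- estimate_qtl_separation(list(grid = grid, lod = rep(2, 800)),
                                  bin_width = 1e6),
    "flat")
  expect_equal(sf$distance, max(sf$curve$dist))
})

test_that("the FDR sweep reproduces the count arithmetic and monotonicity", {
  co <- tiny_cohort(n_families = 6, sibs = c(10, 12), mean_sibs = 11,
                    n_snps = 2000, n_elevated = 20, seed = 91)
  csnp <- co$snps$snp[co$pool$elevated][which.max(co$pool$pool_freq[co$pool$elevated])]
  mod <- phenotype_model(h2_total = 0.86,
                         causal = data.frame(snp = csnp, beta = 0.8))
  h <- cohort_heights(co, mod, seed = 11)
  vl <- truth_vectors_list(co)
  scan <- cohort_scan(vl, h, co$map, grid_step = 1e5, n_perm = 120, seed = 13)
  md <- 33e6 * sum(co$map$length) / 2.88e9
  fdr <- fdr_sweep(scan, seq(3.6, 1.0, by = -0.1), md)

  # counts can only grow as the threshold drops
  expect_true(all(diff(fdr$observed) >= 0))
  expect_true(all(diff(fdr$expected) >= -1e-12))
  # the definitions hold at every step
  pos <- fdr$observed > 0
  expect_equal(fdr$fdr[pos],
               pmin(fdr$expected[pos] / fdr$observed[pos], 1))
  expect_true(all(is.na(fdr$fdr[!pos])))
  expect_equal(fdr$estimated_true, fdr$observed - fdr$expected)
  expect_true(all(fdr$p_value >= 0 & fdr$p_value <= 1))

  # constructed track: 2 observed QTLs with 11/100 permutations carrying one
  # chance QTL -> expected 0.11, FDR 5.5%, 1.89 estimated true
  grid2 <- data.frame(chrom = 1, pos = seq(1e6, 500e6, by = 1e6))
  lod_real <- numeric(500); lod_real[c(100, 400)] <- 4
  perm_lod <- matrix(0, 100, 500)
  perm_lod[1:11, 250] <- 4
  fake <- list(grid = grid2, lod = lod_real, perm_lod = perm_lod, n_perm = 100)
  f2 <- fdr_sweep(fake, thresholds = 3.6, merge_distance = 33e6)
  expect_equal(f2$observed, 2)
  expect_equal(f2$expected, 0.11)
  expect_equal(f2$fdr, 0.055)
  expect_equal(f2$estimated_true, 1.89)
  expect_equal(f2$p_value, 0)
})
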