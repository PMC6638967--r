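# The cohort generator: founder pool, Mendelian transmission with
# recombination, phenotype model and genotyping noise.

test_that("founder pool frequencies behave as specified", {
  map <- genetic_map(n_chrom = 1, lengths = 1e7)
  snps <- place_snps(map, 1000)

  # no elevated SNPs requested -> none flagged
  p0 <- simulate_founder_pool(snps, 50, n_elevated = 0, seed = 1)
  expect_false(any(p0$elevated))

  # forced frequency is realized as an exact allele count
  forced <- rep(NA_real_, nrow(snps)); forced[1] <- 0.5
  p1 <- simulate_founder_pool(snps, 4, n_elevated = 0, seed = 2,
                              forced_freq = forced)
  expect_identical(sum(p1$haplotypes[, 1]), 2L)

  # binomial sampling: realized frequencies within 3 SE of the uniform draw
  n_hap <- 200
  p2 <- simulate_founder_pool(snps, n_hap, n_elevated = 0, seed = 3)
  se <- sqrt(p2$pool_freq * (1 - p2$pool_freq) / n_hap)
  # compare realized to itself is circular; redraw targets with same seed
  set.seed(3)
  target <- runif(nrow(snps), 0.05, 0.5)
  dev <- abs(p2$pool_freq - target) / sqrt(target * (1 - target) / n_hap)
  expect_lt(mean(dev > 3), 0.01)

  # elevated SNPs satisfy the frequency contrast by construction
  p3 <- simulate_founder_pool(snps, 100, n_elevated = 25, seed = 4)
  expect_identical(sum(p3$elevated), 25L)
  expect_true(all(p3$pool_freq[p3$elevated] >= 0.05))
  expect_true(all(p3$cosmopolitan_freq[p3$elevated] < 0.01))

  expect_error(simulate_founder_pool(snps, 2, seed = 1), "n_haplotypes")
  expect_error(simulate_founder_pool(snps, 10, n_elevated = 2000, seed = 1),
               "n_elevated")
  expect_error(simulate_founder_pool(snps, 10), "seed")
})

test_that("gametes obey Mendelian transmission and the genetic map", {
  # zero recombination rate: grandparental labels constant per chromosome
  map0 <- genetic_map(n_chrom = 2, lengths = c(2e7, 1e7), cm_per_mb = 0)
  snps0 <- place_snps(map0, 200)
  pool0 <- simulate_founder_pool(snps0, 20, n_elevated = 0, seed = 1)
  ped0 <- make_cohort_pedigree(1, c(6, 6), 6, seed = 2)
  fam0 <- simulate_families(ped0, pool0, map0, seed = 3)
  expect_identical(nrow(fam0$truth$crossovers), 0L)
  lab <- fam0$truth$families[["F01"]]$mat
  for (c in 1:2) {
    sel <- snps0$chrom == c
    expect_true(all(apply(lab[, sel], 1, function(x) all(x == x[1]))))
  }

  # conservation: child dosage = maternal + paternal transmitted allele
  co <- tiny_cohort(n_families = 2, n_snps = 2000, seed = 5)
  fid <- "F01"
  fam <- co$truth$families[[fid]]
  mo <- paste0(fid, "_mo"); fa <- paste0(fid, "_fa")
  mh <- co$pool$haplotypes[co$truth$parent_haps[[mo]], ]
  fh <- co$pool$haplotypes[co$truth$parent_haps[[fa]], ]
  for (s in fam$sibs[1:3]) {
    expected <- mh[cbind(fam$mat[s, ], seq_len(ncol(mh)))] +
      fh[cbind(fam$pat[s, ] - 2L, seq_len(ncol(fh)))]
    expect_identical(unname(co$geno$dosage[s, ]), unname(expected))
  }

  # Aa x aa cross: child dosage in {0,1}, each ~50%
  map1 <- genetic_map(n_chrom = 1, lengths = 1e6)
  snps1 <- place_snps(map1, 3)
  pool1 <- simulate_founder_pool(snps1, 4, n_elevated = 0, seed = 1,
                                 forced_freq = c(NA, NA, NA))
  pool1$haplotypes[] <- 0L
  pool1$haplotypes[1, 2] <- 1L       # one carrier haplotype at snp 2
  ped1 <- make_cohort_pedigree(500, c(2, 2), 2, seed = 7)
  parents <- ped1$iid[ped1$role == "parent"]
  ph <- lapply(stats::setNames(nm = parents), function(p) {
    if (grepl("_mo$", p)) c(1L, 2L) else c(3L, 4L)   # mother Aa, father aa
  })
  fam1 <- simulate_families(ped1, pool1, map1, seed = 8, parent_haps = ph)
  sib_dos <- fam1$geno$dosage[grep("_s", rownames(fam1$geno$dosage)), 2]
  expect_true(all(sib_dos %in% 0:1))
  expect_lt(abs(mean(sib_dos) - 0.5), 3 * sqrt(0.25 / length(sib_dos)))

  # crossover counts are Poisson with mean = genetic length in Morgans
  mapM <- genetic_map(n_chrom = 1, lengths = 5e7, cm_per_mb = 3)  # 1.5 M
  snpsM <- place_snps(mapM, 50)
  poolM <- simulate_founder_pool(snpsM, 20, n_elevated = 0, seed = 1)
  pedM <- make_cohort_pedigree(250, c(2, 2), 2, seed = 2)
  famM <- simulate_families(pedM, poolM, mapM, seed = 3)
  n_gametes <- 250 * 2 * 2
  rate <- nrow(famM$truth$crossovers) / n_gametes
  expect_lt(abs(rate - 1.5), 3 * sqrt(1.5 / n_gametes))
})

test_that("expected sib sharing approaches 25/50/25 on a long genome", {
  co <- tiny_cohort(n_families = 6, total_morgans = 12, n_snps = 4000,
                    seed = 11)
  acc <- rowMeans(vapply(family_ids(co$ped), function(f) truth_sharing(co, f),
                         numeric(3)))
  expect_lt(abs(acc[1] - 0.25), 0.02)
  expect_lt(abs(acc[2] - 0.50), 0.02)
  expect_lt(abs(acc[3] - 0.25), 0.02)
})

test_that("phenotype model realizes its variance structure", {
  # null model: pure sex-mean + residual, siblings uncorrelated
  map <- genetic_map(n_chrom = 1, lengths = 1e7)
  snps <- place_snps(map, 300)
  pool <- simulate_founder_pool(snps, 400, n_elevated = 0, seed = 1)
  ped <- make_cohort_pedigree(400, c(2, 2), 2, sib_ages = c(25L, 30L), seed = 2)
  fam <- simulate_families(ped, pool, map, seed = 3)
  m0 <- phenotype_model(h2_total = 0)
  ph0 <- simulate_phenotypes(ped, fam$geno, m0, seed = 4,
                             freqs = pool$pool_freq)
  lat <- attr(ph0, "latent")
  sib <- lat[grepl("_s", lat$iid), ]
  z1 <- sib$z[seq(1, nrow(sib), 2)]; z2 <- sib$z[seq(2, nrow(sib), 2)]
  expect_lt(abs(cor(z1, z2)), 3 / sqrt(length(z1)))

  # full-sib phenotype correlation ~ 0.5 h2 under a polygenic-only model
  # (averaged over effect draws; one draw is noisy at small genome size)
  cors <- vapply(1:4, function(r) {
    phs <- simulate_phenotypes(ped, fam$geno, phenotype_model(h2_total = 0.86),
                               seed = 40 + r, freqs = pool$pool_freq)
    l <- attr(phs, "latent"); s <- l[grepl("_s", l$iid), ]
    cor(s$z[seq(1, nrow(s), 2)], s$z[seq(2, nrow(s), 2)])
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.43), 0.08)

  # single causal variant: carrier groups differ by ~beta within families
  co <- tiny_cohort(n_families = 10, n_snps = 1000, n_elevated = 10, seed = 6)
  csnp <- co$snps$snp[co$pool$elevated][1]
  mod <- phenotype_model(h2_total = 0.5, causal = data.frame(snp = csnp, beta = 0.7))
  php <- simulate_phenotypes(co$ped, co$geno_clean, mod, seed = 7,
                             freqs = co$pool$pool_freq)
  l <- attr(php, "latent")
  p <- co$pool$pool_freq[csnp]
  x <- co$geno$dosage[l$iid, csnp]
  fit <- stats::lm(l$z ~ I((x - 2 * p) / sqrt(2 * p * (1 - p))))
  expect_lt(abs(unname(coef(fit)[2]) - 0.7), 0.1)

  # inconsistent variance fractions are rejected
  expect_error(phenotype_model(h2_total = 0.3,
                               causal = data.frame(snp = "s", beta = 1)),
               "variance fractions")
})

test_that("genotyping noise reproduces the array error structure", {
  co <- tiny_cohort(n_families = 3, n_snps = 4000, seed = 21)

  # zero rates: identity
  nz <- noise_model(nocall = 0, lowq = 0, err_hq = 0, err_lowq = 0)
  g0 <- apply_genotyping_noise(co$geno_clean, nz, seed = 1)
  expect_identical(g0$dosage, co$geno_clean$dosage)

  g1 <- apply_genotyping_noise(co$geno_clean, noise_model(), seed = 2)
  n_calls <- length(g1$dosage)
  # no-call fraction ~ 1.3%
  expect_lt(abs(mean(is.na(g1$dosage)) - 0.013),
            3 * sqrt(0.013 * 0.987 / n_calls))
  # overall error rate ~ 1/110 = 9.1e-3
  ok <- !is.na(g1$dosage)
  err <- mean(g1$dosage[ok] != co$geno_clean$dosage[ok])
  expect_lt(abs(err - 1 / 110), 3 * sqrt((1 / 110) / n_calls))
  # errors concentrate in low-quality calls
  err_hq <- mean((g1$dosage != co$geno_clean$dosage)[ok & !g1$lowq])
  err_lq <- mean((g1$dosage != co$geno_clean$dosage)[ok & g1$lowq])
  expect_gt(err_lq, 10 * err_hq)

  expect_error(noise_model(err_hq = 0.5, err_lowq = 0.01), "low-quality")
})

test_that("founder frequency contrast separates drift from sampling noise", {
  # identical frequency tables: no contrast
  f <- runif(500, 0, 0.3)
  r0 <- founder_frequency_contrast(f, f, 7500, 150, seed = 1)
  expect_identical(r0$observed, 0L)

  # all 100 rare-in-A SNPs common in B
  r1 <- founder_frequency_contrast(rep(0.005, 100), rep(0.10, 100),
                                   7500, 150, seed = 2)
  expect_identical(r1$observed, 100L)

  # subsampling control: binomial resampling of rare frequencies at n=151
  # essentially never reaches the common cutoff
  set.seed(3)
  fa <- rexp(10000, 400); fa <- pmin(fa, 0.009)
  fb <- pmin(fa * 15, 0.4)            # drift-elevated population
  r2 <- founder_frequency_contrast(fa, fb, 7500, 151, seed = 4,
                                   n_control = 50)
  expect_gt(r2$observed, 1000)
  expect_lte(stats::quantile(r2$control, 0.95), 2)

  expect_error(founder_frequency_contrast(fa, fb, 7500, 151, seed = 1,
                                          rare_cut = 1.5), "cutoffs")
})

test_that("seeded simulation is bit-reproducible", {
  a <- tiny_cohort(n_families = 2, n_snps = 500, seed = 31)
  b <- tiny_cohort(n_families = 2, n_snps = 500, seed = 31)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$truth$crossovers, b$truth$crossovers)
})
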