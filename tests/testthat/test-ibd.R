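# IBD reconstruction: evidence classes, run-anchored pairwise calls, family
# reconciliation, inheritance vectors.

test_that("site evidence classes follow the opposite-hom / het-hom / identical rules", {
  expect_identical(classify_pair_sites(0L, 2L), 0L)
  expect_identical(classify_pair_sites(2L, 0L), 0L)
  expect_identical(classify_pair_sites(1L, 1L), 2L)
  expect_identical(classify_pair_sites(2L, 2L), 2L)
  expect_identical(classify_pair_sites(1L, 2L), 1L)
  expect_identical(classify_pair_sites(0L, 1L), 1L)
  expect_identical(classify_pair_sites(NA_integer_, 1L), NA_integer_)
  expect_identical(classify_pair_sites(1L, 1L, excl1 = TRUE), NA_integer_)
  expect_error(classify_pair_sites(3L, 1L), "dosages")
})

test_that("uninformative (identically homozygous) sites are excluded per family", {
  co <- tiny_cohort(n_families = 1, n_snps = 1000, seed = 41)
  keep <- informative_sites(co$geno, co$ped, "F01")
  sibs <- family_sibs(co$ped, "F01")
  d <- co$geno$dosage[sibs, ]
  allsame_hom <- apply(d, 2, function(x) all(x == x[1]) && x[1] %in% c(0, 2))
  expect_identical(unname(keep), unname(!allsame_hom))
  expect_error(informative_sites(co$geno, co$ped, "nope"), "family")
})

test_that("pairwise calling anchors on runs and shrugs off isolated errors", {
  map1 <- genetic_map(n_chrom = 1, lengths = 1e7)
  pos <- seq(2e4, 1e7, by = 2e4)
  sites <- data.frame(chrom = 1, pos = pos)

  # error-free IBD2: every site identical -> single state-2 segment
  tr2 <- call_pair_ibd(rep(2L, length(pos)), sites, map1, warn = FALSE)
  expect_identical(nrow(tr2), 1L)
  expect_identical(tr2$state, 2L)
  expect_identical(c(tr2$start, tr2$end), c(1, 1e7))

  # a single opposite-homozygote inside the level-2 sea is ignored
  cl <- rep(2L, length(pos)); cl[250] <- 0L
  tr2b <- call_pair_ibd(cl, sites, map1, warn = FALSE)
  expect_true(all(tr2b$state == 2L))

  # the full genome is assigned exactly once
  co <- tiny_cohort(n_families = 1, n_snps = 3000, seed = 43, noise = TRUE)
  sibs <- family_sibs(co$ped, "F01")
  keep <- informative_sites(co$geno, co$ped, "F01")
  cl2 <- classify_pair_sites(co$geno$dosage[sibs[1], keep],
                             co$geno$dosage[sibs[2], keep],
                             co$geno$lowq[sibs[1], keep],
                             co$geno$lowq[sibs[2], keep])
  tr <- call_pair_ibd(cl2, co$snps[keep, c("chrom", "pos")], co$map,
                      warn = FALSE)
  for (c in co$map$chrom) {
    t <- tr[tr$chrom == c, ]
    expect_identical(t$start[1], 1)
    expect_identical(t$end[nrow(t)], co$map$length[c])
    expect_true(all(t$start[-1] == t$end[-nrow(t)] + 1))
  }
})

test_that("pairwise calls recover truth on noisy genotypes", {
  # repeated-seed calibration puts single-pair accuracy near 98% at this
  # marker density (boundary jitter dominates); the family-level chain below
  # is what reaches 99.9%
  co <- tiny_cohort(n_families = 1, sibs = c(6, 6), mean_sibs = 6,
                    total_bp = 5e7, total_morgans = 2, n_chrom = 2,
                    n_snps = 12000, seed = 47, noise = TRUE)
  sibs <- family_sibs(co$ped, "F01")
  keep <- informative_sites(co$geno, co$ped, "F01")
  acc <- vapply(1:5, function(k) {
    s1 <- sibs[1]; s2 <- sibs[k + 1]
    cl <- classify_pair_sites(co$geno$dosage[s1, keep], co$geno$dosage[s2, keep],
                              co$geno$lowq[s1, keep], co$geno$lowq[s2, keep])
    tr <- call_pair_ibd(cl, co$snps[keep, c("chrom", "pos")], co$map,
                        warn = FALSE)
    t12 <- truth_pair_ibd(co$truth, "F01", s1, s2)
    mean(unlist(lapply(co$map$chrom, function(c) {
      sel <- co$snps$chrom == c
      state_at(tr, c, co$snps$pos[sel]) == t12[sel]
    })))
  }, numeric(1))
  expect_gt(mean(acc), 0.97)
})

test_that("family reconciliation fixes the classic 6-pair contradiction", {
  # sibs 1..4 with pairs (1,2),(1,3),(1,4),(2,3),(2,4) sharing 2 but (3,4)
  # observed as 1: the minimal correction sets (3,4) to 2
  M <- matrix(2L, 4, 4)
  M[3, 4] <- M[4, 3] <- 1L
  fit <- fit_bipartitions(M)
  expect_identical(fit$cost, 1L)
  expect_identical(config_matrix(fit$bm, fit$bp)[3, 4], 2L)

  # an already-realizable matrix is returned unchanged
  bm <- c(0L, 0L, 1L, 1L, 0L); bp <- c(0L, 1L, 0L, 1L, 1L)
  M2 <- config_matrix(bm, bp)
  fit2 <- fit_bipartitions(M2)
  expect_identical(fit2$cost, 0L)
  expect_identical(config_matrix(fit2$bm, fit2$bp), M2)
})

test_that("minimal-correction search matches brute force and recovers planted errors", {
  set.seed(7)
  for (s_n in c(6, 8)) {
    for (rep in 1:8) {
      bm <- c(0L, sample(0:1, s_n - 1, replace = TRUE))
      bp <- c(0L, sample(0:1, s_n - 1, replace = TRUE))
      M <- config_matrix(bm, bp)
      k <- sample(0:2, 1)
      if (k > 0) {
        ut <- which(upper.tri(M), arr.ind = TRUE)
        hit <- ut[sample(nrow(ut), k), , drop = FALSE]
        for (r in seq_len(k)) {
          i <- hit[r, 1]; j <- hit[r, 2]
          M[i, j] <- M[j, i] <- (M[i, j] + 1L) %% 3L
        }
      }
      fit <- fit_bipartitions(M)
      expect_identical(fit$cost, oracle_min_corrections(M))
      expect_lte(fit$cost, k)
    }
  }

  # 10 siblings, planted truth with up to 2 errors is recovered exactly
  set.seed(8)
  for (rep in 1:5) {
    bm <- c(0L, sample(0:1, 9, replace = TRUE))
    bp <- c(0L, sample(0:1, 9, replace = TRUE))
    M <- config_matrix(bm, bp)
    ut <- which(upper.tri(M), arr.ind = TRUE)
    hit <- ut[sample(nrow(ut), 2), , drop = FALSE]
    for (r in 1:2) {
      i <- hit[r, 1]; j <- hit[r, 2]
      M[i, j] <- M[j, i] <- (M[i, j] + 1L) %% 3L
    }
    fit <- fit_bipartitions(M)
    expect_identical(config_matrix(fit$bm, fit$bp), config_matrix(bm, bp))
  }
})

test_that("every reconciled family state is realizable and label-consistent", {
  co <- tiny_cohort(n_families = 2, n_snps = 4000, seed = 53, noise = TRUE)
  for (f in family_ids(co$ped)) {
    rec <- reconstruct_family_ibd(co$geno, co$ped, f, co$map)
    for (ch in rec$state$chroms) {
      n_seg <- ncol(ch$mat)
      for (t in seq_len(n_seg)) {
        M <- config_matrix(ch$mat[, t] - 1L, ch$pat[, t] - 3L)
        expect_true(is_realizable_state(M))
      }
      expect_true(all(ch$mat %in% 1:2))
      expect_true(all(ch$pat %in% 3:4))
    }
    # sharing fractions from the implied tracks sum to one
    shr <- ibd_sharing_summary(family_pair_tracks(rec$vectors))
    expect_equal(sum(shr), 1)
  }
})

test_that("noiseless reconstruction recovers the true inheritance (>= 99.9%)", {
  co <- tiny_cohort(n_families = 1, sibs = c(12, 12), mean_sibs = 12,
                    total_bp = 4e7, total_morgans = 3, n_chrom = 2,
                    n_snps = 16000, seed = 61)
  rec <- reconstruct_family_ibd(co$geno, co$ped, "F01", co$map)
  agr <- ibd_truth_agreement(rec$vectors, co$truth, "F01", co$snps)
  expect_gte(agr, 0.999)

  # every true crossover is found as an event of the right sibling, and is
  # localized to about one flanking-marker interval
  xo <- co$truth$crossovers[co$truth$crossovers$fid == "F01", ]
  loc <- vapply(seq_len(nrow(xo)), function(r) {
    cn <- as.character(xo$chrom[r])
    ev <- rec$vectors$chroms[[cn]]$events
    evs <- ev[rec$sibs[ev$sib] == xo$iid[r], ]
    if (!nrow(evs)) return(Inf)
    min(abs(evs$pos - xo$pos[r]))
  }, numeric(1))
  spacing <- 4e7 / 16000
  expect_gte(mean(loc < 1e5), 0.95)            # detection
  expect_lte(stats::median(loc), 2 * spacing)  # localization
})

test_that("reconstructed sharing approaches the 25/50/25 expectation", {
  co <- tiny_cohort(n_families = 4, sibs = c(10, 12), mean_sibs = 11,
                    total_bp = 1e8, total_morgans = 10, n_chrom = 6,
                    n_snps = 10000, seed = 67)
  tracks <- list()
  for (f in family_ids(co$ped)) {
    rec <- reconstruct_family_ibd(co$geno, co$ped, f, co$map)
    tracks <- c(tracks, family_pair_tracks(rec$vectors))
  }
  shr <- ibd_sharing_summary(tracks)
  # close to theory, and nearly unbiased against this cohort's own truth
  tru <- rowMeans(vapply(family_ids(co$ped), function(f) truth_sharing(co, f),
                         numeric(3)))
  expect_lt(max(abs(shr - c(0.25, 0.50, 0.25))), 0.025)
  expect_lt(max(abs(shr - tru)), 0.01)

  # inferred recombination events per gamete ~ genetic length in Morgans
  n_events <- 0
  for (f in family_ids(co$ped)) {
    rec <- reconstruct_family_ibd(co$geno, co$ped, f, co$map)
    n_events <- n_events + sum(vapply(rec$vectors$chroms, function(ch)
      nrow(ch$events), numeric(1)))
  }
  n_gametes <- 2 * sum(vapply(family_ids(co$ped), function(f)
    length(family_sibs(co$ped, f)), numeric(1)))
  rate <- n_events / n_gametes
  expect_lt(abs(rate - 10) / 10, 0.15)
})

test_that("sharing summary arithmetic", {
  t_all2 <- data.frame(chrom = 1, start = 1, end = 100, state = 2L)
  expect_equal(unname(ibd_sharing_summary(list(t_all2))), c(0, 0, 1))
  t_a <- data.frame(chrom = 1, start = 1, end = 100, state = 0L)
  t_b <- data.frame(chrom = 1, start = 1, end = 100, state = 2L)
  expect_equal(unname(ibd_sharing_summary(list(t_a, t_b))), c(0.5, 0, 0.5))
})
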