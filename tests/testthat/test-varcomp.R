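# GRMs, EM-REML, QTL SNP selection, the random-segment null, cross-validated
# variance, chromosome partitioning and infinitesimal simulations.

geno_from_matrix <- function(dos, chrom = NULL, pos = NULL) {
  m <- ncol(dos)
  structure(list(
    dosage = dos,
    lowq = matrix(FALSE, nrow(dos), m, dimnames = dimnames(dos)),
    snps = data.frame(snp = colnames(dos),
                      chrom = if (is.null(chrom)) rep(1, m) else chrom,
                      pos = if (is.null(pos)) seq_len(m) * 1e4 else pos)),
    class = "famlink_geno")
}

test_that("the GRM follows the standardized-dosage formula", {
  # one SNP, genotypes {0, 2}, p = 0.5: (x - 2p)^2 / (2p(1-p)) = 2
  g <- geno_from_matrix(matrix(c(0L, 2L), 2, 1,
                               dimnames = list(c("a", "b"), "s1")))
  A <- compute_grm(g)$A
  expect_equal(unname(diag(A)), c(2, 2))
  expect_equal(A["a", "b"], -2)

  # duplicated individuals: off-diagonal equals the shared diagonal
  set.seed(1)
  dos <- matrix(rbinom(400, 2, 0.3), nrow = 4,
                dimnames = list(letters[1:4], paste0("s", 1:100)))
  dos[2, ] <- dos[1, ]
  A2 <- compute_grm(geno_from_matrix(dos))$A
  expect_equal(A2["a", "b"], A2["a", "a"])

  # unrelated individuals: off-diagonals concentrate at 0 (up to the
  # sample-frequency centering term of order -1/(n-1))
  set.seed(2)
  n <- 200; m <- 5000
  p <- runif(m, 0.1, 0.5)
  dos3 <- matrix(rbinom(n * m, 2, rep(p, each = n)), n,
                 dimnames = list(paste0("i", 1:n), paste0("s", 1:m)))
  A3 <- compute_grm(geno_from_matrix(dos3))$A
  off <- A3[upper.tri(A3)]
  expect_lt(abs(mean(off)), 0.01)
  # trace/n -> 1 on Hardy-Weinberg data
  expect_lt(abs(mean(diag(A3)) - 1), 0.05)

  # monomorphic SNPs are dropped (messaged), all-monomorphic errors
  dos4 <- cbind(dos3, mono = rep(2L, n))
  expect_message(g4 <- compute_grm(geno_from_matrix(dos4)), "monomorphic")
  expect_identical(g4$m, as.integer(m))
  expect_error(compute_grm(geno_from_matrix(
    matrix(2L, 4, 2, dimnames = list(letters[1:4], c("x", "y"))))),
    "monomorphic")
})

test_that("EM-REML recovers planted variance fractions within 2 SE", {
  set.seed(3)
  n <- 200
  make_A <- function() {
    Z <- matrix(rnorm(n * 400), n, 400)
    A <- tcrossprod(scale(Z)) / 400
    dimnames(A) <- list(paste0("i", 1:n), paste0("i", 1:n))
    A
  }
  A <- make_A()
  cA <- chol(A + diag(1e-8, n))

  # null phenotype: fraction ~ 0
  y0 <- stats::setNames(rnorm(n), rownames(A))
  f0 <- reml_fit(y0, list(g = A))
  expect_lt(f0$fractions["g"], 2 * max(f0$fraction_se["g"], 0.05))

  # planted 0.4: mean estimate over seeds within 2 SE of the mean
  ests <- vapply(1:8, function(s) {
    set.seed(10 + s)
    g <- drop(crossprod(cA, rnorm(n))) * sqrt(0.4)
    y <- stats::setNames(g + rnorm(n, 0, sqrt(0.6)), rownames(A))
    fit <- reml_fit(y, list(g = A))
    expect_true(fit$converged)
    expect_true(all(diff(fit$loglik_trace) > -1e-6))  # EM monotonicity
    unname(fit$fractions["g"])
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.4), 2 * sd(ests) / sqrt(length(ests)) + 0.02)

  # AI acceleration agrees with plain EM
  set.seed(30)
  g <- drop(crossprod(cA, rnorm(n))) * sqrt(0.4)
  y <- stats::setNames(g + rnorm(n, 0, sqrt(0.6)), rownames(A))
  em <- reml_fit(y, list(g = A), method = "em")
  ai <- reml_fit(y, list(g = A), method = "ai")
  expect_lt(abs(em$fractions["g"] - ai$fractions["g"]), 0.01)

  # identical matrices are non-identifiable: dropped with a warning
  expect_warning(fd <- reml_fit(y, list(g1 = A, g2 = A)), "non-identifiable")
  expect_identical(names(fd$varcomp), c("g1", "residual"))

  # single-component fit agrees with a Haseman-Elston style regression
  he <- he_regression_h2(y, A)
  expect_lt(abs(unname(em$fractions["g"]) - he),
            2 * unname(em$fraction_se["g"]) + 0.05)
})

test_that("QTL SNP selection takes the k nearest markers per peak", {
  snps <- data.frame(snp = paste0("s", 1:100), chrom = rep(1:2, each = 50),
                     pos = rep(seq(1e6, 50e6, by = 1e6), 2))
  qtls <- data.frame(chrom = c(1, 2), peak_pos = c(10e6, 49e6),
                     peak_lod = c(3, 2))
  sel <- qtl_snp_selection(qtls, snps, k = 5)
  expect_length(sel, 10)
  expect_true(all(c("s10", "s9", "s11") %in% sel))
  # chromosome end: one-sided neighbourhood still returns k SNPs
  expect_identical(sum(grepl("^s9[5-9]|^s100", sel)), 5L)
  # k = 1 tie toward the lower position
  q1 <- data.frame(chrom = 1, peak_pos = 10.5e6, peak_lod = 1)
  expect_identical(qtl_snp_selection(q1, snps, k = 1), "s10")
  # overlapping windows are deduplicated with a message
  q2 <- data.frame(chrom = c(1, 1), peak_pos = c(10e6, 11e6), peak_lod = 1)
  expect_message(s2 <- qtl_snp_selection(q2, snps, k = 5), "deduplicated")
  expect_identical(anyDuplicated(s2), 0L)
})

test_that("random QTL-like segments respect spacing and sample uniformly", {
  map <- genetic_map(n_chrom = 3, lengths = c(6e7, 3e7, 1e7))
  snps <- place_snps(map, 1000)
  r1 <- random_qtl_segments(1, snps, map, min_distance = 1e6, k = 10, seed = 1)
  expect_length(r1$snps, 10)
  expect_identical(nrow(r1$centers), 1L)

  # infeasible spacing errors out (single chromosome, spacing > its span)
  map1 <- genetic_map(n_chrom = 1, lengths = 5e7)
  snps1 <- place_snps(map1, 200)
  expect_error(random_qtl_segments(2, snps1, map1, min_distance = 2e8,
                                   k = 10, seed = 2, max_tries = 50),
               "minimal distance")

  # centers land on chromosomes proportionally to length
  draws <- vapply(1:600, function(s) {
    random_qtl_segments(1, snps, map, 1e6, k = 1, seed = 1000 + s)$centers$chrom
  }, numeric(1))
  gof <- stats::chisq.test(tabulate(draws, 3), p = map$length / sum(map$length))
  expect_gt(gof$p.value, 0.01)

  # spacing is honoured on the same chromosome
  r3 <- random_qtl_segments(4, snps, map, min_distance = 5e6, k = 5, seed = 3)
  cc <- r3$centers
  for (a in 1:3) for (b in (a + 1):4) {
    if (cc$chrom[a] == cc$chrom[b]) {
      expect_gte(abs(cc$peak_pos[a] - cc$peak_pos[b]), 5e6)
    }
  }
})

test_that("cross-validation never leaks test families and nulls out on noise", {
  co <- tiny_cohort(n_families = 6, sibs = c(8, 10), mean_sibs = 9,
                    n_snps = 1500, seed = 101)
  h <- cohort_heights(co, phenotype_model(h2_total = 0), seed = 5)
  cohort <- list(ped = co$ped, geno = co$geno,
                 vectors_list = truth_vectors_list(co),
                 heights = h, map = co$map)
  design <- cv_design(co$ped, n_splits = 2, train_families = 4,
                      balance_tol = 8, seed = 7)
  # train and test are disjoint and cover the cohort
  for (sp in design$splits) {
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), family_ids(co$ped))
  }
  cv <- cross_validate_variance(cohort, design, thresholds = c(1.2),
                                n_random = 2, grid_step = 2e5, n_perm = 60,
                                k_snps = 30, seed = 11)
  # with no causal variants the QTL component explains nothing above null
  expect_lt(abs(cv$above_null), max(2 * cv$se, 0.15))

  # a corrupted design (overlapping families) is a hard error
  bad <- design
  bad$splits[[1]]$test <- c(bad$splits[[1]]$test, bad$splits[[1]]$train[1])
  expect_error(cross_validate_variance(cohort, bad, thresholds = 1.2,
                                       n_random = 1, n_perm = 40, seed = 1),
               "overlap")
})

test_that("chromosome partitioning finds a planted single-chromosome signal", {
  co <- tiny_cohort(n_families = 10, sibs = c(8, 10), mean_sibs = 9,
                    n_snps = 2000, seed = 103)
  snps2 <- co$snps$snp[co$snps$chrom == 2]
  wins <- 0
  for (s in 1:4) {
    mod <- phenotype_model(h2_total = 0.8, polygenic_snps = snps2)
    h <- cohort_heights(co, mod, seed = 50 + s)
    cp <- chromosome_partition(h, co$geno, co$map)
    if (which.max(cp$table$fraction) == 2) wins <- wins + 1
    expect_equal(nrow(cp$table), nrow(co$map))
  }
  expect_gte(wins, 3)

  # pure noise: every chromosome's fraction stays small
  fr0 <- vapply(1:4, function(s) {
    h0 <- cohort_heights(co, phenotype_model(h2_total = 0), seed = 80 + s)
    max(chromosome_partition(h0, co$geno, co$map)$table$fraction)
  }, numeric(1))
  # single-chromosome fractions are noisy at this sample size; on average
  # they stay well below the planted-signal regime
  expect_lt(mean(fr0), 0.3)
})

test_that("infinitesimal simulations conserve heritability across chromosomes", {
  co <- tiny_cohort(n_families = 8, sibs = c(8, 10), mean_sibs = 9,
                    n_snps = 1600, seed = 107)
  sim <- infinitesimal_simulation(co$geno, co$map, h2 = 0.8, n_sets = 4,
                                  seed = 9)
  expect_identical(dim(sim$fractions), c(4L, nrow(co$map)))
  # per set, the chromosome contributions approximately add up to h2
  tot <- rowSums(sim$fractions)
  expect_lt(abs(mean(tot) - 0.8), 0.25)
  # monotone exceedance of the pooled fraction distribution
  fr <- as.vector(sim$fractions)
  ex <- vapply(c(0.05, 0.15, 0.25), function(q) sum(fr > q), numeric(1))
  expect_true(all(diff(ex) <= 0))

  # h2 = 0: all fractions collapse to zero
  sim0 <- infinitesimal_simulation(co$geno, co$map, h2 = 0, n_sets = 2,
                                   seed = 10)
  expect_lt(max(sim0$fractions), 0.15)
})
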