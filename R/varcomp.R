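# Genomic relatedness matrices and joint variance-components estimation by
# EM-REML; QTL-region SNP selection, the random-segment null, the
# cross-validated estimate of QTL-explained variance, per-chromosome
# partitioning and infinitesimal-model simulations.

#' Genomic relatedness matrix from SNP dosages
#'
#' `A_jk = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with allele frequencies `p_i` estimated from the sample.  Monomorphic
#' SNPs are dropped (count reported via message); missing dosages are
#' mean-imputed.
#'
#' @param geno `famlink_geno`.
#' @param snps SNP ids to use (default: all).
#' @param samples sample ids (default: all).
#' @return list of class `grm`: `A` (symmetric matrix), `m` (SNPs used),
#'   `snps`.
#' @export
compute_grm <- function(geno, snps = NULL, samples = NULL) {
  d <- geno$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(snps)) d <- d[, snps, drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic in this sample")
  if (any(!poly)) {
    message(sprintf("compute_grm: dropping %d monomorphic SNP(s)", sum(!poly)))
  }
  d <- d[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(d, 2, 2 * p)
  Z[is.na(Z)] <- 0                       # mean imputation after centering
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(Z) / ncol(Z)
  structure(list(A = A, m = ncol(Z), snps = colnames(d)), class = "grm")
}

#' Joint variance-components model fit by EM-REML
#'
#' Model: `y = X b + sum_k u_k + e`, `u_k ~ N(0, s2_k K_k)`,
#' `e ~ N(0, s2_e I)`.  Variance components are estimated by EM-REML
#' iterations (non-negativity enforced by projection to a small floor) until
#' the restricted log-likelihood changes by less than `tol`; the
#' log-likelihood is non-decreasing along the EM path.  Standard errors come
#' from the inverse Fisher information at convergence.  Pairs of
#' numerically identical relatedness matrices are non-identifiable; the
#' later one is dropped with a warning.
#'
#' @param y named numeric phenotype.
#' @param K list of relatedness matrices (dimnames covering `names(y)`), one
#'   per genetic component.
#' @param X fixed-effect design matrix (default: intercept).
#' @param max_iter,tol EM control (defaults 2000 and 1e-6).
#' @param check_psd verify positive semi-definiteness of each `K` (error if
#'   violated).
#' @param method `"em"` (default) or `"ai"` (average-information updates
#'   after a short EM warm-up; faster on large problems, same model).
#' @return list of class `vc_fit`: `varcomp` (named, incl. `residual`),
#'   `se`, `fractions`, `fraction_se`, `loglik`, `iterations`, `converged`,
#'   `cov` (covariance of the variance estimates), `loglik_trace`.
#' @export
reml_fit <- function(y, K, X = NULL, max_iter = 2000L, tol = 1e-6,
                     check_psd = FALSE, method = c("em", "ai")) {
  method <- match.arg(method)
  ids <- names(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(names(K))) names(K) <- paste0("K", seq_along(K))
  K <- lapply(K, function(k) {
    if (!is.null(ids) && !is.null(rownames(k))) k[ids, ids] else k
  })
  p <- length(K)
  if (n <= p + 1) stop("need more observations than components")
  for (k in K) {
    if (!isTRUE(all.equal(k, t(k), tolerance = 1e-8))) stop("K must be symmetric")
    if (check_psd && min(eigen(k, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8 * n) {
      stop("relatedness matrix is not positive semi-definite")
    }
  }
  # non-identifiable duplicates
  if (p > 1) {
    drop <- logical(p)
    for (a in seq_len(p - 1)) for (b in (a + 1):p) {
      if (!drop[b] && isTRUE(all.equal(K[[a]], K[[b]], tolerance = 1e-10))) {
        drop[b] <- TRUE
      }
    }
    if (any(drop)) {
      warning(sprintf("dropping %d duplicated (non-identifiable) component(s): %s",
                      sum(drop), paste(names(K)[drop], collapse = ", ")))
      K <- K[!drop]; p <- length(K)
    }
  }

  vy <- stats::var(y)
  s2 <- rep(vy / (p + 1), p + 1)          # components then residual
  floor_v <- 1e-8 * vy
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L

  Kall <- c(K, list(diag(n)))
  ycol <- matrix(y, ncol = 1)

  for (iter in seq_len(max_iter)) {
    V <- matrix(0, n, n)
    for (k in seq_len(p)) V <- V + s2[k] * K[[k]]
    diag(V) <- diag(V) + s2[p + 1]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) { diag(V) <- diag(V) + 1e-8 * vy; ch <- chol(V) }
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    P <- Vi - t(XtVi) %*% solve(XtViX, XtVi)
    Py <- P %*% ycol
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
                    sum(ycol * Py))
    ll_trace <- c(ll_trace, ll)
    if (iter > 1 && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll

    if (method == "em" || iter <= 5L) {
      for (k in seq_len(p + 1)) {
        KPy <- Kall[[k]] %*% Py
        quad <- sum(Py * KPy)
        trPK <- sum(P * Kall[[k]])
        s2[k] <- s2[k] + s2[k]^2 * (quad - trPK) / n
      }
    } else {
      # average-information step with EM fallback on failure
      g <- vapply(seq_len(p + 1), function(k) {
        KPy <- Kall[[k]] %*% Py
        -0.5 * (sum(P * Kall[[k]]) - sum(Py * KPy))
      }, numeric(1))
      PKPy <- lapply(Kall, function(Kk) P %*% (Kk %*% Py))
      AI <- matrix(0, p + 1, p + 1)
      for (a in seq_len(p + 1)) for (b in a:(p + 1)) {
        AI[a, b] <- AI[b, a] <- 0.5 * sum((Kall[[a]] %*% Py) * PKPy[[b]])
      }
      step <- tryCatch(solve(AI, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) {
        for (k in seq_len(p + 1)) {
          KPy <- Kall[[k]] %*% Py
          s2[k] <- s2[k] + s2[k]^2 * (sum(Py * KPy) - sum(P * Kall[[k]])) / n
        }
      } else {
        s2 <- s2 + step
      }
    }
    s2 <- pmax(s2, floor_v)
  }

  # information matrix and standard errors at convergence
  PK <- lapply(Kall, function(Kk) P %*% Kk)
  FI <- matrix(0, p + 1, p + 1)
  for (a in seq_len(p + 1)) for (b in a:(p + 1)) {
    FI[a, b] <- FI[b, a] <- 0.5 * sum(PK[[a]] * t(PK[[b]]))
  }
  covm <- tryCatch(solve(FI), error = function(e) matrix(NA_real_, p + 1, p + 1))
  se <- sqrt(pmax(diag(covm), 0))
  tot <- sum(s2)
  frac <- s2 / tot
  # delta-method SEs of the fractions
  Jac <- (diag(p + 1) * tot - matrix(s2, p + 1, p + 1)) / tot^2
  frac_cov <- Jac %*% covm %*% t(Jac)
  nm <- c(names(K), "residual")
  structure(
    list(varcomp = stats::setNames(s2, nm), se = stats::setNames(se, nm),
         fractions = stats::setNames(frac, nm),
         fraction_se = stats::setNames(sqrt(pmax(diag(frac_cov), 0)), nm),
         loglik = ll_trace[length(ll_trace)], iterations = iter,
         converged = converged, cov = covm, loglik_trace = ll_trace),
    class = "vc_fit"
  )
}

#' SNPs tagging the detected QTLs
#'
#' The `k` SNPs physically closest to each QTL peak (ties broken toward the
#' lower bp position), concatenated over QTLs and deduplicated.
#'
#' @param qtls `qtl_table`.
#' @param snps SNP map.
#' @param k SNPs per QTL (100 at full scale, ~1 Mb around a peak).
#' @return character vector of SNP ids.
#' @export
qtl_snp_selection <- function(qtls, snps, k = 100L) {
  sel <- character(0)
  for (q in seq_len(nrow(qtls))) {
    cand <- snps[snps$chrom == qtls$chrom[q], ]
    d <- abs(cand$pos - qtls$peak_pos[q])
    ord <- order(d, cand$pos)
    sel <- c(sel, cand$snp[ord[seq_len(min(k, nrow(cand)))]])
  }
  dup <- duplicated(sel)
  if (any(dup)) message(sprintf("qtl_snp_selection: %d overlapping SNP(s) deduplicated", sum(dup)))
  sel[!dup]
}

#' Random QTL-like segments (the null for variance explained)
#'
#' Samples segment centers uniformly on the physical genome (chromosome
#' chosen proportionally to length), rejecting draws until all pairwise
#' distances (same chromosome) are at least `min_distance`, then takes the
#' `k` nearest SNPs per center, mirroring [qtl_snp_selection()].
#'
#' @param n_qtls number of segments.
#' @param snps SNP map.
#' @param map `genetic_map`.
#' @param min_distance minimal pairwise center distance (bp).
#' @param k SNPs per segment.
#' @param seed integer seed (mandatory).
#' @param max_tries rejection-sampling budget.
#' @return list: `snps` (character vector), `centers` (data.frame).
#' @export
random_qtl_segments <- function(n_qtls, snps, map, min_distance, k = 100L,
                                seed, max_tries = 10000L) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    chrom <- sample(map$chrom, n_qtls, replace = TRUE,
                    prob = map$length / sum(map$length))
    pos <- stats::runif(n_qtls, 1, map$length[match(chrom, map$chrom)])
    ok <- TRUE
    if (n_qtls > 1) {
      for (a in seq_len(n_qtls - 1)) for (b in (a + 1):n_qtls) {
        if (chrom[a] == chrom[b] && abs(pos[a] - pos[b]) < min_distance) ok <- FALSE
      }
    }
    if (ok) {
      centers <- data.frame(chrom = chrom, peak_pos = round(pos))
      fake <- cbind(centers, peak_lod = NA_real_)
      return(list(snps = qtl_snp_selection(fake, snps, k), centers = centers))
    }
  }
  stop("could not place random segments at the requested minimal distance")
}

#' Cross-validation design over families
#'
#' Random train/test splits of the families with the participant balance
#' constrained by rejection sampling: the training fraction of participants
#' must match the training fraction of families within `balance_tol`
#' participants.
#'
#' @param ped pedigree.
#' @param n_splits number of splits (100 at full scale).
#' @param train_families number of training families (19 of 29 at full
#'   scale); default 2/3 of the families.
#' @param balance_tol allowed deviation (participants) from the proportional
#'   participant count.
#' @param seed integer seed (mandatory).
#' @param max_tries rejection budget per split.
#' @return list of class `cv_design`: per split `train` / `test` family ids.
#' @export
cv_design <- function(ped, n_splits = 100L, train_families = NULL,
                      balance_tol = 2L, seed, max_tries = 1e5) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  fams <- family_ids(ped)
  sizes <- vapply(fams, function(f) length(family_sibs(ped, f)), numeric(1))
  if (is.null(train_families)) train_families <- round(2 / 3 * length(fams))
  target <- sum(sizes) * train_families / length(fams)
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    for (try in seq_len(max_tries)) {
      tr <- sample(fams, train_families)
      if (abs(sum(sizes[tr]) - target) <= balance_tol) break
      if (try == max_tries) stop("could not balance a split within tolerance")
    }
    splits[[s]] <- list(train = sort(tr), test = sort(setdiff(fams, tr)))
  }
  structure(list(splits = splits, n_splits = n_splits,
                 train_families = train_families, balance_tol = balance_tol),
            class = "cv_design")
}

#' Cross-validated variance explained by QTLs above a random-segment null
#'
#' For every split, QTLs are mapped on the training families only; on the
#' held-out test families a joint variance-components model is fit with a
#' QTL GRM, a whole-genome GRM and (optionally) a known-variants GRM, and
#' the QTL-component fraction recorded.  The same fit is repeated
#' `n_random` times per split with random QTL-like segments (matched in
#' number, SNP count and minimal spacing).  The reported estimate per
#' threshold is `median(real) - median(random)`, with a bootstrap standard
#' error of the median difference; the subtraction removes variance the QTL
#' component captures merely through pedigree structure, shared environment
#' or polygenic tagging.  Test families never enter the scan (checked).
#'
#' @param cohort list with `ped`, `geno` (inferred genotypes), `vectors_list`
#'   (named by family), `heights` (named z-scores), `map`.
#' @param design `cv_design`.
#' @param thresholds LOD thresholds to sweep.
#' @param n_random random-segment fits per split.
#' @param grid_step,n_perm scan parameters for the training scans.
#' @param k_snps SNPs per QTL.
#' @param gwas_snps optional character vector: the known-variants GRM.
#' @param seed integer seed (mandatory).
#' @param reml_method passed to [reml_fit()].
#' @param n_boot bootstrap replicates for the SE of the median difference.
#' @return data.frame of class `cv_variance`: per threshold the median real
#'   and random QTL-component fractions, their difference (`above_null`),
#'   its bootstrap SE, and the mean QTL count per split.
#' @export
cross_validate_variance <- function(cohort, design, thresholds = c(3.0, 2.0),
                                    n_random = 100L, grid_step = 5000,
                                    n_perm = 200L, k_snps = 100L,
                                    gwas_snps = NULL, seed,
                                    reml_method = "ai", n_boot = 200L) {
  if (missing(seed)) stop("'seed' is required")
  ped <- cohort$ped; geno <- cohort$geno; map <- cohort$map
  snps <- geno$snps
  merge_distance <- 33e6 * (sum(map$length) / 2.88e9)  # scale with the genome
  res <- list()
  grm_all_cache <- list()
  for (s in seq_along(design$splits)) {
    sp <- design$splits[[s]]
    if (length(intersect(sp$train, sp$test))) stop("train/test families overlap")
    train_vec <- cohort$vectors_list[sp$train]
    stopifnot(!any(names(cohort$vectors_list[sp$test]) %in% sp$train))
    scan <- cohort_scan(train_vec, cohort$heights, map, grid_step, n_perm,
                        seed = (seed + 104729L * s) %% .Machine$integer.max)
    test_ids <- unlist(lapply(sp$test, function(f) family_sibs(ped, f)))
    test_ids <- intersect(test_ids, names(cohort$heights))
    y <- cohort$heights[test_ids]
    key <- paste(sort(test_ids), collapse = "|")
    if (is.null(grm_all_cache[[key]])) {
      grm_all_cache[[key]] <- compute_grm(geno, samples = test_ids)$A
    }
    A_genome <- grm_all_cache[[key]]
    A_gwas <- if (!is.null(gwas_snps)) {
      compute_grm(geno, snps = gwas_snps, samples = test_ids)$A
    } else NULL

    for (th in thresholds) {
      qtls <- call_qtls(scan, th, merge_distance)
      if (nrow(qtls) == 0) {
        res[[length(res) + 1]] <- data.frame(
          split = s, threshold = th, n_qtls = 0, real = 0, random = NA_real_)
        next
      }
      qsnps <- qtl_snp_selection(qtls, snps, k_snps)
      Kl <- list(qtl = compute_grm(geno, snps = qsnps, samples = test_ids)$A,
                 genome = A_genome)
      if (!is.null(A_gwas)) Kl$gwas <- A_gwas
      fit <- reml_fit(y, Kl, method = reml_method)
      min_d <- if (nrow(qtls) > 1) {
        dd <- Inf
        for (a in seq_len(nrow(qtls) - 1)) for (b in (a + 1):nrow(qtls)) {
          if (qtls$chrom[a] == qtls$chrom[b]) {
            dd <- min(dd, abs(qtls$peak_pos[a] - qtls$peak_pos[b]))
          }
        }
        if (is.finite(dd)) dd else merge_distance
      } else merge_distance
      rnd <- numeric(n_random)
      for (r in seq_len(n_random)) {
        rs <- random_qtl_segments(nrow(qtls), snps, map, min_d, k_snps,
                                  seed = (seed + 31L * s + 977L * r + round(1000 * th)) %%
                                    .Machine$integer.max)
        Kr <- Kl; Kr$qtl <- compute_grm(geno, snps = rs$snps,
                                        samples = test_ids)$A
        rnd[r] <- suppressWarnings(
          reml_fit(y, Kr, method = reml_method)$fractions["qtl"])
      }
      res[[length(res) + 1]] <- data.frame(
        split = s, threshold = th, n_qtls = nrow(qtls),
        real = unname(fit$fractions["qtl"]), random = mean(rnd))
      attr(res[[length(res)]], "random_draws") <- rnd
    }
  }
  long <- do.call(rbind, res)
  rnd_by_th <- lapply(split(seq_len(nrow(long)), long$threshold), function(ix) {
    unlist(lapply(ix, function(i) attr(res[[i]], "random_draws")))
  })
  out <- do.call(rbind, lapply(unique(long$threshold), function(th) {
    li <- long[long$threshold == th, ]
    rn <- rnd_by_th[[as.character(th)]]
    med_real <- stats::median(li$real)
    med_rand <- if (length(rn)) stats::median(rn) else 0
    boot <- replicate(n_boot, {
      stats::median(sample(li$real, replace = TRUE)) -
        (if (length(rn)) stats::median(sample(rn, replace = TRUE)) else 0)
    })
    data.frame(threshold = th, median_real = med_real, median_random = med_rand,
               above_null = med_real - med_rand, se = stats::sd(boot),
               mean_qtls = mean(li$n_qtls))
  }))
  attr(out, "splits") <- long
  class(out) <- c("cv_variance", "data.frame")
  out
}

#' Per-chromosome variance partitioning
#'
#' One GRM per autosome, all fit jointly; reports each chromosome's variance
#' fraction with its SE and the Pearson/Spearman correlations of the
#' fractions with chromosome length and with the chromosome's top LOD
#' score, plus the same correlations with the top-fraction chromosome left
#' out.
#'
#' @param y named phenotype z-scores.
#' @param geno `famlink_geno`.
#' @param map `genetic_map`.
#' @param max_lod optional named numeric: top LOD per chromosome (e.g. from a
#'   `linkage_scan`).
#' @param reml_method passed to [reml_fit()].
#' @return list of class `chrom_partition`: `table` (per-chromosome), `fit`,
#'   correlation tests, leave-one-out correlations.
#' @export
chromosome_partition <- function(y, geno, map, max_lod = NULL,
                                 reml_method = "ai") {
  ids <- intersect(names(y), rownames(geno$dosage))
  y <- y[ids]
  Kl <- list()
  for (c in map$chrom) {
    csnps <- geno$snps$snp[geno$snps$chrom == c]
    Kl[[paste0("chr", c)]] <- compute_grm(geno, snps = csnps, samples = ids)$A
  }
  fit <- reml_fit(y, Kl, method = reml_method)
  frac <- fit$fractions[seq_len(nrow(map))]
  tab <- data.frame(chrom = map$chrom, length = map$length,
                    fraction = unname(frac),
                    se = unname(fit$fraction_se[seq_len(nrow(map))]),
                    max_lod = if (is.null(max_lod)) NA_real_ else
                      unname(max_lod[as.character(map$chrom)]))
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  ct_len <- if (stats::sd(tab$fraction) > 0) {
    stats::cor.test(tab$fraction, tab$length)
  } else NULL
  ct_lod <- if (!all(is.na(tab$max_lod)) && stats::sd(tab$fraction) > 0) {
    list(pearson = stats::cor.test(tab$fraction, tab$max_lod),
         spearman = suppressWarnings(
           stats::cor.test(tab$fraction, tab$max_lod,
                           method = "spearman", exact = FALSE)))
  } else NULL
  top <- which.max(tab$fraction)
  loo <- tab[-top, ]
  loo_len <- safe_cor(loo$fraction, loo$length)
  loo_lod <- if (!all(is.na(loo$max_lod))) safe_cor(loo$fraction, loo$max_lod) else NA
  structure(
    list(table = tab, fit = fit, cor_length = ct_len, cor_lod = ct_lod,
         converged = fit$converged,
         leave_one_out = list(dropped = tab$chrom[top],
                              cor_length = loo_len, cor_lod = loo_lod)),
    class = "chrom_partition"
  )
}

#' Infinitesimal-model simulations of chromosome contributions
#'
#' Draws `n_sets` phenotypes in which every SNP carries an i.i.d. normal
#' effect (total heritability `h2`), runs [chromosome_partition()] on each,
#' and returns the pooled distribution of per-chromosome variance fractions
#' together with each set's fraction-vs-length correlation.  Under this
#' model chromosome contributions scale with length; a single real
#' chromosome far out in this distribution indicates concentrated
#' large-effect regions instead.
#'
#' @param geno `famlink_geno`.
#' @param map `genetic_map`.
#' @param h2 heritability of the simulated trait, in (0, 1).
#' @param n_sets number of simulated phenotype sets.
#' @param seed integer seed (mandatory).
#' @param samples sample ids (default: all genotyped).
#' @param reml_method passed to [reml_fit()].
#' @return list of class `infinitesimal_sim`: `fractions` (sets x
#'   chromosomes), `cor_length` (per set), `h2`.
#' @export
infinitesimal_simulation <- function(geno, map, h2, n_sets = 100L, seed,
                                     samples = NULL, reml_method = "ai") {
  if (missing(seed)) stop("'seed' is required")
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  set.seed(seed)
  ids <- if (is.null(samples)) rownames(geno$dosage) else samples
  d <- geno$dosage[ids, , drop = FALSE]
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  d <- d[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(d, 2, 2 * p); Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  m <- ncol(Z)
  snpsub <- geno$snps[match(colnames(d), geno$snps$snp), ]
  fr <- matrix(NA_real_, n_sets, nrow(map))
  cl <- numeric(n_sets)
  for (s in seq_len(n_sets)) {
    u <- stats::rnorm(m, 0, sqrt(h2 / m))
    g <- drop(Z %*% u)
    e <- stats::rnorm(length(ids), 0, sqrt(1 - h2))
    y <- stats::setNames(g + e, ids)
    cp <- chromosome_partition(y, geno, map, reml_method = reml_method)
    fr[s, ] <- cp$table$fraction
    cl[s] <- if (stats::sd(cp$table$fraction) > 0) {
      stats::cor(cp$table$fraction, cp$table$length)
    } else NA_real_
  }
  structure(list(fractions = fr, cor_length = cl, h2 = h2, map = map),
            class = "infinitesimal_sim")
}
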