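# QTL mapping by per-parent haplotype contrast tests on a genome grid,
# calibrated by within-family height permutations; genome-wide empirical P
# values, LOD conversion, QTL calling, separation distance and the
# threshold-sweep FDR analysis.

#' Genome grid for the linkage scan
#'
#' @param map `genetic_map`.
#' @param step grid spacing in bp (5,000 at full scale).
#' @return data.frame (`chrom`, `pos`).
#' @export
scan_grid <- function(map, step = 5000) {
  out <- lapply(seq_len(nrow(map)), function(c) {
    data.frame(chrom = map$chrom[c],
               pos = seq(step, map$length[c], by = step))
  })
  do.call(rbind, out)
}

#' Coefficient of determination of a two-group contrast
#'
#' R-squared of the simple linear regression of a quantitative phenotype on
#' a binary group indicator; identical to between-group sum of squares over
#' total sum of squares.
#'
#' @param heights numeric phenotypes.
#' @param labels two-level grouping (any type).
#' @return R-squared in `[0, 1]`; `NA` if either group is empty or the
#'   phenotype is constant.
#' @export
contrast_r2 <- function(heights, labels) {
  g <- labels == labels[1]
  if (all(g) || !any(g)) return(NA_real_)
  if (stats::sd(heights) == 0) return(NA_real_)
  stats::cor(heights, as.numeric(g))^2
}

#' Per-family permutation contrast scan
#'
#' At every grid position the family's siblings are split by the haplotype
#' inherited from each parent and the contrast R-squared with (corrected)
#' height is computed, for the real heights and for `n_perm` within-family
#' permutations of the heights with the genetics held fixed.  Each
#' permutation replicate uses one height permutation applied identically at
#' every position, so replicates are coherent whole-genome scans.  The local
#' P value of a score is the fraction of permuted replicates reaching an
#' equal or larger R-squared at that position (computed identically for the
#' real and each permuted replicate); the per-family local P is the minimum
#' over the two parents, which also captures dominance-like signals.
#' Positions where a parent is uninformative (all siblings share its
#' haplotype) get local P 1 for that parent.
#'
#' @param vectors `inheritance_vectors` of the family.
#' @param heights named numeric: corrected height z-scores of the siblings.
#' @param grid data.frame from [scan_grid()].
#' @param n_perm number of within-family permutations.
#' @param seed integer seed (mandatory).
#' @return list of class `family_scan`: `local_p` (real, per position),
#'   `perm_local_p` (`n_perm` x positions), `r2` (positions x 2 parents).
#' @export
family_scan <- function(vectors, heights, grid, n_perm = 1000, seed) {
  if (missing(seed)) stop("'seed' is required")
  sibs <- vectors$sibs
  if (is.null(names(heights))) names(heights) <- sibs
  h <- heights[sibs]
  if (sum(!is.na(h)) < 4) {
    warning("fewer than 4 phenotyped siblings; family skipped")
    return(NULL)
  }
  set.seed(seed)
  s_n <- length(h)
  H <- matrix(0, s_n, n_perm + 1)
  H[, 1] <- h
  for (r in seq_len(n_perm)) H[, r + 1] <- h[sample.int(s_n)]
  Hs <- scale(H)
  Hs[, is.na(colSums(Hs))] <- 0          # constant heights -> zero correlation

  n_pos <- nrow(grid)
  r2_real <- matrix(NA_real_, n_pos, 2)
  p_real <- matrix(1, n_pos, 2)
  p_perm <- array(1, dim = c(n_perm, n_pos, 2))

  for (cn in names(vectors$chroms)) {
    sel <- which(grid$chrom == as.integer(cn))
    if (!length(sel)) next
    lab <- labels_at(vectors, as.integer(cn), grid$pos[sel])
    for (par in 1:2) {
      G <- (if (par == 1) lab$mat else lab$pat)
      G <- (G == min(G)) * 1                 # indicator of the lower label
      Gs <- scale(G)                          # columns: positions
      inf <- !is.na(colSums(Gs))
      if (any(inf)) {
        R <- crossprod(Hs, Gs[, inf, drop = FALSE]) / (s_n - 1)
        R2 <- R^2
        r2_real[sel[inf], par] <- R2[1, ]
        # local P: fraction of permuted replicates with R^2 >= the value
        pp <- apply(R2, 2, function(v) {
          perm <- v[-1]
          # each replicate is scored against the other replicates (leaving
          # itself out), exactly as the real scan is scored against all of
          # them: real and permuted local P are then exchangeable and a
          # local P of zero is representable on both sides
          c(mean(perm >= v[1]),
            (n_perm - rank(perm, ties.method = "min")) / n_perm)
        })
        p_real[sel[inf], par] <- pp[1, ]
        p_perm[, sel[inf], par] <- pp[-1, , drop = FALSE]
      }
    }
  }
  structure(
    list(local_p = pmin(p_real[, 1], p_real[, 2]),
         perm_local_p = pmin(p_perm[, , 1], p_perm[, , 2]),
         r2 = r2_real, n_perm = n_perm, grid = grid),
    class = "family_scan"
  )
}

#' Combine family scans and calibrate genome-wide significance
#'
#' The cross-family score at each position is the mean of the per-family
#' local P values; the same combination is applied to every permutation
#' replicate (replicate r of the cohort combines replicate r of each
#' family).  The genome-wide empirical P of a score x is the fraction of
#' (replicate, position) pairs in the permuted scans with score <= x, and is
#' transformed to a LOD score via the one-sided chi-square(1) quantile (see
#' [p_to_lod()]).
#'
#' @param scans list of `family_scan` objects (NULL entries dropped).
#' @return object of class `linkage_scan`: `grid`, `score`, `gw_p`, `lod`,
#'   `perm_lod` (replicate x position), `perm_score`, `n_perm`.
#' @export
combine_and_calibrate <- function(scans) {
  scans <- Filter(Negate(is.null), scans)
  if (length(scans) < 2) stop("need at least 2 families")
  n_perm <- scans[[1]]$n_perm
  grid <- scans[[1]]$grid
  score <- Reduce(`+`, lapply(scans, `[[`, "local_p")) / length(scans)
  perm_score <- Reduce(`+`, lapply(scans, `[[`, "perm_local_p")) / length(scans)

  pool <- sort(as.vector(perm_score))
  n_pool <- length(pool)
  gw_p <- findInterval(score, pool) / n_pool
  perm_gw <- matrix(findInterval(perm_score, pool) / n_pool,
                    nrow = n_perm)
  floor_p <- 0.5 / n_pool                  # smallest resolvable P
  lod <- p_to_lod(pmax(gw_p, floor_p))
  perm_lod <- matrix(p_to_lod(pmax(perm_gw, floor_p)), nrow = n_perm)
  structure(
    list(grid = grid, score = score, gw_p = gw_p, lod = lod,
         perm_score = perm_score, perm_lod = perm_lod,
         n_perm = n_perm, n_pos = nrow(grid), n_families = length(scans)),
    class = "linkage_scan"
  )
}

#' Convert a genome-wide empirical P value to a LOD score
#'
#' One-sided linkage convention: for p < 0.5 the LOD is the upper-tail
#' chi-square(1 df) quantile of 2p divided by 2 ln 10; p >= 0.5 maps to 0.
#' Under this convention LOD 3.6 corresponds to p ~ 2e-5, the classical
#' genome-wide significance threshold for sibling-pair linkage.
#'
#' @param p P value(s) in `[0, 1]`.
#' @return LOD score(s) >= 0.
#' @seealso [lod_alpha()], its inverse.
#' @export
p_to_lod <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  out <- rep(0, length(p))
  low <- !is.na(p) & p < 0.5
  out[low] <- stats::qchisq(2 * p[low], df = 1, lower.tail = FALSE) / (2 * log(10))
  out[is.na(p)] <- NA_real_
  out
}

#' Call QTLs from a LOD track
#'
#' Local maxima above the detection threshold are merged when closer than
#' `merge_distance` (linkage signals bleed over tens of megabases); the
#' confidence interval of each QTL runs between the furthest positions from
#' the peak that stay above a 1-LOD drop, truncated at +/- `merge_distance`.
#'
#' @param scan `linkage_scan`, or a list with `grid` and `lod`.
#' @param threshold LOD detection threshold.
#' @param merge_distance bp; peaks closer than this are one QTL.
#' @param lod optional explicit LOD vector overriding `scan$lod`.
#' @return data.frame of class `qtl_table`: `chrom`, `peak_pos`, `peak_lod`,
#'   `start`, `end`, `n_merged`.  Zero rows when nothing exceeds the
#'   threshold.
#' @export
call_qtls <- function(scan, threshold, merge_distance = 33e6, lod = NULL) {
  if (is.null(lod)) lod <- scan$lod
  grid <- scan$grid
  out <- list()
  for (c in unique(grid$chrom)) {
    sel <- which(grid$chrom == c)
    lv <- lod[sel]; pv <- grid$pos[sel]
    above <- !is.na(lv) & lv >= threshold
    if (!any(above)) next
    # candidate peaks are the local maxima of the whole track (plateaus
    # contribute their first position); the threshold only filters them, so
    # the candidate set can only grow as the threshold drops
    n <- length(lv)
    lv0 <- ifelse(is.na(lv), -Inf, lv)
    left_ok <- c(TRUE, lv0[-1] > lv0[-n])
    right_ok <- c(lv0[-n] >= lv0[-1], TRUE)
    is_peak <- left_ok & right_ok & above
    if (!any(is_peak)) next
    peaks <- data.frame(pos = pv[is_peak], lod = lv[is_peak])
    # greedy exclusion merge: highest peak first, peaks within
    # merge_distance of a chosen peak belong to it.  (Chain-merging instead
    # can fuse two previously distinct QTLs when a lower threshold adds a
    # bridging peak, making counts non-monotone across a threshold sweep.)
    ord <- order(-peaks$lod, peaks$pos)
    chosen <- integer(0)
    for (i in ord) {
      if (!length(chosen) ||
          all(abs(peaks$pos[chosen] - peaks$pos[i]) >= merge_distance)) {
        chosen <- c(chosen, i)
      }
    }
    for (i in sort(chosen)) {
      top <- peaks[i, ]
      n_mem <- sum(abs(peaks$pos - top$pos) < merge_distance)
      win <- pv >= top$pos - merge_distance & pv <= top$pos + merge_distance
      drop1 <- win & !is.na(lv) & lv > top$lod - 1
      out[[length(out) + 1]] <- data.frame(
        chrom = c, peak_pos = top$pos, peak_lod = top$lod,
        start = min(pv[drop1]), end = max(pv[drop1]), n_merged = n_mem)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = integer(0), peak_pos = numeric(0), peak_lod = numeric(0),
               start = numeric(0), end = numeric(0), n_merged = integer(0))
  class(res) <- c("qtl_table", "data.frame")
  res
}

#' Distance at which linkage signals decorrelate
#'
#' Mean absolute LOD difference between position pairs, binned by genomic
#' distance and averaged over chromosomes.  Nearby positions have similar
#' LOD scores (linkage); the curve rises with distance until it reaches the
#' level it fluctuates around — its median — at the separation distance
#' beyond which two peaks can be treated as independent QTLs.
#'
#' @param scan `linkage_scan`.
#' @param bin_width bp; default twice the grid step.
#' @param max_pairs cap on position pairs per chromosome (subsampled beyond,
#'   deterministically from `seed`).
#' @param seed seed for the subsampling.
#' @return list: `distance` (bp at which the curve first reaches its median
#'   level), `curve` (data.frame `dist`, `mean_abs_dlod`), `median_level`.
#'   Degenerate flat tracks return the maximum distance with a warning.
#' @export
estimate_qtl_separation <- function(scan, bin_width = NULL, max_pairs = 2e5,
                                    seed = 1) {
  grid <- scan$grid; lod <- scan$lod
  chroms <- unique(grid$chrom)
  if (length(chroms) < 2) stop("need at least 2 chromosomes")
  step <- min(diff(sort(unique(grid$pos[grid$chrom == chroms[1]]))))
  if (is.null(bin_width)) bin_width <- 2 * step
  set.seed(seed)
  acc <- list()
  for (c in chroms) {
    sel <- which(grid$chrom == c)
    n <- length(sel)
    if (n < 2) next
    npair <- n * (n - 1) / 2
    if (npair > max_pairs) {
      i <- sample.int(n, size = ceiling(sqrt(2 * max_pairs)))
      sel <- sel[sort(i)]
      n <- length(sel)
    }
    pv <- grid$pos[sel]; lv <- lod[sel]
    dmat <- abs(outer(pv, pv, "-"))[upper.tri(diag(n))]
    ldif <- abs(outer(lv, lv, "-"))[upper.tri(diag(n))]
    acc[[length(acc) + 1]] <- data.frame(chrom = c, dist = dmat, dlod = ldif)
  }
  dd <- do.call(rbind, acc)
  dd$bin <- floor(dd$dist / bin_width)
  # average within chromosome, then across chromosomes at each distance bin
  perc <- stats::aggregate(dlod ~ bin + chrom, data = dd, FUN = mean)
  curve <- stats::aggregate(dlod ~ bin, data = perc, FUN = mean)
  curve <- curve[order(curve$bin), ]
  curve$dist <- (curve$bin + 0.5) * bin_width
  med <- stats::median(curve$dlod)
  if (all(curve$dlod < 1e-12)) {
    warning("flat LOD track: no decorrelation distance; returning maximum")
    return(list(distance = max(curve$dist), curve = curve[, c("dist", "dlod")],
                median_level = med))
  }
  hit <- which(curve$dlod >= med)
  list(distance = curve$dist[hit[1]],
       curve = curve[, c("dist", "dlod")],
       median_level = med)
}

#' Threshold-sweep FDR analysis of QTL counts
#'
#' For each LOD threshold, the observed number of QTLs is compared with the
#' number called, by the identical procedure, in each permutation replicate
#' of the cohort.  The empirical P value of the count is the fraction of
#' permutations yielding an equal or larger number of QTLs; the FDR is the
#' ratio of the permutation-average count (QTLs expected by chance) to the
#' observed count; the estimated number of true QTLs is their difference.
#'
#' @param scan `linkage_scan` (carries the permutation LOD tracks).
#' @param thresholds LOD thresholds, default 3.6 down to 1.0 in steps of 0.1.
#' @param merge_distance passed to [call_qtls()].
#' @return data.frame of class `fdr_curve`: `threshold`, `observed`,
#'   `expected`, `p_value`, `fdr` (capped at 1; `NA` when nothing observed),
#'   `estimated_true`.
#' @export
fdr_sweep <- function(scan, thresholds = seq(3.6, 1.0, by = -0.1),
                      merge_distance = 33e6) {
  n_perm <- scan$n_perm
  counts_perm <- matrix(0L, n_perm, length(thresholds))
  for (r in seq_len(n_perm)) {
    lv <- scan$perm_lod[r, ]
    for (t in seq_along(thresholds)) {
      counts_perm[r, t] <- nrow(call_qtls(scan, thresholds[t],
                                          merge_distance, lod = lv))
    }
  }
  observed <- vapply(thresholds, function(th) {
    nrow(call_qtls(scan, th, merge_distance))
  }, numeric(1))
  expected <- colMeans(counts_perm)
  p_value <- vapply(seq_along(thresholds), function(t) {
    mean(counts_perm[, t] >= observed[t])
  }, numeric(1))
  fdr <- ifelse(observed > 0, pmin(expected / observed, 1), NA_real_)
  out <- data.frame(threshold = thresholds, observed = observed,
                    expected = expected, p_value = p_value, fdr = fdr,
                    estimated_true = observed - expected)
  class(out) <- c("fdr_curve", "data.frame")
  out
}

#' Run the full linkage scan for a cohort
#'
#' Convenience wrapper: per-family permutation scans (one seed substream per
#' family derived from `seed`) combined and calibrated genome-wide.
#'
#' @param vectors_list list of `inheritance_vectors`, one per family.
#' @param heights named numeric of corrected z-scores covering all siblings.
#' @param map `genetic_map`.
#' @param grid_step grid spacing (bp).
#' @param n_perm permutations per family.
#' @param seed integer root seed.
#' @return `linkage_scan`.
#' @export
cohort_scan <- function(vectors_list, heights, map, grid_step = 5000,
                        n_perm = 1000, seed) {
  if (missing(seed)) stop("'seed' is required")
  grid <- scan_grid(map, grid_step)
  scans <- lapply(seq_along(vectors_list), function(k) {
    family_scan(vectors_list[[k]], heights, grid, n_perm,
                seed = (seed + 7919L * k) %% .Machine$integer.max)
  })
  combine_and_calibrate(scans)
}
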