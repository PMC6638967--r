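# IBD reconstruction in large sibships from dense SNP genotypes, without
# parental genotypes.
#
# The chain is: per-SNP evidence classes for each sibling pair ->
# run-anchored pairwise 0/1/2 segment calls -> family-wide reconciliation of
# all C(S,2) pairwise tracks into two per-parent sibling bipartitions per
# segment (the fully informative inheritance pattern) -> inheritance vectors
# with localized recombination events.

#' Run-length parameters for pairwise IBD calling
#'
#' A region is only declared on the strength of a run of at least `min_run`
#' evidence sites of the same class, spanning at most the class-specific
#' window: opposite-homozygote evidence is sparse, so its window (2 Mb) is
#' twice that of the other classes (1 Mb).  The run requirement suppresses
#' isolated genotyping errors.
#'
#' @param min_run minimum evidence sites per qualifying run.
#' @param span0,span1,span2 maximum first-to-last span (bp) of a qualifying
#'   run for 0-, 1- and 2-shared evidence.
#' @param noise_tol tolerated fraction of contradicting (0/1-class) sites
#'   inside a region declared as 2 alleles shared.
#' @param pure_break number of consecutive contradiction-free identical-call
#'   sites that breaks a 1-shared evidence chain and qualifies the gap as a
#'   2-shared region: under 1 allele shared roughly half the informative
#'   sites are het-vs-hom, so a pure identical stretch of length k has
#'   probability ~0.5^k and 10 sites give a per-site false-break rate below
#'   1e-3 while keeping short 2-shared segments detectable.
#' @param cluster_sites breakpoint-cluster tolerance for family
#'   reconciliation, in units of the median informative-site spacing.
#' @param bidirectional reconcile with forward and backward continuity
#'   walks stitched by dynamic programming (resolves locally unidentifiable
#'   stretches); turning it off halves reconciliation time.
#' @param refine_span half-width (bp) of the window searched when a family
#'   recombination breakpoint is re-localized from site-level evidence;
#'   defaults to `span0`.
#' @return list of class `run_params`.
#' @export
run_params <- function(min_run = 3L, span0 = 2e6, span1 = 1e6, span2 = 1e6,
                       noise_tol = 0.05, pure_break = 10L, cluster_sites = 6,
                       bidirectional = TRUE, refine_span = NULL) {
  stopifnot(min_run >= 1, span0 > 0, span1 > 0, span2 > 0, pure_break >= 1)
  structure(list(min_run = as.integer(min_run), span0 = span0, span1 = span1,
                 span2 = span2, noise_tol = noise_tol,
                 pure_break = as.integer(pure_break),
                 cluster_sites = cluster_sites,
                 bidirectional = bidirectional,
                 refine_span = if (is.null(refine_span)) span0 else refine_span),
            class = "run_params")
}

#' Informative SNPs within one family
#'
#' A SNP is uninformative for IBD inference in a family when every sibling
#' carries the same homozygous genotype; such sites can never distinguish
#' inheritance patterns and are excluded.  (Low-quality and missing calls are
#' additionally excluded per sibling pair downstream.)
#'
#' @param geno `famlink_geno`.
#' @param ped pedigree.
#' @param fid family id.
#' @return named logical vector over SNPs: `TRUE` = retained.
#' @export
informative_sites <- function(geno, ped, fid) {
  sibs <- family_sibs(ped, fid)
  if (length(sibs) < 2) stop("family must have at least 2 genotyped siblings")
  if (!all(sibs %in% rownames(geno$dosage))) stop("family absent from genotypes")
  d <- geno$dosage[sibs, , drop = FALSE]
  mn <- apply(d, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_integer_)
    if (all(x == x[1])) x[1] else -1L
  })
  keep <- is.na(mn) | mn == 1L | mn == -1L
  keep[is.na(mn)] <- FALSE       # all-missing sites carry no information
  stats::setNames(keep, colnames(geno$dosage))
}

#' Classify per-SNP evidence for a sibling pair
#'
#' Opposite homozygotes (0 vs 2) imply 0 alleles shared; one heterozygous and
#' one homozygous call implies at most 1; identical calls are consistent with
#' 2.  Flagged (low-quality) and missing calls are excluded (`NA`).
#'
#' @param g1,g2 integer dosage vectors (0/1/2, `NA` = no call).
#' @param excl1,excl2 optional logical vectors of calls to exclude.
#' @return integer vector: 0, 1, 2 or `NA` (excluded).
#' @export
classify_pair_sites <- function(g1, g2, excl1 = NULL, excl2 = NULL) {
  stopifnot(length(g1) == length(g2))
  ok1 <- is.na(g1) | g1 %in% 0:2; ok2 <- is.na(g2) | g2 %in% 0:2
  if (!all(ok1) || !all(ok2)) stop("dosages must be 0, 1, 2 or NA")
  cl <- ifelse(g1 == g2, 2L, ifelse(abs(g1 - g2) == 2L, 0L, 1L))
  cl[is.na(g1) | is.na(g2)] <- NA_integer_
  if (!is.null(excl1)) cl[excl1] <- NA_integer_
  if (!is.null(excl2)) cl[excl2] <- NA_integer_
  cl
}

# Qualifying runs ("anchors") among the positions of one evidence class:
# every maximal chain of class sites containing at least one min_run-tuple of
# successive class sites spanning <= w.  Returns data.frame(first, last, n,
# egap) where egap is the mean spacing of class sites inside the anchor --
# used as the posterior-mean extension of the anchored region past its last
# evidence site.
.class_anchors <- function(p, w, k, all_pos = NULL, pure_break = Inf) {
  n <- length(p)
  none <- data.frame(first = numeric(0), last = numeric(0),
                     n = integer(0), egap = numeric(0))
  if (n < k) return(none)
  qual_start <- which(p[k:n] - p[seq_len(n - k + 1)] <= w)
  if (!length(qual_start)) return(none)
  mark <- logical(n)
  for (off in 0:(k - 1)) mark[qual_start + off] <- TRUE
  idx <- which(mark)
  gap_bp <- diff(p[idx])
  brk <- gap_bp > w
  if (is.finite(pure_break) && !is.null(all_pos)) {
    # number of intervening informative sites of other classes in each gap
    n_between <- findInterval(p[idx[-1]], all_pos) -
      findInterval(p[idx[-length(idx)]], all_pos) - 1L
    brk <- brk | n_between >= pure_break
  }
  brk <- which(brk)
  starts <- c(1L, brk + 1L); ends <- c(brk, length(idx))
  first <- p[idx[starts]]; last <- p[idx[ends]]
  nn <- ends - starts + 1L
  egap <- ifelse(nn > 1, (last - first) / (nn - 1), w / k)
  data.frame(first = first, last = last, n = nn, egap = egap)
}

# interval helpers: intervals as data.frame(start, end), closed, sorted
.merge_iv <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv$start), ]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  res <- list()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out_e + 1) {
      out_e <- max(out_e, iv$end[i])
    } else {
      res[[length(res) + 1]] <- c(out_s, out_e)
      out_s <- iv$start[i]; out_e <- iv$end[i]
    }
  }
  res[[length(res) + 1]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2])
}

.subtract_iv <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a)
  res <- list()
  for (i in seq_len(nrow(a))) {
    pieces <- data.frame(start = a$start[i], end = a$end[i])
    for (j in seq_len(nrow(b))) {
      nxt <- list()
      for (k in seq_len(nrow(pieces))) {
        s <- pieces$start[k]; e <- pieces$end[k]
        bs <- b$start[j]; be <- b$end[j]
        if (be < s || bs > e) { nxt[[length(nxt) + 1]] <- c(s, e); next }
        if (bs > s) nxt[[length(nxt) + 1]] <- c(s, bs - 1)
        if (be < e) nxt[[length(nxt) + 1]] <- c(be + 1, e)
      }
      pieces <- if (length(nxt)) {
        m <- do.call(rbind, nxt); data.frame(start = m[, 1], end = m[, 2])
      } else data.frame(start = numeric(0), end = numeric(0))
      if (!nrow(pieces)) break
    }
    res[[i]] <- pieces
  }
  do.call(rbind, res)
}

# Pairwise IBD calling on one chromosome.  cl/pos: evidence classes and
# positions (NA classes already removed).  Returns data.frame(start, end,
# state) covering [1, L].
.call_pair_ibd_chrom <- function(cl, pos, L, params, warn = TRUE) {
  empty <- data.frame(start = 1, end = L, state = 2L)
  if (!length(cl)) {
    if (warn) warning("no usable evidence on chromosome; calling 2 alleles shared")
    return(empty)
  }
  k <- params$min_run
  a0 <- .class_anchors(pos[cl == 0L], params$span0, k)
  a1 <- .class_anchors(pos[cl == 1L], params$span1, k,
                       all_pos = pos, pure_break = params$pure_break)
  if (!nrow(a0) && !nrow(a1)) {
    if (warn && any(cl != 2L)) {
      warning("no qualifying run on chromosome; calling 2 alleles shared")
    }
    return(empty)
  }
  ext <- function(a, cap) {
    if (!nrow(a)) return(data.frame(start = numeric(0), end = numeric(0)))
    e <- pmin(a$egap, cap)
    data.frame(start = pmax(1, a$first - e), end = pmin(L, a$last + e))
  }
  s0 <- .merge_iv(ext(a0, params$span0))
  s1 <- .merge_iv(ext(a1, params$span1))
  s1 <- if (nrow(s0)) .subtract_iv(s1, s0) else s1
  s1 <- s1[s1$end - s1$start >= 0, , drop = FALSE]

  assigned <- rbind(
    if (nrow(s0)) cbind(s0, state = 0L) else NULL,
    if (nrow(s1)) cbind(s1, state = 1L) else NULL
  )
  assigned <- assigned[order(assigned$start), ]

  # decide the gaps between assigned intervals: a long evidence-bearing gap
  # essentially free of 0/1-class sites is a region of 2 alleles shared;
  # anything else is boundary slack, split between its neighbours.
  qualifies2 <- function(lo, hi) {
    in_gap <- pos >= lo & pos <= hi
    n_g <- sum(in_gap)
    if (n_g < params$min_run) return(FALSE)
    n01 <- sum(cl[in_gap] != 2L)
    if (n01 > max(0, floor(params$noise_tol * n_g))) return(FALSE)
    hi - lo > params$span2 || n_g >= params$pure_break
  }
  segs <- list()
  push <- function(s, e, st) {
    if (e >= s) segs[[length(segs) + 1]] <<- c(s, e, st)
  }
  # leading gap
  first_s <- assigned$start[1]
  if (first_s > 1) {
    if (qualifies2(1, first_s - 1)) push(1, first_s - 1, 2L)
    else assigned$start[1] <- 1
  }
  for (i in seq_len(nrow(assigned))) {
    if (i > 1) {
      lo <- assigned$end[i - 1] + 1; hi <- assigned$start[i] - 1
      if (hi >= lo) {
        if (qualifies2(lo, hi)) {
          push(lo, hi, 2L)
        } else {
          mid <- floor((lo + hi) / 2)
          segs[[length(segs)]][2] <- mid          # grow previous interval
          assigned$start[i] <- mid + 1
        }
      }
    }
    push(assigned$start[i], assigned$end[i], assigned$state[i])
  }
  last_e <- assigned$end[nrow(assigned)]
  if (last_e < L) {
    if (qualifies2(last_e + 1, L)) push(last_e + 1, L, 2L)
    else segs[[length(segs)]][2] <- L
  }
  m <- do.call(rbind, segs)
  out <- data.frame(start = m[, 1], end = m[, 2], state = as.integer(m[, 3]))
  # merge adjacent equal states
  keep <- c(TRUE, out$state[-1] != out$state[-nrow(out)])
  grp <- cumsum(keep)
  data.frame(start = tapply(out$start, grp, min),
             end = tapply(out$end, grp, max),
             state = out$state[keep], row.names = NULL)
}

#' Call pairwise IBD segments for one sibling pair
#'
#' Partitions the genome into segments where the pair shares 0, 1 or 2
#' alleles IBD, anchored on qualifying evidence runs (see [run_params()]):
#' opposite-homozygote runs declare 0; heterozygote-vs-homozygote runs
#' declare 1 where no 0-evidence overrides them; long stretches of
#' exclusively identical calls are 2.  Anchored regions are extended past
#' their outermost evidence site by the mean within-anchor evidence spacing
#' (the posterior-mean position of the true boundary given that evidence of
#' the class stopped appearing), and residual slack is split midway.
#'
#' @param classes integer evidence classes from [classify_pair_sites()].
#' @param sites data.frame (`chrom`, `pos`) aligned with `classes`.
#' @param map `genetic_map`.
#' @param params `run_params`.
#' @param warn warn on chromosomes with no qualifying run.
#' @return data.frame of class `pair_ibd` (`chrom`, `start`, `end`, `state`),
#'   contiguous and exhaustive per chromosome.
#' @export
call_pair_ibd <- function(classes, sites, map, params = run_params(),
                          warn = TRUE) {
  stopifnot(length(classes) == nrow(sites), all(diff(sites$pos[sites$chrom == sites$chrom[1]]) > 0) || nrow(sites) < 2)
  out <- lapply(seq_len(nrow(map)), function(c) {
    sel <- sites$chrom == map$chrom[c] & !is.na(classes)
    seg <- .call_pair_ibd_chrom(classes[sel], sites$pos[sel],
                                map$length[c], params, warn)
    cbind(chrom = map$chrom[c], seg)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("pair_ibd", "data.frame")
  out
}

# ---- family reconciliation ------------------------------------------------

# site-evidence emission log-probabilities used for breakpoint refinement:
# rows = IBD state 0/1/2, cols = evidence class 0/1/2.  Opposite homozygotes
# are (error aside) impossible under states 1 and 2, het-vs-hom impossible
# under 2; small masses keep single miscalls from dominating.
.EMIT_LOG <- log(matrix(c(0.10, 0.45, 0.45,
                          0.005, 0.4975, 0.4975,
                          0.0025, 0.0075, 0.99), 3, 3, byrow = TRUE))

# cost of a label configuration against observed pair states
.config_cost <- function(mvec, bm, bp, pi, pj) {
  pred <- (bm[pi] == bm[pj]) + (bp[pi] == bp[pj])
  sum(pred != mvec)
}

# per-sibling index into the pair list (which pairs contain sib s, and who
# the other sibling is) -- lets label-flip costs be evaluated incrementally
.pair_index <- function(s_n, pi, pj) {
  lapply(seq_len(s_n), function(s) {
    k <- which(pi == s | pj == s)
    list(k = k, other = pi[k] + pj[k] - s)
  })
}

# local search: single-sib label moves with incremental cost updates
.local_search <- function(mvec, bm, bp, pi, pj, max_sweeps = 25L, idx = NULL) {
  s_n <- length(bm)
  if (is.null(idx)) idx <- .pair_index(s_n, pi, pj)
  pred <- (bm[pi] == bm[pj]) + (bp[pi] == bp[pj])
  cost <- sum(pred != mvec)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (s in seq_len(s_n)) {
      k <- idx[[s]]$k; oth <- idx[[s]]$other
      mk <- mvec[k]; pk <- pred[k]
      mis0 <- sum(pk != mk)
      dm <- 1L - 2L * (bm[s] == bm[oth])     # change in pred if bm[s] flips
      dp <- 1L - 2L * (bp[s] == bp[oth])
      d1 <- sum((pk + dm) != mk) - mis0
      d2 <- sum((pk + dp) != mk) - mis0
      d3 <- sum((pk + dm + dp) != mk) - mis0
      best <- which.min(c(d1, d2, d3))
      dbest <- c(d1, d2, d3)[best]
      if (dbest < 0) {
        if (best == 1L || best == 3L) { pred[k] <- pred[k] + dm; bm[s] <- 1L - bm[s] }
        if (best == 2L || best == 3L) {
          dp <- 1L - 2L * (bp[s] == bp[oth]); pred[k] <- pred[k] + dp
          bp[s] <- 1L - bp[s]
        }
        cost <- cost + dbest
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(bm = bm, bp = bp, cost = cost)
}

#' Fit per-parent sibling bipartitions to a pairwise IBD matrix
#'
#' Finds maternal and paternal bipartitions of the siblings whose implied
#' shared-allele counts (`match_m + match_p`) disagree with the observed
#' pairwise states at as few pairs as possible.  Greedy construction plus
#' single-sibling local search; if a residual cost remains and the sibship is
#' small enough, an exhaustive scan over all `2^(S-1)` maternal bipartitions
#' (with the implied paternal bipartition fitted per candidate) guarantees
#' the minimal-correction solution.
#'
#' @param M symmetric integer matrix of observed pairwise states (diagonal
#'   ignored).
#' @param exhaustive_limit largest sibship for which the exhaustive fallback
#'   runs.
#' @return list: `bm`, `bp` (0/1 vectors, sibling 1 fixed to group 0 where
#'   possible), `cost` (number of pair states the fit overrides).
#' @export
fit_bipartitions <- function(M, exhaustive_limit = 12L, idx = NULL) {
  s_n <- nrow(M)
  pr <- which(upper.tri(M), arr.ind = TRUE)
  pi <- pr[, 1]; pj <- pr[, 2]
  mvec <- M[upper.tri(M)]
  if (is.null(idx)) idx <- .pair_index(s_n, pi, pj)

  bm <- integer(s_n); bp <- integer(s_n)
  for (s in seq_len(s_n)[-1]) {
    best <- NULL; best_c <- Inf
    for (gm in 0:1) for (gp in 0:1) {
      prev <- seq_len(s - 1)
      pred <- (bm[prev] == gm) + (bp[prev] == gp)
      cc <- sum(pred != M[prev, s])
      if (cc < best_c) { best_c <- cc; best <- c(gm, gp) }
    }
    bm[s] <- best[1]; bp[s] <- best[2]
  }
  fit <- .local_search(mvec, bm, bp, pi, pj, idx = idx)

  if (fit$cost > 0 && s_n <= exhaustive_limit) {
    n_bm <- 2^(s_n - 1)
    # all maternal bipartitions at once; rows with an impossible implied
    # paternal residual at >= fit$cost pairs cannot beat the incumbent
    B <- matrix(0L, n_bm, s_n)
    for (b in seq_len(s_n - 1)) {
      B[, b + 1] <- bitwAnd(0:(n_bm - 1), bitwShiftL(1L, b - 1L)) > 0
    }
    mm <- B[, pi, drop = FALSE] == B[, pj, drop = FALSE]
    tgt <- matrix(mvec, n_bm, length(mvec), byrow = TRUE) - mm
    lower <- rowSums(tgt < 0 | tgt > 1)
    ord <- order(lower)
    # the scan stays exhaustive up to 10 siblings (512 maternal
    # bipartitions); beyond that only the best-bounded candidates are tried
    if (n_bm > 512L) ord <- ord[seq_len(256L)]
    for (g in ord) {
      if (lower[g] >= fit$cost) break
      cand_bm <- B[g, ]
      target <- tgt[g, ]
      cand_bp <- integer(s_n)
      for (s in seq_len(s_n)[-1]) {
        prev <- seq_len(s - 1)
        t_s <- target[pj == s]
        same <- sum((cand_bp[prev] == 0) == (t_s == 1))
        cand_bp[s] <- if (same >= length(prev) - same) 0L else 1L
      }
      res <- .local_search(mvec, cand_bm, cand_bp, pi, pj, max_sweeps = 3L,
                           idx = idx)
      if (res$cost < fit$cost) fit <- res
      if (fit$cost == 0) break
    }
  }
  # canonical orientation
  if (fit$bm[1] == 1L) fit$bm <- 1L - fit$bm
  if (fit$bp[1] == 1L) fit$bp <- 1L - fit$bp
  fit
}

# all 8 label-preserving symmetries of a configuration (flip either
# bipartition, swap the parents); used to align a fresh fit with the previous
# segment's labels.
.config_variants <- function(bm, bp) {
  list(
    list(bm = bm, bp = bp), list(bm = 1L - bm, bp = bp),
    list(bm = bm, bp = 1L - bp), list(bm = 1L - bm, bp = 1L - bp),
    list(bm = bp, bp = bm), list(bm = 1L - bp, bp = bm),
    list(bm = bp, bp = 1L - bm), list(bm = 1L - bp, bp = 1L - bm)
  )
}

#' Reconcile all pairwise IBD tracks of one family
#'
#' At every genomic segment the matrix of pairwise shared-allele counts must
#' be realizable as the sum of two match matrices, one per parent, of
#' sibling bipartitions.  Candidate breakpoints are pooled from all pairwise
#' tracks (clustered within a small tolerance); between breakpoints the
#' per-pair majority state is reconciled by [fit_bipartitions()], which
#' applies the minimal number of corrections to the pairwise calls.  Moving
#' along the chromosome, configurations are propagated by preferring the
#' previous labels and single-sibling label changes (one change = one
#' recombination); ties keep the longest-running previous labels.  When
#' site-level `evidence` is supplied, every retained breakpoint is
#' re-localized by maximizing a two-sided evidence likelihood over the
#' flanking window, which concentrates the information of all affected pairs
#' on the crossover interval.
#'
#' @param tracks list of `pair_ibd` tracks, one per sibling pair.
#' @param pairs data.frame (`i`, `j`) indexing siblings for each track.
#' @param n_sibs number of siblings.
#' @param map `genetic_map`.
#' @param params `run_params`.
#' @param evidence optional list (`sites` = data.frame(chrom, pos),
#'   `classes` = site x pair matrix) enabling breakpoint refinement.
#' @return object of class `family_ibd`: per chromosome the segment bounds,
#'   per-sibling maternal (1/2) and paternal (3/4) labels per segment, the
#'   number of corrected pair states and the recombination events.
#' @export
reconcile_family_ibd <- function(tracks, pairs, n_sibs, map,
                                 params = run_params(), evidence = NULL) {
  stopifnot(length(tracks) == nrow(pairs))
  pi <- pairs$i; pj <- pairs$j
  chroms <- vector("list", nrow(map))
  names(chroms) <- as.character(map$chrom)

  for (c in seq_len(nrow(map))) {
    cid <- map$chrom[c]; L <- map$length[c]
    ev_sel <- if (!is.null(evidence)) which(evidence$sites$chrom == cid) else integer(0)
    ev_pos <- if (length(ev_sel)) evidence$sites$pos[ev_sel] else numeric(0)

    # candidate breakpoints: pooled pair-track boundaries, clustered
    bnds <- unlist(lapply(tracks, function(t) {
      s <- t$start[t$chrom == cid]; s[s > 1]
    }))
    tol <- if (length(ev_pos) > 2) {
      # cluster pairwise boundary estimates; too wide merges distinct nearby
      # crossovers, too narrow multiplies slivers (absorbed downstream)
      min(params$span1 / 2, params$cluster_sites * stats::median(diff(ev_pos)))
    } else params$span1 / 2
    bps <- numeric(0)
    if (length(bnds)) {
      bnds <- sort(bnds)
      grp <- cumsum(c(1, diff(bnds) > tol))
      bps <- round(tapply(bnds, grp, mean))
    }
    bounds <- c(1, sort(bps), L + 1)
    n_seg <- length(bounds) - 1

    # per pair, per segment: length-weighted majority state
    M_obs <- matrix(2L, nrow = length(tracks), ncol = n_seg)
    for (k in seq_along(tracks)) {
      t <- tracks[[k]][tracks[[k]]$chrom == cid, ]
      acc <- matrix(0, 3, n_seg)
      for (r in seq_len(nrow(t))) {
        s <- t$start[r]; e <- t$end[r]; st <- t$state[r] + 1L
        i1 <- findInterval(s, bounds); i2 <- findInterval(e, bounds)
        i2 <- min(i2, n_seg)
        if (i1 == i2) {
          acc[st, i1] <- acc[st, i1] + (e - s + 1)
        } else {
          acc[st, i1] <- acc[st, i1] + (bounds[i1 + 1] - s)
          if (i2 > i1 + 1) {
            mid <- (i1 + 1):(i2 - 1)
            acc[st, mid] <- acc[st, mid] + (bounds[mid + 1] - bounds[mid])
          }
          acc[st, i2] <- acc[st, i2] + (e - bounds[i2] + 1)
        }
      }
      M_obs[k, ] <- max.col(t(acc), ties.method = "first") - 1L
    }

    # reconcile segment by segment with temporal continuity: one pass in
    # each direction, then a dynamic-programming stitch that trades
    # overridden pair states against label-change events (a greedy
    # single-direction walk can lock in the wrong branch at segments where
    # the two parental bipartitions coincide and the labels are locally
    # unidentifiable)
    idx <- .pair_index(n_sibs, pi, pj)
    to_mat <- function(v) { M <- matrix(2L, n_sibs, n_sibs); M[cbind(pi, pj)] <- v; M[cbind(pj, pi)] <- v; M }
    step_from <- function(mvec, bm0, bp0) {
      best_bm <- bm0; best_bp <- bp0
      pred0 <- (bm0[pi] == bm0[pj]) + (bp0[pi] == bp0[pj])
      cost0 <- sum(pred0 != mvec)
      best_cost <- cost0
      if (cost0 > 0) {
        best_flip <- NULL
        for (s in seq_len(n_sibs)) {
          k <- idx[[s]]$k; oth <- idx[[s]]$other
          mk <- mvec[k]; pk <- pred0[k]
          mis0 <- sum(pk != mk)
          dm <- 1L - 2L * (bm0[s] == bm0[oth])
          dp <- 1L - 2L * (bp0[s] == bp0[oth])
          d1 <- sum((pk + dm) != mk) - mis0
          d2 <- sum((pk + dp) != mk) - mis0
          if (cost0 + d1 < best_cost) { best_cost <- cost0 + d1; best_flip <- c(s, 1L) }
          if (cost0 + d2 < best_cost) { best_cost <- cost0 + d2; best_flip <- c(s, 2L) }
        }
        if (!is.null(best_flip)) {
          if (best_flip[2] == 1L) best_bm[best_flip[1]] <- 1L - best_bm[best_flip[1]]
          else best_bp[best_flip[1]] <- 1L - best_bp[best_flip[1]]
        }
      }
      if (best_cost > 0) {
        ls <- .local_search(mvec, best_bm, best_bp, pi, pj, idx = idx)
        if (ls$cost < best_cost) {
          best_bm <- ls$bm; best_bp <- ls$bp; best_cost <- ls$cost
        }
      }
      # escalate to a fresh exhaustive fit only when substantial
      # disagreement remains (not mere boundary-sliver noise)
      if (best_cost > max(4L, ceiling(0.08 * length(mvec)))) {
        fresh <- fit_bipartitions(to_mat(mvec), idx = idx)
        if (fresh$cost < best_cost) {
          vars <- .config_variants(fresh$bm, fresh$bp)
          ham <- vapply(vars, function(v) sum(v$bm != bm0) + sum(v$bp != bp0),
                        numeric(1))
          v <- vars[[which.min(ham)]]
          best_bm <- v$bm; best_bp <- v$bp; best_cost <- fresh$cost
        }
      }
      list(bm = best_bm, bp = best_bp, cost = best_cost)
    }
    walk <- function(ord) {
      bm <- matrix(0L, n_sibs, n_seg); bp <- matrix(0L, n_sibs, n_seg)
      f1 <- fit_bipartitions(to_mat(M_obs[, ord[1]]), idx = idx)
      bm[, ord[1]] <- f1$bm; bp[, ord[1]] <- f1$bp
      for (t in seq_along(ord)[-1]) {
        st <- step_from(M_obs[, ord[t]], bm[, ord[t - 1]], bp[, ord[t - 1]])
        bm[, ord[t]] <- st$bm; bp[, ord[t]] <- st$bp
      }
      list(bm = bm, bp = bp)
    }
    fwd <- walk(seq_len(n_seg))
    cfg_bm <- fwd$bm; cfg_bp <- fwd$bp
    corrections <- 0L
    if (n_seg > 1 && isTRUE(params$bidirectional)) {
      bwd <- walk(rev(seq_len(n_seg)))
      # align the backward path's arbitrary label orientation to the forward
      # path before comparing them
      vars_tot <- vapply(1:8, function(v) {
        sum(vapply(seq_len(n_seg), function(t) {
          vv <- .config_variants(bwd$bm[, t], bwd$bp[, t])[[v]]
          sum(vv$bm != fwd$bm[, t]) + sum(vv$bp != fwd$bp[, t])
        }, numeric(1)))
      }, numeric(1))
      vbest <- which.min(vars_tot)
      for (t in seq_len(n_seg)) {
        vv <- .config_variants(bwd$bm[, t], bwd$bp[, t])[[vbest]]
        bwd$bm[, t] <- vv$bm; bwd$bp[, t] <- vv$bp
      }
      # DP stitch: emission = overridden pair states (weighted), transition =
      # label changes (recombination events)
      W <- 2
      cand <- function(t, cs) {
        if (cs == 1) list(bm = fwd$bm[, t], bp = fwd$bp[, t])
        else list(bm = bwd$bm[, t], bp = bwd$bp[, t])
      }
      emis <- matrix(0, 2, n_seg)
      for (t in seq_len(n_seg)) for (cs in 1:2) {
        cc <- cand(t, cs)
        emis[cs, t] <- .config_cost(M_obs[, t], cc$bm, cc$bp, pi, pj)
      }
      dp <- matrix(Inf, 2, n_seg); back <- matrix(1L, 2, n_seg)
      dp[, 1] <- W * emis[, 1]
      for (t in 2:n_seg) for (cs in 1:2) {
        cc <- cand(t, cs)
        for (cp in 1:2) {
          pp <- cand(t - 1, cp)
          trans <- sum(pp$bm != cc$bm) + sum(pp$bp != cc$bp)
          tot <- dp[cp, t - 1] + trans + W * emis[cs, t]
          if (tot < dp[cs, t]) { dp[cs, t] <- tot; back[cs, t] <- cp }
        }
      }
      path <- integer(n_seg)
      path[n_seg] <- which.min(dp[, n_seg])
      for (t in n_seg:2) path[t - 1] <- back[path[t], t]
      for (t in seq_len(n_seg)) {
        cc <- cand(t, path[t])
        cfg_bm[, t] <- cc$bm; cfg_bp[, t] <- cc$bp
        corrections <- corrections + emis[path[t], t]
      }
    } else {
      for (t in seq_len(n_seg)) {
        corrections <- corrections +
          .config_cost(M_obs[, t], cfg_bm[, t], cfg_bp[, t], pi, pj)
      }
    }

    # polish segment configurations against the site-level evidence: the
    # pairwise majority states can smear short segments (e.g. a brief
    # 0-shared stretch seen by a single pair), so each segment's labels are
    # re-scored by the evidence log-likelihood of all pairs at all its
    # sites, with a recombination-prior penalty per extra label change
    if (length(ev_sel) && n_seg > 0) {
      cl_mat <- evidence$classes[ev_sel, , drop = FALSE]
      site_seg <- findInterval(ev_pos, bounds)
      site_seg <- pmin(pmax(site_seg, 1L), n_seg)
      # class counts per pair x class x segment
      n_cnt <- array(0L, dim = c(length(tracks), 3L, n_seg))
      for (cl_v in 0:2) {
        hit <- cl_mat == cl_v
        hit[is.na(hit)] <- FALSE
        rs <- rowsum(hit * 1L, site_seg)      # segments with sites only
        n_cnt[, cl_v + 1L, as.integer(rownames(rs))] <- t(rs)
      }
      seg_ll <- function(t, bm, bp) {
        pred <- (bm[pi] == bm[pj]) + (bp[pi] == bp[pj])
        sum(n_cnt[, , t] * .EMIT_LOG[pred + 1L, ])
      }
      lambda <- 4   # ~ -log prior odds of a crossover per segment boundary
      ham_cfg <- function(t1, t2) {
        sum(cfg_bm[, t1] != cfg_bm[, t2]) + sum(cfg_bp[, t1] != cfg_bp[, t2])
      }
      # only segments with contradicted evidence or a multi-label boundary
      # are candidates for repair; clean single-event segments are left alone
      suspicious <- vapply(seq_len(n_seg), function(t) {
        cc <- .config_cost(M_obs[, t], cfg_bm[, t], cfg_bp[, t], pi, pj)
        if (cc > 0) return(TRUE)
        (t > 1 && ham_cfg(t - 1, t) >= 2) || (t < n_seg && ham_cfg(t, t + 1) >= 2)
      }, logical(1))
      for (sweep in 1:3) {
        improved <- FALSE
        for (t in which(suspicious)) {
          cur_ll <- seg_ll(t, cfg_bm[, t], cfg_bp[, t])
          ev_cur <- (if (t > 1) ham_cfg(t - 1, t) else 0) +
            (if (t < n_seg) ham_cfg(t, t + 1) else 0)
          best_gain <- 0; best_mv <- NULL
          for (s in seq_len(n_sibs)) for (mv in 1:3) {
            nbm <- cfg_bm[, t]; nbp <- cfg_bp[, t]
            if (mv == 1L || mv == 3L) nbm[s] <- 1L - nbm[s]
            if (mv == 2L || mv == 3L) nbp[s] <- 1L - nbp[s]
            ev_new <- (if (t > 1) sum(cfg_bm[, t - 1] != nbm) +
                         sum(cfg_bp[, t - 1] != nbp) else 0) +
              (if (t < n_seg) sum(cfg_bm[, t + 1] != nbm) +
                 sum(cfg_bp[, t + 1] != nbp) else 0)
            gain <- seg_ll(t, nbm, nbp) - cur_ll - lambda * (ev_new - ev_cur)
            if (gain > best_gain + 1e-9) { best_gain <- gain; best_mv <- list(nbm, nbp) }
          }
          if (!is.null(best_mv)) {
            cfg_bm[, t] <- best_mv[[1]]; cfg_bp[, t] <- best_mv[[2]]
            improved <- TRUE
          }
        }
        if (!improved) break
      }
    }

    # drop boundaries with no configuration change
    if (n_seg > 1) {
      changed <- vapply(2:n_seg, function(t) {
        any(cfg_bm[, t] != cfg_bm[, t - 1]) || any(cfg_bp[, t] != cfg_bp[, t - 1])
      }, logical(1))
      keep <- c(TRUE, changed)
      bounds <- c(bounds[c(keep, FALSE)], L + 1)
      cfg_bm <- cfg_bm[, keep, drop = FALSE]
      cfg_bp <- cfg_bp[, keep, drop = FALSE]
      n_seg <- sum(keep)
    }

    # refine retained breakpoints on site-level evidence
    events <- list()
    if (n_seg > 1) {
      for (t in 2:n_seg) {
        bL <- cfg_bm[, t - 1]; bR <- cfg_bm[, t]
        pL <- cfg_bp[, t - 1]; pR <- cfg_bp[, t]
        predL <- (bL[pi] == bL[pj]) + (pL[pi] == pL[pj])
        predR <- (bR[pi] == bR[pj]) + (pR[pi] == pR[pj])
        aff <- which(predL != predR)
        b <- bounds[t]
        left_site <- NA_real_; right_site <- NA_real_
        if (length(ev_sel) && length(aff)) {
          lo <- max(bounds[t - 1], b - params$refine_span)
          hi <- min(bounds[t + 1] - 1, b + params$refine_span)
          win <- which(ev_pos >= lo & ev_pos <= hi)
          if (length(win) >= 2) {
            d <- numeric(length(win))
            for (k in aff) {
              clk <- evidence$classes[ev_sel[win], k]
              ok <- !is.na(clk)
              if (any(ok)) {
                contrib <- .EMIT_LOG[predL[k] + 1L, clk[ok] + 1L] -
                  .EMIT_LOG[predR[k] + 1L, clk[ok] + 1L]
                d[ok] <- d[ok] + contrib
              }
            }
            sc <- c(0, cumsum(d))
            jj <- which.max(sc)
            pw <- ev_pos[win]
            cand <- c((lo + pw[1]) / 2,
                      if (length(pw) > 1) (pw[-length(pw)] + pw[-1]) / 2 else NULL,
                      (pw[length(pw)] + hi) / 2)
            b_new <- round(cand[jj])
            if (b_new > bounds[t - 1] && b_new <= bounds[t + 1] - 1) {
              bounds[t] <- b_new
              b <- b_new
            }
            left_site <- if (jj > 1) pw[jj - 1] else lo
            right_site <- if (jj <= length(pw)) pw[jj] else hi
          }
        }
        flip_m <- which(bL != bR); flip_p <- which(pL != pR)
        nf <- length(flip_m) + length(flip_p)
        if (nf) {
          events[[length(events) + 1]] <- list(
            sib = c(flip_m, flip_p),
            parent = rep(c("mother", "father"), c(length(flip_m), length(flip_p))),
            pos = rep(b, nf), left = rep(left_site, nf),
            right = rep(right_site, nf), multi = rep(nf > 1, nf))
        }
      }
    }
    ev_df <- if (length(events)) {
      data.frame(sib = unlist(lapply(events, `[[`, "sib")),
                 parent = unlist(lapply(events, `[[`, "parent")),
                 chrom = cid,
                 pos = unlist(lapply(events, `[[`, "pos")),
                 left = unlist(lapply(events, `[[`, "left")),
                 right = unlist(lapply(events, `[[`, "right")),
                 multi = unlist(lapply(events, `[[`, "multi")))
    } else {
      data.frame(sib = integer(0), parent = character(0), chrom = integer(0),
                 pos = numeric(0), left = numeric(0), right = numeric(0),
                 multi = logical(0))
    }
    chroms[[c]] <- list(
      bounds = bounds,
      mat = cfg_bm + 1L,
      pat = cfg_bp + 3L,
      corrections = corrections,
      events = ev_df
    )
  }
  structure(list(n_sibs = n_sibs, pairs = pairs, chroms = chroms, map = map,
                 params = params),
            class = "family_ibd")
}

#' Extract inheritance vectors from a reconciled family state
#'
#' Repackages the per-segment bipartitions as grandparental labels per
#' sibling (maternal 1/2, paternal 3/4; label identity is arbitrary per
#' chromosome and parent but consistent along it) together with the list of
#' recombination events, each localized to the interval between the flanking
#' informative sites of its breakpoint.
#'
#' @param state `family_ibd` from [reconcile_family_ibd()].
#' @param sibs optional sibling ids (stored as dimnames).
#' @return object of class `inheritance_vectors`.
#' @export
infer_inheritance_vectors <- function(state, sibs = NULL) {
  chroms <- lapply(state$chroms, function(ch) {
    n_seg <- length(ch$bounds) - 1
    list(segments = data.frame(start = ch$bounds[-length(ch$bounds)],
                               end = ch$bounds[-1] - 1),
         mat = ch$mat, pat = ch$pat, events = ch$events)
  })
  structure(list(n_sibs = state$n_sibs, sibs = sibs, chroms = chroms,
                 map = state$map),
            class = "inheritance_vectors")
}

#' Grandparental labels at arbitrary positions
#'
#' @param vectors `inheritance_vectors`.
#' @param chrom chromosome id.
#' @param pos positions (bp).
#' @return list of two matrices (`mat`, `pat`), siblings x positions.
#' @export
labels_at <- function(vectors, chrom, pos) {
  ch <- vectors$chroms[[as.character(chrom)]]
  bounds <- c(ch$segments$start, ch$segments$end[nrow(ch$segments)] + 1)
  seg <- findInterval(pos, bounds)
  seg <- pmin(pmax(seg, 1L), nrow(ch$segments))
  list(mat = ch$mat[, seg, drop = FALSE], pat = ch$pat[, seg, drop = FALSE])
}

#' Pairwise IBD tracks implied by inheritance vectors
#'
#' @param vectors `inheritance_vectors`.
#' @return list of `pair_ibd` tracks with a `pairs` attribute, consistent by
#'   construction with the family state.
#' @export
family_pair_tracks <- function(vectors) {
  s_n <- vectors$n_sibs
  pr <- utils::combn(s_n, 2)
  out <- vector("list", ncol(pr))
  for (k in seq_len(ncol(pr))) {
    i <- pr[1, k]; j <- pr[2, k]
    rows <- lapply(names(vectors$chroms), function(cn) {
      ch <- vectors$chroms[[cn]]
      sh <- (ch$mat[i, ] == ch$mat[j, ]) + (ch$pat[i, ] == ch$pat[j, ])
      keep <- c(TRUE, sh[-1] != sh[-length(sh)])
      grp <- cumsum(keep)
      data.frame(chrom = as.integer(cn),
                 start = tapply(ch$segments$start, grp, min),
                 end = tapply(ch$segments$end, grp, max),
                 state = as.integer(sh[keep]), row.names = NULL)
    })
    t <- do.call(rbind, rows)
    class(t) <- c("pair_ibd", "data.frame")
    out[[k]] <- t
  }
  attr(out, "pairs") <- data.frame(i = pr[1, ], j = pr[2, ])
  out
}

#' Genome fractions shared 0/1/2 alleles IBD
#'
#' Length-weighted average over a list of pairwise IBD tracks.  For full
#' siblings the theoretical expectation is 25% / 50% / 25%.
#'
#' @param tracks list of `pair_ibd` tracks (or a single track).
#' @return named numeric: fractions at 0, 1, 2 alleles shared (sums to 1).
#' @export
ibd_sharing_summary <- function(tracks) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  len <- c(`0` = 0, `1` = 0, `2` = 0)
  for (t in tracks) {
    w <- t$end - t$start + 1
    for (s in 0:2) len[s + 1] <- len[s + 1] + sum(w[t$state == s])
  }
  len / sum(len)
}

#' Check realizability of a pairwise-state matrix
#'
#' @param M symmetric pairwise shared-allele matrix.
#' @return `TRUE` iff `M` decomposes exactly into two bipartition match
#'   matrices.
#' @export
is_realizable_state <- function(M) {
  fit_bipartitions(M)$cost == 0
}

#' Full IBD reconstruction for one family
#'
#' Convenience wrapper running the whole chain: informative-site selection,
#' per-pair evidence classification, pairwise segment calling, family
#' reconciliation and inheritance-vector extraction.
#'
#' @param geno `famlink_geno`.
#' @param ped pedigree.
#' @param fid family id.
#' @param map `genetic_map`.
#' @param params `run_params`.
#' @param refine re-localize breakpoints on site evidence.
#' @return list: `sibs`, `sites`, `pairs`, `tracks`, `state`, `vectors`.
#' @export
reconstruct_family_ibd <- function(geno, ped, fid, map, params = run_params(),
                                   refine = TRUE) {
  sibs <- family_sibs(ped, fid)
  info <- informative_sites(geno, ped, fid)
  sites <- geno$snps[info, c("chrom", "pos")]
  snp_sel <- which(info)
  s_n <- length(sibs)
  pr <- utils::combn(s_n, 2)
  pairs <- data.frame(i = pr[1, ], j = pr[2, ])
  classes <- matrix(NA_integer_, nrow(sites), ncol(pr))
  tracks <- vector("list", ncol(pr))
  d <- geno$dosage[sibs, snp_sel, drop = FALSE]
  lq <- geno$lowq[sibs, snp_sel, drop = FALSE]
  for (k in seq_len(ncol(pr))) {
    i <- pr[1, k]; j <- pr[2, k]
    classes[, k] <- classify_pair_sites(d[i, ], d[j, ], lq[i, ], lq[j, ])
    tracks[[k]] <- call_pair_ibd(classes[, k], sites, map, params, warn = FALSE)
  }
  evidence <- list(sites = sites, classes = classes)
  state <- reconcile_family_ibd(tracks, pairs, s_n, map, params,
                                evidence = if (refine) evidence else NULL)
  vectors <- infer_inheritance_vectors(state, sibs = sibs)
  list(sibs = sibs, sites = sites, pairs = pairs, tracks = tracks,
       state = state, vectors = vectors)
}

#' Agreement between inferred and true inheritance vectors
#'
#' Compares labels at every SNP, allowing the arbitrary per-chromosome
#' relabelings that the data cannot determine: the flip of the two
#' grandparental haplotypes within each parent, and (when no parental
#' genotypes anchor them) the swap of the two parents.
#'
#' @param vectors `inheritance_vectors` (with `sibs` set).
#' @param truth `famlink_truth`.
#' @param fid family id.
#' @param snps SNP map (`snp`, `chrom`, `pos`).
#' @return overall fraction of (sibling, SNP) labels recovered, length-
#'   weighted across chromosomes.
#' @export
ibd_truth_agreement <- function(vectors, truth, fid, snps) {
  fam <- truth$families[[fid]]
  sibs <- vectors$sibs
  tot <- 0; hit <- 0
  for (cn in names(vectors$chroms)) {
    sel <- snps$chrom == as.integer(cn)
    if (!any(sel)) next
    lab <- labels_at(vectors, as.integer(cn), snps$pos[sel])
    tm <- fam$mat[sibs, sel, drop = FALSE]
    tp <- fam$pat[sibs, sel, drop = FALSE]
    side_hits <- function(est, tr) {
      # est and tr on a common 1/2 scale; best of the two global flips
      max(sum(est == tr), sum((3L - est) == tr))
    }
    m12 <- lab$mat; p12 <- lab$pat - 2L     # inferred, as 1/2
    straight <- side_hits(m12, tm) + side_hits(p12, tp - 2L)
    swapped <- side_hits(p12, tm) + side_hits(m12, tp - 2L)
    hit <- hit + max(straight, swapped)
    tot <- tot + length(tm) + length(tp)
  }
  hit / tot
}
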