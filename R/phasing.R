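# Haplotype phasing: resolve the four parental haplotypes of each family
# from the reconstructed inheritance vectors, sibling genotypes, parental
# genotypes where available, and finally a reference panel of already-phased
# study haplotypes.

# enumeration of the 16 possible allele assignments of the four parental
# haplotypes at one site: rows = assignments, cols = haplotypes 1..4
.HAP_ASSIGN <- as.matrix(expand.grid(h1 = 0:1, h2 = 0:1, h3 = 0:1, h4 = 0:1))

# majority consensus dosage of a group of siblings at each site; ties -> NA
.group_consensus <- function(d, lq) {
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  if (is.null(dim(lq))) lq <- matrix(lq, nrow = 1)
  d[lq] <- NA_integer_
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  counts <- rbind(n0, n1, n2)
  tot <- colSums(counts)
  best <- max.col(t(counts), ties.method = "first") - 1L
  top <- counts[cbind(best + 1L, seq_along(best))]
  tie <- colSums(counts == rep(top, each = 3)) > 1L
  out <- ifelse(tot == 0L | tie, NA_integer_, best)
  as.integer(out)
}

# solve haplotype alleles at each site of one segment from group-consensus
# equations: dosage(group carrying haps a,b) = x_a + x_b.  cons: site x
# equation matrix of consensus dosages (NA = no equation), hap_pairs: 2 x
# n_equation matrix of haplotype indices.  Returns list(hap = site x 4
# matrix with NA where unresolved, contradiction = logical per site).
.solve_sites <- function(cons, hap_pairs) {
  n_site <- nrow(cons)
  n_eq <- ncol(cons)
  consistent <- matrix(TRUE, n_site, 16L)
  for (g in seq_len(n_eq)) {
    pred <- .HAP_ASSIGN[, hap_pairs[1, g]] + .HAP_ASSIGN[, hap_pairs[2, g]]
    cg <- cons[, g]
    has <- !is.na(cg)
    if (!any(has)) next
    # site r stays consistent with assignment a unless the observed consensus
    # contradicts the predicted dosage
    bad <- outer(cg[has], pred, FUN = "!=")
    consistent[has, ] <- consistent[has, , drop = FALSE] & !bad
  }
  ncons <- rowSums(consistent)
  ones <- consistent %*% .HAP_ASSIGN          # consistent assignments with x_h = 1
  hap <- matrix(NA_integer_, n_site, 4L)
  for (h in 1:4) {
    hap[ones[, h] == 0L & ncons > 0L, h] <- 0L
    hap[ones[, h] == ncons & ncons > 0L, h] <- 1L
  }
  list(hap = hap, contradiction = ncons == 0L)
}

#' Phase one family into its four parental haplotypes
#'
#' At every SNP the siblings fall into up to four grandparental groups, each
#' carrying a known pair of parental haplotypes.  A homozygous group fixes
#' both of its haplotypes; heterozygous groups constrain the sum of theirs,
#' and information propagates through groups sharing one haplotype.  All of
#' this is the unique solution set of the per-site linear system
#' `dosage(group) = x_a + x_b` over binary alleles, which is what is solved
#' here (by enumeration of the 16 assignments).  When parental genotypes are
#' available, each parent is matched to the haplotype pair with which its
#' genotypes are compatible on already-solved sites (mismatch < `parent_tol`)
#' and then contributes its own equation.  Contradictory sites are left
#' unresolved and counted.
#'
#' @param geno `famlink_geno` (observed, possibly noisy).
#' @param vectors `inheritance_vectors` of the family (with `sibs`).
#' @param ped pedigree.
#' @param fid family id.
#' @param use_parents use parental genotypes where present.
#' @param parent_tol maximum genotype-incompatibility rate for accepting a
#'   parent-to-haplotype-pair match on a chromosome.
#' @return object of class `phased_family`: per chromosome the SNP column
#'   indices, the 4 x SNP haplotype matrix (0/1/NA), inferred sibling
#'   genotypes, and counters (contradictions, unresolved).
#' @export
phase_family <- function(geno, vectors, ped, fid, use_parents = TRUE,
                         parent_tol = 0.01) {
  sibs <- vectors$sibs
  snps <- geno$snps
  frec <- ped[ped$fid == fid, ]
  par_ids <- frec$iid[frec$role == "parent" & frec$genotyped]
  par_ids <- intersect(par_ids, rownames(geno$dosage))

  chroms <- list()
  n_contra <- 0L; n_unres <- 0L; n_sites <- 0L
  parent_assign <- list()

  for (cn in names(vectors$chroms)) {
    cid <- as.integer(cn)
    sel <- which(snps$chrom == cid)
    if (!length(sel)) next
    pos <- snps$pos[sel]
    d <- geno$dosage[sibs, sel, drop = FALSE]
    lq <- geno$lowq[sibs, sel, drop = FALSE]
    ch <- vectors$chroms[[cn]]
    segv <- findInterval(pos, c(ch$segments$start, utils::tail(ch$segments$end, 1) + 1))
    segv <- pmin(pmax(segv, 1L), nrow(ch$segments))

    hap <- matrix(NA_integer_, 4L, length(sel))
    contra <- logical(length(sel))

    solve_chrom <- function(parent_rows = NULL) {
      for (s in unique(segv)) {
        js <- which(segv == s)
        grp_key <- paste(ch$mat[, s], ch$pat[, s])
        groups <- split(seq_along(sibs), grp_key)
        cons <- NULL; hp <- NULL
        for (g in groups) {
          cons <- cbind(cons, .group_consensus(d[g, js, drop = FALSE],
                                               lq[g, js, drop = FALSE]))
          key <- strsplit(names(groups)[match(list(g), groups)], " ")[[1]]
          hp <- cbind(hp, c(as.integer(key[1]), as.integer(key[2])))
        }
        if (!is.null(parent_rows)) {
          for (pr in parent_rows) {
            cons <- cbind(cons, pr$dos[js])
            hp <- cbind(hp, pr$haps)
          }
        }
        res <- .solve_sites(cons, hp)
        hap[, js] <<- t(res$hap)
        contra[js] <<- res$contradiction
      }
    }
    solve_chrom()

    # match parents to haplotype pairs on solved sites, then re-solve
    parent_rows <- NULL
    if (use_parents && length(par_ids)) {
      d12 <- hap[1, ] + hap[2, ]
      d34 <- hap[3, ] + hap[4, ]
      mm <- function(p_dos, pred) {
        ok <- !is.na(p_dos) & !is.na(pred)
        if (sum(ok) < 10) return(1)
        mean(p_dos[ok] != pred[ok])
      }
      pdos <- lapply(par_ids, function(p) {
        x <- geno$dosage[p, sel]
        x[geno$lowq[p, sel]] <- NA_integer_
        x
      })
      names(pdos) <- par_ids
      if (length(par_ids) == 2) {
        a <- par_ids[1]; b <- par_ids[2]
        c1 <- mm(pdos[[a]], d12) + mm(pdos[[b]], d34)
        c2 <- mm(pdos[[a]], d34) + mm(pdos[[b]], d12)
        assign <- if (c1 <= c2) list(c(a, "12"), c(b, "34")) else
          list(c(a, "34"), c(b, "12"))
      } else {
        a <- par_ids[1]
        assign <- if (mm(pdos[[a]], d12) <= mm(pdos[[a]], d34)) {
          list(c(a, "12"))
        } else list(c(a, "34"))
      }
      parent_rows <- list()
      for (as_ in assign) {
        p <- as_[1]; pair <- as_[2]
        pred <- if (pair == "12") d12 else d34
        rate <- mm(pdos[[p]], pred)
        parent_assign[[cn]] <- rbind(parent_assign[[cn]],
          data.frame(parent = p, pair = pair, mismatch = rate,
                     used = rate < parent_tol))
        if (rate < parent_tol) {
          parent_rows[[length(parent_rows) + 1]] <- list(
            dos = pdos[[p]],
            haps = if (pair == "12") c(1L, 2L) else c(3L, 4L))
        }
      }
      if (length(parent_rows)) solve_chrom(parent_rows)
    }

    mlab <- ch$mat[, segv, drop = FALSE]    # per sib, per site: hap index 1/2
    plab <- ch$pat[, segv, drop = FALSE]    # 3/4
    inferred <- matrix(NA_integer_, length(sibs), length(sel),
                       dimnames = list(sibs, snps$snp[sel]))
    for (i in seq_along(sibs)) {
      inferred[i, ] <- hap[cbind(mlab[i, ], seq_along(sel))] +
        hap[cbind(plab[i, ], seq_along(sel))]
    }
    n_contra <- n_contra + sum(contra)
    n_unres <- n_unres + sum(is.na(hap))
    n_sites <- n_sites + length(sel)
    chroms[[cn]] <- list(snp_cols = sel, pos = pos, hap = hap,
                         inferred = inferred, segv = segv,
                         mlab = mlab, plab = plab)
  }
  structure(
    list(fid = fid, sibs = sibs, chroms = chroms,
         counts = c(sites = n_sites, contradictions = n_contra,
                    unresolved_hap_sites = n_unres),
         parent_assignment = parent_assign),
    class = "phased_family"
  )
}

#' Fraction of haplotype sites resolved by within-family phasing
#' @param phased `phased_family`.
#' @return fraction in `[0, 1]`.
#' @export
phase_completeness <- function(phased) {
  1 - phased$counts["unresolved_hap_sites"] / (4 * phased$counts["sites"])
}

#' Build a reference panel from already-phased families
#'
#' Stacks the phased parental haplotypes of every family except `exclude_fid`
#' into a haplotype x SNP matrix aligned to the genotype SNP order.
#'
#' @param phased_list list of `phased_family` objects.
#' @param n_snps total number of SNPs in the genotype matrix.
#' @param exclude_fid family to leave out (the one being completed).
#' @return matrix (0/1/NA), rows = panel haplotypes.
#' @export
build_reference_panel <- function(phased_list, n_snps, exclude_fid = NULL) {
  rows <- list()
  for (ph in phased_list) {
    if (!is.null(exclude_fid) && ph$fid == exclude_fid) next
    hm <- matrix(NA_integer_, 4L, n_snps)
    for (ch in ph$chroms) hm[, ch$snp_cols] <- ch$hap
    rownames(hm) <- paste0(ph$fid, "_h", 1:4)
    rows[[length(rows) + 1]] <- hm
  }
  do.call(rbind, rows)
}

#' Complete unresolved haplotype calls from a reference panel
#'
#' For every still-unresolved haplotype allele, panel haplotypes are scored
#' by the number of consecutive solved sites they match on each side of the
#' unknown call; the allele is copied from the longest two-sided match.
#' When equally long matches disagree, the majority over all two-sided
#' matching haplotypes decides; with no usable information the call defaults
#' to the B allele (an array-convention constant) and is counted.
#'
#' @param phased `phased_family`.
#' @param panel matrix from [build_reference_panel()].
#' @param snps SNP map of the genotype matrix.
#' @param max_flank cap on the number of solved sites scanned per side.
#' @param default_allele allele used when the panel is uninformative.
#' @return the completed `phased_family`, with counters
#'   `filled_from_panel`, `filled_by_majority`, `no_information` added.
#' @export
phase_with_reference <- function(phased, panel, snps, max_flank = 100L,
                                 default_allele = 1L) {
  n_fill <- 0L; n_major <- 0L; n_noinfo <- 0L
  for (cn in names(phased$chroms)) {
    ch <- phased$chroms[[cn]]
    pan <- panel[, ch$snp_cols, drop = FALSE]
    for (h in 1:4) {
      hv <- ch$hap[h, ]
      unres <- which(is.na(hv))
      if (!length(unres)) next
      solved <- which(!is.na(hv))
      for (j in unres) {
        lidx <- rev(solved[solved < j]); lidx <- lidx[seq_len(min(length(lidx), max_flank))]
        ridx <- solved[solved > j]; ridx <- ridx[seq_len(min(length(ridx), max_flank))]
        allele <- NA_integer_
        if (length(lidx) && length(ridx)) {
          lm <- pan[, lidx, drop = FALSE] == rep(hv[lidx], each = nrow(pan))
          rm_ <- pan[, ridx, drop = FALSE] == rep(hv[ridx], each = nrow(pan))
          lm[is.na(lm)] <- FALSE; rm_[is.na(rm_)] <- FALSE
          lrun <- rowSums(t(apply(lm, 1, cumprod)))
          rrun <- rowSums(t(apply(rm_, 1, cumprod)))
          cand <- which(lrun > 0 & rrun > 0 & !is.na(pan[, j]))
          if (length(cand)) {
            tot <- lrun[cand] + rrun[cand]
            top <- cand[tot == max(tot)]
            al <- unique(pan[top, j])
            if (length(al) == 1L) {
              allele <- al; n_fill <- n_fill + 1L
            } else {
              votes <- table(pan[cand, j])
              if (length(votes) && max(votes) > min(votes)) {
                allele <- as.integer(names(votes)[which.max(votes)])
                n_major <- n_major + 1L
              }
            }
          }
        }
        if (is.na(allele)) { allele <- default_allele; n_noinfo <- n_noinfo + 1L }
        hv[j] <- allele
      }
      ch$hap[h, ] <- hv
    }
    # refresh inferred sibling genotypes with the completed haplotypes
    for (i in seq_along(phased$sibs)) {
      ch$inferred[i, ] <- ch$hap[cbind(ch$mlab[i, ], seq_len(ncol(ch$hap)))] +
        ch$hap[cbind(ch$plab[i, ], seq_len(ncol(ch$hap)))]
    }
    phased$chroms[[cn]] <- ch
  }
  phased$counts <- c(phased$counts, filled_from_panel = n_fill,
                     filled_by_majority = n_major, no_information = n_noinfo)
  phased
}

#' Quality control of IBD reconstruction and phasing
#'
#' Compares observed genotype calls to the calls inferred back from the
#' phased haplotypes and inheritance vectors.  Reports the overall mismatch
#' rate, the rate restricted to high-quality observed calls (errors should
#' concentrate in low-quality calls), per-sample counts, and blocks of
#' contiguous mismatches that sit next to inferred recombination breakpoints
#' (the signature of a misplaced breakpoint).
#'
#' @param geno observed `famlink_geno`.
#' @param phased `phased_family` (after any reference completion).
#' @param vectors `inheritance_vectors` of the family.
#' @param block_adjacency distance (bp) within which a mismatch block counts
#'   as adjacent to a recombination breakpoint.
#' @param min_block_sites minimum number of mismatching sites in a block.
#' @param gap_sites mismatching sites separated by at most this many
#'   intervening matching sites are clustered into one block (a mislabeled
#'   stretch only mismatches where the two parental haplotypes differ, so
#'   its mismatches are dense but not strictly consecutive).
#' @return list of class `phasing_qc`: `rate_all`, `rate_hq`, `per_sample`,
#'   `blocks`, `n_compared`.
#' @export
phasing_qc <- function(geno, phased, vectors, block_adjacency = 1e6,
                       min_block_sites = 3L, gap_sites = 10L) {
  sibs <- phased$sibs
  mism_all <- 0L; n_all <- 0L; mism_hq <- 0L; n_hq <- 0L
  per_sample <- stats::setNames(integer(length(sibs)), sibs)
  blocks <- list()
  for (cn in names(phased$chroms)) {
    ch <- phased$chroms[[cn]]
    obs <- geno$dosage[sibs, ch$snp_cols, drop = FALSE]
    lq <- geno$lowq[sibs, ch$snp_cols, drop = FALSE]
    inf <- ch$inferred    # genotypes implied by the (completed) haplotypes
    vch <- vectors$chroms[[cn]]
    cmp <- !is.na(obs) & !is.na(inf)
    mm <- cmp & obs != inf
    mism_all <- mism_all + sum(mm); n_all <- n_all + sum(cmp)
    hq <- cmp & !lq
    mism_hq <- mism_hq + sum(mm & hq); n_hq <- n_hq + sum(hq)
    per_sample <- per_sample + rowSums(mm)
    ev <- vch$events
    for (i in seq_along(sibs)) {
      mi <- which(mm[i, ])
      if (!length(mi)) next
      grp <- cumsum(c(1, diff(mi) > gap_sites))
      for (g in unique(grp)) {
        run <- mi[grp == g]
        if (length(run) < min_block_sites) next
        p1 <- ch$pos[run[1]]; p2 <- ch$pos[run[length(run)]]
        evi <- ev[ev$sib == i, , drop = FALSE]
        adj <- nrow(evi) > 0 &&
          any(evi$pos >= p1 - block_adjacency & evi$pos <= p2 + block_adjacency)
        blocks[[length(blocks) + 1]] <- data.frame(
          iid = sibs[i], chrom = as.integer(cn), start = p1, end = p2,
          n_sites = length(run), adjacent_to_breakpoint = adj)
      }
    }
  }
  structure(
    list(rate_all = if (n_all) mism_all / n_all else 0,
         rate_hq = if (n_hq) mism_hq / n_hq else 0,
         per_sample = per_sample,
         blocks = if (length(blocks)) do.call(rbind, blocks) else
           data.frame(iid = character(0), chrom = integer(0), start = numeric(0),
                      end = numeric(0), n_sites = integer(0),
                      adjacent_to_breakpoint = logical(0)),
         n_compared = c(all = n_all, high_quality = n_hq)),
    class = "phasing_qc"
  )
}

#' Inferred genotype matrix across phased families
#'
#' Assembles the genotypes implied by the phased haplotypes and inheritance
#' vectors of every family; these corrected calls are the genotype source
#' for downstream variance partitioning.
#'
#' @param phased_list list of `phased_family`.
#' @param geno observed `famlink_geno` (for dimensions and fallback values).
#' @param fallback_observed use the observed call where the inferred one is
#'   missing.
#' @return `famlink_geno` with inferred dosages (lowq all FALSE).
#' @export
inferred_genotypes <- function(phased_list, geno, fallback_observed = TRUE) {
  out <- geno$dosage
  out[] <- NA_integer_
  for (k in seq_along(phased_list)) {
    ph <- phased_list[[k]]
    for (cn in names(ph$chroms)) {
      ch <- ph$chroms[[cn]]
      out[ph$sibs, ch$snp_cols] <- ch$inferred
    }
  }
  if (fallback_observed) {
    miss <- is.na(out)
    out[miss] <- geno$dosage[miss]
  }
  structure(list(dosage = out,
                 lowq = matrix(FALSE, nrow(out), ncol(out), dimnames = dimnames(out)),
                 snps = geno$snps),
            class = "famlink_geno")
}
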