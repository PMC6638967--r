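# Gamete-level simulation of nuclear families, the height-like phenotype
# model, and array genotyping noise.

#' Simulate genotypes and true inheritance for a pedigree
#'
#' Every parent draws two haplotypes (without replacement) from the founder
#' pool; each transmitted gamete is formed with crossovers placed by a
#' Haldane (no-interference) process: per chromosome, a Poisson number of
#' crossovers with mean equal to the genetic length in Morgans, positions
#' uniform on the physical map (the map's recombination rate is uniform).
#' Child dosages are the sum of the two transmitted alleles at every SNP.
#' The returned truth records, per sibling and SNP, which grandparental
#' haplotype was inherited (maternal label 1/2, paternal 3/4), plus every
#' crossover position — the ground truth the IBD reconstruction must recover.
#'
#' @param ped pedigree from [make_cohort_pedigree()].
#' @param pool founder pool from [simulate_founder_pool()].
#' @param map `genetic_map` used to draw crossovers.
#' @param seed integer seed (mandatory).
#' @param parent_haps optional named list `iid -> c(h1, h2)` of pool haplotype
#'   rows, overriding the random draw for those parents.
#' @return list: `geno` (a `famlink_geno`: integer dosage matrix sample x SNP,
#'   `lowq` all-FALSE flags, `snps` map) and `truth` (class `famlink_truth`):
#'   per family maternal/paternal label matrices, crossover table, and the
#'   pool rows assigned to each parent.
#' @export
simulate_families <- function(ped, pool, map, seed, parent_haps = NULL) {
  if (missing(seed)) stop("'seed' is required")
  validate_pedigree(ped)
  set.seed(seed)
  snps <- pool$snps
  m <- nrow(snps)
  hap <- pool$haplotypes
  fams <- family_ids(ped)

  parents <- ped[ped$role == "parent", ]
  hap_of <- vector("list", nrow(parents)); names(hap_of) <- parents$iid
  for (p in parents$iid) {
    hap_of[[p]] <- if (!is.null(parent_haps) && p %in% names(parent_haps)) {
      as.integer(parent_haps[[p]])
    } else {
      sample.int(nrow(hap), 2L, replace = FALSE)
    }
  }

  chrom_of <- snps$chrom
  pos_of <- snps$pos
  snp_idx_by_chrom <- split(seq_len(m), chrom_of)
  morgans <- map$length / 1e6 * map$cm_per_mb / 100

  geno_ids <- ped$iid[ped$genotyped]
  geno <- matrix(NA_integer_, nrow = length(geno_ids), ncol = m,
                 dimnames = list(geno_ids, snps$snp))
  geno_row <- stats::setNames(seq_along(geno_ids), geno_ids)
  fam_rows <- split(seq_len(nrow(ped)), ped$fid)
  truth_fam <- list()
  xo_rows <- list()

  # one transmitted gamete: returns list(allele = 0/1 vector over all SNPs,
  # label = 1/2 vector, crossovers = data.frame(chrom, pos))
  draw_gamete <- function(h1, h2) {
    allele <- integer(m); label <- integer(m)
    xo <- list()
    for (c in seq_len(nrow(map))) {
      idx <- snp_idx_by_chrom[[as.character(map$chrom[c])]]
      nx <- stats::rpois(1L, morgans[c])
      start <- sample.int(2L, 1L)
      if (nx > 0) {
        xpos <- sort(stats::runif(nx, 0, map$length[c]))
        k <- findInterval(pos_of[idx], xpos)
        lab <- ((start - 1L + k) %% 2L) + 1L
        xo[[length(xo) + 1L]] <- data.frame(chrom = map$chrom[c], pos = xpos)
      } else {
        lab <- rep(start, length(idx))
      }
      label[idx] <- lab
      allele[idx] <- ifelse(lab == 1L, h1[idx], h2[idx])
    }
    list(allele = allele, label = label,
         crossovers = if (length(xo)) do.call(rbind, xo) else NULL)
  }

  for (fid in fams) {
    frec <- ped[fam_rows[[fid]], ]
    sibs <- frec$iid[frec$role == "sib"]
    fa <- unique(stats::na.omit(frec$father[frec$role == "sib"]))
    mo <- unique(stats::na.omit(frec$mother[frec$role == "sib"]))
    fh <- hap_of[[fa]]; mh <- hap_of[[mo]]
    fa_h <- list(hap[fh[1], ], hap[fh[2], ])
    mo_h <- list(hap[mh[1], ], hap[mh[2], ])

    s_n <- length(sibs)
    mat_lab <- matrix(0L, s_n, m, dimnames = list(sibs, snps$snp))
    pat_lab <- mat_lab
    for (s in seq_len(s_n)) {
      gm <- draw_gamete(mo_h[[1]], mo_h[[2]])
      gp <- draw_gamete(fa_h[[1]], fa_h[[2]])
      mat_lab[s, ] <- gm$label               # 1/2: maternal grandparents
      pat_lab[s, ] <- gp$label + 2L          # 3/4: paternal grandparents
      gr <- geno_row[sibs[s]]
      if (!is.na(gr)) {
        geno[gr, ] <- gm$allele + gp$allele
      }
      for (side in c("mother", "father")) {
        g <- if (side == "mother") gm else gp
        if (!is.null(g$crossovers)) {
          xo_rows[[length(xo_rows) + 1L]] <- cbind(
            fid = fid, iid = sibs[s], parent = side, g$crossovers)
        }
      }
    }
    for (p in c(fa, mo)) {
      gr <- geno_row[p]
      if (!is.na(gr)) {
        hp <- hap_of[[p]]
        geno[gr, ] <- hap[hp[1], ] + hap[hp[2], ]
      }
    }
    truth_fam[[fid]] <- list(sibs = sibs, mat = mat_lab, pat = pat_lab)
  }

  crossovers <- if (length(xo_rows)) do.call(rbind, xo_rows) else
    data.frame(fid = character(), iid = character(), parent = character(),
               chrom = integer(), pos = numeric())
  rownames(crossovers) <- NULL
  truth <- structure(
    list(families = truth_fam, crossovers = crossovers,
         parent_haps = hap_of, pool = pool, map = map),
    class = "famlink_truth"
  )
  geno_obj <- structure(
    list(dosage = geno,
         lowq = matrix(FALSE, nrow(geno), ncol(geno), dimnames = dimnames(geno)),
         snps = snps),
    class = "famlink_geno"
  )
  list(geno = geno_obj, truth = truth)
}

#' True pairwise IBD state of two siblings at every SNP
#'
#' Number of alleles shared identical by descent (0/1/2), read off the true
#' grandparental labels.  Used as the oracle when scoring the reconstruction.
#'
#' @param truth `famlink_truth`.
#' @param fid family id.
#' @param sib1,sib2 sibling ids.
#' @return integer vector over SNPs.
#' @export
truth_pair_ibd <- function(truth, fid, sib1, sib2) {
  fam <- truth$families[[fid]]
  (fam$mat[sib1, ] == fam$mat[sib2, ]) + (fam$pat[sib1, ] == fam$pat[sib2, ])
}

#' Phenotype model for the synthetic cohort
#'
#' Describes a height-like trait: sex-specific means and SDs (cm), a few
#' large-effect causal variants (effects in phenotype SD per allele, on the
#' standardized dosage scale), a polygenic background bringing total
#' narrow-sense heritability to `h2_total`, an optional shared-environment
#' fraction per sibship, quadratic height shrinkage with age, and repeated
#' measurements at instrument precision.
#'
#' @param sex_mean,sex_sd named numeric (`male`, `female`), cm.
#' @param h2_total total narrow-sense heritability of the latent age-corrected
#'   trait.
#' @param causal data.frame (`snp`, `beta`) or NULL; `sum(beta^2)` must not
#'   exceed `h2_total`.
#' @param shared_env variance fraction shared by siblings of one family.
#' @param polygenic_snps SNP ids carrying the polygenic background; default:
#'   every SNP not in `causal`.
#' @param n_repeats,repeat_sd technical measurement repeats and their SD (cm).
#' @param age age model from [age_model()].
#' @return list of class `phenotype_model`.
#' @export
phenotype_model <- function(sex_mean = c(male = 172.7, female = 161.6),
                            sex_sd = c(male = 5.7, female = 5.5),
                            h2_total = 0.86, causal = NULL, shared_env = 0,
                            polygenic_snps = NULL,
                            n_repeats = 4, repeat_sd = 0.1,
                            age = age_model()) {
  beta_var <- if (is.null(causal)) 0 else sum(causal$beta^2)
  if (!is.null(causal) && any(!is.finite(causal$beta))) stop("beta must be finite")
  poly <- h2_total - beta_var
  resid <- 1 - h2_total - shared_env
  if (h2_total < 0 || h2_total > 1 || poly < -1e-12 || resid < -1e-12 ||
      shared_env < 0) {
    stop("variance fractions must lie in [0, 1] and sum to at most 1")
  }
  structure(
    list(sex_mean = sex_mean, sex_sd = sex_sd, h2_total = h2_total,
         causal = causal, polygenic = max(poly, 0), shared_env = shared_env,
         residual = max(resid, 0), polygenic_snps = polygenic_snps,
         n_repeats = n_repeats, repeat_sd = repeat_sd, age = age),
    class = "phenotype_model"
  )
}

#' Simulate height measurements for a genotyped cohort
#'
#' The latent standardized phenotype is
#' `z = sum_j beta_j x~_j + g + c + e`, with `x~` the dosage standardized by
#' the pool allele frequency, `g` a polygenic value (i.i.d. normal effects on
#' the polygenic SNPs, total variance = polygenic fraction), `c` a shared
#' sibship effect and `e ~ N(0, residual)`.  Measured height is
#' `sex mean + sex SD * z + HeightLoss(age, sex)` plus per-repeat instrument
#' noise, rounded to 0.1 cm.
#'
#' @param ped pedigree.
#' @param geno `famlink_geno` (ideally the noise-free truth genotypes).
#' @param model `phenotype_model`; causal SNPs must exist in `geno`.
#' @param seed integer seed (mandatory).
#' @param freqs per-SNP allele frequencies for standardization; defaults to
#'   the founder-pool frequencies stored with `truth`, or sample frequencies.
#' @return data.frame (`fid`, `iid`, `sex`, `age`, `rep`, `height`), one row
#'   per measurement, with attribute `latent`: per-person latent components
#'   (`z`, `genetic`) before measurement noise and age shrinkage.
#' @export
simulate_phenotypes <- function(ped, geno, model = phenotype_model(), seed,
                                freqs = NULL) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  dos <- geno$dosage
  ids <- rownames(dos)
  keep <- ids[ids %in% ped$iid[ped$role %in% c("sib", "parent")]]
  dos <- dos[keep, , drop = FALSE]
  info <- ped[match(keep, ped$iid), ]
  if (is.null(freqs)) freqs <- colMeans(dos, na.rm = TRUE) / 2
  freqs <- pmin(pmax(freqs, 1e-6), 1 - 1e-6)

  std <- function(snp_ids) {
    x <- dos[, snp_ids, drop = FALSE]
    p <- freqs[snp_ids]
    sweep(sweep(x, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  }

  qtl <- numeric(length(keep))
  if (!is.null(model$causal)) {
    if (!all(model$causal$snp %in% colnames(dos))) {
      stop("causal SNPs absent from the genotype matrix")
    }
    qtl <- drop(std(model$causal$snp) %*% model$causal$beta)
  }
  g <- numeric(length(keep))
  if (model$polygenic > 0) {
    psnp <- model$polygenic_snps
    if (is.null(psnp)) {
      psnp <- setdiff(colnames(dos), if (is.null(model$causal)) character() else model$causal$snp)
    }
    u <- stats::rnorm(length(psnp), 0, sqrt(model$polygenic / length(psnp)))
    g <- drop(std(psnp) %*% u)
  }
  cenv <- numeric(length(keep))
  if (model$shared_env > 0) {
    cf <- stats::rnorm(length(unique(info$fid)), 0, sqrt(model$shared_env))
    names(cf) <- unique(info$fid)
    cenv <- ifelse(info$role == "sib", cf[info$fid], 0)
  }
  e <- stats::rnorm(length(keep), 0, sqrt(model$residual))
  z <- qtl + g + cenv + e

  mu <- model$sex_mean[info$sex]
  sdv <- model$sex_sd[info$sex]
  base <- mu + sdv * z + height_loss(info$age, info$sex, model$age)

  reps <- lapply(seq_len(model$n_repeats), function(r) {
    data.frame(fid = info$fid, iid = keep, sex = info$sex, age = info$age,
               rep = r,
               height = round(base + stats::rnorm(length(base), 0, model$repeat_sd), 1))
  })
  out <- do.call(rbind, reps)
  out <- out[order(match(out$iid, keep), out$rep), ]
  rownames(out) <- NULL
  attr(out, "latent") <- data.frame(
    fid = info$fid, iid = keep, sex = info$sex, age = info$age,
    z = z, genetic = qtl + g, qtl = qtl, polygenic = g
  )
  out
}

#' Genotyping noise model
#'
#' No-call, low-quality and miscall structure of a dense genotyping array.
#' With the defaults, low-quality calls carry most of the errors: the
#' low-quality error rate is back-computed so that the *overall* error rate
#' equals `overall_error` given the low-quality fraction and the high-quality
#' error rate.
#'
#' @param nocall fraction of calls reported as missing.
#' @param lowq fraction of calls flagged low-quality.
#' @param err_hq per-call error probability for high-quality calls.
#' @param overall_error target overall error rate (used to derive the
#'   low-quality error rate); ignored when `err_lowq` is given.
#' @param err_lowq per-call error probability for low-quality calls.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(nocall = 0.013, lowq = 0.078, err_hq = 1 / 2247,
                        overall_error = 1 / 110, err_lowq = NULL) {
  if (is.null(err_lowq)) {
    err_lowq <- if (lowq > 0) (overall_error - (1 - lowq) * err_hq) / lowq else 0
  }
  rates <- c(nocall = nocall, lowq = lowq, err_lowq = err_lowq, err_hq = err_hq)
  if (any(rates < 0 | rates > 1)) stop("noise rates must lie in [0, 1]")
  if (err_lowq < err_hq) stop("low-quality calls cannot be cleaner than high-quality calls")
  structure(as.list(rates), class = "noise_model")
}

#' Apply genotyping noise to a clean genotype matrix
#'
#' Flags a random subset of calls low-quality, miscalls flagged and unflagged
#' calls at their respective error rates (an error replaces the dosage by one
#' of the two other values, uniformly), and masks no-calls as missing.
#'
#' @param geno `famlink_geno` (clean).
#' @param noise `noise_model`.
#' @param seed integer seed (mandatory).
#' @return A `famlink_geno` whose `dosage` differs from the input only at
#'   error draws, with `NA` at no-calls and the `lowq` flag matrix filled in.
#' @export
apply_genotyping_noise <- function(geno, noise = noise_model(), seed) {
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  dos <- geno$dosage
  n <- length(dos)
  lowq <- matrix(stats::runif(n) < noise$lowq, nrow(dos), ncol(dos),
                 dimnames = dimnames(dos))
  err_p <- ifelse(lowq, noise$err_lowq, noise$err_hq)
  err <- matrix(stats::runif(n) < err_p, nrow(dos), ncol(dos))
  if (any(err)) {
    old <- dos[err]
    shift <- sample.int(2L, sum(err), replace = TRUE)   # one of the two other values
    dos[err] <- (old + shift) %% 3L
  }
  nc <- matrix(stats::runif(n) < noise$nocall, nrow(dos), ncol(dos))
  dos[nc] <- NA_integer_
  structure(list(dosage = dos, lowq = lowq, snps = geno$snps),
            class = "famlink_geno")
}

#' Inheritance vectors from simulated truth
#'
#' Converts the true grandparental labels of a simulated family into the
#' same `inheritance_vectors` structure the IBD reconstruction produces,
#' with exact crossover breakpoints.  Useful for studying the linkage
#' machinery in isolation from reconstruction error.
#'
#' @param truth `famlink_truth`.
#' @param fid family id.
#' @param map `genetic_map`.
#' @param snps SNP map.
#' @return `inheritance_vectors`.
#' @export
truth_inheritance_vectors <- function(truth, fid, map, snps) {
  fam <- truth$families[[fid]]
  sibs <- fam$sibs
  s_n <- length(sibs)
  chroms <- list()
  for (c in seq_len(nrow(map))) {
    cid <- map$chrom[c]
    sel <- which(snps$chrom == cid)
    xo <- truth$crossovers[truth$crossovers$fid == fid &
                             truth$crossovers$chrom == cid, ]
    bps <- sort(unique(round(xo$pos)))
    bounds <- c(1, bps[bps > 1 & bps <= map$length[c]], map$length[c] + 1)
    n_seg <- length(bounds) - 1
    mat <- matrix(0L, s_n, n_seg); pat <- matrix(0L, s_n, n_seg)
    mid <- (bounds[-length(bounds)] + bounds[-1] - 1) / 2
    snp_at <- findInterval(mid, snps$pos[sel])
    snp_at <- pmin(pmax(snp_at, 1L), length(sel))
    for (t in seq_len(n_seg)) {
      mat[, t] <- fam$mat[, sel[snp_at[t]]]
      pat[, t] <- fam$pat[, sel[snp_at[t]]]
    }
    ev <- data.frame(sib = match(xo$iid, sibs),
                     parent = xo$parent, chrom = cid, pos = round(xo$pos),
                     left = NA_real_, right = NA_real_, multi = FALSE)
    chroms[[as.character(cid)]] <- list(
      segments = data.frame(start = bounds[-length(bounds)],
                            end = bounds[-1] - 1),
      mat = mat, pat = pat, events = ev)
  }
  structure(list(n_sibs = s_n, sibs = sibs, chroms = chroms, map = map),
            class = "inheritance_vectors")
}
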