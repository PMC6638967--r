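# Pedigree construction and validation for the synthetic cohort.

#' Build a cohort of very large nuclear families
#'
#' Generates a pedigree table emulating a cohort of nuclear families with
#' 10-20 siblings each (mean ~12 by default).  Optionally, pairs of families
#' can be linked through a shared grandparental couple (one parent in each
#' linked family becomes a child of that couple), producing first cousins
#' across families.
#'
#' @param n_families number of nuclear families.
#' @param sib_range integer range of siblings per family.
#' @param mean_sibs target mean sibship size; sizes are
#'   `min + Binomial(max - min, (mean - min)/(max - min))`.
#' @param cousin_pairs number of family pairs sharing a grandparental couple
#'   (0 = all families unrelated, the default; the linkage machinery treats
#'   families as independent either way).
#' @param sib_ages,parent_ages integer age ranges (years).
#' @param parents_genotyped logical scalar or one value per family: whether
#'   the parents have genotype data.
#' @param seed integer seed (mandatory).
#' @return A `data.frame` of class `famlink_ped` with columns `fid`, `iid`,
#'   `father`, `mother`, `sex`, `age`, `role`, `genotyped`.
#' @export
make_cohort_pedigree <- function(n_families = 29, sib_range = c(10L, 20L),
                                 mean_sibs = 12, cousin_pairs = 0,
                                 sib_ages = c(25L, 70L), parent_ages = c(55L, 90L),
                                 parents_genotyped = TRUE, seed) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(n_families >= 1, sib_range[1] >= 2, sib_range[2] >= sib_range[1],
            mean_sibs >= sib_range[1], mean_sibs <= sib_range[2],
            2 * cousin_pairs <= n_families)
  set.seed(seed)
  span <- sib_range[2] - sib_range[1]
  nsib <- rep_len(sib_range[1], n_families) + if (span > 0) {
    stats::rbinom(n_families, span, (mean_sibs - sib_range[1]) / span)
  } else 0L
  pg <- rep_len(parents_genotyped, n_families)

  fids <- sprintf("F%02d", seq_len(n_families))
  per_fam <- nsib + 2L
  fid_col <- rep(fids, per_fam)
  role <- unlist(lapply(nsib, function(k) c("parent", "parent", rep("sib", k))),
                 use.names = FALSE)
  sib_idx <- unlist(lapply(nsib, function(k) c(0L, 0L, seq_len(k))),
                    use.names = FALSE)
  iid <- sprintf("%s_s%02d", fid_col, sib_idx)
  # the two parent rows per family are father then mother
  iid[role == "parent"] <- paste0(fid_col[role == "parent"],
                                  rep(c("_fa", "_mo"), n_families))
  is_sib <- role == "sib"
  ped <- data.frame(
    fid = fid_col,
    iid = iid,
    father = ifelse(is_sib, paste0(fid_col, "_fa"), NA),
    mother = ifelse(is_sib, paste0(fid_col, "_mo"), NA),
    sex = ifelse(role == "parent",
                 rep(c("male", "female"), n_families),
                 sample(c("male", "female"), length(iid), replace = TRUE)),
    age = ifelse(role == "parent",
                 sample(parent_ages[1]:parent_ages[2], length(iid), replace = TRUE),
                 sample(sib_ages[1]:sib_ages[2], length(iid), replace = TRUE)),
    role = role,
    genotyped = ifelse(role == "parent", rep(pg, per_fam), TRUE)
  )

  if (cousin_pairs > 0) {
    grows <- vector("list", cousin_pairs)
    for (j in seq_len(cousin_pairs)) {
      gfa <- sprintf("G%02d_fa", j); gmo <- sprintf("G%02d_mo", j)
      f1 <- sprintf("F%02d", 2 * j - 1); f2 <- sprintf("F%02d", 2 * j)
      # the two linked families' mothers are full sisters
      for (fid in c(f1, f2)) {
        i <- which(ped$fid == fid & ped$iid == paste0(fid, "_mo"))
        ped$father[i] <- gfa
        ped$mother[i] <- gmo
      }
      grows[[j]] <- data.frame(
        fid = sprintf("G%02d", j), iid = c(gfa, gmo),
        father = NA_character_, mother = NA_character_,
        sex = c("male", "female"),
        age = sample(85:99, 2, replace = TRUE),
        role = "grandparent", genotyped = FALSE
      )
    }
    ped <- rbind(ped, do.call(rbind, grows))
  }
  rownames(ped) <- NULL
  validate_pedigree(ped)
  class(ped) <- c("famlink_ped", "data.frame")
  ped
}

#' Validate a pedigree table
#'
#' Checks structural invariants: unique ids, parents present where referenced,
#' both parents of every sibling in the same family record, and acyclicity.
#'
#' @param ped pedigree data.frame.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_pedigree <- function(ped) {
  need <- c("fid", "iid", "father", "mother", "sex", "age", "role", "genotyped")
  if (!all(need %in% names(ped))) stop("pedigree lacks required columns")
  if (anyDuplicated(ped$iid)) stop("duplicate individual ids")
  refs <- stats::na.omit(c(ped$father, ped$mother))
  if (!all(refs %in% ped$iid)) stop("pedigree references unknown ids")
  sibs <- ped[ped$role == "sib", ]
  if (any(is.na(sibs$father) | is.na(sibs$mother))) {
    stop("every sibling must have both parents")
  }
  fa_fid <- ped$fid[match(sibs$father, ped$iid)]
  mo_fid <- ped$fid[match(sibs$mother, ped$iid)]
  if (!all(fa_fid == sibs$fid & mo_fid == sibs$fid)) {
    stop("siblings' parents must belong to the same family record")
  }
  .pedigree_order(ped)  # errors on cycles
  invisible(TRUE)
}

# Topological order (parents before children); errors on cycles.
.pedigree_order <- function(ped) {
  n <- nrow(ped)
  placed <- logical(n)
  ord <- integer(0)
  fa <- match(ped$father, ped$iid)
  mo <- match(ped$mother, ped$iid)
  repeat {
    ready <- !placed &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("pedigree contains a cycle")
  ord
}

#' Siblings of one family
#' @param ped pedigree.
#' @param fid family id.
#' @param genotyped_only keep only genotyped siblings.
#' @return character vector of individual ids.
#' @export
family_sibs <- function(ped, fid, genotyped_only = TRUE) {
  sel <- ped$fid == fid & ped$role == "sib"
  if (genotyped_only) sel <- sel & ped$genotyped
  ped$iid[sel]
}

#' Family ids of a pedigree (nuclear families only)
#' @param ped pedigree.
#' @return character vector.
#' @export
family_ids <- function(ped) unique(ped$fid[ped$role == "sib"])
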