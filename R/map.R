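# Genetic map and SNP placement for the synthetic genome.

# hg19 autosome lengths in bp (chr1..chr22), used as the default shape of the
# synthetic genome; everything is scalable by a single factor.
.HG19_AUTOSOMES <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 155270560, 146364022, 141213431, 135006516, 133851895,
  115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
  59128983, 63025520, 48129895, 51304566
)

#' Construct a genetic map
#'
#' A genetic map describes the synthetic genome: one row per autosome with its
#' physical length (bp) and a uniform recombination rate (cM/Mb).  By default
#' the 22 autosomes have hg19-proportional lengths; `scale` shrinks the whole
#' genome so simulations run in seconds while keeping relative chromosome
#' sizes.
#'
#' @param n_chrom number of autosomes (1..22).
#' @param scale multiplicative factor applied to the hg19 lengths.
#' @param cm_per_mb recombination rate in centimorgan per megabase; scalar or
#'   one value per chromosome.
#' @param lengths optional explicit chromosome lengths in bp (overrides
#'   `n_chrom`/`scale`).
#' @return A `data.frame` of class `genetic_map` with columns `chrom`,
#'   `length`, `cm_per_mb`.
#' @examples
#' m <- genetic_map(n_chrom = 4, scale = 0.02)
#' map_morgans(m)
#' @export
genetic_map <- function(n_chrom = 22, scale = 1, cm_per_mb = 1, lengths = NULL) {
  if (is.null(lengths)) {
    stopifnot(n_chrom >= 1, n_chrom <= 22)
    lengths <- round(.HG19_AUTOSOMES[seq_len(n_chrom)] * scale)
  }
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (any(cm_per_mb < 0)) stop("cm_per_mb must be non-negative")
  map <- data.frame(
    chrom = seq_along(lengths),
    length = lengths,
    cm_per_mb = rep_len(cm_per_mb, length(lengths))
  )
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Genetic map with a fixed total physical and genetic size
#'
#' Convenience constructor used for scaled-down experiments: hg19-proportional
#' chromosome lengths rescaled to a total of `total_bp` base pairs, with a
#' uniform recombination rate chosen so that the genome spans `total_morgans`
#' Morgans.  Keeping the genetic length realistic while shrinking the physical
#' genome preserves crossover counts at a fraction of the memory cost.
#'
#' @param total_bp total physical genome size in bp.
#' @param total_morgans total genetic length in Morgans.
#' @param n_chrom number of autosomes.
#' @return A `genetic_map`.
#' @export
scaled_genome <- function(total_bp = 350e6, total_morgans = 35, n_chrom = 22) {
  prop <- .HG19_AUTOSOMES[seq_len(n_chrom)] / sum(.HG19_AUTOSOMES[seq_len(n_chrom)])
  lengths <- round(prop * total_bp)
  cmmb <- total_morgans * 100 / (sum(lengths) / 1e6)
  genetic_map(lengths = lengths, cm_per_mb = cmmb)
}

#' Total genetic length of a map in Morgans
#' @param map a `genetic_map`.
#' @return numeric, Morgans.
#' @export
map_morgans <- function(map) {
  sum(map$length / 1e6 * map$cm_per_mb) / 100
}

#' Place SNPs on a genetic map
#'
#' Distributes `n_snps` markers across chromosomes proportionally to physical
#' length (at least `min_per_chrom` each), evenly spaced.  Even spacing keeps
#' marker density—and therefore the information content of the IBD
#' reconstruction—homogeneous along the genome.
#'
#' @param map a `genetic_map`.
#' @param n_snps total number of SNPs.
#' @param min_per_chrom minimum markers per chromosome.
#' @return A `data.frame` (`snp`, `chrom`, `pos`) with 1-based positions,
#'   strictly increasing within chromosome.
#' @export
place_snps <- function(map, n_snps, min_per_chrom = 3) {
  stopifnot(n_snps >= min_per_chrom * nrow(map))
  alloc <- pmax(min_per_chrom, floor(n_snps * map$length / sum(map$length)))
  # distribute the remainder to the largest chromosomes
  rem <- n_snps - sum(alloc)
  if (rem > 0) {
    ord <- order(map$length, decreasing = TRUE)
    idx <- rep_len(ord, rem)
    for (i in idx) alloc[i] <- alloc[i] + 1
  }
  out <- lapply(seq_len(nrow(map)), function(c) {
    m <- alloc[c]
    pos <- round((seq_len(m) - 0.5) / m * map$length[c])
    pos <- pmin(pmax(pos, 1), map$length[c])
    pos <- unique(pos)
    data.frame(
      snp = sprintf("snp%02d_%06d", map$chrom[c], seq_along(pos)),
      chrom = map$chrom[c],
      pos = pos
    )
  })
  do.call(rbind, out)
}
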