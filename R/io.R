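# Plain-text writers (and a matching minimal reader) for the standard
# exchange formats: PLINK-style .ped/.map, a minimal VCF, tab-separated
# phenotype tables, BED-like segment tracks and GCTA-style text GRMs.

#' Write genotypes as PLINK-style .ped/.map text
#'
#' @param geno `famlink_geno`.
#' @param ped pedigree (for family/parent/sex columns).
#' @param prefix output path prefix (writes `prefix.ped`, `prefix.map`).
#' @return invisibly the two file paths.
#' @export
write_ped_map <- function(geno, ped, prefix) {
  ids <- rownames(geno$dosage)
  info <- ped[match(ids, ped$iid), ]
  sex_code <- ifelse(info$sex == "male", 1L, 2L)
  alleles <- function(d) {
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, "B", "A"))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, "B", "A"))
    paste(a1, a2)
  }
  lines <- vapply(seq_along(ids), function(i) {
    paste(info$fid[i], ids[i],
          ifelse(is.na(info$father[i]), "0", info$father[i]),
          ifelse(is.na(info$mother[i]), "0", info$mother[i]),
          sex_code[i], -9,
          paste(alleles(geno$dosage[i, ]), collapse = " "))
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  utils::write.table(
    data.frame(geno$snps$chrom, geno$snps$snp, 0, geno$snps$pos),
    paste0(prefix, ".map"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read PLINK-style .ped/.map text written by [write_ped_map()]
#'
#' @param prefix path prefix.
#' @return list: `geno` (`famlink_geno`), `info` (sample table).
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chrom", "snp", "cm", "pos"))
  lines <- readLines(paste0(prefix, ".ped"))
  parts <- strsplit(lines, " ")
  m <- nrow(map)
  ids <- vapply(parts, `[`, character(1), 2)
  dos <- t(vapply(parts, function(p) {
    a <- p[-(1:6)]
    a1 <- a[seq(1, 2 * m, by = 2)]; a2 <- a[seq(2, 2 * m, by = 2)]
    ifelse(a1 == "0", NA_integer_, (a1 == "B") + (a2 == "B"))
  }, integer(m)))
  rownames(dos) <- ids; colnames(dos) <- map$snp
  info <- data.frame(
    fid = vapply(parts, `[`, character(1), 1), iid = ids,
    father = vapply(parts, `[`, character(1), 3),
    mother = vapply(parts, `[`, character(1), 4),
    sex = ifelse(vapply(parts, `[`, character(1), 5) == "1", "male", "female"))
  list(geno = structure(list(dosage = dos,
                             lowq = matrix(FALSE, nrow(dos), ncol(dos),
                                           dimnames = dimnames(dos)),
                             snps = map[, c("snp", "chrom", "pos")]),
                        class = "famlink_geno"),
       info = info)
}

#' Write genotypes as a minimal VCF
#'
#' Unphased GT records (`0/0`, `0/1`, `1/1`, `./.`), REF=A, ALT=B.  When a
#' list of phased haplotype matrices is supplied (sample -> `c(hap_a,
#' hap_b)` alleles per SNP), phased pipe-separated genotypes are written
#' instead.
#'
#' @param geno `famlink_geno`.
#' @param path output file.
#' @param map optional `genetic_map` for contig headers.
#' @return invisibly `path`.
#' @export
write_vcf <- function(geno, path, map = NULL) {
  ids <- rownames(geno$dosage)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=famlink", con)
  if (!is.null(map)) {
    writeLines(sprintf("##contig=<ID=%d,length=%d>", map$chrom,
                       as.integer(map$length)), con)
  }
  writeLines("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(geno$snps))) {
    d <- geno$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(geno$snps$chrom[j], geno$snps$pos[j], geno$snps$snp[j],
                       "A", "B", ".", "PASS", ".", "GT", gt), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Write IBD tracks or truth labels as BED-like text
#'
#' 0-based half-open intervals (`chrom`, `start`, `end`) followed by the
#' remaining columns of the track.
#'
#' @param segments data.frame with `chrom`, `start`, `end` (1-based,
#'   inclusive) plus annotation columns.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_segments_bed <- function(segments, path) {
  out <- segments
  out$start <- out$start - 1          # 1-based inclusive -> 0-based half-open
  extra <- setdiff(names(out), c("chrom", "start", "end"))
  utils::write.table(out[, c("chrom", "start", "end", extra)], path,
                     quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write a phenotype or results table as TSV
#' @param x data.frame.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write a GRM as GCTA-style text triplets
#'
#' `prefix.grm.gz`-style plain text (`i j m value`, lower triangle including
#' the diagonal, uncompressed) plus `prefix.grm.id`.
#'
#' @param grm `grm` object.
#' @param prefix output prefix.
#' @return invisibly the file paths.
#' @export
write_grm_text <- function(grm, prefix) {
  ids <- rownames(grm$A)
  n <- length(ids)
  idx <- which(lower.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  tab <- data.frame(i = idx[, 1], j = idx[, 2], m = grm$m,
                    value = grm$A[idx])
  tab <- tab[tab$i >= tab$j, ]
  utils::write.table(tab, paste0(prefix, ".grm.txt"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(fid = ids, iid = ids),
                     paste0(prefix, ".grm.id"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".grm.txt", ".grm.id")))
}
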