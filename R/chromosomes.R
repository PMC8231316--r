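# Chromosome-wise distribution summaries for a hexaploid wheat panel: per
# chromosome count, first/last SNP position (Mb), coverage, mean spacing and
# density, with roll-ups over the A/B/D subgenomes and homoeologous groups
# 1-7. Wheat chromosome names look like "1A".."7D"; other labels are
# tolerated but excluded from subgenome/group roll-ups.

parse_wheat_chrom <- function(chrom) {
  m <- regmatches(chrom, regexec("^([0-9]+)([ABD])$", chrom))
  grp <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_,
                character(1))
  gen <- vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_,
                character(1))
  data.frame(group = grp, genome = gen, stringsAsFactors = FALSE)
}

#' Roll up a per-chromosome SNP distribution table
#'
#' Core arithmetic of the chromosome-distribution report, operating on
#' per-chromosome counts and first/last SNP positions (in Mb). Coverage is
#' `last - first`, mean spacing `coverage / count` and density
#' `count / coverage`; chromosomes carrying a single SNP get coverage 0 and
#' undefined (`NA`) spacing and density rather than a division error.
#' Subgenome (A/B/D) and homoeologous-group totals aggregate counts and
#' coverages, with spacing recomputed as total coverage / total count.
#'
#' @param tbl data.frame with columns `chrom`, `snp_count`, `first_mb`,
#'   `last_mb`.
#' @return list of data.frames: `chromosomes`, `genomes` (with `pct` of all
#'   SNPs), `groups`, `total`.
#' @export
chrom_rollup <- function(tbl) {
  stopifnot(all(c("chrom", "snp_count", "first_mb", "last_mb") %in%
                  names(tbl)))
  if (any(tbl$last_mb < tbl$first_mb)) stop("last_mb before first_mb")
  chr <- data.frame(chrom = tbl$chrom, snp_count = tbl$snp_count,
                    first_mb = round(tbl$first_mb, 3),
                    last_mb = round(tbl$last_mb, 3),
                    stringsAsFactors = FALSE)
  chr$coverage_mb <- round(chr$last_mb - chr$first_mb, 3)
  single <- chr$snp_count <= 1
  chr$mean_spacing_mb <- ifelse(single | chr$coverage_mb == 0, NA_real_,
                                round(chr$coverage_mb / chr$snp_count, 3))
  chr$density <- ifelse(single | chr$coverage_mb == 0, NA_real_,
                        round(chr$snp_count / chr$coverage_mb, 3))
  total_snps <- sum(chr$snp_count)

  wc <- parse_wheat_chrom(chr$chrom)
  roll <- function(key) {
    ok <- !is.na(key)
    s <- rowsum(cbind(snp_count = chr$snp_count[ok],
                      coverage_mb = chr$coverage_mb[ok]), key[ok])
    agg <- data.frame(level = rownames(s), snp_count = s[, "snp_count"],
                      coverage_mb = s[, "coverage_mb"], row.names = NULL,
                      stringsAsFactors = FALSE)
    agg$mean_spacing_mb <- round(agg$coverage_mb / agg$snp_count, 3)
    agg$pct <- round(100 * agg$snp_count / total_snps, 2)
    agg
  }
  genomes <- if (any(!is.na(wc$genome))) roll(wc$genome) else NULL
  groups <- if (any(!is.na(wc$group))) roll(wc$group) else NULL
  total <- data.frame(snp_count = total_snps,
                      coverage_mb = sum(chr$coverage_mb),
                      mean_spacing_mb = round(sum(chr$coverage_mb) /
                                                total_snps, 3))
  list(chromosomes = chr, genomes = genomes, groups = groups, total = total)
}

#' Chromosome-wise SNP distribution of a panel
#'
#' Computes the per-chromosome distribution table (positions reported in Mb
#' to 3 decimals) directly from a genotype panel and rolls it up with
#' [chrom_rollup()].
#'
#' @param gm a [genotype_matrix()].
#' @return the [chrom_rollup()] list, with class `chrom_distribution`.
#' @export
chromosome_distribution <- function(gm) {
  stopifnot(is_genotype_matrix(gm))
  mk <- gm$markers
  spl <- split(mk$pos, mk$chrom)
  tbl <- data.frame(chrom = names(spl),
                    snp_count = vapply(spl, length, integer(1)),
                    first_mb = vapply(spl, min, numeric(1)) / 1e6,
                    last_mb = vapply(spl, max, numeric(1)) / 1e6,
                    stringsAsFactors = FALSE)
  out <- chrom_rollup(tbl)
  class(out) <- c("chrom_distribution", class(out))
  out
}

#' @export
print.chrom_distribution <- function(x, ...) {
  cat("SNP distribution across", nrow(x$chromosomes), "chromosomes;",
      x$total$snp_count, "markers,",
      sprintf("%.1f Mb covered, mean spacing %.3f Mb\n",
              x$total$coverage_mb, x$total$mean_spacing_mb))
  print(x$chromosomes, row.names = FALSE)
  invisible(x)
}

#' Write the chromosome-distribution report as TSV
#'
#' Column order follows the conventional distribution table: Group, SNPs,
#' First SNP, Last SNP, Coverage, Dist. b/w SNP, Density; subgenome and
#' grand-total rows are appended.
#'
#' @param cd result of [chromosome_distribution()].
#' @param path output path.
#' @export
write_chrom_distribution <- function(cd, path) {
  chr <- cd$chromosomes
  out <- data.frame(Group = chr$chrom, SNPs = chr$snp_count,
                    First.SNP = chr$first_mb, Last.SNP = chr$last_mb,
                    Coverage = chr$coverage_mb,
                    Dist.bw.SNP = chr$mean_spacing_mb,
                    Density = chr$density, stringsAsFactors = FALSE)
  if (!is.null(cd$genomes)) {
    out <- rbind(out, data.frame(
      Group = paste("Genome", cd$genomes$level), SNPs = cd$genomes$snp_count,
      First.SNP = NA, Last.SNP = NA, Coverage = cd$genomes$coverage_mb,
      Dist.bw.SNP = cd$genomes$mean_spacing_mb, Density = NA))
  }
  out <- rbind(out, data.frame(
    Group = "Total", SNPs = cd$total$snp_count, First.SNP = NA,
    Last.SNP = NA, Coverage = cd$total$coverage_mb,
    Dist.bw.SNP = cd$total$mean_spacing_mb, Density = NA))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
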