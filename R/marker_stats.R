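# Per-marker and per-sample summary statistics: MAF, observed
# heterozygosity, and the biallelic polymorphism information content
#   PIC = 1 - (MAF^2 + (1-MAF)^2) - 2 MAF^2 (1-MAF)^2,
# which attains its maximum 0.375 at MAF = 0.5.

#' Minor allele frequency of one locus
#'
#' @param calls numeric vector of dosages in \{0, 1, 2, NA\}.
#' @return `min(p, 1 - p)` where `p` is the frequency of the counted allele
#'   among non-missing calls.
#' @examples
#' maf(c(0, 0, 0, 1)) # 0.125
#' @export
maf <- function(calls) {
  obs <- calls[!is.na(calls)]
  if (length(obs) == 0) stop("maf: every call is missing")
  p <- sum(obs) / (2 * length(obs))
  min(p, 1 - p)
}

#' Polymorphism information content of a biallelic marker
#'
#' Evaluates `1 - (maf^2 + (1 - maf)^2) - 2 maf^2 (1 - maf)^2`; vectorized.
#'
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @export
pic <- function(maf) {
  if (any(!is.na(maf) & (maf < 0 | maf > 0.5))) {
    stop("pic: maf must lie in [0, 0.5]")
  }
  1 - (maf^2 + (1 - maf)^2) - 2 * maf^2 * (1 - maf)^2
}

#' Observed heterozygosity of one locus
#'
#' @inheritParams maf
#' @return fraction of non-missing calls equal to dosage 1.
#' @export
observed_heterozygosity <- function(calls) {
  obs <- calls[!is.na(calls)]
  if (length(obs) == 0) stop("observed_heterozygosity: every call is missing")
  mean(obs == 1)
}

#' Per-sample heterozygosity
#'
#' Fraction of each line's non-missing calls that are heterozygous; high
#' values flag residually segregating or outcrossed lines in an inbred panel.
#'
#' @param gm a [genotype_matrix()].
#' @return named numeric vector, one value per sample.
#' @export
sample_heterozygosity <- function(gm) {
  stopifnot(is_genotype_matrix(gm))
  het <- rowSums(gm$calls == 1, na.rm = TRUE)
  n_obs <- rowSums(!is.na(gm$calls))
  if (any(n_obs == 0)) stop("sample with no observed calls")
  setNames(het / n_obs, rownames(gm$calls))
}

#' Per-marker summary table
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame (class `marker_summary`) with one row per marker:
#'   `id`, `chrom`, `pos`, `call_rate`, `maf`, `he_obs`, `pic`. Markers with
#'   no observed calls get `NA` statistics and call rate 0.
#' @export
marker_summary <- function(gm) {
  stopifnot(is_genotype_matrix(gm))
  n_obs <- colSums(!is.na(gm$calls))
  p <- colSums(gm$calls, na.rm = TRUE) / (2 * pmax(n_obs, 1))
  mafs <- pmin(p, 1 - p)
  mafs[n_obs == 0] <- NA_real_
  he <- colSums(gm$calls == 1, na.rm = TRUE) / pmax(n_obs, 1)
  he[n_obs == 0] <- NA_real_
  out <- data.frame(id = gm$markers$id, chrom = gm$markers$chrom,
                    pos = gm$markers$pos,
                    call_rate = n_obs / nrow(gm$calls),
                    maf = mafs, he_obs = he, pic = pic(mafs),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_summary", "data.frame")
  out
}

#' Histograms of per-marker statistics
#'
#' Bins the MAF, observed-heterozygosity and PIC columns of a marker summary
#' into user-supplied intervals (left-closed, right-open; the last bin closed
#' on both sides), the binning behind the usual marker-characteristics
#' figure panels.
#'
#' @param ms a [marker_summary()].
#' @param bins increasing numeric vector of bin edges.
#' @return list of data.frames (`maf`, `he_obs`, `pic`), each with bin
#'   edges and counts; each count column sums to the number of markers with
#'   a defined statistic.
#' @export
summary_histograms <- function(ms, bins) {
  stopifnot(inherits(ms, "marker_summary"))
  if (nrow(ms) == 0) stop("empty marker summary")
  if (length(bins) < 2 || any(diff(bins) <= 0)) {
    stop("bins must be strictly increasing with at least two edges")
  }
  bin_one <- function(x) {
    x <- x[!is.na(x)]
    if (any(x < bins[1] | x > bins[length(bins)])) {
      stop("values fall outside the bin range")
    }
    idx <- findInterval(x, bins, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = length(bins) - 1)
    data.frame(lower = bins[-length(bins)], upper = bins[-1], count = counts)
  }
  list(maf = bin_one(ms$maf), he_obs = bin_one(ms$he_obs),
       pic = bin_one(ms$pic))
}
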