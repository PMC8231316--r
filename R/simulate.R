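# Balding-Nichols simulator of wheat-like inbred genotype panels. Ancestral
# minor-allele frequencies are Uniform(maf_floor, 1 - maf_floor); each of K
# subpopulations draws its locus frequency from
#   Beta(p (1-F)/F, (1-p)(1-F)/F),
# so that E[p_k] = p and the expected differentiation equals F. Lines are
# modelled as advanced inbred material: heterozygous (dosage 1) with a small
# residual probability, otherwise homozygous for the counted allele with
# probability p_k. Markers are laid out on the 21 bread-wheat chromosomes
# with A/B/D subgenome shares of roughly 41/51/9 % of markers.

# approximate bread-wheat chromosome lengths (Mb), cosmetic marker layout
WHEAT_CHROM_MB <- c(
  "1A" = 594, "2A" = 781, "3A" = 751, "4A" = 745, "5A" = 710, "6A" = 618,
  "7A" = 737, "1B" = 689, "2B" = 801, "3B" = 830, "4B" = 673, "5B" = 713,
  "6B" = 721, "7B" = 750, "1D" = 495, "2D" = 651, "3D" = 616, "4D" = 510,
  "5D" = 566, "6D" = 474, "7D" = 638)

#' Simulation configuration
#'
#' Defaults emulate an advanced-breeding-line panel: 141 lines in two
#' subpopulations, 14,563 biallelic SNPs over 21 wheat chromosomes with
#' A/B/D marker shares 0.41/0.51/0.09, weak differentiation (F = 0.006),
#' residual heterozygosity 0.015, a 0.05 floor on ancestral minor allele
#' frequencies, and no missing data (the panel stands in for a
#' post-imputation call set).
#'
#' @param n_per_group integer vector of subpopulation sizes.
#' @param n_loci number of markers.
#' @param fst Balding-Nichols differentiation parameter, in (0, 1).
#' @param residual_het per-call probability of a heterozygous (dosage 1)
#'   genotype.
#' @param missing_rate i.i.d. missing-call probability, in [0, 1).
#' @param maf_floor lower bound of the ancestral minor-allele-frequency
#'   draw, in (0, 0.5).
#' @param genome_weights marker-share weights for the A/B/D subgenomes
#'   (normalized internally).
#' @param seed integer seed; mandatory, the panel is fully reproducible
#'   from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(70, 71), n_loci = 14563,
                       fst = 0.006, residual_het = 0.015,
                       missing_rate = 0, maf_floor = 0.05,
                       genome_weights = c(A = 0.41, B = 0.51, D = 0.09),
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(length(n_per_group) >= 1, all(n_per_group >= 1), n_loci >= 1,
            fst > 0, fst < 1, residual_het >= 0, residual_het <= 1,
            missing_rate >= 0, missing_rate < 1,
            maf_floor > 0, maf_floor < 0.5, length(genome_weights) == 3)
  a <- maf_floor * (1 - fst) / fst
  if (a <= 0) stop("fst too extreme for this maf_floor (Beta shape <= 0)")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_loci = as.integer(n_loci), fst = fst,
                 residual_het = residual_het, missing_rate = missing_rate,
                 maf_floor = maf_floor,
                 genome_weights = genome_weights / sum(genome_weights),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a structured inbred genotype panel
#'
#' Draws a panel under the Balding-Nichols model described in
#' [sim_config()] and returns both the panel and its ground truth. The
#' emitted panel is polarized to the minor-allele convention; the truth
#' frequencies refer to the allele the dosages count after polarization.
#'
#' @param config a [sim_config()].
#' @return list with `gm` (a [genotype_matrix()]) and `truth` (class
#'   `sim_truth`: `labels`, `pop_freq` (K x loci), `realized_fst`,
#'   `config`).
#' @examples
#' sim <- simulate_panel(sim_config(n_per_group = c(20, 20), n_loci = 200,
#'                                  fst = 0.05, seed = 1))
#' sim$gm
#' sim$truth$realized_fst
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- length(config$n_per_group)
  N <- sum(config$n_per_group)
  L <- config$n_loci
  p_anc <- runif(L, config$maf_floor, 1 - config$maf_floor)
  scale <- (1 - config$fst) / config$fst
  pop_freq <- t(vapply(seq_len(K), function(k) {
    rbeta(L, p_anc * scale, (1 - p_anc) * scale)
  }, numeric(L)))
  labels <- rep(seq_len(K), config$n_per_group)
  calls <- matrix(NA_real_, N, L)
  for (i in seq_len(N)) {
    pk <- pop_freq[labels[i], ]
    het <- runif(L) < config$residual_het
    hom <- 2 * (runif(L) < pk)
    calls[i, ] <- ifelse(het, 1, hom)
  }
  if (config$missing_rate > 0) {
    calls[runif(N * L) < config$missing_rate] <- NA_real_
  }
  rownames(calls) <- sprintf("line_%03d", seq_len(N))

  # wheat-like marker layout: subgenome by weight, chromosome uniform in it
  genomes <- sample(names(config$genome_weights), L, replace = TRUE,
                    prob = config$genome_weights)
  chrom <- paste0(sample.int(7, L, replace = TRUE), genomes)
  pos <- integer(L)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(WHEAT_CHROM_MB[[ch]] * 1e6,
                                length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  major <- sample(bases, L, replace = TRUE)
  minor <- vapply(major, function(b) sample(setdiff(bases, b), 1),
                  character(1))
  gm <- genotype_matrix(calls,
                        data.frame(id = sprintf("S%s_%d", chrom, pos),
                                   chrom = chrom, pos = pos, major = major,
                                   minor = minor, stringsAsFactors = FALSE))
  # polarize and carry the allele flips into the truth frequencies
  before <- match(gm$markers$id, sprintf("S%s_%d", chrom, pos))
  pop_freq <- pop_freq[, before, drop = FALSE]
  gm_pol <- polarize_minor(gm)
  flipped <- gm_pol$markers$major != gm$markers$major
  pop_freq[, flipped] <- 1 - pop_freq[, flipped]
  colnames(pop_freq) <- gm_pol$markers$id
  truth <- structure(list(labels = labels, pop_freq = pop_freq,
                          config = config), class = "sim_truth")
  truth$realized_fst <- realized_fst(truth)
  list(gm = gm_pol, truth = truth)
}

#' FST realized by simulated subpopulation frequencies
#'
#' Variance-component FST on the true frequencies: per locus
#' `s2 / (s2 + hw)` where `s2` is the sample variance of the subpopulation
#' frequencies (k - 1 divisor) and `hw = mean(p_k (1 - p_k))` the average
#' within-subpopulation gene diversity, averaged over loci. This is the
#' quantity on the scale of the Balding-Nichols parameter F and of the
#' AMOVA PhiPT estimator, which the recovery tests compare it against (the
#' Nei population-variance convention would sit a factor ~(k-1)/k lower).
#' Loci fixed for the same allele in every subpopulation carry no
#' information and are excluded; if every locus is such, an error is
#' raised.
#'
#' @param truth a `sim_truth` object from [simulate_panel()], or a K x loci
#'   matrix of subpopulation allele frequencies.
#' @export
realized_fst <- function(truth) {
  pf <- if (inherits(truth, "sim_truth")) truth$pop_freq else as.matrix(truth)
  if (nrow(pf) < 2) stop("realized_fst needs >= 2 subpopulations")
  s2 <- apply(pf, 2, stats::var)
  hw <- colMeans(pf * (1 - pf))
  ok <- (s2 + hw) > 0
  if (!any(ok)) stop("every locus is fixed; FST undefined")
  mean(s2[ok] / (s2[ok] + hw[ok]))
}
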