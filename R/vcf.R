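#' Read a VCF file into a genotype panel
#'
#' Reads biallelic records from a VCF 4.x file (via the vcfR package) and
#' converts GT fields to minor-allele dosages: `0/0 -> 0`, `0/1 -> 1`,
#' `1/1 -> 2`, `./. -> NA`, with ALT taken as the candidate minor allele and
#' every locus then re-polarized so that dosage counts the true minor allele
#' by observed frequency. Multi-allelic records are skipped with a warning.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0) stop("VCF contains no genotype records")
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    stop("VCF records lack a GT field")
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  bad_allele <- !(fix$REF %in% c("A", "C", "G", "T")) |
    (!multi & !(fix$ALT %in% c("A", "C", "G", "T")))
  drop <- multi | bad_allele
  if (any(drop)) {
    warning(sum(drop), " non-biallelic-SNP record(s) skipped")
  }
  if (all(drop)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[!drop, , drop = FALSE]
  fix <- fix[!drop, , drop = FALSE]
  alt_dosage <- function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  dos <- apply(gt, c(1, 2), alt_dosage)
  calls <- t(dos)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0("S", fix$CHROM, "_",
                                         fix$POS)[is.na(ids) | ids == "."]
  gm <- genotype_matrix(calls,
                        data.frame(id = ids, chrom = fix$CHROM,
                                   pos = as.integer(fix$POS),
                                   major = fix$REF, minor = fix$ALT,
                                   stringsAsFactors = FALSE))
  polarize_minor(gm)
}
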