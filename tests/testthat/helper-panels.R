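# in-code fixtures shared across test files

# small genotype_matrix straight from a dosage matrix
toy_gm <- function(calls, chrom = NULL) {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1A", L)
  genotype_matrix(calls,
                  data.frame(id = paste0("m", seq_len(L)), chrom = chrom,
                             pos = seq_len(L) * 1000L,
                             major = rep("A", L), minor = rep("G", L),
                             stringsAsFactors = FALSE))
}

# random panel via the simulator (already polarized and wheat-shaped)
random_panel <- function(n = 10, L = 20, fst = 0.1, missing = 0,
                         het = 0.02, seed = 1) {
  simulate_panel(sim_config(n_per_group = c(ceiling(n / 2), floor(n / 2)),
                            n_loci = L, fst = fst, residual_het = het,
                            missing_rate = missing, seed = seed))$gm
}

# write a HapMap file from header + body lines
write_hapmap_text <- function(rows, samples) {
  path <- tempfile(fileext = ".hmp.txt")
  header <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                    "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                    samples), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

hapmap_row <- function(id, alleles, chrom, pos, calls) {
  paste(c(id, alleles, chrom, pos, "+", rep("NA", 6), calls),
        collapse = "\t")
}

# minimal VCF 4.2 text file
write_vcf_text <- function(records, samples) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
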