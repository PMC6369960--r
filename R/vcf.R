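#' Read genotype records from a multi-sample VCF
#'
#' Thin wrapper around `VariantAnnotation::readVcf()` producing the
#' [genotype_set()] consumed by [filter_informative()] and
#' [counts_from_genotypes()]. Only biallelic SNVs are kept (others are
#' dropped with a message). `GT` is required; `GQ` and `AD` are carried
#' when present.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param genome genome label passed to the VCF reader.
#' @return a [genotype_set()].
#' @export
read_genotypes_vcf <- function(path, genome = "unknown") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCFs requires the VariantAnnotation package")
  v <- VariantAnnotation::readVcf(path, genome = genome)
  ref <- as.character(VariantAnnotation::ref(v))
  alt1 <- vapply(as.list(VariantAnnotation::alt(v)), function(a) {
    if (length(a) == 1) as.character(a) else NA_character_
  }, character(1))
  keep <- !is.na(alt1) & nchar(ref) == 1 & nchar(alt1) == 1
  if (any(!keep))
    message("dropping ", sum(!keep), " non-biallelic/non-SNV record(s)")
  geno <- VariantAnnotation::geno(v)
  gt <- geno$GT[keep, , drop = FALSE]
  gq <- if ("GQ" %in% names(geno)) geno$GQ[keep, , drop = FALSE] else NULL
  ad <- if ("AD" %in% names(geno)) geno$AD[keep, , drop = FALSE] else NULL
  rr <- SummarizedExperiment::rowRanges(v)[keep]
  genotype_set(chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = BiocGenerics::start(rr),
               ref = ref[keep], alt = alt1[keep],
               gt = gt, gq = gq, ad = ad, samples = colnames(gt))
}
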