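# Small builders shared across test files. Everything is generated in code;
# no stored fixtures.

make_counts <- function(pos, germ_lyr, germ_hal, soma_lyr = germ_lyr,
                        soma_hal = germ_hal, chrom = "chr1") {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             allele_lyr = rep_len("A", n), allele_hal = rep_len("T", n),
             soma_lyr = soma_lyr, soma_hal = soma_hal,
             germ_lyr = germ_lyr, germ_hal = germ_hal,
             stringsAsFactors = FALSE)
}

# Linear 1 cM/Mb map over a single chromosome, the simulator default.
toy_map <- function(length_bp = 25e6, chrom = "chr1") {
  linear_map(chrom, length_bp)
}

# Independent oracle for the chromosome likelihood: per-read product.
# Walks every single read and multiplies its probability of showing the
# lyrata-lineage allele; identical to the binomial form without the
# coefficient. Deliberately naive.
brute_force_loglik <- function(counts, map, chrom, i, k, error_rate, bias) {
  ll <- 0
  for (s in seq_len(nrow(counts))) {
    r <- recomb_fraction(map, chrom, i, counts$pos[s])
    q <- k * (1 - r) + (1 - k) * r
    qp <- q * (1 - error_rate) + (1 - q) * error_rate
    p <- bias * qp / (bias * qp + (1 - qp))
    if (counts$germ_lyr[s] > 0)
      for (rd in seq_len(counts$germ_lyr[s])) ll <- ll + log(p)
    if (counts$germ_hal[s] > 0)
      for (rd in seq_len(counts$germ_hal[s])) ll <- ll + log(1 - p)
  }
  ll
}

# The four sampling configurations for observing allele A at a marker:
# distorter-allele chromosome x (no) recombination x (no) error.
four_term_prob <- function(k, r, E) {
  k * (1 - r) * (1 - E) +      # A-carrying chromosome, no recomb, no error
    (1 - k) * r * (1 - E) +    # a-carrying chromosome, recomb, no error
    k * r * E +                # A chromosome recombined away, error back to A
    (1 - k) * (1 - r) * E      # a chromosome retained, error to A
}

# Six-sample toy VCF (two parents per species, F1 soma + germ) with GT/GQ/AD.
write_toy_vcf <- function(path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "lyr1", "lyr2", "hal1", "hal2", "f1s", "f1g",
          sep = "\t"))
  gt <- function(g, gq, ad) paste(g, gq, ad, sep = ":")
  rows <- c(
    # informative: lyrata ref-fixed, halleri alt-fixed, F1 het
    paste("chr1", 1000, ".", "A", "T", 50, "PASS", ".", "GT:GQ:AD",
          gt("0/0", 99, "20,0"), gt("0/0", 99, "22,0"),
          gt("1/1", 99, "0,25"), gt("1/1", 99, "0,21"),
          gt("0/1", 99, "11,9"), gt("0/1", 99, "14,6"), sep = "\t"),
    # informative the other way round (lyrata alt-fixed)
    paste("chr1", 2000, ".", "G", "C", 50, "PASS", ".", "GT:GQ:AD",
          gt("1/1", 99, "0,18"), gt("1/1", 99, "0,20"),
          gt("0/0", 99, "19,0"), gt("0/0", 99, "23,0"),
          gt("0/1", 99, "10,10"), gt("0/1", 99, "7,13"), sep = "\t"),
    # one parent heterozygous: not fixed between species
    paste("chr1", 3000, ".", "A", "G", 50, "PASS", ".", "GT:GQ:AD",
          gt("0/1", 99, "9,10"), gt("0/0", 99, "18,0"),
          gt("1/1", 99, "0,20"), gt("1/1", 99, "0,22"),
          gt("0/1", 99, "10,10"), gt("0/1", 99, "12,8"), sep = "\t"),
    # F1 homozygous
    paste("chr1", 4000, ".", "C", "T", 50, "PASS", ".", "GT:GQ:AD",
          gt("0/0", 99, "21,0"), gt("0/0", 99, "19,0"),
          gt("1/1", 99, "0,24"), gt("1/1", 99, "0,18"),
          gt("0/0", 99, "20,0"), gt("0/1", 99, "9,11"), sep = "\t"),
    # low genotype quality
    paste("chr1", 5000, ".", "T", "G", 50, "PASS", ".", "GT:GQ:AD",
          gt("0/0", 10, "12,0"), gt("0/0", 99, "20,0"),
          gt("1/1", 99, "0,19"), gt("1/1", 99, "0,21"),
          gt("0/1", 99, "10,10"), gt("0/1", 99, "8,12"), sep = "\t"))
  writeLines(c(hdr, rows), path)
  path
}
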