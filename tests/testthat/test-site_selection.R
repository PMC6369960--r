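# Site selection: fixed-difference/heterozygote rule, depth quantiles,
# spacing.

toy_genotypes <- function() {
  # six sites: 2 informative, 1 parent-het, 1 F1-homozygous, 1 shared
  # allele between species, 1 low GQ
  gt <- rbind(
    c("0/0", "0/0", "1/1", "1/1", "0/1", "0/1"),  # informative (lyr = ref)
    c("1/1", "1/1", "0/0", "0/0", "0/1", "0/1"),  # informative (lyr = alt)
    c("0/1", "0/0", "1/1", "1/1", "0/1", "0/1"),  # parent heterozygous
    c("0/0", "0/0", "1/1", "1/1", "0/0", "0/1"),  # F1 homozygous
    c("0/0", "0/0", "0/0", "0/0", "0/1", "0/1"),  # same allele in both species
    c("0/0", "0/0", "1/1", "1/1", "0/1", "0/1"))  # informative but low GQ
  gq <- matrix(99, 6, 6)
  gq[6, 1] <- 10
  genotype_set(chrom = rep("chr1", 6), pos = c(100, 300, 500, 700, 900, 1100),
               ref = c("A", "G", "A", "C", "T", "A"),
               alt = c("T", "C", "G", "T", "G", "C"),
               gt = gt, gq = gq,
               samples = c("lyr1", "lyr2", "hal1", "hal2", "f1s", "f1g"))
}

toy_roles <- list(lyrata = c("lyr1", "lyr2"), halleri = c("hal1", "hal2"),
                  f1 = c("f1s", "f1g"))

test_that("filter_informative enforces the fixed-difference/het/GQ rules", {
  sites <- filter_informative(toy_genotypes(), toy_roles, min_gq = 30)
  expect_equal(sites$pos, c(100, 300))
  # allele labels follow which parental lineage is homozygous for which
  expect_equal(sites$allele_lyr, c("A", "C"))
  expect_equal(sites$allele_hal, c("T", "G"))
  # dropping the quality filter rescues the low-GQ site only
  sites10 <- filter_informative(toy_genotypes(), toy_roles, min_gq = 10)
  expect_equal(sites10$pos, c(100, 300, 1100))
})

test_that("missing genotypes drop a site; missing samples are an error", {
  g <- toy_genotypes()
  g$gt[1, 3] <- "./."
  g$gt[2, 5] <- NA
  expect_equal(nrow(filter_informative(g, toy_roles)), 0)
  bad_roles <- toy_roles
  bad_roles$halleri <- c("hal1", "nope")
  expect_error(filter_informative(toy_genotypes(), bad_roles), "absent")
  expect_error(filter_informative(toy_genotypes(), toy_roles["f1"]),
               "roles")
})

test_that("depth-quantile filter uses closed nearest-rank interval", {
  sites <- data.frame(chrom = "chr1", pos = seq_len(100) * 1000)
  depths <- sample(1:100) # one depth per site, values 1..100
  res <- filter_depth_quantiles(sites, depths, 0.10, 0.90)
  expect_equal(unname(res$cutoffs), c(10, 90))
  expect_setequal(sites$pos[depths >= 10 & depths <= 90], res$sites$pos)
  expect_equal(nrow(res$sites), 81)
  # (0, 1) is the identity
  expect_equal(filter_depth_quantiles(sites, depths, 0, 1)$sites, sites)
  # all depths equal: everything retained
  all40 <- filter_depth_quantiles(sites, rep(40, 100), 0.10, 0.90)
  expect_equal(nrow(all40$sites), 100)
  # idempotent at the realized cutoffs (re-estimating quantiles on the
  # truncated distribution would shrink further; cutoffs are returned for
  # exactly this reason)
  d2 <- depths[res$kept]
  again <- res$sites[d2 >= res$cutoffs["lower"] & d2 <= res$cutoffs["upper"], ]
  expect_equal(again, res$sites)
  # re-application can only shrink (subset property)
  again_q <- filter_depth_quantiles(res$sites, d2, 0.10, 0.90)
  expect_true(all(again_q$sites$pos %in% res$sites$pos))
  expect_error(filter_depth_quantiles(sites[0, ], numeric(0)), "empty")
})

test_that("spacing filter keeps greedy left-to-right survivors", {
  s <- data.frame(chrom = "chr1", pos = c(100, 150, 260, 500))
  expect_equal(enforce_spacing(s, 100)$pos, c(100, 260, 500))
  expect_equal(enforce_spacing(s[1, , drop = FALSE], 100)$pos, 100)
  # per-chromosome: each chromosome keeps its own leftmost site
  s2 <- data.frame(chrom = rep(c("chr1", "chr2"), each = 2),
                   pos = c(100, 150, 100, 150))
  expect_equal(enforce_spacing(s2, 100)$pos, c(100, 100))
  expect_error(enforce_spacing(data.frame(chrom = "chr1",
                                          pos = c(500, 100))), "sorted")
})

test_that("spacing output always exceeds the gap; filter is idempotent", {
  set.seed(11)
  for (rep in 1:5) {
    s <- data.frame(chrom = sort(sample(c("c1", "c2"), 200, replace = TRUE)),
                    pos = NA)
    s$pos <- unlist(lapply(split(s$chrom, s$chrom),
                           function(x) sort(sample.int(5000, length(x)))))
    s <- s[order(s$chrom, s$pos), ]
    rownames(s) <- NULL
    out <- enforce_spacing(s, 100)
    gaps <- unlist(lapply(split(out$pos, out$chrom), diff))
    expect_true(all(gaps > 100))
    expect_equal(enforce_spacing(out, 100), out)
    expect_true(nrow(out) <= nrow(s))
  }
})

test_that("VCF round trip: genotypes -> informative sites -> counts", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path)
  g <- read_genotypes_vcf(path)
  expect_s3_class(g, "sd_genotypes")
  expect_equal(length(g$pos), 5)
  sites <- filter_informative(
    g, list(lyrata = c("lyr1", "lyr2"), halleri = c("hal1", "hal2"),
            f1 = c("f1s", "f1g")), min_gq = 30)
  expect_equal(sites$pos, c(1000, 2000))
  counts <- counts_from_genotypes(g, sites, soma = "f1s", germ = "f1g")
  # at pos 1000 lyrata carries the ref allele: AD = (11,9) soma, (14,6) germ
  expect_equal(counts$soma_lyr, c(11, 10))
  expect_equal(counts$soma_hal, c(9, 10))
  expect_equal(counts$germ_lyr, c(14, 13))
  expect_equal(counts$germ_hal, c(6, 7))
  expect_equal(counts$allele_lyr, c("A", "C"))
})
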