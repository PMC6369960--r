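#' Container for multi-sample genotype records
#'
#' Light-weight holder for per-site, per-sample genotype calls used by
#' [filter_informative()]. Genotypes are VCF-style strings (`"0/0"`,
#' `"0/1"`, `"1/1"`, phased `"|"` accepted, `"./."` or `NA` = missing).
#'
#' @param chrom,pos,ref,alt per-site chromosome, 1-based position and
#'   allele labels.
#' @param gt character matrix (sites x samples) of genotype calls.
#' @param gq optional numeric matrix of genotype qualities (same shape);
#'   when absent all sites pass any quality threshold.
#' @param ad optional list-matrix or 3-d array of allelic depths
#'   `(ref, alt)` per site and sample, used by [counts_from_genotypes()].
#' @param samples sample names; default `colnames(gt)`.
#' @return list of class `sd_genotypes`.
#' @export
genotype_set <- function(chrom, pos, ref, alt, gt, gq = NULL, ad = NULL,
                         samples = colnames(gt)) {
  gt <- as.matrix(gt)
  n <- length(pos)
  stopifnot(length(chrom) == n, nrow(gt) == n, all(pos >= 1))
  if (is.null(samples)) stop("sample names are required")
  colnames(gt) <- samples
  if (is.null(gq)) gq <- matrix(Inf, n, ncol(gt))
  gq <- as.matrix(gq)
  stopifnot(all(dim(gq) == dim(gt)))
  colnames(gq) <- samples
  structure(list(chrom = as.character(chrom), pos = as.numeric(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 gt = gt, gq = gq, ad = ad, samples = samples),
            class = "sd_genotypes")
}

norm_gt <- function(x) {
  x <- gsub("|", "/", x, fixed = TRUE)
  x[x %in% c(".", "./.", "")] <- NA_character_
  x
}

#' Select ancestry-informative sites from genotype records
#'
#' Retains exactly the sites that are fixed between the parental species
#' and heterozygous in every F1 sample: all lyrata-lineage parents
#' homozygous for one allele, all halleri-lineage parents homozygous for
#' the other, all F1 samples heterozygous, every genotype quality at or
#' above `min_gq`, and no missing genotypes (sites with any missing call
#' are dropped).
#'
#' @param genotypes a [genotype_set()].
#' @param roles named list with character vectors `lyrata`, `halleri` and
#'   `f1` giving the sample names of each role (F1 entries are typically
#'   the somatic and germline libraries of the same individual).
#' @param min_gq minimum genotype quality (default 30).
#' @return data.frame of informative sites: `chrom`, `pos`, `allele_lyr`,
#'   `allele_hal` (the allele labels carried by each parental lineage).
#' @export
filter_informative <- function(genotypes, roles, min_gq = 30) {
  stopifnot(inherits(genotypes, "sd_genotypes"))
  req <- c("lyrata", "halleri", "f1")
  if (!all(req %in% names(roles)))
    stop("`roles` must name samples for: ", paste(req, collapse = ", "))
  missing_samples <- setdiff(unlist(roles[req]), genotypes$samples)
  if (length(missing_samples) > 0)
    stop("sample column(s) absent from genotypes: ",
         paste(missing_samples, collapse = ", "))
  gt <- apply(genotypes$gt, 2, norm_gt)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, genotypes$samples))
  lyr <- gt[, roles$lyrata, drop = FALSE]
  hal <- gt[, roles$halleri, drop = FALSE]
  f1 <- gt[, roles$f1, drop = FALSE]
  all_eq <- function(m, val) rowSums(m == val, na.rm = TRUE) == ncol(m) &
    rowSums(is.na(m)) == 0
  het <- rowSums(f1 == "0/1" | f1 == "1/0", na.rm = TRUE) == ncol(f1) &
    rowSums(is.na(f1)) == 0
  gq_ok <- rowSums(genotypes$gq[, unlist(roles[req]), drop = FALSE] <
                     min_gq) == 0
  gq_ok[is.na(gq_ok)] <- FALSE
  lyr_ref <- all_eq(lyr, "0/0") & all_eq(hal, "1/1")
  lyr_alt <- all_eq(lyr, "1/1") & all_eq(hal, "0/0")
  keep <- (lyr_ref | lyr_alt) & het & gq_ok
  data.frame(chrom = genotypes$chrom[keep], pos = genotypes$pos[keep],
             allele_lyr = ifelse(lyr_ref[keep], genotypes$ref[keep],
                                 genotypes$alt[keep]),
             allele_hal = ifelse(lyr_ref[keep], genotypes$alt[keep],
                                 genotypes$ref[keep]),
             stringsAsFactors = FALSE)
}

#' Filter sites by empirical depth quantiles
#'
#' Retains sites whose total depth lies in the closed interval
#' `[Q(lower_q), Q(upper_q)]` of the empirical depth distribution, the
#' standard guard against collapsed repeats and other structural variants
#' that distort pooled allele frequencies. Quantiles use the nearest-rank
#' (type 1) convention; the realized absolute cutoffs are returned so runs
#' can be reproduced with fixed thresholds.
#'
#' @param sites data.frame of sites (any columns; one row per site).
#' @param total_depths numeric vector, one total depth per site.
#' @param lower_q,upper_q quantile bounds, `0 <= lower_q < upper_q <= 1`
#'   (defaults 0.10 / 0.90).
#' @return list with `sites` (the filtered data.frame), `cutoffs` (named
#'   vector `lower`/`upper` of realized depths) and `kept` (logical).
#' @export
filter_depth_quantiles <- function(sites, total_depths, lower_q = 0.10,
                                   upper_q = 0.90) {
  if (nrow(sites) == 0) stop("empty site list")
  stopifnot(length(total_depths) == nrow(sites),
            lower_q >= 0, upper_q <= 1, lower_q < upper_q)
  cuts <- stats::quantile(total_depths, c(lower_q, upper_q), type = 1,
                          names = FALSE)
  kept <- total_depths >= cuts[1] & total_depths <= cuts[2]
  list(sites = sites[kept, , drop = FALSE],
       cutoffs = c(lower = cuts[1], upper = cuts[2]),
       kept = kept)
}

#' Enforce a minimum spacing between informative sites
#'
#' Greedy left-to-right retention per chromosome: a site is kept iff its
#' position exceeds the last kept position on the same chromosome by more
#' than `min_gap_bp`. This precludes a single read spanning (and being
#' counted at) two retained sites.
#'
#' @param sites data.frame with `chrom` and `pos`, sorted by
#'   (chromosome, position); unsorted input is an error.
#' @param min_gap_bp minimum distance in bp (default 100).
#' @return the filtered data.frame.
#' @export
enforce_spacing <- function(sites, min_gap_bp = 100) {
  if (nrow(sites) == 0) return(sites)
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("sites must be sorted by (chromosome, position)")
  keep <- unlist(lapply(split(sites$pos, sites$chrom)[unique(sites$chrom)],
                        cpp_spacing, min_gap = min_gap_bp),
                 use.names = FALSE)
  sites[keep, , drop = FALSE]
}

#' Assemble per-library allele counts at informative sites
#'
#' Looks up the allelic depths (`AD`) of the F1 somatic and germline
#' libraries at each informative site and maps ref/alt depths to
#' lyrata/halleri-lineage counts. Counts are summed when a role lists
#' several libraries.
#'
#' @param genotypes a [genotype_set()] carrying allelic depths (`ad`).
#' @param sites informative sites from [filter_informative()] (needs
#'   `chrom`, `pos`, `allele_lyr`).
#' @param soma,germ sample name(s) of the somatic and germline libraries.
#' @return the standard 8-column counts data.frame (see [read_counts()]).
#' @export
counts_from_genotypes <- function(genotypes, sites, soma, germ) {
  stopifnot(inherits(genotypes, "sd_genotypes"))
  if (is.null(genotypes$ad))
    stop("genotypes carry no allelic depths (ad); counts cannot be derived")
  key_g <- paste(genotypes$chrom, genotypes$pos)
  idx <- match(paste(sites$chrom, sites$pos), key_g)
  if (anyNA(idx)) stop("some sites are absent from the genotype records")
  get_ad <- function(samples, allele_idx) {
    tot <- numeric(nrow(sites))
    for (s in samples) {
      j <- match(s, genotypes$samples)
      if (is.na(j)) stop("sample column absent: ", s)
      ad_s <- genotypes$ad[idx, j]
      tot <- tot + vapply(seq_along(ad_s),
                          function(ii) as.numeric(ad_s[[ii]][allele_idx[ii]]),
                          numeric(1))
    }
    tot
  }
  lyr_is_ref <- sites$allele_lyr == genotypes$ref[idx]
  il <- ifelse(lyr_is_ref, 1L, 2L)
  ih <- ifelse(lyr_is_ref, 2L, 1L)
  data.frame(chrom = sites$chrom, pos = sites$pos,
             allele_lyr = sites$allele_lyr, allele_hal = sites$allele_hal,
             soma_lyr = get_ad(soma, il), soma_hal = get_ad(soma, ih),
             germ_lyr = get_ad(germ, il), germ_hal = get_ad(germ, ih),
             stringsAsFactors = FALSE)
}
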