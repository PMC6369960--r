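#' Windowed raw ancestry ratios
#'
#' Summarizes paired somatic/germline counts in nonoverlapping windows of a
#' fixed number of SNPs (default 1000) per chromosome: the lyrata-read
#' fraction of each library and their difference
#' (germline minus somatic). Positive differences indicate excess lyrata
#' ancestry in the germline. The terminal window of a chromosome holds the
#' remainder; windows with zero total depth in a library yield `NA`
#' fractions.
#'
#' @param counts counts data.frame (see [read_counts()]), sorted by
#'   position within chromosome.
#' @param snps_per_window SNPs per window.
#' @return data.frame with one row per window: `chrom`, `window`, `start`,
#'   `end`, `n_sites`, `germ_frac`, `soma_frac`, `diff`.
#' @export
window_ratios <- function(counts, snps_per_window = 1000) {
  stopifnot(snps_per_window >= 1)
  out <- lapply(unique(as.character(counts$chrom)), function(ch) {
    d <- counts[counts$chrom == ch, , drop = FALSE]
    if (is.unsorted(d$pos)) stop("counts must be sorted by position")
    n <- nrow(d)
    win <- (seq_len(n) - 1) %/% snps_per_window + 1
    do.call(rbind, lapply(split(seq_len(n), win), function(ii) {
      gt <- sum(d$germ_lyr[ii]) + sum(d$germ_hal[ii])
      st <- sum(d$soma_lyr[ii]) + sum(d$soma_hal[ii])
      gf <- if (gt > 0) sum(d$germ_lyr[ii]) / gt else NA_real_
      sf <- if (st > 0) sum(d$soma_lyr[ii]) / st else NA_real_
      data.frame(chrom = ch, window = win[ii[1]], start = d$pos[ii[1]],
                 end = d$pos[ii[length(ii)]], n_sites = length(ii),
                 germ_frac = gf, soma_frac = sf, diff = gf - sf)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Relative viability of gametes carrying the disfavored allele
#'
#' Solves `1/(1 + X) = k_maj` for `X`, where `k_maj = max(k, 1 - k)` is the
#' majority-class fraction of the germline ancestry ratio: `X = (1 -
#' k_maj)/k_maj` is the viability of gametes carrying the disfavored allele
#' relative to the favored one, so `X <= 1` always reports the disfavored
#' side regardless of which parental lineage is in the majority.
#'
#' @param k germline segregation ratio(s) in (0, 1).
#' @return relative viability `X` in (0, 1].
#' @export
relative_viability <- function(k) {
  if (any(k <= 0 | k >= 1)) stop("k must lie strictly within (0, 1)")
  kmaj <- pmax(k, 1 - k)
  (1 - kmaj) / kmaj
}

#' Proportional decrease in viable gamete production at one locus
#'
#' `(1 - X)/2` with `X` the [relative_viability()]: half the gametes carry
#' the disfavored allele and each survives with relative viability `X`, so
#' the pool loses a fraction `(1 - X)/2` of its production.
#'
#' @inheritParams relative_viability
#' @return fraction of gamete production lost, in `[0, 0.5)`.
#' @export
viability_decrease <- function(k) {
  (1 - relative_viability(k)) / 2
}

#' Combined viability decrease across distorting loci
#'
#' `"independent"`: per-locus viable fractions `1 - decrease_l` multiply
#' across loci (each locus an independent distorter), giving
#' `1 - prod(1 - decrease_l)`. `"minimum"`: uses only the maximally
#' distorted locus as a lower bound, appropriate when the skews may reflect
#' non-independent allelic interactions.
#'
#' @param k germline segregation ratios, one per locus.
#' @param model `"independent"` or `"minimum"`.
#' @return combined fraction of gamete production lost.
#' @export
combined_decrease <- function(k, model = c("independent", "minimum")) {
  model <- match.arg(model)
  if (length(k) < 1) stop("supply at least one k")
  dec <- viability_decrease(k)
  if (model == "independent") 1 - prod(1 - dec) else max(dec)
}

#' Rate of origination of segregation distortion loci
#'
#' Divides the total branch length separating the two lineages
#' (`lineages * divergence_years`, default both branches of the split) by
#' the number of distorters detected, giving the waiting time between
#' origination-and-spread events, reported as "one per `value` years".
#'
#' @param n_loci number of distorting loci detected (>= 1).
#' @param divergence_years divergence time of the two lineages in years.
#' @param lineages number of lineages the distorters accumulated over
#'   (2 = both branches, the default convention; 1 = per-lineage rate).
#' @return years per new distorter.
#' @export
distorter_rate <- function(n_loci, divergence_years, lineages = 2) {
  stopifnot(n_loci >= 1, divergence_years > 0, lineages %in% c(1, 2))
  lineages * divergence_years / n_loci
}
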