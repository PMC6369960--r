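counts_cols <- c("chrom", "pos", "allele_lyr", "allele_hal",
                 "soma_lyr", "soma_hal", "germ_lyr", "germ_hal")

#' Read / write the standard allele-counts table
#'
#' The counts dialect is a tab-separated table with header columns
#' `chrom, pos, allele_lyr, allele_hal, soma_lyr, soma_hal, germ_lyr,
#' germ_hal`: per ancestry-informative site, the read counts of the two
#' parental-lineage alleles in the somatic and germline libraries of one
#' F1 individual. Positions are 1-based bp.
#'
#' @param path file path.
#' @return `read_counts`: the validated data.frame.
#' @export
read_counts <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  validate_counts(x)
}

#' @rdname read_counts
#' @param counts counts data.frame.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_counts <- function(x) {
  miss <- setdiff(counts_cols, names(x))
  if (length(miss) > 0)
    stop("counts table lacks column(s): ", paste(miss, collapse = ", "))
  cc <- c("soma_lyr", "soma_hal", "germ_lyr", "germ_hal")
  for (col in cc)
    if (any(x[[col]] < 0)) stop("negative counts in ", col)
  if (any(x$pos < 1)) stop("positions must be >= 1 (1-based bp)")
  x[counts_cols]
}

#' Read a recombination-map anchor table
#'
#' Tab-separated with header `chrom, pos, cM`: cumulative genetic position
#' (centiMorgans) at physical anchor points. `zero_based = TRUE` accepts
#' BED-like 0-based positions and shifts them to 1-based.
#'
#' @param path file path.
#' @param zero_based are the physical positions 0-based?
#' @param ... passed to [genetic_map()].
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path, zero_based = FALSE, ...) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "cM") %in% names(x)))
    stop("map table needs columns chrom, pos, cM")
  if (zero_based) x$pos <- x$pos + 1
  genetic_map(x, ...)
}

#' Write scan results as JSON
#'
#' One record per chromosome with the position estimate, `K_s`, `K_g`, the
#' likelihood-ratio statistic, nominal p-value and any bootstrap CI.
#'
#' @param results an `sd_scan`, a list of them, or the output of
#'   [scan_genome()].
#' @param path output path.
#' @export
write_scan_json <- function(results, path) {
  if (is.list(results) && !is.null(results$scans)) results <- results$scans
  if (inherits(results, "sd_scan")) results <- list(results)
  recs <- lapply(results, function(x) {
    r <- list(chrom = x$chrom, i_star = x$i_star, ks = x$ks, kg = x$kg,
              lr = x$lr, p_value = x$p_value, n_sites = x$n_sites)
    if (!is.null(x$ci))
      r <- c(r, list(ci_lower = x$ci$lower, ci_upper = x$ci$upper,
                     bootstraps = x$ci$B, level = x$ci$level))
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
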