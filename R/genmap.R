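#' Build a genetic map from physical/genetic anchor points
#'
#' Fits a monotone piecewise-linear map from physical position (bp) to
#' cumulative genetic position per chromosome. Evaluation reproduces every
#' anchor exactly and interpolates linearly between anchors; beyond the
#' terminal anchors the map extrapolates with the terminal segment's slope
#' (or, with `extrapolate = "clamp"`, holds the terminal genetic position).
#'
#' The piecewise-linear form is the simplest monotone interpolator of a
#' cumulative recombination map; any monotone interpolator can be swapped in
#' by supplying denser anchors.
#'
#' @param anchors data.frame with columns `chrom`, `pos` (1-based bp) and
#'   `cM` (cumulative centiMorgans, non-decreasing in `pos` within each
#'   chromosome).
#' @param extrapolate `"slope"` (default) or `"clamp"`; behaviour beyond the
#'   terminal anchors of each chromosome.
#' @return An object of class `genetic_map`.
#' @examples
#' gm <- genetic_map(data.frame(chrom = "chr1",
#'                              pos = c(1, 1e6, 2e6),
#'                              cM = c(0, 1, 5)))
#' map_position(gm, "chr1", 1.5e6) # 0.03 Morgans
#' @seealso [map_position()], [recomb_fraction()]
#' @export
genetic_map <- function(anchors, extrapolate = c("slope", "clamp")) {
  extrapolate <- match.arg(extrapolate)
  req <- c("chrom", "pos", "cM")
  if (!is.data.frame(anchors) || !all(req %in% names(anchors)))
    stop("`anchors` must be a data.frame with columns chrom, pos, cM")
  if (any(anchors$pos < 1)) stop("anchor positions must be >= 1 (1-based bp)")
  chroms <- unique(as.character(anchors$chrom))
  maps <- lapply(chroms, function(ch) {
    a <- anchors[anchors$chrom == ch, , drop = FALSE]
    if (nrow(a) < 2)
      stop("chromosome ", ch, ": need at least 2 anchors")
    if (is.unsorted(a$pos, strictly = TRUE))
      stop("chromosome ", ch, ": anchors must be sorted by strictly ",
           "increasing position")
    if (is.unsorted(a$cM))
      stop("chromosome ", ch, ": genetic positions (cM) must be ",
           "non-decreasing in physical position")
    list(pos = as.numeric(a$pos), cM = as.numeric(a$cM))
  })
  names(maps) <- chroms
  structure(list(chrom = maps, extrapolate = extrapolate),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", length(x$chrom), "chromosome(s)\n")
  for (ch in names(x$chrom)) {
    m <- x$chrom[[ch]]
    cat(sprintf("  %s: %d anchors, %.0f-%.0f bp, %.2f-%.2f cM\n", ch,
                length(m$pos), min(m$pos), max(m$pos), min(m$cM), max(m$cM)))
  }
  invisible(x)
}

#' Evaluate a genetic map at physical positions
#'
#' @param map a [genetic_map()] object.
#' @param chrom chromosome identifier (single value).
#' @param pos numeric vector of physical positions (bp).
#' @return Genetic positions in Morgans (100 cM = 1 Morgan).
#' @export
map_position <- function(map, chrom, pos) {
  stopifnot(inherits(map, "genetic_map"))
  chrom <- as.character(chrom)
  m <- map$chrom[[chrom]]
  if (is.null(m)) stop("chromosome ", chrom, " not covered by the map")
  x <- m$pos; y <- m$cM
  n <- length(x)
  out <- stats::approx(x, y, xout = pos, rule = 2, ties = "ordered")$y
  if (map$extrapolate == "slope") {
    left <- pos < x[1]
    if (any(left)) {
      sl <- max(0, (y[2] - y[1]) / (x[2] - x[1]))
      out[left] <- y[1] + sl * (pos[left] - x[1])
    }
    right <- pos > x[n]
    if (any(right)) {
      sr <- max(0, (y[n] - y[n - 1]) / (x[n] - x[n - 1]))
      out[right] <- y[n] + sr * (pos[right] - x[n])
    }
  }
  out / 100
}

#' Haldane's mapping function
#'
#' Converts genetic distance `d` (Morgans) to the probability that an odd
#' number of crossovers -- i.e. an observable recombination -- occurred in
#' the interval, assuming no crossover interference:
#' \deqn{r = (1 - e^{-2d})/2.}
#'
#' @param d non-negative genetic distance in Morgans.
#' @return Recombination probability in `[0, 0.5)`.
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("genetic distance must be non-negative")
  0.5 * (1 - exp(-2 * d))
}

#' Recombination probability between two positions on a chromosome
#'
#' Maps both physical positions to genetic positions and applies Haldane's
#' mapping function to their distance. Only defined within a chromosome.
#'
#' @inheritParams map_position
#' @param pos_i,pos_p physical positions (bp) on `chrom`; either may be a
#'   vector (recycled pairwise).
#' @return `r` in `[0, 0.5)`, symmetric in its two position arguments.
#' @export
recomb_fraction <- function(map, chrom, pos_i, pos_p) {
  if (length(chrom) != 1)
    stop("recombination probability is only defined within one chromosome")
  gi <- map_position(map, chrom, pos_i)
  gp <- map_position(map, chrom, pos_p)
  haldane(abs(gi - gp))
}

#' Linear genetic map for simulated genomes
#'
#' Convenience constructor for a constant-rate map (default 1 cM/Mb), the
#' default recombination landscape of the simulator.
#'
#' @param chroms chromosome names.
#' @param length_bp chromosome length in bp (recycled).
#' @param cM_per_Mb recombination rate.
#' @return A [genetic_map()].
#' @export
linear_map <- function(chroms, length_bp, cM_per_Mb = 1) {
  length_bp <- rep_len(length_bp, length(chroms))
  anchors <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    data.frame(chrom = chroms[i], pos = c(1, length_bp[i]),
               cM = c(0, (length_bp[i] - 1) / 1e6 * cM_per_Mb))
  }))
  genetic_map(anchors)
}
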