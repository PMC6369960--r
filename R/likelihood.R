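#' Probability that a sampled gamete chromosome carries the focal allele
#'
#' For a distorter with segregation ratio `k` (fraction of functional
#' gametes carrying the lyrata-lineage allele at the distorting site) and a
#' marker separated from it by recombination probability `r`, a sampled
#' gamete chromosome carries the lyrata-lineage allele at the marker with
#' probability
#' \deqn{q = k(1 - r) + (1 - k)\,r,}
#' the two terms being the no-recombination and recombination routes from
#' either distorter background.
#'
#' @param k segregation ratio in (0, 1); 0.5 is Mendelian.
#' @param r recombination probability in `[0, 0.5]`.
#' @return `q` in `[0, 1]`. Vectorized over `k` and `r`.
#' @export
ancestry_prob <- function(k, r) {
  if (any(k <= 0 | k >= 1)) stop("k must lie strictly within (0, 1)")
  if (any(r < 0 | r > 0.5)) stop("r must lie within [0, 0.5]")
  k * (1 - r) + (1 - k) * r
}

#' Per-read probability of observing the focal allele
#'
#' Mixes the gamete-chromosome ancestry probability `q` with a uniform
#' sequencing/mapping error `E`, then applies the reference-mapping bias as
#' a read-sampling odds `b`:
#' \deqn{q' = q(1-E) + (1-q)E, \qquad p = \frac{b\,q'}{b\,q' + (1-q')}.}
#' With `bias = 1` this reduces to the pure four-configuration error model
#' (distorter allele/no recombination/no error etc.); with `q = 0.5` it
#' returns `b/(1+b)`, so calibrating `b` from the somatic ratio `K_s` makes
#' a Mendelian germline reproduce the somatic ratio at every site.
#'
#' @param q ancestry probability from [ancestry_prob()].
#' @param error_rate uniform per-read error probability `E` in `[0, 0.5)`.
#' @param bias read-sampling odds `b > 0`; `K_s/(1 - K_s)` calibrates the
#'   null to the somatic ratio.
#' @return Probability of observing the lyrata-lineage allele in one read.
#' @export
read_prob <- function(q, error_rate = 0, bias = 1) {
  if (any(q < 0 | q > 1)) stop("q must lie within [0, 1]")
  if (any(error_rate < 0 | error_rate >= 0.5))
    stop("error_rate must lie within [0, 0.5)")
  if (any(bias <= 0)) stop("bias must be positive")
  qp <- q * (1 - error_rate) + (1 - q) * error_rate
  bias * qp / (bias * qp + (1 - qp))
}

#' Estimate the somatic null ancestry ratio K_s
#'
#' Maximum-likelihood estimate of the proportion of reads derived from the
#' lyrata lineage under the position-free somatic model
#' `P(lyrata read) = K_s (1 - E) + (1 - K_s) E`, binomial per site. The MLE
#' has the closed form `(f - E) / (1 - 2E)` where `f` is the pooled
#' lyrata-read fraction, clamped to (0, 1). `K_s` absorbs reference-mapping
#' bias and is the empirical null against which germline distortion is
#' tested.
#'
#' @param counts either a counts data.frame (columns `soma_lyr`,
#'   `soma_hal`; see [read_counts()]) or a numeric vector of per-site
#'   lyrata-allele counts.
#' @param n_hal numeric vector of halleri-allele counts when `counts` is a
#'   vector; ignored otherwise.
#' @param error_rate uniform error probability `E`.
#' @param weights optional non-negative per-site multiplicities (site
#'   bootstrap support).
#' @return `K_s`, a single fraction in (0, 1).
#' @export
estimate_null_ratio <- function(counts, n_hal = NULL, error_rate = 0.001,
                                weights = NULL) {
  if (is.data.frame(counts)) {
    n_lyr <- counts$soma_lyr
    n_hal <- counts$soma_hal
    if (is.null(n_lyr) || is.null(n_hal))
      stop("counts data.frame must have columns soma_lyr and soma_hal")
  } else {
    n_lyr <- counts
    if (is.null(n_hal)) stop("supply halleri counts via `n_hal`")
  }
  if (is.null(weights)) weights <- rep(1, length(n_lyr))
  tl <- sum(weights * n_lyr)
  th <- sum(weights * n_hal)
  if (tl + th <= 0) stop("no somatic reads: all-zero depth")
  f <- tl / (tl + th)
  ks <- (f - error_rate) / (1 - 2 * error_rate)
  min(max(ks, 1e-6), 1 - 1e-6)
}

## Internal: per-site recombination probabilities of `pos` (sites) to a
## candidate at `i`, all on `chrom`.
site_recomb <- function(map, chrom, pos, i) {
  g <- map_position(map, chrom, pos)
  gi <- map_position(map, chrom, i)
  haldane(abs(g - gi))
}

check_counts_chrom <- function(counts, chrom) {
  req <- c("chrom", "pos", "germ_lyr", "germ_hal")
  if (!all(req %in% names(counts)))
    stop("counts must have columns ", paste(req, collapse = ", "))
  if (!all(counts$chrom == chrom))
    stop("all counts must lie on chromosome ", chrom,
         " (found: ", paste(unique(counts$chrom), collapse = ", "), ")")
}

#' Chromosome-wide log-likelihood of germline counts given a distorter
#'
#' Sums, over informative sites `p` on the chromosome, the binomial
#' log-likelihood of the germline allele counts with success probability
#' `read_prob(ancestry_prob(k, r_ip), E, b)`, where `r_ip` is the Haldane
#' recombination probability between site `p` and the candidate distorter
#' position `i`. Binomial coefficients are omitted (constant in `k`);
#' zero-depth sites are skipped and reported in the bookkeeping.
#'
#' @param counts counts data.frame for one chromosome (see [read_counts()]).
#' @param map a [genetic_map()] covering `chrom`.
#' @param chrom chromosome identifier.
#' @param i candidate distorter physical position (bp).
#' @param k segregation ratio to evaluate.
#' @param error_rate uniform error probability `E`.
#' @param bias read-sampling odds `b` (1 disables mapping bias).
#' @param weights optional per-site multiplicities (site bootstrap).
#' @return list with `loglik`, `k`, `sites_used` (non-zero-depth sites) and
#'   `n_sites` (sites supplied).
#' @export
loglik_germline <- function(counts, map, chrom, i, k, error_rate = 0.001,
                            bias = 1, weights = NULL) {
  check_counts_chrom(counts, chrom)
  n <- nrow(counts)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n)
  if (n == 0)
    return(list(loglik = 0, k = k, sites_used = 0L, n_sites = 0L))
  if (length(k) != 1 || k <= 0 || k >= 1) stop("k must be a fraction in (0, 1)")
  r <- site_recomb(map, chrom, counts$pos, i)
  ll <- cpp_loglik(as.numeric(counts$germ_lyr), as.numeric(counts$germ_hal),
                   as.numeric(weights), r, k, error_rate, bias)
  used <- sum((counts$germ_lyr + counts$germ_hal) > 0 & weights > 0)
  list(loglik = ll, k = k, sites_used = as.integer(used),
       n_sites = as.integer(n))
}

#' Maximum-likelihood segregation ratio at a fixed candidate position
#'
#' Bounded derivative-free 1-D maximization (Brent, via [stats::optimize()])
#' of [loglik_germline()] in `k` at fixed position `i`.
#'
#' @inheritParams loglik_germline
#' @param bounds search interval for `k`, within (0, 1).
#' @param tol convergence tolerance on `k`.
#' @return list with `k` (the MLE, `K_g` when `i` is the scan maximum) and
#'   `loglik`.
#' @export
optimize_k <- function(counts, map, chrom, i, error_rate = 0.001, bias = 1,
                       bounds = c(1e-6, 1 - 1e-6), tol = 1e-6,
                       weights = NULL) {
  check_counts_chrom(counts, chrom)
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[2] < 1,
            bounds[1] < bounds[2])
  n <- nrow(counts)
  if (n == 0) stop("no sites supplied")
  if (is.null(weights)) weights <- rep(1, n)
  r <- site_recomb(map, chrom, counts$pos, i)
  nl <- as.numeric(counts$germ_lyr)
  nh <- as.numeric(counts$germ_hal)
  w <- as.numeric(weights)
  f <- function(k) cpp_loglik(nl, nh, w, r, k, error_rate, bias)
  opt <- stats::optimize(f, interval = bounds, maximum = TRUE, tol = tol)
  if (!is.finite(opt$objective))
    stop("non-finite likelihood in the search bracket")
  list(k = opt$maximum, loglik = opt$objective)
}
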