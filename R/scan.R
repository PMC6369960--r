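#' Likelihood-ratio position scan for a segregation distorter
#'
#' Scans candidate distorter positions along one chromosome. For each
#' candidate `i` the germline segregation ratio is profiled out
#' (`K_g(i)` maximizes the chromosome-wide likelihood) and the statistic
#' `LR(i) = 2 [logL(K_g(i)) - logL(null)]` is recorded; the reported
#' position estimate maximizes `LR` over the grid (smallest position on
#' ties).
#'
#' Two null operationalizations are available. The default, `"constant"`,
#' decomposes the somatic ratio `K_s` into a read-sampling odds
#' `b = K_s/(1 - K_s)` applied to every site, so the null "no distortion"
#' is `k = 0.5` with bias `b`: a constant expected germline ratio equal to
#' the somatic ratio, matching the use of `K_s` as the empirical null.
#' `"decay"` instead fixes `k = K_s` inside the unbiased (`b = 1`) decay
#' model at each candidate position.
#'
#' The nominal p-value applies the chi-square(1df) tail to the maximized
#' `LR`; because of the maximization over positions this is
#' anti-conservative, which is conventionally accommodated with a stringent
#' cutoff (see [significance_report()], default `alpha = 5e-4`).
#'
#' @param counts counts data.frame (see [read_counts()]); somatic columns
#'   of *all* rows (genome-wide) feed the `K_s` estimate, germline columns
#'   of the `chrom` rows feed the scan.
#' @param map a [genetic_map()] covering `chrom`.
#' @param chrom chromosome to scan.
#' @param error_rate uniform error probability `E`.
#' @param grid candidate positions (bp). Default: every informative-site
#'   position on `chrom` -- under the monotone Haldane decay, no
#'   between-site position can beat both flanking sites.
#' @param max_candidates cap on likelihood evaluations: when the grid is
#'   larger, a coarse scan over `max_candidates` evenly spaced grid points
#'   is refined around its maximum (both stages capped). `Inf` disables.
#' @param bins number of genetic-distance classes used to pool sites per
#'   candidate (runtime approximation for large site sets); `0` = exact.
#' @param null `"constant"` (default) or `"decay"`, see Details.
#' @param ks somatic null ratio; default estimated from the somatic
#'   columns of `counts` via [estimate_null_ratio()].
#' @param weights optional per-site multiplicities for the `chrom` sites
#'   (site bootstrap support).
#' @param bounds,tol_iters search interval for `k` and bisection iteration
#'   count of the profile optimizer.
#' @return An object of class `sd_scan`: list with `chrom`, `i_star`, `ks`,
#'   `kg`, `lr`, `p_value`, `profile` (data.frame `pos`, `k`, `lr`),
#'   `n_sites`, `sites_used`, and the model settings.
#' @export
scan_chromosome <- function(counts, map, chrom, error_rate = 0.001,
                            grid = NULL, max_candidates = Inf, bins = 0,
                            null = c("constant", "decay"), ks = NULL,
                            weights = NULL, bounds = c(1e-6, 1 - 1e-6),
                            tol_iters = 40L) {
  null <- match.arg(null)
  sub <- counts[counts$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) stop("no sites on chromosome ", chrom)
  if (is.unsorted(sub$pos)) sub <- sub[order(sub$pos), , drop = FALSE]
  n <- nrow(sub)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n)
    stop("weights must match the number of sites on ", chrom)
  if (is.null(ks))
    ks <- estimate_null_ratio(counts, error_rate = error_rate)
  b <- if (null == "constant") ks / (1 - ks) else 1
  if (is.null(grid)) grid <- unique(sub$pos)
  grid <- sort(unique(as.numeric(grid)))
  if (length(grid) == 0) stop("empty candidate grid")

  nl <- as.numeric(sub$germ_lyr)
  nh <- as.numeric(sub$germ_hal)
  w <- as.numeric(weights)
  g <- map_position(map, chrom, sub$pos)
  kfix <- if (null == "decay") ks else -1

  profile_at <- function(pos) {
    gc <- map_position(map, chrom, pos)
    pr <- cpp_scan_profile(nl, nh, w, g, gc, error_rate, b,
                           bounds[1], bounds[2], as.integer(bins),
                           as.integer(tol_iters), kfix)
    if (null == "constant") {
      pn <- read_prob(0.5, error_rate, b)
      ll0 <- sum(w * nl) * log(pn) + sum(w * nh) * log1p(-pn)
      lr <- 2 * (pr$loglik - ll0)
    } else {
      lr <- 2 * (pr$loglik - pr$loglik_fixed)
    }
    data.frame(pos = pos, k = pr$k, lr = pmax(0, lr))
  }

  thin <- function(x, m) {
    if (length(x) <= m) x else x[unique(round(seq(1, length(x),
                                                  length.out = m)))]
  }

  if (is.finite(max_candidates) && length(grid) > max_candidates) {
    coarse_pos <- thin(grid, max_candidates)
    prof <- profile_at(coarse_pos)
    jb <- which.max(prof$lr)
    lo <- coarse_pos[max(1, jb - 1)]
    hi <- coarse_pos[min(length(coarse_pos), jb + 1)]
    refine_pos <- setdiff(grid[grid >= lo & grid <= hi], coarse_pos)
    if (length(refine_pos) > 0) {
      refine_pos <- thin(refine_pos, max_candidates)
      prof <- rbind(prof, profile_at(refine_pos))
      prof <- prof[order(prof$pos), , drop = FALSE]
      rownames(prof) <- NULL
    }
  } else {
    prof <- profile_at(grid)
  }

  jmax <- which.max(prof$lr) # which.max takes the first (smallest pos) tie
  lr_max <- prof$lr[jmax]
  structure(list(
    chrom = chrom,
    i_star = prof$pos[jmax],
    ks = ks,
    kg = prof$k[jmax],
    lr = lr_max,
    p_value = stats::pchisq(lr_max, df = 1, lower.tail = FALSE),
    profile = prof,
    n_sites = n,
    sites_used = as.integer(sum((nl + nh) > 0 & w > 0)),
    error_rate = error_rate,
    bias = b,
    null = null,
    ci = NULL
  ), class = "sd_scan")
}

#' @export
print.sd_scan <- function(x, ...) {
  cat(sprintf("sd_scan: %s (%d sites, %d used)\n", x$chrom, x$n_sites,
              x$sites_used))
  cat(sprintf("  K_s = %.4f  K_g = %.4f  i* = %.0f bp\n", x$ks, x$kg,
              x$i_star))
  cat(sprintf("  LR = %.2f  nominal p = %.3g  (null: %s)\n", x$lr,
              x$p_value, x$null))
  if (!is.null(x$ci))
    cat(sprintf("  %g%% bootstrap CI: %.0f-%.0f bp (B = %d)\n",
                100 * x$ci$level, x$ci$lower, x$ci$upper, x$ci$B))
  invisible(x)
}

#' Bootstrap mapping confidence interval for the distorter position
#'
#' Resamples ancestry-informative sites along the chromosome with
#' replacement (paired somatic and germline counts move together), reruns
#' the position scan on each replicate, and returns the percentile interval
#' of the bootstrap position estimates. All randomness is determined by
#' `seed`.
#'
#' By default `K_s` is estimated once from the original somatic data and
#' held fixed across replicates; `reestimate_null = TRUE` re-estimates it
#' from each replicate's resampled somatic counts.
#'
#' Note the percentile interval is not guaranteed to contain the point
#' estimate `i*` of the original data.
#'
#' @inheritParams scan_chromosome
#' @param B number of bootstrap replicates (1000 is typical for real scans;
#'   simulation harnesses use 100-200).
#' @param level confidence level in (0, 1).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param reestimate_null re-estimate `K_s` from resampled somatic counts
#'   in each replicate?
#' @param ... further arguments passed to [scan_chromosome()] (`grid`,
#'   `max_candidates`, `bins`, `null`, ...).
#' @return list with `lower`, `upper` (bp), `positions` (the `B` bootstrap
#'   position estimates), `B` and `level`.
#' @export
bootstrap_ci <- function(counts, map, chrom, B = 1000, level = 0.95,
                         seed = NULL, error_rate = 0.001, ks = NULL,
                         reestimate_null = FALSE, ...) {
  if (B < 1) stop("B must be >= 1")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  sub <- counts[counts$chrom == chrom, , drop = FALSE]
  n <- nrow(sub)
  if (n == 0) stop("no sites on chromosome ", chrom)
  if (is.unsorted(sub$pos)) sub <- sub[order(sub$pos), , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ks))
    ks <- estimate_null_ratio(counts, error_rate = error_rate)
  pos_star <- numeric(B)
  for (bb in seq_len(B)) {
    w <- as.numeric(stats::rmultinom(1, n, rep(1 / n, n)))
    ks_b <- if (reestimate_null)
      estimate_null_ratio(sub, error_rate = error_rate, weights = w)
    else ks
    sc <- scan_chromosome(sub, map, chrom, error_rate = error_rate,
                          ks = ks_b, weights = w, ...)
    pos_star[bb] <- sc$i_star
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(pos_star, c(alpha, 1 - alpha), type = 1,
                        names = FALSE)
  list(lower = ci[1], upper = ci[2], positions = pos_star, B = as.integer(B),
       level = level)
}

#' Significance annotation across chromosome scans
#'
#' Flags each chromosome's scan as significant at the nominal level `alpha`
#' (uncorrected; the stringent default accommodates the scan's inherent
#' multiple testing) and also reports Bonferroni-across-chromosomes
#' p-values.
#'
#' @param results an `sd_scan` object or a list of them.
#' @param alpha nominal p-value cutoff (comparison is `<=`).
#' @return data.frame with one row per chromosome: `chrom`, `i_star`, `ks`,
#'   `kg`, `lr`, `p_value`, `p_bonferroni`, `significant`, and CI bounds
#'   when present.
#' @export
significance_report <- function(results, alpha = 0.0005) {
  if (inherits(results, "sd_scan")) results <- list(results)
  nchr <- length(results)
  rows <- lapply(results, function(x) {
    data.frame(chrom = x$chrom, i_star = x$i_star, ks = x$ks, kg = x$kg,
               lr = x$lr, p_value = x$p_value,
               ci_lower = if (is.null(x$ci)) NA_real_ else x$ci$lower,
               ci_upper = if (is.null(x$ci)) NA_real_ else x$ci$upper)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nchr)
  out$significant <- out$p_value <= alpha
  rownames(out) <- NULL
  out
}

#' Scan every chromosome of a counts table
#'
#' Convenience wrapper: estimates `K_s` once from the genome-wide somatic
#' counts, runs [scan_chromosome()] on each chromosome, optionally attaches
#' bootstrap confidence intervals, and returns the annotated table.
#'
#' @inheritParams scan_chromosome
#' @inheritParams bootstrap_ci
#' @param bootstrap number of bootstrap replicates per chromosome (0 = none).
#' @param alpha nominal significance cutoff.
#' @param ... passed to [scan_chromosome()].
#' @return list with `scans` (named list of `sd_scan`) and `table` (the
#'   [significance_report()] data.frame).
#' @export
scan_genome <- function(counts, map, error_rate = 0.001, bootstrap = 0,
                        level = 0.95, seed = NULL, alpha = 0.0005, ...) {
  ks <- estimate_null_ratio(counts, error_rate = error_rate)
  chroms <- unique(as.character(counts$chrom))
  scans <- lapply(chroms, function(ch) {
    sc <- scan_chromosome(counts, map, ch, error_rate = error_rate,
                          ks = ks, ...)
    if (bootstrap > 0) {
      ci <- bootstrap_ci(counts, map, ch, B = bootstrap, level = level,
                         seed = seed, error_rate = error_rate, ks = ks, ...)
      ci$positions <- NULL
      sc$ci <- ci
    }
    sc
  })
  names(scans) <- chroms
  list(scans = scans, table = significance_report(scans, alpha = alpha))
}
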