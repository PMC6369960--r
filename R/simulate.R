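#' Simulation configuration for pooled gamete/somatic counts
#'
#' Describes a scaled-down version of the empirical design: ancestry
#' informative sites scattered uniformly along a chromosome, constant
#' per-library per-site depth, a linear recombination map, a genome-wide
#' reference-mapping bias toward the lyrata lineage, uniform error, and a
#' single distorter whose effect decays with recombination distance.
#'
#' The somatic null ratio is estimated genome-wide in the real analysis, so
#' the simulator also generates Mendelian "background" chromosomes
#' (`genome_chromosomes` in total, default 8, the chromosome number of the
#' study system); only `chrom` carries the distorter and is scanned.
#'
#' @param n_sites informative sites per chromosome.
#' @param length_bp chromosome length (bp).
#' @param depth germline per-site depth: scalar, per-site vector, or a
#'   `function(n)` returning depths (to mimic an empirical distribution).
#' @param depth_soma somatic per-site depth (same forms); defaults to
#'   `depth`.
#' @param k true segregation ratio of the distorter (0.5 = Mendelian null).
#' @param distorter_pos true distorter position (bp) or `NULL` to draw it
#'   uniformly among the simulated sites.
#' @param error_rate uniform error probability `E`.
#' @param ks genome-wide somatic ancestry ratio emulating reference-mapping
#'   bias; the read-sampling odds are `b = ks/(1 - ks)`.
#' @param genome_chromosomes total chromosomes simulated (>= 1); the extra
#'   ones are Mendelian and only contribute somatic reads to the `K_s`
#'   estimate.
#' @param chrom name of the focal (scanned) chromosome.
#' @param cM_per_Mb recombination rate of the linear map.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 5000, length_bp = 25e6, depth = 40,
                       depth_soma = depth, k = 0.5, distorter_pos = NULL,
                       error_rate = 0.001, ks = 0.55,
                       genome_chromosomes = 8, chrom = "chr1",
                       cM_per_Mb = 1) {
  stopifnot(n_sites >= 1, length_bp >= n_sites, k > 0, k < 1,
            error_rate >= 0, error_rate < 0.5, ks > 0, ks < 1,
            genome_chromosomes >= 1)
  structure(list(n_sites = n_sites, length_bp = length_bp, depth = depth,
                 depth_soma = depth_soma, k = k,
                 distorter_pos = distorter_pos, error_rate = error_rate,
                 ks = ks, genome_chromosomes = genome_chromosomes,
                 chrom = chrom, cM_per_Mb = cM_per_Mb),
            class = "sim_config")
}

draw_depth <- function(spec, n) {
  d <- if (is.function(spec)) spec(n) else rep_len(spec, n)
  if (any(d < 0)) stop("depths must be non-negative")
  as.numeric(d)
}

#' Simulate paired somatic and germline allele counts
#'
#' For each site `p`, the somatic lyrata-allele count is
#' `Binomial(depth_soma, read_prob(0.5, E, b))` and the germline count is
#' `Binomial(depth, read_prob(ancestry_prob(k, r_ip), E, b))`, with `r_ip`
#' the Haldane recombination probability to the distorter. Background
#' chromosomes are Mendelian everywhere. Fully reproducible under `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list of class `sd_sim` with `counts` (the standard 8-column
#'   counts data.frame), `map` (linear [genetic_map()] over all simulated
#'   chromosomes), `distorter_pos`, `chrom` and `config`.
#' @export
simulate_counts <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  b <- cfg$ks / (1 - cfg$ks)
  nchr <- cfg$genome_chromosomes
  chroms <- c(cfg$chrom,
              if (nchr > 1) paste0("bg", seq_len(nchr - 1)) else character())
  map <- linear_map(chroms, cfg$length_bp, cfg$cM_per_Mb)
  ps <- read_prob(0.5, cfg$error_rate, b)

  sim_chrom <- function(ch, focal) {
    pos <- sort(sample.int(cfg$length_bp, cfg$n_sites))
    dg <- draw_depth(cfg$depth, cfg$n_sites)
    ds <- draw_depth(cfg$depth_soma, cfg$n_sites)
    if (focal) {
      ipos <- cfg$distorter_pos
      if (is.null(ipos)) ipos <- pos[sample.int(length(pos), 1)]
      if (ipos < 1 || ipos > cfg$length_bp)
        stop("distorter position lies off the simulated chromosome")
      r <- haldane(abs(map_position(map, ch, pos) -
                         map_position(map, ch, ipos)))
      q <- ancestry_prob(cfg$k, r)
    } else {
      ipos <- NA_real_
      q <- rep(0.5, cfg$n_sites)
    }
    pg <- read_prob(q, cfg$error_rate, b)
    gl <- stats::rbinom(cfg$n_sites, dg, pg)
    sl <- stats::rbinom(cfg$n_sites, ds, ps)
    list(ipos = ipos,
         df = data.frame(chrom = ch, pos = pos,
                         allele_lyr = "A", allele_hal = "T",
                         soma_lyr = sl, soma_hal = ds - sl,
                         germ_lyr = gl, germ_hal = dg - gl,
                         stringsAsFactors = FALSE))
  }

  focal <- sim_chrom(cfg$chrom, TRUE)
  counts <- focal$df
  for (ch in setdiff(chroms, cfg$chrom))
    counts <- rbind(counts, sim_chrom(ch, FALSE)$df)
  structure(list(counts = counts, map = map, distorter_pos = focal$ipos,
                 chrom = cfg$chrom, config = cfg),
            class = "sd_sim")
}

## Deterministic child seeds below 2^31, one stream per replicate.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 2654435) %% 2147483629 + 1)
}

default_scan_options <- function() list(max_candidates = 96, bins = 256)

run_one_replicate <- function(cfg, seed_sim, seed_boot, bootstraps, level,
                              scan_options) {
  sim <- simulate_counts(cfg, seed = seed_sim)
  sc <- do.call(scan_chromosome,
                c(list(counts = sim$counts, map = sim$map, chrom = sim$chrom,
                       error_rate = cfg$error_rate), scan_options))
  ci <- c(NA_real_, NA_real_)
  if (bootstraps > 0) {
    bt <- do.call(bootstrap_ci,
                  c(list(counts = sim$counts, map = sim$map,
                         chrom = sim$chrom, B = bootstraps, level = level,
                         seed = seed_boot, error_rate = cfg$error_rate,
                         ks = sc$ks), scan_options))
    ci <- c(bt$lower, bt$upper)
  }
  data.frame(k_true = cfg$k, i_true = sim$distorter_pos, i_star = sc$i_star,
             ks = sc$ks, kg = sc$kg, lr = sc$lr, p_value = sc$p_value,
             ci_lower = ci[1], ci_upper = ci[2])
}

#' Power, mapping-error and CI-coverage experiment
#'
#' For each true segregation ratio in `k_values`, simulates `replicates`
#' data sets under `config`, scans each, constructs a `bootstraps`-replicate
#' site-bootstrap confidence interval, and tabulates detection power at
#' `alpha`, mean absolute position error, mean CI width, CI coverage (the
#' fraction of replicates whose interval contains the true position) and
#' the mean/SD of the estimated ratio `K_g`.
#'
#' @param k_values true segregation ratios to simulate (the calibration
#'   ladder of the method is `c(0.505, 0.510, 0.520, 0.550, 0.640)`).
#' @param replicates simulation replicates per `k`.
#' @param bootstraps bootstrap replicates per simulation (0 disables CIs).
#' @param alpha nominal detection cutoff.
#' @param config a [sim_config()]; its `k` is overridden by `k_values`.
#' @param seed master seed; every replicate derives deterministic child
#'   seeds from it.
#' @param level CI confidence level.
#' @param scan_options list of arguments forwarded to [scan_chromosome()]
#'   and [bootstrap_ci()]; the default caps candidate evaluations at 96
#'   (two-stage scan) and pools sites into 256 genetic-distance bins.
#' @return list of class `sd_power` with `summary` (one row per `k`) and
#'   `replicates` (one row per simulation).
#' @export
run_power_experiment <- function(k_values, replicates = 100,
                                 bootstraps = 200, alpha = 0.0005,
                                 config = sim_config(), seed = 1,
                                 level = 0.95,
                                 scan_options = default_scan_options()) {
  stopifnot(replicates >= 1)
  rows <- vector("list", length(k_values) * replicates)
  idx <- 0L
  for (ki in seq_along(k_values)) {
    cfg <- config
    cfg$k <- k_values[ki]
    for (rep in seq_len(replicates)) {
      idx <- idx + 1L
      rows[[idx]] <- run_one_replicate(
        cfg,
        seed_sim = child_seed(seed, 2L * idx),
        seed_boot = child_seed(seed, 2L * idx + 1L),
        bootstraps = bootstraps, level = level,
        scan_options = scan_options)
    }
  }
  det <- do.call(rbind, rows)
  det$covered <- det$ci_lower <= det$i_true & det$i_true <= det$ci_upper
  det$pos_error <- abs(det$i_star - det$i_true)
  det$ci_width <- det$ci_upper - det$ci_lower
  summ <- do.call(rbind, lapply(split(det, det$k_true), function(d) {
    data.frame(k_true = d$k_true[1],
               replicates = nrow(d),
               power = mean(d$p_value <= alpha),
               mean_pos_error = mean(d$pos_error),
               mean_ci_width = mean(d$ci_width),
               coverage = mean(d$covered),
               mean_kg = mean(d$kg),
               sd_kg = stats::sd(d$kg))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, replicates = det, alpha = alpha,
                 level = level, bootstraps = bootstraps, seed = seed),
            class = "sd_power")
}

#' @export
print.sd_power <- function(x, ...) {
  cat("sd_power experiment (", x$bootstraps, " bootstraps, alpha = ",
      x$alpha, ")\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Null (Mendelian) calibration of the scan
#'
#' Runs the scan on `replicates` simulations with `k = 0.5` and returns the
#' extreme statistics used to calibrate detection thresholds: the maximum
#' deviation of `K_g` from 0.5 and the maximum likelihood ratio, together
#' with the full empirical distributions.
#'
#' @inheritParams run_power_experiment
#' @return list of class `sd_null_calibration` with `max_kg_dev`, `max_lr`,
#'   and per-replicate vectors `kg`, `lr`, `p_value`.
#' @export
run_null_calibration <- function(replicates = 100, config = sim_config(),
                                 seed = 1,
                                 scan_options = default_scan_options()) {
  stopifnot(replicates >= 1)
  cfg <- config
  cfg$k <- 0.5
  rows <- vector("list", replicates)
  for (rep in seq_len(replicates)) {
    rows[[rep]] <- run_one_replicate(cfg, seed_sim = child_seed(seed, rep),
                                     seed_boot = NULL, bootstraps = 0,
                                     level = 0.95,
                                     scan_options = scan_options)
  }
  det <- do.call(rbind, rows)
  structure(list(max_kg_dev = max(abs(det$kg - 0.5)), max_lr = max(det$lr),
                 kg = det$kg, lr = det$lr, p_value = det$p_value,
                 replicates = replicates, seed = seed),
            class = "sd_null_calibration")
}

#' @export
print.sd_null_calibration <- function(x, ...) {
  cat(sprintf(
    "Mendelian null calibration (%d replicates):\n  max |K_g - 0.5| = %.4f\n  max LR = %.2f (nominal p = %.3g)\n",
    x$replicates, x$max_kg_dev, x$max_lr,
    stats::pchisq(x$max_lr, 1, lower.tail = FALSE)))
  invisible(x)
}
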