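# Core model: sampling-configuration probabilities, somatic null, and the
# chromosome-wide germline likelihood.

test_that("ancestry_prob matches the two-route enumeration", {
  # k = 0.5 is invariant under recombination
  expect_equal(ancestry_prob(0.5, c(0, 0.1, 0.5)), rep(0.5, 3))
  # complete linkage
  expect_equal(ancestry_prob(0.64, 0), 0.64)
  # enumerated: 0.64 * 0.75 + 0.36 * 0.25
  expect_equal(ancestry_prob(0.64, 0.25), 0.57)
  expect_error(ancestry_prob(1, 0.1), "strictly within")
  expect_error(ancestry_prob(0.5, 0.6), "0, 0.5")
})

test_that("read_prob reduces to the four-configuration sum when b = 1", {
  grid <- expand.grid(k = c(0.505, 0.55, 0.64, 0.9), r = c(0, 0.1, 0.25, 0.5),
                      E = c(0, 0.001, 0.01, 0.2))
  q <- ancestry_prob(grid$k, grid$r)
  expect_equal(read_prob(q, grid$E, bias = 1),
               four_term_prob(grid$k, grid$r, grid$E), tolerance = 1e-12)
  # worked case: k = 0.64, r = 0.25, E = 0.001
  expect_equal(read_prob(0.57, 0.001, 1), 0.56986)
  expect_equal(read_prob(0.64, 0, 1), 0.64)
})

test_that("bias calibration: Mendelian germline reproduces the somatic ratio", {
  ks <- c(0.52, 0.55, 0.61)
  b <- ks / (1 - ks)
  for (E in c(0, 0.001)) {
    # q = 0.5 at every r under k = 0.5, so the site's r is irrelevant
    q <- ancestry_prob(0.5, c(0, 0.07, 0.4))
    for (i in seq_along(ks))
      expect_equal(read_prob(q, E, b[i]), rep(ks[i], 3))
  }
})

test_that("read_prob is strictly increasing in q and in b", {
  q <- seq(0.01, 0.99, length.out = 30)
  p <- read_prob(q, 0.001, 1.3)
  expect_true(all(diff(p) > 0))
  b <- seq(0.5, 3, length.out = 30)
  expect_true(all(diff(read_prob(0.4, 0.01, b)) > 0))
})

test_that("estimate_null_ratio equals the error-corrected pooled fraction", {
  expect_equal(estimate_null_ratio(c(300, 250), c(250, 200), error_rate = 0),
               0.55)
  expect_equal(estimate_null_ratio(c(10, 40), c(10, 40), error_rate = 0), 0.5)
  expect_equal(estimate_null_ratio(c(550), c(450), error_rate = 0.001),
               (0.55 - 0.001) / 0.998)
  # data.frame method and bootstrap weights
  cnt <- make_counts(pos = c(100, 200), germ_lyr = c(0, 0), germ_hal = c(0, 0),
                     soma_lyr = c(30, 10), soma_hal = c(10, 30))
  expect_equal(estimate_null_ratio(cnt, error_rate = 0), 0.5)
  expect_equal(estimate_null_ratio(cnt, error_rate = 0, weights = c(1, 0)),
               0.75)
  expect_error(estimate_null_ratio(c(0, 0), c(0, 0)), "all-zero")
})

test_that("single-site log-likelihood has the binomial closed form", {
  cnt <- make_counts(pos = 5e6, germ_lyr = 7, germ_hal = 3)
  gm <- toy_map()
  res <- loglik_germline(cnt, gm, "chr1", i = 5e6, k = 0.7, error_rate = 0,
                         bias = 1)
  expect_equal(res$loglik, 7 * log(0.7) + 3 * log(0.3))
  expect_equal(res$sites_used, 1L)
})

test_that("the Mendelian likelihood is flat in candidate position", {
  set.seed(4)
  cnt <- make_counts(pos = sort(sample.int(25e6, 40)),
                     germ_lyr = rbinom(40, 30, 0.5),
                     germ_hal = NA)
  cnt$germ_hal <- 30 - cnt$germ_lyr
  gm <- toy_map()
  ll <- vapply(c(1e6, 8e6, 19e6),
               function(i) loglik_germline(cnt, gm, "chr1", i, k = 0.5,
                                           error_rate = 0,
                                           bias = 1)$loglik,
               numeric(1))
  expect_equal(ll[1], ll[2])
  expect_equal(ll[1], ll[3])
})

test_that("empty and zero-depth sites are bookkept, off-chromosome errors", {
  gm <- toy_map()
  empty <- make_counts(numeric(0), integer(0), integer(0))
  res <- loglik_germline(empty, gm, "chr1", 1e6, 0.6)
  expect_equal(res$loglik, 0)
  expect_equal(res$sites_used, 0L)
  cnt <- make_counts(pos = c(1e6, 2e6), germ_lyr = c(5, 0),
                     germ_hal = c(5, 0))
  expect_equal(loglik_germline(cnt, gm, "chr1", 1e6, 0.6)$sites_used, 1L)
  cnt$chrom <- c("chr1", "chr2")
  expect_error(loglik_germline(cnt, gm, "chr1", 1e6, 0.6), "chromosome")
})

test_that("likelihood equals brute-force per-read enumeration (<= 20 reads)", {
  gm <- toy_map()
  cnt <- make_counts(pos = c(2e6, 9e6, 17e6), germ_lyr = c(4, 2, 5),
                     germ_hal = c(1, 3, 5)) # 20 reads
  cases <- expand.grid(i = c(2e6, 9.5e6), k = c(0.52, 0.64, 0.5),
                       E = c(0, 0.001), b = c(1, 0.55 / 0.45))
  for (cs in seq_len(nrow(cases))) {
    expected <- brute_force_loglik(cnt, gm, "chr1", cases$i[cs], cases$k[cs],
                                   cases$E[cs], cases$b[cs])
    got <- loglik_germline(cnt, gm, "chr1", cases$i[cs], cases$k[cs],
                           error_rate = cases$E[cs], bias = cases$b[cs])
    expect_equal(got$loglik, expected, tolerance = 1e-10)
  }
})

test_that("optimize_k recovers closed-form and simulated ratios", {
  gm <- toy_map()
  # single site at the candidate: binomial MLE 70/100
  cnt <- make_counts(pos = 5e6, germ_lyr = 70, germ_hal = 30)
  opt <- optimize_k(cnt, gm, "chr1", i = 5e6, error_rate = 0, bias = 1)
  expect_equal(opt$k, 0.7, tolerance = 1e-4)
  # dense simulation at k = 0.64, optimizing at the true position
  sim <- simulate_counts(sim_config(n_sites = 3000, depth = 60, k = 0.64,
                                    ks = 0.55, genome_chromosomes = 1),
                         seed = 31)
  sub <- sim$counts
  se <- sqrt(0.25 / sum(sub$germ_lyr + sub$germ_hal)) # binomial SE bound
  opt <- optimize_k(sub, sim$map, "chr1", i = sim$distorter_pos,
                    bias = 0.55 / 0.45)
  expect_lt(abs(opt$k - 0.64), 4 * se + 0.002)
  # Mendelian recovery
  sim0 <- simulate_counts(sim_config(n_sites = 2000, depth = 40, k = 0.5,
                                     ks = 0.5, genome_chromosomes = 1),
                          seed = 32)
  opt0 <- optimize_k(sim0$counts, sim0$map, "chr1", i = 12e6, bias = 1)
  expect_lt(abs(opt0$k - 0.5), 0.01)
})

test_that("optimizer dominance: no grid value of k beats the optimum", {
  gm <- toy_map()
  set.seed(8)
  for (rep in 1:5) {
    n <- 50
    cnt <- make_counts(pos = sort(sample.int(25e6, n)),
                       germ_lyr = rbinom(n, 35, 0.56), germ_hal = NA)
    cnt$germ_hal <- 35 - cnt$germ_lyr
    i <- sample.int(25e6, 1)
    opt <- optimize_k(cnt, gm, "chr1", i, bias = 1.1)
    for (k in seq(0.05, 0.95, by = 0.09)) {
      ll <- loglik_germline(cnt, gm, "chr1", i, k, bias = 1.1)$loglik
      expect_lte(ll, opt$loglik + 1e-8)
    }
  }
})

test_that("C++ profile solver agrees with derivative-free optimize_k", {
  sim <- simulate_counts(sim_config(n_sites = 400, depth = 40, k = 0.58,
                                    genome_chromosomes = 1), seed = 13)
  sc <- scan_chromosome(sim$counts, sim$map, "chr1")
  chk <- optimize_k(sim$counts, sim$map, "chr1", i = sc$i_star,
                    bias = sc$bias, tol = 1e-8)
  expect_equal(sc$kg, chk$k, tolerance = 1e-5)
  expect_equal(sc$profile$lr[match(sc$i_star, sc$profile$pos)], sc$lr)
})
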