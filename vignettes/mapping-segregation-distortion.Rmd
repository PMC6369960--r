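---
title: "Mapping haploid-acting segregation distortion from pooled gamete sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping haploid-acting segregation distortion from pooled gamete sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdscan)
```

## The problem

Some genetic elements subvert Mendelian segregation: through meiotic drive
or haploid (gametic) selection they end up in functional gametes at a ratio
`k != 0.5`. Classical transmission-ratio-distortion experiments detect this
by genotyping large F2 cohorts, which confounds gametic and zygotic effects
and has little power for small `k`. Sequencing a bulk gamete pool (e.g.
pollen) and a somatic library from the *same* F1 hybrid sidesteps both
problems: every gamete is an independent meiosis, and gametes are sampled
before viability selection on offspring can act.

At an *ancestry-informative site* — a SNP fixed for different alleles in
the two parental species and heterozygous in the F1 — every read can be
assigned to a parental lineage. A distorter at position `i` with
segregation ratio `k` drags linked markers along: a marker `p` at
recombination probability `r_ip` shows the attenuated ratio

    q = k (1 - r_ip) + (1 - k) r_ip .

`r_ip` comes from a recombination map and Haldane's mapping function
`r = (1 - exp(-2 d)) / 2` (`d` in Morgans, no interference). Because *all*
sites on a chromosome carry information about `i` and `k` through this
decay, the model is fit chromosome-wide rather than window by window.

## The likelihood

Reads are noisy in two ways. A uniform sequencing/mapping error `E` mixes
the ancestry probability to `q' = q(1 - E) + (1 - q)E`; with no mapping
bias this equals the four-configuration sum (distorter-allele chromosome x
recombination x error). Reference-mapping bias — reads from the lineage
closer to the reference genome map more successfully — is absorbed
empirically: the somatic library of the same individual cannot carry
germline distortion, so its genome-wide ancestry ratio `K_s` *is* the null.
We estimate `K_s` by maximum likelihood under the position-free model
`P = K_s(1 - E) + (1 - K_s)E` (closed form: the error-corrected pooled read
fraction) and convert it to a read-sampling odds `b = K_s / (1 - K_s)`
applied after ancestry and error mixing:

    p = b q' / (b q' + (1 - q')) .

Per site, allele counts are binomial in `p`; the chromosome log-likelihood
is the sum over sites (binomial coefficients, constant in `k`, are
omitted). Zero-depth sites are skipped and bookkept.

**Null composition (a genuinely open design point).** The source framework
tests the germline data against `K_s` but does not spell out how mapping
bias combines with recombination decay. We operationalize the null
"no distortion" as `k = 0.5` *with* bias `b`, i.e. a constant expected
germline ratio equal to `K_s` at every site — this matches the description
of `K_s` as the empirical null model, and calibrates exactly
(`read_prob(0.5, E, b) = K_s`). The alternative reading — the decay model
with `k` fixed at `K_s` and `b = 1` — is implemented as
`scan_chromosome(..., null = "decay")`. The pure unbiased four-term model
is always available via `bias = 1`.

`E` is fixed by configuration (default 0.001), not estimated: under the
constant-ratio somatic model `E` and `K_s` are not jointly identifiable.

## The scan, p-values and confidence intervals

For each candidate `i` on a grid (default: every informative-site
position — under the monotone Haldane decay no intermediate position can
beat both flanking sites), `K_g(i)` maximizes the likelihood and
`LR(i) = 2 [logL(K_g(i)) - logL(null)]`; the reported `i*`, `K_g` and `LR`
maximize the profile (ties to the smallest position). The nominal p-value
is the chi-square(1) tail of the maximal LR. Because the statistic is
maximized over positions this is anti-conservative; the framework
compensates with a stringent uncorrected cutoff (`alpha = 5e-4` by
default), and `significance_report()` also emits Bonferroni-across-
chromosomes p-values. Seeded Mendelian calibration
(`run_null_calibration()`) shows the practical false-positive rate is low
(at the default desk-scale design, max LR across 100 null replicates is
about 9; the chi-square cutoff at `5e-4` is 12.1).

Mapping uncertainty: `bootstrap_ci()` resamples sites (paired somatic +
germline counts) with replacement, reruns the scan, and takes the
percentile interval of the bootstrap `i*` sample. `K_s` is held fixed
across replicates by default (`reestimate_null = TRUE` to resample it too).
Note a percentile interval need not contain `i*` itself.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `error_rate` (`E`) | 0.001 | uniform per-read error; fixed, not fitted |
| `min_gq` | 30 | genotype-quality floor for site selection |
| depth quantiles | 0.10 / 0.90 | closed nearest-rank interval; realized cutoffs are returned (the empirical study's 220/400) |
| `min_gap_bp` | 100 | greedy spacing so one read never covers two sites |
| `alpha` | 5e-4 | stringent nominal cutoff for the maximized LR |
| `B` | 1000 real scans / 100–200 in simulation | bootstrap replicates |
| `bounds`, `tol` | (1e-6, 1-1e-6), 1e-6 | `k` search interval and tolerance |

## The simulator: what it emulates, what it does not

`sim_config()` / `simulate_counts()` generate the *stated world* used by
the calibration experiments: 5,000 sites uniform on a 25 Mb chromosome,
constant 40x per-library depth, a linear 1 cM/Mb map, uniform error
`E = 0.001`, a genome-wide lyrata-ward bias `ks = 0.55`, and one distorter
at a uniformly drawn site. This is a deliberate scale-down of the empirical
design (hundreds of thousands of sites, higher total depth): Monte-Carlo
properties (coverage, monotonicity in `k`) transfer, absolute power and CI
widths do not — a green coverage test does *not* establish the full-scale
false-positive ceiling, which the original study reports separately.

Because `K_s` is estimated from *genome-wide* somatic data in the real
analysis, the simulator generates `genome_chromosomes = 8` chromosomes
(the study organism's count) of Mendelian background whose somatic reads
feed the `K_s` estimate; only the focal chromosome is scanned. On a single
desk-scale chromosome the `K_s` sampling noise would otherwise rival the
germline noise and roughly double the null LR variance — an artifact of
the scale-down, not of the method.

Not emulated: read-level artifacts (FASTQ, aligner reference bias beyond
the odds `b`), depth heterogeneity between sites of the real libraries
(available via a `depth` function), somatic aneuploidy/endoreduplication,
multi-locus distorters.

## Numerical choices

- The map is monotone piecewise-linear through the cumulative cM anchors
  (the cited smoother is external and equation-free; any monotone
  interpolator can substitute by densifying anchors). Beyond terminal
  anchors: terminal-segment slope, or clamping by flag. 100 cM = 1 Morgan.
- `optimize_k()` is bounded derivative-free Brent search. The C++ scan
  profile instead solves the score equation by bisection (40 halvings);
  the two agree to ~1e-6 in tests.
- Large scans use two runtime approximations, both off by default and
  switched on by the simulation harness: a two-stage candidate grid
  (coarse `max_candidates`, then refinement around the coarse maximum) and
  pooling of sites into `bins` equal-width genetic-distance classes per
  candidate, evaluated at the depth-weighted mean distance. At the default
  harness settings (96/256) these reproduce the exact scan's `K_g` to
  5e-4 and LR to 1%.
- Ties in the LR profile resolve to the smallest position; `LR` is clamped
  at 0 (the null is nested); all randomness flows through explicit seeds,
  replicate `r` of an experiment using a deterministic child seed.
- Degenerate inputs: empty count sets give log-likelihood 0 with 0 sites
  used; all-zero somatic depth is an error; sites with missing genotypes
  are dropped (conservative); unsorted input to the spacing filter is an
  error rather than silently reordered.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(k = 0.55)                 # the default stated world
sim <- simulate_counts(cfg, seed = 7)
scan <- scan_chromosome(sim$counts, sim$map, "chr1",
                        max_candidates = 96, bins = 256)
scan
ci <- bootstrap_ci(sim$counts, sim$map, "chr1", B = 200, seed = 8,
                   ks = scan$ks, max_candidates = 96, bins = 256)
c(ci$lower, sim$distorter_pos, ci$upper)
viability_decrease(scan$kg)                 # per-locus pollen-production loss
```

## Known limitations

- The chi-square(1) p-value at the maximized position is nominal; treat
  borderline detections with the stringent cutoff and replicates.
- The recombination map of an interspecific cross may differ from the F1
  hybrid's own map; mapping CIs inherit that uncertainty.
- Weak distorters (`k < ~0.505`) undercover and are hard to separate from
  unmodeled somatic artifacts; estimated effect sizes are likely
  underestimates when aborted gametes still contribute DNA.
- The single-locus model is fit per chromosome; two linked distorters will
  be summarized by one compromise position.
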