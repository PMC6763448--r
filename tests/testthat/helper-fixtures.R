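# Small in-code fixtures shared across test files.

make_profile <- function(pos, meth, cov, chrom = "chr1", id = "s1",
                         genotype = "WT", stage = "E11.5") {
  sample_profile(data.frame(chrom = chrom, pos = pos, meth = meth,
                            unmeth = cov - meth),
                 sample_id = id, genotype = genotype, stage = stage)
}

# build a cohort whose per-sample percents equal `pct` exactly
# (pct: site x sample matrix in [0,100]; one replicate per column).
# `groups` maps column index -> group label.
make_cohort_from_percents <- function(pos, pct, groups, chrom = "chr1",
                                      cov = 1000L) {
  stopifnot(length(groups) == ncol(pct))
  gl <- split(seq_along(groups), groups)
  gl <- gl[unique(groups)]
  profs <- lapply(names(gl), function(g) {
    lapply(gl[[g]], function(j)
      make_profile(pos, as.integer(round(pct[, j] * cov / 100)), cov,
                   chrom = chrom, id = paste0("s", j), genotype = g))
  })
  names(profs) <- names(gl)
  build_cohort(profs, min_cov = 1)
}

random_profile <- function(n = 1000, seed = 1, chrom_levels = c("chr1", "chr2"),
                           genotype = "WT", id = "r1") {
  set.seed(seed)
  chrom <- sample(chrom_levels, n, replace = TRUE)
  pos <- integer(n)
  for (ch in chrom_levels)
    pos[chrom == ch] <- sort(sample.int(1e6, sum(chrom == ch)))
  cov <- rpois(n, 30) + 1L
  meth <- rbinom(n, cov, runif(n))
  make_profile(pos, meth, cov, chrom = chrom, genotype = genotype, id = id)
}

# tiny simulated study shared by several test files
small_sim <- function(seed = 7, ...) {
  cfg <- sim_config(seed = seed, n_chromosomes = 2, chrom_length = 1e6,
                    n_background_cpgs = 2000, n_genes = 30,
                    n_enhancers = 10, n_repeats = 10, n_weak = 25,
                    n_strong = 8, n_ci_only = 4, n_gain = 0, n_loss = 0,
                    ...)
  genome <- simulate_genome(cfg)
  sim <- simulate_methylation(cfg, genome)
  list(cfg = cfg, genome = genome, sim = sim)
}
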