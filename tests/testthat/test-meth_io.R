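# Per-CpG call-file parsing, replicate pooling and cohort construction.

test_that("both call-file dialects parse to identical 0-based profiles", {
  bis <- tempfile(fileext = ".cov")
  md <- tempfile(fileext = ".bedGraph")
  # same underlying site: cytosine at 0-based position 100, 15 meth / 5 unmeth
  writeLines("chr1\t101\t101\t75.0\t15\t5", bis)
  writeLines("chr1\t100\t101\t75\t15\t5", md)
  pb <- read_bismark_cov(bis)
  pm <- read_methyldackel_bedgraph(md)
  expect_equal(pb$sites, pm$sites)
  expect_equal(pb$sites$pos, 100L)
  expect_equal(pb$sites$meth, 15L)
  expect_equal(pb$sites$unmeth, 5L)
  expect_equal(profile_percent(pb), 75)

  # unsorted input comes out sorted; empty file gives an empty profile
  writeLines(c("chr2\t10\t11\t0\t0\t9", "chr1\t500\t501\t50\t3\t3",
               "chr1\t20\t21\t100\t8\t0"), md)
  p <- read_methyldackel_bedgraph(md)
  expect_equal(p$sites$pos, c(20L, 500L, 10L))
  expect_equal(p$sites$chrom, c("chr1", "chr1", "chr2"))
  writeLines(character(), md)
  expect_equal(nrow(read_methyldackel_bedgraph(md)$sites), 0L)
})

test_that("malformed or negative-count lines are rejected with line numbers", {
  f <- tempfile()
  writeLines(c("chr1\t100\t101\t75\t15\t5", "chr1\t200\t201\t50\t3"), f)
  expect_error(read_methyldackel_bedgraph(f), "line 2")
  writeLines("chr1\t100\t101\t75\t-1\t5", f)
  expect_error(read_methyldackel_bedgraph(f), "[Nn]egative")
  expect_error(read_bismark_cov(tempfile()), "exist")
})

test_that("write/read round trip reproduces a random 1000-site profile", {
  p <- random_profile(1000, seed = 42)
  for (dialect in c("methyldackel", "bismark")) {
    f <- tempfile()
    write_sample_profile(p, f, dialect = dialect)
    back <- if (dialect == "bismark") read_bismark_cov(f)
            else read_methyldackel_bedgraph(f)
    expect_equal(back$sites, p$sites)
  }
})

test_that("pooling sums counts and matches the coverage-weighted mean", {
  a <- make_profile(c(10, 20), meth = c(3, 5), cov = c(10, 10), id = "a")
  b <- make_profile(c(10, 20), meth = c(7, 1), cov = c(10, 20), id = "b")
  pooled <- pool_group(list(a, b))
  expect_equal(pooled$sites$meth, c(10L, 6L))
  expect_equal(profile_percent(pooled)[1], 50)
  # single profile is the identity
  expect_equal(pool_group(list(a))$sites, a$sites)
  # mixed genotypes rejected
  b_ko <- make_profile(c(10), 1, 10, genotype = "KO")
  expect_error(pool_group(list(a, b_ko)), "mixed genotypes")
  # algebraic oracle on random fixtures: pooled percent equals the
  # coverage-weighted mean of replicate percents; counts conserved
  set.seed(3)
  for (i in 1:5) {
    pos <- sort(sample.int(1e5, 200))
    reps <- lapply(1:3, function(j) {
      cov <- rpois(200, 30) + 1L
      make_profile(pos, rbinom(200, cov, runif(200)), cov,
                   id = paste0("r", j))
    })
    pooled <- pool_group(reps)
    covs <- sapply(reps, profile_coverage)
    pcts <- sapply(reps, profile_percent)
    expect_equal(profile_percent(pooled),
                 rowSums(pcts * covs, na.rm = TRUE) / rowSums(covs),
                 tolerance = 1e-12)
    expect_equal(sum(pooled$sites$meth), sum(sapply(reps, function(p)
      sum(p$sites$meth))))
  }
})

test_that("build_cohort keeps exactly the sites covered in all samples", {
  # coverage 14 in one sample excludes the site at min_cov 15
  a <- make_profile(c(10, 20, 30), meth = c(5, 5, 5), cov = c(15, 14, 40))
  b <- make_profile(c(10, 20, 30), meth = c(5, 5, 5), cov = c(20, 20, 20),
                    id = "b")
  coh <- build_cohort(list(WT = list(a, b)), min_cov = 15)
  expect_equal(coh$sites$pos, c(10L, 30L))
  # identical samples: common set equals each sample's filtered set
  coh1 <- build_cohort(list(WT = list(a), KO = list(a)), min_cov = 15)
  expect_equal(coh1$sites$pos, c(10L, 30L))
  expect_equal(unname(coh1$group_percent[, "WT"]),
               unname(coh1$group_percent[, "KO"]))
})

test_that("common-site count equals brute-force intersection; raising min_cov is monotone", {
  for (i in 1:4) {
    reps <- lapply(1:4, function(j) random_profile(300, seed = 10 * i + j,
                                                   id = paste0("s", j)))
    groups <- list(WT = reps[1:2], KO = reps[3:4])
    prev <- Inf
    for (mc in c(5, 15, 25)) {
      coh <- suppressWarnings(build_cohort(groups, min_cov = mc))
      keys <- lapply(reps, function(p) {
        s <- p$sites
        paste(s$chrom, s$pos)[profile_coverage(p) >= mc]
      })
      expect_equal(nrow(coh$sites), length(Reduce(intersect, keys)))
      expect_lte(nrow(coh$sites), prev)
      prev <- nrow(coh$sites)
      if (nrow(coh$sites)) {
        expect_true(all(coh$per_sample_cov >= mc))
        expect_true(all(coh$group_percent >= 0 & coh$group_percent <= 100))
      }
    }
  }
  # empty intersection warns and returns an empty table, not an error
  a <- make_profile(1, 1, 20); b <- make_profile(2, 1, 20, id = "b")
  expect_warning(coh <- build_cohort(list(WT = list(a), KO = list(b)),
                                     min_cov = 15), "no CpG site")
  expect_equal(nrow(coh$sites), 0L)
})

test_that("DMR BED output round-trips intervals and validates them", {
  f <- tempfile(fileext = ".bed")
  write_dmr_bed(data.frame(), f)
  expect_equal(readLines(f), paste(c("#chrom", "start", "end", "name",
                                     "score", "strand", "n_dmcs", "p_value",
                                     "direction", "label"), collapse = "\t"))
  expect_equal(nrow(read_dmr_bed(f)), 0L)
  dmrs <- data.frame(chrom = c("chr1", "chr2"), start = c(100L, 5L),
                     end = c(220L, 60L), n_dmcs = c(3L, 4L),
                     mean_delta = c(-41.2, 35.5),
                     direction = c("hypo", "hyper"),
                     p_value = c(0.01, 0.002))
  write_dmr_bed(dmrs, f)
  back <- read_dmr_bed(f)
  expect_equal(as.data.frame(back)[, c("chrom", "start", "end")],
               dmrs[, c("chrom", "start", "end")])
  expect_true(all(back$end > back$start))
  expect_equal(back$direction, dmrs$direction)
  expect_equal(back$p_value, dmrs$p_value)
})

test_that("destranding merges adjacent dyad calls by summing counts", {
  p <- make_profile(c(100, 101, 300), meth = c(3, 4, 5),
                    cov = c(10, 10, 10))
  d <- destrand_profile(p)
  expect_equal(d$sites$pos, c(100L, 300L))
  expect_equal(d$sites$meth, c(7L, 5L))
  expect_equal(d$sites$unmeth, c(13L, 5L))
})
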