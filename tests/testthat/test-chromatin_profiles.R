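# Meta-profiles around TSSs and over scaled region bodies, and
# enrichment comparisons.

uniform_track <- function(value = 5, chrom = "chr1", len = 20000,
                          bw = 10) {
  nb <- len / bw
  signal_track(data.frame(chrom = chrom, start = (seq_len(nb) - 1) * bw,
                          end = seq_len(nb) * bw, value = value), "test")
}

test_that("signal tracks validate, load and round-trip", {
  tr <- uniform_track()
  f <- tempfile(fileext = ".bedGraph")
  write_signal_track(tr, f)
  back <- load_signal_track(f, "test")
  expect_equal(back$bins, tr$bins)
  # overlapping intervals are rejected
  expect_error(signal_track(data.frame(chrom = "chr1", start = c(0, 5),
                                       end = c(10, 15), value = 1)),
               "overlapping")
  # empty file loads as an empty track
  writeLines(character(), f)
  expect_equal(nrow(load_signal_track(f)$bins), 0L)
})

test_that("TSS profiles are flat on uniform signal and mirror under strand flip", {
  genes <- data.frame(chrom = "chr1", start = c(5000L, 9000L),
                      end = c(8000L, 12000L), strand = c("+", "-"))
  tr <- uniform_track(5)
  prof <- tss_meta_profile(tr, genes, half_window = 2000, bin_size = 100)
  expect_equal(nrow(prof), 40L)
  expect_true(all(abs(prof$mean - 5) < 1e-12))
  expect_true(all(prof$sem >= 0))
  # gradient track: flipping every strand mirrors the profile
  nb <- 2000
  grad <- signal_track(data.frame(chrom = "chr1",
                                  start = (seq_len(nb) - 1) * 10,
                                  end = seq_len(nb) * 10,
                                  value = seq_len(nb)), "grad")
  g1 <- data.frame(chrom = "chr1", start = 10000L, end = 15000L,
                   strand = "+")
  g2 <- g1; g2$strand <- "-"; g2$start <- 5000L; g2$end <- 10001L
  p1 <- tss_meta_profile(grad, g1, 1000, 100)
  p2 <- tss_meta_profile(grad, g2, 1000, 100)
  # g2's TSS is at the same coordinate; upstream now runs rightwards
  expect_equal(p1$mean - p1$mean[1], -(p2$mean - p2$mean[1]),
               tolerance = 0.05)
})

test_that("TSS profiles match brute-force per-bin averaging (both input kinds)", {
  set.seed(61)
  nb <- 1000
  tr <- signal_track(data.frame(chrom = "chr1",
                                start = (seq_len(nb) - 1) * 10,
                                end = seq_len(nb) * 10,
                                value = rnorm(nb, 10, 3)), "x")
  genes <- data.frame(chrom = "chr1", start = c(3000L, 6130L),
                      end = c(5000L, 8000L), strand = c("+", "-"))
  prof <- tss_meta_profile(tr, genes, half_window = 500, bin_size = 50)
  tssv <- c(3000L, 8000L - 1L)
  val_at <- function(p) tr$bins$value[floor(p / 10) + 1]
  for (b in seq_len(nrow(prof))) {
    means <- sapply(1:2, function(g) {
      off <- prof$bin[b]
      s <- if (genes$strand[g] == "+") tssv[g] + off
           else tssv[g] - off - 50 + 1
      mean(val_at(s:(s + 49)))
    })
    expect_equal(prof$mean[b], mean(means), tolerance = 1e-9)
  }
  # methylation mode: per-CpG values averaged within bins
  sites <- data.frame(chrom = "chr1", pos = c(2740L, 2760L, 2990L, 3050L),
                      value = c(10, 30, 80, 40))
  mprof <- tss_meta_profile(sites, genes[1, ], half_window = 500,
                            bin_size = 50)
  expect_equal(mprof$mean[mprof$bin == -300], 10)  # [2700, 2750)
  expect_equal(mprof$mean[mprof$bin == -250], 30)  # [2750, 2800)
  expect_equal(mprof$mean[mprof$bin == -50], 80)
  expect_equal(mprof$mean[mprof$bin == 50], 40)
  expect_true(is.na(mprof$mean[mprof$bin == -500]))
})

test_that("scaled-region profiles have the right shape and match per-bp means", {
  tr <- uniform_track(3, len = 50000)
  regions <- data.frame(chrom = "chr1",
                        start = c(10000L, 20000L, 30000L),
                        end = c(10400L, 21000L, 32000L))
  prof <- scaled_region_profile(tr, regions)
  expect_equal(nrow(prof), 100 + 2 * 10)
  expect_true(all(abs(prof$mean - 3) < 1e-12))
  # a region of exactly 1000 bp maps bins 1:100 onto successive 10-bp bins
  nb <- 5000
  grad <- signal_track(data.frame(chrom = "chr1",
                                  start = (seq_len(nb) - 1) * 10,
                                  end = seq_len(nb) * 10,
                                  value = seq_len(nb)), "grad")
  r1k <- data.frame(chrom = "chr1", start = 20000L, end = 21000L)
  p <- scaled_region_profile(grad, r1k)
  body <- p$mean[p$bin %in% 1:100]
  expect_equal(body, as.numeric(2000 + seq_len(100)))
  # brute-force per-bp oracle on a random-length region
  set.seed(62)
  r <- data.frame(chrom = "chr1", start = 12345L, end = 12345L + 777L)
  pr <- scaled_region_profile(grad, r)
  val_at <- function(pos) grad$bins$value[floor(pos / 10) + 1]
  len <- r$end - r$start
  for (j in c(1, 37, 100)) {
    lo <- r$start + floor(len * (j - 1) / 100)
    hi <- max(r$start + ceiling(len * j / 100), lo + 1)
    expect_equal(pr$mean[pr$bin == j], mean(val_at(lo:(hi - 1))),
                 tolerance = 1e-9)
  }
  # profiles are invariant under region input order
  p3 <- scaled_region_profile(tr, regions[c(3, 1, 2), ])
  expect_equal(p3$mean, prof$mean)
})

test_that("enrichment comparison detects planted differences and is symmetric", {
  set.seed(63)
  nb <- 8000
  v <- rlnorm(nb, 0, 0.3)
  regions_a <- data.frame(chrom = "chr1",
                          start = seq(1000, by = 800, length.out = 50))
  regions_a$end <- regions_a$start + 400
  regions_b <- data.frame(chrom = "chr1",
                          start = seq(41000, by = 800, length.out = 50))
  regions_b$end <- regions_b$start + 400
  # plant a 3x enrichment over set A
  bs <- (seq_len(nb) - 1) * 10
  ina <- vapply(bs, function(s) any(s >= regions_a$start &
                                      s < regions_a$end), TRUE)
  tr <- signal_track(data.frame(chrom = "chr1", start = bs, end = bs + 10,
                                value = v * ifelse(ina, 3, 1)), "mark")
  ce <- compare_enrichment(tr, regions_a, regions_b)
  expect_lt(ce$test$p.value, 0.05)
  expect_gt(ce$mean_a, ce$mean_b)
  # swapping the sets preserves the p-value
  ce2 <- compare_enrichment(tr, regions_b, regions_a)
  expect_equal(ce2$test$p.value, ce$test$p.value)
  # identical sets are degenerate-null
  ce3 <- compare_enrichment(tr, regions_a, regions_a)
  expect_gte(ce3$test$p.value, 0.99)
  # per-region means match direct recomputation
  val_at <- function(pos) tr$bins$value[floor(pos / 10) + 1]
  m1 <- mean(val_at(regions_a$start[1]:(regions_a$end[1] - 1)))
  expect_equal(ce$values_a[1], m1, tolerance = 1e-9)
})

test_that("stratified enrichment reports no-test for thin strata", {
  set.seed(64)
  tr <- uniform_track(2, len = 60000)
  ra <- data.frame(chrom = "chr1", start = c(1000L, 3000L, 5000L),
                   end = c(1400L, 3400L, 5400L))
  rb <- data.frame(chrom = "chr1", start = c(31000L, 33000L),
                   end = c(31400L, 33400L))
  cat <- data.frame(chrom = "chr1",
                    start = c(900L, 2900L, 4900L, 30900L, 32900L, 700L),
                    end = c(1500L, 3500L, 5500L, 31500L, 33500L, 1500L),
                    kind = c(rep("exon", 5), "enhancer"),
                    gene_id = NA)
  ann_a <- annotate_dmrs(ra, cat); ann_b <- annotate_dmrs(rb, cat)
  se <- stratified_enrichment(tr, ra, rb, ann_a, ann_b)
  exon <- se[se$kind == "exon", ]
  expect_equal(exon$n_a, 3L); expect_equal(exon$n_b, 2L)
  expect_equal(exon$mean_a, 2); expect_equal(exon$mean_b, 2)
  enh <- se[se$kind == "enhancer", ]
  expect_equal(enh$n_a, 1L)
  expect_true(is.na(enh$p_value))   # < 2 regions on a side -> no-test
})
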