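# The synthetic cohort generator: determinism, parseability of emitted
# files, statistical calibration at zero effect, and end-to-end recovery
# of planted truth.

test_that("the generator is fully deterministic under the seed", {
  s1 <- small_sim(seed = 9)
  s2 <- small_sim(seed = 9)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$sim$profiles, s2$sim$profiles)
  s3 <- small_sim(seed = 10)
  expect_false(identical(s1$genome$cpgs, s3$genome$cpgs))
  # expression and tracks are deterministic too
  e1 <- simulate_expression(sim_config(seed = 9, n_expr_genes = 500,
                                       de_up = 20, de_down = 30,
                                       group_sizes = c(5, 5, 5)))
  e2 <- simulate_expression(sim_config(seed = 9, n_expr_genes = 500,
                                       de_up = 20, de_down = 30,
                                       group_sizes = c(5, 5, 5)))
  expect_identical(e1$em$fpkm, e2$em$fpkm)
})

test_that("simulated genomes are well-formed", {
  s <- small_sim(seed = 19)
  g <- s$genome
  # CpG positions unique and sorted per chromosome
  expect_false(any(duplicated(paste(g$cpgs$chrom, g$cpgs$pos))))
  for (ch in unique(g$cpgs$chrom))
    expect_false(is.unsorted(g$cpgs$pos[g$cpgs$chrom == ch]))
  # all features inside chromosome bounds
  feats <- rbind(g$elements[, c("chrom", "start", "end")],
                 g$planted[, c("chrom", "start", "end")],
                 g$icr_panel[, c("chrom", "start", "end")])
  expect_true(all(feats$start >= 0))
  expect_true(all(feats$end <= g$chromosomes$length[
    match(feats$chrom, g$chromosomes$chrom)]))
  # each planted region holds the configured number of CpGs
  tab <- table(g$cpgs$region_id)
  expect_true(all(tab == s$cfg$region_cpgs))
  # ICR panel is 22 germline + 9 somatic
  expect_equal(sum(g$icr_panel$icr_class == "germline"), 22L)
  expect_equal(sum(g$icr_panel$icr_class == "somatic"), 9L)
  # too-small genomes fail loudly
  expect_error(simulate_genome(sim_config(seed = 1, n_chromosomes = 1,
                                          chrom_length = 5e4,
                                          n_genes = 100)),
               "too small")
})

test_that("planted regions narrower than 3 CpGs are a generation error", {
  cfg <- sim_config(seed = 2, n_chromosomes = 1, chrom_length = 5e5,
                    n_background_cpgs = 100, n_genes = 5, n_enhancers = 2,
                    n_repeats = 2, n_weak = 3, n_strong = 0, n_ci_only = 0,
                    n_gain = 0, n_loss = 0, region_cpgs = 2L)
  genome <- simulate_genome(cfg)
  expect_error(simulate_methylation(cfg, genome), "weak_000.*fewer than 3")
})

test_that("emitted profiles and tracks parse with the package readers", {
  s <- small_sim(seed = 29)
  p <- s$sim$profiles[["WT_E11.5_1"]]
  f <- tempfile()
  write_sample_profile(p, f, "methyldackel")
  expect_equal(read_methyldackel_bedgraph(f)$sites, p$sites)
  cfg <- sim_config(seed = 29, n_chromosomes = 1, chrom_length = 1e5,
                    n_background_cpgs = 100, n_genes = 3, n_enhancers = 2,
                    n_repeats = 2, n_weak = 3, n_strong = 2, n_ci_only = 0,
                    n_gain = 0, n_loss = 0,
                    track_marks = c("H3K27me3", "H3K36me3"))
  g <- simulate_genome(cfg)
  trks <- simulate_tracks(cfg, g)
  expect_setequal(names(trks), c("H3K27me3", "H3K36me3"))
  ftr <- tempfile()
  write_signal_track(trks$H3K27me3, ftr)
  expect_equal(nrow(load_signal_track(ftr)$bins),
               nrow(trks$H3K27me3$bins))
})

test_that("a zero-effect cohort is null: DMC rate matches the analytic noise model", {
  cfg <- sim_config(seed = 3, n_chromosomes = 2, chrom_length = 2e6,
                    n_background_cpgs = 12000, n_genes = 0, n_enhancers = 0,
                    n_repeats = 0, n_weak = 0, n_strong = 0, n_ci_only = 0,
                    n_gain = 0, n_loss = 0,
                    icr_states = within(methrescue:::.default_icr_states(), {
                      hypo_ko <- FALSE; restored_ci <- FALSE
                    }),
                    bg_high = 0.5)   # mid-scale level, worst-case noise
  genome <- simulate_genome(cfg)
  sim <- simulate_methylation(cfg, genome)
  coh <- build_cohort(profiles_by_genotype(sim$profiles, "E11.5",
                                           c("WT", "KO")), min_cov = 15)
  th <- dmr_thresholds(min_diff = 15)  # threshold low enough to see noise
  dmcs <- call_dmcs(coh, "WT", "KO", th)
  emp <- nrow(dmcs) / nrow(coh$sites)
  # analytic oracle: the latent level is shared between genotypes, so the
  # pooled-percent difference is binomial noise on ~2x pooled coverage;
  # integrate a normal approximation over the Beta site-level law
  mus <- rbeta(20000, 0.5 * cfg$bb_precision, 0.5 * cfg$bb_precision)
  ns <- cfg$coverage_mean * cfg$replicates     # pooled coverage per group
  pred <- mean(2 * pnorm(-0.15 / sqrt(2 * mus * (1 - mus) / ns)))
  expect_lt(abs(emp - pred), 0.25 * pred)
  # same prediction at the default 30-point DMC threshold
  pred30 <- mean(2 * pnorm(-0.30 / sqrt(2 * mus * (1 - mus) / ns)))
  emp30 <- nrow(call_dmcs(coh, "WT", "KO", dmr_thresholds())) /
    nrow(coh$sites)
  expect_lt(abs(emp30 - pred30), 3 * sqrt(pred30 / nrow(coh$sites)))
  # no false-positive DMRs (rate well below alpha)
  dmrs <- call_dmrs(coh, "WT", "KO", dmr_thresholds())
  expect_equal(nrow(dmrs), 0L)
})

test_that("planted rescue truth is recovered end-to-end", {
  s <- small_sim(seed = 39)
  coh <- build_cohort(profiles_by_genotype(s$sim$profiles, "E11.5"),
                      min_cov = 15)
  ko <- call_dmrs(coh, "WT", "KO")
  ci <- call_dmrs(coh, "WT", "CI")
  rs <- classify_rescue(ko, ci)
  tr <- s$genome$planted
  # map each called KO DMR to its planted region (if any)
  lab_of <- vapply(seq_len(nrow(ko)), function(i) {
    hit <- tr$chrom == ko$chrom[i] & tr$start < ko$end[i] &
      tr$end > ko$start[i]
    if (any(hit)) tr$class[hit][1] else "icr"
  }, "")
  # planted weak regions come back labeled weak, strong as strong
  expect_true(all(rs$labels$label[lab_of == "weak"] == "weak"))
  expect_true(all(rs$labels$label[lab_of == "strong"] == "strong"))
  # recovery of at least 90% of regions per class at effect 50 / 30x
  expect_gte(sum(lab_of == "weak"), 0.9 * sum(tr$class == "weak"))
  expect_gte(sum(lab_of == "strong"), 0.9 * sum(tr$class == "strong"))
  # ci_only regions are CI DMRs but never KO DMRs
  expect_false(any(lab_of == "ci_only"))
  expect_gte(rs$n_ci_only, 0.9 * sum(tr$class == "ci_only"))
})

test_that("planted regions are recovered with tight boundaries at effect 50", {
  # 100 planted regions, 30x coverage: expect >= 95% recovered with a
  # boundary error of at most one CpG on each side
  cfg <- sim_config(seed = 4, n_chromosomes = 2, chrom_length = 2e6,
                    n_background_cpgs = 4000, n_genes = 20, n_enhancers = 5,
                    n_repeats = 5, n_weak = 100, n_strong = 0,
                    n_ci_only = 0, n_gain = 0, n_loss = 0,
                    icr_states = within(methrescue:::.default_icr_states(), {
                      hypo_ko <- FALSE; restored_ci <- FALSE
                    }))
  genome <- simulate_genome(cfg)
  sim <- simulate_methylation(cfg, genome)
  coh <- build_cohort(profiles_by_genotype(sim$profiles, "E11.5",
                                           c("WT", "KO")), min_cov = 15)
  ko <- call_dmrs(coh, "WT", "KO")
  tr <- genome$planted
  cp <- genome$cpgs
  ok <- vapply(seq_len(nrow(tr)), function(i) {
    pos <- cp$pos[!is.na(cp$region_id) & cp$region_id == tr$region_id[i]]
    j <- which(ko$chrom == tr$chrom[i] & ko$start < tr$end[i] &
                 ko$end > tr$start[i])
    if (length(j) != 1) return(FALSE)
    # boundary error in CpGs on each side
    sum(pos < ko$start[j]) <= 1 && sum(pos >= ko$end[j]) <= 1
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("planted expression truth is recovered and nulls are calibrated", {
  cfg <- sim_config(seed = 5, n_expr_genes = 2000, de_up = 40, de_down = 60,
                    group_sizes = c(10, 12, 8))
  se <- simulate_expression(cfg)
  de <- differential_expression(se$em, "WT", "KO")
  tr <- se$truth$de
  called_up <- de$gene[de$status == "up"]
  # ordinary planted up genes (fold 4, moderate base) come back exactly;
  # the low-expression Group-3 subset sits near the pseudocount-damped
  # fold-change gate, so it is held to >= 90%
  g3 <- se$truth$groups$gene[se$truth$groups$group == "3"]
  plain_up <- setdiff(tr$gene[tr$direction == "up"], g3)
  expect_true(all(plain_up %in% called_up))
  expect_gte(mean(g3 %in% called_up), 0.85)
  # no planted gene is called with the wrong sign
  expect_false(any(tr$gene[tr$direction == "up"] %in%
                     de$gene[de$status == "down"]))
  expect_true(all(tr$gene[tr$direction == "down"] %in%
                    de$gene[de$status == "down"] |
                    tr$gene[tr$direction == "down"] %in%
                    de$gene[de$status == "ns"]))
  # zero planted effects: about alpha * n false positives, not more
  cfg0 <- sim_config(seed = 6, n_expr_genes = 2000, de_up = 0, de_down = 0,
                     group_sizes = c(0, 0, 0))
  de0 <- differential_expression(simulate_expression(cfg0)$em, "WT", "KO")
  # the fold-change gate keeps the null far below alpha * n
  expect_lte(sum(de0$status != "ns"), 0.05 * 2000)
})

test_that("planted track enrichment is detected and the null is quiet", {
  cfg <- sim_config(seed = 7, n_chromosomes = 1, chrom_length = 4e5,
                    n_background_cpgs = 200, n_genes = 5, n_enhancers = 2,
                    n_repeats = 2, n_weak = 40, n_strong = 40,
                    n_ci_only = 0, n_gain = 0, n_loss = 0,
                    track_marks = c("H3K27me3", "H3K9Ac"))
  genome <- simulate_genome(cfg)
  trks <- simulate_tracks(cfg, genome)
  strong <- genome$planted[genome$planted$class == "strong", ]
  weak <- genome$planted[genome$planted$class == "weak", ]
  # planted 3x H3K27me3 over strong regions is detected
  ce <- compare_enrichment(trks$H3K27me3, strong, weak)
  expect_lt(ce$test$p.value, 0.05)
  expect_gt(ce$mean_a / ce$mean_b, 2)
  # H3K9Ac has no planted enrichment: no signal
  ce0 <- compare_enrichment(trks$H3K9Ac, strong, weak)
  expect_gt(ce0$test$p.value, 0.05)
})
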