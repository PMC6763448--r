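# Synthetic cohort generator. Emits genomes, RRBS-like methylation
# profiles, expression matrices and chromatin tracks with the statistical
# structure the analysis assumes, plus machine-readable planted truth.
# Counts are drawn binomially around a per-site latent methylation level
# shared across samples (the latent level is Beta-distributed across
# sites, so single-sample counts are marginally beta-binomial); planted
# effects shift the latent level deterministically, and coverage is
# negative-binomial.

.gicr_names <- c("Impact", "Gnas1a", "Dlk1-Gtl2", "6330408a02Rik",
                 "AK008011", "Snrpn", "Kcnq1ot1", "Airn", "Peg1", "Peg3",
                 "Peg5", "Peg10", "Peg13", "Grb10", "Plagl1", "Rasgrf1",
                 "Zrsr1", "Nnat", "Inpp5f", "Mcts2", "Nap1l5", "Gpr1-Zdbf2")
.sicr_names <- c("Mkrn3", "Nesp", "Cdkn1c", "Gtl2", "H19", "Peg12",
                 "Igf2r", "Gtl2-Mirg", "Eif2c2")

.default_icr_states <- function() {
  g_hypo <- c("Gnas1a", "Dlk1-Gtl2", "6330408a02Rik", "AK008011")
  g_rest <- c("Gnas1a", "Dlk1-Gtl2")
  s_hypo <- c("Mkrn3", "Nesp", "Cdkn1c", "Gtl2", "H19", "Peg12", "Igf2r")
  s_rest <- c("H19", "Nesp", "Gtl2", "Igf2r")
  rbind(
    data.frame(name = .gicr_names, icr_class = "germline",
               hypo_ko = .gicr_names %in% g_hypo,
               restored_ci = .gicr_names %in% g_rest),
    data.frame(name = .sicr_names, icr_class = "somatic",
               hypo_ko = .sicr_names %in% s_hypo,
               restored_ci = .sicr_names %in% s_rest))
}

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 2 RRBS replicates and 3
#' expression replicates per genotype, mean 30x coverage, ~9-point
#' per-site percent noise at 30x, 4133 weak / 205 strong / 110 CI-only
#' rescue regions, 133 temporal gains (18 Dnmt3b-dependent, 6 of those
#' catalytic) and 196 losses, a 22-germline + 9-somatic ICR panel with the
#' described per-locus states, 253 up- and 819 down-regulated genes among
#' 12,000, and promoter groups of 150/163/34 genes. The seed fully
#' determines all outputs.
#'
#' @param seed integer RNG seed.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_background_cpgs CpGs scattered outside planted features.
#' @param n_genes,n_enhancers,n_repeats element counts.
#' @param coverage_mean,coverage_size negative-binomial read coverage per
#'   site and sample (mean 30; size 50 keeps the commonly-covered-site
#'   coverage spread tight).
#' @param bb_precision Beta precision of the per-site latent methylation
#'   level (60: at 30x coverage the observed per-site percent SD is about
#'   9 points at high methylation).
#' @param replicates RRBS replicates per genotype (2).
#' @param expr_replicates expression replicates per genotype (3).
#' @param genotypes genotype labels (WT, KO, CI).
#' @param stages stage labels, early to late; single-stage configs treat
#'   that stage as late.
#' @param n_weak,n_strong,n_ci_only planted rescue-class region counts.
#' @param dmr_effect rescue-region hypomethylation effect in percent
#'   points (50).
#' @param n_gain,n_loss,n_gain_dependent,n_gain_catalytic planted
#'   temporal region counts (gains absent in KO when dependent; dependent
#'   gains absent in CI when catalytic).
#' @param temporal_effect stage effect in percent points (40).
#' @param region_cpgs CpGs per planted region (5).
#' @param region_spacing min/max intra-region CpG spacing in bp.
#' @param bg_high,bg_cgi,dmr_base,gain_base,loss_base,icr_base latent
#'   base methylation levels (proportions) by context; gains start fully
#'   unmethylated (de novo targets).
#' @param icr_effect,icr_cpgs ICR hypomethylation effect and CpGs per
#'   locus.
#' @param icr_states data.frame of per-locus planted states (`name`,
#'   `icr_class`, `hypo_ko`, `restored_ci`); default follows the study
#'   panel descriptions.
#' @param n_expr_genes,de_up,de_down,de_fc,expr_sdlog expression design:
#'   gene universe, planted up/down counts, fold change, log-normal
#'   noise sd (natural log).
#' @param group_sizes,group_high_fpkm,group_low_fpkm,group3_fold promoter
#'   group design; Group-3 genes are a subset of the planted up genes
#'   with their own fold change.
#' @param track_bin,track_marks,track_enrichment chromatin-track design:
#'   bin width, mark names, and per-mark enrichment factors over planted
#'   region classes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L, chrom_length = 5e6,
                       n_background_cpgs = 20000L,
                       n_genes = 200L, n_enhancers = 60L, n_repeats = 120L,
                       coverage_mean = 30, coverage_size = 50,
                       bb_precision = 60,
                       replicates = 2L, expr_replicates = 3L,
                       genotypes = c("WT", "KO", "CI"),
                       stages = "E11.5",
                       n_weak = 4133L, n_strong = 205L, n_ci_only = 110L,
                       dmr_effect = 50,
                       n_gain = 133L, n_loss = 196L,
                       n_gain_dependent = 18L, n_gain_catalytic = 6L,
                       temporal_effect = 40,
                       region_cpgs = 5L, region_spacing = c(25L, 25L),
                       bg_high = 0.85, bg_cgi = 0.07, dmr_base = 0.90,
                       gain_base = 0, loss_base = 0.90, icr_base = 0.80,
                       icr_effect = 40, icr_cpgs = 12L,
                       icr_states = .default_icr_states(),
                       n_expr_genes = 12000L, de_up = 253L, de_down = 819L,
                       de_fc = 4, expr_sdlog = 0.2,
                       group_sizes = c(150L, 163L, 34L),
                       group_high_fpkm = 50, group_low_fpkm = 0.2,
                       group3_fold = 8,
                       track_bin = 10L,
                       track_marks = c("H3K27me3", "H3K36me3", "H3K4me2",
                                       "H3K4me3", "H3K9Ac", "H3K27Ac",
                                       "DNase"),
                       track_enrichment = list(
                         H3K27me3 = c(strong = 3),
                         H3K36me3 = c(weak = 3),
                         H3K4me2 = c(weak = 2),
                         H3K4me3 = c(weak = 2))) {
  cfg <- as.list(environment())
  cfg$n_gain_dependent <- min(n_gain_dependent, n_gain)
  cfg$n_gain_catalytic <- min(n_gain_catalytic, cfg$n_gain_dependent)
  stopifnot(all(abs(c(dmr_effect, temporal_effect, icr_effect)) <= 100),
            n_weak >= 0, n_strong >= 0, n_ci_only >= 0, n_gain >= 0,
            n_loss >= 0, group_sizes[3] <= de_up)
  structure(cfg, class = "sim_config")
}

.rbeta_mean <- function(n, mean, precision) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  rbeta(n, mean * precision, (1 - mean) * precision)
}

#' Simulate a genome layout
#'
#' Lays out non-overlapping gene models (with exons, introns, promoter
#' CpG islands), enhancers, repeats, the ICR panel, and the planted
#' rescue/temporal region intervals with their CpG positions, plus
#' scattered background CpGs.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_genome`: `chromosomes`, `genes`, `elements`
#'   (exon/intron/CGI/enhancer/repeat catalog), `icr_panel`, `planted`
#'   (region intervals with class labels), `cpgs` (chrom/pos/context).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  # feature queue: each row is one footprint to place
  reg_classes <- rep(c("weak", "strong", "ci_only", "gain", "loss"),
                     times = c(config$n_weak, config$n_strong,
                               config$n_ci_only, config$n_gain,
                               config$n_loss))
  n_reg <- length(reg_classes)
  feat <- data.frame(
    type = c(rep("gene", config$n_genes), rep("region", n_reg),
             rep("icr", nrow(config$icr_states)),
             rep("enhancer", config$n_enhancers),
             rep("repeat", config$n_repeats)),
    len = c(sample(3000:10000, config$n_genes, replace = TRUE) + 1000L,
            rep((config$region_cpgs - 1L) * config$region_spacing[2L] + 2L,
                n_reg),
            rep(config$icr_cpgs * 30L, nrow(config$icr_states)),
            rep(600L, config$n_enhancers), rep(400L, config$n_repeats)))
  feat <- feat[sample(nrow(feat)), , drop = FALSE]
  feat$chrom <- NA_character_; feat$start <- NA_integer_
  ci <- 1L; cursor <- 2000L
  for (i in seq_len(nrow(feat))) {
    gap <- sample(300:1500, 1L)
    if (cursor + gap + feat$len[i] > config$chrom_length - 2000L) {
      ci <- ci + 1L
      if (ci > length(chroms))
        .stopf(paste0("simulate_genome: genome too small for the requested",
                      " features; increase chrom_length or n_chromosomes"))
      cursor <- 2000L
      gap <- sample(300:1500, 1L)
    }
    feat$chrom[i] <- chroms[ci]
    feat$start[i] <- cursor + gap
    cursor <- cursor + gap + feat$len[i]
  }
  feat$end <- feat$start + feat$len

  # genes with exon/intron structure and promoter CGIs; the footprint
  # reserves 500 bp on each side so promoter CGIs stay inside it
  gf <- feat[feat$type == "gene", , drop = FALSE]
  genes <- NULL; elements <- list(); cpg_list <- list()
  if (nrow(gf)) {
    gf$start <- gf$start + 500L
    gf$end <- gf$end - 500L
    genes <- data.frame(gene_id = sprintf("g%05d", seq_len(nrow(gf))),
                        chrom = gf$chrom, start = gf$start, end = gf$end,
                        strand = sample(c("+", "-"), nrow(gf),
                                        replace = TRUE))
    for (i in seq_len(nrow(gf))) {
      n_ex <- sample(2:4, 1L)
      cuts <- sort(sample(seq(gf$start[i] + 200L, gf$end[i] - 200L,
                              by = 50L), 2L * (n_ex - 1L)))
      bounds <- c(gf$start[i], cuts, gf$end[i])
      for (j in seq_len(n_ex)) {
        elements[[length(elements) + 1L]] <- data.frame(
          chrom = gf$chrom[i], start = bounds[2L * j - 1L],
          end = bounds[2L * j], kind = "exon",
          gene_id = genes$gene_id[i])
        if (j < n_ex)
          elements[[length(elements) + 1L]] <- data.frame(
            chrom = gf$chrom[i], start = bounds[2L * j],
            end = bounds[2L * j + 1L], kind = "intron",
            gene_id = genes$gene_id[i])
      }
    }
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    has_cgi <- runif(nrow(genes)) < 0.6
    for (i in which(has_cgi)) {
      s <- tss[i] - 500L; e <- tss[i] + 500L
      elements[[length(elements) + 1L]] <- data.frame(
        chrom = genes$chrom[i], start = s, end = e, kind = "CGI",
        gene_id = genes$gene_id[i])
      pos <- s + cumsum(sample(30:70, 25L, replace = TRUE))
      pos <- pos[pos < e]
      cpg_list[[length(cpg_list) + 1L]] <- data.frame(
        chrom = genes$chrom[i], pos = pos, context = "cgi",
        region_id = NA_integer_, icr_name = NA_character_)
    }
  }
  for (ty in c("enhancer", "repeat")) {
    tf <- feat[feat$type == ty, , drop = FALSE]
    if (nrow(tf))
      elements[[length(elements) + 1L]] <- data.frame(
        chrom = tf$chrom, start = tf$start, end = tf$end, kind = ty,
        gene_id = NA_character_)
  }
  elements <- if (length(elements)) do.call(rbind, elements) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               kind = character(), gene_id = character())

  # planted regions and their CpGs
  rf <- feat[feat$type == "region", , drop = FALSE]
  planted <- NULL
  if (nrow(rf)) {
    starts <- ends <- integer(nrow(rf))
    spvals <- seq(config$region_spacing[1L], config$region_spacing[2L])
    for (i in seq_len(nrow(rf))) {
      sp <- spvals[sample.int(length(spvals), config$region_cpgs - 1L,
                              replace = TRUE)]
      pos <- rf$start[i] + c(0L, cumsum(sp))
      starts[i] <- pos[1L]; ends[i] <- pos[length(pos)] + 1L
      cpg_list[[length(cpg_list) + 1L]] <- data.frame(
        chrom = rf$chrom[i], pos = pos, context = "region",
        region_id = i, icr_name = NA_character_)
    }
    planted <- data.frame(region_id = seq_len(nrow(rf)),
                          name = sprintf("%s_%04d", reg_classes,
                                         seq_len(nrow(rf))),
                          class = reg_classes, chrom = rf$chrom,
                          start = starts, end = ends,
                          n_cpgs = config$region_cpgs)
    # which gains are Dnmt3b-dependent / catalytic
    gidx <- which(planted$class == "gain")
    planted$dependent <- FALSE; planted$catalytic <- FALSE
    if (config$n_gain_dependent > 0) {
      dep <- gidx[seq_len(config$n_gain_dependent)]
      planted$dependent[dep] <- TRUE
      if (config$n_gain_catalytic > 0)
        planted$catalytic[tail(dep, config$n_gain_catalytic)] <- TRUE
    }
  }

  # ICR loci and their CpGs
  icrf <- feat[feat$type == "icr", , drop = FALSE]
  icr_panel <- data.frame(name = config$icr_states$name,
                          icr_class = config$icr_states$icr_class,
                          chrom = icrf$chrom, start = icrf$start,
                          end = icrf$end)
  for (i in seq_len(nrow(icrf))) {
    pos <- icrf$start[i] + cumsum(sample(15:30, config$icr_cpgs,
                                         replace = TRUE))
    cpg_list[[length(cpg_list) + 1L]] <- data.frame(
      chrom = icrf$chrom[i], pos = pos, context = "icr",
      region_id = NA_integer_, icr_name = icr_panel$name[i])
  }

  # background CpGs, kept out of planted/ICR intervals so planted runs
  # are not interrupted by unaffected sites
  if (config$n_background_cpgs > 0) {
    bchrom <- sample(chroms, config$n_background_cpgs, replace = TRUE)
    bpos <- as.integer(runif(config$n_background_cpgs, 1000,
                             config$chrom_length - 1000))
    excl <- rbind(
      if (!is.null(planted)) planted[, c("chrom", "start", "end")],
      icr_panel[, c("chrom", "start", "end")])
    if (!is.null(excl) && nrow(excl)) {
      bq <- data.table(chrom = bchrom, start = bpos, end = bpos + 1L)
      ex <- data.table(chrom = excl$chrom, start = as.integer(excl$start),
                       end = as.integer(excl$end))
      setkey(ex, chrom, start, end)
      hit <- !is.na(foverlaps(bq, ex, type = "any", which = TRUE,
                              mult = "first"))
      bchrom <- bchrom[!hit]; bpos <- bpos[!hit]
    }
    cpg_list[[length(cpg_list) + 1L]] <- data.frame(
      chrom = bchrom, pos = bpos, context = "background",
      region_id = NA_integer_, icr_name = NA_character_)
  }
  cpgs <- do.call(rbind, cpg_list)
  cpgs <- cpgs[!duplicated(paste(cpgs$chrom, cpgs$pos)), , drop = FALSE]
  cpgs <- cpgs[.site_order(cpgs$chrom, cpgs$pos), , drop = FALSE]
  rownames(cpgs) <- NULL

  structure(list(
    chromosomes = data.frame(chrom = chroms, length = config$chrom_length),
    genes = genes, elements = elements, icr_panel = icr_panel,
    planted = planted, cpgs = cpgs, config = config),
    class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf(
    "<sim_genome> %d chromosome(s), %d CpGs, %d gene(s), %d planted region(s)\n",
    nrow(x$chromosomes), nrow(x$cpgs),
    NROW(x$genes), NROW(x$planted)))
  invisible(x)
}

# latent methylation level per site for one (genotype, stage)
.sim_levels <- function(mu0, genome, config, genotype, stage_state) {
  lv <- mu0
  cp <- genome$cpgs
  pl <- genome$planted
  eff <- config$dmr_effect / 100
  teff <- config$temporal_effect / 100
  ieff <- config$icr_effect / 100
  if (!is.null(pl)) {
    cls <- pl$class[cp$region_id]   # NA for non-region sites
    isreg <- !is.na(cp$region_id)
    if (genotype == "KO")
      lv[isreg & cls %in% c("weak", "strong")] <-
        lv[isreg & cls %in% c("weak", "strong")] - eff
    if (genotype == "CI")
      lv[isreg & cls %in% c("strong", "ci_only")] <-
        lv[isreg & cls %in% c("strong", "ci_only")] - eff
    if (stage_state == "late") {
      dep <- pl$dependent[cp$region_id]
      cat_ <- pl$catalytic[cp$region_id]
      gain <- isreg & cls == "gain"
      present <- switch(genotype,
                        KO = gain & !dep,
                        CI = gain & !(dep & cat_),
                        gain)
      lv[present] <- lv[present] + teff
      loss <- isreg & cls == "loss"
      lv[loss] <- lv[loss] - teff
    }
  }
  isicr <- !is.na(cp$icr_name)
  if (any(isicr)) {
    st <- config$icr_states
    hypo <- st$hypo_ko[match(cp$icr_name, st$name)]
    rest <- st$restored_ci[match(cp$icr_name, st$name)]
    if (genotype == "KO") {
      sel <- isicr & hypo %in% TRUE
      lv[sel] <- lv[sel] - ieff
    }
    if (genotype == "CI") {
      sel <- isicr & (hypo %in% TRUE) & !(rest %in% TRUE)
      lv[sel] <- lv[sel] - ieff
    }
  }
  pmin(pmax(lv, 0), 1)
}

#' Simulate RRBS methylation profiles with planted truth
#'
#' Draws a per-site latent methylation level (bimodal background: low at
#' CpG islands, high elsewhere; Beta-distributed across sites and shared
#' across samples), applies the planted genotype/stage effects
#' deterministically, then draws per-sample negative-binomial coverages
#' and binomial methylated counts.
#'
#' @param config a [sim_config()].
#' @param genome a [simulate_genome()] result.
#' @return list: `profiles` (named list of [sample_profile()],
#'   `GENOTYPE_STAGE_REP`), `truth` (planted regions with class and
#'   effect, ICR states), `levels` (latent level matrix, for
#'   diagnostics).
#' @export
simulate_methylation <- function(config, genome) {
  set.seed(config$seed + 1L)
  cp <- genome$cpgs
  n <- nrow(cp)
  if (!is.null(genome$planted)) {
    tab <- table(cp$region_id)
    bad <- genome$planted$region_id[!genome$planted$region_id %in%
                                      as.integer(names(tab))]
    few <- as.integer(names(tab)[tab < 3L])
    if (length(bad) || length(few))
      .stopf("simulate_methylation: planted region '%s' has fewer than 3 CpGs",
             genome$planted$name[c(bad, few)][1L])
  }
  mu0 <- numeric(n)
  for (ctx in unique(cp$context)) {
    sel <- cp$context == ctx
    base <- switch(ctx, background = config$bg_high, cgi = config$bg_cgi,
                   icr = config$icr_base, region = NA)
    if (ctx == "region") {
      cls <- genome$planted$class[cp$region_id[sel]]
      base_by_class <- c(weak = config$dmr_base, strong = config$dmr_base,
                         ci_only = config$dmr_base, gain = config$gain_base,
                         loss = config$loss_base)
      mu0[sel] <- vapply(base_by_class[cls], function(b)
        .rbeta_mean(1L, b, config$bb_precision), numeric(1))
    } else {
      mu0[sel] <- .rbeta_mean(sum(sel), base, config$bb_precision)
    }
  }
  stages <- config$stages
  late <- stages[length(stages)]
  profiles <- list()
  levels_used <- list()
  for (gt in config$genotypes) for (st in stages) {
    lv <- .sim_levels(mu0, genome, config, gt,
                      stage_state = if (st == late) "late" else "early")
    levels_used[[paste(gt, st, sep = "_")]] <- lv
    for (r in seq_len(config$replicates)) {
      cov <- rnbinom(n, size = config$coverage_size,
                     mu = config$coverage_mean)
      meth <- rbinom(n, cov, lv)
      id <- sprintf("%s_%s_%d", gt, st, r)
      profiles[[id]] <- sample_profile(
        data.frame(chrom = cp$chrom, pos = cp$pos, meth = meth,
                   unmeth = cov - meth),
        sample_id = id, genotype = gt, stage = st)
    }
  }
  truth <- list(regions = genome$planted, icr_states = config$icr_states,
                effects = c(dmr = config$dmr_effect,
                            temporal = config$temporal_effect,
                            icr = config$icr_effect))
  list(profiles = profiles, truth = truth, levels = levels_used)
}

#' Group simulated profiles for [build_cohort()]
#'
#' @param profiles named profile list from [simulate_methylation()].
#' @param stage stage to keep.
#' @param genotypes genotype labels to keep.
#' @return Named list of profile lists, one element per genotype.
#' @export
profiles_by_genotype <- function(profiles, stage,
                                 genotypes = c("WT", "KO", "CI")) {
  out <- lapply(genotypes, function(gt)
    Filter(function(p) p$genotype == gt && p$stage == stage, profiles))
  names(out) <- genotypes
  out[lengths(out) > 0]
}

#' Simulate a gene x sample FPKM matrix with planted truth
#'
#' Log-normal expression with planted KO fold changes: `de_up` /
#' `de_down` genes at fold `de_fc`, with the Group-3 promoter genes a
#' subset of the up set at fold `group3_fold`; Group-1 genes high in WT
#' and unchanged, Group-2 low and unchanged. The CI genotype is fully
#' rescued (WT levels).
#'
#' @param config a [sim_config()].
#' @param genome optional [simulate_genome()]; its gene ids are reused
#'   (padded with synthetic ids up to `n_expr_genes`).
#' @return list: `em` (an [expression_matrix()]), `truth` (`de` gene
#'   table with directions and folds, `groups` gene table).
#' @export
simulate_expression <- function(config, genome = NULL) {
  set.seed(config$seed + 2L)
  ng <- config$n_expr_genes
  ids <- if (!is.null(genome) && !is.null(genome$genes))
    genome$genes$gene_id else character()
  if (length(ids) < ng)
    ids <- c(ids, sprintf("sgene%05d", seq_len(ng - length(ids))))
  ids <- ids[seq_len(ng)]
  gs <- config$group_sizes
  n_up <- config$de_up; n_down <- config$de_down
  if (n_up + n_down + gs[1L] + gs[2L] > ng)
    .stopf("simulate_expression: more planted genes than n_expr_genes")
  up_ids <- ids[seq_len(n_up)]
  g3_ids <- head(up_ids, gs[3L])              # Group 3 subset of up genes
  down_ids <- ids[n_up + seq_len(n_down)]
  g1_ids <- ids[n_up + n_down + seq_len(gs[1L])]
  g2_ids <- ids[n_up + n_down + gs[1L] + seq_len(gs[2L])]
  base <- rlnorm(ng, meanlog = log(8), sdlog = 1.2)
  names(base) <- ids
  base[setdiff(up_ids, g3_ids)] <- rlnorm(n_up - length(g3_ids),
                                          meanlog = log(10), sdlog = 1)
  base[down_ids] <- rlnorm(n_down, meanlog = log(10), sdlog = 1)
  base[g1_ids] <- config$group_high_fpkm * rlnorm(gs[1L], 0, 0.3)
  base[g2_ids] <- config$group_low_fpkm * rlnorm(gs[2L], 0, 0.3)
  base[g3_ids] <- config$group_low_fpkm * rlnorm(gs[3L], 0, 0.3)
  mu <- sapply(config$genotypes, function(gt) {
    m <- base
    if (gt == "KO") {
      m[up_ids] <- m[up_ids] * config$de_fc
      m[g3_ids] <- base[g3_ids] * config$group3_fold
      m[down_ids] <- m[down_ids] / config$de_fc
    }
    m
  })
  samples <- expand.grid(replicate = seq_len(config$expr_replicates),
                         genotype = config$genotypes,
                         stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_%d", samples$genotype, samples$replicate),
    genotype = samples$genotype, replicate = samples$replicate)
  fpkm <- matrix(0, ng, nrow(samples),
                 dimnames = list(ids, samples$sample_id))
  for (j in seq_len(nrow(samples)))
    fpkm[, j] <- mu[, samples$genotype[j]] *
      exp(rnorm(ng, 0, config$expr_sdlog))
  truth_de <- data.frame(
    gene = c(up_ids, down_ids),
    direction = rep(c("up", "down"), c(n_up, n_down)),
    fold = c(ifelse(up_ids %in% g3_ids, config$group3_fold, config$de_fc),
             rep(1 / config$de_fc, n_down)))
  truth_groups <- data.frame(gene = c(g1_ids, g2_ids, g3_ids),
                             group = rep(c("1", "2", "3"), times = gs))
  list(em = expression_matrix(fpkm, samples),
       truth = list(de = truth_de, groups = truth_groups))
}

#' Simulate binned chromatin signal tracks
#'
#' Smooth positive background signal per mark with multiplicative
#' enrichment over designated planted region classes (e.g. repressive
#' H3K27me3 over strong regions, H3K36me3 over weak ones).
#'
#' @param config a [sim_config()] (fields `track_bin`, `track_marks`,
#'   `track_enrichment`).
#' @param genome a [simulate_genome()] result.
#' @return Named list of [signal_track()] objects, one per mark.
#' @export
simulate_tracks <- function(config, genome) {
  set.seed(config$seed + 3L)
  bw <- config$track_bin
  pl <- genome$planted
  out <- list()
  for (mark in config$track_marks) {
    per_chrom <- list()
    for (i in seq_len(nrow(genome$chromosomes))) {
      chrom <- genome$chromosomes$chrom[i]
      nb <- ceiling(genome$chromosomes$length[i] / bw)
      noise <- as.numeric(stats::filter(rnorm(nb), rep(1 / 20, 20),
                                        circular = TRUE))
      v <- pmax(0.05, 1 + 0.6 * noise)
      enr <- config$track_enrichment[[mark]]
      if (!is.null(enr) && !is.null(pl)) for (cls in names(enr)) {
        rr <- pl[pl$class == cls & pl$chrom == chrom, , drop = FALSE]
        for (k in seq_len(nrow(rr))) {
          b1 <- floor(rr$start[k] / bw) + 1L
          b2 <- min(nb, ceiling(rr$end[k] / bw))
          v[b1:b2] <- v[b1:b2] * enr[[cls]]
        }
      }
      per_chrom[[i]] <- data.frame(chrom = chrom,
                                   start = (seq_len(nb) - 1L) * bw,
                                   end = pmin(seq_len(nb) * bw,
                                              genome$chromosomes$length[i]),
                                   value = v)
    }
    out[[mark]] <- signal_track(do.call(rbind, per_chrom), mark)
  }
  out
}
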