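# Stage-to-stage (de novo) methylation analysis: gains and losses between
# an early and a late embryonic stage in one genotype, Dnmt3b-dependence
# of gains, and the link from de novo promoter/enhancer methylation to
# down-regulated expression.

#' Call temporal (stage-to-stage) DMRs
#'
#' Reuses the DMC/DMR machinery with reference = early stage and test =
#' late stage on a cohort restricted to CpGs covered in all samples of
#' both stages. Hypermethylated regions are reported as `gain` (de novo
#' methylation), hypomethylated as `loss`.
#'
#' @param early_profiles,late_profiles lists of [sample_profile()]
#'   replicates of the same genotype at the two stages.
#' @param th a [dmr_thresholds()] list (also supplies `min_cov`).
#' @return A `dmr_set` with direction `gain`/`loss` (class additionally
#'   `temporal_dmr_set`).
#' @export
temporal_dmrs <- function(early_profiles, late_profiles,
                          th = dmr_thresholds()) {
  gt <- unique(c(vapply(early_profiles, `[[`, "", "genotype"),
                 vapply(late_profiles, `[[`, "", "genotype")))
  gt <- gt[!is.na(gt)]
  if (length(gt) > 1L)
    .stopf("temporal_dmrs: profiles span multiple genotypes (%s)",
           paste(gt, collapse = ", "))
  cohort <- build_cohort(list(early = early_profiles, late = late_profiles),
                         min_cov = th$min_cov)
  dmrs <- call_dmrs(cohort, reference = "early", test = "late", th)
  if (nrow(dmrs))
    dmrs$direction <- ifelse(dmrs$direction == "hyper", "gain", "loss")
  class(dmrs) <- c("temporal_dmr_set", class(dmrs))
  attr(dmrs, "cohort") <- cohort
  dmrs
}

.interval_mean_delta <- function(cohort, chrom, start, end, group_a,
                                 group_b) {
  s <- cohort$sites
  inreg <- s$chrom == chrom & s$pos >= start & s$pos < end
  if (!any(inreg)) return(NA_real_)
  mean(cohort$group_percent[inreg, group_a] -
       cohort$group_percent[inreg, group_b])
}

#' Classify Dnmt3b dependence of de novo methylation gains
#'
#' A WT gain region is `dnmt3b_dependent` when the mean pooled KO-minus-WT
#' methylation difference over the region at the late stage is at most
#' `-min_diff` (i.e. the gain is absent in the knockout). Among dependent
#' gains, the mechanism is `accessory` when the CI genotype sits within
#' `restore_window` points of WT over the region (the catalytically
#' inactive allele suffices), and `catalytic` otherwise. Regions without
#' covered CpGs in the late cohort are labelled no-data.
#'
#' @param gains a `dmr_set` of gain-direction temporal DMRs (WT).
#' @param cohort_late a [build_cohort()] of the late stage holding the
#'   three genotypes.
#' @param th a [dmr_thresholds()] list (supplies `min_diff`).
#' @param restore_window percent-point restoration window (default 10,
#'   shared with the ICR report).
#' @param wt,ko,ci group labels in `cohort_late`.
#' @return `gains` with added columns `dependence`
#'   (`dnmt3b_dependent` / `dnmt3b_independent` / `no-data`), `mechanism`
#'   (`accessory` / `catalytic` / `n/a`), `ko_delta`, `ci_delta`.
#' @export
classify_dependence <- function(gains, cohort_late, th = dmr_thresholds(),
                                restore_window = 10, wt = "WT", ko = "KO",
                                ci = "CI") {
  n <- NROW(gains)
  dependence <- character(n); mechanism <- rep("n/a", n)
  ko_delta <- ci_delta <- numeric(n)
  for (i in seq_len(n)) {
    kd <- .interval_mean_delta(cohort_late, gains$chrom[i], gains$start[i],
                               gains$end[i], ko, wt)
    cd <- .interval_mean_delta(cohort_late, gains$chrom[i], gains$start[i],
                               gains$end[i], ci, wt)
    ko_delta[i] <- kd; ci_delta[i] <- cd
    if (is.na(kd)) { dependence[i] <- "no-data"; next }
    if (kd <= -th$min_diff) {
      dependence[i] <- "dnmt3b_dependent"
      mechanism[i] <- if (!is.na(cd) && abs(cd) < restore_window)
        "accessory" else "catalytic"
    } else dependence[i] <- "dnmt3b_independent"
  }
  gains$dependence <- dependence
  gains$mechanism <- mechanism
  gains$ko_delta <- ko_delta
  gains$ci_delta <- ci_delta
  gains
}

#' Link de novo promoter/enhancer methylation to down-regulation
#'
#' Genes whose core promoter or enhancer holds a gain-direction temporal
#' DMR and which are down-regulated (late vs early) by the differential-
#' expression stand-in.
#'
#' @param gains a gain-direction `dmr_set`.
#' @param annotations an [annotate_dmrs()] result for `gains` against a
#'   catalog containing `core_promoter` and/or `enhancer` elements with
#'   gene ids.
#' @param de_results a [differential_expression()] result (late vs early).
#' @return data.frame of genes with the element kind, the gain region and
#'   the expression change.
#' @export
de_novo_expression_link <- function(gains, annotations, de_results) {
  h <- annotations$hits
  h <- h[h$kind %in% c("core_promoter", "enhancer") & !is.na(h$gene_id), ,
         drop = FALSE]
  down <- de_results$gene[de_results$status == "down"]
  h <- h[h$gene_id %in% down, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(gene = character(), kind = character(),
                      chrom = character(), start = integer(),
                      end = integer(), log2_fold_change = numeric(),
                      p_value = numeric()))
  de_idx <- match(h$gene_id, de_results$gene)
  out <- data.frame(gene = h$gene_id, kind = h$kind,
                    chrom = gains$chrom[h$dmr_idx],
                    start = gains$start[h$dmr_idx],
                    end = gains$end[h$dmr_idx],
                    log2_fold_change = de_results$log2_fold_change[de_idx],
                    p_value = de_results$p_value[de_idx])
  out[!duplicated(paste(out$gene, out$kind)), , drop = FALSE]
}
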