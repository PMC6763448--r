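# End-to-end orchestration: simulate or load inputs, build cohorts, call
# DMRs for KO-vs-WT and CI-vs-WT, classify rescue, annotate, report the
# ICR panel, run the temporal and expression stages when inputs allow,
# and write a TSV/BED report bundle with a JSON run manifest.

#' Run the full analysis pipeline
#'
#' Stages (each skipped cleanly when its inputs are absent): cohort build
#' -> DMR calling (KO vs WT, CI vs WT) -> rescue classification ->
#' genomic/ICR annotation -> temporal analysis (two stages) ->
#' differential expression + promoter-group integration. All outputs are
#' deterministic given the inputs and configuration; every parameter is
#' echoed into the run manifest.
#'
#' @param profiles named list of [sample_profile()] objects covering the
#'   genotypes (and stages) to analyse — e.g. the `profiles` element of
#'   [simulate_methylation()], or profiles read with
#'   [read_methyldackel_bedgraph()].
#' @param out_dir output directory (created if needed).
#' @param th a [dmr_thresholds()] list.
#' @param genes optional gene table for element derivation (see
#'   [derive_elements()]).
#' @param elements optional extra element catalog rows (exons, CGIs,
#'   enhancers, repeats, ...).
#' @param icr_panel optional ICR panel (see [icr_report()]).
#' @param em optional [expression_matrix()].
#' @param params an [annotation_params()] list.
#' @param fpkm_high_cutoff,restore_window integration parameters.
#' @param wt,ko,ci genotype labels.
#' @return Invisibly, a list with the stage results (`cohorts`,
#'   `dmrs_ko`, `dmrs_ci`, `rescue`, `annotation`, `icr`, `temporal`,
#'   `de`, `groups`, `manifest`).
#' @export
run_pipeline <- function(profiles, out_dir, th = dmr_thresholds(),
                         genes = NULL, elements = NULL, icr_panel = NULL,
                         em = NULL, params = annotation_params(),
                         fpkm_high_cutoff = 1.0, restore_window = 10,
                         wt = "WT", ko = "KO", ci = "CI") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- sort(unique(vapply(profiles, `[[`, "", "stage")))
  late <- stages[length(stages)]
  genotypes <- unique(vapply(profiles, `[[`, "", "genotype"))
  if (!wt %in% genotypes)
    .stopf("run_pipeline: no profiles for reference genotype '%s'", wt)
  res <- list()
  manifest <- list(package = "methrescue",
                   version = as.character(packageVersion("methrescue")),
                   thresholds = unclass(th),
                   annotation = params,
                   fpkm_high_cutoff = fpkm_high_cutoff,
                   restore_window = restore_window,
                   stages = stages, genotypes = genotypes,
                   n_profiles = length(profiles), counts = list())

  stage_try <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- cohort (late stage, all genotypes) --------------------------------
  groups <- stage_try("cohort", {
    g <- profiles_by_genotype(profiles, late, genotypes)
    build_cohort(g, min_cov = th$min_cov)
  })
  res$cohort <- groups
  manifest$counts$common_sites <- nrow(groups$sites)

  # --- DMR calling + rescue ---------------------------------------------
  catalog <- NULL
  if (!is.null(genes)) catalog <- derive_elements(genes, params)
  if (!is.null(elements)) catalog <- rbind(catalog,
    elements[, c("chrom", "start", "end", "kind", "gene_id")])
  if (ko %in% genotypes) {
    res$dmrs_ko <- stage_try("dmr_ko",
      call_dmrs(groups, reference = wt, test = ko, th))
    write_dmr_bed(res$dmrs_ko, file.path(out_dir, "dmrs_ko_vs_wt.bed"))
    manifest$counts$dmrs_ko <- nrow(res$dmrs_ko)
  }
  if (ci %in% genotypes) {
    res$dmrs_ci <- stage_try("dmr_ci",
      call_dmrs(groups, reference = wt, test = ci, th))
    write_dmr_bed(res$dmrs_ci, file.path(out_dir, "dmrs_ci_vs_wt.bed"))
    manifest$counts$dmrs_ci <- nrow(res$dmrs_ci)
  }
  if (!is.null(res$dmrs_ko) && !is.null(res$dmrs_ci)) {
    res$rescue <- stage_try("rescue",
      classify_rescue(res$dmrs_ko, res$dmrs_ci))
    write_dmr_bed(res$rescue$labels,
                  file.path(out_dir, "dmrs_ko_labeled.bed"))
    rep_ <- restoration_report(res$rescue)
    utils::write.table(rep_, file.path(out_dir, "restoration_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$weak <- res$rescue$n_weak
    manifest$counts$strong <- res$rescue$n_strong
  }

  # --- annotation --------------------------------------------------------
  if (!is.null(catalog) && !is.null(res$dmrs_ko)) {
    res$annotation <- stage_try("annotation",
      annotate_dmrs(res$dmrs_ko, catalog, params))
    dist <- element_distribution(res$annotation)
    utils::write.table(
      data.frame(kind = names(dist), n_dmrs = as.integer(dist)),
      file.path(out_dir, "element_distribution.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    chrd <- chromosome_distribution(res$dmrs_ko)
    utils::write.table(
      data.frame(chrom = names(chrd), n_dmrs = as.integer(chrd)),
      file.path(out_dir, "chromosome_distribution.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  if (!is.null(icr_panel)) {
    res$icr <- stage_try("icr",
      icr_report(groups, icr_panel, restore_window = restore_window,
                 wt = wt, ko = ko, ci = ci))
    utils::write.table(res$icr, file.path(out_dir, "icr_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- temporal ----------------------------------------------------------
  if (length(stages) >= 2L) {
    early <- stages[1L]
    wt_early <- Filter(function(p) p$genotype == wt && p$stage == early,
                       profiles)
    wt_late <- Filter(function(p) p$genotype == wt && p$stage == late,
                      profiles)
    if (length(wt_early) && length(wt_late)) {
      res$temporal <- stage_try("temporal",
        temporal_dmrs(wt_early, wt_late, th))
      gains <- res$temporal[res$temporal$direction == "gain", ,
                            drop = FALSE]
      if (nrow(gains) && all(c(ko, ci) %in% genotypes))
        res$temporal_dependence <- stage_try("dependence",
          classify_dependence(gains, groups, th, restore_window,
                              wt = wt, ko = ko, ci = ci))
      write_dmr_bed(res$temporal, file.path(out_dir, "temporal_dmrs.bed"))
      manifest$counts$temporal_gain <- sum(res$temporal$direction == "gain")
      manifest$counts$temporal_loss <- sum(res$temporal$direction == "loss")
    }
  }

  # --- expression integration -------------------------------------------
  if (!is.null(em) && ko %in% genotypes) {
    res$de <- stage_try("de",
      differential_expression(em, reference = wt, test = ko))
    utils::write.table(res$de, file.path(out_dir, "de_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$de_up <- sum(res$de$status == "up")
    manifest$counts$de_down <- sum(res$de$status == "down")
    if (!is.null(res$annotation) && !is.null(res$dmrs_ko)) {
      hits <- res$annotation$hits
      hypo_lp <- unique(hits$gene_id[
        hits$kind == "long_promoter" & !is.na(hits$gene_id) &
        res$dmrs_ko$direction[hits$dmr_idx] == "hypo"])
      hypo_lp <- hypo_lp[hypo_lp %in% rownames(em$fpkm)]
      if (length(hypo_lp)) {
        res$groups <- stage_try("groups",
          classify_promoter_groups(hypo_lp, em, res$de,
                                   fpkm_high_cutoff, wt = wt))
        utils::write.table(res$groups,
                           file.path(out_dir, "promoter_groups.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$counts$group3 <- sum(res$groups$group == "3")
      }
    }
  }

  manifest$de_method <- if (!is.null(res$de)) attr(res$de, "method") else NULL
  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
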