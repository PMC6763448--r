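# Expression handling, the differential-expression stand-in (Welch t on
# log2 FPKM; the published analysis used a count-based DESeq model, which
# is outside this package's scope), methylation-expression overlap, and
# the promoter Group 1/2/3 classifier.

#' Construct an expression matrix object
#'
#' @param fpkm numeric matrix, genes x samples, non-negative, with gene
#'   rownames and sample colnames.
#' @param samples data.frame with columns `sample_id`, `genotype` and
#'   optionally `stage`, `replicate`; defaults are parsed from column
#'   names of the form `GENOTYPE_rep`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(fpkm, samples = NULL) {
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) .stopf("expression_matrix: negative FPKM values")
  if (nrow(fpkm) && is.null(rownames(fpkm)))
    .stopf("expression_matrix: need gene names")
  if (anyDuplicated(rownames(fpkm)))
    .stopf("expression_matrix: duplicate gene ids")
  if (is.null(samples)) {
    ids <- colnames(fpkm)
    samples <- data.frame(sample_id = ids,
                          genotype = sub("_[^_]*$", "", ids),
                          replicate = sub("^.*_", "", ids))
  }
  structure(list(fpkm = fpkm, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%s)\n",
              nrow(x$fpkm), ncol(x$fpkm),
              paste(unique(x$samples$genotype), collapse = ", ")))
  invisible(x)
}

#' Load a gene x sample FPKM table
#'
#' Tab-separated, first column gene id, remaining columns one per sample
#' with a header of sample ids.
#'
#' @param path input TSV path.
#' @param samples optional sample metadata (see [expression_matrix()]).
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path, samples = NULL) {
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) .stopf("load_expression: no sample columns in %s", path)
  genes <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (anyDuplicated(genes)) .stopf("load_expression: duplicate gene ids")
  if (nrow(m) && (!is.numeric(m) || anyNA(m)))
    .stopf("load_expression: non-numeric FPKM values")
  rownames(m) <- genes
  expression_matrix(m, samples)
}

#' Write an expression matrix as a TSV
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(em, path) {
  out <- data.frame(gene = rownames(em$fpkm), em$fpkm, check.names = FALSE)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Differential expression stand-in (fold change + Welch t on log2 FPKM)
#'
#' Log2 fold change is computed on pseudocount-stabilised group mean FPKM
#' (`log2((mean_test + pc) / (mean_ref + pc))`); the p-value is a Welch
#' t-test on per-sample `log2(FPKM + pc)`. A gene is `up` iff its fold
#' change is at least `fc_min` (inclusive) and p < `alpha`; `down`
#' symmetrically; otherwise `ns`. Genes that are all-zero in both groups
#' are `ns` and flagged. This is a documented stand-in for a count-based
#' DESeq analysis.
#'
#' @param em an [expression_matrix()].
#' @param reference,test genotype labels in the sample metadata.
#' @param fc_min minimum fold change (default 2).
#' @param alpha significance level (default 0.05).
#' @param pseudocount stabilising pseudocount (default 0.5).
#' @return data.frame (class `de_result`): `gene`, `mean_ref`,
#'   `mean_test`, `log2_fold_change`, `p_value`, `status`, `flag`.
#' @export
differential_expression <- function(em, reference, test, fc_min = 2,
                                    alpha = 0.05, pseudocount = 0.5) {
  gsel <- function(g) em$samples$genotype == g
  for (g in c(reference, test))
    if (!any(gsel(g))) .stopf("differential_expression: no samples for '%s'", g)
  if (sum(gsel(reference)) < 2L || sum(gsel(test)) < 2L)
    .stopf("differential_expression: need >= 2 replicates per group")
  mr <- em$fpkm[, gsel(reference), drop = FALSE]
  mt <- em$fpkm[, gsel(test), drop = FALSE]
  mean_ref <- rowMeans(mr); mean_test <- rowMeans(mt)
  l2fc <- log2((mean_test + pseudocount) / (mean_ref + pseudocount))
  lr <- log2(mr + pseudocount); lt <- log2(mt + pseudocount)
  pv <- vapply(seq_len(nrow(em$fpkm)), function(i)
    welch_t(lt[i, ], lr[i, ])$p.value, numeric(1))
  allzero <- mean_ref == 0 & mean_test == 0
  thr <- log2(fc_min)
  status <- ifelse(l2fc >= thr & pv < alpha, "up",
                   ifelse(l2fc <= -thr & pv < alpha, "down", "ns"))
  status[allzero] <- "ns"
  out <- data.frame(gene = rownames(em$fpkm), mean_ref = mean_ref,
                    mean_test = mean_test, log2_fold_change = l2fc,
                    p_value = pv, status = status,
                    flag = ifelse(allzero, "all-zero", ""),
                    row.names = NULL)
  attr(out, "method") <-
    "fold-change + Welch t on log2(FPKM + pseudocount) [DESeq stand-in]"
  attr(out, "params") <- list(fc_min = fc_min, alpha = alpha,
                              pseudocount = pseudocount,
                              reference = reference, test = test)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Overlap of hypomethylated-DMR genes with up-regulated genes
#'
#' Venn-style counts of genes carrying a hypomethylated DMR in the chosen
#' element kind versus genes with increased expression, with a one-sided
#' hypergeometric over-representation p-value.
#'
#' @param hypo_genes character vector of genes with a hypomethylated DMR
#'   in the element of interest.
#' @param de_results a [differential_expression()] result.
#' @param universe_n size of the gene universe for the hypergeometric
#'   test (caller-supplied; e.g. number of expressed genes).
#' @return list: `n_hypo`, `n_up`, `n_overlap`, `overlap_genes`, `test`
#'   (an `htest`).
#' @export
methylation_expression_overlap <- function(hypo_genes, de_results,
                                           universe_n) {
  hypo_genes <- unique(hypo_genes)
  up <- unique(de_results$gene[de_results$status == "up"])
  k <- length(intersect(hypo_genes, up))
  list(n_hypo = length(hypo_genes), n_up = length(up), n_overlap = k,
       overlap_genes = intersect(hypo_genes, up),
       test = hypergeom_overlap(k, length(hypo_genes), length(up),
                                universe_n))
}

#' Classify promoter-hypomethylated genes into Groups 1-3
#'
#' For genes carrying a KO-hypomethylated long-promoter DMR:
#' Group 1 = high WT FPKM, expression unchanged; Group 2 = low WT FPKM,
#' unchanged; Group 3 = low WT FPKM with increased expression in the
#' knockout (> 2-fold and significant). Genes that are high-WT and
#' up-regulated fall outside the scheme and are `unassigned`; genes
#' absent from the matrix are `unassigned` and flagged. Down-regulated
#' genes are folded into "unchanged" (flagged).
#'
#' @param genes character vector of promoter-hypomethylated genes.
#' @param em an [expression_matrix()].
#' @param de_results a [differential_expression()] result (KO vs WT).
#' @param fpkm_high_cutoff WT mean FPKM at or above which a gene counts
#'   as high (default 1.0; declared parameter, config-exposed).
#' @param wt WT genotype label.
#' @return data.frame (class `promoter_groups`): `gene`, `wt_fpkm`,
#'   `wt_fpkm_level`, `expression_change`, `group`, `flag`.
#' @export
classify_promoter_groups <- function(genes, em, de_results,
                                     fpkm_high_cutoff = 1.0, wt = "WT") {
  wt_cols <- em$samples$genotype == wt
  rows <- lapply(genes, function(g) {
    if (!g %in% rownames(em$fpkm))
      return(data.frame(gene = g, wt_fpkm = NA_real_,
                        wt_fpkm_level = NA_character_,
                        expression_change = NA_character_,
                        group = "unassigned", flag = "missing-from-matrix"))
    wtf <- mean(em$fpkm[g, wt_cols])
    level <- if (wtf >= fpkm_high_cutoff) "high" else "low"
    di <- match(g, de_results$gene)
    up <- !is.na(di) && de_results$status[di] == "up" &&
      de_results$log2_fold_change[di] > 1
    change <- if (up) "up" else "unchanged"
    flag <- if (!is.na(di) && de_results$status[di] == "down")
      "down-folded-into-unchanged" else ""
    group <- if (level == "high" && change == "unchanged") "1"
      else if (level == "low" && change == "unchanged") "2"
      else if (level == "low" && change == "up") "3"
      else "unassigned"
    data.frame(gene = g, wt_fpkm = wtf, wt_fpkm_level = level,
               expression_change = change, group = group, flag = flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("promoter_groups", "data.frame")
  out
}

#' Normalised mean expression per promoter group and genotype
#'
#' Mean FPKM per group x genotype, normalised to the Group-3 mean in the
#' reference (WT) genotype. Empty groups are absent from the output.
#'
#' @param assignments a [classify_promoter_groups()] result.
#' @param em an [expression_matrix()].
#' @param wt WT genotype label (the normaliser genotype).
#' @return data.frame: `group`, `genotype`, `mean_fpkm`, `normalized`.
#' @export
group_mean_expression_report <- function(assignments, em, wt = "WT") {
  asg <- assignments[assignments$group %in% c("1", "2", "3"), , drop = FALSE]
  genotypes <- unique(em$samples$genotype)
  rows <- list()
  for (g in sort(unique(asg$group))) {
    gg <- asg$gene[asg$group == g]
    gg <- gg[gg %in% rownames(em$fpkm)]
    for (gt in genotypes) {
      cols <- em$samples$genotype == gt
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, genotype = gt,
        mean_fpkm = mean(em$fpkm[gg, cols, drop = FALSE]))
    }
  }
  out <- do.call(rbind, rows)
  norm <- out$mean_fpkm[out$group == "3" & out$genotype == wt]
  out$normalized <- if (length(norm) == 1L && norm > 0)
    out$mean_fpkm / norm else NA_real_
  out
}
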