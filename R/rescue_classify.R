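# Weak/strong rescue classification: a KO DMR whose interval overlaps a
# same-direction CI DMR is "strong" (methylation requires Dnmt3b's
# catalytic activity); otherwise "weak" (restored by the catalytically
# inactive allele, i.e. accessory function suffices).

.dmr_granges <- function(dmrs, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(as.character(dmrs$chrom))
  GRanges(seqnames = factor(as.character(dmrs$chrom), levels = seqlevels),
          ranges = IRanges(start = dmrs$start + 1L, end = dmrs$end))
}

#' Classify KO DMRs as weak or strong by CI overlap
#'
#' A KO DMR is **strong** iff it overlaps (>= `min_overlap` bp, default
#' any overlap) at least one CI DMR of the same direction, and **weak**
#' otherwise. Both DMR sets must come from same-reference (vs WT)
#' comparisons with the same direction convention. CI DMRs overlapping no
#' KO DMR are counted separately and excluded from the partition.
#'
#' @param dmrs_ko,dmrs_ci `dmr_set` data.frames (KO vs WT and CI vs WT).
#' @param min_overlap minimum overlap in bp (default 1).
#' @param min_overlap_frac optional reciprocal requirement: minimum
#'   overlap as a fraction of the KO DMR length (default 0, i.e. off).
#' @return A list of class `rescue_summary`: `n_total`, `n_weak`,
#'   `n_strong`, `restoration_pct` (`NA` and flagged when `n_total` is 0),
#'   `n_ci_only`, `labels` (the KO DMRs with a `label` column), and
#'   `pairs` (KO/CI index pairs that overlapped).
#' @export
classify_rescue <- function(dmrs_ko, dmrs_ci, min_overlap = 1L,
                            min_overlap_frac = 0) {
  n_total <- NROW(dmrs_ko)
  labels <- rep("weak", n_total)
  pairs <- data.frame(ko = integer(), ci = integer())
  ci_hit <- logical(NROW(dmrs_ci))
  if (n_total && NROW(dmrs_ci)) {
    sl <- unique(c(as.character(dmrs_ko$chrom), as.character(dmrs_ci$chrom)))
    gko <- .dmr_granges(dmrs_ko, sl); gci <- .dmr_granges(dmrs_ci, sl)
    hits <- findOverlaps(gko, gci, minoverlap = as.integer(min_overlap))
    qh <- queryHits(hits); sh <- subjectHits(hits)
    same_dir <- dmrs_ko$direction[qh] == dmrs_ci$direction[sh]
    ow <- width(pintersect(gko[qh], gci[sh]))
    frac_ok <- ow >= min_overlap_frac * width(gko[qh])
    keep <- same_dir & frac_ok
    labels[unique(qh[keep])] <- "strong"
    ci_hit[unique(sh[keep])] <- TRUE
    pairs <- data.frame(ko = qh[keep], ci = sh[keep])
  }
  out <- dmrs_ko
  if (n_total) out$label <- labels
  n_strong <- sum(labels == "strong")
  structure(list(
    n_total = n_total, n_weak = n_total - n_strong, n_strong = n_strong,
    restoration_pct = if (n_total) 100 * (n_total - n_strong) / n_total
                      else NA_real_,
    undefined = n_total == 0L,
    n_ci_only = NROW(dmrs_ci) - sum(ci_hit),
    labels = out, pairs = pairs), class = "rescue_summary")
}

#' @export
print.rescue_summary <- function(x, ...) {
  cat(sprintf("<rescue_summary> %d KO DMRs: %d weak, %d strong", x$n_total,
              x$n_weak, x$n_strong))
  if (!x$undefined)
    cat(sprintf(" (restoration %.1f%%)", x$restoration_pct))
  cat(sprintf("; %d CI-only DMR(s)\n", x$n_ci_only))
  invisible(x)
}

#' Tabulate the restoration summary
#'
#' @param summary a [classify_rescue()] result.
#' @return One-row data.frame with total/weak/strong counts, restoration
#'   percent (weak / total * 100) and the CI-only DMR count.
#' @export
restoration_report <- function(summary) {
  data.frame(n_total = summary$n_total, n_weak = summary$n_weak,
             n_strong = summary$n_strong,
             restoration_pct = summary$restoration_pct,
             n_ci_only = summary$n_ci_only)
}
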