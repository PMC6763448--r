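# DMC calling and DMR segmentation. A DMC is a commonly covered CpG whose
# pooled group methylation differs by at least min_diff percent points; a
# DMR is a maximal run of >= min_dmcs same-direction DMCs, consecutive
# among covered CpGs, within max_gap bp of each other, whose mean change
# passes min_diff and whose per-sample per-CpG percents differ by MWU at
# alpha.

#' DMC/DMR calling thresholds
#'
#' @param min_cov minimum per-sample coverage for cohort construction
#'   (default 15; 10 is conventional for cell-line data).
#' @param min_diff minimum absolute pooled methylation difference in
#'   percent points (default 30, inclusive).
#' @param min_dmcs minimum number of consecutive DMCs per DMR (default 3).
#' @param max_gap maximum distance in bp between consecutive member DMCs
#'   (default 50; 100 in cell-line mode).
#' @param max_span optional cap on total region length in bp (`NULL` =
#'   unset; 200 or 100 reproduce alternative published wordings).
#' @param alpha significance level for the region-level MWU test
#'   (default 0.05). No multiple-testing correction is applied by default.
#' @param allow_skip number of intervening covered non-DMC CpGs tolerated
#'   inside a run (default 0: any covered non-DMC CpG breaks a run).
#' @return A list of class `dmr_thresholds`.
#' @export
dmr_thresholds <- function(min_cov = 15, min_diff = 30, min_dmcs = 3,
                           max_gap = 50, max_span = NULL, alpha = 0.05,
                           allow_skip = 0) {
  if (min_diff <= 0 || min_diff > 100) .stopf("min_diff must be in (0, 100]")
  if (min_dmcs < 2) .stopf("min_dmcs must be >= 2")
  if (max_gap <= 0) .stopf("max_gap must be > 0")
  structure(list(min_cov = min_cov, min_diff = min_diff,
                 min_dmcs = as.integer(min_dmcs), max_gap = max_gap,
                 max_span = max_span, alpha = alpha,
                 allow_skip = as.integer(allow_skip)),
            class = "dmr_thresholds")
}

#' Call differentially methylated cytosines (DMCs)
#'
#' One DMC per common site where the pooled test-minus-reference percent
#' difference is at least `min_diff` in absolute value (inclusive: a
#' change of exactly 30.0 is a DMC at the default threshold). The delta
#' sign is test minus reference, so hypomethylation in a KO-vs-WT
#' comparison appears as negative delta.
#'
#' @param cohort a [build_cohort()] result.
#' @param reference,test group labels present in the cohort.
#' @param th a [dmr_thresholds()] list.
#' @return data.frame with columns `chrom`, `pos`, `site_idx` (row index
#'   into the cohort's common sites), `delta` and `direction`
#'   (`hyper`/`hypo`); attributes record the comparison.
#' @export
call_dmcs <- function(cohort, reference, test, th = dmr_thresholds()) {
  for (g in c(reference, test))
    if (!g %in% colnames(cohort$group_percent))
      .stopf("call_dmcs: unknown group '%s'", g)
  delta <- cohort$group_percent[, test] - cohort$group_percent[, reference]
  keep <- which(!is.na(delta) & abs(delta) >= th$min_diff)
  out <- data.frame(chrom = cohort$sites$chrom[keep],
                    pos = cohort$sites$pos[keep],
                    site_idx = keep, delta = delta[keep],
                    direction = ifelse(delta[keep] > 0, "hyper", "hypo"),
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- reference
  attr(out, "test") <- test
  out
}

.empty_dmr_set <- function(reference, test, th) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    n_dmcs = integer(), mean_delta = numeric(),
                    direction = character(), p_value = numeric())
  out$members <- list()
  class(out) <- c("dmr_set", "data.frame")
  attr(out, "reference") <- reference
  attr(out, "test") <- test
  attr(out, "thresholds") <- th
  out
}

#' Segment DMCs into differentially methylated regions (DMRs)
#'
#' Builds maximal runs of same-direction DMCs that are consecutive among
#' the cohort's covered common CpGs (an intervening covered non-DMC CpG
#' breaks a run unless `allow_skip` permits it), with each consecutive
#' pair at most `max_gap` bp apart, broken at chromosome boundaries and
#' where `max_span` would be exceeded. Runs are kept when they hold at
#' least `min_dmcs` DMCs, their mean delta passes `min_diff`, and a
#' Mann-Whitney U test comparing all per-sample per-CpG percents of the
#' two groups within the run gives p < `alpha`.
#'
#' @param dmcs result of [call_dmcs()].
#' @param cohort the cohort the DMCs were called from.
#' @param th a [dmr_thresholds()] list.
#' @return A `dmr_set` data.frame: `chrom`, `start`, `end` (0-based
#'   half-open, first to last member CpG), `n_dmcs`, `mean_delta`,
#'   `direction`, `p_value`, and a `members` list-column of CpG positions.
#' @export
segment_dmrs <- function(dmcs, cohort, th = dmr_thresholds()) {
  reference <- attr(dmcs, "reference"); test <- attr(dmcs, "test")
  if (!nrow(dmcs)) return(.empty_dmr_set(reference, test, th))
  if (any(dmcs$site_idx < 1L | dmcs$site_idx > nrow(cohort$sites)) ||
      any(cohort$sites$pos[dmcs$site_idx] != dmcs$pos))
    .stopf("segment_dmrs: DMCs do not match the cohort's common sites")
  idx <- dmcs$site_idx
  chrom <- dmcs$chrom; pos <- dmcs$pos
  dirn <- dmcs$direction; delta <- dmcs$delta
  n <- length(idx)
  # break between successive DMCs unless consecutive-in-common (allowing
  # allow_skip intervening covered CpGs), same chrom/direction, gap ok
  brk <- rep(TRUE, n)
  if (n > 1L) {
    i <- 2:n
    brk[i] <- chrom[i] != chrom[i - 1L] |
      dirn[i] != dirn[i - 1L] |
      (idx[i] - idx[i - 1L] - 1L) > th$allow_skip |
      (pos[i] - pos[i - 1L]) > th$max_gap
  }
  run_id <- cumsum(brk)
  # apply the span cap greedily within runs
  if (!is.null(th$max_span)) {
    new_id <- run_id
    counter <- 0L
    for (r in unique(run_id)) {
      members <- which(run_id == r)
      counter <- counter + 1L
      anchor <- pos[members[1L]]
      for (m in members) {
        if (pos[m] + 1L - anchor > th$max_span) {
          counter <- counter + 1L
          anchor <- pos[m]
        }
        new_id[m] <- counter
      }
    }
    run_id <- new_id
  }
  ref_samples <- cohort$samples$group == reference
  test_samples <- cohort$samples$group == test
  rows <- lapply(split(seq_len(n), run_id), function(members) {
    if (length(members) < th$min_dmcs) return(NULL)
    md <- mean(delta[members])
    if (abs(md) < th$min_diff) return(NULL)
    sidx <- idx[members]
    xs <- as.vector(cohort$per_sample_percent[sidx, test_samples])
    ys <- as.vector(cohort$per_sample_percent[sidx, ref_samples])
    pv <- mann_whitney_u(xs, ys)$p.value
    if (pv >= th$alpha) return(NULL)
    data.frame(chrom = chrom[members[1L]], start = pos[members[1L]],
               end = pos[members[length(members)]] + 1L,
               n_dmcs = length(members), mean_delta = md,
               direction = dirn[members[1L]], p_value = pv,
               members = I(list(pos[members])),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(.empty_dmr_set(reference, test, th))
  out <- do.call(rbind, rows)
  out <- out[.site_order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dmr_set", "data.frame")
  attr(out, "reference") <- reference
  attr(out, "test") <- test
  attr(out, "thresholds") <- th
  out
}

#' Call DMRs in one step
#'
#' Convenience wrapper chaining [call_dmcs()] and [segment_dmrs()].
#' @inheritParams call_dmcs
#' @return A `dmr_set` (see [segment_dmrs()]).
#' @export
call_dmrs <- function(cohort, reference, test, th = dmr_thresholds()) {
  segment_dmrs(call_dmcs(cohort, reference, test, th), cohort, th)
}

#' @export
print.dmr_set <- function(x, ...) {
  ref <- attr(x, "reference"); tst <- attr(x, "test")
  cmp <- if (!is.null(ref)) sprintf(" (%s vs %s)", tst, ref) else ""
  cat(sprintf("<dmr_set>%s: %d region(s)", cmp, nrow(x)))
  if (nrow(x)) {
    tab <- table(x$direction)
    cat(" [", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "]",
        sep = "")
  }
  cat("\n")
  if (nrow(x)) print.data.frame(head(
    x[, c("chrom", "start", "end", "n_dmcs", "mean_delta", "direction",
          "p_value")], 10))
  invisible(x)
}

#' @export
summary.dmr_set <- function(object, ...) {
  data.frame(n = nrow(object),
             n_hyper = sum(object$direction %in% c("hyper", "gain")),
             n_hypo = sum(object$direction %in% c("hypo", "loss")),
             mean_abs_delta = if (nrow(object)) mean(abs(object$mean_delta))
                              else NA_real_,
             total_dmcs = sum(object$n_dmcs))
}

#' Pooled-percent Pearson correlation between two cohort groups
#'
#' @param cohort a [build_cohort()] result.
#' @param group_a,group_b group labels.
#' @return Pearson correlation of the pooled methylation percents over
#'   common sites.
#' @export
pairwise_site_correlation <- function(cohort, group_a, group_b) {
  for (g in c(group_a, group_b))
    if (!g %in% colnames(cohort$group_percent))
      .stopf("pairwise_site_correlation: unknown group '%s'", g)
  pearson_r(cohort$group_percent[, group_a], cohort$group_percent[, group_b])
}

#' Matrix of DMR member CpG methylation by group
#'
#' Rows are the union of member CpGs across all DMRs; columns are the
#' cohort's groups; values are pooled group percents. Suitable input for
#' [uncentered_avg_linkage()].
#'
#' @param cohort a [build_cohort()] result.
#' @param dmrs a `dmr_set` with a `members` column.
#' @return Numeric matrix (CpGs x groups) with `chrom:pos` rownames.
#' @export
dmr_cpg_matrix <- function(cohort, dmrs) {
  if (!NROW(dmrs))
    return(matrix(numeric(), 0, ncol(cohort$group_percent),
                  dimnames = list(NULL, colnames(cohort$group_percent))))
  key <- paste(cohort$sites$chrom, cohort$sites$pos)
  want <- unique(unlist(Map(function(ch, m) paste(ch, m),
                            dmrs$chrom, dmrs$members)))
  sidx <- sort(match(want, key))
  if (anyNA(sidx)) .stopf("dmr_cpg_matrix: member CpG missing from cohort")
  m <- cohort$group_percent[sidx, , drop = FALSE]
  rownames(m) <- paste0(cohort$sites$chrom[sidx], ":", cohort$sites$pos[sidx])
  m
}
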