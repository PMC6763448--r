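# Meta-profiles of methylation and binned chromatin signal around TSSs
# and over length-scaled DMR bodies, and weak-vs-strong enrichment
# comparisons. Signal is consumed as pre-binned bedGraph; no BAM/bigWig
# dependency.

#' Construct a signal track
#'
#' @param bins data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, non-overlapping) and `value` (finite).
#' @param mark mark name (e.g. `"H3K27me3"`, `"DNase"`).
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(bins, mark = NA_character_) {
  bins <- as.data.frame(bins)[, c("chrom", "start", "end", "value")]
  bins$start <- as.integer(bins$start); bins$end <- as.integer(bins$end)
  if (nrow(bins)) {
    if (any(!is.finite(bins$value))) .stopf("signal_track: non-finite values")
    if (any(bins$end <= bins$start)) .stopf("signal_track: empty interval")
    bins <- bins[.site_order(bins$chrom, bins$start), , drop = FALSE]
    same <- bins$chrom[-1L] == bins$chrom[-nrow(bins)]
    if (nrow(bins) > 1L && any(same & bins$start[-1L] < bins$end[-nrow(bins)]))
      .stopf("signal_track: overlapping intervals")
    rownames(bins) <- NULL
  }
  structure(list(bins = bins, mark = as.character(mark)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %s: %d bins\n", x$mark, nrow(x$bins)))
  invisible(x)
}

#' Load a bedGraph signal track
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based
#'   half-open).
#' @param mark mark name (default: file base name).
#' @return A [signal_track()].
#' @export
load_signal_track <- function(path,
                              mark = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines))
    return(signal_track(data.frame(chrom = character(), start = integer(),
                                   end = integer(), value = numeric()),
                        mark))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  signal_track(data.frame(chrom = vapply(parts, `[`, "", 1L),
                          start = as.integer(vapply(parts, `[`, "", 2L)),
                          end = as.integer(vapply(parts, `[`, "", 3L)),
                          value = as.numeric(vapply(parts, `[`, "", 4L))),
               mark)
}

#' Write a signal track as bedGraph
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @export
write_signal_track <- function(track, path) {
  utils::write.table(track$bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# mean signal of a track over a set of intervals (0-based half-open);
# bp-weighted over overlapping track bins; NA where no bin overlaps.
.track_interval_means <- function(track, chrom, start, end) {
  q <- data.table(qid = seq_along(chrom), chrom = chrom,
                  start = as.integer(start), end = as.integer(end))
  tb <- as.data.table(track$bins)
  if (!nrow(tb)) return(rep(NA_real_, nrow(q)))
  setkey(tb, chrom, start, end)
  ov <- foverlaps(q, tb, by.x = c("chrom", "start", "end"),
                  type = "any", nomatch = NULL)
  if (!nrow(ov)) return(rep(NA_real_, nrow(q)))
  ov[, w := pmin(end, i.end) - pmax(start, i.start)]
  agg <- ov[w > 0, list(m = sum(value * w) / sum(w)), by = "qid"]
  out <- rep(NA_real_, nrow(q))
  out[agg$qid] <- agg$m
  out
}

# mean of per-site values over intervals (methylation mode)
.site_interval_means <- function(values, chrom, start, end) {
  q <- data.table(qid = seq_along(chrom), chrom = chrom,
                  start = as.integer(start), end = as.integer(end))
  sv <- data.table(chrom = values$chrom, start = as.integer(values$pos),
                   end = as.integer(values$pos) + 1L, value = values$value)
  if (!nrow(sv)) return(rep(NA_real_, nrow(q)))
  setkey(sv, chrom, start, end)
  ov <- foverlaps(q, sv, by.x = c("chrom", "start", "end"),
                  type = "any", nomatch = NULL)
  out <- rep(NA_real_, nrow(q))
  if (!nrow(ov)) return(out)
  agg <- ov[, list(m = mean(value)), by = "qid"]
  out[agg$qid] <- agg$m
  out
}

.interval_means <- function(x, chrom, start, end) {
  if (inherits(x, "signal_track")) .track_interval_means(x, chrom, start, end)
  else .site_interval_means(x, chrom, start, end)
}

.meta_profile <- function(bin_mat, bin_labels, mode) {
  n <- colSums(!is.na(bin_mat))
  mu <- colMeans(bin_mat, na.rm = TRUE)
  sem <- apply(bin_mat, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
  })
  mu[n == 0L] <- NA_real_
  out <- data.frame(bin = bin_labels, mean = mu, sem = sem, n = n,
                    row.names = NULL)
  class(out) <- c("meta_profile", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "n_regions") <- nrow(bin_mat)
  out
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("<meta_profile> (%s): %d bins over %d regions\n",
              attr(x, "mode"), nrow(x), attr(x, "n_regions")))
  invisible(x)
}

#' TSS-centred meta-profile
#'
#' Per-bin mean and SEM of methylation or chromatin signal in a window
#' around transcription start sites, strand-aware (upstream is negative).
#' `x` is either a [signal_track()] or a data.frame of per-CpG values
#' (`chrom`, `pos`, `value`, e.g. from [site_values()]).
#'
#' @param x signal track or per-site value data.frame.
#' @param genes data.frame with `chrom`, `start`, `end`, `strand` (TSS =
#'   `start` on `+`, `end - 1` on `-`).
#' @param half_window half window in bp (default 2000), a multiple of
#'   `bin_size`.
#' @param bin_size bin width in bp (default 100).
#' @return A `meta_profile` data.frame (`bin` = offset of bin start from
#'   the TSS, `mean`, `sem`, `n` = TSSs with data in the bin).
#' @export
tss_meta_profile <- function(x, genes, half_window = 2000, bin_size = 100) {
  if (half_window %% bin_size != 0)
    .stopf("tss_meta_profile: half_window must be a multiple of bin_size")
  nb <- 2L * half_window / bin_size
  offs <- seq(-half_window, half_window - bin_size, by = bin_size)
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end - 1L)
  nt <- length(tss)
  # oriented genomic interval of each (gene, bin), gene-major order
  gene_i <- rep(seq_len(nt), each = nb)
  off_i <- rep(offs, times = nt)
  gstart <- ifelse(plus[gene_i], tss[gene_i] + off_i,
                   tss[gene_i] - off_i - bin_size + 1L)
  vals <- .interval_means(x, genes$chrom[gene_i], gstart, gstart + bin_size)
  mat <- matrix(vals, nrow = nt, ncol = nb, byrow = TRUE)
  .meta_profile(mat, offs, mode = "tss")
}

#' Scaled-region meta-profile
#'
#' Each region is linearly rescaled onto `body_bins` bins (the published
#' convention scales regions to 1000 bp in 10 bp bins) with unscaled
#' flanks of `flank` bp on both sides; per-bin mean and SEM are taken
#' across regions.
#'
#' @param x signal track or per-site value data.frame (see
#'   [tss_meta_profile()]).
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param body_bins number of bins the body is scaled onto (default 100).
#' @param bin_size flank bin width in bp (default 10).
#' @param flank unscaled flank in bp on each side (default 100).
#' @return A `meta_profile`; `bin` runs from `-flank/bin_size` over
#'   `1..body_bins` to the right flank.
#' @export
scaled_region_profile <- function(x, regions, body_bins = 100, bin_size = 10,
                                  flank = 100) {
  if (!NROW(regions)) .stopf("scaled_region_profile: no regions")
  fb <- as.integer(flank / bin_size)
  nb <- body_bins + 2L * fb
  nr <- nrow(regions)
  starts <- ends <- matrix(0L, nr, nb)
  for (j in seq_len(fb)) {      # left flank
    starts[, j] <- regions$start - flank + (j - 1L) * bin_size
    ends[, j] <- starts[, j] + bin_size
  }
  len <- regions$end - regions$start
  for (j in seq_len(body_bins)) {
    starts[, fb + j] <- regions$start + floor(len * (j - 1L) / body_bins)
    ends[, fb + j] <- pmax(regions$start + ceiling(len * j / body_bins),
                           starts[, fb + j] + 1L)
  }
  for (j in seq_len(fb)) {      # right flank
    starts[, fb + body_bins + j] <- regions$end + (j - 1L) * bin_size
    ends[, fb + body_bins + j] <- starts[, fb + body_bins + j] + bin_size
  }
  vals <- .interval_means(x, rep(regions$chrom, nb), as.vector(starts),
                          as.vector(ends))
  mat <- matrix(vals, nrow = nr, ncol = nb)
  labels <- c(-(fb:1), seq_len(body_bins), body_bins + seq_len(fb))
  .meta_profile(mat, labels, mode = "scaled")
}

#' Compare signal enrichment between two region sets
#'
#' Per-region mean signal over the region body (flanks excluded) is
#' compared between the two sets with a two-sided Welch t-test — the test
#' used for strong-vs-weak DMR chromatin comparisons.
#'
#' @param track a [signal_track()].
#' @param regions_a,regions_b data.frames with `chrom`, `start`, `end`.
#' @return list: `mean_a`, `mean_b`, `test` (an `htest`), `values_a`,
#'   `values_b`.
#' @export
compare_enrichment <- function(track, regions_a, regions_b) {
  va <- .track_interval_means(track, regions_a$chrom, regions_a$start,
                              regions_a$end)
  vb <- .track_interval_means(track, regions_b$chrom, regions_b$start,
                              regions_b$end)
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) < 2L || length(vb) < 2L)
    .stopf("compare_enrichment: need >= 2 regions with signal per set")
  list(mean_a = mean(va), mean_b = mean(vb), test = welch_t(va, vb),
       values_a = va, values_b = vb)
}

#' Per-element-kind enrichment comparison of two region sets
#'
#' Runs [compare_enrichment()] within each element-kind stratum of an
#' annotation; strata with fewer than 2 regions on either side are
#' reported as no-test.
#'
#' @param track a [signal_track()].
#' @param regions_a,regions_b annotated region sets.
#' @param ann_a,ann_b [annotate_dmrs()] results for the two sets against
#'   a shared catalog.
#' @return data.frame: `kind`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `p_value` (NA = no-test).
#' @export
stratified_enrichment <- function(track, regions_a, regions_b, ann_a,
                                  ann_b) {
  rows <- lapply(colnames(ann_a$matrix), function(k) {
    ia <- which(ann_a$matrix[, k]); ib <- which(ann_b$matrix[, k])
    if (length(ia) < 2L || length(ib) < 2L)
      return(data.frame(kind = k, n_a = length(ia), n_b = length(ib),
                        mean_a = NA_real_, mean_b = NA_real_,
                        p_value = NA_real_))
    ce <- compare_enrichment(track, regions_a[ia, , drop = FALSE],
                             regions_b[ib, , drop = FALSE])
    data.frame(kind = k, n_a = length(ia), n_b = length(ib),
               mean_a = ce$mean_a, mean_b = ce$mean_b,
               p_value = ce$test$p.value)
  })
  do.call(rbind, rows)
}
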