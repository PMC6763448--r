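# Reading, writing and pooling of per-CpG bisulfite call files, and
# construction of the commonly-covered cohort table that all downstream
# calling operates on. Internal coordinates are 0-based, half-open.

#' Construct a per-sample CpG methylation profile
#'
#' A `sample_profile` holds ordered per-CpG methylated/unmethylated read
#' counts for one RRBS sample together with its genotype and embryonic
#' stage. Sites are unique by (chrom, pos) and sorted; positions are
#' 0-based cytosine coordinates.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `meth`, `unmeth`.
#' @param sample_id sample identifier.
#' @param genotype genotype label, conventionally one of `"WT"`, `"KO"`,
#'   `"CI"` (free-form labels are allowed).
#' @param stage embryonic day label such as `"E11.5"`.
#' @return An object of class `sample_profile`.
#' @export
sample_profile <- function(sites, sample_id, genotype = NA_character_,
                           stage = NA_character_) {
  sites <- as.data.frame(sites)[, c("chrom", "pos", "meth", "unmeth")]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$meth <- as.integer(sites$meth)
  sites$unmeth <- as.integer(sites$unmeth)
  if (nrow(sites)) {
    if (any(is.na(sites$meth)) || any(is.na(sites$unmeth)) ||
        any(sites$meth < 0L) || any(sites$unmeth < 0L))
      .stopf("sample '%s': negative or missing methylation counts", sample_id)
    sites <- sites[.site_order(sites$chrom, sites$pos), , drop = FALSE]
    if (anyDuplicated(paste(sites$chrom, sites$pos)))
      .stopf("sample '%s': duplicate (chrom, pos) sites", sample_id)
    rownames(sites) <- NULL
  }
  structure(list(sample_id = as.character(sample_id),
                 genotype = as.character(genotype),
                 stage = as.character(stage), sites = sites),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("<sample_profile> %s (genotype %s, stage %s): %d CpG sites\n",
              x$sample_id, x$genotype, x$stage, nrow(x$sites)))
  invisible(x)
}

#' Per-site coverage of a sample profile
#' @param profile a [sample_profile()].
#' @return integer vector of per-site read coverage (meth + unmeth).
#' @export
profile_coverage <- function(profile) profile$sites$meth + profile$sites$unmeth

#' Per-site methylation percent of a sample profile
#'
#' Defined as `100 * meth / (meth + unmeth)`; `NaN` where coverage is zero.
#' @inheritParams profile_coverage
#' @export
profile_percent <- function(profile) {
  cov <- profile_coverage(profile)
  100 * profile$sites$meth / cov
}

.read_call_file <- function(path, zero_based, sample_id, genotype, stage) {
  if (!file.exists(path)) .stopf("file does not exist: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(sample_profile(
      data.frame(chrom = character(), pos = integer(), meth = integer(),
                 unmeth = integer()), sample_id, genotype, stage))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    .stopf("%s: malformed line %d (expected 6 tab-separated fields, got %d)",
           path, which(nf != 6L)[1L], nf[nf != 6L][1L])
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  meth <- suppressWarnings(as.integer(m[, 5L]))
  unmeth <- suppressWarnings(as.integer(m[, 6L]))
  bad <- which(is.na(start) | is.na(meth) | is.na(unmeth))
  if (length(bad))
    .stopf("%s: malformed line %d (non-numeric coordinate or count)",
           path, bad[1L])
  if (any(meth < 0L) || any(unmeth < 0L))
    .stopf("%s: negative counts at line %d", path,
           which(meth < 0L | unmeth < 0L)[1L])
  pos <- if (zero_based) start else start - 1L
  sample_profile(data.frame(chrom = m[, 1L], pos = pos, meth = meth,
                            unmeth = unmeth),
                 sample_id, genotype, stage)
}

#' Read a Bismark coverage file
#'
#' Bismark `.cov` dialect: chrom, start (1-based), end, methylation percent,
#' methylated count, unmethylated count. Positions are converted to 0-based
#' on read and the percent column is ignored — counts are authoritative.
#'
#' @param path path to the file.
#' @param sample_id,genotype,stage sample metadata (default: file base name,
#'   unknown genotype/stage).
#' @return A [sample_profile()].
#' @export
read_bismark_cov <- function(path,
                             sample_id = sub("\\.[^.]*$", "", basename(path)),
                             genotype = NA_character_,
                             stage = NA_character_) {
  .read_call_file(path, zero_based = FALSE, sample_id, genotype, stage)
}

#' Read a MethylDackel bedGraph file
#'
#' MethylDackel dialect: chrom, start (0-based), end, methylation percent,
#' methylated count, unmethylated count. Positions are taken as 0-based
#' directly; the percent column is recomputed from counts.
#'
#' @inheritParams read_bismark_cov
#' @return A [sample_profile()].
#' @export
read_methyldackel_bedgraph <- function(path,
                                       sample_id = sub("\\.[^.]*$", "",
                                                       basename(path)),
                                       genotype = NA_character_,
                                       stage = NA_character_) {
  .read_call_file(path, zero_based = TRUE, sample_id, genotype, stage)
}

#' Write a sample profile as a per-CpG call file
#'
#' @param profile a [sample_profile()].
#' @param path output path.
#' @param dialect `"methyldackel"` (0-based start) or `"bismark"`
#'   (1-based start).
#' @return `path`, invisibly.
#' @export
write_sample_profile <- function(profile, path,
                                 dialect = c("methyldackel", "bismark")) {
  dialect <- match.arg(dialect)
  s <- profile$sites
  cov <- s$meth + s$unmeth
  pct <- ifelse(cov > 0, 100 * s$meth / cov, 0)
  start <- if (dialect == "methyldackel") s$pos else s$pos + 1L
  end <- s$pos + 1L
  out <- data.frame(s$chrom, start, end, signif(pct, 6), s$meth, s$unmeth)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge opposite-strand CpG calls
#'
#' Optionally merges + and - strand calls reported at positions `p` and
#' `p + 1` of a CpG dyad by summing their counts onto the cytosine at `p`.
#' Input dialects usually carry already-destranded counts, so this step is
#' off by default in the pipeline.
#'
#' @param profile a [sample_profile()].
#' @return A destranded [sample_profile()].
#' @export
destrand_profile <- function(profile) {
  s <- profile$sites
  if (nrow(s) < 2L) return(profile)
  prev <- c(FALSE, s$chrom[-1L] == s$chrom[-nrow(s)] &
                   s$pos[-1L] == s$pos[-nrow(s)] + 1L)
  anchor <- cumsum(!prev)
  merged <- data.frame(
    chrom = s$chrom[!prev],
    pos = s$pos[!prev],
    meth = as.vector(tapply(s$meth, anchor, sum)),
    unmeth = as.vector(tapply(s$unmeth, anchor, sum)))
  sample_profile(merged, profile$sample_id, profile$genotype, profile$stage)
}

#' Pool replicate profiles into one group-level profile
#'
#' Counts are summed across replicates per position, so the pooled percent
#' equals the coverage-weighted mean of the replicate percents. All profiles
#' must share one genotype (the study design uses n = 2 RRBS replicates per
#' genotype).
#'
#' @param profiles list of [sample_profile()] objects of one genotype/stage.
#' @return A pooled [sample_profile()].
#' @export
pool_group <- function(profiles) {
  if (!length(profiles)) .stopf("pool_group: need at least one profile")
  gt <- unique(vapply(profiles, `[[`, "", "genotype"))
  st <- unique(vapply(profiles, `[[`, "", "stage"))
  if (length(gt) > 1L)
    .stopf("pool_group: mixed genotypes (%s)", paste(gt, collapse = ", "))
  if (length(st) > 1L)
    .stopf("pool_group: mixed stages (%s)", paste(st, collapse = ", "))
  dt <- rbindlist(lapply(profiles, function(p) as.data.table(p$sites)))
  pooled <- dt[, list(meth = sum(meth), unmeth = sum(unmeth)),
               by = c("chrom", "pos")]
  sample_profile(as.data.frame(pooled),
                 sample_id = paste0(gt, "_pooled"),
                 genotype = gt, stage = st)
}

#' Build a cohort table of commonly covered CpG sites
#'
#' Restricts to CpG sites with coverage of at least `min_cov` in **every**
#' sample of every group (the "present in all samples" rule), then records
#' per-sample percents and group-pooled percents at those sites. Pooled
#' group percents are computed from summed counts; per-sample percents are
#' retained for the rank test used in DMR calling.
#'
#' @param groups named list; each element is a list of [sample_profile()]
#'   replicates for one group (e.g. `list(WT = list(...), KO = list(...))`).
#' @param min_cov minimum per-sample coverage (default 15 as used for
#'   embryo RRBS; 10 is conventional for cell-line data).
#' @return An object of class `cohort_table` with components `sites`
#'   (data.frame chrom/pos), `per_sample_percent`, `per_sample_meth`,
#'   `per_sample_cov` (site x sample matrices), `group_percent`,
#'   `group_meth`, `group_cov` (site x group matrices), and `samples`
#'   (metadata data.frame).
#' @export
build_cohort <- function(groups, min_cov = 15) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    .stopf("build_cohort: 'groups' must be a named list")
  if (!.is_count(min_cov) || min_cov < 1) .stopf("min_cov must be >= 1")
  samples <- list(); info <- list()
  for (g in names(groups)) {
    for (p in groups[[g]]) {
      samples[[length(samples) + 1L]] <- p
      info[[length(info) + 1L]] <- data.frame(
        sample_id = p$sample_id, group = g, genotype = p$genotype,
        stage = p$stage, stringsAsFactors = FALSE)
    }
  }
  info <- do.call(rbind, info)
  if (anyDuplicated(info$sample_id))
    info$sample_id <- make.unique(info$sample_id)
  tabs <- lapply(samples, function(p) {
    dt <- as.data.table(p$sites)
    dt[, cov := meth + unmeth]
    dt[cov >= min_cov]
  })
  common <- tabs[[1L]][, c("chrom", "pos")]
  if (length(tabs) > 1L) for (i in 2L:length(tabs)) {
    common <- merge(common, tabs[[i]][, c("chrom", "pos")],
                    by = c("chrom", "pos"))
  }
  setorder(common, chrom, pos)
  n <- nrow(common)
  if (n == 0L)
    warning("build_cohort: no CpG site covered >= ", min_cov,
            "x in all samples; returning an empty cohort", call. = FALSE)
  meth <- cov <- matrix(0L, nrow = n, ncol = length(samples),
                        dimnames = list(NULL, info$sample_id))
  for (i in seq_along(tabs)) {
    m <- merge(common, tabs[[i]], by = c("chrom", "pos"), sort = TRUE)
    meth[, i] <- m$meth
    cov[, i] <- m$cov
  }
  pct <- 100 * meth / cov
  gms <- vapply(names(groups), function(g) {
    rowSums(meth[, info$group == g, drop = FALSE])
  }, numeric(n))
  gcs <- vapply(names(groups), function(g) {
    rowSums(cov[, info$group == g, drop = FALSE])
  }, numeric(n))
  if (n == 0L) {
    gms <- matrix(0, 0, length(groups), dimnames = list(NULL, names(groups)))
    gcs <- gms
  }
  structure(list(sites = as.data.frame(common),
                 per_sample_percent = pct, per_sample_meth = meth,
                 per_sample_cov = cov,
                 group_percent = 100 * gms / gcs,
                 group_meth = gms, group_cov = gcs,
                 samples = info, min_cov = min_cov,
                 groups = names(groups)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d common CpG sites (min coverage %dx) across %d samples\n",
    nrow(x$sites), as.integer(x$min_cov), nrow(x$samples)))
  for (g in x$groups)
    cat(sprintf("  group %-6s: %d replicate(s)\n", g, sum(x$samples$group == g)))
  invisible(x)
}

#' Extract per-site values of one cohort group
#'
#' Convenience accessor returning a data.frame of `chrom`, `pos`, `value`
#' (pooled group methylation percent), suitable for meta-profiles.
#' @param cohort a [build_cohort()] result.
#' @param group group label.
#' @export
site_values <- function(cohort, group) {
  if (!group %in% x_groups(cohort)) .stopf("unknown group '%s'", group)
  data.frame(chrom = cohort$sites$chrom, pos = cohort$sites$pos,
             value = cohort$group_percent[, group])
}

x_groups <- function(cohort) colnames(cohort$group_percent)

.dmr_bed_header <- c("#chrom", "start", "end", "name", "score", "strand",
                     "n_dmcs", "p_value", "direction", "label")

#' Write DMRs to a BED6+ file
#'
#' Coordinates are 0-based half-open; the BED score column is the rounded
#' absolute mean methylation change; extra columns carry the DMC count,
#' MWU p-value, direction (hyper/hypo or gain/loss) and an optional label
#' (e.g. weak/strong).
#'
#' @param dmrs a `dmr_set` data.frame (see [segment_dmrs()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(.dmr_bed_header, collapse = "\t"), con)
  if (NROW(dmrs)) {
    label <- if ("label" %in% names(dmrs)) dmrs$label else "."
    name <- if ("name" %in% names(dmrs)) dmrs$name
            else sprintf("dmr_%d", seq_len(nrow(dmrs)))
    out <- data.frame(dmrs$chrom, dmrs$start, dmrs$end, name,
                      round(abs(dmrs$mean_delta)), ".", dmrs$n_dmcs,
                      signif(dmrs$p_value, 6), dmrs$direction, label)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a DMR BED6+ file written by [write_dmr_bed()]
#'
#' @param path input path.
#' @return A `dmr_set` data.frame (without per-CpG member positions, which
#'   are not stored in BED).
#' @export
read_dmr_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      n_dmcs = integer(), mean_delta = numeric(),
                      direction = character(), p_value = numeric(),
                      label = character())
    class(out) <- c("dmr_set", "data.frame")
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  m <- matrix(unlist(parts), ncol = 10L, byrow = TRUE)
  out <- data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]),
                    end = as.integer(m[, 3L]), name = m[, 4L],
                    n_dmcs = as.integer(m[, 7L]),
                    mean_delta = as.numeric(m[, 5L]) *
                      ifelse(m[, 9L] %in% c("hypo", "loss"), -1, 1),
                    direction = m[, 9L],
                    p_value = as.numeric(m[, 8L]), label = m[, 10L])
  if (any(out$end <= out$start)) .stopf("%s: interval with end <= start", path)
  class(out) <- c("dmr_set", "data.frame")
  out
}
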