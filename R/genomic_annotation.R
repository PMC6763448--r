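# Annotation of DMRs to genomic elements under the 50%-of-DMR-length
# overlap rule, chromosome distributions, and imprinted control region
# (ICR) panel reports.

.element_kinds <- c("long_promoter", "core_promoter", "gene_body", "exon",
                    "intron", "CGI", "enhancer", "repeat")

#' Annotation parameters
#'
#' @param min_overlap_frac minimum overlap as a fraction of the DMR length
#'   for an element assignment (default 0.5, inclusive).
#' @param long_prom_up,long_prom_down long promoter window: bp upstream /
#'   downstream of the TSS (defaults 1500 / 500).
#' @param core_prom_up,core_prom_down core promoter window (defaults
#'   300 / 150).
#' @param gene_body_offset gene body starts this many bp downstream of the
#'   TSS and runs to the transcript end (default 500).
#' @export
annotation_params <- function(min_overlap_frac = 0.5, long_prom_up = 1500,
                              long_prom_down = 500, core_prom_up = 300,
                              core_prom_down = 150, gene_body_offset = 500) {
  list(min_overlap_frac = min_overlap_frac, long_prom_up = long_prom_up,
       long_prom_down = long_prom_down, core_prom_up = core_prom_up,
       core_prom_down = core_prom_down, gene_body_offset = gene_body_offset)
}

#' Derive promoter and gene-body elements from a gene table
#'
#' Long promoter: 1500 bp upstream to 500 bp downstream of the TSS; core
#' promoter: 300 bp upstream to 150 bp downstream; gene body: 500 bp
#' downstream of the TSS to the transcript end. All windows are
#' strand-aware (minus-strand genes mirror the offsets) and returned in
#' 0-based half-open coordinates.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (transcript span, 0-based half-open, `start < end` regardless
#'   of strand) and `strand` (`"+"`/`"-"`).
#' @param params an [annotation_params()] list.
#' @return data.frame element catalog with columns `chrom`, `start`,
#'   `end`, `kind`, `gene_id`. Transcripts shorter than the gene-body
#'   offset yield no gene-body row (flagged with a warning).
#' @export
derive_elements <- function(genes, params = annotation_params()) {
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end - 1L)
  win <- function(up, down) {
    s <- ifelse(plus, tss - up, tss - down + 1L)
    e <- ifelse(plus, tss + down, tss + up + 1L)
    data.frame(chrom = genes$chrom, start = as.integer(s),
               end = as.integer(e), gene_id = genes$gene_id)
  }
  lp <- win(params$long_prom_up, params$long_prom_down); lp$kind <- "long_promoter"
  cp <- win(params$core_prom_up, params$core_prom_down); cp$kind <- "core_promoter"
  gb <- data.frame(
    chrom = genes$chrom,
    start = as.integer(ifelse(plus, tss + params$gene_body_offset,
                              genes$start)),
    end = as.integer(ifelse(plus, genes$end,
                            tss - params$gene_body_offset + 1L)),
    gene_id = genes$gene_id)
  gb$kind <- "gene_body"
  short <- gb$end <= gb$start
  if (any(short))
    warning(sum(short), " transcript(s) shorter than the gene-body offset; ",
            "no gene body emitted for them", call. = FALSE)
  gb <- gb[!short, , drop = FALSE]
  out <- rbind(lp, cp, gb)[, c("chrom", "start", "end", "kind", "gene_id")]
  out <- out[.site_order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED file of genomic elements
#'
#' Plain BED (0-based half-open); column 4, when present, is taken as the
#' element/gene identifier.
#'
#' @param path BED file path.
#' @param kind element kind label to attach (one of the catalog
#'   vocabulary: long_promoter, core_promoter, gene_body, exon, intron,
#'   CGI, enhancer, repeat).
#' @return data.frame with columns `chrom`, `start`, `end`, `kind`,
#'   `gene_id`.
#' @export
read_bed_elements <- function(path, kind) {
  if (!kind %in% .element_kinds)
    .stopf("unknown element kind '%s'", kind)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), kind = character(),
                      gene_id = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             start = as.integer(vapply(parts, `[`, "", 2L)),
             end = as.integer(vapply(parts, `[`, "", 3L)),
             kind = kind,
             gene_id = vapply(parts, function(p)
               if (length(p) >= 4L) p[4L] else NA_character_, ""))
}

#' Annotate DMRs to genomic elements (50%-overlap rule)
#'
#' For each element kind independently, a DMR is assigned to that kind iff
#' some element of the kind overlaps it by at least
#' `min_overlap_frac * DMR length` bp (inclusive; 0.5 by default). Kinds
#' are non-exclusive: one DMR may be, e.g., both CGI and core promoter.
#'
#' @param dmrs a `dmr_set` (or any data.frame with `chrom`, `start`,
#'   `end`).
#' @param catalog element catalog (see [derive_elements()] /
#'   [read_bed_elements()]), rows of any mixture of kinds.
#' @param params an [annotation_params()] list.
#' @return A list: `matrix` (logical, DMR x kind), `hits` (long-form
#'   data.frame `dmr_idx`, `kind`, `gene_id`, `overlap_bp`).
#' @export
annotate_dmrs <- function(dmrs, catalog, params = annotation_params()) {
  kinds <- intersect(.element_kinds, unique(catalog$kind))
  mat <- matrix(FALSE, NROW(dmrs), length(.element_kinds),
                dimnames = list(NULL, .element_kinds))
  hits_out <- data.frame(dmr_idx = integer(), kind = character(),
                         gene_id = character(), overlap_bp = integer())
  if (!NROW(dmrs) || !NROW(catalog))
    return(list(matrix = mat, hits = hits_out))
  sl <- unique(c(as.character(dmrs$chrom), as.character(catalog$chrom)))
  gd <- .dmr_granges(dmrs, sl)
  need <- ceiling(params$min_overlap_frac * width(gd))
  acc <- list()
  for (k in kinds) {
    el <- catalog[catalog$kind == k, , drop = FALSE]
    ge <- .dmr_granges(el, sl)
    h <- findOverlaps(gd, ge)
    if (!length(h)) next
    qh <- queryHits(h); sh <- subjectHits(h)
    ow <- width(pintersect(gd[qh], ge[sh]))
    keep <- ow >= need[qh]
    if (!any(keep)) next
    mat[unique(qh[keep]), k] <- TRUE
    acc[[k]] <- data.frame(dmr_idx = qh[keep], kind = k,
                           gene_id = el$gene_id[sh[keep]],
                           overlap_bp = ow[keep])
  }
  if (length(acc)) hits_out <- do.call(rbind, c(acc, make.row.names = FALSE))
  list(matrix = mat, hits = hits_out)
}

#' Count DMRs per element kind
#'
#' Non-exclusive counts: each DMR contributes to every kind it is assigned
#' to.
#' @param annotations an [annotate_dmrs()] result.
#' @return Named integer vector over the element-kind vocabulary.
#' @export
element_distribution <- function(annotations) {
  colSums(annotations$matrix)
}

#' Count DMRs per chromosome
#'
#' @param dmrs a `dmr_set` data.frame.
#' @return Named integer vector of DMR counts by chromosome.
#' @export
chromosome_distribution <- function(dmrs) {
  if (!NROW(dmrs)) return(integer())
  tab <- table(dmrs$chrom)
  setNames(as.integer(tab), names(tab))
}

#' Imprinted control region methylation panel report
#'
#' For each ICR locus, reports the mean pooled methylation percent per
#' genotype over the commonly covered CpGs it contains, a
#' hypomethylated-in-KO call (WT - KO mean drop of at least `hypo_drop`
#' points) and a restored-in-CI call (hypomethylated and |CI - WT| within
#' `restore_window` points). Loci without covered CpGs are reported as
#' no-data. The call thresholds are declared analysis parameters, not
#' literature values.
#'
#' @param cohort a [build_cohort()] result whose groups include the three
#'   genotypes.
#' @param panel data.frame with columns `name`, `icr_class`
#'   (`"germline"`/`"somatic"`), `chrom`, `start`, `end` (0-based
#'   half-open). The study panel holds 22 germline and 9 somatic loci.
#' @param hypo_drop percent-point drop calling a locus hypomethylated
#'   (default 30).
#' @param restore_window percent-point window around WT calling a locus
#'   restored (default 10).
#' @param wt,ko,ci group labels of the three genotypes in the cohort.
#' @return data.frame (class `icr_report`) with one row per locus: per-
#'   genotype means, `n_cpgs`, `hypo_ko`, `restored_ci` (NA when no-data).
#' @export
icr_report <- function(cohort, panel, hypo_drop = 30, restore_window = 10,
                       wt = "WT", ko = "KO", ci = "CI") {
  for (g in c(wt, ko, ci))
    if (!g %in% colnames(cohort$group_percent))
      .stopf("icr_report: unknown group '%s'", g)
  sites <- cohort$sites
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    inlocus <- sites$chrom == panel$chrom[i] &
      sites$pos >= panel$start[i] & sites$pos < panel$end[i]
    n <- sum(inlocus)
    if (n == 0L)
      return(data.frame(name = panel$name[i],
                        icr_class = panel$icr_class[i], n_cpgs = 0L,
                        wt_pct = NA_real_, ko_pct = NA_real_,
                        ci_pct = NA_real_, hypo_ko = NA,
                        restored_ci = NA))
    mw <- mean(cohort$group_percent[inlocus, wt])
    mk <- mean(cohort$group_percent[inlocus, ko])
    mc <- mean(cohort$group_percent[inlocus, ci])
    hypo <- (mw - mk) >= hypo_drop
    data.frame(name = panel$name[i], icr_class = panel$icr_class[i],
               n_cpgs = n, wt_pct = mw, ko_pct = mk, ci_pct = mc,
               hypo_ko = hypo,
               restored_ci = hypo & abs(mc - mw) <= restore_window)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("icr_report", "data.frame")
  out
}
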