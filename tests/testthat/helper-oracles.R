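# Independent brute-force oracles shared across test files.

# enumeration oracle: exact two-sided MWU p by listing all rank subsets
enum_mwu_p <- function(xs, ys) {
  n1 <- length(xs); n <- n1 + length(ys)
  r <- rank(c(xs, ys))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n, n1)
  us <- apply(subsets, 2, function(ix) sum(seq_len(n)[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# independent quadratic oracle: enumerate all maximal qualifying windows
bf_segment <- function(cohort, reference, test, th) {
  delta <- cohort$group_percent[, test] - cohort$group_percent[, reference]
  dmc <- abs(delta) >= th$min_diff
  dirn <- ifelse(delta > 0, "hyper", "hypo")
  chrom <- cohort$sites$chrom; pos <- cohort$sites$pos
  n <- length(delta)
  valid <- function(i, j) {
    if (i < 1 || j > n) return(FALSE)
    ix <- i:j
    if (!all(dmc[ix])) return(FALSE)
    if (length(unique(chrom[ix])) > 1) return(FALSE)
    if (length(unique(dirn[ix])) > 1) return(FALSE)
    if (j > i && any(diff(pos[ix]) > th$max_gap)) return(FALSE)
    TRUE
  }
  out <- NULL
  ref_s <- cohort$samples$group == reference
  test_s <- cohort$samples$group == test
  for (i in seq_len(n)) for (j in i:n) {
    if (!valid(i, j)) next
    if (valid(i - 1, j) || valid(i, j + 1)) next  # not maximal
    if (j - i + 1 < th$min_dmcs) next
    if (abs(mean(delta[i:j])) < th$min_diff) next
    xs <- as.vector(cohort$per_sample_percent[i:j, test_s])
    ys <- as.vector(cohort$per_sample_percent[i:j, ref_s])
    if (mann_whitney_u(xs, ys)$p.value >= th$alpha) next
    out <- rbind(out, data.frame(chrom = chrom[i], start = pos[i],
                                 end = pos[j] + 1L, n_dmcs = j - i + 1L))
  }
  out
}

random_instance <- function(seed, n = 200) {
  set.seed(seed)
  chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
  pos <- integer(n)
  for (ch in unique(chrom))
    pos[chrom == ch] <- cumsum(sample(10:120, sum(chrom == ch),
                                      replace = TRUE))
  base <- runif(n, 20, 90)
  offset <- numeric(n)
  k <- 0
  while (k < n) {             # random blocks of planted offsets
    len <- sample(1:6, 1)
    offset[(k + 1):min(n, k + len)] <- sample(c(-60, -40, -31, -15, 0, 31, 45), 1)
    k <- k + len
  }
  pcts <- sapply(1:4, function(j) {
    v <- base + ifelse(j >= 3, offset, 0) + rnorm(n, 0, 4)
    pmin(pmax(v, 0), 100)
  })
  make_cohort_from_percents(pos, pcts, c("WT", "WT", "KO", "KO"),
                            chrom = chrom)
}
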