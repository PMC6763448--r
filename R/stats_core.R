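# Statistical primitives used by the calling and comparison stages.
# The Mann-Whitney U test (with an exact small-sample branch), Welch's t
# and the chi-squared goodness-of-fit statistic are implemented here;
# results are returned as standard "htest" objects.

.htest <- function(statistic, p.value, method, n1, n2,
                   alternative = "two.sided", degenerate = FALSE) {
  structure(list(statistic = statistic, p.value = p.value,
                 parameter = c(n1 = n1, n2 = n2), method = method,
                 alternative = alternative, degenerate = degenerate,
                 data.name = "xs and ys"),
            class = "htest")
}

# number of ways to choose n1 ranks out of 1..n with rank-sum s, for all s
# (classic Mann-Whitney counting recursion).
.mwu_exact_dist <- function(n1, n2) {
  n <- n1 + n2
  maxu <- n1 * n2
  # f[u + 1] = number of subsets of size n1 with U statistic u
  f <- c(1, numeric(maxu))
  # DP over items 1..n, bounded subset-sum count of "greater" pairs
  # g[k, u]: ways to pick k of first i ranks with U = u
  g <- matrix(0, nrow = n1 + 1L, ncol = maxu + 1L)
  g[1L, 1L] <- 1
  for (i in seq_len(n)) {
    kmax <- min(i, n1)
    for (k in rev(seq_len(kmax))) {
      # choosing rank i as the k-th member contributes (i - k) to U
      add <- i - k
      if (add <= maxu)
        g[k + 1L, (add + 1L):(maxu + 1L)] <-
          g[k + 1L, (add + 1L):(maxu + 1L)] +
          g[k, 1L:(maxu + 1L - add)]
    }
  }
  g[n1 + 1L, ] / choose(n, n1)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test comparing two samples. For small samples
#' (`n1 + n2 <= exact_limit`, default 16, and no ties) the exact null
#' distribution of U is computed by counting rank assignments; otherwise a
#' normal approximation with tie and continuity corrections is used.
#' Regions in this pipeline typically contribute 3-10 CpGs x 2 replicates
#' per group, where the exact branch matters.
#'
#' @param xs,ys numeric vectors (non-empty).
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   branch.
#' @param exact_limit maximum `n1 + n2` for the exact branch.
#' @return An object of class `htest` with the U statistic (for `xs`) and
#'   two-sided p-value; `$degenerate` flags an all-identical input.
#' @export
mann_whitney_u <- function(xs, ys, exact = NULL, exact_limit = 16L) {
  if (!length(xs) || !length(ys)) .stopf("mann_whitney_u: empty sample")
  n1 <- length(xs); n2 <- length(ys)
  pooled <- c(xs, ys)
  if (length(unique(pooled)) == 1L)
    return(.htest(c(U = n1 * n2 / 2), 1,
                  "Mann-Whitney U test (degenerate: identical values)",
                  n1, n2, degenerate = TRUE))
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  use_exact <- if (is.null(exact)) (n1 + n2 <= exact_limit) && !ties
               else isTRUE(exact) && !ties
  if (use_exact) {
    dist <- .mwu_exact_dist(n1, n2)
    pu <- sum(dist[seq_len(u + 1L)])          # P(U <= u)
    po <- sum(dist[(u + 1L):length(dist)])    # P(U >= u)
    p <- min(1, 2 * min(pu, po))
    method <- "Mann-Whitney U test (exact)"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- (u - mu - sign(u - mu) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Mann-Whitney U test (normal approximation)"
  }
  .htest(c(U = u), p, method, n1, n2)
}

#' Welch's two-sample t-test (two-tailed)
#'
#' Unequal-variances t-test with Welch-Satterthwaite degrees of freedom,
#' the default test for mean comparisons throughout the pipeline.
#'
#' @param xs,ys numeric vectors of length >= 2.
#' @return An `htest`; `$degenerate` flags zero variance in both samples.
#' @export
welch_t <- function(xs, ys) {
  n1 <- length(xs); n2 <- length(ys)
  if (n1 < 2L || n2 < 2L) .stopf("welch_t: need n >= 2 per sample")
  v1 <- stats::var(xs); v2 <- stats::var(ys)
  if (v1 == 0 && v2 == 0) {
    t <- if (mean(xs) == mean(ys)) 0 else Inf * sign(mean(xs) - mean(ys))
    return(.htest(c(t = t), as.numeric(mean(xs) == mean(ys)),
                  "Welch two-sample t-test (degenerate: zero variance)",
                  n1, n2, degenerate = TRUE))
  }
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(xs) - mean(ys)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  out <- .htest(c(t = t), p, "Welch two-sample t-test", n1, n2)
  out$parameter <- c(out$parameter, df = df)
  out
}

#' Chi-squared goodness-of-fit test against expected proportions
#'
#' Used for observed vs expected genotype representation of embryos.
#'
#' @param observed non-negative counts.
#' @param expected_ratios expected proportions summing to 1 (default:
#'   uniform).
#' @return An `htest` with the chi-squared statistic on `k - 1` degrees of
#'   freedom.
#' @export
chi_square_gof <- function(observed,
                           expected_ratios = rep(1 / length(observed),
                                                 length(observed))) {
  if (length(observed) != length(expected_ratios))
    .stopf("chi_square_gof: length mismatch")
  if (abs(sum(expected_ratios) - 1) > 1e-8)
    .stopf("chi_square_gof: expected ratios must sum to 1")
  e <- sum(observed) * expected_ratios
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  out <- .htest(c("X-squared" = stat), pchisq(stat, df, lower.tail = FALSE),
                "Chi-squared goodness-of-fit test", length(observed), NA)
  out$parameter <- c(df = df)
  out
}

#' One-sided hypergeometric over-representation test
#'
#' Probability of observing an overlap of at least `k` between a set of
#' size `n_a` and a set of size `n_b` drawn from a universe of size `n`
#' (the test used for gene-set overlaps).
#'
#' @param k observed overlap.
#' @param n_a,n_b set sizes.
#' @param n universe size.
#' @return An `htest` with `p = P(X >= k)`.
#' @export
hypergeom_overlap <- function(k, n_a, n_b, n) {
  if (k > min(n_a, n_b) || max(n_a, n_b) > n || k < 0)
    .stopf("hypergeom_overlap: need 0 <= k <= min(n_a, n_b) <= n")
  p <- phyper(k - 1, n_a, n - n_a, n_b, lower.tail = FALSE)
  .htest(c(overlap = k), p,
         "Hypergeometric over-representation test (one-sided)", n_a, n_b,
         alternative = "greater")
}

#' Pearson correlation coefficient
#'
#' @param xs,ys numeric vectors of equal length.
#' @return The correlation coefficient (a single number).
#' @export
pearson_r <- function(xs, ys) {
  ok <- stats::complete.cases(xs, ys)
  cor(xs[ok], ys[ok], method = "pearson")
}

#' Uncentered-correlation distance matrix
#'
#' Distance `d(x, y) = 1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2))` between
#' the rows of a matrix; rows with zero norm are at distance 1 to
#' everything (flagged with a warning).
#'
#' @param m numeric matrix (items x features).
#' @return A `dist` object.
#' @export
uncentered_distance <- function(m) {
  m <- as.matrix(m)
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0))
    warning("uncentered_distance: zero-norm row(s); distance set to 1",
            call. = FALSE)
  cp <- tcrossprod(m)
  denom <- outer(norms, norms)
  sim <- ifelse(denom > 0, cp / denom, 0)
  sim <- pmin(pmax(sim, -1), 1)
  as.dist(1 - sim)
}

#' Average-linkage hierarchical clustering with uncentered correlation
#'
#' Agglomerative average-linkage clustering of the rows of `m` under the
#' uncentered correlation distance, the scheme used to cluster DMR CpG
#' methylation across genotypes.
#'
#' @param m numeric matrix (items x features), >= 2 rows.
#' @return An `hclust` object (leaf order in `$order`).
#' @export
uncentered_avg_linkage <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) .stopf("uncentered_avg_linkage: need >= 2 items")
  hclust(uncentered_distance(m), method = "average")
}

#' Export a cluster tree in Newick text form
#'
#' @param hc an `hclust` object.
#' @param labels leaf labels (default: `hc$labels` or item indices).
#' @return A single Newick string.
#' @export
cluster_newick <- function(hc, labels = NULL) {
  if (is.null(labels)) labels <- hc$labels
  if (is.null(labels)) labels <- as.character(seq_len(nrow(hc$merge) + 1L))
  rec <- function(i) {
    if (i < 0) return(labels[-i])
    h <- hc$height[i]
    kids <- hc$merge[i, ]
    sprintf("(%s:%g,%s:%g)", rec(kids[1]), h / 2, rec(kids[2]), h / 2)
  }
  paste0(rec(nrow(hc$merge)), ";")
}
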