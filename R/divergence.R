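# Cross-species divergence statistics: per-metagene Welch t tests with
# Benjamini-Hochberg FDR flags, median-rank top-fraction sets and their
# overlaps, the arcsine-transformed one-sample test for overlap
# differences, the rank-concordance ("rankmap") curve with exact
# binomial confidence bands, and the binomial proportions test.

row_var <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

#' Per-metagene Welch t tests between two species
#'
#' Computes, for every shared row, the two-sample unequal-variance
#' (Welch) t statistic and two-sided p-value between the replicate
#' arrays of species A and species B, applies Benjamini-Hochberg FDR
#' control at level `q`, and attaches each species' median expression
#' rank (1 = highest). Rows with zero variance in both groups and equal
#' means get t = 0, p = 1.
#'
#' @param expr_A,expr_B Normalized log expression matrices sharing the
#'   same row (metagene) ids; each must have >= 2 columns.
#' @param q FDR level for the divergence flag (default 0.001, i.e. the
#'   0.1% level).
#' @return data.frame (`divergence table`) with columns `metagene_id`,
#'   `mean_A`, `mean_B`, `t_stat`, `df`, `p_value`, `p_adjusted`,
#'   `q_flag`, `median_rank_A`, `median_rank_B`.
#' @export
welch_ttest_table <- function(expr_A, expr_B, q = 0.001) {
  if (ncol(expr_A) < 2L || ncol(expr_B) < 2L)
    stop("each species needs >= 2 replicate arrays")
  if (!setequal(rownames(expr_A), rownames(expr_B)))
    stop("expression matrices must share the same metagene rows")
  expr_B <- expr_B[rownames(expr_A), , drop = FALSE]
  nA <- ncol(expr_A); nB <- ncol(expr_B)
  mA <- rowMeans(expr_A); mB <- rowMeans(expr_B)
  vA <- row_var(expr_A); vB <- row_var(expr_B)
  se2 <- vA / nA + vB / nB
  t_stat <- ifelse(se2 > 0, (mA - mB) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L)),
               nA + nB - 2L)
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- se2 == 0
  p[degenerate & abs(mA - mB) < .Machine$double.eps^0.5] <- 1
  p[degenerate & abs(mA - mB) >= .Machine$double.eps^0.5] <- 0
  t_stat[degenerate & abs(mA - mB) >= .Machine$double.eps^0.5] <-
    sign((mA - mB)[degenerate & abs(mA - mB) >= .Machine$double.eps^0.5]) * Inf
  fdr <- bh_fdr(p, q)
  data.frame(metagene_id = rownames(expr_A),
             mean_A = mA, mean_B = mB, t_stat = t_stat, df = df,
             p_value = p, p_adjusted = fdr$p_adjusted,
             q_flag = fdr$flag,
             median_rank_A = median_expression_rank(expr_A),
             median_rank_B = median_expression_rank(expr_B),
             row.names = NULL)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q Target FDR level in (0, 1).
#' @return List with `flag` (logical rejections) and `p_adjusted`
#'   (BH-adjusted p-values); a test is flagged iff its adjusted p-value
#'   is at most `q`, which equals the classical step-up rejection set.
#' @export
bh_fdr <- function(p_values, q = 0.001) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(q > 0, q < 1)
  adj <- stats::p.adjust(p_values, method = "BH")
  list(flag = adj <= q, p_adjusted = adj)
}

#' Median expression rank across replicates
#'
#' Ranks every row within each replicate column (rank 1 = highest
#' expression, average ranks on ties) and returns the per-row median
#' rank across replicates.
#'
#' @param expr Expression matrix.
#' @return Named numeric vector of median ranks.
#' @export
median_expression_rank <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 1L)
  ranks <- apply(expr, 2L, function(col) rank(-col, ties.method = "average"))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, ncol = ncol(expr))
  stats::setNames(apply(ranks, 1L, stats::median), rownames(expr))
}

#' Top-fraction highly expressed set by median rank
#'
#' Returns the ids of the `floor(fraction * N)` rows with the smallest
#' median expression rank, expanded to include every row tied at the
#' boundary rank (the set is deterministic and independent of column
#' or row order).
#'
#' @param expr Expression matrix (>= 1 replicate column).
#' @param fraction Fraction of rows to keep (default 0.05).
#' @return Character vector of row ids.
#' @export
median_rank_top_set <- function(expr, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1)
  if (nrow(expr) == 0L) stop("empty expression matrix")
  m <- floor(fraction * nrow(expr))
  if (m < 1L) stop("fraction * N < 1: no rows selected")
  med <- median_expression_rank(expr)
  cutoff <- sort(med)[m]
  sort(names(med)[med <= cutoff])
}

#' Overlap fraction of two top sets
#'
#' @param set_A,set_B Character vectors of gene/metagene ids.
#' @param denominator Which set's size divides the intersection
#'   (default `"A"`); the study reports per-species percentages using
#'   each species' own top set as denominator.
#' @return Fraction in \[0, 1\].
#' @export
overlap_fraction <- function(set_A, set_B, denominator = c("A", "B")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "A") unique(set_A) else unique(set_B)
  if (length(den) == 0L) stop("empty denominator set")
  length(intersect(set_A, set_B)) / length(den)
}

#' Pairwise top-fraction overlap matrix across samples
#'
#' For a named collection of expression matrices over the same ortholog
#' universe, computes every pairwise overlap of top-`fraction` sets.
#' Entry (i, j) is |top_i n top_j| / |top_i| (the row sample's own top
#' set as denominator), so the diagonal is 1 and blocks of samples with
#' identical top-set sizes are symmetric.
#'
#' @param expr_list Named list of expression matrices with identical
#'   row-id universes.
#' @param fraction Top fraction (default 0.05).
#' @return Square numeric matrix of overlap fractions.
#' @export
overlap_matrix <- function(expr_list, fraction = 0.05) {
  stopifnot(is.list(expr_list), length(expr_list) >= 2L,
            !is.null(names(expr_list)))
  universe <- rownames(expr_list[[1L]])
  for (nm in names(expr_list))
    if (!setequal(rownames(expr_list[[nm]]), universe))
      stop("sample '", nm, "' is not on the shared ortholog universe")
  tops <- lapply(expr_list, median_rank_top_set, fraction = fraction)
  n <- length(tops)
  out <- matrix(NA_real_, n, n, dimnames = list(names(tops), names(tops)))
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- overlap_fraction(tops[[i]], tops[[j]], "A")
  out
}

#' Arcsine-transformed one-sample t test on overlap fractions
#'
#' Transforms all fractions by `asin(sqrt(p))` (the variance-stabilizing
#' transform for proportions) and performs a two-sided one-sample t test
#' of the transformed tissue overlaps against the transformed reference
#' overlap.
#'
#' @param reference_overlap Single reference fraction in \[0, 1\].
#' @param tissue_overlaps Numeric vector (length >= 2) of fractions.
#' @return List with `t_stat`, `df`, `p_value`.
#' @export
arcsine_one_sample_test <- function(reference_overlap, tissue_overlaps) {
  vals <- c(reference_overlap, tissue_overlaps)
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1))
    stop("overlap fractions must lie in [0, 1]")
  if (length(tissue_overlaps) < 2L) stop("need >= 2 tissue overlaps")
  y <- asin(sqrt(tissue_overlaps))
  mu <- asin(sqrt(reference_overlap))
  if (stats::sd(y) == 0) {
    eq <- abs(mean(y) - mu) < .Machine$double.eps^0.5
    return(list(t_stat = if (eq) 0 else sign(mean(y) - mu) * Inf,
                df = length(y) - 1L, p_value = if (eq) 1 else 0))
  }
  tt <- stats::t.test(y, mu = mu)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Rank-concordance (rankmap) curve between two species
#'
#' Ranks each species' genes by expression (rank 1 = highest, average
#' ranks on ties; matrices are first summarized by per-row median over
#' replicates). For each rank k in `[k_min, k_max]` the concordance is,
#' among species-A genes of rank <= k, the fraction whose species-B
#' ortholog also has rank <= k. Confidence bands are exact
#' Clopper-Pearson intervals at level
#' `1 - (1 - conf_level) / bonferroni_factor`.
#'
#' @param expr_A,expr_B Expression matrices (or named numeric vectors)
#'   over the same ortholog universe; names pair the orthologs.
#' @param k_min,k_max Rank range (defaults 31 and 500).
#' @param conf_level Unadjusted confidence level (default 0.95).
#' @param bonferroni_factor Bonferroni factor for the bands
#'   (default 500, the number of ranks compared).
#' @return data.frame with columns `k`, `n_top_A`, `n_concordant`,
#'   `concordance`, `ci_low`, `ci_high`.
#' @export
rank_concordance_curve <- function(expr_A, expr_B, k_min = 31L,
                                   k_max = 500L, conf_level = 0.95,
                                   bonferroni_factor = 500L) {
  as_summary <- function(x) {
    if (is.matrix(x)) apply(x, 1L, stats::median) else x
  }
  sA <- as_summary(expr_A); sB <- as_summary(expr_B)
  if (!setequal(names(sA), names(sB)))
    stop("species share no common ortholog universe")
  sB <- sB[names(sA)]
  N <- length(sA)
  if (k_max >= N) stop("k_max (", k_max, ") must be < universe size (", N, ")")
  rA <- rank(-sA, ties.method = "average")
  rB <- rank(-sB, ties.method = "average")
  ks <- seq.int(k_min, k_max)
  n_top <- n_conc <- integer(length(ks))
  ord <- order(rA)
  rA_s <- rA[ord]; rB_s <- rB[ord]
  for (i in seq_along(ks)) {
    k <- ks[i]
    idx <- rA_s <= k
    n_top[i] <- sum(idx)
    n_conc[i] <- sum(rB_s[idx] <= k)
  }
  conc <- ifelse(n_top > 0L, n_conc / n_top, NA_real_)
  ci <- t(mapply(binomial_ci_bonferroni, n_conc, pmax(n_top, 1L),
                 MoreArgs = list(level = conf_level,
                                 factor = bonferroni_factor)))
  data.frame(k = ks, n_top_A = n_top, n_concordant = n_conc,
             concordance = conc,
             ci_low = ifelse(n_top > 0L, ci[, 1L], NA_real_),
             ci_high = ifelse(n_top > 0L, ci[, 2L], NA_real_))
}

#' Bonferroni-adjusted exact binomial confidence interval
#'
#' Clopper-Pearson exact interval at the adjusted level
#' `1 - (1 - level) / factor`. The exact interval is used because the
#' rankmap's smallest rank (31) gives denominators where the normal
#' approximation is poor.
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n >= 1`.
#' @param level Unadjusted confidence level (default 0.95).
#' @param factor Bonferroni factor (default 500).
#' @return Numeric vector `c(low, high)`.
#' @export
binomial_ci_bonferroni <- function(successes, n, level = 0.95,
                                   factor = 500L) {
  stopifnot(factor >= 1, level > 0, level < 1)
  if (n < 1L) stop("n must be >= 1")
  if (successes < 0L || successes > n)
    stop("successes must lie in [0, n]")
  alpha <- (1 - level) / factor
  low <- if (successes == 0L) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1L)
  high <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1L, n - successes)
  c(low = low, high = high)
}

#' Two-sample binomial proportions test
#'
#' Two-sided test of equal proportions between x1/n1 and x2/n2. The
#' default is the pooled z test without continuity correction (p = 1
#' when the sample proportions are equal); `"chisq"` gives the
#' continuity-corrected chi-square test and `"exact"` Fisher's exact
#' test.
#'
#' @param x1,n1,x2,n2 Success counts and totals.
#' @param variant `"z"` (default), `"chisq"` or `"exact"`.
#' @return List with `p_value`, `estimate` (the two proportions) and
#'   `statistic` (z or chi-square statistic; NA for the exact test).
#' @export
two_proportion_test <- function(x1, n1, x2, n2,
                                variant = c("z", "chisq", "exact")) {
  variant <- match.arg(variant)
  if (n1 < 1L || n2 < 1L) stop("group sizes must be >= 1")
  if (x1 < 0L || x1 > n1 || x2 < 0L || x2 > n2)
    stop("counts must lie in [0, n]")
  p1 <- x1 / n1; p2 <- x2 / n2
  if (variant == "z") {
    pool <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p1 - p2) / se
    return(list(p_value = 2 * stats::pnorm(-abs(z)),
                estimate = c(p1, p2), statistic = z))
  }
  if (variant == "chisq") {
    ht <- stats::prop.test(c(x1, x2), c(n1, n2))
    return(list(p_value = ht$p.value, estimate = c(p1, p2),
                statistic = unname(ht$statistic)))
  }
  ht <- stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2L))
  list(p_value = ht$p.value, estimate = c(p1, p2), statistic = NA_real_)
}
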