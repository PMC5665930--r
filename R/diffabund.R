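#' Convert counts to relative abundances
#'
#' Within each feature category, every sample column is scaled to sum to 1.
#' Idempotent on already-normalized tables; a sample with zero total within
#' a category is an error.
#'
#' @param table Non-negative features x samples matrix.
#' @param category Optional per-feature category vector (single category if
#'   NULL); normalization is done within category.
#' @return Matrix of the same shape on proportion scale.
#' @export
to_relative <- function(table, category = NULL) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative abundances are not allowed")
  category <- category %||% rep("all", nrow(table))
  stopifnot(length(category) == nrow(table))
  out <- table
  for (cat in unique(category)) {
    rows <- category == cat
    tot <- colSums(table[rows, , drop = FALSE])
    if (any(tot == 0))
      stop("zero-total sample(s) in category '", cat, "': ",
           paste(colnames(table)[tot == 0], collapse = ", "))
    out[rows, ] <- sweep(table[rows, , drop = FALSE], 2, tot, "/")
  }
  out
}

#' Welch's unequal-variance t-test
#'
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with
#' Welch--Satterthwaite degrees of freedom and a two-sided p-value. Chosen
#' over Student's t because the metabotype groups are unequal in size.
#' Degenerate zero-variance groups: equal means give t = 0, p = 1; unequal
#' means give p = 0 with a `degenerate` flag.
#'
#' @param a,b Numeric vectors, each of length >= 2, finite.
#' @return List with `t`, `df`, `p` and `degenerate`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  num <- mean(a) - mean(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (num == 0) return(list(t = 0, df = na + nb - 2, p = 1, degenerate = FALSE))
    return(list(t = sign(num) * Inf, df = na + nb - 2, p = 0, degenerate = TRUE))
  }
  t_stat <- num / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df), degenerate = FALSE)
}

#' Storey q-values with a single-lambda pi0 estimate
#'
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) m))`, floored at `1/m` when
#' the raw estimate is zero. Q-values follow the step-wise minimum: with p
#' sorted ascending at ranks i, `q(i) = min over j >= i of pi0 m p(j) / j`,
#' capped at 1. Equivalently q = pi0 times the Benjamini-Hochberg adjusted p.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @param lambda Tuning value in \[0, 1) for the pi0 estimate (default 0.5).
#' @return List with `pi0`, `lambda` and `q_values` (original order).
#' @export
storey_qvalues <- function(pvalues, lambda = 0.5) {
  m <- length(pvalues)
  stopifnot(m >= 1, lambda >= 0, lambda < 1)
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  pi0 <- min(1, sum(pvalues > lambda) / ((1 - lambda) * m))
  if (pi0 <= 0) pi0 <- 1 / m
  o <- order(pvalues)
  q_sorted <- pi0 * m * pvalues[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(pi0 = pi0, lambda = lambda, q_values = q)
}

#' Ratio-of-proportions effect size
#'
#' Symmetric ratio `max(m_high, m_low) / min(m_high, m_low)`. A zero mean is
#' replaced by a pseudo-proportion (by default half the smallest nonzero
#' value among the supplied means) before forming the ratio; two zero means
#' give a ratio of 1 (no effect). Direction is not part of the ratio.
#'
#' @param mean_low,mean_high Non-negative group mean proportions
#'   (vectorized).
#' @param pseudo Pseudo-proportion substituted for zeros; default half the
#'   smallest nonzero value among the inputs.
#' @return Numeric vector of effect ratios >= 1.
#' @export
effect_ratio <- function(mean_low, mean_high, pseudo = NULL) {
  stopifnot(length(mean_low) == length(mean_high),
            all(mean_low >= 0), all(mean_high >= 0))
  vals <- c(mean_low, mean_high)
  pseudo <- pseudo %||% (if (any(vals > 0)) min(vals[vals > 0]) / 2 else 1)
  both_zero <- mean_low == 0 & mean_high == 0
  lo <- pmax(mean_low, pseudo * (mean_low == 0))
  hi <- pmax(mean_high, pseudo * (mean_high == 0))
  r <- pmax(hi, lo) / pmin(hi, lo)
  r[both_zero] <- 1
  r
}

#' Differential feature abundance between metabotypes
#'
#' For each feature: relative abundance within its category, Welch's
#' two-sided t-test of high vs low samples, Storey q-values computed across
#' the features of the same category, then the ratio-of-proportions filter.
#' A feature is significant iff `q < q_threshold` and
#' `effect_ratio >= effect_threshold`.
#'
#' @param table Non-negative features x samples matrix (counts or
#'   proportions).
#' @param labels Per-sample metabotype labels ("low"/"high"); if named, the
#'   names must match the table's sample columns.
#' @param q_threshold,effect_threshold Significance thresholds (defaults
#'   0.05 and 2).
#' @param lambda Storey pi0 tuning value.
#' @param category Optional per-feature category (taxon/BG/transporter/KO);
#'   q-values and normalization are per category.
#' @return data.frame, one row per feature: group means (proportion units),
#'   t, df, p, q, effect ratio, direction and significance.
#' @export
differential_features <- function(table, labels, q_threshold = 0.05,
                                  effect_threshold = 2.0, lambda = 0.5,
                                  category = NULL) {
  table <- as.matrix(table)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), colnames(table)))
      stop("label names do not match the table's samples")
    labels <- labels[colnames(table)]
  }
  stopifnot(length(labels) == ncol(table),
            all(labels %in% c("low", "high")))
  if (sum(labels == "low") < 2 || sum(labels == "high") < 2)
    stop("each metabotype group needs >= 2 samples")
  category <- category %||% rep("all", nrow(table))
  rel <- to_relative(table, category)
  lo <- labels == "low"; hi <- labels == "high"
  mean_low <- rowMeans(rel[, lo, drop = FALSE])
  mean_high <- rowMeans(rel[, hi, drop = FALSE])
  tests <- apply(rel, 1, function(v) welch_t(v[hi], v[lo]))
  res <- data.frame(
    feature_id = rownames(rel) %||% sprintf("F%04d", seq_len(nrow(rel))),
    category = category,
    mean_low = mean_low, mean_high = mean_high,
    t_statistic = vapply(tests, `[[`, 0, "t"),
    welch_df = vapply(tests, `[[`, 0, "df"),
    p_two_sided = vapply(tests, `[[`, 0, "p"),
    stringsAsFactors = FALSE)
  res$q_value <- NA_real_
  res$effect_ratio <- NA_real_
  for (cat in unique(category)) {
    rows <- category == cat
    res$q_value[rows] <- storey_qvalues(res$p_two_sided[rows], lambda)$q_values
    res$effect_ratio[rows] <- effect_ratio(res$mean_low[rows],
                                           res$mean_high[rows])
  }
  res$direction <- ifelse(res$mean_high > res$mean_low, "high",
                          ifelse(res$mean_high < res$mean_low, "low", "none"))
  res$significant <- res$q_value < q_threshold &
    res$effect_ratio >= effect_threshold
  rownames(res) <- NULL
  res
}

#' Shapiro-Wilk normality check
#'
#' QC gate for the approximate-normality assumption behind the Welch test;
#' intended to warn, not block.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(values) == 0) stop("degenerate input: zero variance")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}
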