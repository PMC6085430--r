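#' Tukey boxplot statistics for a set of lag ratios
#'
#' Quartiles by linear interpolation of order statistics (quantile type 7);
#' outliers are points beyond 1.5 * IQR fences; whiskers reach the most
#' extreme non-outlier values. The published plots pair whiskers with
#' singly plotted outlier points, which is the Tukey convention.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param group Optional group label recorded in the summary.
#' @return An object of class `group_summary` with `group`, `n`, `q1`,
#'   `median`, `q3`, `whisker_low`, `whisker_high` and `outliers`.
#' @export
#' @examples
#' boxplot_stats(c(1, 2, 3, 4, 5, 100))
boxplot_stats <- function(values, group = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  is_out <- values < lo_fence | values > hi_fence
  inliers <- values[!is_out]
  structure(
    list(group = group, n = length(values), q1 = q[1], median = q[2],
         q3 = q[3], whisker_low = min(inliers), whisker_high = max(inliers),
         outliers = sort(values[is_out])),
    class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s  n=%d  q1=%.3g  median=%.3g  q3=%.3g  whiskers [%.3g, %.3g]  %d outlier(s)\n",
              x$group, x$n, x$q1, x$median, x$q3, x$whisker_low,
              x$whisker_high, length(x$outliers)))
  invisible(x)
}

#' @export
as.data.frame.group_summary <- function(x, ...) {
  data.frame(group = x$group, n = x$n, q1 = x$q1, median = x$median,
             q3 = x$q3, whisker_low = x$whisker_low,
             whisker_high = x$whisker_high, n_outliers = length(x$outliers))
}

.star_tier <- function(p) {
  if (p < 0.001) "**" else if (p < 0.05) "*" else "ns"
}

# two-sided permutation p for the difference in means; exact enumeration of
# all group assignments when total n <= max_exact, else seeded Monte-Carlo
.perm_test <- function(a, b, max_exact = 12, n_mc = 10000, seed = 1) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  obs <- abs(mean(a) - mean(b))
  tol <- 1e-12 * max(1, abs(obs))
  if (n <= max_exact) {
    idx <- utils::combn(n, na)
    stats_all <- apply(idx, 2, function(ix) {
      abs(mean(pooled[ix]) - mean(pooled[-ix]))
    })
    p <- mean(stats_all >= obs - tol)
    list(p = p, exact = TRUE)
  } else {
    draws <- with_seed(seed, replicate(n_mc, {
      ix <- sample.int(n, na)
      abs(mean(pooled[ix]) - mean(pooled[-ix]))
    }))
    # observed assignment counts as one draw (never report p = 0)
    p <- (sum(draws >= obs - tol) + 1) / (n_mc + 1)
    list(p = p, exact = FALSE)
  }
}

#' Compare two groups of lag ratios
#'
#' Two-sided test with star tiers `**` (p < 0.001), `*` (p < 0.05), `ns`
#' otherwise. `welch_t` (the default, robust to unequal variance at small
#' n), `mann_whitney` (rank-based), or `permutation` (difference in means;
#' exact enumeration of all assignments when the pooled n is at most 12,
#' seeded Monte-Carlo otherwise). Zero-variance identical groups break the
#' t statistic; that case falls back to the permutation test with a
#' warning.
#'
#' @param a,b Numeric vectors, each `n >= 3`.
#' @param method `"welch_t"`, `"mann_whitney"` or `"permutation"`.
#' @param n_mc Monte-Carlo draws for large permutation tests.
#' @param seed Seed for Monte-Carlo permutation.
#' @return List with `p_value`, `tier`, `method` (the method actually used)
#'   and `exact` (permutation only).
#' @export
#' @examples
#' compare_groups(c(1, 1, 1), c(2, 2, 2), method = "permutation")
compare_groups <- function(a, b,
                           method = c("welch_t", "mann_whitney",
                                      "permutation"),
                           n_mc = 10000, seed = 1) {
  method <- match.arg(method)
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 values", call. = FALSE)
  }
  if (method == "welch_t" &&
      stats::sd(a) == 0 && stats::sd(b) == 0) {
    warning("zero-variance groups: falling back to permutation test")
    method <- "permutation"
  }
  res <- switch(method,
    welch_t = {
      ht <- stats::t.test(a, b, var.equal = FALSE)
      list(p = ht$p.value, exact = NA)
    },
    mann_whitney = {
      ht <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
      list(p = ht$p.value, exact = NA)
    },
    permutation = .perm_test(a, b, n_mc = n_mc, seed = seed))
  list(p_value = res$p, tier = .star_tier(res$p), method = method,
       exact = res$exact)
}

#' Order groups by median lag ratio and test all pairs
#'
#' Reports the strain hierarchy: groups sorted by median normalized lag
#' ratio, every pairwise comparison with its star tier (plus a
#' Holm-adjusted column for transparency; the stars themselves are
#' per-pair, unadjusted), and, when an expected order is supplied, a
#' concordance flag that is true only if the observed order matches and
#' every adjacent pair is significant at the `*` tier.
#'
#' @param groups Named list mapping group label to a numeric vector of
#'   ratios.
#' @param expected_order Optional character vector of labels in expected
#'   ascending order of median ratio.
#' @param method Test passed to [compare_groups()].
#' @param ... Further arguments for [compare_groups()].
#' @return List with `ordering` (labels, ascending median), `medians`,
#'   `pairwise` (data.frame: group_a, group_b, p_value, p_holm, tier) and
#'   `concordant` (`NA` when `expected_order` is missing).
#' @export
hierarchy_report <- function(groups, expected_order = NULL,
                             method = "welch_t", ...) {
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be named", call. = FALSE)
  }
  medians <- vapply(groups, stats::median, numeric(1))
  ordering <- names(sort(medians))

  pairs <- utils::combn(names(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    cmp <- compare_groups(groups[[pr[1]]], groups[[pr[2]]],
                          method = method, ...)
    data.frame(group_a = pr[1], group_b = pr[2], p_value = cmp$p_value,
               tier = cmp$tier, stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, rows)
  pairwise$p_holm <- stats::p.adjust(pairwise$p_value, method = "holm")
  pairwise <- pairwise[, c("group_a", "group_b", "p_value", "p_holm", "tier")]

  concordant <- NA
  if (!is.null(expected_order)) {
    if (!setequal(expected_order, names(groups))) {
      stop("`expected_order` must name exactly the supplied groups",
           call. = FALSE)
    }
    adj_sig <- vapply(seq_len(length(ordering) - 1L), function(i) {
      pr <- sort(c(ordering[i], ordering[i + 1L]))
      hit <- pairwise$group_a == pr[1] & pairwise$group_b == pr[2]
      pairwise$p_value[hit] < 0.05
    }, logical(1))
    concordant <- identical(ordering, as.character(expected_order)) &&
      all(adj_sig)
  }
  list(ordering = ordering, medians = medians, pairwise = pairwise,
       concordant = concordant)
}
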