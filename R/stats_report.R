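#' Mann-Whitney U test
#'
#' Two-sided (by default) rank-sum comparison of two independent
#' groups, the package's default test for non-normally distributed
#' per-adhesion or per-cell quantities. The p value is exact (from the
#' null rank distribution) for small tie-free samples and otherwise
#' uses the normal approximation with tie and continuity corrections,
#' as implemented in [stats::wilcox.test()].
#'
#' @param a,b Numeric vectors (each >= 1 value).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A `TestResult`: list with `test`, `statistic` (U, the number
#'   of (a, b) pairs with a > b, plus half the ties), `p_value`,
#'   `group_sizes`, `exact`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  if (!length(a) || !length(b)) {
    fq_stop("both groups need at least one value", "validation_error")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  res <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, correct = TRUE)
  )
  structure(list(test = "mann_whitney_u",
                 statistic = unname(res$statistic),
                 p_value = min(res$p.value, 1),
                 group_sizes = c(length(a), length(b)),
                 exact = !ties && max(length(a), length(b)) < 50,
                 alternative = alternative),
            class = "TestResult")
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Omnibus tie-corrected Kruskal-Wallis H across k groups, followed
#' (for k >= 3) by Dunn's z tests on the pooled ranks for every group
#' pair, with multiplicity adjustment (default Bonferroni across all
#' pairs; also `"holm"` or `"none"`).
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 1
#'   value).
#' @param adjust Adjustment method for the pairwise p values.
#' @return List with `omnibus` (a `TestResult` with H and p) and
#'   `pairwise` (data frame: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`, `stars`; empty for 2 groups).
#' @export
kruskal_dunn <- function(groups, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2L) {
    fq_stop("need at least 2 groups", "validation_error")
  }
  if (any(!vapply(groups, length, integer(1)))) {
    fq_stop("every group needs at least one value", "validation_error")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- kruskal.test(groups)
  omnibus <- structure(list(test = "kruskal_wallis",
                            statistic = unname(kw$statistic),
                            p_value = kw$p.value,
                            group_sizes = vapply(groups, length, integer(1))),
                       class = "TestResult")
  pairwise <- data.frame(group1 = character(), group2 = character(),
                         z = numeric(), p_value = numeric(),
                         p_adjusted = numeric(), stars = character())
  if (length(groups) >= 3L) {
    x <- unlist(groups, use.names = FALSE)
    g <- rep(names(groups), times = lengths(groups))
    n <- length(x)
    rk <- rank(x)
    mean_rank <- tapply(rk, g, mean)
    sizes <- tapply(rk, g, length)
    tie_tab <- table(x)
    tie_sum <- sum(tie_tab^3 - tie_tab)
    var_term <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))
    combs <- utils::combn(names(groups), 2)
    z <- p <- numeric(ncol(combs))
    for (j in seq_len(ncol(combs))) {
      g1 <- combs[1, j]; g2 <- combs[2, j]
      se <- sqrt(var_term * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
      z[j] <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
      p[j] <- 2 * pnorm(-abs(z[j]))
    }
    p_adj <- p.adjust(p, method = adjust)
    pairwise <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                           z = z, p_value = p, p_adjusted = p_adj,
                           stars = significance_stars(p_adj))
  }
  list(omnibus = omnibus, pairwise = pairwise, adjust = adjust)
}

#' Significance star labels
#'
#' Maps p values to the conventional labels with strict cutoffs:
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' otherwise `ns`.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Character vector of labels.
#' @export
#' @examples
#' significance_stars(c(0.03, 0.05, 5e-5)) # "*", "ns", "****"
significance_stars <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    fq_stop("p values must lie in [0, 1]", "validation_error")
  }
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s), n = %s\n",
              x$test, x$statistic, x$p_value,
              significance_stars(x$p_value),
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Group comparison report for tidy per-object results
#'
#' The end-to-end statistics step: takes a tidy table (one row per
#' adhesion/cell), optionally averages values within each group in
#' random bins (the 10-random-FA convention), then compares groups with
#' the appropriate nonparametric test — Mann-Whitney U for two groups,
#' Kruskal-Wallis with Dunn's post hoc for three or more — and reports
#' medians, sizes, p values and star labels.
#'
#' @param data Data frame.
#' @param group Name of the grouping column.
#' @param value Name of the numeric value column.
#' @param bin_size Objects per random bin; `NULL` or 1 tests raw values.
#' @param seed Seed for the random binning.
#' @param adjust Post hoc adjustment (>= 3 groups).
#' @return List with `summary` (per-group medians and sizes), `test`
#'   (the omnibus/two-group `TestResult`), `pairwise` (Dunn table or
#'   empty), `binned`.
#' @export
run_report <- function(data, group, value, bin_size = 10, seed = 1L,
                       adjust = "bonferroni") {
  if (!all(c(group, value) %in% names(data))) {
    fq_stop(sprintf("columns '%s' and '%s' must exist", group, value),
            "validation_error")
  }
  raw <- split(data[[value]], data[[group]])
  binned <- !is.null(bin_size) && bin_size > 1
  groups <- if (binned) {
    out <- lapply(seq_along(raw), function(i) {
      bin_random(raw[[i]], bin_size = bin_size, seed = seed + i - 1L)
    })
    names(out) <- names(raw)
    out
  } else {
    lapply(raw, function(v) v[!is.na(v)])
  }
  if (any(!lengths(groups))) {
    fq_stop("a group has no values after binning", "validation_error")
  }
  summary_df <- data.frame(
    group = names(groups),
    n_raw = lengths(raw),
    n_tested = lengths(groups),
    median = vapply(groups, median, numeric(1))
  )
  if (length(groups) == 2L) {
    tr <- mann_whitney_u(groups[[1]], groups[[2]])
    pairwise <- data.frame(group1 = names(groups)[1], group2 = names(groups)[2],
                           p_value = tr$p_value, p_adjusted = tr$p_value,
                           stars = significance_stars(tr$p_value))
  } else {
    kd <- kruskal_dunn(groups, adjust = adjust)
    tr <- kd$omnibus
    pairwise <- kd$pairwise
  }
  list(summary = summary_df, test = tr, pairwise = pairwise, binned = binned)
}
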