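# Statistical battery for expression-score tables and clinical covariates:
# normality (Lilliefors) and variance-homogeneity (Levene) gates, one-way
# ANOVA vs Kruskal-Wallis omnibus, pairwise post-hocs with Holm correction,
# Spearman correlation, and the chlorpromazine-equivalent dose utility.

stat_result <- function(test, statistic, p_value, df = NULL, alpha = 0.05) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), df = unname(df), alpha = alpha,
                 reject = unname(p_value) < alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g (%s at alpha %.3g)\n",
              x$test, x$statistic, x$p_value,
              if (x$reject) "reject" else "retain", x$alpha))
  invisible(x)
}

# Run a block with a deterministic RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  Fz <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - Fz), max(Fz - (i - 1) / n))
}

#' Lilliefors test of composite normality
#'
#' Kolmogorov-Smirnov sup-distance between the sample ECDF and the normal
#' CDF with estimated mean and sd; the p-value comes from a seeded
#' Monte-Carlo null of `n_mc` standard-normal samples of the same size
#' (rather than tabulated critical values), making results exactly
#' reproducible for a given seed.
#'
#' @param x Numeric sample, `n >= 4`, positive sd.
#' @param n_mc Monte-Carlo null size (default 10000).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param alpha Decision level.
#' @return A `stat_result` (`df` holds the Monte-Carlo null size).
#' @export
lilliefors_test <- function(x, n_mc = 10000, seed = NULL, alpha = 0.05) {
  n <- length(x)
  if (n < 4L)
    ssm_stop("Lilliefors test needs n >= 4", "validation_error")
  if (!all(is.finite(x)) || stats::sd(x) == 0)
    ssm_stop("sample has zero variance or non-finite values",
             "degeneracy_error")
  D <- lilliefors_statistic(x)
  Dmc <- with_seed(seed, {
    X <- matrix(stats::rnorm(n * n_mc), n, n_mc)
    X <- matrix(X[order(col(X), X)], n)       # column-wise sort
    mu <- colMeans(X)
    s <- sqrt((colSums(X^2) - n * mu^2) / (n - 1))
    Z <- stats::pnorm((X - rep(mu, each = n)) / rep(s, each = n))
    i_over_n <- seq_len(n) / n
    d <- rep(-Inf, n_mc)
    for (i in seq_len(n))
      d <- pmax(d, i_over_n[i] - Z[i, ], Z[i, ] - (i - 1) / n)
    d
  })
  p <- (1 + sum(Dmc >= D)) / (n_mc + 1)
  stat_result("Lilliefors", D, p, df = n_mc, alpha = alpha)
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) ssm_stop("expected a list of numeric samples",
                                      "validation_error")
  lapply(groups, as.numeric)
}

#' Levene's test of variance homogeneity
#'
#' Levene's statistic on absolute deviations from the group means
#' (mean-centered variant), with an F null distribution.
#'
#' @param groups List of numeric samples, each `n >= 2`.
#' @param alpha Decision level.
#' @return A `stat_result` with `df = c(k - 1, N - k)`.
#' @export
levene_test <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  if (length(groups) < 2L)
    ssm_stop("Levene's test needs >= 2 groups", "validation_error")
  if (any(vapply(groups, length, 1L) < 2L))
    ssm_stop("every group needs n >= 2", "validation_error")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  lt <- car::leveneTest(y, g, center = mean)
  Fv <- lt[1, "F value"]
  if (!is.finite(Fv)) Fv <- 0
  p <- lt[1, "Pr(>F)"]
  if (!is.finite(p)) p <- 1
  stat_result("Levene", Fv, p, df = c(lt[1, "Df"], lt[2, "Df"]), alpha = alpha)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA:
#' `F` = between-group mean square / within-group mean square, with
#' `df = (k - 1, N - k)`.
#'
#' @param groups List of numeric samples, each `n >= 2`.
#' @param alpha Decision level.
#' @return A `stat_result`.
#' @export
oneway_anova <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  if (length(groups) < 2L)
    ssm_stop("ANOVA needs >= 2 groups", "validation_error")
  if (any(vapply(groups, length, 1L) < 2L))
    ssm_stop("every group needs n >= 2", "validation_error")
  if (all(vapply(groups, stats::var, 1) == 0))
    ssm_stop("zero within-group variance in every group", "degeneracy_error")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  stat_result("one-way ANOVA", ow$statistic, ow$p.value,
              df = unname(ow$parameter), alpha = alpha)
}

#' Kruskal-Wallis rank test
#'
#' H statistic on average ranks with the standard tie correction and a
#' chi-square null (`df = k - 1`).
#'
#' @param groups List of numeric samples (each `n >= 1`, total `n >= 3`).
#' @param alpha Decision level.
#' @return A `stat_result`.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  if (length(groups) < 2L)
    ssm_stop("Kruskal-Wallis needs >= 2 groups", "validation_error")
  y <- unlist(groups)
  if (length(y) < 3L)
    ssm_stop("Kruskal-Wallis needs total n >= 3", "validation_error")
  if (length(unique(y)) == 1L)
    ssm_stop("all observations identical", "degeneracy_error")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kw <- stats::kruskal.test(y, g)
  stat_result("Kruskal-Wallis", kw$statistic, kw$p.value,
              df = unname(kw$parameter), alpha = alpha)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The p-value is exact (by enumeration) when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie-corrected variance is used (no continuity
#' correction, so the approximate branch matches the plain large-sample
#' formula).
#'
#' @param a,b Non-empty numeric samples.
#' @param alpha Decision level.
#' @return A `stat_result`; `statistic` is the U of the first sample.
#' @export
mann_whitney <- function(a, b, alpha = 0.05) {
  if (!length(a) || !length(b))
    ssm_stop("both samples must be non-empty", "validation_error")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  stat_result("Mann-Whitney U", wt$statistic, wt$p.value, alpha = alpha)
}

#' Holm (step-down Bonferroni) adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, in input order, capped at 1 and monotone in
#'   the sorted order.
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    ssm_stop("p-values must lie in [0, 1]", "validation_error")
  stats::p.adjust(p, method = "holm")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged); two-sided p-value
#' from the t approximation `t = R sqrt((n - 2) / (1 - R^2))` with `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param alpha Decision level.
#' @return A `stat_result` whose `statistic` is Spearman's R.
#' @export
spearman_corr <- function(x, y, alpha = 0.05) {
  n <- length(x)
  if (length(y) != n || n < 3L)
    ssm_stop("'x' and 'y' must have equal length n >= 3", "validation_error")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    ssm_stop("zero rank variance", "degeneracy_error")
  r <- stats::cor(rx, ry)
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  stat_result("Spearman", r, p, df = n - 2, alpha = alpha)
}

#' Omnibus group comparison with gated parametric/nonparametric branches
#'
#' Mirrors the standard decision logic for expression-score comparisons:
#' Lilliefors normality per group and Levene variance homogeneity across
#' groups are checked first at the fixed gate level `p > 0.05`; if every
#' group passes normality and variances are homogeneous, a one-way ANOVA
#' with pairwise pooled-t post-hocs is run, otherwise Kruskal-Wallis with
#' pairwise Mann-Whitney post-hocs. The post-hoc p-values are
#' Holm-adjusted as one family (the omnibus test is not in the family).
#'
#' @param scores A `score_table` / data frame with a `group` column and a
#'   score column, or a named list of numeric samples.
#' @param value Name of the score column (default `"z_score"`, falling back
#'   to the first numeric column).
#' @param alpha Omnibus significance level.
#' @param fwer Family-wise error level for the Holm-adjusted post-hocs.
#' @param n_mc Monte-Carlo size of the Lilliefors null.
#' @param seed Optional seed for the Lilliefors Monte-Carlo.
#' @return A `group_comparison` list: `branch` ("parametric" or
#'   "nonparametric"), `normality` (per-group results), `levene`,
#'   `omnibus`, and `posthoc` (pairwise table with raw and Holm-adjusted p).
#' @export
compare_groups <- function(scores, value = "z_score", alpha = 0.05,
                           fwer = 0.05, n_mc = 10000, seed = NULL) {
  gate_p <- 0.05   # fixed gate level for the normality/homogeneity checks
  if (is.data.frame(scores)) {
    col <- if (value %in% names(scores)) value
           else names(scores)[vapply(scores, is.numeric, TRUE)][1]
    groups <- split(scores[[col]], scores$group)
  } else {
    groups <- lapply(scores, as.numeric)
  }
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L)
    ssm_stop("group comparison needs >= 2 groups", "validation_error")
  labels <- names(groups) %||% as.character(seq_along(groups))

  normal <- TRUE
  norm_results <- vector("list", length(groups))
  names(norm_results) <- labels
  for (i in seq_along(groups)) {
    res <- tryCatch(
      lilliefors_test(groups[[i]], n_mc = n_mc,
                      seed = if (is.null(seed)) NULL else seed + i,
                      alpha = gate_p),
      ssmpca_error = function(e) NULL)
    norm_results[[i]] <- res
    if (is.null(res) || res$p_value <= gate_p) normal <- FALSE
  }
  lev <- tryCatch(levene_test(groups, alpha = gate_p),
                  ssmpca_error = function(e) NULL)
  if (is.null(lev) || lev$p_value <= gate_p) normal <- FALSE

  branch <- if (normal) "parametric" else "nonparametric"
  omnibus <- if (normal) oneway_anova(groups, alpha = alpha)
             else kruskal_wallis(groups, alpha = alpha)

  pairs <- utils::combn(seq_along(groups), 2L)
  ph <- data.frame(group1 = labels[pairs[1, ]], group2 = labels[pairs[2, ]],
                   statistic = NA_real_, p_raw = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- groups[[pairs[1, k]]]
    b <- groups[[pairs[2, k]]]
    if (normal) {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      ph$statistic[k] <- unname(tt$statistic)
      ph$p_raw[k] <- tt$p.value
    } else {
      mw <- mann_whitney(a, b)
      ph$statistic[k] <- mw$statistic
      ph$p_raw[k] <- mw$p_value
    }
  }
  ph$p_holm <- holm_adjust(ph$p_raw)
  ph$significant <- ph$p_holm < fwer

  structure(list(branch = branch, normality = norm_results, levene = lev,
                 omnibus = omnibus, posthoc = ph,
                 group_means = vapply(groups, mean, 1),
                 alpha = alpha, fwer = fwer),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> branch: %s\n", x$branch))
  print(x$omnibus)
  cat("post-hoc (Holm-adjusted):\n")
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Read a chlorpromazine-equivalence ratio table
#'
#' CSV with header `drug,multiplier,source`; multipliers convert a daily
#' dose in mg to its chlorpromazine-equivalent mg. The package ships only a
#' small illustrative example table
#' (`system.file("extdata", "cpz_ratios_example.csv", package = "ssmpca")`);
#' ratio sets for actual use must be supplied by the user from a published
#' source.
#'
#' @param path CSV path.
#' @return Data frame with columns `drug`, `multiplier`, `source`.
#' @export
read_ratio_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "multiplier", "source")
  if (!all(need %in% names(tab)))
    ssm_stop("ratio table must have columns drug, multiplier, source",
             "validation_error")
  if (anyDuplicated(tab$drug))
    ssm_stop("duplicate drug names in ratio table", "validation_error")
  if (any(!is.finite(tab$multiplier)) || any(tab$multiplier <= 0))
    ssm_stop("multipliers must be positive", "validation_error")
  tab[, need]
}

#' Chlorpromazine-equivalent total dose
#'
#' Sums `dose_mg * multiplier` over the administered drugs, looking each
#' drug up in the ratio table.
#'
#' @param doses Data frame with columns `drug` and `dose_mg` (an empty
#'   frame yields 0).
#' @param ratio_table Data frame as from [read_ratio_table()].
#' @return Total chlorpromazine-equivalent dose in mg.
#' @export
cpz_equivalent <- function(doses, ratio_table) {
  if (!nrow(doses)) return(0)
  idx <- match(doses$drug, ratio_table$drug)
  if (anyNA(idx))
    ssm_stop(sprintf("drug(s) not in ratio table: %s",
                     paste(doses$drug[is.na(idx)], collapse = ", ")),
             "lookup_error")
  sum(doses$dose_mg * ratio_table$multiplier[idx])
}
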