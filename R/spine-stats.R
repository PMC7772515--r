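# Normality-gated test selection: Shapiro-Wilk decides between parametric
# and rank-based correlation / comparison, with Bonferroni-corrected
# pairwise follow-ups for three or more groups.

stars_for <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# Shapiro-Wilk normality gate at alpha = 0.05, applied per sample.
# shapiro.test needs 3 <= n <= 5000; larger samples are subsampled
# deterministically (every k-th order statistic) to stay within its range.
is_normal <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) > 5000) x <- sort(x)[round(seq(1, length(x), length.out = 5000))]
  if (stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

new_stat_result <- function(test_name, statistic, p_value, n, direction = NA,
                            correction = "none", pairwise = NULL,
                            normal_gate = NA) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, direction = direction,
                 correction = correction, pairwise = pairwise,
                 normal_gate = normal_gate,
                 stars = stars_for(unname(p_value))),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s\n",
              x$test_name, x$statistic, x$p_value, x$stars))
  if (!is.na(x$direction) && nzchar(x$direction))
    cat("  direction:", x$direction, "\n")
  cat("  n =", paste(x$n, collapse = ", "), "\n")
  if (!is.null(x$pairwise)) {
    cat(sprintf("  pairwise (%s-corrected):\n", x$correction))
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Normality-gated correlation
#'
#' Tests both variables for normality (Shapiro-Wilk at alpha = 0.05); if
#' both pass, Pearson's correlation is used, otherwise Spearman's rank
#' order test (midranks for ties).
#'
#' @param x,y Paired numeric samples, n >= 4.
#' @param alpha Normality-gate level (default 0.05).
#' @return A `stat_result` with the test name, correlation coefficient
#'   (`statistic`) and p value.
#' @examples
#' r <- choose_and_correlate(1:10, 2 * (1:10) + 1)
#' r$statistic  # 1
#' @export
choose_and_correlate <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate correlation: constant input", call. = FALSE)
  gate <- is_normal(x, alpha) && is_normal(y, alpha)
  method <- if (gate) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  new_stat_result(
    test_name = if (gate) "Pearson correlation" else "Spearman rank correlation",
    statistic = unname(ct$estimate), p_value = ct$p.value, n = length(x),
    direction = if (ct$estimate >= 0) "positive" else "negative",
    normal_gate = gate
  )
}

#' Normality-gated group comparison with Bonferroni-corrected pairwise tests
#'
#' For two groups: Student's t test when every group passes the
#' Shapiro-Wilk gate, otherwise the Mann-Whitney U test. For three or more
#' groups: one-way ANOVA vs the Kruskal-Wallis test, followed by all
#' pairwise comparisons in the same family with Bonferroni-adjusted p
#' values (capped at 1).
#'
#' @param groups List of numeric samples (>= 2 groups, each n >= 3),
#'   optionally named.
#' @param alpha Normality-gate level (default 0.05).
#' @return A `stat_result`; for >= 3 groups the `pairwise` field is a data
#'   frame with columns `comparison, test, statistic, p_raw, p_adjusted,
#'   stars`.
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(10), b = rnorm(10, 2))
#' choose_and_compare(g)$p_value < 0.01
#' @export
choose_and_compare <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of >= 2 samples", call. = FALSE)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  ns <- lengths(groups)
  if (any(ns < 3L))
    stop("every group needs n >= 3", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  gate <- all(vapply(groups, is_normal, logical(1), alpha = alpha))

  if (length(groups) == 2L) {
    if (gate) {
      ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      name <- "Student t test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                                exact = FALSE))
      name <- "Mann-Whitney U test"
    }
    dir <- sprintf("%s %s %s (medians %.4g vs %.4g)",
                   names(groups)[1],
                   if (stats::median(groups[[1]]) >= stats::median(groups[[2]]))
                     ">=" else "<",
                   names(groups)[2],
                   stats::median(groups[[1]]), stats::median(groups[[2]]))
    return(new_stat_result(name, ht$statistic, ht$p.value, ns, dir,
                           normal_gate = gate))
  }

  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), ns), levels = names(groups))
  if (gate) {
    ht <- stats::oneway.test(values ~ labels, var.equal = TRUE)
    name <- "one-way ANOVA"
  } else {
    ht <- stats::kruskal.test(values, labels)
    name <- "Kruskal-Wallis test"
  }

  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    if (gate) {
      t2 <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(comparison = paste(pr, collapse = " vs "),
                 test = "t", statistic = unname(t2$statistic),
                 p_raw = t2$p.value, stringsAsFactors = FALSE)
    } else {
      w2 <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
      data.frame(comparison = paste(pr, collapse = " vs "),
                 test = "wilcoxon", statistic = unname(w2$statistic),
                 p_raw = w2$p.value, stringsAsFactors = FALSE)
    }
  }))
  pw$p_adjusted <- stats::p.adjust(pw$p_raw, method = "bonferroni")
  pw$stars <- stars_for(pw$p_adjusted)

  new_stat_result(name, ht$statistic, ht$p.value, ns,
                  correction = "bonferroni", pairwise = pw,
                  normal_gate = gate)
}

#' Tidy correlation / comparison results
#'
#' Flattens one or more `stat_result` objects into a results table
#' (comparison, test, statistic, p_raw, p_adjusted, stars), the layout used
#' by the pipeline's report stage.
#'
#' @param results A `stat_result` or list of them, optionally named.
#' @return A data frame.
#' @export
stat_results_table <- function(results) {
  if (inherits(results, "stat_result")) results <- list(results)
  if (is.null(names(results)))
    names(results) <- paste0("result", seq_along(results))
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    top <- data.frame(comparison = nm, test = r$test_name,
                      statistic = r$statistic, p_raw = r$p_value,
                      p_adjusted = r$p_value, stars = r$stars,
                      stringsAsFactors = FALSE)
    if (!is.null(r$pairwise)) {
      pw <- r$pairwise
      top <- rbind(top, data.frame(comparison = paste(nm, pw$comparison,
                                                      sep = ": "),
                                   test = pw$test, statistic = pw$statistic,
                                   p_raw = pw$p_raw,
                                   p_adjusted = pw$p_adjusted,
                                   stars = pw$stars,
                                   stringsAsFactors = FALSE))
    }
    top
  }))
}
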