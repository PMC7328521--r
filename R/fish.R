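#' Colocalization fraction of FISH probe pairs
#'
#' Fraction of interprobe distances strictly below the colocalization
#' threshold (0.2 micrometres by convention: signals closer than that are
#' scored as a single focus).
#'
#' @param distances numeric vector of interprobe distances (micrometres);
#'   `NA` entries are dropped.
#' @param threshold colocalization threshold (micrometres); strictly less-than.
#' @return tibble `fraction`, `count`, `n`, `threshold`.
#' @export
colocalization_fraction <- function(distances, threshold = 0.2) {
  distances <- distances[!is.na(distances)]
  if (!length(distances)) pcg_abort("empty distance vector")
  if (any(distances < 0)) pcg_abort("negative distances")
  count <- sum(distances < threshold)
  tibble::tibble(fraction = count / length(distances), count = count,
                 n = length(distances), threshold = threshold)
}

#' Compare two FISH measurement distributions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with tie correction —
#' the comparison used for interprobe distances, foci counts and nuclear
#' areas. Exact enumeration for small untied samples, normal approximation
#' otherwise. Constant pooled data (no ordering information) returns p = 1,
#' flagged degenerate.
#'
#' @param group_a,group_b numeric vectors (`NA` dropped).
#' @return tibble `statistic` (U for group_a), `p.value`, `n_a`, `n_b`,
#'   `degenerate`.
#' @export
compare_distributions <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  if (!length(a) || !length(b)) pcg_abort("both groups must be nonempty")
  if (length(unique(c(a, b))) == 1L) {
    return(tibble::tibble(statistic = length(a) * length(b) / 2, p.value = 1,
                          n_a = length(a), n_b = length(b), degenerate = TRUE))
  }
  exact <- length(a) <= 20 && length(b) <= 20 &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  tibble::tibble(statistic = unname(wt$statistic), p.value = wt$p.value,
                 n_a = length(a), n_b = length(b), degenerate = FALSE)
}

#' Classify a triple-probe constellation
#'
#' Counts probe pairs at or below the clustering threshold (0.35
#' micrometres by default) among the three pairwise distances and maps the
#' count to a category: 3 pairs close = clustered (`Cl`); exactly 1 pair
#' close = two probes together with the third excluded (`SE`,
#' single-excluded); 2 pairs close = intermediate (`Int`); none = dispersed
#' (`Dis`). The pair-count formalisation of the category names is this
#' package's convention. Vectorised over nuclei; any missing distance
#' yields `NA` (the nucleus is excluded).
#'
#' @param d12,d13,d23 pairwise distances (micrometres).
#' @param threshold clustering threshold, non-strict (<=).
#' @return factor with levels `Cl`, `SE`, `Int`, `Dis`.
#' @export
triple_clustering_classify <- function(d12, d13, d23, threshold = 0.35) {
  k <- (d12 <= threshold) + (d13 <= threshold) + (d23 <= threshold)
  out <- dplyr::case_when(
    is.na(k) ~ NA_character_,
    k == 3 ~ "Cl",
    k == 2 ~ "Int",
    k == 1 ~ "SE",
    TRUE ~ "Dis"
  )
  factor(out, levels = c("Cl", "SE", "Int", "Dis"))
}

#' Chi-square test of clustering categories across conditions
#'
#' Pearson chi-square on the condition x category contingency table of
#' triple-probe clustering classes, with per-condition category percentages
#' for plotting. Tables with any expected cell below 1 additionally report
#' a Fisher exact p-value.
#'
#' @param categories named list (one element per condition) of category
#'   factors from [triple_clustering_classify()], or a data frame with
#'   `condition` and `category` columns.
#' @return list of class `clustering_test`: `statistic`, `p`, `df`, `table`,
#'   `percentages`, optional `fisher_p`.
#' @export
clustering_contingency_test <- function(categories) {
  if (is.data.frame(categories)) {
    tab <- table(categories$condition, categories$category)
  } else {
    if (length(categories) < 2) pcg_abort("need >= 2 conditions")
    lv <- c("Cl", "SE", "Int", "Dis")
    tab <- t(vapply(categories, function(x) {
      table(factor(x, levels = lv))
    }, numeric(4)))
    colnames(tab) <- lv
    tab <- as.table(tab)
  }
  keep <- colSums(tab) > 0
  test_tab <- tab[, keep, drop = FALSE]
  ct <- suppressWarnings(stats::chisq.test(test_tab, correct = FALSE))
  out <- list(statistic = unname(ct$statistic), p = ct$p.value,
              df = unname(ct$parameter), table = tab,
              percentages = prop.table(tab, 1) * 100)
  if (any(ct$expected < 1)) {
    warn("expected cell count < 1; reporting Fisher exact p as fallback")
    out$fisher_p <- stats::fisher.test(test_tab,
                                       simulate.p.value = TRUE,
                                       B = 1e4)$p.value
  }
  structure(out, class = "clustering_test")
}

#' @export
print.clustering_test <- function(x, ...) {
  cat(sprintf("<clustering_test> X-squared = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p))
  print(round(x$percentages, 1))
  invisible(x)
}
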