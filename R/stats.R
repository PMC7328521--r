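#' Permutation z-score test for a region of interest
#'
#' Tests whether a genomic region of interest (ROI) — a single interval
#' (local block) or an interval pair (distal block) — is enriched in
#' observed/expected contacts relative to matched random placements. The
#' observed statistic is the mean O/E over valid ROI pixels; the null is
#' built from `n` rigid translations of the ROI along the same chromosome
#' (preserving interval lengths, their separation, and hence the distance
#' from the diagonal), resampled when a translation overlaps the original
#' ROI. Permuted means are log-transformed (and by default the observed
#' value too, for a symmetric statistic), the z-score is
#' `(log observed - mean) / sd`, and the p-value is the standard-normal
#' upper tail `1 - pnorm(z)`.
#'
#' Single-interval ROIs exclude diagonal offsets 0 and 1 from the pixel
#' block, the same convention as the local-compaction analysis.
#'
#' @param mat a [contact_matrix()].
#' @param roi list or one-row data frame with `chrom`, `start`, `end`, and
#'   optionally `start2`, `end2` for an interval-pair ROI.
#' @param n number of permutations (default 1000).
#' @param seed RNG seed.
#' @param log_observed also log-transform the observed mean (default TRUE).
#' @param oe optional precomputed O/E map.
#' @return object of class `roi_test`: `observed`, `perm_mean_log`,
#'   `perm_sd_log`, `z`, `p`, `n_perm`, `roi`.
#' @export
roi_permutation_test <- function(mat, roi, n = 1000, seed = 1L,
                                 log_observed = TRUE, oe = NULL) {
  if (is.data.frame(roi)) roi <- as.list(roi[1, ])
  chrom <- roi$chrom
  if (is.null(chrom) || !chrom %in% chromosomes(mat)) {
    pcg_abort("ROI chromosome not in matrix")
  }
  if (is.null(oe)) oe <- observed_over_expected(mat)
  m <- oe_matrix(oe, chrom)
  nb <- nrow(m)
  res <- mat$resolution
  span <- function(s, e) (floor(s / res) + 1):(ceiling(e / res))
  I1 <- span(roi$start, roi$end)
  paired <- !is.null(roi$start2) && !is.na(roi$start2 %||% NA)
  I2 <- if (paired) span(roi$start2, roi$end2) else I1
  if (min(I1, I2) < 1 || max(I1, I2) > nb) {
    pcg_abort("ROI does not fit within its chromosome")
  }
  mask <- if (!paired) {
    outer(I1, I2, function(i, j) j - i >= 2)
  } else {
    matrix(TRUE, length(I1), length(I2))
  }
  block_mean <- function(d) {
    blk <- m[I1 + d, I2 + d, drop = FALSE]
    v <- blk[mask]
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    mean(v)
  }
  observed <- block_mean(0L)
  lo <- 1L - min(I1, I2)
  hi <- nb - max(I1, I2)
  w1 <- length(I1); w2 <- length(I2)
  overlaps_roi <- function(d) {
    (min(I1) + d <= max(I1) && max(I1) + d >= min(I1)) ||
      (min(I2) + d <= max(I2) && max(I2) + d >= min(I2)) ||
      (paired && ((min(I1) + d <= max(I2) && max(I1) + d >= min(I2)) ||
                  (min(I2) + d <= max(I1) && max(I2) + d >= min(I1))))
  }
  # distinct candidate translations; sampled without replacement so a short
  # chromosome reduces the permutation count rather than duplicating regions
  cand <- setdiff(lo:hi, 0L)
  cand <- cand[!vapply(cand, overlaps_roi, logical(1))]
  if (length(cand) < 2) {
    pcg_abort("chromosome too short to place non-overlapping permutations")
  }
  use <- cand
  if (length(cand) > n) {
    use <- with_seed(seed, sample(cand, n))
  } else if (length(cand) < n) {
    warn(sprintf("only %d of %d requested permutations could be placed",
                 length(cand), n))
  }
  perms <- vapply(use, block_mean, numeric(1))
  perms <- perms[is.finite(perms) & perms > 0]
  if (length(perms) < 2 || !is.finite(observed)) {
    pcg_abort("insufficient valid permutations or undefined observed value")
  }
  lp <- log(perms)
  obs_stat <- if (log_observed) log(observed) else observed
  sd_lp <- stats::sd(lp)
  z <- if (sd_lp < 1e-12) {
    # degenerate null (e.g. noise-free uniform O/E): no spread to score against
    if (abs(obs_stat - mean(lp)) < 1e-9) 0 else
      sign(obs_stat - mean(lp)) * Inf
  } else (obs_stat - mean(lp)) / sd_lp
  structure(list(roi = roi, observed = observed,
                 perm_mean_log = mean(lp), perm_sd_log = sd_lp,
                 z = z, p = stats::pnorm(z, lower.tail = FALSE),
                 n_perm = length(perms), log_observed = log_observed),
            class = "roi_test")
}

#' @export
print.roi_test <- function(x, ...) {
  r <- x$roi
  loc <- sprintf("%s:%g-%g%s", r$chrom, r$start, r$end,
                 if (!is.null(r$start2)) sprintf(" x %g-%g", r$start2, r$end2)
                 else "")
  cat(sprintf("<roi_test> %s\n  observed mean O/E = %.4g | z = %.3f | p = %.3g (%d permutations)\n",
              loc, x$observed, x$z, x$p, x$n_perm))
  invisible(x)
}

#' Linear model of loopability on chromatin-factor occupancy
#'
#' Ordinary least squares of per-region loopability (`enrichment1`) on
#' standardized predictors: ChIP reads of H3K27me3, RING1B, MEL18, CBX2,
#' KDM2B and RYBP over the merged peak regions, plus merged peak length.
#' Rows are filtered to regions with positive enrichment in every supplied
#' condition column and with RING1B reads below `max_ring1b_reads`
#' (excluding high-coverage technical artifacts). Coefficient p-values come
#' from the usual t statistics; the predicted-versus-observed Pearson r
#' summarises fit quality.
#'
#' @param table tibble joining loopability with predictor quantitation.
#' @param response response column (e.g. `"enrichment1_WT"`).
#' @param predictors predictor column names.
#' @param enrichment_cols columns that must all be positive (default: every
#'   column starting with `enrichment1`).
#' @param max_ring1b_reads upper RING1B read-count filter (default 1000).
#' @param ring1b_col column holding RING1B reads.
#' @return object of class `loopability_model`; see [tidy.loopability_model()].
#' @export
fit_loopability_model <- function(table, response,
                                  predictors = c("reads_H3K27me3",
                                                 "reads_RING1B", "reads_MEL18",
                                                 "reads_CBX2", "reads_KDM2B",
                                                 "reads_RYBP", "length"),
                                  enrichment_cols = NULL,
                                  max_ring1b_reads = 1000,
                                  ring1b_col = "reads_RING1B") {
  if (is.null(enrichment_cols)) {
    enrichment_cols <- grep("^enrichment1", names(table), value = TRUE)
  }
  miss <- setdiff(c(response, predictors, enrichment_cols), names(table))
  if (length(miss)) {
    pcg_abort(paste0("table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(table))
  for (col in enrichment_cols) {
    keep <- keep & !is.na(table[[col]]) & table[[col]] > 0
  }
  if (ring1b_col %in% names(table) && is.finite(max_ring1b_reads)) {
    keep <- keep & table[[ring1b_col]] < max_ring1b_reads
  }
  dat <- table[keep, , drop = FALSE]
  if (nrow(dat) <= length(predictors) + 1) {
    pcg_abort("too few regions after filtering to fit the model")
  }
  # population-SD standardization: invariant under row duplication
  Xr <- as.matrix(dat[predictors])
  mu <- colMeans(Xr)
  sdev <- sqrt(colMeans(sweep(Xr, 2, mu)^2))
  X <- sweep(sweep(Xr, 2, mu), 2, sdev, "/")
  if (any(!is.finite(X))) {
    pcg_abort("constant or non-finite predictor after standardization")
  }
  kap <- kappa(cbind(1, X), exact = FALSE)
  if (kap > 1e8) {
    warn(sprintf("collinear predictors (condition number %.3g); coefficients still reported", kap))
  }
  df <- data.frame(.y = dat[[response]], X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = co[, 1], std.error = co[, 2],
    statistic = co[, 3], p.value = co[, 4]
  )
  structure(list(fit = fit, coefficients = coefs,
                 r = stats::cor(stats::fitted(fit), dat[[response]]),
                 n = nrow(dat), response = response,
                 predictors = predictors,
                 filters = list(enrichment_cols = enrichment_cols,
                                max_ring1b_reads = max_ring1b_reads),
                 condition_number = kap),
            class = "loopability_model")
}

#' @export
print.loopability_model <- function(x, ...) {
  cat(sprintf("<loopability_model> %s ~ %d standardized predictors | n = %d | Pearson r(pred, obs) = %.3f\n",
              x$response, length(x$predictors), x$n, x$r))
  print(x$coefficients)
  invisible(x)
}

#' Local compaction versus occupancy
#'
#' For each genome window, the total observed/expected contact in the
#' window's intra-window pixels, excluding the first two diagonals and any
#' pixel touching a filtered-out bin; summarised per occupancy group as the
#' mean with a normal-approximation 95% confidence interval
#' (mean +/- 1.96 SE). Windows with no admissible pixel are missing.
#'
#' @param mat a [contact_matrix()].
#' @param windows region table whose width is a multiple of the matrix
#'   resolution, with a grouping column (e.g. from [percentile_group()]).
#' @param group_key grouping column name.
#' @param oe optional precomputed O/E map.
#' @return list of class `compaction_result`: `window_scores` (windows with
#'   `oe_sum`), `group_summary` (`group`, `n`, `mean`, `ci_lo`, `ci_hi`).
#' @export
compaction_by_occupancy <- function(mat, windows, group_key = "percentile_group",
                                    oe = NULL) {
  windows <- validate_regions(windows)
  if (!group_key %in% names(windows)) {
    pcg_abort(sprintf("no grouping column '%s'", group_key))
  }
  res <- mat$resolution
  cs <- matrix_chromsizes(mat)
  chrom_len <- cs$length[match(windows$chrom, cs$chrom)]
  aligned <- abs((windows$end - windows$start) %% res) < 1e-9 |
    (!is.na(chrom_len) & windows$end == chrom_len)
  if (any(!aligned, na.rm = TRUE)) {
    pcg_abort("window width must be a multiple of the matrix resolution")
  }
  if (is.null(oe)) oe <- observed_over_expected(mat)
  windows$oe_sum <- NA_real_
  for (chrom in unique(windows$chrom)) {
    if (!chrom %in% chromosomes(mat)) next
    m <- oe_matrix(oe, chrom)
    nb <- nrow(m)
    sel <- which(windows$chrom == chrom)
    for (i in sel) {
      b0 <- floor(windows$start[i] / res) + 1
      b1 <- min(ceiling(windows$end[i] / res), nb)
      if (b1 - b0 < 2) next
      blk <- m[b0:b1, b0:b1]
      idx <- which(upper.tri(blk) & row(blk) <= col(blk) - 2, arr.ind = TRUE)
      v <- blk[idx]
      v <- v[is.finite(v)]
      if (length(v)) windows$oe_sum[i] <- sum(v)
    }
  }
  grp <- windows %>%
    dplyr::filter(is.finite(.data$oe_sum)) %>%
    dplyr::group_by(group = .data[[group_key]]) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$oe_sum),
                     se = stats::sd(.data$oe_sum) / sqrt(dplyr::n()),
                     .groups = "drop") %>%
    dplyr::mutate(ci_lo = .data$mean - 1.96 * .data$se,
                  ci_hi = .data$mean + 1.96 * .data$se)
  structure(list(window_scores = windows, group_summary = grp,
                 condition = mat$genome),
            class = "compaction_result")
}

#' @export
print.compaction_result <- function(x, ...) {
  cat(sprintf("<compaction_result> %s | %d windows\n", x$condition,
              nrow(x$window_scores)))
  print(x$group_summary)
  invisible(x)
}

#' Compartment-score change versus expression change
#'
#' Compares the per-window compartment score difference (mutant minus
#' wild-type) across gene expression classes: strictly up-regulated
#' (log2 ratio >= `strict_lfc`, adjusted p <= `strict_p`), down-regulated
#' (mirror thresholds), and unchanged (|log2 ratio| < `unchanged_lfc`).
#' Classes are compared by two-sided rank-sum tests.
#'
#' @param score_wt,score_mut score tracks (`chrom`, `start`, `end`, `score`)
#'   on one bin grid.
#' @param genes region table with `name`.
#' @param expression tibble with `gene`, `log2_ratio`, `padj`.
#' @param strict_lfc,strict_p,unchanged_lfc class thresholds.
#' @return list: `summary` (class, n, mean_delta), `tests` (pairwise
#'   rank-sum p-values), `gene_table`.
#' @export
compartment_expression_association <- function(score_wt, score_mut, genes,
                                               expression,
                                               strict_lfc = 1, strict_p = 0.01,
                                               unchanged_lfc = 0.5) {
  if (nrow(score_wt) != nrow(score_mut)) {
    pcg_abort("score tracks must share one bin grid")
  }
  delta <- score_mut$score - score_wt$score
  genes <- validate_regions(genes)
  ex <- expression[match(genes$name, expression$gene), ]
  cls <- dplyr::case_when(
    !is.na(ex$log2_ratio) & ex$log2_ratio >= strict_lfc &
      !is.na(ex$padj) & ex$padj <= strict_p ~ "up",
    !is.na(ex$log2_ratio) & ex$log2_ratio <= -strict_lfc &
      !is.na(ex$padj) & ex$padj <= strict_p ~ "down",
    !is.na(ex$log2_ratio) & abs(ex$log2_ratio) < unchanged_lfc ~ "unchanged",
    TRUE ~ NA_character_
  )
  mid <- region_midpoint(genes)
  win <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    j <- which(score_wt$chrom == genes$chrom[i] & score_wt$start <= mid[i] &
                 score_wt$end > mid[i])
    win[i] <- if (length(j)) j[1] else NA_integer_
  }
  gt <- tibble::tibble(gene = genes$name, class = cls,
                       delta_score = delta[win])
  gt <- gt[!is.na(gt$class) & is.finite(gt$delta_score), ]
  summ <- gt %>%
    dplyr::group_by(class = .data$class) %>%
    dplyr::summarise(n = dplyr::n(), mean_delta = mean(.data$delta_score),
                     .groups = "drop")
  present <- unique(gt$class)
  combos <- if (length(present) >= 2) utils::combn(sort(present), 2) else
    matrix(character(0), 2, 0)
  tests <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- gt$delta_score[gt$class == combos[1, k]]
    b <- gt$delta_score[gt$class == combos[2, k]]
    tibble::tibble(class_a = combos[1, k], class_b = combos[2, k],
                   p = suppressWarnings(stats::wilcox.test(a, b)$p.value))
  })
  list(summary = summ, tests = tests, gene_table = gt)
}
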