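#' Chromosome-wide expected profile
#'
#' Mean balanced contact value per diagonal offset, computed independently
#' for each chromosome. Pairs touching invalid bins are excluded from both
#' the numerator and the valid-pair denominator; offsets with no valid pair
#' are reported as `NA`, never silently zero. The arithmetic mean (not a
#' median, not smoothed) is used, matching the convention of aggregate
#' pileup analysis.
#'
#' @param mat a [contact_matrix()].
#' @return tibble of class `expected_profile` with `chrom`, `diag` (offset in
#'   bins), `mean`, `n` (valid pairs), and a `resolution` attribute.
#' @export
compute_expected <- function(mat) {
  comp <- expected_components(mat)
  out <- comp %>%
    dplyr::mutate(mean = ifelse(.data$n > 0, .data$sum / .data$n, NA_real_)) %>%
    dplyr::select("chrom", "diag", "mean", "n")
  attr(out, "resolution") <- mat$resolution
  class(out) <- c("expected_profile", class(out))
  out
}

# per-chromosome sums of balanced values and valid-pair counts per offset
expected_components <- function(mat) {
  res <- list()
  for (chrom in chromosomes(mat)) {
    rows <- chrom_bin_rows(mat, chrom)
    n <- length(rows)
    off <- rows[1] - 1L
    valid <- is.finite(mat$bins$weight[rows])
    n_pairs <- vapply(0:(n - 1), function(s) {
      if (s == 0) sum(valid) else sum(valid[1:(n - s)] & valid[(1 + s):n])
    }, numeric(1))
    px <- mat$pixels[mat$pixels$bin1 >= rows[1] & mat$pixels$bin2 <= rows[n], ,
                     drop = FALSE]
    i <- px$bin1 - off; j <- px$bin2 - off
    w <- mat$bins$weight[rows]
    val <- px$count * w[i] * w[j]
    keep <- is.finite(val)
    s <- (j - i)[keep]; val <- val[keep]
    sums <- numeric(n)
    if (length(val)) {
      agg <- rowsum(val, s)
      sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    }
    res[[chrom]] <- tibble::tibble(chrom = chrom, diag = 0:(n - 1),
                                   sum = sums, n = n_pairs)
  }
  dplyr::bind_rows(res)
}

#' Observed/expected map
#'
#' Wraps a contact matrix and its expected profile into a lazily-evaluated
#' pixel-wise O/E accessor: `oe_matrix()` materialises the dense O/E matrix
#' of one chromosome (cached). O/E is `balanced(i,j) / E_c(|i-j|)`;
#' undefined wherever the expected is zero/undefined or a bin is invalid
#' (`NA`, never zero).
#'
#' @param mat a [contact_matrix()].
#' @param expected an [compute_expected()] profile; computed from `mat` when
#'   omitted. Must be at the same resolution.
#' @return an object of class `oe_map`.
#' @export
observed_over_expected <- function(mat, expected = NULL) {
  if (is.null(expected)) expected <- compute_expected(mat)
  if (!isTRUE(all.equal(attr(expected, "resolution"), mat$resolution))) {
    pcg_abort("expected profile resolution does not match the matrix",
              class = "pcgloop_format_error")
  }
  structure(list(matrix = mat, expected = expected, cache = new.env()),
            class = "oe_map")
}

#' @export
print.oe_map <- function(x, ...) {
  cat("<oe_map> observed/expected accessor over:\n")
  print(x$matrix)
  invisible(x)
}

#' Dense O/E matrix of one chromosome
#'
#' @param x an `oe_map` or a `contact_matrix` (expected computed on the fly).
#' @param chrom chromosome name.
#' @return dense numeric matrix; `NA` on invalid bins and undefined expected.
#' @export
oe_matrix <- function(x, chrom) {
  if (inherits(x, "contact_matrix")) x <- observed_over_expected(x)
  if (!inherits(x, "oe_map")) pcg_abort("`x` must be an oe_map or contact_matrix")
  key <- chrom
  if (!is.null(x$cache[[key]])) return(x$cache[[key]])
  mat <- x$matrix
  rows <- chrom_bin_rows(mat, chrom)
  if (!length(rows)) pcg_abort(sprintf("unknown chromosome '%s'", chrom))
  n <- length(rows)
  off <- rows[1] - 1L
  e <- x$expected[x$expected$chrom == chrom, ]
  ev <- e$mean[order(e$diag)]
  w <- mat$bins$weight[rows]
  # zero-count pixels have O/E = 0 where E is defined; start from zeros and
  # blank the diagonals with undefined expected and the invalid bins
  oe <- matrix(0, n, n)
  px <- mat$pixels[mat$pixels$bin1 >= rows[1] & mat$pixels$bin2 <= rows[n], ,
                   drop = FALSE]
  if (nrow(px)) {
    i <- px$bin1 - off; j <- px$bin2 - off
    v <- px$count * w[i] * w[j] / ev[j - i + 1L]
    oe[cbind(i, j)] <- v
    oe[cbind(j, i)] <- v
  }
  bad_diag <- which(!is.finite(ev) | ev == 0)
  for (s in bad_diag - 1L) {
    len <- n - s
    idx <- seq_len(len)
    oe[cbind(idx, idx + s)] <- NA_real_
    if (s > 0) oe[cbind(idx + s, idx)] <- NA_real_
  }
  bad_bin <- which(!is.finite(w))
  if (length(bad_bin)) {
    oe[bad_bin, ] <- NA_real_
    oe[, bad_bin] <- NA_real_
  }
  x$cache[[key]] <- oe
  oe
}

#' Contact probability versus genomic distance, P(s)
#'
#' Mean balanced contact value in geometrically widening distance bins,
#' pooled over chromosomes (sums and valid-pair counts are combined before
#' dividing).
#'
#' @param mat a [contact_matrix()].
#' @param log_bin_factor geometric bin growth factor (> 1).
#' @param normalize divide the curve by its own sum.
#' @return tibble with `s_mid` (bp, geometric midpoint), `s_lo`, `s_hi`,
#'   `mean_contact`, `n_pairs`.
#' @export
contact_probability_curve <- function(mat, log_bin_factor = 1.25,
                                      normalize = FALSE) {
  if (log_bin_factor <= 1) pcg_abort("`log_bin_factor` must be > 1")
  comp <- expected_components(mat)
  comp <- comp[comp$diag >= 1, ]
  s_bp <- comp$diag * mat$resolution
  edge0 <- mat$resolution
  bin <- floor(log(s_bp / edge0) / log(log_bin_factor))
  agg <- comp %>%
    dplyr::mutate(bin = bin) %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::summarise(sum = sum(.data$sum), n_pairs = sum(.data$n),
                     .groups = "drop") %>%
    dplyr::filter(.data$n_pairs > 0)
  lo <- edge0 * log_bin_factor^agg$bin
  hi <- lo * log_bin_factor
  out <- tibble::tibble(s_mid = sqrt(lo * hi), s_lo = lo, s_hi = hi,
                        mean_contact = agg$sum / agg$n_pairs,
                        n_pairs = agg$n_pairs)
  if (normalize) out$mean_contact <- out$mean_contact / sum(out$mean_contact)
  out
}
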