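#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a loopability model
#'
#' One row per model term with the standardized coefficient, its standard
#' error, t statistic and p-value.
#'
#' @param x a `loopability_model`.
#' @param ... unused.
#' @return tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy loopability_model
#' @export
tidy.loopability_model <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.loopability_model
#' @return for `glance`: one-row tibble with `r` (predicted-vs-observed
#'   Pearson correlation), `n`, `r.squared`, `sigma`, `condition_number`.
#' @method glance loopability_model
#' @export
glance.loopability_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r = x$r, n = x$n, r.squared = sm$r.squared,
                 sigma = sm$sigma, condition_number = x$condition_number)
}

#' Tidy an ROI permutation test
#'
#' @param x an `roi_test`.
#' @param ... unused.
#' @return one-row tibble with the ROI location, observed mean O/E,
#'   log-scale permutation mean and SD, z and p.
#' @method tidy roi_test
#' @export
tidy.roi_test <- function(x, ...) {
  r <- x$roi
  tibble::tibble(
    chrom = r$chrom, start = r$start, end = r$end,
    start2 = r$start2 %||% NA_real_, end2 = r$end2 %||% NA_real_,
    observed = x$observed, perm_mean_log = x$perm_mean_log,
    perm_sd_log = x$perm_sd_log, z = x$z, p = x$p, n_perm = x$n_perm
  )
}

#' Tidy a pileup into long pixel form
#'
#' @param x an `hic_pileup`.
#' @param ... unused.
#' @return tibble `row`, `col`, `value`, `support`, with row/col offsets in
#'   bins from the centre for point pileups.
#' @method tidy hic_pileup
#' @export
tidy.hic_pileup <- function(x, ...) {
  side_r <- nrow(x$values); side_c <- ncol(x$values)
  off_r <- if (!x$rescaled) seq_len(side_r) - (side_r + 1) / 2 else seq_len(side_r)
  off_c <- if (!x$rescaled) seq_len(side_c) - (side_c + 1) / 2 else seq_len(side_c)
  tibble::tibble(
    row = rep(off_r, times = side_c),
    col = rep(off_c, each = side_r),
    value = as.vector(x$values),
    support = as.vector(x$support)
  )
}

#' @rdname tidy.hic_pileup
#' @method glance hic_pileup
#' @export
glance.hic_pileup <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs, mode = x$mode, rescaled = x$rescaled,
    condition = x$condition,
    central = if (x$rescaled) block_enrichment(x)$central else
      central_enrichment(x)
  )
}
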