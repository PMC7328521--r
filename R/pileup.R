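#' Pileup job parameters
#'
#' Bundles the knobs shared by all pileup flavours. Defaults follow the
#' reference analysis: pairs closer than 100 kb are excluded, rescaled local
#' pileups use a 75 x 75 target with flanks of 2 region lengths, a 10-kb
#' minimum region size, and 10 randomly shifted control regions per region
#' of interest. The point-pileup flank is 10 bins per side (a 21 x 21
#' window, about +/-100 kb at 10-kb resolution).
#'
#' @param min_sep minimum pair separation in bp (inclusive).
#' @param max_sep maximum pair separation in bp (exclusive), or `NULL`.
#' @param flank_bins half-width of point pileups in bins.
#' @param rescale_size odd side length of rescaled pileups.
#' @param rescale_pad flank size in region lengths for rescaled pileups.
#' @param min_size minimum region size (bp) for rescaled pileups.
#' @param n_shifts shifted control regions per region of interest.
#' @param seed RNG seed for control shifts.
#' @return list of class `pileup_job`.
#' @export
pileup_job <- function(min_sep = 100e3, max_sep = NULL, flank_bins = 10,
                       rescale_size = 75, rescale_pad = 2, min_size = 10e3,
                       n_shifts = 10, seed = 1L) {
  if (min_sep < 0) pcg_abort("`min_sep` must be >= 0")
  if (!is.null(max_sep) && max_sep <= min_sep) {
    pcg_abort("`max_sep` must exceed `min_sep`")
  }
  if (rescale_size %% 2 != 1) pcg_abort("`rescale_size` must be odd")
  if (n_shifts < 1) pcg_abort("`n_shifts` must be >= 1")
  structure(list(min_sep = min_sep, max_sep = max_sep,
                 flank_bins = as.integer(flank_bins),
                 rescale_size = as.integer(rescale_size),
                 rescale_pad = rescale_pad, min_size = min_size,
                 n_shifts = as.integer(n_shifts), seed = seed),
            class = "pileup_job")
}

new_pileup <- function(values, support, mode, job, n_pairs, rescaled = FALSE,
                       condition = NA_character_, resolution = NA_real_,
                       extra = list()) {
  structure(c(list(values = values, support = support, mode = mode,
                   job = job, n_pairs = n_pairs, rescaled = rescaled,
                   condition = condition, resolution = resolution),
              extra),
            class = "hic_pileup")
}

#' @export
print.hic_pileup <- function(x, ...) {
  kind <- if (x$rescaled) "rescaled local" else "point"
  cat(sprintf("<hic_pileup> %s | %dx%d | %d pair(s)/region(s) | mode=%s\n",
              kind, nrow(x$values), ncol(x$values), x$n_pairs, x$mode))
  if (!x$rescaled && x$n_pairs > 0) {
    cat(sprintf("  central enrichment: %.4g\n", central_enrichment(x)))
  }
  invisible(x)
}

# enumerate midpoint-bin pairs of one or two region sets per chromosome
enumerate_pairs <- function(mat, regions, regions2 = NULL, job) {
  regions <- validate_regions(regions)
  res <- mat$resolution
  pairs <- list()
  for (chrom in chromosomes(mat)) {
    n <- length(chrom_bin_rows(mat, chrom))
    a <- regions[regions$chrom == chrom, , drop = FALSE]
    if (!nrow(a)) next
    mid_a <- region_midpoint(a)
    bin_a <- pos_to_bin_local(mid_a, res, n)
    if (is.null(regions2)) {
      if (nrow(a) < 2) next
      cmb <- t(utils::combn(seq_len(nrow(a)), 2))
      p1 <- mid_a[cmb[, 1]]; p2 <- mid_a[cmb[, 2]]
      b1 <- bin_a[cmb[, 1]]; b2 <- bin_a[cmb[, 2]]
    } else {
      b <- regions2[regions2$chrom == chrom, , drop = FALSE]
      if (!nrow(b)) next
      mid_b <- region_midpoint(b)
      bin_b <- pos_to_bin_local(mid_b, res, n)
      g <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
      p1 <- mid_a[g$i]; p2 <- mid_b[g$j]
      b1 <- bin_a[g$i]; b2 <- bin_b[g$j]
    }
    sep <- abs(p2 - p1)
    keep <- !is.na(b1) & !is.na(b2) & b1 != b2 & sep >= job$min_sep
    if (!is.null(job$max_sep)) keep <- keep & sep < job$max_sep
    if (!any(keep)) next
    lo <- pmin(b1[keep], b2[keep]); hi <- pmax(b1[keep], b2[keep])
    pairs[[chrom]] <- tibble::tibble(chrom = chrom, bin1 = lo, bin2 = hi)
  }
  if (!length(pairs)) {
    return(tibble::tibble(chrom = character(), bin1 = integer(),
                          bin2 = integer()))
  }
  dplyr::bind_rows(pairs)
}

# core accumulation of (2k+1)^2 O/E submatrices over local-bin anchor pairs
pileup_from_pairs <- function(oe, pairs, job, condition = NA_character_) {
  k <- job$flank_bins
  side <- 2L * k + 1L
  acc <- matrix(0, side, side)
  sup <- matrix(0L, side, side)
  mat <- oe$matrix
  if (nrow(pairs)) {
    for (chrom in unique(pairs$chrom)) {
      m <- oe_matrix(oe, chrom)
      n <- nrow(m)
      pp <- pairs[pairs$chrom == chrom, , drop = FALSE]
      for (q in seq_len(nrow(pp))) {
        ri <- (pp$bin1[q] - k):(pp$bin1[q] + k)
        cj <- (pp$bin2[q] - k):(pp$bin2[q] + k)
        rok <- ri >= 1 & ri <= n
        cok <- cj >= 1 & cj <= n
        if (!any(rok) || !any(cok)) next
        blk <- matrix(NA_real_, side, side)
        blk[rok, cok] <- m[ri[rok], cj[cok]]
        fin <- is.finite(blk)
        acc[fin] <- acc[fin] + blk[fin]
        sup <- sup + fin
      }
    }
  }
  vals <- acc / sup
  vals[sup == 0] <- NA_real_
  new_pileup(vals, sup, mode = "expected", job = job,
             n_pairs = nrow(pairs), condition = condition,
             resolution = mat$resolution,
             extra = list(empty = nrow(pairs) == 0))
}

#' Distal pair pileup
#'
#' Averages the O/E submatrix of size (2k+1)^2 centred at every eligible
#' midpoint-bin pair of `regions` (or of every cross pair between `regions`
#' and `regions2`), within chromosomes only. The lower-coordinate region
#' sits on the row axis. Pixels touching invalid bins or matrix edges are
#' excluded via support counts. Normalisation is chromosome-wide expected.
#'
#' @param mat a [contact_matrix()].
#' @param regions region table (anchor set A).
#' @param regions2 optional second region table (two-set mode).
#' @param job a [pileup_job()].
#' @param oe optional precomputed [observed_over_expected()] map for `mat`
#'   (reused across calls for speed).
#' @return an `hic_pileup`; empty (all-`NA`, flagged) when no pair is
#'   eligible.
#' @export
distal_pileup <- function(mat, regions, regions2 = NULL, job = pileup_job(),
                          oe = NULL) {
  if (is.null(oe)) oe <- observed_over_expected(mat)
  pairs <- enumerate_pairs(mat, regions, regions2, job)
  pileup_from_pairs(oe, pairs, job, condition = mat$genome)
}

#' Central enrichment of a point pileup
#'
#' Mean of the central `k x k` pixel block; the loop-strength readout.
#'
#' @param pileup an `hic_pileup` from a point pileup.
#' @param k odd block size (1 = the central pixel).
#' @return scalar.
#' @export
central_enrichment <- function(pileup, k = 1) {
  if (!inherits(pileup, "hic_pileup")) pcg_abort("`pileup` must be an hic_pileup")
  if (pileup$rescaled) {
    pcg_abort("central_enrichment is undefined for rescaled pileups; use block_enrichment()")
  }
  side <- nrow(pileup$values)
  if (side %% 2 != 1) pcg_abort("point pileup must have odd side length")
  c0 <- (side + 1) %/% 2
  h <- (k - 1) %/% 2
  mean(pileup$values[(c0 - h):(c0 + h), (c0 - h):(c0 + h)], na.rm = TRUE)
}

#' Distance-stratified pileups
#'
#' One [distal_pileup()] per distance stratum. Strata must be disjoint;
#' empty strata come back flagged, not dropped.
#'
#' @param mat a [contact_matrix()].
#' @param regions region table.
#' @param strata list of `c(min, max)` bp ranges (min inclusive, max
#'   exclusive), e.g. twofold-increasing ranges from 0.05-0.1 Mb upward.
#' @param job base [pileup_job()]; each stratum overrides `min_sep`/`max_sep`.
#' @param regions2 optional second region set.
#' @param oe optional precomputed O/E map.
#' @return named list of `hic_pileup`.
#' @export
distance_stratified_pileups <- function(mat, regions, strata,
                                        job = pileup_job(), regions2 = NULL,
                                        oe = NULL) {
  iv <- do.call(rbind, lapply(strata, function(s) sort(as.numeric(s[1:2]))))
  ord <- order(iv[, 1])
  if (any(iv[ord, 1][-1] < iv[ord, 2][-nrow(iv)])) {
    pcg_abort("strata must be disjoint")
  }
  if (is.null(oe)) oe <- observed_over_expected(mat)
  out <- lapply(seq_along(strata), function(i) {
    j <- job
    j$min_sep <- iv[i, 1]; j$max_sep <- iv[i, 2]
    distal_pileup(mat, regions, regions2, j, oe = oe)
  })
  names(out) <- vapply(seq_along(strata), function(i) {
    sprintf("%s-%s", fmt_bp(iv[i, 1]), fmt_bp(iv[i, 2]))
  }, character(1))
  out
}

#' Orientation-aware CTCF pair pileup
#'
#' Classifies ordered pairs of stranded sites — upstream site `u`
#' (lower coordinate) versus downstream site `d` — as convergent (`u:+`,
#' `d:-`), divergent (`u:-`, `d:+`), left-facing (both `-`) or right-facing
#' (both `+`), and piles up the selected class.
#'
#' @param mat a [contact_matrix()].
#' @param sites stranded region table (`strand` column, `+`/`-`).
#' @param orientation_class one of `"convergent"`, `"divergent"`,
#'   `"left-facing"`, `"right-facing"`.
#' @param job a [pileup_job()].
#' @param oe optional precomputed O/E map.
#' @return an `hic_pileup`.
#' @export
oriented_pair_pileup <- function(mat, sites, orientation_class,
                                 job = pileup_job(), oe = NULL) {
  sites <- validate_regions(sites, stranded = TRUE)
  orientation_class <- match.arg(orientation_class,
                                 c("convergent", "divergent",
                                   "left-facing", "right-facing"))
  if (is.null(oe)) oe <- observed_over_expected(mat)
  res <- mat$resolution
  pairs <- list()
  for (chrom in chromosomes(mat)) {
    n <- length(chrom_bin_rows(mat, chrom))
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    if (nrow(s) < 2) next
    s <- dplyr::arrange(s, .data$start)
    mid <- region_midpoint(s)
    bins <- pos_to_bin_local(mid, res, n)
    cmb <- t(utils::combn(seq_len(nrow(s)), 2))
    u <- cmb[, 1]; d <- cmb[, 2]    # u upstream of d after sorting
    cls <- dplyr::case_when(
      s$strand[u] == "+" & s$strand[d] == "-" ~ "convergent",
      s$strand[u] == "-" & s$strand[d] == "+" ~ "divergent",
      s$strand[u] == "-" & s$strand[d] == "-" ~ "left-facing",
      TRUE ~ "right-facing"
    )
    sep <- mid[d] - mid[u]
    keep <- cls == orientation_class & !is.na(bins[u]) & !is.na(bins[d]) &
      bins[u] != bins[d] & sep >= job$min_sep
    if (!is.null(job$max_sep)) keep <- keep & sep < job$max_sep
    if (!any(keep)) next
    pairs[[chrom]] <- tibble::tibble(chrom = chrom,
                                     bin1 = pmin(bins[u], bins[d])[keep],
                                     bin2 = pmax(bins[u], bins[d])[keep])
  }
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(chrom = character(), bin1 = integer(), bin2 = integer())
  pileup_from_pairs(oe, pairs, job, condition = mat$genome)
}

#' Per-region loopability
#'
#' For each region, the central-pixel O/E enrichment of its pileup against
#' all other regions on the same chromosome ("enrichment1"): a per-region
#' proxy for the capacity to form distal loops. Regions with no eligible
#' partner (all closer than `min_sep`, or no valid pixel) get `NA`.
#'
#' @param mat a [contact_matrix()].
#' @param regions region table with a `name` column (ids generated if absent).
#' @param job a [pileup_job()].
#' @param oe optional precomputed O/E map.
#' @return tibble `name`, `chrom`, `start`, `end`, `enrichment1`, `n_partners`.
#' @export
loopability_by_window <- function(mat, regions, job = pileup_job(), oe = NULL) {
  regions <- validate_regions(regions)
  if (!"name" %in% names(regions)) {
    regions$name <- sprintf("region_%04d", seq_len(nrow(regions)))
  }
  if (is.null(oe)) oe <- observed_over_expected(mat)
  res <- mat$resolution
  out <- regions[, c("name", "chrom", "start", "end")]
  out$enrichment1 <- NA_real_
  out$n_partners <- 0L
  for (chrom in chromosomes(mat)) {
    idx <- which(regions$chrom == chrom)
    if (length(idx) < 2) next
    n <- length(chrom_bin_rows(mat, chrom))
    m <- oe_matrix(oe, chrom)
    mid <- region_midpoint(regions[idx, ])
    bins <- pos_to_bin_local(mid, res, n)
    for (a in seq_along(idx)) {
      sep <- abs(mid - mid[a])
      ok <- seq_along(idx) != a & !is.na(bins) & bins != bins[a] &
        sep >= job$min_sep
      if (!is.null(job$max_sep)) ok <- ok & sep < job$max_sep
      part <- which(ok)
      if (!length(part) || is.na(bins[a])) next
      vals <- m[cbind(pmin(bins[a], bins[part]), pmax(bins[a], bins[part]))]
      vals <- vals[is.finite(vals)]
      out$n_partners[idx[a]] <- length(vals)
      if (length(vals)) out$enrichment1[idx[a]] <- mean(vals)
    }
  }
  out
}
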