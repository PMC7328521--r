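#' Rescaled local pileup with shifted controls
#'
#' Domain-scale compaction readout over variable-length regions: for each
#' region of at least `min_size`, the O/E square covering the region plus
#' `rescale_pad` region-lengths of flank on each side is extracted,
#' bilinearly interpolated to `rescale_size` x `rescale_size`, and averaged
#' across regions. The same procedure applied to `n_shifts` randomly
#' shifted control windows per region (shifted along the chromosome,
#' avoiding overlap closer than one region length with the source) yields
#' the normalisation surface; the reported pileup is the element-wise ratio.
#' Regions whose padded window leaves the chromosome are skipped and
#' recorded.
#'
#' @param mat a [contact_matrix()].
#' @param regions region table.
#' @param job a [pileup_job()]; uses `rescale_size`, `rescale_pad`,
#'   `min_size`, `n_shifts`, `seed`.
#' @param oe optional precomputed O/E map.
#' @return an `hic_pileup` with `rescaled = TRUE`; elements `n_pairs`
#'   (regions used), `skipped` (names/indices of skipped regions),
#'   `region_lengths` (bp of regions used), `raw` and `control` component
#'   surfaces.
#' @export
rescaled_local_pileup <- function(mat, regions, job = pileup_job(), oe = NULL) {
  regions <- validate_regions(regions)
  if (is.null(oe)) oe <- observed_over_expected(mat)
  R <- job$rescale_size
  pad <- job$rescale_pad
  res <- mat$resolution
  acc <- matrix(0, R, R); sup <- matrix(0, R, R)
  cacc <- matrix(0, R, R); csup <- matrix(0, R, R)
  used <- 0L; skipped <- character(0); used_len <- numeric(0)
  with_seed(job$seed, {
    for (chrom in unique(regions$chrom)) {
      if (!chrom %in% chromosomes(mat)) {
        skipped <- c(skipped, paste0("off-genome:", chrom))
        next
      }
      n <- length(chrom_bin_rows(mat, chrom))
      chrom_len <- n * res
      m <- oe_matrix(oe, chrom)
      rr <- regions[regions$chrom == chrom, , drop = FALSE]
      for (q in seq_len(nrow(rr))) {
        len <- rr$end[q] - rr$start[q]
        id <- if ("name" %in% names(rr)) rr$name[q] else
          sprintf("%s:%g-%g", chrom, rr$start[q], rr$end[q])
        if (len < job$min_size) { skipped <- c(skipped, id); next }
        w_start <- rr$start[q] - pad * len
        w_end <- rr$end[q] + pad * len
        if (w_start < 0 || w_end > chrom_len || (w_end - w_start) > chrom_len) {
          skipped <- c(skipped, id)
          next
        }
        b0 <- floor(w_start / res) + 1
        b1 <- ceiling(w_end / res)
        blk <- bilinear_resize(m[b0:b1, b0:b1, drop = FALSE], R)
        fin <- is.finite(blk)
        acc[fin] <- acc[fin] + blk[fin]; sup <- sup + fin
        used <- used + 1L
        used_len <- c(used_len, len)
        # shifted controls: same window size, random along-chromosome shift
        w_len <- w_end - w_start
        got <- 0L; tries <- 0L
        while (got < job$n_shifts && tries < 200L * job$n_shifts) {
          tries <- tries + 1L
          c_start <- floor(stats::runif(1, 0, chrom_len - w_len))
          # require the shifted source-region window to keep >= 1 region
          # length of distance from the original region
          c_reg_start <- c_start + pad * len
          if (abs(c_reg_start - rr$start[q]) < len) next
          cb0 <- floor(c_start / res) + 1
          cb1 <- ceiling((c_start + w_len) / res)
          if (cb1 > n) next
          cblk <- bilinear_resize(m[cb0:cb1, cb0:cb1, drop = FALSE], R)
          cfin <- is.finite(cblk)
          cacc[cfin] <- cacc[cfin] + cblk[cfin]; csup <- csup + cfin
          got <- got + 1L
        }
        if (got < job$n_shifts) {
          warn(sprintf("only %d/%d control shifts placed for %s",
                       got, job$n_shifts, id))
        }
      }
    }
  })
  raw <- acc / sup; raw[sup == 0] <- NA_real_
  ctrl <- cacc / csup; ctrl[csup == 0] <- NA_real_
  vals <- raw / ctrl
  vals[!is.finite(vals)] <- NA_real_
  new_pileup(vals, sup, mode = "shifted-controls", job = job,
             n_pairs = used, rescaled = TRUE, condition = mat$genome,
             resolution = res,
             extra = list(skipped = skipped, region_lengths = used_len,
                          raw = raw, control = ctrl, empty = used == 0L))
}

#' Block statistics of a rescaled pileup
#'
#' Mean of the central block (the rescaled region itself, the middle
#' 1/(1+2*pad) of each axis, shrunk by `margin` of its width on each side
#' so boundary interpolation smear does not dilute the domain signal) and
#' of the four flank corner blocks; the domain-compaction summary for
#' rescaled pileups, where a single central pixel is not meaningful.
#'
#' @param pileup a rescaled `hic_pileup`.
#' @param margin fraction of the central block trimmed from each side
#'   (default 0.25).
#' @return tibble with `central`, `corners`.
#' @export
block_enrichment <- function(pileup, margin = 0.25) {
  if (!inherits(pileup, "hic_pileup") || !pileup$rescaled) {
    pcg_abort("`pileup` must be a rescaled hic_pileup")
  }
  R <- nrow(pileup$values)
  pad <- pileup$job$rescale_pad
  lo <- floor(R * pad / (1 + 2 * pad)) + 1
  hi <- ceiling(R * (1 + pad) / (1 + 2 * pad))
  trim <- floor((hi - lo + 1) * margin)
  lo <- lo + trim; hi <- hi - trim
  central <- mean(pileup$values[lo:hi, lo:hi], na.rm = TRUE)
  k <- max(2, floor(R * pad / (1 + 2 * pad) / 2))
  corners <- mean(c(pileup$values[1:k, 1:k],
                    pileup$values[1:k, (R - k + 1):R],
                    pileup$values[(R - k + 1):R, 1:k],
                    pileup$values[(R - k + 1):R, (R - k + 1):R]),
                  na.rm = TRUE)
  tibble::tibble(central = central, corners = corners)
}
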