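#' Merge peaks separated by small gaps
#'
#' Unions intervals whose gap is strictly below `gap` bp (default 5000, the
#' merge distance used for RING1B peak regions). The merged interval spans
#' min start to max end.
#'
#' @param peaks region table.
#' @param gap merge distance in bp; gaps of exactly `gap` are not merged.
#' @return region table of merged intervals with `name` and `length`.
#' @export
merge_peaks <- function(peaks, gap = 5000) {
  peaks <- validate_regions(peaks)
  if (!nrow(peaks)) return(dplyr::mutate(peaks, length = numeric(0)))
  gr <- GenomicRanges::reduce(regions_to_gr(peaks), min.gapwidth = gap,
                              ignore.strand = TRUE)
  out <- gr_to_regions(gr) %>% dplyr::arrange(.data$chrom, .data$start)
  out$name <- sprintf("merged_%04d", seq_len(nrow(out)))
  out$length <- out$end - out$start
  out
}

#' Quantify track signal over regions
#'
#' Sums a coverage track (bedGraph-style bins with a `value` column of read
#' counts) over each region, pro-rating partially overlapping track bins by
#' the overlapped fraction, and converts to RPKM:
#' `reads * 1e9 / (length * total_reads)`.
#'
#' @param track tibble `chrom`, `start`, `end`, `value`.
#' @param regions region table.
#' @param total_reads library size; defaults to `sum(track$value)`.
#' @param prefix name for the output columns, e.g. `"RING1B"` gives
#'   `reads_RING1B` and `rpkm_RING1B`; `NULL` gives `reads`/`rpkm`.
#' @return `regions` with reads and RPKM columns appended.
#' @export
quantify_signal <- function(track, regions, total_reads = NULL, prefix = NULL) {
  regions <- validate_regions(regions)
  vcol <- track_value_col(track, c("value", "score"))
  track <- validate_regions(track)
  if (is.null(total_reads)) total_reads <- sum(track[[vcol]])
  # region off the track's chromosomes is an error, per contract
  bad <- setdiff(unique(regions$chrom), unique(track$chrom))
  if (length(bad)) {
    pcg_abort(paste0("region chromosome(s) absent from track: ",
                     paste(bad, collapse = ", ")),
              class = "pcgloop_format_error")
  }
  gr_t <- regions_to_gr(track)
  gr_r <- regions_to_gr(regions)
  hits <- GenomicRanges::findOverlaps(gr_r, gr_t, ignore.strand = TRUE)
  reads <- numeric(nrow(regions))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov_start <- pmax(regions$start[qi], track$start[si])
    ov_end <- pmin(regions$end[qi], track$end[si])
    frac <- (ov_end - ov_start) / (track$end[si] - track$start[si])
    contrib <- track[[vcol]][si] * frac
    agg <- rowsum(contrib, qi)
    reads[as.integer(rownames(agg))] <- agg[, 1]
  }
  len <- regions$end - regions$start
  rpkm <- if (total_reads > 0) reads * 1e9 / (len * total_reads) else
    rep(0, nrow(regions))
  rn <- if (is.null(prefix)) "reads" else paste0("reads_", prefix)
  kn <- if (is.null(prefix)) "rpkm" else paste0("rpkm_", prefix)
  regions[[rn]] <- reads
  regions[[kn]] <- rpkm
  regions
}

#' Split regions into quartiles of a value
#'
#' Q1 = lowest, Q4 = highest quarter; ties broken by stable input order so
#' group sizes differ by at most one. All-equal values are flagged
#' degenerate (attribute), the split still returned.
#'
#' @param regions region table.
#' @param value_key column name to stratify on.
#' @return `regions` with a `quartile` factor column (`Q1`..`Q4`);
#'   attribute `degenerate` if the values carry no order.
#' @export
stratify_quartiles <- function(regions, value_key) {
  regions <- validate_regions(regions)
  v <- regions[[value_key]]
  if (is.null(v)) pcg_abort(sprintf("no column '%s'", value_key))
  if (nrow(regions) < 4) pcg_abort("need at least 4 regions")
  if (any(!is.finite(v))) pcg_abort("values must be finite")
  ord <- order(v)            # stable: ties keep input order
  n <- nrow(regions)
  grp <- integer(n)
  bounds <- floor(n * (1:4) / 4)
  lo <- 1L
  for (qq in 1:4) {
    grp[ord[lo:bounds[qq]]] <- qq
    lo <- bounds[qq] + 1L
  }
  regions$quartile <- factor(paste0("Q", grp), levels = paste0("Q", 1:4))
  if (length(unique(v)) == 1L) attr(regions, "degenerate") <- TRUE
  regions
}

#' Split regions into quartiles of a signal ratio
#'
#' Quartiles of `(numerator + pseudocount) / (denominator + pseudocount)`,
#' the canonical-versus-noncanonical occupancy stratification (e.g. CBX2
#' vs. RYBP, or MEL18 vs. KDM2B).
#'
#' @param regions region table.
#' @param numerator_key,denominator_key signal column names.
#' @param pseudocount added to both before dividing (default 1 read).
#' @return `regions` with `ratio` and `quartile` columns; degenerate flag as
#'   in [stratify_quartiles()].
#' @export
ratio_stratify <- function(regions, numerator_key, denominator_key,
                           pseudocount = 1) {
  regions <- validate_regions(regions)
  num <- regions[[numerator_key]]; den <- regions[[denominator_key]]
  if (is.null(num) || is.null(den)) pcg_abort("ratio columns not found")
  if (any(num < 0) || any(den < 0)) pcg_abort("negative signals")
  regions$ratio <- (num + pseudocount) / (den + pseudocount)
  stratify_quartiles(regions, "ratio")
}

#' Classify CpG islands by Polycomb occupancy
#'
#' Splits CGIs into the four classes compared in CGI-pair pileups: all
#' CGIs, RING1B-negative, RING1B-positive, and RING1B/H3K27me3
#' double-positive, by >= 1 bp overlap.
#'
#' @param cgis,ring1b_peaks,k27_regions region tables on one genome.
#' @return named list of region tables: `all`, `negative`, `positive`,
#'   `double_positive`.
#' @export
classify_cgis <- function(cgis, ring1b_peaks, k27_regions) {
  cgis <- validate_regions(cgis)
  gr_c <- regions_to_gr(cgis)
  pos <- GenomicRanges::countOverlaps(gr_c, regions_to_gr(ring1b_peaks),
                                      ignore.strand = TRUE) > 0
  k27 <- GenomicRanges::countOverlaps(gr_c, regions_to_gr(k27_regions),
                                      ignore.strand = TRUE) > 0
  list(all = cgis,
       negative = cgis[!pos, , drop = FALSE],
       positive = cgis[pos, , drop = FALSE],
       double_positive = cgis[pos & k27, , drop = FALSE])
}

#' Tile a genome into abutting windows
#'
#' @param chromsizes tibble `chrom`, `length`.
#' @param width window width in bp (default 25 kb); the last window of each
#'   chromosome is truncated.
#' @return region table of windows with `name`.
#' @export
genome_windows <- function(chromsizes, width = 25e3) {
  stopifnot_scalar_number(width, "width", positive = TRUE)
  out <- dplyr::bind_rows(lapply(seq_len(nrow(chromsizes)), function(i) {
    len <- chromsizes$length[i]
    starts <- seq(0, len - 1, by = width)
    tibble::tibble(chrom = chromsizes$chrom[i], start = starts,
                   end = pmin(starts + width, len))
  }))
  out$name <- sprintf("win_%06d", seq_len(nrow(out)))
  out
}

#' Group windows by signal percentile
#'
#' Labels genome windows by percentile of a quantified ChIP signal.
#' Zero-signal windows form their own class (`"zero"`); percentile edges
#' are computed over the nonzero-signal windows only.
#'
#' @param windows region table with a quantified signal column.
#' @param value_key signal column name.
#' @param edges increasing percentile edges in (0, 100), e.g.
#'   `c(25, 50, 75, 90)` yields 5 nonzero groups.
#' @return `windows` with a `percentile_group` factor (lowest first, `zero`
#'   class first of all).
#' @export
percentile_group <- function(windows, value_key, edges = c(25, 50, 75, 90)) {
  windows <- validate_regions(windows)
  v <- windows[[value_key]]
  if (is.null(v)) pcg_abort(sprintf("no column '%s'", value_key))
  nz <- v > 0
  qs <- stats::quantile(v[nz], probs = edges / 100, names = FALSE, type = 7)
  brk <- unique(c(-Inf, qs, Inf))
  lab <- paste0("P", c(0, edges), "-", c(edges, 100))[seq_len(length(brk) - 1)]
  grp <- rep(NA_character_, length(v))
  grp[nz] <- as.character(cut(v[nz], breaks = brk, labels = lab,
                              right = TRUE, include.lowest = TRUE))
  grp[!nz] <- "zero"
  windows$percentile_group <- factor(grp, levels = c("zero", lab))
  windows
}

#' Classify peaks by proximity to expression changes
#'
#' Implements the expression-versus-distal-interaction split: peaks within
#' `near_dist` of a strictly up-regulated gene (log2 ratio >= 1 and
#' adjusted p <= 0.01) are `upregulated-proximal`; peaks farther than
#' `far_dist` from every relaxed-up gene (log2 ratio >= 0.5) are
#' `not-upregulated-distant`; everything else is `other` and excluded from
#' the comparison. Distances are unstranded TSS-to-peak-edge.
#'
#' @param peaks region table.
#' @param genes region table with `strand` (TSS = `start` on `+`, `end` on
#'   `-`) and a `name` column matching the expression table's `gene`.
#' @param expression tibble with `gene`, `log2_ratio` and `padj` columns.
#' @param strict_lfc,strict_p strict up-regulation thresholds.
#' @param relaxed_lfc relaxed up-regulation threshold.
#' @param near_dist,far_dist proximity rules in bp (0-50 kb; >100 kb).
#' @return `peaks` with an `expression_class` column.
#' @export
classify_peaks_by_expression <- function(peaks, genes, expression,
                                         strict_lfc = 1, strict_p = 0.01,
                                         relaxed_lfc = 0.5,
                                         near_dist = 50e3, far_dist = 100e3) {
  peaks <- validate_regions(peaks)
  genes <- validate_regions(genes, stranded = TRUE)
  if (!nrow(genes)) pcg_abort("empty gene set")
  ex <- expression[match(genes$name, expression$gene), ]
  strict <- !is.na(ex$log2_ratio) & ex$log2_ratio >= strict_lfc &
    !is.na(ex$padj) & ex$padj <= strict_p
  relaxed <- !is.na(ex$log2_ratio) & ex$log2_ratio >= relaxed_lfc
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  dist_to <- function(sel) {
    vapply(seq_len(nrow(peaks)), function(i) {
      j <- sel & genes$chrom == peaks$chrom[i]
      if (!any(j)) return(Inf)
      # unstranded TSS-to-peak-edge distance; 0 if the TSS is inside
      d <- pmax(peaks$start[i] - tss[j], tss[j] - peaks$end[i], 0)
      min(d)
    }, numeric(1))
  }
  d_strict <- dist_to(strict)
  d_relaxed <- dist_to(relaxed)
  cls <- dplyr::case_when(
    d_strict <= near_dist ~ "upregulated-proximal",
    d_relaxed > far_dist ~ "not-upregulated-distant",
    TRUE ~ "other"
  )
  peaks$expression_class <- cls
  peaks
}
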