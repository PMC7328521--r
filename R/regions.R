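#' Region tables
#'
#' Genomic region sets are plain tibbles with at least `chrom`, `start`,
#' `end` columns (0-based, half-open, as in BED). Optional columns carry a
#' `name`, a `strand` (`"+"`/`"-"`), and arbitrary per-region annotations
#' (ChIP read counts, RPKM, occupancy, quartile labels). All package
#' functions accept and return this shape so results chain with the pipe.
#'
#' @param chrom character chromosome names.
#' @param start,end 0-based half-open coordinates.
#' @param ... further per-region columns, recycled tibble-style.
#' @return a tibble of class `region_tbl`.
#' @examples
#' region_tbl(chrom = "chr1", start = c(0, 5000), end = c(1000, 9000))
#' @export
region_tbl <- function(chrom, start, end, ...) {
  out <- tibble::tibble(chrom = as.character(chrom),
                        start = as.numeric(start),
                        end = as.numeric(end), ...)
  validate_regions(out)
}

#' Validate a region table
#'
#' Checks the 0-based half-open convention (`end > start`, `start >= 0`) and
#' column presence; called by every function consuming regions.
#'
#' @param regions data frame with `chrom`, `start`, `end`.
#' @param stranded require a `strand` column restricted to `+`/`-`.
#' @return the input as a validated tibble (invisibly classed).
#' @export
validate_regions <- function(regions, stranded = FALSE) {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(regions))
  if (length(miss)) {
    pcg_abort(paste0("region table lacks column(s): ", paste(miss, collapse = ", ")),
              class = "pcgloop_format_error")
  }
  regions <- tibble::as_tibble(regions)
  if (nrow(regions)) {
    if (any(!is.finite(regions$start)) || any(!is.finite(regions$end))) {
      pcg_abort("region coordinates must be finite", class = "pcgloop_format_error")
    }
    if (any(regions$end <= regions$start)) {
      bad <- which(regions$end <= regions$start)[1L]
      pcg_abort(sprintf(
        "interval with end <= start at row %d (%s:%g-%g); coordinates must be 0-based half-open",
        bad, regions$chrom[bad], regions$start[bad], regions$end[bad]),
        class = "pcgloop_format_error")
    }
    if (any(regions$start < 0)) {
      pcg_abort("negative start coordinate", class = "pcgloop_format_error")
    }
  }
  if (stranded) {
    if (!"strand" %in% names(regions) || !all(regions$strand %in% c("+", "-"))) {
      pcg_abort("stranded input required: `strand` column with values '+'/'-'",
                class = "pcgloop_format_error")
    }
  }
  regions
}

# Convert a region tibble to GRanges (internal; 0-based half-open -> 1-based).
regions_to_gr <- function(regions) {
  regions <- validate_regions(regions)
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end),
    strand = if ("strand" %in% names(regions)) regions$strand else "*"
  )
}

gr_to_regions <- function(gr) {
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Region midpoints
#'
#' Midpoint coordinate of each region; even-length ties resolve to the lower
#' position so downstream bin assignment is deterministic.
#'
#' @param regions region table.
#' @return numeric vector of midpoint coordinates (bp).
#' @export
region_midpoint <- function(regions) {
  regions <- validate_regions(regions)
  floor((regions$start + regions$end) / 2)
}
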