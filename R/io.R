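#' Read and write genomic region sets (BED)
#'
#' BED3/BED6 with 0-based half-open coordinates. 1-based or end <= start
#' input raises a convention error; requesting `stranded` input fails when
#' the strand column is absent or `.`.
#'
#' @param path BED file path.
#' @param stranded require `+`/`-` strand on every record.
#' @return region tibble (see [region_tbl()]).
#' @export
read_regions <- function(path, stranded = FALSE) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
  md <- S4Vectors::mcols(gr)
  if ("name" %in% names(md)) out$name <- md$name
  if ("score" %in% names(md)) out$score <- md$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  if (stranded && (!"strand" %in% names(out) || any(!out$strand %in% c("+", "-")))) {
    pcg_abort("stranded input required: BED6 with '+'/'-' strand",
              class = "pcgloop_format_error")
  }
  validate_regions(out, stranded = stranded)
}

#' @rdname read_regions
#' @param regions region tibble to write.
#' @export
write_regions <- function(regions, path) {
  regions <- validate_regions(regions)
  gr <- regions_to_gr(regions)
  if ("name" %in% names(regions)) names(gr) <- regions$name
  if ("score" %in% names(regions)) S4Vectors::mcols(gr)$score <- regions$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write coverage tracks (bedGraph)
#'
#' @param path bedGraph file path.
#' @return track tibble `chrom`, `start`, `end`, `value`.
#' @export
read_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1,
                 end = GenomicRanges::end(gr),
                 value = S4Vectors::mcols(gr)$score)
}

#' @rdname read_track
#' @param track track tibble with a `value` (or `score`) column.
#' @export
write_track <- function(track, path) {
  vcol <- track_value_col(track, c("value", "score"))
  gr <- regions_to_gr(track)
  S4Vectors::mcols(gr)$score <- track[[vcol]]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read and write chromosome sizes
#' @param path two-column chrom.sizes file.
#' @return tibble `chrom`, `length`.
#' @export
read_chromsizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  col_types = readr::cols(chrom = "c", length = "d"),
                  progress = FALSE)
}

#' @rdname read_chromsizes
#' @param chromsizes tibble `chrom`, `length`.
#' @export
write_chromsizes <- function(chromsizes, path) {
  readr::write_tsv(chromsizes[, c("chrom", "length")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write contact matrices (text COO dialect)
#'
#' A contact matrix is stored as a directory holding `bins.tsv`
#' (`chrom`, `start`, `end`, `weight`; empty weight = invalid bin) and
#' `pixels.tsv` (`bin1`, `bin2`, `count`, 1-based upper-triangular), plus a
#' small `meta.json` with resolution and genome label. Reading validates
#' bin tiling and pixel orientation and can coarsen on load by an integer
#' factor.
#'
#' @param path directory path.
#' @param resolution optional target resolution; must be an integer
#'   multiple of the stored resolution.
#' @return a [contact_matrix()].
#' @export
read_contacts <- function(path, resolution = NULL) {
  bins_f <- file.path(path, "bins.tsv")
  px_f <- file.path(path, "pixels.tsv")
  meta_f <- file.path(path, "meta.json")
  for (f in c(bins_f, px_f, meta_f)) {
    if (!file.exists(f)) {
      pcg_abort(sprintf("missing contact-matrix component: %s", f),
                class = "pcgloop_format_error")
    }
  }
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  bins <- readr::read_tsv(bins_f, col_types = readr::cols(
    chrom = "c", start = "d", end = "d", weight = "d"), progress = FALSE)
  px <- readr::read_tsv(px_f, col_types = readr::cols(
    bin1 = "i", bin2 = "i", count = "d"), progress = FALSE)
  if (any(is.na(px$bin1)) || any(is.na(px$bin2)) || any(is.na(px$count))) {
    bad <- which(is.na(px$bin1) | is.na(px$bin2) | is.na(px$count))[1L]
    pcg_abort(sprintf("malformed pixel record at row %d", bad),
              class = "pcgloop_format_error")
  }
  mat <- contact_matrix(bins, px, resolution = meta$resolution,
                        genome = meta$genome %||% "unknown")
  if (!is.null(resolution)) {
    fac <- resolution / mat$resolution
    if (abs(fac - round(fac)) > 1e-9 || fac < 1) {
      pcg_abort("requested resolution is not an integer multiple of the stored one",
                class = "pcgloop_format_error")
    }
    if (fac > 1) mat <- coarsen_contacts(mat, round(fac))
  }
  mat
}

#' @rdname read_contacts
#' @param mat a [contact_matrix()] to write.
#' @export
write_contacts <- function(mat, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(mat$bins[, c("chrom", "start", "end", "weight")],
                   file.path(path, "bins.tsv"), progress = FALSE)
  readr::write_tsv(mat$pixels, file.path(path, "pixels.tsv"), progress = FALSE)
  jsonlite::write_json(list(resolution = mat$resolution, genome = mat$genome),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write plain TSV tables
#' @param path file path.
#' @return tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' @rdname read_table_tsv
#' @param x data frame.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

# Provenance JSON written next to every pipeline output set.
write_provenance <- function(dir, seed, params, inputs = character(0)) {
  prov <- list(
    package = "pcgloop",
    version = as.character(utils::packageVersion("pcgloop")),
    seed = seed,
    params = params,
    input_checksums = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else list()
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prov)
}
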