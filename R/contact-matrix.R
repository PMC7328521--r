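#' Binned Hi-C contact matrix
#'
#' The package's contact-map container: a bin table tiling each chromosome
#' contiguously at a fixed resolution, plus a sparse upper-triangular pixel
#' table of raw counts, mirroring the cooler bins/pixels layout. Balancing
#' weights live on the bins; a bin with a non-finite weight is invalid and is
#' excluded from every downstream statistic (never treated as zero).
#'
#' @param bins tibble with `chrom`, `start`, `end`, and optionally `weight`
#'   (balancing weight, `NA` = invalid bin). Bins must tile each chromosome
#'   contiguously in order.
#' @param pixels tibble with `bin1`, `bin2` (1-based row indices into `bins`,
#'   `bin1 <= bin2`) and `count` (raw contact count, >= 0).
#' @param resolution bin size in bp.
#' @param genome free-text genome label.
#' @return an object of class `contact_matrix` with elements `bins`,
#'   `pixels`, `resolution`, `genome`.
#' @examples
#' bins <- tibble::tibble(chrom = "chr1", start = seq(0, 40, 10),
#'                        end = seq(10, 50, 10), weight = 1)
#' px <- tibble::tibble(bin1 = c(1, 1, 2), bin2 = c(1, 3, 4), count = c(5, 2, 1))
#' contact_matrix(bins, px, resolution = 10)
#' @export
contact_matrix <- function(bins, pixels, resolution, genome = "synthetic") {
  bins <- tibble::as_tibble(bins)
  pixels <- tibble::as_tibble(pixels)
  stopifnot_scalar_number(resolution, "resolution", positive = TRUE)
  if (!all(c("chrom", "start", "end") %in% names(bins))) {
    pcg_abort("bins need chrom/start/end", class = "pcgloop_format_error")
  }
  if (!"weight" %in% names(bins)) bins$weight <- 1
  # bins must tile each chromosome contiguously
  by_chr <- split(seq_len(nrow(bins)), bins$chrom)
  for (idx in by_chr) {
    b <- bins[idx, ]
    if (any(diff(idx) != 1L)) {
      pcg_abort("bins of one chromosome must be contiguous rows",
                class = "pcgloop_format_error")
    }
    if (b$start[1] != 0 || any(b$start[-1] != b$end[-nrow(b)])) {
      pcg_abort(sprintf("bins do not tile chromosome %s contiguously from 0",
                        b$chrom[1]), class = "pcgloop_format_error")
    }
    if (any((b$end - b$start)[-nrow(b)] != resolution)) {
      pcg_abort(sprintf("non-terminal bin of %s does not match resolution %g",
                        b$chrom[1], resolution), class = "pcgloop_format_error")
    }
  }
  if (!all(c("bin1", "bin2", "count") %in% names(pixels))) {
    pcg_abort("pixels need bin1/bin2/count", class = "pcgloop_format_error")
  }
  if (nrow(pixels)) {
    if (any(pixels$bin1 > pixels$bin2)) {
      pcg_abort("pixels must be upper-triangular (bin1 <= bin2)",
                class = "pcgloop_format_error")
    }
    if (any(pixels$count < 0)) {
      bad <- which(pixels$count < 0)[1L]
      pcg_abort(sprintf("negative count at pixel row %d", bad),
                class = "pcgloop_format_error")
    }
    if (any(pixels$bin1 < 1) || any(pixels$bin2 > nrow(bins))) {
      pcg_abort("pixel bin index outside the bin table",
                class = "pcgloop_format_error")
    }
  }
  structure(
    list(bins = bins, pixels = pixels,
         resolution = as.numeric(resolution), genome = genome),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  nchr <- length(unique(x$bins$chrom))
  cat(sprintf("<contact_matrix> %s | %d bins on %d chromosome(s) @ %s | %s pixels, %s contacts\n",
              x$genome, nrow(x$bins), nchr, fmt_bp(x$resolution),
              format(nrow(x$pixels), big.mark = ","),
              format(sum(x$pixels$count), big.mark = ",")))
  invisible(x)
}

#' Chromosome names of a contact matrix
#' @param mat a `contact_matrix`.
#' @return character vector in bin-table order.
#' @export
chromosomes <- function(mat) unique(mat$bins$chrom)

# rows of the bin table belonging to `chrom`, in order
chrom_bin_rows <- function(mat, chrom) {
  which(mat$bins$chrom == chrom)
}

# logical validity per bin (finite weight)
bin_valid <- function(mat) is.finite(mat$bins$weight)

#' Dense balanced matrix for one chromosome
#'
#' Materialises the symmetric balanced (count x weight_i x weight_j) matrix of
#' one chromosome. Rows/columns of invalid bins are `NA`.
#'
#' @param mat a `contact_matrix`.
#' @param chrom chromosome name.
#' @param balanced multiply counts by bin weights (default) or return raw.
#' @return dense numeric matrix (n_bins x n_bins for that chromosome).
#' @export
dense_chrom_matrix <- function(mat, chrom, balanced = TRUE) {
  rows <- chrom_bin_rows(mat, chrom)
  if (!length(rows)) pcg_abort(sprintf("unknown chromosome '%s'", chrom))
  n <- length(rows)
  off <- rows[1] - 1L
  px <- mat$pixels[mat$pixels$bin1 >= rows[1] & mat$pixels$bin2 <= rows[n], , drop = FALSE]
  # keep only pixels fully inside this chromosome
  px <- px[px$bin1 - off >= 1 & px$bin2 - off <= n, , drop = FALSE]
  i <- px$bin1 - off; j <- px$bin2 - off
  m <- matrix(0, n, n)
  v <- px$count
  if (balanced) {
    w <- mat$bins$weight[rows]
    v <- v * w[i] * w[j]
  }
  m[cbind(i, j)] <- v
  m[cbind(j, i)] <- v
  if (balanced) {
    bad <- !is.finite(mat$bins$weight[rows])
    if (any(bad)) { m[bad, ] <- NA_real_; m[, bad] <- NA_real_ }
  }
  m
}

#' Coarsen a contact matrix to a lower resolution
#'
#' Sums counts into bins of `factor` x the current resolution; a coarse bin is
#' invalid if any constituent fine bin is invalid (weights of coarse valid
#' bins are reset to 1: coarsening is defined on balanced synthetic maps whose
#' weights are unit).
#'
#' @param mat a `contact_matrix`.
#' @param factor integer coarsening factor (>= 2).
#' @return a new `contact_matrix` at `resolution * factor`.
#' @export
coarsen_contacts <- function(mat, factor) {
  stopifnot_scalar_number(factor, "factor", positive = TRUE)
  factor <- as.integer(factor)
  if (factor < 2L) pcg_abort("`factor` must be >= 2")
  bins <- mat$bins
  valid <- bin_valid(mat)
  new_bins <- list(); map <- integer(nrow(bins)); next_id <- 0L
  for (chrom in chromosomes(mat)) {
    rows <- chrom_bin_rows(mat, chrom)
    grp <- (seq_along(rows) - 1L) %/% factor
    for (g in unique(grp)) {
      sel <- rows[grp == g]
      next_id <- next_id + 1L
      map[sel] <- next_id
      new_bins[[next_id]] <- tibble::tibble(
        chrom = chrom,
        start = bins$start[sel[1]],
        end = bins$end[sel[length(sel)]],
        weight = if (all(valid[sel])) 1 else NA_real_
      )
    }
  }
  nb <- dplyr::bind_rows(new_bins)
  px <- mat$pixels
  b1 <- map[px$bin1]; b2 <- map[px$bin2]
  sw <- b1 > b2
  if (any(sw)) { tmp <- b1[sw]; b1[sw] <- b2[sw]; b2[sw] <- tmp }
  key <- (b1 - 1) * nrow(nb) + b2
  agg <- rowsum(px$count, key)
  k <- as.numeric(rownames(agg))
  npx <- tibble::tibble(bin1 = as.integer((k - 1) %/% nrow(nb) + 1),
                        bin2 = as.integer((k - 1) %% nrow(nb) + 1),
                        count = as.numeric(agg[, 1]))
  npx <- dplyr::arrange(npx, .data$bin1, .data$bin2)
  contact_matrix(nb, npx, resolution = mat$resolution * factor, genome = mat$genome)
}

#' Chromosome sizes of a contact matrix
#' @param mat a `contact_matrix`.
#' @return tibble with `chrom`, `length`.
#' @export
matrix_chromsizes <- function(mat) {
  mat$bins %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::summarise(length = max(.data$end), .groups = "drop")
}

# map genomic positions (bp) on `chrom` to local bin index (1-based within chrom)
pos_to_local_bin <- function(mat, chrom, pos) {
  rows <- chrom_bin_rows(mat, chrom)
  n <- length(rows)
  idx <- floor(pos / mat$resolution) + 1
  idx[idx < 1] <- NA; idx[idx > n] <- NA
  as.integer(idx)
}
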