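track_value_col <- function(track, candidates = c("score", "value", "gc")) {
  hit <- intersect(candidates, names(track))
  if (!length(hit)) {
    pcg_abort(paste0("track needs one of columns: ",
                     paste(candidates, collapse = ", ")),
              class = "pcgloop_format_error")
  }
  hit[1]
}

#' A/B compartment eigenvector
#'
#' Leading eigenvector of the per-chromosome Pearson correlation matrix of
#' the observed/expected map, the standard compartment readout. Invalid
#' bins are excluded before the correlation and re-inserted as missing. The
#' sign is oriented so the eigenvector correlates positively with GC
#' content (A = gene-rich/GC-rich). Chromosomes with fewer than `min_bins`
#' valid bins, or with a degenerate leading eigenvalue, or a constant O/E
#' (no compartment signal) return a missing track, flagged rather than given
#' an arbitrary sign.
#'
#' @param mat a [contact_matrix()] at compartment-calling resolution
#'   (200 kb in the reference analysis).
#' @param gc_track tibble with `chrom`, `start`, `end` and a `gc`/`value`
#'   column on the same bin grid.
#' @param min_bins minimum valid bins per chromosome.
#' @return tibble (`chrom`, `start`, `end`, `score`) with attribute
#'   `degenerate`: named logical per chromosome.
#' @export
compartment_eigenvector <- function(mat, gc_track, min_bins = 10) {
  oe <- observed_over_expected(mat)
  gc_col <- track_value_col(gc_track)
  out <- list(); degen <- logical(0)
  for (chrom in chromosomes(mat)) {
    rows <- chrom_bin_rows(mat, chrom)
    bins <- mat$bins[rows, ]
    score <- rep(NA_real_, nrow(bins))
    m <- oe_matrix(oe, chrom)
    valid <- which(colSums(is.finite(m)) > 0)
    is_degen <- FALSE
    if (length(valid) >= min_bins) {
      sub <- m[valid, valid, drop = FALSE]
      sds <- apply(sub, 2, stats::sd, na.rm = TRUE)
      if (all(!is.finite(sds)) || all(sds < 1e-12, na.rm = TRUE)) {
        is_degen <- TRUE
      } else {
        cm <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
        cm[!is.finite(cm)] <- 0
        eg <- eigen(cm, symmetric = TRUE)
        if (eg$values[1] <= 0 ||
            (length(eg$values) > 1 &&
             (eg$values[1] - eg$values[2]) <= 1e-9 * abs(eg$values[1]))) {
          is_degen <- TRUE
        } else {
          ev <- eg$vectors[, 1]
          gcv <- gc_track[[gc_col]][gc_track$chrom == chrom][valid]
          r <- suppressWarnings(stats::cor(ev, gcv, use = "complete.obs"))
          if (is.finite(r) && r < 0) ev <- -ev
          score[valid] <- ev
        }
      }
    } else {
      is_degen <- TRUE
    }
    if (is_degen) score[] <- NA_real_
    degen[chrom] <- is_degen
    out[[chrom]] <- tibble::tibble(chrom = chrom, start = bins$start,
                                   end = bins$end, score = score)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "degenerate") <- degen
  res
}

#' Insulation score
#'
#' For each bin, the mean balanced contact value inside the window x window
#' diamond crossing that bin, log2-normalised to the chromosome-wide mean
#' diamond value. Minima mark domain boundaries. Bins within one window of
#' a chromosome edge, and diamonds with no valid pixel, are missing.
#'
#' @param mat a [contact_matrix()] (25 kb in the reference analysis).
#' @param window diamond window in bp (1 Mb in the reference analysis);
#'   must be a multiple of the resolution.
#' @return tibble `chrom`, `start`, `end`, `score`.
#' @export
insulation_score <- function(mat, window = 1e6) {
  w <- window / mat$resolution
  if (abs(w - round(w)) > 1e-9) {
    pcg_abort("`window` must be a multiple of the matrix resolution")
  }
  w <- as.integer(round(w))
  out <- list()
  for (chrom in chromosomes(mat)) {
    rows <- chrom_bin_rows(mat, chrom)
    bins <- mat$bins[rows, ]
    n <- nrow(bins)
    dia <- rep(NA_real_, n)
    if (n > 2 * w) {
      m <- dense_chrom_matrix(mat, chrom, balanced = TRUE)
      for (i in (w + 1):(n - w)) {
        blk <- m[(i - w):(i - 1), (i + 1):(i + w)]
        if (any(is.finite(blk))) dia[i] <- mean(blk, na.rm = TRUE)
      }
    }
    mu <- mean(dia, na.rm = TRUE)
    score <- if (is.finite(mu) && mu > 0) log2(dia / mu) else rep(NA_real_, n)
    out[[chrom]] <- tibble::tibble(chrom = chrom, start = bins$start,
                                   end = bins$end, score = score)
  }
  dplyr::bind_rows(out)
}

#' Similarity of genome-wide score profiles across conditions
#'
#' Pearson correlation (pairwise-complete), average-linkage hierarchical
#' clustering on 1 - r, and the first two principal-axis coordinates of the
#' conditions, for a set of aligned score tracks (insulation profiles or
#' compartment eigenvectors per condition).
#'
#' @param tracks wide tibble: `chrom`, `start` (optionally `end`) plus one
#'   numeric column per condition, all on the same bin grid; or a named list
#'   of equal-length numeric vectors.
#' @return list with `correlation` (matrix), `order` (condition labels in
#'   dendrogram order), `coords` (tibble `track`, `PC1`, `PC2`), `hclust`.
#' @export
profile_similarity <- function(tracks) {
  if (is.data.frame(tracks)) {
    vals <- tracks[setdiff(names(tracks), c("chrom", "start", "end"))]
    X <- as.matrix(vals)
  } else if (is.list(tracks)) {
    lens <- lengths(tracks)
    if (length(unique(lens)) != 1) pcg_abort("tracks must share one bin grid")
    X <- do.call(cbind, tracks)
  } else pcg_abort("`tracks` must be a data frame or list of numeric vectors")
  if (ncol(X) < 2) pcg_abort("need at least 2 tracks")
  r <- stats::cor(X, use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  complete <- stats::complete.cases(X)
  pc <- stats::prcomp(t(X[complete, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  k <- min(2, ncol(pc$x))
  coords <- tibble::tibble(track = colnames(X),
                           PC1 = pc$x[, 1],
                           PC2 = if (k >= 2) pc$x[, 2] else 0)
  list(correlation = r, order = hc$labels[hc$order], coords = coords,
       hclust = hc)
}
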