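# Brute-force oracles, written independently of the package internals:
# everything here enumerates pixels/pairs explicitly from first principles.

# random small contact matrix: one or two chromosomes, Poisson counts with
# mild distance decay, a few invalid bins
toy_matrix <- function(n_bins = 20, n_chrom = 1, seed = 1, invalid_frac = 0.1,
                       res = 10e3) {
  set.seed(seed)
  bins <- do.call(rbind, lapply(seq_len(n_chrom), function(c) {
    data.frame(chrom = paste0("chr", c),
               start = (seq_len(n_bins) - 1) * res,
               end = seq_len(n_bins) * res,
               weight = ifelse(runif(n_bins) < invalid_frac, NA_real_, 1))
  }))
  px <- list()
  off <- 0L
  for (c in seq_len(n_chrom)) {
    for (i in 1:n_bins) for (j in i:n_bins) {
      lam <- 20 / (j - i + 1)
      cnt <- rpois(1, lam)
      if (cnt > 0) {
        px[[length(px) + 1L]] <- data.frame(bin1 = i + off, bin2 = j + off,
                                            count = cnt)
      }
    }
    off <- off + n_bins
  }
  contact_matrix(tibble::as_tibble(bins), dplyr::bind_rows(px), resolution = res)
}

# dense symmetric balanced matrix of one chromosome, by direct enumeration
oracle_dense <- function(mat, chrom) {
  rows <- which(mat$bins$chrom == chrom)
  n <- length(rows)
  off <- rows[1] - 1L
  m <- matrix(0, n, n)
  for (k in seq_len(nrow(mat$pixels))) {
    b1 <- mat$pixels$bin1[k]; b2 <- mat$pixels$bin2[k]
    if (b1 < rows[1] || b2 > rows[n]) next
    i <- b1 - off; j <- b2 - off
    v <- mat$pixels$count[k] * mat$bins$weight[b1] * mat$bins$weight[b2]
    m[i, j] <- v; m[j, i] <- v
  }
  bad <- which(!is.finite(mat$bins$weight[rows]))
  m[bad, ] <- NA; m[, bad] <- NA
  m
}

# expected profile by enumerating every pair at every offset
oracle_expected <- function(mat, chrom) {
  m <- oracle_dense(mat, chrom)
  n <- nrow(m)
  sapply(0:(n - 1), function(s) {
    vals <- sapply(1:(n - s), function(i) m[i, i + s])
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  })
}

oracle_oe <- function(mat, chrom) {
  m <- oracle_dense(mat, chrom)
  ev <- oracle_expected(mat, chrom)
  n <- nrow(m)
  out <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    e <- ev[abs(i - j) + 1]
    if (!is.na(e) && e != 0 && !is.na(m[i, j])) out[i, j] <- m[i, j] / e
  }
  out
}

# distal pileup by explicit pair enumeration and submatrix averaging
oracle_distal_pileup <- function(mat, regions, k, min_sep, max_sep = NULL,
                                 regions2 = NULL) {
  side <- 2 * k + 1
  acc <- matrix(0, side, side); sup <- matrix(0, side, side)
  for (chrom in unique(mat$bins$chrom)) {
    m <- oracle_oe(mat, chrom)
    n <- nrow(m)
    ra <- regions[regions$chrom == chrom, , drop = FALSE]
    mid_a <- floor((ra$start + ra$end) / 2)
    bin_a <- floor(mid_a / mat$resolution) + 1
    if (is.null(regions2)) {
      if (nrow(ra) < 2) next
      combos <- t(combn(seq_len(nrow(ra)), 2))
      p1 <- mid_a[combos[, 1]]; p2 <- mid_a[combos[, 2]]
      b1 <- bin_a[combos[, 1]]; b2 <- bin_a[combos[, 2]]
    } else {
      rb <- regions2[regions2$chrom == chrom, , drop = FALSE]
      if (!nrow(ra) || !nrow(rb)) next
      g <- expand.grid(a = seq_len(nrow(ra)), b = seq_len(nrow(rb)))
      mid_b <- floor((rb$start + rb$end) / 2)
      bin_b <- floor(mid_b / mat$resolution) + 1
      p1 <- mid_a[g$a]; p2 <- mid_b[g$b]
      b1 <- bin_a[g$a]; b2 <- bin_b[g$b]
    }
    for (q in seq_along(p1)) {
      sep <- abs(p2[q] - p1[q])
      if (sep < min_sep) next
      if (!is.null(max_sep) && sep >= max_sep) next
      if (b1[q] < 1 || b1[q] > n || b2[q] < 1 || b2[q] > n) next
      if (b1[q] == b2[q]) next
      lo <- min(b1[q], b2[q]); hi <- max(b1[q], b2[q])
      for (dr in -k:k) for (dc in -k:k) {
        i <- lo + dr; j <- hi + dc
        if (i < 1 || i > n || j < 1 || j > n) next
        v <- m[i, j]
        if (!is.na(v)) {
          acc[dr + k + 1, dc + k + 1] <- acc[dr + k + 1, dc + k + 1] + v
          sup[dr + k + 1, dc + k + 1] <- sup[dr + k + 1, dc + k + 1] + 1
        }
      }
    }
  }
  vals <- acc / sup
  vals[sup == 0] <- NA
  list(values = vals, support = sup)
}

# Mann-Whitney U null distribution by full enumeration of group assignments
oracle_u_pvalue <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_stat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- u_stat(seq_len(n_a))
  all_idx <- combn(length(pooled), n_a)
  us <- apply(all_idx, 2, u_stat)
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# small genome for generator tests
small_genome <- function(seed = 1, n_peaks = 15, chrom_len = 10e6, ...) {
  make_genome(genome_config(chrom_lengths = c(chrT = chrom_len),
                            n_peaks = n_peaks, n_ctcf = 30, n_cgi = 30,
                            n_genes = 30, seed = seed, ...))
}

random_regions <- function(mat, n, seed, width = 20e3) {
  set.seed(seed)
  cs <- dplyr::group_by(mat$bins, chrom) |>
    dplyr::summarise(len = max(end), .groups = "drop")
  chrom <- sample(cs$chrom, n, replace = TRUE)
  len <- cs$len[match(chrom, cs$chrom)]
  start <- floor(runif(n) * (len - width))
  tibble::tibble(chrom = chrom, start = start, end = start + width,
                 name = sprintf("r%02d", seq_len(n)))
}

# independent bilinear interpolation: explicit per-target-pixel 4-point
# weighting with NA renormalisation (same pixel-centre convention)
oracle_bilinear <- function(m, R) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, R, R)
  coord <- function(i, n_from) {
    x <- (i - 0.5) / R * n_from + 0.5
    min(max(x, 1), n_from)
  }
  for (ti in 1:R) for (tj in 1:R) {
    x <- coord(ti, nr); y <- coord(tj, nc)
    x0 <- min(floor(x), nr - ifelse(nr > 1, 1, 0)); x1 <- min(x0 + 1, nr)
    y0 <- min(floor(y), nc - ifelse(nc > 1, 1, 0)); y1 <- min(y0 + 1, nc)
    wx <- x - x0; wy <- y - y0
    pts <- rbind(c(m[x0, y0], (1 - wx) * (1 - wy)),
                 c(m[x1, y0], wx * (1 - wy)),
                 c(m[x0, y1], (1 - wx) * wy),
                 c(m[x1, y1], wx * wy))
    valid <- !is.na(pts[, 1])
    wsum <- sum(pts[valid, 2])
    if (wsum > 1e-12) out[ti, tj] <- sum(pts[valid, 1] * pts[valid, 2]) / wsum
  }
  out
}

# region-average surface of a rescaled local pileup, by direct enumeration
oracle_rescaled_raw <- function(mat, regions, R, pad, min_size = 10e3) {
  acc <- matrix(0, R, R); sup <- matrix(0, R, R)
  res <- mat$resolution
  for (chrom in unique(regions$chrom)) {
    m <- oracle_oe(mat, chrom)
    n <- nrow(m)
    rr <- regions[regions$chrom == chrom, , drop = FALSE]
    for (q in seq_len(nrow(rr))) {
      len <- rr$end[q] - rr$start[q]
      if (len < min_size) next
      ws <- rr$start[q] - pad * len; we <- rr$end[q] + pad * len
      if (ws < 0 || we > n * res) next
      b0 <- floor(ws / res) + 1; b1 <- ceiling(we / res)
      blk <- oracle_bilinear(m[b0:b1, b0:b1, drop = FALSE], R)
      fin <- !is.na(blk)
      acc[fin] <- acc[fin] + blk[fin]
      sup <- sup + fin
    }
  }
  out <- acc / sup
  out[sup == 0] <- NA
  out
}
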