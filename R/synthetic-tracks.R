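#' Simulate ChIP coverage tracks
#'
#' Per-factor bedGraph-style coverage: background Poisson counts in fixed
#' track bins plus peak-shaped enrichment proportional to the planted
#' occupancy times the condition's per-factor multiplier (attrited peaks are
#' further attenuated for the PRC1 factors under an attrition-carrying
#' profile). Integrating a track over a peak therefore recovers the planted
#' occupancy rank order.
#'
#' @param genome a [make_genome()] result.
#' @param profile a [condition_profile()].
#' @param track_bin track bin width in bp.
#' @param bg_rate expected background reads per track bin.
#' @param reads_per_occ expected peak reads per occupancy unit.
#' @param seed RNG seed.
#' @return named list (one element per ChIP factor) of track tibbles with
#'   `chrom`, `start`, `end`, `value` (read counts).
#' @export
simulate_chip_tracks <- function(genome, profile,
                                 track_bin = 1e3, bg_rate = 0.05,
                                 reads_per_occ = 200, seed = 1L) {
  if (!inherits(genome, "synthetic_genome")) pcg_abort("`genome` must be a synthetic_genome")
  factors <- chip_factors()
  prc1 <- c("RING1B", "MEL18", "CBX2")
  chroms <- genome$chromsizes$chrom
  lens <- genome$chromsizes$length
  att <- rep(1, nrow(genome$peaks))
  if (profile$attrition_frac > 0 && nrow(genome$peaks)) {
    att[genome$peaks$attrited] <- profile$attrition_mult
  }
  grid <- dplyr::bind_rows(lapply(seq_along(chroms), function(ci) {
    starts <- seq(0, lens[ci] - 1, by = track_bin)
    tibble::tibble(chrom = chroms[ci], start = starts,
                   end = pmin(starts + track_bin, lens[ci]))
  }))
  with_seed(seed, {
    out <- lapply(factors, function(f) {
      lam <- rep(bg_rate, nrow(grid))
      mult <- profile$occupancy_mult[[f]]
      if (nrow(genome$peaks) && mult > 0) {
        for (r in seq_len(nrow(genome$peaks))) {
          pk <- genome$peaks[r, ]
          sel <- which(grid$chrom == pk$chrom & grid$start < pk$end &
                         grid$end > pk$start)
          if (!length(sel)) next
          occ <- pk[[paste0("occ_", f)]]
          a <- if (f %in% prc1) att[r] else 1
          # enrichment spread uniformly over the peak's track bins
          lam[sel] <- lam[sel] + occ * mult * a * reads_per_occ / length(sel)
        }
      }
      grid$value <- stats::rpois(nrow(grid), lam)
      grid
    })
    names(out) <- factors
    out
  })
}

#' Simulate a differential expression table
#'
#' Replicate-level log2 expression values for each gene under WT and the
#' supplied condition. Planted de-repressed genes gain the profile's
#' `expression_effect` on the log2 scale in the perturbed condition; all
#' genes carry i.i.d. Gaussian replicate noise. Reports per-gene means, the
#' log2 ratio (condition/WT), a two-sample t-test p-value on the replicate
#' log2 values, and its Benjamini-Hochberg adjustment (`padj`), the quantity
#' the strict up-regulation rule thresholds.
#'
#' @param genome a [make_genome()] result.
#' @param profile a [condition_profile()].
#' @param n_reps replicates per condition.
#' @param noise_sd replicate noise standard deviation (log2 units).
#' @param seed RNG seed.
#' @return tibble: `gene`, `chrom`, `start`, `end`, `mean_wt`, `mean_cond`,
#'   `log2_ratio`, `pvalue`, `padj`, `planted_up`.
#' @export
simulate_expression <- function(genome, profile, n_reps = 3,
                                noise_sd = 0.4, seed = 1L) {
  if (!inherits(genome, "synthetic_genome")) pcg_abort("`genome` must be a synthetic_genome")
  genes <- genome$genes
  if (!nrow(genes)) pcg_abort("genome has no genes")
  with_seed(seed, {
    base <- genes$baseline_log2
    eff <- ifelse(genes$upregulated, profile$expression_effect, 0)
    wt <- matrix(stats::rnorm(nrow(genes) * n_reps, base, noise_sd),
                 nrow = nrow(genes))
    cond <- matrix(stats::rnorm(nrow(genes) * n_reps, base + eff, noise_sd),
                   nrow = nrow(genes))
    pv <- vapply(seq_len(nrow(genes)), function(i) {
      stats::t.test(cond[i, ], wt[i, ], var.equal = TRUE)$p.value
    }, numeric(1))
    tibble::tibble(
      gene = genes$name, chrom = genes$chrom,
      start = genes$start, end = genes$end,
      mean_wt = rowMeans(wt), mean_cond = rowMeans(cond),
      log2_ratio = rowMeans(cond) - rowMeans(wt),
      pvalue = pv, padj = stats::p.adjust(pv, "BH"),
      planted_up = genes$upregulated
    )
  })
}

#' Simulate DNA-FISH interprobe distances and foci counts
#'
#' Places each nucleus's probe signals in 3D using a random-walk polymer
#' law: the displacement between consecutive probes is isotropic Gaussian
#' with mean squared length proportional to (genomic separation)^(2 nu).
#' Probes overlapping Polycomb peaks are then contracted toward their
#' common centroid by the profile's `fish_contraction` factor (1 = no
#' attraction, as in the knockout), shortening Polycomb-pair distances.
#' Localisation noise is added per axis. The first three probes (genomic
#' order) yield the `d12`, `d13`, `d23` columns; the foci count is the
#' number of single-linkage clusters of all probe positions at the
#' colocalization threshold.
#'
#' @param genome a [make_genome()] result.
#' @param probes region table on a single chromosome; a logical `polycomb`
#'   column may mark Polycomb probes, otherwise overlap with the genome's
#'   peaks decides.
#' @param profile a [condition_profile()].
#' @param n_cells number of nuclei.
#' @param seed RNG seed.
#' @param nu polymer scaling exponent (0.5 = ideal random walk).
#' @param um_per_mb root-mean-square 3D distance (micrometres) between loci 1 Mb
#'   apart in the unconstrained polymer.
#' @param loc_noise localisation noise SD per axis (micrometres).
#' @param coloc_threshold single-linkage threshold for foci counting (micrometres).
#' @return tibble with one row per nucleus: `cell`, `condition`, `probe_set`,
#'   `d12`, `d13`, `d23` (micrometres; `NA` where fewer than 3 probes), `foci`,
#'   `area` (nuclear cross-section, square micrometres).
#' @export
simulate_fish <- function(genome, probes, profile, n_cells = 150, seed = 1L,
                          nu = 0.5, um_per_mb = 0.8, loc_noise = 0.05,
                          coloc_threshold = 0.2) {
  probes <- validate_regions(probes)
  if (nrow(probes) < 2) pcg_abort("need at least 2 probes")
  if (length(unique(probes$chrom)) != 1) pcg_abort("probes must lie on one chromosome")
  probes <- dplyr::arrange(probes, .data$start)
  if (!"polycomb" %in% names(probes)) {
    hits <- GenomicRanges::countOverlaps(regions_to_gr(probes),
                                         regions_to_gr(genome$peaks))
    probes$polycomb <- hits > 0
  }
  mid <- region_midpoint(probes)
  k <- nrow(probes)
  gamma <- profile$fish_contraction
  sd_step <- function(ds) sqrt(um_per_mb^2 / 3) * (ds / 1e6)^nu
  steps_sd <- sd_step(diff(mid))
  with_seed(seed, {
    res <- vector("list", n_cells)
    for (cell in seq_len(n_cells)) {
      pos <- matrix(0, k, 3)
      for (p in 2:k) {
        pos[p, ] <- pos[p - 1, ] + stats::rnorm(3, 0, steps_sd[p - 1])
      }
      pc <- which(probes$polycomb)
      if (length(pc) >= 2 && gamma < 1) {
        centroid <- colMeans(pos[pc, , drop = FALSE])
        pos[pc, ] <- sweep(sweep(pos[pc, , drop = FALSE], 2, centroid), 1,
                           rep(gamma, length(pc)), "*")
        pos[pc, ] <- sweep(pos[pc, , drop = FALSE], 2, centroid, "+")
      }
      pos <- pos + matrix(stats::rnorm(3 * k, 0, loc_noise), k, 3)
      d <- as.matrix(stats::dist(pos))
      foci <- if (k >= 2) {
        hc <- stats::hclust(stats::as.dist(d), method = "single")
        length(unique(stats::cutree(hc, h = coloc_threshold)))
      } else 1L
      res[[cell]] <- tibble::tibble(
        cell = cell,
        condition = profile$condition,
        probe_set = paste(probes$name %||% sprintf("p%d", seq_len(k)),
                          collapse = "+"),
        d12 = d[1, 2],
        d13 = if (k >= 3) d[1, 3] else NA_real_,
        d23 = if (k >= 3) d[2, 3] else NA_real_,
        foci = foci,
        area = stats::rlnorm(1, log(110), 0.15)
      )
    }
    dplyr::bind_rows(res)
  })
}
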