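#' Simulate a Hi-C contact matrix with planted architecture
#'
#' Generates a cis-only binned contact map whose expected intensity at bin
#' pair (i, j) is the product of independent structural factors:
#'
#' * power-law distance decay `(s + s0)^-alpha` (s in bins);
#' * a compartment checkerboard factor `1 + c` for same-sign compartment
#'   bins;
#' * a CTCF loop factor at planted convergent site pairs within the reach
#'   bound (identical in every condition);
#' * a Polycomb loop factor `1 + strength * loop_mult` at planted peak-pair
#'   anchor pixels, where `strength` is the product of the two regions'
#'   canonical-occupancy-driven loop propensities (attenuated at attrited
#'   peaks when the condition profile carries attrition);
#' * a domain factor over all bin pairs inside one extended peak,
#'   `1 + (domain_factor - 1) * domain_mult`.
#'
#' The map is scaled to the requested total depth and counts are drawn
#' Poisson; `noise_free = TRUE` returns the expected intensities themselves
#' (continuous "counts"), which makes planted factors exactly recoverable
#' through observed/expected pileups — the closed-form oracle used in tests.
#'
#' @param genome a [make_genome()] result.
#' @param profile a [condition_profile()].
#' @param depth total genome-wide contact count (split across chromosomes
#'   proportionally to length). Default 1e7 gives 5e6 contacts per default
#'   chromosome.
#' @param seed RNG seed for the Poisson draw.
#' @param noise_free return expected intensities instead of Poisson counts.
#' @param scale_to_depth scale intensities so the map total matches
#'   `depth` (default). Disable for closed-form tests where the raw product
#'   of generative factors must be preserved exactly.
#' @param components character subset of
#'   `c("decay", "compartments", "ctcf", "polycomb", "domains")`; factors not
#'   listed are disabled (their multiplier is identically 1).
#' @return a [contact_matrix()] whose `genome` label records the condition.
#' @export
simulate_contact_map <- function(genome, profile,
                                 depth = 1e7, seed = 1L,
                                 noise_free = FALSE, scale_to_depth = TRUE,
                                 components = c("decay", "compartments",
                                                "ctcf", "polycomb", "domains")) {
  if (!inherits(genome, "synthetic_genome")) pcg_abort("`genome` must be a synthetic_genome")
  if (!inherits(profile, "condition_profile")) pcg_abort("`profile` must be a condition_profile")
  stopifnot_scalar_number(depth, "depth", positive = TRUE)
  cfg <- genome$config
  truth <- genome$truth
  chroms <- genome$chromsizes$chrom
  lens <- genome$chromsizes$length
  comp_shift <- isTRUE(profile$compartment_shift)

  # per-peak attrition multiplier under this condition
  att <- rep(1, nrow(genome$peaks))
  if (profile$attrition_frac > 0 && nrow(genome$peaks)) {
    att[genome$peaks$attrited] <- profile$attrition_mult
  }

  if (cfg$compartment_strength <= -1) {
    pcg_abort("compartment strength must exceed -1",
              class = "pcgloop_config_error")
  }
  bins_list <- list(); px_list <- list()
  offset <- 0L
  with_seed(seed, {
    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      n <- as.integer(ceiling(lens[ci] / cfg$bin_size))

      f <- if ("decay" %in% components) {
        (0:(n - 1) + cfg$decay_s0)^(-cfg$decay_alpha)
      } else rep(1, n)

      a <- NULL
      if ("compartments" %in% components) {
        a <- truth$compartment$compartment[truth$compartment$chrom == chrom]
        if (comp_shift) a <- shift_compartment_to_A(a, genome, chrom)
      }

      # intensities stored per diagonal: lam[[s + 1]][i] is pixel (i, i + s)
      lam <- vector("list", n)
      for (s in 0:(n - 1)) {
        len <- n - s
        v <- rep(f[s + 1], len)
        if (!is.null(a)) {
          v <- v * (1 + cfg$compartment_strength *
                      (a[seq_len(len)] * a[(1 + s):n] > 0))
        }
        lam[[s + 1]] <- v
      }

      # point loops (CTCF + Polycomb) on anchor-midpoint pixels
      lp <- list()
      if ("ctcf" %in% components && nrow(truth$ctcf_loops)) {
        cl <- truth$ctcf_loops[truth$ctcf_loops$chrom == chrom, , drop = FALSE]
        if (nrow(cl)) {
          b1 <- pos_to_bin_local(region_midpoint(genome$ctcf_sites[cl$site1, ]),
                                 cfg$bin_size, n)
          b2 <- pos_to_bin_local(region_midpoint(genome$ctcf_sites[cl$site2, ]),
                                 cfg$bin_size, n)
          lp$ctcf <- tibble::tibble(b1 = b1, b2 = b2, fac = cl$factor)
        }
      }
      if ("polycomb" %in% components && nrow(truth$pcg_loops) &&
          profile$loop_mult > 0) {
        pl <- truth$pcg_loops[truth$pcg_loops$chrom == chrom, , drop = FALSE]
        if (nrow(pl)) {
          b1 <- pos_to_bin_local(region_midpoint(genome$peaks[pl$peak1, ]),
                                 cfg$bin_size, n)
          b2 <- pos_to_bin_local(region_midpoint(genome$peaks[pl$peak2, ]),
                                 cfg$bin_size, n)
          fac <- 1 + pl$strength * att[pl$peak1] * att[pl$peak2] *
            profile$loop_mult
          lp$pcg <- tibble::tibble(b1 = b1, b2 = b2, fac = fac)
        }
      }
      if (length(lp)) {
        loops <- dplyr::bind_rows(lp)
        ok <- !is.na(loops$b1) & !is.na(loops$b2) & loops$b1 != loops$b2
        loops <- loops[ok, , drop = FALSE]
        if (any(loops$fac < 0) || any(!is.finite(loops$fac))) {
          pcg_abort("expected intensity overflow or negative factor",
                    class = "pcgloop_config_error")
        }
        if (nrow(loops)) {
          lo <- pmin(loops$b1, loops$b2); hi <- pmax(loops$b1, loops$b2)
          s <- hi - lo
          # pixels hit by several loops take the product of factors
          key <- paste(s, lo)
          fac <- tapply(loops$fac, key, prod)
          ks <- as.integer(sub(" .*", "", names(fac)))
          kp <- as.integer(sub(".* ", "", names(fac)))
          for (q in seq_along(fac)) {
            lam[[ks[q] + 1L]][kp[q]] <- lam[[ks[q] + 1L]][kp[q]] * fac[q]
          }
        }
      }

      if ("domains" %in% components && nrow(genome$peaks) &&
          profile$domain_mult > 0) {
        pk <- genome$peaks[genome$peaks$chrom == chrom, , drop = FALSE]
        for (r in seq_len(nrow(pk))) {
          dfac <- 1 + (pk$domain_factor[r] - 1) * profile$domain_mult
          if (dfac == 1) next
          if (dfac < 0 || !is.finite(dfac)) {
            pcg_abort("expected intensity overflow or negative factor",
                      class = "pcgloop_config_error")
          }
          b0 <- floor(pk$start[r] / cfg$bin_size) + 1
          b1r <- min(ceiling(pk$end[r] / cfg$bin_size), n)
          for (s in 0:(b1r - b0)) {
            lam[[s + 1L]][b0:(b1r - s)] <-
              lam[[s + 1L]][b0:(b1r - s)] * dfac
          }
        }
      }

      sc <- 1
      if (scale_to_depth) {
        # scale the chromosome to its share of the requested depth
        target <- depth * lens[ci] / sum(lens)
        sc <- target / sum(vapply(lam, sum, numeric(1)))
      }

      ii <- vector("list", n); cc <- vector("list", n)
      for (s in 0:(n - 1)) {
        lv <- lam[[s + 1L]] * sc
        cnt <- if (noise_free) lv else stats::rpois(length(lv), lv)
        nz <- which(cnt > 0)
        ii[[s + 1L]] <- nz
        cc[[s + 1L]] <- cnt[nz]
      }
      i <- unlist(ii, use.names = FALSE)
      j <- i + rep.int(0:(n - 1), lengths(ii))
      px_list[[chrom]] <- tibble::tibble(bin1 = i + offset, bin2 = j + offset,
                                         count = as.numeric(unlist(cc, use.names = FALSE)))
      starts <- (seq_len(n) - 1) * cfg$bin_size
      wts <- ifelse(truth$invalid_bins[[chrom]][seq_len(n)], NA_real_, 1)
      bins_list[[chrom]] <- tibble::tibble(
        chrom = chrom, start = starts,
        end = pmin(starts + cfg$bin_size, lens[ci]),
        weight = wts)
      offset <- offset + n
    }
  })
  bins <- dplyr::bind_rows(bins_list)
  px <- dplyr::bind_rows(px_list)
  px <- dplyr::arrange(px, .data$bin1, .data$bin2)
  contact_matrix(bins, px, resolution = cfg$bin_size,
                 genome = profile$condition)
}

# local bin index of genomic positions, clipped to [1, n]
pos_to_bin_local <- function(pos, bin_size, n) {
  b <- floor(pos / bin_size) + 1
  b[b < 1 | b > n] <- NA
  as.integer(b)
}

# flip compartment blocks containing planted up-regulated genes to A (+1)
shift_compartment_to_A <- function(a, genome, chrom) {
  up <- genome$genes[genome$genes$name %in% genome$truth$upregulated_genes &
                       genome$genes$chrom == chrom, , drop = FALSE]
  if (!nrow(up)) return(a)
  bs <- genome$config$bin_size
  gb <- pos_to_bin_local(region_midpoint(up), bs, length(a))
  gb <- gb[!is.na(gb)]
  if (!length(gb)) return(a)
  # expand to whole same-sign blocks
  r <- rle(a)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (b in gb) {
    k <- which(starts <= b & ends >= b)
    a[starts[k]:ends[k]] <- 1
  }
  a
}
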