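test_that("generators are fully deterministic under a fixed seed", {
  cfg <- genome_config(chrom_lengths = c(chrT = 8e6), n_peaks = 10,
                       n_ctcf = 20, n_cgi = 20, n_genes = 20, seed = 42)
  g1 <- make_genome(cfg); g2 <- make_genome(cfg)
  expect_identical(g1$peaks, g2$peaks)
  expect_identical(g1$truth$pcg_loops, g2$truth$pcg_loops)
  expect_identical(g1$truth$compartment, g2$truth$compartment)
  m1 <- simulate_contact_map(g1, condition_profile("WT"), depth = 2e5, seed = 9)
  m2 <- simulate_contact_map(g2, condition_profile("WT"), depth = 2e5, seed = 9)
  expect_identical(m1$pixels, m2$pixels)
  f1 <- simulate_fish(g1, g1$peaks[1:3, ], condition_profile("WT"),
                      n_cells = 10, seed = 5)
  f2 <- simulate_fish(g2, g2$peaks[1:3, ], condition_profile("WT"),
                      n_cells = 10, seed = 5)
  expect_identical(f1, f2)
})

test_that("zero peaks give an empty peak set and no planted loops", {
  g <- make_genome(genome_config(chrom_lengths = c(chrT = 5e6), n_peaks = 0,
                                 n_ctcf = 10, n_cgi = 10, n_genes = 10,
                                 seed = 1))
  expect_equal(nrow(g$peaks), 0)
  expect_equal(nrow(g$truth$pcg_loops), 0)
})

test_that("occupancy quartiles match independently recomputed quantiles", {
  g <- make_genome(genome_config(n_peaks = 200, seed = 3))
  occ <- g$peaks$occ_RING1B
  strat <- stratify_quartiles(g$peaks, "occ_RING1B")
  ord <- order(occ)
  n <- length(occ)
  brute <- integer(n)
  bounds <- floor(n * (1:4) / 4); lo <- 1
  for (q in 1:4) { brute[ord[lo:bounds[q]]] <- q; lo <- bounds[q] + 1 }
  expect_equal(as.integer(strat$quartile), brute)
  # quartile boundaries agree with plain quantiles of the same sample
  qs <- quantile(occ, c(0.25, 0.5, 0.75))
  expect_true(all(occ[strat$quartile == "Q1"] <= qs[1] + 1e-9))
  expect_true(all(occ[strat$quartile == "Q4"] >= qs[3] - 1e-9))
})

test_that("peaks stay inside chromosomes and never overlap", {
  for (seed in 1:3) {
    g <- make_genome(genome_config(seed = seed))
    cs <- g$chromsizes
    expect_true(all(g$peaks$start >= 0))
    expect_true(all(g$peaks$end <= cs$length[match(g$peaks$chrom, cs$chrom)]))
    for (chrom in unique(g$peaks$chrom)) {
      p <- dplyr::arrange(g$peaks[g$peaks$chrom == chrom, ], start)
      if (nrow(p) > 1) expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
    }
  }
})

test_that("canonical subunits track RING1B occupancy more tightly than noncanonical", {
  g <- make_genome(genome_config(n_peaks = 200, seed = 8))
  r_can <- cor(log(g$peaks$occ_RING1B), log(g$peaks$occ_CBX2))
  r_non <- cor(log(g$peaks$occ_RING1B), log(g$peaks$occ_RYBP))
  expect_gt(r_can, r_non)
  expect_gt(r_can, 0.6)
})

test_that("an impossible feature load raises a placement error", {
  cfg <- genome_config(chrom_lengths = c(tiny = 120e3), n_peaks = 50,
                       n_ctcf = 0, n_cgi = 0, n_genes = 2, seed = 1)
  expect_error(make_genome(cfg), class = "pcgloop_placement_error")
})

test_that("a stated fraction of CGIs falls inside peaks", {
  g <- make_genome(genome_config(n_peaks = 100, n_cgi = 200,
                                 cgi_peak_frac = 0.4, seed = 5))
  gr_c <- GenomicRanges::GRanges(g$cgis$chrom,
                                 IRanges::IRanges(g$cgis$start + 1, g$cgis$end))
  gr_p <- GenomicRanges::GRanges(g$peaks$chrom,
                                 IRanges::IRanges(g$peaks$start + 1, g$peaks$end))
  frac <- mean(GenomicRanges::countOverlaps(gr_c, gr_p) > 0)
  expect_gt(frac, 0.3)
})

test_that("KO maps carry no Polycomb signal at planted anchors", {
  g <- small_genome(seed = 2, invalid_frac = 0)
  ko <- simulate_contact_map(g, condition_profile("KO"), seed = 3,
                             noise_free = TRUE, scale_to_depth = FALSE)
  p <- distal_pileup(ko, g$peaks, job = pileup_job(flank_bins = 2))
  expect_lt(abs(central_enrichment(p) - 1), 0.05)
})

test_that("noise-free decay-only map has O/E identically 1", {
  g <- small_genome(seed = 2, invalid_frac = 0)
  m <- simulate_contact_map(g, condition_profile("WT"), seed = 1,
                            noise_free = TRUE, scale_to_depth = FALSE,
                            components = "decay")
  oe <- oe_matrix(m, "chrT")
  expect_lt(max(abs(oe - 1), na.rm = TRUE), 1e-12)
})

test_that("KO and WT noise-free maps differ only at Polycomb-factor pixels", {
  g <- small_genome(seed = 6, n_peaks = 8, invalid_frac = 0)
  wt <- simulate_contact_map(g, condition_profile("WT"), seed = 1,
                             noise_free = TRUE, scale_to_depth = FALSE)
  ko <- simulate_contact_map(g, condition_profile("KO"), seed = 1,
                             noise_free = TRUE, scale_to_depth = FALSE)
  dw <- dense_chrom_matrix(wt, "chrT", balanced = FALSE)
  dk <- dense_chrom_matrix(ko, "chrT", balanced = FALSE)
  diff <- abs(dw - dk) > 1e-9
  # admissible pixels: loop anchors and domain blocks
  ok <- matrix(FALSE, nrow(dw), ncol(dw))
  res <- g$config$bin_size
  pl <- g$truth$pcg_loops
  b <- function(reg) floor(floor((reg$start + reg$end) / 2) / res) + 1
  for (k in seq_len(nrow(pl))) {
    i <- b(g$peaks[pl$peak1[k], ]); j <- b(g$peaks[pl$peak2[k], ])
    ok[i, j] <- TRUE; ok[j, i] <- TRUE
  }
  for (r in seq_len(nrow(g$peaks))) {
    b0 <- floor(g$peaks$start[r] / res) + 1
    b1 <- ceiling(g$peaks$end[r] / res)
    ok[b0:b1, b0:b1] <- TRUE
  }
  expect_true(all(ok[diff]))
})

test_that("ChIP signal recovers planted occupancy and scales linearly", {
  g <- make_genome(genome_config(n_peaks = 100, seed = 12))
  tr <- simulate_chip_tracks(g, condition_profile("WT"), seed = 4)
  pk <- quantify_signal(tr$RING1B, g$peaks, prefix = "RING1B")
  expect_gte(cor(pk$reads_RING1B, pk$occ_RING1B, method = "spearman"), 0.95)
  # KO RING1B track is background-only over peaks
  trk <- simulate_chip_tracks(g, condition_profile("KO"), seed = 4)
  pk_ko <- quantify_signal(trk$RING1B, g$peaks, prefix = "RING1B")
  bg_per_bp <- 0.05 / 1e3
  expect_lt(mean(pk_ko$reads_RING1B),
            3 * bg_per_bp * mean(pk_ko$end - pk_ko$start))
  # doubling the occupancy multiplier doubles expected peak-integrated signal
  prof2 <- condition_profile("custom",
                             occupancy_mult = c(RING1B = 2, H3K27me3 = 1,
                                                MEL18 = 1, CBX2 = 1,
                                                KDM2B = 1, RYBP = 1))
  reps1 <- rowMeans(sapply(1:6, function(s) {
    quantify_signal(simulate_chip_tracks(g, condition_profile("WT"),
                                         seed = s)$RING1B,
                    g$peaks, prefix = "x")$reads_x
  }))
  reps2 <- rowMeans(sapply(1:6, function(s) {
    quantify_signal(simulate_chip_tracks(g, prof2, seed = 100 + s)$RING1B,
                    g$peaks, prefix = "x")$reads_x
  }))
  fit <- lm(reps2 ~ reps1)
  expect_lt(abs(coef(fit)[2] - 2), 0.15)
})

test_that("expression simulation honours planted effects and the strict rule", {
  g <- make_genome(genome_config(n_peaks = 50, n_genes = 300,
                                 frac_upregulated = 0.1, seed = 7))
  # planted effect 2, low noise: every planted gene passes the strict rule
  ex <- simulate_expression(g, condition_profile("KO"), noise_sd = 0.1,
                            n_reps = 4, seed = 3)
  planted <- ex[ex$planted_up, ]
  expect_true(all(planted$log2_ratio >= 1 & planted$padj <= 0.01))
  # null effect: strict-rule hits are at most test-size rare
  ex0 <- simulate_expression(g, condition_profile("WT"), seed = 3)
  expect_lt(mean(ex0$log2_ratio >= 1 & ex0$padj <= 0.01), 0.02)
  # WT vs WT ratios are centred on zero
  expect_lt(abs(mean(ex0$log2_ratio)), 0.05)
})

test_that("FISH distances follow the polymer law and the planted attraction", {
  g <- small_genome(seed = 9, n_peaks = 6, chrom_len = 20e6)
  # attraction off: median distance grows with genomic separation
  probes <- tibble::tibble(chrom = "chrT",
                           start = c(1e6, 2e6, 5e6, 11e6),
                           end = c(1e6, 2e6, 5e6, 11e6) + 5e4,
                           name = paste0("p", 1:4), polycomb = FALSE)
  f <- simulate_fish(g, probes, condition_profile("KO"), n_cells = 400,
                     seed = 2)
  expect_lt(median(f$d12), median(f$d13))
  # extreme attraction collapses Polycomb probes to a single focus
  probes$polycomb <- TRUE
  prof <- condition_profile("custom", fish_contraction = 1e-4)
  fc <- simulate_fish(g, probes, prof, n_cells = 50, seed = 3, loc_noise = 0.001)
  expect_lt(median(fc$d12), 0.05)
  expect_true(all(fc$foci == 1))
  # WT vs KO difference detectable by rank-sum at n = 100
  p2 <- tibble::tibble(chrom = "chrT", start = c(3e6, 6e6), end = c(3.05e6, 6.05e6),
                       name = c("a", "b"), polycomb = TRUE)
  fw <- simulate_fish(g, p2, condition_profile("WT"), n_cells = 100, seed = 4)
  fk <- simulate_fish(g, p2, condition_profile("KO"), n_cells = 100, seed = 5)
  expect_gt(median(fk$d12) - median(fw$d12), 0.3)
  expect_lt(compare_distributions(fw$d12, fk$d12)$p.value, 0.01)
  expect_error(simulate_fish(g, p2[1, ], condition_profile("WT"), 10, 1),
               "at least 2")
})

test_that("truth is serialisable and reloadable bit-identically", {
  g <- small_genome(seed = 13)
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(g$truth$pcg_loops, tmp, digits = NA)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(tibble::as_tibble(back), g$truth$pcg_loops)
})
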