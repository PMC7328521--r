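test_that("ROI test is null-centred on a decay-only noise-free map", {
  g <- small_genome(seed = 3, n_peaks = 0, chrom_len = 15e6, invalid_frac = 0)
  m <- simulate_contact_map(g, condition_profile("WT"), seed = 1,
                            noise_free = TRUE, scale_to_depth = FALSE,
                            components = "decay")
  rt <- roi_permutation_test(m, list(chrom = "chrT", start = 5e6, end = 5.4e6),
                             n = 200, seed = 4)
  expect_lt(abs(rt$z), 1)       # observed equals every permutation up to ties
  expect_gt(rt$p, 0.1)
  # seed determinism
  rt2 <- roi_permutation_test(m, list(chrom = "chrT", start = 5e6, end = 5.4e6),
                              n = 200, seed = 4)
  expect_identical(tidy(rt), tidy(rt2))
})

test_that("a planted factor-3 domain ROI is significant against KO", {
  cfg <- genome_config(chrom_lengths = c(chrA = 25e6), n_peaks = 0, n_ctcf = 0,
                       n_cgi = 0, n_genes = 5, seed = 2)
  g <- make_genome(cfg)
  g$peaks <- tibble::tibble(chrom = "chrA", start = 10e6, end = 10.4e6,
                            name = "dom", domain_factor = 3, occ_RING1B = 1,
                            occ_H3K27me3 = 1, occ_MEL18 = 1, occ_CBX2 = 1,
                            occ_KDM2B = 1, occ_RYBP = 1, loop_propensity = 1,
                            attrited = FALSE)
  roi <- list(chrom = "chrA", start = 10e6, end = 10.4e6)
  wt <- simulate_contact_map(g, condition_profile("WT"), depth = 3e6, seed = 5)
  ko <- simulate_contact_map(g, condition_profile("KO"), depth = 3e6, seed = 6)
  p_wt <- roi_permutation_test(wt, roi, n = 1000, seed = 7)$p
  p_ko <- roi_permutation_test(ko, roi, n = 1000, seed = 7)$p
  expect_lte(p_wt, 0.01)
  expect_gt(p_ko, 0.05)
})

test_that("permutations are reduced with a warning on short chromosomes", {
  mat <- toy_matrix(n_bins = 40, seed = 11, invalid_frac = 0)
  roi <- list(chrom = "chr1", start = 50e3, end = 100e3)
  expect_warning(
    rt <- roi_permutation_test(mat, roi, n = 1000, seed = 1),
    "permutations"
  )
  expect_lt(rt$n_perm, 1000)
  expect_gt(rt$n_perm, 2)
  # an ROI too wide to translate without overlap errors out
  expect_error(
    roi_permutation_test(mat, list(chrom = "chr1", start = 50e3, end = 250e3),
                         n = 10, seed = 1),
    "too short")
})

test_that("loopability model is invariant to row duplication and warns on collinearity", {
  set.seed(9)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3)
  tbl <- tibble::tibble(
    enrichment1 = 1 + 0.5 * x[, 1] - 0.3 * x[, 2] + rnorm(n, 0, 0.2),
    reads_RING1B = 100 + 20 * x[, 1],
    reads_CBX2 = 50 + 10 * x[, 2],
    length = 2e4 + 5e3 * x[, 3]
  )
  fit1 <- fit_loopability_model(tbl, "enrichment1",
                                predictors = c("reads_RING1B", "reads_CBX2",
                                               "length"))
  fit2 <- fit_loopability_model(dplyr::bind_rows(tbl, tbl), "enrichment1",
                                predictors = c("reads_RING1B", "reads_CBX2",
                                               "length"))
  expect_equal(tidy(fit1)$estimate, tidy(fit2)$estimate, tolerance = 1e-10)
  expect_equal(glance(fit1)$r, cor(fitted(fit1$fit), fit1$fit$model$.y))
  # perfectly collinear predictor pair
  tbl$reads_MEL18 <- tbl$reads_RING1B * 2
  expect_warning(
    fit_loopability_model(tbl, "enrichment1",
                          predictors = c("reads_RING1B", "reads_MEL18",
                                         "length")),
    "collinear")
})

test_that("loopability filters drop non-positive enrichment and high RING1B", {
  tbl <- tibble::tibble(
    enrichment1_WT = c(1.2, -0.1, 2.0, 1.4, 1.1, 1.3, 1.2, 1.5, 0.9, 1.8),
    enrichment1_KO = c(1.0, 0.9, NA, 1.1, 0.8, 1.2, 0.7, 1.0, 1.1, 0.9),
    reads_RING1B = c(100, 200, 300, 1500, 120, 80, 90, 60, 200, 110),
    length = rnorm(10, 2e4, 5e2)
  )
  fit <- fit_loopability_model(tbl, "enrichment1_WT",
                               predictors = c("reads_RING1B", "length"))
  # drops: row 2 (negative WT), row 3 (NA KO), row 4 (>=1000 reads)
  expect_equal(fit$n, 7)
})

test_that("compaction sums match brute-force pixel enumeration", {
  mat <- toy_matrix(n_bins = 40, seed = 13)
  wins <- genome_windows(tibble::tibble(chrom = "chr1", length = 400e3),
                         width = 50e3)
  wins$grp <- rep(c("lo", "hi"), each = 4)
  cr <- compaction_by_occupancy(mat, wins, group_key = "grp")
  m <- oracle_oe(mat, "chr1")
  for (i in seq_len(nrow(wins))) {
    b0 <- wins$start[i] / 1e4 + 1; b1 <- wins$end[i] / 1e4
    ref <- 0; any_px <- FALSE
    for (a in b0:b1) for (b in b0:b1) {
      if (b - a >= 2 && !is.na(m[a, b])) { ref <- ref + m[a, b]; any_px <- TRUE }
    }
    if (any_px) {
      expect_equal(cr$window_scores$oe_sum[i], ref, tolerance = 1e-12)
    } else {
      expect_true(is.na(cr$window_scores$oe_sum[i]))
    }
  }
})

test_that("compaction is flat across groups on a decay-only map", {
  g <- small_genome(seed = 5, n_peaks = 0, chrom_len = 20e6, invalid_frac = 0)
  m <- simulate_contact_map(g, condition_profile("WT"), seed = 1,
                            noise_free = TRUE, scale_to_depth = FALSE,
                            components = "decay")
  wins <- genome_windows(g$chromsizes, width = 50e3)
  wins$grp <- rep_len(c("a", "b"), nrow(wins))
  cr <- compaction_by_occupancy(m, wins, group_key = "grp")
  gs <- cr$group_summary
  expect_lt(abs(gs$mean[1] - gs$mean[2]), 1e-9)
})

test_that("compartment-score change tracks planted expression coupling", {
  cfg <- genome_config(chrom_lengths = c(chrA = 60e6), n_peaks = 20,
                       n_ctcf = 0, n_cgi = 0, n_genes = 200,
                       frac_upregulated = 0.05, compartment_block = 1e6,
                       seed = 31, invalid_frac = 0)
  g <- make_genome(cfg)
  wt_prof <- condition_profile("WT")
  ko_prof <- condition_profile("KO", compartment_shift = TRUE)
  mk <- function(prof) {
    m <- simulate_contact_map(g, prof, seed = 3, noise_free = TRUE,
                              scale_to_depth = FALSE,
                              components = c("decay", "compartments"))
    coarsen_contacts(m, 5)   # 50-kb score resolution
  }
  gc50 <- g$truth$compartment |>
    dplyr::group_by(grp = start %/% 5e4) |>
    dplyr::summarise(chrom = chrom[1], start = min(start), end = max(end),
                     gc = mean(gc), .groups = "drop")
  ev_wt <- compartment_eigenvector(mk(wt_prof), gc50)
  ev_ko <- compartment_eigenvector(mk(ko_prof), gc50)
  ex <- simulate_expression(g, ko_prof, noise_sd = 0.1, n_reps = 4, seed = 5)
  res <- compartment_expression_association(ev_wt, ev_ko, g$genes, ex)
  up <- res$summary$mean_delta[res$summary$class == "up"]
  unchanged <- res$summary$mean_delta[res$summary$class == "unchanged"]
  expect_gt(up, unchanged)
  expect_lt(res$tests$p[res$tests$class_a == "unchanged" |
                          res$tests$class_b == "unchanged"][1], 0.05)
  # permuting the expression labels destroys the association
  set.seed(7)
  ex_perm <- ex
  ex_perm$gene <- sample(ex_perm$gene)
  res_p <- compartment_expression_association(ev_wt, ev_ko, g$genes, ex_perm)
  up_p <- res_p$summary$mean_delta[res_p$summary$class == "up"]
  expect_lt(abs(up_p), abs(up))
})

test_that("identical conditions give zero score change everywhere", {
  mat <- toy_matrix(n_bins = 30, seed = 17, invalid_frac = 0)
  sc <- tibble::tibble(chrom = "chr1", start = (0:29) * 1e4,
                       end = (1:30) * 1e4, score = rnorm(30))
  genes <- tibble::tibble(chrom = "chr1", start = c(5e4, 15e4),
                          end = c(6e4, 16e4), name = c("g1", "g2"))
  ex <- tibble::tibble(gene = c("g1", "g2"), log2_ratio = c(1.5, 0),
                       padj = c(0.001, 0.8))
  res <- compartment_expression_association(sc, sc, genes, ex)
  expect_true(all(res$gene_table$delta_score == 0))
})
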