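test_that("distal pileup equals brute-force submatrix averaging on random toys", {
  for (seed in 1:6) {
    mat <- toy_matrix(n_bins = 25, n_chrom = 2, seed = seed)
    regions <- random_regions(mat, 10, seed + 100)
    for (k in c(1, 3)) {
      job <- pileup_job(min_sep = 40e3, flank_bins = k)
      got <- distal_pileup(mat, regions, job = job)
      ref <- oracle_distal_pileup(mat, regions, k, min_sep = 40e3)
      expect_equal(got$values, ref$values, tolerance = 1e-12)
      expect_equal(got$support, ref$support, ignore_attr = TRUE)
    }
  }
})

test_that("two-set pileup equals brute force and respects separation bounds", {
  mat <- toy_matrix(n_bins = 30, n_chrom = 1, seed = 3)
  a <- random_regions(mat, 6, 11)
  b <- random_regions(mat, 5, 12)
  job <- pileup_job(min_sep = 50e3, max_sep = 200e3, flank_bins = 2)
  got <- distal_pileup(mat, a, regions2 = b, job = job)
  ref <- oracle_distal_pileup(mat, a, 2, 50e3, 200e3, regions2 = b)
  expect_equal(got$values, ref$values, tolerance = 1e-12)
})

test_that("pairs closer than the minimum separation contribute nothing", {
  mat <- toy_matrix(n_bins = 30, seed = 4, invalid_frac = 0)
  near <- tibble::tibble(chrom = "chr1", start = c(50e3, 100e3),
                         end = c(60e3, 110e3))
  p <- distal_pileup(mat, near, job = pileup_job(min_sep = 100e3))
  expect_equal(p$n_pairs, 0)
  expect_true(p$empty)
  expect_true(all(is.na(p$values)))
})

test_that("pileups are invariant to region order and depth rescaling", {
  mat <- toy_matrix(n_bins = 25, seed = 5)
  regions <- random_regions(mat, 8, 21)
  job <- pileup_job(min_sep = 30e3, flank_bins = 2)
  p1 <- distal_pileup(mat, regions, job = job)
  p2 <- distal_pileup(mat, regions[sample(nrow(regions)), ], job = job)
  expect_equal(p1$values, p2$values)
  mat2 <- mat; mat2$pixels$count <- mat2$pixels$count * 5
  p3 <- distal_pileup(mat2, regions, job = job)
  expect_equal(p1$values, p3$values, tolerance = 1e-12)
})

test_that("stratified pileups partition the unstratified pair count", {
  mat <- toy_matrix(n_bins = 40, seed = 6)
  regions <- random_regions(mat, 12, 31)
  strata <- list(c(30e3, 60e3), c(60e3, 120e3), c(120e3, 240e3))
  job <- pileup_job(flank_bins = 1)
  sp <- distance_stratified_pileups(mat, regions, strata, job)
  job_all <- pileup_job(min_sep = 30e3, max_sep = 240e3, flank_bins = 1)
  p_all <- distal_pileup(mat, regions, job = job_all)
  expect_equal(sum(vapply(sp, function(p) p$n_pairs, numeric(1))),
               p_all$n_pairs)
  expect_error(distance_stratified_pileups(mat, regions,
                                           list(c(0, 50e3), c(40e3, 100e3)),
                                           job),
               "disjoint")
})

test_that("orientation classification matches manual enumeration on a toy set", {
  mat <- toy_matrix(n_bins = 40, seed = 7, invalid_frac = 0)
  sites <- tibble::tibble(chrom = "chr1",
                          start = c(20e3, 90e3, 200e3, 310e3),
                          end = c(21e3, 91e3, 201e3, 311e3),
                          strand = c("+", "-", "+", "-"),
                          name = paste0("s", 1:4))
  job <- pileup_job(min_sep = 0, flank_bins = 1)
  # manual classes of ordered pairs (upstream, downstream):
  # (1,2)=+- conv, (1,3)=++ right, (1,4)=+- conv, (2,3)=-+ div,
  # (2,4)=-- left, (3,4)=+- conv
  n_of <- function(cls) oriented_pair_pileup(mat, sites, cls, job)$n_pairs
  expect_equal(n_of("convergent"), 3)
  expect_equal(n_of("divergent"), 1)
  expect_equal(n_of("left-facing"), 1)
  expect_equal(n_of("right-facing"), 1)
  # all-plus strands leave the convergent class empty
  sites$strand <- "+"
  p <- oriented_pair_pileup(mat, sites, "convergent", job)
  expect_equal(p$n_pairs, 0)
  expect_true(p$empty)
  sites$strand <- NULL
  expect_error(oriented_pair_pileup(mat, sites, "convergent", job),
               class = "pcgloop_format_error")
})

test_that("loopability equals the mean planted pair factor on noise-free maps", {
  g <- small_genome(seed = 21, n_peaks = 10, invalid_frac = 0)
  m <- simulate_contact_map(g, condition_profile("WT"), seed = 1,
                            noise_free = TRUE, scale_to_depth = FALSE,
                            components = c("decay", "polycomb"))
  ref_oe <- observed_over_expected(
    m, compute_expected(simulate_contact_map(g, condition_profile("WT"),
                                             seed = 1, noise_free = TRUE,
                                             scale_to_depth = FALSE,
                                             components = "decay")))
  job <- pileup_job(min_sep = 100e3)
  lb <- loopability_by_window(m, g$peaks, job, oe = ref_oe)
  mid <- region_midpoint(g$peaks)
  for (r in seq_len(nrow(g$peaks))) {
    sep <- abs(mid - mid[r])
    partners <- which(seq_along(mid) != r & sep >= 100e3)
    pl <- g$truth$pcg_loops
    fac <- vapply(partners, function(q) {
      hit <- (pl$peak1 == r & pl$peak2 == q) | (pl$peak1 == q & pl$peak2 == r)
      1 + pl$strength[hit]
    }, numeric(1))
    expect_equal(lb$enrichment1[r], mean(fac), tolerance = 1e-9)
  }
  # permuting region order leaves each region's value unchanged
  perm <- sample(nrow(g$peaks))
  lb2 <- loopability_by_window(m, g$peaks[perm, ], job, oe = ref_oe)
  expect_equal(lb2$enrichment1[match(lb$name, lb2$name)], lb$enrichment1)
})

test_that("regions with no eligible partner get a missing loopability", {
  mat <- toy_matrix(n_bins = 30, seed = 8, invalid_frac = 0)
  regions <- tibble::tibble(chrom = "chr1", start = c(50e3, 90e3),
                            end = c(60e3, 100e3), name = c("a", "b"))
  lb <- loopability_by_window(mat, regions, pileup_job(min_sep = 100e3))
  expect_true(all(is.na(lb$enrichment1)))
  expect_true(all(lb$n_partners == 0))
})

test_that("central enrichment blocks match direct pixel means", {
  p <- structure(list(values = matrix(as.numeric(1:25), 5, 5),
                      support = matrix(1, 5, 5), mode = "expected",
                      job = pileup_job(), n_pairs = 1, rescaled = FALSE,
                      condition = NA, resolution = 1e4),
                 class = "hic_pileup")
  expect_equal(central_enrichment(p), p$values[3, 3])
  expect_equal(central_enrichment(p, k = 3), mean(p$values[2:4, 2:4]))
  p_resc <- p; p_resc$rescaled <- TRUE
  expect_error(central_enrichment(p_resc), "rescaled")
})

test_that("all-ones pileup has unit central enrichment", {
  mat <- toy_matrix(n_bins = 20, seed = 9, invalid_frac = 0)
  g <- small_genome(seed = 2, n_peaks = 6, invalid_frac = 0)
  m <- simulate_contact_map(g, condition_profile("WT"), seed = 1,
                            noise_free = TRUE, scale_to_depth = FALSE,
                            components = "decay")
  p <- distal_pileup(m, g$peaks, job = pileup_job(flank_bins = 2))
  expect_equal(central_enrichment(p), 1, tolerance = 1e-12)
  expect_true(all(abs(p$values - 1) < 1e-12, na.rm = TRUE))
})

test_that("duplicated regions contribute identically to rescaled pileups", {
  g <- small_genome(seed = 31, n_peaks = 4, chrom_len = 20e6,
                    invalid_frac = 0, peak_len_min = 100e3,
                    peak_len_meanlog = log(150e3), peak_len_max = 300e3)
  m <- simulate_contact_map(g, condition_profile("WT"), seed = 2,
                            noise_free = TRUE, scale_to_depth = FALSE,
                            components = c("decay", "domains"))
  job <- pileup_job(seed = 4)
  p1 <- rescaled_local_pileup(m, g$peaks[1, ], job)
  p2 <- rescaled_local_pileup(m, g$peaks[c(1, 1), ], job)
  expect_equal(p2$raw, p1$raw, tolerance = 1e-12)
  expect_equal(p2$n_pairs, 2)
})

test_that("rescaled pileups skip undersized and edge-hugging regions", {
  mat <- toy_matrix(n_bins = 50, seed = 10, invalid_frac = 0)
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(5e3, 10e3, 200e3),
                            end = c(9e3, 120e3, 260e3),
                            name = c("tiny", "edge", "ok"))
  p <- rescaled_local_pileup(mat, regions, pileup_job(seed = 1, n_shifts = 2))
  expect_equal(p$n_pairs, 1)
  expect_setequal(p$skipped, c("tiny", "edge"))
})
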