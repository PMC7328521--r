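test_that("peak merging follows the strict <5 kb gap rule", {
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(0, 4500, 20000, 25000),
                          end = c(1000, 5000, 24000, 26000))
  m <- merge_peaks(peaks, gap = 5000)
  # gap 3500 merges the first two; gap exactly... 20000 to 24000 then 25000:
  # gap 1000 merges the last two
  expect_equal(m$start, c(0, 20000))
  expect_equal(m$end, c(5000, 26000))
  # gap of exactly 5000 stays unmerged
  exact <- tibble::tibble(chrom = "c", start = c(0, 6000), end = c(1000, 7000))
  expect_equal(nrow(merge_peaks(exact, gap = 5000)), 2)
  just_under <- tibble::tibble(chrom = "c", start = c(0, 5999),
                               end = c(1000, 7000))
  expect_equal(nrow(merge_peaks(just_under, gap = 5000)), 1)
  expect_error(merge_peaks(tibble::tibble(chrom = "c", start = 10, end = 10)),
               class = "pcgloop_format_error")
})

test_that("random interval sets merge identically to a brute-force scan", {
  set.seed(14)
  for (rep in 1:3) {
    start <- sort(sample(0:200, 100)) * 1000
    peaks <- tibble::tibble(chrom = sample(c("a", "b"), 100, replace = TRUE),
                            start = start, end = start + sample(500:8000, 100))
    peaks <- peaks[order(peaks$chrom, peaks$start), ]
    m <- merge_peaks(peaks, gap = 5000)
    # brute force: sweep sorted intervals per chromosome
    ref <- list()
    for (ch in unique(peaks$chrom)) {
      p <- peaks[peaks$chrom == ch, ]
      cur_s <- p$start[1]; cur_e <- p$end[1]
      for (i in seq_len(nrow(p))[-1]) {
        if (p$start[i] - cur_e < 5000) {
          cur_e <- max(cur_e, p$end[i])
        } else {
          ref[[length(ref) + 1]] <- c(ch, cur_s, cur_e)
          cur_s <- p$start[i]; cur_e <- p$end[i]
        }
      }
      ref[[length(ref) + 1]] <- c(ch, cur_s, cur_e)
    }
    ref <- as.data.frame(do.call(rbind, ref), stringsAsFactors = FALSE)
    expect_equal(m$start, as.numeric(ref$V2))
    expect_equal(m$end, as.numeric(ref$V3))
  }
})

test_that("signal quantitation pro-rates partial bins exactly", {
  track <- tibble::tibble(chrom = "c", start = seq(0, 900, 100),
                          end = seq(100, 1000, 100), value = 1:10)
  # zero track
  z <- track; z$value <- 0
  r0 <- quantify_signal(z, tibble::tibble(chrom = "c", start = 100, end = 500))
  expect_equal(r0$reads, 0); expect_equal(r0$rpkm, 0)
  # uniform value v per bin over whole bins
  u <- track; u$value <- 4
  r1 <- quantify_signal(u, tibble::tibble(chrom = "c", start = 200, end = 600),
                        total_reads = 40)
  expect_equal(r1$reads, 16)
  expect_equal(r1$rpkm, 16 * 1e9 / (400 * 40))
  # partial-bin region vs bp-level brute force
  reg <- tibble::tibble(chrom = "c", start = 250, end = 730)
  r2 <- quantify_signal(track, reg)
  bp <- rep(track$value / 100, each = 100)   # per-bp signal
  expect_equal(r2$reads, sum(bp[251:730]), tolerance = 1e-12)
  expect_error(quantify_signal(track, tibble::tibble(chrom = "zz", start = 0,
                                                     end = 10)),
               class = "pcgloop_format_error")
})

test_that("RPKM is invariant to proportional depth scaling", {
  track <- tibble::tibble(chrom = "c", start = seq(0, 900, 100),
                          end = seq(100, 1000, 100), value = rpois(10, 20))
  reg <- tibble::tibble(chrom = "c", start = 100, end = 800)
  a <- quantify_signal(track, reg)
  track2 <- track; track2$value <- track2$value * 13
  b <- quantify_signal(track2, reg)
  expect_equal(a$rpkm, b$rpkm, tolerance = 1e-12)
})

test_that("quartile stratification matches sort-and-split and flags ties", {
  reg <- tibble::tibble(chrom = "c", start = (0:7) * 100, end = (1:8) * 100,
                        v = c(3, 1, 4, 1.5, 5, 9, 2.6, 7))
  s <- stratify_quartiles(reg, "v")
  expect_equal(as.character(s$quartile[order(s$v)]),
               rep(paste0("Q", 1:4), each = 2))
  expect_equal(sort(s$v[s$quartile == "Q4"]), c(7, 9))
  expect_true(all(table(s$quartile) == 2))
  flat <- reg; flat$v <- 1
  expect_true(isTRUE(attr(stratify_quartiles(flat, "v"), "degenerate")))
  expect_error(stratify_quartiles(reg[1:3, ], "v"), "at least 4")
})

test_that("ratio stratification matches brute-force ratio ordering", {
  set.seed(5)
  reg <- tibble::tibble(chrom = "c", start = (0:19) * 1000,
                        end = (1:20) * 1000,
                        num = rpois(20, 30), den = rpois(20, 30))
  rs <- ratio_stratify(reg, "num", "den", pseudocount = 1)
  ratio <- (reg$num + 1) / (reg$den + 1)
  expect_equal(rs$ratio, ratio)
  ord <- order(ratio)
  expect_equal(as.character(rs$quartile[ord]), rep(paste0("Q", 1:4), each = 5))
  same <- reg; same$num <- same$den
  expect_true(isTRUE(attr(ratio_stratify(same, "num", "den"), "degenerate")))
  neg <- reg; neg$num[1] <- -1
  expect_error(ratio_stratify(neg, "num", "den"), "negative")
})

test_that("CGI classification partitions and matches a pairwise overlap scan", {
  set.seed(6)
  cgis <- tibble::tibble(chrom = "c", start = (0:49) * 2000,
                         end = (0:49) * 2000 + 800,
                         name = sprintf("cgi%02d", 0:49))
  peaks <- tibble::tibble(chrom = "c", start = c(1500, 10100, 50200, 80000),
                          end = c(4200, 12000, 55000, 80500))
  k27 <- tibble::tibble(chrom = "c", start = c(1500, 50200),
                        end = c(4200, 55000))
  cls <- classify_cgis(cgis, peaks, k27)
  expect_equal(nrow(cls$negative) + nrow(cls$positive), nrow(cls$all))
  expect_true(all(cls$double_positive$name %in% cls$positive$name))
  # brute force overlap (>= 1 bp)
  ov <- function(a, b) any(a$start < b$end & b$start < a$end)
  for (i in seq_len(nrow(cgis))) {
    hit_p <- any(cgis$start[i] < peaks$end & peaks$start < cgis$end[i])
    expect_equal(cgis$name[i] %in% cls$positive$name, hit_p)
    hit_k <- any(cgis$start[i] < k27$end & k27$start < cgis$end[i])
    expect_equal(cgis$name[i] %in% cls$double_positive$name, hit_p && hit_k)
  }
})

test_that("genome windows tile with truncation and group by signal percentile", {
  cs <- tibble::tibble(chrom = c("a", "b"), length = c(100e3, 60e3))
  w <- genome_windows(cs, width = 25e3)
  expect_equal(sum(w$chrom == "a"), 4)
  expect_equal(sum(w$chrom == "b"), 3)
  expect_equal(w$end[w$chrom == "b"][3], 60e3)
  # percentile grouping matches quantile computation over nonzero windows
  set.seed(8)
  w$sig <- c(0, 0, rpois(5, 50))
  pg <- percentile_group(w, "sig", edges = c(50))
  expect_true(all(pg$percentile_group[pg$sig == 0] == "zero"))
  med <- quantile(w$sig[w$sig > 0], 0.5)
  nz <- pg[pg$sig > 0, ]
  expect_true(all((nz$sig <= med) == (nz$percentile_group == "P0-50")))
})

test_that("expression-based peak classification follows both distance rules", {
  genes <- tibble::tibble(chrom = "c",
                          start = c(100e3, 500e3, 900e3),
                          end = c(105e3, 505e3, 905e3),
                          strand = c("+", "+", "-"),
                          name = c("strictA", "relaxedB", "quietC"))
  expression <- tibble::tibble(gene = c("strictA", "relaxedB", "quietC"),
                               log2_ratio = c(1.6, 0.7, 0.0),
                               padj = c(0.001, 0.2, 0.9))
  peaks <- tibble::tibble(chrom = "c",
                          start = c(110e3, 650e3, 430e3),
                          end = c(120e3, 660e3, 440e3),
                          name = c("near_strict", "far_from_up", "near_relaxed"))
  cls <- classify_peaks_by_expression(peaks, genes, expression)
  # peak 10 kb from a strict-up TSS
  expect_equal(cls$expression_class[1], "upregulated-proximal")
  # peak 145 kb from the relaxed-up TSS and farther from everything else
  expect_equal(cls$expression_class[2], "not-upregulated-distant")
  # peak 60 kb from relaxed gene: neither rule
  expect_equal(cls$expression_class[3], "other")
  # brute-force distances agree
  tss <- c(100e3, 500e3, 905e3)
  d <- abs(outer(tss, (peaks$start + peaks$end) / 2, "-"))
  expect_error(classify_peaks_by_expression(peaks, genes[0, ], expression),
               "empty gene set")
})
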