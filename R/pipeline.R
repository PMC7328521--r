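#' Run the full synthetic analysis pipeline
#'
#' Generates a synthetic genome under three conditions (WT, I53A, KO),
#' simulates Hi-C maps, ChIP tracks, expression and FISH tables, runs the
#' package's analyses — distal and oriented pileups, per-region
#' loopability with the occupancy linear model, local compaction by
#' occupancy percentile, compartment eigenvector and insulation tracks,
#' an ROI permutation test on the strongest planted domain, and the FISH
#' clustering statistics — and writes every output as TSV/BED/bedGraph/JSON
#' under `out_dir`. All randomness derives from `seed`, so two runs with
#' the same seed produce byte-identical outputs.
#'
#' @param out_dir output directory (created).
#' @param seed master seed; every generator seed is derived from it.
#' @param config optional [genome_config()]; default uses the standard
#'   two-chromosome synthetic genome with the seed derived from `seed`.
#' @param depth total Hi-C contacts per condition map.
#' @param n_cells FISH nuclei per condition.
#' @param n_perm permutations for the ROI test.
#' @param write_matrices write the (large) contact-matrix COO directories.
#' @return invisibly, a list with the genome, matrices, analysis summaries
#'   and output paths.
#' @export
run_polycomb_pipeline <- function(out_dir, seed = 1L, config = NULL,
                                  depth = 1e7, n_cells = 150, n_perm = 1000,
                                  write_matrices = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- genome_config(seed = child_seed(seed, "genome"))
  genome <- make_genome(config)

  ## ---- feature tables
  write_chromsizes(genome$chromsizes, file.path(out_dir, "chrom.sizes"))
  write_regions(genome$peaks, file.path(out_dir, "peaks.bed"))
  write_regions(genome$ctcf_sites, file.path(out_dir, "ctcf_sites.bed"))
  write_regions(genome$cgis, file.path(out_dir, "cgis.bed"))
  write_regions(genome$genes, file.path(out_dir, "genes.bed"))
  truth_json <- list(
    loopability_weights = as.list(genome$truth$loopability_weights),
    upregulated_genes = genome$truth$upregulated_genes,
    n_pcg_loops = nrow(genome$truth$pcg_loops),
    n_ctcf_loops = nrow(genome$truth$ctcf_loops)
  )
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  conditions <- c("WT", "I53A", "KO")
  analysis <- list()
  mats <- list(); oes <- list()

  ## ---- simulate maps and condition-level outputs
  for (cond in conditions) {
    prof <- condition_profile(cond)
    mat <- simulate_contact_map(genome, prof, depth = depth,
                                seed = child_seed(seed, paste0("hic_", cond)))
    mats[[cond]] <- mat
    oes[[cond]] <- observed_over_expected(mat)
    if (write_matrices) {
      write_contacts(mat, file.path(out_dir, paste0("contacts_", cond)))
    }
    write_table_tsv(compute_expected(mat),
                    file.path(out_dir, paste0("expected_", cond, ".tsv")))
  }

  ## ---- ChIP quantitation on merged peaks (WT tracks)
  tracks <- simulate_chip_tracks(genome, condition_profile("WT"),
                                 seed = child_seed(seed, "chip"))
  write_track(tracks$RING1B, file.path(out_dir, "RING1B_WT.bedgraph"))
  merged <- merge_peaks(genome$peaks, gap = 5000)
  for (f in chip_factors()) {
    merged <- quantify_signal(tracks[[f]], merged, prefix = f)
  }

  ## ---- loopability per condition + linear models
  job <- pileup_job(seed = child_seed(seed, "pileup"))
  loop_tbl <- merged
  for (cond in conditions) {
    lb <- loopability_by_window(mats[[cond]], merged, job, oe = oes[[cond]])
    loop_tbl[[paste0("enrichment1_", cond)]] <- lb$enrichment1
    write_table_tsv(lb, file.path(out_dir, paste0("loopability_", cond, ".tsv")))
  }
  write_table_tsv(loop_tbl, file.path(out_dir, "loopability_table.tsv"))
  models <- lapply(conditions, function(cond) {
    fit_loopability_model(loop_tbl, paste0("enrichment1_", cond))
  })
  names(models) <- conditions
  analysis$loopability_model <- lapply(models, function(m) {
    list(r = m$r, n = m$n,
         coefficients = stats::setNames(as.list(m$coefficients$estimate),
                                        m$coefficients$term))
  })

  ## ---- Polycomb distal pileups (peak-pair central enrichment)
  analysis$polycomb_central <- lapply(conditions, function(cond) {
    central_enrichment(distal_pileup(mats[[cond]], genome$peaks, job = job,
                                     oe = oes[[cond]]))
  })
  names(analysis$polycomb_central) <- conditions

  ## ---- CTCF orientation classes on the WT map
  analysis$ctcf_oriented <- lapply(
    c(convergent = "convergent", divergent = "divergent"),
    function(cls) {
      jc <- job; jc$max_sep <- 1.6e6
      central_enrichment(oriented_pair_pileup(mats$WT, genome$ctcf_sites, cls,
                                              jc, oe = oes$WT))
    })

  ## ---- compaction by occupancy (50-kb windows at 10-kb bins)
  win_width <- 5 * config$bin_size
  wins <- genome_windows(genome$chromsizes, width = win_width)
  wins <- quantify_signal(tracks$RING1B, wins, prefix = "RING1B")
  wins <- percentile_group(wins, "reads_RING1B")
  for (cond in conditions) {
    comp <- compaction_by_occupancy(mats[[cond]], wins, oe = oes[[cond]])
    write_table_tsv(comp$group_summary,
                    file.path(out_dir, paste0("compaction_", cond, ".tsv")))
    analysis$compaction[[cond]] <- comp$group_summary
  }

  ## ---- compartments and insulation
  gc200 <- genome$truth$compartment %>%
    dplyr::group_by(.data$chrom, grp = (.data$start %/% 200e3)) %>%
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     gc = mean(.data$gc), .groups = "drop") %>%
    dplyr::arrange(.data$chrom, .data$start)
  for (cond in conditions) {
    m200 <- coarsen_contacts(mats[[cond]], 200e3 / config$bin_size)
    ev <- compartment_eigenvector(m200, gc200)
    ev_out <- ev; names(ev_out)[names(ev_out) == "score"] <- "value"
    ev_out$value[!is.finite(ev_out$value)] <- 0
    write_track(ev_out, file.path(out_dir, paste0("eigenvector_", cond, ".bedgraph")))
    ins <- insulation_score(coarsen_contacts(mats[[cond]], 5), window = 1e6)
    ins_out <- ins; names(ins_out)[names(ins_out) == "score"] <- "value"
    ins_out$value[!is.finite(ins_out$value)] <- 0
    write_track(ins_out, file.path(out_dir, paste0("insulation_", cond, ".bedgraph")))
    analysis$eigenvector_planted_r[[cond]] <- {
      planted <- genome$truth$compartment %>%
        dplyr::group_by(.data$chrom, grp = (.data$start %/% 200e3)) %>%
        dplyr::summarise(comp = mean(.data$compartment), .groups = "drop") %>%
        dplyr::arrange(.data$chrom, .data$grp)
      suppressWarnings(abs(stats::cor(ev$score, planted$comp,
                                      use = "complete.obs")))
    }
  }

  ## ---- ROI permutation test on the largest planted domain (WT vs KO)
  big <- genome$peaks[which.max(genome$peaks$end - genome$peaks$start), ]
  roi <- list(chrom = big$chrom, start = big$start, end = big$end)
  analysis$roi_test <- lapply(mats[c("WT", "KO")], function(m) {
    as.list(tidy(roi_permutation_test(m, roi, n = n_perm,
                                      seed = child_seed(seed, "roi"))))
  })

  ## ---- expression and peak classification
  expr <- simulate_expression(genome, condition_profile("KO"),
                              seed = child_seed(seed, "expr"))
  write_table_tsv(expr, file.path(out_dir, "expression_KO_vs_WT.tsv"))
  pk_cls <- classify_peaks_by_expression(genome$peaks, genome$genes, expr)
  analysis$peak_expression_classes <- as.list(table(pk_cls$expression_class))

  ## ---- FISH
  pc_idx <- which(genome$peaks$chrom == genome$chromsizes$chrom[1])
  fish <- NULL
  if (length(pc_idx) >= 3) {
    # probe the tightest consecutive peak triple: clustering categories are
    # informative at the 1-3 Mb scale
    pos <- sort(region_midpoint(genome$peaks[pc_idx, ]))
    spans <- pos[3:length(pos)] - pos[1:(length(pos) - 2)]
    k <- which.min(spans)
    sel <- pc_idx[order(region_midpoint(genome$peaks[pc_idx, ]))][k:(k + 2)]
    probes <- genome$peaks[sel, c("chrom", "start", "end", "name")]
    fish_tabs <- lapply(conditions, function(cond) {
      simulate_fish(genome, probes, condition_profile(cond), n_cells = n_cells,
                    seed = child_seed(seed, paste0("fish_", cond)))
    })
    fish <- dplyr::bind_rows(fish_tabs)
    write_table_tsv(fish, file.path(out_dir, "fish_distances.tsv"))
    cats <- lapply(split(fish, fish$condition), function(df) {
      triple_clustering_classify(df$d12, df$d13, df$d23)
    })
    ct <- clustering_contingency_test(cats[c("WT", "KO")])
    analysis$fish <- list(
      chi_square = ct$statistic, p = ct$p,
      coloc_WT = colocalization_fraction(fish$d12[fish$condition == "WT"])$fraction,
      coloc_KO = colocalization_fraction(fish$d12[fish$condition == "KO"])$fraction,
      rank_sum_p = compare_distributions(
        fish$d12[fish$condition == "WT"],
        fish$d12[fish$condition == "KO"])$p.value
    )
  }

  jsonlite::write_json(analysis, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(out_dir, seed,
                   params = list(depth = depth, n_cells = n_cells,
                                 n_perm = n_perm,
                                 bin_size = config$bin_size,
                                 n_peaks = config$n_peaks))
  invisible(list(genome = genome, matrices = mats, analysis = analysis,
                 out_dir = out_dir, fish = fish,
                 loopability = loop_tbl, models = models))
}
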