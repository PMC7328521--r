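#' Synthetic genome configuration
#'
#' Parameters of the synthetic genome on which every analysis in the package
#' can be exercised with known ground truth. Defaults describe a desk-scale
#' genome — two 50-Mb chromosomes binned at 10 kb — that still spans the
#' distance range over which Polycomb loops are observed (tens of Mb) while
#' keeping contact matrices tractable.
#'
#' Peak occupancies are log-normal; canonical PRC1 subunits (MEL18, CBX2)
#' correlate with RING1B more strongly than noncanonical ones (KDM2B, RYBP),
#' reflecting the composition of the complexes that co-occupy Polycomb
#' targets.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size Hi-C bin size (bp).
#' @param n_peaks number of Polycomb (RING1B) peak regions.
#' @param peak_len_meanlog,peak_len_sdlog log-normal peak length parameters.
#' @param peak_len_min,peak_len_max peak length bounds (bp); minimum 10 kb
#'   matches the extended-region class analysed locally.
#' @param occ_meanlog,occ_sdlog log-normal occupancy parameters (arbitrary
#'   occupancy units; ChIP read counts scale linearly with occupancy).
#' @param cor_canonical,cor_noncanonical log-scale correlation of canonical
#'   (MEL18, CBX2) and noncanonical (KDM2B, RYBP) subunit occupancy with
#'   RING1B; H3K27me3 uses `cor_k27`.
#' @param cor_k27 correlation of H3K27me3 with RING1B occupancy.
#' @param n_ctcf number of CTCF sites; `ctcf_plus_prob` gives the probability
#'   of a site being on the + strand.
#' @param ctcf_plus_prob strand assignment probability.
#' @param n_cgi,n_genes numbers of CpG islands and genes.
#' @param cgi_peak_frac fraction of CGIs placed inside Polycomb peaks
#'   (Polycomb is targeted to CpG islands).
#' @param frac_upregulated fraction of genes designated as de-repressed upon
#'   loss of PRC1.
#' @param compartment_block compartment block length scale (bp); blocks are
#'   drawn in 200-kb multiples so coarse-grained bins stay aligned.
#' @param decay_alpha power-law contact-decay exponent.
#' @param decay_s0 decay offset (bins).
#' @param compartment_strength checkerboard factor `c` in `1 + c * same-sign`.
#' @param ctcf_loop_factor contact enrichment at convergent CTCF site pairs.
#' @param ctcf_reach maximum genomic separation (bp) of CTCF loops.
#' @param loop_scale scale of Polycomb pair-loop enrichment (see
#'   [simulate_contact_map()]).
#' @param domain_factor contact enrichment inside an extended Polycomb peak.
#' @param loopability_weights named numeric vector of generative weights of
#'   the per-region loop propensity over standardized log-occupancies and
#'   log-length.
#' @param invalid_frac fraction of bins masked invalid (exercises mask
#'   handling downstream).
#' @param seed integer random seed.
#' @return a list of class `genome_config`.
#' @export
genome_config <- function(chrom_lengths = c(chr1 = 50e6, chr2 = 50e6),
                          bin_size = 10e3,
                          n_peaks = 200,
                          peak_len_meanlog = log(25e3), peak_len_sdlog = 0.45,
                          peak_len_min = 10e3, peak_len_max = 200e3,
                          occ_meanlog = 0, occ_sdlog = 1,
                          cor_canonical = 0.8, cor_noncanonical = 0.4,
                          cor_k27 = 0.6,
                          n_ctcf = 300, ctcf_plus_prob = 0.5,
                          n_cgi = 400, n_genes = 400,
                          cgi_peak_frac = 0.4,
                          frac_upregulated = 0.1,
                          compartment_block = 2e6,
                          decay_alpha = 1.0, decay_s0 = 1,
                          compartment_strength = 0.3,
                          ctcf_loop_factor = 2.5, ctcf_reach = 1.6e6,
                          loop_scale = 0.4,
                          domain_factor = 2.0,
                          loopability_weights = c(RING1B = 0.6, length = 0.5,
                                                  CBX2 = 0.25, MEL18 = 0.2,
                                                  RYBP = -0.3, H3K27me3 = -0.2,
                                                  KDM2B = 0),
                          invalid_frac = 0.02,
                          seed = 1L) {
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (any(chrom_lengths <= 0)) pcg_abort("chromosome lengths must be > 0")
  stopifnot_scalar_number(bin_size, "bin_size", positive = TRUE)
  if (n_peaks < 0) pcg_abort("`n_peaks` must be >= 0")
  cfg <- as.list(environment())
  structure(cfg, class = "genome_config")
}

chip_factors <- function() c("RING1B", "H3K27me3", "MEL18", "CBX2", "KDM2B", "RYBP")

#' Condition profile
#'
#' Describes how one experimental condition perturbs the synthetic genome.
#' `"WT"` carries full Polycomb loops and domains; `"I53A"` (catalytically
#' dead RING1B) retains loops and domains in slightly attenuated form but
#' loses binding at a designated subset of peaks (25% global RING1B
#' reduction plus an 80% reduction at a 20% peak subset); `"KO"` loses all
#' Polycomb loops and domains. CTCF loop strength never changes across
#' conditions.
#'
#' @param condition one of `"WT"`, `"I53A"`, `"KO"`, or a custom label (then
#'   supply the remaining arguments).
#' @param occupancy_mult named multiplier per ChIP factor.
#' @param loop_mult Polycomb loop-strength multiplier (0 in KO).
#' @param domain_mult Polycomb domain-strength multiplier (0 in KO).
#' @param attrition_frac fraction of peaks with severe region-specific loss.
#' @param attrition_mult residual occupancy at attrited peaks.
#' @param expression_effect expected log2 up-regulation of the planted
#'   de-repressed gene subset relative to WT.
#' @param fish_contraction contraction factor applied to Polycomb-probe
#'   separations in FISH simulation (1 = no attraction).
#' @param compartment_shift if `TRUE`, compartment blocks containing planted
#'   up-regulated genes shift to the A compartment in this condition
#'   (couples expression change to compartment change; off by default).
#' @return a list of class `condition_profile`.
#' @export
condition_profile <- function(condition = c("WT", "I53A", "KO"),
                              occupancy_mult = NULL,
                              loop_mult = NULL,
                              domain_mult = NULL,
                              attrition_frac = NULL,
                              attrition_mult = NULL,
                              expression_effect = NULL,
                              fish_contraction = NULL,
                              compartment_shift = FALSE) {
  condition <- condition[1L]
  defaults <- switch(
    condition,
    WT = list(occupancy_mult = c(RING1B = 1, H3K27me3 = 1, MEL18 = 1,
                                 CBX2 = 1, KDM2B = 1, RYBP = 1),
              loop_mult = 1, domain_mult = 1,
              attrition_frac = 0, attrition_mult = 1,
              expression_effect = 0, fish_contraction = 0.5),
    I53A = list(occupancy_mult = c(RING1B = 0.75, H3K27me3 = 1, MEL18 = 0.85,
                                   CBX2 = 0.85, KDM2B = 1, RYBP = 1),
                loop_mult = 0.8, domain_mult = 0.9,
                attrition_frac = 0.2, attrition_mult = 0.2,
                expression_effect = 0.3, fish_contraction = 0.6),
    KO = list(occupancy_mult = c(RING1B = 0, H3K27me3 = 0.7, MEL18 = 0.3,
                                 CBX2 = 0.3, KDM2B = 0.8, RYBP = 0.8),
              loop_mult = 0, domain_mult = 0,
              attrition_frac = 0, attrition_mult = 1,
              expression_effect = 2.0, fish_contraction = 1),
    list(occupancy_mult = c(RING1B = 1, H3K27me3 = 1, MEL18 = 1,
                            CBX2 = 1, KDM2B = 1, RYBP = 1),
         loop_mult = 1, domain_mult = 1,
         attrition_frac = 0, attrition_mult = 1,
         expression_effect = 0, fish_contraction = 1)
  )
  prof <- list(
    condition = condition,
    occupancy_mult = occupancy_mult %||% defaults$occupancy_mult,
    loop_mult = loop_mult %||% defaults$loop_mult,
    domain_mult = domain_mult %||% defaults$domain_mult,
    attrition_frac = attrition_frac %||% defaults$attrition_frac,
    attrition_mult = attrition_mult %||% defaults$attrition_mult,
    expression_effect = expression_effect %||% defaults$expression_effect,
    fish_contraction = fish_contraction %||% defaults$fish_contraction,
    compartment_shift = compartment_shift
  )
  if (any(prof$occupancy_mult < 0) || prof$loop_mult < 0 || prof$domain_mult < 0) {
    pcg_abort("condition multipliers must be >= 0")
  }
  structure(prof, class = "condition_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Non-overlapping placement of intervals of given lengths on one chromosome,
# on a `quantum` grid. Returned in input order (not sorted).
place_intervals <- function(chrom_len, lengths, quantum = 1, max_tries = 2000L) {
  placed_start <- numeric(0); placed_end <- numeric(0)
  for (len in lengths) {
    if (len >= chrom_len) {
      pcg_abort("chromosome too short to place requested features",
                class = "pcgloop_placement_error")
    }
    ok <- FALSE
    slots <- floor((chrom_len - len) / quantum)
    for (t in seq_len(max_tries)) {
      s <- floor(stats::runif(1, 0, slots + 1)) * quantum
      e <- s + len
      if (!any(s < placed_end & e > placed_start)) {
        placed_start <- c(placed_start, s); placed_end <- c(placed_end, e)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      pcg_abort("chromosome too short to place requested features without overlap",
                class = "pcgloop_placement_error")
    }
  }
  tibble::tibble(start = placed_start, end = placed_end)
}

# alternating-sign compartment blocks in 200-kb multiples
make_compartment_track <- function(chrom_lengths, bin_size, block_mean) {
  quantum <- 200e3
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    nbin <- ceiling(len / bin_size)
    comp <- numeric(0)
    sign <- sample(c(-1, 1), 1)
    pos <- 0
    while (pos < len) {
      blk <- max(quantum, round(stats::rexp(1, 1 / block_mean) / quantum) * quantum)
      blk <- min(blk, len - pos)
      nb <- ceiling(blk / bin_size)
      comp <- c(comp, rep(sign, nb))
      sign <- -sign
      pos <- pos + nb * bin_size
    }
    out[[chrom]] <- comp[seq_len(nbin)]
  }
  out
}

#' Generate a synthetic genome with planted Polycomb architecture
#'
#' Builds the full ground-truth scaffold for one synthetic genome: Polycomb
#' peak regions with per-factor occupancies, stranded CTCF sites, CpG
#' islands, genes with a designated de-repressed subset, a block compartment
#' track with a correlated GC track, planted pairwise Polycomb loop
#' propensities, planted CTCF loops (convergent pairs within reach), and
#' planted domain strengths. Fully deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [genome_config()].
#' @return a list of class `synthetic_genome` with elements `peaks`,
#'   `ctcf_sites`, `cgis`, `genes`, `truth`, `config`, `chromsizes`. `truth`
#'   carries planted occupancies, loop propensities, domain factors, the
#'   compartment and GC tracks, up-regulated gene ids and the generative
#'   loopability weights.
#' @examples
#' g <- make_genome(genome_config(chrom_lengths = c(chrA = 5e6), n_peaks = 10,
#'                                n_ctcf = 20, n_cgi = 20, n_genes = 20))
#' g$peaks
#' @export
make_genome <- function(config) {
  if (!inherits(config, "genome_config")) pcg_abort("`config` must be a genome_config")
  with_seed(config$seed, {
    chroms <- names(config$chrom_lengths)
    factors <- chip_factors()

    ## ---- peaks with correlated factor occupancies
    n_pk <- config$n_peaks
    if (n_pk > 0) {
      lens <- pmin(pmax(stats::rlnorm(n_pk, config$peak_len_meanlog,
                                      config$peak_len_sdlog),
                        config$peak_len_min), config$peak_len_max)
      # round to whole bins so domains align with the bin grid
      lens <- pmax(round(lens / config$bin_size), 1) * config$bin_size
      # allocate peaks to chromosomes proportionally to length
      pk_chrom <- sample(chroms, n_pk, replace = TRUE,
                         prob = config$chrom_lengths / sum(config$chrom_lengths))
      peak_list <- list()
      for (chrom in chroms) {
        sel <- which(pk_chrom == chrom)
        if (!length(sel)) next
        # placed on the bin grid so domains align exactly with bins
        pl <- place_intervals(config$chrom_lengths[[chrom]], lens[sel],
                              quantum = config$bin_size)
        peak_list[[chrom]] <- tibble::tibble(chrom = chrom, start = pl$start,
                                             end = pl$end)
      }
      peaks <- dplyr::bind_rows(peak_list) %>%
        dplyr::arrange(.data$chrom, .data$start)
      peaks$name <- sprintf("peak_%03d", seq_len(nrow(peaks)))

      # latent standard-normal occupancy scores, correlated with RING1B
      zR <- stats::rnorm(nrow(peaks))
      rho <- c(RING1B = 1, H3K27me3 = config$cor_k27,
               MEL18 = config$cor_canonical, CBX2 = config$cor_canonical,
               KDM2B = config$cor_noncanonical, RYBP = config$cor_noncanonical)
      z <- vapply(factors, function(f) {
        r <- rho[[f]]
        r * zR + sqrt(1 - r^2) * stats::rnorm(nrow(peaks))
      }, numeric(nrow(peaks)))
      z <- matrix(z, nrow = nrow(peaks), dimnames = list(NULL, factors))
      occ <- exp(config$occ_meanlog + config$occ_sdlog * z)
      colnames(occ) <- factors
      occ_tbl <- tibble::as_tibble(occ)
      names(occ_tbl) <- paste0("occ_", factors)
      peaks <- dplyr::bind_cols(peaks, occ_tbl)

      # generative loop propensity from standardized log-occupancy + log-length
      w <- config$loopability_weights
      # raw length standardized, the same scale on which the loopability
      # model sees its length predictor
      len_raw <- peaks$end - peaks$start
      len_std <- if (nrow(peaks) > 1 && stats::sd(len_raw) > 0) {
        as.numeric(scale(len_raw))
      } else rep(0, nrow(peaks))
      X <- cbind(z[, c("RING1B", "CBX2", "MEL18", "RYBP", "H3K27me3", "KDM2B"),
                   drop = FALSE],
                 length = len_std)
      eta <- X[, names(w), drop = FALSE] %*% w
      propensity <- exp(eta - mean(eta))
      peaks$loop_propensity <- as.numeric(propensity)
      peaks$domain_factor <- config$domain_factor
    } else {
      peaks <- tibble::tibble(chrom = character(), start = numeric(),
                              end = numeric(), name = character())
      for (f in factors) peaks[[paste0("occ_", f)]] <- numeric()
      peaks$loop_propensity <- numeric()
      peaks$domain_factor <- numeric()
    }

    ## ---- planted Polycomb loops: every same-chromosome peak pair
    loop_list <- list()
    if (nrow(peaks) >= 2) {
      for (chrom in chroms) {
        idx <- which(peaks$chrom == chrom)
        if (length(idx) < 2) next
        pr <- t(utils::combn(idx, 2))
        loop_list[[chrom]] <- tibble::tibble(
          peak1 = pr[, 1], peak2 = pr[, 2],
          chrom = chrom,
          strength = config$loop_scale *
            peaks$loop_propensity[pr[, 1]] * peaks$loop_propensity[pr[, 2]]
        )
      }
    }
    pcg_loops <- if (length(loop_list)) dplyr::bind_rows(loop_list) else
      tibble::tibble(peak1 = integer(), peak2 = integer(),
                     chrom = character(), strength = numeric())

    ## ---- CTCF sites and convergent loops within reach
    if (config$n_ctcf > 0) {
      ct_chrom <- sample(chroms, config$n_ctcf, replace = TRUE,
                         prob = config$chrom_lengths / sum(config$chrom_lengths))
      ct <- lapply(chroms, function(chrom) {
        k <- sum(ct_chrom == chrom)
        if (!k) return(NULL)
        pos <- sort(floor(stats::runif(k, 0, config$chrom_lengths[[chrom]] - 200)))
        tibble::tibble(chrom = chrom, start = pos, end = pos + 200,
                       strand = ifelse(stats::runif(k) < config$ctcf_plus_prob,
                                       "+", "-"))
      })
      ctcf_sites <- dplyr::bind_rows(ct)
      ctcf_sites$name <- sprintf("ctcf_%03d", seq_len(nrow(ctcf_sites)))
    } else {
      ctcf_sites <- tibble::tibble(chrom = character(), start = numeric(),
                                   end = numeric(), strand = character(),
                                   name = character())
    }
    ctcf_loop_list <- list()
    for (chrom in chroms) {
      idx <- which(ctcf_sites$chrom == chrom)
      if (length(idx) < 2) next
      pr <- t(utils::combn(idx, 2))
      up <- pr[, 1]; dn <- pr[, 2]
      sep <- region_midpoint(ctcf_sites[dn, ]) - region_midpoint(ctcf_sites[up, ])
      conv <- ctcf_sites$strand[up] == "+" & ctcf_sites$strand[dn] == "-" &
        sep > 0 & sep <= config$ctcf_reach
      if (any(conv)) {
        ctcf_loop_list[[chrom]] <- tibble::tibble(
          site1 = up[conv], site2 = dn[conv], chrom = chrom,
          factor = config$ctcf_loop_factor
        )
      }
    }
    ctcf_loops <- if (length(ctcf_loop_list)) dplyr::bind_rows(ctcf_loop_list) else
      tibble::tibble(site1 = integer(), site2 = integer(),
                     chrom = character(), factor = numeric())

    ## ---- CGIs: a fraction inside peaks, rest background
    n_at_peak <- if (nrow(peaks)) round(config$n_cgi * config$cgi_peak_frac) else 0L
    cgi_list <- list()
    if (n_at_peak > 0) {
      host <- sample(seq_len(nrow(peaks)), n_at_peak, replace = TRUE)
      width <- 1000
      s <- peaks$start[host] +
        floor(stats::runif(n_at_peak) *
                pmax(peaks$end[host] - peaks$start[host] - width, 1))
      cgi_list$at_peak <- tibble::tibble(chrom = peaks$chrom[host], start = s,
                                         end = s + width)
    }
    n_bg <- config$n_cgi - n_at_peak
    if (n_bg > 0) {
      bg_chrom <- sample(chroms, n_bg, replace = TRUE,
                         prob = config$chrom_lengths / sum(config$chrom_lengths))
      s <- floor(stats::runif(n_bg) *
                   (config$chrom_lengths[bg_chrom] - 1000))
      cgi_list$bg <- tibble::tibble(chrom = bg_chrom, start = s, end = s + 1000)
    }
    cgis <- if (length(cgi_list)) {
      dplyr::arrange(dplyr::bind_rows(cgi_list), .data$chrom, .data$start)
    } else tibble::tibble(chrom = character(), start = numeric(), end = numeric())
    if (nrow(cgis)) cgis$name <- sprintf("cgi_%03d", seq_len(nrow(cgis)))

    ## ---- compartments and GC
    comp <- make_compartment_track(config$chrom_lengths, config$bin_size,
                                   config$compartment_block)
    comp_tbl <- dplyr::bind_rows(lapply(chroms, function(ch) {
      nb <- length(comp[[ch]])
      tibble::tibble(chrom = ch,
                     start = (seq_len(nb) - 1) * config$bin_size,
                     end = pmin(seq_len(nb) * config$bin_size,
                                config$chrom_lengths[[ch]]),
                     compartment = comp[[ch]])
    }))
    comp_tbl$gc <- 0.41 + 0.015 * comp_tbl$compartment +
      stats::rnorm(nrow(comp_tbl), 0, 0.003)

    ## ---- genes: part placed near peaks (for up-regulated/proximal classes)
    n_up <- round(config$n_genes * config$frac_upregulated)
    gene_list <- list()
    n_up_near <- if (nrow(peaks)) min(ceiling(n_up / 2), nrow(peaks)) else 0L
    if (n_up_near > 0) {
      host <- sample(seq_len(nrow(peaks)), n_up_near)
      tss <- peaks$end[host] + floor(stats::runif(n_up_near, 1e3, 30e3))
      gene_list$up_near <- tibble::tibble(
        chrom = peaks$chrom[host], start = tss, end = tss + 5e3,
        upregulated = TRUE)
    }
    n_rest <- config$n_genes - n_up_near
    if (n_rest > 0) {
      g_chrom <- sample(chroms, n_rest, replace = TRUE,
                        prob = config$chrom_lengths / sum(config$chrom_lengths))
      s <- floor(stats::runif(n_rest) * (config$chrom_lengths[g_chrom] - 10e3))
      up_rest <- rep(FALSE, n_rest)
      if (n_up - n_up_near > 0) {
        # remaining up-genes preferentially drawn from the B compartment,
        # where silenced Polycomb targets reside
        in_b <- vapply(seq_len(n_rest), function(i) {
          cc <- comp[[g_chrom[i]]]
          b <- min(length(cc), floor(s[i] / config$bin_size) + 1)
          cc[b] < 0
        }, logical(1))
        want <- n_up - n_up_near
        cand <- if (sum(in_b) >= want) which(in_b) else seq_len(n_rest)
        up_rest[sample(cand, want)] <- TRUE
      }
      gene_list$bg <- tibble::tibble(chrom = g_chrom, start = s, end = s + 5e3,
                                     upregulated = up_rest)
    }
    genes <- dplyr::arrange(dplyr::bind_rows(gene_list), .data$chrom, .data$start)
    genes$end <- pmin(genes$end, config$chrom_lengths[genes$chrom])
    genes <- validate_regions(genes)
    genes$name <- sprintf("gene_%03d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$baseline_log2 <- stats::rnorm(nrow(genes), 5, 1.5)

    ## ---- I53A attrition subset (fixed per genome so conditions share it)
    attrited <- rep(FALSE, nrow(peaks))
    if (nrow(peaks)) attrited[sample(seq_len(nrow(peaks)),
                                     round(0.2 * nrow(peaks)))] <- TRUE
    peaks$attrited <- attrited

    ## ---- invalid-bin mask, shared by all condition maps of this genome
    mask <- lapply(chroms, function(chrom) {
      nb <- ceiling(config$chrom_lengths[[chrom]] / config$bin_size)
      bad <- stats::runif(nb) < config$invalid_frac
      bad
    })
    names(mask) <- chroms

    truth <- list(
      occupancy = peaks[, c("name", paste0("occ_", factors))],
      loop_propensity = stats::setNames(peaks$loop_propensity, peaks$name),
      pcg_loops = pcg_loops,
      ctcf_loops = ctcf_loops,
      domain_factor = stats::setNames(peaks$domain_factor, peaks$name),
      compartment = comp_tbl,
      upregulated_genes = genes$name[genes$upregulated],
      loopability_weights = config$loopability_weights,
      invalid_bins = mask
    )
    structure(list(peaks = peaks, ctcf_sites = ctcf_sites, cgis = cgis,
                   genes = genes, truth = truth, config = config,
                   chromsizes = tibble::tibble(
                     chrom = chroms,
                     length = as.numeric(config$chrom_lengths))),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d chromosome(s), %s total | %d peaks, %d CTCF sites, %d CGIs, %d genes\n",
              nrow(x$chromsizes), fmt_bp(sum(x$chromsizes$length)),
              nrow(x$peaks), nrow(x$ctcf_sites), nrow(x$cgis), nrow(x$genes)))
  invisible(x)
}
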