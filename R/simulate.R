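#' Configuration for the synthetic-study generator
#'
#' One object holds every knob of the synthetic inputs: genome shape, LD
#' decay, hotspot spacing, transcript planting (occupancy, isoforms,
#' tissue-specificity mix), peak tracks, SNP catalogs and allele-specific
#' counts. Defaults give a desk-scale study: a 2 x 2-Mb genome, 20 index
#' SNPs, 5 tissues, 85% block occupancy, 80% single-tissue transcripts, 60%
#' promoter mark coverage and a 30% allelic-imbalance rate at effect 0.8 —
#' the regimes the pipeline is meant to characterise.
#'
#' @param seed Master integer seed; every generator derives its stream from
#'   it, so outputs are byte-identical across runs.
#' @param n_chroms,chrom_len_bp Genome shape.
#' @param n_index_snps Number of index GWAS SNPs.
#' @param n_proxies_per_snp Proxy SNPs simulated per side of each index SNP.
#' @param ld_decay_bp Distance scale of LD decay: expected
#'   `r2(d) = exp(-d / ld_decay_bp)`.
#' @param r2_noise Half-width of the uniform noise added to the decay
#'   profile (0 makes r2 exactly the decay curve).
#' @param hotspot_spacing_bp Spacing of recombination hotspots.
#' @param n_conditions Number of tissues (2-8).
#' @param occupancy_frac Probability a block receives a qualifying
#'   multi-exonic transcript.
#' @param isoforms_per_locus Retained isoforms planted per occupied locus.
#' @param exons_per_transcript Exons per planted transcript.
#' @param minor_isoform_decoy_frac Probability an occupied locus also gets a
#'   sub-1%-share isoform decoy.
#' @param single_exon_decoy_frac Probability an unoccupied block gets a
#'   single-exon decoy transcript.
#' @param tau_profile Fraction of planted loci with single-tissue
#'   (tau = 1) expression profiles; the rest are broadly expressed.
#' @param expr_mean Mean read count of a planted transcript in its
#'   expressing tissue(s).
#' @param promoter_mark_frac Fraction of transcript promoters receiving a
#'   peak.
#' @param background_mark_rate Per-base Poisson rate of background peaks.
#' @param peak_width_bp Width of simulated peaks.
#' @param gwas_element_or Planted odds ratio of GWAS (vs common) SNPs in
#'   non-intron transcript elements relative to introns.
#' @param n_gwas_snps,n_common_snps SNP catalog sizes.
#' @param ai_frac Fraction of transcripts planted with allelic imbalance.
#' @param ai_effect Planted reference-allele fraction for imbalanced
#'   transcripts.
#' @param snps_per_transcript Heterozygous SNPs per transcript.
#' @param depth_mean Mean (Poisson) read depth per SNP.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_len_bp = 2e6,
                       n_index_snps = 20, n_proxies_per_snp = 25,
                       ld_decay_bp = 20000, r2_noise = 0.05,
                       hotspot_spacing_bp = 50000,
                       n_conditions = 5,
                       occupancy_frac = 0.85,
                       isoforms_per_locus = 2,
                       exons_per_transcript = 3,
                       minor_isoform_decoy_frac = 0.5,
                       single_exon_decoy_frac = 0.5,
                       tau_profile = 0.8,
                       expr_mean = 200,
                       promoter_mark_frac = 0.6,
                       background_mark_rate = 2e-6,
                       peak_width_bp = 200,
                       gwas_element_or = 2,
                       n_gwas_snps = 300, n_common_snps = 3000,
                       ai_frac = 0.3, ai_effect = 0.8,
                       snps_per_transcript = 5, depth_mean = 50) {
  cfg <- as.list(environment())
  stopifnot(cfg$ld_decay_bp < cfg$chrom_len_bp,
            cfg$occupancy_frac >= 0, cfg$occupancy_frac <= 1,
            cfg$tau_profile >= 0, cfg$tau_profile <= 1,
            cfg$promoter_mark_frac >= 0, cfg$promoter_mark_frac <= 1,
            cfg$ai_effect > 0, cfg$ai_effect < 1,
            cfg$n_conditions >= 2, cfg$n_conditions <= 8)
  structure(cfg, class = "sim_config")
}

sim_genome <- function(config) {
  tibble(chrom = paste0("chr", seq_len(config$n_chroms)),
         length = config$chrom_len_bp)
}

sim_conditions <- function(config) {
  c("testis", "liver", "brain", "placenta", "colon",
    "spleen", "thymus", "heart")[seq_len(config$n_conditions)]
}

# literal per-SNP walk giving the ground-truth block for one index SNP;
# deliberately written as an explicit scan so generator truth does not share
# code with build_haploblocks()
scan_block_truth <- function(index_pos, pos, r2, hot_pos, rules) {
  cap <- rules$side_cap_bp
  main <- identical(rules$hotspot_extension, "if_insufficient")
  best_l <- index_pos; best_r <- index_pos
  seen_low_l <- FALSE; seen_low_r <- FALSE
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (p == index_pos) next
    if (r2[i] > rules$r2_extend) {
      if (p < index_pos && p < best_l) best_l <- p
      if (p > index_pos && p > best_r) best_r <- p
    }
    if (r2[i] < rules$r2_sufficient && (!main || abs(p - index_pos) <= cap)) {
      if (p < index_pos) seen_low_l <- TRUE else seen_low_r <- TRUE
    }
  }
  if (main) {
    best_l <- max(best_l, index_pos - cap)
    best_r <- min(best_r, index_pos + cap)
  }
  extend_hot <- function(boundary, left) {
    cand <- if (left) hot_pos[hot_pos < boundary] else hot_pos[hot_pos > boundary]
    if (length(cand) == 0) return(boundary)
    if (left) max(cand) else min(cand)
  }
  if (main) {
    if (!seen_low_l) best_l <- extend_hot(best_l, TRUE)
    if (!seen_low_r) best_r <- extend_hot(best_r, FALSE)
  } else {
    best_l <- extend_hot(best_l, TRUE)
    best_r <- extend_hot(best_r, FALSE)
  }
  start <- best_l; end <- best_r + 1
  if (!main && end - start > rules$total_cap_bp) {
    half <- rules$total_cap_bp / 2
    over_l <- max(0, index_pos - start - half)
    over_r <- max(0, end - index_pos - half)
    excess <- (end - start) - rules$total_cap_bp
    trim_l <- if (over_l + over_r > 0) excess * over_l / (over_l + over_r) else 0
    start <- start + round(trim_l)
    end <- end - round(excess - trim_l)
    if (end - start > rules$total_cap_bp) end <- start + rules$total_cap_bp
  }
  c(start = start, end = end)
}

#' Simulate a proxy-SNP panel with decaying LD
#'
#' Per index SNP, proxy r2 values follow `exp(-d / ld_decay_bp)` plus
#' bounded uniform noise (truncated to `[0, 1]`); hotspots are laid out at
#' regular spacing with jitter. Ground-truth block boundaries under both
#' rule sets are computed by an exhaustive per-SNP scan and emitted
#' alongside, so block construction can be checked against planted truth.
#'
#' @param config A [sim_config()].
#' @param rules Rule set used for the emitted truth (default [main_rules()]).
#' @return List: `genome`, `proxies`, `hotspots`, `index_snps`,
#'   `truth_blocks` (tibble `index_snp_id`, `chrom`, `start`, `end`).
#' @export
simulate_ld_panel <- function(config, rules = main_rules()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101)
  genome <- sim_genome(config)
  hotspots <- purrr::pmap(genome, function(chrom, length) {
    base <- seq(config$hotspot_spacing_bp / 2, length - 1,
                by = config$hotspot_spacing_bp)
    jitter <- floor(stats::runif(length(base), -0.2, 0.2) *
                      config$hotspot_spacing_bp)
    tibble(chrom = chrom, pos = pmin(pmax(base + jitter, 1), length - 1))
  }) |> list_rbind()

  per_chrom <- ceiling(config$n_index_snps / config$n_chroms)
  margin <- max(5 * config$ld_decay_bp, 100000)
  idx <- purrr::pmap(genome, function(chrom, length) {
    usable <- length - 2 * margin
    pos <- margin + floor((seq_len(per_chrom) - 0.5) / per_chrom * usable)
    tibble(chrom = chrom, pos = pos)
  }) |> list_rbind()
  idx <- idx[seq_len(config$n_index_snps), , drop = FALSE]
  idx$index_snp_id <- sprintf("rs%04d", seq_len(nrow(idx)))

  max_off <- 4 * config$ld_decay_bp
  proxies <- purrr::pmap(idx, function(chrom, pos, index_snp_id) {
    off <- sort(unique(c(
      -floor(stats::runif(config$n_proxies_per_snp, 1, max_off)),
      floor(stats::runif(config$n_proxies_per_snp, 1, max_off))
    )))
    p <- pos + off
    ok <- p > 0 & p < config$chrom_len_bp
    p <- p[ok]; off <- off[ok]
    r2 <- exp(-abs(off) / config$ld_decay_bp) +
      stats::runif(length(off), -config$r2_noise, config$r2_noise)
    r2 <- pmin(pmax(r2, 0), 1)
    bind_rows(
      tibble(index_snp_id = index_snp_id,
             proxy_snp_id = index_snp_id,
             chrom = chrom, pos = pos, r2 = 1),
      tibble(index_snp_id = index_snp_id,
             proxy_snp_id = paste0(index_snp_id, "_p", seq_along(p)),
             chrom = chrom, pos = p, r2 = r2)
    )
  }) |> list_rbind()

  truth <- purrr::pmap(idx, function(chrom, pos, index_snp_id) {
    px <- proxies[proxies$index_snp_id == index_snp_id &
                    proxies$pos != pos, , drop = FALSE]
    hp <- sort(hotspots$pos[hotspots$chrom == chrom])
    b <- scan_block_truth(pos, px$pos, px$r2, hp, rules)
    tibble(index_snp_id = index_snp_id, chrom = chrom,
           start = b[["start"]], end = b[["end"]])
  }) |> list_rbind()

  list(genome = genome, proxies = proxies, hotspots = hotspots,
       index_snps = idx[, c("index_snp_id", "chrom", "pos")],
       truth_blocks = truth)
}

#' Simulate a set of disjoint haploblock regions directly
#'
#' Tiles the genome with `n_blocks` equal-length, well-separated blocks —
#' the quick way to get a large block panel for occupancy experiments
#' without going through LD delineation.
#'
#' @param config A [sim_config()].
#' @param n_blocks Number of blocks.
#' @param block_len_bp Block length.
#' @return Interval tibble with a `region_id` column.
#' @export
simulate_blocks <- function(config, n_blocks = 200, block_len_bp = 8000) {
  genome <- sim_genome(config)
  per_chrom <- ceiling(n_blocks / nrow(genome))
  slot <- floor((min(genome$length) - 100000) / per_chrom)
  if (slot < block_len_bp + 1000) abort("genome too small for requested blocks")
  out <- purrr::pmap(genome, function(chrom, length) {
    start <- 50000 + (seq_len(per_chrom) - 1) * slot
    tibble(chrom = chrom, start = start, end = start + block_len_bp)
  }) |> list_rbind()
  out <- out[seq_len(n_blocks), , drop = FALSE]
  out$region_id <- sprintf("region_%03d", seq_len(n_blocks))
  out
}

#' Simulate a reference gene annotation and repeat track
#'
#' Plants protein-coding genes inside a fraction of the blocks (so block
#' exclusion has work to do), lincRNA exons at the margins of another
#' fraction (exercising capture-space subtraction), and intergenic repeat
#' intervals.
#'
#' @param config A [sim_config()].
#' @param blocks Interval tibble of haploblock regions.
#' @param coding_frac,linc_frac Fractions of blocks receiving a coding gene
#'   / a marginal lincRNA exon.
#' @return List: `annotation` (exon-level tibble as from [read_gtf()]),
#'   `repeats` (interval tibble).
#' @export
simulate_annotation <- function(config, blocks, coding_frac = 0.1,
                                linc_frac = 0.2) {
  set.seed(config$seed + 151)
  n <- nrow(blocks)
  coding_in <- stats::runif(n) < coding_frac
  linc_in <- !coding_in & stats::runif(n) < linc_frac
  ann <- list()
  for (i in which(coding_in)) {
    s <- blocks$start[i] + floor((blocks$end[i] - blocks$start[i]) / 2)
    ann[[length(ann) + 1]] <- tibble(
      chrom = blocks$chrom[i], start = c(s, s + 800), end = c(s + 200, s + 1000),
      strand = "+", feature = "exon",
      gene_id = sprintf("PCG%03d", i), transcript_id = sprintf("PCG%03d.1", i),
      gene_type = "protein_coding")
  }
  for (i in which(linc_in)) {
    s <- blocks$start[i] + 100  # marginal exon: trimmed out, block survives
    ann[[length(ann) + 1]] <- tibble(
      chrom = blocks$chrom[i], start = s, end = s + 300,
      strand = "-", feature = "exon",
      gene_id = sprintf("LINC%03d", i), transcript_id = sprintf("LINC%03d.1", i),
      gene_type = "lincRNA")
  }
  annotation <- if (length(ann) == 0) {
    tibble(chrom = character(), start = numeric(), end = numeric(),
           strand = character(), feature = character(), gene_id = character(),
           transcript_id = character(), gene_type = character())
  } else list_rbind(ann)
  genome <- sim_genome(config)
  rep_start <- floor(stats::runif(50, 0, config$chrom_len_bp - 500))
  repeats <- tibble(chrom = sample(genome$chrom, 50, replace = TRUE),
                    start = rep_start, end = rep_start + 500) |>
    arrange(.data$chrom, .data$start)
  list(annotation = annotation, repeats = repeats)
}

# one planted multi-exon transcript within [s, e); returns a plain list of
# parallel exon vectors (kept cheap: the generator builds hundreds of these)
plant_transcript <- function(chrom, s, e, strand, tx_id, n_exons,
                             exon_len = 300) {
  span <- e - s
  gap <- floor((span - n_exons * exon_len) / max(1, n_exons - 1))
  if (n_exons > 1 && gap < 50) abort("block too small for requested exon structure")
  starts <- s + (seq_len(n_exons) - 1) * (exon_len + max(gap, 0))
  list(chrom = rep(chrom, n_exons), start = starts, end = starts + exon_len,
       strand = rep(strand, n_exons), transcript_id = rep(tx_id, n_exons))
}

#' Simulate assembled transcript models with planted ground truth
#'
#' Each block independently receives, with probability `occupancy_frac`, a
#' locus of `isoforms_per_locus` multi-exonic isoforms whose maximal FPKM
#' comfortably exceeds 1; unoccupied blocks may receive single-exon decoys,
#' and occupied loci may additionally receive a sub-1%-share isoform decoy
#' (counts a fixed 0.5% of the dominant isoform's, so the share filter
#' removes it deterministically). Condition profiles are single-tissue with
#' probability `tau_profile` (tau = 1) and broad otherwise. Three broadly
#' expressed "housekeeping" transcripts are placed outside the blocks so
#' that median-of-ratios size factors are always computable; they fall
#' outside the capture space and never enter the retained set.
#'
#' @param config A [sim_config()].
#' @param blocks Interval tibble of target block regions (with `region_id`).
#' @return List: `exons` (exon-level tibble), `counts` (counts tibble),
#'   `truth_tx` (per-transcript truth: class, intended retention, tau
#'   class, expressing condition), `truth_blocks` (per-block planted
#'   occupancy).
#' @export
simulate_transcriptome <- function(config, blocks) {
  stopifnot(inherits(config, "sim_config"), nrow(blocks) > 0)
  if (!"region_id" %in% names(blocks)) {
    blocks$region_id <- sprintf("region_%03d", seq_len(nrow(blocks)))
  }
  set.seed(config$seed + 202)
  conds <- sim_conditions(config)
  exons <- list(); truth <- list(); counts <- list()

  draw_profile <- function() {
    if (stats::runif(1) < config$tau_profile) {
      cond <- sample(conds, 1)
      lam <- stats::setNames(rep(0, length(conds)), conds)
      lam[cond] <- config$expr_mean
      list(lambda = lam, tau_class = "specific", max_cond = cond)
    } else {
      lam <- stats::setNames(rep(config$expr_mean, length(conds)) *
                               stats::runif(length(conds), 0.8, 1.2), conds)
      list(lambda = lam, tau_class = "broad", max_cond = names(which.max(lam)))
    }
  }

  add_tx <- function(ex, cnt, class, retained, tau_class, cond, region_id) {
    exons[[length(exons) + 1]] <<- ex
    id <- ex$transcript_id[1]
    counts[[length(counts) + 1]] <<- cnt
    truth[[length(truth) + 1]] <<- list(
      transcript_id = id, region_id = region_id, class = class,
      intended_retained = retained, tau_class = tau_class,
      expressing_condition = cond)
  }

  occupied <- stats::runif(nrow(blocks)) < config$occupancy_frac
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    pad <- floor((b$end - b$start) * 0.15)
    s <- b$start + pad; e <- b$end - pad
    strand <- sample(c("+", "-"), 1)
    if (occupied[i]) {
      prof <- draw_profile()
      dom_counts <- stats::setNames(stats::rpois(length(conds), prof$lambda), conds)
      # the expressing condition must register reads for the plant to count
      if (max(dom_counts) == 0) dom_counts[prof$max_cond] <- 1 + config$expr_mean
      dom_id <- sprintf("TX%s.1", b$region_id)
      add_tx(plant_transcript(b$chrom, s, e, strand, dom_id,
                              config$exons_per_transcript),
             dom_counts, "planted", TRUE, prof$tau_class, prof$max_cond,
             b$region_id)
      if (config$isoforms_per_locus >= 2) {
        for (k in seq_len(config$isoforms_per_locus - 1)) {
          iso_counts <- stats::setNames(
            stats::rpois(length(conds), prof$lambda * 0.3), conds)
          if (sum(iso_counts) == 0) iso_counts[prof$max_cond] <- max(5, config$expr_mean * 0.2)
          add_tx(plant_transcript(b$chrom, s + 40 * k, e, strand,
                                  sprintf("TX%s.%d", b$region_id, k + 1),
                                  config$exons_per_transcript),
                 iso_counts, "planted_minor", TRUE, prof$tau_class,
                 prof$max_cond, b$region_id)
        }
      }
      if (stats::runif(1) < config$minor_isoform_decoy_frac) {
        add_tx(plant_transcript(b$chrom, s + 20, e, strand,
                                sprintf("TX%s.low", b$region_id),
                                config$exons_per_transcript),
               round(dom_counts * 0.005), "decoy_minor_isoform", FALSE,
               NA_character_, prof$max_cond, b$region_id)
      }
    } else if (stats::runif(1) < config$single_exon_decoy_frac) {
      prof <- draw_profile()
      cnt <- stats::setNames(stats::rpois(length(conds), prof$lambda), conds)
      add_tx(list(chrom = b$chrom, start = s, end = s + 600,
                  strand = strand,
                  transcript_id = sprintf("TX%s.se", b$region_id)),
             cnt, "decoy_single_exon", FALSE, NA_character_, prof$max_cond,
             b$region_id)
    }
  }

  # housekeeping controls in the largest gap outside the blocks
  genome <- sim_genome(config)
  gaps <- subtract_intervals(
    tibble(chrom = genome$chrom, start = 0, end = genome$length), blocks)
  gaps <- gaps[order(gaps$end - gaps$start, decreasing = TRUE), ]
  if (nrow(gaps) == 0 || gaps$end[1] - gaps$start[1] < 15000) {
    abort("no intergenic gap large enough for housekeeping controls")
  }
  for (h in 1:3) {
    hs <- gaps$start[1] + 1000 + (h - 1) * 4000
    cnt <- stats::setNames(
      stats::rpois(length(conds), config$expr_mean *
                     stats::runif(length(conds), 0.8, 1.2)) + 1, conds)
    add_tx(plant_transcript(gaps$chrom[1], hs, hs + 3500, "+",
                            sprintf("HK%d", h), 2),
           cnt, "housekeeping", FALSE, "broad", names(which.max(cnt)), NA_character_)
  }

  pull <- function(lst, f) unlist(purrr::map(lst, f), use.names = FALSE)
  exons_tbl <- tibble(chrom = pull(exons, "chrom"),
                      start = pull(exons, "start"),
                      end = pull(exons, "end"),
                      strand = pull(exons, "strand"),
                      transcript_id = pull(exons, "transcript_id"))
  cm <- do.call(rbind, counts)
  counts_tbl <- as_tibble(cm)
  counts_tbl <- counts_tbl[, conds]
  counts_tbl <- mutate(counts_tbl,
                       transcript_id = pull(truth, "transcript_id"),
                       .before = 1)
  truth_tbl <- tibble(transcript_id = pull(truth, "transcript_id"),
                      region_id = pull(truth, "region_id"),
                      class = pull(truth, "class"),
                      intended_retained = pull(truth, "intended_retained"),
                      tau_class = pull(truth, "tau_class"),
                      expressing_condition = pull(truth, "expressing_condition"))

  list(exons = exons_tbl,
       counts = counts_tbl,
       truth_tx = truth_tbl,
       truth_blocks = tibble(region_id = blocks$region_id,
                             chrom = blocks$chrom, start = blocks$start,
                             end = blocks$end, occupied = occupied))
}

#' Simulate peak tracks and SNP catalogs with planted enrichment
#'
#' Peaks for each mark are centred on a `promoter_mark_frac` fraction of
#' transcript 5' ends, plus uniform Poisson background peaks. GWAS and
#' common SNPs are assigned to disjoint transcript element classes
#' (promoters / exons / introns): common SNPs proportionally to element
#' base content, GWAS SNPs with non-intron classes upweighted by
#' `gwas_element_or`, so the planted odds ratio versus introns equals
#' `gwas_element_or` in expectation.
#'
#' @param config A [sim_config()].
#' @param transcripts Exon-level tibble of the transcripts to decorate.
#' @param marks Mark names (one track each).
#' @return List: `tracks` (named list of interval tibbles), `elements`
#'   (named list of disjoint interval tibbles incl. `introns`),
#'   `gwas_snps`, `common_snps`, `truth` (planted fractions/OR and the
#'   per-transcript promoter-mark flags of the first mark).
#' @export
simulate_marks_and_snps <- function(config, transcripts,
                                    marks = c("CAGE", "H3K4me3", "H3K27ac",
                                              "H3K4me1")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 303)
  genome <- sim_genome(config)
  smry <- transcript_summary(transcripts)
  half <- floor(config$peak_width_bp / 2)

  marked_first <- NULL
  tracks <- stats::setNames(purrr::map(marks, function(mk) {
    marked <- stats::runif(nrow(smry)) < config$promoter_mark_frac
    if (is.null(marked_first)) marked_first <<- marked
    prom_peaks <- tibble(chrom = smry$chrom[marked],
                         start = pmax(0, smry$tss[marked] - half),
                         end = smry$tss[marked] + half)
    n_bg <- stats::rpois(1, config$background_mark_rate * sum(genome$length))
    bg_chrom <- sample(genome$chrom, n_bg, replace = TRUE)
    bg_start <- floor(stats::runif(n_bg, 0, config$chrom_len_bp - config$peak_width_bp))
    bg <- tibble(chrom = bg_chrom, start = bg_start,
                 end = bg_start + config$peak_width_bp)
    bind_rows(prom_peaks, bg) |> arrange(.data$chrom, .data$start)
  }), marks)

  # disjoint element classes for SNP planting
  prom <- merge_intervals(tss_windows(smry, genome, 500)[, c("chrom", "start", "end")])
  ex <- subtract_intervals(transcripts[, c("chrom", "start", "end")], prom)
  introns_raw <- split(transcripts, transcripts$transcript_id) |>
    purrr::map(transcript_introns) |> list_rbind()
  introns <- if (nrow(introns_raw) == 0) introns_raw else
    subtract_intervals(introns_raw,
                       bind_rows(prom, transcripts[, c("chrom", "start", "end")]))
  elements <- list(promoters = prom, exons = ex, introns = introns)
  elements <- purrr::keep(elements, function(x) nrow(x) > 0)
  if (!"introns" %in% names(elements)) abort("no intronic bases to host SNPs")

  base_w <- purrr::map_dbl(elements, covered_bases)
  place_snps <- function(n, weights, prefix, class) {
    cls <- sample(names(elements), n, replace = TRUE, prob = weights)
    pos <- purrr::map_dbl(cls, function(cl) {
      iv <- elements[[cl]]
      w <- iv$end - iv$start
      i <- sample.int(nrow(iv), 1, prob = w)
      floor(stats::runif(1, iv$start[i], iv$end[i]))
    })
    chrom <- purrr::map2_chr(cls, pos, function(cl, p) {
      iv <- elements[[cl]]
      iv$chrom[iv$start <= p & iv$end > p][1]
    })
    tibble(chrom = chrom, pos = pos,
           snp_id = paste0(prefix, seq_len(n)), class = class,
           element = cls)
  }
  w_common <- base_w
  w_gwas <- base_w * ifelse(names(base_w) == "introns", 1, config$gwas_element_or)
  gwas <- place_snps(config$n_gwas_snps, w_gwas, "gw", "gwas")
  common <- place_snps(config$n_common_snps, w_common, "cm", "common")

  list(tracks = tracks, elements = elements,
       gwas_snps = gwas, common_snps = common,
       truth = list(promoter_mark_frac = config$promoter_mark_frac,
                    planted_or = config$gwas_element_or,
                    marked_first = tibble(transcript_id = smry$transcript_id,
                                          marked = marked_first)))
}

#' Simulate allele-specific read counts with planted imbalance
#'
#' Per transcript, SNP depths are Poisson(`depth_mean`) (optionally floored)
#' and reference reads binomial with success probability 0.5 for null
#' transcripts and `ai_effect` for the planted fraction.
#'
#' @param config A [sim_config()].
#' @param transcript_ids Character vector of transcripts to cover.
#' @param min_depth Optional depth floor applied to simulated depths.
#' @return List: `ase` (count tibble), `truth` (per-transcript planted
#'   flag).
#' @export
simulate_ase <- function(config, transcript_ids, min_depth = 0) {
  stopifnot(inherits(config, "sim_config"), length(transcript_ids) > 0)
  set.seed(config$seed + 404)
  planted <- stats::runif(length(transcript_ids)) < config$ai_frac
  rows <- purrr::map(seq_along(transcript_ids), function(i) {
    n <- config$snps_per_transcript
    depth <- pmax(stats::rpois(n, config$depth_mean), min_depth)
    p <- if (planted[i]) config$ai_effect else 0.5
    ref <- stats::rbinom(n, depth, p)
    tibble(transcript_id = transcript_ids[i],
           snp_id = sprintf("%s_s%d", transcript_ids[i], seq_len(n)),
           chrom = "chr1", pos = seq_len(n) * 100,
           ref_reads = ref, alt_reads = depth - ref)
  })
  list(ase = list_rbind(rows),
       truth = tibble(transcript_id = transcript_ids, planted_ai = planted))
}
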