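#' Run the full characterisation pipeline on a synthetic study
#'
#' Exercises every stage end-to-end on generated inputs: LD-panel
#' simulation, haploblock delineation (main rules), block collapse,
#' coding-exon/length exclusion, capture-space construction, transcript
#' simulation and filtering, expression tiers, block occupancy, tissue
#' specificity, promoter mark occupancy and aggregate profiles, TSS CAGE
#' enrichment with randomised controls, bidirectionality, element SNP
#' enrichment, and allelic-imbalance calling. Intended both as the smoke
#' test of the whole toolchain and as a template for assembling the stages
#' on real inputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, the main outputs are
#'   written as BED/GTF/TSV files.
#' @param n_rand Randomised-control replicates for the TSS enrichment.
#' @return Named list with the results of every stage (see the vignette for
#'   a walk-through).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL, n_rand = 20) {
  sim <- simulate_ld_panel(config)
  blocks <- build_haploblocks(sim$proxies, sim$hotspots, main_rules())
  collapsed <- collapse_blocks(blocks)

  ann <- simulate_annotation(config, collapsed)
  coding <- exons_of_type(ann$annotation, "protein_coding")
  kept_blocks <- exclude_blocks(collapsed, coding, min_len_bp = 3000)
  capture <- build_capture_space(kept_blocks, ann$annotation)

  txs <- simulate_transcriptome(config, kept_blocks)
  exons <- assign_loci(txs$exons)
  sf <- size_factors(txs$counts)
  fp <- fpkm(txs$counts, lengths = with(
    exons |> group_by(.data$transcript_id) |>
      summarise(len = sum(.data$end - .data$start), .groups = "drop"),
    stats::setNames(len, transcript_id)), sf = sf)
  retained <- retain_transcripts(exons, fp, capture) |> expression_tiers()
  occ <- occupancy(kept_blocks, exons, retained)

  vst <- transform_expression(txs$counts, sf = sf)
  taus <- tau_index(vst[vst$transcript_id %in% retained$transcript_id, ])
  spec <- specific_set(taus, threshold = 0.8)

  retained_exons <- exons[exons$transcript_id %in% retained$transcript_id, ]
  mk <- simulate_marks_and_snps(config, retained_exons)
  prom_occ <- promoter_occupancy(retained_exons, mk$tracks[[1]], sim$genome)
  profile <- aggregate_profile(retained_exons, mk$tracks[[1]],
                               fpkm_tbl = fp, condition = names(fp)[2],
                               min_expr = 0)
  tss_enr <- tss_enrichment(retained_exons, mk$tracks[[1]], sim$genome,
                            reference = ann$annotation,
                            n_rand = n_rand, seed = config$seed)
  bidir <- call_bidirectional(retained_exons)
  snp_enr <- element_snp_enrichment(mk$elements, mk$gwas_snps, mk$common_snps)

  ase <- simulate_ase(config, retained$transcript_id)
  ai <- transcript_ai(ase$ase, min_reads = 30) |> ai_fdr(fdr_threshold = 0.1)

  intron_controls <- pick_intron_controls(retained_exons, ann$repeats,
                                          seed = config$seed)

  res <- list(config = config, genome = sim$genome, blocks = blocks,
              collapsed = collapsed, kept_blocks = kept_blocks,
              capture = capture, exons = exons, counts = txs$counts,
              size_factors = sf, fpkm = fp, retained = retained,
              occupancy = occ, tau = taus, specific = spec,
              marks = mk, promoter_occupancy = prom_occ,
              profile = profile, tss_enrichment = tss_enr,
              bidirectional = bidir, snp_enrichment = snp_enr,
              intron_controls = intron_controls,
              ase = ase, allelic = ai, truth = list(
                blocks = sim$truth_blocks, tx = txs$truth_tx,
                planted_occupancy = txs$truth_blocks,
                marks = mk$truth, ase = ase$truth))
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  blocks_bed <- res$blocks |>
    mutate(name = .data$index_snp_id, score = 0, strand = "+")
  write_bed(blocks_bed[, c("chrom", "start", "end", "name", "score", "strand")],
            p("blocks.bed"))
  readr::write_tsv(res$blocks[, c("index_snp_id", "left_rule", "right_rule",
                                  "rule_set")], p("blocks_provenance.tsv"),
                   progress = FALSE)
  write_bed(res$capture, p("capture_space.bed"))
  write_gtf(res$exons[res$exons$transcript_id %in%
                        res$retained$transcript_id, ], p("retained.gtf"))
  readr::write_tsv(res$retained, p("retained.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(res$tau), p("tau.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(res$profile), p("aggregate_profile.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$snp_enrichment, p("element_enrichment.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$allelic, p("allelic_imbalance.tsv"), progress = FALSE)
  invisible(out_dir)
}

#' Forest plot of element enrichment results
#'
#' @param x Tibble from [element_snp_enrichment()] (or any tibble with
#'   `class`, `log_or`, `ci_low`, `ci_high`).
#' @return A ggplot.
#' @export
plot_enrichment <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$log_or, y = .data$class)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15, colour = "grey40") +
    ggplot2::geom_point(size = 2, colour = "firebrick") +
    ggplot2::labs(x = "log odds ratio (95% CI)", y = NULL,
                  title = "GWAS SNP enrichment by transcript element") +
    ggplot2::theme_minimal()
}
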