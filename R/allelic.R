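#' Depth-filter allele-specific SNP counts
#'
#' Keeps SNPs with total (ref + alt) read depth of at least `min_reads`
#' (inclusive threshold).
#'
#' @param counts Tibble with `transcript_id`, `snp_id`, `ref_reads`,
#'   `alt_reads`.
#' @param min_reads Minimum depth (default 30).
#' @return The surviving rows.
#' @export
filter_snps <- function(counts, min_reads = 30) {
  stopifnot(all(c("ref_reads", "alt_reads") %in% names(counts)))
  if (any(counts$ref_reads < 0 | counts$alt_reads < 0)) {
    abort("negative read counts")
  }
  counts[counts$ref_reads + counts$alt_reads >= min_reads, , drop = FALSE]
}

# Fisher's combination of independent p-values: -2 sum log p ~ chi2(2k)
fisher_combine <- function(p) {
  stats::pchisq(-2 * sum(log(pmax(p, .Machine$double.xmin))),
                df = 2 * length(p), lower.tail = FALSE)
}

#' Per-transcript allelic-imbalance statistics
#'
#' For each transcript with at least one SNP surviving the depth filter:
#' per-SNP allelic ratio `ref / (ref + alt)` and a two-sided exact binomial
#' p-value against `null_ratio`; the transcript p-value combines its SNPs
#' with Fisher's method; the imbalance measure is `|0.5 - median ratio|`
#' (in `[0, 0.5]`, 0 = perfectly balanced).
#'
#' @param counts Allele-specific count tibble (as for [filter_snps()]).
#' @param min_reads Depth filter applied first (default 30).
#' @param null_ratio Null reference-allele fraction (default 0.5; supply a
#'   bias-adjusted value if reference-mapping bias was estimated upstream).
#' @return Tibble: `transcript_id`, `n_snps_used`, `median_ratio`,
#'   `ai_measure`, `p_value`. Transcripts with no surviving SNPs are
#'   omitted (with a message).
#' @export
transcript_ai <- function(counts, min_reads = 30, null_ratio = 0.5) {
  stopifnot(null_ratio > 0, null_ratio < 1)
  all_tx <- unique(counts$transcript_id)
  kept <- filter_snps(counts, min_reads)
  dropped <- setdiff(all_tx, unique(kept$transcript_id))
  if (length(dropped) > 0) {
    message(sprintf("%d transcript(s) omitted: no SNP with >= %d reads",
                    length(dropped), min_reads))
  }
  if (nrow(kept) == 0) {
    return(tibble(transcript_id = character(), n_snps_used = integer(),
                  median_ratio = numeric(), ai_measure = numeric(),
                  p_value = numeric()))
  }
  kept |>
    mutate(total = .data$ref_reads + .data$alt_reads,
           ratio = .data$ref_reads / .data$total,
           p_snp = purrr::map2_dbl(.data$ref_reads, .data$total, function(k, n) {
             stats::binom.test(k, n, p = null_ratio)$p.value
           })) |>
    group_by(.data$transcript_id) |>
    summarise(n_snps_used = n(),
              median_ratio = stats::median(.data$ratio),
              ai_measure = abs(0.5 - stats::median(.data$ratio)),
              p_value = fisher_combine(.data$p_snp),
              .groups = "drop")
}

#' Flag allelically imbalanced transcripts at an FDR threshold
#'
#' Benjamini-Hochberg q-values across transcripts; a transcript is flagged
#' when `q < fdr_threshold`.
#'
#' @param results Tibble from [transcript_ai()].
#' @param fdr_threshold FDR cutoff (default 0.1, strict `<`).
#' @return The input with `q_value` and logical `imbalanced` columns.
#' @export
ai_fdr <- function(results, fdr_threshold = 0.1) {
  stopifnot(all(results$p_value >= 0 & results$p_value <= 1))
  results$q_value <- stats::p.adjust(results$p_value, method = "BH")
  results$imbalanced <- results$q_value < fdr_threshold
  results
}

#' Read an allele-specific count table
#'
#' Tab-separated with header: `transcript_id`, `snp_id`, `chrom`, `pos`,
#' `ref_reads`, `alt_reads`.
#'
#' @param path File path.
#' @return Tibble of allele-specific counts.
#' @export
read_ase <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    transcript_id = "c", snp_id = "c", chrom = "c", pos = "d",
    ref_reads = "d", alt_reads = "d"), progress = FALSE)
}

#' Read a SNP catalog
#'
#' Tab-separated with header: `chrom`, `pos`, `snp_id`, `class` (`gwas` or
#' `common`).
#'
#' @param path File path.
#' @return Tibble of SNP records.
#' @export
read_snps <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "d", snp_id = "c", class = "c"), progress = FALSE)
}

#' Read a counts matrix
#'
#' Tab-separated with header; first column `transcript_id`, remaining
#' columns one per condition.
#'
#' @param path File path.
#' @return Counts tibble.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
}
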