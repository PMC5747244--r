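#' Nucleotide contingency table for region/annotation overlap
#'
#' Builds the 2x2 base-count table behind every enrichment statistic:
#' `a` = bases shared by the region of interest and the annotation,
#' `b` = annotation bases outside the region, `c` = region bases without
#' annotation, `d` = remaining genomic bases. Exclusion regions are removed
#' from the region, the annotation and the genome total before counting, so
#' the four cells always sum to the effective genome size.
#'
#' @param roi Interval tibble: region of interest.
#' @param annotation Interval tibble: annotation being tested.
#' @param genome Genome layout tibble (`chrom`, `length`).
#' @param exclusions Optional interval tibble removed from all terms.
#' @return Named numeric vector `c(a, b, c, d)`.
#' @export
contingency <- function(roi, annotation, genome, exclusions = NULL) {
  total <- sum(genome$length)
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    validate_intervals(exclusions, genome)
    excl_cov <- covered_bases(exclusions)
    if (excl_cov >= total) abort("exclusions cover the entire genome")
    roi <- subtract_intervals(roi, exclusions)
    annotation <- subtract_intervals(annotation, exclusions)
    total <- total - excl_cov
  }
  validate_intervals(roi, genome)
  validate_intervals(annotation, genome)
  a <- overlap_bases(roi, annotation)
  b <- covered_bases(annotation) - a
  cc <- covered_bases(roi) - a
  d <- total - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' Yates-corrected chi-square p-value for a 2x2 table
#'
#' @param table Named vector `c(a, b, c, d)` (row-wise 2x2).
#' @param correct Apply Yates continuity correction (default TRUE).
#' @return The p-value.
#' @export
chi_square_2x2 <- function(table, correct = TRUE) {
  m <- matrix(as.numeric(table[c("a", "b", "c", "d")]), nrow = 2, byrow = TRUE)
  suppressWarnings(stats::chisq.test(m, correct = correct)$p.value)
}

#' Odds ratio with log-scale confidence interval
#'
#' `OR = (a/b) / (c/d)`; the log-OR standard error is
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and the confidence interval is the Wald
#' interval `log OR +/- 1.96 SE`. The p-value comes from the (Yates-
#' corrected by default) chi-square test on the table; `alternative =
#' "greater"` halves it directionally. Zero cells error unless
#' `haldane = TRUE`, which adds 0.5 to each cell for the OR and CI (never
#' for the chi-square).
#'
#' @param table Named vector `c(a, b, c, d)` from [contingency()] (or SNP
#'   counts).
#' @param haldane Apply the Haldane-Anscombe +0.5 correction to zero-cell
#'   tables.
#' @param correct Yates continuity correction for the chi-square.
#' @param alternative `"two.sided"` or `"greater"` (enrichment only).
#' @param conf_mult CI half-width in standard errors (default 1.96).
#' @return An object of class `haplotx_enrichment`: list with `table`,
#'   `odds_ratio`, `log_or`, `se`, `ci_low`, `ci_high`, `p_value` (log
#'   quantities on the natural-log scale). Use [tidy()] for a one-row
#'   tibble.
#' @examples
#' odds_ratio(c(a = 150, b = 850, c = 1000, d = 9000))
#' @export
odds_ratio <- function(table, haldane = FALSE, correct = TRUE,
                       alternative = c("two.sided", "greater"),
                       conf_mult = 1.96) {
  alternative <- match.arg(alternative)
  cells <- as.numeric(table[c("a", "b", "c", "d")])
  if (any(is.na(cells)) || any(cells < 0)) abort("invalid contingency table")
  or_cells <- cells
  if (any(cells == 0)) {
    if (!haldane) {
      abort("zero cell in contingency table; set haldane = TRUE for the +0.5 correction")
    }
    or_cells <- cells + 0.5
  }
  or <- (or_cells[1] / or_cells[2]) / (or_cells[3] / or_cells[4])
  log_or <- log(or)
  se <- sqrt(sum(1 / or_cells))
  p <- chi_square_2x2(stats::setNames(cells, c("a", "b", "c", "d")),
                      correct = correct)
  if (alternative == "greater") {
    p <- if (log_or > 0) p / 2 else 1 - p / 2
  }
  structure(list(
    table = stats::setNames(cells, c("a", "b", "c", "d")),
    odds_ratio = or, log_or = log_or, se = se,
    ci_low = log_or - conf_mult * se, ci_high = log_or + conf_mult * se,
    p_value = p, alternative = alternative,
    haldane = haldane && any(cells == 0)
  ), class = "haplotx_enrichment")
}

#' @export
print.haplotx_enrichment <- function(x, ...) {
  cat(sprintf("<haplotx_enrichment> OR = %.4g, log OR = %.4g [%.4g, %.4g], p = %.3g\n",
              x$odds_ratio, x$log_or, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  table: a=%g b=%g c=%g d=%g\n",
              x$table["a"], x$table["b"], x$table["c"], x$table["d"]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an enrichment result
#'
#' @param x A `haplotx_enrichment` object.
#' @param ... Unused.
#' @return One-row tibble with the table cells, odds ratio, log OR, CI and
#'   p-value.
#' @export
tidy.haplotx_enrichment <- function(x, ...) {
  tibble(a = unname(x$table["a"]), b = unname(x$table["b"]),
         c = unname(x$table["c"]), d = unname(x$table["d"]),
         odds_ratio = x$odds_ratio, log_or = x$log_or,
         se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
         p_value = x$p_value)
}

#' @rdname tidy.haplotx_enrichment
#' @export
glance.haplotx_enrichment <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, log_or = x$log_or, p_value = x$p_value,
         alternative = x$alternative, haldane = x$haldane)
}

#' Enrichment of a region set against an annotation
#'
#' Convenience wrapper chaining [contingency()] and [odds_ratio()].
#'
#' @inheritParams contingency
#' @inheritParams odds_ratio
#' @return A `haplotx_enrichment` object.
#' @export
enrich <- function(roi, annotation, genome, exclusions = NULL,
                   haldane = FALSE, correct = TRUE,
                   alternative = "two.sided") {
  odds_ratio(contingency(roi, annotation, genome, exclusions),
             haldane = haldane, correct = correct, alternative = alternative)
}

# uniform length-preserving placement of intervals in the allowed genome
# (outside exclusions, within chromosomes); same chromosome kept unless
# cross_chrom = TRUE
place_random <- function(roi, genome, exclusions = NULL, cross_chrom = FALSE) {
  allowed <- purrr::pmap(genome, function(chrom, length) {
    tibble(chrom = chrom, start = 0, end = length)
  }) |> list_rbind()
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    allowed <- subtract_intervals(allowed, exclusions)
  }
  gaps_by_chrom <- split(allowed, allowed$chrom)
  lens <- roi$end - roi$start
  placed <- purrr::map(seq_len(nrow(roi)), function(i) {
    L <- lens[i]
    gaps <- if (cross_chrom) allowed else gaps_by_chrom[[roi$chrom[i]]]
    if (is.null(gaps)) gaps <- allowed[0, ]
    fit <- gaps[gaps$end - gaps$start >= L, , drop = FALSE]
    if (nrow(fit) == 0) {
      abort(sprintf("no gap can host an interval of length %d on %s", L, roi$chrom[i]))
    }
    w <- fit$end - fit$start - L + 1
    g <- fit[sample.int(nrow(fit), 1, prob = w), ]
    s <- g$start + floor(stats::runif(1, 0, g$end - g$start - L + 1))
    tibble(chrom = g$chrom, start = s, end = s + L)
  })
  list_rbind(placed)
}

#' Randomised placement controls for an enrichment
#'
#' Repeatedly places the region-of-interest intervals uniformly at random in
#' the allowed genome (length-preserving, same chromosome, outside the
#' exclusions) and recomputes the enrichment, giving an empirical null for
#' the observed odds ratio.
#'
#' @inheritParams contingency
#' @param n_rand Number of randomisations (default 100).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param haldane Passed to [odds_ratio()].
#' @param cross_chrom Allow placement on any chromosome.
#' @return Tibble with one row per replicate (tidied enrichment results plus
#'   a `replicate` column).
#' @export
randomized_control <- function(roi, annotation, genome, exclusions = NULL,
                               n_rand = 100, seed = 1, haldane = TRUE,
                               cross_chrom = FALSE) {
  stopifnot(n_rand >= 1)
  set.seed(seed)
  purrr::map(seq_len(n_rand), function(r) {
    shuffled <- place_random(roi, genome, exclusions, cross_chrom)
    tidy(enrich(shuffled, annotation, genome, exclusions, haldane = haldane)) |>
      mutate(replicate = r)
  }) |> list_rbind()
}

# strand-aware 5'-end windows: TSS +/- flank, clipped to the chromosome
tss_windows <- function(transcripts, genome, flank_bp = 500) {
  smry <- if ("tss" %in% names(transcripts)) transcripts else
    transcript_summary(transcripts)
  len <- genome$length[match(smry$chrom, genome$chrom)]
  tibble(chrom = smry$chrom,
         start = pmax(0, smry$tss - flank_bp),
         end = pmin(len, smry$tss + flank_bp),
         transcript_id = smry$transcript_id,
         strand = smry$strand)
}

#' TSS-proximal enrichment with GENCODE-style exclusions
#'
#' The region of interest is the strand-aware 5' end of each transcript
#' extended by `flank_bp` on both sides; excluded from all terms are the
#' promoters of the reference annotation (TSS +/- `promoter_flank_bp`) and
#' its exons widened by `exon_flank_bp`. Delegates to [contingency()],
#' [odds_ratio()] and optionally [randomized_control()].
#'
#' @param transcripts Exon-level tibble of the captured transcripts (or a
#'   summary with a `tss` column).
#' @param annotation Interval tibble of the mark being tested (CAGE
#'   clusters, histone-mark peaks, ...).
#' @param genome Genome layout tibble.
#' @param reference Annotation tibble from [read_gtf()] supplying the
#'   promoter/exon exclusion zones (may be empty).
#' @param flank_bp Half-width of the TSS window (default 500).
#' @param promoter_flank_bp,exon_flank_bp Exclusion-zone widths.
#' @param n_rand Number of randomised controls (0 for none).
#' @param seed Seed for the randomisation.
#' @param haldane Passed to [odds_ratio()].
#' @return List with `result` (a `haplotx_enrichment`) and `controls` (the
#'   randomised-control tibble, or NULL).
#' @export
tss_enrichment <- function(transcripts, annotation, genome, reference = NULL,
                           flank_bp = 500, promoter_flank_bp = 500,
                           exon_flank_bp = 200, n_rand = 0, seed = 1,
                           haldane = TRUE) {
  roi <- tss_windows(transcripts, genome, flank_bp)[, c("chrom", "start", "end")]
  exclusions <- NULL
  if (!is.null(reference) && nrow(reference) > 0) {
    ref_tx <- reference |> filter(.data$feature == "exon")
    prom <- tss_windows(ref_tx, genome, promoter_flank_bp)[, c("chrom", "start", "end")]
    len <- genome$length[match(ref_tx$chrom, genome$chrom)]
    ex <- tibble(chrom = ref_tx$chrom,
                 start = pmax(0, ref_tx$start - exon_flank_bp),
                 end = pmin(len, ref_tx$end + exon_flank_bp))
    exclusions <- merge_intervals(bind_rows(prom, ex))
  }
  result <- enrich(roi, annotation, genome, exclusions, haldane = haldane)
  controls <- if (n_rand > 0) {
    randomized_control(roi, annotation, genome, exclusions,
                       n_rand = n_rand, seed = seed, haldane = haldane)
  }
  list(result = result, controls = controls)
}

#' GWAS-SNP enrichment in transcript elements
#'
#' For each element class (promoters, exons, 3' UTRs, ...) builds a 2x2
#' SNP-count table of GWAS versus common SNPs falling in the class versus in
#' the intronic reference class, and computes the odds ratio with a
#' one-sided (greater) chi-square p-value; p-values are Benjamini-Hochberg
#' adjusted across classes. Each SNP counts as one event.
#'
#' @param elements Named list of interval tibbles, one per element class;
#'   must include `introns` (the reference class).
#' @param gwas_snps,common_snps Tibbles with `chrom`, `pos` columns.
#' @param haldane Passed to [odds_ratio()].
#' @return Tibble with one row per non-reference class: cells, OR, log OR,
#'   CI, `p_value`, `p_adj`.
#' @export
element_snp_enrichment <- function(elements, gwas_snps, common_snps,
                                   haldane = TRUE) {
  if (!"introns" %in% names(elements)) {
    abort("elements must include an 'introns' reference class")
  }
  snp_in <- function(snps, set) {
    if (nrow(snps) == 0 || nrow(set) == 0) return(0)
    pts <- tibble(chrom = snps$chrom, start = snps$pos, end = snps$pos + 1)
    sum(GenomicRanges::countOverlaps(as_gr(pts), as_gr(set),
                                     ignore.strand = TRUE) > 0)
  }
  introns <- elements$introns
  if (nrow(introns) == 0) abort("intron reference class is empty")
  g_in_intron <- snp_in(gwas_snps, introns)
  c_in_intron <- snp_in(common_snps, introns)
  classes <- setdiff(names(elements), "introns")
  out <- purrr::map(classes, function(cl) {
    tab <- c(a = snp_in(gwas_snps, elements[[cl]]),
             b = g_in_intron,
             c = snp_in(common_snps, elements[[cl]]),
             d = c_in_intron)
    tidy(odds_ratio(tab, haldane = haldane, alternative = "greater")) |>
      mutate(class = cl, .before = 1)
  }) |> list_rbind()
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
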