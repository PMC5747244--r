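#' Group transcripts into loci
#'
#' Transcripts sharing at least one exonic base on the same strand are
#' clustered transitively into one locus, mirroring how assemblers merge
#' overlapping isoforms.
#'
#' @param transcripts Exon-level tibble with `chrom`, `start`, `end`,
#'   `strand`, `transcript_id`.
#' @return The input with a `locus_id` column added.
#' @export
assign_loci <- function(transcripts) {
  stopifnot(all(c("transcript_id", "strand") %in% names(transcripts)))
  ids <- unique(transcripts$transcript_id)
  gr <- as_gr(transcripts)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
  edges <- tibble(
    from = transcripts$transcript_id[S4Vectors::queryHits(hits)],
    to = transcripts$transcript_id[S4Vectors::subjectHits(hits)]
  ) |> distinct()
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  transcripts$locus_id <- sprintf("locus_%04d",
                                  comp[transcripts$transcript_id])
  transcripts
}

# per-transcript summary: span, 5' end, exon count, length
transcript_summary <- function(transcripts) {
  transcripts |>
    group_by(.data$transcript_id) |>
    summarise(chrom = first(.data$chrom),
              strand = first(.data$strand),
              span_start = min(.data$start),
              span_end = max(.data$end),
              n_exons = n(),
              length_nt = sum(.data$end - .data$start),
              locus_id = if ("locus_id" %in% names(transcripts))
                first(.data$locus_id) else NA_character_,
              .groups = "drop") |>
    mutate(tss = ifelse(.data$strand == "-", .data$span_end - 1, .data$span_start))
}

# counts tibble (transcript_id + condition columns) -> numeric matrix
counts_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "transcript_id"), drop = FALSE])
  rownames(m) <- counts$transcript_id
  storage.mode(m) <- "double"
  m
}

#' Median-of-ratios size factors
#'
#' Per-condition normalisation factors computed as the median, over
#' transcripts with all-positive counts, of the ratio of each count to the
#' transcript's geometric mean across conditions — the classical
#' median-of-ratios estimator used for sequencing depth normalisation.
#'
#' @param counts Tibble with a `transcript_id` column and one numeric column
#'   per condition (or a bare numeric matrix).
#' @return Named numeric vector of positive size factors, one per condition.
#' @examples
#' counts <- tibble::tibble(transcript_id = c("t1", "t2"),
#'                          a = c(10, 20), b = c(20, 40))
#' size_factors(counts)
#' @export
size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  if (ncol(m) < 2) abort("need at least two conditions")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort("no transcript has positive counts in every condition; consider adding a pseudocount")
  }
  logm <- log(m[pos, , drop = FALSE])
  geo <- exp(rowMeans(logm))
  apply(m[pos, , drop = FALSE], 2, function(col) stats::median(col / geo))
}

#' Expression as fragments per kilobase per million (FPKM)
#'
#' `fpkm_ij = (count_ij / sf_j) / ((length_i / 1e3) * (N_j / 1e6))` where
#' `N_j` is the size-factor-normalised column total. FPKM is therefore
#' invariant to consistently rescaling a condition's counts and size factor.
#'
#' @param counts Counts tibble (or matrix), as for [size_factors()].
#' @param lengths Named numeric vector of transcript lengths in nt (names =
#'   transcript ids), or a vector in row order.
#' @param sf Size factors; computed with [size_factors()] when `NULL`.
#' @return Tibble with `transcript_id` and one FPKM column per condition.
#' @export
fpkm <- function(counts, lengths, sf = NULL) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  if (is.null(sf)) sf <- size_factors(m)
  stopifnot(length(sf) == ncol(m), all(sf > 0))
  if (!is.null(names(lengths)) && !is.null(rownames(m))) {
    lengths <- lengths[rownames(m)]
  }
  stopifnot(length(lengths) == nrow(m), all(lengths > 0))
  norm <- sweep(m, 2, sf, "/")
  totals <- colSums(norm)
  if (any(totals == 0)) abort("a condition has zero total counts")
  f <- sweep(norm, 2, totals / 1e6, "/")
  f <- sweep(f, 1, lengths / 1e3, "/")
  out <- as_tibble(f)
  out$transcript_id <- rownames(m)
  out[, c("transcript_id", setdiff(names(out), "transcript_id"))]
}

max_fpkm <- function(fpkm_tbl) {
  m <- counts_matrix(fpkm_tbl)
  tibble(transcript_id = rownames(m),
         max_fpkm = apply(m, 1, max),
         max_condition = colnames(m)[apply(m, 1, which.max)])
}

#' Filter assembled transcript models
#'
#' Retains a transcript iff it (i) overlaps the capture-space target regions
#' by at least one exonic base, (ii) reaches FPKM above `fpkm_min` in at
#' least one condition, (iii) is multi-exonic (spliced), and (iv) as an
#' isoform contributes more than `isoform_min_frac` of its locus's total
#' expression, the share being evaluated in the condition where the locus is
#' maximally expressed.
#'
#' @param transcripts Exon-level tibble with `locus_id` (see
#'   [assign_loci()]).
#' @param fpkm_tbl FPKM tibble from [fpkm()].
#' @param capture Interval tibble of capture-space target regions.
#' @param fpkm_min Expression threshold (default 1, strict `>`).
#' @param isoform_min_frac Minimum isoform share of locus expression
#'   (default 0.01, strict `>`).
#' @return Tibble with one row per retained transcript: `transcript_id`,
#'   `locus_id`, `max_fpkm`, `max_condition`, `isoform_frac`.
#' @export
retain_transcripts <- function(transcripts, fpkm_tbl, capture,
                               fpkm_min = 1, isoform_min_frac = 0.01) {
  if (!"locus_id" %in% names(transcripts) ||
      any(is.na(transcripts$locus_id))) {
    abort("every transcript needs a locus assignment; run assign_loci() first")
  }
  smry <- transcript_summary(transcripts)
  fm <- counts_matrix(fpkm_tbl)
  missing_expr <- setdiff(smry$transcript_id, rownames(fm))
  if (length(missing_expr) > 0) {
    abort(paste0("transcripts without expression rows: ",
                 paste(utils::head(missing_expr, 5), collapse = ", ")))
  }

  # (i) exonic overlap with the capture space
  ov <- GenomicRanges::countOverlaps(as_gr(transcripts), as_gr(capture),
                                     ignore.strand = TRUE)
  in_capture <- transcripts |>
    mutate(hit = ov > 0) |>
    group_by(.data$transcript_id) |>
    summarise(in_capture = any(.data$hit), .groups = "drop")

  # (iv) isoform share at the locus's maximal-expression condition
  fm_tx <- fm[smry$transcript_id, , drop = FALSE]
  locus_of <- stats::setNames(smry$locus_id, smry$transcript_id)
  locus_tot <- rowsum(fm_tx, locus_of[rownames(fm_tx)])
  peak_cond <- colnames(locus_tot)[apply(locus_tot, 1, which.max)]
  names(peak_cond) <- rownames(locus_tot)
  share <- vapply(seq_len(nrow(fm_tx)), function(i) {
    loc <- locus_of[rownames(fm_tx)[i]]
    cond <- peak_cond[loc]
    tot <- locus_tot[loc, cond]
    if (tot == 0) 0 else fm_tx[i, cond] / tot
  }, numeric(1))

  smry |>
    left_join(in_capture, by = "transcript_id") |>
    left_join(max_fpkm(fpkm_tbl), by = "transcript_id") |>
    mutate(isoform_frac = share[match(.data$transcript_id, rownames(fm_tx))]) |>
    filter(.data$in_capture,
           .data$max_fpkm > fpkm_min,
           .data$n_exons >= 2,
           .data$isoform_frac > isoform_min_frac) |>
    select("transcript_id", "locus_id", "chrom", "strand", "span_start",
           "span_end", "tss", "n_exons", "length_nt", "max_fpkm",
           "max_condition", "isoform_frac")
}

#' Assign expression tiers
#'
#' Partitions retained transcripts into `low` / `medium` / `high` tiers by
#' tertiles of their maximal FPKM across conditions; ties at a boundary go
#' to the lower tier, so the assignment is monotone in expression.
#'
#' @param retained Tibble with `transcript_id` and `max_fpkm` (e.g. from
#'   [retain_transcripts()]).
#' @return The input with an ordered-factor `tier` column.
#' @export
expression_tiers <- function(retained) {
  stopifnot(nrow(retained) > 0)
  q <- stats::quantile(retained$max_fpkm, c(1/3, 2/3), names = FALSE)
  tier <- ifelse(retained$max_fpkm <= q[1], "low",
                 ifelse(retained$max_fpkm <= q[2], "medium", "high"))
  retained$tier <- factor(tier, levels = c("low", "medium", "high"),
                          ordered = TRUE)
  retained
}

#' Haploblock occupancy by retained transcripts
#'
#' A block is occupied when at least one retained transcript with maximal
#' FPKM above `fpkm_min` has at least one exonic base inside it.
#'
#' @param blocks Interval tibble of haploblocks (any extra columns kept).
#' @param transcripts Exon-level tibble of the retained transcripts.
#' @param retained Retained-transcript tibble with `max_fpkm` (from
#'   [retain_transcripts()]).
#' @param fpkm_min Expression threshold (strict `>`).
#' @return List with `per_block` (blocks plus an `occupied` flag) and
#'   `fraction_occupied` (mean of the flags).
#' @export
occupancy <- function(blocks, transcripts, retained, fpkm_min = 1) {
  validate_intervals(blocks)
  keep_ids <- retained$transcript_id[retained$max_fpkm > fpkm_min]
  ex <- transcripts[transcripts$transcript_id %in% keep_ids, , drop = FALSE]
  occ <- if (nrow(ex) == 0) rep(FALSE, nrow(blocks)) else
    GenomicRanges::countOverlaps(as_gr(blocks), as_gr(ex),
                                 ignore.strand = TRUE) > 0
  blocks$occupied <- occ
  list(per_block = blocks,
       fraction_occupied = if (nrow(blocks) == 0) NA_real_ else mean(occ))
}
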