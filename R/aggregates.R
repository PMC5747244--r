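#' Aggregate (metaplot) profile of peaks around transcript 5' ends
#'
#' For every transcript expressed in the track's condition (FPKM strictly
#' above `min_expr`), peak elements are assigned by midpoint to fixed-width
#' bins of strand-oriented offset from the transcript's 5' end (negative =
#' upstream), summed over transcripts, and divided by the number of
#' transcripts, so `normalized_count * n_transcripts` recovers the integer
#' raw count in every bin.
#'
#' @param transcripts Exon-level tibble (or summary with `tss`, `strand`).
#' @param peaks Interval tibble of peak calls / CAGE clusters.
#' @param fpkm_tbl FPKM tibble; `NULL` skips the expression filter.
#' @param condition Column of `fpkm_tbl` naming the track's tissue.
#' @param flank_bp Window half-width (default 5000).
#' @param bin_bp Bin width (default 100).
#' @param min_expr Strict FPKM lower bound for inclusion (default 0).
#' @return An object of class `haplotx_profile`: tibble with `offset` (bin
#'   left edge relative to the 5' end), `raw_count`, `normalized_count`,
#'   and attribute `n_transcripts`.
#' @export
aggregate_profile <- function(transcripts, peaks, fpkm_tbl = NULL,
                              condition = NULL, flank_bp = 5000,
                              bin_bp = 100, min_expr = 0) {
  smry <- if ("tss" %in% names(transcripts)) transcripts else
    transcript_summary(transcripts)
  if (!is.null(fpkm_tbl)) {
    stopifnot(!is.null(condition), condition %in% names(fpkm_tbl))
    expressed <- fpkm_tbl$transcript_id[fpkm_tbl[[condition]] > min_expr]
    smry <- smry[smry$transcript_id %in% expressed, , drop = FALSE]
  }
  if (nrow(smry) == 0) abort("no transcript passes the expression filter")
  edges <- seq(-flank_bp, flank_bp, by = bin_bp)
  mids <- floor((peaks$start + peaks$end) / 2)
  counts <- rep(0L, length(edges) - 1)
  for (i in seq_len(nrow(smry))) {
    on_chrom <- peaks$chrom == smry$chrom[i]
    if (!any(on_chrom)) next
    off <- if (smry$strand[i] == "-") smry$tss[i] - mids[on_chrom] else
      mids[on_chrom] - smry$tss[i]
    keep <- off >= -flank_bp & off < flank_bp
    if (any(keep)) {
      b <- findInterval(off[keep], edges, rightmost.closed = FALSE)
      tb <- tabulate(b, nbins = length(counts))
      counts <- counts + tb
    }
  }
  res <- tibble(offset = edges[-length(edges)],
                raw_count = counts,
                normalized_count = counts / nrow(smry))
  attr(res, "n_transcripts") <- nrow(smry)
  class(res) <- c("haplotx_profile", class(res))
  res
}

#' @export
autoplot.haplotx_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset + diff(object$offset[1:2]) / 2,
                                       y = .data$normalized_count)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "offset from 5' end (bp)",
                  y = "peaks per transcript",
                  title = sprintf("Aggregate profile (n = %d transcripts)",
                                  attr(object, "n_transcripts"))) +
    ggplot2::theme_minimal()
}

#' Fraction of transcript promoters occupied by a mark
#'
#' A promoter is the transcript's 5'-end window (TSS +/- `flank_bp`); it is
#' occupied when it overlaps at least one peak of the mark.
#'
#' @param transcripts Exon-level tibble (or summary with `tss`).
#' @param peaks Interval tibble of the mark's peaks.
#' @param genome Genome layout (windows are clipped to chromosome ends).
#' @param flank_bp Promoter half-width (default 500).
#' @return List with `per_transcript` (tibble: `transcript_id`, `occupied`)
#'   and `fraction`.
#' @export
promoter_occupancy <- function(transcripts, peaks, genome, flank_bp = 500) {
  win <- tss_windows(transcripts, genome, flank_bp)
  occ <- if (nrow(peaks) == 0) rep(FALSE, nrow(win)) else
    GenomicRanges::countOverlaps(as_gr(win[, c("chrom", "start", "end")]),
                                 as_gr(peaks), ignore.strand = TRUE) > 0
  list(per_transcript = tibble(transcript_id = win$transcript_id, occupied = occ),
       fraction = if (nrow(win) == 0) NA_real_ else mean(occ))
}

#' Expression-matched positive-control selection
#'
#' Ranks candidate transcripts (e.g. annotated lncRNAs) by the distance of
#' their median expression across conditions from a target median, and
#' returns the `size` nearest candidates — an expression-matched positive
#' control set for aggregate profiles.
#'
#' @param candidate_expr Tibble `transcript_id` + condition columns.
#' @param target_median Target median expression (e.g.
#'   `median(apply(fpkm_of_analyzed, 1, median))`).
#' @param size Number of controls; when larger than the candidate pool, all
#'   candidates are returned with a warning.
#' @return Tibble `transcript_id`, `median_expr`, sorted by match quality.
#' @export
matched_lnc_control <- function(candidate_expr, target_median, size) {
  stopifnot(nrow(candidate_expr) > 0)
  m <- counts_matrix(candidate_expr)
  med <- apply(m, 1, stats::median)
  ranked <- tibble(transcript_id = rownames(m), median_expr = unname(med)) |>
    arrange(abs(.data$median_expr - target_median), .data$transcript_id)
  if (size > nrow(ranked)) {
    warn(sprintf("requested %d controls but only %d candidates; returning all",
                 size, nrow(ranked)))
    return(ranked)
  }
  ranked[seq_len(size), ]
}

#' Call bidirectional promoters
#'
#' Each transcript's genomic span is extended by `extend_bp` at its 5' end;
#' a transcript is bidirectional when its extended span overlaps the
#' extended span of at least one opposite-strand transcript. The relation is
#' symmetric by construction.
#'
#' @param transcripts Exon-level tibble (or summary with `span_start`,
#'   `span_end`, `strand`).
#' @param extend_bp 5' extension in bases (default 500).
#' @return List with `per_transcript` (tibble: `transcript_id`,
#'   `bidirectional`) and `fraction`.
#' @export
call_bidirectional <- function(transcripts, extend_bp = 500) {
  smry <- if ("span_start" %in% names(transcripts)) transcripts else
    transcript_summary(transcripts)
  ext <- tibble(
    chrom = smry$chrom,
    start = pmax(0, ifelse(smry$strand == "-", smry$span_start,
                           smry$span_start - extend_bp)),
    end = ifelse(smry$strand == "-", smry$span_end + extend_bp, smry$span_end),
    strand = smry$strand
  )
  gr <- as_gr(ext[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  opp <- q != s & ext$strand[q] != ext$strand[s]
  flag <- seq_len(nrow(ext)) %in% q[opp]
  list(per_transcript = tibble(transcript_id = smry$transcript_id,
                               bidirectional = flag),
       fraction = if (nrow(ext) == 0) NA_real_ else mean(flag))
}
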