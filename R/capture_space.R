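#' Exclude haploblocks containing coding exons or that are too short
#'
#' A block is removed when it overlaps any coding exon by at least one base,
#' or when its total length is under `min_len_bp`.
#'
#' @param blocks Interval tibble of haploblocks.
#' @param coding_exons Interval tibble of coding exons (e.g. the exons of
#'   `protein_coding` genes from one or more annotations).
#' @param min_len_bp Minimum retained block length in bases (default 3000).
#' @return The surviving rows of `blocks`.
#' @export
exclude_blocks <- function(blocks, coding_exons, min_len_bp = 3000) {
  validate_intervals(blocks)
  long_enough <- (blocks$end - blocks$start) >= min_len_bp
  if (nrow(coding_exons) > 0) {
    hits <- GenomicRanges::countOverlaps(as_gr(blocks), as_gr(coding_exons),
                                         ignore.strand = TRUE)
    clean <- hits == 0
  } else {
    clean <- rep(TRUE, nrow(blocks))
  }
  blocks[long_enough & clean, , drop = FALSE]
}

# exon intervals of genes with a given gene_type, from a read_gtf() tibble
exons_of_type <- function(annotation, types) {
  ex <- annotation |>
    filter(.data$feature == "exon", .data$gene_type %in% types)
  ex[, c("chrom", "start", "end")]
}

#' Build the capture space from haploblocks and a gene annotation
#'
#' The capture space is the union of the (collapsed) haploblock regions with
#' all exons of `protein_coding` and `lincRNA` genes removed by interval
#' subtraction; exon removal uses the union of exons across every transcript
#' of those genes.
#'
#' @param blocks Interval tibble of haploblock regions (post-exclusion).
#' @param annotation Annotation tibble from [read_gtf()] with `feature` and
#'   `gene_type` columns.
#' @param exclude_types Gene types whose exons are removed.
#' @param extra_exclusions Optional interval tibble subtracted as well (e.g.
#'   RefSeq coding exons from a second annotation, or pilot intron controls).
#' @return Interval tibble of target regions (merged, sorted, disjoint from
#'   every excluded exon).
#' @export
build_capture_space <- function(blocks, annotation,
                                exclude_types = c("protein_coding", "lincRNA"),
                                extra_exclusions = NULL) {
  excl <- exons_of_type(annotation, exclude_types)
  if (!is.null(extra_exclusions) && nrow(extra_exclusions) > 0) {
    excl <- bind_rows(excl, extra_exclusions[, c("chrom", "start", "end")])
  }
  target <- if (nrow(excl) == 0) merge_intervals(blocks) else
    subtract_intervals(blocks, excl)
  if (nrow(target) == 0) {
    abort("capture space is empty: excluded exons cover every block (annotation/blocks mismatch?)")
  }
  target
}

# introns of one transcript = gaps between its sorted exons
transcript_introns <- function(exons) {
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) < 2) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  tibble(chrom = exons$chrom[-1],
         start = exons$end[-nrow(exons)],
         end = exons$start[-1]) |>
    filter(.data$end > .data$start)
}

#' Select intronic control regions
#'
#' For each expressed locus, one random intron is picked and a subregion of
#' 200 nt to 1 kb is drawn from it (length uniform in the range, placement
#' uniform within the intron). Candidates whose repeat-covered base fraction
#' exceeds `repeat_max_frac` are rejected and another intron of the locus is
#' tried; a locus whose introns all fail is omitted.
#'
#' @param transcripts Exon-level tibble with `chrom`, `start`, `end`,
#'   `transcript_id` and a `locus_id` column (see [assign_loci()]).
#' @param repeats Interval tibble of repeat annotation.
#' @param seed Integer seed making the random selection reproducible.
#' @param len_range Length range of a control region, in bases.
#' @param repeat_max_frac Maximum tolerated repeat base fraction.
#' @return Interval tibble of controls with `locus_id` and `repeat_frac`
#'   columns; at most one row per locus.
#' @export
pick_intron_controls <- function(transcripts, repeats, seed = 1,
                                 len_range = c(200, 1000),
                                 repeat_max_frac = 0.75) {
  stopifnot("locus_id" %in% names(transcripts))
  repeats <- if (nrow(repeats) > 0) merge_intervals(repeats) else repeats
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  loci <- split(transcripts, transcripts$locus_id)
  out <- purrr::imap(loci, function(tx, locus_id) {
    introns <- split(tx, tx$transcript_id) |>
      purrr::map(transcript_introns) |>
      list_rbind() |>
      distinct() |>
      filter(.data$end - .data$start >= len_range[1])
    if (nrow(introns) == 0) return(NULL)
    for (i in sample.int(nrow(introns))) {
      intron <- introns[i, ]
      max_len <- min(len_range[2], intron$end - intron$start)
      len <- floor(stats::runif(1, len_range[1], max_len + 1))
      start <- intron$start +
        floor(stats::runif(1, 0, intron$end - intron$start - len + 1))
      ctrl <- tibble(chrom = intron$chrom, start = start, end = start + len)
      rf <- if (nrow(repeats) == 0) 0 else overlap_bases(ctrl, repeats) / len
      if (rf <= repeat_max_frac) {
        ctrl$locus_id <- locus_id
        ctrl$repeat_frac <- rf
        return(ctrl)
      }
    }
    message(sprintf("locus %s: all introns exceed repeat fraction %.2f; omitted",
                    locus_id, repeat_max_frac))
    NULL
  })
  compact <- purrr::compact(out)
  if (length(compact) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  locus_id = character(), repeat_frac = numeric()))
  }
  list_rbind(compact) |> arrange(.data$chrom, .data$start)
}
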