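#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn
#' @importFrom purrr map map_dbl map_lgl map2 pmap list_rbind
NULL

# Internal coordinates are 0-based half-open throughout: an interval covers
# bases start, start+1, ..., end-1. BED I/O is native; GTF I/O converts from
# 1-based inclusive at the file boundary.

#' Construct an interval tibble
#'
#' Intervals are plain tibbles with columns `chrom`, `start`, `end` and
#' optionally `strand` (`"+"`, `"-"` or `"*"`), using 0-based half-open
#' coordinates. Every interval function in the package takes and returns
#' this shape, so results chain with the pipe.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like vectors; `start >= 0`, `end > start`.
#' @param strand Optional strand vector; recycled.
#' @param ... Further columns carried along (e.g. `name`, `score`).
#' @return A tibble with one row per interval.
#' @examples
#' intervals("chr1", c(10, 15), c(20, 30))
#' @export
intervals <- function(chrom, start, end, strand = NULL, ...) {
  x <- tibble(chrom = as.character(chrom),
              start = as.numeric(start),
              end   = as.numeric(end), ...)
  if (!is.null(strand)) x$strand <- as.character(strand)
  validate_intervals(x)
  x
}

#' Validate an interval tibble
#'
#' Checks column presence, `start >= 0`, `end > start`, non-empty `chrom`,
#' and (when a genome layout is supplied) that every interval lies on a known
#' chromosome with `end <= length`.
#'
#' @param x Interval tibble.
#' @param genome Optional genome layout tibble (`chrom`, `length`), e.g. from
#'   [read_chrom_sizes()].
#' @return `x`, invisibly, for piping.
#' @export
validate_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("interval table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | x$chrom == "")) abort("empty chromosome name")
  if (any(x$start < 0)) abort("interval start < 0")
  if (any(x$end <= x$start)) abort("interval end <= start (half-open, must be non-empty)")
  if (!is.null(genome)) {
    m <- match(x$chrom, genome$chrom)
    if (anyNA(m)) {
      abort(paste0("chromosome not in genome layout: ",
                   paste(unique(x$chrom[is.na(m)]), collapse = ", ")))
    }
    over <- which(x$end > genome$length[m])
    if (length(over) > 0) {
      i <- over[1]
      abort(sprintf("interval %s:%d-%d extends beyond chromosome length %d",
                    x$chrom[i], x$start[i], x$end[i], genome$length[m[i]]))
    }
  }
  invisible(x)
}

# interval tibble -> GRanges (1-based closed internally to GenomicRanges)
as_gr <- function(x) {
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges())
  }
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = strand
  )
}

gr_to_tbl <- function(gr) {
  if (length(gr) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1,
         end   = as.numeric(GenomicRanges::end(gr))) |>
    arrange(.data$chrom, .data$start)
}

#' Merge (collapse) intervals into a disjoint sorted set
#'
#' Strand-agnostic union: bookended and overlapping intervals are collapsed
#' so the result is sorted and pairwise disjoint per chromosome, covering
#' exactly the same bases as the input.
#'
#' @param x Interval tibble.
#' @param genome Optional genome layout; when given, intervals beyond the
#'   chromosome end raise an error naming the offending interval.
#' @return Interval tibble (`chrom`, `start`, `end`), merged and sorted.
#' @examples
#' intervals("chr1", c(10, 15), c(20, 30)) |> merge_intervals()
#' @export
merge_intervals <- function(x, genome = NULL) {
  validate_intervals(x, genome)
  gr_to_tbl(GenomicRanges::reduce(as_gr(x), ignore.strand = TRUE))
}

#' Subtract one interval set from another
#'
#' Returns the bases covered by `a` but not by `b`, as a merged, sorted set.
#'
#' @param a,b Interval tibbles.
#' @return Interval tibble covering `a \ b`.
#' @examples
#' subtract_intervals(intervals("chr1", 0, 10000), intervals("chr1", 2000, 3000))
#' @export
subtract_intervals <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  gr_to_tbl(GenomicRanges::setdiff(
    GenomicRanges::reduce(as_gr(a), ignore.strand = TRUE),
    GenomicRanges::reduce(as_gr(b), ignore.strand = TRUE),
    ignore.strand = TRUE
  ))
}

#' Count bases shared by two interval sets
#'
#' Strand-agnostic: each genomic base is counted once however many intervals
#' cover it, so `overlap_bases(a, a)` equals the covered-base count of `a`.
#'
#' @param a,b Interval tibbles.
#' @return A single numeric base count.
#' @export
overlap_bases <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  ov <- GenomicRanges::intersect(
    GenomicRanges::reduce(as_gr(a), ignore.strand = TRUE),
    GenomicRanges::reduce(as_gr(b), ignore.strand = TRUE),
    ignore.strand = TRUE
  )
  sum(as.numeric(GenomicRanges::width(ov)))
}

#' Total bases covered by an interval set
#'
#' @param x Interval tibble.
#' @return Numeric base count of the union of `x`.
#' @export
covered_bases <- function(x) {
  validate_intervals(x)
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

## ---- readers / writers -----------------------------------------------------

#' Read a genome layout from a chrom-sizes file
#'
#' Two tab-separated columns: chromosome name and length in bases.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  if (any(x$length <= 0)) abort("chromosome length must be > 0")
  x
}

#' Read a BED3/BED6 file as an interval tibble
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' coordinates pass through unchanged. Columns 4-6 (`name`, `score`,
#' `strand`) are kept when present.
#'
#' @param path File path.
#' @return Interval tibble.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       comment = "#", progress = FALSE)
  if (ncol(x) < 3) abort("BED file needs at least 3 columns")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(x)[seq_len(min(ncol(x), 6))] <- nm[seq_len(min(ncol(x), 6))]
  x <- as_tibble(x[, seq_len(min(ncol(x), 6))])
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  validate_intervals(x)
  x
}

#' Write an interval tibble as BED
#'
#' Emits BED3 or, when `name`/`score`/`strand` columns exist, BED6 with
#' missing middle columns filled by `.` / `0`.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  out <- tibble(chrom = x$chrom,
                start = format(x$start, scientific = FALSE, trim = TRUE),
                end = format(x$end, scientific = FALSE, trim = TRUE))
  extras <- intersect(c("name", "score", "strand"), names(x))
  if (length(extras) > 0) {
    out$name <- if ("name" %in% names(x)) as.character(x$name) else "."
    out$score <- if ("score" %in% names(x)) x$score else 0
    if ("strand" %in% names(x)) out$strand <- x$strand
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read transcript/gene models from a GTF file
#'
#' Parses `exon`, `transcript` and `gene` features with their `gene_id`,
#' `transcript_id` and `gene_type` attributes, converting to the package's
#' 0-based half-open coordinates. Rows are exon-level records.
#'
#' @param path GTF file path.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`, `feature`,
#'   `gene_id`, `transcript_id`, `gene_type`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- as.character(gr$type) %in% c("exon", "transcript", "gene")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  grab <- function(col) {
    if (col %in% names(md)) as.character(md[[col]]) else rep(NA_character_, length(gr))
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = as.character(gr$type),
    gene_id = grab("gene_id"),
    transcript_id = grab("transcript_id"),
    gene_type = grab("gene_type")
  ) |> arrange(.data$chrom, .data$start)
}

#' Write exon-level transcript models as GTF
#'
#' @param x Tibble with `chrom`, `start`, `end`, `strand`, `transcript_id`
#'   and optionally `gene_id`, `gene_type`; one row per exon, 0-based
#'   half-open (converted to GTF's 1-based inclusive on output).
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path, source = "haplotx") {
  validate_intervals(x)
  gene_id <- if ("gene_id" %in% names(x)) x$gene_id else x$transcript_id
  gene_type <- if ("gene_type" %in% names(x)) x$gene_type else NA_character_
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', gene_id, x$transcript_id)
  has_type <- !is.na(gene_type)
  attr_str[has_type] <- paste0(attr_str[has_type],
                               sprintf(' gene_type "%s";', gene_type[has_type]))
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   x$chrom, source, as.integer(x$start) + 1L, as.integer(x$end),
                   x$strand, attr_str)
  writeLines(lines, path)
  invisible(path)
}
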