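#' Rule sets for LD-block delineation
#'
#' Two rule sets are supported. Under the `main` rules a block is extended
#' from the index SNP to the most distant proxy with r2 above `r2_extend` on
#' each side, clipped to `side_cap_bp` per side; a side with no proxy below
#' `r2_sufficient` (LD never decays, so the boundary cannot be located) is
#' then extended to the nearest recombination hotspot beyond the current
#' boundary. Under the `pilot` rules both proxy-extent boundaries are always
#' extended to the nearest hotspots and the total block length is capped at
#' `total_cap_bp`.
#'
#' @param r2_extend Proxy r2 threshold for boundary extension (default 0.5,
#'   strict inequality `r2 > r2_extend`).
#' @param r2_sufficient Sufficiency threshold: a side is insufficient when no
#'   proxy on it has `r2 < r2_sufficient` (default 0.6).
#' @param side_cap_bp Per-side cap around the index SNP (main rules; 500 kb).
#' @param total_cap_bp Total block cap (pilot rules; 1 Mb).
#' @param hotspot_extension `"always"` (pilot) or `"if_insufficient"` (main).
#' @return A `block_rules` list.
#' @export
block_rules <- function(r2_extend = 0.5, r2_sufficient = 0.6,
                        side_cap_bp = 500000, total_cap_bp = 1000000,
                        hotspot_extension = c("if_insufficient", "always")) {
  hotspot_extension <- match.arg(hotspot_extension)
  stopifnot(r2_extend > 0, r2_extend <= r2_sufficient, r2_sufficient <= 1,
            side_cap_bp > 0, total_cap_bp > 0)
  structure(list(r2_extend = r2_extend, r2_sufficient = r2_sufficient,
                 side_cap_bp = side_cap_bp, total_cap_bp = total_cap_bp,
                 hotspot_extension = hotspot_extension),
            class = "block_rules")
}

#' @rdname block_rules
#' @export
main_rules <- function() block_rules(hotspot_extension = "if_insufficient")

#' @rdname block_rules
#' @export
pilot_rules <- function() block_rules(hotspot_extension = "always")

# nearest hotspot strictly beyond `from`, moving away from the index SNP;
# ties (equal distance) break toward the smaller extension, which cannot
# occur for distinct positions on one side. Returns NA if none exists.
nearest_hotspot_beyond <- function(hot_pos, from, direction) {
  cand <- if (direction < 0) hot_pos[hot_pos < from] else hot_pos[hot_pos > from]
  if (length(cand) == 0) return(NA_real_)
  if (direction < 0) max(cand) else min(cand)
}

build_block_one <- function(index_pos, chrom, proxy_pos, proxy_r2, hot_pos,
                            rules, index_id, rule_set) {
  stopifnot(index_pos >= 0)
  side_cap <- rules$side_cap_bp
  apply_side_cap <- identical(rules$hotspot_extension, "if_insufficient")

  side <- function(direction) {
    on_side <- if (direction < 0) proxy_pos < index_pos else proxy_pos > index_pos
    pos <- proxy_pos[on_side]; r2 <- proxy_r2[on_side]
    # Step 1: most distant proxy above the extension threshold, then clip
    ext <- pos[r2 > rules$r2_extend]
    boundary <- if (length(ext) == 0) index_pos else if (direction < 0) min(ext) else max(ext)
    rule <- "proxy_extent"
    if (apply_side_cap) {
      lim <- index_pos + direction * side_cap
      if ((direction < 0 && boundary < lim) || (direction > 0 && boundary > lim)) {
        boundary <- lim
        rule <- "cap"
      }
    }
    # Sufficiency uses only proxies within the cap: a side is insufficient
    # when none of them has r2 below the sufficiency threshold (an empty
    # side also counts as insufficient)
    r2_in <- if (apply_side_cap) r2[abs(pos - index_pos) <= side_cap] else r2
    insufficient <- !any(r2_in < rules$r2_sufficient)
    list(boundary = boundary, insufficient = insufficient, rule = rule)
  }

  left <- side(-1); right <- side(+1)
  warnings <- character()

  extend <- function(s, direction, do_extend) {
    if (!do_extend) return(s)
    hp <- nearest_hotspot_beyond(hot_pos, s$boundary, direction)
    if (is.na(hp)) {
      warnings <<- c(warnings, sprintf(
        "no hotspot %s of %s for index %s; boundary left at proxy extent",
        if (direction < 0) "upstream" else "downstream", s$boundary, index_id))
      return(s)
    }
    s$boundary <- hp
    s$rule <- "hotspot"
    s
  }

  if (identical(rules$hotspot_extension, "always")) {
    left <- extend(left, -1, TRUE)
    right <- extend(right, +1, TRUE)
  } else {
    left <- extend(left, -1, left$insufficient)
    right <- extend(right, +1, right$insufficient)
  }

  start <- left$boundary
  end <- right$boundary + 1  # boundary SNP base included (half-open)

  if (identical(rules$hotspot_extension, "always")) {
    # pilot total cap: trim each side proportionally to its overhang beyond
    # half the cap from the index SNP
    total <- end - start
    if (total > rules$total_cap_bp) {
      half <- rules$total_cap_bp / 2
      left_ext <- index_pos - start
      right_ext <- end - index_pos
      over_l <- max(0, left_ext - half)
      over_r <- max(0, right_ext - half)
      excess <- total - rules$total_cap_bp
      trim_l <- if (over_l + over_r > 0) excess * over_l / (over_l + over_r) else 0
      trim_r <- excess - trim_l
      start <- start + round(trim_l)
      end <- end - round(trim_r)
      if (end - start > rules$total_cap_bp) end <- start + rules$total_cap_bp
      if (left$boundary < start) left$rule <- "cap"
      if (right$boundary + 1 > end) right$rule <- "cap"
    }
  }

  tibble(
    chrom = chrom, start = start, end = end,
    index_snp_id = index_id, index_pos = index_pos,
    left_rule = left$rule, right_rule = right$rule,
    rule_set = rule_set,
    flagged = length(warnings) > 0,
    warning = if (length(warnings) > 0) paste(warnings, collapse = "; ") else NA_character_
  )
}

#' Delineate LD blocks around index GWAS SNPs
#'
#' For each index SNP in `proxies`, builds a haploblock from its proxy-SNP r2
#' values and the recombination hotspots on the same chromosome, under either
#' the `main` or `pilot` rule set (see [block_rules()]). Boundary provenance
#' (`proxy_extent`, `hotspot`, or `cap`) is recorded for both sides, and a
#' side that required hotspot extension but had no hotspot available is
#' flagged with its boundary left at the proxy extent.
#'
#' @param proxies Tibble with columns `index_snp_id`, `proxy_snp_id`,
#'   `chrom`, `pos` (0-based), `r2`. Rows for the index SNP itself (with
#'   `pos` equal to the index position) are identified by
#'   `proxy_snp_id == index_snp_id` or may be supplied via `index_snps`.
#' @param hotspots Tibble with columns `chrom`, `pos` (point hotspots).
#'   Interval (BED) hotspots should be reduced to the edge nearer the index
#'   SNP before calling; [read_hotspots()] does this for BED input.
#' @param rules A [block_rules()] object; defaults to the main rules.
#' @param index_snps Optional tibble `index_snp_id`, `chrom`, `pos` giving
#'   index positions explicitly; otherwise taken from self-proxy rows.
#' @return One-row-per-block tibble: `chrom`, `start`, `end`,
#'   `index_snp_id`, `index_pos`, `left_rule`, `right_rule`, `rule_set`,
#'   `flagged`, `warning`. Each block contains its index SNP.
#' @examples
#' pr <- tibble::tibble(index_snp_id = "rs1", proxy_snp_id = c("rs1", "p1", "p2"),
#'                      chrom = "chr1", pos = c(100000, 90000, 110000),
#'                      r2 = c(1, 0.7, 0.7))
#' hs <- tibble::tibble(chrom = "chr1", pos = c(70000, 130000))
#' build_haploblocks(pr, hs, rules = main_rules())
#' @export
build_haploblocks <- function(proxies, hotspots, rules = main_rules(),
                              index_snps = NULL) {
  stopifnot(all(c("index_snp_id", "chrom", "pos", "r2") %in% names(proxies)))
  if (nrow(proxies) > 0 && (any(proxies$r2 < 0, na.rm = TRUE) ||
                            any(proxies$r2 > 1, na.rm = TRUE))) {
    abort("r2 must lie in [0, 1]")
  }
  if (is.null(index_snps)) {
    index_snps <- proxies |>
      filter(.data$proxy_snp_id == .data$index_snp_id) |>
      distinct(.data$index_snp_id, .data$chrom, .data$pos)
    if (nrow(index_snps) == 0) {
      abort("no index-SNP rows found; supply `index_snps` explicitly")
    }
  }
  rule_set <- if (identical(rules$hotspot_extension, "always")) "pilot" else "main"
  out <- purrr::pmap(index_snps, function(index_snp_id, chrom, pos, ...) {
    px <- proxies[proxies$index_snp_id == index_snp_id &
                    proxies$chrom == chrom &
                    proxies$pos != pos, , drop = FALSE]
    hp <- sort(hotspots$pos[hotspots$chrom == chrom])
    build_block_one(pos, chrom, px$pos, px$r2, hp, rules, index_snp_id, rule_set)
  }) |> list_rbind()
  if (any(out$flagged)) {
    warn(sprintf("%d block(s) flagged: hotspot extension requested but no hotspot found",
                 sum(out$flagged)))
  }
  out
}

#' Collapse haploblocks into a non-redundant region set
#'
#' Merges (possibly overlapping) blocks from any mix of rule sets into
#' disjoint genomic regions, retaining the mapping from each region to the
#' index SNPs whose blocks contributed to it.
#'
#' @param blocks Block tibble from [build_haploblocks()] (or any interval
#'   tibble with an `index_snp_id` column).
#' @return Interval tibble with columns `chrom`, `start`, `end`,
#'   `region_id`, `index_snps` (comma-separated contributing index SNP ids).
#' @export
collapse_blocks <- function(blocks) {
  merged <- merge_intervals(blocks)
  merged$region_id <- sprintf("region_%03d", seq_len(nrow(merged)))
  if ("index_snp_id" %in% names(blocks)) {
    hits <- GenomicRanges::findOverlaps(as_gr(merged), as_gr(blocks),
                                        ignore.strand = TRUE)
    contrib <- tibble(region = S4Vectors::queryHits(hits),
                      snp = blocks$index_snp_id[S4Vectors::subjectHits(hits)]) |>
      group_by(.data$region) |>
      summarise(index_snps = paste(unique(.data$snp), collapse = ","),
                .groups = "drop")
    merged$index_snps <- NA_character_
    merged$index_snps[contrib$region] <- contrib$index_snps
  }
  merged
}

#' Read a proxy-SNP table
#'
#' Tab-separated columns `index_snp_id`, `proxy_snp_id`, `chrom`, `pos`,
#' `r2` (header required).
#'
#' @param path File path.
#' @return Tibble of proxy records.
#' @export
read_proxies <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    index_snp_id = "c", proxy_snp_id = "c", chrom = "c",
    pos = "d", r2 = "d"), progress = FALSE)
}

#' Read recombination hotspots
#'
#' Accepts a two-column TSV (`chrom`, `pos`) or a BED file. BED intervals
#' are point-reduced: when `index_pos` for the relevant chromosome is given
#' the edge nearer the index SNP is kept, otherwise the interval midpoint.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `pos`.
#' @export
read_hotspots <- function(path) {
  first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                           col_types = readr::cols(), progress = FALSE)
  if (ncol(first) >= 3 && !is.na(suppressWarnings(as.numeric(first[[3]][1])))) {
    bed <- read_bed(path)
    tibble(chrom = bed$chrom, pos = floor((bed$start + bed$end) / 2))
  } else {
    readr::read_tsv(path, col_names = c("chrom", "pos"), col_types = "cd",
                    progress = FALSE)
  }
}
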