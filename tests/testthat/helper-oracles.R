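# Independent brute-force oracles. These deliberately share no code with the
# package internals: interval operations are checked against literal per-base
# boolean masks, block construction against a per-SNP walk, and statistics
# against textbook formulas evaluated step by step.

# per-base boolean mask of a genome (list of logical vectors, one per chrom)
mask_of <- function(x, genome) {
  masks <- lapply(stats::setNames(genome$length, genome$chrom), function(L) {
    logical(L)
  })
  for (i in seq_len(nrow(x))) {
    m <- masks[[x$chrom[i]]]
    m[(x$start[i] + 1):x$end[i]] <- TRUE
    masks[[x$chrom[i]]] <- m
  }
  masks
}

mask_bases <- function(masks) sum(vapply(masks, sum, numeric(1)))

mask_and <- function(m1, m2) Map(function(a, b) a & b, m1, m2)
mask_diff <- function(m1, m2) Map(function(a, b) a & !b, m1, m2)

# mask -> interval tibble (runs of TRUE)
mask_to_intervals <- function(masks) {
  out <- lapply(names(masks), function(chrom) {
    r <- rle(masks[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  } else {
    dplyr::arrange(res, chrom, start)
  }
}

random_intervals <- function(n, genome, max_len = 500) {
  chrom <- sample(genome$chrom, n, replace = TRUE)
  len <- genome$length[match(chrom, genome$chrom)]
  w <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, len - w))
  tibble::tibble(chrom = chrom, start = start, end = start + w)
}

# literal per-SNP walk for haploblock boundaries (both rule sets)
oracle_block <- function(index_pos, pos, r2, hot_pos,
                         rule_set = c("main", "pilot"),
                         r2_extend = 0.5, r2_sufficient = 0.6,
                         side_cap = 500000, total_cap = 1000000) {
  rule_set <- match.arg(rule_set)
  left <- index_pos; right <- index_pos
  low_left <- FALSE; low_right <- FALSE
  for (i in seq_along(pos)) {
    if (pos[i] == index_pos) next
    if (r2[i] > r2_extend) {
      if (pos[i] < index_pos) left <- min(left, pos[i])
      if (pos[i] > index_pos) right <- max(right, pos[i])
    }
    in_cap <- abs(pos[i] - index_pos) <= side_cap
    if (r2[i] < r2_sufficient && (rule_set == "pilot" || in_cap)) {
      if (pos[i] < index_pos) low_left <- TRUE else low_right <- TRUE
    }
  }
  if (rule_set == "main") {
    left <- max(left, index_pos - side_cap)
    right <- min(right, index_pos + side_cap)
  }
  hot_left <- function(b) {
    h <- hot_pos[hot_pos < b]
    if (length(h) == 0) b else max(h)
  }
  hot_right <- function(b) {
    h <- hot_pos[hot_pos > b]
    if (length(h) == 0) b else min(h)
  }
  if (rule_set == "pilot") {
    left <- hot_left(left); right <- hot_right(right)
  } else {
    if (!low_left) left <- hot_left(left)
    if (!low_right) right <- hot_right(right)
  }
  start <- left; end <- right + 1
  if (rule_set == "pilot" && end - start > total_cap) {
    half <- total_cap / 2
    ol <- max(0, (index_pos - start) - half)
    or <- max(0, (end - index_pos) - half)
    excess <- (end - start) - total_cap
    tl <- if (ol + or > 0) excess * ol / (ol + or) else 0
    start <- start + round(tl)
    end <- end - round(excess - tl)
    if (end - start > total_cap) end <- start + total_cap
  }
  c(start = start, end = end)
}

# textbook Yates-corrected chi-square p for a 2x2 table given row-wise;
# the continuity correction is capped at |ad - bc|/n so the corrected
# statistic can never go negative
yates_p <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * max(0, abs(a * d - b * c) - n / 2)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# tiny transcript fixture builder: one multi-exon transcript as exon rows
fix_tx <- function(id, chrom, starts, ends, strand = "+", locus = NULL) {
  tb <- tibble::tibble(chrom = chrom, start = starts, end = ends,
                       strand = strand, transcript_id = id)
  if (!is.null(locus)) tb$locus_id <- locus
  tb
}
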