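test_that("a peak at a 5' end lands in the central bin, normalised by n", {
  tx1 <- fix_tx("t1", "chr1", c(100000, 104000), c(100300, 104300))
  peak <- tibble::tibble(chrom = "chr1", start = 99950, end = 100050)
  prof <- aggregate_profile(tx1, peak, flank_bp = 5000, bin_bp = 100)
  expect_equal(sum(prof$raw_count), 1)
  expect_equal(prof$normalized_count[prof$offset == 0], 1)
  expect_true(all(prof$normalized_count[prof$offset != 0] == 0))

  # second transcript without a peak halves the normalised central value
  tx2 <- dplyr::bind_rows(tx1, fix_tx("t2", "chr1", c(500000, 504000),
                                      c(500300, 504300)))
  prof2 <- aggregate_profile(tx2, peak, flank_bp = 5000, bin_bp = 100)
  expect_equal(prof2$normalized_count[prof2$offset == 0], 0.5)
  expect_equal(attr(prof2, "n_transcripts"), 2)
})

test_that("profiles match a brute-force per-transcript offset scan", {
  set.seed(23)
  n_tx <- 15
  tss <- sort(sample(seq(20000, 480000, by = 3000), n_tx))
  strand <- sample(c("+", "-"), n_tx, replace = TRUE)
  tx <- purrr::map(seq_len(n_tx), function(i) {
    if (strand[i] == "+") {
      fix_tx(paste0("t", i), "chr1", c(tss[i], tss[i] + 2000),
             c(tss[i] + 300, tss[i] + 2300))
    } else {
      fix_tx(paste0("t", i), "chr1", c(tss[i] - 2300, tss[i] - 300),
             c(tss[i] - 2000, tss[i] + 1), strand = "-")
    }
  }) |> dplyr::bind_rows()
  pstart <- floor(runif(200, 10000, 500000))
  peaks <- tibble::tibble(chrom = "chr1", start = pstart,
                          end = pstart + sample(50:400, 200, TRUE))
  flank <- 5000; bin <- 250
  prof <- aggregate_profile(tx, peaks, flank_bp = flank, bin_bp = bin)
  # literal scan: for every transcript and peak, compute the oriented offset
  edges <- seq(-flank, flank, by = bin)
  raw <- rep(0, length(edges) - 1)
  smry <- tx |> dplyr::group_by(transcript_id) |>
    dplyr::summarise(strand = strand[1],
                     tss = ifelse(strand[1] == "-", max(end) - 1, min(start)))
  for (i in seq_len(nrow(smry))) {
    for (j in seq_len(nrow(peaks))) {
      mid <- floor((peaks$start[j] + peaks$end[j]) / 2)
      off <- if (smry$strand[i] == "-") smry$tss[i] - mid else mid - smry$tss[i]
      if (off >= -flank && off < flank) {
        b <- which(edges[-length(edges)] <= off & off < edges[-1])
        raw[b] <- raw[b] + 1
      }
    }
  }
  expect_equal(prof$raw_count, as.integer(raw))
  # conservation: normalised x n reproduces integer raw counts
  expect_equal(prof$normalized_count * attr(prof, "n_transcripts"),
               as.numeric(prof$raw_count))
  # equivariance under a genome-wide shift of transcripts and peaks
  shift <- 12345
  tx_s <- dplyr::mutate(tx, start = start + shift, end = end + shift)
  pk_s <- dplyr::mutate(peaks, start = start + shift, end = end + shift)
  prof_s <- aggregate_profile(tx_s, pk_s, flank_bp = flank, bin_bp = bin)
  expect_equal(prof_s$raw_count, prof$raw_count)
})

test_that("the expression filter restricts profiled transcripts", {
  tx <- dplyr::bind_rows(
    fix_tx("t1", "chr1", c(100000, 104000), c(100300, 104300)),
    fix_tx("t2", "chr1", c(500000, 504000), c(500300, 504300)))
  fp <- tibble::tibble(transcript_id = c("t1", "t2"),
                       testis = c(5, 0), liver = c(0, 3))
  peak <- tibble::tibble(chrom = "chr1", start = 99950, end = 100050)
  prof <- aggregate_profile(tx, peak, fpkm_tbl = fp, condition = "testis")
  expect_equal(attr(prof, "n_transcripts"), 1)
  expect_error(aggregate_profile(tx, peak, fpkm_tbl = fp,
                                 condition = "testis", min_expr = 100),
               "expression filter")
})

test_that("promoter occupancy counts marked promoters", {
  genome <- tibble::tibble(chrom = "chr1", length = 1e6)
  tx <- dplyr::bind_rows(
    fix_tx("t1", "chr1", c(100000, 104000), c(100300, 104300)),
    fix_tx("t2", "chr1", c(500000, 504000), c(500300, 504300)))
  genome_wide <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
  expect_equal(promoter_occupancy(tx, genome_wide, genome)$fraction, 1)
  expect_equal(promoter_occupancy(tx, genome_wide[0, ], genome)$fraction, 0)
  one_peak <- tibble::tibble(chrom = "chr1", start = 100400, end = 100550)
  expect_equal(promoter_occupancy(tx, one_peak, genome)$fraction, 0.5)
})

test_that("matched controls pick nearest-median candidates", {
  cand <- tibble::tibble(transcript_id = c("x", "y", "z"),
                         a = c(1, 5, 50), b = c(1, 5, 50), c = c(1, 5, 50))
  # medians 1, 5, 50; target 4 -> candidate with median 5 first
  sel <- matched_lnc_control(cand, target_median = 4, size = 1)
  expect_equal(sel$transcript_id, "y")
  exact <- matched_lnc_control(cand, target_median = 50, size = 1)
  expect_equal(exact$transcript_id, "z")
  all3 <- matched_lnc_control(cand, target_median = 4, size = 3)
  expect_setequal(all3$transcript_id, c("x", "y", "z"))
  expect_warning(matched_lnc_control(cand, 4, size = 5), "only 3")
})

test_that("bidirectionality requires opposite strands within the extension", {
  # head-to-head, 5' ends 300 bp apart: extended spans overlap (300 < 2x500)
  pair_close <- dplyr::bind_rows(
    fix_tx("f", "chr1", c(10300, 12000), c(10600, 12300)),
    fix_tx("r", "chr1", c(8000, 9700), c(8300, 10000), strand = "-"))
  bd <- call_bidirectional(pair_close, extend_bp = 500)
  expect_true(all(bd$per_transcript$bidirectional))
  # symmetry: both or neither
  expect_equal(bd$per_transcript$bidirectional[1],
               bd$per_transcript$bidirectional[2])

  # 1500 bp apart: 1500 > 2x500 -> neither flagged
  pair_far <- dplyr::bind_rows(
    fix_tx("f", "chr1", c(11500, 13000), c(11800, 13300)),
    fix_tx("r", "chr1", c(8000, 9700), c(8300, 10000), strand = "-"))
  expect_false(any(call_bidirectional(pair_far, 500)$per_transcript$bidirectional))

  # overlapping same-strand pair is never flagged
  same <- dplyr::bind_rows(
    fix_tx("a", "chr1", c(10000, 12000), c(10300, 12300)),
    fix_tx("b", "chr1", c(10100, 12000), c(10400, 12300)))
  expect_false(any(call_bidirectional(same, 500)$per_transcript$bidirectional))
})
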