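test_that("size factors: symmetry, scale equivariance, oracle agreement", {
  cts <- tibble::tibble(transcript_id = paste0("t", 1:3),
                        a = c(10, 20, 30), b = c(10, 20, 30))
  expect_equal(unname(size_factors(cts)), c(1, 1))

  cts2 <- tibble::tibble(transcript_id = paste0("t", 1:3),
                         a = c(10, 20, 30), b = c(20, 40, 60))
  sf <- size_factors(cts2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # independent step-by-step median-of-ratios computation on a random matrix
  set.seed(21)
  m <- matrix(rpois(200, 40), nrow = 50, ncol = 4,
              dimnames = list(paste0("t", 1:50), paste0("c", 1:4)))
  m[sample(200, 20)] <- 0
  expected <- local({
    allpos <- apply(m, 1, function(r) all(r > 0))
    mm <- m[allpos, ]
    geo <- apply(mm, 1, function(r) prod(r)^(1 / length(r)))
    apply(mm, 2, function(col) median(col / geo))
  })
  expect_equal(size_factors(m), expected)
  # cross-check against the established Bioconductor estimator
  skip_if_not_installed("DESeq2")
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("size factors error without an all-positive transcript", {
  m <- matrix(c(0, 5, 5, 0), nrow = 2,
              dimnames = list(c("t1", "t2"), c("a", "b")))
  expect_error(size_factors(m), "pseudocount")
})

test_that("FPKM follows the normalised-count formula", {
  # count 100, length 1 kb, column total 1e6, factor 1 -> FPKM 100
  m <- matrix(c(100, 1e6 - 100, 50, 1e6 - 50), nrow = 2,
              dimnames = list(c("t1", "t2"), c("a", "b")))
  f <- fpkm(m, lengths = c(t1 = 1000, t2 = 1e6), sf = c(1, 1))
  expect_equal(f$a[1], 100)
  # zero count -> zero FPKM
  m0 <- matrix(c(0, 10, 5, 10), nrow = 2,
               dimnames = list(c("t1", "t2"), c("a", "b")))
  expect_equal(fpkm(m0, c(t1 = 100, t2 = 100), sf = c(1, 1))$a[1], 0)
  # doubling length halves FPKM at fixed count
  f1 <- fpkm(m, lengths = c(t1 = 1000, t2 = 1e6), sf = c(1, 1))
  f2 <- fpkm(m, lengths = c(t1 = 2000, t2 = 1e6), sf = c(1, 1))
  expect_equal(f2$a[1], f1$a[1] / 2)
  # invariance to consistently rescaling a condition's counts and factor
  m3 <- m; m3[, "a"] <- m3[, "a"] * 7
  f3 <- fpkm(m3, lengths = c(t1 = 1000, t2 = 1e6), sf = c(7, 1))
  expect_equal(f3$a, f1$a)
})

test_that("locus assignment clusters same-strand exon-overlapping transcripts", {
  tx <- dplyr::bind_rows(
    fix_tx("t1", "chr1", c(100, 900), c(300, 1100)),
    fix_tx("t2", "chr1", c(250, 900), c(400, 1100)),   # shares exon base with t1
    fix_tx("t3", "chr1", c(100, 900), c(300, 1100), strand = "-"),  # opposite
    fix_tx("t4", "chr1", c(5000, 5900), c(5300, 6100)) # far away
  )
  loc <- assign_loci(tx)
  l <- function(id) unique(loc$locus_id[loc$transcript_id == id])
  expect_equal(l("t1"), l("t2"))
  expect_false(l("t1") == l("t3"))
  expect_false(l("t1") == l("t4"))
})


test_that("retain_transcripts returns exactly the hand-enumerated set", {
  fx <- retention_fixture()
  expect_equal(nrow(fx$counts), 30)
  lens <- tapply(fx$tx$end - fx$tx$start, fx$tx$transcript_id, sum)
  f <- fpkm(fx$counts, lengths = lens, sf = c(1, 1))
  ret <- retain_transcripts(fx$tx, f, fx$capture,
                            fpkm_min = 1, isoform_min_frac = 0.01)
  expected <- c(sprintf("L%d.dom", 1:8), sprintf("L%d.min", 1:8))
  expect_setequal(ret$transcript_id, expected)
  # each filter alone removes a superset-or-equal of its joint removals
  rare <- ret$transcript_id[grepl("rare", ret$transcript_id)]
  expect_length(rare, 0)
  # isoform share evaluated at the locus's maximal-expression condition:
  # after per-million column normalisation the loci peak in condition b,
  # where the shares are 100/126, 25/126, 1/126
  dom <- ret[ret$transcript_id == "L1.dom", ]
  expect_equal(dom$isoform_frac, 100 / 126, tolerance = 1e-10)
})

test_that("retention filters are conjunctive (each alone removes at least as much)", {
  fx <- retention_fixture()
  lens <- tapply(fx$tx$end - fx$tx$start, fx$tx$transcript_id, sum)
  f <- fpkm(fx$counts, lengths = lens, sf = c(1, 1))
  joint <- retain_transcripts(fx$tx, f, fx$capture)$transcript_id
  wide_capture <- tibble::tibble(chrom = c("chr1", "chr9"), start = 0,
                                 end = 5e5)
  no_capture_filter <- retain_transcripts(fx$tx, f, wide_capture)$transcript_id
  no_fpkm_filter <- retain_transcripts(fx$tx, f, fx$capture,
                                       fpkm_min = 0)$transcript_id
  no_share_filter <- retain_transcripts(fx$tx, f, fx$capture,
                                        isoform_min_frac = 0)$transcript_id
  for (relaxed in list(no_capture_filter, no_fpkm_filter, no_share_filter)) {
    expect_true(all(joint %in% relaxed))
  }
})

test_that("transcripts without locus assignment raise an error", {
  tx <- fix_tx("t1", "chr1", c(100, 900), c(300, 1100))
  f <- tibble::tibble(transcript_id = "t1", a = 10, b = 10)
  expect_error(retain_transcripts(tx, f, tibble::tibble(chrom = "chr1",
                                                        start = 0, end = 1e4)),
               "locus")
})

test_that("expression tiers are tertiles, monotone, with ties to the lower tier", {
  r <- tibble::tibble(transcript_id = c("a", "b", "c"),
                      max_fpkm = c(2, 20, 200))
  expect_equal(as.character(expression_tiers(r)$tier),
               c("low", "medium", "high"))
  r2 <- tibble::tibble(transcript_id = letters[1:4], max_fpkm = rep(5, 4))
  expect_equal(as.character(unique(expression_tiers(r2)$tier)), "low")
  set.seed(13)
  r3 <- tibble::tibble(transcript_id = paste0("t", 1:300),
                       max_fpkm = rlnorm(300, 1, 2))
  t3 <- expression_tiers(r3)
  q <- quantile(r3$max_fpkm, c(1/3, 2/3), names = FALSE)
  expect_equal(as.character(t3$tier),
               ifelse(r3$max_fpkm <= q[1], "low",
                      ifelse(r3$max_fpkm <= q[2], "medium", "high")))
  ord <- t3[order(t3$max_fpkm), ]
  expect_true(all(diff(as.integer(ord$tier)) >= 0))
})

test_that("occupancy counts blocks holding an expressed retained transcript", {
  blocks <- tibble::tibble(chrom = "chr1", start = (0:19) * 10000,
                           end = (0:19) * 10000 + 8000)
  # qualifying transcripts planted in the first 17 blocks
  tx <- purrr::map(1:17, function(i) {
    fix_tx(paste0("t", i), "chr1", blocks$start[i] + c(500, 4000),
           blocks$start[i] + c(900, 4400), locus = paste0("t", i))
  }) |> dplyr::bind_rows()
  ret <- tibble::tibble(transcript_id = paste0("t", 1:17), max_fpkm = 50)
  occ <- occupancy(blocks, tx, ret)
  expect_equal(occ$fraction_occupied, 0.85)
  expect_equal(occupancy(blocks, tx[0, ], ret[0, ])$fraction_occupied, 0)
  all_blocks <- occupancy(blocks[1:17, ], tx, ret)
  expect_equal(all_blocks$fraction_occupied, 1)
})
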