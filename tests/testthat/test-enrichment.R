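toy_genome <- tibble::tibble(chrom = "toy", length = 10000)

test_that("contingency cells match the stated definitions", {
  tab <- contingency(intervals("toy", 0, 1000), intervals("toy", 500, 1500),
                     toy_genome)
  expect_equal(tab, c(a = 500, b = 500, c = 500, d = 8500))
  # annotation identical to roi -> b = c = 0
  tab2 <- contingency(intervals("toy", 100, 300), intervals("toy", 100, 300),
                      toy_genome)
  expect_equal(tab2[c("b", "c")], c(b = 0, c = 0))
})

test_that("contingency with exclusions matches the per-base mask oracle", {
  genome <- tibble::tibble(chrom = c("t1", "t2"), length = c(20000, 15000))
  set.seed(17)
  for (rep in 1:20) {
    roi <- random_intervals(30, genome, 800)
    ann <- random_intervals(30, genome, 800)
    excl <- random_intervals(10, genome, 500)
    tab <- contingency(roi, ann, genome, excl)
    mr <- mask_diff(mask_of(roi, genome), mask_of(excl, genome))
    ma <- mask_diff(mask_of(ann, genome), mask_of(excl, genome))
    a <- mask_bases(mask_and(mr, ma))
    expect_equal(unname(tab["a"]), a)
    expect_equal(unname(tab["b"]), mask_bases(ma) - a)
    expect_equal(unname(tab["c"]), mask_bases(mr) - a)
    # cells sum to the effective genome size
    expect_equal(sum(tab), sum(genome$length) - mask_bases(mask_of(excl, genome)))
  }
  expect_error(contingency(intervals("t1", 0, 10), intervals("t1", 0, 10),
                           genome,
                           tibble::tibble(chrom = c("t1", "t2"),
                                          start = 0, end = c(20000, 15000))),
               "entire genome")
})

test_that("odds ratio, CI and chi-square follow the printed formulas", {
  r <- odds_ratio(c(a = 100, b = 100, c = 100, d = 100))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$log_or, 0)
  expect_equal(r$ci_low, -r$ci_high)

  r2 <- odds_ratio(c(a = 150, b = 850, c = 1000, d = 9000))
  expect_equal(r2$odds_ratio, (150 / 850) / (1000 / 9000), tolerance = 1e-12)
  se <- sqrt(1 / 150 + 1 / 850 + 1 / 1000 + 1 / 9000)
  expect_equal(r2$ci_low, log(r2$odds_ratio) - 1.96 * se, tolerance = 1e-12)
  expect_equal(r2$ci_high, log(r2$odds_ratio) + 1.96 * se, tolerance = 1e-12)
  expect_equal(r2$p_value, yates_p(150, 850, 1000, 9000), tolerance = 1e-12)

  # scale invariance of the OR
  r3 <- odds_ratio(c(a = 300, b = 1700, c = 2000, d = 18000))
  expect_equal(r3$odds_ratio, r2$odds_ratio)

  # zero cells: error without, finite with, the Haldane-Anscombe correction
  expect_error(odds_ratio(c(a = 0, b = 10, c = 10, d = 10)), "haldane")
  rh <- odds_ratio(c(a = 0, b = 10, c = 10, d = 10), haldane = TRUE)
  expect_true(is.finite(rh$log_or))
  expect_equal(rh$odds_ratio, (0.5 / 10.5) / (10.5 / 10.5))
})

test_that("chi-square matches the textbook Yates formula and is monotone", {
  expect_equal(chi_square_2x2(c(a = 25, b = 25, c = 25, d = 25)), 1)
  expect_equal(chi_square_2x2(c(a = 30, b = 10, c = 10, d = 30)),
               yates_p(30, 10, 10, 30), tolerance = 1e-12)
  # p decreases as imbalance grows at fixed margins
  p <- vapply(0:9, function(k) {
    chi_square_2x2(c(a = 20 + k, b = 20 - k, c = 20 - k, d = 20 + k))
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("tidy and glance return one-row summaries", {
  r <- odds_ratio(c(a = 150, b = 850, c = 1000, d = 9000))
  td <- tidy(r)
  expect_equal(nrow(td), 1)
  expect_named(td, c("a", "b", "c", "d", "odds_ratio", "log_or", "se",
                     "ci_low", "ci_high", "p_value"))
  expect_equal(glance(r)$odds_ratio, r$odds_ratio)
})

test_that("randomised placement is seeded, length-preserving and bounded", {
  genome <- tibble::tibble(chrom = "toy", length = 50000)
  roi <- intervals("toy", c(100, 9000), c(600, 9500))
  ann <- intervals("toy", seq(0, 49000, 5000), seq(0, 49000, 5000) + 1000)
  r1 <- randomized_control(roi, ann, genome, n_rand = 3, seed = 9)
  r2 <- randomized_control(roi, ann, genome, n_rand = 3, seed = 9)
  expect_equal(r1, r2)
  r3 <- randomized_control(roi, ann, genome, n_rand = 3, seed = 10)
  expect_false(isTRUE(all.equal(r1, r3)))
  # an roi interval wider than any allowed gap cannot be placed
  expect_error(randomized_control(intervals("toy", 0, 60000),
                                  ann, genome, n_rand = 1, seed = 1),
               "no gap")
  expect_error(
    randomized_control(intervals("toy", 0, 49999),
                       ann, genome,
                       exclusions = intervals("toy", 20000, 30000),
                       n_rand = 1, seed = 1),
    "no gap")
  # placements preserve interval lengths (merged coverage can only shrink)
  expect_true(all(r1$a + r1$c <= covered_bases(roi)))
})

test_that("TSS windows follow strand conventions", {
  plus <- fix_tx("p", "chr1", c(10000, 15000), c(10400, 15400))
  minus <- fix_tx("m", "chr1", c(15000, 19600), c(15400, 20000), strand = "-")
  genome <- tibble::tibble(chrom = "chr1", length = 1e6)
  wp <- haplotx:::tss_windows(plus, genome, 500)
  expect_equal(c(wp$start, wp$end), c(9500, 10500))
  wm <- haplotx:::tss_windows(minus, genome, 500)
  # 5' end of a minus-strand transcript is its last covered base (19999)
  expect_equal(c(wm$start, wm$end), c(19499, 20499))
})

test_that("planted TSS signal is recovered with a CI excluding zero", {
  set.seed(31)
  genome <- tibble::tibble(chrom = "chr1", length = 2e6)
  n <- 50
  tss <- sort(sample(seq(10000, 1.99e6, by = 1000), n))
  tx <- purrr::map(seq_len(n), function(i) {
    fix_tx(paste0("t", i), "chr1", c(tss[i], tss[i] + 2000),
           c(tss[i] + 300, tss[i] + 2300))
  }) |> dplyr::bind_rows()
  # CAGE peaks at 60% of TSSs plus sparse background
  hit <- runif(n) < 0.6
  bg <- floor(runif(20, 0, 2e6 - 100))
  peaks <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = tss[hit] - 50, end = tss[hit] + 50),
    tibble::tibble(chrom = "chr1", start = bg, end = bg + 100))
  enr <- tss_enrichment(tx, peaks, genome, n_rand = 0)
  expect_gt(enr$result$log_or, 0)
  expect_gt(enr$result$ci_low, 0)
})

test_that("element SNP enrichment reproduces the direct arithmetic", {
  elements <- list(
    exons = intervals("chr1", 0, 10000),
    introns = intervals("chr1", 20000, 120000))
  place <- function(n, iv) {
    tibble::tibble(chrom = "chr1",
                   pos = floor(seq(iv$start, iv$end - 1,
                                   length.out = n)))
  }
  gwas <- dplyr::bind_rows(place(20, elements$exons), place(80, elements$introns))
  common <- dplyr::bind_rows(place(200, elements$exons), place(1800, elements$introns))
  res <- element_snp_enrichment(elements, gwas, common)
  expect_equal(res$odds_ratio, (20 / 80) / (200 / 1800), tolerance = 1e-12)
  expect_equal(res$a, 20)
  # identical distributions -> OR 1
  res2 <- element_snp_enrichment(elements, common, common)
  expect_equal(res2$odds_ratio, 1)
  # zero GWAS SNPs in a class, with correction -> finite OR < 1
  res3 <- element_snp_enrichment(elements, place(50, elements$introns),
                                 common, haldane = TRUE)
  expect_true(is.finite(res3$log_or) && res3$odds_ratio < 1)
  expect_error(element_snp_enrichment(list(exons = elements$exons),
                                      gwas, common), "introns")
})
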