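# 30-transcript fixture with hand-enumerated retention outcomes: transcripts
# fail exactly one (or none) of the four conjunctive filters
retention_fixture <- function() {
  capture <- tibble::tibble(chrom = "chr1", start = 0, end = 500000)
  tx <- list(); cts <- list()
  add <- function(id, locus, starts, ends, counts_a, counts_b, chrom = "chr1") {
    tx[[length(tx) + 1]] <<- fix_tx(id, chrom, starts, ends, locus = locus)
    cts[[length(cts) + 1]] <<- tibble::tibble(transcript_id = id,
                                              a = counts_a, b = counts_b)
  }
  # 10 loci x 3 isoforms; per locus: dominant (retained), minor at ~20%
  # (retained), rare at ~0.5% (share filter drops it)
  for (i in 1:8) {
    base <- (i - 1) * 20000
    # equal isoform lengths (800 nt), so FPKM shares reduce to count shares
    add(sprintf("L%d.dom", i), sprintf("L%d", i),
        base + c(1000, 3000), base + c(1400, 3400), 1000, 100)
    add(sprintf("L%d.min", i), sprintf("L%d", i),
        base + c(1050, 3000), base + c(1450, 3400), 250, 25)
    add(sprintf("L%d.rare", i), sprintf("L%d", i),
        base + c(1100, 3000), base + c(1500, 3400), 6, 1)
  }
  # 2 single-exon transcripts, well expressed: multi-exonic filter drops them
  add("S1", "S1", 170000, 171000, 800, 80)
  add("S2", "S2", 175000, 176000, 800, 80)
  # 2 multi-exonic but outside the capture space
  add("O1", "O1", c(1000, 3000), c(1400, 3400), 900, 90, chrom = "chr9")
  add("O2", "O2", c(9000, 11000), c(9400, 11400), 900, 90, chrom = "chr9")
  # 2 multi-exonic in capture space with no reads at all: FPKM filter drops them
  add("W1", "W1", c(180000, 182000), c(180400, 182400), 0, 0)
  add("W2", "W2", c(185000, 187000), c(185400, 187400), 0, 0)
  list(tx = dplyr::bind_rows(tx), counts = dplyr::bind_rows(cts),
       capture = capture)
}
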