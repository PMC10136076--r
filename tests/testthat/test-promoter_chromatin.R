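tss1 <- function(pos, strand, gene = "g1") {
  data.frame(gene_id = gene, chrom = "chr1", pos = pos, strand = strand)
}

test_that("build_promoter_window is strand-aware and clamps", {
  expect_equal(build_promoter_window(tss1(10000, "+"))[, c("start", "end")],
               data.frame(start = 2500L, end = 12500L))
  w <- build_promoter_window(tss1(10000, "-"))
  expect_equal(c(w$start, w$end), c(7501L, 17501L))
  # upstream side of a - strand gene has exactly 7500 bases
  expect_equal(w$end - 1L - 10000L, 7500L)
  wc <- build_promoter_window(tss1(5000, "+"))
  expect_equal(c(wc$start, wc$end), c(0L, 7500L))
  expect_error(
    build_promoter_window(tss1(10, "+"), chrom_lengths = c(chr2 = 100)),
    "chrom_lengths")
  # window length is upstream + downstream on both strands when unclamped
  for (s in c("+", "-")) {
    w <- build_promoter_window(tss1(50000, s), 7500, 2500)
    expect_equal(w$end - w$start, 10000L)
    expect_true(w$start <= 50000 && 50000 < w$end)  # TSS inside
  }
  expect_error(build_promoter_window(tss1(100, "+"), 0, 0), "zero")
})

test_that("classify_diff_peaks applies the accessibility criteria", {
  pk <- data.frame(chrom = "chr1", start = c(0, 100, 200), end = c(50, 150, 250),
                   peak_id = c("p1", "p2", "p3"), score = 0, strand = ".",
                   log2fc = c(-0.8, 1.5, 1.5), qvalue = c(0.01, 0.04, 0.5))
  lab <- classify_diff_peaks(pk)$peak_label
  expect_identical(lab, c("EPI_SPECIFIC", "FIBER_SPECIFIC", "NS"))
})

test_that("classify_promoter_state applies the zero-opposite-peak rule", {
  win <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                    start = c(0L, 1000L, 5000L), end = c(500L, 2000L, 6000L),
                    strand = "+")
  pk <- data.frame(chrom = "chr1",
                   start = c(100L, 1100L, 1200L, 1300L, 9000L),
                   end = c(200L, 1150L, 1250L, 1350L, 9100L),
                   peak_id = paste0("p", 1:5), score = 0, strand = ".",
                   log2fc = c(-1, -1, -1, 2, 2), qvalue = 0.01)
  st <- classify_promoter_state(win, classify_diff_peaks(pk))
  expect_identical(st$state, c("EPI_PREFERRED", "BOTH", "NONE"))
  expect_identical(st$n_epi_peaks, c(1L, 2L, 0L))
  expect_identical(st$n_fiber_peaks, c(0L, 1L, 0L))
  # counts invariant under peak input order
  perm <- classify_promoter_state(win,
                                  classify_diff_peaks(pk[c(5, 3, 1, 4, 2), ]))
  expect_identical(st$state, perm$state)
  # one peak overlapping two windows contributes to both (no exclusivity)
  win2 <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                     start = c(0L, 150L), end = c(300L, 400L), strand = "+")
  st2 <- classify_promoter_state(win2, classify_diff_peaks(
    data.frame(chrom = "chr1", start = 140L, end = 180L, peak_id = "p",
               score = 0, strand = ".", log2fc = 2, qvalue = 0.01)))
  expect_identical(st2$state, c("FIBER_PREFERRED", "FIBER_PREFERRED"))
  # NS peaks never count
  st3 <- classify_promoter_state(win2, classify_diff_peaks(
    data.frame(chrom = "chr1", start = 140L, end = 180L, peak_id = "p",
               score = 0, strand = ".", log2fc = 2, qvalue = 0.5)))
  expect_identical(st3$state, c("NONE", "NONE"))
})

test_that("cross_species_promoter_states intersects through orthologs", {
  sa <- data.frame(gene_id = c("a1", "a2", "a3"),
                   state = c("EPI_PREFERRED", "EPI_PREFERRED",
                             "FIBER_PREFERRED"))
  sb <- data.frame(gene_id = c("b1", "b2", "b3"),
                   state = c("EPI_PREFERRED", "BOTH", "FIBER_PREFERRED"))
  orth <- data.frame(gene_a = c("a1", "a2", "a3", "a4"),
                     gene_b = c("b1", "b2", "b3", "b4"))
  expect_message(cross <- cross_species_promoter_states(sa, sb, orth),
                 "skipped")
  expect_identical(cross$conserved_epi_promoter$gene_a, "a1")
  expect_identical(cross$conserved_fiber_promoter$gene_a, "a3")
  expect_identical(cross$n_skipped, 1L)
})

test_that("fixture promoter states recover the planted classes", {
  fx <- fixture_seed1()
  win <- build_promoter_window(
    fx$tss_a, chrom_lengths = c(chr1 = nchar(fx$genomes$a[["chr1"]])))
  st <- classify_promoter_state(win, classify_diff_peaks(fx$peaks_a))
  truth_epi <- fx$truth$gene_a[fx$truth$class == "EPITHELIAL"]
  truth_fib <- fx$truth$gene_a[fx$truth$class == "FIBER"]
  expect_setequal(st$gene_id[st$state == "EPI_PREFERRED"], truth_epi)
  expect_setequal(st$gene_id[st$state == "FIBER_PREFERRED"], truth_fib)
  expect_true(all(st$state[!st$gene_id %in% fx$truth$gene_a] == "NONE"))
})
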