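revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("pfm_to_pwm applies the pseudocount and log-odds formulas", {
  pfm <- list(motif_id = "M", tf_name = "TF",
              counts = matrix(c(2, 0, 0, 2), 4, 1,
                              dimnames = list(c("A", "C", "G", "T"), NULL)))
  pwm <- pfm_to_pwm(pfm, pseudocount = 1)
  # p_A = (2 + 0.25) / 5 = 0.45; log2(0.45 / 0.25) = log2(1.8)
  expect_equal(unname(pwm$logodds["A", 1]), log2(1.8), tolerance = 1e-12)
  expect_equal(round(unname(pwm$logodds["A", 1]), 4), 0.8480)
  # uniform column with uniform background gives all-zero log-odds
  uni <- pfm_to_pwm(list(motif_id = "U", tf_name = "U",
                         counts = matrix(1, 4, 2,
                                         dimnames = list(c("A", "C", "G", "T"),
                                                         NULL))))
  expect_equal(unname(uni$logodds), matrix(0, 4, 2))
  # pseudocount 0 with a zero count yields -Inf
  p0 <- pfm_to_pwm(pfm, pseudocount = 0)
  expect_identical(unname(p0$logodds["C", 1]), -Inf)
  expect_error(pfm_to_pwm(pfm, background = c(0.5, 0.5, 0, 0)), "background")
})

test_that("best_hit_score finds the consensus and is strand-symmetric", {
  pfm <- make_pfm("ACGTACGGTC")
  pwm <- pfm_to_pwm(pfm)
  pad <- function(core) paste0("TTTT", core, "GGGG")
  expect_equal(best_hit_score(pad("ACGTACGGTC"), pwm), pwm$max_score)
  expect_equal(best_hit_score(revcomp(pad("ACGTACGGTC")), pwm),
               pwm$max_score)
  # strand symmetry on arbitrary sequences
  set.seed(5)
  for (i in 1:20) {
    s <- random_dna(60)
    expect_identical(best_hit_score(s, pwm), best_hit_score(revcomp(s), pwm))
  }
  expect_warning(short <- best_hit_score("ACG", pwm), "shorter")
  expect_identical(short, -Inf)
})

test_that("scanner equals brute-force placement enumeration", {
  set.seed(11)
  pwms <- lapply(c("ACGGTA", "TTGACGTCA", "GATAAG"), function(cons) {
    pfm_to_pwm(make_pfm(cons, motif_id = cons))
  })
  for (pwm in pwms) {
    for (i in 1:10) {
      s <- random_dna(120)
      # plant an N occasionally to exercise the -Inf placements
      if (i %% 3 == 0) substr(s, 50, 50) <- "N"
      expect_identical(best_hit_score(s, pwm), brute_best_score(s, pwm))
    }
  }
})

test_that("count_hits applies the fixed-fraction threshold", {
  pwm <- pfm_to_pwm(make_pfm("ACGTACGGTC"))
  seqs <- c(paste0("TT", "ACGTACGGTC", "AA"),
            strrep("N", 30),
            random_dna(30))
  expect_identical(count_hits(seqs[1], pwm, 0.75), 1L)
  expect_identical(count_hits(seqs[2], pwm, 0.75), 0L)
  expect_error(count_hits(seqs, pwm, 0), "threshold_fraction")
})

test_that("shuffle_control preserves dinucleotide counts deterministically", {
  expect_identical(unname(shuffle_control("AAAA", seed = 3)), "AAAA")
  set.seed(99)
  seqs <- vapply(1:15, function(i) random_dna(sample(20:200, 1)), "")
  sh1 <- shuffle_control(seqs, seed = 7)
  sh2 <- shuffle_control(seqs, seed = 7)
  expect_identical(sh1, sh2)
  sh3 <- shuffle_control(seqs, seed = 8)
  expect_false(identical(sh1, sh3))
  for (i in seq_along(seqs)) {
    expect_identical(as.list(dinuc_counts(sh1[i])),
                     as.list(dinuc_counts(seqs[i])))
    expect_identical(nchar(sh1[i]), nchar(seqs[i]))
  }
})

test_that("fisher_motif_test matches exact combinatorics and enumeration", {
  # C(3,3) C(17,7) / C(20,10) = 19448/184756
  expect_equal(fisher_motif_test(3, 10, 0, 10), 19448 / 184756,
               tolerance = 1e-13)
  expect_identical(fisher_motif_test(0, 8, 5, 9), 1)
  # agreement with subset enumeration for all tables with N <= 12
  for (N in 2:12) {
    for (fg_n in 1:(N - 1)) {
      bg_n <- N - fg_n
      for (hits in 0:N) {
        tail_or <- enum_hyper_tail(hits, fg_n, N)
        for (fg_hits in max(0, hits - bg_n):min(hits, fg_n)) {
          expect_equal(fisher_motif_test(fg_hits, fg_n, hits - fg_hits, bg_n),
                       tail_or[fg_hits + 1L], tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("bh_adjust implements step-up with monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(13)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"))  # independent oracle
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("partition_motifs implements the four-way label logic", {
  mk <- function(q) data.frame(motif_id = paste0("m", seq_along(q)),
                               tf_name = paste0("tf", seq_along(q)),
                               fg_hits = 0, fg_n = 1, bg_hits = 0, bg_n = 1,
                               p = q, q = q)
  # rows: one motif per scenario (q values for E, F, D_E, D_F)
  E <- c(0.001, 0.8, 0.01, 0.01, 0.01, 0.8)
  F_ <- c(0.8, 0.001, 0.01, 0.01, 0.01, 0.8)
  DE <- c(1, 1, 0.01, 0.9, 0.9, 0.9)
  DF <- c(1, 1, 0.9, 0.01, 0.9, 0.9)
  lab <- partition_motifs(mk(E), mk(F_), mk(DE), mk(DF))
  expect_identical(lab$label,
                   c("EPI_ONLY", "FIBER_ONLY", "EPI_PREFERRED",
                     "FIBER_PREFERRED", "SHARED", "NONE"))
  # labels are exhaustive and mutually exclusive (one per motif)
  expect_identical(nrow(lab), 6L)
  # both cross-tests significant: EPI_PREFERRED precedence, with a message
  expect_message(
    tie <- partition_motifs(mk(0.01), mk(0.01), mk(0.01), mk(0.01)),
    "EPI_PREFERRED")
  expect_identical(tie$label, "EPI_PREFERRED")
  expect_error(partition_motifs(mk(1), mk(c(1, 1)), mk(1), mk(1)), "missing")
})

test_that("expression_filter keeps motifs with TFs detected in both species", {
  labels <- data.frame(motif_id = c("m1", "m2", "m3"),
                       tf_name = c("t1", "t2", "t3"),
                       label = "EPI_ONLY")
  map <- c(m1 = "TF1", m2 = "TF2")
  de_a <- data.frame(gene_id = c("TF1", "TF2"), log2fc = 0, qvalue = 1)
  de_b <- data.frame(gene_id = "TF1", log2fc = 0, qvalue = 1)
  expect_message(out <- expression_filter(labels, map, de_a, de_b), "m3")
  expect_identical(out$motif_id, "m1")  # m2 absent from species B, m3 unmapped
})

test_that("combine_species_motif_labels requires both-species passage", {
  la <- data.frame(motif_id = c("m1", "m2", "m3", "m4"),
                   tf_name = "tf",
                   label = c("FIBER_ONLY", "FIBER_ONLY", "EPI_ONLY",
                             "SHARED"))
  lb <- data.frame(motif_id = c("m1", "m2", "m3", "m4"),
                   tf_name = "tf",
                   label = c("FIBER_ONLY", "FIBER_PREFERRED", "NONE",
                             "SHARED"))
  comb <- combine_species_motif_labels(la, lb)
  expect_identical(comb$label,
                   c("FIBER_ONLY", "FIBER_PREFERRED", "NONE", "SHARED"))
})

test_that("planted-motif sequences are all hits at the default threshold", {
  fx <- fixture_seed1()
  pwm <- pfm_to_pwm(fx$pfms$SYNM01)
  planted_pk <- unique(fx$motif_truth$peak_id[fx$motif_truth$species == "a"])
  seqs <- extract_sequences(
    fx$genomes$a, fx$peaks_a[fx$peaks_a$peak_id %in% planted_pk, ])
  expect_identical(count_hits(seqs, pwm, 0.75), length(seqs))
})
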