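# Independent oracles and small builders shared across the suite.

# Exhaustive-enumeration oracle for the upper-tail hypergeometric: draw all
# n-subsets of 1..N, mark 1..K, and count subsets with >= k marked items.
# Returns the full tail for every k at once (index k + 1).
enum_hyper_tail <- function(K, n, N) {
  if (n == 0L) return(1)
  subsets <- utils::combn(N, n)
  cnt <- colSums(subsets <= K)
  vapply(0:min(K, n), function(k) mean(cnt >= k), 0)
}

# Brute-force PWM placement oracle, independent of the scanner: enumerates
# every W-placement on both strands with character-level lookups and
# double-precision accumulation in ascending position order.
brute_best_score <- function(sequence, pwm) {
  lo <- rbind(pwm$logodds, N = rep(-Inf, ncol(pwm$logodds)))
  W <- ncol(lo)
  score_one <- function(chars) {
    n <- length(chars)
    if (n < W) return(-Inf)
    best <- -Inf
    for (i in seq_len(n - W + 1L)) {
      acc <- 0
      for (j in seq_len(W)) {
        b <- chars[i + j - 1L]
        if (!b %in% c("A", "C", "G", "T")) b <- "N"
        acc <- acc + lo[b, j]
      }
      if (acc > best) best <- acc
    }
    best
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(toupper(sequence), "")[[1]]
  rc <- rev(unname(ifelse(chars %in% names(comp), comp[chars], "N")))
  max(score_one(chars), score_one(rc))
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2L) return(table(character()))
  table(paste0(ch[-length(ch)], ch[-1]))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# PFM builder from a consensus string: `major` counts on the consensus base,
# remainder spread uniformly over the other bases.
make_pfm <- function(consensus, motif_id = "TEST", tf_name = "TESTTF",
                     major = 97, total = 100) {
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "")[[1]]
  counts <- matrix((total - major) / 3, 4, length(cons),
                   dimnames = list(bases, NULL))
  for (j in seq_along(cons)) counts[cons[j], j] <- major
  list(motif_id = motif_id, tf_name = tf_name, counts = counts)
}

consensus_of <- function(pfm) {
  paste(rownames(pfm$counts)[apply(pfm$counts, 2, which.max)], collapse = "")
}

# The default seed-1 fixture is used by several test files; simulate it once.
.fixture_cache <- new.env(parent = emptyenv())
fixture_seed1 <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$fx <- simulate_fixture(sim_config(seed = 1))
  }
  .fixture_cache$fx
}

# Minimal per-species analysis chain used by fixture-recovery tests.
species_motif_labels <- function(fx, species, seed) {
  tss <- fx[[paste0("tss_", species)]]
  peaks <- fx[[paste0("peaks_", species)]]
  genome <- fx$genomes[[species]]
  labels_a <- classify_expression(fx$de_a)
  labels_b <- classify_expression(fx$de_b)
  cons <- intersect_conserved(labels_a, labels_b, fx$orthologs)
  cg <- conserved_genes(cons, species)
  part <- partition_peaks_by_class(nearest_tss(peaks, tss),
                                   cg$epithelial, cg$fiber)
  seqs <- function(ids) {
    extract_sequences(genome, peaks[peaks$peak_id %in% ids, , drop = FALSE])
  }
  pwms <- lapply(fx$pfms, pfm_to_pwm)
  run_motif_analysis(seqs(part$epi_peaks), seqs(part$fiber_peaks), pwms,
                     seed = seed)$labels
}
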