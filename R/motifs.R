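# DNA alphabet used throughout the scanner; index 5 is any non-ACGT base and
# scores -Inf at every motif position.
.base_levels <- c("A", "C", "G", "T")

.seq_to_int <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], .base_levels)
  v[is.na(v)] <- 5L
  v
}

# integer-coded reverse complement (A<->T, C<->G, anything else stays N)
.revcomp_int <- function(si) {
  rev(c(4L, 3L, 2L, 1L, 5L)[si])
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Column probabilities are computed with a background-weighted pseudocount:
#' `p[b, i] = (count[b, i] + pseudocount * background[b]) /
#' (colsum[i] + pseudocount)`, and the PWM entries are
#' `log2(p[b, i] / background[b])`. With `pseudocount = 0`, zero counts give
#' `-Inf` log-odds.
#'
#' @param pfm A PFM as returned by [read_jaspar_pfm()] (list with `motif_id`,
#'   `tf_name`, `counts`).
#' @param pseudocount Non-negative pseudocount mass (default 1) distributed
#'   over bases in proportion to the background.
#' @param background Base composition (A, C, G, T), summing to 1; default
#'   uniform.
#' @return An object of class `pwm_model`: a list with `motif_id`, `tf_name`,
#'   `logodds` (4 x W matrix), `background` and `max_score` (the maximum
#'   achievable placement score).
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 1, background = rep(0.25, 4)) {
  .check(pseudocount >= 0, "pseudocount must be non-negative")
  .check(length(background) == 4L && all(background >= 0) &&
           abs(sum(background) - 1) < 1e-9,
         "background must be 4 non-negative values summing to 1")
  counts <- pfm$counts
  zero_bg <- background == 0 & rowSums(counts) > 0
  .check(!any(zero_bg),
         "zero background probability for base with nonzero counts: ",
         paste(.base_levels[zero_bg], collapse = ", "))
  colsum <- colSums(counts)
  p <- sweep(counts + pseudocount * background, 2, colsum + pseudocount, "/")
  logodds <- log2(sweep(p, 1, background, "/"))
  rownames(logodds) <- .base_levels
  structure(list(motif_id = pfm$motif_id, tf_name = pfm$tf_name,
                 logodds = logodds, background = background,
                 max_score = sum(apply(logodds, 2, max))),
            class = "pwm_model")
}

# scores of all W-length placements of `lo` (4 x W log-odds) on the
# integer-coded strand `si`; placements covering a non-ACGT base score -Inf
.scan_strand <- function(si, lo) {
  W <- ncol(lo)
  L <- length(si)
  if (L < W) return(numeric(0))
  lo5 <- rbind(lo, rep(-Inf, W))
  np <- L - W + 1L
  sc <- numeric(np)
  for (j in seq_len(W)) {
    sc <- sc + lo5[cbind(si[j:(j + np - 1L)], j)]
  }
  sc
}

#' Best log-odds score of a PWM on a sequence (both strands)
#'
#' Returns the maximum placement score over all ungapped W-length placements
#' of the motif on the sequence and on its reverse complement. Placements
#' covering a non-ACGT base score `-Inf`; a sequence shorter than the motif
#' scores `-Inf` with a warning.
#'
#' @param sequence A DNA string.
#' @param pwm A `pwm_model` from [pfm_to_pwm()].
#' @return A single score (log2 odds units), possibly `-Inf`.
#' @export
best_hit_score <- function(sequence, pwm) {
  si <- .seq_to_int(sequence)
  W <- ncol(pwm$logodds)
  if (length(si) < W) {
    warning("sequence shorter than motif width (", length(si), " < ", W, ")",
            call. = FALSE)
    return(-Inf)
  }
  max(.scan_strand(si, pwm$logodds), .scan_strand(.revcomp_int(si),
                                                  pwm$logodds))
}

#' Count sequences hit by a motif
#'
#' A sequence is a hit iff its best placement score reaches
#' `threshold_fraction` of the motif's maximum achievable score
#' (`pwm$max_score`). This fixed-fraction rule replaces tool-specific score
#' optimization with a reproducible, oracle-testable criterion.
#'
#' @param sequences Character vector of DNA sequences.
#' @param pwm A `pwm_model`.
#' @param threshold_fraction Fraction of the maximum achievable score in
#'   (0, 1]; default 0.75.
#' @return Number of hit sequences (integer).
#' @export
count_hits <- function(sequences, pwm, threshold_fraction = 0.75) {
  .check(threshold_fraction > 0 && threshold_fraction <= 1,
         "threshold_fraction must lie in (0, 1]")
  thr <- threshold_fraction * pwm$max_score
  sum(vapply(sequences, function(s) best_hit_score(s, pwm) >= thr,
             logical(1)))
}

# One Altschul-Erickson dinucleotide-preserving shuffle of a single sequence.
# Builds the dinucleotide transition multigraph, draws a random "last-edge"
# arborescence into the terminal vertex, permutes the remaining out-edges and
# walks the resulting Eulerian path.
.ae_shuffle_one <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 3L || length(unique(ch)) == 1L) return(s)
  verts <- unique(ch)
  edges <- split(ch[-1], factor(ch[-n], levels = verts))
  first <- ch[1]; last <- ch[n]
  inner <- setdiff(verts, last)
  repeat {
    last_edge <- vapply(inner, function(v) {
      outs <- edges[[v]]
      outs[sample.int(length(outs), 1L)]
    }, "")
    ok <- vapply(inner, function(v) {
      seen <- character()
      cur <- v
      while (cur != last) {
        if (cur %in% seen) return(FALSE)
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      TRUE
    }, logical(1))
    if (all(ok)) break
  }
  arranged <- lapply(verts, function(v) {
    outs <- edges[[v]]
    if (v %in% inner) {
      outs <- outs[-match(last_edge[[v]], outs)]
      perm <- if (length(outs)) outs[sample.int(length(outs))] else character()
      c(perm, last_edge[[v]])
    } else {
      if (length(outs)) outs[sample.int(length(outs))] else character()
    }
  })
  names(arranged) <- verts
  out <- character(n)
  out[1] <- first
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- first
  for (i in 2:n) {
    nxt <- arranged[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Dinucleotide-preserving shuffled control sequences
#'
#' Replaces each sequence by an Altschul-Erickson shuffle: a uniformly drawn
#' resequencing with exactly the same dinucleotide count multiset (hence the
#' same length, composition and first/last base). Deterministic given `seed`.
#'
#' @param sequences Non-empty character vector of DNA sequences.
#' @param seed Integer seed for the shuffle RNG.
#' @return A character vector of shuffled sequences, same length and names.
#' @export
shuffle_control <- function(sequences, seed) {
  .check(length(sequences) > 0L, "sequences must be non-empty")
  .check(is.numeric(seed) && length(seed) == 1L, "seed must be a single number")
  set.seed(as.integer(seed))
  out <- vapply(sequences, .ae_shuffle_one, "")
  names(out) <- names(sequences)
  out
}

#' One-sided Fisher exact test for motif hit counts
#'
#' Tests whether the foreground hit rate exceeds the background hit rate:
#' the upper-tail hypergeometric probability of drawing at least `fg_hits`
#' hits when `fg_n` of the `fg_n + bg_n` sequences are foreground and
#' `fg_hits + bg_hits` are hits in total.
#'
#' @param fg_hits,fg_n Foreground hit count and sequence count.
#' @param bg_hits,bg_n Background hit count and sequence count.
#' @return One-sided p-value in (0, 1].
#' @export
fisher_motif_test <- function(fg_hits, fg_n, bg_hits, bg_n) {
  .check(fg_hits <= fg_n && bg_hits <= bg_n, "hits must not exceed n")
  hypergeometric_tail(k = fg_hits, K = fg_hits + bg_hits, n = fg_n,
                      N = fg_n + bg_n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1; returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  .check(all(pvalues >= 0 & pvalues <= 1), "p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues)
  ranked <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Motif enrichment of foreground vs background sequences
#'
#' For each PWM, counts hit sequences (see [count_hits()]) in the foreground
#' and background sets, computes the one-sided Fisher p-value and BH-adjusts
#' across the motif library (one correction per foreground/background
#' family).
#'
#' @param fg_seqs,bg_seqs Character vectors of DNA sequences.
#' @param pwms A list of `pwm_model` objects.
#' @param threshold_fraction Hit threshold passed to [count_hits()].
#' @return A data.frame with columns `motif_id`, `tf_name`, `fg_hits`,
#'   `fg_n`, `bg_hits`, `bg_n`, `p`, `q`.
#' @export
motif_enrichment <- function(fg_seqs, bg_seqs, pwms,
                             threshold_fraction = 0.75) {
  res <- lapply(pwms, function(pwm) {
    fg <- count_hits(fg_seqs, pwm, threshold_fraction)
    bg <- count_hits(bg_seqs, pwm, threshold_fraction)
    data.frame(motif_id = pwm$motif_id, tf_name = pwm$tf_name,
               fg_hits = fg, fg_n = length(fg_seqs),
               bg_hits = bg, bg_n = length(bg_seqs),
               p = fisher_motif_test(fg, length(fg_seqs), bg,
                                     length(bg_seqs)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res$q <- bh_adjust(res$p)
  res
}

#' Four-way partition of motifs over conserved-class chromatin
#'
#' Combines four enrichment runs — epithelial peaks vs shuffled control
#' (`E`), fiber peaks vs shuffled control (`F`), epithelial foreground vs
#' fiber background (`D_E`) and fiber foreground vs epithelial background
#' (`D_F`), each significant iff `q <= alpha` — into one label per motif:
#' * `EPI_ONLY`: `E` and not `F`
#' * `FIBER_ONLY`: `F` and not `E`
#' * `EPI_PREFERRED`: `E`, `F` and `D_E`
#' * `FIBER_PREFERRED`: `E`, `F`, `D_F` and not `D_E`
#' * `SHARED`: `E`, `F`, neither `D_E` nor `D_F`
#' * `NONE`: otherwise
#'
#' When both cross-tests pass, `EPI_PREFERRED` takes precedence (a message is
#' emitted); the partition is exhaustive and mutually exclusive.
#'
#' @param epi_results,fiber_results,epi_vs_fiber_results,fiber_vs_epi_results
#'   Enrichment tables from [motif_enrichment()], all covering the same
#'   motif library.
#' @param alpha Significance level on `q`.
#' @return A data.frame with columns `motif_id`, `tf_name`, `label`.
#' @export
partition_motifs <- function(epi_results, fiber_results,
                             epi_vs_fiber_results, fiber_vs_epi_results,
                             alpha = 0.05) {
  ids <- epi_results$motif_id
  for (tbl in list(fiber_results, epi_vs_fiber_results,
                   fiber_vs_epi_results)) {
    missing <- setdiff(ids, tbl$motif_id)
    .check(length(missing) == 0L && length(setdiff(tbl$motif_id, ids)) == 0L,
           "motif missing from a result collection: ",
           c(missing, setdiff(tbl$motif_id, ids))[1])
  }
  qs <- function(tbl) setNames(tbl$q, tbl$motif_id)[ids]
  E <- qs(epi_results) <= alpha
  F_ <- qs(fiber_results) <= alpha
  D_E <- qs(epi_vs_fiber_results) <= alpha
  D_F <- qs(fiber_vs_epi_results) <= alpha
  label <- rep("NONE", length(ids))
  label[E & !F_] <- "EPI_ONLY"
  label[F_ & !E] <- "FIBER_ONLY"
  label[E & F_ & !D_E & !D_F] <- "SHARED"
  label[E & F_ & D_F & !D_E] <- "FIBER_PREFERRED"
  label[E & F_ & D_E] <- "EPI_PREFERRED"
  if (any(E & F_ & D_E & D_F)) {
    message("motifs significant in both cross-tests labelled EPI_PREFERRED: ",
            paste(ids[E & F_ & D_E & D_F], collapse = ", "))
  }
  data.frame(motif_id = ids, tf_name = epi_results$tf_name, label = label,
             stringsAsFactors = FALSE)
}

#' Filter motif labels by TF expression in both species
#'
#' Keeps a motif only if the gene encoding its transcription factor is
#' present (detected) in both species' differential-expression tables.
#' Motifs without a TF mapping are dropped with a message.
#'
#' @param labels Partition labels from [partition_motifs()].
#' @param motif_tf_map Named character vector mapping `motif_id` to the TF's
#'   `gene_id` (or a data.frame with columns `motif_id`, `gene_id`).
#' @param de_a,de_b The two species' DE tables.
#' @return The filtered label data.frame.
#' @export
expression_filter <- function(labels, motif_tf_map, de_a, de_b) {
  if (is.data.frame(motif_tf_map)) {
    motif_tf_map <- setNames(motif_tf_map$gene_id, motif_tf_map$motif_id)
  }
  tf <- motif_tf_map[labels$motif_id]
  unmapped <- is.na(tf)
  if (any(unmapped)) {
    message(sum(unmapped), " motifs dropped (no TF mapping): ",
            paste(labels$motif_id[unmapped], collapse = ", "))
  }
  keep <- !unmapped & tf %in% de_a$gene_id & tf %in% de_b$gene_id
  out <- labels[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the four-test motif enrichment for one species
#'
#' Scans the epithelial- and fiber-class peak sequences against the motif
#' library, builds dinucleotide-shuffled controls for each class, and runs
#' the four enrichment families needed by [partition_motifs()].
#'
#' @param epi_seqs,fiber_seqs Peak sequences of the two conserved classes.
#' @param pwms A list of `pwm_model` objects.
#' @param alpha Significance level on `q`.
#' @param threshold_fraction Hit threshold (see [count_hits()]).
#' @param seed Seed for the shuffled controls.
#' @return A list with the four enrichment tables (`epi`, `fiber`,
#'   `epi_vs_fiber`, `fiber_vs_epi`), the partition `labels` and the `seed`
#'   used.
#' @export
run_motif_analysis <- function(epi_seqs, fiber_seqs, pwms, alpha = 0.05,
                               threshold_fraction = 0.75, seed = 1) {
  shuf_epi <- shuffle_control(epi_seqs, seed)
  shuf_fib <- shuffle_control(fiber_seqs, seed + 1L)
  epi <- motif_enrichment(epi_seqs, shuf_epi, pwms, threshold_fraction)
  fib <- motif_enrichment(fiber_seqs, shuf_fib, pwms, threshold_fraction)
  evf <- motif_enrichment(epi_seqs, fiber_seqs, pwms, threshold_fraction)
  fve <- motif_enrichment(fiber_seqs, epi_seqs, pwms, threshold_fraction)
  labels <- partition_motifs(epi, fib, evf, fve, alpha)
  list(epi = epi, fiber = fib, epi_vs_fiber = evf, fiber_vs_epi = fve,
       labels = labels, seed = seed)
}

#' Combine per-species motif partitions
#'
#' A motif is reported only when it passes in both species: both labels in
#' the epithelial group (`EPI_ONLY`/`EPI_PREFERRED`) combine to `EPI_ONLY`
#' when both are `EPI_ONLY` and to `EPI_PREFERRED` otherwise; likewise for
#' the fiber group; `SHARED` requires `SHARED` in both; everything else is
#' `NONE`.
#'
#' @param labels_a,labels_b Partition labels from [partition_motifs()] for
#'   the two species.
#' @return A data.frame with columns `motif_id`, `tf_name`, `label_a`,
#'   `label_b`, `label`.
#' @export
combine_species_motif_labels <- function(labels_a, labels_b) {
  .check(setequal(labels_a$motif_id, labels_b$motif_id),
         "species label tables cover different motif libraries")
  lb <- setNames(labels_b$label, labels_b$motif_id)
  a <- labels_a$label
  b <- unname(lb[labels_a$motif_id])
  grp <- function(x) ifelse(x %in% c("EPI_ONLY", "EPI_PREFERRED"), "EPI",
                            ifelse(x %in% c("FIBER_ONLY", "FIBER_PREFERRED"),
                                   "FIBER", x))
  comb <- rep("NONE", length(a))
  both_epi <- grp(a) == "EPI" & grp(b) == "EPI"
  both_fib <- grp(a) == "FIBER" & grp(b) == "FIBER"
  comb[both_epi] <- ifelse(a[both_epi] == "EPI_ONLY" &
                             b[both_epi] == "EPI_ONLY",
                           "EPI_ONLY", "EPI_PREFERRED")
  comb[both_fib] <- ifelse(a[both_fib] == "FIBER_ONLY" &
                             b[both_fib] == "FIBER_ONLY",
                           "FIBER_ONLY", "FIBER_PREFERRED")
  comb[a == "SHARED" & b == "SHARED"] <- "SHARED"
  data.frame(motif_id = labels_a$motif_id, tf_name = labels_a$tf_name,
             label_a = a, label_b = b, label = comb,
             stringsAsFactors = FALSE)
}
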