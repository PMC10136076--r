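#' Classify genes by differentiation state
#'
#' Applies the differentiation-state criteria to a differential-expression
#' table (fiber vs epithelium contrast): a gene is `EPITHELIAL` iff
#' `log2fc < 0` and `qvalue < alpha`, `FIBER` iff `log2fc > 0` and
#' `qvalue < alpha`, otherwise `NS`. The inequalities are strict; a gene with
#' `log2fc == 0` is `NS` whatever its q-value.
#'
#' @param de A data.frame with columns `gene_id`, `log2fc`, `qvalue`
#'   (see [read_de_table()]).
#' @param alpha Significance level on the adjusted p-value, in (0, 1).
#' @return A data.frame with columns `gene_id` and `label` (character, one of
#'   `"EPITHELIAL"`, `"FIBER"`, `"NS"`), one row per gene.
#' @export
classify_expression <- function(de, alpha = 0.05) {
  .check(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1,
         "alpha must be a single number in (0, 1)")
  label <- rep("NS", nrow(de))
  sig <- de$qvalue < alpha
  label[sig & de$log2fc < 0] <- "EPITHELIAL"
  label[sig & de$log2fc > 0] <- "FIBER"
  data.frame(gene_id = de$gene_id, label = label, stringsAsFactors = FALSE)
}

#' Upper-tail hypergeometric probability
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` marked items when `n` items are drawn without
#' replacement from a universe of `N` items of which `K` are marked. The sum
#' is accumulated in log space (`lchoose` + log-sum-exp) for numerical
#' stability at large counts.
#'
#' @param k Observed overlap count.
#' @param K Number of marked items (reference-set size).
#' @param n Number of draws (query-set size).
#' @param N Universe size.
#' @return The upper-tail probability, a single number in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  for (v in list(k, K, n, N)) {
    .check(is.numeric(v) && length(v) == 1L && v >= 0 && v == floor(v),
           "k, K, n, N must be single non-negative integers")
  }
  .check(K <= N && n <= N, "K and n must not exceed N")
  .check(k <= min(K, n), "k must not exceed min(K, n)")
  if (k <= max(0, K + n - N)) return(1)
  j <- k:min(K, n)
  logp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(logp)
  p <- exp(m) * sum(exp(logp - m))
  min(p, 1)
}

#' Intersect per-species expression classes through an ortholog map
#'
#' An ortholog pair is *conserved epithelial* iff both members are labelled
#' `EPITHELIAL`, and *conserved fiber* iff both are labelled `FIBER`. The
#' cross matrix tabulates species-A class against species-B class over the
#' ortholog pairs that are significant (non-`NS`) in both species. Pairs with
#' a member missing from either label table are skipped with a message.
#'
#' @param labels_a,labels_b Label tables from [classify_expression()] for
#'   species A and B.
#' @param orthologs One-to-one ortholog pairs (columns `gene_a`, `gene_b`;
#'   see [read_ortholog_map()]).
#' @return An object of class `conserved_gene_sets`: a list with
#'   `conserved_epithelial` and `conserved_fiber` (data.frames of pairs),
#'   `cross_matrix` (2 x 2 counts, rows = species-A class, columns =
#'   species-B class), `pairs` (per-pair labels for all usable ortholog
#'   pairs) and `n_skipped`.
#' @export
intersect_conserved <- function(labels_a, labels_b, orthologs) {
  la <- setNames(labels_a$label, labels_a$gene_id)
  lb <- setNames(labels_b$label, labels_b$gene_id)
  known <- orthologs$gene_a %in% names(la) & orthologs$gene_b %in% names(lb)
  if (any(!known)) {
    message(sum(!known), " ortholog pairs skipped (member missing from a ",
            "label table)")
  }
  pairs <- orthologs[known, , drop = FALSE]
  pairs$label_a <- unname(la[pairs$gene_a])
  pairs$label_b <- unname(lb[pairs$gene_b])
  rownames(pairs) <- NULL
  epi <- pairs$label_a == "EPITHELIAL" & pairs$label_b == "EPITHELIAL"
  fib <- pairs$label_a == "FIBER" & pairs$label_b == "FIBER"
  both_sig <- pairs$label_a != "NS" & pairs$label_b != "NS"
  classes <- c("EPITHELIAL", "FIBER")
  cm <- table(factor(pairs$label_a[both_sig], classes),
              factor(pairs$label_b[both_sig], classes))
  cm <- matrix(as.integer(cm), 2, 2, dimnames = dimnames(cm))
  structure(list(
    conserved_epithelial = pairs[epi, c("gene_a", "gene_b")],
    conserved_fiber = pairs[fib, c("gene_a", "gene_b")],
    cross_matrix = cm,
    pairs = pairs,
    n_skipped = sum(!known)
  ), class = "conserved_gene_sets")
}

#' @export
print.conserved_gene_sets <- function(x, ...) {
  cat("Conserved gene sets over", nrow(x$pairs), "ortholog pairs\n")
  cat("  conserved epithelial:", nrow(x$conserved_epithelial), "pairs\n")
  cat("  conserved fiber:     ", nrow(x$conserved_fiber), "pairs\n")
  cat("  cross matrix (significant in both species):\n")
  print(x$cross_matrix)
  invisible(x)
}

#' Cross-species association tests for expression classes
#'
#' For each of the four class pairings (A-epithelial x B-epithelial,
#' A-epithelial x B-fiber, A-fiber x B-epithelial, A-fiber x B-fiber) tests
#' whether the species-A class is enriched in the species-B class by an
#' upper-tail hypergeometric test over the ortholog universe: `k` = pairs in
#' both classes, `K` = pairs in the species-A class, `n` = pairs in the
#' species-B class, `N` = universe size.
#'
#' @param conserved A `conserved_gene_sets` object from
#'   [intersect_conserved()].
#' @param universe_size Universe size `N`; defaults to the number of usable
#'   ortholog pairs (one-to-one orthologs labelled in both species).
#' @return A data.frame with one row per test and columns `class_a`,
#'   `class_b`, `k`, `K`, `n`, `N`, `p`.
#' @export
overlap_association_matrix <- function(conserved,
                                       universe_size = nrow(conserved$pairs)) {
  pairs <- conserved$pairs
  N <- universe_size
  tests <- expand.grid(class_a = c("EPITHELIAL", "FIBER"),
                       class_b = c("EPITHELIAL", "FIBER"),
                       stringsAsFactors = FALSE)
  tests <- tests[order(tests$class_a, tests$class_b), ]
  rownames(tests) <- NULL
  res <- lapply(seq_len(nrow(tests)), function(i) {
    in_a <- pairs$label_a == tests$class_a[i]
    in_b <- pairs$label_b == tests$class_b[i]
    K <- sum(in_a); n <- sum(in_b); k <- sum(in_a & in_b)
    .check(K <= N && n <= N,
           "universe smaller than a class set (K=", K, ", n=", n,
           ", N=", N, ")")
    data.frame(class_a = tests$class_a[i], class_b = tests$class_b[i],
               k = k, K = K, n = n, N = N,
               p = hypergeometric_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
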