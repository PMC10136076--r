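#' Build strand-aware promoter windows around TSSs
#'
#' The default window spans 7.5 kb upstream to 2.5 kb downstream of each TSS,
#' oriented by gene strand: for a `+`-strand TSS at `pos` the window is
#' `[pos - upstream, pos + downstream)`, and for a `-`-strand TSS it is the
#' mirror image `[pos - downstream + 1, pos + upstream + 1)`, so the TSS base
#' itself always lies inside the window. Windows are clamped to
#' `[0, chromosome length)` when chromosome lengths are supplied.
#'
#' @param tss TSS table (columns `gene_id`, `chrom`, `pos`, `strand`; see
#'   [read_tss_bed()]).
#' @param upstream_bp,downstream_bp Window extents in bp (non-negative, not
#'   both zero).
#' @param chrom_lengths Optional named vector of chromosome lengths used for
#'   clamping; every TSS chromosome must be present when supplied.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open windows).
#' @export
build_promoter_window <- function(tss, upstream_bp = 7500,
                                  downstream_bp = 2500,
                                  chrom_lengths = NULL) {
  .check(upstream_bp >= 0 && downstream_bp >= 0,
         "window extents must be non-negative")
  .check(upstream_bp + downstream_bp > 0,
         "window extents must not both be zero")
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$pos - upstream_bp, tss$pos - downstream_bp + 1)
  end <- ifelse(plus, tss$pos + downstream_bp, tss$pos + upstream_bp + 1)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    missing <- setdiff(unique(tss$chrom), names(chrom_lengths))
    .check(length(missing) == 0L,
           "chromosome absent from chrom_lengths: ", missing[1])
    end <- pmin(end, unname(chrom_lengths[tss$chrom]))
  }
  .check(all(start < end), "promoter window collapsed to zero length")
  data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = tss$strand, stringsAsFactors = FALSE)
}

#' Classify differential ATAC-seq peaks
#'
#' A peak is `EPI_SPECIFIC` iff its accessibility log2 fold change
#' (fiber/epithelial) is `< 0` with `qvalue < alpha`, `FIBER_SPECIFIC` iff
#' `> 0` with `qvalue < alpha`, otherwise `NS`.
#'
#' @param peaks Peak table (see [read_diff_peaks()]).
#' @param alpha Significance level in (0, 1).
#' @return The input data.frame with an added `peak_label` column.
#' @export
classify_diff_peaks <- function(peaks, alpha = 0.05) {
  .check(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1,
         "alpha must be a single number in (0, 1)")
  label <- rep("NS", nrow(peaks))
  sig <- peaks$qvalue < alpha
  label[sig & peaks$log2fc < 0] <- "EPI_SPECIFIC"
  label[sig & peaks$log2fc > 0] <- "FIBER_SPECIFIC"
  peaks$peak_label <- label
  peaks
}

#' Classify promoter chromatin state per gene
#'
#' Counts labelled differential peaks overlapping each promoter window by at
#' least 1 bp and applies the promoter-state rule: `EPI_PREFERRED` iff at
#' least one epithelial-specific peak and zero fiber-specific peaks overlap;
#' `FIBER_PREFERRED` for the reverse; `BOTH` when both classes are present;
#' `NONE` when the window contains no significant differential peak. A peak
#' overlapping two gene windows contributes to both genes.
#'
#' @param windows Promoter windows from [build_promoter_window()].
#' @param labelled_peaks Peaks from [classify_diff_peaks()].
#' @return A data.frame with columns `gene_id`, `state`, `n_epi_peaks`,
#'   `n_fiber_peaks`.
#' @export
classify_promoter_state <- function(windows, labelled_peaks) {
  epi <- labelled_peaks[labelled_peaks$peak_label == "EPI_SPECIFIC", ]
  fib <- labelled_peaks[labelled_peaks$peak_label == "FIBER_SPECIFIC", ]
  count_overlaps <- function(pk) {
    if (nrow(pk) == 0L) return(integer(nrow(windows)))
    vapply(seq_len(nrow(windows)), function(i) {
      sum(pk$chrom == windows$chrom[i] &
            .overlaps(pk$start, pk$end, windows$start[i], windows$end[i]))
    }, 0L)
  }
  n_epi <- count_overlaps(epi)
  n_fib <- count_overlaps(fib)
  state <- rep("NONE", nrow(windows))
  state[n_epi >= 1L & n_fib == 0L] <- "EPI_PREFERRED"
  state[n_fib >= 1L & n_epi == 0L] <- "FIBER_PREFERRED"
  state[n_epi >= 1L & n_fib >= 1L] <- "BOTH"
  data.frame(gene_id = windows$gene_id, state = state,
             n_epi_peaks = n_epi, n_fiber_peaks = n_fib,
             stringsAsFactors = FALSE)
}

#' Cross-species conserved promoter states
#'
#' Intersects per-species promoter states through the ortholog map: a pair
#' belongs to the conserved epithelial-promoter set iff both members are
#' `EPI_PREFERRED`, and to the conserved fiber-promoter set iff both are
#' `FIBER_PREFERRED`. Pairs with a member missing from either state table are
#' skipped with a message.
#'
#' @param states_a,states_b Promoter-state tables from
#'   [classify_promoter_state()], computed with identical parameters.
#' @param orthologs One-to-one ortholog pairs.
#' @return A list with `conserved_epi_promoter` and `conserved_fiber_promoter`
#'   (data.frames of pairs) and `n_skipped`.
#' @export
cross_species_promoter_states <- function(states_a, states_b, orthologs) {
  sa <- setNames(states_a$state, states_a$gene_id)
  sb <- setNames(states_b$state, states_b$gene_id)
  known <- orthologs$gene_a %in% names(sa) & orthologs$gene_b %in% names(sb)
  if (any(!known)) {
    message(sum(!known), " ortholog pairs skipped (member missing from a ",
            "promoter-state table)")
  }
  pairs <- orthologs[known, , drop = FALSE]
  a <- unname(sa[pairs$gene_a]); b <- unname(sb[pairs$gene_b])
  epi <- a == "EPI_PREFERRED" & b == "EPI_PREFERRED"
  fib <- a == "FIBER_PREFERRED" & b == "FIBER_PREFERRED"
  res_epi <- pairs[epi, , drop = FALSE]; rownames(res_epi) <- NULL
  res_fib <- pairs[fib, , drop = FALSE]; rownames(res_fib) <- NULL
  list(conserved_epi_promoter = res_epi,
       conserved_fiber_promoter = res_fib,
       n_skipped = sum(!known))
}
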