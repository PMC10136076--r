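#' Assign peaks to their nearest TSS
#'
#' Each peak is assigned to the gene whose TSS is closest to the peak
#' midpoint `floor((start + end - 1) / 2)` on the same chromosome. Distance
#' ties are broken by lexicographically smallest `gene_id`. Peaks on
#' chromosomes without any TSS are left unassigned (dropped with a message).
#'
#' @param peaks Peak table (see [read_diff_peaks()]).
#' @param tss TSS table (see [read_tss_bed()]).
#' @return A data.frame with columns `peak_id`, `gene_id`, `distance`
#'   (non-negative bp, midpoint to TSS).
#' @export
nearest_tss <- function(peaks, tss) {
  mid <- floor((peaks$start + peaks$end - 1) / 2)
  tss_by_chrom <- split(tss[, c("gene_id", "pos")], tss$chrom)
  gene <- character(nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cand <- tss_by_chrom[[peaks$chrom[i]]]
    if (is.null(cand) || nrow(cand) == 0L) next
    d <- abs(mid[i] - cand$pos)
    best <- order(d, cand$gene_id)[1]
    gene[i] <- cand$gene_id[best]
    dist[i] <- d[best]
  }
  unassigned <- is.na(dist)
  if (any(unassigned)) {
    message(sum(unassigned), " peaks unassigned (no TSS on chromosome)")
  }
  data.frame(peak_id = peaks$peak_id[!unassigned],
             gene_id = gene[!unassigned],
             distance = dist[!unassigned],
             stringsAsFactors = FALSE)
}

#' Extract one species' members of the conserved gene sets
#'
#' @param conserved A `conserved_gene_sets` object.
#' @param species `"a"` or `"b"`.
#' @return A list with character vectors `epithelial` and `fiber`.
#' @export
conserved_genes <- function(conserved, species = c("a", "b")) {
  species <- match.arg(species)
  col <- paste0("gene_", species)
  list(epithelial = conserved$conserved_epithelial[[col]],
       fiber = conserved$conserved_fiber[[col]])
}

#' Partition peaks by the conserved class of their nearest gene
#'
#' A peak joins the epithelial partition iff its nearest gene is a conserved
#' epithelial gene, and the fiber partition iff it is a conserved fiber gene;
#' peaks nearest to any other gene are excluded. The two partitions are
#' disjoint because the conserved gene sets are.
#'
#' @param assignments Nearest-TSS assignments from [nearest_tss()].
#' @param epi_genes,fiber_genes Character vectors of one species' conserved
#'   epithelial / fiber gene ids (see [conserved_genes()]).
#' @return A list with character vectors `epi_peaks` and `fiber_peaks` of
#'   peak ids.
#' @export
partition_peaks_by_class <- function(assignments, epi_genes, fiber_genes) {
  common <- intersect(epi_genes, fiber_genes)
  .check(length(common) == 0L,
         "conserved epithelial and fiber gene sets must be disjoint")
  list(epi_peaks = assignments$peak_id[assignments$gene_id %in% epi_genes],
       fiber_peaks = assignments$peak_id[assignments$gene_id %in% fiber_genes])
}
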