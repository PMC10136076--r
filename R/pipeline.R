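#' Run the full cross-species conservation analysis in memory
#'
#' Executes every stage on already-loaded inputs: expression classification
#' and ortholog intersection, hypergeometric association tests, promoter
#' chromatin-state classification and cross-species promoter intersection,
#' nearest-TSS peak assignment and conserved-class partition, the four-test
#' motif enrichment per species with the combined cross-species partition
#' and expressed-TF filter, and over-representation of the conserved fiber
#' and epithelial gene lists against the curated sets.
#'
#' @param de_a,de_b Differential-expression tables.
#' @param orthologs One-to-one ortholog pairs.
#' @param tss_a,tss_b TSS tables.
#' @param peaks_a,peaks_b Differential peak tables.
#' @param genome_a,genome_b Named character vectors of chromosome sequences.
#' @param pwms Motif library of `pwm_model` objects (see [pfm_to_pwm()]).
#' @param gene_sets Curated gene sets (see [read_gmt()]); may be `NULL`.
#' @param motif_tf_map Motif-to-TF-gene map (see [expression_filter()]).
#' @param alpha Significance level used throughout.
#' @param threshold_fraction Motif hit threshold (see [count_hits()]).
#' @param seed Seed for the shuffled motif controls.
#' @param upstream_bp,downstream_bp Promoter window extents.
#' @return A named list of result tables.
#' @export
run_conservation_analysis <- function(de_a, de_b, orthologs, tss_a, tss_b,
                                      peaks_a, peaks_b, genome_a, genome_b,
                                      pwms, gene_sets = NULL,
                                      motif_tf_map = NULL, alpha = 0.05,
                                      threshold_fraction = 0.75, seed = 1,
                                      upstream_bp = 7500,
                                      downstream_bp = 2500) {
  labels_a <- classify_expression(de_a, alpha)
  labels_b <- classify_expression(de_b, alpha)
  conserved <- intersect_conserved(labels_a, labels_b, orthologs)
  association <- overlap_association_matrix(conserved)

  lens_a <- vapply(genome_a, nchar, 0L)
  lens_b <- vapply(genome_b, nchar, 0L)
  windows_a <- build_promoter_window(tss_a, upstream_bp, downstream_bp,
                                     lens_a)
  windows_b <- build_promoter_window(tss_b, upstream_bp, downstream_bp,
                                     lens_b)
  lp_a <- classify_diff_peaks(peaks_a, alpha)
  lp_b <- classify_diff_peaks(peaks_b, alpha)
  states_a <- classify_promoter_state(windows_a, lp_a)
  states_b <- classify_promoter_state(windows_b, lp_b)
  promoters <- cross_species_promoter_states(states_a, states_b, orthologs)

  assign_a <- nearest_tss(peaks_a, tss_a)
  assign_b <- nearest_tss(peaks_b, tss_b)
  cg_a <- conserved_genes(conserved, "a")
  cg_b <- conserved_genes(conserved, "b")
  part_a <- partition_peaks_by_class(assign_a, cg_a$epithelial, cg_a$fiber)
  part_b <- partition_peaks_by_class(assign_b, cg_b$epithelial, cg_b$fiber)

  seqs <- function(genome, peaks, ids) {
    extract_sequences(genome, peaks[peaks$peak_id %in% ids, , drop = FALSE])
  }
  motif_a <- run_motif_analysis(seqs(genome_a, peaks_a, part_a$epi_peaks),
                                seqs(genome_a, peaks_a, part_a$fiber_peaks),
                                pwms, alpha, threshold_fraction, seed)
  motif_b <- run_motif_analysis(seqs(genome_b, peaks_b, part_b$epi_peaks),
                                seqs(genome_b, peaks_b, part_b$fiber_peaks),
                                pwms, alpha, threshold_fraction, seed + 2L)
  motif_labels <- combine_species_motif_labels(motif_a$labels,
                                               motif_b$labels)
  if (!is.null(motif_tf_map)) {
    motif_labels <- expression_filter(motif_labels, motif_tf_map, de_a, de_b)
  }

  ora_fiber <- ora_epi <- NULL
  if (!is.null(gene_sets) && length(gene_sets) > 0L) {
    universe <- conserved$pairs$gene_a
    ora_fiber <- ora(conserved$conserved_fiber$gene_a, gene_sets, universe,
                     alpha, query_id = "conserved_fiber")
    ora_epi <- ora(conserved$conserved_epithelial$gene_a, gene_sets,
                   universe, alpha, query_id = "conserved_epithelial")
  }

  list(labels_a = labels_a, labels_b = labels_b, conserved = conserved,
       association = association, states_a = states_a, states_b = states_b,
       promoters = promoters, assignments_a = assign_a,
       assignments_b = assign_b, peak_partition_a = part_a,
       peak_partition_b = part_b, motif_a = motif_a, motif_b = motif_b,
       motif_labels = motif_labels, ora_fiber = ora_fiber,
       ora_epi = ora_epi)
}

#' Run the pipeline on an on-disk fixture directory
#'
#' Reads the standard fixture files (see [write_fixture()]) from
#' `fixture_dir`, runs [run_conservation_analysis()] and, when `out_dir` is
#' given, writes the result tables as TSV files. Output is deterministic:
#' two runs with identical inputs and `seed` produce byte-identical files.
#'
#' @param fixture_dir Directory containing the fixture files.
#' @param out_dir Optional output directory for result TSVs.
#' @param alpha,threshold_fraction,seed,upstream_bp,downstream_bp See
#'   [run_conservation_analysis()].
#' @param motifs Optional path to a JASPAR motif file; defaults to the
#'   synthetic library shipped with the package.
#' @return The result list from [run_conservation_analysis()], invisibly
#'   when `out_dir` is given.
#' @export
run_pipeline <- function(fixture_dir, out_dir = NULL, alpha = 0.05,
                         threshold_fraction = 0.75, seed = 1,
                         upstream_bp = 7500, downstream_bp = 2500,
                         motifs = NULL) {
  p <- function(f) file.path(fixture_dir, f)
  if (is.null(motifs)) {
    motifs <- system.file("extdata", "synthetic_motifs.jaspar",
                          package = "conservomics", mustWork = TRUE)
  }
  pfms <- read_jaspar_pfm(motifs)
  pwms <- lapply(pfms, pfm_to_pwm)
  tf_map_path <- p("motif_tf_map.tsv")
  motif_tf_map <- NULL
  if (file.exists(tf_map_path)) {
    m <- read.delim(tf_map_path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
    motif_tf_map <- setNames(m[[2]], m[[1]])
  }
  gene_sets <- if (file.exists(p("gene_sets.gmt"))) {
    read_gmt(p("gene_sets.gmt"))
  }
  res <- run_conservation_analysis(
    de_a = read_de_table(p("de_a.tsv")), de_b = read_de_table(p("de_b.tsv")),
    orthologs = read_ortholog_map(p("orthologs.tsv")),
    tss_a = read_tss_bed(p("tss_a.bed")), tss_b = read_tss_bed(p("tss_b.bed")),
    peaks_a = read_diff_peaks(p("peaks_a.bed")),
    peaks_b = read_diff_peaks(p("peaks_b.bed")),
    genome_a = read_genome_fasta(p("genome_a.fa")),
    genome_b = read_genome_fasta(p("genome_b.fa")),
    pwms = pwms, gene_sets = gene_sets, motif_tf_map = motif_tf_map,
    alpha = alpha, threshold_fraction = threshold_fraction, seed = seed,
    upstream_bp = upstream_bp, downstream_bp = downstream_bp)
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  }
  w(res$conserved$pairs, "conserved_pairs.tsv")
  w(res$association, "association_tests.tsv")
  w(res$states_a, "promoter_states_a.tsv")
  w(res$states_b, "promoter_states_b.tsv")
  w(rbind(res$promoters$conserved_epi_promoter,
          res$promoters$conserved_fiber_promoter),
    "conserved_promoters.tsv")
  w(res$assignments_a, "peak_assignments_a.tsv")
  w(res$assignments_b, "peak_assignments_b.tsv")
  fam <- function(m, sp) {
    do.call(rbind, lapply(names(m)[1:4], function(f) {
      cbind(species = sp, family = f, m[[f]])
    }))
  }
  w(rbind(fam(res$motif_a, "a"), fam(res$motif_b, "b")),
    "motif_enrichment.tsv")
  w(res$motif_labels, "motif_partition.tsv")
  if (!is.null(res$ora_fiber)) {
    w(rbind(res$ora_fiber, res$ora_epi), "ora_results.tsv")
  }
  invisible(res)
}

#' Validate fixture/input files against their format contracts
#'
#' Attempts to parse each file with the reader matching its extension or
#' name, collecting parse errors instead of stopping at the first.
#'
#' @param paths Character vector of file paths.
#' @return A data.frame with columns `path`, `format`, `ok`, `message`.
#' @export
validate_files <- function(paths) {
  pick <- function(path) {
    base <- tolower(basename(path))
    if (grepl("\\.gmt$", base)) return(list("GMT", read_gmt))
    if (grepl("\\.(fa|fasta)(\\.gz)?$", base)) {
      return(list("FASTA", read_genome_fasta))
    }
    if (grepl("(jaspar|pfm|motif)", base)) {
      return(list("JASPAR PFM", read_jaspar_pfm))
    }
    if (grepl("tss", base) && grepl("\\.bed$", base)) {
      return(list("TSS BED6", read_tss_bed))
    }
    if (grepl("\\.bed$", base)) return(list("peaks BED6+2", read_diff_peaks))
    if (grepl("ortholog", base)) {
      return(list("ortholog TSV", read_ortholog_map))
    }
    list("DE TSV", read_de_table)
  }
  rows <- lapply(paths, function(path) {
    fmt <- pick(path)
    msg <- "ok"
    ok <- TRUE
    tryCatch(fmt[[2]](path), error = function(e) {
      ok <<- FALSE
      msg <<- conditionMessage(e)
    })
    data.frame(path = path, format = fmt[[1]], ok = ok, message = msg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
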