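#' Simulation configuration for the two-species fixture
#'
#' Bundles all knobs of the synthetic two-species lens fixture: genome and
#' annotation geometry, planted differential-expression effects, differential
#' peaks and motif planting. Defaults state the emulated world: 150 genes per
#' species of which 120 are one-to-one orthologs, 25 conserved epithelial and
#' 25 conserved fiber ortholog pairs, planted |log2FC| ~ 2.0 +/- 0.5 with
#' q <= 1e-3, 400 bp differential peaks placed 1 kb upstream of planted
#' genes' TSSs, and two sampled instances of each planted motif written into
#' every fiber-class peak.
#'
#' The chromosome must hold all genes at >= `min_spacing_bp` spacing (the
#' nearest-TSS recovery guarantee rests on it), so the default
#' `chrom_length` is 3.2 Mb.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param n_genes_per_species,n_orthologs Gene and one-to-one ortholog counts.
#' @param n_conserved_epi,n_conserved_fiber Planted conserved pair counts.
#' @param chrom_length Chromosome length in bp (one chromosome per species).
#' @param de_effect_mean,de_effect_sd Location/scale of planted |log2FC|.
#' @param de_q_planted Upper bound of planted genes' q-values.
#' @param peak_width Differential peak width in bp.
#' @param planted_motif_ids Motifs written into fiber-class peaks.
#' @param decoy_motif_ids Motifs scanned but never planted.
#' @param epi_motif_ids Motifs written into epithelial-class peaks
#'   (symmetric-planting mode; empty by default so the fiber/epi asymmetry is
#'   the detectable signal).
#' @param motif_copies_per_peak Planted motif instances per peak.
#' @param n_ns_peaks Non-significant decoy peaks per species, placed outside
#'   all promoter windows.
#' @param tss_margin_bp,tss_jitter_bp,min_spacing_bp TSS layout geometry.
#' @param upstream_bp,downstream_bp Promoter window extents used when placing
#'   decoy peaks.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes_per_species = 150,
                       n_orthologs = 120,
                       n_conserved_epi = 25,
                       n_conserved_fiber = 25,
                       chrom_length = 3200000,
                       de_effect_mean = 2.0,
                       de_effect_sd = 0.5,
                       de_q_planted = 1e-3,
                       peak_width = 400,
                       planted_motif_ids = "SYNM01",
                       decoy_motif_ids = c("SYNM02", "SYNM03", "SYNM04",
                                           "SYNM05", "SYNM06"),
                       epi_motif_ids = character(),
                       motif_copies_per_peak = 2,
                       n_ns_peaks = 50,
                       tss_margin_bp = 50000,
                       tss_jitter_bp = 5000,
                       min_spacing_bp = 20000,
                       upstream_bp = 7500,
                       downstream_bp = 2500) {
  cfg <- list(seed = as.integer(seed),
              n_genes_per_species = n_genes_per_species,
              n_orthologs = n_orthologs,
              n_conserved_epi = n_conserved_epi,
              n_conserved_fiber = n_conserved_fiber,
              chrom_length = chrom_length,
              de_effect_mean = de_effect_mean,
              de_effect_sd = de_effect_sd,
              de_q_planted = de_q_planted,
              peak_width = peak_width,
              planted_motif_ids = planted_motif_ids,
              decoy_motif_ids = decoy_motif_ids,
              epi_motif_ids = epi_motif_ids,
              motif_copies_per_peak = motif_copies_per_peak,
              n_ns_peaks = n_ns_peaks,
              tss_margin_bp = tss_margin_bp,
              tss_jitter_bp = tss_jitter_bp,
              min_spacing_bp = min_spacing_bp,
              upstream_bp = upstream_bp,
              downstream_bp = downstream_bp)
  .check(cfg$n_conserved_epi + cfg$n_conserved_fiber <= cfg$n_orthologs,
         "planted pairs must not exceed ortholog count")
  .check(cfg$n_orthologs <= cfg$n_genes_per_species,
         "orthologs must not exceed genes per species")
  .check(abs(seed) < 2^31, "seed must be a 32-bit integer")
  structure(cfg, class = "sim_config")
}

# deterministic per-stage seed, kept within 32-bit integer range
.stage_seed <- function(config, stage) {
  as.integer((abs(config$seed) %% 21474835L) * 100L + stage)
}

#' Simulate one chromosome per species
#'
#' Sequences are i.i.d. uniform over A/C/G/T from the seeded generator;
#' uniform composition isolates motif-enrichment behaviour from
#' compositional confounds.
#'
#' @param config A [sim_config()].
#' @return A list with elements `a` and `b`, each a named character vector of
#'   one chromosome (`chr1`).
#' @export
simulate_genome <- function(config) {
  set.seed(.stage_seed(config, 1L))
  draw <- function() {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                 replace = TRUE), collapse = "")
  }
  list(a = c(chr1 = draw()), b = c(chr1 = draw()))
}

#' Simulate TSS annotations and the ortholog map
#'
#' TSSs are uniformly spaced with +/- `tss_jitter_bp` jitter and alternating
#' strands; orthologous genes carry the same shared symbol (`G0001`, ...) in
#' both species, species-specific genes an `A`/`B`-prefixed symbol. The
#' ortholog map pairs the first `n_orthologs` index-matched genes.
#'
#' @param config A [sim_config()].
#' @return A list with `tss_a`, `tss_b` (TSS tables) and `orthologs`.
#' @export
simulate_annotation_and_orthologs <- function(config) {
  set.seed(.stage_seed(config, 2L))
  n <- config$n_genes_per_species
  spacing <- floor((config$chrom_length - 2 * config$tss_margin_bp) / n)
  .check(spacing >= config$min_spacing_bp,
         "genes do not fit: spacing ", spacing, " bp < required ",
         config$min_spacing_bp, " bp; increase chrom_length")
  ids <- ifelse(seq_len(n) <= config$n_orthologs,
                sprintf("G%04d", seq_len(n)), NA)
  make_tss <- function(prefix) {
    gene_id <- ifelse(is.na(ids), sprintf("%s%04d", prefix, seq_len(n)), ids)
    jitter <- sample.int(2L * config$tss_jitter_bp + 1L, n, replace = TRUE) -
      config$tss_jitter_bp - 1L
    pos <- config$tss_margin_bp + spacing * (seq_len(n) - 1L) + jitter
    data.frame(gene_id = gene_id, chrom = "chr1", pos = as.integer(pos),
               strand = rep(c("+", "-"), length.out = n),
               stringsAsFactors = FALSE)
  }
  tss_a <- make_tss("A")
  tss_b <- make_tss("B")
  orthologs <- data.frame(gene_a = tss_a$gene_id[seq_len(config$n_orthologs)],
                          gene_b = tss_b$gene_id[seq_len(config$n_orthologs)],
                          stringsAsFactors = FALSE)
  list(tss_a = tss_a, tss_b = tss_b, orthologs = orthologs)
}

#' Simulate the two species' differential-expression tables
#'
#' Conserved ortholog pairs are planted to satisfy the classification
#' criteria strictly in both species: epithelial pairs get
#' `log2fc = -|Normal(de_effect_mean, de_effect_sd)|` and
#' `q ~ Uniform(1e-8, de_q_planted)`, fiber pairs the positive analogue. All
#' other genes get `log2fc ~ Normal(0, 0.3)` and `q ~ Uniform(0.05, 1)`, so
#' no unplanted gene can reach significance at alpha = 0.05.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation_and_orthologs()].
#' @return A list with `de_a`, `de_b` (DE tables) and `truth`
#'   (data.frame: `gene_a`, `gene_b`, `class`).
#' @export
simulate_expression <- function(config, annotation) {
  set.seed(.stage_seed(config, 3L))
  n_planted <- config$n_conserved_epi + config$n_conserved_fiber
  planted_idx <- sample.int(config$n_orthologs, n_planted)
  epi_idx <- planted_idx[seq_len(config$n_conserved_epi)]
  fib_idx <- planted_idx[config$n_conserved_epi +
                           seq_len(config$n_conserved_fiber)]
  truth <- data.frame(
    gene_a = annotation$orthologs$gene_a[c(epi_idx, fib_idx)],
    gene_b = annotation$orthologs$gene_b[c(epi_idx, fib_idx)],
    class = rep(c("EPITHELIAL", "FIBER"),
                c(config$n_conserved_epi, config$n_conserved_fiber)),
    stringsAsFactors = FALSE)
  make_de <- function(tss, planted_genes_by_class) {
    n <- nrow(tss)
    log2fc <- rnorm(n, 0, 0.3)
    qvalue <- runif(n, 0.05, 1)
    for (cls in names(planted_genes_by_class)) {
      i <- match(planted_genes_by_class[[cls]], tss$gene_id)
      eff <- abs(rnorm(length(i), config$de_effect_mean, config$de_effect_sd))
      log2fc[i] <- if (cls == "EPITHELIAL") -eff else eff
      qvalue[i] <- runif(length(i), 1e-8, config$de_q_planted)
    }
    data.frame(gene_id = tss$gene_id, log2fc = log2fc, qvalue = qvalue,
               stringsAsFactors = FALSE)
  }
  split_truth <- function(col) split(truth[[col]], truth$class)
  list(de_a = make_de(annotation$tss_a, split_truth("gene_a")),
       de_b = make_de(annotation$tss_b, split_truth("gene_b")),
       truth = truth)
}

# sample one motif instance column-wise from the PFM's raw probabilities
.sample_motif_instance <- function(pfm) {
  prob <- sweep(pfm$counts, 2, colSums(pfm$counts), "/")
  paste(vapply(seq_len(ncol(prob)), function(j) {
    sample(c("A", "C", "G", "T"), 1L, prob = prob[, j])
  }, ""), collapse = "")
}

#' Simulate differential peaks and plant motif instances
#'
#' For every planted conserved-fiber gene a fiber-specific peak
#' (`log2fc = +2`, `q = 1e-4`) of width `peak_width` is centred 1 kb upstream
#' of the TSS (strand-aware), and `motif_copies_per_peak` instances of each
#' planted motif, sampled column-wise from its PFM, are written into the
#' genome at recorded offsets. Planted conserved-epithelial genes get the
#' analogous epithelial-specific peak (`log2fc = -2`), carrying motifs only
#' in symmetric-planting mode (`epi_motif_ids`). `n_ns_peaks` non-significant
#' peaks are placed at random positions outside every promoter window;
#' placement collisions are redrawn and the retry count reported.
#'
#' @param config A [sim_config()].
#' @param genomes Output of [simulate_genome()] (modified copies returned).
#' @param annotation Output of [simulate_annotation_and_orthologs()].
#' @param truth Planted-class table from [simulate_expression()].
#' @param pfms Motif library (see [read_jaspar_pfm()]) containing the planted
#'   motif ids.
#' @return A list with `peaks_a`, `peaks_b`, modified `genomes`,
#'   `motif_truth` (species, peak_id, gene_id, motif_id, offset, instance)
#'   and `n_retries`.
#' @export
simulate_peaks_and_motifs <- function(config, genomes, annotation, truth,
                                      pfms) {
  set.seed(.stage_seed(config, 4L))
  for (id in c(config$planted_motif_ids, config$epi_motif_ids)) {
    .check(id %in% names(pfms), "planted motif absent from library: ", id)
  }
  half <- floor(config$peak_width / 2)
  retries <- 0L
  motif_truth <- list()

  build_species <- function(species, tss, gene_col) {
    genome <- genomes[[species]][["chr1"]]
    windows <- build_promoter_window(
      tss, config$upstream_bp, config$downstream_bp,
      chrom_lengths = c(chr1 = nchar(genome)))
    planted <- truth[, c(gene_col, "class")]
    names(planted) <- c("gene_id", "class")
    peaks <- list()
    for (i in seq_len(nrow(planted))) {
      g <- planted$gene_id[i]
      row <- tss[tss$gene_id == g, ]
      center <- if (row$strand == "+") row$pos - 1000L else row$pos + 1000L
      start <- center - half
      end <- start + config$peak_width
      fiber <- planted$class[i] == "FIBER"
      pid <- sprintf("%s_pk_%s", species, g)
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = "chr1", start = start, end = end, peak_id = pid, score = 0,
        strand = ".", log2fc = if (fiber) 2 else -2, qvalue = 1e-4,
        stringsAsFactors = FALSE)
      plant_ids <- if (fiber) config$planted_motif_ids else
        config$epi_motif_ids
      for (mid in plant_ids) {
        pfm <- pfms[[mid]]
        W <- ncol(pfm$counts)
        placed <- integer(0)
        for (copy in seq_len(config$motif_copies_per_peak)) {
          repeat {
            off <- start + sample.int(config$peak_width - W + 1L, 1L) - 1L
            if (!any(abs(off - placed) < W)) break
            retries <<- retries + 1L
          }
          placed <- c(placed, off)
          inst <- .sample_motif_instance(pfm)
          substr(genome, off + 1L, off + W) <- inst
          motif_truth[[length(motif_truth) + 1L]] <<- data.frame(
            species = species, peak_id = pid, gene_id = g, motif_id = mid,
            offset = off, instance = inst, stringsAsFactors = FALSE)
        }
      }
    }
    # non-significant decoy peaks, kept clear of all promoter windows and
    # of previously placed peaks
    existing <- do.call(rbind, peaks)
    for (i in seq_len(config$n_ns_peaks)) {
      repeat {
        start <- sample.int(config$chrom_length - 2L * config$tss_margin_bp -
                              config$peak_width, 1L) + config$tss_margin_bp
        end <- start + config$peak_width
        clash <- any(.overlaps(start, end, windows$start, windows$end)) ||
          any(.overlaps(start, end, existing$start, existing$end))
        if (!clash) break
        retries <<- retries + 1L
      }
      pk <- data.frame(chrom = "chr1", start = start, end = end,
                       peak_id = sprintf("%s_ns_%03d", species, i), score = 0,
                       strand = ".", log2fc = rnorm(1, 0, 0.3),
                       qvalue = runif(1, 0.05, 1), stringsAsFactors = FALSE)
      peaks[[length(peaks) + 1L]] <- pk
      existing <- rbind(existing, pk)
    }
    out <- do.call(rbind, peaks)
    out <- out[order(out$start), ]
    rownames(out) <- NULL
    genomes[[species]][["chr1"]] <<- genome
    out
  }

  peaks_a <- build_species("a", annotation$tss_a, "gene_a")
  peaks_b <- build_species("b", annotation$tss_b, "gene_b")
  list(peaks_a = peaks_a, peaks_b = peaks_b, genomes = genomes,
       motif_truth = do.call(rbind, motif_truth), n_retries = retries)
}

#' Simulate the complete in-memory fixture
#'
#' Runs all simulation stages and assembles the curated gene sets (one set of
#' the planted fiber genes, one of the planted epithelial genes, three decoy
#' sets of random ortholog genes) and the motif-to-TF map (every motif mapped
#' to a distinct ortholog symbol, hence present in both DE tables).
#'
#' @param config A [sim_config()].
#' @param pfms Motif library; defaults to the synthetic library shipped in
#'   `inst/extdata/synthetic_motifs.jaspar`.
#' @return A list with all fixture components and the ground truth.
#' @export
simulate_fixture <- function(config = sim_config(), pfms = NULL) {
  if (is.null(pfms)) {
    pfms <- read_jaspar_pfm(system.file("extdata", "synthetic_motifs.jaspar",
                                        package = "conservomics",
                                        mustWork = TRUE))
  }
  genomes <- simulate_genome(config)
  annotation <- simulate_annotation_and_orthologs(config)
  expr <- simulate_expression(config, annotation)
  pk <- simulate_peaks_and_motifs(config, genomes, annotation, expr$truth,
                                  pfms)
  set.seed(.stage_seed(config, 5L))
  planted_fiber <- expr$truth$gene_a[expr$truth$class == "FIBER"]
  planted_epi <- expr$truth$gene_a[expr$truth$class == "EPITHELIAL"]
  decoy <- lapply(1:3, function(i) {
    list(set_id = sprintf("DECOY_SET_%d", i),
         description = "random ortholog genes (synthetic decoy)",
         members = sort(sample(annotation$orthologs$gene_a, 25)))
  })
  gene_sets <- c(list(
    list(set_id = "PLANTED_FIBER", description = "planted fiber genes",
         members = sort(planted_fiber)),
    list(set_id = "PLANTED_EPI", description = "planted epithelial genes",
         members = sort(planted_epi))), decoy)
  names(gene_sets) <- vapply(gene_sets, `[[`, "", "set_id")
  motif_tf_map <- data.frame(
    motif_id = names(pfms),
    gene_id = annotation$orthologs$gene_a[seq_along(pfms)],
    stringsAsFactors = FALSE)
  list(config = config, pfms = pfms, genomes = pk$genomes,
       tss_a = annotation$tss_a, tss_b = annotation$tss_b,
       orthologs = annotation$orthologs, de_a = expr$de_a, de_b = expr$de_b,
       truth = expr$truth, peaks_a = pk$peaks_a, peaks_b = pk$peaks_b,
       motif_truth = pk$motif_truth, n_retries = pk$n_retries,
       gene_sets = gene_sets, motif_tf_map = motif_tf_map)
}

#' Write the fixture to a directory with a ground-truth manifest
#'
#' Emits the 11 fixture data files (two genomes, two TSS BEDs, ortholog map,
#' two DE tables, two peak BEDs, GMT, motif-to-TF map) and `manifest.json`
#' recording the configuration, the per-gene and per-peak ground truth,
#' planted motif positions and the MD5 checksum of every file. Re-running
#' with the same seed reproduces every byte.
#'
#' @param config A [sim_config()].
#' @param dir Output directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param pfms Optional motif library (see [simulate_fixture()]).
#' @param force Overwrite a non-empty directory.
#' @return The manifest (a list), invisibly.
#' @export
write_fixture <- function(config = sim_config(), dir, pfms = NULL,
                          force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop("output directory exists and is not empty: ", dir, call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- simulate_fixture(config, pfms)
  paths <- c(genome_a = "genome_a.fa", genome_b = "genome_b.fa",
             tss_a = "tss_a.bed", tss_b = "tss_b.bed",
             orthologs = "orthologs.tsv",
             de_a = "de_a.tsv", de_b = "de_b.tsv",
             peaks_a = "peaks_a.bed", peaks_b = "peaks_b.bed",
             gene_sets = "gene_sets.gmt",
             motif_tf_map = "motif_tf_map.tsv")
  full <- file.path(dir, paths)
  names(full) <- names(paths)
  write_genome_fasta(fx$genomes$a, full["genome_a"])
  write_genome_fasta(fx$genomes$b, full["genome_b"])
  write_tss_bed(fx$tss_a, full["tss_a"])
  write_tss_bed(fx$tss_b, full["tss_b"])
  write_ortholog_map(fx$orthologs, full["orthologs"])
  write_de_table(fx$de_a, full["de_a"])
  write_de_table(fx$de_b, full["de_b"])
  write_diff_peaks(fx$peaks_a, full["peaks_a"])
  write_diff_peaks(fx$peaks_b, full["peaks_b"])
  write_gmt(fx$gene_sets, full["gene_sets"])
  writeLines(paste(fx$motif_tf_map$motif_id, fx$motif_tf_map$gene_id,
                   sep = "\t"), full["motif_tf_map"])
  manifest <- list(
    config = unclass(fx$config),
    files = as.list(setNames(unname(paths), names(paths))),
    checksums = as.list(setNames(unname(tools::md5sum(full)), names(paths))),
    truth = fx$truth,
    motif_truth = fx$motif_truth,
    n_retries = fx$n_retries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture manifest
#'
#' @param path Path to `manifest.json` (or the fixture directory).
#' @return The manifest as a list (data-frame fields restored).
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
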