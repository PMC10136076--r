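test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_conserved_epi = 100, n_conserved_fiber = 100),
               "planted")
  expect_error(sim_config(n_orthologs = 200), "orthologs")
})

test_that("simulated genomes are deterministic with uniform composition", {
  cfg <- sim_config(seed = 3, chrom_length = 200000)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_identical(nchar(g1$a[["chr1"]]), 200000L)
  freq <- table(strsplit(g1$a[["chr1"]], "")[[1]]) / 200000
  expect_true(all(abs(freq - 0.25) < 0.01))
  expect_false(identical(g1$a, simulate_genome(sim_config(seed = 4))$a))
})

test_that("annotation layout respects spacing, strand and ortholog counts", {
  cfg <- sim_config(seed = 2)
  ann <- simulate_annotation_and_orthologs(cfg)
  expect_identical(nrow(ann$tss_a), 150L)
  expect_identical(nrow(ann$tss_b), 150L)
  expect_identical(nrow(ann$orthologs), 120L)
  for (tss in list(ann$tss_a, ann$tss_b)) {
    expect_true(all(diff(tss$pos) >= 10000))
    expect_identical(as.integer(table(tss$strand)), c(75L, 75L))
  }
  # orthologs share symbols across species; extras are species-specific
  expect_identical(ann$orthologs$gene_a, ann$orthologs$gene_b)
  expect_true(all(grepl("^A", ann$tss_a$gene_id[121:150])))
  # genes that do not fit raise an error
  expect_error(simulate_annotation_and_orthologs(
    sim_config(chrom_length = 1000000)), "do not fit")
})

test_that("planted expression satisfies the classification criteria", {
  fx <- fixture_seed1()
  for (sp in c("a", "b")) {
    de <- fx[[paste0("de_", sp)]]
    lab <- classify_expression(de)
    truth_col <- paste0("gene_", sp)
    planted <- setNames(fx$truth$class, fx$truth[[truth_col]])
    got <- setNames(lab$label, lab$gene_id)[names(planted)]
    expect_identical(unname(got), unname(planted))
    # no null gene reaches significance
    null_genes <- setdiff(de$gene_id, names(planted))
    expect_true(all(de$qvalue[de$gene_id %in% null_genes] >= 0.05))
  }
  # determinism
  ann <- simulate_annotation_and_orthologs(fx$config)
  e1 <- simulate_expression(fx$config, ann)
  e2 <- simulate_expression(fx$config, ann)
  expect_identical(e1, e2)
})

test_that("planted peaks sit in promoter windows with recorded motifs", {
  fx <- fixture_seed1()
  win <- build_promoter_window(fx$tss_a)
  planted_fib <- fx$truth$gene_a[fx$truth$class == "FIBER"]
  for (g in planted_fib) {
    pk <- fx$peaks_a[fx$peaks_a$peak_id == paste0("a_pk_", g), ]
    w <- win[win$gene_id == g, ]
    expect_true(pk$start < w$end && w$start < pk$end)
    expect_true(pk$log2fc > 0 && pk$qvalue < 0.05)
  }
  # planted motif instances lie within peak bounds and match the genome
  mt <- fx$motif_truth[fx$motif_truth$species == "a", ]
  for (i in seq_len(nrow(mt))) {
    pk <- fx$peaks_a[fx$peaks_a$peak_id == mt$peak_id[i], ]
    W <- nchar(mt$instance[i])
    expect_true(mt$offset[i] >= pk$start && mt$offset[i] + W <= pk$end)
    expect_identical(substr(fx$genomes$a[["chr1"]], mt$offset[i] + 1,
                            mt$offset[i] + W), mt$instance[i])
  }
})

test_that("write_fixture emits all files with self-consistent checksums", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 5)
  man <- write_fixture(cfg, file.path(dir, "fx"))
  files <- unlist(man$files)
  expect_length(files, 11L)
  expect_true(all(file.exists(file.path(dir, "fx", files))))
  on_disk <- tools::md5sum(file.path(dir, "fx", files))
  expect_identical(unname(on_disk), unname(unlist(man$checksums)))
  # refusing to clobber without force
  expect_error(write_fixture(cfg, file.path(dir, "fx")), "not empty")
  # manifest round-trips through its serialization
  man2 <- read_manifest(file.path(dir, "fx"))
  expect_equal(man2$config$seed, 5)
  expect_identical(man2$truth$gene_a, man$truth$gene_a)
  expect_identical(unlist(man2$checksums), unlist(man$checksums))
  # the written fixture parses cleanly with the package readers
  rep <- validate_files(file.path(dir, "fx",
                                  c("de_a.tsv", "peaks_a.bed", "tss_a.bed",
                                    "orthologs.tsv", "gene_sets.gmt",
                                    "genome_a.fa")))
  expect_true(all(rep$ok))
})
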