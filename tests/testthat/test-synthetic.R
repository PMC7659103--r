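# Synthetic data generators: determinism, planted structure, file round
# trips, controlled codon divergence, expression truth.

test_that("genome generation is deterministic and plants the configured structure", {
  cfg <- small_genome_config(seed = 11)
  sim1 <- generate_genome(cfg)
  sim2 <- generate_genome(cfg)
  expect_identical(sim1, sim2)

  tr <- sim1$truth
  models <- sim1$bundle$models
  # planted counts
  expect_identical(sum(tr$classes != "none"), 30L)
  expect_identical(sum(tr$classes == "none"), 40L)
  expect_length(tr$tandem_clusters, 2)
  expect_length(tr$segmental_blocks, 1)
  # class mix leans 2R under the default proportions
  expect_gt(sum(tr$classes == "2R"), 15)

  # every truth entity references existing gene ids
  all_ids <- models$gene_id
  expect_true(all(unlist(tr$tandem_clusters) %in% all_ids))
  expect_true(all(unlist(lapply(tr$segmental_blocks, function(b)
    c(b$genes_a, b$genes_b))) %in% all_ids))
  expect_true(all(unlist(tr$triads) %in% all_ids))

  # tandem members occupy consecutive positions in all-genes order
  for (cl in tr$tandem_clusters) {
    chrom <- models$chromosome[match(cl[1], models$gene_id)]
    genes_on <- models$gene_id[models$chromosome == chrom]
    genes_on <- genes_on[order(models$start[match(genes_on, models$gene_id)])]
    pos <- match(cl, genes_on)
    expect_identical(sort(pos), min(pos):max(pos))
  }

  # genes do not overlap and respect the minimum gap
  for (chrom in unique(models$chromosome)) {
    m <- models[models$chromosome == chrom, ]
    m <- m[order(m$start), ]
    if (nrow(m) > 1)
      expect_true(all(m$start[-1] - m$end[-nrow(m)] - 1 >=
                        cfg$min_intergenic_gap))
  }

  # byte-identical files on re-write
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_genome_bundle(sim1$bundle, d1)
  write_genome_bundle(generate_genome(cfg)$bundle, d2)
  for (f in c("genome.fasta", "cds.fasta", "proteins.fasta", "genes.gff3"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("zero repeat noise plants exact consensus copies", {
  cfg <- small_genome_config(seed = 12, repeat_noise = 0,
                             n_tandem_clusters = 0, n_segmental_blocks = 0,
                             homoeolog_fraction = 0)
  sim <- generate_genome(cfg)
  fam <- names(sim$truth$classes)[sim$truth$classes != "none"]
  tid <- stats::setNames(sim$bundle$models$transcript_id,
                         sim$bundle$models$gene_id)
  n_rep <- c(`1R` = 1L, `2R` = 2L, `3R` = 3L, `4R` = 4L)
  for (g in fam) {
    prot <- as.character(sim$bundle$proteins[[tid[[g]]]])
    n_found <- length(gregexpr(MYB_REPEAT_CONSENSUS, prot, fixed = TRUE)[[1]])
    expect_identical(n_found, unname(n_rep[sim$truth$classes[[g]]]))
  }
})

test_that("over-full chromosomes give a capacity error", {
  expect_error(generate_genome(small_genome_config(seed = 1,
                                                   chromosome_length = 8000)),
               "capacity")
})

test_that("genome bundle and truth record round-trip through disk", {
  sim <- generate_genome(small_genome_config(seed = 13))
  d <- withr::local_tempdir()
  write_genome_bundle(sim$bundle, d)
  b2 <- read_genome_bundle(d)
  expect_identical(as_vec <- as.character(sim$bundle$genome),
                   as.character(b2$genome))
  expect_identical(as.character(sim$bundle$cds), as.character(b2$cds))
  expect_identical(as.character(sim$bundle$proteins),
                   as.character(b2$proteins))
  m1 <- sim$bundle$models
  m2 <- b2$models
  for (col in c("gene_id", "transcript_id", "chromosome", "start", "end",
                "strand", "exons"))
    expect_identical(m1[[col]], m2[[col]])

  tf <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, tf)
  tr2 <- read_truth(tf)
  expect_identical(unname(unlist(tr2$classes)), unname(sim$truth$classes))
  expect_identical(tr2$tandem_clusters, sim$truth$tandem_clusters)
  expect_equal(as.data.frame(tr2$kaks), sim$truth$kaks)
})

test_that("codon divergence hits its targets and never creates stops", {
  set.seed(301)
  prot <- paste0("M", random_proteinish(199))
  cds <- backtranslate_fixture(prot)

  # zero targets: identity
  expect_identical(simulate_codon_divergence(cds, 0, 0, seed = 1), cds)

  # synonymous-only: translation unchanged
  d_syn <- simulate_codon_divergence(cds, 0.3, 0, seed = 2)
  expect_false(identical(d_syn, cds))
  expect_identical(translate_fixture(d_syn), prot)

  # determinism + codon safety across seeds
  expect_identical(simulate_codon_divergence(cds, 0.2, 0.05, seed = 9),
                   simulate_codon_divergence(cds, 0.2, 0.05, seed = 9))
  for (s in 1:10) {
    d <- simulate_codon_divergence(cds, 0.4, 0.1, seed = s)
    expect_false(grepl("\\*", translate_fixture(d)))
  }

  # saturation guard
  expect_error(simulate_codon_divergence(cds, 5, 0.05), "saturation")
  expect_error(simulate_codon_divergence(cds, -0.1, 0), ">= 0")
})

test_that("expression generator plants truth it can report", {
  design <- default_stress_design(3)
  # null case
  ex0 <- generate_expression(paste0("g", 1:50), design,
                             planted_fraction = 0, seed = 4)
  expect_identical(nrow(ex0$truth$expression), 0L)

  # noise-free limit: planted log2FC 3 gives an 8x mean ratio (the
  # per-sample TPM rescaling perturbs it only by the planted mass share,
  # which vanishes as the planted fraction shrinks)
  ex <- generate_expression(paste0("g", 1:400), design,
                            planted_fraction = 0.05, effect_log2fc = 3,
                            dispersion = 0, seed = 5)
  tr <- ex$truth$expression
  up <- tr[tr$status == "up", ]
  expect_gt(nrow(up), 0)
  for (i in seq_len(nrow(up))) {
    treated_cond <- sub("_vs_.*$", "", up$contrast[i])
    t_s <- design$samples$sample_id[design$samples$condition == treated_cond]
    c_s <- design$samples$sample_id[design$samples$condition == "CK"]
    ratio <- mean(ex$tpm[up$gene_id[i], t_s]) / mean(ex$tpm[up$gene_id[i], c_s])
    expect_equal(ratio, 8, tolerance = 0.1)
  }

  # determinism, errors
  expect_identical(generate_expression(paste0("g", 1:30), design, seed = 6),
                   generate_expression(paste0("g", 1:30), design, seed = 6))
  expect_error(generate_expression(character(0), design), "empty")
  expect_error(generate_expression("g1", design, planted_fraction = 2),
               "planted_fraction")

  # TSV round trip
  d <- withr::local_tempdir()
  write_expression(ex$tpm, design, d)
  back <- read_expression(d)
  expect_equal(back$tpm, ex$tpm)
  expect_identical(back$design$samples$sample_id, design$samples$sample_id)
})
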