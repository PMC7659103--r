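# Pairwise hits, tandem clusters, segmental blocks, homoeolog groups.

test_that("pairwise_align reports identity over aligned columns", {
  ident <- pairwise_align("ACGTACGT", "ACGTACGT")
  expect_equal(ident$pct_identity, 100)
  expect_identical(ident$aln_length, 8L)

  mm <- pairwise_align("ACGT", "ACGA", mode = "global")
  expect_equal(mm$pct_identity, 75)

  # symmetry
  a <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  expect_equal(pairwise_align(a, b)$pct_identity,
               pairwise_align(b, a)$pct_identity)

  # protein route
  pp <- pairwise_align("MKLVWAMKLVWA", "MKLVWAMKLVWA", type = "protein")
  expect_equal(pp$pct_identity, 100)
  expect_error(pairwise_align("", "ACGT"), "empty")
})

test_that("ingest_pairhits parses outfmt-6, drops self-hits, flags bad rows", {
  tf <- withr::local_tempfile()
  rows <- rbind(
    c("g1", "g2", "95.5", "600", "27", "0", "1", "600", "1", "600",
      "1e-30", "580"),
    c("g3", "g3", "100", "500", "0", "0", "1", "500", "1", "500", "0", "900"),
    c("g2", "g1", "95.5", "600", "27", "0", "1", "600", "1", "600",
      "1e-30", "580"))
  write_outfmt6_fixture(tf, rows)
  hits <- ingest_pairhits(tf)
  expect_identical(nrow(hits), 2L)  # self-hit dropped, reciprocal kept
  expect_equal(hits$pct_identity[1], 95.5)
  expect_equal(hits$evalue[1], 1e-30)
  expect_equal(hits$score[1], 580)

  tf2 <- withr::local_tempfile()
  writeLines(character(0), tf2)
  expect_identical(nrow(ingest_pairhits(tf2)), 0L)

  tf3 <- withr::local_tempfile()
  writeLines("g1\tg2\t95.5", tf3)
  expect_error(ingest_pairhits(tf3), "line 1")
})

test_that("call_tandem enforces each of the four criteria", {
  family <- c("tA", "tB")
  good <- hit_row("tA", "tB", identity = 95, len = 850, evalue = 1e-30)
  lens <- c(tA = 900L, tB = 900L, bgX = 900L)

  # all criteria met, genes adjacent -> one cluster of two
  m <- knockout_models(insert_between = FALSE)
  cl <- call_tandem(good, m, family, seq_lengths = lens)
  expect_identical(unique(cl$cluster_id), "tandem_01")
  expect_identical(cl$gene_id, c("tA", "tB"))

  # criterion 3: an inserted gene of any kind kills the pair
  m_ins <- knockout_models(insert_between = TRUE)
  expect_identical(nrow(call_tandem(good, m_ins, family, seq_lengths = lens)),
                   0L)

  # criterion 2: identity 75 rejected
  bad_id <- hit_row("tA", "tB", identity = 75, len = 850, evalue = 1e-30)
  expect_identical(nrow(call_tandem(bad_id, m, family, seq_lengths = lens)),
                   0L)

  # criterion 1: coverage below 80% of the longer gene rejected
  short <- hit_row("tA", "tB", identity = 95, len = 400, evalue = 1e-30)
  expect_identical(nrow(call_tandem(short, m, family, seq_lengths = lens)),
                   0L)

  # criterion 4: weak E-value rejected; score fallback when E-value absent
  weak <- hit_row("tA", "tB", identity = 95, len = 850, evalue = 1e-5)
  expect_identical(nrow(call_tandem(weak, m, family, seq_lengths = lens)), 0L)
  noev <- hit_row("tA", "tB", identity = 95, len = 850, evalue = NA, score = 500)
  cl2 <- call_tandem(noev, m, family, seq_lengths = lens)
  expect_identical(cl2$evidence[1], "score")
  expect_identical(nrow(call_tandem(
    hit_row("tA", "tB", identity = 95, len = 850, evalue = NA, score = 10),
    m, family, seq_lengths = lens)), 0L)

  expect_error(call_tandem(hit_row("tA", "ghost"), m, family,
                           seq_lengths = lens), "unknown gene")
})

test_that("tandem clusters are permutation-invariant and disjoint", {
  sim <- generate_genome(small_genome_config(seed = 51))
  models <- sim$bundle$models
  family <- names(sim$truth$classes)[sim$truth$classes != "none"]
  tid <- stats::setNames(models$transcript_id, models$gene_id)
  cds <- stats::setNames(
    as.character(sim$bundle$cds)[match(tid[family], names(sim$bundle$cds))],
    family)
  hits <- make_pairhits(cds, type = "dna")
  cl1 <- call_tandem(hits, models, family)
  set.seed(52)
  cl2 <- call_tandem(hits[sample(nrow(hits)), ], models, family)
  expect_identical(lapply(split(cl1$gene_id, cl1$cluster_id), sort),
                   lapply(split(cl2$gene_id, cl2$cluster_id), sort))
  expect_false(anyDuplicated(cl1$gene_id) > 0)

  # loosened thresholds reduce to adjacency components (brute-force oracle)
  loose <- call_tandem(hits, models, family, coverage = 0,
                       min_identity = 0, min_score = -Inf)
  found <- unname(lapply(split(loose$gene_id, loose$cluster_id), sort))
  want <- oracle_adjacency_components(hits, models, family)
  expect_identical(found[order(vapply(found, `[`, "", 1))],
                   want[order(vapply(want, `[`, "", 1))])

  # planted clusters recovered exactly
  got <- unname(lapply(split(cl1$gene_id, cl1$cluster_id), sort))
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(lapply(sim$truth$tandem_clusters, sort),
                         paste, "", collapse = ","))
})

test_that("call_segmental chains collinear anchors under span criteria", {
  # two chromosomes, 4 family genes each, 10 kb apart
  starts <- seq(1000, by = 10000, length.out = 4)
  m <- gene_models(
    gene_id = c(paste0("a", 1:4), paste0("b", 1:4)),
    chromosome = rep(c("chr1A", "chr2A"), each = 4),
    start = rep(starts, 2), end = rep(starts + 900, 2),
    strand = "+",
    exons = c(lapply(starts, function(s) cbind(s, s + 900)),
              lapply(starts, function(s) cbind(s, s + 900))))
  family <- m$gene_id
  anchors <- do.call(rbind, lapply(1:4, function(i)
    hit_row(paste0("a", i), paste0("b", i), identity = 96, evalue = 1e-40)))

  bl <- call_segmental(anchors, m, family, min_span = 20000, min_anchors = 2)
  expect_identical(nrow(bl), 1L)
  expect_identical(bl$n_anchors, 4L)
  expect_identical(bl$genes_a, "a1;a2;a3;a4")

  # span below the threshold: no block
  expect_identical(nrow(call_segmental(anchors, m, family,
                                       min_span = 600000)), 0L)

  # identity below 90: anchors dropped
  weak <- anchors
  weak$pct_identity <- 85
  expect_identical(nrow(call_segmental(weak, m, family, min_span = 20000)),
                   0L)

  # reversed subject order without a consistent orientation: chain breaks
  scrambled <- anchors
  scrambled$subject_id <- paste0("b", c(3, 1, 4, 2))
  expect_identical(nrow(call_segmental(scrambled, m, family,
                                       min_span = 20000, min_anchors = 3)),
                   0L)

  # planted blocks on a generated genome are recovered
  sim <- generate_genome(small_genome_config(seed = 53))
  models <- sim$bundle$models
  fam <- names(sim$truth$classes)[sim$truth$classes != "none"]
  tid <- stats::setNames(models$transcript_id, models$gene_id)
  prot <- stats::setNames(
    as.character(sim$bundle$proteins)[match(tid[fam],
                                            names(sim$bundle$proteins))],
    fam)
  ph <- make_pairhits(prot, type = "protein")
  got <- call_segmental(ph, models, fam, min_span = 10000)
  tr_blocks <- sim$truth$segmental_blocks
  expect_gte(nrow(got), length(tr_blocks))
  for (b in tr_blocks) {
    match_found <- any(vapply(seq_len(nrow(got)), function(i) {
      ga <- strsplit(got$genes_a[i], ";")[[1]]
      gb <- strsplit(got$genes_b[i], ";")[[1]]
      (all(b$genes_a %in% c(ga, gb)) && all(b$genes_b %in% c(ga, gb)))
    }, TRUE))
    expect_true(match_found)
  }
})

test_that("homolog groups use reciprocal best hits per subgenome pair", {
  sub_of <- c(a1 = "A", b1 = "B", d1 = "D", a2 = "A")
  hits <- rbind(hit_row("a1", "b1", score = 900),
                hit_row("a1", "d1", score = 880),
                hit_row("b1", "d1", score = 870),
                hit_row("a2", "b1", score = 100))  # not mutual-best
  res <- find_homolog_groups(hits, names(sub_of), sub_of)
  g <- res$groups
  triad <- g$group_id[g$gene_id == "a1"]
  expect_setequal(g$gene_id[g$group_id == triad], c("a1", "b1", "d1"))
  expect_identical(unique(g$completeness[g$group_id == triad]), 3L)
  # a2 left as a singleton, completeness 1
  single <- g$group_id[g$gene_id == "a2"]
  expect_identical(sum(g$group_id == single), 1L)
  expect_identical(g$completeness[g$gene_id == "a2"], 1L)
  expect_equal(res$fraction_complete, 0.5)

  # triad-only genome: fraction_complete tracks the planted fraction
  sim <- generate_genome(small_genome_config(
    seed = 54, n_tandem_clusters = 0, n_segmental_blocks = 0))
  models <- sim$bundle$models
  fam <- names(sim$truth$classes)[sim$truth$classes != "none"]
  tid <- stats::setNames(models$transcript_id, models$gene_id)
  prot <- stats::setNames(
    as.character(sim$bundle$proteins)[match(tid[fam],
                                            names(sim$bundle$proteins))],
    fam)
  hom <- find_homolog_groups(make_pairhits(prot, type = "protein"), fam,
                             stats::setNames(
                               subgenome_of_chrom(models$chromosome),
                               models$gene_id))
  n_triads <- length(sim$truth$triads)
  n_single <- length(sim$truth$homoeolog_singletons)
  expect_equal(hom$fraction_complete, n_triads / (n_triads + n_single),
               tolerance = 0.1)
})
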