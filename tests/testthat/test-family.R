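# Repeat detection, classification and naming.

test_that("dedupe_transcripts keeps the longest CDS with lexicographic ties", {
  models <- toy_models()
  prots <- c(gA.t1 = "MAAA", gA.t2 = "MCCC", gB.t1 = "MDDD", gC.t1 = "MEEE")
  reps <- dedupe_transcripts(prots, models)
  expect_identical(nrow(reps), 3L)
  # gA.t2 (CDS 750) beats gA.t1 (CDS 600)
  expect_identical(reps$protein_id[reps$gene_id == "gA"], "gA.t2")
  # single-isoform genes unchanged
  expect_identical(reps$protein_id[reps$gene_id == "gB"], "gB.t1")

  # equal lengths: lexicographically smallest transcript id wins
  tie_models <- gene_models(gene_id = c("gT", "gT"),
                            transcript_id = c("t2", "t1"),
                            chromosome = "chr1A", start = 1, end = 300,
                            strand = "+",
                            exons = list(cbind(1, 300), cbind(1, 300)))
  tie <- dedupe_transcripts(c(t2 = "MA", t1 = "MC"), tie_models)
  expect_identical(tie$protein_id, "t1")

  expect_error(dedupe_transcripts(c(orphan = "MA"), models), "no parent gene")
})

test_that("scan_repeats finds planted consensus and honors the threshold", {
  pssm <- build_repeat_pssm(noise = 0)
  set.seed(21)
  flank_l <- random_proteinish(30)
  flank_r <- random_proteinish(40)
  prot <- paste0(flank_l, MYB_REPEAT_CONSENSUS, flank_r)
  hits <- scan_repeats(prot, pssm, bit_threshold = 30, protein_id = "p1")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 31L)
  expect_identical(hits$end, 82L)
  # noise-0 matrix: the planted window achieves the maximum possible score
  expect_equal(hits$score, sum(apply(pssm, 2, max)))

  # threshold -Inf reports every window
  all_w <- scan_repeats(prot, pssm, bit_threshold = -Inf)
  expect_identical(nrow(all_w), nchar(prot) - 52L + 1L)

  # protein shorter than the matrix: empty, not an error
  expect_identical(nrow(scan_repeats("MSHRT", pssm, 0)), 0L)
  expect_error(scan_repeats("MB1Z", pssm, 0), "invalid residue")
})

test_that("random proteins essentially never reach the default threshold", {
  pssm <- build_repeat_pssm()
  set.seed(22)
  n_windows <- 0L
  n_hits <- 0L
  for (i in 1:300) {
    prot <- random_proteinish(300)
    n_windows <- n_windows + (300L - 52L + 1L)
    n_hits <- n_hits + nrow(scan_repeats(prot, pssm, bit_threshold = 30))
  }
  expect_lt(n_hits / n_windows, 1e-3)
})

test_that("merge_hits merges, separates and is idempotent", {
  h <- function(s, e) data.frame(protein_id = rep("p", length(s)),
                                 start = as.integer(s), end = as.integer(e),
                                 score = rep(50, length(s)),
                                 evalue = rep(NA_real_, length(s)))
  m1 <- merge_hits(h(c(10, 40), c(61, 91)))
  expect_identical(m1$repeat_count, 1L)
  expect_identical(unname(m1$repeats[1, ]), c(10L, 91L))

  m2 <- merge_hits(h(c(10, 70), c(61, 121)), min_separation = 5)
  expect_identical(m2$repeat_count, 2L)

  m0 <- merge_hits(h(integer(0), integer(0)))
  expect_identical(m0$repeat_count, 0L)
  expect_identical(classify_family(m0), "none")

  # idempotence on random hit sets
  set.seed(23)
  for (i in 1:20) {
    s <- sort(sample(1:300, 8))
    hits <- h(s, s + sample(30:60, 8, replace = TRUE))
    once <- merge_hits(hits)
    again <- merge_hits(data.frame(protein_id = "p",
                                   start = once$repeats[, 1],
                                   end = once$repeats[, 2],
                                   score = 0, evalue = NA_real_))
    expect_identical(once$repeats, again$repeats)
  }
})

test_that("classification maps repeat counts to subfamilies", {
  expect_identical(classify_family(1L), "1R")
  expect_identical(classify_family(2L), "2R")
  expect_identical(classify_family(3L), "3R")
  expect_identical(classify_family(4L), "4R")
  expect_identical(classify_family(0L), "none")
  expect_identical(classify_family(5L), "none")
})

test_that("domtblout ingest maps envelope fields and rejects bad rows", {
  tf <- withr::local_tempfile(fileext = ".domtblout")
  write_domtblout_fixture(tf, "prot1", env_from = c(10, 70),
                          env_to = c(61, 121), ievalue = 1e-20)
  hits <- ingest_domtblout(tf)
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$start, c(10L, 70L))
  expect_identical(hits$end, c(61L, 121L))
  expect_equal(hits$evalue, c(1e-20, 1e-20))

  # comment-only file
  tf2 <- withr::local_tempfile()
  writeLines(c("# one", "# two"), tf2)
  expect_identical(nrow(ingest_domtblout(tf2)), 0L)

  # end < start names the line
  tf3 <- withr::local_tempfile()
  write_domtblout_fixture(tf3, "prot1", env_from = 61, env_to = 10)
  expect_error(ingest_domtblout(tf3), "line 3")

  # truncated row
  tf4 <- withr::local_tempfile()
  writeLines("prot1 - 400 Myb 52", tf4)
  expect_error(ingest_domtblout(tf4), "22")
})

test_that("PSSM path and domtblout path agree on noise-free architectures", {
  set.seed(24)
  pssm <- build_repeat_pssm(noise = 0)
  for (n_rep in 1:3) {
    parts <- character(0)
    starts <- integer(0)
    pos <- 20L
    parts <- random_proteinish(20)
    for (r in seq_len(n_rep)) {
      starts <- c(starts, pos + 1L)
      parts <- paste0(parts, MYB_REPEAT_CONSENSUS)
      pos <- pos + 52L
      if (r < n_rep) {
        link <- random_proteinish(8)
        parts <- paste0(parts, link)
        pos <- pos + 8L
      }
    }
    prot <- paste0(parts, random_proteinish(25))
    scan_arch <- merge_hits(scan_repeats(prot, pssm, 30, "p1"))
    tf <- withr::local_tempfile()
    write_domtblout_fixture(tf, "p1", env_from = starts,
                            env_to = starts + 51L)
    ingest_arch <- merge_hits(ingest_domtblout(tf))
    expect_identical(scan_arch$repeat_count, ingest_arch$repeat_count)
    expect_identical(classify_family(scan_arch), classify_family(ingest_arch))
  }
})

test_that("assign_names orders by chromosome, subgenome, position", {
  members <- data.frame(
    gene_id = c("x1", "x2", "x3"),
    class = "2R",
    chromosome = c("chr1A", "chr1B", "chr2A"),
    start = c(500, 100, 50), stringsAsFactors = FALSE)
  named <- assign_names(members, prefix = "TaMYB")
  expect_identical(named$assigned_name,
                   paste0("TaMYB", 1:3))
  expect_identical(named$gene_id, c("x1", "x2", "x3"))

  # class series are separate; 3R gets the class tag
  mixed <- rbind(members,
                 data.frame(gene_id = c("y1", "y2", "y3"), class = "3R",
                            chromosome = c("chr1A", "chr3D", "chr5B"),
                            start = c(10, 20, 30)))
  nm <- assign_names(mixed, prefix = "TaMYB")
  expect_identical(nm$assigned_name[nm$class == "3R"],
                   paste0("TaMYB3R", 1:3))
  expect_identical(nm$assigned_name[nm$gene_id == "y1"], "TaMYB3R1")

  # bijection, stable under permutation of the input
  set.seed(25)
  perm <- mixed[sample(nrow(mixed)), ]
  nm2 <- assign_names(perm, prefix = "TaMYB")
  expect_identical(stats::setNames(nm2$assigned_name, nm2$gene_id)[nm$gene_id],
                   stats::setNames(nm$assigned_name, nm$gene_id))
  expect_false(anyDuplicated(nm$assigned_name) > 0)

  # position ties break by gene id; unplaced chromosomes go last
  ties <- data.frame(gene_id = c("b", "a"), class = "2R",
                     chromosome = "chr1A", start = 100)
  expect_identical(assign_names(ties)$gene_id, c("a", "b"))
  unpl <- rbind(members,
                data.frame(gene_id = "z9", class = "2R",
                           chromosome = "scaffold77", start = 5))
  expect_identical(assign_names(unpl)$gene_id[4], "z9")

  expect_error(assign_names(rbind(members, members[1, ])), "duplicate")
})

test_that("family recovery on small genomes is exact over several seeds", {
  for (s in 31:35) {
    sim <- generate_genome(small_genome_config(seed = s))
    fam <- identify_family(sim$bundle$proteins, sim$bundle$models)
    pred <- stats::setNames(fam$class, fam$gene_id)[names(sim$truth$classes)]
    expect_identical(unname(pred), unname(sim$truth$classes))
  }
})
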