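# Gene structure, protein physicochemistry, promoters and motif scanning.

test_that("count_introns is exons minus one", {
  m <- toy_models()
  expect_identical(count_introns(m[2, ]), 0L)   # single exon
  expect_identical(count_introns(m[1, ]), 1L)
  many <- gene_models(gene_id = "g12", chromosome = "chr1A",
                      start = 1, end = 12 * 200, strand = "+",
                      exons = list(cbind(seq(1, by = 200, length.out = 12),
                                         seq(100, by = 200, length.out = 12))))
  expect_identical(count_introns(many[1, ]), 11L)
  bad <- many
  bad$exons[[1]] <- bad$exons[[1]][0, , drop = FALSE]
  expect_error(count_introns(bad[1, ]), "zero exons")
})

test_that("molecular weight matches the residue-mass table and is additive", {
  expect_equal(round(molecular_weight("GG"), 5), 0.13212)
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("GZ"), "unknown")
  # X uses an average mass, no error
  expect_gt(molecular_weight("GXG"), molecular_weight("GG"))

  # additivity: mw(a+b) = mw(a) + mw(b) - water, to 1e-9 kDa
  set.seed(41)
  water_kda <- molecular_weight("G") - 57.0519 / 1000
  for (i in 1:10) {
    a <- random_proteinish(sample(5:50, 1))
    b <- random_proteinish(sample(5:50, 1))
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - water_kda,
                 tolerance = 1e-9)
  }
})

test_that("isoelectric point reproduces the Bjellqvist reference and is monotone", {
  # frozen from an independent Bjellqvist implementation
  # (Biopython IsoelectricPoint, all twenty residues once): 6.7846
  expect_equal(isoelectric_point("ACDEFGHIKLMNPQRSTVWY"), 6.7846,
               tolerance = 0.01)
  expect_gt(isoelectric_point("KKKKKKKK"), isoelectric_point("DDDDDDDD"))
  # appending a lysine never decreases pI
  set.seed(42)
  for (i in 1:15) {
    p <- random_proteinish(sample(10:80, 1))
    expect_gte(isoelectric_point(paste0(p, "K")) - isoelectric_point(p),
               -2e-3)  # bisection tolerance
    expect_true(is.finite(isoelectric_point(p)))
  }
  props <- protein_properties(c(p1 = "MKLVWA", p2 = "DDEEK"))
  expect_identical(props$length, c(6L, 5L))
  expect_true(all(props$pI > 0 & props$pI < 14))
})

test_that("promoter extraction follows strand and chromosome edges", {
  chrom <- paste(rep("ACGT", 2500), collapse = "")  # 10 kb
  genome <- Biostrings::DNAStringSet(c(chr1A = chrom))
  plus <- gene_models(gene_id = "gp", chromosome = "chr1A", start = 2001,
                      end = 3000, strand = "+",
                      exons = list(cbind(2001, 3000)))
  pr <- extract_promoter(genome, plus[1, ], length = 1500)
  expect_false(pr$truncated)
  expect_identical(pr$sequence, substr(chrom, 501, 2000))

  minus <- gene_models(gene_id = "gm", chromosome = "chr1A", start = 2001,
                       end = 3000, strand = "-",
                       exons = list(cbind(2001, 3000)))
  pm <- extract_promoter(genome, minus[1, ], length = 1500)
  expect_identical(
    pm$sequence,
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(chrom, 3001, 4500)))))

  near <- gene_models(gene_id = "gn", chromosome = "chr1A", start = 400,
                      end = 900, strand = "+", exons = list(cbind(400, 900)))
  expect_warning(pn <- extract_promoter(genome, near[1, ], length = 1500),
                 "truncated")
  expect_true(pn$truncated)
  expect_identical(nchar(pn$sequence), 399L)

  at1 <- gene_models(gene_id = "g1", chromosome = "chr1A", start = 1,
                     end = 600, strand = "+", exons = list(cbind(1, 600)))
  p1 <- extract_promoter(genome, at1[1, ], length = 1500)
  expect_identical(p1$sequence, "")
  expect_true(p1$truncated)
})

test_that("motif scanning handles IUPAC codes, strands and overlaps", {
  prom <- paste0(strrep("A", 99), "CAACTG", strrep("A", 50),
                 "TACG", strrep("C", 20), "TATG", strrep("G", 20))
  occ <- scan_motifs(prom, c(MBS = "CAACTG"), both_strands = FALSE)
  expect_identical(occ$offset, 100L)
  expect_identical(occ$strand, "+")

  tay <- scan_motifs(prom, c(TAYG = "TAYG"), both_strands = FALSE)
  expect_identical(sort(tay$offset),
                   c(as.integer(regexpr("TACG", prom)),
                     as.integer(regexpr("TATG", prom))))

  # palindromic pattern on both strands: two occurrences at the same offset
  pal <- scan_motifs(paste0("AAA", "GAATTC", "AAA"), c(EcoRI = "GAATTC"),
                     both_strands = TRUE)
  expect_identical(nrow(pal), 2L)
  expect_setequal(unique(pal$strand), c("-", "+"))
  expect_identical(unique(pal$offset), 4L)

  expect_error(scan_motifs("ACGT", c(bad = "AZGT")), "invalid IUPAC")
  expect_identical(nrow(scan_motifs("", c(MBS = "CAACTG"))), 0L)
})

test_that("planted promoter motifs are all recovered on either strand", {
  sim <- generate_genome(small_genome_config(seed = 44))
  tr <- sim$truth
  expect_gt(nrow(tr$motifs), 10)
  dict <- default_motif_dictionary()
  found <- 0L
  total <- 0L
  for (i in seq_len(nrow(tr$motifs))) {
    mrow <- tr$motifs[i, ]
    gi <- match(mrow$gene_id, sim$bundle$models$gene_id)
    prom <- suppressWarnings(
      extract_promoter(sim$bundle$genome, sim$bundle$models[gi, ],
                       length = 1500))
    L <- nchar(prom$sequence)
    if (L < mrow$upstream + mrow$length) next
    total <- total + 1L
    occ <- scan_motifs(prom$sequence, dict[mrow$motif_name],
                       both_strands = TRUE, gene_id = mrow$gene_id)
    expected_offset <- L - mrow$upstream - mrow$length + 1L
    if (any(occ$offset == expected_offset & occ$strand == mrow$strand))
      found <- found + 1L
  }
  expect_gt(total, 10)
  expect_identical(found, total)
})

test_that("intron counts equal planted exon counts minus one genome-wide", {
  sim <- generate_genome(small_genome_config(seed = 45))
  m <- sim$bundle$models
  for (i in seq_len(nrow(m)))
    expect_identical(count_introns(m[i, ]), nrow(m$exons[[i]]) - 1L)
})

test_that("motif dictionary TSV loads", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tpattern\tnote", "MBS\tCAACTG\tdrought",
               "ABRE\tACGTGKC\tABA"), tf)
  d <- read_motif_dictionary(tf)
  expect_identical(d, c(MBS = "CAACTG", ABRE = "ACGTGKC"))
})
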