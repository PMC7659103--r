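# Shared fixtures: all built in code at test time.

# Test-side sequence helpers, independent of the package internals.
random_proteinish <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Deterministic back-translation: first codon of each amino acid.
backtranslate_fixture <- function(prot) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), as.character(gc))
  paste(vapply(strsplit(prot, "")[[1]], function(a) by_aa[[a]][1], ""),
        collapse = "")
}

translate_fixture <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

# Small gene-model table: gA has two isoforms (CDS 600 vs 750), gB is on the
# minus strand, gC sits on another chromosome.
toy_models <- function() {
  gene_models(
    gene_id = c("gA", "gA", "gB", "gC"),
    transcript_id = c("gA.t1", "gA.t2", "gB.t1", "gC.t1"),
    chromosome = c("chr1A", "chr1A", "chr1A", "chr2B"),
    start = c(1000, 1000, 5000, 300),
    end = c(1898, 1898, 5599, 1098),
    strand = c("+", "+", "-", "+"),
    exons = list(cbind(c(1000, 1500), c(1200, 1898)),
                 cbind(1000, 1749),
                 cbind(5000, 5599),
                 cbind(c(300, 700), c(500, 1098))))
}

# Fast genome config for per-module tests (acceptance uses full defaults);
# ... overrides any of the small defaults.
small_genome_config <- function(seed, ...) {
  args <- list(chromosome_length = 150000,
               n_family_genes = 30,
               n_background_genes = 40,
               n_tandem_clusters = 2,
               tandem_cluster_size = c(2, 3),
               n_segmental_blocks = 1,
               segmental_block_genes = 3,
               segmental_span = 20000,
               seed = seed)
  do.call(synthetic_genome_config, utils::modifyList(args, list(...)))
}

# Write a HMMER3-style per-domain table (22 whitespace columns + free-text
# description) for the given envelope hits.
write_domtblout_fixture <- function(path, protein_id, env_from, env_to,
                                    ievalue = 1e-20, score = 80) {
  n <- length(env_from)
  if (length(protein_id) == 1) protein_id <- rep(protein_id, n)
  if (length(ievalue) == 1) ievalue <- rep(ievalue, n)
  if (length(score) == 1) score <- rep(score, n)
  header <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  rows <- vapply(seq_len(n), function(i) {
    paste(protein_id[i], "-", 400, "Myb_DNA-binding", "PF00249.33", 52,
          format(ievalue[i], scientific = TRUE), score[i] + 1, 0.1,
          i, n, format(ievalue[i] / 10, scientific = TRUE),
          format(ievalue[i], scientific = TRUE), score[i], 0.1,
          1, 52, env_from[i] + 1, env_to[i] - 1, env_from[i], env_to[i],
          0.95, "synthetic fixture", sep = " ")
  }, "")
  writeLines(c(header, rows), path)
  path
}

# Write a 12-column outfmt-6 style tabular hit file.
write_outfmt6_fixture <- function(path, rows) {
  lines <- apply(rows, 1, paste, collapse = "\t")
  writeLines(lines, path)
  path
}

# Minimal pair-hit data.frame builder (evalue path).
hit_row <- function(q, s, identity = 95, len = 600, evalue = 1e-30,
                    score = 500) {
  data.frame(query_id = q, subject_id = s, pct_identity = identity,
             aln_length = len, evalue = evalue, score = score,
             stringsAsFactors = FALSE)
}

# Three-gene chromosome (family A, family B, optional background X between)
# for tandem criterion knock-out tests.
knockout_models <- function(insert_between = FALSE) {
  if (insert_between) {
    gene_models(
      gene_id = c("tA", "bgX", "tB"),
      chromosome = "chr3D",
      start = c(1000, 3000, 5000), end = c(1899, 3899, 5899),
      strand = "+",
      exons = list(cbind(1000, 1899), cbind(3000, 3899), cbind(5000, 5899)))
  } else {
    gene_models(
      gene_id = c("tA", "tB"),
      chromosome = "chr3D",
      start = c(1000, 5000), end = c(1899, 5899),
      strand = "+",
      exons = list(cbind(1000, 1899), cbind(5000, 5899)))
  }
}
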