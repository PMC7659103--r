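# Gene-model table and genome-bundle file I/O.
#
# A gene-model table is a data.frame with one row per transcript:
#   gene_id, transcript_id, chromosome, start, end (1-based inclusive),
#   strand ("+"/"-"), and a list column `exons` holding a 2-column matrix
#   (start, end) of genomic exon coordinates sorted ascending. For generated
#   genomes exons coincide with CDS segments (no UTRs).

#' Construct a gene-model table
#'
#' @param gene_id,transcript_id,chromosome,start,end,strand vectors, one
#'   element per transcript.
#' @param exons list of 2-column matrices (start, end), genomic coordinates,
#'   ascending, one per transcript.
#' @return data.frame with class `myb_gene_models`.
#' @export
gene_models <- function(gene_id, transcript_id = gene_id, chromosome, start,
                        end, strand, exons) {
  if (length(exons) != length(gene_id))
    stop_input("need one exons matrix per transcript")
  # scalar fields recycle across transcripts
  df <- data.frame(gene_id = as.character(gene_id),
                   transcript_id = as.character(transcript_id),
                   chromosome = as.character(chromosome),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  df$exons <- lapply(unname(exons), function(e) {
    e <- matrix(as.integer(e), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    e[order(e[, 1]), , drop = FALSE]
  })
  ok <- vapply(seq_len(nrow(df)), function(i) {
    e <- df$exons[[i]]
    all(e[, 1] <= e[, 2]) && all(e[, 1] >= df$start[i]) &&
      all(e[, 2] <= df$end[i]) &&
      (nrow(e) < 2 || all(e[-1, 1] > e[-nrow(e), 2]))
  }, TRUE)
  if (!all(ok))
    stop_input("exons must be sorted, non-overlapping and within [start,end] (rows: %s)",
               paste(which(!ok), collapse = ","))
  class(df) <- c("myb_gene_models", class(df))
  df
}

#' Write a genome bundle to a directory
#'
#' Writes genome.fasta (one record per chromosome), cds.fasta, proteins.fasta
#' (both named by transcript id) and genes.gff3 (gene/mRNA/exon/CDS features,
#' 1-based inclusive).
#'
#' @param bundle list with elements `genome` (DNAStringSet), `cds`
#'   (DNAStringSet), `proteins` (AAStringSet), `models` (gene-model table).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fasta"))
  Biostrings::writeXStringSet(bundle$cds, file.path(dir, "cds.fasta"))
  Biostrings::writeXStringSet(bundle$proteins, file.path(dir, "proteins.fasta"))
  export_gff3(bundle$models, file.path(dir, "genes.gff3"))
  invisible(dir)
}

#' @rdname write_genome_bundle
#' @export
read_genome_bundle <- function(dir) {
  list(genome = Biostrings::readDNAStringSet(file.path(dir, "genome.fasta")),
       cds = Biostrings::readDNAStringSet(file.path(dir, "cds.fasta")),
       proteins = Biostrings::readAAStringSet(file.path(dir, "proteins.fasta")),
       models = import_gff3(file.path(dir, "genes.gff3")))
}

#' Export a gene-model table as GFF3
#'
#' @param models gene-model table.
#' @param path output file.
#' @export
export_gff3 <- function(models, path) {
  grs <- list()
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    ex <- models$exons[[i]]
    n <- nrow(ex)
    # CDS phase in transcription order
    ord <- if (g$strand == "+") seq_len(n) else rev(seq_len(n))
    lens <- ex[ord, 2] - ex[ord, 1] + 1L
    cum <- cumsum(c(0L, lens))[seq_len(n)]
    phase_tx <- (3L - (cum %% 3L)) %% 3L
    phase <- integer(n)
    phase[ord] <- phase_tx
    gr <- GenomicRanges::GRanges(
      seqnames = g$chromosome,
      ranges = IRanges::IRanges(
        start = c(g$start, g$start, ex[, 1], ex[, 1]),
        end = c(g$end, g$end, ex[, 2], ex[, 2])),
      strand = g$strand)
    gr$source <- "mybfam"
    gr$type <- c("gene", "mRNA", rep("exon", n), rep("CDS", n))
    gr$ID <- c(g$gene_id, g$transcript_id,
               paste0(g$transcript_id, ".exon", seq_len(n)),
               paste0(g$transcript_id, ".cds", seq_len(n)))
    gr$Parent <- c(NA_character_, g$gene_id,
                   rep(g$transcript_id, 2L * n))
    gr$phase <- c(NA_integer_, NA_integer_, rep(NA_integer_, n), phase)
    grs[[i]] <- gr
  }
  all <- suppressWarnings(do.call(c, grs))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Import gene models from a GFF3 file
#'
#' Reads gene/mRNA/exon features (CDS features used as exons when no exon
#' rows are present) and rebuilds the gene-model table.
#'
#' @param path GFF3 file.
#' @return gene-model table.
#' @export
import_gff3 <- function(path) {
  if (!file.exists(path)) stop_input("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  mrnas <- gr[type == "mRNA"]
  seg_type <- if (any(type == "exon")) "exon" else "CDS"
  segs <- gr[type == seg_type]
  seg_parent <- vapply(segs$Parent, function(p) p[1], "")
  mrna_parent <- vapply(mrnas$Parent, function(p) p[1], "")
  exons <- lapply(mrnas$ID, function(tid) {
    s <- segs[seg_parent == tid]
    cbind(start = GenomicRanges::start(s), end = GenomicRanges::end(s))
  })
  gidx <- match(mrna_parent, genes$ID)
  gene_models(gene_id = mrna_parent,
              transcript_id = as.character(mrnas$ID),
              chromosome = as.character(GenomicRanges::seqnames(genes))[gidx],
              start = GenomicRanges::start(genes)[gidx],
              end = GenomicRanges::end(genes)[gidx],
              strand = as.character(GenomicRanges::strand(genes))[gidx],
              exons = exons)
}

#' Serialize / load a planted-truth record
#'
#' Truth records are plain lists (character vectors, data.frames) describing
#' what a generator planted; they round-trip through JSON.
#'
#' @param truth truth record list.
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop_input("truth file not found: %s", path)
  tr <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                           simplifyVector = TRUE, simplifyMatrix = FALSE)
  for (nm in intersect(c("classes", "true_status", "true_log2fc"), names(tr)))
    tr[[nm]] <- unlist(tr[[nm]])
  for (nm in intersect(c("kaks", "expression", "motifs"), names(tr)))
    if (is.list(tr[[nm]]) && !is.data.frame(tr[[nm]]))
      tr[[nm]] <- as.data.frame(tr[[nm]], stringsAsFactors = FALSE)
  # segmental blocks and triads are lists of records, not data frames
  if (is.data.frame(tr$segmental_blocks)) {
    sb <- tr$segmental_blocks
    tr$segmental_blocks <- lapply(seq_len(nrow(sb)), function(i)
      list(genes_a = unlist(sb$genes_a[i]), genes_b = unlist(sb$genes_b[i]),
           chrom_a = sb$chrom_a[i], chrom_b = sb$chrom_b[i]))
  }
  if (is.list(tr$triads))
    tr$triads <- lapply(tr$triads, function(x) unlist(x))
  tr
}
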