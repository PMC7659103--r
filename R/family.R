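# MYB repeat detection, subfamily classification, and systematic naming.

#' Pick one representative protein per gene
#'
#' Keeps the transcript with the longest CDS (sum of exon lengths in the
#' gene-model table); ties go to the lexicographically smallest transcript id.
#'
#' @param proteins named character vector or AAStringSet, names = transcript
#'   ids.
#' @param models gene-model table mapping transcript_id to gene_id.
#' @return data.frame(protein_id, gene_id, sequence, is_representative) with
#'   one row per gene.
#' @export
dedupe_transcripts <- function(proteins, models) {
  seqs <- as_named_chr(proteins)
  ids <- names(seqs)
  if (is.null(ids)) stop_input("proteins must be named by transcript id")
  m <- match(ids, models$transcript_id)
  if (anyNA(m))
    stop_input("protein(s) with no parent gene in models: %s",
               paste(ids[is.na(m)][1:min(3, sum(is.na(m)))], collapse = ", "))
  cds_len <- vapply(models$exons[m], function(e) sum(e[, 2] - e[, 1] + 1L), 0L)
  df <- data.frame(protein_id = ids, gene_id = models$gene_id[m],
                   sequence = unname(seqs), cds_len = cds_len,
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, -df$cds_len, df$protein_id), ]
  keep <- !duplicated(df$gene_id)
  out <- df[keep, c("protein_id", "gene_id", "sequence")]
  out$is_representative <- TRUE
  rownames(out) <- NULL
  out
}

#' Build a log-odds position score matrix for the repeat consensus
#'
#' Columns model a noisy copy of the consensus: the consensus residue has
#' probability 1 - noise, every other residue noise/19, plus a pseudocount,
#' scored in bits against a uniform background (1/20). Unknown residues (X)
#' score 0.
#'
#' @param consensus repeat consensus (default the shipped 52-mer).
#' @param noise assumed per-position substitution probability.
#' @param pseudocount added to each residue probability before normalization.
#' @return 21 x L matrix (rows = 20 amino acids + X) of bit scores.
#' @export
build_repeat_pssm <- function(consensus = MYB_REPEAT_CONSENSUS, noise = 0.1,
                              pseudocount = 0.01) {
  aa <- strsplit(consensus, "")[[1]]
  L <- length(aa)
  pssm <- matrix(0, nrow = 21, ncol = L,
                 dimnames = list(c(AA_ALPHABET20, "X"), NULL))
  for (j in seq_len(L)) {
    p <- rep(noise / 19, 20)
    names(p) <- AA_ALPHABET20
    p[aa[j]] <- 1 - noise
    p <- (p + pseudocount) / sum(p + pseudocount)
    pssm[1:20, j] <- log2(p / 0.05)
  }
  pssm
}

#' Scan a protein for repeat-like windows
#'
#' Slides the PSSM along the sequence and reports every window whose summed
#' bit score reaches `bit_threshold`. Overlapping windows are all reported;
#' merging into repeats is a separate step ([merge_hits()]).
#'
#' @param protein character amino-acid sequence (alphabet: 20 residues + X).
#' @param pssm matrix from [build_repeat_pssm()].
#' @param bit_threshold minimum window score in bits; use -Inf to report all
#'   windows. The default 30 was calibrated so the per-window hit rate on
#'   random uniform-composition proteins is far below 1e-3.
#' @param protein_id optional id recorded in the result.
#' @return data.frame(protein_id, start, end, score, evalue) of hits
#'   (1-based inclusive residue coordinates); empty when the protein is
#'   shorter than the matrix width.
#' @export
scan_repeats <- function(protein, pssm, bit_threshold = 30,
                         protein_id = NA_character_) {
  W <- ncol(pssm)
  seq_chars <- strsplit(protein, "")[[1]]
  idx <- match(seq_chars, rownames(pssm))
  if (anyNA(idx))
    stop_input("invalid residue(s) in protein: %s",
               paste(unique(seq_chars[is.na(idx)]), collapse = ""))
  L <- length(idx)
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
  if (L < W) return(empty)
  nwin <- L - W + 1L
  scores <- numeric(nwin)
  for (j in seq_len(W))
    scores <- scores + pssm[idx[j:(j + nwin - 1L)], j]
  keep <- which(scores >= bit_threshold)
  if (!length(keep)) return(empty)
  data.frame(protein_id = protein_id, start = keep, end = keep + W - 1L,
             score = scores[keep], evalue = NA_real_,
             stringsAsFactors = FALSE)
}

#' Ingest a HMMER3 per-domain table (domtblout)
#'
#' One hit per domain row, using envelope coordinates and the independent
#' E-value (i-Evalue); comment lines are skipped.
#'
#' @param path domtblout file.
#' @return data.frame(protein_id, start, end, score, evalue).
#' @export
ingest_domtblout <- function(path) {
  if (!file.exists(path)) stop_input("domtblout file not found: %s", path)
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) < 22)
      stop_input("malformed domtblout row at line %d (%d fields, need >= 22)",
                 i, length(f))
    start <- suppressWarnings(as.integer(f[20]))
    end <- suppressWarnings(as.integer(f[21]))
    evalue <- suppressWarnings(as.numeric(f[13]))
    score <- suppressWarnings(as.numeric(f[14]))
    if (is.na(start) || is.na(end) || is.na(evalue))
      stop_input("malformed domtblout row at line %d (non-numeric coordinates)", i)
    if (end < start || start < 1 || evalue < 0)
      stop_input("invalid envelope coordinates or E-value at line %d", i)
    rows[[length(rows) + 1L]] <-
      data.frame(protein_id = f[1], start = start, end = end, score = score,
                 evalue = evalue, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Merge overlapping or near-adjacent hits into repeats
#'
#' Hits (all on one protein) whose intervals overlap, or whose gap is below
#' `min_separation` residues, collapse into one repeat. Idempotent.
#'
#' @param hits data.frame with start/end columns (one protein).
#' @param min_separation hits closer than this many residues merge.
#' @return list(repeats = matrix(start, end), repeat_count).
#' @export
merge_hits <- function(hits, min_separation = 5) {
  if (nrow(hits) == 0)
    return(list(repeats = matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("start", "end"))),
                repeat_count = 0L))
  if (length(unique(hits$protein_id)) > 1)
    stop_input("merge_hits expects hits on a single protein")
  o <- order(hits$start, hits$end)
  s <- hits$start[o]
  e <- hits$end[o]
  ms <- s[1]
  me <- e[1]
  out <- list()
  for (i in seq_along(s)[-1]) {
    if (s[i] - me - 1L < min_separation) {
      me <- max(me, e[i])
    } else {
      out[[length(out) + 1L]] <- c(ms, me)
      ms <- s[i]
      me <- e[i]
    }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  list(repeats = m, repeat_count = nrow(m))
}

#' Map a repeat count to a subfamily class
#'
#' 1 repeat -> "1R", 2 -> "2R" (R2R3-MYB), 3 -> "3R" (R1R2R3-MYB), 4 -> "4R";
#' zero or more than four repeats -> "none" (flagged for review, never
#' dropped silently).
#'
#' @param arch list with `repeat_count` (from [merge_hits()]) or a bare count.
#' @return one of "1R","2R","3R","4R","none".
#' @export
classify_family <- function(arch) {
  n <- if (is.list(arch)) arch$repeat_count else arch
  if (n >= 1 && n <= 4) c("1R", "2R", "3R", "4R")[n] else "none"
}

#' Assign systematic family names by chromosomal order
#'
#' Each subfamily class gets its own name series, ordered by chromosome
#' number (1..7), subgenome letter (A < B < D), start coordinate, then
#' gene id. The 2R series is the plain `prefix + ordinal` series; other
#' classes insert the class tag (e.g. `prefix3R1`). Genes on unparseable
#' chromosomes are appended after placed genes in input order.
#'
#' @param members data.frame(gene_id, class, chromosome, start).
#' @param prefix name prefix (e.g. "TaMYB").
#' @return `members` with an `assigned_name` column, sorted in naming order.
#' @export
assign_names <- function(members, prefix = "MYB") {
  if (anyDuplicated(members$gene_id))
    stop_input("duplicate gene_id in members")
  pc <- parse_chrom_label(members$chromosome)
  num <- ifelse(is.na(pc$num), Inf, pc$num)
  sub <- ifelse(is.na(pc$sub), "~", pc$sub)  # '~' sorts after letters
  o <- order(num, sub, members$start, members$gene_id)
  placed <- !is.infinite(num)
  o <- c(o[placed[o]], which(!placed))  # unplaced keep input order
  out <- members[o, , drop = FALSE]
  out$assigned_name <- NA_character_
  for (cl in unique(out$class)) {
    sel <- which(out$class == cl)
    tag <- if (cl == "2R") "" else cl
    out$assigned_name[sel] <- paste0(prefix, tag, seq_along(sel))
  }
  rownames(out) <- NULL
  out
}

#' Identify and name the MYB family in a proteome
#'
#' Full detection path: representative transcripts, PSSM repeat scan, hit
#' merging, classification, and naming. Genes with zero or more than four
#' repeats are reported with class "none" and no name.
#'
#' @param proteins named character vector / AAStringSet of proteins
#'   (transcript ids).
#' @param models gene-model table.
#' @param pssm position score matrix (default built from the shipped
#'   consensus).
#' @param bit_threshold scan threshold in bits.
#' @param min_separation repeat merge separation (residues).
#' @param prefix naming prefix.
#' @return data.frame(gene_id, assigned_name, class, repeat_count,
#'   chromosome, start, end, strand, repeats).
#' @export
identify_family <- function(proteins, models, pssm = build_repeat_pssm(),
                            bit_threshold = 30, min_separation = 5,
                            prefix = "MYB") {
  reps <- dedupe_transcripts(proteins, models)
  arch <- lapply(seq_len(nrow(reps)), function(i) {
    hits <- scan_repeats(reps$sequence[i], pssm, bit_threshold,
                         protein_id = reps$protein_id[i])
    merge_hits(hits, min_separation)
  })
  class_v <- vapply(arch, classify_family, "")
  rep_str <- vapply(arch, function(a) {
    if (a$repeat_count == 0) return("")
    paste(paste0(a$repeats[, 1], "-", a$repeats[, 2]), collapse = ";")
  }, "")
  gidx <- match(reps$gene_id, models$gene_id)
  tab <- data.frame(gene_id = reps$gene_id,
                    class = class_v,
                    repeat_count = vapply(arch, `[[`, 0L, "repeat_count"),
                    chromosome = models$chromosome[gidx],
                    start = models$start[gidx], end = models$end[gidx],
                    strand = models$strand[gidx], repeats = rep_str,
                    stringsAsFactors = FALSE)
  fam <- tab[tab$class != "none", , drop = FALSE]
  if (nrow(fam) > 0) {
    named <- assign_names(fam[, c("gene_id", "class", "chromosome", "start")],
                          prefix)
    tab$assigned_name <- named$assigned_name[match(tab$gene_id, named$gene_id)]
    # return family-first, in naming order, then flagged non-family genes
    tab <- tab[order(match(tab$gene_id, named$gene_id),
                     tab$chromosome, tab$start), ]
  } else {
    tab$assigned_name <- NA_character_
  }
  rownames(tab) <- NULL
  tab[, c("gene_id", "assigned_name", "class", "repeat_count", "chromosome",
          "start", "end", "strand", "repeats")]
}
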