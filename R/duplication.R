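# Tandem clusters, segmental blocks and cross-subgenome homolog groups from
# pairwise similarity evidence plus gene order.
#
# Evidence rows ("pair hits") carry: query_id, subject_id, pct_identity,
# aln_length, evalue (NA on the internal aligner path), score. Tandem
# criteria follow the four classic rules: >=80% coverage of the longer
# sequence, >80% identity, no annotated gene of any kind between the two,
# E-value < 1e-10 (score fallback when E-values are absent, flagged in the
# `evidence` column).

empty_pairhits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_length = integer(0),
             evalue = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Align two sequences and summarize the hit
#'
#' Affine-gap alignment (gap open 10, extend 0.5): nucleotides are scored
#' match +1 / mismatch -1, proteins with BLOSUM62. Identity is the fraction
#' of identical columns over the full alignment length (gap columns count in
#' the denominator).
#'
#' @param seq_a,seq_b sequences (character).
#' @param mode "global" (Needleman-Wunsch) or "local" (Smith-Waterman).
#' @param type "dna" or "protein"; "auto" guesses from the alphabet.
#' @param query_id,subject_id ids recorded in the output row.
#' @return one-row pair-hit data.frame.
#' @export
pairwise_align <- function(seq_a, seq_b, mode = c("global", "local"),
                           type = c("auto", "dna", "protein"),
                           query_id = "query", subject_id = "subject") {
  mode <- match.arg(mode)
  type <- match.arg(type)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop_input("empty sequence")
  if (type == "auto") {
    letters_a <- unique(strsplit(toupper(paste0(seq_a, seq_b)), "")[[1]])
    type <- if (all(letters_a %in% c(DNA_BASES, "N"))) "dna" else "protein"
  }
  if (type == "dna") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5,
      type = mode)
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = mode)
  }
  n_cols <- Biostrings::nchar(al)   # alignment length including gap columns
  n_id <- Biostrings::nmatch(al)
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = 100 * n_id / n_cols,
             aln_length = n_cols, evalue = NA_real_,
             score = Biostrings::score(al), stringsAsFactors = FALSE)
}

# Shared-kmer prefilter: candidate pairs sharing >= min_shared distinct
# kmers, via a sparse sequence x kmer incidence cross-product.
kmer_candidates <- function(seqs, k, min_shared) {
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  ids <- names(seqs)
  all_km <- unique(unlist(km))
  if (!length(all_km)) return(list())
  m <- Matrix::sparseMatrix(
    i = rep(seq_along(km), lengths(km)),
    j = match(unlist(km), all_km),
    x = 1,
    dims = c(length(km), length(all_km)))
  shared <- Matrix::tcrossprod(m)
  hit <- Matrix::which(shared >= min_shared, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  lapply(seq_len(nrow(hit)),
         function(r) c(ids[hit[r, 1]], ids[hit[r, 2]]))
}

#' Compute pair hits among a set of sequences
#'
#' Internal stand-in for a local BLAST run on desk-scale data: candidate
#' pairs passing a shared-k-mer prefilter are aligned with
#' [pairwise_align()]. E-values are NA on this path; downstream criteria
#' fall back to the alignment score.
#'
#' @param seqs named character vector (gene ids).
#' @param type "dna" or "protein".
#' @param k k-mer size for the prefilter (defaults: 12 nt / 6 aa).
#' @param min_shared minimum shared distinct k-mers to attempt an alignment
#'   (defaults 25 nt / 20 aa; in a gene family whose members all carry the
#'   same conserved domain most family pairs legitimately pass the protein
#'   prefilter, so alignments are batched per subject for speed).
#' @return pair-hit data.frame, one row per unordered candidate pair.
#' @export
make_pairhits <- function(seqs, type = c("dna", "protein"), k = NULL,
                          min_shared = NULL) {
  type <- match.arg(type)
  if (is.null(k)) k <- if (type == "dna") 12L else 6L
  if (is.null(min_shared)) min_shared <- if (type == "dna") 25L else 20L
  seqs <- as_named_chr(seqs)
  if (is.null(names(seqs))) stop_input("seqs must be named by gene id")
  cand <- kmer_candidates(seqs, k, min_shared)
  if (!length(cand)) return(empty_pairhits())
  q <- vapply(cand, `[`, "", 1)
  s <- vapply(cand, `[`, "", 2)
  if (type == "dna") {
    xs <- Biostrings::DNAStringSet(seqs)
    subm <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1,
                                                     baseOnly = FALSE)
  } else {
    xs <- Biostrings::AAStringSet(seqs)
    subm <- "BLOSUM62"
  }
  rows <- lapply(unique(s), function(sid) {
    sel <- which(s == sid)
    al <- Biostrings::pairwiseAlignment(
      xs[q[sel]], xs[[sid]], substitutionMatrix = subm,
      gapOpening = 10, gapExtension = 0.5, type = "global")
    n_cols <- Biostrings::nchar(al)
    data.frame(query_id = q[sel], subject_id = sid,
               pct_identity = 100 * Biostrings::nmatch(al) / n_cols,
               aln_length = n_cols, evalue = NA_real_,
               score = Biostrings::score(al), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ingest a 12-column tabular hit file (BLAST outfmt 6 dialect)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Self-hits are dropped; reciprocal duplicates are
#' retained.
#'
#' @param path tabular file.
#' @return pair-hit data.frame (score = bitscore).
#' @export
ingest_pairhits <- function(path) {
  if (!file.exists(path)) stop_input("hit file not found: %s", path)
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 12)
      stop_input("line %d: expected 12 tab-separated columns, got %d",
                 i, length(f))
    if (f[1] == f[2]) next
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = f[1], subject_id = f[2],
      pct_identity = as.numeric(f[3]), aln_length = as.integer(f[4]),
      evalue = as.numeric(f[11]), score = as.numeric(f[12]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_pairhits())
  do.call(rbind, rows)
}

# Does a hit satisfy the similarity criteria (coverage vs longer sequence,
# identity, significance)? Returns logical vector.
hit_passes <- function(hits, seq_lengths, coverage, min_identity, max_evalue,
                       min_score) {
  len_a <- seq_lengths[hits$query_id]
  len_b <- seq_lengths[hits$subject_id]
  longer <- pmax(len_a, len_b)
  sig <- ifelse(is.na(hits$evalue), hits$score >= min_score,
                hits$evalue < max_evalue)
  hits$aln_length >= coverage * longer &
    hits$pct_identity > min_identity & sig
}

# union-find
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

components_of <- function(ids, edges) {
  parent <- stats::setNames(seq_along(ids), ids)
  for (e in edges) {
    ra <- uf_find(parent, which(ids == e[1]))
    rb <- uf_find(parent, which(ids == e[2]))
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(ids), function(i) uf_find(parent, i), 0L)
  split(ids, roots)
}

#' Call tandem duplication clusters
#'
#' A family gene pair is tandem-linked iff (1) the alignment covers at least
#' `coverage` of the longer sequence, (2) identity exceeds `min_identity`,
#' (3) the two genes are adjacent in the all-genes positional order of their
#' chromosome (no annotated gene of any kind between them), and (4) the
#' E-value is below `max_evalue` (alignment score >= `min_score` when
#' E-values are absent). Clusters are connected components of tandem links.
#'
#' @param hits pair-hit data.frame (CDS-level hits by convention).
#' @param models gene-model table (all annotated genes, family or not).
#' @param family character vector of family gene ids.
#' @param seq_lengths named vector of sequence lengths used for coverage
#'   (defaults to CDS length from the models).
#' @param coverage,min_identity,max_evalue,min_score criteria knobs.
#' @return data.frame(cluster_id, chromosome, gene_id, position_rank,
#'   evidence), members in positional order; zero rows when nothing passes.
#' @export
call_tandem <- function(hits, models, family,
                        seq_lengths = NULL, coverage = 0.8,
                        min_identity = 80, max_evalue = 1e-10,
                        min_score = 100) {
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                     models$gene_id)
  if (length(unknown))
    stop_input("hit references unknown gene(s): %s",
               paste(utils::head(unknown, 3), collapse = ", "))
  if (is.null(seq_lengths)) {
    seq_lengths <- stats::setNames(
      vapply(models$exons, function(e) sum(e[, 2] - e[, 1] + 1L), 0L),
      models$gene_id)
  }
  # positional rank of every annotated gene within its chromosome
  rank_in_chrom <- stats::setNames(rep(NA_integer_, nrow(models)),
                                   models$gene_id)
  for (chrom in unique(models$chromosome)) {
    sel <- models$chromosome == chrom
    rank_in_chrom[models$gene_id[sel]] <- rank(models$start[sel],
                                               ties.method = "first")
  }
  chrom_of <- stats::setNames(models$chromosome, models$gene_id)

  fam_hits <- hits[hits$query_id %in% family & hits$subject_id %in% family, ,
                   drop = FALSE]
  if (nrow(fam_hits) == 0)
    return(data.frame(cluster_id = character(0), chromosome = character(0),
                      gene_id = character(0), position_rank = integer(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  same_chrom <- chrom_of[fam_hits$query_id] == chrom_of[fam_hits$subject_id]
  adjacent <- abs(rank_in_chrom[fam_hits$query_id] -
                    rank_in_chrom[fam_hits$subject_id]) == 1L
  pass <- same_chrom & adjacent &
    hit_passes(fam_hits, seq_lengths, coverage, min_identity, max_evalue,
               min_score)
  linked <- fam_hits[pass, , drop = FALSE]
  if (nrow(linked) == 0)
    return(data.frame(cluster_id = character(0), chromosome = character(0),
                      gene_id = character(0), position_rank = integer(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  ids <- sort(unique(c(linked$query_id, linked$subject_id)))
  edges <- lapply(seq_len(nrow(linked)),
                  function(i) c(linked$query_id[i], linked$subject_id[i]))
  comps <- components_of(ids, edges)
  # stable cluster ordering: by chromosome then first member position
  ord <- order(vapply(comps, function(g) chrom_of[g[1]], ""),
               vapply(comps, function(g) min(rank_in_chrom[g]), 0))
  comps <- comps[ord]
  evidence <- if (all(is.na(hits$evalue))) "score" else "evalue"
  out <- lapply(seq_along(comps), function(ci) {
    g <- comps[[ci]]
    g <- g[order(rank_in_chrom[g])]
    data.frame(cluster_id = sprintf("tandem_%02d", ci),
               chromosome = unname(chrom_of[g[1]]), gene_id = g,
               position_rank = unname(rank_in_chrom[g]),
               evidence = evidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Call segmental duplication blocks
#'
#' Anchors are non-adjacent family gene pairs with identity >=
#' `min_identity` and E-value < `max_evalue` (score fallback). Anchors on the
#' same chromosome pair are chained when collinear (consistent order and
#' orientation) with inter-anchor gaps at most `max_gap` on both regions; a
#' chain is reported as a block iff both chained regions span at least
#' `min_span` bases and contain at least `min_anchors` anchors.
#'
#' The classic genome-scale span criterion is 600 kb; `min_span` is a knob so
#' synthetic chromosomes can scale it down.
#'
#' @param hits pair-hit data.frame (protein-level hits by convention, ids =
#'   gene ids).
#' @param models gene-model table.
#' @param family family gene ids.
#' @param min_span minimum genomic span of each region (bases).
#' @param min_identity anchor identity threshold (percent).
#' @param min_anchors minimum anchor pairs per block.
#' @param max_gap maximum inter-anchor genomic gap while chaining (default
#'   2 x min_span: a valid two-anchor block may legitimately carry almost
#'   its whole span in one inter-anchor gap).
#' @param max_evalue,min_score anchor significance.
#' @return data.frame, one row per block: block_id, chrom_a, start_a, end_a,
#'   chrom_b, start_b, end_b, n_anchors, mean_identity, genes_a, genes_b
#'   (";"-separated, in chain order).
#' @export
call_segmental <- function(hits, models, family, min_span = 600000,
                           min_identity = 90, min_anchors = 2,
                           max_gap = 2 * min_span, max_evalue = 1e-10,
                           min_score = 100) {
  empty <- data.frame(block_id = character(0), chrom_a = character(0),
                      start_a = integer(0), end_a = integer(0),
                      chrom_b = character(0), start_b = integer(0),
                      end_b = integer(0), n_anchors = integer(0),
                      mean_identity = numeric(0), genes_a = character(0),
                      genes_b = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  chrom_of <- stats::setNames(models$chromosome, models$gene_id)
  start_of <- stats::setNames(models$start, models$gene_id)
  end_of <- stats::setNames(models$end, models$gene_id)
  rank_in_chrom <- stats::setNames(rep(NA_integer_, nrow(models)),
                                   models$gene_id)
  for (chrom in unique(models$chromosome)) {
    sel <- models$chromosome == chrom
    rank_in_chrom[models$gene_id[sel]] <- rank(models$start[sel],
                                               ties.method = "first")
  }

  h <- hits[hits$query_id %in% family & hits$subject_id %in% family, ,
            drop = FALSE]
  if (nrow(h) == 0) return(empty)
  sig <- ifelse(is.na(h$evalue), h$score >= min_score, h$evalue < max_evalue)
  h <- h[h$pct_identity >= min_identity & sig, , drop = FALSE]
  if (nrow(h) == 0) return(empty)
  # drop tandem-like pairs: same chromosome and adjacent
  same <- chrom_of[h$query_id] == chrom_of[h$subject_id]
  adj <- same & abs(rank_in_chrom[h$query_id] -
                      rank_in_chrom[h$subject_id]) == 1L
  h <- h[!adj, , drop = FALSE]
  if (nrow(h) == 0) return(empty)

  # canonical orientation: region A = lexicographically smaller chromosome
  # (or smaller start on the same chromosome); deduplicate reciprocal rows
  same <- chrom_of[h$query_id] == chrom_of[h$subject_id]
  flip <- chrom_of[h$query_id] > chrom_of[h$subject_id] |
    (same & start_of[h$query_id] > start_of[h$subject_id])
  ga <- ifelse(flip, h$subject_id, h$query_id)
  gb <- ifelse(flip, h$query_id, h$subject_id)
  anchors <- data.frame(gene_a = ga, gene_b = gb,
                        chrom_a = unname(chrom_of[ga]),
                        chrom_b = unname(chrom_of[gb]),
                        pos_a = unname(start_of[ga]),
                        pos_b = unname(start_of[gb]),
                        identity = h$pct_identity,
                        stringsAsFactors = FALSE)
  anchors <- anchors[!duplicated(paste(anchors$gene_a, anchors$gene_b)), ,
                     drop = FALSE]

  blocks <- list()
  for (key in unique(paste(anchors$chrom_a, anchors$chrom_b))) {
    sub <- anchors[paste(anchors$chrom_a, anchors$chrom_b) == key, ,
                   drop = FALSE]
    sub <- sub[order(sub$pos_a, sub$pos_b), , drop = FALSE]
    chain <- list(sub[1, , drop = FALSE])
    dirn <- 0
    flush_chain <- function(ch) {
      ch_df <- do.call(rbind, ch)
      if (nrow(ch_df) < min_anchors) return(NULL)
      span_a <- max(end_of[ch_df$gene_a]) - min(start_of[ch_df$gene_a]) + 1L
      span_b <- max(end_of[ch_df$gene_b]) - min(start_of[ch_df$gene_b]) + 1L
      if (span_a < min_span || span_b < min_span) return(NULL)
      ch_df
    }
    for (i in seq_len(nrow(sub))[-1]) {
      prev <- chain[[length(chain)]]
      step_b <- sub$pos_b[i] - prev$pos_b
      ok_gap <- (sub$pos_a[i] - prev$pos_a) <= max_gap &&
        abs(step_b) <= max_gap
      ok_dir <- if (dirn == 0) TRUE else sign(step_b) == dirn
      if (ok_gap && ok_dir && step_b != 0) {
        if (dirn == 0) dirn <- sign(step_b)
        chain[[length(chain) + 1L]] <- sub[i, , drop = FALSE]
      } else {
        b <- flush_chain(chain)
        if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
        chain <- list(sub[i, , drop = FALSE])
        dirn <- 0
      }
    }
    b <- flush_chain(chain)
    if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  }
  if (!length(blocks)) return(empty)
  out <- lapply(seq_along(blocks), function(bi) {
    b <- blocks[[bi]]
    data.frame(block_id = sprintf("segmental_%02d", bi),
               chrom_a = b$chrom_a[1],
               start_a = min(start_of[b$gene_a]),
               end_a = max(end_of[b$gene_a]),
               chrom_b = b$chrom_b[1],
               start_b = min(start_of[b$gene_b]),
               end_b = max(end_of[b$gene_b]),
               n_anchors = nrow(b),
               mean_identity = mean(b$identity),
               genes_a = paste(b$gene_a, collapse = ";"),
               genes_b = paste(b$gene_b, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Find cross-subgenome homolog groups by reciprocal best hits
#'
#' For each subgenome pair the best-scoring hit per gene is computed;
#' mutual best hits become edges, and groups are the connected components
#' (at most one member per subgenome by construction of RBH edges plus
#' triangle consistency). Family genes without any cross-subgenome RBH form
#' singleton groups.
#'
#' @param hits pair-hit data.frame (protein-level).
#' @param family family gene ids.
#' @param subgenome_of named vector gene_id -> subgenome label (e.g. from
#'   chromosome names via [subgenome_of_chrom()]).
#' @return list(groups = data.frame(group_id, gene_id, subgenome,
#'   completeness), fraction_complete).
#' @export
find_homolog_groups <- function(hits, family, subgenome_of) {
  subs <- sort(unique(stats::na.omit(subgenome_of[family])))
  h <- hits[hits$query_id %in% family & hits$subject_id %in% family, ,
            drop = FALSE]
  if (nrow(h) > 0) {
    # symmetrize
    h2 <- h
    names(h2)[1:2] <- c("subject_id", "query_id")
    h <- rbind(h, h2[, names(h)])
    h$sub_q <- subgenome_of[h$query_id]
    h$sub_s <- subgenome_of[h$subject_id]
    h <- h[!is.na(h$sub_q) & !is.na(h$sub_s) & h$sub_q != h$sub_s, ,
           drop = FALSE]
  }
  edges <- list()
  if (nrow(h) > 0) {
    # best hit of each gene into each other subgenome
    key <- paste(h$query_id, h$sub_s)
    best <- h[order(key, -h$score), ]
    best <- best[!duplicated(paste(best$query_id, best$sub_s)), ]
    bmap <- stats::setNames(best$subject_id,
                            paste(best$query_id, best$sub_s))
    for (i in seq_len(nrow(best))) {
      a <- best$query_id[i]
      b <- best$subject_id[i]
      if (a < b) {  # each unordered pair once
        back <- bmap[paste(b, subgenome_of[a])]
        if (!is.na(back) && back == a)
          edges[[length(edges) + 1L]] <- c(a, b)
      }
    }
  }
  ids <- sort(family)
  comps <- components_of(ids, edges)
  rows <- lapply(seq_along(comps), function(gi) {
    g <- comps[[gi]]
    data.frame(group_id = sprintf("group_%03d", gi), gene_id = g,
               subgenome = unname(subgenome_of[g]),
               completeness = length(unique(stats::na.omit(subgenome_of[g]))),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, rows)
  per_group <- tapply(groups$completeness, groups$group_id, max)
  frac <- if (length(per_group)) mean(per_group == length(subs)) else NA_real_
  list(groups = groups, fraction_complete = unname(frac))
}
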