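# Codon-aware Ka/Ks (Nei-Gojobori 1986, Jukes-Cantor corrected) and
# neighbor-joining phylogenies with bootstrap support.

#' Back-translate a protein alignment into a codon alignment
#'
#' Each aligned residue is replaced by its source codon; residue gaps become
#' "---" codon gaps. The ungapped residues of each row must equal the
#' translation of the corresponding CDS.
#'
#' @param cds_a,cds_b coding sequences (character, length divisible by 3).
#' @param protein_alignment character vector of the two aligned protein
#'   sequences (equal length, "-" gaps).
#' @return list(ids, codons): codons is a 2-row character matrix, one column
#'   per aligned codon position.
#' @export
codon_align <- function(cds_a, cds_b, protein_alignment,
                        ids = c("a", "b")) {
  if (length(protein_alignment) != 2)
    stop_input("protein_alignment must contain exactly two rows")
  if (nchar(protein_alignment[1]) != nchar(protein_alignment[2]))
    stop_input("aligned rows differ in length")
  rows <- lapply(seq_len(2), function(i) {
    cds <- c(cds_a, cds_b)[i]
    cods <- split_codons(cds)
    aas <- translate_codons(cods)
    aln <- strsplit(protein_alignment[i], "")[[1]]
    res_pos <- which(aln != "-")
    if (length(res_pos) != length(cods))
      stop_input("row %d: alignment has %d residues but CDS encodes %d",
                 i, length(res_pos), length(cods))
    mism <- which(aln[res_pos] != aas)
    if (length(mism))
      stop_input("row %d: alignment residue %d ('%s') does not match translation ('%s')",
                 i, res_pos[mism[1]], aln[res_pos[mism[1]]], aas[mism[1]])
    out <- rep("---", length(aln))
    out[res_pos] <- cods
    out
  })
  codons <- do.call(rbind, rows)
  rownames(codons) <- ids
  list(ids = ids, codons = codons)
}

#' Nei-Gojobori (1986) Ka/Ks for a codon alignment
#'
#' Synonymous/nonsynonymous site counts use the classic convention (changes
#' to stop codons excluded from the denominators); between-codon differences
#' average over all minimal substitution paths avoiding stop intermediates;
#' raw proportions are Jukes-Cantor corrected. The ratio is undefined when
#' Ks = 0 or either proportion reaches the correction's saturation point
#' (0.75).
#'
#' @param alignment a [codon_align()] result (gapped columns are skipped).
#' @return list with S, N, Sd, Nd, pS, pN, ka, ks, ratio, selection_label
#'   ("purifying", "neutral", "positive" or "undefined"), n_codons
#'   (compared columns) and flagged_codons (pairs resolved by the
#'   stop-blocked fallback).
#' @export
ng86_kaks <- function(alignment) {
  cods <- alignment$codons
  ok <- cods[1, ] != "---" & cods[2, ] != "---"
  a <- cods[1, ok]
  b <- cods[2, ok]
  if (length(a) == 0) stop_input("all codon columns are gapped")
  sense <- sense_codons()
  if (!all(a %in% sense) || !all(b %in% sense))
    stop_input("internal stop codon (or invalid codon) in ungapped columns")
  sites <- ng86_site_counts()
  tabs <- ng86_pair_tables()
  S <- (sum(sites[a]) + sum(sites[b])) / 2
  N <- 3 * length(a) - S
  ia <- match(a, rownames(tabs$sd))
  ib <- match(b, colnames(tabs$sd))
  lin <- cbind(ia, ib)
  Sd <- sum(tabs$sd[lin])
  Nd <- sum(tabs$nd[lin])
  flagged <- sum(tabs$flagged[lin])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ks <- jc(pS)
  ka <- jc(pN)
  ratio <- if (is.na(ks) || is.na(ka) || ks == 0) NA_real_ else ka / ks
  label <- if (is.na(ratio)) "undefined"
  else if (abs(ratio - 1) <= 1e-9) "neutral"
  else if (ratio < 1) "purifying" else "positive"
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       ka = ka, ks = ks, ratio = ratio, selection_label = label,
       n_codons = length(a), flagged_codons = flagged)
}

#' Ka/Ks for a pair of coding sequences
#'
#' Convenience wrapper: translates both CDS, aligns the proteins globally
#' (BLOSUM62, affine gaps), back-translates to codons and runs
#' [ng86_kaks()].
#'
#' @param cds_a,cds_b coding sequences.
#' @param ids pair ids recorded in the result.
#' @export
kaks_pair <- function(cds_a, cds_b, ids = c("a", "b")) {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  aln <- c(as.character(Biostrings::alignedPattern(al)),
           as.character(Biostrings::alignedSubject(al)))
  res <- ng86_kaks(codon_align(cds_a, cds_b, aln, ids = ids))
  res$gene_a <- ids[1]
  res$gene_b <- ids[2]
  res
}

# alignment input: named character vector of equal-length aligned sequences
as_alignment_matrix <- function(alignment) {
  seqs <- as_named_chr(alignment)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop_input("aligned sequences differ in length")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

#' Pairwise p-distance matrix from a protein alignment
#'
#' Distance = proportion of differing sites over pairwise-ungapped columns.
#'
#' @param alignment named character vector of aligned sequences (equal
#'   length, "-" gaps).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  m <- as_alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 3) stop_input("need at least 3 sequences")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      if (nc == 0)
        stop_input("no comparable columns between %s and %s",
                   rownames(m)[i], rownames(m)[j])
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: repeatedly join the pair minimizing the
#' Q-criterion (ties broken by the first minimal pair in row-major order of
#' the current matrix), compute branch lengths, reduce the matrix. Negative
#' branch lengths are clamped to zero. Returns an unrooted `ape::phylo`.
#'
#' @param d symmetric distance matrix with taxa dimnames.
#' @return an unrooted phylo object.
#' @export
nj_tree <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop_input("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3) stop_input("need at least 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  frag <- labels            # newick fragment per active node
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    best <- NULL
    best_q <- Inf
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < best_q - 1e-15) {
          best_q <- q
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    newf <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    keep <- setdiff(seq_len(m), c(i, j))
    newd <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd), c(newd, 0))
    frag <- c(frag[keep], newf)
    D <- D2
  }
  # final three nodes: star join with three-point branch lengths
  la <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  lb <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  lc <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1], la, frag[2], lb, frag[3], lc)
  ape::read.tree(text = nwk)
}

# Non-trivial bipartitions of an unrooted phylo, canonicalized as the sorted
# tip-label set on the side NOT containing the first reference label.
tree_bipartitions <- function(phy, ref = NULL) {
  tips <- phy$tip.label
  if (is.null(ref)) ref <- sort(tips)[1]
  n <- length(tips)
  parts <- ape::prop.part(phy)
  keys <- character(0)
  for (p in parts) {
    side <- tips[p]
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) <= 1 || length(side) >= n - 1) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining protein tree
#'
#' Resamples alignment columns with replacement, recomputes the p-distance
#' NJ tree per replicate, and reports for each internal edge of the original
#' tree the percentage of replicates containing the same bipartition.
#' Deterministic for a fixed seed.
#'
#' @param alignment named character vector of aligned sequences.
#' @param n_replicates bootstrap replicates (classic scale: 1000).
#' @param seed integer seed.
#' @return list(tree = phylo with `node.label` percentages (root label
#'   empty), support = named vector keyed by bipartition).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1) {
  if (n_replicates < 1) stop_input("n_replicates must be >= 1")
  m <- as_alignment_matrix(alignment)
  orig <- nj_tree(p_distance_matrix_from(m))
  keys <- tree_bipartitions(orig)
  counts <- stats::setNames(numeric(length(keys)), keys)
  with_local_seed(seed, {
    L <- ncol(m)
    for (rep_i in seq_len(n_replicates)) {
      idx <- sample.int(L, L, replace = TRUE)
      dm <- p_distance_matrix_from(m[, idx, drop = FALSE])
      bt <- nj_tree(dm)
      bk <- tree_bipartitions(bt, ref = sort(rownames(m))[1])
      hit <- keys %in% bk
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / n_replicates
  orig$node.label <- node_labels_from_support(orig, support)
  list(tree = orig, support = support)
}

# p-distance from a character matrix (internal fast path; zero comparable
# columns fall back to distance 0 so degenerate bootstrap replicates never
# abort).
p_distance_matrix_from <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      d[i, j] <- d[j, i] <- if (nc == 0) 0 else
        sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  d
}

# Map bipartition supports onto internal node labels of an unrooted phylo.
node_labels_from_support <- function(phy, support) {
  tips <- phy$tip.label
  ref <- sort(tips)[1]
  n <- length(tips)
  nl <- rep("", phy$Nnode)
  parts <- ape::prop.part(phy)
  for (k in seq_along(parts)) {
    side <- tips[parts[[k]]]
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) <= 1 || length(side) >= n - 1) next
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      nl[k] <- sprintf("%g", support[[key]])
  }
  nl
}
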