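# Independent oracles used by the test suite. These deliberately do not
# share code with the implementation paths they check.

# Exhaustive substitution-path enumeration for one codon pair: recursively
# walk every ordering of the differing positions, discard orderings that
# pass through a stop codon, and average synonymous/nonsynonymous step
# counts over the surviving paths. Returns c(sd, nd) or NULL when every
# ordering is stop-blocked.
.oracle_gc <- local({
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  gc
})

oracle_codon_pair <- function(codon_a, codon_b) {
  gc <- .oracle_gc
  av <- strsplit(codon_a, "")[[1]]
  bv <- strsplit(codon_b, "")[[1]]
  diffs <- which(av != bv)
  if (!length(diffs)) return(c(0, 0))
  acc <- list()
  walk <- function(cur, remaining, sd, nd) {
    if (!length(remaining)) {
      acc[[length(acc) + 1L]] <<- c(sd, nd)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- bv[p]
      nxt_c <- paste(nxt, collapse = "")
      if (gc[[nxt_c]] == "*") next
      syn <- gc[[paste(cur, collapse = "")]] == gc[[nxt_c]]
      walk(nxt, setdiff(remaining, p), sd + syn, nd + !syn)
    }
  }
  walk(av, diffs, 0, 0)
  if (!length(acc)) return(NULL)
  colMeans(do.call(rbind, acc))
}

# Brute-force tandem oracle under fully loosened similarity criteria:
# connected components of "family genes adjacent in all-genes order with any
# hit between them", computed by direct scanning.
oracle_adjacency_components <- function(hits, models, family) {
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  hit_keys <- unique(mapply(pair_key, hits$query_id, hits$subject_id))
  comps <- list()
  for (chrom in unique(models$chromosome)) {
    genes <- models$gene_id[models$chromosome == chrom]
    genes <- genes[order(models$start[match(genes, models$gene_id)])]
    current <- character(0)
    for (i in seq_along(genes)) {
      g <- genes[i]
      linked <- length(current) > 0 &&
        g %in% family && current[length(current)] %in% family &&
        i > 1 && pair_key(genes[i - 1], g) %in% hit_keys &&
        genes[i - 1] == current[length(current)]
      if (linked) {
        current <- c(current, g)
      } else {
        if (length(current) >= 2) comps[[length(comps) + 1L]] <- current
        current <- g
      }
    }
    if (length(current) >= 2) comps[[length(comps) + 1L]] <- current
  }
  lapply(comps, sort)
}

# Random additive distance matrix from a random tree, with the generating
# tree's cophenetic matrix as the ground truth.
random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) stats::runif(k, 0.05, 1))
  dm <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(dm))
  dm[ord, ord]
}

# Best-permutation agreement between two k-group labelings (k small).
label_agreement <- function(pred, truth) {
  ks <- sort(unique(truth))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- 0
  for (p in perms(ks)) {
    mapped <- p[match(pred, ks)]
    best <- max(best, mean(mapped == truth))
  }
  best
}
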