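# Standard genetic code tables and Nei-Gojobori (1986) per-codon machinery.
#
# Site counting follows the classic convention: at each codon position the
# synonymous site fraction is (# synonymous one-step changes) /
# (# one-step changes that do not create a stop); changes to stop codons are
# excluded from the denominator. Between-codon differences are partitioned by
# averaging over all orderings of the single-nucleotide steps that avoid
# stop-codon intermediates.

.mybfam_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

all_codons <- function() {
  as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
}

sense_codons <- function() {
  gc <- genetic_code()
  sort(names(gc)[gc != "*"])
}

translate_codons <- function(codons) {
  unname(genetic_code()[codons])
}

# Synonymous site count per sense codon (0..3), NG86 convention.
ng86_site_counts <- function() {
  if (!is.null(.mybfam_cache$sites)) return(.mybfam_cache$sites)
  gc <- genetic_code()
  sense <- sense_codons()
  s <- vapply(sense, function(cod) {
    aa <- gc[[cod]]
    bases <- strsplit(cod, "")[[1]]
    total <- 0
    for (pos in 1:3) {
      syn <- 0L
      ok <- 0L
      for (b in setdiff(DNA_BASES, bases[pos])) {
        mut <- bases
        mut[pos] <- b
        mutc <- paste(mut, collapse = "")
        if (gc[[mutc]] == "*") next
        ok <- ok + 1L
        if (gc[[mutc]] == aa) syn <- syn + 1L
      }
      if (ok > 0) total <- total + syn / ok
    }
    total
  }, 0)
  .mybfam_cache$sites <- s
  s
}

# Permutations of 1..k for k <= 3 (row per ordering).
.perms <- list(
  matrix(1L, 1, 1),
  rbind(c(1L, 2L), c(2L, 1L)),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Partition the differences between two sense codons into expected synonymous
# (sd) and nonsynonymous (nd) counts by averaging over stop-avoiding
# substitution paths. Returns c(sd, nd, flagged) where flagged = 1 if no
# stop-free path existed and the per-position fallback was used.
ng86_pair_diff <- function(codon_a, codon_b) {
  gc <- genetic_code()
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0, flagged = 0))
  orders <- .perms[[k]]
  sd_tot <- 0
  nd_tot <- 0
  n_valid <- 0L
  for (r in seq_len(nrow(orders))) {
    cur <- a
    sd <- 0
    nd <- 0
    valid <- TRUE
    for (p in pos[orders[r, ]]) {
      nxt <- cur
      nxt[p] <- b[p]
      nxtc <- paste(nxt, collapse = "")
      if (gc[[nxtc]] == "*") { valid <- FALSE; break }
      if (gc[[paste(cur, collapse = "")]] == gc[[nxtc]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (valid) {
      sd_tot <- sd_tot + sd
      nd_tot <- nd_tot + nd
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid > 0)
    return(c(sd = sd_tot / n_valid, nd = nd_tot / n_valid, flagged = 0))
  # No stop-free ordering: classify each differing position by applying it
  # alone to codon_a (stop-creating or amino-acid-changing -> nonsynonymous).
  sd <- 0
  nd <- 0
  for (p in pos) {
    one <- a
    one[p] <- b[p]
    onec <- paste(one, collapse = "")
    if (gc[[onec]] != "*" && gc[[onec]] == gc[[codon_a]]) sd <- sd + 1
    else nd <- nd + 1
  }
  c(sd = sd, nd = nd, flagged = 1)
}

# Cached 61x61 sd/nd/flag matrices over sense codons.
ng86_pair_tables <- function() {
  if (!is.null(.mybfam_cache$pair_sd)) {
    return(list(sd = .mybfam_cache$pair_sd, nd = .mybfam_cache$pair_nd,
                flagged = .mybfam_cache$pair_flag))
  }
  sense <- sense_codons()
  n <- length(sense)
  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  nd <- sd
  fl <- sd
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      v <- ng86_pair_diff(sense[i], sense[j])
      sd[i, j] <- sd[j, i] <- v[["sd"]]
      nd[i, j] <- nd[j, i] <- v[["nd"]]
      fl[i, j] <- fl[j, i] <- v[["flagged"]]
    }
  }
  .mybfam_cache$pair_sd <- sd
  .mybfam_cache$pair_nd <- nd
  .mybfam_cache$pair_flag <- fl
  list(sd = sd, nd = nd, flagged = fl)
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop_input("CDS length %d is not divisible by 3", n)
  if (n == 0) return(character(0))
  substring(cds, seq(1, n, by = 3), seq(3, n, by = 3))
}

# Translate a CDS string (no internal stop check here).
translate_cds <- function(cds) {
  paste(translate_codons(split_codons(cds)), collapse = "")
}
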