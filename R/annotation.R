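# Gene-structure and protein physicochemical characterization plus
# promoter cis-element scanning.

# ExPASy-style average residue masses (Da) for the 20 standard amino acids;
# X scores the mean of the twenty.
.residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_mass <- 18.01524

# Bjellqvist pKa values as used by the ExPASy Compute pI/Mw tool family.
.pk_cterm <- 3.55
.pk_cterm_special <- c(D = 4.55, E = 4.75)
.pk_nterm <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70, G = 7.50)
.pk_nterm_default <- 7.50
.pk_positive <- c(K = 10.00, R = 12.00, H = 5.98)
.pk_negative <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)

#' Count introns in a gene model
#'
#' @param model one row of a gene-model table (or a list with an `exons`
#'   matrix).
#' @return number of exons minus one.
#' @export
count_introns <- function(model) {
  exons <- if (is.data.frame(model)) model$exons[[1]] else model$exons
  if (is.null(exons) || nrow(exons) == 0)
    stop_input("gene model has zero exons")
  nrow(exons) - 1L
}

#' Protein molecular weight in kilodaltons
#'
#' Sum of average residue masses plus one water molecule. Unknown residue X
#' contributes the mean residue mass; any other letter is an error.
#'
#' @param sequence amino-acid string.
#' @return weight in kDa.
#' @export
molecular_weight <- function(sequence) {
  if (!nzchar(sequence)) stop_input("empty protein sequence")
  aa <- strsplit(sequence, "")[[1]]
  masses <- .residue_mass[aa]
  masses[aa == "X"] <- mean(.residue_mass)
  if (anyNA(masses))
    stop_input("unknown residue(s): %s",
               paste(unique(aa[is.na(masses)]), collapse = ""))
  (sum(masses) + .water_mass) / 1000
}

# Net charge of a protein at a given pH under Henderson-Hasselbalch with the
# Bjellqvist pKa set.
protein_charge <- function(counts, nterm_aa, cterm_aa, ph) {
  pos <- 1 / (1 + 10^(ph - (.pk_nterm[nterm_aa] %||% NA)))
  if (is.na(pos)) pos <- 1 / (1 + 10^(ph - .pk_nterm_default))
  for (a in names(.pk_positive)) {
    n <- counts[a]
    if (!is.na(n) && n > 0)
      pos <- pos + n / (1 + 10^(ph - .pk_positive[[a]]))
  }
  ct <- .pk_cterm_special[cterm_aa] %||% NA
  if (is.na(ct)) ct <- .pk_cterm
  neg <- 1 / (1 + 10^(ct - ph))
  for (a in names(.pk_negative)) {
    n <- counts[a]
    if (!is.na(n) && n > 0)
      neg <- neg + n / (1 + 10^(.pk_negative[[a]] - ph))
  }
  pos - neg
}

#' Protein isoelectric point (Bjellqvist pKa set)
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge over the
#' termini and the ionizable side chains (D, E, C, Y, H, K, R) is zero, by
#' bisection on (0, 14). The charge function is strictly decreasing in pH so
#' the root is unique.
#'
#' @param sequence amino-acid string (X allowed; it is not ionizable).
#' @param tol bisection tolerance in pH units.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, tol = 1e-3) {
  if (!nzchar(sequence)) stop_input("empty protein sequence")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(aa), c(AA_ALPHABET20, "X"))
  if (length(bad))
    stop_input("unknown residue(s): %s", paste(bad, collapse = ""))
  counts <- table(factor(aa, levels = AA_ALPHABET20))
  lo <- 0
  hi <- 14
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (protein_charge(counts, aa[1], aa[length(aa)], mid) > 0) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

#' Tabulate length, pI and Mw for a set of proteins
#'
#' @param proteins named character vector / AAStringSet (names = gene or
#'   transcript ids).
#' @return data.frame(gene_id, length, pI, mw_kda).
#' @export
protein_properties <- function(proteins) {
  seqs <- as_named_chr(proteins)
  data.frame(gene_id = names(seqs),
             length = nchar(seqs),
             pI = vapply(seqs, isoelectric_point, 0),
             mw_kda = vapply(seqs, molecular_weight, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract the promoter (upstream) sequence of a gene
#'
#' For a + strand gene the promoter is bases [start - length, start - 1] of
#' the chromosome; for a - strand gene it is the reverse complement of
#' [end + 1, end + length]. Promoters truncated by the chromosome edge are
#' flagged.
#'
#' @param genome DNAStringSet of chromosomes.
#' @param model one row of a gene-model table.
#' @param length promoter length in bases (paper-scale default 1500).
#' @return list(sequence, truncated).
#' @export
extract_promoter <- function(genome, model, length = 1500) {
  chrom <- if (is.data.frame(model)) model$chromosome[1] else model$chromosome
  strand <- if (is.data.frame(model)) model$strand[1] else model$strand
  gstart <- if (is.data.frame(model)) model$start[1] else model$start
  gend <- if (is.data.frame(model)) model$end[1] else model$end
  if (!chrom %in% names(genome))
    stop_input("chromosome %s not present in genome", chrom)
  chrom_len <- Biostrings::width(genome[chrom])
  if (strand == "+") {
    from <- max(1L, gstart - as.integer(length))
    to <- gstart - 1L
    truncated <- (gstart - length) < 1L
    if (to < from)
      return(list(sequence = "", truncated = TRUE))
    seq <- as.character(Biostrings::subseq(genome[[chrom]], from, to))
  } else {
    from <- gend + 1L
    to <- min(chrom_len, gend + as.integer(length))
    truncated <- (gend + length) > chrom_len
    if (to < from)
      return(list(sequence = "", truncated = TRUE))
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(genome[[chrom]], from, to)))
  }
  if (truncated)
    warning(sprintf("promoter of %s truncated at chromosome edge (%d bp)",
                    if (is.data.frame(model)) model$gene_id[1] else
                      model$gene_id, nchar(seq)))
  list(sequence = seq, truncated = truncated)
}

#' Scan a promoter for IUPAC motif occurrences
#'
#' Every exact IUPAC match is reported with its 1-based offset from the
#' promoter's 5' end; overlapping matches are all reported. With
#' `both_strands` the reverse complement of each pattern is also scanned and
#' reported with strand "-" (offset still refers to the promoter's forward
#' coordinates of the match start).
#'
#' @param promoter promoter sequence (character).
#' @param dictionary named character vector of IUPAC patterns
#'   (e.g. c(MBS = "CAACTG")).
#' @param both_strands also scan the minus strand.
#' @param gene_id optional id recorded in the result.
#' @return data.frame(gene_id, motif_name, strand, offset).
#' @export
scan_motifs <- function(promoter, dictionary, both_strands = TRUE,
                        gene_id = NA_character_) {
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  empty <- data.frame(gene_id = character(0), motif_name = character(0),
                      strand = character(0), offset = integer(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(promoter)) return(empty)
  bad <- vapply(dictionary, function(p) {
    any(!strsplit(p, "")[[1]] %in% valid)
  }, TRUE)
  if (any(bad))
    stop_input("invalid IUPAC letter in motif(s): %s",
               paste(names(dictionary)[bad], collapse = ", "))
  subject <- Biostrings::DNAString(promoter)
  rows <- list()
  for (nm in names(dictionary)) {
    pat <- dictionary[[nm]]
    hits <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    if (length(hits))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id, motif_name = nm, strand = "+",
        offset = Biostrings::start(hits), stringsAsFactors = FALSE)
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pat)))
      hits2 <- Biostrings::matchPattern(rc, subject, fixed = FALSE)
      if (length(hits2))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, motif_name = nm, strand = "-",
          offset = Biostrings::start(hits2), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$offset, out$motif_name), , drop = FALSE]
}

#' Convenience dictionary of common stress-responsive cis-elements
#'
#' A convenience set of drought (MBS), heat (HSE), ABA (ABRE), salicylic
#' acid (TCA-element) and TGA-box motifs in IUPAC notation. These are
#' community-standard consensus patterns supplied for demonstrations; real
#' analyses should load a curated dictionary with
#' [read_motif_dictionary()].
#'
#' @export
default_motif_dictionary <- function() {
  c(MBS = "CAACTG",
    HSE = "AGAANNTTCT",
    ABRE = "ACGTGKC",
    TCA = "CCATCTTTTT",
    TGA = "AACGAC")
}

#' Read / write a motif dictionary TSV (name, pattern[, note])
#'
#' @param path TSV file with columns name, pattern (IUPAC), optional note.
#' @export
read_motif_dictionary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(df)))
    stop_input("motif dictionary needs columns name, pattern")
  stats::setNames(toupper(df$pattern), df$name)
}
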