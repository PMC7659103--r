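# Synthetic hexaploid-style genomes with planted MYB-repeat gene families.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: three subgenomes (A/B/D) of seven chromosomes, family genes whose
# proteins carry 1-4 mutated copies of a 52-residue repeat consensus,
# consecutive near-identical tandem clusters, collinear segmental blocks
# copied onto another chromosome of the same subgenome, homoeologous copies
# of a configurable fraction of family genes across the three subgenomes,
# and unrelated background genes. Every planted entity is recorded in a
# machine-readable truth record.

# A 52-residue R2-like MYB repeat consensus (three spaced tryptophans,
# helix-turn-helix flavour); length is asserted in the config validator.
MYB_REPEAT_CONSENSUS <-
  "KGPWTEEEDQKLVAYIQKHGHGNWRALPKLAGLNRCGKSCRLRWTNYLRPDI"

.class_repeats <- c(`1R` = 1L, `2R` = 2L, `3R` = 3L, `4R` = 4L)

#' Configuration for the synthetic genome generator
#'
#' Defaults describe a desk-scale hexaploid genome: 3 subgenomes (A/B/D) of
#' 7 chromosomes, 300 kb each, ~90 family genes (mostly 2R, as in plant MYB
#' families) plus 200 background genes, 3 tandem clusters of 2-4 members,
#' 2 segmental blocks of 5 genes spanning ~`segmental_span`, and homoeologous
#' triads for 85% of non-duplicate family genes.
#'
#' @param n_subgenomes number of subgenome copies (labels taken from
#'   `subgenome_labels`).
#' @param subgenome_labels single letters naming the subgenomes.
#' @param chromosomes_per_subgenome chromosomes per subgenome.
#' @param chromosome_length chromosome length in bases.
#' @param n_family_genes total family gene count (tandem/segmental copies and
#'   homoeologs all draw on this budget).
#' @param n_background_genes unrelated protein-coding genes.
#' @param class_mix named proportions over c("1R","2R","3R","4R"); must sum
#'   to 1.
#' @param n_tandem_clusters,tandem_cluster_size tandem clusters to plant and
#'   the inclusive range of members per cluster.
#' @param n_segmental_blocks,segmental_block_genes segmental blocks to plant
#'   and family genes per block region.
#' @param segmental_span genomic span (bases) each planted block region is
#'   laid out to cover (the copy sits on a different chromosome of the same
#'   subgenome).
#' @param homoeolog_fraction fraction of homoeolog groups planted as complete
#'   triads (remainder are single-subgenome genes).
#' @param repeat_consensus 52-residue repeat consensus.
#' @param repeat_noise per-position substitution probability applied to each
#'   planted repeat copy.
#' @param min_intergenic_gap minimum bases between adjacent genes.
#' @param plant_motifs also plant cis-element motifs in family-gene
#'   promoters (recorded in the truth record).
#' @param motif_dictionary named IUPAC patterns to plant (default
#'   [default_motif_dictionary()]).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `myb_genome_config` list.
#' @export
synthetic_genome_config <- function(n_subgenomes = 3,
                                    subgenome_labels = c("A", "B", "D"),
                                    chromosomes_per_subgenome = 7,
                                    chromosome_length = 300000,
                                    n_family_genes = 90,
                                    n_background_genes = 200,
                                    class_mix = c(`1R` = 0.05, `2R` = 0.80,
                                                  `3R` = 0.10, `4R` = 0.05),
                                    n_tandem_clusters = 3,
                                    tandem_cluster_size = c(2, 4),
                                    n_segmental_blocks = 2,
                                    segmental_block_genes = 5,
                                    segmental_span = 60000,
                                    homoeolog_fraction = 0.85,
                                    repeat_consensus = MYB_REPEAT_CONSENSUS,
                                    repeat_noise = 0.1,
                                    min_intergenic_gap = 200,
                                    plant_motifs = TRUE,
                                    motif_dictionary = NULL,
                                    seed = 1) {
  cfg <- list(n_subgenomes = as.integer(n_subgenomes),
              subgenome_labels = subgenome_labels[seq_len(n_subgenomes)],
              chromosomes_per_subgenome = as.integer(chromosomes_per_subgenome),
              chromosome_length = as.integer(chromosome_length),
              n_family_genes = as.integer(n_family_genes),
              n_background_genes = as.integer(n_background_genes),
              class_mix = class_mix,
              n_tandem_clusters = as.integer(n_tandem_clusters),
              tandem_cluster_size = as.integer(tandem_cluster_size),
              n_segmental_blocks = as.integer(n_segmental_blocks),
              segmental_block_genes = as.integer(segmental_block_genes),
              segmental_span = as.integer(segmental_span),
              homoeolog_fraction = homoeolog_fraction,
              repeat_consensus = repeat_consensus,
              repeat_noise = repeat_noise,
              min_intergenic_gap = as.integer(min_intergenic_gap),
              plant_motifs = isTRUE(plant_motifs),
              motif_dictionary = motif_dictionary,
              seed = as.integer(seed))
  validate_genome_config(cfg)
  class(cfg) <- "myb_genome_config"
  cfg
}

validate_genome_config <- function(cfg) {
  if (nchar(cfg$repeat_consensus) != 52L)
    stop_input("repeat_consensus must be 52 residues, got %d",
               nchar(cfg$repeat_consensus))
  if (abs(sum(cfg$class_mix) - 1) > 1e-8)
    stop_input("class_mix proportions must sum to 1")
  if (!all(names(cfg$class_mix) %in% names(.class_repeats)))
    stop_input("class_mix names must be among 1R/2R/3R/4R")
  counts <- c(cfg$n_family_genes, cfg$n_background_genes,
              cfg$n_tandem_clusters, cfg$n_segmental_blocks)
  if (any(counts < 0)) stop_input("all counts must be >= 0")
  if (cfg$repeat_noise < 0 || cfg$repeat_noise > 1)
    stop_input("repeat_noise must be in [0,1]")
  invisible(cfg)
}

# --- protein / CDS construction -------------------------------------------

mutate_repeat <- function(consensus, noise) {
  if (noise <= 0) return(consensus)
  aa <- strsplit(consensus, "")[[1]]
  hit <- stats::runif(length(aa)) < noise
  if (any(hit)) {
    aa[hit] <- vapply(aa[hit], function(a) {
      sample(setdiff(AA_ALPHABET20, a), 1)
    }, "")
  }
  paste(aa, collapse = "")
}

build_family_protein <- function(n_repeats, consensus, noise) {
  leader <- paste0("M", random_protein(sample(4:14, 1)))
  parts <- character(2 * n_repeats)
  starts <- integer(n_repeats)
  pos <- nchar(leader)
  for (r in seq_len(n_repeats)) {
    rep_seq <- mutate_repeat(consensus, noise)
    starts[r] <- pos + 1L
    pos <- pos + 52L
    linker <- if (r < n_repeats) random_protein(sample(5:10, 1)) else ""
    pos <- pos + nchar(linker)
    parts[2 * r - 1] <- rep_seq
    parts[2 * r] <- linker
  }
  tail <- random_protein(sample(20:60, 1))
  list(sequence = paste0(leader, paste(parts, collapse = ""), tail),
       repeat_starts = starts)
}

# Back-translate a protein into a CDS by sampling synonymous codons
# (vectorized: one uniform draw per residue against a padded codon table).
backtranslate <- function(protein) {
  if (is.null(.mybfam_cache$bt_mat)) {
    gc <- genetic_code()
    by_aa <- split(names(gc), gc)
    by_aa <- by_aa[names(by_aa) != "*"]
    kmax <- max(lengths(by_aa))
    mat <- matrix(NA_character_, nrow = length(by_aa), ncol = kmax,
                  dimnames = list(names(by_aa), NULL))
    for (a in names(by_aa)) mat[a, seq_along(by_aa[[a]])] <- by_aa[[a]]
    .mybfam_cache$bt_mat <- mat
    .mybfam_cache$bt_n <- lengths(by_aa)
  }
  mat <- .mybfam_cache$bt_mat
  ncod <- .mybfam_cache$bt_n
  aa <- strsplit(protein, "")[[1]]
  idx <- match(aa, rownames(mat))
  if (anyNA(idx))
    stop_input("cannot back-translate residue '%s'",
               aa[which(is.na(idx))[1]])
  pick <- 1L + floor(stats::runif(length(idx)) * ncod[idx])
  paste(mat[cbind(idx, pick)], collapse = "")
}

# Split a CDS into n_exons genomic exon pieces with random intron lengths.
# Returns list(exon_cds_lens, intron_lens).
plan_exons <- function(cds_len, n_exons) {
  if (n_exons == 1) return(list(exon_lens = cds_len, intron_lens = integer(0)))
  cuts <- sort(sample(seq(30, cds_len - 30), n_exons - 1))
  exon_lens <- diff(c(0L, cuts, cds_len))
  intron_lens <- sample(60:300, n_exons - 1, replace = TRUE)
  list(exon_lens = as.integer(exon_lens), intron_lens = as.integer(intron_lens))
}

# --- main generator --------------------------------------------------------

#' Generate a synthetic genome with planted MYB-family truth
#'
#' @param config a [synthetic_genome_config()].
#' @return list with `bundle` (genome/cds/proteins/models, see
#'   [write_genome_bundle()]) and `truth` (planted classes, tandem clusters,
#'   segmental blocks, homoeolog triads, divergence targets).
#' @export
generate_genome <- function(config) {
  validate_genome_config(config)
  with_local_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(cfg) {
  subs <- cfg$subgenome_labels
  chrom_names <- as.vector(t(outer(seq_len(cfg$chromosomes_per_subgenome),
                                   subs, function(n, s) paste0("chr", n, s))))

  tandem_sizes <- if (cfg$n_tandem_clusters > 0)
    sample(seq(cfg$tandem_cluster_size[1], cfg$tandem_cluster_size[2]),
           cfg$n_tandem_clusters, replace = TRUE) else integer(0)
  seg_total <- cfg$n_segmental_blocks * cfg$segmental_block_genes * 2L
  remainder <- cfg$n_family_genes - sum(tandem_sizes) - seg_total
  if (remainder < 0)
    stop_input(paste0("n_family_genes (%d) too small for planted tandem (%d) ",
                      "and segmental (%d) genes"),
               cfg$n_family_genes, sum(tandem_sizes), seg_total)
  phi <- cfg$homoeolog_fraction
  n_triads <- floor(phi * remainder / (1 + 2 * phi))
  n_singles <- remainder - 3L * n_triads
  while (n_singles < 0) { n_triads <- n_triads - 1L; n_singles <- remainder - 3L * n_triads }

  gene_seq_id <- 0L
  next_gene_id <- function() {
    gene_seq_id <<- gene_seq_id + 1L
    sprintf("g%04d", gene_seq_id)
  }
  draw_class <- function() {
    sample(names(cfg$class_mix), 1, prob = cfg$class_mix)
  }
  draw_seed <- function() sample.int(.Machine$integer.max - 1L, 1)

  genes <- list()   # per-gene records
  add_gene <- function(id, class, cds, protein, role, unit) {
    genes[[id]] <<- list(gene_id = id, class = class, cds = cds,
                         protein = protein, role = role, unit = unit)
    id
  }

  units <- list()   # placement units: list(kind, chrom, gene_ids, span)
  truth_tandem <- list()
  truth_seg <- list()
  truth_triads <- list()
  truth_singles <- character(0)
  kaks_rows <- list()

  new_family_cds <- function(class) {
    p <- build_family_protein(.class_repeats[[class]], cfg$repeat_consensus,
                              cfg$repeat_noise)
    backtranslate(p$sequence)
  }
  diverge <- function(cds, ks, ka) {
    simulate_codon_divergence(cds, target_ks = ks, target_ka = ka,
                              seed = draw_seed())
  }
  chrom_of <- function(num, sub) paste0("chr", num, sub)

  # homoeolog triads: one member per subgenome on the same chromosome number
  for (i in seq_len(n_triads)) {
    class <- draw_class()
    template <- new_family_cds(class)
    num <- sample(cfg$chromosomes_per_subgenome, 1)
    ids <- character(length(subs))
    for (s in seq_along(subs)) {
      cds <- diverge(template, 0.25, 0.05)
      ids[s] <- add_gene(next_gene_id(), class, cds, translate_cds(cds),
                         "triad", paste0("triad", i))
      units[[length(units) + 1L]] <- list(kind = "single",
                                          chrom = chrom_of(num, subs[s]),
                                          gene_ids = ids[s])
    }
    truth_triads[[i]] <- stats::setNames(ids, subs)
    for (a in 1:(length(ids) - 1)) for (b in (a + 1):length(ids))
      kaks_rows[[length(kaks_rows) + 1L]] <-
        data.frame(gene_a = ids[a], gene_b = ids[b], relation = "homoeolog",
                   target_ks = NA_real_, target_ka = NA_real_)
  }

  # single-subgenome family genes
  for (i in seq_len(n_singles)) {
    class <- draw_class()
    cds <- new_family_cds(class)
    id <- add_gene(next_gene_id(), class, cds, translate_cds(cds),
                   "single", paste0("single", i))
    truth_singles <- c(truth_singles, id)
    units[[length(units) + 1L]] <-
      list(kind = "single", chrom = sample(chrom_names, 1), gene_ids = id)
  }

  # tandem clusters: consecutive near-identical copies on one chromosome
  for (i in seq_along(tandem_sizes)) {
    class <- draw_class()
    template <- new_family_cds(class)
    k <- tandem_sizes[i]
    ids <- character(k)
    for (j in seq_len(k)) {
      cds <- diverge(template, 0.08, 0.02)
      ids[j] <- add_gene(next_gene_id(), class, cds, translate_cds(cds),
                         "tandem", paste0("tandem", i))
    }
    truth_tandem[[i]] <- ids
    for (a in 1:(k - 1))
      kaks_rows[[length(kaks_rows) + 1L]] <-
        data.frame(gene_a = ids[a], gene_b = ids[a + 1], relation = "tandem",
                   target_ks = 0.16, target_ka = 0.04)
    units[[length(units) + 1L]] <-
      list(kind = "tandem", chrom = sample(chrom_names, 1), gene_ids = ids)
  }

  # segmental blocks: a run of genes on one chromosome, its diverged copy on
  # another chromosome of the same subgenome, both laid out to span
  # ~segmental_span
  for (i in seq_len(cfg$n_segmental_blocks)) {
    sub <- sample(subs, 1)
    nums <- sample(cfg$chromosomes_per_subgenome, 2)
    ids_a <- character(cfg$segmental_block_genes)
    ids_b <- character(cfg$segmental_block_genes)
    for (j in seq_len(cfg$segmental_block_genes)) {
      class <- draw_class()
      cds_a <- new_family_cds(class)
      cds_b <- diverge(cds_a, 0.10, 0.025)
      ids_a[j] <- add_gene(next_gene_id(), class, cds_a,
                           translate_cds(cds_a), "segmental", paste0("seg", i, "A"))
      ids_b[j] <- add_gene(next_gene_id(), class, cds_b,
                           translate_cds(cds_b), "segmental", paste0("seg", i, "B"))
      kaks_rows[[length(kaks_rows) + 1L]] <-
        data.frame(gene_a = ids_a[j], gene_b = ids_b[j],
                   relation = "segmental", target_ks = 0.10, target_ka = 0.025)
    }
    span <- round(cfg$segmental_span * stats::runif(1, 1.0, 1.2))
    truth_seg[[i]] <- list(genes_a = ids_a, genes_b = ids_b,
                           chrom_a = chrom_of(nums[1], sub),
                           chrom_b = chrom_of(nums[2], sub))
    units[[length(units) + 1L]] <- list(kind = "segrun", span = span,
                                        chrom = chrom_of(nums[1], sub),
                                        gene_ids = ids_a)
    units[[length(units) + 1L]] <- list(kind = "segrun", span = span,
                                        chrom = chrom_of(nums[2], sub),
                                        gene_ids = ids_b)
  }

  # background genes
  for (i in seq_len(cfg$n_background_genes)) {
    prot <- paste0("M", random_protein(sample(149:499, 1)))
    cds <- backtranslate(prot)
    id <- add_gene(next_gene_id(), "none", cds, prot, "background", "bg")
    units[[length(units) + 1L]] <-
      list(kind = "single", chrom = sample(chrom_names, 1), gene_ids = id)
  }

  # --- chromosome assembly -------------------------------------------------
  exon_weights <- c(0.15, 0.30, 0.30, 0.25)  # 0-3 introns, modal 1-3
  gene_plan <- list()   # per gene: genomic length, exon/intron plan, strand
  for (id in names(genes)) {
    cds_len <- nchar(genes[[id]]$cds)
    n_ex <- sample(1:4, 1, prob = exon_weights)
    ep <- plan_exons(cds_len, n_ex)
    gene_plan[[id]] <- list(exon_lens = ep$exon_lens,
                            intron_lens = ep$intron_lens,
                            glen = sum(ep$exon_lens) + sum(ep$intron_lens),
                            strand = sample(c("+", "-"), 1))
  }

  unit_chrom <- vapply(units, `[[`, "", "chrom")
  chrom_seqs <- character(length(chrom_names))
  names(chrom_seqs) <- chrom_names
  model_rows <- list()

  for (chrom in chrom_names) {
    cunits <- units[unit_chrom == chrom]
    if (length(cunits) > 1) cunits <- cunits[sample(length(cunits))]
    # genomic footprint per unit
    unit_len <- vapply(cunits, function(u) {
      glens <- vapply(u$gene_ids, function(g) gene_plan[[g]]$glen, 0)
      if (u$kind == "segrun") max(u$span, sum(glens) +
                                   (length(glens) - 1) * cfg$min_intergenic_gap)
      else if (u$kind == "tandem") sum(glens) +
        (length(glens) - 1) * (cfg$min_intergenic_gap + 150L)
      else sum(glens)
    }, 0)
    n_gaps <- length(cunits) + 1L
    needed <- sum(unit_len) + n_gaps * cfg$min_intergenic_gap
    slack <- cfg$chromosome_length - needed
    if (slack < 0)
      stop_input("capacity error: %s needs %d bases but chromosome_length is %d",
                 chrom, needed, cfg$chromosome_length)
    extra <- if (length(cunits) > 0) {
      br <- sort(stats::runif(n_gaps - 1)) * slack
      as.integer(round(diff(c(0, br, slack))))
    } else integer(0)

    pieces <- character(0)
    pos <- 0L
    for (ui in seq_along(cunits)) {
      u <- cunits[[ui]]
      gap <- cfg$min_intergenic_gap + extra[ui]
      pieces <- c(pieces, random_dna(gap))
      pos <- pos + gap
      k <- length(u$gene_ids)
      # intra-unit gaps
      glens <- vapply(u$gene_ids, function(g) gene_plan[[g]]$glen, 0)
      intra <- if (k < 2) integer(0) else if (u$kind == "segrun") {
        budget <- max(u$span - sum(glens), (k - 1) * cfg$min_intergenic_gap)
        g <- rep(budget %/% (k - 1), k - 1)
        g[seq_len(budget %% (k - 1))] <- g[seq_len(max(0, budget %% (k - 1)))] + 1L
        pmax(g, cfg$min_intergenic_gap)
      } else {
        sample(cfg$min_intergenic_gap:(cfg$min_intergenic_gap + 300L),
               k - 1, replace = TRUE)
      }
      for (j in seq_len(k)) {
        id <- u$gene_ids[j]
        gp <- gene_plan[[id]]
        cds <- genes[[id]]$cds
        # gene genomic sequence in transcription orientation
        exon_lens <- gp$exon_lens
        intron_lens <- gp$intron_lens
        offs <- cumsum(c(0L, exon_lens))
        exon_seqs <- substring(cds, offs[-length(offs)] + 1L, offs[-1])
        gseq_parts <- character(0)
        tx_coords <- matrix(0L, nrow = length(exon_lens), ncol = 2)
        p <- 0L
        for (e in seq_along(exon_lens)) {
          tx_coords[e, ] <- c(p + 1L, p + exon_lens[e])
          gseq_parts <- c(gseq_parts, exon_seqs[e])
          p <- p + exon_lens[e]
          if (e < length(exon_lens)) {
            iseq <- paste0("GT", random_dna(intron_lens[e] - 4L), "AG")
            gseq_parts <- c(gseq_parts, iseq)
            p <- p + intron_lens[e]
          }
        }
        gseq <- paste(gseq_parts, collapse = "")
        glen <- nchar(gseq)
        gstart <- pos + 1L
        gend <- pos + glen
        strand <- gp$strand
        if (strand == "+") {
          ex <- tx_coords + gstart - 1L
        } else {
          gseq <- revcomp_chr(gseq)
          ex <- cbind(gend - tx_coords[, 2] + 1L, gend - tx_coords[, 1] + 1L)
        }
        pieces <- c(pieces, gseq)
        pos <- pos + glen
        model_rows[[id]] <- list(gene_id = id,
                                 transcript_id = paste0(id, ".1"),
                                 chromosome = chrom, start = gstart,
                                 end = gend, strand = strand,
                                 exons = ex)
        if (j < k) {
          pieces <- c(pieces, random_dna(intra[j]))
          pos <- pos + intra[j]
        }
      }
    }
    pad <- cfg$chromosome_length - pos
    if (pad > 0) pieces <- c(pieces, random_dna(pad))
    chrom_seqs[chrom] <- paste(pieces, collapse = "")
  }

  model_rows <- model_rows[order(names(model_rows))]

  # --- promoter motif planting --------------------------------------------
  # Insert cis-element instances into the intergenic DNA immediately
  # upstream (in promoter orientation) of family genes, staying inside the
  # near half of the flanking gap so neighbouring promoters cannot collide.
  truth_motifs <- data.frame(gene_id = character(0), motif_name = character(0),
                             strand = character(0), upstream = integer(0),
                             length = integer(0), stringsAsFactors = FALSE)
  if (cfg$plant_motifs) {
    dict <- cfg$motif_dictionary %||% default_motif_dictionary()
    iupac <- Biostrings::IUPAC_CODE_MAP
    instantiate <- function(pat) {
      paste(vapply(strsplit(pat, "")[[1]], function(ch) {
        opts <- strsplit(iupac[[ch]], "")[[1]]
        if (length(opts) == 1) opts else sample(opts, 1)
      }, ""), collapse = "")
    }
    by_chrom <- split(model_rows, vapply(model_rows, `[[`, "", "chromosome"))
    for (chrom in names(by_chrom)) {
      rows <- by_chrom[[chrom]]
      starts <- vapply(rows, function(x) as.integer(x$start), 0L)
      ends <- vapply(rows, function(x) as.integer(x$end), 0L)
      o <- order(starts)
      rows <- rows[o]; starts <- starts[o]; ends <- ends[o]
      cl <- nchar(chrom_seqs[chrom])
      for (ri in seq_along(rows)) {
        g <- rows[[ri]]
        if (genes[[g$gene_id]]$class == "none") next
        space <- if (g$strand == "+") {
          g$start - 1L - (if (ri > 1) ends[ri - 1] else 0L)
        } else {
          (if (ri < length(rows)) starts[ri + 1] else cl + 1L) - g$end - 1L
        }
        half <- (space - 10L) %/% 2L
        picks <- sample(names(dict), min(2L, length(dict)))
        u <- 5L
        for (nm in picks) {
          len <- nchar(dict[[nm]])
          if (u + len > half) break
          inst <- instantiate(dict[[nm]])
          pstrand <- sample(c("+", "-"), 1)
          if (g$strand == "+") {
            seg <- c(g$start - u - len, g$start - u - 1L)
            ins <- if (pstrand == "+") inst else revcomp_chr(inst)
          } else {
            seg <- c(g$end + u + 1L, g$end + u + len)
            ins <- if (pstrand == "+") revcomp_chr(inst) else inst
          }
          substr(chrom_seqs[chrom], seg[1], seg[2]) <- ins
          truth_motifs <- rbind(truth_motifs, data.frame(
            gene_id = g$gene_id, motif_name = nm, strand = pstrand,
            upstream = u, length = len, stringsAsFactors = FALSE))
          u <- u + len + sample(20:40, 1)
        }
      }
    }
  }

  models <- gene_models(
    gene_id = vapply(model_rows, `[[`, "", "gene_id"),
    transcript_id = vapply(model_rows, `[[`, "", "transcript_id"),
    chromosome = vapply(model_rows, `[[`, "", "chromosome"),
    start = vapply(model_rows, function(x) as.integer(x$start), 0L),
    end = vapply(model_rows, function(x) as.integer(x$end), 0L),
    strand = vapply(model_rows, `[[`, "", "strand"),
    exons = lapply(model_rows, `[[`, "exons"))

  ids <- models$gene_id
  cds_set <- Biostrings::DNAStringSet(vapply(ids, function(i) genes[[i]]$cds, ""))
  names(cds_set) <- models$transcript_id
  prot_set <- Biostrings::AAStringSet(vapply(ids, function(i) genes[[i]]$protein, ""))
  names(prot_set) <- models$transcript_id
  genome <- Biostrings::DNAStringSet(chrom_seqs)

  truth <- list(
    classes = vapply(ids, function(i) genes[[i]]$class, ""),
    tandem_clusters = truth_tandem,
    segmental_blocks = truth_seg,
    triads = truth_triads,
    homoeolog_singletons = truth_singles,
    motifs = truth_motifs,
    kaks = if (length(kaks_rows)) do.call(rbind, kaks_rows) else
      data.frame(gene_a = character(0), gene_b = character(0),
                 relation = character(0), target_ks = numeric(0),
                 target_ka = numeric(0)))

  list(bundle = list(genome = genome, cds = cds_set, proteins = prot_set,
                     models = models),
       truth = truth)
}
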