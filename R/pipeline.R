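# End-to-end orchestration: simulate -> identify -> annotate -> dup -> kaks
# -> tree -> expr -> report, restartable from per-stage TSV/FASTA/GFF3
# artifacts on disk.

#' Pipeline configuration
#'
#' Defaults equal the classic criteria: tandem coverage 0.8 and identity
#' 80%, segmental identity 90% and span 600 kb, E-value 1e-10, |log2FC| > 1
#' at p < 0.05, 1000 bootstrap replicates, 1500 bp promoters.
#'
#' @param out_dir output directory (stages write and re-read artifacts
#'   here).
#' @param genome_dir directory with genome.fasta/cds.fasta/proteins.fasta/
#'   genes.gff3; defaults to the simulate stage's output inside `out_dir`.
#' @param expression_dir directory with expression.tsv + design TSVs;
#'   defaults to the simulate stage's output.
#' @param simulate run the synthetic generator first.
#' @param prefix family name prefix.
#' @param bit_threshold,min_separation repeat scan/merge knobs.
#' @param coverage,tandem_identity,max_evalue,min_score tandem criteria.
#' @param segmental_identity,min_span,min_anchors,max_gap segmental criteria
#'   (`min_span` should be scaled down for synthetic chromosomes).
#' @param fc_threshold,alpha screening thresholds.
#' @param n_bootstrap bootstrap replicates; `tree_max_taxa` caps the tree to
#'   the first members by name for desk-scale runs.
#' @param promoter_length promoter window (bases).
#' @param expression_k profile cluster count.
#' @param seed master seed (generators and bootstrap).
#' @param genome_config overrides passed to [synthetic_genome_config()]
#'   (list).
#' @return a `myb_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            genome_dir = file.path(out_dir, "genome"),
                            expression_dir = file.path(out_dir, "expression"),
                            simulate = TRUE,
                            prefix = "MYB",
                            bit_threshold = 30, min_separation = 5,
                            coverage = 0.8, tandem_identity = 80,
                            max_evalue = 1e-10, min_score = 100,
                            segmental_identity = 90, min_span = 600000,
                            min_anchors = 2, max_gap = 2 * min_span,
                            fc_threshold = 1, alpha = 0.05,
                            n_bootstrap = 1000, tree_max_taxa = 15,
                            promoter_length = 1500, expression_k = 5,
                            seed = 1, genome_config = list()) {
  cfg <- as.list(environment())
  class(cfg) <- "myb_pipeline_config"
  cfg
}

# Flat "key: value" config file; vectors comma-separated, genome_config keys
# namespaced as genome.<key>.
flatten_config <- function(cfg) {
  out <- list()
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (nm == "genome_config") {
      for (gn in names(v))
        out[[paste0("genome.", gn)]] <- paste(v[[gn]], collapse = ",")
    } else {
      out[[nm]] <- paste(format(v, scientific = FALSE, trim = TRUE),
                         collapse = ",")
    }
  }
  out
}

#' Write / read a pipeline config file (flat key: value text)
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  fl <- flatten_config(cfg)
  writeLines(paste0(names(fl), ": ", unlist(fl)), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^([^:]+):[[:space:]]*(.*)$", lines))
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  base <- pipeline_config(out_dir = ".")
  numeric_keys <- names(base)[vapply(base, is.numeric, TRUE)]
  logical_keys <- names(base)[vapply(base, is.logical, TRUE)]
  cfg <- base
  gcfg <- list()
  for (i in seq_along(keys)) {
    k <- trimws(keys[i])
    v <- trimws(vals[i])
    if (startsWith(k, "genome.")) {
      gk <- sub("^genome\\.", "", k)
      num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
      gcfg[[gk]] <- if (anyNA(num)) strsplit(v, ",")[[1]] else num
    } else if (k %in% numeric_keys) {
      cfg[[k]] <- as.numeric(v)
    } else if (k %in% logical_keys) {
      cfg[[k]] <- as.logical(v)
    } else {
      cfg[[k]] <- v
    }
  }
  cfg$genome_config <- gcfg
  class(cfg) <- "myb_pipeline_config"
  cfg
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# trivial gap-free stack alignment: right-pad with gaps (fallback for
# synthetic fixtures; real runs should supply a proper MSA)
stack_alignment <- function(seqs) {
  seqs <- as_named_chr(seqs)
  L <- max(nchar(seqs))
  stats::setNames(vapply(seqs, function(s) {
    paste0(s, strrep("-", L - nchar(s)))
  }, ""), names(seqs))
}

pipeline_paths <- function(cfg) {
  o <- cfg$out_dir
  list(family = file.path(o, "family_table.tsv"),
       properties = file.path(o, "protein_properties.tsv"),
       motifs = file.path(o, "motif_occurrences.tsv"),
       clusters = file.path(o, "tandem_clusters.tsv"),
       clusters_bed = file.path(o, "tandem_clusters.bed"),
       blocks = file.path(o, "segmental_blocks.tsv"),
       blocks_bed = file.path(o, "segmental_blocks.bed"),
       homologs = file.path(o, "homolog_groups.tsv"),
       kaks = file.path(o, "kaks.tsv"),
       tree = file.path(o, "family_tree.nwk"),
       zscore = file.path(o, "zscore_matrix.tsv"),
       calls = file.path(o, "differential_calls.tsv"),
       expr_clusters = file.path(o, "expression_clusters.tsv"),
       updown = file.path(o, "updown_summary.tsv"),
       report_json = file.path(o, "report.json"),
       report_txt = file.path(o, "report.txt"))
}

read_family_table <- function(cfg) {
  p <- pipeline_paths(cfg)$family
  if (!file.exists(p))
    stop_input("family table missing (%s); run the identify stage first", p)
  utils::read.delim(p, stringsAsFactors = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order; every stage re-reads its inputs
#' from `out_dir` so any suffix of the pipeline can be rerun after deleting
#' downstream outputs. Inputs are validated before the first stage runs.
#'
#' @param cfg a [pipeline_config()].
#' @param stages subset of c("simulate","identify","annotate","dup","kaks",
#'   "tree","expr","report").
#' @return the run report (list), invisibly written to report.json/.txt.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "identify", "annotate",
                                         "dup", "kaks", "tree", "expr",
                                         "report")) {
  all_stages <- c("simulate", "identify", "annotate", "dup", "kaks", "tree",
                  "expr", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!cfg$simulate) stages <- setdiff(stages, "simulate")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  # upfront validation of required inputs
  if (!("simulate" %in% stages)) {
    need <- c(file.path(cfg$genome_dir, "genes.gff3"),
              file.path(cfg$genome_dir, "proteins.fasta"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop_input("missing input file(s): %s", paste(miss, collapse = ", "))
  }
  for (st in stages) {
    res <- tryCatch(switch(st,
                           simulate = stage_simulate(cfg),
                           identify = stage_identify(cfg),
                           annotate = stage_annotate(cfg),
                           dup = stage_dup(cfg),
                           kaks = stage_kaks(cfg),
                           tree = stage_tree(cfg),
                           expr = stage_expr(cfg),
                           report = stage_report(cfg)),
                    error = function(e) {
                      stop_input("stage '%s' failed: %s", st,
                                 conditionMessage(e))
                    })
  }
  if ("report" %in% stages) res else invisible(NULL)
}

stage_simulate <- function(cfg) {
  gargs <- cfg$genome_config
  gargs$seed <- gargs$seed %||% cfg$seed
  gcfg <- do.call(synthetic_genome_config, gargs)
  sim <- generate_genome(gcfg)
  write_genome_bundle(sim$bundle, cfg$genome_dir)
  write_truth(sim$truth, file.path(cfg$genome_dir, "truth.json"))
  design <- default_stress_design()
  expr <- generate_expression(sim$bundle$models$gene_id, design,
                              planted_fraction = 0.1, seed = cfg$seed)
  write_expression(expr$tpm, design, cfg$expression_dir)
  write_truth(expr$truth, file.path(cfg$expression_dir, "truth.json"))
  stage_log("simulate", "%d genes on %d chromosomes; %d samples",
            nrow(sim$bundle$models), length(sim$bundle$genome),
            nrow(design$samples))
  invisible(NULL)
}

stage_identify <- function(cfg) {
  bundle <- read_genome_bundle(cfg$genome_dir)
  fam <- identify_family(bundle$proteins, bundle$models,
                         bit_threshold = cfg$bit_threshold,
                         min_separation = cfg$min_separation,
                         prefix = cfg$prefix)
  write_tsv(fam, pipeline_paths(cfg)$family)
  stage_log("identify", "%d family members (%s)",
            sum(fam$class != "none"),
            paste(sprintf("%s:%d", names(table(fam$class[fam$class != "none"]))
                          , table(fam$class[fam$class != "none"])),
                  collapse = " "))
  invisible(NULL)
}

stage_annotate <- function(cfg) {
  bundle <- read_genome_bundle(cfg$genome_dir)
  fam <- read_family_table(cfg)
  fam <- fam[fam$class != "none", , drop = FALSE]
  p <- pipeline_paths(cfg)
  gidx <- match(fam$gene_id, bundle$models$gene_id)
  tidx <- match(bundle$models$transcript_id[gidx], names(bundle$proteins))
  seqs <- stats::setNames(as.character(bundle$proteins)[tidx], fam$gene_id)
  props <- protein_properties(seqs)
  props$introns <- vapply(gidx, function(i)
    count_introns(bundle$models[i, ]), 0L)
  write_tsv(props, p$properties)
  dict <- default_motif_dictionary()
  occs <- do.call(rbind, lapply(gidx, function(i) {
    prom <- suppressWarnings(
      extract_promoter(bundle$genome, bundle$models[i, ],
                       length = cfg$promoter_length))
    scan_motifs(prom$sequence, dict, both_strands = TRUE,
                gene_id = bundle$models$gene_id[i])
  }))
  write_tsv(occs, p$motifs)
  stage_log("annotate", "%d proteins, %d motif occurrences",
            nrow(props), nrow(occs))
  invisible(NULL)
}

stage_dup <- function(cfg) {
  bundle <- read_genome_bundle(cfg$genome_dir)
  fam <- read_family_table(cfg)
  family <- fam$gene_id[fam$class != "none"]
  p <- pipeline_paths(cfg)
  models <- bundle$models
  tid <- stats::setNames(models$transcript_id, models$gene_id)
  cds <- stats::setNames(as.character(bundle$cds)[match(tid[family],
                                                        names(bundle$cds))],
                         family)
  prot <- stats::setNames(as.character(bundle$proteins)[
    match(tid[family], names(bundle$proteins))], family)
  cds_hits <- make_pairhits(cds, type = "dna")
  prot_hits <- make_pairhits(prot, type = "protein")
  clusters <- call_tandem(cds_hits, models, family,
                          coverage = cfg$coverage,
                          min_identity = cfg$tandem_identity,
                          max_evalue = cfg$max_evalue,
                          min_score = cfg$min_score)
  blocks <- call_segmental(prot_hits, models, family,
                           min_span = cfg$min_span,
                           min_identity = cfg$segmental_identity,
                           min_anchors = cfg$min_anchors,
                           max_gap = cfg$max_gap,
                           max_evalue = cfg$max_evalue,
                           min_score = cfg$min_score)
  subg <- stats::setNames(subgenome_of_chrom(models$chromosome),
                          models$gene_id)
  hom <- find_homolog_groups(prot_hits, family, subg)
  write_tsv(clusters, p$clusters)
  write_tsv(blocks, p$blocks)
  hg <- hom$groups
  hg$fraction_complete <- hom$fraction_complete
  write_tsv(hg, p$homologs)
  # BED6 tracks (0-based half-open starts)
  if (nrow(clusters)) {
    gidx <- match(clusters$gene_id, models$gene_id)
    bed <- data.frame(models$chromosome[gidx], models$start[gidx] - 1L,
                      models$end[gidx],
                      paste0(clusters$cluster_id, "|", clusters$gene_id),
                      0L, models$strand[gidx])
    utils::write.table(bed, p$clusters_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else writeLines(character(0), p$clusters_bed)
  if (nrow(blocks)) {
    bed <- data.frame(c(blocks$chrom_a, blocks$chrom_b),
                      c(blocks$start_a, blocks$start_b) - 1L,
                      c(blocks$end_a, blocks$end_b),
                      rep(blocks$block_id, 2), 0L, "+")
    utils::write.table(bed, p$blocks_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else writeLines(character(0), p$blocks_bed)
  stage_log("dup", "%d tandem clusters, %d segmental blocks, %.2f complete triads",
            length(unique(clusters$cluster_id)), nrow(blocks),
            hom$fraction_complete %||% NA_real_)
  invisible(NULL)
}

stage_kaks <- function(cfg) {
  bundle <- read_genome_bundle(cfg$genome_dir)
  p <- pipeline_paths(cfg)
  models <- bundle$models
  tid <- stats::setNames(models$transcript_id, models$gene_id)
  cds_all <- stats::setNames(as.character(bundle$cds), names(bundle$cds))
  get_cds <- function(g) cds_all[[tid[[g]]]]
  pairs <- list()
  if (file.exists(p$clusters)) {
    cl <- utils::read.delim(p$clusters, stringsAsFactors = FALSE)
    for (cid in unique(cl$cluster_id)) {
      g <- cl$gene_id[cl$cluster_id == cid]
      for (i in seq_along(g)[-1])
        pairs[[length(pairs) + 1L]] <- c(g[i - 1], g[i], "tandem")
    }
  }
  if (file.exists(p$blocks)) {
    bl <- utils::read.delim(p$blocks, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(bl))) {
      ga <- strsplit(bl$genes_a[i], ";")[[1]]
      gb <- strsplit(bl$genes_b[i], ";")[[1]]
      for (j in seq_along(ga))
        pairs[[length(pairs) + 1L]] <- c(ga[j], gb[j], "segmental")
    }
  }
  rows <- lapply(pairs, function(pr) {
    r <- kaks_pair(get_cds(pr[1]), get_cds(pr[2]), ids = pr[1:2])
    data.frame(gene_a = pr[1], gene_b = pr[2], pair_type = pr[3],
               S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
               ka = r$ka, ks = r$ks, ratio = r$ratio,
               selection = r$selection_label, stringsAsFactors = FALSE)
  })
  kk <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               pair_type = character(0), S = numeric(0), N = numeric(0),
               Sd = numeric(0), Nd = numeric(0), ka = numeric(0),
               ks = numeric(0), ratio = numeric(0),
               selection = character(0), stringsAsFactors = FALSE)
  write_tsv(kk, p$kaks)
  stage_log("kaks", "%d duplicate pairs (%d purifying)",
            nrow(kk), sum(kk$selection == "purifying"))
  invisible(NULL)
}

stage_tree <- function(cfg) {
  bundle <- read_genome_bundle(cfg$genome_dir)
  fam <- read_family_table(cfg)
  fam <- fam[fam$class != "none", , drop = FALSE]
  p <- pipeline_paths(cfg)
  take <- utils::head(order(fam$assigned_name), cfg$tree_max_taxa)
  genes <- fam$gene_id[take]
  if (length(genes) < 3) {
    writeLines(character(0), p$tree)
    stage_log("tree", "skipped (<3 family members)")
    return(invisible(NULL))
  }
  models <- bundle$models
  tid <- stats::setNames(models$transcript_id, models$gene_id)
  prot <- stats::setNames(
    as.character(bundle$proteins)[match(tid[genes], names(bundle$proteins))],
    fam$assigned_name[take])
  aln <- stack_alignment(prot)
  bs <- bootstrap_support(aln, n_replicates = cfg$n_bootstrap,
                          seed = cfg$seed)
  ape::write.tree(bs$tree, p$tree)
  stage_log("tree", "%d taxa, %d bootstrap replicates",
            length(genes), cfg$n_bootstrap)
  invisible(NULL)
}

stage_expr <- function(cfg) {
  ex <- read_expression(cfg$expression_dir)
  p <- pipeline_paths(cfg)
  zs <- zscore_normalize(ex$tpm)
  zdf <- data.frame(gene_id = rownames(zs$z),
                    zero_variance = zs$zero_variance, zs$z,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(zdf, p$zscore)
  calls <- screen_all_contrasts(ex$tpm, ex$design,
                                fc_threshold = cfg$fc_threshold,
                                alpha = cfg$alpha)
  write_tsv(calls, p$calls)
  keep <- !zs$zero_variance
  k <- min(cfg$expression_k, sum(keep))
  groups <- hierarchical_cluster(zs$z[keep, , drop = FALSE], k)
  write_tsv(data.frame(gene_id = names(groups), group = unname(groups),
                       stringsAsFactors = FALSE), p$expr_clusters)
  write_tsv(summarize_updown(calls), p$updown)
  stage_log("expr", "%d genes x %d samples, %d contrasts",
            nrow(ex$tpm), ncol(ex$tpm), nrow(ex$design$contrasts))
  invisible(NULL)
}

#' Summarize stage outputs into the run-report counts section
#'
#' @param cfg a [pipeline_config()] whose stages have run.
#' @return list of count tables: per-class totals, per-chromosome totals,
#'   duplication totals, selection labels, up/down per contrast.
#' @export
summarize_counts <- function(cfg) {
  p <- pipeline_paths(cfg)
  out <- list()
  if (file.exists(p$family)) {
    fam <- utils::read.delim(p$family, stringsAsFactors = FALSE)
    mem <- fam[fam$class != "none", , drop = FALSE]
    out$members_per_class <- as.list(table(mem$class))
    out$members_per_chromosome <- as.list(table(mem$chromosome))
    out$total_members <- nrow(mem)
  }
  if (file.exists(p$clusters)) {
    cl <- utils::read.delim(p$clusters, stringsAsFactors = FALSE)
    out$tandem_clusters <- length(unique(cl$cluster_id))
    out$tandem_genes <- nrow(cl)
  }
  if (file.exists(p$blocks)) {
    bl <- utils::read.delim(p$blocks, stringsAsFactors = FALSE)
    out$segmental_blocks <- nrow(bl)
  }
  if (file.exists(p$homologs)) {
    hg <- utils::read.delim(p$homologs, stringsAsFactors = FALSE)
    out$homolog_groups <- length(unique(hg$group_id))
    out$fraction_complete_triads <-
      if (nrow(hg)) hg$fraction_complete[1] else NA_real_
  }
  if (file.exists(p$kaks)) {
    kk <- utils::read.delim(p$kaks, stringsAsFactors = FALSE)
    out$selection_labels <- as.list(table(kk$selection))
  }
  if (file.exists(p$updown)) {
    ud <- utils::read.delim(p$updown, stringsAsFactors = FALSE)
    out$updown_per_contrast <- ud
  }
  out
}

stage_report <- function(cfg) {
  p <- pipeline_paths(cfg)
  counts <- summarize_counts(cfg)
  report <- list(package = "mybfam",
                 version = as.character(utils::packageVersion("mybfam")),
                 config = flatten_config(cfg),
                 counts = counts)
  jsonlite::write_json(report, p$report_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- c("mybfam run report",
           "=================",
           sprintf("family members: %s", counts$total_members %||% NA),
           sprintf("tandem clusters: %s", counts$tandem_clusters %||% NA),
           sprintf("segmental blocks: %s", counts$segmental_blocks %||% NA),
           sprintf("complete homoeolog triads (fraction): %s",
                   counts$fraction_complete_triads %||% NA))
  writeLines(txt, p$report_txt)
  stage_log("report", "written to %s", p$report_json)
  report
}

#' Command-line entry point
#'
#' Subcommands: simulate, identify, annotate, dup, kaks, tree, expr, ddct,
#' run-all. All read `--config <file>`; individual `--<key> <value>` flags
#' override config keys. `ddct` instead takes `--ct <tsv>` with columns
#' sample, target_ct, reference_ct, group.
#'
#' @param args character vector (default: command line).
#' @export
myb_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: mybfam <simulate|identify|annotate|dup|kaks|tree|expr|ddct|run-all>",
        "[--config file] [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    if (startsWith(args[i], "--") && i < length(args)) {
      opts[[sub("^--", "", args[i])]] <- args[i + 1]
      i <- i + 2
    } else i <- i + 1
  }
  if (cmd == "ddct") {
    if (is.null(opts$ct)) stop_input("ddct requires --ct <tsv>")
    res <- ddct(utils::read.delim(opts$ct, stringsAsFactors = FALSE))
    utils::write.table(res, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(0L))
  }
  cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
         else pipeline_config(out_dir = opts$out_dir %||% "mybfam_out")
  for (nm in setdiff(names(opts), c("config"))) {
    if (nm %in% names(cfg)) {
      cfg[[nm]] <- if (is.numeric(cfg[[nm]])) as.numeric(opts[[nm]])
                   else if (is.logical(cfg[[nm]])) as.logical(opts[[nm]])
                   else opts[[nm]]
    }
  }
  stages <- if (cmd == "run-all")
    c("simulate", "identify", "annotate", "dup", "kaks", "tree", "expr",
      "report")
  else if (cmd %in% c("simulate", "identify", "annotate", "dup", "kaks",
                      "tree", "expr")) cmd
  else stop_input("unknown subcommand '%s'", cmd)
  run_pipeline(cfg, stages = stages)
  invisible(0L)
}
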