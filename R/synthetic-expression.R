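# Synthetic TPM expression matrices with planted differential truth.

#' Describe an expression experiment design
#'
#' @param samples data.frame with columns sample_id, condition, timepoint,
#'   replicate (timepoint may be NA).
#' @param contrasts data.frame with columns treated, control naming
#'   conditions.
#' @return a `myb_expression_design` list.
#' @export
expression_design <- function(samples, contrasts) {
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% names(samples)))
    stop_input("samples must have columns %s", paste(need, collapse = ", "))
  if (!all(c("treated", "control") %in% names(contrasts)))
    stop_input("contrasts must have columns treated, control")
  missing <- setdiff(unique(c(contrasts$treated, contrasts$control)),
                     unique(samples$condition))
  if (length(missing))
    stop_input("contrast conditions absent from samples: %s",
               paste(missing, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop_input("duplicate sample_id in design")
  out <- list(samples = as.data.frame(samples, stringsAsFactors = FALSE),
              contrasts = as.data.frame(contrasts, stringsAsFactors = FALSE))
  class(out) <- "myb_expression_design"
  out
}

#' Default stress-course design
#'
#' Drought (D), heat (H) and combined (DH) at 1 and 6 hours post stress
#' versus an untreated control (CK), with `n_reps` replicates per condition.
#'
#' @param n_reps replicates per condition.
#' @export
default_stress_design <- function(n_reps = 3) {
  conds <- c("CK", "D_1", "D_6", "H_1", "H_6", "DH_1", "DH_6")
  samples <- do.call(rbind, lapply(conds, function(cn) {
    data.frame(sample_id = paste0(cn, "_r", seq_len(n_reps)),
               condition = cn,
               timepoint = sub("^[A-Z]+_?", "", cn),
               replicate = seq_len(n_reps), stringsAsFactors = FALSE)
  }))
  contrasts <- data.frame(treated = conds[-1], control = "CK",
                          stringsAsFactors = FALSE)
  expression_design(samples, contrasts)
}

#' Generate a TPM matrix with planted up/down genes
#'
#' Counts are drawn per sample from a negative binomial around gene base
#' means (log-normal across genes), planted genes have their mean multiplied
#' by 2^log2FC in the treated condition(s) of one randomly chosen contrast,
#' and each sample is scaled to one million to mimic TPM normalization.
#'
#' @param genes character vector of gene ids.
#' @param design an [expression_design()].
#' @param planted_fraction fraction of genes planted as differential (split
#'   evenly up/down).
#' @param effect_log2fc absolute log2 fold-change of planted genes (a single
#'   value or a sampler function of n).
#' @param dispersion negative-binomial dispersion (size = 1/dispersion);
#'   0 gives noise-free means.
#' @param base_mean_log_sd spread of log-normal gene base means.
#' @param seed integer seed.
#' @return list(tpm = genes x samples matrix, design, truth) where truth has
#'   per-gene per-contrast status and true log2FC.
#' @export
generate_expression <- function(genes, design, planted_fraction = 0.1,
                                effect_log2fc = 3, dispersion = 0.1,
                                base_mean_log_sd = 1.5, seed = 1) {
  if (length(genes) == 0) stop_input("empty gene list")
  if (planted_fraction < 0 || planted_fraction > 1)
    stop_input("planted_fraction must be in [0,1]")
  with_local_seed(seed, {
    ns <- nrow(design$samples)
    ng <- length(genes)
    base <- exp(log(100) + stats::rnorm(ng, 0, base_mean_log_sd))
    n_planted <- round(planted_fraction * ng)
    planted_idx <- if (n_planted > 0) sample(ng, n_planted) else integer(0)
    dir <- rep(c("up", "down"), length.out = n_planted)
    contrast_of <- if (n_planted > 0)
      sample(nrow(design$contrasts), n_planted, replace = TRUE) else integer(0)
    lfc <- if (is.function(effect_log2fc)) effect_log2fc(n_planted)
           else rep(abs(effect_log2fc), n_planted)
    lfc <- ifelse(dir == "up", lfc, -lfc)

    mu <- matrix(rep(base, ns), nrow = ng, ncol = ns,
                 dimnames = list(genes, design$samples$sample_id))
    truth <- data.frame(gene_id = character(0), contrast = character(0),
                        status = character(0), log2fc = numeric(0),
                        stringsAsFactors = FALSE)
    for (k in seq_len(n_planted)) {
      g <- planted_idx[k]
      ctr <- design$contrasts[contrast_of[k], ]
      treated_samples <- design$samples$condition == ctr$treated
      mu[g, treated_samples] <- mu[g, treated_samples] * 2^lfc[k]
      truth <- rbind(truth, data.frame(
        gene_id = genes[g],
        contrast = paste0(ctr$treated, "_vs_", ctr$control),
        status = dir[k], log2fc = lfc[k], stringsAsFactors = FALSE))
    }
    counts <- if (dispersion > 0) {
      matrix(stats::rnbinom(ng * ns, mu = as.vector(mu), size = 1 / dispersion),
             nrow = ng, dimnames = dimnames(mu))
    } else mu
    tpm <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
    list(tpm = tpm, design = design,
         truth = list(expression = truth,
                      null_genes = setdiff(genes, genes[planted_idx])))
  })
}

#' Write / read an expression matrix and design as TSV
#'
#' @param tpm genes x samples matrix.
#' @param design an [expression_design()].
#' @param dir output directory.
#' @export
write_expression <- function(tpm, design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(design$samples, file.path(dir, "design_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(design$contrasts, file.path(dir, "design_contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression
#' @export
read_expression <- function(dir) {
  df <- utils::read.delim(file.path(dir, "expression.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  tpm <- as.matrix(df[, -1, drop = FALSE])
  rownames(tpm) <- df$gene_id
  design <- expression_design(
    utils::read.delim(file.path(dir, "design_samples.tsv"),
                      stringsAsFactors = FALSE),
    utils::read.delim(file.path(dir, "design_contrasts.tsv"),
                      stringsAsFactors = FALSE))
  list(tpm = tpm, design = design)
}
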