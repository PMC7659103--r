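# TPM Z-score normalization, differential screening, profile clustering and
# qPCR 2^-ddCt relative expression.

#' Z-score normalize a TPM matrix
#'
#' Per gene: z_i = (log2(TPM_i + pseudocount) - mean over samples) / sample
#' standard deviation (n-1 form). Zero-variance genes get an all-zero row
#' and are flagged rather than producing NaN.
#'
#' @param m genes x samples TPM matrix (non-negative).
#' @param pseudocount added before log2 (default 1 keeps zeros at 0).
#' @return list(z = matrix, zero_variance = logical vector per gene).
#' @export
zscore_normalize <- function(m, pseudocount = 1) {
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    stop_input("expression matrix must be a non-empty matrix")
  if (ncol(m) < 2) stop_input("need >= 2 samples (sd undefined)")
  if (any(m < 0)) stop_input("TPM values must be >= 0")
  lg <- log2(m + pseudocount)
  mu <- rowMeans(lg)
  sd_ <- apply(lg, 1, stats::sd)
  flat <- sd_ == 0 | is.na(sd_)
  z <- (lg - mu) / ifelse(flat, 1, sd_)
  z[flat, ] <- 0
  list(z = z, zero_variance = stats::setNames(flat, rownames(m)))
}

#' Screen differential genes for one contrast
#'
#' log2FC = log2((mean treated TPM + pseudocount) / (mean control TPM +
#' pseudocount)); p-value from a t-test on log2(TPM + pseudocount)
#' replicates (Welch by default). Status: "up" iff log2FC > fc_threshold and
#' p < alpha; "down" iff log2FC < -fc_threshold and p < alpha; genes with
#' zero TPM in every sample of the contrast are "undetected"; otherwise
#' "ns". No multiple-testing correction is applied by default (an FDR
#' column is added when `fdr = TRUE`, informational only).
#'
#' @param m genes x samples TPM matrix.
#' @param design an [expression_design()].
#' @param treated,control condition names of the contrast.
#' @param fc_threshold absolute log2FC threshold (classic 2-fold rule: 1).
#' @param alpha p-value threshold.
#' @param pseudocount added before log/ratio.
#' @param var_equal use pooled-variance t-test instead of Welch.
#' @param fdr add a Benjamini-Hochberg adjusted column.
#' @return data.frame(gene_id, contrast, log2fc, p_value, status).
#' @export
screen_differential <- function(m, design, treated, control,
                                fc_threshold = 1, alpha = 0.05,
                                pseudocount = 1, var_equal = FALSE,
                                fdr = FALSE) {
  conds <- design$samples$condition
  t_samples <- design$samples$sample_id[conds == treated]
  c_samples <- design$samples$sample_id[conds == control]
  if (length(t_samples) == 0 || length(c_samples) == 0)
    stop_input("contrast conditions '%s'/'%s' absent from design",
               treated, control)
  if (length(t_samples) < 2 || length(c_samples) < 2)
    stop_input("need >= 2 replicates per condition for screening")
  mt <- m[, t_samples, drop = FALSE]
  mc <- m[, c_samples, drop = FALSE]
  lfc <- log2((rowMeans(mt) + pseudocount) / (rowMeans(mc) + pseudocount))
  lt <- log2(mt + pseudocount)
  lc <- log2(mc + pseudocount)
  p <- vapply(seq_len(nrow(m)), function(i) {
    x <- lt[i, ]
    y <- lc[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    stats::t.test(x, y, var.equal = var_equal)$p.value
  }, 0)
  undetected <- rowSums(cbind(mt, mc)) == 0
  status <- rep("ns", nrow(m))
  status[p < alpha & lfc > fc_threshold] <- "up"
  status[p < alpha & lfc < -fc_threshold] <- "down"
  status[undetected] <- "undetected"
  out <- data.frame(gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                    contrast = paste0(treated, "_vs_", control),
                    log2fc = unname(lfc), p_value = p, status = status,
                    stringsAsFactors = FALSE)
  if (fdr) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Screen every contrast in a design
#'
#' @inheritParams screen_differential
#' @return row-bound [screen_differential()] results for all contrasts.
#' @export
screen_all_contrasts <- function(m, design, fc_threshold = 1, alpha = 0.05,
                                 pseudocount = 1, var_equal = FALSE) {
  do.call(rbind, lapply(seq_len(nrow(design$contrasts)), function(i) {
    screen_differential(m, design, design$contrasts$treated[i],
                        design$contrasts$control[i], fc_threshold, alpha,
                        pseudocount, var_equal)
  }))
}

#' Cluster expression profiles
#'
#' Agglomerative clustering with average linkage on 1 - Pearson correlation
#' of Z-score rows, cut to k groups. Zero-variance (flagged) rows must be
#' excluded by the caller.
#'
#' @param z Z-score matrix (genes x samples).
#' @param k number of groups.
#' @return named integer vector gene -> group label.
#' @export
hierarchical_cluster <- function(z, k) {
  if (k < 1) stop_input("k must be >= 1")
  if (k > nrow(z)) stop_input("k (%d) exceeds number of genes (%d)", k, nrow(z))
  if (k == 1)
    return(stats::setNames(rep(1L, nrow(z)), rownames(z)))
  cc <- stats::cor(t(z))
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  stats::cutree(hc, k = k)
}

#' qPCR relative expression by the 2^-ddCt method
#'
#' Per sample: dCt = target Ct - reference Ct; ddCt = dCt - mean dCt of the
#' calibrator samples; relative expression = 2^-ddCt.
#'
#' @param measurements data.frame with columns sample, target_ct,
#'   reference_ct, group ("treated" or "calibrator").
#' @return `measurements` with dct, ddct and rel_expression columns.
#' @export
ddct <- function(measurements) {
  need <- c("sample", "target_ct", "reference_ct", "group")
  if (!all(need %in% names(measurements)))
    stop_input("measurements must have columns %s", paste(need, collapse = ", "))
  cal <- measurements$group == "calibrator"
  if (!any(cal)) stop_input("no calibrator sample")
  dct <- measurements$target_ct - measurements$reference_ct
  ddct_v <- dct - mean(dct[cal])
  out <- measurements
  out$dct <- dct
  out$ddct <- ddct_v
  out$rel_expression <- 2^(-ddct_v)
  out
}

#' Per-contrast up/down counts
#'
#' The summary-table analogue of a stress-screening figure: how many genes
#' are up- and down-regulated in each contrast.
#'
#' @param calls row-bound [screen_differential()] results.
#' @return data.frame(contrast, up, down, ns, undetected).
#' @export
summarize_updown <- function(calls) {
  do.call(rbind, lapply(split(calls, calls$contrast), function(cc) {
    data.frame(contrast = cc$contrast[1],
               up = sum(cc$status == "up"),
               down = sum(cc$status == "down"),
               ns = sum(cc$status == "ns"),
               undetected = sum(cc$status == "undetected"),
               stringsAsFactors = FALSE)
  }))
}
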