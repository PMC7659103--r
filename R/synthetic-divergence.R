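# Controlled codon-level divergence for Ka/Ks validation.

#' Diverge a coding sequence at target synonymous/nonsynonymous rates
#'
#' Plants single-nucleotide substitutions so that Nei-Gojobori counting of
#' the (input, output) pair recovers approximately `target_ks` and
#' `target_ka` after Jukes-Cantor correction: targets are converted to raw
#' difference proportions pS/pN by the inverse correction, scaled by the
#' sequence's NG86 site counts, and planted as synonymous / nonsynonymous
#' changes (preferring untouched codons, never creating stop codons).
#'
#' @param cds coding sequence (character), length divisible by 3, no internal
#'   stop codons.
#' @param target_ks,target_ka target corrected rates, >= 0 and below the
#'   Jukes-Cantor saturation point (raw proportion 0.75).
#' @param seed integer seed; fixed seed gives identical output.
#' @return the diverged coding sequence (character).
#' @export
simulate_codon_divergence <- function(cds, target_ks, target_ka, seed = 1) {
  if (target_ks < 0 || target_ka < 0) stop_input("targets must be >= 0")
  p_s <- 0.75 * (1 - exp(-4 * target_ks / 3))
  p_n <- 0.75 * (1 - exp(-4 * target_ka / 3))
  # practical saturation guard: near the Jukes-Cantor ceiling (0.75) the
  # planted differences could not be counted back recoverably
  if (p_s >= 0.70 || p_n >= 0.70)
    stop_input("target approaches Jukes-Cantor saturation (raw proportion >= 0.70 of the 0.75 ceiling)")
  codons <- split_codons(cds)
  aa <- translate_codons(codons)
  if (any(is.na(aa)) || any(aa == "*"))
    stop_input("cds contains internal stop codons or invalid codons")
  with_local_seed(seed, {
    sites <- ng86_site_counts()
    S <- sum(sites[codons])
    N <- 3 * length(codons) - S
    sd_goal <- round(p_s * S)
    nd_goal <- round(p_n * N)
    gc <- genetic_code()
    touched <- rep(FALSE, length(codons))
    rounds <- 0L
    while ((sd_goal > 0 || nd_goal > 0) && rounds < 200L) {
      rounds <- rounds + 1L
      # batch of proposals: codon index, position, replacement base offset
      nb <- 4L * (sd_goal + nd_goal) + 16L
      pool <- if (any(!touched)) which(!touched) else seq_along(codons)
      ci_v <- pool[1L + floor(stats::runif(nb) * length(pool))]
      pos_v <- 1L + floor(stats::runif(nb) * 3)
      off_v <- 1L + floor(stats::runif(nb) * 3)
      for (t in seq_len(nb)) {
        if (sd_goal == 0 && nd_goal == 0) break
        ci <- ci_v[t]
        if (touched[ci] && length(pool) > 1) next
        bases <- strsplit(codons[ci], "")[[1]]
        pos <- pos_v[t]
        newb <- setdiff(DNA_BASES, bases[pos])[off_v[t]]
        mut <- bases
        mut[pos] <- newb
        mutc <- paste(mut, collapse = "")
        if (gc[[mutc]] == "*") next
        syn <- gc[[mutc]] == gc[[codons[ci]]]
        if (syn && sd_goal > 0) {
          codons[ci] <- mutc
          touched[ci] <- TRUE
          sd_goal <- sd_goal - 1L
        } else if (!syn && nd_goal > 0) {
          codons[ci] <- mutc
          touched[ci] <- TRUE
          nd_goal <- nd_goal - 1L
        }
      }
    }
    if (sd_goal > 0 || nd_goal > 0)
      stop_input("could not place requested substitutions (targets too high for sequence)")
    paste(codons, collapse = "")
  })
}
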