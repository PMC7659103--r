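# Shared internal helpers: RNG scoping, alphabets, small validators.

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a private RNG stream
#'
#' Saves and restores the caller's `.Random.seed` so generators are
#' deterministic for a fixed seed without disturbing the session RNG.
#' @param seed integer seed; NULL leaves the RNG untouched.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random amino-acid string(s), uniform composition.
random_protein <- function(n_residues) {
  if (n_residues == 0) return("")
  intToUtf8(utf8ToInt(paste(AA_ALPHABET20, collapse = ""))[
    sample.int(20L, n_residues, replace = TRUE)])
}

random_dna <- function(n_bases) {
  if (n_bases == 0) return("")
  intToUtf8(utf8ToInt("ACGT")[sample.int(4L, n_bases, replace = TRUE)])
}

# Coerce XStringSet / character to a character vector, preserving names
# (base as.character drops attributes).
as_named_chr <- function(x) {
  nm <- names(x)
  out <- as.character(x)
  names(out) <- nm
  out
}

# Fast reverse complement for plain ACGT character strings.
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", intToUtf8(rev(utf8ToInt(s))))
}

# Parse a chromosome label like "chr3B" / "3B" into number and subgenome letter.
# Returns list(num, sub); non-conforming labels give NA in both.
parse_chrom_label <- function(chrom) {
  m <- regmatches(chrom, regexec("^(?:[Cc]hr)?([0-9]+)([A-Za-z])$", chrom))
  num <- vapply(m, function(x) if (length(x) == 3) as.numeric(x[2]) else NA_real_, 0)
  sub <- vapply(m, function(x) if (length(x) == 3) toupper(x[3]) else NA_character_, "")
  list(num = num, sub = sub)
}

subgenome_of_chrom <- function(chrom) parse_chrom_label(chrom)$sub
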