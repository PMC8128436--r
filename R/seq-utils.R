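# Small sequence helpers shared across modules.

#' Normalise an RNA sequence
#'
#' Uppercases and maps T to U. Any character outside `{A,C,G,U}` raises an
#' `az_invalid_alphabet` error.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return character vector over the RNA alphabet.
#' @export
normalize_rna <- function(x, what = "sequence") {
  x <- chartr("t", "u", toupper(as.character(x)))
  x <- chartr("T", "U", x)
  az_check_alphabet(x, what)
  x
}

#' Reverse complement of RNA sequences
#'
#' @param x character vector of RNA sequences.
#' @return character vector of reverse complements.
#' @export
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# TRUE if nucleotides a and b can pair (Watson-Crick or GU wobble).
can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# Split sequences into single-character matrices/lists.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

# Translate an IUPAC degenerate nucleotide motif into a regular expression.
iupac_to_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", U = "U", T = "U",
           R = "[AG]", Y = "[CU]", S = "[GC]", W = "[AU]",
           K = "[GU]", M = "[AC]", B = "[CGU]", D = "[AGU]",
           H = "[ACU]", V = "[ACG]", N = "[ACGU]")
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  unknown <- setdiff(chars, names(map))
  if (length(unknown)) {
    az_stop("az_invalid_alphabet", "unknown IUPAC code(s): %s",
            paste(unknown, collapse = ", "))
  }
  paste0(map[chars], collapse = "")
}

# Run fn with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
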