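# Cross-library shared-sequence analysis, positional consensus matrices,
# and motif-conditioned activity contrasts.

#' Count library membership of designed variable loops
#'
#' For every design (a variable-loop sequence at a given loop position),
#' counts in how many of the supplied designed libraries it appears.
#' Identity includes the loop position: the same sequence on loop I and on
#' loop II are distinct designs.
#'
#' @param libraries named list; each element is a data frame with columns
#'   `variable_loop` and `variable_position` (`"I"`/`"II"`), or a character
#'   vector of `"position:sequence"` keys.
#' @return data frame with columns `variable_position`, `variable_loop`,
#'   `n_libraries`, sorted by decreasing `n_libraries`.
#' @export
shared_membership <- function(libraries) {
  if (length(libraries) < 2L) {
    az_stop("az_shape_error", "need at least 2 libraries")
  }
  keysets <- lapply(libraries, function(lib) {
    keys <- if (is.character(lib)) {
      lib
    } else {
      paste(lib$variable_position, lib$variable_loop, sep = ":")
    }
    if (!length(keys)) az_stop("az_empty_library", "a library is empty")
    unique(keys)
  })
  tab <- table(unlist(keysets))
  parts <- strsplit(names(tab), ":", fixed = TRUE)
  out <- data.frame(
    variable_position = vapply(parts, `[`, character(1), 1L),
    variable_loop = vapply(parts, `[`, character(1), 2L),
    n_libraries = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_libraries, out$variable_position, out$variable_loop), ]
  rownames(out) <- NULL
  out
}

#' Positional consensus matrix
#'
#' 5'-anchored per-position nucleotide frequencies of a sequence set.
#' Sequences shorter than the longest contribute gap mass at their missing
#' tail positions, so every column sums to 1.
#'
#' @param seqs character vector of RNA sequences.
#' @return numeric matrix with rows `A`, `C`, `G`, `U`, `-` (gap) and one
#'   column per position.
#' @export
consensus_matrix <- function(seqs) {
  if (!length(seqs)) az_stop("az_empty_input", "no sequences")
  seqs <- normalize_rna(seqs)
  L <- max(nchar(seqs))
  mat <- matrix(0, nrow = 5L, ncol = L,
                dimnames = list(c(AZ_NT, "-"), paste0("pos", seq_len(L))))
  chars <- seq_chars(seqs)
  for (s in chars) {
    padded <- c(s, rep("-", L - length(s)))
    for (j in seq_len(L)) {
      mat[padded[j], j] <- mat[padded[j], j] + 1
    }
  }
  mat / length(seqs)
}

#' Motif-conditioned activity contrast
#'
#' Compares the activity of training-set ribozymes whose designated loop
#' contains a motif (IUPAC degenerate codes supported, e.g. `"UGGAR"`)
#' against all remaining ribozymes, with a two-sided Wilcoxon rank-sum test.
#'
#' @param records data frame with columns `loop1`, `loop2`, `activity`.
#' @param motif IUPAC motif string.
#' @param loop `"I"` or `"II"` — which loop is scanned for the motif.
#' @return list with `matched_mean`, `background_mean`, `difference`,
#'   `p_value`, `n_matched`, `n_background`.
#' @export
motif_activity_contrast <- function(records, motif, loop = c("II", "I")) {
  loop <- match.arg(loop)
  seqs <- if (loop == "I") records$loop1 else records$loop2
  hit <- grepl(iupac_to_regex(motif), seqs)
  if (!any(hit)) az_stop("az_no_match", "motif '%s' matches no record", motif)
  matched <- records$activity[hit]
  background <- records$activity[!hit]
  if (!length(background)) {
    # motif present everywhere: contrast degenerates to the overall mean
    return(list(matched_mean = mean(matched), background_mean = mean(matched),
                difference = 0, p_value = 1, n_matched = length(matched),
                n_background = 0L))
  }
  test <- suppressWarnings(wilcox.test(matched, background, exact = FALSE))
  list(matched_mean = mean(matched), background_mean = mean(background),
       difference = mean(matched) - mean(background),
       p_value = test$p.value,
       n_matched = length(matched), n_background = length(background))
}
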