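#' Predict RNA secondary structure
#'
#' Returns the predicted secondary structure of one or more RNA sequences as
#' dot-bracket strings. Two backends are available:
#'
#' * `"rnafold"` (default): the ViennaRNA `RNAfold` command-line program,
#'   a thermodynamic minimum-free-energy predictor. Requires `RNAfold` on
#'   the `PATH`; raises `az_backend_error` otherwise.
#' * `"nussinov"`: a built-in deterministic maximum base-pairing folder
#'   (Watson-Crick + GU, minimum hairpin loop of 3) useful for fast,
#'   dependency-free testing and for folding short loop inserts. It ignores
#'   stacking thermodynamics, so its full-length structures are cruder than
#'   MFE structures.
#'
#' Both backends are deterministic for a fixed sequence and version.
#'
#' @param sequence character vector of RNA sequences (T mapped to U).
#' @param backend `"rnafold"` or `"nussinov"`.
#' @param max_len maximum sequence length accepted (guards against runaway
#'   cubic-time folding); longer input raises `az_input_too_long`.
#' @param min_loop minimum hairpin loop size for the Nussinov backend.
#' @return for a single sequence, an `az_structure` (list with `sequence`,
#'   `dot_bracket`, `backend`); for several, a list of them.
#' @examples
#' fold("GGGGAAAACCCC", backend = "nussinov")$dot_bracket
#' @export
fold <- function(sequence, backend = c("rnafold", "nussinov"),
                 max_len = 300L, min_loop = 3L) {
  backend <- match.arg(backend)
  sequence <- normalize_rna(sequence)
  if (!length(sequence)) az_stop("az_empty_input", "no sequences to fold")
  too_long <- nchar(sequence) > max_len
  if (any(too_long)) {
    az_stop("az_input_too_long", "sequence of length %d exceeds max_len = %d",
            max(nchar(sequence)), max_len)
  }
  db <- switch(backend,
    nussinov = nussinov_fold_cpp(sequence, as.integer(min_loop)),
    rnafold = rnafold_run(sequence)
  )
  out <- Map(function(s, d) {
    structure(list(sequence = s, dot_bracket = d, backend = backend),
              class = "az_structure")
  }, sequence, db)
  names(out) <- NULL
  if (length(out) == 1L) out[[1]] else out
}

#' @export
print.az_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, "  [", x$backend, "]\n", sep = "")
  invisible(x)
}

rnafold_run <- function(sequences) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    az_stop("az_backend_error", "RNAfold executable not found on PATH")
  }
  out <- suppressWarnings(
    system2(exe, args = c("--noPS"), input = sequences, stdout = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    az_stop("az_backend_error", "RNAfold exited with status %d", status)
  }
  # output alternates sequence / "structure ( energy)"
  struct_lines <- out[seq(2, length(out), by = 2)]
  db <- sub("^([.()]+).*$", "\\1", struct_lines)
  if (length(db) != length(sequences) || any(nchar(db) != nchar(sequences))) {
    az_stop("az_backend_error", "could not parse RNAfold output")
  }
  db
}

# Partner table from a dot-bracket string: integer vector, pt[i] = index of
# the partner of position i, or 0 if unpaired. Errors on unbalanced input.
pair_table <- function(dot_bracket) {
  chars <- strsplit(dot_bracket, "", fixed = TRUE)[[1]]
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) az_stop("az_shape_error", "unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    } else if (chars[i] != ".") {
      az_stop("az_shape_error", "dot-bracket contains '%s'", chars[i])
    }
  }
  if (length(stack)) az_stop("az_shape_error", "unbalanced dot-bracket")
  pt
}
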