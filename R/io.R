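# File formats: FASTA for constructs, TSV for count/activity tables.

#' Write construct sequences to FASTA
#'
#' @param sequences character vector of RNA sequences.
#' @param path output file.
#' @param names sequence names (default `seq_1`, `seq_2`, ...).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, names = NULL) {
  if (is.null(names)) names <- paste0("seq_", seq_along(sequences))
  set <- Biostrings::RNAStringSet(sequences)
  names(set) <- names
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences (T mapped to U).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- normalize_rna(as.character(set))
  names(out) <- names(set)
  out
}

#' Read / write tab-separated tables
#'
#' Thin wrappers fixing the dialect used throughout the package (header,
#' tab separator, no quoting, no row names).
#'
#' @param path file path.
#' @param table a data frame.
#' @return `read_tsv_table` returns a data frame; `write_tsv_table` returns
#'   `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export / import an encoded feature matrix
#'
#' The array is stored as a serialized R object with a JSON sidecar
#' (`<path>.json`) describing shape, channel order and grid geometry, so
#' downstream runs can verify encoder compatibility without loading the
#' data.
#'
#' @param X encoded matrix from [batch_encode()] or [encode_loop_pairs()].
#' @param path output file; the sidecar is written next to it.
#' @return `export_tensor` returns `path` invisibly; `import_tensor`
#'   returns the matrix with its encoder metadata.
#' @export
export_tensor <- function(X, path) {
  meta <- attr(X, "encoder")
  if (is.null(meta)) az_stop("az_metadata_error", "matrix lacks encoder metadata")
  saveRDS(X, path)
  jsonlite::write_json(c(list(n = nrow(X), n_features = ncol(X)), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname export_tensor
#' @export
import_tensor <- function(path) {
  X <- readRDS(path)
  if (is.null(attr(X, "encoder"))) {
    az_stop("az_metadata_error", "'%s' does not contain an encoded matrix", path)
  }
  X
}

#' Write a bin scheme to JSON / read it back
#'
#' @param scheme an `az_bin_scheme`.
#' @param path JSON file path.
#' @return `read_bin_scheme` returns an `az_bin_scheme`.
#' @export
write_bin_scheme <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bin_scheme
#' @export
read_bin_scheme <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n_bins = as.integer(raw$n_bins),
                 boundaries = as.numeric(raw$boundaries)),
            class = "az_bin_scheme")
}
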