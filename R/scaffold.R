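#' Read a ribozyme scaffold definition
#'
#' A scaffold is the fixed part of a hammerhead ribozyme construct: ordered
#' sequence blocks (5' spacer, stem-I arms, catalytic core, stem-II arms,
#' core continuation, 3' spacer) with two loop-insertion sites between the
#' arms of stems I and II. The bundled `sTRSV` fixture carries the
#' literature-derived 52-nt sTRSV hammerhead; it is a plain JSON file and can
#' be copied and edited to change spacers or stems.
#'
#' The assembled layout, 5' to 3', is
#' `spacer5 | stem1_5p | loop1 | stem1_3p | core | stem2_5p | loop2 |
#' stem2_3p | core3 | spacer3`.
#'
#' @param path path to a scaffold JSON file, or the name of a bundled
#'   scaffold (currently `"sTRSV"`).
#' @return an object of class `az_scaffold`.
#' @examples
#' sc <- read_scaffold()
#' sc$default_stem1_len
#' @export
read_scaffold <- function(path = "sTRSV") {
  if (!file.exists(path)) {
    bundled <- system.file("extdata", paste0("scaffold_", path, ".json"),
                           package = "aptazyme")
    if (!nzchar(bundled)) {
      az_stop("az_io_error", "scaffold '%s' not found (no such file or bundled fixture)", path)
    }
    path <- bundled
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- lapply(raw$segments, function(s) normalize_rna(s, "scaffold segment"))
  required <- c("spacer5", "stem1_5p", "stem1_3p", "core",
                "stem2_5p", "stem2_3p", "core3", "spacer3")
  missing <- setdiff(required, names(segs))
  if (length(missing)) {
    az_stop("az_io_error", "scaffold file lacks segment(s): %s",
            paste(missing, collapse = ", "))
  }
  if (segs$stem1_5p != rna_revcomp(segs$stem1_3p)) {
    az_stop("az_io_error", "stem-I arms are not reverse complements")
  }
  if (segs$stem2_5p != rna_revcomp(segs$stem2_3p)) {
    az_stop("az_io_error", "stem-II arms are not reverse complements")
  }
  sc <- list(
    name = raw$name,
    segments = segs,
    default_stem1_len = as.integer(raw$default_stem1_len %||% nchar(segs$stem1_5p)),
    default_stem2_len = as.integer(raw$default_stem2_len %||% nchar(segs$stem2_5p)),
    native_loops = raw$native_loops,
    native_full_sequence = if (!is.null(raw$native_full_sequence))
      normalize_rna(raw$native_full_sequence) else NULL
  )
  class(sc) <- "az_scaffold"
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.az_scaffold <- function(x, ...) {
  cat(sprintf("<az_scaffold '%s'> stem I %d bp, stem II %d bp, fixed length %d nt\n",
              x$name, x$default_stem1_len, x$default_stem2_len,
              sum(nchar(unlist(x$segments)))))
  invisible(x)
}

# 0-based half-open coordinates of the two insert sites and arm blocks for a
# construct with the given insert lengths.
scaffold_coords <- function(scaffold, n1, n2) {
  s <- scaffold$segments
  lens <- nchar(unlist(s[c("spacer5", "stem1_5p")]))
  loop1_start <- sum(lens)                      # 0-based
  stem1_3p_start <- loop1_start + n1
  core_start <- stem1_3p_start + nchar(s$stem1_3p)
  stem2_5p_start <- core_start + nchar(s$core)
  loop2_start <- stem2_5p_start + nchar(s$stem2_5p)
  stem2_3p_start <- loop2_start + n2
  list(
    stem1_5p = c(loop1_start - nchar(s$stem1_5p), loop1_start),
    loop1 = c(loop1_start, loop1_start + n1),
    stem1_3p = c(stem1_3p_start, stem1_3p_start + nchar(s$stem1_3p)),
    stem2_5p = c(loop2_start - nchar(s$stem2_5p), loop2_start),
    loop2 = c(loop2_start, loop2_start + n2),
    stem2_3p = c(stem2_3p_start, stem2_3p_start + nchar(s$stem2_3p)),
    total = stem2_3p_start + nchar(s$stem2_3p) + nchar(s$core3) + nchar(s$spacer3)
  )
}

#' Assemble a full ribozyme construct from two loop inserts
#'
#' Inserts `loop1_insert` and `loop2_insert` into the scaffold's two
#' insertion sites. `T` is silently mapped to `U` and lowercase is
#' uppercased; any other non-nucleotide character raises
#' `az_invalid_alphabet`, and an empty insert raises `az_invalid_loop`.
#'
#' @param loop1_insert,loop2_insert RNA strings inserted as loops I and II.
#' @param scaffold an `az_scaffold` (default: bundled sTRSV).
#' @return an object of class `az_construct` with fields `full_sequence`,
#'   `loop1_insert`, `loop2_insert`, `scaffold_name`.
#' @examples
#' con <- assemble("GUGA", "ACAA")
#' nchar(con$full_sequence)
#' @export
assemble <- function(loop1_insert, loop2_insert, scaffold = read_scaffold()) {
  if (!nzchar(loop1_insert) || !nzchar(loop2_insert)) {
    az_stop("az_invalid_loop", "loop inserts must be nonempty")
  }
  l1 <- normalize_rna(loop1_insert, "loop1 insert")
  l2 <- normalize_rna(loop2_insert, "loop2 insert")
  s <- scaffold$segments
  full <- paste0(s$spacer5, s$stem1_5p, l1, s$stem1_3p, s$core,
                 s$stem2_5p, l2, s$stem2_3p, s$core3, s$spacer3)
  structure(list(
    loop1_insert = l1,
    loop2_insert = l2,
    full_sequence = full,
    scaffold_name = scaffold$name
  ), class = "az_construct")
}

#' Recover the loop inserts from a full construct sequence
#'
#' Slices the assembled sequence at the scaffold's insertion sites. The two
#' insert lengths must be supplied (the fixed blocks determine everything
#' else).
#'
#' @param full_sequence assembled RNA string.
#' @param n1,n2 lengths of the loop-I and loop-II inserts.
#' @param scaffold an `az_scaffold`.
#' @return list with elements `loop1` and `loop2`.
#' @export
slice_inserts <- function(full_sequence, n1, n2, scaffold = read_scaffold()) {
  co <- scaffold_coords(scaffold, n1, n2)
  if (nchar(full_sequence) != co$total) {
    az_stop("az_shape_error", "sequence length %d does not match scaffold + insert lengths (%d)",
            nchar(full_sequence), co$total)
  }
  list(
    loop1 = substr(full_sequence, co$loop1[1] + 1, co$loop1[2]),
    loop2 = substr(full_sequence, co$loop2[1] + 1, co$loop2[2])
  )
}
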