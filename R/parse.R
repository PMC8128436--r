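# Stem-loop parsing: turn a predicted secondary structure into the two
# stem-loop descriptions that feed the encoder.

new_stemloop <- function(which, stem_len, stem5_seq, stem3_seq, loop_seq,
                         paired_flags, branch_stems, loop_positions) {
  structure(list(
    which = which,
    stem_len = stem_len,
    stem5_seq = stem5_seq,        # base -> loop, 5' strand side
    stem3_seq = stem3_seq,        # base -> loop, 3' strand side
    loop_seq = loop_seq,
    paired_flags = paired_flags,  # one flag per loop position (branch-stem pairing)
    branch_stems = branch_stems,  # list of list(open=, close=) index vectors (loop-local)
    loop_positions = loop_positions  # 1-based indices into the full sequence, or NULL
  ), class = "az_stemloop")
}

#' @export
print.az_stemloop <- function(x, ...) {
  cat(sprintf("<az_stemloop %s> stem %d bp, loop %d nt (%s), %d branch stem(s)\n",
              x$which, x$stem_len, nchar(x$loop_seq), x$loop_seq,
              length(x$branch_stems)))
  invisible(x)
}

# Given the insert-local pair table (0 = unpaired), how many contiguous
# outermost pairs (k, n+1-k) stack directly on the scaffold stem?
insert_stem_extension <- function(pt) {
  n <- length(pt)
  ext <- 0L
  k <- 1L
  while (k <= n - k && pt[k] == n + 1L - k) {
    ext <- ext + 1L
    k <- k + 1L
  }
  ext
}

# Extract branch helices from pairing among loop-local positions.
branch_stems_from_pt <- function(pt) {
  n <- length(pt)
  stems <- list()
  open <- which(pt > seq_len(n))
  if (!length(open)) return(stems)
  cur_open <- integer(0); cur_close <- integer(0)
  for (i in open) {
    j <- pt[i]
    if (length(cur_open) &&
        i == cur_open[length(cur_open)] + 1L &&
        j == cur_close[length(cur_close)] - 1L) {
      cur_open <- c(cur_open, i); cur_close <- c(cur_close, j)
    } else {
      if (length(cur_open)) stems[[length(stems) + 1L]] <-
          list(open = cur_open, close = rev(cur_close))
      cur_open <- i; cur_close <- j
    }
  }
  stems[[length(stems) + 1L]] <- list(open = cur_open, close = rev(cur_close))
  stems
}

# Build one stem-loop from scaffold arms plus the insert-local pair table.
stemloop_from_insert <- function(which, arm5, arm3, insert, pt_local,
                                 loop_offset = NA_integer_) {
  ins <- strsplit(insert, "", fixed = TRUE)[[1]]
  n <- length(ins)
  ext <- insert_stem_extension(pt_local)
  loop_idx <- if (ext < n - ext) seq(ext + 1L, n - ext) else integer(0)
  loop_chars <- ins[loop_idx]
  # pair table restricted to the loop region, loop-local indices
  pt_loop <- pt_local[loop_idx]
  inside <- pt_loop %in% loop_idx
  pt_loop[!inside] <- 0L
  pt_loop[inside] <- match(pt_loop[inside], loop_idx)
  new_stemloop(
    which = which,
    stem_len = nchar(arm5) + ext,
    stem5_seq = paste0(arm5, paste0(ins[seq_len(ext)], collapse = "")),
    stem3_seq = paste0(
      paste0(rev(strsplit(arm3, "", fixed = TRUE)[[1]]), collapse = ""),
      paste0(ins[n + 1L - seq_len(ext)], collapse = "")
    ),
    loop_seq = paste0(loop_chars, collapse = ""),
    paired_flags = pt_loop > 0L,
    branch_stems = branch_stems_from_pt(pt_loop),
    loop_positions = if (is.na(loop_offset)) NULL else loop_offset + loop_idx - 1L
  )
}

#' Parse the two stem-loops of a folded ribozyme construct
#'
#' Interprets a predicted secondary structure of an assembled construct in
#' terms of the scaffold: checks that both scaffold stems are formed,
#' credits contiguous insert-edge pairs that stack on a scaffold stem as
#' stem extensions, and records pairing within each loop (branch stems).
#'
#' If either scaffold stem is broken in the structure, or a loop nucleotide
#' pairs with a position outside its own loop, the construct is flagged as
#' misfolded (`$misfolded = TRUE`) instead of raising an error; misfolded
#' constructs are excluded from encoding and training.
#'
#' @param construct an `az_construct` from [assemble()].
#' @param structure an `az_structure` for the construct's full sequence
#'   (from [fold()]). Ignored when `mode = "loop"`.
#' @param scaffold the `az_scaffold` used for assembly.
#' @param mode `"full"` parses a full-sequence structure; `"loop"` folds
#'   each loop insert independently (closed-stem approximation: the
#'   scaffold stems are taken as formed and only intra-insert pairing is
#'   predicted). Loop mode is fast and is used for large design libraries.
#' @param backend folding backend for `mode = "loop"`.
#' @return list with elements `sl1`, `sl2` (class `az_stemloop`) and
#'   `misfolded` (logical; when `TRUE`, `sl1`/`sl2` are `NULL` and `reason`
#'   says why).
#' @export
parse_stemloops <- function(construct, structure = NULL,
                            scaffold = read_scaffold(),
                            mode = c("full", "loop"),
                            backend = "nussinov") {
  mode <- match.arg(mode)
  s <- scaffold$segments
  n1 <- nchar(construct$loop1_insert)
  n2 <- nchar(construct$loop2_insert)
  co <- scaffold_coords(scaffold, n1, n2)

  if (mode == "loop") {
    pt1 <- pair_table(fold(construct$loop1_insert, backend = backend)$dot_bracket)
    pt2 <- pair_table(fold(construct$loop2_insert, backend = backend)$dot_bracket)
    sl1 <- stemloop_from_insert("I", s$stem1_5p, s$stem1_3p,
                                construct$loop1_insert, pt1, co$loop1[1] + 1L)
    sl2 <- stemloop_from_insert("II", s$stem2_5p, s$stem2_3p,
                                construct$loop2_insert, pt2, co$loop2[1] + 1L)
    return(list(sl1 = sl1, sl2 = sl2, misfolded = FALSE, reason = NULL))
  }

  if (is.null(structure)) {
    az_stop("az_shape_error", "mode = 'full' requires a folded structure")
  }
  if (structure$sequence != construct$full_sequence) {
    az_stop("az_shape_error", "structure sequence does not match construct")
  }
  pt <- pair_table(structure$dot_bracket)

  stem_ok <- function(arm5_rng, arm3_rng) {
    a5 <- seq(arm5_rng[1] + 1L, arm5_rng[2])
    a3 <- seq(arm3_rng[1] + 1L, arm3_rng[2])
    all(pt[a5] == rev(a3))
  }
  if (!stem_ok(co$stem1_5p, co$stem1_3p)) {
    return(list(sl1 = NULL, sl2 = NULL, misfolded = TRUE,
                reason = "scaffold stem I broken in predicted structure"))
  }
  if (!stem_ok(co$stem2_5p, co$stem2_3p)) {
    return(list(sl1 = NULL, sl2 = NULL, misfolded = TRUE,
                reason = "scaffold stem II broken in predicted structure"))
  }

  local_pt <- function(loop_rng) {
    idx <- if (loop_rng[2] > loop_rng[1]) seq(loop_rng[1] + 1L, loop_rng[2]) else integer(0)
    ptl <- pt[idx]
    outside <- ptl != 0L & !(ptl %in% idx)
    if (any(outside)) return(NULL)  # loop pairs with the rest of the molecule
    ptl[ptl != 0L] <- match(ptl[ptl != 0L], idx)
    ptl
  }
  ptl1 <- local_pt(co$loop1)
  ptl2 <- local_pt(co$loop2)
  if (is.null(ptl1) || is.null(ptl2)) {
    return(list(sl1 = NULL, sl2 = NULL, misfolded = TRUE,
                reason = "loop nucleotides pair outside their stem-loop"))
  }
  sl1 <- stemloop_from_insert("I", s$stem1_5p, s$stem1_3p,
                              construct$loop1_insert, ptl1, co$loop1[1] + 1L)
  sl2 <- stemloop_from_insert("II", s$stem2_5p, s$stem2_3p,
                              construct$loop2_insert, ptl2, co$loop2[1] + 1L)
  list(sl1 = sl1, sl2 = sl2, misfolded = FALSE, reason = NULL)
}

#' Structural segment key of a stem-loop pair
#'
#' Ribozymes sharing stem lengths, loop lengths and branch-stem presence for
#' both stem-loops form a structural segment; segments are the unit of the
#' structure-stratified hold-out in [segment_holdout()].
#'
#' @param sl1,sl2 `az_stemloop` objects for stem-loops I and II.
#' @return an `az_structure_key`; its character representation
#'   (`format()`/`as.character()`) is `"S<stem1>.<stem2>|L<loop1>.<loop2>|B<b1><b2>"`.
#' @export
structure_key <- function(sl1, sl2) {
  k <- list(
    stem1_len = sl1$stem_len, stem2_len = sl2$stem_len,
    loop1_len = nchar(sl1$loop_seq), loop2_len = nchar(sl2$loop_seq),
    branch1 = length(sl1$branch_stems) > 0L,
    branch2 = length(sl2$branch_stems) > 0L
  )
  class(k) <- "az_structure_key"
  k
}

#' @export
format.az_structure_key <- function(x, ...) {
  sprintf("S%d.%d|L%d.%d|B%d%d", x$stem1_len, x$stem2_len,
          x$loop1_len, x$loop2_len, as.integer(x$branch1), as.integer(x$branch2))
}

#' @export
as.character.az_structure_key <- function(x, ...) format(x)

#' @export
print.az_structure_key <- function(x, ...) {
  cat("<az_structure_key>", format(x), "\n")
  invisible(x)
}
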