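# Plumbing between modules: encode whole loop-pair tables for training and
# annotate construct tables with structure information.

# Parse one insert into a stem-loop (closed-stem approximation), memoised.
insert_stemloop <- function(insert, which, scaffold, backend,
                            cache = NULL, pt = NULL) {
  key <- paste("sl", which, insert, backend, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  arm5 <- if (which == "I") scaffold$segments$stem1_5p else scaffold$segments$stem2_5p
  arm3 <- if (which == "I") scaffold$segments$stem1_3p else scaffold$segments$stem2_3p
  if (is.null(pt)) pt <- pair_table(fold(insert, backend = backend)$dot_bracket)
  sl <- stemloop_from_insert(which, arm5, arm3, insert, pt)
  if (!is.null(cache)) cache[[key]] <- sl
  sl
}

#' Encode a table of loop pairs for model training
#'
#' Folds every unique insert in the closed-stem approximation (each loop
#' insert folded independently, the scaffold stems taken as formed), parses
#' the stem-loops, and encodes all pairs into one feature matrix. Records
#' whose encoding walk exceeds `L_max` are skipped and reported.
#'
#' @param loop1,loop2 character vectors of loop inserts.
#' @param scaffold an `az_scaffold`.
#' @param L_max rows per stem-loop grid.
#' @param stem_depth row-alignment convention (see [encode_stemloop()]);
#'   `NULL` anchors at the stem base, an integer anchors the loop interface
#'   at a fixed row.
#' @param backend folding backend for the insert folds.
#' @return list with `X` (feature matrix with encoder metadata), `kept`
#'   (indices of encoded records), `skipped`, and `keys` (structure key
#'   strings for the kept records).
#' @export
encode_loop_pairs <- function(loop1, loop2, scaffold = read_scaffold(),
                              L_max = 16L, stem_depth = NULL,
                              backend = "nussinov") {
  stopifnot(length(loop1) == length(loop2))
  n <- length(loop1)
  if (!n) az_stop("az_empty_batch", "no records to encode")
  loop1 <- normalize_rna(loop1, "loop1")
  loop2 <- normalize_rna(loop2, "loop2")

  encode_side <- function(loops, which) {
    uniq <- unique(loops)
    structs <- fold(uniq, backend = backend)
    if (length(uniq) == 1L) structs <- list(structs)
    sls <- lapply(seq_along(uniq), function(i) {
      insert_stemloop(uniq[i], which, scaffold, backend,
                      pt = pair_table(structs[[i]]$dot_bracket))
    })
    grids <- lapply(sls, function(sl) {
      tryCatch(as.vector(encode_stemloop(sl, L_max, stem_depth)),
               az_encoding_overflow = function(e) NULL)
    })
    stats <- t(vapply(sls, function(sl) {
      c(stem = sl$stem_len, loop = nchar(sl$loop_seq),
        branch = as.integer(length(sl$branch_stems) > 0))
    }, integer(3)))
    idx <- match(loops, uniq)
    list(grids = grids, stats = stats, idx = idx)
  }

  s1 <- encode_side(loop1, "I")
  s2 <- encode_side(loop2, "II")
  ok1 <- !vapply(s1$grids, is.null, logical(1))[s1$idx]
  ok2 <- !vapply(s2$grids, is.null, logical(1))[s2$idx]
  kept <- which(ok1 & ok2)
  if (!length(kept)) az_stop("az_empty_batch", "every record overflowed L_max = %d", L_max)

  D <- L_max * 32L
  colsI <- stemloop_columns(L_max, 1L)
  colsII <- stemloop_columns(L_max, 2L)
  g1 <- do.call(rbind, s1$grids[s1$idx[kept]])
  g2 <- do.call(rbind, s2$grids[s2$idx[kept]])
  X <- matrix(0, length(kept), D)
  X[, colsI] <- g1
  X[, colsII] <- g2
  attr(X, "encoder") <- encoder_meta(L_max, stem_depth)

  st1 <- s1$stats[s1$idx[kept], , drop = FALSE]
  st2 <- s2$stats[s2$idx[kept], , drop = FALSE]
  keys <- sprintf("S%d.%d|L%d.%d|B%d%d",
                  st1[, "stem"], st2[, "stem"],
                  st1[, "loop"], st2[, "loop"],
                  st1[, "branch"], st2[, "branch"])

  list(X = X, kept = kept, skipped = setdiff(seq_len(n), kept), keys = keys)
}

#' Fold and annotate a table of constructs
#'
#' Assembles each loop pair on the scaffold, predicts the full-sequence
#' structure, parses the stem-loops and reports the dot-bracket, structure
#' key and misfold flag per record — the per-construct table written by the
#' structure step of the pipeline.
#'
#' @param loop1,loop2 character vectors of loop inserts.
#' @param scaffold an `az_scaffold`.
#' @param backend folding backend for the full-sequence fold.
#' @return data frame with `loop1`, `loop2`, `full_sequence`,
#'   `dot_bracket`, `structure_key`, `misfolded`.
#' @export
annotate_constructs <- function(loop1, loop2, scaffold = read_scaffold(),
                                backend = "rnafold") {
  stopifnot(length(loop1) == length(loop2))
  cons <- Map(assemble, loop1, loop2, MoreArgs = list(scaffold = scaffold))
  full <- vapply(cons, `[[`, character(1), "full_sequence")
  structs <- fold(full, backend = backend)
  if (length(full) == 1L) structs <- list(structs)
  rows <- Map(function(con, st) {
    pr <- parse_stemloops(con, st, scaffold, mode = "full")
    data.frame(
      loop1 = con$loop1_insert, loop2 = con$loop2_insert,
      full_sequence = con$full_sequence, dot_bracket = st$dot_bracket,
      structure_key = if (pr$misfolded) NA_character_
                      else format(structure_key(pr$sl1, pr$sl2)),
      misfolded = pr$misfolded, stringsAsFactors = FALSE
    )
  }, cons, structs)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
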