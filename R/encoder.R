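# Binary structural encoding of stem-loop pairs.
#
# Tensor axes: (row, side, stemloop, channel) with
#   row      1..L_max, row 1 at the stem base (closest to the catalytic core),
#   side     1 = 5' strand, 2 = 3' strand,
#   stemloop 1 = stem-loop I, 2 = stem-loop II,
#   channel  8 = (A,C,G,U) unpaired then (A,C,G,U) paired.
# Flattened feature vectors use R's column-major order over these axes;
# models record this layout in their metadata and refuse mismatched input.

AZ_CHANNELS <- c("A.unpaired", "C.unpaired", "G.unpaired", "U.unpaired",
                 "A.paired", "C.paired", "G.paired", "U.paired")
AZ_NT <- c("A", "C", "G", "U")

encoder_meta <- function(L_max, stem_depth = NULL) {
  list(L_max = as.integer(L_max), channels = AZ_CHANNELS,
       stem_depth = if (is.null(stem_depth)) NULL else as.integer(stem_depth),
       layout = "row,side,stemloop,channel (column-major)")
}

#' Encode one stem-loop as a binary grid
#'
#' Stem base pairs occupy both strand sides at the same row with paired
#' channels; loop nucleotides then walk up the 5' side to the apex and down
#' the 3' side (for a loop of n nucleotides the 5' side receives
#' `ceiling(n/2)`, the 3' side `floor(n/2)`). Nucleotides inside branch
#' stems carry paired channels. Rows beyond the walk are all-zero.
#'
#' Two row-alignment conventions are available. The default anchors the
#' stem base at row 1 and lets the loop start wherever the stem ends. With
#' `stem_depth` set, the grid is instead anchored at the loop interface:
#' the innermost stem pair sits at row `stem_depth` (stems longer than
#' `stem_depth` are truncated at the base) and the loop walk always starts
#' at row `stem_depth + 1`, so apposed loop nucleotides of the two
#' stem-loops share a row regardless of stem length or stem extensions —
#' the registration the loop-loop docking interface actually has. Models
#' record the convention in their metadata.
#'
#' @param sl an `az_stemloop`.
#' @param L_max number of rows; the walk must satisfy
#'   `stem_rows + ceiling(loop_len/2) <= L_max`, otherwise an
#'   `az_encoding_overflow` error is raised.
#' @param stem_depth `NULL` for stem-base anchoring (default), or the fixed
#'   row of the innermost stem pair for loop-interface anchoring.
#' @return binary array of dimension `c(L_max, 2, 8)` with an occupancy
#'   `mask` attribute of dimension `c(L_max, 2)`.
#' @export
encode_stemloop <- function(sl, L_max = 16L, stem_depth = NULL) {
  nl <- nchar(sl$loop_seq)
  n_up <- ceiling(nl / 2)
  loop_base <- if (is.null(stem_depth)) sl$stem_len else as.integer(stem_depth)
  if (loop_base + n_up > L_max) {
    az_stop("az_encoding_overflow",
            "walk of %d rows exceeds L_max = %d (stem %d bp, loop %d nt)",
            loop_base + n_up, L_max, sl$stem_len, nl)
  }
  g <- array(0, dim = c(L_max, 2L, 8L),
             dimnames = list(NULL, c("side5", "side3"), AZ_CHANNELS))
  mask <- array(FALSE, dim = c(L_max, 2L))
  put <- function(row, side, nt, paired) {
    ch <- match(nt, AZ_NT) + if (paired) 4L else 0L
    g[row, side, ch] <<- 1
    mask[row, side] <<- TRUE
  }
  s5 <- strsplit(sl$stem5_seq, "", fixed = TRUE)[[1]]
  s3 <- strsplit(sl$stem3_seq, "", fixed = TRUE)[[1]]
  # stem rows: base -> loop; under loop anchoring the innermost pair is at
  # row loop_base and over-deep stem bases are truncated
  n_stem <- min(sl$stem_len, loop_base)
  for (k in seq_len(n_stem)) {
    r <- loop_base - n_stem + k
    put(r, 1L, s5[sl$stem_len - n_stem + k], TRUE)
    put(r, 2L, s3[sl$stem_len - n_stem + k], TRUE)
  }
  lp <- strsplit(sl$loop_seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nl)) {
    if (i <= n_up) {
      put(loop_base + i, 1L, lp[i], sl$paired_flags[i])
    } else {
      put(loop_base + (nl - i + 1L), 2L, lp[i], sl$paired_flags[i])
    }
  }
  attr(g, "mask") <- mask
  g
}

#' Encode a stem-loop pair as the model input tensor
#'
#' Stacks the two stem-loop grids along the stemloop axis (index 1 =
#' stem-loop I, 2 = stem-loop II), both indexed from the stem base at row 1,
#' mirroring the assumed spatial apposition of the two stem-loops.
#'
#' @param sl1,sl2 `az_stemloop` objects for stem-loops I and II.
#' @inheritParams encode_stemloop
#' @return binary array of dimension `c(L_max, 2, 2, 8)` with attributes
#'   `mask` (`c(L_max, 2, 2)`) and `encoder` (layout metadata).
#' @export
encode_pair <- function(sl1, sl2, L_max = 16L, stem_depth = NULL) {
  g1 <- encode_stemloop(sl1, L_max, stem_depth)
  g2 <- encode_stemloop(sl2, L_max, stem_depth)
  out <- array(0, dim = c(L_max, 2L, 2L, 8L),
               dimnames = list(NULL, c("side5", "side3"),
                               c("I", "II"), AZ_CHANNELS))
  out[, , 1L, ] <- g1
  out[, , 2L, ] <- g2
  mask <- array(FALSE, dim = c(L_max, 2L, 2L))
  mask[, , 1L] <- attr(g1, "mask")
  mask[, , 2L] <- attr(g2, "mask")
  attr(out, "mask") <- mask
  attr(out, "encoder") <- encoder_meta(L_max, stem_depth)
  out
}

# Column indices of stem-loop I / II cells inside the flattened feature
# vector of length L_max*2*2*8 (used to assemble design batches from cached
# per-stem-loop grids).
stemloop_columns <- function(L_max, which) {
  idx <- array(seq_len(L_max * 2L * 2L * 8L), dim = c(L_max, 2L, 2L, 8L))
  as.vector(idx[, , which, ])
}

#' Encode a batch of parsed stem-loop pairs
#'
#' @param pairs list of `list(sl1 = , sl2 = )` stem-loop pairs (e.g. the
#'   non-misfolded results of [parse_stemloops()]).
#' @param L_max rows per grid.
#' @param stem_depth row-alignment convention, see [encode_stemloop()].
#' @param on_overflow `"skip"` drops records whose walk exceeds `L_max`
#'   (reported in `skipped`); `"error"` raises `az_encoding_overflow`.
#' @return list with `X` (numeric matrix, one flattened tensor per row,
#'   `encoder` metadata attached as attribute), `kept` (indices into
#'   `pairs`), `skipped` (indices dropped for overflow).
#' @export
batch_encode <- function(pairs, L_max = 16L, stem_depth = NULL,
                         on_overflow = c("skip", "error")) {
  on_overflow <- match.arg(on_overflow)
  if (!length(pairs)) az_stop("az_empty_batch", "no records to encode")
  D <- L_max * 2L * 2L * 8L
  rows <- vector("list", length(pairs))
  kept <- logical(length(pairs))
  for (i in seq_along(pairs)) {
    res <- tryCatch(
      as.vector(encode_pair(pairs[[i]]$sl1, pairs[[i]]$sl2, L_max, stem_depth)),
      az_encoding_overflow = function(e) if (on_overflow == "skip") NULL else stop(e)
    )
    if (!is.null(res)) {
      rows[[i]] <- res
      kept[i] <- TRUE
    }
  }
  X <- do.call(rbind, rows[kept])
  if (is.null(X)) X <- matrix(numeric(0), nrow = 0, ncol = D)
  attr(X, "encoder") <- encoder_meta(L_max, stem_depth)
  list(X = X, kept = which(kept), skipped = which(!kept))
}
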