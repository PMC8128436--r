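# Forward design: graft an aptamer onto one loop, enumerate variable loops
# on the other, score with a trained model, select the lowest-predicted
# candidates.

#' Read aptamer definitions
#'
#' Loads aptamers (sequence, annotated dot-bracket, binding-bulge range,
#' allowed loop positions) from a JSON file. The bundled file
#' `aptamers_synthetic.json` provides constructed stand-ins for the five
#' aptamers used in switch design work (theophylline, tetracycline,
#' neomycin, chloramphenicol, folinic acid); they carry the literature core
#' motifs inside simplified architectures and are meant as editable
#' examples, not as the published full-length sequences.
#'
#' @param path JSON file; default is the bundled fixture.
#' @return named list of `az_aptamer` objects.
#' @export
read_aptamers <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aptamers_synthetic.json", package = "aptazyme")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- raw$aptamers
  out <- lapply(seq_len(nrow(entries)), function(i) {
    a <- list(
      name = entries$name[i],
      full_sequence = normalize_rna(entries$full_sequence[i], "aptamer sequence"),
      full_structure = entries$full_structure[i],
      binding_bulge = as.integer(entries$binding_bulge[[i]]),
      allowed_positions = as.character(entries$allowed_positions[[i]])
    )
    pair_table(a$full_structure)  # validates balance
    if (nchar(a$full_structure) != nchar(a$full_sequence)) {
      az_stop("az_annotation_error", "aptamer '%s': structure/sequence length mismatch",
              a$name)
    }
    class(a) <- "az_aptamer"
    a
  })
  names(out) <- entries$name
  out
}

#' @export
print.az_aptamer <- function(x, ...) {
  cat(sprintf("<az_aptamer '%s'> %d nt, bulge %d-%d\n", x$name,
              nchar(x$full_sequence), x$binding_bulge[1], x$binding_bulge[2]))
  invisible(x)
}

#' Derive the loop insert of an aptamer
#'
#' Removes the closing helix on the terminal side of the ligand-binding
#' bulge — the contiguous stack of outermost pairs `(1, n), (2, n-1), ...`
#' in the annotated structure — and returns the remaining nucleotides in
#' 5'-to-3' order. Grafting this insert onto a ribozyme stem makes the stem
#' take the role of the removed helix. `retained_pairs` keeps that many
#' closing pairs per side attached to the insert.
#'
#' @param aptamer an `az_aptamer`.
#' @param retained_pairs closing pairs to retain on each side (default 0).
#' @return RNA string.
#' @export
derive_loop_insert <- function(aptamer, retained_pairs = 0L) {
  n <- nchar(aptamer$full_sequence)
  pt <- pair_table(aptamer$full_structure)
  if (!any(pt > 0)) az_stop("az_no_bulge", "aptamer structure has no helix to remove")
  if (any(aptamer$binding_bulge < 1L) || any(aptamer$binding_bulge > n)) {
    az_stop("az_annotation_error", "binding bulge outside the aptamer sequence")
  }
  outer <- 0L
  while (outer + 1L <= n - outer - 1L && pt[outer + 1L] == n - outer) {
    outer <- outer + 1L
  }
  if (outer == 0L) az_stop("az_no_bulge", "no terminal closing helix found")
  if (!any(pt == 0L)) {
    az_stop("az_no_bulge", "structure has no internal loop or bulge")
  }
  cut <- outer - as.integer(retained_pairs)
  if (cut < 0L) cut <- 0L
  substr(aptamer$full_sequence, cut + 1L, n - cut)
}

# All RNA strings of the given length, in lexicographic (A<C<G<U) order.
all_loops_of_length <- function(len) {
  grid <- do.call(expand.grid,
                  c(rev(rep(list(AZ_NT), len)),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  do.call(paste0, rev(grid))
}

#' Enumerate the design candidate library for one aptamer
#'
#' Exhaustive, duplicate-free enumeration: the aptamer loop insert occupies
#' one loop and the variable loop runs over all sequences of the given
#' lengths, for each allowed aptamer position. The candidate count is
#' `length(positions) * sum(4^lengths)` (174,080 for the default N5--N8 on
#' both loops).
#'
#' @param aptamer an `az_aptamer`.
#' @param lengths variable-loop lengths (default 5:8).
#' @param positions loop positions the aptamer may occupy (default: the
#'   aptamer's `allowed_positions`).
#' @return data frame with columns `aptamer_name`, `aptamer_loop` (position
#'   of the aptamer), `variable_position`, `variable_loop`.
#' @export
enumerate_library <- function(aptamer, lengths = 5:8, positions = NULL) {
  if (!length(lengths)) az_stop("az_config_error", "empty length set")
  if (is.null(positions)) positions <- aptamer$allowed_positions
  positions <- match.arg(positions, c("I", "II"), several.ok = TRUE)
  var_loops <- unlist(lapply(sort(unique(as.integer(lengths))),
                             all_loops_of_length))
  out <- do.call(rbind, lapply(positions, function(p) {
    data.frame(
      aptamer_name = aptamer$name,
      aptamer_loop = p,
      variable_position = if (p == "I") "II" else "I",
      variable_loop = var_loops,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

# ---- scoring ---------------------------------------------------------------

# Flattened stem-loop grid for an insert at loop `which`, folding the insert
# in the closed-stem approximation; NULL when the walk exceeds L_max.
# Results are memoised in `cache` (an environment) across candidates and
# aptamers.
insert_grid <- function(insert, which, scaffold, L_max, backend,
                        cache = NULL, stem_depth = NULL) {
  key <- paste(which, insert, L_max, backend,
               if (is.null(stem_depth)) "base" else stem_depth, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) {
    g <- cache[[key]]
    return(if (identical(g, NA)) NULL else g)
  }
  arm5 <- if (which == "I") scaffold$segments$stem1_5p else scaffold$segments$stem2_5p
  arm3 <- if (which == "I") scaffold$segments$stem1_3p else scaffold$segments$stem2_3p
  pt <- pair_table(fold(insert, backend = backend)$dot_bracket)
  sl <- stemloop_from_insert(which, arm5, arm3, insert, pt)
  g <- tryCatch(as.vector(encode_stemloop(sl, L_max, stem_depth)),
                az_encoding_overflow = function(e) NULL)
  if (!is.null(cache)) cache[[key]] <- if (is.null(g)) NA else g
  g
}

# Predict activities for candidate rows (one aptamer, possibly both
# positions). Returns numeric vector with NA for unscoreable (overflow)
# candidates.
score_candidates <- function(candidates, aptamer_insert, model,
                             scaffold = read_scaffold(),
                             backend = "nussinov", batch_size = 4096L,
                             cache = new.env(parent = emptyenv())) {
  L_max <- model$meta$L_max
  stem_depth <- model$meta$stem_depth
  D <- L_max * 32L
  colsI <- stemloop_columns(L_max, 1L)
  colsII <- stemloop_columns(L_max, 2L)
  pred <- rep(NA_real_, nrow(candidates))
  for (p in unique(candidates$aptamer_loop)) {
    rows <- which(candidates$aptamer_loop == p)
    var_pos <- if (p == "I") "II" else "I"
    apt_grid <- insert_grid(aptamer_insert, p, scaffold, L_max, backend,
                            cache, stem_depth)
    if (is.null(apt_grid)) next  # aptamer itself does not fit: all unscoreable
    apt_cols <- if (p == "I") colsI else colsII
    var_cols <- if (p == "I") colsII else colsI
    uniq <- unique(candidates$variable_loop[rows])
    grids <- lapply(uniq, insert_grid, which = var_pos, scaffold = scaffold,
                    L_max = L_max, backend = backend, cache = cache,
                    stem_depth = stem_depth)
    names(grids) <- uniq
    ok_loop <- !vapply(grids, is.null, logical(1))
    gm <- do.call(rbind, grids[ok_loop])
    loop_row <- match(candidates$variable_loop[rows], rownames(gm))
    scoreable <- rows[!is.na(loop_row)]
    loop_row <- loop_row[!is.na(loop_row)]
    for (start in seq(1L, length(scoreable), by = batch_size)) {
      idx <- start:min(start + batch_size - 1L, length(scoreable))
      Xb <- matrix(0, length(idx), D)
      Xb[, apt_cols] <- matrix(apt_grid, length(idx), length(apt_cols), byrow = TRUE)
      Xb[, var_cols] <- gm[loop_row[idx], , drop = FALSE]
      attr(Xb, "encoder") <- encoder_meta(L_max, stem_depth)
      pred[scoreable[idx]] <- predict(model, Xb)
    }
  }
  pred
}

# Full construct sequences for candidate rows.
candidate_sequences <- function(candidates, aptamer_insert, scaffold) {
  l1 <- ifelse(candidates$aptamer_loop == "I", aptamer_insert,
               candidates$variable_loop)
  l2 <- ifelse(candidates$aptamer_loop == "II", aptamer_insert,
               candidates$variable_loop)
  s <- scaffold$segments
  paste0(s$spacer5, s$stem1_5p, l1, s$stem1_3p, s$core,
         s$stem2_5p, l2, s$stem2_3p, s$core3, s$spacer3)
}

#' Rank candidates by predicted activity and select the lowest k
#'
#' Scores every candidate with the trained model and returns the `k`
#' candidates with the lowest predicted basal activity, ranked ascending.
#' Ties are broken lexicographically by full construct sequence. Candidates
#' that cannot be scored (their encoding walk exceeds the model's `L_max`)
#' are excluded but counted.
#'
#' @param candidates data frame from [enumerate_library()].
#' @param model a trained `az_model`.
#' @param k number of designs to select.
#' @param aptamer the `az_aptamer` (used to derive the grafted insert).
#' @param scaffold scaffold used for construct assembly.
#' @param backend folding backend for the closed-stem loop folds.
#' @param batch_size scoring batch size.
#' @return data frame of class `az_designed_library`: `rank`,
#'   `aptamer_name`, `aptamer_loop`, `variable_position`, `variable_loop`,
#'   `full_sequence`, `predicted_activity`; attribute `n_unscoreable`.
#' @export
rank_and_select <- function(candidates, model, k, aptamer,
                            scaffold = read_scaffold(),
                            backend = "nussinov", batch_size = 4096L) {
  insert <- derive_loop_insert(aptamer)
  pred <- score_candidates(candidates, insert, model, scaffold,
                           backend = backend, batch_size = batch_size)
  scoreable <- which(!is.na(pred))
  if (k > length(scoreable)) {
    az_stop("az_selection_error", "k = %d exceeds the %d scoreable candidates",
            k, length(scoreable))
  }
  full <- candidate_sequences(candidates[scoreable, , drop = FALSE], insert, scaffold)
  ord <- order(pred[scoreable], full)[seq_len(k)]
  sel <- candidates[scoreable[ord], , drop = FALSE]
  out <- data.frame(
    rank = seq_len(k),
    sel,
    full_sequence = full[ord],
    predicted_activity = pred[scoreable[ord]],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_unscoreable") <- nrow(candidates) - length(scoreable)
  class(out) <- c("az_designed_library", class(out))
  out
}

#' Design the switch library for one aptamer
#'
#' End-to-end forward design: derive the aptamer's loop insert, enumerate
#' all variable loops, score the candidates in streamed batches (keeping
#' only a running set of the best `k`, so the 174,080-candidate run stays
#' in modest memory), and return the designed library of the `k`
#' lowest-predicted-activity sequences.
#'
#' @inheritParams rank_and_select
#' @inheritParams enumerate_library
#' @param cache optional environment memoising encoded stem-loop grids
#'   across aptamers.
#' @return an `az_designed_library` (see [rank_and_select()]).
#' @export
design_library <- function(aptamer, model, k = 200L,
                           scaffold = read_scaffold(), lengths = 5:8,
                           positions = NULL, backend = "nussinov",
                           batch_size = 4096L,
                           cache = new.env(parent = emptyenv())) {
  insert <- derive_loop_insert(aptamer)
  candidates <- enumerate_library(aptamer, lengths = lengths, positions = positions)
  best <- NULL
  n_unscoreable <- 0L
  n_scoreable <- 0L
  for (start in seq(1L, nrow(candidates), by = batch_size)) {
    chunk <- candidates[start:min(start + batch_size - 1L, nrow(candidates)), ,
                        drop = FALSE]
    pred <- score_candidates(chunk, insert, model, scaffold,
                             backend = backend, batch_size = batch_size,
                             cache = cache)
    ok <- !is.na(pred)
    n_unscoreable <- n_unscoreable + sum(!ok)
    n_scoreable <- n_scoreable + sum(ok)
    if (!any(ok)) next
    chunk <- chunk[ok, , drop = FALSE]
    chunk$predicted_activity <- pred[ok]
    chunk$full_sequence <- candidate_sequences(chunk, insert, scaffold)
    best <- rbind(best, chunk)
    # prune the running pool to the current best k
    if (nrow(best) > k) {
      ord <- order(best$predicted_activity, best$full_sequence)
      best <- best[ord[seq_len(min(k, nrow(best)))], , drop = FALSE]
    }
  }
  if (is.null(best) || k > n_scoreable) {
    az_stop("az_selection_error", "k = %d exceeds the %d scoreable candidates",
            k, n_scoreable)
  }
  ord <- order(best$predicted_activity, best$full_sequence)
  best <- best[ord, , drop = FALSE]
  out <- data.frame(
    rank = seq_len(nrow(best)),
    best[, c("aptamer_name", "aptamer_loop", "variable_position",
             "variable_loop", "full_sequence", "predicted_activity")],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_unscoreable") <- n_unscoreable
  class(out) <- c("az_designed_library", class(out))
  out
}

#' Top n designs of a designed library
#'
#' @param designed an `az_designed_library`.
#' @param n how many top-ranked designs to keep (default 15, the number
#'   typically synthesised for individual characterisation).
#' @return the first `n` rows in rank order.
#' @export
top_n_designs <- function(designed, n = 15L) {
  if (n > nrow(designed)) {
    az_stop("az_selection_error", "n = %d exceeds the %d designs", n, nrow(designed))
  }
  designed[seq_len(n), , drop = FALSE]
}
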