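# Sort-seq (FACS-Seq) quantification: 8-bin scheme, read counting, and
# interval-censored normal fitting of per-sequence activity.

#' Build the 8-bin sorting scheme
#'
#' The sorter partitions cells into 8 bins by log10(GFP/mCherry). The first
#' and last bins are unbounded below/above (each holding roughly the extreme
#' percentile of expression) and the six interior bins span equal
#' log10-distances between the two extreme boundaries.
#'
#' @param lower_pct_boundary,upper_pct_boundary log10(GFP/mCherry) values of
#'   the boundary between bin 1 and 2, and between bin 7 and 8.
#' @return list of class `az_bin_scheme` with `n_bins = 8` and the 7
#'   ascending `boundaries`.
#' @examples
#' make_bin_scheme(-2, 1)$boundaries
#' @export
make_bin_scheme <- function(lower_pct_boundary = -2, upper_pct_boundary = 1) {
  if (!(lower_pct_boundary < upper_pct_boundary)) {
    az_stop("az_boundary_error", "lower boundary must be strictly below upper")
  }
  boundaries <- seq(lower_pct_boundary, upper_pct_boundary, length.out = 7L)
  structure(list(n_bins = 8L, boundaries = boundaries),
            class = "az_bin_scheme")
}

#' @export
print.az_bin_scheme <- function(x, ...) {
  cat("<az_bin_scheme> 8 bins, boundaries:",
      paste(signif(x$boundaries, 4), collapse = " "), "\n")
  invisible(x)
}

# P(bin) for a Normal(mean, sd) discretised by the scheme. Returns a
# length-8 vector (or matrix for vector mean).
bin_probabilities <- function(mean, sd, scheme) {
  b <- c(-Inf, scheme$boundaries, Inf)
  p <- vapply(seq_len(8L), function(i) {
    pnorm(b[i + 1L], mean, sd) - pnorm(b[i], mean, sd)
  }, numeric(length(mean)))
  if (length(mean) == 1L) as.numeric(p) else p
}

#' Count reads per sequence and bin
#'
#' Exact multiset counting of merged sort-seq reads: each read carries a bin
#' barcode; reads with unrecognized barcodes are dropped and tallied.
#'
#' @param sequences character vector of read sequences (the construct part,
#'   barcode already removed).
#' @param barcodes character vector, parallel to `sequences`, of bin
#'   barcodes.
#' @param barcode_map named integer vector mapping barcode strings to bin
#'   indices 1..8.
#' @return data frame with columns `sequence`, `bin1`..`bin8`, `n_reads`;
#'   attribute `unrecognized` counts dropped reads.
#' @export
count_reads <- function(sequences, barcodes, barcode_map) {
  if (!length(sequences)) az_stop("az_empty_input", "no reads supplied")
  if (length(sequences) != length(barcodes)) {
    az_stop("az_shape_error", "sequences and barcodes differ in length")
  }
  bin <- unname(barcode_map[barcodes])
  ok <- !is.na(bin)
  tab <- table(factor(sequences[ok], levels = unique(sequences[ok])),
               factor(bin[ok], levels = 1:8))
  out <- data.frame(sequence = rownames(tab), stringsAsFactors = FALSE)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(NULL, paste0("bin", 1:8)))
  out <- cbind(out, as.data.frame(counts))
  out$n_reads <- rowSums(counts)
  rownames(out) <- NULL
  attr(out, "unrecognized") <- sum(!ok)
  out
}

count_columns <- function(table) {
  cols <- paste0("bin", 1:8)
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    az_stop("az_shape_error", "count table lacks column(s): %s",
            paste(missing, collapse = ", "))
  }
  as.matrix(table[, cols, drop = FALSE])
}

#' Fit a per-sequence activity estimate from bin counts
#'
#' Fits a normal distribution over log10(GFP/mCherry) to the binned read
#' profile of one sequence. Counts are first normalized by the total reads
#' obtained from each bin and rescaled by the fraction of sorted cells per
#' bin (so bins sequenced at different depths are comparable); the default
#' `per_bin_totals`/`bin_cell_fractions` of 1 leaves raw counts untouched.
#' The normalized profile then enters either
#'
#' * `method = "ml"` (default): weighted maximum likelihood of an
#'   interval-censored normal — extreme bins are treated as open
#'   intervals; or
#' * `method = "ls"`: least squares between the normalized profile and the
#'   discretised normal bin probabilities.
#'
#' A fit with all reads in one open extreme bin is not identifiable; the
#' mean is then reported just beyond the corresponding boundary (offset by
#' the sigma floor) with `converged = FALSE`.
#'
#' @param counts numeric vector of 8 bin counts for one sequence.
#' @param scheme an [make_bin_scheme()] scheme.
#' @param per_bin_totals total reads obtained from each bin (length 8).
#' @param bin_cell_fractions fraction of sorted cells per bin (length 8).
#' @param method `"ml"` or `"ls"`.
#' @param sigma_floor lower bound on the fitted sigma (log10 units).
#' @return list of class `az_activity` with `mean`, `sigma`, `n_reads`,
#'   `converged`.
#' @export
fit_activity <- function(counts, scheme, per_bin_totals = rep(1, 8),
                         bin_cell_fractions = rep(1, 8),
                         method = c("ml", "ls"), sigma_floor = 0.01) {
  method <- match.arg(method)
  counts <- as.numeric(counts)
  if (length(counts) != 8L || any(counts < 0)) {
    az_stop("az_shape_error", "counts must be 8 non-negative numbers")
  }
  n_reads <- sum(counts)
  if (n_reads < 1) az_stop("az_empty_input", "no reads for this sequence")
  w <- counts / per_bin_totals * bin_cell_fractions
  w <- w / sum(w)
  b <- scheme$boundaries
  width <- b[2] - b[1]
  centers <- c(b[1] - width / 2, (b[-7] + b[-1]) / 2, b[7] + width / 2)

  occupied <- which(w > 0)
  if (identical(occupied, 1L) || identical(occupied, 8L)) {
    mean_out <- if (occupied == 1L) b[1] - sigma_floor else b[7] + sigma_floor
    return(structure(list(mean = mean_out, sigma = sigma_floor,
                          n_reads = n_reads, converged = FALSE),
                     class = "az_activity"))
  }

  mu0 <- sum(w * centers)
  s0 <- max(sqrt(sum(w * (centers - mu0)^2)), 0.05)
  obj <- if (method == "ml") {
    function(par) {
      p <- bin_probabilities(par[1], exp(par[2]), scheme)
      -sum(w * log(pmax(p, 1e-300)))
    }
  } else {
    function(par) {
      p <- bin_probabilities(par[1], exp(par[2]), scheme)
      sum((w - p)^2)
    }
  }
  fit <- optim(c(mu0, log(s0)), obj, method = "L-BFGS-B",
               lower = c(b[1] - 10, log(sigma_floor)),
               upper = c(b[7] + 10, log(20)))
  structure(list(mean = fit$par[1], sigma = exp(fit$par[2]),
                 n_reads = n_reads, converged = fit$convergence == 0L),
            class = "az_activity")
}

#' @export
print.az_activity <- function(x, ...) {
  cat(sprintf("<az_activity> mean %.3f, sigma %.3f, %d reads%s\n",
              x$mean, x$sigma, x$n_reads,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fit activities for a whole count table
#'
#' @param table data frame with columns `bin1`..`bin8` (e.g. from
#'   [count_reads()] or [simulate_facs_reads()]).
#' @inheritParams fit_activity
#' @return the input table with columns `mean`, `sigma`, `n_reads`,
#'   `converged` appended.
#' @export
fit_activity_table <- function(table, scheme, per_bin_totals = NULL,
                               bin_cell_fractions = NULL,
                               method = "ml", sigma_floor = 0.01) {
  cm <- count_columns(table)
  if (is.null(per_bin_totals)) per_bin_totals <- rep(1, 8)
  if (is.null(bin_cell_fractions)) bin_cell_fractions <- rep(1, 8)
  fits <- apply(cm, 1L, fit_activity, scheme = scheme,
                per_bin_totals = per_bin_totals,
                bin_cell_fractions = bin_cell_fractions,
                method = method, sigma_floor = sigma_floor)
  table$mean <- vapply(fits, `[[`, numeric(1), "mean")
  table$sigma <- vapply(fits, `[[`, numeric(1), "sigma")
  table$n_reads <- vapply(fits, `[[`, numeric(1), "n_reads")
  table$converged <- vapply(fits, `[[`, logical(1), "converged")
  table
}

#' Merge exactly-overlapping read pairs
#'
#' A minimal merger for constructing test fixtures: the reverse read is
#' reverse-complemented and merged with the forward read when the two agree
#' on an exact suffix/prefix overlap of at least `min_overlap` nucleotides
#' (no mismatches). Pairs with no such overlap yield `NA`. Real paired-end
#' data should be merged with a dedicated tool before quantification.
#'
#' @param fwd,rev character vectors of forward and reverse reads.
#' @param min_overlap minimum exact overlap (default 20).
#' @return character vector of merged reads (`NA` where merging failed).
#' @export
merge_read_pairs <- function(fwd, rev, min_overlap = 20L) {
  stopifnot(length(fwd) == length(rev))
  fwd <- normalize_rna(fwd, "forward read")
  rc <- rna_revcomp(normalize_rna(rev, "reverse read"))
  vapply(seq_along(fwd), function(i) {
    a <- fwd[i]; b <- rc[i]
    na <- nchar(a); nb <- nchar(b)
    for (ov in seq(min(na, nb), min_overlap)) {
      if (substr(a, na - ov + 1L, na) == substr(b, 1L, ov)) {
        return(paste0(a, substr(b, ov + 1L, nb)))
      }
    }
    NA_character_
  }, character(1))
}

#' Read merged sort-seq reads from FASTQ
#'
#' @param path FASTQ file of (pre-merged) reads.
#' @return named character vector of RNA sequences.
#' @export
read_merged_fastq <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fastq")
  out <- normalize_rna(as.character(set))
  names(out) <- names(set)
  out
}

#' Drop sequences with too few reads
#'
#' Sequences are kept when they have at least `threshold` reads (inclusive,
#' so the default keeps `n_reads == 20`).
#'
#' @param table data frame with a `n_reads` column (or `bin1..bin8` from
#'   which it is computed).
#' @param threshold minimum read count, default 20.
#' @return filtered table; attribute `removed` holds the number of dropped
#'   rows.
#' @export
filter_min_reads <- function(table, threshold = 20L) {
  if (threshold < 0) az_stop("az_boundary_error", "threshold must be >= 0")
  if (is.null(table$n_reads)) table$n_reads <- rowSums(count_columns(table))
  keep <- table$n_reads >= threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep)
  out
}
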