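scheme_fx <- make_bin_scheme(-2, 1)

test_that("the bin scheme has equal-width interior bins", {
  expect_equal(scheme_fx$boundaries, seq(-2, 1, by = 0.5))
  widths <- diff(scheme_fx$boundaries)
  expect_true(all(abs(widths - widths[1]) < 1e-12))
  expect_error(make_bin_scheme(0, 0), class = "az_boundary_error")
  expect_error(make_bin_scheme(1, -1), class = "az_boundary_error")
})

test_that("read counting is exact and conserves reads", {
  bc_map <- setNames(1:8, paste0("BC", 1:8))
  reads <- c(rep("AAAA", 10))
  tab <- count_reads(reads, rep("BC3", 10), bc_map)
  expect_equal(unname(unlist(tab[1, paste0("bin", 1:8)])),
               c(0, 0, 10, 0, 0, 0, 0, 0))

  # mixed barcodes incl. unrecognized ones, against a brute-force tally
  set.seed(41)
  seqs <- sample(c("AAAA", "CCCC", "GGGG", "UUUU"), 1000, replace = TRUE)
  bcs <- sample(c(paste0("BC", 1:8), "JUNK"), 1000, replace = TRUE)
  tab <- count_reads(seqs, bcs, bc_map)
  expect_equal(sum(tab[paste0("bin", 1:8)]) + attr(tab, "unrecognized"), 1000)
  for (s in unique(seqs)) {
    for (b in 1:8) {
      expect_equal(tab[tab$sequence == s, paste0("bin", b)],
                   sum(seqs == s & bcs == paste0("BC", b)))
    }
  }
  expect_error(count_reads(character(0), character(0), bc_map),
               class = "az_empty_input")
})

test_that("single-interior-bin profiles fit to the bin center", {
  for (k in 2:7) {
    counts <- rep(0, 8); counts[k] <- 50
    est <- fit_activity(counts, scheme_fx)
    center <- (scheme_fx$boundaries[k - 1] + scheme_fx$boundaries[k]) / 2
    expect_lt(abs(est$mean - center), 0.01)
    expect_true(est$converged)
  }
})

test_that("two equal adjacent interior bins fit to their shared boundary", {
  counts <- c(0, 0, 30, 30, 0, 0, 0, 0)
  est <- fit_activity(counts, scheme_fx)
  expect_lt(abs(est$mean - scheme_fx$boundaries[3]), 0.01)
})

test_that("profiles confined to an open extreme bin do not converge", {
  est <- fit_activity(c(100, 0, 0, 0, 0, 0, 0, 0), scheme_fx)
  expect_false(est$converged)
  expect_equal(est$mean, scheme_fx$boundaries[1] - 0.01)
  est <- fit_activity(c(0, 0, 0, 0, 0, 0, 0, 100), scheme_fx)
  expect_false(est$converged)
  expect_equal(est$mean, scheme_fx$boundaries[7] + 0.01)
})

test_that("the ML fit matches an independent censored-normal fit", {
  tab <- simulate_facs_reads(0.3, scheme_fx, depth = 400, sigma = 0.4, seed = 5)
  counts <- unlist(tab[1, paste0("bin", 1:8)])
  est <- fit_activity(counts, scheme_fx)
  # independent route: fitdistrplus on interval-censored observations
  b <- scheme_fx$boundaries
  left <- c(NA, b)[rep(1:8, counts)]
  right <- c(b, NA)[rep(1:8, counts)]
  cens <- data.frame(left = left, right = right)
  ref <- fitdistrplus::fitdistcens(cens, "norm")
  expect_equal(est$mean, unname(ref$estimate["mean"]), tolerance = 0.01)
  expect_equal(est$sigma, unname(ref$estimate["sd"]), tolerance = 0.02)
})

test_that("the estimate recovers the simulated mean and tightens with depth", {
  # recovery at depth 1000 (subset of the full 200-replicate check)
  hits <- vapply(1:50, function(i) {
    tab <- simulate_facs_reads(0.30, scheme_fx, depth = 1000, sigma = 0.4,
                               seed = i)
    est <- fit_activity(unlist(tab[1, paste0("bin", 1:8)]), scheme_fx)
    abs(est$mean - 0.30) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # RMSE decreases with read depth
  rmse_at <- function(depth) {
    errs <- vapply(1:60, function(i) {
      tab <- simulate_facs_reads(0.30, scheme_fx, depth = depth, sigma = 0.4,
                                 seed = 1000 * depth + i)
      fit_activity(unlist(tab[1, paste0("bin", 1:8)]), scheme_fx)$mean - 0.30
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  r <- vapply(c(50, 200, 1000), rmse_at, numeric(1))
  expect_gt(r[1], r[3])
})

test_that("normalization is invariant to rescaling the per-bin totals", {
  counts <- c(0, 2, 10, 40, 30, 8, 0, 0)
  totals <- c(5, 4, 6, 8, 7, 5, 4, 3) * 100
  est1 <- fit_activity(counts, scheme_fx, per_bin_totals = totals)
  est2 <- fit_activity(counts, scheme_fx, per_bin_totals = totals * 7)
  expect_equal(est1$mean, est2$mean)
  expect_equal(est1$sigma, est2$sigma)
})

test_that("the read filter is inclusive at the threshold", {
  tab <- data.frame(sequence = c("a", "b", "c"))
  tab[paste0("bin", 1:8)] <- 0
  tab$bin4 <- c(19, 20, 25)
  tab$n_reads <- tab$bin4
  out <- filter_min_reads(tab, 20)
  expect_identical(out$sequence, c("b", "c"))
  expect_equal(attr(out, "removed"), 1L)
  expect_equal(nrow(filter_min_reads(tab, 0)), 3)
})

test_that("exact-overlap merging reconstructs the template or returns NA", {
  template <- paste0(withr::with_seed(55, sample(c("A", "C", "G", "U"), 48,
                                                 replace = TRUE)),
                     collapse = "")
  fwd <- substr(template, 1, 30)
  rev_read <- rna_revcomp(substr(template, 11, 48))  # 20 nt overlap with fwd
  merged <- merge_read_pairs(fwd, rev_read, min_overlap = 20)
  expect_identical(merged, template)
  # disjoint reads cannot merge
  expect_true(is.na(merge_read_pairs("AAAAAAAAAAAAAAAAAAAAAA",
                                     "GGGGGGGGGGGGGGGGGGGGGG")))
})

test_that("merged reads round-trip through FASTQ", {
  path <- withr::local_tempfile(fileext = ".fastq")
  seqs <- c(r1 = "ACGUACGUACGU", r2 = "GGGGCCCCAAAA")
  writeLines(c("@r1", chartr("U", "T", seqs[1]), "+", strrep("I", 12),
               "@r2", chartr("U", "T", seqs[2]), "+", strrep("I", 12)), path)
  got <- read_merged_fastq(path)
  expect_equal(unname(got), unname(seqs))
})
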