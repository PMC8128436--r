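test_that("assembly inserts loops at the scaffold sites and is reversible", {
  con <- assemble("GUGA", "ACAA", az_scaffold_fx)
  fixed <- sum(nchar(unlist(az_scaffold_fx$segments)))
  expect_equal(nchar(con$full_sequence), fixed + 8)

  # round trip for many random inserts
  l1 <- random_loops(1000, 3, 13, seed = 101)
  l2 <- random_loops(1000, 3, 13, seed = 102)
  for (i in seq_len(1000)) {
    con <- assemble(l1[i], l2[i], az_scaffold_fx)
    rec <- slice_inserts(con$full_sequence, nchar(l1[i]), nchar(l2[i]),
                         az_scaffold_fx)
    if (rec$loop1 != l1[i] || rec$loop2 != l2[i]) {
      fail(sprintf("round trip broke for %s / %s", l1[i], l2[i]))
    }
  }
  succeed()
})

test_that("native loops reconstruct the literature sTRSV ribozyme", {
  con <- assemble(az_scaffold_fx$native_loops$loop1,
                  az_scaffold_fx$native_loops$loop2, az_scaffold_fx)
  expect_identical(con$full_sequence, az_scaffold_fx$native_full_sequence)
})

test_that("assembly normalises input and rejects bad alphabets", {
  con <- assemble("gtga", "acaa", az_scaffold_fx)
  expect_identical(con$loop1_insert, "GUGA")
  expect_error(assemble("GUXA", "ACAA", az_scaffold_fx),
               class = "az_invalid_alphabet")
  expect_error(assemble("", "ACAA", az_scaffold_fx), class = "az_invalid_loop")
})

test_that("folding backends return sane deterministic structures", {
  expect_identical(fold("GGGGAAAACCCC", backend = "nussinov")$dot_bracket,
                   "((((....))))")
  expect_identical(fold("GGGGAAAACCCC", backend = "rnafold")$dot_bracket,
                   "((((....))))")
  expect_identical(fold("AAAAAAAA", backend = "nussinov")$dot_bracket,
                   "........")
  seqs <- vapply(1:50, function(i) {
    paste0(random_loops(1, 20, 60, seed = i), collapse = "")
  }, character(1))
  for (b in c("nussinov", "rnafold")) {
    s1 <- vapply(fold(seqs, backend = b), `[[`, character(1), "dot_bracket")
    s2 <- vapply(fold(seqs, backend = b), `[[`, character(1), "dot_bracket")
    expect_identical(s1, s2)
    # balanced brackets, matched lengths
    expect_true(all(nchar(s1) == nchar(seqs)))
    for (d in s1) expect_silent(aptazyme:::pair_table(d))
  }
  expect_error(fold(strrep("A", 400)), class = "az_input_too_long")
})

test_that("the native construct folds with both scaffold stems fully paired", {
  con <- assemble(az_scaffold_fx$native_loops$loop1,
                  az_scaffold_fx$native_loops$loop2, az_scaffold_fx)
  st <- fold(con$full_sequence, backend = "rnafold")
  pr <- parse_stemloops(con, st, az_scaffold_fx)
  expect_false(pr$misfolded)
  expect_equal(pr$sl1$stem_len, 6)
  expect_equal(pr$sl2$stem_len, 4)
  expect_identical(pr$sl1$loop_seq, "UGUGCUU")
  expect_identical(pr$sl2$loop_seq, "GUGA")
})

test_that("loop-flanking pairs extend the stem and shrink the loop", {
  # first/last insert bases pair in the MFE structure -> stem +1, loop -2
  con <- assemble("GUUUUUC", "GUGA", az_scaffold_fx)
  pr <- parse_stemloops(con, fold(con$full_sequence, backend = "rnafold"),
                        az_scaffold_fx)
  expect_false(pr$misfolded)
  expect_equal(pr$sl1$stem_len, az_scaffold_fx$default_stem1_len + 1)
  expect_identical(pr$sl1$loop_seq, "UUUUU")

  # two stacked flanking pairs
  con <- assemble("GCAAAAAAGC", "GUGA", az_scaffold_fx)
  pr <- parse_stemloops(con, fold(con$full_sequence, backend = "rnafold"),
                        az_scaffold_fx)
  expect_equal(pr$sl1$stem_len, az_scaffold_fx$default_stem1_len + 2)
  expect_identical(pr$sl1$loop_seq, "AAAAAA")

  # no extension for a GAAA tetraloop
  con <- assemble("GAAA", "GUGA", az_scaffold_fx)
  pr <- parse_stemloops(con, fold(con$full_sequence, backend = "rnafold"),
                        az_scaffold_fx)
  expect_equal(pr$sl1$stem_len, az_scaffold_fx$default_stem1_len)
  expect_identical(pr$sl1$loop_seq, "GAAA")
})

test_that("a long insert with an internal hairpin is parsed as a branch stem", {
  con <- assemble("UGGGAAAACCCAA", "GUGA", az_scaffold_fx)
  pr <- parse_stemloops(con, fold(con$full_sequence, backend = "rnafold"),
                        az_scaffold_fx)
  expect_false(pr$misfolded)
  expect_gt(length(pr$sl1$branch_stems), 0)
  expect_equal(sum(pr$sl1$paired_flags), 6)  # one 3-bp branch helix
  # paired-flag count is always even (flags come in pairs)
  expect_equal(sum(pr$sl1$paired_flags) %% 2, 0)
})

test_that("structures that break the scaffold stems are flagged, not parsed", {
  con <- assemble("GAAA", "GUGA", az_scaffold_fx)
  open_struct <- structure(list(
    sequence = con$full_sequence,
    dot_bracket = strrep(".", nchar(con$full_sequence)),
    backend = "manual"
  ), class = "az_structure")
  pr <- parse_stemloops(con, open_struct, az_scaffold_fx)
  expect_true(pr$misfolded)
  expect_null(pr$sl1)
})

test_that("structure keys are deterministic, ordered, and partition data", {
  con <- assemble("GAAA", "GUGA", az_scaffold_fx)
  pr <- parse_stemloops(con, fold(con$full_sequence, backend = "rnafold"),
                        az_scaffold_fx)
  k1 <- structure_key(pr$sl1, pr$sl2)
  k2 <- structure_key(pr$sl1, pr$sl2)
  expect_identical(format(k1), format(k2))
  # swapping stem-loop statistics gives a different key
  expect_false(format(structure_key(pr$sl2, pr$sl1)) == format(k1))

  # keys partition a random set: every parseable record gets exactly one key
  l1 <- random_loops(60, 4, 8, seed = 7)
  l2 <- random_loops(60, 4, 8, seed = 8)
  enc <- encode_loop_pairs(l1, l2, az_scaffold_fx, L_max = 16)
  expect_length(enc$keys, length(enc$kept))
  groups <- split(enc$kept, enc$keys)
  expect_equal(sort(unname(unlist(groups))), sort(enc$kept))

  # an N4N4 slice shares a single key
  l1 <- random_loops(30, 4, 4, seed = 9)
  l2 <- random_loops(30, 4, 4, seed = 10)
  # restrict to loops without pairable ends so no stem extension occurs
  keep <- !aptazyme:::can_pair(substr(l1, 1, 1), substr(l1, 4, 4)) &
          !aptazyme:::can_pair(substr(l2, 1, 1), substr(l2, 4, 4))
  enc <- encode_loop_pairs(l1[keep], l2[keep], az_scaffold_fx, L_max = 16)
  expect_length(unique(enc$keys), 1)
})
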