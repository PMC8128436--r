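test_that("a loop nucleotide lights exactly its unpaired channel", {
  sl <- make_sl(stem5 = "GC", stem3 = "GC", loop = "U")
  g <- encode_stemloop(sl, L_max = 6)
  cell <- g[3, 1, ]  # first loop position: row stem_len+1, 5' side
  expect_equal(unname(cell[4]), 1)      # U-unpaired channel
  expect_equal(sum(cell), 1)            # nothing else set in that cell
  expect_equal(sum(g[4:6, , ]), 0)      # rows beyond the walk are all-zero
  expect_equal(dim(g)[3], 8)
})

test_that("total ones equal the number of encoded nucleotides", {
  sl <- make_sl(stem5 = "GCGC", stem3 = "GCGC", loop = "GAAA")
  g <- encode_stemloop(sl, L_max = 8)
  expect_equal(sum(g), 12)  # 4 bp stem on both sides + 4 loop nt

  sl2 <- make_sl(which = "II", stem5 = "GG", stem3 = "CC", loop = "UUCGA")
  te <- encode_pair(sl, sl2, L_max = 8)
  expect_equal(sum(te), 12 + 9)
})

test_that("branch-stem nucleotides carry paired channels", {
  sl <- make_sl(stem5 = "GC", stem3 = "GC", loop = "AGGGAAACCCA",
                paired = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                           TRUE, TRUE, TRUE, FALSE))
  g <- encode_stemloop(sl, L_max = 10)
  # channel block 5:8 is the paired block; count paired loop cells
  expect_equal(sum(g[3:10, , 5:8]), 6)
  expect_equal(sum(g), 2 * 2 + 11)
})

test_that("the stemloop axis is ordered I then II and swaps symmetrically", {
  a <- make_sl(stem5 = "GC", stem3 = "GC", loop = "GAAA")
  b <- make_sl(which = "II", stem5 = "GG", stem3 = "CC", loop = "UUUU")
  te <- encode_pair(a, b, L_max = 6)
  sw <- encode_pair(b, a, L_max = 6)
  expect_equal(unname(te[, , 1, ]), unname(sw[, , 2, ]))
  expect_equal(unname(te[, , 2, ]), unname(sw[, , 1, ]))
  ident <- encode_pair(a, a, L_max = 6)
  expect_equal(unname(ident[, , 1, ]), unname(ident[, , 2, ]))
})

test_that("the walk overflows loud and clear", {
  sl <- make_sl(stem5 = "GCGC", stem3 = "GCGC", loop = strrep("A", 12))
  expect_error(encode_stemloop(sl, L_max = 8), class = "az_encoding_overflow")
})

test_that("batch encoding equals stacked single encodings and skips overflows", {
  a <- make_sl(stem5 = "GC", stem3 = "GC", loop = "GAAA")
  b <- make_sl(which = "II", stem5 = "GG", stem3 = "CC", loop = "UUUU")
  big <- make_sl(stem5 = "GC", stem3 = "GC", loop = strrep("A", 20))
  pairs <- list(list(sl1 = a, sl2 = b), list(sl1 = b, sl2 = a),
                list(sl1 = a, sl2 = a))
  batch <- batch_encode(pairs, L_max = 6)
  expect_equal(nrow(batch$X), 3)
  for (i in 1:3) {
    expect_equal(unname(batch$X[i, ]),
                 as.vector(encode_pair(pairs[[i]]$sl1, pairs[[i]]$sl2, L_max = 6)))
  }
  # one overflow record under skip policy
  batch2 <- batch_encode(c(pairs, list(list(sl1 = big, sl2 = b))), L_max = 6)
  expect_equal(nrow(batch2$X), 3)
  expect_equal(batch2$skipped, 4L)
  expect_error(batch_encode(list(), L_max = 6), class = "az_empty_batch")
  expect_error(batch_encode(c(pairs, list(list(sl1 = big, sl2 = b))),
                            L_max = 6, on_overflow = "error"),
               class = "az_encoding_overflow")
})

test_that("encoding conserves one-hot mass for random parsed constructs", {
  l1 <- random_loops(1000, 4, 9, seed = 21)
  l2 <- random_loops(1000, 4, 9, seed = 22)
  enc <- encode_loop_pairs(l1, l2, az_scaffold_fx, L_max = 16)
  # ones per record = scaffold stems (2*(6+4)) + insert lengths, regardless
  # of how extensions/branches redistribute bases between stem and loop rows
  expected <- 20 + nchar(l1[enc$kept]) + nchar(l2[enc$kept])
  expect_equal(unname(rowSums(enc$X)), expected)
  # every occupied cell is one-hot across the 8 channels
  n <- nrow(enc$X)
  arr <- array(t(enc$X), dim = c(16, 2, 2, 8, n))
  per_cell <- apply(arr, c(1, 2, 3, 5), sum)
  expect_true(all(per_cell <= 1))
})

test_that("encoding is injective on an exhaustive N3xN3 set", {
  n3 <- aptazyme:::all_loops_of_length(3)
  grid <- expand.grid(l1 = n3, l2 = n3, stringsAsFactors = FALSE)
  enc <- encode_loop_pairs(grid$l1, grid$l2, az_scaffold_fx, L_max = 16)
  expect_equal(length(enc$kept), nrow(grid))
  expect_false(any(duplicated(enc$X)))
})

test_that("batch encoding is independent of record order", {
  l1 <- random_loops(40, 4, 8, seed = 31)
  l2 <- random_loops(40, 4, 8, seed = 32)
  enc <- encode_loop_pairs(l1, l2, az_scaffold_fx, L_max = 16)
  perm <- rev(seq_along(l1))
  enc_p <- encode_loop_pairs(l1[perm], l2[perm], az_scaffold_fx, L_max = 16)
  expect_equal(enc_p$X[match(seq_along(l1), perm)[enc$kept], ], enc$X,
               ignore_attr = TRUE)
})

test_that("tensor export round-trips with an accurate sidecar", {
  enc <- encode_loop_pairs(random_loops(5, 4, 6, seed = 41),
                           random_loops(5, 4, 6, seed = 42),
                           az_scaffold_fx, L_max = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  export_tensor(enc$X, path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$n, nrow(enc$X))
  expect_equal(side$L_max, 12)
  back <- import_tensor(path)
  expect_identical(unname(back), unname(enc$X))
  expect_identical(attr(back, "encoder"), attr(enc$X, "encoder"))
})
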