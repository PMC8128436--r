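# Shared fixtures, built in code at test time.

az_scaffold_fx <- read_scaffold()

# Random loop inserts of lengths within [min_len, max_len].
random_loops <- function(n, min_len = 4, max_len = 10, seed = 1) {
  withr::with_seed(seed, {
    pool <- min_len:max_len
    lens <- pool[sample.int(length(pool), n, replace = TRUE)]
    vapply(lens, function(L) paste0(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                                    collapse = ""), character(1))
  })
}

# Reattach encoder metadata after row-subsetting a feature matrix.
as_encoded <- function(X, like) {
  attr(X, "encoder") <- attr(like, "encoder")
  X
}

# A stem-loop object built directly (bypassing folding) for encoder tests.
make_sl <- function(which = "I", stem5 = "GC", stem3 = "GC", loop = "GAAA",
                    paired = rep(FALSE, nchar(loop)), branch = list()) {
  aptazyme:::new_stemloop(
    which = which, stem_len = nchar(stem5),
    stem5_seq = stem5, stem3_seq = stem3, loop_seq = loop,
    paired_flags = paired, branch_stems = branch, loop_positions = NULL
  )
}

# A toy aptamer object.
make_aptamer <- function(seq = "GGGAUACCC", str = "(((...)))",
                         bulge = c(4L, 6L), name = "toy") {
  structure(list(name = name, full_sequence = seq, full_structure = str,
                 binding_bulge = bulge, allowed_positions = c("I", "II")),
            class = "az_aptamer")
}

# Small surrogate-trained models shared across designer/acceptance tests.
# Built lazily and cached for the session.
small_design_model <- local({
  cache <- NULL
  function(L_max = 26L) {
    if (!is.null(cache)) return(cache)
    tab <- generate_training_set(1500, loop_lengths = 5:10, seed = 11)
    enc <- encode_loop_pairs(tab$loop1, tab$loop2, L_max = L_max,
                             backend = "nussinov")
    cache <<- train_cnn(enc$X, tab$activity[enc$kept],
                        cnn_config(epochs = 10, seed = 5))
    cache
  }
})
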