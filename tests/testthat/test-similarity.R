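test_that("tanimoto handles the boundary conventions", {
  fa <- fingerprint(c(1, 2, 3), 16)
  fb <- fingerprint(c(2, 3, 4), 16)
  expect_equal(tanimoto(fa, fa), 1)
  expect_equal(tanimoto(fingerprint(c(0, 1), 16), fingerprint(c(2, 3), 16)), 0)
  expect_equal(tanimoto(fa, fb), 0.5)  # |{2,3}| / |{1,2,3,4}|
  expect_equal(tanimoto(fingerprint(integer(0), 16), fingerprint(integer(0), 16)), 0)
  expect_error(tanimoto(fa, fingerprint(1, 32)), "mismatch")
})

test_that("tanimoto is symmetric on random fingerprints", {
  set.seed(1)
  for (i in 1:20) {
    fa <- fingerprint(sample(0:63, sample(0:20, 1)), 64)
    fb <- fingerprint(sample(0:63, sample(0:20, 1)), 64)
    expect_identical(tanimoto(fa, fb), tanimoto(fb, fa))
  }
})

test_that("circular fingerprints are deterministic and non-empty", {
  f1 <- circular_fingerprint("CCO", radius = 2, nbits = 2048)
  f2 <- circular_fingerprint("CCO", radius = 2, nbits = 2048)
  expect_identical(f1$bits, f2$bits)
  expect_gte(length(circular_fingerprint("C", 2, 2048)$bits), 1)
  expect_equal(tanimoto(f1, f2), 1)
  expect_error(circular_fingerprint(NA, id = "D9"), "D9")
})

test_that("smith_waterman matches the DP oracle on toy scoring", {
  sc <- smith_waterman("ACGT", "ACGT", toy_submat, gap_open = 0, gap_extend = 1)
  expect_equal(sc, 8)
  expect_equal(sc, sw_dp_oracle("ACGT", "ACGT", toy_submat, 0, 1))
  # no positive-scoring residue pair -> local floor 0
  expect_equal(smith_waterman("AAAA", "CCCC", toy_submat, 0, 1), 0)
  expect_warning(expect_equal(smith_waterman("", "ACGT", toy_submat, 0, 1), 0))
})

test_that("smith_waterman agrees with the DP oracle on random sequences", {
  set.seed(5)
  for (i in 1:15) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:9, 1), replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:9, 1), replace = TRUE), collapse = "")
    expect_equal(smith_waterman(a, b, toy_submat, gap_open = 1, gap_extend = 1),
                 sw_dp_oracle(a, b, toy_submat, 1, 1),
                 info = paste(a, b))
  }
})

test_that("self-alignment equals the sum of diagonal substitution scores", {
  seqs <- c("MKV", "ACDEFGH", "WYYW")
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  for (s in seqs) {
    diag_sum <- sum(vapply(strsplit(s, "")[[1]],
                           function(ch) env$BLOSUM62[ch, ch], numeric(1)))
    expect_equal(smith_waterman(s, s), diag_sum)
  }
})

test_that("normalized sequence similarity lives in [0,1] with self-similarity 1", {
  expect_equal(normalized_seq_similarity("MKVLA", "MKVLA"), 1)
  expect_equal(normalized_seq_similarity("AAAA", "CCCC", toy_submat, 0, 1), 0)
  # frozen value via the DP oracle: SW(MKV,MKL)/min(self,self)
  env <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = env)
  expected <- sw_dp_oracle("MKV", "MKL", env$BLOSUM62, 11, 1) /
    min(sw_dp_oracle("MKV", "MKV", env$BLOSUM62, 11, 1),
        sw_dp_oracle("MKL", "MKL", env$BLOSUM62, 11, 1))
  expect_equal(normalized_seq_similarity("MKV", "MKL"), expected)
  expect_equal(normalized_seq_similarity("MKV", "MKL"),
               normalized_seq_similarity("MKL", "MKV"))
})

test_that("similarity matrices are symmetric with unit diagonal", {
  expect_equal(build_similarity_matrix(list(list(id = "a")),
                                       function(x, y) stop("never called")),
               matrix(1, 1, 1, dimnames = list("a", "a")),
               ignore_attr = "measure")
  fps <- list(D1 = fingerprint(1:5, 32), D2 = fingerprint(1:5, 32),
              D3 = fingerprint(1:5, 32))
  S <- fingerprint_similarity_matrix(fps)
  expect_true(all(S == 1))
  set.seed(2)
  fps <- lapply(1:6, function(i) fingerprint(sample(0:31, 8), 32))
  names(fps) <- paste0("D", 1:6)
  S <- fingerprint_similarity_matrix(fps)
  expect_equal(S, t(S))
  expect_true(all(diag(S) == 1))
  expect_error(build_similarity_matrix(list(list(id = "a"), list(id = "b")),
                                       function(x, y) stop("boom")),
               "\\(a, b\\)")
})
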