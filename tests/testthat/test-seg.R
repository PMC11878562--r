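cycle20 <- function(n) paste(rep(AA20_test, length.out = n), collapse = "")
AA20_test <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

test_that("window_entropy matches closed forms and is permutation invariant", {
  expect_equal(window_entropy(strrep("A", 15)), 0)
  expect_equal(window_entropy("AAAAAGGGGGSSSSS"), log2(3))
  expect_equal(window_entropy("ACDEFGHIKLMNPQR"), log2(15))
  # X is a 21st symbol type
  expect_equal(window_entropy(strrep("X", 10)), 0)
  expect_equal(window_entropy("XXXXXAAAAA"), 1)
  set.seed(1)
  w <- paste(sample(AA20_test, 15, replace = TRUE), collapse = "")
  shuf <- paste(sample(strsplit(w, "")[[1L]]), collapse = "")
  expect_equal(window_entropy(w), window_entropy(shuf))
  expect_error(window_entropy(""), "empty")
})

test_that("trigger windows follow the K1 threshold", {
  p <- seg_params()
  expect_equal(find_trigger_windows(strrep("Q", 30), p), 1:16)
  expect_length(find_trigger_windows(cycle20(100), p), 0L)
  expect_length(find_trigger_windows(strrep("Q", 10), p), 0L)
})

test_that("segment handles the degenerate and frozen planted cases", {
  expect_equal(seg_detect(strrep("Q", 100))[, c("start", "end")],
               data.frame(start = 1L, end = 100L))
  expect_equal(nrow(seg_detect(cycle20(100))), 0L)
  # frozen 100-mer: polyQ30 at 41..70 in a high-complexity background with
  # all off-tract windows above K2; expectations computed with the
  # brute-force oracle and frozen
  s <- paste0("CSTFNHDMHPCTIRHGQDDMVNCDLSMCKIHIHYPTFVFY",
              strrep("Q", 30),
              "TIVYMDFHPTIKHQPCSQKMCSLIWNHPHE")
  r <- seg_detect(s)
  expect_equal(r[, c("start", "end")], data.frame(start = 41L, end = 70L))
  m <- seg_detect(s, seg_params(refine = FALSE))
  expect_equal(m[, c("start", "end")], data.frame(start = 33L, end = 77L))
  # the called tract is within W-1 residues of the planted interval
  expect_lte(abs(r$start - 41L), 14L)
  expect_lte(abs(r$end - 70L), 14L)
})

test_that("segmentation equals the brute-force oracle on random sequences", {
  p <- seg_params()
  for (s in random_seqs(150, c("A", "C", "G", "S"), seed = 7)) {
    expect_identical(find_trigger_windows(s, p),
                     oracle_triggers(s, 15, 1.9))
    im <- seg_detect(s, seg_params(refine = FALSE))
    om <- oracle_segment(s, 15, 1.9, 2.5, refine = FALSE)
    expect_identical(im$start, om$start)
    expect_identical(im$end, om$end)
    ir <- seg_detect(s, p)
    or <- oracle_segment(s, 15, 1.9, 2.5, refine = TRUE)
    expect_identical(ir$start, or$start)
    expect_identical(ir$end, or$end)
  }
})

test_that("intervals are disjoint, sorted, in bounds, with trigger evidence", {
  p <- seg_params()
  for (s in random_seqs(80, c("A", "C", "G", "S", "T"), seed = 13)) {
    d <- seg_detect(s, p)
    if (!nrow(d)) next
    expect_true(all(d$start >= 1L & d$end <= nchar(s)))
    expect_true(all(d$end >= d$start))
    if (nrow(d) > 1L) expect_true(all(diff(d$start) > 0))
    if (nrow(d) > 1L) expect_true(all(d$start[-1L] > d$end[-nrow(d)]))
    # some internal window (length min(W, len)) has entropy <= K1
    for (k in seq_len(nrow(d))) {
      sub <- substring(s, d$start[k], d$end[k])
      w <- min(p$W, nchar(sub))
      expect_lte(min(window_entropies(sub, w)), p$K1)
    }
  }
})

test_that("raising K1 never decreases LCR residue coverage", {
  cov <- function(d) if (nrow(d)) sum(d$end - d$start + 1L) else 0L
  k1s <- c(0.5, 1.0, 1.5, 1.9, 2.3, 2.5)
  for (s in random_seqs(60, c("A", "C", "G", "S", "T", "P"), seed = 21)) {
    for (ref in c(FALSE, TRUE)) {
      cv <- vapply(k1s, function(k)
        cov(seg_detect(s, seg_params(K1 = k, refine = ref))), numeric(1))
      expect_false(is.unsorted(cv))
    }
  }
})

test_that("a pure homopolymer run >= W is fully contained in a call", {
  set.seed(31)
  for (rep in 1:40) {
    run_len <- sample(15:40, 1L)
    left <- paste(sample(AA20_test, 60, replace = TRUE), collapse = "")
    right <- paste(sample(AA20_test, 60, replace = TRUE), collapse = "")
    s <- paste0(left, strrep("Q", run_len), right)
    d <- seg_detect(s)
    a <- nchar(left) + 1L
    b <- nchar(left) + run_len
    expect_true(any(d$start <= a & d$end >= b))
  }
})

test_that("segmentation is deterministic", {
  s <- random_seqs(1, c("A", "C", "G", "S"), c(200L, 200L), seed = 3)
  expect_identical(seg_detect(s), seg_detect(s))
  expect_identical(window_entropies(s), window_entropies(s))
})

test_that("lcr_residue_fraction weights by total length", {
  rec <- data.frame(protein_id = c("a", "b"), length = c(100L, 300L))
  lcr <- data.frame(protein_id = c("a", "b"), start = c(1L, 1L),
                    end = c(10L, 30L))
  expect_equal(lcr_residue_fraction(rec, lcr), 0.10)
  expect_equal(lcr_residue_fraction(rec, lcr[0, ]), 0)
  expect_equal(lcr_residue_fraction(
    data.frame(protein_id = "a", length = 100L),
    data.frame(protein_id = "a", start = 1L, end = 25L)), 0.25)
  expect_error(lcr_residue_fraction(rec[0, ], lcr), "empty")
})
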