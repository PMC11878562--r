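test_that("homopolymer rule truth table, including both rejection modes", {
  expect_true(classify_homopolymer("QQQQQQQ")$is_homopolymer)
  expect_equal(classify_homopolymer("QQQQQQQ")$dominant_residue, "Q")
  # run 5, fraction 0.9
  h <- classify_homopolymer("QQQQQSQQQQ")
  expect_true(h$is_homopolymer)
  expect_equal(h$dominant_residue, "Q")
  # neither run nor fraction
  expect_false(classify_homopolymer("QSQSQSQSQS")$is_homopolymer)
  # run >= 5 but fraction 6/11 < 0.70 ("run but not fraction")
  expect_false(classify_homopolymer("AAAAAAGGGGG")$is_homopolymer)
  # fraction 0.8 >= 0.70 but max run 4 < 5 ("fraction but not run")
  expect_false(classify_homopolymer("QQQQSQQQQS")$is_homopolymer)
  # boundary: run exactly 5, fraction exactly 0.70 -> accepted
  h <- classify_homopolymer("QQQQQSQQSS")  # run 5, 7/10 = 0.70
  expect_true(h$is_homopolymer)
  expect_equal(h$dominant_residue, "Q")
  expect_true(is.na(classify_homopolymer("QSQSQSQSQS")$dominant_residue))
})

test_that("homopolymer rule is symmetric over the residue alphabet", {
  for (r in strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]) {
    pat <- paste0(strrep(r, 8), "GA")
    h <- classify_homopolymer(pat)
    expect_true(h$is_homopolymer)
    expect_equal(h$dominant_residue, r)
  }
})

test_that("overlap rule: 80% inclusive, per-domain, with union option", {
  dom <- data.frame(start = 1L, end = 8L)
  expect_equal(classify_overlap(1L, 10L, dom), "within_domain")  # 8/10
  dom7 <- data.frame(start = 1L, end = 7L)
  expect_equal(classify_overlap(1L, 10L, dom7),
               "outside_domain_in_domain_protein")               # 7/10
  expect_equal(classify_overlap(1L, 10L, NULL), "nondomain_protein")
  expect_equal(classify_overlap(1L, 10L, dom[0, ]), "nondomain_protein")
  # two domains jointly covering 9/10 but each < 80%
  two <- data.frame(start = c(1L, 6L), end = c(5L, 9L))
  expect_equal(classify_overlap(1L, 10L, two),
               "outside_domain_in_domain_protein")
  expect_equal(classify_overlap(1L, 10L, two, mode = "union"),
               "within_domain")
})

test_that("position_bin midpoint formula and reversal equivariance", {
  expect_equal(position_bin(1L, 10L, 100L), 0L)
  expect_equal(position_bin(91L, 100L, 100L), 9L)
  expect_equal(position_bin(1L, 10L, 10L), 4L)
  set.seed(17)
  for (i in 1:80) {
    len <- sample(50:500, 1L)
    a <- sample.int(len - 10L, 1L)
    b <- a + sample.int(min(10L, len - a), 1L)
    m <- (a + b) / 2 - 1
    rev_a <- len - b + 1L; rev_b <- len - a + 1L
    # reversal maps midpoint m to len - 1 - m (not len - m), so exact
    # equivariance needs the midpoint at least one residue below the next
    # bin boundary
    f <- (10 * m / len) %% 1
    if (f > 0 && f <= 1 - 10 / len)
      expect_equal(position_bin(rev_a, rev_b, len),
                   9L - position_bin(a, b, len))
  }
})

test_that("positional_profile normalizes and rejects empty groups", {
  expect_equal(positional_profile(rep(0L, 4)), c(1, rep(0, 9)))
  expect_equal(positional_profile(0:9), rep(0.1, 10))
  expect_equal(positional_profile(c(0L, 0L, 9L)),
               c(2 / 3, rep(0, 8), 1 / 3))
  expect_error(positional_profile(integer(0)), "empty")
})

test_that("overlap classes partition all LCRs on simulated data", {
  sim <- simulate_proteomes(synth_config(
    n_proteomes = 1, proteome_size_range = c(250L, 250L), seed = 19))
  cl <- classify_lcrs(seg_detect_all(sim$records), sim$records, sim$hits)
  tab <- table(factor(cl$overlap_class,
                      levels = c("within_domain",
                                 "outside_domain_in_domain_protein",
                                 "nondomain_protein")))
  expect_equal(sum(tab), nrow(cl))
  expect_true(all(tab > 0))  # generator creates all three classes
})

test_that("recovered homopolymers are stochastically shorter than complex LCRs", {
  sim <- simulate_proteomes(synth_config(
    n_proteomes = 2, proteome_size_range = c(600L, 800L),
    homopolymer_share = 0.3, seed = 23))
  cl <- classify_lcrs(seg_detect_all(sim$records), sim$records, sim$hits)
  rep <- recovery_report(sim$truth, cl, sim$records, sim$hits)
  det <- rep$detail[rep$detail$detected, ]
  len <- det$end - det$start + 1L
  w <- stats::wilcox.test(len[det$type == "homopolymer"],
                          len[det$type == "complex"],
                          alternative = "less", exact = FALSE)
  expect_lt(w$p.value, 1e-6)
})

test_that("cooccurrence counts tally domains, LCRs and feature flags", {
  rec <- data.frame(
    protein_id = paste0("p", 1:4),
    sequence = strrep("A", 30), proteome_id = "x", taxon = "t",
    length = 30L, stringsAsFactors = FALSE)
  hits <- data.frame(protein_id = c("p1", "p2"), start = 1L, end = 10L,
                     pfam_acc = "PF00001", pfam_name = "d",
                     stringsAsFactors = FALSE)
  lcrs <- data.frame(protein_id = c("p1", "p3", "p3", "p3"),
                     start = 1L, end = 5L, stringsAsFactors = FALSE)
  fl <- data.frame(protein_id = "p3", has_signal_peptide = TRUE,
                   n_tm_helices = 2L, stringsAsFactors = FALSE)
  cc <- cooccurrence_counts(rec, lcrs, hits, fl)
  all_row <- cc$counts[cc$counts$proteome_id == "ALL", ]
  expect_equal(all_row$n_with_domain, 2L)
  expect_equal(all_row$n_domain_and_lcr, 1L)
  expect_equal(all_row$n_with_lcr, 2L)
  expect_equal(all_row$n_lcr_total, 4L)
  expect_equal(all_row$n_signal_and_lcr, 1L)
  expect_equal(all_row$n_tm_and_lcr, 1L)
  # p3 contributes 1 protein with 3 LCRs
  expect_equal(cc$lcr_per_protein$n_proteins[
    cc$lcr_per_protein$n_lcr == 3L], 1L)
  # empty annotations -> zero co-occurrence
  cc0 <- cooccurrence_counts(rec, lcrs[0, ], NULL, NULL)
  expect_true(all(cc0$counts[, c("n_with_lcr", "n_domain_and_lcr",
                                 "n_signal", "n_tm")] == 0L))
})
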