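small_cfg <- function(seed = 11L, ...) synth_config(
  n_proteomes = 1, proteome_size_range = c(150L, 150L), seed = seed, ...)

test_that("zero LCR rate plants nothing and background stays clean", {
  sim <- simulate_proteomes(small_cfg(lcr_per_protein_rate = 0))
  expect_equal(nrow(sim$truth), 0L)
  lcrs <- seg_detect_all(sim$records)
  rep <- recovery_report(sim$truth, lcrs, sim$records)
  # false-positive calls on pure background cover < 1% of residues
  expect_lt(rep$false_positive_residue_fraction, 0.01)
})

test_that("identical seeds give byte-identical outputs", {
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  write_simulation(simulate_proteomes(small_cfg()), d1)
  write_simulation(simulate_proteomes(small_cfg()), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  sim3 <- simulate_proteomes(small_cfg(seed = 12L))
  sim1 <- simulate_proteomes(small_cfg())
  expect_false(identical(sim1$records$sequence, sim3$records$sequence))
})

test_that("planted intervals respect bounds, ranges and separation", {
  sim <- simulate_proteomes(synth_config(
    n_proteomes = 2, proteome_size_range = c(300L, 400L),
    homopolymer_share = 0.3, seed = 43L))
  tr <- sim$truth
  plen <- sim$records$length[match(tr$protein_id, sim$records$protein_id)]
  expect_true(all(tr$start >= 1L & tr$end <= plen))
  len <- tr$end - tr$start + 1L
  expect_true(all(len[tr$type == "homopolymer"] %in% 10:20))
  expect_true(all(len[tr$type == "complex"] %in% 20:30))
  expect_true(all(is.na(tr$residue) == (tr$type == "complex")))
  # per-protein planted intervals do not overlap
  for (p in unique(tr$protein_id[duplicated(tr$protein_id)])) {
    iv <- tr[tr$protein_id == p, ]
    iv <- iv[order(iv$start), ]
    expect_true(all(iv$start[-1L] > iv$end[-nrow(iv)]))
  }
})

test_that("homopolymer construction always satisfies the classifier rule", {
  sim <- simulate_proteomes(synth_config(
    n_proteomes = 1, proteome_size_range = c(300L, 300L),
    homopolymer_share = 1, seed = 47L))
  expect_true(all(sim$truth$type == "homopolymer"))
  seqs <- sim$records$sequence[match(sim$truth$protein_id,
                                     sim$records$protein_id)]
  for (i in seq_len(nrow(sim$truth))) {
    h <- classify_homopolymer(substring(seqs[i], sim$truth$start[i],
                                        sim$truth$end[i]))
    expect_true(h$is_homopolymer)
    expect_equal(h$dominant_residue, sim$truth$residue[i])
  }
})

test_that("written simulation round-trips through the format readers", {
  dir <- file.path(tempdir(), "sim_rt")
  sim <- simulate_proteomes(small_cfg())
  man <- write_simulation(sim, dir)
  rec <- read_fasta(man$fasta[1L], man$proteome_id[1L], man$taxon[1L])
  expect_identical(rec$sequence, sim$records$sequence)
  hits <- read_pfamscan(file.path(dir, "pfamscan.txt"))
  expect_equal(nrow(hits), nrow(sim$hits))
  expect_identical(hits$pfam_acc, sim$hits$pfam_acc)  # version stripped
  fl <- read_feature_tables(file.path(dir, "tmhmm_short.txt"),
                            file.path(dir, "signalp.txt"))
  i <- match(sim$flags$protein_id, fl$protein_id)
  expect_equal(fl$n_tm_helices[i], sim$flags$n_tm_helices)
  expect_equal(fl$has_signal_peptide[i], sim$flags$has_signal_peptide)
  p2g <- read_pfam2go(file.path(dir, "pfam2go.txt"))
  expect_identical(p2g[order(names(p2g))],
                   sim$pfam2go[order(names(sim$pfam2go))])
})

test_that("recovery_report validates ids and scores a perfect pipeline", {
  sim <- simulate_proteomes(small_cfg())
  # feeding the truth back as calls gives sensitivity 1 and no FPs
  calls <- sim$truth[, c("protein_id", "start", "end")]
  rep <- recovery_report(sim$truth, calls, sim$records)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$false_positive_residue_fraction, 0)
  bad <- sim$truth
  bad$protein_id[1L] <- "nonexistent"
  expect_error(recovery_report(bad, calls, sim$records), "unknown")
})

test_that("planted and detected LCR residue coverage agree within 10%", {
  sim <- simulate_proteomes(synth_config(
    n_proteomes = 1, proteome_size_range = c(800L, 800L), seed = 53L))
  lcrs <- seg_detect_all(sim$records)
  planted <- sum(sim$truth$end - sim$truth$start + 1L)
  called <- sum(lcrs$end - lcrs$start + 1L)
  expect_lt(abs(called - planted) / planted, 0.10)
})
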