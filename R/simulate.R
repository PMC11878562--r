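default_lcr_profile <- function() {
  # Over-weights the residues enriched in fungal LCRs (A, D, E, P, N, Q, S,
  # T, serine and glutamine leading), depletes the bulky hydrophobic /
  # aromatic and positively charged set (C, F, I, L, M, V, W, Y, R, K).
  p <- c(A = 0.10, D = 0.07, E = 0.08, P = 0.07, N = 0.10, Q = 0.13,
         S = 0.16, T = 0.09, G = 0.04, H = 0.02,
         C = 0.014, F = 0.014, I = 0.014, L = 0.014, M = 0.014,
         V = 0.014, W = 0.014, Y = 0.014, R = 0.014, K = 0.014)
  p[AA20] / sum(p)
}

default_homopolymer_profile <- function() {
  # Homopolymer dominant-residue draw: glutamine-led, then asparagine and
  # serine, echoing the composition reported for fungal homorepeats.
  p <- c(Q = 0.31, N = 0.15, S = 0.12, A = 0.08, T = 0.07, E = 0.06,
         D = 0.05, P = 0.04, G = 0.04, H = 0.01,
         C = 0.007, F = 0.007, I = 0.007, L = 0.007, M = 0.007,
         V = 0.007, W = 0.007, Y = 0.007, R = 0.007, K = 0.007)
  p[AA20] / sum(p)
}

#' Synthetic proteome configuration
#'
#' The generator's stated world: uniform 20-letter background (windowed
#' entropy far above the extension threshold), planted complex LCRs of
#' 20-30 residues drawn from at most three residue types of an enriched
#' profile, planted homopolymers of 10-20 residues with at most 10%
#' substitutions (never inside the first five positions, so the homopolymer
#' rule — run of five or more, fraction 70% or more — holds by
#' construction), terminal placement bias
#' with a C-terminal preference for homopolymers, synthetic Pfam-style
#' domain intervals, and signal-peptide / transmembrane flags.
#'
#' @param n_proteomes number of proteomes to generate.
#' @param proteome_size_range integer interval of proteins per proteome;
#'   sizes are evenly spaced across the range when `n_proteomes > 1`.
#' @param protein_length_meanlog,protein_length_sdlog log-normal protein
#'   length parameters (median `exp(meanlog)` residues); lengths clamped to
#'   `[60, 5000]`.
#' @param lcr_per_protein_rate Poisson mean of planted LCRs per protein.
#' @param homopolymer_share fraction of planted LCRs that are homopolymers.
#' @param complex_lcr_length_range,homopolymer_length_range planted length
#'   intervals (uniform integer draw).
#' @param lcr_aa_profile named 20-letter frequency vector for complex LCR
#'   residues.
#' @param homopolymer_residue_profile named 20-letter frequency vector for
#'   the homopolymer dominant residue draw.
#' @param substitution_rate per-homopolymer substitution fraction (<= 0.3;
#'   `floor(rate * length)` positions outside the leading run).
#' @param terminal_bias probability that a planted LCR is placed in the
#'   first or last protein decile.
#' @param homopolymer_cterm_share among terminally placed homopolymers, the
#'   probability of the C-terminal (vs N-terminal) decile.
#' @param domain_rate fraction of proteins receiving 1-3 synthetic domain
#'   intervals.
#' @param domain_cover_rate probability that a planted LCR in a
#'   domain-receiving protein gets a domain interval covering it (creates
#'   the `within_domain` class in known proportion).
#' @param signal_peptide_rate,tm_rate per-protein rates of the
#'   signal-peptide flag and of having 1-7 transmembrane helices.
#' @param seed integer RNG seed; all outputs are reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteomes = 1L,
                         proteome_size_range = c(2000L, 20000L),
                         protein_length_meanlog = log(400),
                         protein_length_sdlog = 0.45,
                         lcr_per_protein_rate = 0.45,
                         homopolymer_share = 0.07,
                         complex_lcr_length_range = c(20L, 30L),
                         homopolymer_length_range = c(10L, 20L),
                         lcr_aa_profile = default_lcr_profile(),
                         homopolymer_residue_profile =
                           default_homopolymer_profile(),
                         substitution_rate = 0.10,
                         terminal_bias = 0.40,
                         homopolymer_cterm_share = 0.75,
                         domain_rate = 0.62,
                         domain_cover_rate = 0.15,
                         signal_peptide_rate = 0.06,
                         tm_rate = 0.17,
                         seed = 1L) {
  stopifnot(n_proteomes >= 1L,
            length(proteome_size_range) == 2L,
            proteome_size_range[1L] <= proteome_size_range[2L],
            proteome_size_range[1L] >= 1L,
            lcr_per_protein_rate >= 0,
            homopolymer_share >= 0, homopolymer_share <= 1,
            diff(complex_lcr_length_range) >= 0,
            diff(homopolymer_length_range) >= 0,
            homopolymer_length_range[1L] >= 5L,
            substitution_rate >= 0, substitution_rate <= 0.3,
            terminal_bias >= 0, terminal_bias <= 1,
            domain_rate >= 0, domain_rate <= 1,
            abs(sum(lcr_aa_profile) - 1) < 1e-6,
            setequal(names(lcr_aa_profile), AA20))
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# sample() without the scalar-x trap
sample1 <- function(v) v[sample.int(length(v), 1L)]

# Build one homopolymer tract satisfying the >= 5-run / >= 70% rule by
# construction: substitutions (floor(rate * l) of them, always <= 0.3 * l)
# are confined to positions 6..l.
make_homopolymer <- function(l, residue, rate) {
  chars <- rep(residue, l)
  nsub <- floor(rate * l)
  if (nsub > 0L && l > 5L) {
    pos <- sample(6:l, min(nsub, l - 5L))
    chars[pos] <- sample(setdiff(AA20, residue), length(pos),
                         replace = TRUE)
  }
  paste(chars, collapse = "")
}

make_complex_lcr <- function(l, profile, max_types = 3L) {
  types <- sample(AA20, max_types, prob = profile)
  w <- profile[types] / sum(profile[types])
  paste(sample(types, l, replace = TRUE, prob = w), collapse = "")
}

# Sample a placement for an LCR of length l in a protein of length len,
# honoring decile targeting; returns start or NA when it cannot be placed
# at min_gap distance from the already accepted intervals (acc_s, acc_e).
place_interval <- function(l, len, acc_s, acc_e, decile, min_gap = 30L,
                           tries = 50L) {
  if (l > len) return(NA_integer_)
  for (t in seq_len(tries)) {
    start <- switch(decile,
      N = sample.int(max(1L, min(len - l + 1L, floor(len / 10))), 1L),
      C = {
        lo <- max(1L, len - floor(len / 10) + 1L - l + 1L)
        hi <- len - l + 1L
        if (lo > hi) lo <- hi
        sample1(lo:hi)
      },
      sample.int(len - l + 1L, 1L))
    end <- start + l - 1L
    if (!length(acc_s) ||
        all(start > acc_e + min_gap | end < acc_s - min_gap))
      return(start)
  }
  NA_integer_
}

#' Generate synthetic proteomes with recorded ground truth
#'
#' Draws proteomes per [synth_config()], plants LCRs and domain intervals,
#' and records every planted feature so the pipeline's recovery can be
#' measured. All randomness is seeded from `config$seed`.
#'
#' @param config a [synth_config()] object.
#' @return List with elements `records` (protein table), `hits` (synthetic
#'   pfam_scan-style domain hits), `flags` (signal peptide / TM flags),
#'   `truth` (planted LCR intervals with `type` and `residue`), `pfam2go`
#'   (synthetic accession -> GO mapping) and `config`.
#' @export
simulate_proteomes <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  np <- config$n_proteomes
  sizes <- if (np == 1L)
    round(mean(config$proteome_size_range))
  else
    round(seq(config$proteome_size_range[1L],
              config$proteome_size_range[2L], length.out = np))

  pf_pool <- sprintf("PF9%04d", 1:40)
  pf_names <- sprintf("SynDom_%d", 1:40)
  go_pool <- sprintf("GO:70%05d", 1:25)
  pfam2go <- setNames(lapply(seq_along(pf_pool), function(i)
    sort(sample(go_pool, sample(1:3, 1L)))), pf_pool)

  all_rec <- all_hits <- all_flags <- all_truth <- vector("list", np)
  for (pi in seq_len(np)) {
    n <- sizes[pi]
    pid <- sprintf("synth%02d", pi)
    ids <- sprintf("%s_p%05d", pid, seq_len(n))
    lens <- pmin(5000L, pmax(60L, round(rlnorm(
      n, config$protein_length_meanlog, config$protein_length_sdlog))))
    # background: one concatenated uniform draw, sliced per protein
    total <- sum(lens)
    bg <- sample(AA20, total, replace = TRUE)
    ends <- cumsum(lens)
    seqs <- substring(paste(bg, collapse = ""), ends - lens + 1L, ends)

    n_lcr <- rpois(n, config$lcr_per_protein_rate)
    dom_flag <- runif(n) < config$domain_rate
    # vector accumulators: one slot per planted LCR / domain interval
    t_pid <- character(0); t_start <- t_end <- integer(0)
    t_type <- t_res <- character(0)
    d_pid <- d_acc <- d_name <- character(0); d_start <- d_end <- integer(0)
    for (i in which(n_lcr > 0L)) {
      acc_s <- acc_e <- integer(0)
      for (k in seq_len(n_lcr[i])) {
        homo <- runif(1) < config$homopolymer_share
        l <- if (homo)
          sample1(config$homopolymer_length_range[1L]:
                  config$homopolymer_length_range[2L])
        else
          sample1(config$complex_lcr_length_range[1L]:
                  config$complex_lcr_length_range[2L])
        decile <- "any"
        if (runif(1) < config$terminal_bias) {
          decile <- if (homo) {
            if (runif(1) < config$homopolymer_cterm_share) "C" else "N"
          } else if (runif(1) < 0.5) "N" else "C"
        }
        start <- place_interval(l, lens[i], acc_s, acc_e, decile)
        if (is.na(start)) next
        end <- start + l - 1L
        acc_s <- c(acc_s, start); acc_e <- c(acc_e, end)
        if (homo) {
          res <- sample(AA20, 1L, prob = config$homopolymer_residue_profile)
          tract <- make_homopolymer(l, res, config$substitution_rate)
        } else {
          res <- NA_character_
          tract <- make_complex_lcr(l, config$lcr_aa_profile)
        }
        substr(seqs[i], start, end) <- tract
        t_pid <- c(t_pid, ids[i]); t_start <- c(t_start, start)
        t_end <- c(t_end, end)
        t_type <- c(t_type, if (homo) "homopolymer" else "complex")
        t_res <- c(t_res, res)
      }
    }
    for (i in which(dom_flag)) {
      nd <- sample(1:3, 1L)
      for (k in seq_len(nd)) {
        dl <- min(sample(50:200, 1L), lens[i] - 2L)
        ds <- sample.int(lens[i] - dl + 1L, 1L)
        j <- sample.int(length(pf_pool), 1L)
        d_pid <- c(d_pid, ids[i]); d_start <- c(d_start, ds)
        d_end <- c(d_end, ds + dl - 1L)
        d_acc <- c(d_acc, pf_pool[j]); d_name <- c(d_name, pf_names[j])
      }
      # optionally cover planted LCRs so the within_domain class exists
      tk <- which(t_pid == ids[i])
      for (k in tk) {
        if (runif(1) < config$domain_cover_rate) {
          pad <- sample(3:15, 2L, replace = TRUE)
          j <- sample.int(length(pf_pool), 1L)
          d_pid <- c(d_pid, ids[i])
          d_start <- c(d_start, max(1L, t_start[k] - pad[1L]))
          d_end <- c(d_end, min(lens[i], t_end[k] + pad[2L]))
          d_acc <- c(d_acc, pf_pool[j]); d_name <- c(d_name, pf_names[j])
        }
      }
    }
    all_rec[[pi]] <- data.frame(
      protein_id = ids, sequence = seqs, proteome_id = pid,
      taxon = sprintf("phylum%d", (pi - 1L) %% 5L + 1L),
      length = lens, stringsAsFactors = FALSE)
    all_hits[[pi]] <- if (length(d_pid)) data.frame(
      protein_id = d_pid, start = d_start, end = d_end,
      pfam_acc = d_acc, pfam_name = d_name,
      stringsAsFactors = FALSE) else NULL
    all_truth[[pi]] <- if (length(t_pid)) data.frame(
      proteome_id = pid, protein_id = t_pid, start = t_start,
      end = t_end, type = t_type, residue = t_res,
      stringsAsFactors = FALSE) else NULL
    all_flags[[pi]] <- data.frame(
      protein_id = ids,
      has_signal_peptide = runif(n) < config$signal_peptide_rate,
      n_tm_helices = ifelse(runif(n) < config$tm_rate,
                            sample(1:7, n, replace = TRUE), 0L),
      stringsAsFactors = FALSE)
  }
  empty_hits <- data.frame(protein_id = character(), start = integer(),
                           end = integer(), pfam_acc = character(),
                           pfam_name = character(), stringsAsFactors = FALSE)
  empty_truth <- data.frame(proteome_id = character(),
                            protein_id = character(), start = integer(),
                            end = integer(), type = character(),
                            residue = character(), stringsAsFactors = FALSE)
  keep <- function(lst, empty) {
    lst <- lst[!vapply(lst, is.null, logical(1))]
    if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE)))
    else empty
  }
  list(records = do.call(rbind, c(all_rec, list(make.row.names = FALSE))),
       hits = keep(all_hits, empty_hits),
       flags = do.call(rbind, c(all_flags, list(make.row.names = FALSE))),
       truth = keep(all_truth, empty_truth),
       pfam2go = pfam2go,
       config = config)
}

#' Write a simulation to disk in the pipeline's input dialects
#'
#' Emits one FASTA per proteome, a pfam_scan-style domain table, TMHMM
#' short and SignalP 5 summary tables, a pfam2go snippet and the
#' ground-truth TSV, plus an input manifest usable by [run_survey()].
#'
#' @param sim result of [simulate_proteomes()].
#' @param dir output directory (created if needed).
#' @return The manifest data.frame (proteome_id, taxon, fasta path),
#'   invisibly; file paths are all inside `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- unique(sim$records[, c("proteome_id", "taxon")])
  man$fasta <- paste0(man$proteome_id, ".fasta")  # relative: reruns diff
  for (i in seq_len(nrow(man))) {
    rec <- sim$records[sim$records$proteome_id == man$proteome_id[i], ]
    write_fasta(rec, file.path(dir, man$fasta[i]))
  }
  h <- sim$hits
  pf_lines <- if (nrow(h)) sprintf(
    "%s %d %d %d %d %s.1 %s Domain 1 %d %d 50.0 1e-10 1",
    h$protein_id, h$start, h$end, pmax(1L, h$start - 2L), h$end + 2L,
    h$pfam_acc, h$pfam_name, h$end - h$start + 1L, h$end - h$start + 1L)
  else character()
  writeLines(c("# pfam_scan.pl synthetic output", pf_lines),
             file.path(dir, "pfamscan.txt"))
  fl <- sim$flags
  lens <- sim$records$length[match(fl$protein_id, sim$records$protein_id)]
  writeLines(sprintf(
    "%s len=%d ExpAA=%.2f First60=0.00 PredHel=%d Topology=o",
    fl$protein_id, lens, fl$n_tm_helices * 20.5, fl$n_tm_helices),
    file.path(dir, "tmhmm_short.txt"))
  writeLines(c("# SignalP-5.0 synthetic output", sprintf(
    "%s\t%s\t%.3f\t%.3f\tCS pos: 20-21",
    fl$protein_id,
    ifelse(fl$has_signal_peptide, "SP(Sec/SPI)", "OTHER"),
    ifelse(fl$has_signal_peptide, 0.98, 0.02),
    ifelse(fl$has_signal_peptide, 0.02, 0.98))),
    file.path(dir, "signalp.txt"))
  writeLines(c("!version date: synthetic", unlist(lapply(
    names(sim$pfam2go), function(acc) sprintf(
      "Pfam:%s SynDom > GO:synthetic term ; %s",
      acc, sim$pfam2go[[acc]])))),
    file.path(dir, "pfam2go.txt"))
  write.table(sim$truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man$fasta <- file.path(dir, man$fasta)
  invisible(man)
}

#' Recovery of planted LCRs by the pipeline
#'
#' A planted LCR counts as detected when some called LCR on the same
#' protein has at least 50% reciprocal overlap with it (intersection at
#' least half of BOTH intervals).
#'
#' @param truth planted LCR table (`protein_id`, `start`, `end`, `type`).
#' @param detected called (classified) LCR table; needs `protein_id`,
#'   `start`, `end`, and for the accuracy/confusion outputs
#'   `is_homopolymer` and `overlap_class`.
#' @param records protein record table (residue totals for the
#'   false-positive fraction).
#' @param hits domain hit table used to derive the planted interval's
#'   expected overlap class (optional).
#' @return List: `sensitivity`, `n_planted`, `n_detected`,
#'   `homopolymer_accuracy` (fraction of planted homopolymer tracts whose
#'   planted subsequence satisfies the homopolymer rule — the construction
#'   guarantee; `NA` when none), `homopolymer_called_agreement` (fraction
#'   of detected planted homopolymers whose matched called interval is
#'   classified homopolymeric; lower, since refinement may absorb flanking
#'   residues and dilute the dominant fraction),
#'   `false_positive_residue_fraction`, `overlap_confusion`
#'   (expected vs called class on matched pairs, when `hits` given),
#'   `positional_profiles` (planted vs called 10-bin profiles), and the
#'   per-planted-LCR `detail` table.
#' @export
recovery_report <- function(truth, detected, records, hits = NULL) {
  stopifnot(is.data.frame(truth), is.data.frame(detected))
  if (nrow(truth) &&
      length(setdiff(truth$protein_id, records$protein_id)))
    stop("ground truth references unknown protein id(s)")
  det_by <- if (nrow(detected))
    split(seq_len(nrow(detected)), detected$protein_id) else list()
  n <- nrow(truth)
  det <- logical(n); match_idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- det_by[[truth$protein_id[i]]]
    if (!length(j)) next
    d <- detected[j, , drop = FALSE]
    inter <- pmax(0L, pmin(truth$end[i], d$end) -
                       pmax(truth$start[i], d$start) + 1L)
    lt <- truth$end[i] - truth$start[i] + 1L
    lc <- d$end - d$start + 1L
    rec_ov <- inter / pmax(lt, lc)
    if (any(rec_ov >= 0.5)) {
      det[i] <- TRUE
      match_idx[i] <- j[which.max(rec_ov)]
    }
  }
  sens <- if (n) mean(det) else NA_real_
  # construction guarantee: planted homopolymer tracts satisfy the rule
  hp_acc <- NA_real_
  hp_all <- which(truth$type == "homopolymer")
  if (length(hp_all)) {
    seqs <- records$sequence[match(truth$protein_id[hp_all],
                                   records$protein_id)]
    hp_acc <- mean(vapply(seq_along(hp_all), function(k) {
      i <- hp_all[k]
      classify_homopolymer(substring(seqs[k], truth$start[i],
                                     truth$end[i]))$is_homopolymer
    }, logical(1)))
  }
  # agreement of the matched called interval with the planted type
  hp_called <- NA_real_
  hp <- which(truth$type == "homopolymer" & det)
  if (length(hp) && "is_homopolymer" %in% names(detected))
    hp_called <- mean(detected$is_homopolymer[match_idx[hp]])
  # false positives: called LCRs with no >= 50% reciprocal truth match
  fp_res <- 0
  if (nrow(detected)) {
    matched_calls <- unique(match_idx[!is.na(match_idx)])
    tr_by <- if (n) split(seq_len(n), truth$protein_id) else list()
    fp <- setdiff(seq_len(nrow(detected)), matched_calls)
    is_fp <- vapply(fp, function(j) {
      i <- tr_by[[detected$protein_id[j]]]
      if (!length(i)) return(TRUE)
      inter <- pmax(0L, pmin(detected$end[j], truth$end[i]) -
                         pmax(detected$start[j], truth$start[i]) + 1L)
      lt <- truth$end[i] - truth$start[i] + 1L
      lc <- detected$end[j] - detected$start[j] + 1L
      all(inter / pmax(lt, lc) < 0.5)
    }, logical(1))
    fp <- fp[is_fp]
    fp_res <- sum(detected$end[fp] - detected$start[fp] + 1L) /
      sum(records$length)
  }
  confusion <- NULL
  if (!is.null(hits) && any(det) && "overlap_class" %in% names(detected)) {
    hidx <- if (nrow(hits)) split(seq_len(nrow(hits)), hits$protein_id)
            else list()
    di <- which(det)
    exp_cl <- vapply(di, function(i) {
      d <- hidx[[truth$protein_id[i]]]
      classify_overlap(truth$start[i], truth$end[i],
                       if (length(d)) hits[d, , drop = FALSE] else NULL)
    }, character(1))
    confusion <- table(expected = exp_cl,
                       called = detected$overlap_class[match_idx[di]])
  }
  profiles <- NULL
  if (n && nrow(detected)) {
    plen <- records$length[match(truth$protein_id, records$protein_id)]
    tb <- vapply(seq_len(n), function(i)
      position_bin(truth$start[i], truth$end[i], plen[i]), integer(1))
    plen2 <- records$length[match(detected$protein_id,
                                  records$protein_id)]
    cb <- vapply(seq_len(nrow(detected)), function(j)
      position_bin(detected$start[j], detected$end[j], plen2[j]),
      integer(1))
    profiles <- list(planted = positional_profile(tb),
                     called = positional_profile(cb))
  }
  list(sensitivity = sens, n_planted = n, n_detected = sum(det),
       homopolymer_accuracy = hp_acc,
       homopolymer_called_agreement = hp_called,
       false_positive_residue_fraction = fp_res,
       overlap_confusion = confusion,
       positional_profiles = profiles,
       detail = data.frame(truth, detected = det,
                           stringsAsFactors = FALSE))
}
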