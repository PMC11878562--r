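#' Run the full LCR survey over a proteome set
#'
#' Per proteome: X-tract filtering, entropy segmentation, classification
#' and the integrated per-protein dataset. Across proteomes: co-occurrence
#' counts, positional profiles (overall and per taxon), composition tables,
#' homopolymer vs complex length histograms, enrichment tables (Pfam, GO,
#' taxon), a proteome-size correlation report, and a machine-readable run
#' manifest (parameter values and input checksums, no timestamps, so reruns
#' are byte-identical).
#'
#' @param manifest data.frame with columns `proteome_id`, `taxon`, `fasta`
#'   and optionally `pfamscan`, `tmhmm`, `signalp` (`NA` or missing =
#'   absent).
#' @param out_dir output directory, created if needed.
#' @param params a [seg_params()] object.
#' @param pfam2go_path optional pfam2go flat file.
#' @param reference_path optional 20-letter reference frequency TSV; the
#'   packaged UniProt-statistics-like table is used when `NULL`.
#' @param overlap_mode passed to [classify_overlap()].
#' @param fdr logical, Benjamini-Hochberg column in enrichment tables.
#' @return `out_dir`, invisibly. Side effect: report TSVs and
#'   `run_manifest.json` under `out_dir`.
#' @export
run_survey <- function(manifest, out_dir, params = seg_params(),
                       pfam2go_path = NULL, reference_path = NULL,
                       overlap_mode = "single", fdr = TRUE) {
  stopifnot(is.data.frame(manifest),
            all(c("proteome_id", "taxon", "fasta") %in% names(manifest)))
  for (col in c("fasta", "pfamscan", "tmhmm", "signalp")) {
    if (col %in% names(manifest)) {
      p <- manifest[[col]]
      p <- p[!is.na(p)]
      if (!all(file.exists(p)))
        stop("stage input: missing ", col, " file(s): ",
             paste(p[!file.exists(p)], collapse = ", "))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opt_path <- function(col, i) {
    if (!col %in% names(manifest)) return(NULL)
    p <- manifest[[col]][i]
    if (is.na(p) || !nzchar(p)) NULL else p
  }
  p2g <- if (!is.null(pfam2go_path)) read_pfam2go(pfam2go_path) else NULL
  if (is.null(reference_path))
    reference_path <- system.file("extdata", "uniprot_reference_freqs.tsv",
                                  package = "lcrsurvey")
  reference <- read_reference_composition(reference_path)

  recs <- lcrs <- hits <- flags <- removed <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    stage <- function(name, expr) tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for proteome ",
           manifest$proteome_id[i], ": ", conditionMessage(e),
           call. = FALSE))
    rec <- stage("read_fasta",
                 read_fasta(manifest$fasta[i], manifest$proteome_id[i],
                            manifest$taxon[i]))
    fx <- stage("filter_x_tracts", filter_x_tracts(rec))
    removed[[i]] <- fx$removed_ids
    rec <- fx$kept
    h <- if (!is.null(opt_path("pfamscan", i)))
      stage("read_pfamscan", read_pfamscan(manifest$pfamscan[i])) else NULL
    if (!is.null(h)) h <- h[h$protein_id %in% rec$protein_id, , drop = FALSE]
    fl <- stage("read_feature_tables",
                read_feature_tables(opt_path("tmhmm", i),
                                    opt_path("signalp", i)))
    l <- stage("segment", seg_detect_all(rec, params))
    l <- stage("classify", classify_lcrs(l, rec, h, overlap_mode))
    message(sprintf(
      "[%s] %d proteins (%d removed by X-tract filter), %d LCRs, %d domain hits",
      manifest$proteome_id[i], nrow(rec), length(fx$removed_ids), nrow(l),
      if (is.null(h)) 0L else nrow(h)))
    recs[[i]] <- rec; lcrs[[i]] <- l; hits[[i]] <- h; flags[[i]] <- fl
  }
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  lcr_all <- do.call(rbind, c(lcrs, list(make.row.names = FALSE)))
  hit_all <- do.call(rbind, c(hits[!vapply(hits, is.null, logical(1))],
                              list(make.row.names = FALSE)))
  flag_all <- do.call(rbind, c(flags, list(make.row.names = FALSE)))

  tsv <- function(x, name) write.table(
    x, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)

  write_main_dataset(records, lcr_all, hit_all, flag_all,
                     file.path(out_dir, "main_dataset.tsv"), p2g)

  cc <- cooccurrence_counts(records, lcr_all, hit_all, flag_all)
  tsv(cc$counts, "cooccurrence.tsv")
  tsv(cc$lcr_per_protein, "lcr_per_protein.tsv")

  # positional profiles, overall / per taxon / homopolymer vs complex
  prof_rows <- list()
  add_prof <- function(group, bins) {
    if (!length(bins)) return()
    prof_rows[[length(prof_rows) + 1L]] <<- data.frame(
      group = group, bin = 0:9, fraction = positional_profile(bins),
      stringsAsFactors = FALSE)
  }
  if (nrow(lcr_all)) {
    taxon_of <- records$taxon[match(lcr_all$protein_id,
                                    records$protein_id)]
    add_prof("all", lcr_all$position_bin)
    add_prof("homopolymer", lcr_all$position_bin[lcr_all$is_homopolymer])
    add_prof("complex", lcr_all$position_bin[!lcr_all$is_homopolymer])
    for (tx in sort(unique(taxon_of)))
      add_prof(paste0("taxon:", tx), lcr_all$position_bin[taxon_of == tx])
  }
  tsv(if (length(prof_rows)) do.call(rbind, prof_rows)
      else data.frame(group = character(), bin = integer(),
                      fraction = numeric()),
      "positional_profiles.tsv")

  # composition: LCR vs proteome background vs reference
  bg <- background_composition(records)
  comp <- data.frame(letter = AA20,
                     background_freq = unname(bg$frequencies),
                     reference_freq = unname(reference$frequencies),
                     stringsAsFactors = FALSE)
  if (nrow(lcr_all)) {
    lc <- aa_composition(lcr_all$subsequence, label = "LCR")
    comp$lcr_freq <- unname(lc$frequencies)
    comp$deviation_vs_background_pp <-
      unname(composition_deviation(lc, bg))
    comp$deviation_vs_reference_pp <-
      unname(composition_deviation(lc, reference))
  } else {
    comp$lcr_freq <- NA_real_
    comp$deviation_vs_background_pp <- NA_real_
    comp$deviation_vs_reference_pp <- NA_real_
  }
  tsv(comp, "composition.tsv")

  # homopolymer vs complex length histograms
  if (nrow(lcr_all)) {
    len <- lcr_all$end - lcr_all$start + 1L
    grp <- ifelse(lcr_all$is_homopolymer, "homopolymer", "complex")
    tt <- as.data.frame(table(group = grp, length = len),
                        stringsAsFactors = FALSE)
    tt$length <- as.integer(tt$length)
    tt <- tt[tt$Freq > 0L, ]
    names(tt)[3L] <- "n"
    tsv(tt[order(tt$group, tt$length), ], "length_histograms.tsv")
  } else {
    tsv(data.frame(group = character(), length = integer(),
                   n = integer()), "length_histograms.tsv")
  }

  # enrichment tables: Pfam, GO, taxon
  lcr_prot <- unique(lcr_all$protein_id)
  suppress_empty <- function(expr) withCallingHandlers(
    expr, warning = function(w) invokeRestart("muffleWarning"))
  if (!is.null(hit_all) && nrow(hit_all)) {
    pf_mem <- lapply(split(hit_all$protein_id, hit_all$pfam_acc), unique)
    tsv(suppress_empty(
      enrichment_table(pf_mem, lcr_prot, records$protein_id, fdr)),
      "enrichment_pfam.tsv")
    if (!is.null(p2g)) {
      go_of_hit <- p2g[hit_all$pfam_acc]
      go_mem <- list()
      for (k in seq_along(go_of_hit)) for (g in go_of_hit[[k]])
        go_mem[[g]] <- c(go_mem[[g]], hit_all$protein_id[k])
      go_univ <- unique(hit_all$protein_id[
        lengths(go_of_hit) > 0L])
      tsv(suppress_empty(
        enrichment_table(lapply(go_mem, unique), lcr_prot, go_univ, fdr)),
        "enrichment_go.tsv")
    }
  }
  tx_mem <- lapply(split(records$protein_id, records$taxon), unique)
  tsv(suppress_empty(
    enrichment_table(tx_mem, lcr_prot, records$protein_id, fdr)),
    "enrichment_taxon.tsv")

  # per-proteome abundance summaries + correlation report
  has_dom <- records$protein_id %in%
    (if (is.null(hit_all)) character() else hit_all$protein_id)
  summ <- do.call(rbind, lapply(sort(unique(records$proteome_id)),
    function(p) {
      sel <- records$proteome_id == p
      ids <- records$protein_id[sel]
      lp <- lcr_all[lcr_all$protein_id %in% ids, , drop = FALSE]
      lcr_ids <- unique(lp$protein_id)
      data.frame(
        proteome_id = p, n_proteins = sum(sel),
        n_lcr = nrow(lp),
        n_lcr_proteins = length(lcr_ids),
        n_lcr_domain = sum(lcr_ids %in% records$protein_id[sel & has_dom]),
        n_lcr_nodomain = sum(!lcr_ids %in%
                             records$protein_id[sel & has_dom]),
        n_homopolymer = sum(lp$is_homopolymer),
        lcr_residue_fraction = lcr_residue_fraction(
          records[sel, , drop = FALSE], lp),
        stringsAsFactors = FALSE)
    }))
  tsv(summ, "proteome_summaries.tsv")
  if (nrow(summ) >= 3L) {
    corr <- tryCatch(abundance_scaling(summ), error = function(e) NULL)
    if (!is.null(corr)) tsv(corr, "correlations.tsv")
  }

  inputs <- unlist(manifest[intersect(
    c("fasta", "pfamscan", "tmhmm", "signalp"), names(manifest))])
  inputs <- inputs[!is.na(inputs)]
  run_manifest <- list(
    package = "lcrsurvey",
    params = list(W = params$W, K1 = params$K1, K2 = params$K2,
                  refine = params$refine,
                  alphabet_size = params$alphabet_size,
                  overlap_mode = overlap_mode, fdr = fdr),
    proteomes = manifest$proteome_id,
    n_proteins = nrow(records),
    n_lcrs = nrow(lcr_all),
    x_tract_removed = sum(lengths(removed)),
    input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(run_manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
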