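#' Homopolymer test for one LCR subsequence
#'
#' An LCR is a homopolymer when some residue type has a run of at least
#' five consecutive occurrences AND makes up at least 70% of the LCR's
#' length. Ties between qualifying residues are broken by longest run,
#' then higher total count, then alphabetical order.
#'
#' @param lcr_sequence non-empty LCR subsequence.
#' @param min_run minimum run length (default 5).
#' @param min_fraction minimum fraction of the LCR length (default 0.70,
#'   inclusive).
#' @return `list(is_homopolymer = <logical>, dominant_residue = <letter or
#'   NA>)`.
#' @examples
#' classify_homopolymer("QQQQQSQQQQ")   # TRUE, Q (run 5, fraction 0.9)
#' classify_homopolymer("AAAAAAGGGGG")  # FALSE (run ok, fraction 6/11)
#' @export
classify_homopolymer <- function(lcr_sequence, min_run = 5L,
                                 min_fraction = 0.70) {
  stopifnot(is.character(lcr_sequence), length(lcr_sequence) == 1L,
            nchar(lcr_sequence) > 0L)
  chars <- strsplit(lcr_sequence, "")[[1L]]
  n <- length(chars)
  r <- rle(chars)
  run_len <- tapply(r$lengths, r$values, max)
  counts <- tapply(r$lengths, r$values, sum)
  ok <- run_len >= min_run & counts / n >= min_fraction
  if (!any(ok))
    return(list(is_homopolymer = FALSE, dominant_residue = NA_character_))
  cand <- names(ok)[ok]
  cand <- cand[order(-run_len[cand], -counts[cand], cand)]
  list(is_homopolymer = TRUE, dominant_residue = cand[1L])
}

#' Domain-overlap class of one LCR
#'
#' `nondomain_protein` when the protein has no domain hits; otherwise
#' `within_domain` when at least 80% of the LCR's residues lie inside SOME
#' single domain interval (boundary inclusive); otherwise
#' `outside_domain_in_domain_protein`. With `mode = "union"` the 80% is
#' evaluated against the union of all domain intervals instead.
#'
#' @param start,end LCR interval, 1-based inclusive.
#' @param domains data.frame of this protein's domain hits (`start`, `end`),
#'   zero rows for a domain-less protein.
#' @param min_fraction overlap threshold (default 0.80, inclusive).
#' @param mode `"single"` (default; per-domain test) or `"union"`.
#' @return One of `"within_domain"`, `"outside_domain_in_domain_protein"`,
#'   `"nondomain_protein"`.
#' @export
classify_overlap <- function(start, end, domains, min_fraction = 0.80,
                             mode = c("single", "union")) {
  mode <- match.arg(mode)
  stopifnot(start >= 1L, end >= start)
  if (is.null(domains) || nrow(domains) == 0L) return("nondomain_protein")
  len <- end - start + 1L
  if (mode == "single") {
    ov <- pmax(0L, pmin(end, domains$end) - pmax(start, domains$start) + 1L)
    frac <- max(ov) / len
  } else {
    covered <- rep(FALSE, len)
    for (i in seq_len(nrow(domains))) {
      a <- max(start, domains$start[i]); b <- min(end, domains$end[i])
      if (a <= b) covered[(a - start + 1L):(b - start + 1L)] <- TRUE
    }
    frac <- sum(covered) / len
  }
  if (frac >= min_fraction) "within_domain"
  else "outside_domain_in_domain_protein"
}

#' Positional decile of an LCR
#'
#' Index 0-9 of the LCR's midpoint along its protein, from N-terminus (0)
#' to C-terminus (9). The midpoint of the 1-based inclusive interval
#' `[start, end]` is `(start + end) / 2 - 1` on the 0-based residue axis;
#' the bin is `floor(10 * midpoint / protein_length)`, clamped to 9.
#'
#' @param start,end LCR interval, 1-based inclusive.
#' @param protein_length length of the containing protein.
#' @return Integer in `0:9`.
#' @export
position_bin <- function(start, end, protein_length) {
  stopifnot(protein_length >= 1L, start >= 1L, end >= start,
            end <= protein_length)
  m <- (start + end) / 2 - 1
  min(9L, as.integer(floor(10 * m / protein_length)))
}

#' Normalized positional profile of a group of LCRs
#'
#' @param bins integer vector of positional bins (0-9), one per LCR.
#' @return Numeric vector of 10 fractions summing to 1.
#' @export
positional_profile <- function(bins) {
  if (!length(bins)) stop("empty group")
  stopifnot(all(bins %in% 0:9))
  as.vector(tabulate(bins + 1L, nbins = 10L)) / length(bins)
}

#' Classify every detected LCR
#'
#' Applies the homopolymer rule, the domain-overlap rule and positional
#' binning to a table of detected LCRs.
#'
#' @param lcrs LCR table from [seg_detect_all()].
#' @param records protein record table (for protein lengths).
#' @param hits domain hit table (may have zero rows or be `NULL`).
#' @param overlap_mode passed to [classify_overlap()].
#' @return `lcrs` with added columns `is_homopolymer`, `dominant_residue`,
#'   `overlap_class`, `position_bin`.
#' @export
classify_lcrs <- function(lcrs, records, hits = NULL,
                          overlap_mode = "single") {
  if (is.null(lcrs) || nrow(lcrs) == 0L) {
    out <- if (is.null(lcrs))
      data.frame(protein_id = character(), start = integer(),
                 end = integer(), subsequence = character(),
                 stringsAsFactors = FALSE) else lcrs
    out$is_homopolymer <- logical(0)
    out$dominant_residue <- character(0)
    out$overlap_class <- character(0)
    out$position_bin <- integer(0)
    return(out)
  }
  plen <- records$length[match(lcrs$protein_id, records$protein_id)]
  if (anyNA(plen)) stop("LCR references unknown protein id")
  hidx <- if (!is.null(hits) && nrow(hits))
    split(seq_len(nrow(hits)), hits$protein_id) else list()
  n <- nrow(lcrs)
  is_h <- logical(n); dom_r <- character(n)
  ocl <- character(n); pbin <- integer(n)
  for (i in seq_len(n)) {
    h <- classify_homopolymer(lcrs$subsequence[i])
    is_h[i] <- h$is_homopolymer
    dom_r[i] <- h$dominant_residue
    d <- hidx[[lcrs$protein_id[i]]]
    ocl[i] <- classify_overlap(lcrs$start[i], lcrs$end[i],
                               if (length(d)) hits[d, , drop = FALSE]
                               else NULL,
                               mode = overlap_mode)
    pbin[i] <- position_bin(lcrs$start[i], lcrs$end[i], plen[i])
  }
  lcrs$is_homopolymer <- is_h
  lcrs$dominant_residue <- dom_r
  lcrs$overlap_class <- ocl
  lcrs$position_bin <- pbin
  lcrs
}

#' Feature co-occurrence counts
#'
#' Per proteome and overall: proteins with domains, with LCRs, with both;
#' signal-peptide and transmembrane co-occurrence with LCRs; total LCR
#' count; plus the distribution of LCR count per protein.
#'
#' @param records protein record table.
#' @param lcrs classified LCR table (may have zero rows).
#' @param hits domain hit table (may have zero rows or `NULL`).
#' @param flags feature flag table (or `NULL`).
#' @return `list(counts = <data.frame, one row per proteome plus "ALL">,
#'   lcr_per_protein = <data.frame n_lcr/n_proteins over proteins with >= 1
#'   LCR>)`.
#' @export
cooccurrence_counts <- function(records, lcrs, hits = NULL, flags = NULL) {
  fl <- join_flags(records, flags)
  has_dom <- records$protein_id %in% (if (is.null(hits)) character()
                                      else hits$protein_id)
  nl <- integer(nrow(records))
  if (!is.null(lcrs) && nrow(lcrs)) {
    tab <- table(lcrs$protein_id)
    i <- match(records$protein_id, names(tab))
    nl[!is.na(i)] <- as.integer(tab[i[!is.na(i)]])
  }
  has_lcr <- nl > 0L
  one <- function(sel, id) {
    data.frame(
      proteome_id = id,
      n_proteins = sum(sel),
      n_with_domain = sum(has_dom[sel]),
      n_with_lcr = sum(has_lcr[sel]),
      n_domain_and_lcr = sum(has_dom[sel] & has_lcr[sel]),
      n_signal = sum(fl$has_signal_peptide[sel]),
      n_signal_and_lcr = sum(fl$has_signal_peptide[sel] & has_lcr[sel]),
      n_tm = sum(fl$n_tm_helices[sel] > 0L),
      n_tm_and_lcr = sum(fl$n_tm_helices[sel] > 0L & has_lcr[sel]),
      n_lcr_total = sum(nl[sel]),
      stringsAsFactors = FALSE)
  }
  ids <- sort(unique(records$proteome_id))
  counts <- do.call(rbind, c(lapply(ids, function(p)
    one(records$proteome_id == p, p)),
    list(one(rep(TRUE, nrow(records)), "ALL"))))
  dist <- if (any(has_lcr)) {
    tt <- table(nl[has_lcr])
    data.frame(n_lcr = as.integer(names(tt)),
               n_proteins = as.integer(tt), stringsAsFactors = FALSE)
  } else data.frame(n_lcr = integer(), n_proteins = integer(),
                    stringsAsFactors = FALSE)
  list(counts = counts, lcr_per_protein = dist)
}
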