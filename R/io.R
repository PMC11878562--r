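#' Normalize a protein sequence
#'
#' Uppercases and maps the ambiguity codes B, Z, U, O, J to X so that
#' downstream entropy computation and the X-tract filter see a single
#' non-standard symbol.
#'
#' @param sequence character vector of raw sequences.
#' @return Character vector over `ACDEFGHIKLMNPQRSTVWYX`.
#' @export
normalize_sequence <- function(sequence) {
  chartr("BZUOJ", "XXXXX", toupper(sequence))
}

#' Read a protein FASTA file
#'
#' Parses with `Biostrings::readAAStringSet`, keeps the first whitespace
#' token of each header as the protein id, uppercases sequences and maps
#' B/Z/U/O/J to X. Record order is preserved.
#'
#' @param path FASTA file.
#' @param proteome_id label attached to every record.
#' @param taxon phylum (or other grouping) label attached to every record.
#' @return data.frame with columns `protein_id`, `sequence`, `proteome_id`,
#'   `taxon`, `length`. An empty or record-less file yields zero rows with a
#'   warning.
#' @export
read_fasta <- function(path, proteome_id = "proteome", taxon = "unassigned") {
  stopifnot(file.exists(path))
  empty <- data.frame(protein_id = character(), sequence = character(),
                      proteome_id = character(), taxon = character(),
                      length = integer(), stringsAsFactors = FALSE)
  # BStringSet: accept arbitrary letters at parse time so that residue
  # validation below can name the offending record
  aa <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) NULL)
  if (is.null(aa) || length(aa) == 0L) {
    warning("no FASTA records in ", path)
    return(empty)
  }
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate protein ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- normalize_sequence(as.character(aa))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad))
    stop("illegal characters after normalization in record(s): ",
         paste(ids[bad], collapse = ", "))
  data.frame(protein_id = ids, sequence = unname(seqs),
             proteome_id = proteome_id, taxon = taxon,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write protein records as FASTA
#'
#' @param records protein record data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$protein_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Remove sequences with long X tracts
#'
#' Drops every record containing a run of more than five consecutive X
#' (i.e. six or more); runs of exactly five are kept. Such tracts mark
#' unresolved sequence and produce artifactual LCR calls.
#'
#' @param records protein record data.frame.
#' @return `list(kept = <data.frame>, removed_ids = <character>)`.
#' @export
filter_x_tracts <- function(records) {
  stopifnot(is.data.frame(records))
  drop <- grepl("X{6,}", records$sequence)
  list(kept = records[!drop, , drop = FALSE],
       removed_ids = records$protein_id[drop])
}

#' Read pfam_scan output
#'
#' Whitespace-delimited `pfam_scan.pl` rows; `#` comments and blank lines
#' are ignored. Alignment start/end (columns 2-3) define the domain
#' interval; the `.N` version suffix is stripped from the HMM accession.
#'
#' @param path pfam_scan output file.
#' @return data.frame with columns `protein_id`, `start`, `end`,
#'   `pfam_acc`, `pfam_name`; one row per hit, overlaps retained.
#' @export
read_pfamscan <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), pfam_acc = character(),
                      pfam_name = character(), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  n <- lengths(fields)
  if (any(n < 13L))
    stop("malformed pfam_scan line ", idx[which(n < 13L)[1L]],
         " in ", path)
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(starts) || anyNA(ends))
    stop("malformed pfam_scan line ",
         idx[which(is.na(starts) | is.na(ends))[1L]], " in ", path)
  data.frame(protein_id = vapply(fields, `[`, "", 1L),
             start = starts, end = ends,
             pfam_acc = sub("\\.\\d+$", "", vapply(fields, `[`, "", 6L)),
             pfam_name = vapply(fields, `[`, "", 7L),
             stringsAsFactors = FALSE)
}

#' Read a pfam2go mapping
#'
#' Lines of the form
#' `Pfam:PF00076 RRM_1 > GO:mRNA binding ; GO:0003729`; `!` comment lines
#' are ignored; several lines per accession accumulate.
#'
#' @param path pfam2go flat file.
#' @return Named list: accession -> character vector of GO ids (sorted,
#'   unique).
#' @export
read_pfam2go <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(!|$)", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec(
      "^Pfam:(PF\\d+)\\s+\\S+\\s*>\\s*GO:.*;\\s*(GO:\\d+)\\s*$", ln))[[1L]]
    if (length(m) != 3L) {
      warning("skipping unparseable pfam2go line: ", ln)
      next
    }
    out[[m[2L]]] <- union(out[[m[2L]]], m[3L])
  }
  lapply(out, sort)
}

#' Read TMHMM / SignalP summary tables
#'
#' TMHMM `--short` format: one line per protein with `key=value` pairs
#' including `PredHel=N`. SignalP 5 tab/whitespace summary: protein id in
#' column 1, prediction (`SP(Sec/SPI)` vs `OTHER`) in column 2. Either table
#' may be absent; a protein absent from a table gets that field's default
#' (0 helices / no signal peptide).
#'
#' @param tmhmm_path optional TMHMM short-format file (`NULL` to skip).
#' @param signalp_path optional SignalP 5 summary file (`NULL` to skip).
#' @return data.frame `protein_id`, `has_signal_peptide` (logical),
#'   `n_tm_helices` (integer), one row per protein mentioned in either table.
#' @export
read_feature_tables <- function(tmhmm_path = NULL, signalp_path = NULL) {
  tm <- data.frame(protein_id = character(), n_tm_helices = integer(),
                   stringsAsFactors = FALSE)
  if (!is.null(tmhmm_path)) {
    stopifnot(file.exists(tmhmm_path))
    lines <- readLines(tmhmm_path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(lines)) {
      ids <- sub("\\s.*$", "", lines)
      ph <- regmatches(lines, regexpr("PredHel=\\S+", lines))
      if (length(ph) != length(lines))
        stop("TMHMM line without PredHel in ", tmhmm_path)
      nh <- suppressWarnings(as.integer(sub("PredHel=", "", ph)))
      if (anyNA(nh)) stop("unparseable PredHel value in ", tmhmm_path)
      tm <- data.frame(protein_id = ids, n_tm_helices = nh,
                       stringsAsFactors = FALSE)
    }
  }
  sp <- data.frame(protein_id = character(), has_signal_peptide = logical(),
                   stringsAsFactors = FALSE)
  if (!is.null(signalp_path)) {
    stopifnot(file.exists(signalp_path))
    lines <- readLines(signalp_path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(lines)) {
      fields <- strsplit(trimws(lines), "\\s+")
      sp <- data.frame(
        protein_id = vapply(fields, `[`, "", 1L),
        has_signal_peptide = vapply(fields, `[`, "", 2L) == "SP(Sec/SPI)",
        stringsAsFactors = FALSE)
    }
  }
  ids <- union(tm$protein_id, sp$protein_id)
  data.frame(
    protein_id = ids,
    has_signal_peptide = ids %in% sp$protein_id[sp$has_signal_peptide],
    n_tm_helices = ifelse(match(ids, tm$protein_id, nomatch = 0L) > 0L,
                          tm$n_tm_helices[match(ids, tm$protein_id)], 0L),
    stringsAsFactors = FALSE)
}

join_flags <- function(records, flags) {
  has_sp <- rep(FALSE, nrow(records))
  n_tm <- rep(0L, nrow(records))
  if (!is.null(flags) && nrow(flags)) {
    i <- match(records$protein_id, flags$protein_id)
    hit <- !is.na(i)
    has_sp[hit] <- flags$has_signal_peptide[i[hit]]
    n_tm[hit] <- flags$n_tm_helices[i[hit]]
  }
  data.frame(protein_id = records$protein_id,
             has_signal_peptide = has_sp, n_tm_helices = n_tm,
             stringsAsFactors = FALSE)
}

#' Write the integrated per-protein dataset
#'
#' One tab-separated row per protein integrating domains, GO terms, LCR
#' calls (with homopolymer flag and overlap class), signal peptide and
#' transmembrane annotations. Rows are sorted by `(proteome_id,
#' protein_id)`; the layout is fixed so files can be diffed.
#'
#' @param records protein record data.frame.
#' @param lcrs classified LCR table from [classify_lcrs()] (may have zero
#'   rows). Needs `protein_id`, `start`, `end`, `is_homopolymer`,
#'   `overlap_class`.
#' @param hits domain hit table from [read_pfamscan()] (may have zero rows).
#' @param flags feature flag table from [read_feature_tables()] (or `NULL`).
#' @param path output TSV.
#' @param pfam2go optional accession -> GO ids mapping from [read_pfam2go()].
#' @return `path`, invisibly.
#' @export
write_main_dataset <- function(records, lcrs, hits, flags, path,
                               pfam2go = NULL) {
  stopifnot(is.data.frame(records))
  for (tab in list(lcrs, hits)) {
    if (!is.null(tab) && nrow(tab)) {
      missing <- setdiff(tab$protein_id, records$protein_id)
      if (length(missing))
        stop("annotation references unknown protein id(s): ",
             paste(head(missing, 5L), collapse = ", "))
    }
  }
  fl <- join_flags(records, flags)
  ord <- order(records$proteome_id, records$protein_id, method = "radix")
  rec <- records[ord, , drop = FALSE]

  dom_str <- go_str <- lcr_str <- rep("", nrow(rec))
  n_dom <- n_lcr <- integer(nrow(rec))
  if (!is.null(hits) && nrow(hits)) {
    hits <- hits[order(hits$protein_id, hits$start, hits$end,
                       method = "radix"), , drop = FALSE]
    sp <- split(seq_len(nrow(hits)), hits$protein_id)
    i <- match(rec$protein_id, names(sp))
    for (k in which(!is.na(i))) {
      h <- hits[sp[[i[k]]], , drop = FALSE]
      n_dom[k] <- nrow(h)
      dom_str[k] <- paste(sprintf("%s:%s:%d-%d", h$pfam_acc, h$pfam_name,
                                  h$start, h$end), collapse = ";")
      if (!is.null(pfam2go)) {
        gos <- sort(unique(unlist(pfam2go[h$pfam_acc], use.names = FALSE)))
        go_str[k] <- paste(gos, collapse = ";")
      }
    }
  }
  if (!is.null(lcrs) && nrow(lcrs)) {
    lcrs <- lcrs[order(lcrs$protein_id, lcrs$start, method = "radix"),
                 , drop = FALSE]
    sp <- split(seq_len(nrow(lcrs)), lcrs$protein_id)
    i <- match(rec$protein_id, names(sp))
    for (k in which(!is.na(i))) {
      l <- lcrs[sp[[i[k]]], , drop = FALSE]
      n_lcr[k] <- nrow(l)
      lcr_str[k] <- paste(sprintf("%d-%d:%s:%s", l$start, l$end,
                                  ifelse(l$is_homopolymer, "H", "C"),
                                  l$overlap_class), collapse = ";")
    }
  }
  out <- data.frame(
    proteome_id = rec$proteome_id, taxon = rec$taxon,
    protein_id = rec$protein_id, length = rec$length,
    n_domains = n_dom, domains = dom_str, go_terms = go_str,
    n_lcr = n_lcr, lcrs = lcr_str,
    has_signal_peptide = as.integer(fl$has_signal_peptide[ord]),
    n_tm = fl$n_tm_helices[ord],
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Main Dataset TSV back
#'
#' Inverse of [write_main_dataset()] at the row level; the packed `domains`
#' and `lcrs` fields stay packed (counts are in `n_domains` / `n_lcr`).
#'
#' @param path TSV written by [write_main_dataset()].
#' @return data.frame with the written columns.
#' @export
read_main_dataset <- function(path) {
  stopifnot(file.exists(path))
  read.table(path, sep = "\t", header = TRUE, quote = "",
             colClasses = c(proteome_id = "character", taxon = "character",
                            protein_id = "character", domains = "character",
                            go_terms = "character", lcrs = "character"),
             stringsAsFactors = FALSE, comment.char = "")
}

#' Unpack the `lcrs` column of a Main Dataset
#'
#' @param md data.frame from [read_main_dataset()].
#' @return data.frame `protein_id`, `start`, `end`, `is_homopolymer`,
#'   `overlap_class`, one row per LCR.
#' @export
unpack_lcrs <- function(md) {
  rows <- md[md$n_lcr > 0L, , drop = FALSE]
  if (!nrow(rows))
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), is_homopolymer = logical(),
                      overlap_class = character(), stringsAsFactors = FALSE))
  parts <- strsplit(rows$lcrs, ";", fixed = TRUE)
  pid <- rep(rows$protein_id, lengths(parts))
  tok <- strsplit(unlist(parts, use.names = FALSE), ":", fixed = TRUE)
  iv <- strsplit(vapply(tok, `[`, "", 1L), "-", fixed = TRUE)
  data.frame(protein_id = pid,
             start = as.integer(vapply(iv, `[`, "", 1L)),
             end = as.integer(vapply(iv, `[`, "", 2L)),
             is_homopolymer = vapply(tok, `[`, "", 2L) == "H",
             overlap_class = vapply(tok, `[`, "", 3L),
             stringsAsFactors = FALSE)
}
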