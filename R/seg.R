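#' Segmentation parameters
#'
#' Bundles the entropy-segmentation parameters. Defaults are the moderate
#' setting widely used for protein LCR surveys: a 15-residue window, a
#' 1.9-bit trigger threshold and a 2.5-bit extension threshold.
#'
#' @param W integer window length in residues (>= 2).
#' @param K1 trigger entropy threshold in bits: a window with Shannon entropy
#'   <= `K1` seeds a low-complexity region.
#' @param K2 extension entropy threshold in bits (`K1 <= K2`): windows with
#'   entropy <= `K2` extend a seeded region.
#' @param refine logical; reduce each merged region to its
#'   minimum-probability subsequence (see [seg_detect()]).
#' @param alphabet_size size of the residue alphabet used by the refinement
#'   null model (20 standard residues; X participates in entropy but not in
#'   the null).
#' @return An object of class `seg_params`.
#' @examples
#' seg_params()
#' seg_params(K1 = 2.2)
#' @export
seg_params <- function(W = 15L, K1 = 1.9, K2 = 2.5, refine = TRUE,
                       alphabet_size = 20L) {
  W <- as.integer(W)
  stopifnot(length(W) == 1L, W >= 2L,
            length(K1) == 1L, length(K2) == 1L,
            K1 >= 0, K1 <= K2, K2 <= log2(alphabet_size + 1),
            is.logical(refine), length(refine) == 1L,
            alphabet_size >= 2)
  structure(list(W = W, K1 = K1, K2 = K2, refine = refine,
                 alphabet_size = as.numeric(alphabet_size)),
            class = "seg_params")
}

#' @export
print.seg_params <- function(x, ...) {
  cat(sprintf("seg_params: W = %d, K1 = %g, K2 = %g, refine = %s\n",
              x$W, x$K1, x$K2, x$refine))
  invisible(x)
}

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence))
    stop("sequence contains letters outside ACDEFGHIKLMNPQRSTVWYX; ",
         "normalize with read_fasta()/normalize_sequence() first")
  sequence
}

#' Shannon entropy of a residue window
#'
#' Entropy in bits, `H = -sum(p_i log2 p_i)` over the residue types present
#' in the window. X counts as a 21st residue type.
#'
#' @param window non-empty string over the 20 amino-acid letters plus X.
#' @return Entropy in bits, in `[0, log2(min(nchar(window), 21))]`.
#' @examples
#' window_entropy(strrep("A", 15))               # 0
#' window_entropy("AAAAAGGGGGSSSSS")             # log2(3)
#' @export
window_entropy <- function(window) {
  check_sequence(window)
  if (nchar(window) == 0L) stop("empty window")
  h <- .seg_window_entropies(window, nchar(window))
  h[1L]
}

#' Sliding-window entropies
#'
#' Entropy (bits) of every length-`W` window of `sequence`; element `p` is
#' the window starting at position `p` (1-based). Returns a zero-length
#' vector when the sequence is shorter than `W`.
#'
#' @param sequence normalized protein sequence.
#' @param W window length.
#' @return Numeric vector of length `max(0, nchar(sequence) - W + 1)`.
#' @export
window_entropies <- function(sequence, W = 15L) {
  check_sequence(sequence)
  .seg_window_entropies(sequence, as.integer(W))
}

#' Trigger window positions
#'
#' Positions (1-based window starts) whose length-`W` window has entropy
#' `<= K1`, i.e. the seeds of low-complexity regions.
#'
#' @param sequence normalized protein sequence.
#' @param params a [seg_params()] object.
#' @return Integer vector of window start positions (empty when the sequence
#'   is shorter than `W`).
#' @export
find_trigger_windows <- function(sequence, params = seg_params()) {
  h <- window_entropies(sequence, params$W)
  which(h <= params$K1)
}

#' Detect low-complexity regions in one sequence
#'
#' Entropy-based segmentation: every window with entropy `<= K1` seeds a
#' region; the seed is extended over the maximal surrounding run of window
#' positions with entropy `<= K2`; overlapping or adjoining extended regions
#' are merged; when `params$refine` is `TRUE` each merged region is reduced
#' to its minimum-probability subsequence — the contiguous subinterval
#' minimizing `L * (H - log2(alphabet_size))`, the Stirling approximation of
#' the log-probability of the subinterval's residue composition under an
#' equiprobable null (ties broken toward the longer subinterval, then the
#' smaller start).
#'
#' @param sequence normalized protein sequence.
#' @param params a [seg_params()] object.
#' @return data.frame with columns `start`, `end` (1-based inclusive) and
#'   `subsequence`; intervals sorted and non-overlapping. Zero rows when
#'   nothing triggers or the sequence is shorter than `params$W`.
#' @examples
#' seg_detect(strrep("Q", 100))                        # one interval 1..100
#' seg_detect(paste(rep(c("A","C","D","E"), 25), collapse = ""))
#' @export
seg_detect <- function(sequence, params = seg_params()) {
  check_sequence(sequence)
  m <- .seg_segment(sequence, params$W, params$K1, params$K2,
                    params$refine, params$alphabet_size)
  if (nrow(m) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      subsequence = character(), stringsAsFactors = FALSE))
  data.frame(start = unname(m[, 1L]), end = unname(m[, 2L]),
             subsequence = substring(sequence, m[, 1L], m[, 2L]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect LCRs across a protein table
#'
#' Runs [seg_detect()] on every row of a protein record table.
#'
#' @param records protein record data.frame from [read_fasta()].
#' @param params a [seg_params()] object.
#' @return data.frame with one row per detected LCR: `proteome_id`,
#'   `protein_id`, `start`, `end`, `subsequence`.
#' @export
seg_detect_all <- function(records, params = seg_params()) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "sequence") %in% names(records)))
  pid <- if ("proteome_id" %in% names(records)) records$proteome_id
         else rep(NA_character_, nrow(records))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", records$sequence)
  if (any(bad))
    stop("non-normalized sequence(s): ",
         paste(head(records$protein_id[bad], 5L), collapse = ", "))
  res <- lapply(records$sequence, .seg_segment, params$W, params$K1,
                params$K2, params$refine, params$alphabet_size)
  nr <- vapply(res, nrow, integer(1))
  if (!sum(nr))
    return(data.frame(proteome_id = character(), protein_id = character(),
                      start = integer(), end = integer(),
                      subsequence = character(), stringsAsFactors = FALSE))
  idx <- rep.int(seq_len(nrow(records)), nr)
  m <- do.call(rbind, res)
  data.frame(proteome_id = pid[idx], protein_id = records$protein_id[idx],
             start = unname(m[, 1L]), end = unname(m[, 2L]),
             subsequence = substring(records$sequence[idx], m[, 1L],
                                     m[, 2L]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of residues inside LCRs
#'
#' Total LCR length divided by total protein length over a proteome set.
#'
#' @param records protein record data.frame (must have `length`).
#' @param lcrs LCR table from [seg_detect_all()] (`start`, `end`).
#' @return Fraction in `[0, 1]`.
#' @export
lcr_residue_fraction <- function(records, lcrs) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty proteome")
  tot <- sum(records$length)
  if (tot <= 0) stop("empty proteome")
  if (is.null(lcrs) || nrow(lcrs) == 0L) return(0)
  sum(lcrs$end - lcrs$start + 1L) / tot
}
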