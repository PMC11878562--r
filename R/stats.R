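#' Amino-acid composition profile
#'
#' Frequencies of the 20 standard residues over a residue multiset given as
#' one or more sequences. X is excluded from both the profile and the
#' residue count.
#'
#' @param sequences character vector of (sub)sequences; their residues are
#'   pooled.
#' @param label profile label (e.g. `"LCR"`, `"background"`).
#' @return `list(frequencies = <named numeric over the 20 letters>,
#'   n_residues = <int>, label = <chr>)`, class `aa_composition`.
#' @examples
#' aa_composition("QSQS")$frequencies[c("Q", "S")]
#' @export
aa_composition <- function(sequences, label = "composition") {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  all <- paste(sequences, collapse = "")
  chars <- strsplit(chartr("X", " ", all), "")[[1L]]
  chars <- chars[chars != " "]
  if (!length(chars)) stop("no residues left after excluding X")
  bad <- setdiff(unique(chars), AA20)
  if (length(bad)) stop("non-standard residue(s): ",
                        paste(bad, collapse = ", "))
  counts <- table(factor(chars, levels = AA20))
  freqs <- setNames(as.vector(counts) / length(chars), AA20)
  structure(list(frequencies = freqs, n_residues = length(chars),
                 label = label),
            class = "aa_composition")
}

#' @export
print.aa_composition <- function(x, ...) {
  cat(sprintf("aa_composition '%s' over %d residues\n", x$label,
              x$n_residues))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Background composition of a proteome set
#'
#' Pooled residue frequencies over all residues of all proteins (not
#' averaged per protein).
#'
#' @param records protein record table.
#' @return An `aa_composition` labelled `"background"`.
#' @export
background_composition <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  aa_composition(records$sequence, label = "background")
}

#' Read a 20-letter reference frequency table
#'
#' Two-column TSV (letter, frequency), e.g. UniProt-statistics-like
#' reference frequencies. Frequencies are renormalized to sum to 1.
#'
#' @param path TSV with columns `letter` and `freq` (header optional).
#' @return An `aa_composition` labelled `"reference"`.
#' @export
read_reference_composition <- function(path) {
  stopifnot(file.exists(path))
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  stopifnot(ncol(tab) >= 2L)
  f <- setNames(as.numeric(tab[[2L]]), tab[[1L]])
  if (!setequal(names(f), AA20))
    stop("reference table must cover exactly the 20 standard residues")
  f <- f[AA20] / sum(f)
  structure(list(frequencies = f, n_residues = NA_integer_,
                 label = "reference"), class = "aa_composition")
}

#' Percentage-point deviation between two composition profiles
#'
#' `100 * (profile - reference)` per letter; the deviations sum to zero.
#'
#' @param profile,reference `aa_composition` objects over the 20 letters.
#' @return Named numeric vector of percentage-point differences.
#' @export
composition_deviation <- function(profile, reference) {
  stopifnot(inherits(profile, "aa_composition"),
            inherits(reference, "aa_composition"))
  100 * (profile$frequencies - reference$frequencies[names(profile$frequencies)])
}

#' Enrichment arithmetic for one category
#'
#' Given a category's protein count, its observed count of LCR-containing
#' proteins and the expected count under the global LCR fraction, computes
#' the difference, the enrichment in percentage points
#' `100 * (O - E) / N`, and the 2x2 chi-squared contribution
#' `(O-E)^2/E + ((N-O)-(N-E))^2/(N-E)`.
#'
#' @param n_total proteins in the category.
#' @param n_observed category proteins with at least one LCR.
#' @param expected expected count `n_total * p0`.
#' @return data.frame with `difference`, `enrichment_pp`,
#'   `chi2_contribution` (vectorized over the inputs).
#' @export
enrichment_stats <- function(n_total, n_observed, expected) {
  stopifnot(all(n_observed >= 0), all(n_observed <= n_total))
  diff <- n_observed - expected
  data.frame(
    difference = diff,
    enrichment_pp = 100 * diff / n_total,
    chi2_contribution = ifelse(
      diff == 0, 0,
      diff^2 / expected + diff^2 / (n_total - expected)))
}

#' Observed/expected enrichment table over categories
#'
#' For every category (GO term, Pfam accession, taxon, ...) counts the
#' member proteins with at least one LCR and compares with the expectation
#' under the universe-wide LCR fraction `p0 = |lcr_proteins n universe| /
#' |universe|`.
#'
#' @param membership named list: category id -> character vector of member
#'   protein ids (must be subsets of `universe`).
#' @param lcr_proteins protein ids with at least one LCR.
#' @param universe protein ids forming the analysis universe.
#' @param fdr add Benjamini-Hochberg adjusted p-values (default `TRUE`).
#' @return data.frame with one row per category: `category_id`, `n_total`,
#'   `n_observed`, `expected`, `difference`, `enrichment_pp`,
#'   `chi2_contribution`, `p_value` (1 df) and `fdr`; sorted by decreasing
#'   `|difference|`. Categories with no members are skipped with a warning.
#' @export
enrichment_table <- function(membership, lcr_proteins, universe,
                             fdr = TRUE) {
  stopifnot(is.list(membership), length(universe) >= 1L)
  universe <- unique(universe)
  lcr_in <- intersect(unique(lcr_proteins), universe)
  p0 <- length(lcr_in) / length(universe)
  rows <- lapply(names(membership), function(cat) {
    members <- intersect(unique(membership[[cat]]), universe)
    if (!length(members)) {
      warning("category '", cat, "' has no members in universe; skipped")
      return(NULL)
    }
    n <- length(members)
    o <- sum(members %in% lcr_in)
    e <- n * p0
    st <- enrichment_stats(n, o, e)
    data.frame(category_id = cat, n_total = n, n_observed = o,
               expected = e, st, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(category_id = character(), n_total = integer(),
                      n_observed = integer(), expected = numeric(),
                      difference = numeric(), enrichment_pp = numeric(),
                      chi2_contribution = numeric(), p_value = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_value <- pchisq(out$chi2_contribution, df = 1, lower.tail = FALSE)
  out$fdr <- if (fdr) stats::p.adjust(out$p_value, method = "BH")
             else NA_real_
  out[order(-abs(out$difference)), , drop = FALSE]
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction; `df = (r-1)(c-1)`.
#'
#' @param tab matrix of non-negative counts, at least 2x2.
#' @return `list(statistic, df, p_value)`.
#' @export
chi2_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) >= 2L, ncol(tab) >= 2L, all(tab >= 0))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in table")
  e <- outer(rs, cs) / n
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  cor(x, y, method = "pearson")
}

#' Proteome-size scaling of LCR abundance
#'
#' Pearson correlations between proteome size and the LCR abundance
#' summaries, one row per metric.
#'
#' @param summaries data.frame with one row per proteome and columns
#'   `n_proteins` plus any of `n_lcr_proteins`, `n_lcr_nodomain`,
#'   `n_lcr_domain`, `n_homopolymer`.
#' @return data.frame `metric`, `r`.
#' @export
abundance_scaling <- function(summaries) {
  stopifnot(is.data.frame(summaries), "n_proteins" %in% names(summaries))
  if (nrow(summaries) < 3L) stop("need at least 3 proteomes")
  metrics <- intersect(c("n_lcr_proteins", "n_lcr_nodomain",
                         "n_lcr_domain", "n_homopolymer"),
                       names(summaries))
  if (!length(metrics)) stop("no abundance metric columns found")
  data.frame(metric = metrics,
             r = vapply(metrics, function(m)
               pearson_r(summaries$n_proteins, summaries[[m]]),
               numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
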