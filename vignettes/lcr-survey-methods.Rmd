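---
title: "Detecting and classifying low-complexity regions in protein sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying low-complexity regions in protein sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrsurvey)
```

## The problem

Low-complexity regions (LCRs) are protein segments built from few residue
types — poly-glutamine tracts, serine-rich stretches, and similar
compositionally biased sequence. They are abundant across eukaryotic
proteomes, tend to avoid conserved domain cores, favour protein termini,
and carry a characteristic residue palette (enriched in small/polar and
negatively charged residues, depleted in bulky hydrophobics and in
arginine/lysine). `lcrsurvey` packages the full survey workflow: entropy
segmentation, classification, composition and enrichment statistics, and a
ground-truthed synthetic proteome generator so every stage can be validated
without downloading data.

## The segmentation model

Detection follows the classical entropy-segmentation scheme. For a window
of length $W$ the Shannon entropy over residue types present is

$$H = -\sum_i \frac{n_i}{W}\,\log_2 \frac{n_i}{W},$$

where $n_i$ are residue counts; the unknown residue X participates as a
21st type. A window with $H \le K_1$ *triggers* a candidate region; the
trigger is extended over the maximal surrounding run of window positions
with $H \le K_2$; overlapping or directly adjoining extended regions are
merged. The defaults, $W = 15$, $K_1 = 1.9$ bits, $K_2 = 2.5$ bits, are the
moderate parameter set in wide use for protein LCR surveys; they are
deliberately conservative (lower $K_1$ means fewer, more strongly biased
triggers).

**Refinement.** Each merged region is optionally reduced to its
minimum-probability subsequence. The probability of a composition
$\{n_i\}$ of length $L$ under an equiprobable $\Omega$-letter null is
$\binom{L}{n_1\ldots n_\Omega}\,\Omega^{-L}$, whose log is, by Stirling,
$L\,H - L\log_2\Omega$ (bits). We minimize that quantity over all
contiguous subintervals, breaking ties toward the longer subinterval and
then the smaller start. The $-L\log_2\Omega$ term matters: minimizing
$L\,H$ alone is degenerate (any single residue scores 0, so every
multi-letter LCR would collapse to its longest single-residue run), whereas
the full objective trims high-entropy flanks while retaining biased cores.
This objective, with $\Omega = 20$, is this package's fixed, testable
surrogate for classical SEG refinement; byte-compatibility with the
original C program is explicitly not promised.

Numerical choices: entropies are compared with plain `<=` (entropy values
are sums of logs of small rationals and do not sit at the thresholds);
refinement ties use an absolute tolerance of $10^{-9}$; sequences shorter
than $W$ yield no calls (no full window exists — a documented limitation);
no minimum length is imposed on refined calls. A brute-force oracle —
per-window entropy recomputed from scratch and an exhaustive $O(m^2)$
subinterval scan — is implemented independently in the test suite and the
two paths are required to agree exactly on thousands of random sequences.

## Classification rules

* **Homopolymer**: an LCR is homopolymeric when some residue has a run of
  at least 5 consecutive copies *and* makes up at least 70% of the LCR
  length. Both thresholds are inclusive. At most one residue can reach
  70%, but the dominant-residue tie-break (longest run, then count, then
  alphabetical) is still fixed for determinism.
* **Domain overlap**: with respect to its protein's domain annotations an
  LCR is `nondomain_protein` (no hits), `within_domain` (at least 80% —
  inclusive — of its residues inside *some single* domain interval), or
  `outside_domain_in_domain_protein`. Testing each hit separately is the
  default because overlap is with "a domain"; a union-of-domains mode is
  available (`classify_overlap(mode = "union")`).
* **Position**: each protein is treated as 10 equal bins from N- to
  C-terminus and an LCR votes once, with its midpoint
  ($m = (start+end)/2 - 1$ on the 0-based axis, bin
  $\lfloor 10m/L\rfloor$ clamped to 9). Midpoint voting matches per-LCR
  accounting elsewhere; note that exact reversal equivariance
  ($bin_{rev} = 9 - bin$) holds only when the midpoint is at least one
  residue below the next bin boundary, because reversal maps midpoint $m$
  to $L-1-m$.

## Statistics

Composition profiles are pooled residue frequencies over the 20 standard
letters (X excluded). The proteome background pools all residues of all
proteins; an external 20-line reference table (UniProt-statistics-like,
shipped in `extdata`) provides the fixed reference. Deviations are
reported in percentage points and sum to zero.

Category enrichment compares each category's observed count of
LCR-containing proteins $O$ with the expectation $E = N p_0$, where $p_0$
is the LCR-protein fraction of the analysis universe (GO-annotated
proteins for GO tables, all proteins otherwise — the universe is
configurable because published tables leave it implicit). The enrichment
statistic is percentage points, $100\,(O-E)/N$; this algebraic form exactly
reproduces every row of the published GO-term reference table shipped in
`extdata` (the acceptance suite recomputes all 31 rows). Each category also
gets its 2×2 Pearson chi-squared contribution
$(O-E)^2/E + (O'-E')^2/E'$, a raw p-value (1 df) and a Benjamini–Hochberg
FDR; the FDR is reported alongside raw values because published
chi-squared tables typically state no correction. GO terms are used as
mapped (no ancestor propagation), a known divergence risk for absolute
counts on real data.

`chi2_test()` is an uncorrected Pearson test with $(r-1)(c-1)$ df; zero
marginals are an error, as is zero variance in `pearson_r()`.

## The synthetic world

No generative model is published for fungal LCRs; the generator's
distributions are inventions constrained by descriptive statistics of real
surveys, fixed once and stated here:

* **Proteomes**: protein count uniform/evenly spaced in
  `proteome_size_range` (default 2 000–20 000, the span of real fungal
  proteomes); protein lengths log-normal with median 400 aa (`sdlog`
  0.45), clamped to 60–5000.
* **Background**: uniform over the 20 residues. A 15-residue window of
  uniform draws essentially never reaches 2.5 bits of entropy from above,
  so the background is detection-silent (the false-positive residue
  fraction is checked to be below 1%).
* **Planted LCRs**: Poisson per protein (mean 0.45 — with ~22 aa mean
  LCR length and 400 aa proteins this reproduces the ≈2.5% LCR residue
  share real surveys report). 7% are homopolymers (10–20 aa, dominant
  residue drawn from a glutamine-led profile, substitutions at 10% of
  positions but never in the first five, so the run-and-fraction rule
  holds by construction); the rest are complex LCRs (20–30 aa, at most 3
  residue types drawn from a profile over-weighting A, D, E, P, N, Q, S, T
  — serine and glutamine leading — and depleting
  C, F, I, L, M, V, W, Y, R, K). At most 3 types guarantees every full
  window inside a complex LCR is at or below $\log_2 3 \approx 1.58 <
  K_1$, i.e. planted LCRs are detectable by construction.
* **Placement**: 40% of LCRs land in a terminal decile (homopolymers
  choose the C-terminal one 75% of the time, echoing the C-terminal
  preference of real homorepeats); planted intervals keep a 30-residue
  gap so separate plants are called separately.
* **Annotations**: 62% of proteins get 1–3 synthetic domain intervals
  (50–200 aa); 15% of planted LCRs in such proteins get a covering domain
  so all three overlap classes occur in known proportion; signal peptides
  (6%) and transmembrane helix counts (17%, 1–7 helices) are emitted in
  SignalP-5 / TMHMM-short dialects.

What a green recovery test establishes is therefore limited: the generator
emulates the *statistical* structure the analysis assumes (length ranges,
composition bias, terminal preference, proportional scaling of LCR counts
with proteome size), not the evolutionary texture of real proteomes (no
repeat expansion dynamics, no homology, no length/composition coupling,
uniform background rather than real residue frequencies). Dataset-dependent
published numbers (correlation coefficients, per-phylum counts, the 2.52%
residue share) are echoed qualitatively on synthetic data, not reproduced.

Detection slop is expected and quantified rather than hidden: window
extension and refinement may absorb flanking residues that repeat an
LCR's letters, so a called interval can exceed its plant. Recovery uses
50% *reciprocal* overlap, and the homopolymer-accuracy metric evaluates
the rule on the planted tract (the construction guarantee); agreement on
the called interval is reported separately since flank absorption can
dilute a short homopolymer below the 70% rule.

## Scaled-down test sizes

The acceptance tests run the full stated world but at desk scale: the
proteome-size scaling check uses 30 proteomes spanning 400–4 000 proteins
rather than 2 000–20 000. Under the generator's proportional-rate model the
Pearson correlation between size and LCR-protein count is scale-free, so
the reduction changes runtime, not the property being tested.

## Worked example

```{r example, eval = FALSE}
library(lcrsurvey)

sim <- simulate_proteomes(synth_config(
  n_proteomes = 2, proteome_size_range = c(300, 500), seed = 7))
lcrs <- classify_lcrs(seg_detect_all(sim$records), sim$records, sim$hits)
lcr_residue_fraction(sim$records, lcrs)
recovery_report(sim$truth, lcrs, sim$records, sim$hits)$sensitivity
```

## Known limitations

* Not byte-compatible with the original SEG binary; the refinement
  objective is a stated surrogate, checked against this package's own
  brute-force oracle instead.
* Domain boundaries come from pfam_scan *alignment* coordinates (its
  primary reported boundaries); envelope coordinates would shift overlap
  classes slightly and are not currently parsed.
* GO enrichment uses direct pfam2go terms only — no GO-graph ancestor
  propagation.
* Pipeline configuration files are JSON or flat `key=value` (no YAML
  parser in the dependency footprint).
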