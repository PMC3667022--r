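---
title: "Methods and design of txmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of txmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txmine)
```

# Scope and model

`txmine` implements the analysis core of a two-library de novo transcriptome
study: exact-test digital gene expression on RPKM-normalized counts,
hypergeometric term enrichment, microsatellite (EST-SSR) marker mining, and
six-frame ORF coding triage, together with a ground-truthed synthetic-data
generator. This vignette records the statistical model, the parameter
conventions, and the design decisions that were genuinely open.

# Read counting

Reads are assigned to unigenes by full-length, ungapped alignment with at
most `max_mismatch = 2` substitutions. Candidate placements come from exact
k-mer seed hits (default `k = 21`): a read of length 75 is covered by three
disjoint 21-mers, and two mismatches can corrupt at most two of them, so by
pigeonhole every qualifying placement shares at least one seed exactly — the
seeded search therefore loses nothing relative to an exhaustive scan, which
the test suite confirms against a brute-force all-offsets scanner
(`hamming_scan()`). Design choices:

* **Ungapped, substitutions only.** The mismatch budget is a
  substitution-style contract; indel-tolerant alignment would need scoring
  choices the counting model does not define.
* **Ties discarded.** A read whose best score is achieved by two *distinct*
  unigenes is left unassigned. This makes counts deterministic and
  conservative; multi-mapping within one unigene still counts once.
* **Unstranded by default.** Reverse-complement placements are searched
  unless `revcomp = FALSE`.
* **Library total `N`** is the realized number of *assigned* reads, matching
  the normalization formula's own definition of "mappable reads", not the
  sequencer yield.

# RPKM

`rpkm(C, N, L) = 1e9 * C / (N * L)` in double precision, no pseudocounts.
Zero-count unigenes are kept with RPKM 0; zeros are handled downstream (an
infinite log-ratio is a legitimate, potentially significant observation; a
0-vs-0 unigene is never significant). RPKM is invariant to scaling a library
and inversely proportional to length at fixed counts — both are property
tests.

# The exact test

For a unigene with `x` reads out of `N1` and `y` reads out of `N2`, the
Audic–Claverie model treats `y | x` as negative binomial with
`size = x + 1` and success probability `N1 / (N1 + N2)`:

$$p(y \mid x) = \left(\tfrac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}}$$

`ac_term()` evaluates this in log space (stable for `x + y` well past 1e5).
`ac_pvalue()` forms the two-sided p-value as
`min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`:

* **Tail summation.** The tail on the far side of the distribution mode
  (`floor(x * N2/N1)`) is summed directly with a log-sum-exp accumulator and
  truncated once a term falls below 1e-18 of the running sum — beyond the
  mode the term ratio is below 1 and eventually geometric, so the truncation
  error is provably below the tolerance. The other tail is taken by
  complement; whichever tail is *small* (the one that decides the p-value) is
  always the directly summed one, so no cancellation affects the result.
  The reference implementation in the tests goes through `pnbinom` instead,
  and the two agree to 1e-10 over the full `x, y <= 50` grid at three
  library-size ratios.
* **Two-sided by doubling.** The source method does not state sidedness;
  doubling the smaller tail (capped at 1) is the conservative standard for
  exact tests and is pinned here.
* **Conditioning asymmetry.** The published form conditions on sample 1, so
  `ac_pvalue(x, y, N1, N2)` and `ac_pvalue(y, x, N2, N1)` are *not*
  identical (the single terms differ by exactly the factor `N1/N2`, which is
  a property test). The package keeps the published orientation rather than
  symmetrizing; at the 0.001 cutoff the distinction rarely changes a call.
* **Significance rule.** `direction != not_significant` iff BH-FDR
  `q <= 0.001` *and* `|log2(RPKM2/RPKM1)| >= 1`. The ratio is oriented
  library 2 over library 1.

**Compositional caveat.** With no replicates and only within-library
normalization, a strong expression shift in part of the transcriptome moves
the relative abundance of everything else, and the exact test reports those
shifts as differential too. The null false-positive rate (validated at
`de_fraction = 0`: the fraction of calls at `q <= 0.001` stays below 0.5% in
at least 95% of 50 replicate simulations) is a statement about the no-change
null, not about per-gene error under asymmetric global change. This mirrors
the behaviour of the original study design, which reported very large DE
fractions between tissues.

# Enrichment

`hypergeom_pvalue(N, n, M, m)` is the upper tail
`P(X >= m) = 1 - sum_{i<m} C(M,i) C(N-M,n-i) / C(N,n)`, computed through
`phyper` (log-space binomials; the test oracle is exhaustive enumeration for
all feasible quadruples with `N <= 60`). Decisions:

* Over-representation only; depletion is not tested.
* The background `N` is the *annotated* unigene set, not the transcriptome.
* The Bonferroni divisor is the number of terms actually tested (those with
  at least one annotated member); testing vacuous terms would only inflate
  the correction.
* Both corrections use the same cutoff, 0.05, on the corrected value.

# EST-SSR mining

A microsatellite is a perfect tandem repeat: at least 5 repetitions of a
primitive 2–6 bp unit. `detect_ssrs()` finds maximal runs per unit length by
comparing the sequence against its own k-shift (`N` breaks any run), trims
each run to whole units anchored at the run start, rejects non-primitive
units (their repeats are found at the primitive unit length), and resolves
overlaps deterministically — longest span, then leftmost, then smallest unit.
Coordinates are 0-based half-open throughout; only human-readable reports
convert to 1-based.

Motif classes group units under **cyclic rotation only**: `canonical_motif()`
maps each primitive unit to its lexicographically minimal rotation. This
convention is pinned by the observed category counts in the reference study
(6 dinucleotide and 20 trinucleotide classes, the analytic maxima);
reverse-complement merging would give 4 and 10 instead, contradicting them.
The class counts for k = 1..6 (4, 6, 20, 60, 204, 670) are verified against
the aperiodic-necklace closed form in the tests.

Marker selection (`select_marker_loci()`) re-expresses the study's
primer-design filters without external tools: sequence uniqueness is "shares
no exact 60 bp window with another unigene" — an alignment-free stand-in for
an all-against-all BLAST screen at a stringent E-value, with the window size
configurable; flanks of 50 bp on each side must be free of short repeats
(>= 3 repetitions); and the unigene must accommodate a spanning PCR product
of >= 150 bp.

# Coding triage

`find_orfs()` reports, per frame and strand, the longest open span between
stop codons (getORF-like stop-to-stop spans by default; a start-anchored mode
requires a leading in-frame ATG). Codons containing `N` count as neither stop
nor start. A unigene is "coding" when its best ORF is strictly longer than
300 bp (`classify_coding()`); the trained coding-potential model the original
study also used is intentionally out of scope — this module reproduces only
the length-threshold triage, which is why its false-negative behaviour on
genuinely coding but fragmented unigenes is inherited from that rule.

# The synthetic generator

`synthetic_spec()` fixes the simulated study conditions used by the test
suite; the defaults are deliberate and not tuned per test:

| parameter | default | rationale |
|---|---|---|
| `n_unigenes` | 2000 | desk-scale stand-in for a 1e5-unigene assembly |
| length law | log-normal(log 600, 0.6) clamped to [100, 3000] bp | matches the short-contig-dominated size range of de novo assemblies; the true empirical length law of the reference assembly is not published beyond histogram bins, so this is a stand-in, not a claim |
| `library_sizes` | (5e5, 5e5) | two un-replicated libraries |
| `de_fraction`, `de_log2fc` | 0.1, 3 | planted signal strong enough that power is a property of the method, not of borderline counts |
| `dispersion` | 0 (Poisson) | the tag-sampling model underlying the exact test; negative binomial available for robustness checks |
| enriched term | M = 50, odds 8:1, among 50 terms | one unambiguous planted positive against a uniform-random null annotation |

Counts are drawn with expectation proportional to length x expression,
scaled to the target library size; the realized totals (the actual column
sums) are what downstream stages use as `N1`, `N2`. Reads are uniform
substrings with i.i.d. substitution errors; planted ORFs are intact
ATG..stop spans; planted SSRs overwrite the sequence verbatim at their
offset. Everything is reproducible byte-for-byte from the seed.

What the generator does **not** emulate: assembly artifacts (chimeras,
fragmented or redundant isoforms), positional coverage bias, quality-score
profiles, strand-specific protocols, and annotation structure beyond a flat
term map. Passing tests therefore demonstrate correctness of the algorithms
under the stated sampling model, not robustness to assembly pathology.

# Numerical conventions and degenerate inputs

* Printed percentages use half-up rounding to 2 decimals (`percent_of()`),
  the convention that reproduces the reference study's printed values;
  banker's rounding differs in edge cases.
* `p = 1` at `x = y`, `N1 = N2` holds to ~1e-12 numerically (an exact
  identity mathematically); p-values are clamped into `(0, 1]`.
* Zero-length libraries, zero-length unigenes, infeasible hypergeometric
  quadruples, mismatched unigene sets and dangling locus references all
  raise errors naming the offender; empty inputs (no unigenes, no reads, no
  DE genes, no loci) flow through and produce empty, well-typed results.
* The reference tables packaged under `inst/extdata` assert their internal
  invariants at load time; the repeat-element table preserves one printed
  figure verbatim ("31,8339" bp of simple repeats) alongside the
  interpretation (318,339) consistent with its percentage column.

# Problem sizes in the test suite

The suite validates operating characteristics by simulation at the spec'd
conditions: 50 replicate null simulations of 2000 unigenes for false-positive
control, 20 replicates for DE recall (>= 80% of truly DE unigenes with
expected count >= 20 at |log2 fc| = 3) and planted-term recovery (>= 90% of
replicates under both corrections), oracle equivalence of the exact test on
the full `x, y <= 50` grid, of the SSR detector on 500 random 1 kb sequences
per run, of the hypergeometric tail on every feasible quadruple with
`N <= 60`, and of the read counter on a 50-unigene x 2000-read instance.

# Known limitations

* No replicate-aware inference (negative-binomial GLMs and shrinkage
  estimators are the right tool when replicates exist).
* No between-library normalization (TMM/quantile): the exact test interprets
  compositional shifts as differential expression by design.
* SSR detection covers perfect repeats only — no compound or interrupted
  microsatellites — and the uniqueness filter is an exact-window proxy, not
  an aligner.
* Coding triage is length-only; short or fragmented CDS below 300 bp are
  systematically missed, as in the rule it reproduces.
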