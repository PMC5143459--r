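---
title: "Methods: 3'-end annotation, CAU classification and CCA-templating rollups"
author: "trnacca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3'-end annotation, CAU classification and CCA-templating rollups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnacca)
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the parameters that matter, the numerical
choices made where the design was genuinely open, what the synthetic-data
generator does and does not emulate, and the known limitations.

## The 3'-end alignment model

Bacterial tRNA gene records frequently stop the annotated gene short of
the CCA template even when the template is genomically present at the
start of the 3' trailer. To call CCA-templating consistently we need
Sprinzl coordinates 66-76 assigned to the 3' region of every record, and
we obtain them by optimally base-pairing the acceptor stem's two strands.

For each record, `x` is the reverse of the 5'-most seven annotated
acceptor-stem bases (`m = 7`) and `y` is the last 12 bases of the
annotated 3' end followed by the first five bases of the trailer
(`n = 17`; records with fewer than 12 annotated 3' bases are flagged
truncated and aligned on what is there). The matrix recurrence is

$$H(i,j) = \max\bigl(H(i-1,j-1) + s(x_i,y_j) + a(x_i,y_j),\;
H(i-1,j) + g,\; H(i,j-1) + g\bigr)$$

with a zero boundary row and column, and **no floor at zero** — this is a
semi-global alignment, not a local one. The assumption built into the
model is that the acceptor stem is (mostly) base-paired: Watson-Crick and
wobble juxtapositions score `s = 4`, everything else `s = 1`, gaps cost
`g = -5` per residue, and an optional bonus `a = 1` rewards
juxtapositions the source database itself annotated as stem pairs. These
values are deliberately blunt — the optimisation landscape is tiny
(7 x 17) and the parameters only need to make seven pairings beat any
gapped or shifted alternative. All four are user-settable through
`ScoringScheme()`, with the validity constraint
`matchScore > mismatchScore > gapPenalty`.

### Numerical choices in the dynamic program

Three details are under-determined by the recurrence alone; the package
fixes them explicitly, for reproducibility:

* **Boundary reading.** A literal reading of the boundary conditions as
  zeroing row/column *1* would make stem base 1 unscorable; the package
  uses the standard `(m+1) x (n+1)` convention where the zero boundary is
  an index-0 row/column and cell `(i, j)` scores `x_i` against `y_j`.
* **Traceback start.** The optimum is taken over the *final row*, not at
  `H(m, n)`: the stem heptamer must be fully consumed, but `y`
  deliberately extends past the stem (discriminator, 74-76, trailer).
  The boundary cell of the final row is always reachable, so the optimum
  is never negative. Ties are broken toward the smallest column
  (the 5'-most placement), and at equal-score steps the traceback
  prefers diagonal, then up, then left. All ties are therefore resolved
  deterministically.
* **Coordinate 73 after a gapped stem end.** Positions 73-76 are defined
  as the four `y` residues following the traceback start column. When
  the alignment ends with a pair on stem position 1 this is exactly
  "the four residues after coordinate 72"; when it ends in a gap,
  coordinate 72 is reported absent and 73-76 still follow the consumed
  region. Ambiguity codes (N) in `y` score as mismatches, never as
  pairs.

The aligner never rewrites the acceptor-stem annotation itself; it only
assigns 3'-region coordinates. A gene **templates CCA** iff its residues
at 74-76 read CCA (T/U and case-insensitive); records whose 74-76 could
not all be assigned are conservatively called non-templating.

Correctness is checked against an independent brute-force oracle that
enumerates every monotone gapped alignment as a monotone index matching
and scores it in closed form; the test suite compares the dynamic
program against this enumeration on hundreds of random instances (up to
5 x 7, where the enumeration is exhaustive), plus closed-form cases: a
perfectly paired heptamer scores 28, or 35 with a full annotation bonus.

## Profile classification of CAU-anticodon genes

The three CAU-anticodon classes — initiator fMet, elongator Met and the
lysidinylated-Ile elongator — are distinguished by position-specific
log-odds models over a fixed 29-column Sprinzl frame (acceptor positions
1-7 and 66-76, the 11:24 D-stem partners, anticodon-stem strands
29-31/39-41, anticodon 34-36). The frame is an *input* contract: this
package does not compute structural alignments, it consumes them.

Per class `c`, column `k` and symbol `b` (A, C, G, U and gap as a fifth
symbol), the model probability is the pseudocount-smoothed within-class
frequency, and the score of a sequence is
$\sum_k \log_2 p_c(b_k, k) / q(b_k)$ bits. The background `q` is the
pooled training composition *under the same smoothing* — concretely the
class-size-weighted mean of the smoothed model columns. Matching the
smoothing on both sides matters: a naive raw-count background makes any
symbol that is rare everywhere (gaps, in clean training data) score as a
spurious bonus, because the class-level smoothing mass (1 pseudocount in
~100 observations) exceeds the pooled-level one (1 in thousands). With
matched smoothing an everywhere-absent symbol scores ~0 bits, and as the
pseudocount grows all log-odds flatten to zero.

Tunable parameters, with defaults:

* `pseudocount = 1` per symbol per column — the classical add-one
  choice; the training sets here (hundreds per class) make the result
  insensitive to it.
* `marginMin = 1` bit — calls whose margin over the runner-up is smaller
  are flagged ambiguous but keep their best class. One bit (a twofold
  likelihood ratio) is an arbitrary but conventional floor.
* `backgroundShuffles = 1000`, `zMin = 5` — the background score
  distribution is estimated from seed-fixed within-sequence shuffles,
  and a genome is flagged as lacking a viable initiator when no gene is
  called `Ini` at `z >= zMin`. Five standard deviations is deliberately
  strict: the flag is meant to find genomes whose putative initiators
  score *inside* the shuffle background, and real profile hits on these
  short frames sit far outside it.

Prior annotations are only ever revised within the CAU family
(`Ini`/`Met`/`kIle`/`Unspecified`); the twenty canonical elongator
labels, Sec and Pyl pass through untouched, and overwriting a prior
initiator label raises a warning because initiator calls are expected to
be stable.

## Feature tables and summary statistics

Structural features are read off the same frame: the 1:72 acceptor pair,
the 11:24 D-stem pair, and the juxtaposed anticodon-stem triplets
29-31/39-41. Pair categories partition all 16 base combinations into 4
Watson-Crick, 2 wobble and 10 mismatches; gaps form an `absent` category
counted in its own row. Derived percentages divide one row-set by
another within chosen columns and are rounded **half-up** to one decimal
so they can be compared against published one-decimal figures at a
±0.1 tolerance (base R's round-half-even would make 0.05-boundary cases
unstable).

The shipped fixtures under `inst/extdata/` transcribe printed summary
tables (a reannotation confusion matrix over 9,917 CAU-anticodon genes
and three feature-by-class tables); their margins are recomputed from
the cells rather than stored. On the 1:72 table, treating every
non-Watson-Crick row as "mismatched" reproduces the published derived
fractions (77.5% C1-A72 among mismatched initiators; 99.5% paired
1:72 among elongators at the package's rounding).

The G-test of independence uses natural logs, `G = 2 sum(O ln(O/E))`
with margin-derived expectations, zero cells contributing zero, and the
chi-square survival function for p. No Williams or continuity correction
is applied by default — the correction is available via a flag but off,
since it is rarely material at the gene counts involved and its use in
comparable analyses is typically unstated.

## Taxonomic rollups and pattern calls

Genome summaries count genes and CCA-templating genes per functional
class (multi-copy genes count individually). Clade rollups group genomes
by their lineage ancestor at a requested rank. Two frequency readings
are implemented because the choice is genuinely open: the default pools
genes (`sum templating / sum genes`, gene-weighted), the alternative
averages per-genome frequencies unweighted; genome size is always
averaged unweighted. Classes are ordered by decreasing pooled frequency
over the whole input.

Clades are called into four phyletic patterns from their pooled
initiator and elongator frequencies, with thresholds `high = 0.5` and
`low = 0.10` (the low threshold mirrors the conventional reading of
"intermediate" templating as above 10%): `all_template` (both >= high),
`none_template` (both < low), `initiator_predominant` (initiator >= high
and elongator below half the initiator frequency),
`elongator_predominant` (elongator >= high, initiator < low). Rules are
tried in that order; a clade matching none exactly gets the rule with
the smallest total threshold violation, so every clade receives exactly
one deterministic label. Clades without initiator genes are called from
the elongator side alone and flagged.

## The synthetic-data generator

`simulateGenomes()` emits per-genome gene record sets with the
statistical structure the analysis assumes, and records every ground
truth (class, templating flag, 1:72 pair, true 66-76 placement). Its
defaults *are* the study conditions the package targets:

* initiator 1:72 motif: C1-A72 mismatch with probability 0.775, the
  rare U1:A72 Watson-Crick match at 0.015, the remainder spread over the
  other mismatches;
* elongator 1:72: Watson-Crick or wobble with probability 0.995 (drawn
  uniformly over the six pairing combinations);
* CCA-templating probability 0.741 for initiators and 0.662 for
  elongator classes;
* a 10% chance that the 74-76 triplet sits in the trailer rather than
  inside the annotated gene end, emulating the records whose annotated
  gene stops before the CCA template;
* gene bodies of fixed length 55 random bases, 10-base context windows,
  complementary 7-bp acceptor stems outside the 1:72 motif position, and
  a small two-phylum/four-genus default taxonomy.

One integer seed drives everything; per-genome substreams are derived
from a stated string hash of the genome id, so genome order never
changes any genome's genes. `simulateTrainingAlignment()` emits labelled
frame-aligned sequences per class, with class-distinct consensus at the
1:72, 11:24 and anticodon-stem motif columns and independent per-column
noise (default 5%: a column is replaced by a uniformly random base).

What the generator does **not** emulate — and hence what passing tests
do and do not show about real data: no covariation beyond the planted
stem complementarity, no real alignment uncertainty (the frame is exact
by construction), no introns or split genes, no class-specific
anticodon-loop biology beyond the motif columns, no database-level
annotation noise other than the trailer-placement and missing-3'-strand
options, and class consensus separations that are cleaner than real
inter-genus variation. Tests against the generator validate the
*machinery* (the aligner recovers planted placements; the classifier
recovers planted classes at better than 98% sensitivity/specificity
under 5% noise; rollups reproduce planted frequencies within binomial
bounds); they do not certify performance on real database records.

## Problem sizes and runtime choices

The test-suite simulations are desk-scale by design: oracle equivalence
runs 500 random instances at sizes where exhaustive enumeration is exact
(up to 5 x 7); end-to-end templating recovery uses 10 genomes with 1,000
initiator and 1,000 elongator genes at the default probabilities and
checks the 3-sigma binomial band; classifier performance uses 200
training and 200 held-out sequences per class. These sizes put every
Monte-Carlo check comfortably inside its stochastic tolerance while the
whole suite runs in well under a minute.

## Known limitations

* The record dialect is this package's own single-line TSV stand-in for
  a defunct database dump format; a byte-level reproduction of the
  original layout was never published.
* The profile classifier is a functional analogue of profile-based tRNA
  classifiers, not a byte-level reimplementation of any external tool or
  its shipped model files; published database-wide figures that depend
  on those inputs are reproduced only as generator defaults, not as
  recomputable targets.
* Full-length Sprinzl numbering (positions 8-65), covariance-model
  alignment, acceptor-stem re-annotation and gene finding are all out of
  scope; the features module consumes already-aligned sequences.
* Published derived fractions carry small internal inconsistencies at
  the last digit (row-total versus quoted-count mismatches); the
  fixtures transcribe the printed cells and the package documents, but
  does not resolve, those discrepancies.
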