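---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactomir)
```

This vignette is the package's own account of the science it implements:
the models and rules behind each stage, the tunable parameters with their
defaults and the reasoning behind them, what the synthetic-data generator
does and does not emulate, and the numerical conventions that make results
deterministic.

## The analysis design

The pipeline targets the single-replicate, two-library small-RNA sequencing
design: two pooled libraries (here called *peak* and *late*) of 18–30 nt
reads, compared without biological replicates.  In that design, expression
differences can only be assessed by an exact count-based test conditional on
the library totals, novel miRNAs can only be supported by structural
evidence (a hairpin precursor that folds), and target prediction falls back
on complementarity rules because no interaction data exist.  Each stage
below is the standard form of that generation of analyses, implemented so
that every rule is explicit, configurable and testable.

## Read cleaning

Raw reads pass six filters applied in a fixed order (a→f), so that every
removed read is attributed to exactly one cause and the attribution is
reproducible:

| filter | rule | default |
|---|---|---|
| a. low quality | mean Phred below threshold | 20 |
| b. no 3' adapter | exact seed-and-extend match required | ≥ 6 nt overlap |
| c. 5' contaminant | insert starts with the 3' end of the 5' adapter | 6 nt |
| d. no insert | adapter found at position 1 | — |
| e. poly-A | fraction of A in the trimmed insert | ≥ 0.8 |
| f. length | insert outside `[min_len, max_len]` | 18–30 nt |

Three of these thresholds are genuinely open choices — no published value
exists for the quality cutoff, the poly-A fraction, or the adapter-matching
dialect.  The package uses a mean-Phred rule (simple, monotone, easily
reasoned about), a 0.8 poly-A fraction, and exact adapter matching with a
seed-and-extend scheme (first occurrence of the adapter's leading 6-mer
whose extension matches the adapter up to the read end).  Exact matching
was preferred over mismatch-tolerant trimming because it is deterministic
and auditable; all three are exposed in `clean_filter_config()`.

## The folding engine

Discovery and target prediction need secondary-structure and duplex
energies.  The built-in engine uses a deliberately small, fully specified
model:

* **Pairs** are Watson–Crick or G:U; hairpin loops hold at least 3 unpaired
  bases; no pseudoknots.
* **Energy** is the sum of nearest-neighbour stack terms between adjacently
  nested pairs (a 6×6 table over pair types, Turner-style defaults in
  kcal/mol, `default_stack_energies()`), plus a **helix initiation penalty**
  of +4.1 kcal/mol charged once per maximal helix.  Loops are otherwise
  free.
* **Determinism**: on energy ties the traceback prefers leaving a base
  unpaired and otherwise takes the 5'-most partner, so a sequence always
  returns one dot-bracket; a structure with no pairs has energy exactly 0.

The initiation penalty matters.  Under pure stacking with free loops, every
chance 2–3-pair helix in random sequence is profitable, and a random 120 nt
window folds to around −60 kcal/mol — which would make an absolute
precursor threshold of −18 kcal/mol vacuous.  With the +4.1 kcal/mol charge
(the order of the duplex initiation term in standard nearest-neighbour
models), a helix must recover its initiation cost, random sequence folds
near the threshold scale (≈ −10 to −30 kcal/mol depending on length), and
genuine planted hairpins fold far below it (≈ −40 to −70 kcal/mol).  The
engine's scale is not that of a full loop-parameterised model, so the
energy thresholds below are interpreted on the built-in scale and are all
config-exposed; a higher-fidelity external folding backend can be slotted
in by supplying energies through the same interfaces.

The engine is validated against an exhaustive enumeration oracle — an
independent recursion that generates *every* valid structure and scores
each with a separate linear scan — on random sequences up to 30 nt
(1,000 cases in the acceptance suite).

The duplex fold is the intermolecular analogue: the best ungapped
antiparallel offset of two strands, each maximal run of consecutive pairs
scoring its stacks plus one initiation charge.  The randomization test uses
Altschul–Erickson dinucleotide-preserving shuffles (an Euler-path
construction, exact dinucleotide counts asserted per shuffle) and the
add-one estimator `P = (1 + #{E_shuffle ≤ E_obs}) / (n + 1)`.

## Novel miRNA discovery

Unannotated, perfectly mapped tags with abundance ≥ 2 and ≤ 20 genomic
copies seed candidate loci (overlapping hits clustered, most-abundant tag =
putative mature).  Because no published description of precursor excision
exists at this level of detail, the package scans precursor spans of
60–120 nt in 10 nt steps positioned around the mature, adds 10 nt flanks,
folds every window and keeps the lowest-energy one.  The candidate is then
screened against all criteria at once, each verdict recorded
(`crit_*` columns), with acceptance being their conjunction:

mature length 18–26 nt · cut-site depth ≥ 3 (reads sharing the mature 5'
end — the standard reading of a minimal Drosha/Dicer cut-site depth) ·
copy number ≤ 20 · precursor energy ≤ −18 kcal/mol · mature within one arm ·
≥ 14 mature/star pairs · largest bulge ≤ 4 nt · asymmetry ≤ 5 nt ·
mature/star spacing ≤ 35 nt · intergenic or intronic context · and the
pseudo-hairpin rejection: energy > −20 kcal/mol requires a shuffle-test
P ≤ 0.05.

Two derived conventions: the star sequence is computed geometrically from
the pairing map with a 2 nt 3' overhang (observed star reads are not
required — the design cannot guarantee them), and the genomic context is
judged at the expressed mature locus rather than over the whole excised
window, because windows extend up to ~70 nt beyond the hairpin and can
graze neighbouring annotation without changing where the miRNA actually
lies.  Overlapping accepted loci are merged keeping the highest-expression
mature (ties: 5'-most).

## Differential expression

Per-entity counts `x, y` with library totals `N1, N2`:

* `NE = count / total × 10⁶`; **reported** NE is truncated toward zero,
  the convention that reproduces the worked table rows used in the test
  suite (one published cell rounds instead — truncation is this package's
  single convention, applied uniformly).
* zero NE → 0.01; entities with NE < 1 in both libraries are removed.
* fold change = `log₂(late/peak)` on the substituted reported values (a
  full-precision variant via `fc_basis = "full"`); when truncation would
  zero a non-zero count the full-precision NE is used instead, so the
  logarithm is always defined.
* the exact conditional count test:
  `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^{x+y+1})`, two-sided as
  `min(1, 2·min(P(Y≤y), P(Y≥y)))`, computed by log-domain summation (no
  overflow at library scale, relative accuracy better than 1e−10 against a
  closed-form tail oracle).  The conditioning direction is canonicalised —
  condition on the larger count, ties to the larger library — which makes
  the statistic exactly symmetric under swapping the libraries; the raw
  one-directional form is only approximately so.
* flags: `#` when P ≥ 0.01 or |log₂FC| < 1; `*` when both thresholds are
  met; `**` when the entity is additionally detected in only one library.
  The conjunction (P **and** fold change) is the only rule consistent with
  highly expressed entities of small fold change being flagged
  non-significant; both cutoffs are arguments.

## Target prediction

Rules are positional over the full-length, ungapped, antiparallel duplex
(gapped duplexes would leave the positional windows ill-defined): total
mismatch score ≤ 4 with G:U = 0.5; no run of > 2 adjacent mismatches; no
adjacent mismatches in positions 2–12; no mismatch at 10–11; ≤ 2.5 in
positions 1–12; duplex energy ≥ 75 % of the perfect-complement energy; and
a strict ≤ 2 total override, on by default.  "Adjacent mismatch" is defined
as two consecutive non-Watson-Crick positions of which at least one is a
true mismatch — two adjacent wobbles do not count, since wobbles are
thermodynamically tolerated; the alternative behaviour is available via
`gu_adjacent = TRUE`.

The default transcript scan is exhaustive: every window of every transcript
is scored (with an exact vectorised mismatch-count prefilter — not a
heuristic — before energies are computed).  A 5'-seed k-mer prefilter is
available as an opt-in speed knob (`seed_length`), but it is not the
default because a seed requirement can miss sites whose two allowed
mismatches fall inside the seed region.

## Enrichment

For a background of `N` annotated genes, `n` target candidates, `M` genes
carrying a term and `m` targets carrying it, the upper tail
`P(X ≥ m) = Σ_{i=m} C(M,i)·C(N−M,n−i)/C(N,n)` is summed directly in log
space (exact against draw enumeration for `N ≤ 20`, and against the
standard distribution function at scale).  Bonferroni and BH-FDR go through
`stats::p.adjust()`.  The permissive significance threshold of 0.5 on the
corrected value is the convention of this analysis family and is kept as
the default, flagged as permissive; `alpha = 0.05` is one argument away.
No GO-graph ancestor propagation is performed — the term map is taken as
given.

## The synthetic-data generator

`generate_toy_genome()` plants, without overlap, on one random chromosome
(100 kb default): 20 hairpin precursors built as
stem + loop + reverse-complement(stem) (stems 22–28 nt, loops 8–12 nt,
matures 20–24 nt at the 5' arm) — foldable far below every threshold *by
construction*; 20 expressed decoy loci, built by dinucleotide-shuffling a
hairpin until the result folds **above** −18 kcal/mol (redrawing the source
hairpin when its composition admits no such shuffle), so each decoy fails
the energy criterion at its locus by construction; ncRNA decoys emitted as
GenBank-/Rfam-style catalogs; repeat copies; and exon/intron gene models.
`simulate_libraries()` writes adapter-ligated 36 nt reads with two-level
qualities (Phred 40/2 — sufficient to trigger the mean-quality filter,
which is the role qualities play here) and configurable noise classes that
map one-to-one onto the cleaning filters, recording every read's origin in
a truth manifest.  The default expression profile splits the miRNAs half
up- and half down-regulated at a planted 10-fold difference with library
totals near 100,000 reads — large enough that every planted difference is
unambiguously significant under the exact test, small enough that the full
end-to-end run takes well under a minute.

What the generator does **not** emulate: sequencer error models and quality
gradients, ligation bias, isomiR end-heterogeneity, expression dispersion
between replicates (there are none in this design), imperfect hairpins with
bulged stems, and cross-mapping between paralogues.  Passing the end-to-end
tests therefore demonstrates that the pipeline's logic is correct and its
criteria discriminate planted structure from shuffled background — not that
its thresholds are optimal for any particular real dataset.

## Validation problem sizes

The test suite validates each numerical engine against an independent
oracle at sizes where the oracle is exact: structure enumeration on 1,000
random sequences of 10–30 nt; duplex energies against offset enumeration at
≤ 15 nt; the count P-value against a closed-form tail oracle on 100 random
count/total tuples; the hypergeometric tail against full draw enumeration
at `N ≤ 20` plus a 1,000-draw null simulation at `N = 50,000, n = M = 5,000`
(sizes chosen so the discrete null P distribution is dense near the 0.05
level being checked); target verdicts against a literal transcription of
the rules on 10⁴ random duplexes; and one end-to-end synthetic run with 20
planted miRNAs, 20 decoys and 2 × 100,000 zero-noise reads.

## Known limitations

* The folding model is threshold-calibrated, not thermodynamically
  complete: no loop-size terms, no dangles, no multiloop penalties.  Its
  energies order structures sensibly but are not comparable to full
  nearest-neighbour implementations cell for cell.
* Counts from the two libraries are single observations; the exact test
  conditions on totals and cannot model biological dispersion.
* Annotation is priority-based and winner-takes-all; multi-category tags
  keep only their highest-priority label, as the design dictates.
* The target rules are complementarity-only; no conservation filtering, no
  3'-UTR restriction, no accessibility term.
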