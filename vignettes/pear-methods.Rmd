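---
title: "Quantifying prime editing with a splice-donor reporter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prime editing with a splice-donor reporter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peartools)
```

## Background

Prime editors (PE) are Cas9 nickases fused to a reverse transcriptase. A
prime-editing guide RNA (pegRNA) carries, beyond its 20-nt spacer, a 3'
extension consisting of a reverse-transcriptase template (RT) followed by a
primer binding site (PBS). The nickase cuts the PAM-containing
(protospacer) strand; the PBS hybridises to the freed 3' end and the RT is
copied into the genome, writing the programmed edit downstream (3') of the
nick. Editing efficiency depends strongly on PBS length, RT length and an
optional second nick on the complementary strand, so each target is
screened over a grid of designs.

A splice-donor fluorescent reporter (PEAR: prime editor activity reporter)
turns this editing event into a gain-of-function signal: a split
fluorescent protein is interrupted by an intron whose 5' splice donor has
been disabled (canonical context 5'-G-GT-AAGT-3' changed to G-AC-AAGT).
Prime editing reverts the donor to the canonical sequence, splicing is
restored, and edited cells fluoresce. Because the reporter is edited by the
same machinery as the chromosomal target, reporter-positive cells are
enriched for genomic editing, and sorting on the reporter (rather than on a
transfection marker) concentrates edited cells.

`peartools` implements the computational layer around such experiments:

1. target geometry and edit application on reference amplicons;
2. a seedable synthetic generator for amplicon reads and cell populations;
3. read alignment, anchor filtering, cut-site indel calling and per-read
   classification;
4. per-sample editing/indel/specificity quantification;
5. GUIDE-seq dsODN tag counting and mismatch-based off-target filtering;
6. pegRNA PBS/RT design and complementary-nick enumeration;
7. the three-gate enrichment analysis and an assumption-driven group
   comparison decision tree.

## Coordinate and sequence conventions

All coordinates are 0-based, half-open, on the forward strand of the
reference amplicon. Cut sites are inter-base integers: `cut_site = k` means
the nick falls between forward offsets `k - 1` and `k`. The SpCas9 nick is
placed between protospacer positions 17 and 18 (3 nt 5' of the NGG PAM on
the protospacer strand); the published screens express every secondary-nick
offset (+17, +103, +112) relative to this primary nick, which presupposes
exactly this fixed geometry. Spacers are written in the protospacer-strand
convention (the sequence followed by NGG), and degenerate bases are
rejected throughout. For minus-strand protospacers all design arithmetic is
performed after canonicalising the spec to the protospacer strand
(`canonicalize_spec`), and results are mapped back.

The intended edit is an `edit_spec` (substitution, insertion or deletion)
whose `ref_allele` must match the reference at its position; `apply_edit`
derives the edited amplicon and `invert_edit` gives the exact inverse, so
edit application round-trips by construction.

## Read alignment

`align_semi_global` is an affine-gap Gotoh alignment, global in the read
and with free end gaps in the reference: every read base is placed, but
unaligned reference flanks are not penalised, matching single-end amplicon
reads that start at the amplicon 5' end and may stop anywhere inside it.
Scoring defaults are match +1, mismatch −1 and a gap of length L costing
`gap_open + L * gap_extend = −4 − L`. The gap-cost convention (the opening
charge is added on top of a per-base extension charge for every gapped
base, including the first) is a deliberate choice; the test oracle scores
gaps identically, so the tests verify the optimisation rather than the
convention.

Tie-breaking is deterministic: diagonal moves are preferred over gaps at
every choice point and the smallest reference end position is taken on
final ties. Because a mismatch (−1) and a gap extension (−1) cost the
same, co-optimal alignments with different operation multisets exist on
essentially unrelated sequence pairs; on homologous read/template pairs —
the pipeline's actual inputs — the optimum is almost always unique. After
traceback, indels are left-normalised (shifted to their leftmost equivalent
placement, as in VCF normalisation) so indel positions are reproducible
regardless of traceback internals.

The implementation is compiled (Rcpp) because per-sample inputs are tens of
thousands of reads; an independent plain-R memoised recursion and, for tiny
inputs, a true exhaustive enumeration of all alignments serve as test
oracles.

## Read classification

Classification applies, in order:

1. **Anchor filter.** The read must match at least 75% of the first 20
   reference bases (anchor identity over reference positions 0–19;
   unaligned, deleted, mismatched or gapped anchor positions count as
   non-matches). 15/20 passes, 14/20 fails; reads whose alignment does not
   cover the anchor are filtered too.
2. **Intended edit.** For substitution edits the read must carry the
   alternate allele at the edit position *and contain no indel anywhere* —
   the "substitution without indels" rule. For intended insertions or
   deletions, the alignment must contain an indel identical to the
   (left-normalised) intended edit in kind, position, length and inserted
   bases.
3. **Byproduct indel.** Otherwise, an indel of any size whose reference
   anchor point — insertion point, or the nearer deletion boundary
   (inclusive) — lies within ±2 bp of the cut site makes the read an
   `indel_byproduct`.
4. Otherwise the read is `unedited`.

Two ambiguities in the verbal rules were resolved as follows. "Indels
without mismatches" is interpreted as: the indel call itself must be a
clean gap in the alignment; mismatches elsewhere in the read (sequencing
errors) are tolerated subject to the anchor rule. This keeps sequencing
errors from vetoing genuine indel calls while the anchor filter still
rejects junk reads. Second, the ±2 bp window keys on the indel's nearest
boundary/insertion point rather than on any-overlap semantics; with
left-normalised indels this makes window membership a deterministic
function of the called indel. Reads are classified in the given orientation
by default (the simulator and the specification share the 5'-anchored
orientation); `both_strands = TRUE` also tries the reverse complement and
keeps the orientation with the better anchor identity.

## Quantification

For a sample, `editing_pct = 100 * n_intended / n_total` and
`indel_pct = 100 * n_indel / n_total`, where `n_total` counts **all** reads
including anchor-filtered ones — "number of total reads" is taken
literally. Because the published analysis does not state whether
aligner-rejected reads counted toward totals, `denominator = "passing"`
optionally excludes them. Specificity is `editing_pct / max(indel_pct,
0.05)`: indel percentages below 0.05% — the stated resolution limit of the
sequencing assay — are replaced by 0.05 so that near-zero denominators do
not produce spuriously high specificity. The floor is a configurable
constant defaulting to that published value. TSV output is rounded to two
decimals; in-memory values keep full precision.

## The synthetic data generators

`simulate_reads` draws each read from the intended-edit template, a
byproduct-indel template or the unedited reference with fixed mixture
proportions, truncates to `read_len` from the amplicon 5' end, and applies
i.i.d. substitution errors per base. Defaults used across the tests and the
analysis scripts — 10,000 reads per sample, 30% intended editing, 5%
cut-site byproduct indels, 0.1%/base error — represent a realistic
well-performing prime-editing sample on a modern short-read instrument.
The error model is substitutions-only by default so that the ±2 bp window's
false-positive behaviour stays interpretable (sequencing indel errors would
otherwise be confounded with byproduct calls); quality strings are constant
because the classification applies no quality filtering. The generator does
**not** model PCR duplicates, chimeras, paired-end structure, position- or
motif-dependent error rates, or real indel-error processes — so passing
tests demonstrate correctness of the quantification rules, not robustness
to every artefact of real libraries.

`simulate_population` is a hierarchical Bernoulli model per cell:
transfection; plasmid (reporter) editing given transfection; genomic
editing with one of three conditionals depending on whether the plasmid was
edited, the cell was merely transfected, or untransfected. The constraint
`p(genomic | plasmid edited) >= p(genomic | transfected only)` encodes the
surrogate-marker hypothesis — cells that edit the reporter are the cells in
which editing works well. Observed BFP/GFP flags are the latent states
flipped by false-positive/false-negative detection rates (default 0).
Fluorescence is binary; continuous intensities, spectral spillover and
instrument gating are out of scope. The reference analytic population
(transfection 0.5, plasmid|transfect 0.4, genomic|plasmid 0.6,
genomic|transfect-only 0.1, genomic|untransfected 0) gives expected gate
rates of 15% (no enrichment), 30% (transfection gate) and 60% (reporter
gate) by the law of total probability, and simulations converge to these.

## GUIDE-seq tag counting and off-target filtering

A read counts as tag-positive when it contains the dsODN — or the 15-bp
centre fragment `GTTGTCATATGTTAA`/`TTAACATATGACAAC` — as an exact substring
in either orientation; matching is exact because the assay counts the tag
sequence itself, and each read counts at most once per category. The centre
fragment is a subsequence of the full 34-nt dsODN, so centre counts bound
full-tag counts from above. Counts are per read; read consolidation/UMI
logic belongs to the upstream genome-wide discovery software and is out of
scope. `tag_pct_of_modified` reports centre-tag counts against the modified
(indel- or tag-carrying) read population, the denominator used for "tag
integration frequency of the modified cells"; passing all reads as the
denominator is supported.

Candidate off-target sites are retained iff they have at most 7 mismatches
against the 20-nt target spacer (position-wise Hamming count, PAM excluded,
per GUIDE-seq convention) and are absent from background controls; output
is sorted by mismatch count, then read support.

## pegRNA design

For a nick at inter-base `cut` on the protospacer strand, the PBS is the
reverse complement (as RNA) of the `pbs_len` reference bases immediately 5'
of the nick, and the RT template is the reverse complement (as RNA) of the
first `rt_len` bases of the **edited** sequence immediately 3' of the nick.
The extension is RT then PBS, 5'→3'. The RT must span the intended edit;
deletions must additionally be bridged by at least one base of 3' flank
beyond the junction, otherwise the deletion would not be encoded.
`pegrna_apply` decodes the RT back onto the reference and must reproduce
`apply_edit(ref, edit)` exactly — the design round-trip that the tests and
the default `pegrna_grid` (PBS 10/13/16 × RT 16/24/33, the commonly
screened grid) enforce. The guide scaffold is not designed here, and no
thermodynamic efficiency prediction is attempted.

Complementary-strand nick candidates are protospacers with an NGG PAM on
the strand opposite the primary protospacer; offsets are nick-to-nick and
signed with positive values 3' of the primary nick on the protospacer
(edited) strand — the convention in which the published optimum at +17 is
expressed.

Splice-donor activity is a pure registry lookup on the 7-nt context (last
exonic base + first six intronic): the canonical `GGTAAGT` seeds the
registry and further active variants are configuration entries
(`active_donor_contexts`), because the full 7-nt contexts of empirically
active variants are data, not derivable rules. Adding a variant changes
only that context's state.

## Group comparisons

`compare_groups` implements the decision tree used for grouped editing-rate
comparisons:

1. Brown-Forsythe (Levene with median centring, via `car::leveneTest`) for
   homogeneity of variances, and D'Agostino-Pearson K2 on the pooled
   one-way ANOVA residuals for normality. The K2 test is applied to pooled
   residuals rather than per group because triplicate groups are far too
   small to test individually.
2. Both pass (at the assumption level, default 0.05) → one-way ANOVA with
   Tukey's HSD.
3. Assumptions fail on strictly positive data → Box-Cox transformation with
   the maximum-likelihood λ over \[−2, 2\] (step 0.05, `MASS::boxcox`),
   then the assumptions are re-tested on the transformed data; if they then
   hold, ANOVA/Tukey runs on the transformed values.
4. Otherwise — including non-positive data — Kruskal-Wallis with Dunn's
   post hoc test. Dunn's pairwise z statistics use the pooled-rank variance
   with the tie correction; pairwise p values are Bonferroni-adjusted
   because the original analysis names Dunn's test without an adjustment
   scheme and Bonferroni is the conservative default.

Groups of identical constants short-circuit to an explicit `no_variance`
outcome rather than feeding zero variances into the tests. D'Agostino's K2
and Dunn's test are implemented in-package from the standard published
formulas (no maintained implementation ships with the environment's R
packages); K2 is verified against an independent implementation on frozen
vectors, and Dunn's two-group z² is verified against the Kruskal-Wallis H
identity.

Under a Gaussian null (3 groups × 3 replicates, the typical triplicate
layout), the whole tree's type-I error at α = 0.05 stays within
\[0.03, 0.07\] over 1000 replicates; grossly heteroscedastic lognormal
groups (log-scale spread differing several-fold, raw variance ratios ≫
100) route to Kruskal-Wallis/Dunn because Box-Cox can normalise but cannot
equalise their variances.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to make
binomial error bars meaningful while keeping the whole suite fast on a
single CPU: 10,000-read samples (five replicate seeds) for parameter
recovery, 100,000-cell populations for gate rates, 1000 replicates for the
type-I simulation, 200 random pairs (≤25 nt) for the alignment oracle plus
40 tiny pairs for full enumeration. Stochastic checks use 3-standard-
deviation bounds tied to the binomial oracle (a 4σ bound where a fixed-seed
check would otherwise have a non-trivial false-alarm rate). All generators
take explicit seeds and restore the caller's RNG state.

## Known limitations

* The aligner is amplicon-local; there is no genome-scale search, mapping
  quality, or SAM/BAM emission (per-read TSV is the exchange format).
* Quantification reports the three summary quantities only; no per-allele
  spectrum tables.
* The read generator's error model is deliberately simple (see above), and
  the population model uses binary fluorescence.
* Matched plasmid/chromosome correlation analyses (`pearson_r`,
  `read_condition_means`) operate on user-supplied condition-mean tables;
  the package ships no measured screen data.
* The splice-donor activity model is a lookup, not a predictive splicing
  model: contexts absent from the registry are reported inactive.
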