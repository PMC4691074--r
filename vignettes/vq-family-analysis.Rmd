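---
title: "Methods: gene-family characterisation with vqfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterisation with vqfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqfam)
```

`vqfam` re-implements, as testable desk-scale code, the complete derived
analysis of a plant gene-family survey: motif identification and typing,
protein physicochemistry, gene structure, distance-based phylogeny,
duplication-mode classification across a triplicated genome, and qRT-PCR
relative quantification. This vignette records the models, the parameters
that matter, the numerical choices, and what the packaged tests do and do
not establish.

## The motif model

VQ proteins are defined by a ten-residue consensus window,
`FxxxVQxL/F/VTG`: an `F` anchor (window position 1), the `VQ` dipeptide
at positions 5–6, and a three-residue tail (positions 8–10) whose first
and third residues vary. The **strict** pattern used for typing,
`F-x(3)-V-Q-x-x-T-x`, fixes the threonine at position 9 because every
motif type observed in this family (LTG, FTG, VTG, LTS, LTV, YTG) shares
it. A **relaxed** pattern (`F-x(3)-V-[QH]-x(4)`) admits the histidine
variant and frees position 9 for cross-species scans, where types such as
LTD occur. Patterns are PROSITE-like strings, so the scanner generalises
to other families.

A protein is assigned **one** motif type — that of its *leftmost* strict
hit. Family surveys conventionally assign a single type per protein but
rarely state a tie rule for sequences carrying two windows; leftmost is
deterministic and is exposed alongside an `all_hits` mode so the choice
is auditable. Overlapping windows are all reported by `scan_vq()`
(matching is done with lookahead), and a census is invariant under input
order.

## Protein properties

*Length.* A CDS of $n$ bp encodes $n/3 - 1$ residues (the stop codon is
untranslated).

*Molecular weight.* The sum of average (not monoisotopic) residue masses
plus one water, 18.0153 Da. The residue-mass table is a versioned TSV
asset (`inst/extdata/residue_masses_average.tsv`), never hard-coded, so
an exactness dispute is a data edit. The unknown residue `X` contributes
zero mass but counts toward length — conservative and explicit.

*Isoelectric point.* The net charge at pH $p$ is

$$Q(p) = \sum_{\text{basic}} \frac{1}{1+10^{\,p-pK_a}}
       - \sum_{\text{acidic}} \frac{1}{1+10^{\,pK_a-p}},$$

summing each ionizable side chain (D, E, C, Y acidic; H, K, R basic) once
per occurrence plus both termini. $Q$ is strictly decreasing in pH, so
the root is found by bisection on $[0, 14]$ — unconditionally convergent,
unlike Newton steps on a nearly flat $Q$. Iteration stops when
$|Q| < 10^{-4}$ (an interval width of $10^{-9}$ pH acts as a numerical
backstop). Two pKa sets ship as editable assets: a Bjellqvist-style set
(default, the family of constants behind the ProtParam web tool that
produced the published per-protein values) and an EMBOSS-style set for
sensitivity checks. Exact constants behind the published pI column are
not recoverable, which is why agreement there is a tolerance contract
(±0.2 pH) rather than bit-exactness.

## Gene structure

With an exon list, the intron count is `|exons| - 1`. With only a locus
table, intronless status is inferred from *span = CDS length*: a genomic
span equal to the CDS can hold no intron, while a longer span implies at
least one (reported as a lower bound, not a count). The inference is
exact for locus tables whose coordinate column spans the CDS without
UTRs — which holds for every intronless row of the packaged family table,
making the published 54/57 tally reproducible without the genome. A
property test confirms the inference agrees with exon-list-based status
on simulated GFF3.

## Phylogeny

*Pairwise alignment* is Needleman–Wunsch with affine gaps over BLOSUM62
(defaults: gap open 10, gap extend 0.5), delegated to Biostrings.
Identity is exact matches over all alignment columns; similarity also
counts substitution pairs with a positive matrix score. Gap columns stay
in the denominator — a conservative convention; published "similarity"
figures rarely state theirs, which is why cross-checks against such
figures carry a wide tolerance.

*Progressive MSA* is intentionally simple: pairwise NW identities give
guide distances (`1 - identity/100`), a neighbor-joining guide tree is
built, and profiles are merged leaf-to-root by profile–profile NW with a
linear gap cost (default 8). Column scores are
$f_1^\top B f_2$ over residue frequency vectors. Traceback prefers
diagonal, then up, then left, so the output is deterministic given input
order. There is no iterative refinement; nothing downstream requires a
specific third-party aligner, and the planted-indel test (a 6-aa
insertion appears as a clean 6-column gap block) pins the behaviour that
matters.

*Distances.* p-distance (mismatches over valid columns) or its Poisson
correction $-\ln(1-p)$, under pairwise or complete gap deletion. The
default — p-distance with pairwise deletion — is stated explicitly
because distance-model defaults of desktop phylogeny suites are not
reliably documented; both models are flags. A pair with no valid columns,
or $p = 1$ under Poisson, is an error rather than a silent infinity.

*Neighbor joining* follows Saitou–Nei with the Studier–Keppler criterion
$Q_{ij} = (n-2)d_{ij} - R_i - R_j$. Branch lengths use the two-point
formulas; a negative length is clamped to zero with the deficit moved to
the sibling edge (common NJ practice, documented here because sources are
usually silent). Ties in $Q$ are broken by the lexicographically smallest
taxon pair, an internal cluster inheriting the smallest leaf id it
contains — so the tree is reproducible. The key correctness property,
checked against both simulation and an independent implementation
(`ape::nj`): NJ exactly inverts tree → additive-matrix simulation for
random binary trees up to 12 taxa.

*Bootstrap.* Columns are resampled with replacement per replicate
(indices drawn once per replicate from a single documented seed), the
distance matrix and NJ tree rebuilt, and each internal edge of the
full-data tree annotated with the percentage of replicates containing the
same bipartition. Two identical sequence pairs across many columns give
support 100 by construction — frozen as a test.

*Subgroups.* `cut_subgroups(tree, k)` removes the $k-1$ longest internal
edges (ties: higher support, then lexicographic split order) and returns
the leaf sets of the components; when internal edges run out (large $k$),
terminal edges are cut next so $k$ leaf-bearing groups always exist. The
published seven-subgroup partition of this family was drawn manually on a
figure, so the cutter parameterises rather than guesses: recovery is
asserted only for planted clades with long stems.

## Duplication and subgenomes

Synteny itself is an *input* (a locus-group table), not recomputed: the
original groups came from a genome-database service, and whole-genome
collinearity detection is out of scope. Within each multi-member group,
a gene pair is **tandem** when both members share a chromosome with an
intergenic gap ≤ `tandem_max_gap`, else **segmental**. The default gap is
25 kb: in the packaged family the sole tandem pair sits ~2.4 kb apart
while the closest same-chromosome segmental pair is >7 Mb away, so any
threshold in that span reproduces the published classification; 25 kb is
a conventional middle value, and it is a flag. A gene in a tandem pair is
labelled tandem and **excluded** from the segmental count — the only
reading under which the published 41 segmental genes (rather than 43)
follow from the tables; this is deliberate and prominent.

The subgenome tabulator counts member genes per LF/MF1/MF2 label and
builds a per-locus copy-number histogram over anchored groups. On the
packaged table this gives 21/23/12 and a 10/11/7 histogram of
one/two/three-copy loci; the histogram reports what the input implies
(a prose summary elsewhere of 13 single-copy and 11 two-copy loci is
arithmetically inconsistent with the table as printed, and is not
forced). Both member totals are visible: 56 genes appear in the table,
53 of them anchored to 28 reference loci.

Ortholog naming maps each query protein to its best global-alignment
reference hit; queries sharing a reference receive `-1..-n` suffixes by
descending similarity with locus-id tie-breaks, and singletons get the
bare family name.

## Expression

The 2^−ΔΔCt model: per replicate, ΔCt = Ct(target) − Ct(reference gene);
per cell (gene × condition × timepoint), ΔΔCt is the difference of mean
ΔCt from the gene's calibrator cell and the fold change is
$2^{-\Delta\Delta Ct}$ (amplification efficiency fixed at 2.0; a Pfaffl
efficiency-corrected mode is out of scope). The calibrator is a per-gene
parameter — a single `"condition:timepoint"` string or a per-gene table —
because published designs sometimes rebase individual genes onto
alternative calibrators.

Significance uses a two-sided Welch t-test on replicate ΔCt against the
calibrator replicates (a flag pools variances); Welch avoids an
equal-variance assumption the data cannot support at $n = 3$. A cell is
called `up` when rq ≥ 2 and $p < 0.05$, `down` when rq ≤ 0.5 and
$p < 0.05$, else `ns`; stars mark $p < 0.05$ / $p < 0.01$. No
multiple-testing correction drives the calls, matching per-gene testing
practice in qRT-PCR surveys; a BH-adjusted column is emitted for
transparency. A single-replicate cell reports its fold change with the
test and call marked unavailable, and a missing calibrator is an error.

## The synthetic generator, and what passing tests show

`simulate_family()` plants everything the pipeline is supposed to
recover. Its defaults are the study conditions of the family it
emulates, fixed once: 28 reference loci; copy numbers 1/2/3 with
probabilities 10/28, 11/28, 7/28 (the copy distribution implied by the
packaged synteny table); motif types at the observed family frequencies
(43/57 LTG, 8/57 FTG, 3/57 VTG, 1/57 each LTS/LTV/YTG); one expected
tandem pair among the multi-copy loci (tandem copies within 5 kb,
segmental copies on distinct chromosomes of a 10 × 30 Mb genome);
ancestral protein lengths uniform on the observed 93–568 aa range; a
per-site substitution rate of 0.12 between copies (giving within-locus
similarities around the ~83%–90% seen for recent paralogs); three planted
intron genes out of a family-sized gene set; and a qPCR design with three
replicates, 0.2-cycle Gaussian replicate noise on ΔCt, and planted log2
fold changes in {−3, −2, 0, 2, 3} — effects either null or comfortably
beyond the two-fold call threshold, so expected calls are well defined.
Back-translation uses a fixed (alphabetically first) codon per residue,
making CDS fixtures deterministic; the motif window is
substitution-protected by default so planted type counts are exact, with
a flag to allow erosion for robustness testing.

What the generator does *not* emulate: real amino-acid composition and
codon usage, indel evolution, UTRs, overlapping gene models, pseudogenes,
primer efficiency drift, or between-biological-replicate variance
structure. Passing the planted-recovery tests therefore shows the
*algorithms* are correct under their stated models — not that the models
capture every feature of wet-lab data.

A related limitation is explicit: the package does not redistribute the
family's actual 57 protein/CDS sequences (they live in a public genome
database, not in the tables transcribed here). Tallies derived from the
locus and synteny tables — intron census, protein-length census,
chromosome and subgenome counts, the tandem/segmental split — are
reproduced exactly from the packaged fixtures. Sequence-level published
values (the motif-type census, per-protein Mw/pI) are exercised instead
on a clearly-labelled synthetic stand-in proteome whose planted ground
truth equals the published census; per-protein agreement with the
published Mw/pI columns cannot be verified without the original
sequences, and no test pretends otherwise.

## Problem sizes and determinism

The shipped tests run the property suites at deliberate desk scale: NJ
inversion up to 12 taxa, 1000 planted-motif scanner trials, 200-replicate
bootstraps on 8-taxon families, 100 null expression datasets and 200
effect-recovery simulations, and simulated families of 5–15 loci. All
randomised tests fix seeds; `simulate_family()` is reproducible from its
single seed, and `bootstrap_tree()` from its seed argument. The
`scripts/acceptance.R` entry point recomputes the segmental-duplicate
tally from the installed package and packaged fixtures alone.
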