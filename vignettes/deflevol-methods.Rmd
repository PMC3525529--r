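---
title: "Methods: detecting and characterising species-specific DEFL gene clusters"
author: "deflevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterising species-specific DEFL gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Defensin-like (DEFL) peptides are short secreted cysteine-rich proteins.
In crucifers some of them — the LURE peptides — act as species-preferential
pollen-tube attractants, which makes their evolutionary history directly
relevant to reproductive isolation. The signature of interest is a
*species-specific gene cluster*: a set of paralogs that amplified by tandem
duplication *after* two species split, so that in a joint gene tree each
species' copies form their own clade (reciprocal monophyly), and the
genomic neighbourhood of the expansion in one genome has a syntenic
counterpart in the other genome that lacks the family entirely.

`deflevol` implements that discovery procedure end to end:

1. progressive alignment of family coding sequences,
2. a neighbor-joining tree with bootstrap bipartition support,
3. detection of same-species paralog groups of at least `min_size = 4`
   genes under an edge with support `min_support = 90` percent,
4. cross-species classification of each group (reciprocal monophyly,
   rooted by an outgroup),
5. reciprocal-best-hit (RBH) orthology over both proteomes,
6. tandem-array detection (intergenic gap at most `max_gap_kb = 15` kb)
   and flanking-anchor synteny tests,
7. a duplication-history verdict,
8. NG86 dN/dS among intact members, per-gene integrity (pseudogene)
   reports, and a McDonald-Kreitman (MK) polymorphism/divergence test.

A built-in simulator generates two-species gene families with full ground
truth, so every stage is testable without genome downloads.

## Models and procedures

### Alignment

Pairwise and profile-profile alignment use Needleman-Wunsch with affine
gaps (gap run of length $L$ costs `gap_open` $+ (L-1)\,$`gap_extend`;
defaults BLOSUM62/10/0.5 for proteins, match $+2$ / mismatch $-1$ /
10/0.5 for nucleotides). The traceback tie-break is fixed
(substitution $>$ gap in the second sequence $>$ gap in the first), so
alignments are byte-reproducible. The multiple aligner is progressive:
all pairwise identities give a distance matrix, an average-linkage
(UPGMA) guide tree orders the merges, and clusters are merged by
profile-profile alignment. We use UPGMA rather than NJ for the guide
because the merge schedule needs a rooted tree and UPGMA produces one
directly for any number of sequences; for families at 70-95% identity
the resulting merge order is the same in practice. The aligner is not
intended to reproduce any particular external program's output.

### Trees and support

Protein or nucleotide distances are p-distances with pairwise deletion of
gap columns (a Poisson correction $d = -\ln(1-p)$ is available; pairs
with $p \ge 1$ are flagged, not silently truncated). Trees are
Saitou-Nei neighbor joining; negative branch lengths are clamped to zero
with a warning. Bootstrap support resamples alignment columns with
replacement, rebuilds the tree per replicate, and scores each internal
edge of the full-data tree by the percentage of replicates containing
the same leaf bipartition; the resampling RNG is seeded explicitly, so
supports are reproducible.

### Paralog groups and cross-species classification

A paralog group is a maximal clade (no reported group nested in another)
whose leaves are at least `min_size` genes of one species and whose
subtending edge carries at least `min_support` percent bootstrap. The
threshold applies to the subtending edge only, not to every edge inside
the group. Cross-species classification roots the joint tree by the
outgroup (falling back to the outgroup's most recent common ancestor,
with a warning, if the outgroup is not monophyletic) and calls
`species_specific` when both species' gene sets are monophyletic,
`interleaved` when neither is, and `unresolved` otherwise.

### Synteny and duplication history

Orthologs are reciprocal best hits by global protein alignment score;
ties for a top hit leave both sequences unassigned (conservative).
Tandem arrays split family genes, per scaffold, wherever the intergenic
distance (next start minus previous end) exceeds `max_gap_kb`. The
synteny test takes up to `flank = 3` non-family genes per side of a
focal region, maps them through the RBH table, and requires at least
`min_anchors = 2` anchors on one counterpart scaffold with order
preserved; one whole-block orientation flip is allowed because
inversions between close genomes are common. The counterpart interval,
extended by one flanking gene on each side, is then checked for family
members. The history call combines these signals: reciprocal monophyly
plus at least one family-containing counterpart (the ancestral copy)
plus at least one family-free counterpart (the expansion) gives
`ancestral_copy_plus_lineage_specific_expansion`; regions that are all
mutually syntenic with family present give `shared_ancestral_array`;
anything else is `unresolved`.

### NG86 dN/dS

Synonymous site counts follow Nei-Gojobori (1986): per codon position,
the fraction of the three single-nucleotide changes that preserve the
amino acid, with stop-creating changes counted as nonsynonymous, so
$S + N = 3L$ exactly. Codon pairs differing at 2 or 3 positions are
averaged over all 2 or 6 mutational pathways; pathways through stop
codons are excluded (if all are blocked, all are used and a flag is
set). Proportions are Jukes-Cantor corrected,
$d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$; $p \ge 3/4$ sets a domain flag
and leaves $d$ undefined. $\omega = d_N/d_S$ is reported as `NA` (never
infinity) when $d_S = 0$. Codon columns containing gaps, ambiguities or
stop codons are deleted pairwise.

### McDonald-Kreitman test

A nucleotide site is polymorphic when the ingroup panel segregates at
least two states (each state beyond the first counts one change — the
paper trail gives no rule for three-state sites, so this choice is
stated in the output contract) and fixed when the ingroup is invariant
but differs from the outgroup. Changes are classified in the context of
the majority ingroup codon; codons with several fixed differences are
resolved by the same pathway averaging as NG86, and fractional fixed
counts are accumulated across sites before one final rounding. The test
itself is a two-sided Fisher exact test on $[[P_n, P_s], [D_n, D_s]]$;
the neutrality index $(P_n/P_s)/(D_n/D_s)$ is reported when defined.
Exact 2x2 and binomial tests are delegated to R's `fisher.test` and
`binom.test`; the test suite checks both against full enumeration for
all margins up to 12.

### Integrity (pseudogene) classification

A family consensus is built from at least two intact members: a
majority-rule consensus CDS, and conserved cysteine positions defined as
protein-alignment columns where at least 80% of members carry a cysteine
(the literature says "conserved" without a threshold; 80% is this
package's choice and is echoed in the report). A gene is
`putative_loss_of_function` iff it has (i) a frameshift — an indel run
of length not divisible by 3, downstream of the start codon, in the
global alignment to the consensus, reported as the 1-based consensus
nucleotide of the first indel column — (ii) a premature stop, or (iii) a
non-cysteine residue at a conserved cysteine column. The C-terminal CXC
motif is scored in a 3-residue terminal window of the mature peptide
(configurable); signal-peptide cleavage positions are inputs, not
predictions.

## The simulator and its calibration

`simulate_family()` evolves codon sequences along an explicit gene tree:
two species diverge from a common ancestor (`root_branch` 0.05 expected
substitutions/site before the split, `species_branch` 0.18 per lineage
after it); within each lineage, duplications occur at times drawn
uniformly from the recent part of the branch (`dup_time_range`
c(0.45, 0.9) as fractions of the branch), the first duplication founding
a new tandem locus and later ones expanding it with spacings uniform on
0.5-15 kb. The family root carries a planted DEFL cysteine scaffold —
six cysteine codons in the mature region, the last two forming the
C-terminal CXC motif, with no background cysteines elsewhere — and the
scaffold codons accept nonsynonymous change with probability 0.02,
emulating the strong purifying selection that keeps the cysteine
complement of real defensin-like families aligned while the remaining
residues drift. Codon evolution is an accept/reject scheme: proposals arrive
uniformly over sites at the branch-length rate, mutate to one of the
three other bases, stop-creating proposals are rejected, and synonymous
vs nonsynonymous proposals are accepted with probabilities $(1, \omega)$
for $\omega \le 1$ and $(1/\omega, 1)$ for $\omega > 1$, so the accepted
nonsynonymous:synonymous rate ratio is $\omega$ in both regimes. This is
deliberately simpler than a full codon rate matrix; it is exact for the
quantity NG86 estimates and is what the parameter-recovery tests rely
on.

The defaults were calibrated once against the family's published
sequence statistics, not against any test outcome: with
`species_branch = 0.18` and recent duplications, simulated cross-species
protein identity comes out near 70% and within-species identity near
85-90%, matching the reported ~70% between-species and 80-95%
within-species identities of the target family; the outgroup
(`outgroup_branch = 0.25`) is a close relative, as in the original
design, because a saturated outgroup attaches to the joint tree almost
at random and would test nothing. Family genes evolve at
`omega_family = 0.5` (moderate purifying selection on a conserved
cysteine scaffold with otherwise drifting residues); anchors at
`omega_flank = 0.1`. The planted scenario (`crp810_preset()`) has one
ancestral gene, 5 duplications in species A (6 genes, the youngest
carrying a 1-bp deletion at nucleotide 17) and 9 in species B (10
genes); its expected outcome is a species-specific cluster with an
ancestral-copy-plus-expansion history.

What the simulator does *not* emulate: gene conversion between
paralogs, recombination, coalescent population structure in the MK
panels (a star genealogy is used — sufficient for a 2x2 independence
null, but real polymorphism data have correlated genealogies),
alignment-hostile repeat regions, and annotation error. Passing tests on
simulated data therefore demonstrate correctness of the inference
machinery under the stated model, not robustness to every property of
real genome annotations.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale problem sizes chosen as the
smallest that leave comfortable statistical margins: 100-codon family
genes, 100 bootstrap replicates for end-to-end runs (the planted clades
sit near 100% support, where 100 replicates resolve the 90% threshold
reliably; the `tree` interface defaults to 1000), 500 replicates for the
neutral MK calibration, 100 replicate pairs of 500 codons for omega
recovery, and 50 simulated datasets for the end-to-end recovery rate.
Ties in NJ joins, alignment traceback and RBH top hits are broken
deterministically (documented in each function); all stochastic steps
take explicit integer seeds.

## Known limitations

- Paralog groups are clades of a rooted tree; on a tree with no
  meaningful root the group boundary can shift by one edge.
- `find_paralog_groups` reports the best-supported maximal clades; when
  the full species clade's subtending edge falls below the support
  threshold, a well-supported subclade is reported instead — mirroring
  how support-thresholded surveys behave on real data.
- The RBH implementation scores all pairs by global alignment; it is
  quadratic and intended for the focal-region proteomes used here, not
  whole proteomes.
- The MK implementation treats sites independently when classifying
  polymorphisms; linked multi-codon haplotypes are not reconstructed.
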