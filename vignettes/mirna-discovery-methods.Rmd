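---
title: "Methods: small RNA sequencing discovery and annotation of mosquito miRNA genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA sequencing discovery and annotation of mosquito miRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`mosmir` re-implements, as a tested pipeline, the small-RNA-sequencing
analysis used to discover, classify, quantify and functionally annotate
miRNA genes in a mosquito from six developmental-stage libraries (embryo,
larva, pupa, adult male, sugar-fed female, blood-fed female). The pipeline
runs end to end on synthetic data with a planted ground truth, so every
inference step is testable at desk scale. This vignette documents the models
and procedures, the tunable parameters with their defaults, the numerical
choices, and what passing the tests does and does not establish about real
data.

# The pipeline

## Preprocessing

Raw reads are 3'-adapter trimmed (leftmost adapter-prefix match, at least
6 nt of overlap, at most 1 mismatch), quality-filtered (any insert base
below Phred 10 drops the read), restricted to the closed 18-30 nt range, and
collapsed into unique tags carrying a six-sample count vector. Tags exactly
matching (either strand) rRNA, tRNA, snRNA, snoRNA or repeat annotation are
removed as contaminants. Tags matching exon or intron sequence are *not*
removed; they are flagged and consumed later by the locus-context criterion.
This resolves an inherent tension in small-RNA cleaning: discarding all
exon/intron-matching reads would also discard intronic miRNAs, which the
discovery criteria explicitly allow. The adapter-match and quality rules are
declared defaults (standard small-RNA practice), configurable per call.

Read accounting is asserted at every step: input = kept + dropped(by
reason), per sample.

## Mapping

Tags are aligned to the reference genome keeping all loci on both strands
with Hamming distance at most 1 and no best-hit pruning. The mapper is a
seed-and-extend hash index: each tag is split into two halves, and any
one-mismatch hit leaves one half exact (pigeonhole), so looking up the
leading 9-mer of each half against a genome 9-mer hash enumerates every
candidate locus, which direct comparison then verifies. k = 9 equals half
the minimum tag length, the largest k that preserves the guarantee. The test
suite proves exact equivalence against an independent brute-force scan
(Biostrings `matchPattern`) on a 50 kb genome with 1000 tags.

## Hairpin discovery

Each supported locus (tags with at least 5 pooled reads; nearby seed stacks
within 40 nt merge into one locus so a precursor's mature- and star-arm
stacks seed a single candidate) is extended by 100 nt of genomic flank on
each side, reverse-complemented for minus-strand loci, and folded.

**The folding engine** is a built-in single-stem nearest-neighbour
minimum-free-energy dynamic program: it searches all single-hairpin
(non-multibranch) structures — one chain of nested pairs connected by
stacks, bulges and internal loops (interior size capped at 30), closed by a
hairpin loop of at least 3 nt — under embedded stack free energies for the
36 adjacent-pair combinations over {AT, TA, GC, CG, GT, TG} and tabulated
loop penalties with Jacobson-Stockmayer extrapolation
(`folding_params()`). Pre-miRNA evaluation needs only hairpin geometry, so
the single-stem restriction keeps the engine self-contained, deterministic
and fast; ties break toward the 5'-most closing pair. The engine is verified
against an exhaustive enumeration of single-stem structures for sequences up
to 30 nt (where the interior-size cap never binds, so the two search spaces
coincide). An external folding backend (e.g. RNAfold) can be used for
cross-checks but all decisions use the built-in engine.

**Criteria.** A candidate passes when all of the following hold:

1. *One arm*: the most abundant tag (the mature) lies entirely on one arm of
   the hairpin, with a 2-nt tolerance at the loop boundary that accommodates
   the Dicer duplex geometry (the mature's 2-nt 3' overhang of a 5p mature
   sits against the loop).
2. *Clean duplex*: at most 4 unpaired mature bases and no bulge or internal
   loop larger than 3 nt within the mature:star duplex. These
   quantifications of "lacks large internal loops or mismatches" are
   configurable; the defaults accept all designed precursors.
3. *Energy*: folding free energy strictly below -20 kcal/mol (the boundary
   is tested: -19.9 fails, -20.1 passes).
4. *Context*: the window midpoint lies in intergenic or intronic space. The
   midpoint (rather than the full span) gives a single unambiguous rule for
   precursors straddling boundaries.
5. *Read stack*: at least 5 reads land on the precursor; at least 70% of
   mature-arm reads share the modal 5' end; at most 10% of read mass falls
   on the loop or outside the two arms; star reads, when present, have their
   modal 5' end within 1 nt of the predicted star.

The star span follows the 2-nt 3'-overhang duplex rule: with the mature at
[a, b] in the folded window, the star runs from pairing(b-2) to
pairing(a)+2. Overlapping candidate windows merge keeping the lower-energy
fold. Discovery support (5 reads) is kept deliberately separate from the
15-read *expression* gate.

## Homology and lineage

Two search modes mirror the published analysis. A word-seeded catalog search
(7-mer seeds, ungapped extension, +1/-2 scoring, E-value
`K*m*n*exp(-lambda*S)` with lambda = 1.33, K = 0.621, cutoff E <= 10) plays
the role of a permissive BLAST pre-filter; because that filter was followed
by manual inspection in the original analysis, a declared surrogate rule
(identity >= 60% over >= 16 nt) stands in where a hard decision is needed.
A genome scan finds all loci within 1 or 3 mismatches (both published
settings are computed and reported) and scores each locus
`S = 2(L - mm) - 4 mm + B`, with a bonus B = +5 when the 100-nt-flanked
locus passes the structural criteria 1-2 and B = -20 otherwise; a homologue
is present when the best score reaches 35. The published pipeline's internal
score is not printed in the source analysis, so this formula is a declared
stand-in calibrated to preserve the decision role of the cutoff: exact
hairpin-context hits score 2L+5 (49 for a 22-mer, well above 35),
three-mismatch hits score 31 (below), and non-hairpin exact hits score 24
(below).

Lineage labels form a lattice over the presence map {Aal, Aae, Cqu, Aga,
Dmel-group}: presence in the Drosophila group means conserved beyond
mosquitoes; all three mosquito genera, mosquito-specific; Aedes + Culex
only, Culicinae-specific; the two Aedes species only, Aedes-specific;
anything else is species-specific, with a warning for patterns inconsistent
with mosquito phylogeny (e.g. Aedes + Anopheles without Culex). An arm
switch is called when the query's mature aligns with >= 18 matching
nucleotides to a homologue's star arm and vice versa.

## Expression

A tag counts toward a mature or star row when its 5' end is within 2 nt and
its 3' end within 5 nt of the annotated span on the same strand (isomiR
tolerance); multimapping tags count fully at each gene copy and are
flagged. A gene is *expressed* when either arm reaches 15 raw pooled reads
("reads" is taken to mean raw counts, so the gate precedes normalisation).
Normalisation is exactly `count / column_total * 1e6`; normalising the
pre-gate matrix makes every column sum to one million, which the tests
assert. The denominator includes all counted rows (mature and star), a
declared choice where the source is silent.

Stage profiles are clustered on `log2(cpm + 1)` with distance `1 - Pearson
correlation` and average linkage (via `stats::hclust`), cut to k = 5
clusters; zero-variance rows get distance 1 to everything, with a message.
The log transform is heat-map practice and can be disabled. Stage
specificity labels a row with the sample holding at least half its total
CPM; the blood-meal flag is up/down at a 2-fold change between blood-fed
and sugar-fed females with a 10 CPM floor. All three thresholds are
declared defaults for what the source describes qualitatively.

## Targets and GO

Target sites are scored by local affine-gap alignment of the mature
(antisense, 3'->5' against the UTR 5'->3'): Watson-Crick +5, G:U wobble +1,
mismatch -3, gap open -9, gap extend -4, with positions 2-8 from the miRNA
5' end (the seed) weighted 4-fold. Under these constants a perfect 22-nt
complement scores 215 and a perfect seed alone contributes 140, which makes
the published cutoff of 150 meaningful: it demands an essentially intact
seed plus productive 3' pairing. Sites at or above 150 are emitted
greedily, best first, non-overlapping. The full energy filter of the
original target predictor is omitted because only the score cutoff is
quoted; acceptance is score-only.

GO enrichment is a one-sided Fisher's exact test per term (only terms
carried by at least 3 target transcripts are tested — a small-count guard),
with Benjamini-Hochberg adjustment and significance at q < 0.01, against
the background of all transcripts with an annotated 3'UTR. Terms are
treated as flat labels; GO-graph ancestor propagation is out of scope, and
enrichment is run separately per expression cluster.

# The synthetic-data generator

The generator (`sim_config()`, `simulate_dataset()`) defines the study
conditions: 2 contigs x 200 kb of i.i.d. background at GC 0.5; 120 gene
models (exon-intron-exon, 70% with an annotated 250-nt 3'UTR), structural
ncRNA loci and 20 repeat intervals; 40 planted miRNA genes (4 exon-planted
negative controls); six libraries of 100,000 reads. Reads are 70%
miRNA-derived (85% mature / 15% star arm, 5' shifts {-1,0,+1} with
P(0) = 0.8, 3' shifts {-2..+2} with mode 0.6), 12% piRNA-like 26-30 nt
fragments from repeat loci in the embryo, larva and female libraries only
(reallocated to miRNA reads in pupa and male), 10% structural-ncRNA
contaminants, and the remainder random noise of 18-25 nt; every read
carries the 3' adapter, a 0.2% per-base error rate and occasional
low-quality bases. These choices make the dominant 21-23 nt class hold more
than 50% of every library and confine the 26-30 nt band to the four
libraries where it is reported, with presence operationalised as >= 5% of
reads in the band (the two bins [21,23] and [26,30] are the explicit
versions of "~22 nt" and "~28 nt").

Planted precursors are designed stem-loops: the mature, an unstructured
loop of 14-18 nt, and a near-reverse-complement star with two designed
mismatches and 2-nt 3' overhangs. The two mismatches emulate the bulged
stems of real precursors and, deliberately, prevent the two arms from
cross-mapping to each other under one-mismatch alignment (a perfectly
palindromic stem would create a mirror locus on the opposite strand).
Placement is rejection-sampled until the *discovery window itself* — the
mature plus 100 nt of genomic flank — folds into the designed clean duplex
below -25 kcal/mol and predicts exactly the designed star. This matters
because a single-stem MFE over a 220-nt window can otherwise chain random
flank helices into a long stem that outcompetes a compact hairpin; real
miRNA loci are hairpin-dominant in context, and the generator enforces that
property rather than leaving it to chance. Mock species genomes apply the
same validation to each homologous locus. Stage profiles come from five
templates (embryo-, larva-, larval/pupal-, male- and female-biased) with a
per-gene blood-meal up/down modifier and lognormal abundance spread, giving
clustering a recoverable truth; one conserved gene is planted arm-switched
in the Culex mock. Target sites are perfect complements of ten regulator
miRNAs embedded into thirty 3'UTRs (two regulators per targeted
transcript), and each targeted transcript receives, with probability 0.8
per site, a marker GO term keyed to its regulator's expression template
(background transcripts carry a random marker at rate 0.1) — so the targets
of co-expressed miRNAs are functionally coherent, which is the pattern the
per-cluster enrichment step is meant to recover.

What the generator does **not** emulate: realistic base-quality models,
ligation and amplification bias, true piRNA cluster biology (the 26-30 nt
band is a size class, nothing more), multi-locus miRNA families, paralogue
structure, or genuine evolutionary divergence (species differences are
planted point substitutions). Passing the recovery tests therefore shows
the pipeline's logic is correct and self-consistent under the declared read
model — not that its thresholds are optimal for any real library.

# Reproducibility and problem sizes

One master seed drives every stochastic stage through stage-name-salted
substreams (`stage_seed()`), so a stage can be re-run without replaying its
predecessors and a fixed seed gives byte-identical outputs. The default
problem sizes — 600k reads, ~60k unique tags, ~70 candidate windows — run
end to end in about a minute; the test suite's dataset-level checks reuse
one cached default-scale run. The negative control is a first-order Markov
(dinucleotide-preserving) resample of the genome, on which the pipeline
must call zero genes from the same tags.

# Known limitations

- The folder ignores dangling ends, coaxial stacking and multibranch loops;
  its energies are comparable only to themselves, and the -20 kcal/mol
  threshold is interpreted within this model.
- Tags that do not map to the reference never become candidates (consistent
  with the source analysis, which deferred such reads to a future genome
  assembly).
- The Mapmi-style score and the manual-inspection surrogate are declared
  stand-ins for tools whose internals are not printed in the source
  analysis; both preserve the published decision boundaries (35; E <= 10).
- Sub-cluster discovery, differential-expression statistics, GO ancestor
  propagation and conservation-filtered targeting are out of scope.
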