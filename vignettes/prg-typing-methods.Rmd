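---
title: "Population reference graphs for HLA-style genotyping: models and methods"
author: "prgtyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population reference graphs for HLA-style genotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prgtyper)
```

## The problem

The classical HLA genes are the most polymorphic loci in the human genome:
thousands of known alleles per gene, strong sequence similarity between
paralogous genes, and clinically decisive differences concentrated in the
exons that encode the peptide-binding groove. Reads from a short-read
sequencing run of such a region mismap badly against a single linear
reference, and genotype calls built on those mappings inherit the errors.

`prgtyper` addresses this by mapping reads against a *population reference
graph* (PRG): a leveled directed acyclic graph in which every known allele —
and every known insertion and deletion — is an alternative labelled path.
Reads are mapped directly to the graph, and the diploid genotype at each
locus is inferred at **G group** resolution (alleles identical over the
peptide-binding-site exons: exons 2 and 3 for class I-like loci, exon 2 for
class II-like loci), the resolution of gold-standard sequence-based typing.

## Graph construction

### Input tiers and the merging rule

Allele databases are layered. Exonic sequences are plentiful; full genomic
(UTR/exon/intron) sequences are fewer; long regional haplotypes that supply
non-genic "padding" context are fewest. Each tier is an aligned FASTA MSA,
and adjacent tiers are connected through *shared alleles* — identifiers
present in both.

For each shared allele the un-gapped inner (higher-resolution) sequence must
occur as a substring of the un-gapped outer sequence. Writing $P_L$ and $P_R$
for the sets of inner-MSA columns at which each shared allele's sequence
starts and ends (a row `--ACGT...` starts at column 3), the consensus switch
points are

$$G_L = \max(P_L), \qquad G_R = \min(P_R).$$

Inner columns $[G_L, G_R]$ are used verbatim for every inner allele (the
highest-resolution tier always wins where tiers overlap). For each shared
allele, whatever outer sequence remains to the left and right of its own
extracted block is collected, and the left and right flank sets are
*re-aligned from scratch*. Outer-only alleles are cut at the consensus outer
columns and their middle substring is threaded through the inner block by a
global alignment against the block consensus; tied threading placements are
reported. Multiple exon blocks are merged left to right by the same base
case, and the merged gene is then merged into the regional-haplotype tier,
which contributes the padding segments.

### Graph shape

One graph level per merged-alignment column; one edge per distinct character
in that column, so identical characters are collapsed onto shared edges and
the number of edges equals the summed per-column character diversity. `-`
edges are *graph-encoded gaps*: they represent known deletion alleles,
consume no read base and cost nothing to traverse. `N` edges are literal
wildcards that match any base; runs of 2000 `N` levels separate genes in the
joint graph so that no k-mer or alignment can cross a gene boundary. Padding
defaults to 500 bp per side, the spacer to 2000 levels; both are
configurable.

Full-length (genomic or regional) alleles are source-to-sink paths. Alleles
known only from exon sequences are stored as one coverage run per exon
block: threading them through introns with gap edges would fabricate
intron-skipping walks (and a combinatorial k-mer blow-up) that no real
molecule supports. Every allele, of either kind, reconstructs exactly:
concatenating its path labels and deleting `-` yields its input sequence,
character for character, and the test suite asserts this across hundreds of
random databases.

## Read filtering

Because graph alignment is the expensive step, read pairs are pre-screened
with two k-mer tests (default $k = 31$, strand-canonical membership):

* **positive selection** — the fraction of the pair's pooled k-mers present
  in the graph index must strictly exceed 0.30;
* **negative selection** — at least one mate must carry a k-mer *unique to
  the PRG* (present in the graph, absent from the background k-mer set built
  from reference sequence outside the graph), or have a background k-mer
  fraction strictly below 0.45.

Discarded pairs carry a reason code (`too_short`, `positive_selection`,
`negative_selection`) for auditability. An optional per-base quality floor
can mask low-quality bases to `N` before k-mer extraction (off by default);
the published modified criteria for low-quality-rich reads are not
reproduced — only these configurable thresholds are exposed.

The graph k-mer index enumerates every gap-skipping k-character walk.
Walks containing `N` are dropped entirely — not only spacer walks — because
an N-containing k-mer can never equal a read k-mer and rare wildcard bases
in input alleles would otherwise inflate the walk frontier. Dense variant
regions make the walk count combinatorial; enumeration is guarded by a
frontier cap (default 50 000 open walks) and aborts with the offending
window rather than silently truncating.

## Read-to-graph alignment

Alignment is seed-and-extend:

1. **Seeds.** Read k-mers are looked up in the index on both strands; hits at
   successive offsets whose graph walks advance consistently are chained
   into maximal exact matches.
2. **Extension.** Each seed-implied window is aligned by an affine-gap
   dynamic program over the graph (C++ core): base-quality-aware match
   $\log(1-\varepsilon)$ and mismatch $\log(\varepsilon/3)$ scores, read-gap
   open/extend penalties, free `-`-edge traversal that preserves the gap
   state, soft clipping at a per-base penalty, and pruning of cells more
   than a score drop below the running maximum.
3. **Pairing.** Candidate alignments of the two mates are combined in a
   Cartesian product. A proper pair (opposite strands, forward mate
   upstream) adds a normal log-density of the implied insert size, measured
   in graph levels between the outermost aligned levels; anything else adds
   a flat improper-pair penalty.
4. **Posterior.** Pair log-likelihoods are softmax-normalized. The
   maximum-posterior pair is the fixed maximum-likelihood (ML) alignment;
   its posterior is the mapping quality, and the per-position quality of an
   aligned base is the posterior mass of candidate pairs placing that base
   at the same level.

The scoring constants are package defaults, not published values: gap open
$\ln 0.01 = -4.605$, extend $\ln 0.1 = -2.303$, clip $-1.386$ per base,
improper pair $-13.8$, score-drop 25, all in natural-log units and all
configurable. Correctness does not rest on these numbers: with clipping and
pruning disabled, the graph DP provably returns the best score over *all*
source-to-sink paths, and the suite checks exact equality against a
brute-force oracle (path enumeration plus an independent linear DP in pure
R) on hundreds of random graph/read instances.

Error probabilities from Phred qualities are floored at $10^{-4}$ and capped
at 0.75 so no single base can contribute an infinite score. Ties in ML
selection break deterministically (lowest start level, then lexicographic
walk). Pairs with no seeds on either mate are unmapped and excluded from
genotyping. One known numerical corner: both the DP and the oracle require
at least one aligned base, and in a pathological case where a pure-gap
prefix outscores every anchored prefix the DP may return a marginally
sub-optimal anchored alignment; no realistic read triggers this.

## Genotype inference

Let $R$ be the set of ML-aligned read pairs assigned to a locus that overlap
its PBS levels. Each read contributes observations $(g_r, g_a)$ per PBS
level: its base (or gap) against the candidate allele's genotype (which may
itself be a gap). With

$$L(r \mid a) = \prod_{(g_r, g_a) \in O_r} \mathrm{score}(g_r, g_a), \qquad
L(r \mid (a_1, a_2)) = \tfrac{1}{2} L(r \mid a_1) + \tfrac{1}{2} L(r \mid a_2),
\qquad
L(R \mid (a_1, a_2)) = \prod_{r \in R} L(r \mid (a_1, a_2)),$$

the posterior over all $n(n+1)/2$ unordered G-group pairs is the normalized
likelihood (log-sum-exp; the homozygous case collapses exactly to
$\prod_r L(r \mid a)$). The score table: match $\log(1-\varepsilon)$,
mismatch $\log(\varepsilon/3)$, read base against allele gap and read gap
against allele base both take the gap-open penalty per column (the published
scoring function is not specified beyond being base-quality-aware),
gap–gap scores 0, and an `N` allele base matches anything.

Calling follows the two-step best-guess rule: the first allele maximizes the
marginal probability of occurring at least once (homozygous pairs counted
once), reported as Q1; the second allele maximizes the pair posterior among
pairs containing the first, reported as Q2. Ties break lexicographically.
Candidate alleles are G-group representatives (lexicographically smallest
member, `G` suffix); likelihoods are evaluated on representative PBS
genotypes only.

Two auxiliary metrics accompany each call. *Allele k-mer coverage*: the
proportion of the called allele's path 31-mers observed in the kept reads,
computed per coverage run so exon-only representatives contribute no
fictitious exon–exon junction k-mers. *Unaccounted columns*: PBS pileup
columns (ML alignments, minimum depth 5 — a package choice to suppress
low-coverage noise) where some residue reaches frequency 0.2 yet matches
neither called allele; residual evidence of this kind flags contamination,
mismapping or an allele absent from the database.

## The synthetic world

The generator emulates an IMGT-like database rather than downloading one:
several paralogous loci derived from a common family ancestor (10% pairwise
divergence by default, optionally with exon 2 shared verbatim as a
worst-case paralogy fixture), 10 exonic alleles per locus of which 4 have
genomic and 2 regional-haplotype sequence, ~1.3 kb gene bodies (exon layout
150/270/276 with 200 bp introns and 100 bp UTRs), 500 bp padding, intron
indels of 1–6 bp, and per-allele PBS substitution rates of 2% (pairwise ~4%)
against 0.5–1% elsewhere. Homology is tracked during mutation, so tier MSAs
are exact by construction and carry per-column feature annotations.
Sampling: 2x100 bp pairs, fragment length 350 ± 35, 0.2% uniform base error
with quality strings encoding the planted rate, 30x default coverage. All
outputs are byte-reproducible from the seed.

What a green test does and does not establish: the simulation plants
independent substitutions per allele, uniform coverage and uniform errors.
Real data add phylogenetic correlation between alleles, coverage waves,
indel sequencing errors, quality-by-cycle structure and contamination — so
the parameter-recovery results here demonstrate the correctness of the
machinery at stated noise levels, not clinical-grade accuracy. The headline
published accuracies for this family of methods depend on cohort-scale WGS
data and the full allele database, which desk-scale tests deliberately do
not reproduce.

## Numerical and design choices

* MSA columns and PRG levels are 1-based closed intervals everywhere a
  coordinate is serialized or reported.
* The flank re-aligner is a built-in progressive profile aligner (match +1,
  mismatch −1, gap −2, guide order = input order); any function honouring
  the same contract can be substituted, e.g. to call an external aligner.
* Inner-only alleles with sequence outside the consensus region cannot be
  represented and raise a construction error rather than silently losing
  bases.
* The insert-size model is normal with parameters either configured or
  estimated from proper pairs by median/MAD during a provisional alignment
  pass.
* Serialized alignments re-quantize per-base error probabilities to Phred
  characters; placements and scores round-trip exactly.

## Limitations

Novel alleles are not discovered or flagged — evidence from an allele absent
from the database surfaces only through the quality metrics. Copy-number
variation of paralogs is not modelled. Structural variation beyond gap
columns is out of scope. The aligner is deliberately exhaustive rather than
fast; it is intended for gene-scale graphs, not genome-scale ones.
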