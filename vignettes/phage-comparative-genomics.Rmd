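---
title: "Methods: comparative genomics of small circular ssDNA phage genomes"
author: "phagecg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of small circular ssDNA phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecg)
```

# Scope and assumptions

`phagecg` reconstructs and compares small circular single-stranded DNA
phage genomes (the Microviridae scale, roughly 4.4–6.1 kb, ~8–12 genes in
a modular arrangement, GC near 40%). The pipeline assumes:

* genomes are **circular**: coordinate arithmetic is modulo the genome
  length, ORFs may span the origin, and k-mer windows wrap;
* genes are **densely packed** on one strand (both strands are still
  scanned by default), so coding capacity approaches 90–100%;
* comparisons happen at **three levels** — nucleotide composition
  (tetranucleotide signatures), predicted proteome (alignment and
  clustering), and functional profiles (category counts) — because at
  these divergences no single level is informative on its own.

# Models and statistics

## Exact-overlap assembly

Fragments are merged greedily on the longest exact suffix/prefix overlap
of at least `min_overlap` nucleotides (default 250 nt, the overlap a
~1 kb primer-walking subclone design leaves), in either orientation. A
contig whose own ends share an exact overlap is circularized by trimming
one copy. Exactness is a modelling choice, not a limitation: the
assembly criterion being emulated is "100% nucleotide identity within
the overlapping regions", and it keeps the round-trip oracle exact
(reassembly of shredded synthetic genomes must recover a rotation of the
truth byte-for-byte). Ties are broken lexicographically by fragment id,
so assembly is deterministic and invariant (up to rotation/orientation)
under permutation of the input.

## ORF calling on circles

For each strand and frame, every stop-to-stop interval contributes at
most one ORF — the one beginning at the interval's first in-frame start
codon (default `ATG`; `GTG`/`TTG` optional). An ORF is kept when its
start-through-stop span is at least `min_nt` (default 100 nt, the
literal reading of "greater than 99 nucleotides"); it may wrap the
origin but not overlap itself (span ≤ genome length). Translation uses
genetic code 11. This deterministic rule replaces trained viral gene
finders; it will differ from them when a real gene starts at a non-first
ATG, which is why the threshold and start-codon set are exposed.

Coordinates are 1-based inclusive, GFF-style (`start ≤ end`, strand
flag); `end < start` is reserved for origin-wrapping ORFs, which are
serialized in GFF3 as two CDS parts sharing an `ID` with a `wrap=true`
attribute.

## Tetranucleotide z-scores

For tetramer $w = n_1n_2n_3n_4$ with both-strand circular counts $N$,
the maximal-order Markov expectation and variance are

$$E(w) = \frac{N(n_1n_2n_3)\,N(n_2n_3n_4)}{N(n_2n_3)},\qquad
\mathrm{var}(w) = E(w)\Big(1-\tfrac{N(n_1n_2n_3)}{N(n_2n_3)}\Big)
                       \Big(1-\tfrac{N(n_2n_3n_4)}{N(n_2n_3)}\Big)$$

and $z(w) = (N(w)-E(w))/\sqrt{\mathrm{var}(w)}$, with $z = 0$ for
degenerate divisors. The sequence and its reverse complement are counted
independently (no chimeric junction words), making the profile strand
invariant — appropriate for ssDNA genomes, which are effectively
compared via their replicative-form statistics. Genome pairs are scored
by the squared Pearson correlation ($R^2$) of their z-vectors. Windows
containing `N` are skipped. Circular counting is the default because the
genomes are circular; a linear mode and a raw-frequency mode exist for
sensitivity analysis.

## Alignment and E-values

Global alignment is Needleman–Wunsch with affine gaps and end gaps
penalized (a gap of length $L$ costs $\mathrm{open} + L\cdot
\mathrm{ext}$; defaults 10/0.5 with BLOSUM62), local alignment is
Smith–Waterman (defaults 11/1). The percent-identity denominator is the
total number of alignment columns including gap columns; the
shorter-sequence denominator (the CD-HIT convention) is available via
`alignment_identity()` because published identity tables rarely state
their convention. "Similarity" counts aligned pairs with positive
substitution score (identities always included). The unknown residue `X`
scores 0 against everything — a simplification of BLAST's treatment.
Local scores get Karlin–Altschul E-values $E = K\,m\,n\,e^{-\lambda S}$
with fixed gapped-BLOSUM62 parameters ($K = 0.041$, $\lambda = 0.267$);
no composition-based or finite-length corrections are applied, so
E-values here are comparable with each other, not with BLAST output to
the last digit.

## Greedy clustering and its sharp edges

Sequences are processed longest-first; each joins the best-matching
existing representative whose similarity (identities in the optimal
global alignment over the shorter length) **strictly exceeds** the
threshold (default 0.40), else founds a cluster. Best-match assignment
(not first-fit) makes the result robust to input order.

Two properties of the shorter-sequence denominator deserve attention.
First, *boundary equality founds a new cluster* (">40%" is strict).
Second, a very short random protein can reach ~40% identity against an
unrelated long one simply because the alignment may place its few
residues favorably: we measured ~0.41 for a random 90-aa vs 550-aa pair.
Clustering claims at the 0.40 threshold are therefore only sharp when
gene lengths are within a factor of ~3, and the test suite constructs
its analytic cases accordingly. The `columns` denominator avoids this at
the cost of penalizing genuine domain-level matches.

## Pangenome shared/unique logic

The pangenome is the **plain union** of the reference gene sets (no
deduplication unless requested). The cluster route and the local route
are computed and reported independently: global-identity clustering at
40% is much stricter than E ≤ 0.01 local similarity, so a gene can be
shared by local alignment yet cluster with nothing — exactly the
situation of a divergent phage whose three core genes are recognizable
only by local alignment. The local route's search space is the total
pangenome residue count (database-style E-values), mirroring a pooled
protein database search rather than per-pair statistics.

## Profile distances and UPGMA

Cluster memberships are binarized and compared by Jaccard distance
($d = 1-|A\cap B|/|A\cup B|$; two empty profiles are at distance 0);
functional-category count tables use Bray–Curtis
($d = \sum|x-y|/\sum(x+y)$, all-zero rows are an error). Neither the
metric nor the linkage of the emulated analyses is documented anywhere
authoritative, so these defaults are the standard ecology choices and
both are configuration-exposed; topology-level reproduction of published
figure dendrograms is consequently *not* an acceptance claim. UPGMA is
implemented explicitly so the tie-break is fully specified (merge the
lexicographically smallest minimum-distance pair; heights are half the
merge distance), which makes tree output deterministic and lets the test
suite compare against average-linkage `hclust` on tie-free matrices.
Robinson–Foulds distances count the symmetric difference of non-trivial
bipartitions.

# The synthetic world

`simulate_dataset()` generates the world the analyses assume, with truth
tables for every stage:

* a rooted bifurcating tree over `n_genomes` (default 15: a query plus
  14 references), random or user-supplied;
* ancestral protein families in a modular size scheme — one capsid-sized
  gene (480–600 aa), one replication-initiator-sized gene (300–400 aa),
  the rest 40–150 aa — first residue fixed at `M`;
* evolution by a **uniform replacement model**: along a branch of length
  $b$ (expected substitutions/site) each site is hit with probability
  $1-e^{-b}$ and redrawn uniformly from the 20 amino acids. This gives
  the closed-form expected identity between leaves at path distance $d$,
  $\mathbb{E}[\mathrm{id}] = e^{-d} + (1-e^{-d})/20$, which the tests
  check at 500-aa lengths to within 3 points. PAM/WAG matrices would be
  more realistic but would buy nothing here: the tests need controlled
  identity levels, not realistic exchangeabilities;
* **codon-level evolution**: the ancestor is back-translated once under
  a two-point GC-bias scheme (max-GC synonymous codon with probability
  $\pi$, else min-GC, $\pi$ solved for the target GC; feasible range
  ~0.25–0.75, default 0.40) and codons then evolve down the tree —
  replacement events redraw the codon, synonymous churn redraws it at
  the neutral rate, and spacers mutate per site. An earlier design that
  re-back-translated every leaf independently was discarded: it
  destroys nucleotide-level phylogenetic signal, and the
  tetranucleotide nearest-match recovery rate collapsed to ~0.44
  against the 0.80 the pipeline should achieve on well-separated clades
  (measured 0.91 with the present design);
* optional per-family **rate multipliers**: real phage genes evolve at
  very different rates (capsid conserved, hypotheticals fast), and rate
  heterogeneity is also what lets a single 40% clustering threshold
  resolve several depths of the tree — with uniform rates the
  membership profile is informative at exactly one depth and deep
  topology recovery from it is impossible in principle;
* intergenic spacers (12–60 nt) each end with an in-frame `TAA`
  immediately before the next gene start, so the first-ATG rule recovers
  true gene starts exactly; ORF-coordinate recovery is ≥ 95% by test
  (misses can still arise on the reverse strand or from chance spacer
  content);
* `shred()` tiles the circle with fixed-length fragments every `step`
  nucleotides (overlap = `fragment_len − step`, defaults 1000/250),
  randomly reverse-complementing each, with the layout recorded.

All randomness flows from one integer seed through fixed per-stage
derived seeds; identical seeds give byte-identical datasets.

**What a green test does not establish.** The generator has no
recombination, no gene gain/loss, no overlapping genes, no indels within
genes, no sequencing error, and its spacers are nearly neutral. Green
parameter-recovery tests therefore establish the *pipeline logic* —
clustering, membership profiles, UPGMA, tetra comparison — under the
stated world, not performance on real, messier genomes.

# Numerical choices and degenerate inputs

* Composition excludes `N` from denominators; an all-`N` sequence is an
  error. Display rounding is one decimal for percentages, nearest
  integer for coding capacity; returned values are never rounded.
* `tetra_zscores` requires length ≥ 7; constant z-vectors make $R^2$
  undefined and raise an error naming the genome.
* Local alignments with no positive-scoring segment return the empty
  alignment (score 0, identity 0) rather than a forced one.
* UPGMA tie-break and the greedy-merge tie-break (longest overlap, then
  lexicographic ids, unflipped before flipped) are the only two places
  ties can occur; both are fixed so every output is reproducible.
* The pipeline report excludes only the timestamp from its canonical
  JSON; reruns on identical inputs are byte-identical.

# Known limitations

* The ORF caller's first-ATG rule can disagree with trained gene finders
  on real genomes (documented flag: `min_nt`, `start_codons`,
  `forward_only`).
* E-values use fixed Karlin–Altschul parameters; scores from other
  matrices/gap regimes would need their own parameters.
* The assembler is exact-overlap only — by design it cannot absorb
  sequencing error or resolve repeats longer than `min_overlap`.
* Tetranucleotide $R^2$ saturates near zero for genomes beyond ~1
  substitution/site; at that range only protein-level comparison is
  informative, which is the reason the pipeline runs all three levels.
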