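---
title: "Methods: post-assembly analysis of population-level EST data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-assembly analysis of population-level EST data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estpop)
```

## Scope and data model

`estpop` analyses the *output* of a de novo EST (expressed sequence tag)
assembly built from pooled population samples: the padded multiple
alignments of reads within each contig, the unigene set (contigs plus
unassembled singletons), and precomputed translated-search hits of
unigenes against reference protein databases. Assembly itself, read
cleaning, and running the similarity searches are out of scope: those
are consumed as files. The central objects are

* `multiple_alignment` — one contig's padded consensus row plus each
  read's padded sequence and 0-based start offset. Column analysis uses
  padded coordinates; every length or rate denominated in bp uses the
  unpadded (pad-free) consensus. The consensus row is trusted as the
  assembler produced it; `consensus_discrepancies()` reports columns
  where the read majority disagrees, but nothing downstream recomputes
  the consensus.
* hit records in an extended tabular dialect — standard translated
  search tabular columns plus frame, query/subject lengths and the two
  gapped alignment rows, which make gap-aware completeness and codon
  reconstruction possible. The 12-column standard dialect is accepted
  with degraded (gap-blind) behaviour and an explicit warning.

In memory all coordinates are 1-based (the R convention); the 0-based
conventions of the on-disk SNP table are produced only in the writers,
so exactly one code path performs the shift.

## SNP calling

Each padded column is analysed independently. A column is a candidate
when the consensus character is not a pad and at least two distinct
nucleotide alleles (`A,C,G,T`) occur among the covering reads; reads
showing a pad or `N` at the column count neither as alleles nor toward
the coverage used by the criteria. Two published criteria are evaluated:

* **loose** — the two most common alleles each appear in ≥ 2 reads;
  designed to maximise discovery of rare alleles.
* **strict** — coverage ≥ 6× and the minority allele accounts for
  ≥ 25% of covering reads; designed to suppress sequencing-error false
  positives.

At the default thresholds strict implies loose (coverage ≥ 6 and
fraction ≥ 0.25 force a minor count ≥ 2); the test suite asserts this
containment on a thousand randomised alignments, and checks the whole
caller against a deliberately naive per-column recount written
independently of the vectorised implementation. Tri-allelic columns
yield one call on the top two alleles; rank ties break alphabetically
so results are deterministic. Indels are not called: pads are excluded
by construction.

Variant regions follow the assembler-style grouping rule: columns with
≥ 2 character states (pads count as a state here) each supported by
≥ 2 reads are chained while at most 11 non-polymorphic columns separate
them; single-column chains are not regions. A region's variants are the
distinct spanning strings of reads that cover the *entire* region, each
requiring ≥ 2 supporting reads — partially spanning reads are ignored
because truncated strings would otherwise manufacture phantom variants.
Base qualities are not consulted anywhere: the inputs carry none, which
is a documented deviation from assembler-internal variant calling.

## Ortholog hit ratio and coding classification

The ortholog hit ratio divides the non-gap characters of the query's
hit region — counted in residue (codon) units on the translated query
row — by the best-hit subject's length in residues. Counting residues
rather than nucleotides keeps the ratio dimensionless; a gapless HSP
covering the whole subject gives exactly 1.0 and values above 1.0
indicate query insertions. All HSPs of the best subject are merged by
the union of the query nucleotide positions their non-gap residues
occupy, so overlaps count once and duplicated HSPs cannot inflate the
ratio. Best hits are chosen by lowest e-value (records at or above the
1e-5 cutoff are discarded), then highest bit score, then subject id —
the last step only to make results reproducible.

The merged hit region doubles as a conservative putative coding region.
When HSPs disagree on reading frame the frame with the largest merged
region is kept and the annotation flagged. A SNP inside the region is
classified by rebuilding its codon on the frame's lattice (anchored at
the interval start for forward frames; reverse frames anchor at the
interval end and translate the reverse complement), substituting the
two alleles, and comparing translations under the standard genetic
code. Codons truncated at region edges, or containing `N`, are
`unassigned` rather than guessed. SNP positions map to query positions
identically because the unigene *is* the query sequence.

## Diversity statistics

With reads pooled from an unknown number of haplotypes, classical
estimators that condition on sample size are unavailable. The package
uses the depth-corrected relative diversity

$$\beta = \frac{S}{L \cdot H_{\mathrm{round}(D) - 1}},$$

with $S$ the strict-criterion SNP count, $L$ the relevant length
(whole contig for $\beta_t$; putative coding region for $\beta_n$ and
$\beta_s$), $D$ the average fold coverage and $H_n$ the $n$-th harmonic
number. $D$ is rounded half-up before forming $H_{D-1}$; a
digamma-based continuous variant is available
(`harmonic_terms = "digamma"`) for sensitivity analysis, and agrees
with the integer form to a few percent at moderate depth. $\beta_n$ and
$\beta_s$ both use the coding length $L_c$ as denominator — no
synonymous/non-synonymous site partitioning is attempted, favouring
fidelity to the simple published construction over Nei–Gojobori-style
sophistication. Contigs qualify at $D \ge 6$ by default (a 2× variant
is a single argument away), and summary means/medians are computed per
statistic over the contigs where that statistic is individually
defined.

Because $\beta$ conditions on read depth rather than on the true number
of sampled haplotypes, it is a *relative* measure: with $K$ haplotypes
sequenced to depth $D > K$, the expectation of $\beta$ is biased by the
factor $H_{K-1}/H_{D-1}$ relative to the planted per-site rate. This is
exactly what the recovery study measures (below).

## Clustering

Unigenes are aggressively clustered through a best-hit association
graph: each unigene connects to its best same-species unigene match
(self-matches excluded) and to its best protein hit per database;
connected components (computed with igraph, and cross-checked in the
tests against an independently written union-find) define clusters.
Protein nodes connect but do not count as members, so cluster sizes are
pure unigene counts. There are no reciprocal-best or edge-weight
requirements — single-linkage semantics are the point, since the
procedure exists to reveal families (e.g. unassembled rRNA reads) that
splinter across many unigenes while sharing one protein hub.

## The synthetic-data generator

`simulate_est()` emulates the statistical structure of a pooled-sample
454-style EST study so that every stage can be tested against known
truth without external data:

* coding transcripts (UTR + CDS + UTR) back-translated from random
  reference proteins; protein lengths normal around 250 residues, UTRs
  around 60/120 nt;
* $K = 16$ population haplotypes; a site segregates with probability
  $\theta \cdot H_{K-1}$ (the Watterson expectation for a sample of
  $K$ sequences), so `theta` is the quantity a depth-corrected
  estimator should recover; derived-allele counts follow the neutral
  $1/i$ frequency spectrum by default, or are fixed at $K/2$
  (`allele_freq_model = "balanced"`);
* reads of ~400 ± 50 nt placed with chained random offsets so
  consecutive reads overlap; the contig is the covered transcript
  window and all emitted coordinates are window-relative; per-contig
  depth is lognormal with median 3.3× and mean ≈ 10×, matching the
  scale of real 454 transcriptome assemblies; per-base errors are iid
  substitutions (no homopolymer indel model — pads never arise, which
  is consistent with the SNP criteria ignoring pads);
* about 35% of genes are emitted as single unassembled reads
  (singletons), which carry their own truncated, frame-correct hit
  records;
* hit records encode each unigene's true CDS overlap as a gapless HSP
  with correct frame and subject length; `truncate_hits()` replaces
  them with prefix/suffix HSPs whose completeness is drawn from
  `Uniform(0.2, 1)` and anti-coupled to subject length, reproducing the
  observation that longer genes are discovered less completely;
* an optional `rrna_family` block emits a high-divergence singleton
  family sharing one protein hub, the structure that clustering should
  recover as a single large cluster.

Identical seeds give byte-identical output files. What the generator
does *not* emulate: assembler errors (true read placements stand in for
assembler output, deliberately isolating the post-assembly analysis),
homopolymer indels, chimeras, paralog collapse, and expression-level
biology beyond the lognormal depth distribution. Passing tests
therefore validate the analysis given a correct assembly, not
robustness to assembly artefacts.

### Calibration choices in the recovery studies

The β recovery study runs 300 contigs (proteins ~330 residues) of
16 haplotypes at uniform 30× full-length-read coverage, error-free,
with *balanced* (50/50) allele frequencies and $\theta = 0.005$. The
balanced spectrum is chosen deliberately: the strict criterion censors
sites with minor-read fraction below 25%, so under a neutral $1/i$
spectrum much of the frequency mass would be filtered and the study
would measure the censoring, not the estimator. At 50/50 the expected
loss is ≈ 0.5% (binomial tail at depth 30) and the remaining deviation
of mean $\beta_t$ from $\theta$ is the depth-conditioning bias
$H_{15}/H_{29} \approx 0.84$ — a relative error of ≈ 16%, inside the
20% band the recovery criterion allows and an honest display of the
estimator's documented bias. The truth-replay study (120 contigs at
20×, $\theta = 0.008$) measures strict-criterion sensitivity ≈ 99%
(binomial censoring at depth 20 predicts ≈ 98.8%), zero false
positives without sequencing error, and exact agreement of
synonymous/non-synonymous labels with generator truth; truth labels are
computed in consensus context so that multi-SNP codons are labelled the
same way the classifier sees them. These problem sizes keep the whole
suite and the acceptance script comfortably fast while leaving the
statistical margins quoted above.

## Numerical and degenerate-input conventions

* Medians of even-sized sets are the mean of the central pair.
* Empty inputs produce zero counts and absent (`NA`) means; rates with
  zero denominators are `NA`, never `Inf`.
* `beta_stat` is `NA` below the coverage floor or when
  $\mathrm{round}(D) - 1 < 1$.
* Ties anywhere (major/minor alleles, best hits) resolve
  alphabetically after the substantive keys, for determinism.
* `read_fasta` uppercases and maps `U → T`; `N` counts toward coverage
  but never toward alleles.
* The alignment layout format round-trips bit-exactly; an ACE reader
  maps CAP3-style files onto the same model, trimming assembler
  overhang to the consensus bounds.

## Worked example

```{r example}
cfg <- sim_config(seed = 42, n_genes = 40)
sim <- simulate_est(cfg)
sim

calls <- call_snps(sim$alignments, "any")
anns <- annotate_unigenes(sim$hits, db = "bmori")
calls <- classify_snps(calls, anns, sim$unigenes)
snp_rate_summary(sim$alignments, calls, "strict")

div <- diversity_table(sim$alignments, calls, anns)
diversity_summary(div)

strat <- ohr_by_stratum(anns, sim$alignments,
                        sim$unigenes$id[sim$unigenes$kind == "singleton"])
strat
```

## Known limitations

* Quality values are ignored throughout; variant regions therefore
  differ from assembler-internal calls where qualities matter.
* $\beta$ comparisons across datasets with different depth profiles
  inherit the $H_{K-1}/H_{D-1}$ bias and should be read as relative.
* The ratio denominator uses the single best subject; paralogous or
  chimeric best hits violate the orthology assumption silently.
* The generator's uniform-haplotype pool ignores family structure in
  real pooled samples (a Dirichlet skew would be the natural
  extension).
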