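---
title: "Methods: tag-based digital gene expression analysis with tagdge"
author: "tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based digital gene expression analysis with tagdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The measurement model

Tag-based digital gene expression (DGE) counts short sequence tags as a
proxy for transcript abundance. Each mRNA is anchored at its 3'-most
NlaIII recognition site (CATG); MmeI then releases a 21-nt tag — the
CATG plus the next 17 nt — which is sequenced at depth. A transcript
database digested *in silico* at every CATG with at least 17 nt
downstream, on both strands, gives the *reference tag library*; an
observed tag is assigned to a gene by looking it up there.

Three structural facts drive the whole analysis:

* a tag sequence carried by exactly one gene is *unambiguous* and usable
  for quantification; a tag shared by several genes is discarded from
  gene counts;
* CATG is its own reverse complement, so every sense site is also an
  antisense site — tags matching only the antisense strand of a gene
  are evidence of antisense transcription and are reported separately,
  never added to the gene's count;
* sites are ranked from the 3' end (rank 1 = 3'-most full-length site),
  so a library behaving as the protocol intends concentrates its mass
  at rank 1. `tag_position_profile()` measures exactly that.

## Filtering and the conservation ledger

Raw reads are cleaned in a fixed order: adaptor matches first, then
low-quality reads, then *singletons* (reads whose tag has library copy
number 1 after the first two filters). The ledger identity

    n_raw = n_adaptor + n_low_quality + n_singleton + n_clean

is asserted on every run. Two choices here were genuinely open:

* **Low quality** is not a published rule for this protocol; we define a
  read as low-quality when it contains N or any base under a Phred
  threshold (default 10), and apply only the N rule when qualities are
  absent. This is the minimal reproducible stand-in for a proprietary
  sequencer pipeline filter.
* **Singleton order**: singleton status must be evaluated on a fixed
  multiset; we evaluate it after the adaptor and quality filters, so
  each copy-1 tag removes exactly one read and the singleton column is
  simultaneously a read count and a unique-tag count.

Saturation is assessed by a single seeded shuffle of the read stream
(sampling without replacement — the cumulative-sequencing view of
rarefaction), scanning prefixes at a fixed step; curves are monotone by
construction and end at the exact library totals.

## Mapping cascade

Annotation proceeds gene library → mitochondrial genome → nuclear
genome → unknown, each unique tag landing in exactly one category:

* Against the reference library, exact matches take precedence over
  1-mismatch matches (the single mismatch accommodates polymorphism
  between the profiled animals and the database). Within the best tier,
  sense hits beat antisense hits; one gene is unambiguous, several are
  ambiguous. The 1-mismatch lookup enumerates all 63 single-substitution
  neighbours of the 21-mer, which is Hamming-1 complete; tests compare
  it against an exhaustive distance scan.
* Genome stages use exact 21-mer membership on either strand only. A
  mismatch tolerance there would manufacture spurious "novel
  transcript" candidates from sequencing error, and nothing in the
  protocol motivates it.
* Percentages in the census divide category totals by the clean total
  and unique-category counts by the unique clean total, rounded to two
  decimals. The "mapped to gene" row counts every reference-library hit
  (unambiguous + ambiguous + antisense); the "unambiguous" row counts
  sense single-gene hits only, which is also exactly the set that feeds
  gene counts.

## Differential expression

Counts are normalised to tags per million (TPM), `count / N * 1e6`,
where N is the library's **total clean tags** — not the gene-mapped
subset; back-calculation of published tables supports this denominator.
Zero counts report a 0.01 TPM floor so presence/absence genes have a
defined fold change; the floor applies only to zeros.

The two-library test is the Audic–Claverie exact test: conditioning on
count *x* in library 1 (sizes N1, N2), the null distribution of *y* is

    P(y | x) = (N2/N1)^y (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) )

— a negative binomial with size x+1 and probability N1/(N1+N2). The
one-tail p is the smaller of the inclusive tails Σ_{j≤y} and Σ_{j≥y};
the two-sided p doubles it, capped at 1. Sums are accumulated in log
space with an adaptive upper cutoff (the pmf decays geometrically past
its mode); the implementation agrees with an arbitrary-precision tail
summation to better than 1e-10 relative error across a frozen grid, and
is *more* accurate than naive `1 - cumulative` evaluation for extreme
tails.

One subtlety worth stating: with both tails endpoint-inclusive the test
is not exactly label-symmetric — swapping (x, y) at equal depths changes
the two-sided p by exactly twice the shared pmf point. This is inherent
to the tail definition, immaterial at any realistic count, and is
asserted as an identity in the test suite rather than papered over.

Multiplicity is Benjamini–Hochberg (`stats::p.adjust`); a gene is called
at p < 0.001 **and** FDR < 0.001 **and** |log2FC| > 2, all three
configurable (published practice around this protocol is not fully
consistent about the FDR cutoff, so the thresholds are parameters with
these defaults).

## Enrichment and qPCR validation

Enrichment is the upper-tail hypergeometric test of the significant
genes against a background, Bonferroni-corrected within each annotation
category (GO branches and pathways are corrected separately). The
background defaults to the genes detected in either library rather than
a whole-genome annotation: for expression data, genes with no chance of
detection should not inflate N. Genes lacking any term annotation still
count toward N.

qPCR validation uses 2^-ddCt: technical replicates are averaged per
sample, dCt = Ct(target) − Ct(reference), ddCt is the difference of
group means, and groups are compared by a two-sided Welch t-test on
per-animal dCt (the safe default at n = 3 per group, giving 1–4 degrees
of freedom). Efficiency correction and reference-gene stability
selection are out of scope.

## The synthetic study

The generator defines the study conditions once:

* 2,000 genes; library depths 200,000 and 319,000 raw tags, preserving
  the ≈0.63 depth ratio of a two-breed comparison at desk scale;
* log-normal abundances (sdlog 1.5), so a small minority of tags
  dominates totals — the qualitative signature of real tag libraries;
* 200 planted genes at |log2FC| = 3 (8-fold), half up in each library,
  drawn only from genes whose expected baseline count in the shallower
  library is ≥ 25, so every planted effect is statistically reachable;
* per-base substitution error 0.001 (the per-read error count is exact
  truncated-binomial, not one-error-per-read); adaptor reads at 0.2%
  and N-containing reads at 0.5% of raw, mirroring the bookkeeping
  categories of real runs; small mitochondrial (0.05%) and intergenic
  (0.5%) decoy fractions to exercise the genome cascade;
* transcripts are assembled from CATG-free chunks around planted
  CATG + 17 nt sites with junction guards, so the sense digest yields a
  known site count and the 3'-most tag is known per gene — making every
  downstream expectation computable from the truth ledger.

What the generator does **not** emulate: position-dependent Illumina
error profiles, PCR duplication, incomplete digestion, and
database incompleteness (real studies leave ~10–20% of unique tags
unmapped; here unmapped mass comes only from planted decoys). Passing
tests therefore demonstrate correctness of the algorithms under the
stated model, not the field error structure of a sequencer.

## Numerical and design choices

* Truncated 3' sites (< 17 nt downstream) yield no tag — MmeI cannot
  produce a short tag — and tags containing N are dropped from the
  reference; position ranks are assigned over full-length sites before
  the N filter.
* Cross-database gene identity uses an optional cross-reference table;
  without one, identifiers are compared verbatim. Equal-priority
  duplicates keep the first record and warn.
* Ambiguity is classified on exact reference tag sequences; mismatch
  ambiguity is resolved at mapping time over the union of all hit
  sequences.
* All randomness flows from one master seed; stage generators derive
  fixed offsets from it, and every report carries the configuration
  hash and seed in a `##` provenance line.
* Problem sizes in the test suite (desk-scale libraries of 2 × 10^5
  tags, 10-seed recovery studies, 2,000-gene null simulations) were
  chosen so the whole suite characterises the estimator distributions
  in seconds while keeping every planted effect in the testable regime.

## Limitations

Two pooled libraries support no biological-replicate variance; the
exact test measures sampling noise only, which is why published work in
this design validates by qPCR on independent animals. Gapped or spliced
genome alignment, GO graph propagation, and novel-transcript assembly
are deliberately out of scope; genome hits are reported as exact 21-mer
membership and nothing more.
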