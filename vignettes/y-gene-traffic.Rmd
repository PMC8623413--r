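---
title: "Characterizing a repeat-rich Y chromosome: methods and design notes"
author: "YTraffic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a repeat-rich Y chromosome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(YTraffic))
```

## The problem

Drosophila Y chromosomes grow by importing genes from the autosomes and the
X rather than by degenerating from an ancestral X–Y pair. Characterizing
such a chromosome from a draft assembly raises a chain of computational
problems, each of which this package implements as a tested, reusable
component:

1. which assembly scaffolds are Y-linked (no female individual carries
   them);
2. which autosomal regions were copied into the Y as large segmental
   duplications, and in how many copies;
3. which duplicated gene copies are still functional and which are
   pseudogenes, and whether the duplication was DNA-mediated;
4. on which branches of the species phylogeny genes were gained and lost,
   and how strongly gains outnumber losses.

Every stage can be exercised end to end on synthetic genomes, read sets and
event histories with known truth, which is how the test suite validates the
implementations.

## Y-linked scaffold identification (YGS)

A scaffold is scored by comparing the assembly against male and female
short-read sets at the k-mer level. For each scaffold we count canonical
k-mers (the lexicographic minimum of a k-mer and its reverse complement;
windows containing ambiguous bases are dropped) and retain those occurring
exactly once in the whole assembly. Of these single-copy k-mers, the ones
also observed in the male read set are *valid* — the male support screens
out assembly artifacts. The scaffold's score is

$$\mathrm{pct\_unmatched} = 100 \times
  \frac{\#\{\text{valid single-copy k-mers absent from female reads}\}}
       {\#\{\text{valid single-copy k-mers}\}}.$$

Autosomal and X scaffolds are covered by female reads and score near 0;
Y-linked scaffolds score near 100; the distribution is sharply bimodal and
a cutoff of 60% (80% as a robustness check) separates the classes.
Scaffolds with fewer than 20 valid single-copy k-mers are uninformative and
are reported as `unclassified` rather than forced into a class.

Parameters and defaults:

| parameter        | default | meaning                                          |
|------------------|---------|--------------------------------------------------|
| `k`              | 15      | k-mer length; 15 is the customary choice for chromosome-of-origin classification |
| `minValid`       | 20      | minimum valid single-copy k-mers to classify     |
| `cutoff`         | 60 (%)  | Y call threshold on `pct_unmatched`; ties classify as Y |
| `femaleMinCount` | 1       | female occurrences needed to call a k-mer matched |

Numerical note: canonical k-mers are 2-bit packed into doubles, which is
exact for $k \le 26$ (52 bits); the implementation therefore accepts
$k \in [7, 26]$. Counting uses sort-plus-run-length encoding and membership
queries are binary searches on the sorted code vector, so a few-Mbp genome
with 10× read sets classifies within a couple of minutes on one core. The
test suite checks the whole computation against an independent oracle that
manipulates explicit k-mer *string* sets.

## Segmental duplications from the male/female depth ratio

Reads are binned (1 kb by default) and each sex's binned depth is divided
by its own autosomal baseline — the median bin depth over confidently
XA-classified scaffolds, which is robust to the duplications being sought.
On an unduplicated autosomal region both normalized tracks sit near 1.
Every hemizygous Y copy of a region adds half the per-copy autosomal depth
to the *male* track only, so $n$ Y copies give a normalized male depth of
about $1 + n/2$ against a female depth of 1. Copy number is estimated by
inverting this relation, $\hat n = \mathrm{round}\,[2(\bar m - \bar f)]$.

Visual inspection of coverage is replaced by an explicit rule: maximal runs
of bins with normalized male depth $\ge$ 1.4 and normalized female depth
below the same threshold, allowing interruptions up to 5 bins, emitted when
they span at least 10 kb. The 1.4 default makes a single hemizygous copy
(expected 1.5) the smallest detectable event at 20× depth; coordinates are
bin-aligned, so boundary error is at most one bin. A caveat worth knowing:
raising the elevation threshold can split one gap-merged run into two
calls, so the *count* of calls is not monotone in the threshold; the total
called span is.

Male-specific SNPs corroborate a diverged Y copy: a site counts when some
allele has at least 3 male reads, makes up at least 10% of the male depth,
and has zero female reads while the female depth is at least 5. With many
co-located Y copies an allele private to one copy can fall below the 10%
male-fraction filter; the count is therefore conservative for high copy
numbers.

Internally the pipeline never shells out to an aligner: depth is accepted
either as a per-base TSV (the shape standard depth tools emit) or from the
exact placements of simulated reads, with reads originating from implanted
Y copies projected back onto their source interval — which is precisely
what an aligner does to real male reads from the Y copies.

## Functional gene vs pseudogene

Two criteria, both required for a `functional` verdict:

* **intact CDS** — the candidate is globally aligned to the reference CDS
  (match 1, mismatch −1, gap open 4, gap extend 1; declared defaults, the
  procedure is insensitive to reasonable choices). Indels whose *net*
  length is not a multiple of 3 break the frame (`frameshift`);
  compensating indels that restore the frame do not. Otherwise an in-frame
  stop before the final codon is a `premature_stop`. An empty candidate is
  `truncated`.
* **expression share** — the copy must contribute more than 10% of its
  copy group's summed TPM. The denominator is the whole copy group (Y plus
  autosomal copies); a pairwise Y-vs-counterpart comparison gives the same
  verdict in the two-copy case, which is the common one, and the group
  share is the better-defined quantity for multicopy genes.

Nucleotide identity to the counterpart copy at or above 96% flags a recent
duplication; a separate 95% threshold governs which candidates count as
full-length copies in per-gene copy-count bookkeeping. The two thresholds
serve different rules and are deliberately kept apart.

Duplication mechanism: membership in a called segmental duplication proves
a DNA-mediated duplication; otherwise one exactly shared CDS-relative
intron position with the outgroup ortholog does. An intron-less outgroup
leaves the mechanism `undetermined` — absence of introns from the Y copy
alone is *not* evidence of RNA mediation, because intron loss can be
lineage-specific.

## Gains and losses on the phylogeny

Each Y-linked gene is assumed to have been acquired exactly once
(single-origin parsimony, Dollo-style): a duplication to the Y on some
branch, followed by any number of per-lineage losses of the source copy or
of the Y copy. Leaf states are `Y` (Y copy present, source lost), `XA`
(source only), `absent` (both lost) or `unknown`. For every candidate
acquisition branch — including the stem above the root — the minimum number
of losses explaining the leaves is computed by placing each loss as high in
the tree as possible; the scenario minimizing total events wins. Ties are
reported, and resolved toward the most recent acquisition, reflecting that
later acquisition with fewer intervening losses is the conservative
reading. The implementation is checked against exhaustive enumeration of
every (gain branch × loss-set) assignment on quartet trees.

The state alphabet is single-valued per species, so a species carrying
*both* a functional Y copy and a functional source copy cannot be encoded
exactly; such recent duplications are handled by including/excluding them
from the event set, mirroring the paired analyses this kind of study
reports.

### Rate model

Gains follow a Poisson process at rate $g$ per My of branch time; each
resident gene is lost at rate $\ell$ per gene-My of Y-residency. With $G$
gains over exposure $T_g$ (total branch time, stem included) and $L$
losses over exposure $T_\ell$ (summed residency, gains and losses placed
at branch midpoints when reconstructed by parsimony, at their exact times
when simulated):

$$\hat g = G/T_g, \qquad \hat\ell = L/T_\ell, \qquad
  \widehat{\mathrm{ratio}} = \hat g / \hat\ell .$$

The test of equal rates is a likelihood-ratio test on the
$\chi^2_1$ scale, and the confidence interval is a profile-likelihood
interval on the ratio, solved by bisection on the log scale to a tolerance
of 1e−8. Zero observed losses (or gains) produce a flagged one-sided
bound with the far CI endpoint at infinity (or zero) rather than a
pretend point estimate. The published headline ratio for this kind of data
depends on an appendix model whose exact exposure bookkeeping is not
reproduced here; the estimator is instead validated by simulation
recovery (below).

```{r rate-example}
# 25 gains over 250 My of branch time, 3 losses over 120 gene-My
gainLossFit(gains = 25, losses = 3, gainExposure = 250, lossExposure = 120)
```

## What the simulators emulate — and what they do not

* `simulateGenome()` builds i.i.d. background sequence at a configured GC
  with an explicit planted repeat library (0.5–5 kb elements shared
  between Y and XA scaffolds). This is the simplest structure that
  stresses single-copy filtering; it does not emulate transposable-element
  families, tandem arrays, satellite DNA or GC heterogeneity, so passing
  tests demonstrate correctness of the *classification logic*, not
  robustness to every repeat landscape of a real heterochromatic Y.
* `simulateReads()` draws uniform single-end reads (default 100 bp) with
  i.i.d. substitution errors; real libraries have indel errors, quality
  ramps, coverage biases and insert-size structure. Females sample zero
  fragments from Y scaffolds; males sample them at half the autosomal
  rate; pooled libraries at `maleFraction / 2` — an unsexed pool at 0.5
  reproduces the 8.4× → 2.1× expected-Y-coverage arithmetic of
  `expectedYDepth()`.
* `implantSegdup()` appends independently mutated copies of a source
  interval as Y scaffolds (per-base substitutions, 1-bp indels); real
  duplications also suffer internal deletions and rearrangements, which is
  why the caller tolerates gaps inside elevated runs.
* `pseudogenize()` introduces per-codon premature stops and 1-bp
  frameshifts; `simulateEventHistory()` draws gains as a Poisson process
  along branches and losses as per-lineage exponential first events, and
  records exact exposures, so estimator recovery is tested against the
  model's own truth.

Truth labels are emitted as sidecar tables, never encoded in the sequence
records that downstream stages consume.

## Problem sizes used by the checks

The package's own validation runs at sizes chosen to exercise every code
path while staying desk-scale: a 2 Mbp genome (10 XA + 6 Y scaffolds of
125 kb, 10% shared repeats) with error-free 10× sexed reads for scaffold
classification, checked k-mer-for-k-mer against the string-set oracle; a
10-copy, 200 kb implanted duplication at 20× depth and 1% per-copy
divergence for the caller (boundary error ≤ 1 bin, copy number ±1); 40
gene copies, half defect-bearing, for fate recovery; all 65 informative
quartet state patterns for the parsimony oracle; and 200 simulated
histories at a true gain:loss ratio of 10 (≈36 expected gains, ≈16
expected losses each) for estimator recovery and CI coverage. Genome-scale
published figures (tens of Mbp, thousands of scaffolds) require the
original sequencing accessions and are deliberately out of scope.

## Known limitations

* k is capped at 26 by the exact-integer range of doubles; a full-genome
  tool would use 64-bit or disk-backed k-mer structures.
* The segmental-duplication caller assumes the source region is still
  present and diploid; a duplication whose source was subsequently deleted
  would show a different depth signature.
* Copy-number estimates are rounded to integers; sub-clonal or partially
  deleted copies bias them downward.
* Parsimony reports tied acquisition branches rather than resolving them;
  the rate model assumes branch-homogeneous rates, and the
  likelihood-ratio test inherits the usual asymptotics (small event counts
  make the profile CI the more trustworthy summary).
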