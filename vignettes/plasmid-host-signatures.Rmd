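---
title: "Genomic-signature scoring of plasmid host range: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic-signature scoring of plasmid host range: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidhost)
```

## The model

A plasmid replicating in a host is slowly ameliorated toward the host's
mutational biases, so its short-word composition converges on the
host lineage's *genomic signature*. `plasmidhost` turns that observation
into a statistical test: a plasmid signature **x** is scored against the
distribution of signatures of non-overlapping chromosomal segments,
summarized by mean **μ** and covariance **S**, with the Mahalanobis
distance

$$D^2 = (x - \mu)^\top S^{-1} (x - \mu).$$

If segment signatures were multivariate normal and (μ, S) known, D² of a
segment-like sequence would follow a chi-square distribution with df
equal to the signature dimension d. The reported P-value is the
chi-square survival function at D²: P close to 1 means the plasmid is
compositionally indistinguishable from the chromosome's own segments; a
chromosome with P strictly greater than 0.6 is called an *evolutionary
host candidate*. The threshold is strict ("larger than 0.6"), and
raising it can only shrink the candidate set.

Assumptions worth keeping in mind:

* **Approximate normality of segment signatures.** Rho values of 5 kb
  segments are averages over thousands of windows and are close to
  normal for real and simulated chromosomes; heavy compositional
  heterogeneity (large mobile islands, rRNA arrays) fattens the tails.
* **df = d.** The chi-square reference with df equal to the canonical
  dimension is the standard choice for a multivariate-normal D² and
  reproduces the qualitative behaviour the method relies on (small D²
  gives P near 1). It ignores the estimation error in (μ, S); see
  *Calibration* below for how large that effect is and how we sized the
  fit to keep it small.
* **Whole-plasmid signature.** The plasmid is summarized by one
  signature over its entire length. Long accessory regions (tens of kb
  acquired recently) shift the whole-plasmid signature measurably; the
  clustering module makes such plasmids visible as outliers.

## The signature

K-mers are counted on *both strands*: an occurrence of word w on the
forward strand is also an occurrence of revcomp(w) on the reverse
strand. This makes every statistic of w identical to that of its
reverse complement, so the full 4^k vector carries duplicated
coordinates and its covariance is exactly singular — the Mahalanobis
step would be impossible. The feature space is therefore collapsed to
*canonical* words, the lexicographically smaller of each
reverse-complement pair: d = 10 (k = 2), 32 (k = 3), 136 (k = 4). The
count of a canonical class is the number of occurrences of either
member on either strand, so counts always sum to twice the number of
unambiguous windows, and the signature is exactly invariant — bit for
bit — under reverse complementation of the input.

Each class count is normalized to the rho statistic, observed over
expected frequency, with the expectation from the zero-order background:
the product of both-strand mononucleotide frequencies (p(A) = p(T),
p(C) = p(G) by construction). The zero-order background is deliberate —
it removes GC content from the signature's *scale* while keeping the
word-preference structure; higher-order (maximal Markov) normalization
would remove most of the lineage signal the method depends on.

Handling of degenerate input is explicit: windows containing `N` are
skipped; `N` is excluded from the base composition; a word class with
zero expected frequency (a base absent from the whole sequence) has
zero observed frequency too and its rho is defined as 0; a sequence
with no usable window at all is a classed error, never a silent NaN.

## The segment model

Chromosomes are cut into non-overlapping 5 kb segments (the window
length at which plasmid–host signature similarity ranks best among 2,
5, 10 and 20 kb alternatives); a trailing remainder is discarded, and
all-N segments are dropped. The covariance uses denominator n − 1 by
default; because the original convention is not fixed, `cov_denominator
= "n"` is available, and the two satisfy an exact identity used in the
tests: the mean in-sample D² of the n fitted segments is d with
denominator n and d·(n − 1)/n with denominator n − 1.

**Minimum length.** Inverting S requires more segments than dimensions;
we enforce n ≥ d + 2, i.e. a chromosome of at least (d + 2)·L bases —
170 kb for k = 3 at L = 5 kb, 690 kb for k = 4. We derive the bound from
(k, L) rather than hard-coding a single cutoff because any fixed cutoff
is k-specific: a 320 kb genome has 64 segments, enough for d = 32 but
not for d = 136. Exclusions are reported as classed errors (and
`predict_hosts()` warns with the excluded ids); they are never silent.

Numerical choices: D² is computed by a linear solve of S rather than
multiplication by the stored inverse; a condition-number guard at 1e12
rejects numerically singular covariances with an error naming the
chromosome; D² is clamped at 0 against tiny negative round-off.

## Calibration and the size of the fit

With (μ, S) *estimated* from n segments, the D² of a held-out segment is
inflated relative to chi-square by a factor of roughly
(1 + 1/n)·(n − 1)/(n − d − 2). At d = 32 this is ~24% for n = 200 but
only ~4% for n = 1000. The packaged calibration check therefore fits on
1000 segments (5 Mb) of a homogeneous 6 Mb simulated chromosome and
scores 200 held-out segments, where the Kolmogorov–Smirnov distance of
the P-values from uniform stays below 0.1; the fit size was chosen from
this variance argument, to measure miscalibration of the reference
distribution rather than estimation noise. The practical reading for
real data: P-values against short chromosomes (a few hundred kb) are
conservative — D² runs high and P low — so candidate calls near the 0.6
threshold deserve more trust on long chromosomes than on short ones.

## Ranking and prediction

For one plasmid against a host set, scores are ranked by ascending D²
(ties broken by chromosome id, so the order is deterministic), which is
equivalent to ranking by descending P-value. Each table reports the two
summaries used to judge the host-range character of a plasmid: the
maximum P-value (is there *any* candidate?) and the median D² (how far
is the plasmid from the host set as a whole?). A broad-host-range
plasmid characteristically shows *no* chromosome above 0.6 even when
its experimentally confirmed recipients are in the set.

## Clustering

Plasmid signatures are compared by Euclidean distance and grouped by
agglomerative clustering. Only the distance is fixed by the analysis
convention; the linkage is not, so average linkage (UPGMA) is the
default — the common choice for compositional profiles — with single,
complete and Ward exposed for matching other code. The deliverables are
the distance matrix, the group labels, and the dendrogram in Newick; a
heatmap is a presentation concern left to the caller (`pheatmap` or
`ComplexHeatmap` consume the matrix directly).

## The synthetic benchmark

`make_taxon_model()` builds one "lineage" as an order-2 Markov chain
over ACGT. Each context row is a convex combination, weighted by
`divergence`, of the GC-matched i.i.d. distribution and a seeded random
perturbation that is renormalized within the AT and GC pools, so every
row keeps P(G) + P(C) exactly at the GC target: GC content and
transition structure are controlled independently. Order 2 is the
default because it is the cheapest order that produces distinct 3-mer
signatures. `simulate_benchmark()` spaces taxa evenly across GC
0.35–0.68 — the span of real candidate-host chromosomes — with defaults
of 10 taxa, 1 Mb chromosomes, 50 kb plasmids, divergence 0.3, k = 3,
L = 5 kb.

"Broad" plasmids are 50/50 concatenations of two taxa's models. By
default the two parents are GC-adjacent: a mixture of two
compositionally *distant* lineages resembles neither parent — which is
precisely the empirical behaviour of natural broad-host-range plasmids,
whose best P-values stay far below 0.6 against thousands of genomes —
so adjacent pairing is the regime in which expecting both parents in
the top two ranks is meaningful. The weaker acceptance bar for mixture
plasmids (top-2 containment rather than rank-1) reflects the same
point.

What the generator deliberately does *not* emulate: repeats, mobile
islands and rRNA operons (real segment distributions are
heavier-tailed); amelioration over time (plasmids are drawn directly
from the host model, the best case for recovery); assembly artefacts
and ambiguity codes beyond what the N-handling tests cover. Passing the
benchmark therefore shows the statistical machinery is correct and the
effect is recoverable when the compositional model holds — not that
every real plasmid–host pair will score this cleanly.

Problem sizes in the packaged checks were chosen to keep the full suite
in the minutes range on one CPU: 20 benchmark seeds of 10 × 1 Mb
chromosomes for host recovery, a single 6 Mb chromosome for
calibration, 20 seeds of 4 × 6 plasmids for clustering, and 200 random
1 kb sequences against the naive counting oracle.

## Known limitations

* Tested word sizes are 2–4; larger k inflates d faster than real
  chromosomes supply segments.
* One signature per plasmid: chimeric plasmids with large recently
  acquired regions are scored as their average.
* The chi-square reference ignores (μ, S) estimation error; against
  minimum-length chromosomes the P-values are conservative (see
  *Calibration*).
* No shrinkage covariance estimator: chromosomes below (d + 2)·L are
  excluded outright rather than scored with a regularized S.
* GC clustering of conserved gene sets, taxonomy-aware aggregation and
  heatmap rendering are out of scope; the TSV/Newick outputs feed the
  standard tools for those steps.
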