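---
title: "Quantifying protease specificity from substrate phage display: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protease specificity from substrate phage display: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A protease recognizes substrates through a small number of subsites in its
catalytic cleft. For matrix metalloproteinases the S3-S1' subsites form the
dominant recognition unit, so the P3-P1' tetramer around the scissile bond
(Schechter-Berger numbering: P3-P2-P1 before the bond, P1' after it) is the
primary substrate motif. A randomized-hexapeptide phage display library
offers every tetramer in 1,200 distinct hexamer contexts (3 placements x
20^2 flanking pairs; self-overlapping tetramers slightly fewer), and deep
sequencing of protease selections reads out, for each of the 20^4 = 160,000
tetramers, how many of those contexts were accepted as substrates. That
count — the tetramer cluster size — is the raw material for everything this
package computes.

`selectome` implements the full analysis: insert extraction from reads,
tetramer clustering, the information-theoretic statistics, positional
profiles, kinetic validation, cleavage-site annotation in proteins, and a
generative simulator of the whole experiment.

## From reads to clusters

Reads are translated in all six frames (standard genetic code; codons
containing ambiguity symbols become `X`, stops become `*`) and the variable
region is accepted only when it lies strictly between the two constant
flanking tags, has exactly the configured insert length, and contains only
standard residues. One read contributes at most one hexamer: the first
valid frame wins, in the fixed order forward 0, 1, 2 then reverse 0, 1, 2.
The flank sequences are a property of the display vector and therefore
mandatory configuration; the defaults (`DLA`/`GAE`) are simply what the
package's own read simulator uses. Peptides observed in the untreated
control are removed from selections by sequence identity — anything that
survives immunodepletion without being cleaved is background.

Clustering differs by sample role. In the **naive library** no selective
pressure distinguishes a hexamer's three candidate tetramers, so each
distinct hexamer joins all of its candidate clusters (once per distinct
tetramer). In a **selection**, a hexamer was retained because one site was
cleaved, so it is assigned to a single cluster: the most abundant candidate
in the initial multi-membership table, with redundancy eliminated from the
least abundant clusters upward. Ties are resolved deterministically —
clusters are visited in lexicographic order within the same initial size,
and a hexamer's own tied candidates resolve to the smallest offset, then
the lexicographically smallest tetramer. Two consequences matter:

* abundances are **static** initial counts; the elimination order therefore
  cannot change the result, and the procedure reduces to "each hexamer
  keeps its maximally abundant candidate" (the test suite checks this
  against a literal implementation of the staged elimination);
* all statistics count **distinct hexamers**, never reads — read counts
  ride along as metadata only.

## The statistics

With $n_t$ the number of hexamers in cluster $t$ and $N$ the total number
of cluster assignments in the same table,

$$P(t) = \frac{n_t}{\sum_i n_i}, \qquad
  H(T) = -\sum_t P(t)\log_2 P(t),$$

computed separately for the selection (partitioned counts) and the naive
library (multi-membership counts). The fitness statistic is the relative
probability

$$\mathrm{RP}(t) = \frac{P_S(t)}{P_{NL}(t)},$$

which cancels library composition bias and sequencing-depth differences;
its theoretical maxima run from 1 (non-specific enzyme) to 160,000 (single
substrate). Overall specificity is the Kullback-Leibler divergence

$$D_{KL}(P_S \| P_{NL}) = \sum_t P_S(t)\log_2 \mathrm{RP}(t),$$

0 bits for an enzyme indistinguishable from the library, up to
$\log_2 160{,}000 = 17.288$ bits for perfect specificity against a uniform
reference. Clusters with RP below 1 contribute negatively, clusters above 1
positively; sorting clusters by ascending RP and accumulating contributions
gives a curve that dips and then rises. The RP at which the running sum
first returns to zero closes the region with no net contribution to the
divergence; everything strictly above that threshold is the **selectome** —
the set of motifs that, only as a whole, constitutes the enzyme's
specificity signature. Membership is strict (`RP > threshold`): the
crossing cluster itself completes the zero-sum region. When no cluster
exceeds RP = 1 there is no positive divergence mass and the enzyme has no
definable specificity; the threshold is reported as `NA`.

Numerical choices: logs are base 2 throughout (a `base` argument on
`shannon_entropy()` exposes the log20 per-subsite convention used for
database-derived matrices); the zero-crossing comparison carries a relative
tolerance of `1e-9` of the largest contribution so that exactly cancelling
toy tables behave; and a cluster observed in the selection but absent from
the naive table receives a naive pseudocount of one hexamer and a flag —
with realistic naive depth this is rare, but the statistic must not divide
by zero. `fold_specificity()` converts entropy differences to fold
narrowing, $b^{H_{ref}-H_{obs}}$.

## Profiles and validation

Cluster members share the P3-P1' core at offsets 0-2, so each hexamer
occupies six consecutive positions of the P5-P3' window (offset 0 spans
P3-P3', offset 2 spans P5-P1'). Position frequency matrices count each
distinct hexamer once and normalize by per-position coverage — positions
reached by fewer members (P5, P3') are normalized by what covers them, and
the alternative (normalizing by all members) is deliberately not used so
that information content, $\log_2 20 - H(\text{position})$, stays
comparable across positions. Substrates are stratified into ten
RP/RP~max~ groups with right-closed bins, `((k-1)/10, k/10]`, exact zeros
joining the lowest bin; the per-group matrices show how composition shifts
with fitness.

Validation against measured constants works in two modes. The binned
correlation groups substrates contiguously along ascending RP (equal count
per bin by default, equal RP width behind a flag), then regresses mean
constant on mean RP; binning averages out the context contribution of the
P5-P4/P2'-P3' residues, so the binned correlation exceeds the raw one
whenever RP genuinely tracks fitness. Binary classification treats
`RP > threshold` as the prediction and a non-zero constant (or an
isotopic-enrichment call) as the truth, reporting sensitivity, specificity,
accuracy, FP rate, precision and the Matthews correlation coefficient, with
a zero denominator reported as MCC 0 plus a flag.

For proteins, the P3-P1' tetramer is projected either from a P4-P4'
octamer record (characters 2-5) or from a protein position (residues
`p1prime_index - 3` to `p1prime_index`, 1-based, on the annotated mature
sequence); neo-N-terminal peptides locate their P1' by exact substring
match (first hit wins, multiple hits warn). Sites too close to the
N-terminus are flagged unprojectable and excluded from fractions. Isotopic
enrichment is averaged across replicate channels on the log2 scale, and a
site counts as enrichment-positive strictly above one sample (n-1)
standard deviation over the population mean. Each projectable site is then
`selectome`, `sub_threshold` (0 < RP <= threshold) or `absent` (RP = 0).

## What the simulator emulates — and what it cannot

`make_landscape()` assigns every tetramer a catalytic efficiency from an
additive position-weight model on the log scale plus log-normal noise;
`simulate_selection()` runs rounds of pseudo-first-order cleavage
($p = 1 - e^{-k\,E\,t}$, substrate far below $K_M$), binomial survival,
immunodepletion escape of uncleaved phage, and multinomial resampling to
sequencing depth. Each hexamer's rate is the best of its three candidate
tetramers (one dominant scissile site; a sum-of-rates mode exists behind a
flag) times a per-hexamer log-normal context factor emulating the
unpredictable P5-P4/P2'-P3' contribution.

Defaults are the study conditions, chosen once: 200 nM active enzyme, 2 h
per round, two rounds; naive library of 3x10^6 distinct hexamers sequenced
at 9x10^6 reads versus 10^6 reads for selections (preserving the roughly
ten-fold depth ratio of the profiled experiment); immunodepletion
efficiency 0.99; landscape scale 20 M^-1^s^-1^ with position-weight SD 1.6
and tetramer noise SD 0.5, placing a minority of tetramers above the
99%-cleavage anchor of 3,289 M^-1^s^-1^; context SD 0.6. At these settings
a simulated selection occupies ~75,000 of the 160,000 clusters with ~75% of
its hexamers inside the selectome, and the naive cluster entropy is within
2% of the uniform 17.288 bits — the qualitative regime of the real
experiment.

The deliberate scale reduction has consequences a user should know before
reading simulated numbers as if they were full-scale ones. With 3x10^6
distinct hexamers each cluster holds ~56 library contexts instead of up to
1,200, so cluster sizes — and therefore RP — are far noisier: the simulated
divergence (~1.7 bits), threshold (~2), and raw RP-vs-constant correlation
(~0.2-0.3, rising to ~0.9 after binning) sit below the values a full-scale
experiment produces, while the *shape* of the analysis (negative-then-
positive cumulative divergence, majority of hexamers above threshold,
recovery of the true landscape ranking) is preserved. Two idealized limits
are not reachable by any finite-sampling simulation: a truly flat enzyme
still yields a *defined* threshold, because the selection-mode partition is
systematically more concentrated than the naive multi-membership reference
and the plug-in divergence estimate of a null comparison is strictly
positive; and a single-peak enzyme recovers its hot tetramer at the top of
the selectome but accompanied by background clusters above the adaptive
threshold. The analytic statements hold exactly (identical distributions
have no RP > 1 cluster and no definable threshold) and are tested at that
level. Passing simulator-based tests therefore demonstrates correct
mechanics and faithful statistical structure, not full-scale effect sizes.
The simulator also ignores phage growth bias, codon-level (NNK/NNN)
composition bias and PCR duplication; only the final selection round is
sequenced.

## Problem sizes and other fixed choices

The test suite and the acceptance script run the generator at its default
scale once and reuse the result; auxiliary behavior tests use a 2x10^5
library, which keeps the whole suite in a few minutes of CPU. Parameter
recovery is summarized as the Spearman correlation between true log rates
and recovered RP over occupied clusters, averaged over three replicate
selections of the same library — single replicates fluctuate around
0.5-0.65 at this scale. Kinetic tables censor at 12,792 M^-1^s^-1^,
matching the saturation ceiling of phage-based rate measurements.

## Known limitations

* The constant flank sequences of the published library are not public;
  extraction is correct for any configured flanks but defaults are ours.
* Whether the original redundancy elimination recomputed abundances
  dynamically is unknown; the static choice here is deterministic and
  order-independent, and can differ on adversarial toy inputs.
* Full-scale reproduction of published values requires the published
  million-hexamer supplementary tables as input; the package reads such
  tables (`read_hexamer_tsv()`, `selectome_analysis()`) but does not ship
  them.
* Replicate-level p-values for enrichment calls are out of scope; only the
  z-statistic is reported.
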