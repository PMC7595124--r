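---
title: "Dissecting an allotetraploid genome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting an allotetraploid genome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subgenomics)
library(dplyr)
```

Many paleopolyploid plant genomes arose by hybridization of two diverged
diploid progenitors (allotetraploidy) followed by genome doubling. When the
progenitor lineages are extinct, the classical proof of hybrid origin --
showing that one chromosome set is closer to a known diploid -- is
unavailable. This package implements an alternative that needs only the
polyploid genome itself: transposable elements that were active in exactly
one progenitor before hybridization survive as *subgenome-specific repeats*,
and short k-mers drawn from them partition homeologous chromosomes into the
two ancestral subgenomes. Around that core the package builds the natural
companion analyses: ancestry segmentation along chromosomes (homeologous
exchange detection), molecular dating of the divergence/burst/hybridization
timeline, subgenome bias in gene retention and homeolog expression, and
chromosome painting of admixed accessions at arbitrary ploidy.

Every method here is exercised against synthetic data with planted ground
truth, generated by the package itself; this vignette explains the models,
the tunable parameters, and what the synthetic tests do and do not
demonstrate.

## The synthetic allotetraploid

`simulate_allotetraploid()` replays the assumed history explicitly:

1. a random ancestral genome (default 4 chromosomes x 500 kb, GC 0.44);
2. two progenitor lineages diverge for `divergence_time_my` (default 7.2 My)
   under Jukes-Cantor at `rate` (default 2.1e-8 substitutions/site/year);
3. each lineage receives a burst of a distinct LTR retrotransposon family
   (default 200 copies of a 1 kb element with 300 bp terminal repeats, age
   4 My -- inside the window in which the progenitors were separate);
4. a third, shared family (age 1.5 My, postdating hybridization) hits both
   chromosome sets;
5. the genomes merge into a tetraploid; optional reciprocal exchanges swap
   the distal tails of a homeolog pair.

Mutation uses the exact Jukes-Cantor marginal: each site substitutes with
probability $\tfrac{3}{4}(1 - e^{-\frac{4}{3} r t})$ to a uniformly chosen
other base, so observed p-distances match the closed form in expectation and
invert exactly through `jukes_cantor()`. Because substitution is applied
per-branch independently, the two terminal repeats of a planted LTR copy
diverge with expectation $2 r \cdot \text{age}$ -- the clock that
`ltr_insertion_age()` reads -- and composing two marginal steps equals one
step at twice the distance, so no hidden approximation error enters the
dating tests.

Scale choices: 8 x 500 kb chromosomes and 200-copy families keep a full
pipeline run under ~15 s on one core while leaving planted-family k-mers
about 50 occurrences per carrier chromosome, comfortably above the selection
threshold. Truth (subgenome labels, exchange intervals, a TE registry with
every copy's coordinates and age) is emitted alongside every dataset and can
be serialized with `write_truth()`. Coordinates are 0-based half-open
throughout. TE insertions do not nest by default (positions landing inside a
registered copy are re-drawn) so the k-mer ground truth stays clean; a copy
that straddles an exchange breakpoint stays registered to the chromosome
holding its start and is truncated by the swap -- a rare, documented edge.

## Diagnostic k-mers and subgenome phasing

Canonical 13-mers (lexicographic minimum of k-mer and reverse complement)
are counted per chromosome; `select_diagnostic_kmers()` retains those that

* occur at least `min_total` times genome-wide (the reference threshold of
  100 per 2 Gb assembly is scaled to the genome at hand, floored at 10), and
* are at least twofold enriched in one member of **every** homeolog pair,
  on length-normalized densities (counts per Mb) by default -- homeolog
  lengths differ -- with a pseudocount of 1 so zero counts stay finite while
  "at least twofold" keeps its meaning; ties at exactly the threshold are
  retained.

Chromosomes are then clustered on their diagnostic k-mer density profiles
(correlation distance, average linkage) and the top-level bipartition is the
subgenome partition; `consistency_filter()` removes k-mers whose per-pair
favored side conflicts with the partition. The "A" label is attached to the
cluster containing the lexicographically smallest chromosome name (or a
user-supplied anchor on real data) purely for reproducibility -- on
synthetic data orientation is arbitrary. Raw-count enrichment and the
clustering distance are exposed as options because the choice between raw
and normalized densities is genuinely open; normalized is the default for
the length-difference reason above.

A 13-mer has $4^{13} \approx 6.7 \times 10^7$ canonical forms, so in a
4 Mb synthetic genome a given 13-mer also lands in the *background* by
chance about once per 10 chromosomes. These coincidences matter twice: a
background k-mer overlapping a planted-copy interval is background, not a
family marker; and stray cross-subgenome hits put a floor on how clean the
windowed tracks can be (below).

## Homeologous exchange detection

`density_track()` counts A- and B-labeled k-mer occurrences in
non-overlapping windows (10 kb default at synthetic scale, 100 kb suggested
for Gb-scale genomes). The two-state HMM treats the number of A-specific
occurrences in a window as binomial in the window total: in state A an
occurrence is A-specific with probability `p_A`, in state B with `p_B`.
Conditioning on the total makes the model invariant to TE-density
fluctuations from window to window, at the documented cost of discarding
density information. Empty windows emit likelihood 1 in both states --
uninformative but coordinate-preserving. Emissions are estimated by pooling
windows of each subgenome's chromosomes, trimmed of their distal 25% so
exchanged tails cannot contaminate the estimate, with optional Baum-Welch
refinement (50 iterations, 1e-6 tolerance). The per-boundary switch
probability defaults to 1e-3; Viterbi ties resolve toward the previous
state, favoring fewer segments.

Decoded paths are smoothed: runs supported by fewer than `min_windows = 3`
*informative* windows are absorbed into the flanking run with the higher
posterior, weakest run first. Counting support in informative windows only,
and merging the least-supported run first, follow from the same principle as
the emission model: empty windows carry no evidence, and a one-occurrence
blip should never override a neighbor backed by hundreds of occurrences.
A segment's `mean_posterior` is likewise the occurrence-weighted mean of its
state posterior.

`call_exchanges()` reports segments that differ from their chromosome's bulk
assignment, annotates them distal/internal, flags a call reciprocal when the
homeolog partner carries a complementary segment with at least 50% mutual
overlap, and applies a call-confidence floor (`min_posterior = 0.9`): true
exchanged segments decode at weighted posterior ~1, while clusters of two or
three stray cross-subgenome coincidences sit well below it. Short internal
segments backed by larger stray clusters can still be reported at high
posterior -- under a density-blind emission model they are genuinely
indistinguishable from short low-density exchanged segments. They are left
annotated `distal = FALSE` and unclassified; on planted-truth sweeps the
distal reciprocal exchanges themselves are recovered with boundary error
within two windows and both partners flagged reciprocal.

## Molecular dating

The dating layer is deliberately closed-form: p-distance over comparable
(ungapped, unambiguous) columns; Jukes-Cantor correction
$d = -\tfrac{3}{4}\ln(1 - 4p/3)$ with a hard saturation error at
$p \ge 0.75$; LTR insertion age $d_{\mathrm{LTR}}/(2r)$; and rate
calibration from TE families shared with an outgroup lineage,
$r = \mathrm{median}_f\, d_f / (2 T_{\mathrm{split}})$ with a 10 My default
split. The rate is handled in substitutions/site/year everywhere -- the
only unit under which ages land in the My range.

Ks/Ka uses Nei-Gojobori (1986) pathway counting rather than maximum
likelihood because it is fully specifiable and oracle-checkable codon by
codon: synonymous site fractions per codon (changes to stop codons count as
nonsynonymous), differences averaged over equally weighted mutational
pathways with stop-passing pathways excluded (if every pathway passes
through a stop, all are counted with stop steps as nonsynonymous), and the
same Jukes-Cantor correction applied to $p_S$ and $p_N$. Note that a single
codon pair can saturate ($p_S \ge 0.75$) even for one synonymous change;
saturated values are reported missing, never extrapolated.

Event times come from the *mode* of a Ks distribution (Gaussian kernel,
Silverman bandwidth), not the mean -- Ks distributions are right-skewed by
saturation -- with all local maxima reported so bimodal inputs expose both
components, and a seeded bootstrap CI (200 resamples). At least 20 values
are required for a stable mode.

## Retention and expression bias

Gene retention treats each outgroup (pre-duplication) gene as one trial per
subgenome: retained if its co-ortholog list is non-empty. The 2x2
retained/lost table is tested with a two-sided exact test implemented by
full hypergeometric enumeration (sum of all same-margin tables whose point
probability does not exceed the observed, 1e-7 relative tolerance); the
orthology clustering itself is consumed from a table, never computed.

Expression bias works on cpm computed after summing replicate counts within
groups. Two Methods-style rules coexist and are implemented exactly: the
median B/A ratio is taken over pairs where **both** homeologs pass
`cpm > 0.5` (a one-sided silent member would make the ratio infinite), while
X-fold bias counts (X = 2, 5, 10) require only **one** member to pass, with
the silent member floored at a 0.5-cpm pseudocount. In exchanged regions the
ratio is oriented by *source* subgenome -- an exchanged pair's current
A-location gene descends from the B progenitor -- so
`exchanged_region_bias()` distinguishes "bias follows source" from "bias
follows location" by the sign of the stratum median difference (seeded
bootstrap CI).

The count generator plants a per-pair B/A ratio whose median is the target
(default 1.04), log-normal baselines (sdlog 1.2), negative-binomial noise
(dispersion 0.05), and 10% silenced gene-group cells -- scales a
practitioner would recognize from tissue-panel RNA-seq. At n = 5000 pairs
the median estimator has a sampling sd near 0.006, so recovery of the
planted median is assessed on the mean of a 10-seed sweep; single seeds
deviating by ~0.012 are expected order statistics, not estimator bias.

## Ancestry painting

`discover_markers()` keeps sites where every non-missing exemplar of one
species is homozygous for one allele and every non-missing exemplar of the
other species homozygous for the other (at least one informative exemplar
per species, at least two exemplars per species demanded up front), minus a
repeat mask. For an accession of ploidy m, `window_dosage()` scores each
window and dosage $g \in \{0..m\}$ by summing binomial log-likelihoods of
the species-1 read counts with success probability $g/m$ shifted by a
sequencing error rate ($\varepsilon = 0.01$ default); read-level modeling
(rather than hard genotype calls) is what makes ploidy 2, 3, and 4 uniform.
Smoothing uses the same Viterbi machinery over $m+1$ dosage states
(per-boundary switch 1e-3, uniform over alternatives); missing windows are
bridged by the flanking state. `genome_summary()` reports length-weighted
ancestry fractions, the modal dosage, and deviant segments -- candidate
introgressions or conversions, reported but not interpreted. The triploid
preset plants a genome-wide 2:1 dosage with 5% deviant 1:2 blocks aligned
to the window grid, emulating a high-yielding interspecific triploid; note
its expected species-1 fraction is $0.95 \cdot \tfrac{2}{3} + 0.05 \cdot
\tfrac{1}{3} = 0.65$, slightly below 2/3, exactly because of the planted
deviants.

## What the synthetic tests do not show

The generator's genomes are i.i.d. random sequence plus planted elements:
no satellite arrays, no nested or truncated TE copies (nesting exists only
behind a flag), no GC heterogeneity, no assembly gaps, and exchanges are
single clean crossovers. Passing recovery tests therefore demonstrates the
*estimators* are correct under the stated models at desk scale, not that
real 2-Gb assemblies -- with collapsed repeats, fused homeologs, and
recurrent exchange -- will yield the same accuracy. The fused-homeolog case
in particular is handled only by exclusion from the pairing map. Problem
sizes in the test-suite sweeps (500 kb chromosomes, 200-copy families,
n = 5000 expression pairs, 1000 markers/chromosome) were chosen as the
smallest scales at which the planted signals dominate sampling noise by a
comfortable margin.

## A worked run

```{r pipeline, eval = FALSE}
sim <- simulate_allotetraploid(
  seed = 1,
  exchanges = tibble::tibble(pair = 1, breakpoint_fraction = 0.2,
                             reciprocal = TRUE))
res <- assign_subgenomes(sim$genome, sim$homeolog_map)
tidy(res$partition)

params <- estimate_emissions(res$track, res$partition)
segments <- segment_ancestry(decode_ancestry(res$track, params))
call_exchanges(segments, res$partition, sim$homeolog_map)

dated <- date_ltr_copies(
  extract_ltr_pairs(sim$genome, sim$truth$te_registry, family = "famA"),
  rate = sim$rate)
median(dated$age_my)  # planted burst age: 4 My
```
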