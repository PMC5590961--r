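---
title: "Detecting ancient whole-genome duplications from Ks age distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ancient whole-genome duplications from Ks age distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A whole-genome duplication (WGD) duplicates every gene of a genome at the
same instant. Most duplicates are subsequently lost, but the survivors form
a cohort of paralog pairs that all diverged at the same time. Because
synonymous (silent) substitutions accumulate roughly clock-like, the
synonymous distance $K_S$ between two paralogs is a proxy for the age of
their duplication. Plotting the distribution of $K_S$ values across a
transcriptome's paralogs (its *paranome*) therefore reveals duplication
history: small-scale duplications (SSDs) arise continuously and produce a
quasi-exponential background, while a WGD leaves a discrete burst — a peak —
at the age of the event. This is the standard approach for detecting ancient
polyploidy in lineages such as gymnosperms, where slow substitution rates
keep even very old events visible as distinct peaks. With two species, the
$K_S$ distribution of their one-to-one orthologs dates the speciation on the
same axis, so peak ordering shows whether a WGD preceded or followed the
split — the test for a *shared* event.

`paranome` implements this entire analysis as a tested pipeline, together
with a codon-level simulator that plants WGDs of known age so every stage
can be validated against ground truth.

## Pipeline and model

1. **Similarity search** (`all_vs_all`): every ordered pair of translated
   CDS is aligned by exact affine-gap Smith–Waterman–Gotoh under BLOSUM62
   (gap open 11, extend 1 — a gap of length $L$ costs $11 + L$). Raw scores
   are converted to E-values by the Karlin–Altschul formula
   $E = K m n e^{-\lambda S}$ with the gapped BLOSUM62/11/1 constants
   $\lambda = 0.267$, $K = 0.041$, $m$ the query length and $n$ the summed
   database length. Hits are kept at $E \le 10^{-10}$. No heuristic seeding
   or edge-effect length corrections are applied: with full-length ORFs the
   graph topology is what matters, and the exact DP is fast enough.
2. **Gene families** (`mcl_cluster`): the similarity graph (edge weight
   $\min(200, -\log_{10} E)$, averaged over the two directions) is
   partitioned by Markov clustering with inflation 2.0, the customary
   default. Self-loops equal to each node's maximum incident weight (at
   least 1) regularize the flow; entries below $10^{-5}$ are pruned each
   iteration; iteration stops when the flow matrix changes by less than
   $10^{-8}$.
3. **Codon alignment** (`progressive_msa`, `backtranslate`): each family is
   aligned at the protein level — neighbor-joining guide tree on
   Poisson-corrected p-distances, profile–profile Needleman–Wunsch with
   mean-of-pairs column scores — and back-translated so each column is a
   codon. A single progressive pass (no iterative refinement) is used:
   $K_S$ estimation needs homologous columns, not optimal alignments, and
   families of full-length transcripts are gap-light.
4. **Pairwise $K_S$** (`estimate_ks_ng86`, `estimate_ks_ml`): the default
   estimator is Nei–Gojobori (1986) counting. Synonymous sites per codon
   are the fraction of possible single-nucleotide changes (to sense codons)
   that are synonymous; differences between codons are decomposed by
   averaging over all minimal mutational pathways, skipping pathways through
   stop codons. The Jukes–Cantor correction
   $K_S = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p_S)$ handles multiple hits;
   $p_S \ge 3/4$ is recorded as saturated ($K_S = \infty$) and excluded
   from densities. Gap columns are excluded per gene pair, not
   alignment-wide, maximizing usable sites. A pairwise maximum-likelihood
   alternative under a GY94 codon model with F3x4 frequencies is provided
   (`ks_method = "ML"`); it optimizes divergence, transition/transversion
   ratio and $\omega$ jointly and decomposes the fitted divergence into
   $dS$/$dN$ by the synonymous flux share of the fitted rate matrix with
   mutational-opportunity site proportions ($\omega$ set to 1). Counting is
   the default because it is exactly hand-verifiable and the downstream
   distribution analysis is estimator-agnostic.
5. **Redundancy correction** (`split_subfamilies`, `nj_tree`,
   `midpoint_root`, `weight_duplication_nodes`): a family of $n$ members
   yields $n(n-1)/2$ pairwise estimates but only $n-1$ duplication events,
   and large families would otherwise swamp the distribution. Families are
   split into subfamilies by single-linkage connected components over pairs
   with finite $K_S \le 5$ (beyond 5, synonymous distance is saturated and
   unreliable). For each subfamily a neighbor-joining tree is built from
   the pairwise $K_S$ matrix and midpoint-rooted; each internal node of the
   rooted tree is one duplication event, and its $m$ cross-clade pairwise
   estimates enter the distribution with weight $1/m$, so every event
   contributes unit mass and a fully resolved subfamily carries total mass
   $n-1$.
6. **Density and peaks** (`kde_density`, `detect_peaks`): the weighted
   multiset is rendered as a Gaussian KDE on $[0, 5]$ with boundary
   reflection (so the curve integrates to the retained weight). Entries
   with $K_S < 0.05$ are excluded — near-identical sequences mostly reflect
   thresholds for calling two genes distinct, not duplication events. Peaks
   are local maxima above 1.5 times the median density level over the
   curve's support, delimited by half-height bounds clipped at the nearest
   valley; each peak reports its mode, the weighted median of the entries
   in its interval, and their summed mass.
7. **Orthologs** (`reciprocal_best_hits`, `filter_ortholog_pairs`,
   `ortholog_ks_distribution`): cross-species reciprocal best hits by bit
   score (ties: E-value, then subject id), filtered to at least 30%
   identity over at least 150 aligned amino acids (identity counted over
   all alignment columns, gaps included). Orthologs date a single event,
   so each pair enters at weight 1 with the same exclusions as the
   paranome.

## The simulator

`simulate_paranome` and `simulate_species_pair` generate transcriptomes
with known duplication histories. Sequences evolve under a GY94-style
codon substitution process with uniform codon frequencies: single-nucleotide
codon changes occur at relative rate $\kappa$ (default 2) for transitions
and are damped by $\omega$ (default 0.2, purifying selection) when
nonsynonymous; stop codons are inaccessible. Branch durations are measured
directly in one-sided $K_S$ units: the rate matrix is scaled so that one
unit of time produces one expected synonymous substitution per synonymous
site, with sites counted in the NG86 sense — the same denominator the
estimator uses, which makes the estimator consistent by construction at low
divergence. Descendant codons are drawn from the exact transition kernel
$e^{Qt}$, so no trajectory simulation is needed.

Per base gene, a WGD duplicate is retained with probability
`wgd_retention` (default 0.6), the pair's divergence split evenly across
the two branches under the clock assumption; `Poisson(ssd_rate)` SSD copies
are added at pair ages drawn uniformly from `ssd_ks_range` (default
0.05–3). The default `ssd_rate` of 0.3 expected duplications per gene gives
a visible but non-dominant background, the regime in which peak detection
is actually exercised; SSD ages are uniform rather than birth–death because
only the background's flatness relative to the WGD spike matters here. In
the two-species scenario the WGD (and SSDs older than the speciation) occur
in the common ancestor, every lineage splits at `speciation_ks`, and
younger SSDs arise independently per species, with expected counts
partitioned by the fraction of the age range on either side of the
speciation so each lineage still sees `ssd_rate` expected events. The truth
table lists every within-family pair with its true path $K_S$ and the event
class (WGD, SSD, SPECIATION) of the pair's most recent common ancestor.

What the simulator deliberately does **not** emulate: indels and alignment
error, assembly artifacts and isoform redundancy, sequencing error, codon
usage bias, rate variation among sites or lineages, gene conversion, and
gene loss after SSD. Passing tests therefore show that the pipeline's
inference machinery is correct under a clean substitution process — not
that it is robust to assembly noise in real transcriptomes, which upstream
tools must handle.

## Numerical choices and degenerate inputs

* CDS records must be stop-free multiples of 3 over ACGT; terminal stop
  codons are stripped on input, internal stops or ambiguity codes reject
  the record (NG86 counting is undefined on ambiguous codons). The minimum
  input length of 9 nt applies before stop-trimming.
* Non-standard amino acids score $-4$ (the BLOSUM62 minimum) against
  everything, avoiding spurious positives.
* NG86 codon positions whose possible changes all lead to stops contribute
  reduced denominators rather than being dropped; codon pairs connected
  only through stop-containing pathways fall back to averaging over all
  pathways.
* For tree building, saturated or missing pairwise estimates inside a
  subfamily are capped at twice the $K_S$ ceiling (10) so NJ always sees a
  finite matrix; negative NJ branch lengths are clamped to zero. Cross-clade
  pairs above the ceiling keep their weight (node normalization stays
  exact) but are excluded from the density.
* Midpoint rooting is used because duplication-node identification needs a
  root, the method is the standard clock-friendly default, and the analysis
  already assumes clock-like synonymous rates. NJ on the $K_S$ matrix
  replaces likelihood tree inference: it is self-consistent with the
  estimates being weighted, has no external dependency, and topology errors
  only reshuffle weights among nodes — total mass is conserved by
  construction.
* Whether the subfamily criterion is single- or complete-linkage is an open
  choice; single linkage is used (components of the $K_S \le 5$ graph), so
  a chained subfamily can contain individual pairs above the ceiling —
  those never enter the density.
* KDE bandwidth defaults to Silverman's rule on the weighted sample using
  the effective sample size $(\sum w)^2 / \sum w^2$; it can be overridden
  in `pipeline_config`.
* MCL attractor overlaps are resolved by flow mass with lexicographic tie
  break, and families are ordered by smallest member id, making the whole
  pipeline deterministic for a fixed seed; all randomness flows from the
  single `rng_seed`.

## Known limitations

* NG86 counting is mildly biased upward at high divergence when
  transition bias and purifying selection act together (the simulator's
  defaults); at $K_S \approx 1.5$ the bias is of order 5–10%. The ML
  estimator reduces but does not remove this, and neither reproduces
  CODEML's exact optimizer output.
* The $1/m$ correction assumes the subfamily tree is approximately right;
  with very noisy $K_S$ matrices the weights can land on the wrong nodes,
  though per-event mass is always conserved.
* Peak calling is intentionally simple (threshold + half-height bounds);
  it reports candidate bursts, not statistical significance or mixture
  components.

## Problem sizes used in the test-suite

The packaged tests validate the pipeline at 300 base genes (roughly 570
transcripts at the default retention and SSD rate) for the planted-WGD
recovery and two-species scenarios, 60–80 base genes for structural
checks, 200 replicate pairs of 500 codons for estimator consistency, and
exhaustive enumeration (all $61 \times 61$ codon pairs; brute-force DP on
peptides up to 50 aa) for the oracle cross-checks. These sizes were chosen
as the smallest at which the distributional signatures under test are
unambiguous.
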