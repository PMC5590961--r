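# paranome

Detects ancient whole-genome duplications (WGDs) in transcriptomes from
**Ks age distributions of paralogs**, with the phylogeny-based redundancy
correction that makes such distributions interpretable, and reciprocal-
best-hit ortholog divergences for dating a speciation against the WGD
peaks of two lineages.

## The science

A WGD duplicates every gene at once. The surviving duplicate pairs all
share one age, measured as the synonymous distance *K*<sub>S</sub>
(substitutions per synonymous site, a clock-like proxy for time). The
distribution of *K*<sub>S</sub> over a transcriptome's paralogs therefore
shows a quasi-continuous background of small-scale duplications plus a
discrete peak for each WGD.

Raw pairwise estimates overweight large families: *n* members give
*n*(*n*−1)/2 pairs but only *n*−1 duplication events. The pipeline
corrects this by splitting families into subfamilies at *K*<sub>S</sub> ≤ 5,
building a tree per subfamily, and adding each internal (duplication)
node's *m* cross-clade estimates to the distribution with weight 1/*m* —
so every duplication event contributes exactly unit mass.

The full pipeline: all-against-all affine-gap Smith–Waterman (BLOSUM62,
gap 11/1) with Karlin–Altschul E-values at a 1e-10 cutoff → Markov
clustering (inflation 2.0) into gene families → protein-guided progressive
codon alignment → pairwise *K*<sub>S</sub> by Nei–Gojobori (1986) counting
with Jukes–Cantor correction (or GY94 maximum likelihood) → 1/*m*
node-weighted distribution → weighted kernel density with peak calls.
For two species, one-to-one orthologs (reciprocal best hits at ≥ 30%
identity over ≥ 150 aa) date the speciation on the same axis.

A codon-level simulator (`simulate_paranome`, `simulate_species_pair`)
generates transcriptomes with planted WGDs, SSD backgrounds and species
splits of known age, so the whole analysis is testable against ground
truth.

## Worked example

Simulate a transcriptome carrying a WGD at *K*<sub>S</sub> 0.8 with 60%
duplicate retention over an SSD background, then run the full analysis:

```r
library(paranome)
sim <- simulate_paranome(simulation_config(n_base_genes = 60, wgd_ks = 0.8,
                                           wgd_retention = 0.6, ssd_rate = 0.3,
                                           seed = 42))
rs <- run_full(pipeline_config(rng_seed = 42), sim$transcriptome,
               outdir = "demo_out")
print(rs)
#> Ks age-distribution analysis
#>   species_a: 115 genes, 60 families (41 multi-gene), 68 entries, total weight 52.0
#>     peak: mode Ks 0.832 (weighted median 0.844, mass 34.0)
```

Reading the output: 60 base genes became 115 transcripts through retained
WGD copies and SSDs; clustering recovered the 60 families; the corrected
distribution holds 68 weighted entries of total mass 52 (one unit per
inferred duplication event); and peak calling finds a single major burst
whose mode (0.832) and weighted median (0.844) recover the planted age of
0.8, with 34 units of event mass under the peak — the WGD cohort standing
above the SSD background. `demo_out/` contains the hit table, families,
pairwise *K*<sub>S</sub> table, weighted distribution, density curve, peak
calls and the overlaid distribution figure.

The same analysis is scriptable from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/paranome.R simulate --n-base-genes 60 --seed 42 --outdir sim_out
Rscript inst/cli/paranome.R ksd --cds sim_out/species_a.fasta --outdir ks_out
```

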