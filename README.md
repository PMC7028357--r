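# metatrait

Community-level genomic traits from metagenomes, for microbial ecologists
studying the oligotrophy–copiotrophy strategy continuum.

Several universal genomic traits govern the cost and rate of the
biochemical information processing that underpins growth: genome size, GC
content, the multiplicity of rRNA operons and tRNA genes, and codon usage
bias in highly expressed (ribosomal protein) genes. Under nutrient
enrichment, taxa adapted to fast growth (copiotrophs) — larger genomes,
more rRNA/tRNA genes, stronger codon bias, higher GC — should displace
streamlined oligotrophs, so these traits measured at the *community* level
from shotgun metagenomes should shift together. `metatrait` computes the
five traits per sample, runs the statistical battery for a fertilized
vs. unfertilized comparison, and collapses the trait set onto a single PCA
axis quantifying where each community sits on the continuum. A
synthetic-community generator with closed-form expectations makes the whole
pipeline testable without any sequencing data.

## The statistics at the core

**Codon usage bias.** For each ribosomal-protein coding sequence, the
effective number of codons

&nbsp;&nbsp;ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆,&nbsp;&nbsp;
F̂ = (n·Σᵢpᵢ² − 1)/(n − 1)

where F̂ is the synonymous-family homozygosity and F̄ₖ averages it over the
families of degeneracy class k (9 two-fold, Ile, 5 four-fold, and the three
six-fold families Leu/Ser/Arg). ENC runs from 20 (one codon used
exclusively per amino acid) to 61 (all synonymous codons equally likely).
ENC′ replaces F̂ with the χ²-corrected homozygosity
F̂꜀ = (X² + n − k)/(k(n − 1)), where X² measures deviation from the codon
frequencies expected under the metagenome's background nucleotide
composition — so compositional bias is not mistaken for selected codon
bias. Community bias is summarized as 1/mean(ENC).

**Mean genome size.** Genome equivalents GE = mean over universal
single-copy markers of (length-normalized hit count), scaled to coverage
units; mean genome size = bacterial predicted-protein count / GE, in genes
per genome equivalent.

**The other traits.** GC content of six-frame ORFs of the reads
(pooled, length-weighted); per-read occurrence rates and log₁₀ counts of
16S rRNA genes (one per rRNA operon) and tRNA genes, with
sequencing-depth-residual versions.

**The battery.** One-tailed Welch t-tests with directions fixed a priori,
treatment R² from a binary-factor linear model, exact conditional Poisson
rate tests (X₁ | X₁+X₂ ~ Binomial with exposure = samples × mean reads),
two-sided Bonett variance tests, KS tests on per-gene ENC/ENC′
distributions, and variance-change factors. The trophic axis is PC1 of the
z-scored five-trait matrix (genome size, GC, log tRNA, log rRNA, median
ENC′), oriented so higher scores mean copiotrophy.

## Worked example

Simulate a whole-ecosystem fertilization experiment (5 + 5 water samples,
of which 2 fertilized + 1 unfertilized fail the 20% depth-exclusion rule),
profile the samples, and compare:

```r
library(metatrait)
run <- run_experiment(seed = 7, depth_mean = 2e4)
print(run)
```

```
trait_profile: 7 retained samples (3 excluded: unfe5, fert4, fert5)
background composition: A 0.247 C 0.253 G 0.253 T 0.247
  sample_id    treatment total_reads genome_size gc_content trna_count ...
1     unfe1 unfertilized       14644    1893.992  0.4896871         20
...
Trait comparison: 3 fertilized vs 4 unfertilized samples
          trait    tail mean_unfert mean_fert pct_change     t   df      p_t    r2
    genome_size greater    1.99e+03  2.70e+03      35.30  7.70 4.86 0.000333 0.910
     gc_content greater    5.06e-01  5.62e-01      10.90  7.54 3.50 0.001400 0.894
      trna_rate greater    1.49e-03  2.62e-03      75.70  3.75 4.08 0.009670 0.746
      rrna_rate greater    1.97e-03  4.37e-03     122.00  5.87 4.96 0.001050 0.863
       mean_enc    less    5.63e+01  5.33e+01      -5.19 -3.05 3.41 0.023300 0.678
...
Kolmogorov-Smirnov tests on per-gene distributions:
  enc: D = 0.2526, p = 2.142e-06

Oligotrophy-copiotrophy axis (PC1 of 5 z-scored traits)
  variance captured: 87.3%
  treatment R^2 along the axis: 87.0% (p = 0.002169)
```

Reading the output: every trait moved in the direction predicted for
enrichment — genome size up, GC up, tRNA/rRNA occurrence rates up (+76%
and +122% here), mean ENC down (−5.2%, i.e. stronger codon usage bias) —
and a single principal component captures 87% of the trait covariance with
treatment explaining 87% of the variation along it. `report(run, "out/")`
writes the trait table, the statistics table, ENC′ histogram/ECDF point
sets, axis scores, and a PDF with the corresponding panels.

Real data enter through the same surface: a tab-separated manifest naming
per-sample FASTQ reads, ribosomal-protein CDS FASTA, marker-gene hit
tables, and detector counts (`profile_samples("dir/manifest.tsv")`).

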