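# spetkit

Targeted genotyping of crop germplasm collections with single primer
enrichment technology (SPET), end to end and at desk scale.

SPET interrogates thousands of SNPs by hybridizing a single ~40-base probe
immediately adjacent to each target variant and sequencing outward from the
probe 3′ end, so every assay genotypes the designed **target SNP** and also
discovers **accessory (non-target) SNPs** in the ~110 bp readout window.
`spetkit` is for researchers who curate genebank collections of largely
autogamous crops (tomato- and eggplant-like genepools) and their wild
relatives, and who need to design probe panels, validate them in silico,
and use the resulting genotypes for fingerprinting, duplicate/mislabel
detection and relationship analysis.

The package provides four connected components:

1. **Panel design** — from a candidate VCF, reference FASTA and GFF3:
   eligibility filtering (tomato-like mode: cohort-wise alternative allele
   count > 8 on anchored chromosomes; eggplant-like mode: count ≥ 4 and
   MAF > 0.25), feature classification (CDS / intron / UTR; intergenic
   candidates are excluded), greedy spacing enforcement (CDS–CDS pairs
   ≥ 5 kbp apart; any pair involving an intron/UTR SNP ≥ 15 kbp), probe
   placement on the forward strand with the target within the first 25 bp
   after the probe 3′ end, and pilot-coverage probe selection (mean depth
   46–90× with < 4 samples at ≤ 5 reads, or 79–130× with < 3 samples
   below 5×).
2. **SPET read simulator** — synthetic reference + gene models, a
   multi-species germplasm ladder (a selfing crop plus progressively
   diverged outcrossing wild relatives), negative-binomial probe coverage,
   and per-read hybridization success `(1 − λ)^m` for `m` probe-footprint
   mismatches, which makes probe dropout grow with divergence from the
   reference.
3. **Targeted genotyper** — alignment-free allele tallies per readout
   position, genotype calls (missing below 10 reads; homozygous at minor
   read fraction ≤ 0.04; heterozygous at 0.25–0.5; ambiguous fractions
   are conservatively missing), site discovery with target/non-target
   labeling, high-confidence filters (mean depth ≥ 30, vcftools-style
   max-missing 0.80/0.95, ≥ 1 non-reference allele) and the 80%
   genotyping-ratio re-call filter.
4. **Diversity and relationships** — polymorphic information content
   `PIC = 1 − Σ p_j²`, per-accession missing/heterozygosity/reference-
   identity, pairwise discordance with duplicate grouping (< 0.2%) and
   mislabel flagging, allele-sharing distances, neighbor-joining trees
   with site-resampling bootstrap supports, Robinson–Foulds distances
   (normalized by `2(n − 3)`), and genotype PCA with `√(p(1−p))` scaling.

Everything runs from a structured simulation, so the whole workflow is
testable without any external download.

## Worked example

```r
library(spetkit)

fx <- defaultFixture(seed = 1)          # reference + germplasm + panel
fx$report
#>        stage count
#> 1 candidates 14521
#> 2   eligible   409
#> 3     spaced    40
#> 4     probes    40
#> 5      final    40

reads <- simulateReads(fx$panel, fx$germplasm, seed = 2)
gm <- genotypeReads(reads, fx$panel, fx$genome, fx$config)
nrow(gm); sum(isTargetSite(gm))
#> [1] 384
#> [1] 39
```

Of the 14,521 simulated candidate SNPs, 409 pass tomato-like eligibility,
the 5/15 kbp spacing rules thin them to 40, and all 40 place valid probes.
Genotyping the 15-accession cohort against this panel yields 384
high-confidence SNPs, of which 39 are the designed targets and 345 are
accessory discoveries in the readout windows.

```r
st <- accessionStats(gm)
acc <- accessionTable(fx$germplasm)
st$species <- acc$species[match(st$accession, acc$accession)]
aggregate(cbind(missing_pct, het_pct, ref_identity_pct) ~ species, st, mean)
#>     species missing_pct het_pct ref_identity_pct
#> 1      crop       2.561    0.00             87.4
#> 2  wild_far      11.372    4.60             53.0
#> 3  wild_mid       0.868    4.46             76.7
#> 4 wild_near       3.733    2.53             89.8
```

The selfing crop shows zero heterozygosity while the outcrossing wild
species run 2.5–4.6%; missing data and loss of reference identity grow
with divergence (the most distant species loses nearly half its
reference-allele calls and misses 11% of genotypes through probe
dropout).

```r
ss <- siteStats(gm)
mean(ss$pic); mean(ss$pic[ss$target])
#> [1] 0.295
#> [1] 0.471
```

Target SNPs — ascertained in the crop and its nearest relative — carry a
higher mean PIC (0.471) than the full SNP set (0.295), the expected
ascertainment-bias signature.

```r
tree <- bootstrapSupport(gm, replicates = 100, seed = 3)  # NJ + supports
writeNewick(tree, "cohort.nwk")
pcaGenotypes(gm, k = 2)
#> SpetPCA: 15 accessions, 2 components returned
#>   variance fractions: 0.467, 0.256
```

A command-line front end covering the same steps is installed at
`inst/scripts/spetkit` (`simulate`, `design`, `genotype`, `stats`,
`tree`, `pca`, `treedist`).

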