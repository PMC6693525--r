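---
title: "The spetkit workflow: models, thresholds and design decisions"
author: "spetkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spetkit workflow: models, thresholds and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spetkit` implements a complete single primer enrichment technology
(SPET) workflow at desk scale: panel design, read simulation, targeted
genotyping, and germplasm diversity/relationship analysis. This vignette
is the package's account of the science: what each stage assumes, which
thresholds matter and why they default to the values they do, what the
simulator does and does not emulate, and where the design was genuinely
open and a choice had to be made.

## The assay being modeled

A SPET probe is a single ~40-base oligo complementary to the reference
sequence immediately adjacent to a target SNP. Sequencing extends from
the probe 3′ end through the variant, yielding (after trimming the probe
bases from a 150 b read) about 110 b of usable sequence. Because the
readout covers a window rather than a point, the assay genotypes the
designed target SNP *and* discovers accessory SNPs segregating in the
window — the target/non-target distinction that runs through the whole
package. Probes hybridize less efficiently against diverged templates, so
wild relatives of the crop the panel was designed on show progressively
more missing data; and because candidate SNPs are ascertained from
resequencing data of the crop itself, target SNPs over-represent
within-crop polymorphism. Both effects are first-class in the simulator
so that downstream analyses can be validated against them.

## Panel design

Candidate SNPs come from a VCF (only simple biallelic SNPs are kept;
`AC`/`AN` INFO fields or sample genotypes supply cohort allele counts).
Design then proceeds through five stages, each with its thresholds in
`spetConfig()`:

| stage | tomato-like | eggplant-like |
|---|---|---|
| eligibility | alt count > 8 (strict) | alt count ≥ 4 **and** MAF > 0.25 (strict) |
| location | anchored contigs, non-intergenic | same |
| spacing | CDS–CDS ≥ 5 kbp; pairs involving intron/UTR ≥ 15 kbp | same |
| probe window | target within 1–25 bp of the 3′ end (inclusive) | same |
| pilot coverage | mean 46–90× (inclusive); < 4 samples with ≤ 5 reads | mean 79–130× (inclusive); < 3 samples with < 5 reads |

Boundary inclusivity follows the plain-language reading of each rule:
"greater than 8" is strict, "at least 5 kbp" and "46× to 90×" are
inclusive, "five or less mapped reads" includes depth 5 while "below 5×"
does not. Each is an independent config slot, so any other reading is one
override away.

**Spacing selection order.** Which SNPs to keep when several violate a
spacing constraint is under-determined; the package's default is a greedy
left-to-right sweep within each contig (CDS prioritized at equal
positions), which is deterministic, auditable, and — as the test suite
verifies by brute force — always yields a valid set that is maximal with
respect to the processing order. `order = "random"` processes candidates
in a seed-determined random order instead, for panels meant to emulate a
randomised draw from the eligible set. A uniform random down-sample to a
target panel size (under the run seed) is available as the final stage.

**Probe side and placement.** A probe can sit on either side of its
target. The package always places it immediately adjacent (target offset
1 from the 3′ end), maximizing the downstream window, and chooses the
side by three ordered preferences: (1) a side whose full 110 bp readout
stays on-contig beats a truncated one; (2) otherwise the probe GC
fraction nearest 0.5 wins (a hybridization-practice proxy); (3) remaining
ties go to the readout-right side. Probes whose reference sequence
contains `N` are rejected as unsynthesizable. Probes, readout windows and
read sequences are all recorded on the forward reference strand —
orientation is an attribute, never a reverse-complement of stored
sequence — which removes a whole class of strand bookkeeping errors.

## The simulator

`generateReference()` draws uniform-random DNA and places non-overlapping
gene models (2–5 exons, UTRs at gene ends, introns between exons).
Uniform base composition is a simplification; none of the downstream
logic is composition-sensitive.

`simulateGermplasm()` builds each species from two layers:

* a **backbone** of `Poisson(divergence × L)` homozygous substitutions
  shared by all accessions of the species — `divergence` is the expected
  substitutions/site separating the species from the reference lineage;
* a **within-species pool** of `Poisson(3 × diversity × L)` segregating
  sites with allele frequencies drawn uniformly; each accession draws its
  two haplotypes per site as independent Bernoulli(frequency) trials. The
  factor 3 calibrates `diversity` to equal the expected per-site
  difference between two random haplotypes (uniform frequencies give
  `E[2f(1−f)] = 1/3` per pool site).

A frequency-spectrum pool, rather than private per-accession mutations,
is what lets within-species variants reach intermediate cohort
frequencies — without it no within-crop SNP could ever pass the
alt-count-> 8 eligibility bar in a small resequencing cohort, and target
SNPs could not discriminate crop accessions, contradicting the
ascertainment-bias behaviour the assay is known for.

**Selfing.** Each accession then undergoes `g` generations of selfing:
every heterozygous site fixes, with probability `1 − 2^−g`, to one of its
two alleles chosen uniformly. This reproduces the textbook halving of
heterozygosity per generation exactly; at the crop default `g = 20`
residual heterozygosity is `2^−20` of the outcrossed level, i.e. zero for
practical purposes.

**Biallelic consistency.** Mutations are infinite-sites in spirit: the
first alternative base drawn at any position is reused by all later
mutations there, so every site stays biallelic across the whole
germplasm set (multi-allelic handling in the genotyper is still exercised
by dedicated unit fixtures).

**The default ladder** (`defaultSpeciesLadder()`) is a four-species
genepool: a selfing crop (divergence 0.002, diversity 0.001, g = 20,
6 accessions) and three outcrossing wild relatives at divergence
0.006/0.015/0.030 with diversities 0.003–0.005 (3 accessions each).
Divergences bracket the few-percent sequence distance typical of a crop
and its crossable wild relatives; diversities make the crop markedly
poorer in within-species variation than the wilds, as expected for a
bottlenecked autogamous domesticate. These values are the package's
fixed study conditions, chosen once.

**Reads.** Per probe × accession the read count is negative-binomial
(mean 60×, dispersion 3 — overdispersed, as capture coverage is), each
read originates from a random haplotype, and hybridization succeeds per
read with probability `(1 − λ)^m`, `m` being the count of that
haplotype's mismatches across the 40 bp probe footprint. λ defaults to
0.3: a single-parameter model chosen to be the simplest mechanism that
yields the observed qualitative gradient (more divergence → more
zero-coverage probes → more missing genotypes). No quantitative
hybridization curve is claimed. Surviving reads copy the haplotype's
readout window with per-base error ε = 2×10⁻⁴. A `depthModel = "fixed"`
mode removes coverage randomness for truth-recovery checks.

What the simulator deliberately does **not** emulate: recombination and
linkage (each variant is placed independently), PCR duplicates,
quality-score structure, indels, paralogy/mapping artifacts, and
reference bias beyond probe-footprint mismatches. Passing tests therefore
demonstrate the internal correctness of design, calling and analysis
logic under a clean error model — not robustness to alignment artifacts
or structural variation in real data.

## The genotyper

Reads carry their probe of origin, so tallying is alignment-free: each
read contributes one count per covered reference position. Calls per
site × sample use total depth `d` and minor-base fraction `f` (second
largest base count over `d`):

* `d < 10` → missing;
* `f ≤ 0.04` → homozygous for the major base;
* `0.25 ≤ f ≤ 0.5` → heterozygous, provided the two top bases are the
  site's ref and alt alleles;
* anything else → missing.

The published re-call rules mix site-level MAF with genotype-level depth;
the package interprets the 0.04 MAF as the per-genotype homozygote
ceiling (minor fractions in (0.04, 0.25) are ambiguous — neither
confidently homozygous nor balanced enough for a het) and applies it
per cell. This is one coherent mechanism reproducing the intent: hom
calls confidently hom, het calls confidently balanced, everything
doubtful conservatively missing rather than forced. Sites where a third
allele intrudes keep their two most frequent alleles; carriers of the
third allele are set to missing and the event is logged.

Site discovery keeps every position where at least one sample carries a
non-reference base meeting the thresholds; sites coinciding with a panel
target position are flagged `target`, everything else is an accessory
discovery. Two site filters follow: high-confidence (mean depth across
all samples ≥ 30 — zero-depth samples included, vcftools semantics;
called fraction ≥ 0.80 tomato-like / 0.95 eggplant-like; at least one
non-reference allele) and the re-call genotyping ratio (≥ 80% callable
samples, inclusive at the boundary). Both filters are idempotent and
their reports are attached as metadata.

## Diversity and relationships

Per-site statistics use called genotypes only, so allele frequencies sum
to one; `PIC = 1 − Σ p_j²`. Per-accession statistics: missing % over all
sites; heterozygosity % and reference identity % over non-missing calls,
identity counting only hom-ref calls (a het is not identical to the
reference). The half-credit alternative for hets was considered and
rejected as the default because inbred reference controls — the yardstick
this metric exists for — have essentially no hets, and full-credit
scoring keeps "over 99.9% identity" interpretable; there is no published
formula for this metric, so the definition is a declared choice.

Duplicate detection flags pairs with discordance strictly below 0.002
(motivated by replicate-pair discordance below 0.2%) and groups them into
connected components. Mislabel flagging compares each accession's mean
discordance to its passport group against its nearest group, requiring
the nearest group to be different and closer by at least the margin
factor (default 0.5) — a deliberately conservative two-condition rule so
that borderline accessions are not flagged on noise.

**Trees.** Distances are allele-sharing (`1` identical, `0.5` het vs
hom, `0` opposite homozygotes, averaged over pairwise-complete sites).
Neighbor joining is implemented in the package with two stated policies:
ties in the Q-criterion break to the lowest node-index pair, and negative
branch-length estimates are clamped to zero with the deficit moved to the
sister branch so pairwise path lengths are preserved. Bootstrap supports
come from site resampling with replacement (default 100 replicates),
counting how often each internal bipartition of the full-data tree
recurs. Robinson–Foulds is the symmetric difference of non-trivial
bipartition sets, normalized by `2(n − 3)` for binary trees and by the
total internal-edge count in the presence of polytomies. The NJ and RF
implementations are validated in the test suite against independent
routes (brute-force bipartition enumeration via graph components,
additive-matrix recovery, and the `ape`/`phangorn` implementations as
cross-checks).

**PCA.** Genotypes are encoded as alt-dosage 0/1/2, missing cells imputed
with the site mean, sites centered and scaled by `√(p(1−p))` (the
binomial sampling variance at alt frequency `p`); the accession
covariance is eigendecomposed via SVD. Sites monomorphic after imputation
are dropped by a zero-variance guard (`sd > 10⁻¹²`). Loadings are
orthonormal to 10⁻⁹ and variance fractions over all components sum to 1.
Missing-data policy intentionally differs between distances
(pairwise-complete, like discordance) and PCA (mean imputation, the
field's standard) — stated here so the divergence is not silent.

## Numerical and reproducibility choices

* All randomness flows from one integer seed; internal stages derive
  per-stage streams (`seed × 1103 + stream × 12347 mod 2³¹`-ish) so that
  adding a stage never perturbs another stage's draws. Identical seeds
  give byte-identical TSV/BED/VCF/newick outputs, and the seed plus all
  thresholds are recorded in the `#`/`##` headers of those formats (FASTA
  and newick carry no portable comment syntax; their seed lives in the
  sibling files of the same write).
* Coordinates: VCF/GFF3/TSV are 1-based inclusive, BED 0-based
  half-open; probes and windows are stored 1-based inclusive internally.
* `pic()` rejects frequency vectors not summing to 1 within 10⁻⁹.
* Degenerate inputs: accessions with zero non-missing calls, pairs with
  zero co-called sites, singleton passport groups and all-one-group label
  sets all warn (or error, where no sensible value exists) rather than
  returning silent numbers.

## Problem sizes used by the test suite

The default fixture is two 400 kb contigs with 40 gene models each,
giving a ~40-probe panel and a 15-accession cohort — large enough that
every rule (spacing classes, dropout gradient, ascertainment contrast)
is exercised with hundreds of sites, small enough to iterate on. The
divergence-gradient check averages 20 independent germplasm/read
simulations; the spacing audit covers 200 random candidate sets of up to
1,000 SNPs; tree oracles cover 200 random tree pairs and 50 additive
matrices. These sizes are the package's own validation choices.

## Known limitations

* The hybridization parameter λ is a free modeling knob, not an inferred
  physical quantity; only the direction of its effect is validated.
* The genotyper assumes reads know their probe of origin — it replaces
  alignment, and alignment-specific failure modes (multi-mapping, soft
  clipping) are out of scope by design.
* Maximum-likelihood tree inference and ultrafast bootstrap are not
  implemented; NJ with standard site bootstrap is the package's
  self-contained, oracle-testable stand-in, and trees from the two
  approaches can differ on real data.
* Mislabel detection is discordance-based and needs ≥ 2 groups with ≥ 2
  members; it assigns no formal probability (no admixture/assignment
  model).
* The identity-with-reference metric is a declared definition (hom-ref
  fraction of non-missing calls), not a community standard.
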