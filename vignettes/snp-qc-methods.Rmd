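---
title: "Methods: SNP quality control and population-genetic analysis in snpsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP quality control and population-genetic analysis in snpsieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the data model

Reduced-representation sequencing (RADseq, GBS, DArTseq) genotypes many
individuals at a restriction-site-defined subset of the genome. After
variant calling — by whichever pipeline — the analysis-ready object is a
multi-sample set of biallelic SNPs. `snpsieve` represents this as a
`genotype_matrix`: loci × samples, each call stored as ALT-allele dose
(0/1/2, `NA` missing) with optional per-call REF/ALT read depths from
the VCF `AD` field. Loci are keyed by genomic position
(`contig:pos`), which is what makes callsets from different callers
comparable on a common reference: merging is by position, never by
caller-specific locus identifiers.

Ingestion (`read_vcf`) keeps only biallelic single-nucleotide records;
multi-allelic sites, indels and duplicate positions are excluded and
*counted* in an ingestion log rather than silently dropped or turned
into errors — these records are expected in raw caller output and their
number is itself a useful QC quantity. Half-calls (`0/.`) and
non-diploid calls become missing (conservative: they count against call
rate). Phase separators are accepted and phase discarded; none of the
downstream statistics are haplotype-aware. If `AD` is absent the matrix
is flagged depth-free and the two depth-based filters refuse to run
rather than guessing depths from `DP`.

## The filter suite

Each filter is a pure function `(matrix, threshold) → (matrix, report
entry)`; filters never modify calls, only locus membership, so any
chain's report entries add up exactly. Defaults are the package's
reference protocol for RRS data:

| filter | default | unit / boundary semantics |
|---|---|---|
| mean allelic depth | ≥ 2.5 | reads; each allele averaged over its carriers, inclusive |
| coverage difference | ≤ 80 | % of het-call mean depth, inclusive |
| reproducibility | > 0.85 | fraction of replicate pairs, **strict** |
| sex linkage | XY | rule-based, no threshold |
| observed heterozygosity | ≤ 0.70 | fraction of called genotypes, inclusive |
| call rate | ≥ 0.70 | fraction of samples, inclusive (0.30 for relaxed runs) |
| minor allele frequency | ≥ 0.01 | over called alleles, inclusive |
| thinning window | 77 | bp, single-linkage |

Notes on the less standard choices:

* **Coverage difference** is the symmetric percentage difference
  `100·|R−A| / ((R+A)/2)` where `R` and `A` are the mean REF and ALT
  depths over *heterozygous* calls only — allelic imbalance (a paralogy
  or reference-bias signal) is observable only where both alleles
  should be present. The statistic is bounded in [0, 200], which
  matches an "≤ 80%" cut-off scale. Over a fixed set of het calls the
  "mean of depths" and "sum of depths" readings are algebraically
  identical, so the only substantive alternative offered is
  `coverage_diff_mode = "all_sum"` (all called genotypes, hom depths
  included). Loci with zero het calls pass: no evidence is not
  failure.
* **Allelic-depth means** are taken per allele over calls carrying at
  least one copy of that allele. A locus where an allele has no
  carriers fails that allele's criterion — a "SNP" whose ALT allele is
  never seen in a genotype has no depth support at all.
* **Sex linkage**: at an X-linked locus typed as diploid, hemizygous
  males (XY) can never be truly heterozygous, so zero male hets
  combined with ≥ 1 female het flags the locus; ZW systems reverse the
  roles. Samples of unknown sex are excluded from both tallies, and
  both sexes must have at least one called genotype. This is a
  deliberately stringent rule: a single genotyping error in the
  heterogametic sex un-flags the locus, which is why it is applied
  after the depth and reproducibility filters in the default chain.
* **Reproducibility** is strict (`> 0.85`): a locus at exactly 0.85 is
  removed. Loci with *undefined* reproducibility (no replicate pair
  with both members called) are retained with a count in the report —
  again, absence of evidence is not failure.
* **Thinning** emulates "one SNP per sequencing locus" for callers that
  do not provide locus grouping: SNPs on a contig are chained by single
  linkage with a 77 bp window (a typical RRS read length — SNPs within
  one read length belong to one locus), and one SNP per cluster is
  kept uniformly at random under a fixed seed. Callers that already
  emit one SNP per locus simply see no clusters.

`run_filter_chain` applies the stages in a configurable order. The
default — depth, coverage difference, reproducibility, sex linkage,
then heterozygosity, call rate, MAF, thinning — puts per-call evidence
filters before population-level summaries, so that e.g. MAF is computed
on depth-credible genotypes. Stages whose prerequisites are missing
(depth-free matrix, no replicates, no sexed samples) are *skipped with
a zero-removal report entry* by default rather than erroring, because
real projects routinely lack replicates or sex data and the protocol
then simply omits those filters; `skip_unavailable = FALSE` restores
strict failure with the stage named.

## Replicate error rate

Technical replicates (same DNA, sequenced twice) estimate the
genotyping error rate. A pair-call is *comparable* when both members
are non-missing; identity is identity of genotype state (depths are
never compared). The dataset error rate is pooled (micro-averaged):
discordant / comparable over all loci, which satisfies the audit
identity `error = 1 − weighted mean locus reproducibility` with weights
equal to comparable pair-calls; a macro-averaged variant is available.
Because the reproducibility filter removes exactly the loci with the
highest discordance, the post-filter pooled rate can never exceed the
pre-filter rate — the suite asserts this on simulations.
Deduplication keeps, per replicate group, the member with the least
missing data (ties broken lexically, so deterministic), or an explicit
keep-list when the same physical sample must be retained across
several callsets.

## Diversity and concordance

H_O is the heterozygous fraction of called genotypes per locus; H_E is
uncorrected `2p(1−p)` from called allele frequencies (the small-sample
factor `2n/(2n−1)` is available behind `corrected = TRUE`, but the
uncorrected form is the common default in this field's toolchain and
the difference is < 1% at n ≥ 50). MLH is each individual's
heterozygous fraction over its called loci. Genotype ratios are
reported on the major/minor-allele axis (ties assign REF as major) so
that polarity differences between callers cannot distort the profile.

Cross-caller concordance merges loci by position. REF/ALT swaps between
callers are reconciled by flipping dose polarity (`g → 2 − g`);
irreconcilable allele pairs are excluded and logged. Discordance is
classified directionally as hom→hom (opposite homozygotes), hom→het
and het→hom. The percentage denominator is ambiguous in common usage,
so both are offered: comparable cells (both called; the default) and
all shared cells.

## PCoA and F_ST

PCoA codes individuals as dose vectors, imputes missing cells with the
locus mean (the conventional neutral choice: imputed individuals move
toward the centroid rather than toward either pole), computes squared
pairwise Euclidean distances, Gower double-centres, and
eigendecomposes. No allele-frequency scaling is applied — the distance
is the plain squared dose distance, not a PCA variant. For this
embedding negative eigenvalues arise only as numerical noise
(threshold `max|λ|·1e-9`); they are reported but carry no axes. Axis
orientation is arbitrary in theory, so it is fixed deterministically:
each axis is flipped so its largest-magnitude coordinate is positive.

F_ST is the Weir & Cockerham (1984) θ: per-locus variance components
a (among populations), b (among individuals within populations) and
c (within individuals), combined across loci as Σa / Σ(a+b+c)
(ratio-of-sums, the standard; mean-of-ratios is biased at low-MAF
loci). Per-locus sample sizes use called genotypes only; loci with
fewer than two called genotypes in any population of a pair are
skipped for that pair. Confidence intervals are percentile bootstrap
over loci (default 2000 replicates, seeded). The implementation is
checked against an independent scalar transcription of the same
estimator, and against closure: Balding–Nichols simulations at
F = 0.10 and 0.03 recover the target within ±0.03 with CI coverage
consistent with the nominal 95% (at 20 simulations the coverage count
is binomial, so 17/20–20/20 is the expected range).

## The synthetic generator: what it emulates, and what it does not

`simulate_dataset` draws ancestral ALT frequencies uniformly on
[0.05, 0.5], per-population frequencies from the Balding–Nichols
Beta(q(1−F)/F, (1−q)(1−F)/F), genotypes in Hardy–Weinberg proportions
within populations, total depths Poisson(13) (typical RRS mean
coverage) split Binomial(·, 0.5) between alleles in heterozygotes,
13.4% missing data, and technical replicates whose called genotypes
are flipped to a random different state with probability 0.06 —
magnitudes chosen to match a typical well-behaved RADseq dataset.
Planted locus classes exercise each filter: low call rate (0.4), a
single heterozygote (MAF = 1/2N < 0.01), 95% heterozygosity
(paralog-like), depth ~2x, skewed het depth split 0.77 (coverage
difference ≈ 108% while both allele means stay ≥ 2.5×, so the class
fails only the coverage filter), and X-like loci with hemizygous-male
genotypes and at least one female het.

Three structural choices keep the planted classes disjoint, which the
filter-exactness test depends on: singleton/guaranteed heterozygotes
in the low-MAF, low-call and imbalance classes are placed in the
heterogametic sex (a male het can never satisfy the sex-linkage rule);
those cells are exempted from random missingness; and replicate flips
at sex-linked loci in hemizygous individuals go homozygote →
homozygote (biologically, a hemizygote's miscall cannot be
heterozygous), so the flagging signal survives replication. The flip
count is recorded in the truth ledger, so the realised discordance
rate is exact, not nominal.

What the generator does **not** emulate: linkage disequilibrium (loci
are independent, 1 kb apart on one contig), read-level error processes
(allelic dropout, PCR duplicates — replicate discordance is a flat
state-flip), depth–missingness correlation, null alleles, and
demographic history beyond the single-F island model. A green
simulation test therefore establishes that the estimators and filters
compute what they claim on data satisfying their own assumptions — it
does not establish robustness to the ways real RRS data violate them.

## Numerical and degenerate-input conventions

* Zero-called loci: MAF and H_O are defined as 0 (retained by MAF only
  if the threshold is 0); H_E is `NA`; such loci fall to the call-rate
  filter.
* All-missing samples get `NA` MLH with a warning naming them.
* Empty matrices round-trip through VCF as header-only files.
* All stochastic operations (thinning, bootstrap, simulation) take
  explicit seeds, run under a saved-and-restored RNG state, and are
  byte-reproducible; nothing touches the caller's `.Random.seed`.
* VCF writing is a deterministic text emitter (fixed column set,
  `GT:AD`), guaranteeing byte-identical output for identical matrices
  — the round-trip identity `read(write(m)) = m` is asserted on random
  matrices.

## Known limitations

Only biallelic SNPs are supported end to end. Strand-flip
reconciliation across *different* reference genomes (A/T, C/G
ambiguity) is out of scope — concordance assumes one shared reference.
No HWE exact-test or LD-pruning filters are provided. F_ST inference
offers bootstrap CIs only; no permutation p-values. The sex-linkage
rule tolerates zero errors in the heterogametic sex and will miss
sex-linked loci with even one miscalled het; with few sexed samples or
rare alleles its false-positive rate grows (binomial chance of zero
hets among few males), which is why specificity is asserted at
n = 100, MAF 0.3 in the acceptance suite.
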