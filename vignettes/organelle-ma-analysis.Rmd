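---
title: "Estimating organelle mutation rates from MA-line sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating organelle mutation rates from MA-line sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organelleMA)
```

## The problem

Mutation-accumulation (MA) experiments propagate lines through
single-individual bottlenecks so that nearly all non-lethal mutations drift
to observability free of selection. Resequencing the lines after several
generations and counting de novo variants yields a direct estimate of the
germline mutation rate,

$$\mu = \frac{V}{G \cdot N},$$

where $V$ is the number of identified variants, $G$ the genome size in bp
available to variant calling, and $N$ the total number of generations summed
across lines. organelleMA implements this estimator for plant organelle
genomes, where three features make the analysis unusual:

* **Heteroplasmy.** Organelles are polyploid within a cell; a new mutation
  is carried by some fraction of genome copies, so SNVs are weighted by
  their measured allele frequency when summing $V$. Indel frequencies at
  homopolymers are too noisy to trust, so indel rates use unscaled counts.
* **numts.** The nuclear genome carries near-identical insertions of
  mitochondrial DNA. Reads from these nuclear copies match the
  mitochondrial reference, so even a fixed (homoplasmic) mitochondrial
  variant keeps "reference" support. Frequencies are corrected by
  subtracting the expected nuclear read count before recomputing.
* **Large repeats.** Organelle genomes carry large repeat pairs (the
  plastid inverted repeat and mitochondrial repeat pairs) that interconvert
  by recombination. One copy of each pair is masked, and $G$ is reduced by
  the masked length, so variants in these regions are counted once.

## The filter chain

Variant candidates come from per-site allele-count tables (one row per
sample and position with depth and counts of A/C/G/T/insertion/deletion
reads). Filters add flags instead of dropping rows, so the chain is
order-independent and auditable:

1. `low_freq` / `low_depth`: a candidate needs a raw frequency of at least
   20% and a depth of at least 50x (both boundaries inclusive). The high
   frequency cutoff deliberately sacrifices sensitivity to low-frequency
   heteroplasmies to avoid counting somatic variants and systematic
   sequencing error as germline mutations.
2. `background`: low-complexity regions (long homopolymers especially)
   inflate apparent variant frequencies in *every* sample. A call must be
   at least three-fold above the mean frequency of the same allele across
   all wild-type lines (absent alleles contribute zero; a zero WT mean
   passes automatically).
3. `repeat_copy` / `artefact`: interval masks for the excluded repeat
   copies and for known rearrangement/numt artefact zones.
4. `homology`: recombination between dispersed repeats relocates
   pre-existing sequence, and mapped against the reference such reads look
   like clustered de novo variants. The check rebuilds the
   variant-containing k-mer (30 bp of reference flank on each side with the
   alternate allele applied) and flags the call if that exact k-mer occurs
   anywhere else in the genome set, on either strand. This replaces an
   alignment-based search with a deterministic exact-match criterion, which
   is appropriate because a variant explainable by relocation of existing
   sequence matches exactly by construction.

After filtering, mitochondrial frequencies are numt-corrected
(`corrected = alt / max(depth - cov_nuc \cdot copies, alt)`, clamped into
[0, 1]; the correction is approximate and the raw value is retained),
homoplasmy is classified (plastid: frequency $\ge$ 0.98; mitochondrial:
corrected frequency strictly $>$ 0.90, the stricter rule reflecting the
approximate correction; indels: unclassified), and adjacent SNVs with
frequencies within 0.1 of each other merge into a single multinucleotide
variant. The 0.1 tolerance is our choice: co-occurring substitutions from a
single mutational event ride the same genome copies, so their frequencies
should agree up to binomial sampling noise at typical depths.

## Rates, bounds and folds

`mutation_rate()` applies $\mu = V/(G N)$. When a panel yields zero
variants, a point estimate is impossible but an upper bound is not: a
Poisson mutation count with mean $\mu G N$ produces zero with probability
$e^{-\mu G N}$, so setting this to $\alpha = 0.05$ gives
$\mu_{upper} = \ln(1/\alpha)/(G N)$ — the smallest rate that would have been
detected with 95% probability (`poisson_upper_bound()`). The companion
`single_variant_rate()` ($1/(G N)$) is the estimate a single homoplasmic
variant would have produced; the two differ by exactly $\ln 20 \approx 3$.
`fold_ratio()` compares a measured mutant rate against such a bound.

```{r}
mutation_rate(258, G = 357025, N = 150)   # mitochondrial indels
signif(poisson_upper_bound(357025, 2835), 1)
signif(fold_ratio(6.1e-7, poisson_upper_bound(357025, 2835)), 1)
```

## Spectrum, annotation and the synonymous permutation test

Substitutions are strand-collapsed into six classes (AT>GC, GC>AT, AT>CG,
GC>TA, AT>TA, GC>CG); AT>GC and GC>AT are the transitions. Spectrum rates
are frequency-weighted counts divided by the number of A/T or G/C base
pairs of the unmasked genome (matching the exclusion used for $G$) and by
$N$, so genomes of different composition are comparable. We divide by $N$
because the table reports rates, not counts.

Variants are assigned a location class by interval containment with the
priority CDS > rRNA > tRNA > intron > intergenic (the priority is our
tie-break for overlapping annotations), and CDS SNVs a
synonymous/nonsynonymous effect under the standard genetic code, which
plant organelles use.

The permutation test asks whether synonymous changes are enriched among
the observed CDS SNVs, as selection against nonsynonymous mutations would
produce. Each permutation keeps the number and class of variants fixed per
genome but redraws each variant's position uniformly (with replacement —
collisions are negligible at genome scale and the simplest reading of
"randomized positions") over the CDS sites whose reference base matches the
class source pair; the class substitution is applied and synonymous
outcomes counted. The one-tailed P-value is the plain proportion of
permutations with at least the observed synonymous count, with no +1
smoothing, matching the frequency definition of the test. Restricting
eligible sites to the matching source pair is an interpretation choice: the
alternative (unrestricted placement with re-evaluated classes) would change
the marginal class counts the test is meant to hold fixed.

## Homopolymer-centric indel analysis

Maximal single-base runs of 5 bp or more are catalogued (below 5 bp,
slippage rates fall into the background); runs fully inside masked repeat
copies are excluded so the catalogue matches the calling space. On circular
genomes a run spanning the origin is merged and reported once. Tandem
dinucleotide arrays need at least 3 units (6 bp) by default — two units are
indistinguishable from chance adjacency — and the threshold is exposed as a
parameter.

Each small indel (default ceiling 10 bp; the data are dominated by ±1 bp
events) is assigned to the homopolymer whose interval contains its
left-aligned anchor and whose base the indel sequence repeats, else to a
matching dinucleotide array (unit rotations count as the same array), else
`non-repetitive`. An indel longer than its run but composed of the run's
base still counts as an expansion; the boundary case of two adjacent runs
both matching cannot occur for maximal runs of different bases. Bias tables
then count insertions versus deletions per context, the analysis that
exposes deletion bias at A/T homopolymers and insertion bias at G/C
homopolymers.

## The simulator

`simulate_ma_experiment()` emulates the statistical structure the analysis
assumes, with known truth at every layer:

* **Genomes.** Two circular sequences with contrasting GC content (defaults
  50 kb at 45% GC and 30 kb at 35% GC) carrying planted homopolymers and
  dinucleotide arrays at recorded coordinates, one verbatim large-repeat
  pair per genome (second copy masked), a numt interval with copy number on
  the mitochondrial genome, and toy genes (CDS with introns, rRNA, tRNA).
  The background is generated with no run of 5 bp or more, so the
  homopolymer catalogue equals the planted truth exactly; random
  dinucleotide arrays do arise by chance, so truth assertions on them are
  one-sided. Default planted homopolymer counts give an AT:GC homopolymer
  ratio far higher in the "plastid" than the "mitochondrial" genome,
  mirroring the real contrast.
* **Lines.** 22 mutant lines (18 x 7 + 4 x 6 homozygous generations,
  N = 150) and 20 wild-type lines (8 generations) in three founder
  families. Per generation, new SNVs arrive as Poisson draws per spectrum
  class over the unmasked genome, and slippage indels per homopolymer locus
  at rate $q_0 (L - 4)$ per generation for run length $L$ — a linear
  ramp chosen as the simplest form that reproduces "longer runs are
  noisier and more mutable"; $q_0$ is configurable.
* **Heteroplasmy.** New mutations start at frequency 0.5 and drift by a
  per-generation beta perturbation with organelle-specific concentration
  (plastid 8, mitochondrial 40, so the plastid sorts faster), absorbing at
  0 and 1. This is an invented observation-level model — the study observes
  sorting but does not model it — and all parameters are exposed. A
  `fixation` mode transmits every mutation homoplasmic instead.
* **Reads.** Depth is Poisson; variant reads are binomial in the frequency;
  uniform per-base error spreads over the three non-reference bases;
  homopolymer anchors receive slippage indel reads with per-read
  probability $q_0(L-4)$ split between insertion and deletion; and
  mitochondrial positions inside the numt interval receive additional
  reference-matching reads at `nuclear_cov x copies`, the bleed-through the
  numt correction must undo.

All randomness derives from one root seed through named substreams, so
genomes, line histories and reads are independently reproducible.

## Calibration and what the tests show

The test suite validates the pipeline end to end on 100 simulated
replicates: the estimated SNV rate must fall inside the central 95% Poisson
interval of the planted expectation in at least 93, and wild-type lines
must yield zero passing calls in at least 99. These calibration runs use
`fixation` mode deliberately: under neutral drift the frequency-weighted
estimator targets $\mu \cdot E[f]$ rather than $\mu$, so fixed transmission
is the condition under which "recovering $\mu$" is well-defined — and it
matches the observation that most real plastid variants are at or near
homoplasmy. The replicates use scaled-down problem sizes (5 kb and 1.5 kb
genomes, 6 mutant and 4 wild-type lines, 4 generations, 80x depth, planted
rate 1.2e-4 per bp per generation so that the expected variant count is
about 13 per replicate); rate estimation is size-free, so the scale affects
only the width of the Poisson interval being hit.

Separate property tests check that numt bleed-through depresses raw
frequencies of planted homoplasmic mitochondrial variants to roughly the
organelle coverage share while the corrected frequencies recover 0.95 or
better; that the permutation P-value agrees with exhaustive enumeration on
a toy two-gene genome within Monte-Carlo error; and that the homopolymer
scanner is identical to a brute-force oracle on 1,000 random sequences.

What passing does **not** show: the simulator draws depth and error
independently per site, has no mapping ambiguity, GC-coverage bias,
strand bias or read-level artefacts, and its drift model is phenomenological.
Results on real data depend on upstream mapping quality and on
user-supplied masks; in particular, reproducing the published effective
sizes $G$ = 357,025 / 128,214 bp requires the real reference sequences and
the repeat-mask coordinates used there, which are inputs, not package data.

## Numerical and degenerate-input choices

* Frequencies are allele count / total depth (pileup-column semantics), not
  count / sum of counted alleles.
* The background three-fold rule is evaluated with a 1e-9 absolute
  tolerance so that a call at exactly three-fold passes despite floating
  point.
* numt correction clamps the corrected reference count at 0 and the
  frequency at 1; zero alternate reads give frequency 0.
* Indels are left-aligned with the repeat-locus start as anchor, making
  "same homopolymer, several lines" comparisons well-defined; assignment is
  invariant to the anchor's position within the locus, so right-shifted
  representations agree.
* A flank too close to a linear sequence end is truncated with a warning;
  circular genomes wrap instead.
* Degenerate rate inputs ($N \le 0$, $G \le 0$, $\alpha \notin (0,1)$,
  zero denominators) error rather than return infinities.

## Limitations

The package starts from allele-count tables: read trimming, mapping and
pileup counting are upstream concerns. Structural variants and
repeat-mediated recombination products are out of scope (they are masked,
not detected). Confidence intervals on $\mu$ beyond the Poisson
zero-observation bound are not provided. The synthetic reconstructions of
the per-variant supplementary tables (`synthetic_sd1_snvs()`,
`synthetic_sd2_indels()`) carry only published marginal counts and uniform
implied frequencies; they exercise the computation path but are not data.
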