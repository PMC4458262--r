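---
title: "Methods: duplicate-recessive GMS, from segregation to haplotype selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplicate-recessive GMS, from segregation to haplotype selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmshap)
```

## The genetic model and its assumptions

`gmshap` models genetic male sterility (GMS) under duplicate-recessive
epistasis: two nuclear loci, *ms5* on chromosome A12 and *ms6* on D12, and
a plant is male sterile if and only if it is homozygous recessive at
**both**. The model assumes

- **biallelic loci**, genotypes unordered (`Aa` ≡ `aA`), canonicalised on
  construction;
- **independent assortment between the loci** — they reside on different
  chromosomes, so two-locus gamete probabilities factor across loci.
  Linkage is modelled only *within* a chromosome, between a causal locus
  and its markers;
- **full penetrance by default** — the sterile genotype always expresses
  sterility. A `penetrance` parameter (probability the sterile genotype is
  scored sterile, default 1.0) exists only in the simulator, to study the
  robustness of downstream inference; the exact model itself is
  deterministic. A genetically fertile plant is never scored sterile;
- **sterile plants set no pollen**: they are legal seed parents in every
  crossing scheme but can never self or serve as pollen parents. The
  crossing functions enforce this as a contract.

Expected segregation ratios are computed by exhaustive gamete enumeration
in exact integer rational arithmetic (numerators over a denominator of 16)
and reduced to coprime parts, because the classical expectations are exact
small fractions — 1:0, 3:1, 15:1, 1:1 — and floating-point ratios would
obscure exactness. Sampling-based probabilities appear only in the
simulator.

## Segregation testing

`chisq_ratio_test()` is the Pearson chi-square against an expected
fertile:sterile ratio with 1 df and **no Yates continuity correction**.
This was a deliberate, verified decision: the bundled
`sibcross_family_counts()` — the published fertile/sterile counts from the
original characterization of this GMS material — reproduce their printed
probabilities (0.144, 0.564, 0.083, 0.05, 0.05, 0.441, 0.19, 0.283,
0.118) only under the uncorrected statistic. A ratio with a zero expected
class (e.g. 1:0) is not chi-square testable and errors with a pointer to
the exact binomial alternative.

`classify_segregation()` treats the candidate ratio set as *data*, not
code (default `{1:1, 3:1, 15:1}`, the set reachable in this model's
breeding schemes), retains candidates with p ≥ α (α = 0.05 by default),
and maps each retained ratio back to parental genotype classes by
enumeration over all selfs and sterile-testcrosses in the exact model.
Boundary cases — p within ±0.005 of α — are retained but flagged, never
silently kept or dropped: a family printing p = 0.05 should be looked at,
not adjudicated by the fourth decimal.

## What the simulator emulates — and what it does not

The simulator reproduces the study design that generated this kind of
data:

1. **Breeding scheme** (`simulate_breeding_scheme()`): inbred fertile
   parent × inbred sterile donor → F1 (double heterozygote) → selfed F2 →
   fertile×sterile **sibcross** families (expected 1:1, 3:1 or all-fertile
   depending on the fertile sib's genotype) → selfed sibcross-F2 families
   (3:1, 15:1 or all-fertile). Family sizes default to 200 (F2), 3 × 30
   (sibcross F1) and 14 × 80 (sibcross F2), matching the scale of the
   published families.
2. **Meiosis** (`simulate_gametes()`): per adjacent map interval, a
   crossover occurs with probability equal to the inverse **Haldane** map
   function of the cM gap; no crossover interference. Haldane is the
   default because two-point analysis assumes independent recombination
   events; Kosambi (partial interference) is available everywhere a map
   function is named. Units are centimorgans throughout.
3. **Diversity panel** (`simulate_diversity_panel()`): an unstructured
   random-mating population segregating for both loci at high frequency,
   defaulting to 1044 individuals with an expected 164 steriles — the
   composition of the published association panel. A founder gamete pool
   carries the recessive **carrier haplotype** (recessive causal allele
   plus its diagnostic marker alleles in phase) at a frequency calibrated
   in closed form: with fertile-only pollen parents, the expected sterile
   fraction is \(c^4/(1+c^2)\) (the fertility conditioning correlates a
   father's two loci, so the naive \(c^4\) underestimates), inverted
   analytically for the target. One round of random mating then
   recombines founder gametes into the panel.
4. **Genotyping noise** (`add_genotyping_noise()`): each call is
   independently replaced by a uniformly chosen *different* genotype with
   probability `error_rate` and set missing with probability
   `missing_rate`; the true matrix is retained for scoring.

Two panel-design choices deserve justification because the haplotype
scan's behaviour depends on them:

- **Marker placement.** The two diagnostic SNPs per locus sit at −0.2 and
  +0.3 cM from their causal gene in `default_marker_map()`. The published
  haplotypes span roughly 150 kb, a fraction of a centimorgan at typical
  cotton physical-to-genetic ratios, so sub-centimorgan placement is the
  realistic regime. The 19 remaining markers are decoys 4–44 cM away,
  plus one chromosome-specific anchor marker per chromosome for linkage
  assignment. All distances are configurable.
- **Background allele sharing.** On non-carrier founder haplotypes each
  diagnostic marker's recessive-linked allele appears singly at frequency
  0.15 (`background_single_freq`), but the full in-phase multi-marker
  haplotype is private to the carrier lineage. This encodes the premise
  that makes haplotype diagnostics necessary at all: individual SNP
  alleles recur across diverse germplasm, while the joint haplotype does
  not. It is also why the scan's selected rule converges on two markers
  per locus — single-marker rules admit false positives at rate ~0.15 per
  background haplotype, which the AND over two markers suppresses
  quadratically.

What the generator does **not** emulate: population structure and kinship
(the panel is unstructured by construction, so passing tests say nothing
about confounded panels), crossover interference, multi-allelic markers,
copy-number or deletion polymorphism, environment-dependent partial
sterility, and any sequence-level process (reads, primers, probe
chemistry). Results on real data with those features need the usual care.

**Seeding.** A single integer seed drives a *named sub-stream* per
generation stage (FNV-hash of the stage name mixed into the master seed),
so adding a new population to the scheme never perturbs the draws of
earlier ones, and the full pipeline is byte-for-byte reproducible — the
test suite asserts byte-identical artifacts across reruns.

## Two-point linkage

`estimate_rf_f2()` maximises the standard F2 intercross likelihood over
the 9 two-marker genotype classes by EM. Latent structure: (i) the double
heterozygote is a mixture of zero- and two-recombinant gamete
configurations — its expected recombinant count, \(2r^2/((1-r)^2+r^2)\),
is the same expression under either phase, since the two resolving gamete
pairs swap roles; (ii) with multiple families (the pooled sibcross-F2
design), each family's linkage **phase** (coupling/repulsion) is latent
with a 50/50 prior, and the pooled objective is the sum of per-family
mixture log-likelihoods. Numerical choices: initialisation r₀ = 0.25,
convergence |Δr| < 1e-8, cap 200 iterations; families in which either
marker is monomorphic carry no linkage information and are dropped;
missing calls are removed pairwise per marker pair. The estimate is
reported with a LOD score (log₁₀ likelihood ratio against r = 0.5) and a
Wald SE from the numerical observed information. Tests verify the EM
against an independent grid-search oracle (grid step 0.001) and check
near-nominal Wald coverage by simulation.

`assign_to_anchor()` assigns each marker to the chromosome of its
maximum-LOD anchor if LOD ≥ 3 — the community's conventional linkage
threshold, since no threshold is dictated by the design — with ties broken
by smaller r̂, then anchor name order.

## The two-step haplotype scan

Step 1 (`single_marker_scan()`) fits, per marker and per candidate
recessive-allele orientation, a logistic regression of sterility on the
**recessive-coded** indicator (1 = homozygous for the candidate allele),
reporting the better orientation. Recessive coding is the default because
the trait model is recessive; additive (dosage) coding is available behind
a flag. Truly diagnostic markers produce complete or quasi-complete
separation, where ordinary maximum likelihood diverges; a zero cell in the
indicator-by-phenotype table switches the fit to **Firth-penalised**
likelihood (Jeffreys-prior penalty, penalised-LR p-values), flagged in the
output. For the saturated single-binary-predictor case the Firth estimate
equals the add-half (Haldane–Anscombe) table estimate, which the tests
exploit as a closed-form check.

Step 2 (`cross_locus_scan()`) enumerates **every** rule with up to
`markers_per_locus` markers per locus (default 2, matching the published
four-SNP set) over the two disjoint candidate sets — all marker subsets ×
all allele orientations — and evaluates each rule's confusion table
against observed phenotypes, with per-rule exclusion (not imputation) of
individuals missing any rule call. Ranking is **accuracy first** (the
predictability headline of this analysis), then two-sided Fisher exact p,
then fewer markers, then lexicographic marker names; sterile is the
positive class, and the confusion table is printed in both orientations
because the field codes fertile = 1. The Fisher p is computed by direct
hypergeometric enumeration (with the customary (1+1e-7) tie tolerance),
implemented in-package because the scan evaluates ~10⁵ candidate tables;
tests verify exact agreement with brute-force tail summation and with
`stats::fisher.test`. Degenerate margins yield `NA` sensitivity or
specificity rather than 0. A combinatorial cap (`max_rules`, default
2×10⁵) turns runaway enumerations into an informative error.

No multiplicity correction is applied across the enumerated rules — the
selection procedure is reported as such, and the printout recommends
validating the selected rule on held-out material.

## Prediction and screening

`classify_individuals()` calls per-locus zygosity from the joint pattern
of a rule's markers: all homozygous-recessive, all heterozygous, all
homozygous-dominant, `"missing"` (any missing call), or `"inconsistent"`
when a locus's markers disagree. Inconsistency is surfaced, never
resolved — on real data it flags recombination between the haplotype's
markers or a genotyping error, both of which a breeder should see. The
phenotype is `"sterile"` only when both loci are homozygous recessive,
`"fertile"` when either locus shows a dominant-bearing pattern, and
`"undetermined"` otherwise; predictions carry the rule's hash so output
files trace to a ruleset. `screen_lines_for_alleles()` reports carriage
(hom or het) of each locus's recessive haplotype per line — the screen
used to trace which ancestral germplasm contributed each recessive
allele; historical inference from the pattern remains narrative, not
computed.

## Problem sizes used in the checks

The package's acceptance-level checks run at the scale of the study
design, chosen as the sizes at which the statistical claims are meaningful:
50,000-offspring crosses for distributional fidelity; 100,000 gametes for
map-function recovery; 50 replicates of n = 1000 F2 individuals at r ∈
{0.05, 0.1, 0.2} for linkage bias; and 50 independent 1044-line panels
(164 expected steriles, 0.5 % genotyping error) for the scan, on which the
median predictability of the selected rule is ~99.5 % and the selected
markers are the causal-flanking four in every replicate. The exact-test
oracle is verified exhaustively over all 2×2 tables with margins ≤ 30.

## Known limitations

- Only the two-locus duplicate-recessive architecture is modelled; other
  GMS genes, cytoplasmic male sterility and restorer genetics are out of
  scope.
- The F2 linkage likelihood assumes codominant biallelic markers;
  dominant-marker likelihoods are not implemented.
- Physical (bp) positions are carried as annotation only; no bp→cM
  conversion is attempted.
- The panel simulator's idealisations (private carrier haplotype, single
  random-mating round, uniform error) bound what a passing scan
  demonstrates: with heavy structure, relatedness, or locus-specific error
  the real-data predictability of a selected rule can be lower.
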