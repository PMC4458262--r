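# gmshap — two-locus recessive genetic male sterility: simulation, linkage and haplotype marker selection

Genetic male sterility (GMS) is the workhorse of hybrid cotton seed
production: sterile plants need no hand emasculation, so any pollen they set
comes from the chosen male parent. In *Gossypium hirsutum* the widely used
GMS source is governed by **duplicate-recessive epistasis** — a plant is
male sterile if and only if it is homozygous recessive at *both* the *ms5*
locus (chromosome A12) and the *ms6* locus (chromosome D12):

```
phenotype(g) = sterile  ⟺  g_ms5 = ms5/ms5  and  g_ms6 = ms6/ms6
```

Under this model a fertile × sterile sibcross segregates 1:1
(fertile:sterile) when one locus segregates, a selfed single-locus
heterozygote segregates 3:1, and a selfed double heterozygote segregates
15:1. Because field phenotyping of sterility is slow (repeated flower
inspection at anthesis), breeders instead genotype a small **haplotype SNP
set** — two SNPs in tight linkage with each causal locus — and predict
sterility as *homozygous for the recessive-linked allele at every marker of
both haplotypes*.

`gmshap` implements that entire analysis as a tested R package, for
breeders and quantitative geneticists working with two-locus recessive
traits:

- **Exact genetic model** — gamete enumeration over both loci (exact
  rational arithmetic): `cross_genotype_distribution()`,
  `expected_segregation()`, `phenotype_from_genotype()`.
- **Simulator** — meiosis with Haldane (or Kosambi) recombination, the
  breeding scheme (F1 → F2 → fertile×sterile sibcross → selfed families)
  and a random-mating diversity panel calibrated to a target sterile count,
  plus genotyping error/missingness: `simulate_breeding_scheme()`,
  `simulate_diversity_panel()`, `add_genotyping_noise()`.
- **Segregation testing** — uncorrected Pearson chi-square GOF against
  candidate ratios, with inversion back to parental genotype classes:
  `chisq_ratio_test()`, `classify_segregation()`, `segregation_report()`.
- **Two-point linkage** — EM maximum-likelihood recombination fractions
  for intercross data (phase resolved per family), LOD scores, map
  functions, and LOD-threshold chromosome assignment to anchor markers:
  `estimate_rf_f2()`, `map_distance()`, `assign_to_anchor()`.
- **Two-step association scan** — recessive-coded logistic regression per
  marker (Firth-penalised under separation), then an exhaustive cross-locus
  search over all marker subsets × allele orientations, ranked by
  predictability (overall accuracy) with Fisher-exact tie-breaking:
  `single_marker_scan()`, `cross_locus_scan()`, `evaluate_ruleset()`.
- **Marker-assisted selection** — apply a haplotype rule to new genotypes:
  per-individual sterility prediction with per-locus zygosity calls, and
  germplasm screening for carried recessive haplotypes:
  `classify_individuals()`, `screen_lines_for_alleles()`,
  `published_gms_rule()`.

File formats (genotype TSV / minimal VCF, phenotype CSV, marker-map TSV,
ruleset JSON) are handled by `read_genotypes()` and friends; a thin CLI
(`inst/cli/gms.R`) exposes `simulate`, `segtest`, `linkage`, `scan` and
`predict` subcommands.

## Worked example

Test a selfed family's 399 fertile : 35 sterile progeny against the 15:1
expectation:

```r
library(gmshap)
chisq_ratio_test(399, 35, c(15, 1))
#> Segregation GOF: 399 fertile : 35 sterile vs 15:1
#>   X-squared = 2.439, df = 1, p = 0.1184
```

The fit is accepted (p = 0.118): consistent with both loci segregating in a
selfed double heterozygote. Now simulate a 1044-line diversity panel with
~164 steriles, add 0.5 % genotyping error, and search all cross-locus
haplotype rules (23 candidate markers, up to 2 per locus — 67,600 rules):

```r
map   <- default_marker_map()
set.seed(2)
panel <- simulate_diversity_panel(map)                       # 1044 lines
calls <- add_genotyping_noise(genotype_calls(panel), map, error_rate = 0.005)
mk    <- setdiff(map_marker_names(map), names(default_anchors()))
chr   <- map$chromosome[match(mk, map$name)]
scan  <- cross_locus_scan(calls, panel$phenotype,
                          ms5_candidates = mk[chr == "A12"],
                          ms6_candidates = mk[chr == "D12"], map = map)
scan$best
#> Haplotype rule (sterile iff homozygous at every marker):
#>   ms5 { MOGH582973:TT + MOGH583971:TT } & ms6 { MOGH211275:CC + MOGH493571:GG }
#>   hash: 970d6449
scan$best_confusion
#> Haplotype-rule confusion (sterile = positive class):
#>          predicted
#> observed  sterile fertile
#>   sterile     149       2
#>   fertile       0     893
#> accuracy 0.9981  sensitivity 0.9868  specificity 1
#> Fisher exact p = 4.67e-181;  1044 used, 0 excluded (missing calls)
```

The scan recovers the four diagnostic SNPs flanking the two causal loci
and predicts the phenotype of 99.8 % of the panel; the two errors are
genotyping-error/recombinant individuals, exactly the failure mode the
two-marker-per-locus haplotype is designed to minimise. The selected rule
can then be applied to new material with
`classify_individuals(new_calls, scan$best)`, which also reports per-locus
zygosity (so heterozygous maintainer plants can be distinguished from
homozygous-dominant ones) and flags marker disagreement as
`"inconsistent"` rather than guessing.

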