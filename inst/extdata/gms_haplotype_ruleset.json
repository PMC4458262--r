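{
  "description": "Validated four-SNP haplotype set calling the ms5ms5 (A12) and ms6ms6 (D12) recessive genotypes; an individual is predicted male sterile iff homozygous for the recessive-associated allele at all four markers.",
  "ms5": [
    {"marker": "MOGH583971", "recessive_allele": "T"},
    {"marker": "MOGH582973", "recessive_allele": "T"}
  ],
  "ms6": [
    {"marker": "MOGH211275", "recessive_allele": "C"},
    {"marker": "MOGH493571", "recessive_allele": "G"}
  ]
}
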