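# Extended heritability grid (robustness check at higher h2).
assumption: pleiotropy
architectures:
  - additive2
  - additive5
  - additive10
  - single
  - epistatic
  - heterogeneous
  - compensatory
h2_pheno: [0.10, 0.20, 0.40, 0.60, 0.80]
h2_apa: [0.10, 0.20, 0.40, 0.60, 0.80]
trait_type: quantitative
prevalence: 0.5
ld_mode: random
n_samples: 670
n_genes: 100
n_snps: 20
seed: 1
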