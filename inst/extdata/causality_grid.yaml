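# Causality study grid: 7 architectures x 5 phenotype x 5 APA
# heritabilities = 175 scenario cells.
assumption: causality
architectures:
  - additive2
  - additive5
  - additive10
  - single
  - epistatic
  - heterogeneous
  - compensatory
h2_pheno: [0.05, 0.10, 0.15, 0.20, 0.25]
h2_apa: [0.05, 0.10, 0.15, 0.20, 0.25]
trait_type: quantitative
prevalence: 0.5
ld_mode: random
n_samples: 670
n_genes: 100
n_snps: 20
seed: 1
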