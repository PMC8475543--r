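assays:
- assay_id: SNP A
  marker_class: taqman_snp
  chromosome: 1/Z
  position: 14104488
  c_allele: A
  r_allele: G
  product_length: 62
  primers:
    forward: GCAAGTGCAATTTTCCCATCTGATG
    reverse: CAAGCCGTTCGCGGTTAG
  probes:
    fam: AGACCAAAAGGACTCAT
    vic: CTAGACCAAAAAGACTCAT
  linkage: Z
  thresholds:
    het_max_delta: 2.0
    homo_min_delta: 3.0
    max_valid_cq: 30.0
    max_cycles: 40.0
- assay_id: SNP B
  marker_class: taqman_snp
  chromosome: 1/Z
  position: 4933322
  c_allele: G
  r_allele: C
  product_length: 113
  primers:
    forward: GGGAACTCATATACTAAAATCGGAAAAACCT
    reverse: ACACTCGCATTATTTGTGTGCAATT
  probes:
    fam: CCGCAGTAGCGTATGT
    vic: TCCGCAGTACCGTATGT
  linkage: Z
  thresholds:
    het_max_delta: 2.0
    homo_min_delta: 3.0
    max_valid_cq: 30.0
    max_cycles: 40.0
- assay_id: SNP C
  marker_class: taqman_snp
  chromosome: 1/Z
  position: 4683787
  c_allele: C
  r_allele: T
  product_length: 57
  primers:
    forward: TGACAGCATTGATGTGCTGGAT
    reverse: CGCCGGAGCGTTACAGA
  probes:
    fam: CGCTACCAAAGCCAG
    vic: CGCTACCAGAGCCAG
  linkage: Z
  thresholds:
    het_max_delta: 2.0
    homo_min_delta: 3.0
    max_valid_cq: 30.0
    max_cycles: 40.0
- assay_id: SNP D
  marker_class: taqman_snp
  chromosome: '16'
  position: 14134047
  c_allele: C
  r_allele: G
  product_length: 70
  primers:
    forward: TGAGTGCCAACAGCTATCTTCTG
    reverse: GCAGTCCATTACAGCTGGTGAA
  probes:
    fam: AGCTCATGTCCTACTCC
    vic: AGCTCATGTCGTACTCC
  linkage: autosomal
  thresholds:
    het_max_delta: 2.0
    homo_min_delta: 3.0
    max_valid_cq: 30.0
    max_cycles: 40.0
- assay_id: COI
  marker_class: rflp_coi
  chromosome: mtDNA
  position: ~
  c_allele: ~
  r_allele: ~
  product_length: 568
  primers:
    forward: GAGCTGAATTAGGRACTCCAGG
    reverse: ATCACCTCCWCCTGCAGGATC
  probes: ~
  linkage: mitochondrial
  thresholds:
    het_max_delta: 2.0
    homo_min_delta: 3.0
    max_valid_cq: 30.0
    max_cycles: 40.0
- assay_id: Tpi
  marker_class: rflp_tpi
  chromosome: 1/Z
  position: ~
  c_allele: ~
  r_allele: ~
  product_length: 600
  primers:
    forward: GGTTGCCCATGCTCTTGAGTCCGGACTGAAGG
    reverse: AGTCACTGACCCACCATACTG
  probes: ~
  linkage: Z
  thresholds:
    het_max_delta: 2.0
    homo_min_delta: 3.0
    max_valid_cq: 30.0
    max_cycles: 40.0
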