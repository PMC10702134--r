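# The ten published discordant embryos: first-pass Gap-PCR call, first-pass
# haplotype result, chromosome-16 CNV review, call rate, and the
# retest/rebiopsy outcomes, together with the published final genotype and
# cause for cross-checking. Call rates other than case 8's printed 0.88 were
# not published; a representative passing value (0.96) is used (synthetic).
# For cases whose first-pass haplotype was confounded by the chromosome-16
# trisomy (three haplotypes present), the effective genotype is encoded as
# UNDETERMINED with the printed wording kept as the annotation. The paternal
# (non-origin parent) haplotype at the locus carried the risk allele in every
# trisomy case, as implied by the published three-allele final genotypes.
cases:
  - id: "1"
    pcr: NORMAL
    haplotype: {genotype: CARRIER, annotation: "maternal heterozygous",
                paternal: NONRISK, maternal: RISK}
    chr16_cnv: {copy_number: 2}
    call_rate: 0.96
    retest: CARRIER
    published: {final: "--/αα", cause: ADO_MUTANT_ALLELE}
  - id: "2"
    pcr: CARRIER
    haplotype: {genotype: AFFECTED, annotation: "abnormal homozygous",
                paternal: RISK, maternal: NOCALL}
    chr16_cnv: {copy_number: 3, origin: mother, stage: MI}
    call_rate: 0.96
    published: {final: "--/--/αα", cause: TRISOMY16_BPH}
  - id: "3"
    pcr: CARRIER
    haplotype: {genotype: UNDETERMINED, annotation: "heterozygous",
                paternal: RISK, maternal: NOCALL}
    chr16_cnv: {copy_number: 3, origin: mother, stage: MI}
    call_rate: 0.96
    published: {final: "--/--/αα", cause: TRISOMY16_BPH}
  - id: "4"
    pcr: CARRIER
    haplotype: {genotype: AFFECTED, annotation: "abnormal homozygous",
                paternal: RISK, maternal: NOCALL}
    chr16_cnv: {copy_number: 3, origin: mother, stage: MI}
    call_rate: 0.96
    published: {final: "--/--/αα", cause: TRISOMY16_BPH}
  - id: "5"
    pcr: CARRIER
    haplotype: {genotype: AFFECTED, annotation: "abnormal homozygous",
                paternal: RISK, maternal: NOCALL}
    chr16_cnv: {copy_number: 3, origin: mother, stage: MI}
    call_rate: 0.96
    published: {final: "--/--/αα", cause: TRISOMY16_BPH}
  - id: "6"
    pcr: AFFECTED
    haplotype: {genotype: CARRIER, annotation: "maternal heterozygous",
                paternal: NONRISK, maternal: RISK}
    chr16_cnv: {copy_number: 2}
    call_rate: 0.96
    retest: CARRIER
    published: {final: "--/αα", cause: ADO_NORMAL_ALLELE}
  - id: "7"
    pcr: CARRIER
    haplotype: {genotype: UNDETERMINED, annotation: "heterozygous",
                paternal: RISK, maternal: NOCALL}
    chr16_cnv: {copy_number: 3, origin: mother, stage: MI}
    call_rate: 0.96
    published: {final: "--/--/αα", cause: TRISOMY16_BPH}
  - id: "8"
    pcr: AFFECTED
    haplotype: {genotype: CARRIER, annotation: "maternal heterozygous",
                paternal: NONRISK, maternal: RISK}
    chr16_cnv: {copy_number: 2}
    call_rate: 0.88
    retest: AFFECTED
    rebiopsy: {pcr: AFFECTED, call_rate: 0.95, haplotype: AFFECTED}
    published: {final: "--/--", cause: POOR_WGA_QUALITY}
  - id: "9"
    pcr: CARRIER
    haplotype: {genotype: NORMAL, annotation: "normal homozygous",
                paternal: RISK, maternal: NOCALL}
    chr16_cnv: {copy_number: 3, origin: mother, stage: MI}
    call_rate: 0.96
    published: {final: "--/--/αα", cause: TRISOMY16_BPH}
  - id: "10"
    pcr: NORMAL
    haplotype: {genotype: CARRIER, annotation: "heterozygous",
                paternal: NONRISK, maternal: RISK}
    chr16_cnv: {copy_number: 1, lost: mother, retained: father,
                retained_risk: false}
    call_rate: 0.96
    published: {final: "αα", cause: MONOSOMY16}
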