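---
title: "Methods: PGT for SEA-type alpha-thalassemia in alphapgt"
author: "alphapgt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PGT for SEA-type alpha-thalassemia in alphapgt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphapgt)
```

# Scope

`alphapgt` models a combined preimplantation genetic testing workflow for
couples in which both partners carry the Southeast-Asian (SEA) deletion of
the alpha-globin gene cluster on chromosome 16p13.3. Each parent carries
one normal chromosome (two functional alpha-globin genes, written αα) and
one chromosome with the ~20 kb SEA deletion (written --). Embryos from
such a couple are, by Mendelian segregation, expected in a 1:2:1 ratio of
affected (--/--, Hb Bart's hydrops fetalis), carrier (--/αα), and
unaffected (αα/αα).

The package implements three analytical layers over whole-genome-amplified
(WGA) single-blastomere or trophectoderm DNA:

1. **Direct mutation testing** — fluorescent gap-PCR producing two
   diagnostic amplicons: a ~178 bp product spanning the deletion
   breakpoint (present only when a -- chromosome is present) and a
   ~280 bp product internal to the deleted region (present only when an
   αα chromosome is present).
2. **Linkage analysis** — SNP haplotypes flanking the locus, phased
   against a reference embryo of known genotype (or, failing that,
   directly from the carrier parents), used as an independent genotype
   call robust to allele dropout (ADO) in the PCR.
3. **Chromosome screening** — B-allele-frequency (BAF) and
   log-R-ratio (LRR) style copy-number calls per chromosome, with
   parental origin and meiotic stage assignment for trisomies.

A decision engine reconciles the three layers per embryo, explains
discordances (aneuploidy, ADO, poor WGA quality), and ranks euploid,
non-affected embryos for transfer. A paired simulator generates synthetic
families with full ground truth, which is how the package validates its
own calling stack.

# Genomic model

## Locus and flanks

The deleted segment is fixed at GRCh37 chr16:222,846–227,521 inside the
package's coordinate model (`family_config()`), with 2 Mb of flanking
sequence considered on each side for linkage SNPs. Because the locus sits
near the p-terminus, the upstream (telomeric, 5′) flank is clipped at
position 1 — `partition_region()` returns the three analysis windows
(upstream 5′, in-gene, downstream 3′) after clipping. This asymmetry is
deliberate: it reproduces the real situation in which far fewer
informative SNPs are available telomeric of the alpha-globin cluster than
centromeric of it.

## SNP panel

`default_panel()` places SNPs in two tiers:

* a genome-wide backbone, by default 2,000 evenly spaced SNPs per
  autosome, used for copy-number, origin, and stage calls; and
* a dense targeted tier around the locus: 42 upstream-5′, 10 in-gene,
  and 355 downstream-3′ SNPs.

The 42/10/355 flank layout is a package choice made to echo the observed
imbalance between the short telomeric flank and the long centromeric
flank at this locus; the in-gene SNPs matter because parents are
hemizygous there (they carry only the retained chromosome's allele),
which the carrier-pair phasing fallback exploits (see below).

## Parents, meiosis, and embryos

`simulate_parents()` draws two phased parental genomes. Each parent has a
designated risk haplotype carrying the deletion. `simulate_meiosis()`
transmits one recombined haplotype per parent per embryo using a
distance-based crossover model (`default_recomb_map()`, roughly 1 cM/Mb).
Aneuploidy events (`aneuploidy_spec()`) inject whole-chromosome gains or
losses:

* **Trisomy, MI origin** — the two transmitted homologues from the
  error parent derive from *both* parental haplotypes near the
  centromere (BPH, "both parental homologues"), converging to identical
  (SPH) beyond the first crossover.
* **Trisomy, MII origin** — the two copies are identical (SPH) near the
  centromere and may diverge distally after crossover.
* **Monosomy** — one parent's contribution is absent entirely.

The embryo array is rendered from the surviving copies: genotype calls,
BAF (drawn around the band implied by the allelic ratio: 0, 1/3, 1/2,
2/3, 1), and LRR (around log2(copies/2)). Chromosomes carrying the
deletion contribute no allele at in-gene SNPs.

## Noise model

`noise_model()` controls measurement corruption, applied independently
per SNP per sample:

| parameter | default | meaning |
|---|---|---|
| `ado_rate` | 0.05 | heterozygous array call collapses to one allele |
| `miscall_rate` | 0.002 | call replaced by a random wrong genotype |
| `nocall_rate` | 0.02 | call replaced by NC |
| `baf_sd` | 0.03 | Gaussian jitter on BAF around its band |
| `lrr_sd` | 0.15 | Gaussian jitter on LRR |
| `pcr_ado_rate` | 0.01 | a gap-PCR allele's peak drops out |

Defaults were chosen to sit in the range typical of single-cell
multiple-displacement-amplification data — ADO a few percent, miscalls an
order of magnitude rarer — while keeping the workflow's quality-control
failure modes (call rate below 0.90, PCR dropout) reachable in
moderate-sized simulations. `no_noise()` zeroes everything and is the
basis for oracle testing.

What the generator does **not** emulate: segmental (sub-chromosomal)
imbalances, mosaicism within a biopsy, preferential-amplification
(allelic skew short of dropout), linkage-disequilibrium structure among
panel SNPs (alleles are drawn independently at a configurable MAF), and
sex chromosomes (the screen covers autosomes).

# Calling methods

## Gap-PCR

`call_pcr_genotype()` reads a peak table (size, height, optional dye)
and matches peaks to the two diagnostic products within a size tolerance
and above a height floor. Both products seen → CARRIER; deletion product
only → AFFECTED; normal product only → NORMAL; neither → FAIL. The call
carries its peak evidence as an attribute, and `compare_pcr_runs()`
classifies a re-test against the first run (confirmation, dropout of the
mutant or normal allele, or uninformative).

Under PCR dropout at rate ε per allele, a true carrier is miscalled
homozygous when exactly one of its two products drops: probability
2ε(1−ε) ≈ 2ε for small ε. This analytic relationship is one of the
package's self-checks.

## Informative SNPs and phasing

A SNP is informative for a given parent when that parent is heterozygous
(AB) and the other parent is homozygous — then the heterozygous parent's
transmitted allele can be read off the embryo by subtracting the
homozygous parent's obligate contribution (`transmitted_allele`,
Mendelian subtraction).

`phase_from_reference()` anchors the phase with an embryo whose genotype
is already known from an unambiguous PCR result: an AFFECTED embryo
received both risk haplotypes, a NORMAL embryo both non-risk haplotypes.
Each informative SNP where the reference yields a transmitted allele
labels that allele risk (or non-risk, inverted for a NORMAL reference).
References are screened for adequate call rate and Mendelian consistency
(tolerance 10% of checkable SNPs — set above the ~2.5–3% apparent
conflict rate that 5% ADO alone produces, so that ordinary noise does not
veto a usable reference). `analyze_family()` tries AFFECTED references
first, then NORMAL, falling through ranked candidates until one phases
cleanly.

## Carrier-pair fallback

When no homozygous-genotype reference exists (e.g., all embryos are
carriers), `phase_from_carrier_pair()` phases from two carrier embryos.
Flanking SNPs alone leave a two-fold ambiguity — the true assignment and
its full flip explain the data equally well — so the package breaks the
symmetry with deletion-origin evidence from the in-gene SNPs: each parent
is hemizygous there (typed as homozygous for the retained allele), and a
carrier embryo's in-gene calls reveal which parent contributed its
retained (αα) chromosome, hence which parent contributed the deletion.
In-gene SNPs where the parents' retained alleles differ vote on the
origin (`deletion_origin`, ≥2 votes at ≥80% majority); the resolved
origin for each embryo then pins the haplotype assignment uniquely.
Without parental in-gene data the function honestly reports the
ambiguity as a no-call rather than guessing.

## Embryo haplotype calls

`call_embryo_haplotype()` scores each informative SNP's transmitted
allele against the phased risk/non-risk labels and segments the flank
into blocks. A uniform block is RISK or NONRISK; a single clean switch
is RECOMBINANT, annotated with the breakpoint interval and — decisive for
diagnosis — which side of the locus the risk segment lies on. A switch
straddling the locus itself, or conflicting blocks, yields UNDETERMINED
with a low-confidence flag; fewer than `min_informative` usable SNPs
yields NOCALL. `haplotype_genotype()` combines the paternal and maternal
calls into a diagnostic genotype.

## Copy number, origin, and stage

`call_chromosome_cnv()` classifies each chromosome from median LRR
(gain above +0.3, loss below −0.5, against theoretical +0.585 and −1.0)
corroborated by BAF band structure: a trisomy shows 1/3 and 2/3 bands
where a disomy shows a 1/2 band. `trisomy_parental_origin()` scores SNPs
where the parents are opposite homozygotes — an embryo BAF near 1/3 or
2/3 indicates which parent contributed two copies.

`meiotic_stage()` distinguishes MI from MII using the BPH/SPH signature.
Because BPH extends only from the centromere to the first crossover, the
classifier restricts itself to the `max_stage_snps = 10` usable SNPs
*nearest the centromere* (a chromosome-wide nearest-N selection, not a
fixed fraction of the arm, so it adapts to panel density) and votes:
≥70% BPH → MI, ≤30% → MII, with at least 3 votes required, otherwise
"unknown". `monosomy_retained_parent()` identifies which parent's
chromosome survives from obligate-transmission SNPs, and
`format_iscn_like()` renders results as e.g. `arr(16)×3 mat`. Note the
convention: for trisomies the suffix names the *extra*-copy parent; for
monosomies it names the *lost* homolog's parent.

## Trisomy-16 disease genotypes

For a chromosome-16 trisomy the alpha-globin genotype must count risk
haplotypes among three copies. The error parent's contribution is
constrained by stage: an MI trisomy contributes exactly one risk
haplotype (both homologues present), an MII trisomy zero or two
(duplicated single homologue); the other parent contributes 0 or 1. The
engine enumerates the feasible risk counts, intersects them with what the
gap-PCR pattern allows (CARRIER ⇒ 1 or 2 of 3; NORMAL ⇒ 0; AFFECTED ⇒
3), and reports the genotype only if a unique count survives —
otherwise NA. An unknown stage enumerates the full 0–2 range before
intersection.

# Discordance resolution

`resolve_discordance()` orders explanations by mechanistic specificity:

1. chr16 copy number 3 → `TRISOMY16_BPH` (trisomy genotype logic above);
2. chr16 copy number 1 → `MONOSOMY16` (genotype of the retained
   haplotype);
3. call rate below the QC threshold (0.90) → re-biopsy request →
   `POOR_WGA_QUALITY`;
4. a failed first-pass PCR with a clean re-test that matches the
   haplotype genotype → `POOR_WGA_QUALITY` (the re-test is the result);
5. a clean re-test that flips the PCR to agree with the haplotype →
   `ADO_MUTANT_ALLELE` or `ADO_NORMAL_ALLELE` by direction;
6. otherwise `UNRESOLVED`, which is never transferable.

Aneuploidy outranks ADO deliberately: a trisomic embryo can *also* show
a PCR/haplotype mismatch, and the copy-number explanation subsumes it.
`transfer_priority()` then excludes affected, aneuploid, unresolved, and
screen-failed embryos and ranks the rest (unaffected before carrier,
higher call rate first), flagging any residual elevated misdiagnosis
risk.

`cohort_summary()` aggregates per-embryo reports into the headline
cohort rates. Printed percentages use a fixed-point convention: two
decimals below 2%, one decimal otherwise — so 2 of 172 prints as 1.16
while 162 of 172 prints as 94.2.

# Numerical and reproducibility choices

* All stochastic entry points take an integer `seed`; internal
  substreams are derived as `(seed × 48271 + 7919·i) mod 2147483629`, a
  Lehmer-style mix that keeps every derived seed strictly below 2³¹
  (valid for `set.seed()`) and decorrelates embryos within a family.
* Thresholds (`cnv_options()`, `qc_threshold`, phasing tolerances) are
  exposed as arguments with documented defaults rather than hard-coded,
  and the defaults are set from the theory (LRR gain cut at roughly half
  the theoretical +0.585; loss cut at half of −1.0) rather than tuned to
  any particular simulation.
* Statistical self-checks in the test suite use explicit sampling-error
  budgets (binomial standard deviations at the stated n), not ad-hoc
  tolerances.

# Problem sizes

The package's own validation workloads, chosen to finish in seconds to a
few minutes on a laptop while leaving no statistical ambiguity:

* oracle (zero-noise) equivalence: 100 embryos covering every event
  type on a reduced 120-SNP-per-chromosome backbone;
* default-noise end-to-end recovery: 25 families × 20 embryos
  (500 embryos) with a 10% aneuploidy rate;
* segregation ratio: 2,000 embryos on a minimal panel;
* PCR dropout calibration: 10,000 independent amplifications.

# Worked example

```{r example}
cfg <- family_config()
panel <- default_panel(cfg, backbone_per_chrom = 200)
fam <- simulate_family(cfg, panel, n_embryos = 10,
                       aneuploidy_rate = 0.1, seed = 42)
prov <- simulation_providers(fam, noise_model(), seed = 43)
res <- analyze_family(fam$father_array, fam$mother_array,
                      lapply(fam$embryos, `[[`, "array"),
                      do.call(rbind, lapply(fam$embryos, `[[`, "peaks")),
                      cfg,
                      retest_provider = prov$retest,
                      rebiopsy_provider = prov$rebiopsy)
res$summary
res$transfer
```

# Limitations

The simulator and callers are a desk-scale model of the workflow, not a
clinical device. Beyond the generator gaps listed above: breakpoint
coordinates and product sizes are fixed to the SEA allele (other
alpha-globin deletions — e.g. Thai, Filipino — would need their own
configuration); phasing assumes exactly one risk haplotype per parent;
the copy-number caller is whole-chromosome only; and the decision
engine's categories mirror a specific clinical reporting style rather
than an exhaustive taxonomy of WGA artefacts.
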