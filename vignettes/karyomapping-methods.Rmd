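---
title: "Karyomapping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyomapping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(karyomapr)
```

This vignette is the package's own account of the science it implements:
the phasing model and its assumptions, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
choices made where the method's published description left the design
open. Every empirical statement here is one the test suite or the
acceptance script computes itself.

## The problem

Preimplantation genetic diagnosis of single-gene defects works on one or
a few cells biopsied from an IVF embryo. Whole-genome amplification
(typically multiple displacement amplification, MDA) of so little input
is noisy in a characteristic way: at a heterozygous locus one allele may
simply fail to amplify — *allele dropout* (ADO) — making the locus look
homozygous. A diagnostic method for this setting must treat "allele
absent" as weak evidence and "allele present" as strong evidence.

Karyomapping turns a genome-wide SNP array into a generic linkage test.
Genotype the father, the mother, a relative of known disease status (the
*reference*), and the embryo samples; then:

1. **Informative loci**: one parent heterozygous (AB), the other
   homozygous. The heterozygous parent's allele that the homozygous
   parent lacks (the *unique allele*) sits on exactly one of the four
   parental chromosomes.
2. **Reference linkage**: if a sibling reference carries the unique
   allele, the chromosome it inherited from the informative parent (H1)
   carries it; if not, the other chromosome (H2) does. A grandparent or
   other relative on one parental side phases that parent only, and only
   at loci where the reference is homozygous — heterozygous reference
   calls are ambiguous across two generations. This homozygosity
   restriction removes about half of that parent's informative loci,
   which the test suite checks against its binomial expectation at
   allele frequency 0.5.
3. **Key / non-key evidence**: an embryo call *containing* the unique
   allele supports the linked haplotype and cannot have been fabricated
   by dropout (key). A called homozygote *lacking* it supports the other
   haplotype, but dropout of the unique allele produces the same signal
   (non-key). The ADO-immunity of key calls is not a hope but a theorem
   over a finite space; the suite proves it by exhaustive enumeration of
   all parental/embryo genotype and dropout combinations.
4. **Haploblocks, crossovers, diagnosis**: a two-state hidden Markov
   model per (embryo, parent, chromosome) turns the evidence sequence
   into haploblocks; block boundaries are crossovers; the haplotype at
   the disease locus, combined with which haplotypes carry the mutation
   (implied by the reference's disease status), yields the call.

An embryo homozygous for the unique allele is biologically anomalous at
an informative locus (the other parent's obligate allele is missing),
but the unique allele's *presence* is still dropout-proof: we grade it
key, flag it anomalous, and the aneuploidy screen consumes the flag's
genome-wide pattern. Whether the original software kept or discarded
such calls is not derivable from its published description; keeping them
is the choice consistent with the key definition.

## The hidden Markov model

States are the two haplotypes {H1, H2} of one parent. Only loci with
usable evidence enter; no-calls are skipped rather than imputed.

**Emissions.** With per-allele dropout `p_ado` and key error `e_key`:

| observation | from carrier state | from other state |
|---|---|---|
| key (unique allele seen) | `(1 - p_ado)(1 - e_key)` | `e_key` |
| non-key (allele absent) | `p_ado (1 - e_key) + e_key` | `1 - e_key` |

Each column sums to one, so this is a proper generative model over the
two observable evidence outcomes — the reading we committed to where the
informal description ("key calls are wrong with probability e_key")
conflicts with renormalization. The dynamic-programming decoder is
checked against brute-force enumeration over all `2^L` paths on random
instances, scored by an independently written oracle.

**Transitions.** Haldane map under a uniform rate:
`theta = (1 - exp(-2 d)) / 2`, `d = distance_bp * cM_per_Mb * 1e-8`
Morgans. A genetic-map-aware rate can be emulated by adjusting
`cM_per_Mb`; a per-interval map file is a possible extension, not
currently implemented.

**Decoding.** Most-probable path (Viterbi) defines blocks — it yields
clean segmentations and is directly checkable against exhaustive
enumeration. Posteriors from forward–backward are exported for
confidence display. Ties break toward the previous state, so a tie never
invents a transition. Whether the original implementation used path or
posterior decoding is unknowable from its description; equivalences are
tested against this package's stated model only.

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `e_key` | 0.005 | probability | residual array genotyping error; single-cell karyomaps show "few genotyping errors excluding ADO" |
| `p_ado` | estimated per sample; fallback 0.15 | per-allele probability | measured at obligate-heterozygous loci (opposite-homozygous parents force AB); autosomes only, since a male embryo's X is hemizygous and would saturate the estimator; clamped at 0.9 before entering emissions so likelihoods stay finite |
| `cM_per_Mb` | 1.0 | cM/Mb | the crude uniform rate that reproduces the published double-recombination arithmetic (415 kb → 1.72e-5) |
| `min_block_keys` | 2 | key calls | a haploblock must be supported by two dropout-proof calls; single-SNP blocks are merged away (two isolated key SNPs are treated as presumed miscalls, not a block) |

The per-sample ADO estimator is the homozygous fraction of *called*
obligate-heterozygous loci. Under the per-allele model it converges to
`2a/(1+a)`, not to the per-allele `a` — at `a = 0.15` this equals the
per-locus heterozygote dropout rate `1-(1-a)^2` to within 0.017. The
acceptance suite asserts recovery of the estimator's own estimand; the
distinction matters only if you compare the number to a per-allele rate.

### Crossover intervals

Two intervals are reported per crossover. `left_bp`/`right_bp` spans the
adjacent evidence loci of the flanking blocks — the tightest statement
the decoded path makes. `key_left_bp`/`key_right_bp` is the
*miscall-robust* interval, running to the second supporting key call
inward of each flanking block: non-key calls are ADO-corruptible and
cannot pin a crossover, and a single key call can itself be an isolated
miscall, so two consecutive keys are required to anchor a boundary (the
same two-key logic as `min_block_keys`). The crossover-recovery
acceptance test (99% of simulated crossovers inside the reported
interval, at most 1% spurious events, 500 meioses) is evaluated on the
key-bounded interval; the evidence-adjacent interval excludes the true
position whenever an ADO artifact sits next to the switch, which at 15%
ADO happens too often for any decoder to meet a 99% containment claim.

## Disease-locus phasing and calling

Evidence is counted in the gene and its two flanks (`flank_bp`, default
2 Mb — wide enough to contain tens of informative SNPs at array density,
narrow enough that a double recombination between flanking markers and
the mutation stays at the 1e-5 scale). Assignment requires ≥2 supporting
key calls, or 1 key plus 3 non-key, within the window — numeric
thresholds declared here, since the published account reasons
qualitatively from figures. Conflicting key calls are tolerated only
while they look like isolated miscalls: any run of more than 2
consecutive conflicting keys (a contiguous stretch would be a double
recombination, not noise) or conflicts outnumbering supporters makes the
locus undetermined. A flat cap on conflict counts was rejected: in a
4-Mb window with ~100 key calls, miscalls alone cross any small fixed
cap in a fraction of a percent of embryos, which a 156-embryo validation
series actually exposes.

Crossovers inside a flank truncate the usable window to the segment
between the crossover and the gene. A crossover whose uncertainty
interval *overlaps the gene itself* yields `no_result`: the crossover
position is roughly uniform over its interval, so assigning the nearer
block would misphase the mutation in a material fraction of such cases,
and a wrong transfer decision is the one error this method must never
make. This is deliberately stricter than voiding only crossovers
strictly contained in the gene.

Mode logic derives a mutant-haplotype map from the reference's status
(affected child: H1 mutant on both sides; carrier sibling: H1 on the
configured carried side, H2 on the other; known non-carrier: H2/H2),
then combines per mode. Grandparent references give exclusion-style
`high_risk`/`low_risk` labels — the at-risk parent's own status is never
asserted. Carrier-reference recessive cases require the carried side to
be configured explicitly; the tool refuses to guess. X-linked modes are
maternal by construction: a heterozygous father call on X contradicts
hemizygosity and is excluded, so paternal-informative X loci cannot
exist. Unknown embryo sex is inferred as male when under 2% of called
informative X loci are heterozygous; X-linked calls with sex still
unknown return `no_result`.

## QC and aneuploidy

Samples below 60% genome-wide call rate are excluded (`no_result`); the
rate is not re-normalized for suspected aneuploidy, and the caveat rides
along in the report. Monosomy of a parental chromosome is called when
both haplotypes' key fractions collapse (< `k_mono` = 0.02) *and* that
parent's allele looks dropped at > `d_mono` = 0.9 of called
obligate-heterozygous loci, each on ≥30 loci. Meiotic trisomy is called
when a 30-key window cannot be explained by two crossovers plus isolated
miscalls — the best two-changepoint fit must leave ≥ 25% of the window's
keys mismatched. The two-changepoint form is essential: a single
changepoint false-fires exactly where an embryo crossover lands near a
common (reference) crossover. Identical-by-descent parental regions are
maximal runs of ≥100 dual-called SNPs over ≥5 Mb with zero
opposite-homozygote pairs; at unrelated-parent allele frequencies the
per-locus opposite-homozygote rate (`2 p^2 q^2` ≈ 0.04–0.09) makes such
runs effectively impossible, which the suite checks by construction.
Diagnoses whose locus falls in an IBD region carry a consanguinity
warning: informativeness collapses there and linkage evidence thins.

All QC thresholds are this package's decisions, configurable per call;
the published description states the qualitative signatures only.

## The simulator: what it emulates, and what a green test means

`simulate_family()` draws per-locus B-allele frequencies uniform on
[0.1, 0.5], SNP spacing exponential with median 6 kb (the array's
published median; informative spacing then lands near the published
26 kb), four independent parental haplotypes, Poisson crossover counts
with mean equal to map length (no interference — the same independence
assumption as the double-recombination arithmetic), sibling or
grandparent references observed at genomic-DNA quality (≥98% call rate),
and single-cell observations with per-allele ADO (default 0.15),
miscalls (0.005) and no-calls (0.10), giving call rates inside the
published 75–95% MDA range. Aneuploidy injections drop a gamete
(monosomy) or add a second gamete from the same parent forced to differ
at the centromere (meiosis-I trisomy); IBD injections copy a paternal
haplotype segment onto a maternal one.

Not emulated: spatial correlation of MDA dropout along the genome (no
published parameterization), raw array intensities, contamination,
population linkage disequilibrium between loci, interference, and real
genetic-map variation. A green pipeline test therefore establishes
correctness of the *inference* under the stated noise model, not
robustness to every failure mode of real amplified DNA — most
importantly, correlated dropout would weaken the independence arguments
behind non-key evidence accumulation.

The headline acceptance benchmark simulates 37 non-consanguineous
families (156 embryos; the published validation series' shape) across
modes and reference types and scores disease-status concordance against
truth, counting any `no_result` as discordant — including the rare seeds
where the simulated truth itself is a recombination inside the gene, per
the benchmark's stated rule. At the fixed test seed concordance is 100%;
across other seeds an occasional single embryo is honestly voided
(crossover interval overlapping the gene), which is the safe behavior.

## Degenerate inputs and numerical notes

- Empty evidence tracks produce no blocks; informative-SNP deserts stay
  uncovered rather than interpolated, and block spans never extend past
  their member loci.
- Forward–backward uses per-step scaling; posteriors sum to 1 within
  1e-9 (asserted).
- A lone block below `min_block_keys` is dropped, not reported.
- Mendelian-impossible sibling-reference calls void the locus and are
  counted as reference inconsistencies; no correction is attempted. The
  check is skipped on X, where a male sibling homozygous for the unique
  allele is a legitimate hemizygous call.
- Parent no-calls exclude the locus; parental genotypes are never
  imputed.
- All coordinates are 1-based inclusive internally; BED export converts
  to 0-based half-open.

## Known limitations

- Linkage only: the mutation itself is never observed, so de novo
  mutations and recombination between mutation and all markers are out
  of reach by design.
- One reference individual; no population phasing or imputation.
- Copy-number is inferred from genotype patterns only (no B-allele
  frequency / log-R ratio), so mitotic-origin trisomy without
  both-haplotype regions is invisible, and classification of abnormal
  fertilization patterns is not attempted.
- The uniform genetic map is a deliberate simplification; hotspots
  compress real crossover intervals relative to the model.
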