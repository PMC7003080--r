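---
title: "Calling POLLED diplotypes from diagnostic SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling POLLED diplotypes from diagnostic SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollcall)
```

## The genetic model

Polledness in cattle is dominant and genetically heterogeneous: at the
POLLED locus on BTA1 (2.2–2.8 Mb, ARS-UCD1.2) the Celtic variant P_C (a
complex 212 bp duplication–insertion around 2.429 Mb) and the Friesian
variant P_F (an 80,128 bp duplication, g.2629113_2709240) each cause the
phenotype. Rarer Mongolian and Guarani analogs exist; `pollcall` records
their coordinates (`poll_locus_info()`) but does not detect them.

Commercial chips do not type the structural variants directly. Ten nearby
SNPs/indels are in strong LD with them (`poll_registry()`): one tags P_C
(rs383143898, P_202ID, poll allele T) and nine tag P_F. Each haplotype an
animal carries is one of

* **H** — wild type: no poll allele at any marker;
* **P_C** — poll allele at rs383143898 only;
* **P_F** — poll alleles at every P_F-linked marker;
* **P_C+P_F** — a rare cis recombinant carrying both (see below).

Under complete LD the poll-allele *dosage* (0/1/2) at the Celtic marker
equals the number of P_C haplotypes, and the shared dosage across P_F
markers equals the number of P_F haplotypes. The diplotype follows from the
dosage pair: (0,0) HH, (1,0) HPC, (0,1) HPF, (2,0) PCPC, (1,1) PCPF,
(0,2) PFPF.

## Rule budgets and No Results

Real panels have missing calls and discordant markers, so each panel
carries explicit budgets (`poll_panel()`):

| panel | P_F markers | missing budget | discordance budget |
|-------|-------------|----------------|--------------------|
| CPT   | 7           | ≤ 2 missing    | ≤ 1 discordant     |
| OPT   | 4           | missing + discordant ≤ 1 (≥ 3 of 4 called) |

The Celtic marker is mandatory in both panels; its failure is always a
`NO_RESULT` (`PC_MISSING`). The P_F consensus is the modal dosage among
called markers; called markers off the mode are discordant. Three choices
here were genuinely open and are resolved as follows:

* **Dosage-level consensus.** Discordance is evaluated on dosages (0/1/2),
  not on a binary H-versus-P_F prediction, so a 1-versus-2 conflict counts
  as a haplotype contradiction just like 0-versus-1. A heterozygote/
  homozygote conflict is equally impossible under complete LD, and
  collapsing it would silently accept contradictory evidence.
* **Ties.** If two dosage values tie for the mode the consensus is refused
  and all markers outside one modal class count as discordant. For both
  built-in panels this arithmetic guarantees a budget breach, so a tied
  sample is always `NO_RESULT`; we refuse to guess, matching the test's
  conservative No Result philosophy.
* **Trans assumption.** The two mutations lie ~200 kb apart and arose
  independently, so a double carrier is assumed to hold them on opposite
  haplotypes; a dosage pair summing above 2 (e.g. Celtic homozygote with
  P_F evidence) is `NO_RESULT` (`DOSAGE_INCONSISTENT`) rather than an
  error, since it can arise from genotyping error or a cis recombinant and
  the panel cannot distinguish the two.

The CPT membership is itself a reconstruction: the commercial 8-SNP set is
the ten registry markers minus the two declared non-informative
(rs798116945, rs800767839, near-monomorphic across breeds). The redundant
marker rs799920960 is treated as a full-weight P_F predictor within CPT.

The engine is verified two ways: every rule combination against an
independently written exhaustive rule table (all 4^5 per-marker dosage
patterns for OPT), and end-to-end against simulated truth.

## Tunable parameters of the simulator

`sim_config()` draws, per animal, two gametes i.i.d. from per-breed
haplotype frequencies (Hardy–Weinberg), emits complete-LD genotypes, then
layers noise:

* **Haplotype frequencies** (per breed, sum to 1). Default H = 0.6,
  P_C = 0.3, P_F = 0.1 — a composite beef population with the Celtic allele
  several-fold more frequent than the Friesian, as in the breeds the test
  targets.
* **Call rates** (per marker, per breed, in [0,1]). Default: the published
  mean call rates of the ten markers (96.3%–100%). Each genotype is
  independently missing with probability 1 − call rate.
* **Genotyping error** (per genotype). Default 1e-4, the "< 0.01%"
  background assay failure range; an erroneous call is replaced by a
  uniformly chosen different dosage.
* **Probe artifact** at rs800947704. A latent interfering SNP 3 bp upstream
  (g.2378742A>G) defeats the probe in G carriers. Carriers are drawn under
  Hardy–Weinberg at `interfering_allele_freq`; each loses the call with
  `dropout_prob_given_G` or, failing that, is miscalled (dosage decremented
  toward 0, hiding a poll allele) with `miscall_prob_given_G`. Default off;
  a carrier frequency of 0.0743 with certain dropout reproduces the ~14.3%
  marker loss observed in Brahman. The interfering SNP is latent — no assay
  in scope genotypes it — and the published mechanism report is internally
  inconsistent about which target genotypes fail, so the artifact is
  parameterized rather than hard-coded to one mechanism.
* **Recombination** (`recomb_prob`, default 0.002). Each transmitted P_C or
  P_F gamete independently becomes a cis P_C+P_F recombinant with this
  probability (~0.2%, the approximate genetic distance between the
  mutations). Only the cis product is modeled: the reciprocal null gamete
  is indistinguishable from H at every panel marker. A cis/H animal carries
  one poll allele at every marker, so the trans-assuming engine calls it
  PCPF even though it transmits both mutations together — the simulator
  exposes exactly this caveat. A cis haplotype alongside another P
  haplotype (probability of order `recomb_prob` × P frequency, negligible
  at defaults) is classed PCPF by mutation content for penetrance purposes.
* **Penetrance** (distribution over Horn/Scur/Poll per true diplotype).
  Two presets: `"validation"` (HH fully horned; HPC scurred 0.599 / polled
  0.401; everything else fully polled — the pattern of accurately
  phenotyped herds) and `"breedplan"` (field records, including ~5% of HH
  animals misrecorded as scurred or polled; the PCPF row is normalized from
  the printed 0.37/0.37/99.2 to sum to one, Poll = 0.9926).

Complete LD is the baseline: residual marker–mutation discordance is
modeled only through the error and artifact channels, not as imperfect LD,
because in practice it is technical rather than recombinational except for
the explicit cis case.

## What the simulator does and does not emulate

It reproduces the *structure* of multi-breed panel data: haplotype
frequency differences between breeds, per-marker and per-breed call rates,
a breed-concentrated probe artifact, background error, and penetrance-based
phenotypes. It does not emulate pedigree structure, linkage decay with
distance (LD is all-or-nothing), chip batch effects, allele-frequency drift,
or the unresolved genetics of scurs (penetrance tables are the entire
phenotype model; sex effects on scurring are not modeled). Passing tests
therefore demonstrate that the rule engine is correct and robust to the
modeled failure modes — not that any particular field cohort will show a
specific No Result rate, which depends on breed composition and chip
version.

## Numerical conventions and degenerate inputs

* Percentages round half-up (9.68695% → 9.69), matching the reporting
  convention of the benchmark tables; rates use 2 dp, concordance rows 1 dp.
* Genotypes are unphased and order-insensitive; readers normalize "CT",
  "C/T", "C T" to a sorted "C/T". Indel alleles map to the registry's
  pseudo-SNP symbols through an `alias_map` at read time (the same hook
  accommodates strand-complement dialects).
* Missing-call slots exist for every registry marker: a marker absent from
  the input is missing for every sample, not an error.
* Empty datasets, all-missing samples, all-zero margins and unused group
  levels return empty/NA results or informative errors, never crashes; the
  test suite pins each case.
* Simulations are byte-reproducible under `sim_config(seed = )`; the
  acceptance script derives all randomness from its `--seed` argument.

## Problem sizes

The exhaustive rule-table check enumerates all 1,024 OPT dosage patterns.
Simulation-based tests use 3,000–20,000 animals: large enough that binomial
3σ bands around Hardy–Weinberg class proportions, call rates and penetrance
are a few tenths of a percentage point, small enough that the whole suite
runs in well under a minute per file. The acceptance computation uses 5,000
animals, where the stability property is exact (a property of the rules
under complete LD, not an asymptotic one).

## Known limitations

* P_M and P_G carriers would type as H at every panel marker and be called
  HH or a single-mutation class; the package records their coordinates only.
* No imputation: a failed Celtic marker is unrecoverable by design.
* The heterozygote poll-rate comparison pools Horn and Scur as "not
  polled"; with very small heterozygote classes (flagged at n < 30) the
  exact test is valid but the proportion estimates are imprecise.
* Breed-specific No Result rates of any real cohort are not reproducible
  here: they require the original proprietary genotypes. The package ships
  the published class counts (`published_cohort_counts()`) for their
  arithmetic identities only.
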