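---
title: "Family-based exome filtering and rare-variant-sharing consanguinity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based exome filtering and rare-variant-sharing consanguinity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triokin)
```

## The problem

When a child presents with a severe disease of suspected genetic origin and
no accession-level data are available, the standard desk workflow is
family-based exome filtering: sequence the proband together with one or both
parents, classify each variant by its segregation pattern, and then pare the
candidate list down by population frequency, predicted protein impact and
in-silico deleteriousness, optionally intersecting the survivors with
disease-relevant gene panels. A companion question, cheap to answer from the
same data, is whether the parents are cryptically related — relevant both
clinically (it raises the prior on recessive causes) and as a data sanity
check.

`triokin` implements this workflow as composable, tibble-first functions,
plus a synthetic-exome generator that makes every stage testable with exact
or statistical oracles and no external downloads.

## Segregation models

Genotypes are VCF-style strings over post-split allele indices. All rules
operate on the classification `hom_ref` / `het` / `hom_alt` / `missing`;
a hemizygous alternate call (male X) is treated as homozygous-equivalent.

* **Recessive homozygous** — child `hom_alt`, both parents `het` (trio), or
  the one available parent `het` (duo). Duos cannot evaluate the trio rule,
  yet families with a single sequenced parent still need reportable
  candidates, so the duo rule accepts a carrier-but-not-homozygous parent.
* **Parental-homozygote exclusion** — a variant homozygous (or hemizygous)
  alternate in any *unaffected* parent is never reported, whatever else it
  satisfies: an unaffected homozygote is direct evidence against
  pathogenic recessiveness.
* **Dominant** — dual mode, because pedigrees differ in whether a
  transmitting affected parent is plausible: `de_novo` (child `het`, all
  available parents `hom_ref`) or `affected_parent` (child `het`, carrier
  parents exactly the affected ones).
* **Compound heterozygous** — two distinct `het` child variants in the same
  gene, one carried by exactly the mother and one by exactly the father
  (in trans by parental origin). With one parent the phase is undetermined,
  and the function raises an error rather than silently returning nothing.
* **Missing genotypes disqualify.** A variant with an ungenotyped parent is
  never positively classified. This is a deliberate conservative
  false-negative bias; imputing `hom_ref` would inflate recessive calls
  because per-sample VCFs rarely emit reference calls.

On the X we add the only sex-aware refinements the data support: a
hemizygous alternate son qualifies as recessive through a heterozygous
mother (the father's X never reaches a son, so the father is only required
to be genotyped and not an excluded unaffected homozygote), and a
homozygous daughter requires a transmitting father — who is then himself a
hemizygous alternate and, if unaffected, triggers the exclusion. The
exclusion is allowed to win: that asymmetry is inherent in combining the
exclusion rule with X genetics, and we keep the rule uniform rather than
special-casing it.

## The filter cascade

`cascade_counts()` applies, in fixed order, each stage to the survivors of
the previous one:

1. recessive homozygous (above);
2. **rare** — selected population MAF strictly `< threshold`
   (default 1%, `GLOBAL`); a *missing* frequency counts as rare, because a
   variant absent from the reference panel is novel, and novel variants are
   reportable findings, not discards;
3. **nonsynonymous** — protein-altering consequences, plus splice-affecting
   terms: `splice_donor`/`splice_acceptor` always, `splice_region` only at
   impact `MODERATE` or above (LOW-impact near-splice synonymous calls are
   numerous and rarely meaningful);
4. **deleterious in silico** — SIFT deleterious (either confidence), or
   PolyPhen probably *or possibly* damaging, or annotated impact `HIGH`
   (nonsense/frameshift variants carry no SIFT/PolyPhen score and must not
   be lost). Missing predictors contribute `FALSE`.

The counts are monotone by construction, which is asserted
property-style over random synthetic families.

## The consanguinity statistic

For a mother–father pair, `consanguinity_ratio()` repeats `n_reps = 100`
times: draw uniformly **one** father-carried variant per chromosome
(1–22 and X; Y excluded) among those with a known population MAF in
`(0, threshold)`, count how many of the drawn variants the mother carries
(identical `chrom:pos:ref:alt`), and compare with the Hardy–Weinberg
expectation for an unrelated individual,

$$\Pr(\text{carrier}) = 1 - (1 - p)^2 \approx 2p ,$$

summed over the drawn variants. Sampling one variant per chromosome
de-correlates the draws (a crude guard against linkage disequilibrium).
The screen is run at MAF thresholds 0.01, 0.02, 0.05 and 0.1: the rarer
the variants, the more informative sharing is about identity by descent,
so a related pair shows its largest ratio at the strictest threshold.

Design choices that required a decision:

* **Ratio orientation is observed/expected** — high means related. For a
  pair with kinship coefficient $\varphi$ the probability that a rare
  allele carried by the father is identical-by-descent in the mother is
  about $2\varphi$, so the pooled ratio scales like
  $(2\varphi + 2\bar p)/2\bar p$: at $\bar p \approx 0.5\%$ that is ~1 for
  unrelated pairs, and roughly 4, 13 and 50 for second cousins, first
  cousins and siblings — large, well-separated signals.
* **The family-level scalar is the pooled ratio**
  $\sum_r \text{obs}_r / \sum_r \text{exp}_r$, not the mean of
  per-repetition ratios: for very rare variants the per-repetition
  observed count is frequently zero and the per-repetition ratio is
  unstable (and undefined when a repetition's expectation is zero), while
  the pooled estimator is defined whenever any expectation is positive.
  Per-repetition ratios are still emitted (`tidy()`) for distribution
  plots, with undefined entries flagged `NA`.
* **Variants with missing or zero MAF are ineligible**: their
  Hardy–Weinberg expectation is zero and would degenerate the ratio; the
  statistic is defined on panel-annotated variants only.
* **"Present in" means carrier** (at least one alternate allele), for both
  the father's eligibility and the mother's sharing; nothing in the
  construction requires homozygosity.
* `interfamily_baseline()` pairs fathers of different families as
  pseudo-couples, yielding the unrelated-population distribution a
  family's own ratio should be judged against.

## The synthetic generator

`simulate_family()` chains four pieces, each independently usable:

* `simulate_spectrum()` — a two-component site-frequency spectrum:
  a fraction `rare_fraction = 0.8` of sites uniform on
  `rare_maf_range = (0.002, 0.0099)` and the rest a scaled
  Beta(1.2, 3) on (0.01, 0.5). EUR frequencies are GLOBAL ones under
  bounded multiplicative noise (log-uniform within ±20%), so the two
  panels genuinely disagree and population-selection code paths are
  exercised. The rare band deliberately sits just *below* the 1% cutoff
  rather than extending into the sub-0.1% tail of a real exome: at a
  desk-scale 5,000 sites each parent must still carry a workable number
  (~40–50) of threshold-eligible rare variants for sharing statistics to
  have power, which a real exome achieves through millions of sites. A
  consequence worth stating: passing calibration here shows the statistic
  is unbiased and discriminating given a reasonable rare-variant load, not
  that 5,000 arbitrary sites from any spectrum would suffice.
* `gene_drop()` — founder haplotypes Bernoulli(MAF) under Hardy–Weinberg,
  Mendelian transmission through an explicit `pedigree_spec()` graph with
  sex-correct X handling (fathers pass X to daughters only; sons are
  hemizygous). Founder alleles are drawn from the EUR panel frequency —
  the population the sharing expectation is evaluated against — so the
  unrelated-pair calibration target is exactly 1. `pedigree_trio()`
  provides parent pairs at kinship 0, 1/64 (second cousins, i.e. a shared
  great-grandparent couple), 1/16 and 1/4, verified against the classical
  kinship recursion.
* `annotate_sites()` — gene assignment by non-overlapping intervals
  (1 Mb tiles carrying generic symbols, with well-known cholestasis /
  liver / drug-metabolism loci named at approximately their real
  positions) and consequence/impact/SIFT/PolyPhen labels drawn from a
  configurable exome-like categorical mixture.
* `inject_ground_truth()` — overwrites randomly chosen autosomal sites to
  realise exact counts per class (a nested recessive ladder, in-trans
  compound-het pairs, de novos, panel hits), returning a truth manifest.
  After injection, background sites that *coincidentally* satisfy a
  monitored pattern are demoted — coincidental recessive genotypes
  softened to heterozygous (Mendelian-consistent, both parents are
  carriers there), coincidental compound-het or panel matches detached by
  renaming the background gene to a private symbol — so that recovered
  sets equal the manifest exactly. This exclusivity is a fixture property
  enabling exact end-to-end oracles, not a biological claim.

Sites are simulated without linkage disequilibrium. That is a documented
limitation, but a tolerable one here: the statistic samples one variant
per chromosome precisely to suppress LD effects, so an LD-free null is a
faithful enough model of what the method sees.

## What the tests establish, and at what problem sizes

All randomness is seeded; simulations are sized to run on a single CPU in
minutes. The segregation rules are checked against exhaustive truth tables
over all 27 diploid trio genotype combinations (plus hemizygous X grids and
affected-status variants). The injected-fixture oracle uses a 1,500-site
trio with a (10, 4, 3, 2) recessive ladder, two compound-het pairs and
three panel hits, recovered exactly. The consanguinity statistic is
calibrated on 50 unrelated pairs at 5,000 sites (batch mean within three
standard errors of 1 at each threshold), and its sensitivity is checked
with 20 gene-dropped pairs per kinship level: the per-kinship batch-pooled
ratios (observed and expected summed over a level's pairs — the batch-level
analogue of the family scalar, chosen for the same robustness-to-zeros
reason) must rank with kinship, first-cousin pairs must exceed the 95th
percentile of the unrelated inter-pair distribution in at least 90% of
pairs, and the mean ratio must be larger at threshold 0.01 than at 0.1.
Numerical edge cases pinned by tests: self-paired parents reduce to a
closed-form sum, an empty eligible set yields an `NA` ratio with a
diagnostic rather than a crash, and chromosomes with no eligible variant
are simply skipped in a repetition.

## Known limitations

* Gene matching is by uppercased symbol, as in panel lists exported from
  curated databases; no coordinate-based matching or alias resolution.
* No indel left-alignment or normalisation is attempted beyond
  multi-allelic splitting; inputs from different callers should be
  normalised upstream if keys must match across files.
* The dominant model's dual mode reflects a genuine ambiguity in how
  "dominant" is meant for families with unaffected parents; the default is
  `de_novo`.
* X-linked handling stops at hemizygote bookkeeping: no X-inactivation,
  mosaicism or imprinting models.
* The generator's spectrum and label mixture are convenient stand-ins, not
  fits to any cohort; conclusions about real data should rest on the
  method, not on these defaults.
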