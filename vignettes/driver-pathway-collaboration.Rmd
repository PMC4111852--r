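---
title: "Identifying collaborative driver pathways from somatic mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying collaborative driver pathways from somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Motivation and model

Somatic driver mutations are individually rare: most genes are mutated in
only a handful of tumors, and different cohorts implicate poorly overlapping
gene lists. The premise of this package is that the *functional units* —
pathways, and groups of pathways acting together — are far more stable
across tumors of one subtype than the identities of the mutated genes. Two
hypotheses shape the method: (1) a cancer phenotype arises from cooperative
disruption of several pathways, simultaneously aberrant in most samples of a
subtype, and (2) any functionally disruptive mutation in a pathway can drive
it, so a driver pathway need not be dominated by one recurrently mutated
gene.

The pipeline has two steps: a mutational enrichment analysis that ranks
pathways, followed by a constrained greedy search for a *collaborative* set
of pathways co-mutated in a maximal fraction of samples.

## Step 1: gene scoring and pathway enrichment

**Impact scoring.** Functional impact scores (as produced by external
missense-impact predictors) are consumed as an input table keyed on
`(gene, sample, position)`. The scoring rule is total over variant classes:
indels, nonsense and splice-site mutations receive the highest attainable
score (they are at least as disruptive as the most disruptive scored
missense change), silent mutations the lowest, scored missense mutations
keep their score, and unscored missense mutations receive the cohort
missense mean. Variant classes outside this vocabulary are kept in the
records but excluded from scoring.

**Mutation matrix.** For gene $i$ and sample $j$, separately for
non-synonymous (NSY) and synonymous (SY) classes,
$$M_{ij}^{*} = \frac{\sum_k b_k \, s_k}{\mathrm{cov}(i)}$$
with $b_k$ the mutated base count of event $k$ (1 unless a length is
recorded), $s_k$ its impact score, and $\mathrm{cov}(i)$ the gene's bases
with sufficient read depth. Normalizing by covered bases removes gene-length
and coverage bias; synonymous mutations provide the neutral background.

**Mutation Factor.**
$$MF_i \;=\; \frac{N_i^{NSY}}{\max(N_i^{SY},\,1)} \cdot
\frac{1}{m}\sum_{j=1}^m \bigl(M_{ij}^{NSY} - M_{ij}^{SY}\bigr).$$
The contrast is averaged over *all* $m$ samples (not only mutated ones), so
a gene mutated in few samples is not inflated. The count-ratio weight is
undefined when a gene has no synonymous mutation — a common case — so the
denominator is guarded at one, which preserves the ratio's intent without
pseudocounting observed events.

**Interaction Factor.** Within a pathway with undirected topology, for each
ordered pair $(i,j)$:

* $d_{ij}$ — shortest-path hop count (functional propinquity; mutational
  influence is assumed to decay with network distance);
* $C_{ij}$ — fraction of samples in which *exactly one* of the two genes is
  non-synonymously mutated;
* $ME_{ij}$ — mutual exclusivity: exclusive samples over the union of
  mutated samples (0 when neither gene is mutated).

These are combined as
$$f_{ij} = \frac{C_{ij} \cdot ME_{ij}}{1 + d_{ij}},$$
which increases with co-coverage and exclusivity, decays with distance, is
bounded in $[0,1)$, and is defined as 0 for disconnected pairs (no
functional route, no influence). The Interaction Factor of gene $i$ is the
average over its $|P|-1$ partners of the strengths passing a threshold
$\alpha$:
$$IF_i = \frac{1}{|P|-1}\sum_{j \ne i} f_{ij}\,\mathbf{1}[f_{ij} \ge \alpha],$$
floored at $\alpha$ when no pair passes so that $IF_i$ stays strictly
positive. Failing partners contribute zero but remain in the denominator.
This functional form is this package's own concretization: the combination
of the three pair statistics is specified here (bounded, monotone in each
ingredient) and isolated behind `interaction_strength()` so it can be
swapped without touching anything else.

**Ranking score.** $score_i = e^{MF_i} \cdot IF_i$; the exponential maps the
signed $MF$ to a positive multiplier so the score is positive and strictly
increasing in both factors.

**Imputation for outside genes.** The weighted KS statistic compares member
ranks against non-member ranks, but genes outside a pathway have no
topology, hence no $IF$. Their scores are imputed from a cohort-wide
background: with probability equal to the pathway's fraction of members
whose $IF$ had at least one passing partner, a score is drawn from a
Gaussian parameterized by the mean and standard deviation of all real
(non-imputed) member scores across all pathways, truncated below at
$10^{-12}$; otherwise the gene receives the non-passing fallback
$e^{MF}\alpha$ — exactly the score a non-passing member would get. Matching
the passing fraction inside and outside the pathway avoids an artificial
rank bias toward members.

**Weighted KS statistic.** Walking the ranked list from the top, the member
CDF accumulates member scores normalized by their total while the non-member
CDF takes uniform steps; the statistic is the maximum absolute deviation
(MD) between the two. Ties in score are broken by gene symbol in
`ranked_list()`; in the permutation test, a member tying with outside scores
is placed after them, identically for the observed and permuted walks.

**Permutation null.** Two schemes are provided.

* `wks_gene_perm_test()` (the pipeline default): each permutation draws a
  random gene set of the pathway's size from the cohort, places it on the
  pathway's own topology, and recomputes $IF$, scores and MD against the
  fixed imputed outside list. On a cohort without pathway-linked mutational
  structure the members are exchangeable with a random draw, so the p-value
  is calibrated by construction, while elevated mutation burden *and*
  mutually exclusive arrangement both push the observed MD beyond the
  permutations. Because sparse cohorts give the MD permutation distribution
  sizeable atoms (many random sets produce identical statistics), exact ties
  are broken uniformly at random — the randomized permutation p-value — and
  a $+1$ smoothing keeps $p > 0$:
  $$p = \frac{\#\{MD_{perm} > MD_{obs}\} + U\cdot\#\{MD_{perm} = MD_{obs}\} + 1}{n_{perm}+1}.$$
* `enrichment_pvalue()`: a fast label shuffle over the positions of an
  already-ranked list. It is appropriate for generic ranked lists, but for
  the full pipeline it is anti-conservative: member scores of one pathway
  share a common component (topology, size, shared pair statistics — about
  30% of IF variance between pathways in null simulations), which label
  shuffling cannot reproduce. Two alternatives were measured during design:
  label shuffling (pooled null KS distance to uniform ≈ 0.08–0.18) and
  within-pathway mutation-status reshuffling, which is calibrated but
  conditions on per-gene event counts and is therefore blind to mutation
  burden. The gene-set permutation is the scheme that is simultaneously
  calibrated (pooled null KS distance ≈ 0.045, within the Monte-Carlo bound)
  and sensitive to planted signal; it also matches the method's gene-set
  enrichment ancestry.

**Multiple testing.** With pathways sorted by increasing $p$ and rank $k$,
$FDR = p\,m/k$ capped at one, where $m$ is the total number of pathways
tested. The raw sequence $p\,m/k$ is not necessarily monotone in $k$, so a
running maximum is applied down the list; this never reports a smaller FDR
than the raw formula and leaves typical (already monotone) sequences
unchanged.

## Step 2: collaborative set assembly

A pathway *covers* a sample when at least one member gene carries a
non-synonymous mutation there; a set of pathways is *collaborative* in a
sample when every member is mutated there. The Maximal Coverage Rate (MCR)
of a set is its intersection coverage. From the top-$k$ enriched candidates
(default 60):

1. The first pathway is the one with the highest coverage rate that passes
   the dominance filter; it is exempt from the collaboration test, having no
   partners yet.
2. At each later step, the unselected candidates are ordered by the joint
   MCR they would produce with the current set (ties by candidate-pool
   order), and the best candidate passing both constraints is added:
   * **dominance**: joint MCR $\ge$ the candidate's highest single-gene
     mutation rate $+\;\delta$ (default 5%, boundary passes) — a pathway
     whose apparent contribution is one recurrently mutated gene adds no
     collaborative information;
   * **significance**: a mutation-redistribution permutation test. Every
     non-synonymous event of the candidate's genes is independently
     reassigned to a uniformly random sample (with replacement, preserving
     the total event count); the background MCR is the fraction of samples
     covered by the permuted candidate and by every already-selected
     pathway. $p = \#\{MCR_{bg} \ge MCR_{obs}\}/n_{perm}$, compared strictly
     against the threshold (default 0.01). Coverage comparisons are made on
     integer covered-sample counts to avoid floating-point boundary
     artifacts; when the full assignment space $m^K$ is small the p-value is
     computed by exact enumeration, which is what makes the toy cases
     exactly checkable.
3. The search stops when no candidate qualifies; an empty result is legal.

Choosing candidates by conditional (joint) coverage rather than by marginal
coverage rank follows the natural greedy objective — maximize the samples in
which the whole set stays co-mutated. An unconstrained variant
(`constrained = FALSE`) drops both filters and adds pathways by decreasing
joint coverage until it reaches zero, for comparison.

Two conventions worth noting. The redistribution samples *with replacement*,
so a candidate whose observed events occupy distinct samples is compared
against backgrounds with occasional collisions; this makes the test very
slightly anti-conservative for such candidates (a decoy pathway clears
$p<0.01$ in roughly 1–3% of runs). And the observed MCR in the test is the
candidate's *tentative* joint MCR, i.e. including the candidate before
acceptance.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.005 | pass threshold on $f_{ij}$, controlling IF sensitivity vs selectivity; also the IF floor and the non-passing fallback scale |
| `n_perm_enrichment` | 5000 | gene-set permutations per pathway |
| `n_perm_collab` | 5000 | mutation redistributions per candidate |
| `top_k_pathways` | 60 | enrichment candidates passed to the greedy search |
| `dominance_delta` | 0.05 | required MCR margin over the best single-gene rate |
| `collab_p_threshold` | 0.01 | strict bound on the collaboration p-value |
| `rng_seed` | 1 | master seed; stage and group sub-seeds derive from it |

All per-stage and per-group randomness derives deterministically from
`rng_seed` (per-group sub-seeds hash the group label, so adding a group
never perturbs the others' results). Two runs with one seed are
byte-identical; the resolved configuration is persisted next to the results
and reproduces the run when fed back in.

# The synthetic-data generator

`generate_cohort()` emulates the statistical structure the method assumes:

* background non-synonymous and silent mutations drawn independently per
  gene and sample at configurable rates;
* planted collaborative blocks: a Bernoulli per-sample indicator selects the
  co-mutated samples, each of which receives one non-synonymous mutation in
  *every* member pathway, placed on a randomly chosen member gene — not a
  fixed one, which is exactly what makes the dominance filter and MCR tests
  meaningful;
* dominated pathways whose planted coverage flows entirely through one
  designated gene;
* random connected topologies (random attachment tree plus ~30% extra
  edges), covered bases uniform in $[5\times10^4, 2\times10^5]$, missense
  impacts uniform in a configurable range, a small fraction of
  indel/nonsense/splice events to exercise the max-score branch of the
  scoring rule, and a fraction of unscored missense events to exercise the
  cohort-mean branch;
* optional sample groups with group-specific planted sets.

Presets fix the study conditions used throughout validation: `null` (200
pathways x 200 samples, background only — p-value calibration),
`planted_trio` (3 pathways co-mutated in an expected 60% of 500 samples
among 7 decoys — greedy recovery), `dominated` (one gene carrying 70%
coverage over a near-silent background — the dominance filter), and
`breast_like` (four groups of 93/57/224/124 samples, the layout of a
four-subtype tumor cohort, each with its own planted set sharing one common
pathway). Background rates (1–2% non-synonymous per gene-sample, half that
for silent) give per-gene mutation frequencies of a few percent, the typical
scale of non-hotspot somatic mutation data.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: mutational signatures and trinucleotide context,
copy-number alteration, gene-length heterogeneity beyond the uniform
covered-base range, overlapping pathway membership (generated pathways draw
disjoint gene blocks; the implementation itself supports overlap), hypermutators,
and subclonal structure. Real impact scores are also bimodal rather than
uniform.

# Numerical and degenerate-input choices

* Permutation MDs are evaluated only at corner points (just after each
  member, just before the next), which is exact because the deviation decays
  linearly between members; this is what makes thousands of permutations per
  pathway affordable.
* Singleton pathways have no defined IF and are skipped with a warning, as
  are pathways sharing no gene with the matrix universe.
* A candidate with zero mutations gets collaboration $p = 1$ by convention.
* Equal ranking scores are ordered by gene symbol; equal enrichment
  p-values by pathway id; equal single-gene rates alphabetically — all
  deterministic.
* Mutated genes absent from the coverage table are a hard error (coverage
  is the normalizer); samples absent from the mutation file are supported by
  passing an explicit sample list, since a MAF cannot enumerate unmutated
  samples.
* Problem sizes used in the shipped validation: the calibration study runs
  20 null cohorts at 500 permutations; greedy recovery uses 1000
  redistribution permutations over 10 candidates; the exhaustive
  collaborative-set oracle enumerates all $2^{10}$ candidate subsets.

# Known limitations

* The interaction strength $f_{ij}$ and the imputation distribution are this
  package's concretizations of loosely specified components; both are
  isolated behind single functions (`interaction_strength()`,
  `impute_outside_scores()`) for substitution.
* The gene-set permutation is a competitive null: it asks whether a
  pathway's genes look different from random gene sets of the same size on
  the same topology. Self-contained questions (is this pathway's mutation
  arrangement non-random given its burden?) need the redistribution ideas of
  the collaboration test instead.
* Pathway topology is undirected and unweighted; KEGG relation types and
  directions are ignored, and only shortest-path distance enters.
* The collaboration test's with-replacement redistribution is slightly
  anti-conservative for candidates whose events occupy distinct samples
  (see above); with many decoy candidates, an occasional false admission
  after the true set is expected.
* Inherited variants, copy-number alterations, methylation and expression
  are outside the model; impact scoring consumes an external score table and
  provides only the rule-based fallbacks described above.
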