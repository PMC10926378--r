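---
title: "Methods: pedigree reconstruction and caste morphometrics in matriline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree reconstruction and caste morphometrics in matriline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriline)
```

`matriline` implements the analysis chain used to characterise the genetic
structure of social-wasp colonies from microsatellite genotypes, together
with the landmark-based wing-shape analysis used to discriminate female
castes, and the simulators needed to validate both. This vignette explains
the models, the tunable parameters, and the design choices made where the
procedure was genuinely open.

## The inheritance model

Everything in the genetics modules rests on haplodiploid Mendelian
inheritance with error-free genotype calls:

* a **queen** is diploid: an unordered allele pair per locus;
* a **male mate** is haploid: one allele per locus;
* a **daughter** receives one queen allele (each with probability 1/2) and
  her father's allele;
* a **queen's son** receives one queen allele; a **worker's son** receives
  one of his worker mother's two alleles.

Individuals with a missing call at any polymorphic locus are excluded from
inference by default (`incomplete_individuals()` lists them). This mirrors
datasets built on complete multilocus profiles; the exact-compatibility
rules below have no tolerance for genotyping error, and a mistyped allele
would surface as a spurious extra father. Likelihood-based sibship methods
are the right tool when call error is non-negligible; they are out of scope
here.

## Drifter detection

Workers sometimes drift between nests. `detect_drifters()` flags an
individual carrying, at a minimum number of polymorphic loci
(`min_unique_loci`, default 4), at least one allele found in no other
member of its nest, other flagged individuals included. The rule is applied
iteratively — after flagging, uniqueness is re-assessed among the remaining
members — so two drifters sharing an origin cannot shield each other.
Drifters are removed before any pedigree inference and before allele
frequencies are computed, since they are not colony offspring.

The threshold of four loci is conservative for a panel of seven polymorphic
loci of moderate diversity (mean He 0.63): a true nestmate shares maternal
alleles with her siblings at every locus, so private alleles at four loci
essentially cannot arise within a family, while an unrelated immigrant
carries private alleles wherever her ancestry differs.

## Queen inference at one locus

At a single locus, a candidate explanation of a matriline is a queen pair
`{q1, q2}` plus a set of father alleles such that every daughter carries
one queen allele and one father allele, and every son carries a queen
allele. `enumerate_locus_solutions()` enumerates all such explanations over
the alleles observed at the locus (homozygous queens included) with the
minimal father set for each queen pair, by exhaustive search; the candidate
list is the raw material for everything downstream. Three ambiguity states
are distinguished in the inferred queen genotype:

* `resolved` — a unique most-parsimonious solution;
* `homozygosity_unresolved` — only one shared allele is observable, so the
  queen is recorded as a putative homozygote rather than inventing a second
  allele;
* `multiple_solutions` — several solutions tie under the parsimony
  criterion.

## Global parsimony: fewest parents

Per-locus parsimony alone is *not* sufficient. Two structural pathologies
motivated the global criterion:

1. If a queen is homozygous at a locus and her two mates differ there, the
   locus admits a spurious one-father solution in which the queen "absorbs"
   one father allele. Locally it looks more parsimonious; jointly it
   shreds the patrilines at other loci.
2. Two unrelated singly-mated queens produce daughter sets that, at any one
   locus, can always be "explained" by a single queen made of the two
   fathers' alleles — every daughter carries her father's allele — at the
   cost of about four inferred fathers at that locus.

Both are cured by scoring whole hypotheses by the **total number of parents
they require (queens plus fathers, counted jointly across loci), with ties
resolved toward fewer queens** and then lexicographically by member ids.
This formalises the field rule of accounting for offspring genotypes with
as few queens and male mates as necessary: one singly-mated queen scores 2
and beats any alternative, while the pathological single-queen reading of a
two-matriline colony needs ~5+ parents and loses to the true split (4).

Implementation:

* **Candidate partitions** (`partition_matrilines()`) are seeded from the
  allele-sharing graph: at each polymorphic locus, females are connected
  when they share an allele, and the connected components are grouped into
  2 … `max_queens` (default 3) sets in every way. Under monandry all
  members of a matriline share the father allele, so one matriline is one
  component; two unrelated queens sharing no alleles at some locus are
  guaranteed to split there. A colony whose matrilines overlap at every
  locus cannot be split by this seeding — the same limit the shared-allele
  procedure has when applied by hand.
* **Joint father counts** come from `infer_queen_genotype()` +
  `assign_patrilines()`. Queen inference starts from the per-locus
  most-parsimonious candidates and, whenever the joint father count exceeds
  the per-locus lower bound (the largest per-locus minimal count), searches
  the product of per-locus candidate solutions by iterative deepening on
  the father budget, visiting high-father-count (non-absorbing) candidates
  first. The product search is capped at 800 combinations per budget level;
  beyond the cap the greedy solution stands. The cap was never reached in
  any simulated scenario exercised by the tests.
* **Patriline grouping** (`assign_patrilines()`) subtracts the queen pair
  from each daughter's genotype — forced paternal allele when exactly one
  allele is non-queen, a two-allele candidate set when her genotype lies
  inside the queen pair — and greedily merges daughters into fathers in
  order of increasing ambiguity (ties by id), intersecting candidate sets,
  with a final merge pass. The procedure is deterministic and exact for
  singly-mated queens; for higher mating frequencies it is a heuristic
  minimal cover whose occasional overcount is exactly what the deepening
  search above corrects for.

Males are deliberately *not* allowed to create matrilines: the partition is
fitted on diploid offspring, and each male is afterwards assigned to the
unique matriline whose queen can have produced him. A male compatible with
no queen is reported in `unassigned_males` — this is the worker-derived
male signal, quantified (not acted upon) by the error models, matching the
working assumption that males are queen-derived.

## Error models

Four analytic probabilities qualify the inference
(`patriline_nondetection()`, `patriline_nonsampling()`,
`worker_male_nondetection()`, `worker_male_combined_nonsampling()`):

* **Paternal non-detection** `Π_l p_f(l)` over polymorphic loci — the
  probability a second male mate is genotypically identical to the
  inferred father, using population-pooled allele frequencies (a per-nest
  panel can be supplied instead).
* **Paternal non-sampling** `(1 − m)^n` — the probability that a father
  siring a fraction `m` of the brood has no offspring among `n` sampled.
  The assumed minority fraction defaults to 0.10.
* **Worker-male non-detection** `(1/2)^k` — a worker's son betrays his
  origin only by inheriting his mother's paternal allele, which happens
  with probability 1/2 per informative locus (`k` = loci where the
  paternal allele is absent from the queen's genotype,
  `informative_loci()`).
* **Combined worker-male non-sampling** `(1 − r(1 − 2^{−k}))^n` — the
  probability that, among `n` genotyped males, none is both worker-derived
  (rate `r`) and detectable. The detectability factor matters: the pure
  non-sampling form `(1 − r)^n` gives 55% where the combined form gives
  57% at `r = 0.02, k = 4, n = 30`, and only the combined form reproduces
  the published 57%/5% pair. `simulate_worker_male_detection()` checks the
  formula by simulating the underlying per-locus coin flips.

Display rounding follows the source convention — one decimal below 10%,
integer percent above — and is **half-up** (`format_percent()`): R's
default half-to-even would print `(1/2)^4` as 6.2% instead of the published
6.3%. Raw probabilities are always retained.

## Wing morphometrics

`gpa()` implements generalized Procrustes analysis: configurations are
centred, scaled to unit centroid size, rotated onto the evolving consensus
by the determinant-corrected SVD solution, and iterated until the
Procrustes sum of squares changes by less than `tol` (default 1e-8, cap
100 iterations). Two documented choices:

* **Reflections are disallowed.** All wings of one side share chirality; an
  improper rotation would align a left wing onto a right one. The SVD
  solution is corrected to determinant +1.
* **No tangent-space projection.** Shape variation in these data is small
  (Procrustes distances ≪ 1), where aligned coordinates and tangent
  coordinates are indistinguishable in practice; aligned coordinates are
  used directly, as is standard in Procrustes ANOVA practice.

`procrustes_anova()` decomposes the summed squared deviations of the
aligned coordinates sequentially (type I) for `shape ~ size + caste +
size:caste`, testing allometry first and caste after size is accounted
for. Significance uses residual randomization (RRPP): for each term the
residuals of the reduced model (preceding terms only) are permuted,
`p = (#{F* ≥ F} + 1)/(n_perm + 1)` with `n_perm = 999` by default and a
seedable generator. Because the hat matrices are nested, the reduced-model
fit drops out of both numerator and denominator and only the permuted
residual matrix enters the statistic. The effect size `Z` is the location
of `log F` in the permuted `log F*` distribution (mean/sd standardised) —
monotone with `p`, which is what the tests assert; no specific `Z` value
is promised.

`common_allometric_component()` returns the normalized direction of the
regression of (group-mean-centred) shape on ln centroid size, specimen
scores along it, and per-group least-squares lines for plotting. One
caveat discovered during validation and worth stating: because the CAC
axis is *estimated from the same data*, the score–size regression is
biased away from zero even under no allometry (axis-selection effect).
The CAC plot is therefore descriptive; inference about allometry belongs
to the ANOVA size term, whose type-I error is calibrated (see below).

`split_castes_by_size()` cuts ln centroid size either at the widest gap
between sorted values (default) or at a fixed threshold (default 1.09, the
published break between workers and gynes in these units). Visually
ambiguous females near the threshold are resolved the same way the study
resolved them: by where they fall in the shape/size analysis.

## The simulators

`simulate_colony()` draws queens, mates and drifters from a locus panel —
by default the published eight-locus *V. soror* panel (seven polymorphic
loci, mean He 0.63), so simulations live in the study's parameter regime —
and produces offspring by the inheritance model above. Options cover
polygyny with arbitrary contribution weights (e.g. the published 0.85/0.15
split), sister queens, polyandry, worker-laid males, and drifters from a
separate panel. `force_disjoint_locus` draws queens and mates without
replacement at one locus, making a multi-queen colony detectable by
construction. Allele labels are synthetic stable integers: published
frequency tables do not include fragment lengths, and no computation
depends on the labels.

`simulate_wings()` builds each specimen as `template + caste offset +
allometric term + isotropic landmark noise`, scaled to its drawn centroid
size and randomly rotated and translated. Defaults mirror the study
design: 86 workers and 45 gynes, worker/gyne mean ln centroid sizes 1.04
and 1.14 straddling the 1.09 break (sd 0.02), 19 landmarks. The template
is a stylised wing (documented as synthetic); the caste-offset and
allometry directions are fixed unit vectors; defaults for the effect
magnitudes (offset 0.01, slope 0.05, noise sd 0.005 in Procrustes units)
were chosen so the simulated ANOVA reproduces the qualitative published
pattern — strong allometry, weaker but real caste effect, null
interaction.

What the simulators deliberately do not model: genotyping error, null
alleles, mutation, age structure within nests, and real wing venation
geometry. Passing recovery tests therefore certify the *inference logic*
under the stated model, not robustness to call error or to landmarks that
violate the isotropic-noise assumption.

## Numerical and scale choices

* GPA tolerance 1e-8 on the Procrustes sum of squares; invariance to input
  rotation/translation/scaling is asserted at the same tolerance.
* Permutation p-values are exact-form `(b + 1)/(B + 1)`; test runs use
  `n_perm` 49–199 to keep the suite fast, analyses default to 999.
* Frequencies must sum to 1 within 1e-9 (panels) / 1e-6 (He input).
* Deterministic tie-breaks throughout: lexicographic queen pairs,
  heterozygous before homozygous at equal parsimony, members sorted by id,
  seeded permutations.
* Test problem sizes: 200 colonies of 30 offspring for monandry recovery;
  20 two-queen colonies of 100 for polygyny detection; 500 null datasets
  (24 specimens, 8 landmarks, 199 permutations) for the ANOVA type-I error
  band [0.03, 0.07]; 10,000 replicates for the worker-male Monte-Carlo.
  These sizes put Monte-Carlo error comfortably inside the asserted bands
  while keeping the suite to a few minutes.

## Known limitations

* Exact-compatibility inference assumes error-free genotypes (above).
* The patriline grouping is exact for monandry and near-exact at low
  polyandry; at high mating frequencies with few loci the father count is
  a lower-bound-seeking heuristic.
* Matrilines that share alleles at every polymorphic locus cannot be
  separated by the component seeding; the partition then reports the
  parsimonious merged reading, as manual analysis would.
* The wing template is abstract: morphometric conclusions transfer to real
  wings only insofar as the landmark-noise model holds.
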