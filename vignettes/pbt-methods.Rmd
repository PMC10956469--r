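---
title: "Methods: parentage-based tagging for hatchery broodstock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parentage-based tagging for hatchery broodstock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbtped)
```

`pbtped` reconstructs multigenerational pedigrees of hatchery broodstock
from SNP genotype archives and derives the life-history quantities those
pedigrees support: age at spawning, iteroparity and within-season repeat
spawning, straying among programs, and genotype associations at a
chromosomal-inversion indicator locus. This vignette documents the models,
the tunable parameters, the numerical choices, and the limits of what the
synthetic validation shows.

## The trio likelihood and its assumptions

Parent-pair assignment is likelihood-based. At each biallelic locus with
alternate-allele frequency $p$, the parental hypothesis assumes the two
candidate parents are draws from Hardy–Weinberg proportions, the offspring
a Mendelian transmission from them, and all three *observed* genotypes
noisy versions of the true ones under a per-gene-copy error model: each of
the two gene copies is read correctly with probability $1-\varepsilon$ and
as the other allele with probability $\varepsilon$, independently
(`genotype_error_kernel()`). The unrelated hypothesis replaces the
Mendelian transmission by an independent Hardy–Weinberg draw for the
offspring. Per-locus likelihoods are precomputed for all 27 observable trio
configurations (`trio_tables()`), and a trio's LOD is the sum of
$\log_{10}$ likelihood ratios over loci called in all three members;
monomorphic loci are excluded. The assumptions worth stating:

* *Error independence across gene copies and loci.* Real assay error is
  partly systematic per marker; the two-pass marker-exclusion loop (below)
  is the corrective for markers whose error is not well described by the
  exchangeable model.
* *Hardy–Weinberg parental priors at known frequencies.* Frequencies are
  estimated from the data. By default they are estimated **per program**
  (`allele_freq_source = "per_program"`): the package targets systems of
  several partially diverged broodstocks, and using pooled frequencies in a
  structured system both deflates true-trio LODs and — more damagingly —
  makes two unrelated members of the most divergent program look
  "surprisingly" alike, which concentrated essentially all false
  acceptances in that program in our simulations. A `pooled` option remains
  for panmictic systems.
* *Per-locus complete-case.* Loci missing in any trio member are skipped
  for that trio; the number of used and Mendelian-incompatible loci is
  recorded per trio.

Each offspring's best pair is chosen by maximizing the trio LOD, and the
assignment is kept only if the maximum-a-posteriori relationship among
*parent pair*, *mother only*, *father only* (single-parent likelihoods with
the other parent integrated over HWE) and *unrelated*, at equal priors, is
the parent pair. LOD ties break toward unrelated.

### Candidate pools and the two run modes

Candidate parents for an offspring first spawning in season $y$ are all
fish with a spawn event in seasons $y-a$, $a \in [2, 6]$ (the observed
range of spawning ages), across all programs; iteroparous fish enter the
pool of every season they spawned. The **constrained** mode additionally
requires a candidate pair to consist of two opposite-sex fish recorded at
the same program on the same spawn date — the physical definition of a
hatchery mating; we add the same-program condition to the shared-date rule
since a mating cannot span two hatcheries. The **unconstrained** mode pairs
any two distinct pool adults and ignores recorded sex, which is what lets
it recover trios whose metadata (sex or date) were recorded wrongly.
Reconciliation keeps identical accepted trios (`both_runs`), adopts
unconstrained-only trios as presumed metadata errors, resolves conflicting
acceptances toward the lower q-value (ties toward the constrained run —
the spec of record for this choice is the package's own: the two runs'
FDRs are the only principled comparison available), and finally removes
improbable trios (same-sex parent pairs, parents not spawning at least the
minimum age gap before the offspring, self-parentage), each with a logged
reason. The accounting identity
`final = both_runs + unconstrained_only + constrained_preferred +
constrained_only − improbable` is asserted on every pipeline run.

### Computation: prescreen then exact evaluation

Evaluating every mother × father pair exactly is quadratic in pool size
(millions of pairs per offspring-year at realistic scale). The package
first computes the *exact* single-parent LOD of every (offspring, adult)
pair in one matrix product of one-hot-encoded genotypes — missing calls
contribute zero on both sides, so the product equals the per-pair sum — and
then evaluates full trio LODs only among pairs drawn from each offspring's
`top_k` (default 15) single-parent candidates. At $\varepsilon = 0.005$
over ~90 informative loci, a true parent's single-parent LOD exceeds the
unrelated distribution by many $\log_{10}$ units, so the prescreen loses
essentially no recall (the property-style tests assert that both true
parents rank in the top two of the prescreen on simulated data). For a
truly unrelated offspring the prescreened maximum can only underestimate
the full-pool maximum, which makes the resulting p-values conservative.

### False discovery control

The null hypothesis that matters is "this offspring is unrelated to
everyone in its pool", and the relevant statistic is the *maximum* pair
LOD over the pool. The package simulates that null directly: for each
offspring-year stratum and each program with offspring in it,
`null_sim_size` (default 500) fully unrelated offspring are generated from
the program's own observed-genotype marginals (so population structure is
in the null), given the empirical per-locus missingness, and pushed through
the identical pool-evaluation machinery. The offspring's p-value is the
fraction of null maxima at or above its best LOD; Benjamini–Hochberg across
offspring converts p to q, and trios are accepted at q ≤ 0.01. Two
numerical notes: the p-value resolution is `1/null_sim_size` (a warning is
raised if that is coarser than the FDR threshold), and a best LOD above
every null draw reports p = 0 — the honest statement that it is beyond
Monte-Carlo resolution. We considered the analytic alternative (single-pair
null with $p_{\text{adj}} = 1-(1-p_{\text{single}})^{\text{poolsize}}$) and
rejected it after simulation: with realistic pools of $10^6$ pairs it is
simultaneously too liberal at $\hat p_{\text{single}} = 0$ (the best of a
large pool beats any feasible single-pair null sample a few percent of the
time) and, with any nonzero floor, too conservative for everyone.

## Identity resolution and its limits

Samples are compared by the fraction of matching unordered genotypes over
loci called in both (`match_fraction`), with an edge when the fraction is
at least 0.95 over at least `min_shared_loci = 60` loci; connected
components of the edge graph are individual fish. The 0.95 threshold is
the field's operating point for ~90-locus panels and sits in the gap
between duplicate pairs and the closest relatives (full sibs match at
roughly 0.7–0.85), which is why false merges do not occur in any of our
simulations. The threshold's other side deserves honesty: two samples of
the same fish differ per co-called locus with probability
$\approx 2\cdot 2\varepsilon(1-\varepsilon) \approx 0.02$ at
$\varepsilon = 0.005$, so the mismatch count of a two-sample fish is
roughly $\mathrm{Bin}(88, 0.02)$ and exceeds the 5% band with probability
about 3%. A corresponding ~3% of two-sample fish therefore *split* into
two singleton clusters; this is a property of the 95% rule itself at this
error rate, not of the implementation, and the simulation tests measure the
split rate against exactly this binomial tail. Splits are benign for
parentage (both copies of a split parent carry nearly identical genotypes)
but undercount repeat/iteroparous spawners by the same few percent.
Clusters whose members disagree in resolved sex, or contain a pair called
as opposite homozygotes at any locus, are removed with a report.

## The simulator: what it emulates, what it does not

`simulate_population()` runs programs forward season by season: pools are
returning offspring (age at return drawn per lineage × sex over ages 2–6,
reweighted by inversion genotype via an odds multiplier on age-2 return),
scheduled iteroparous returners, and founders topping up to the program
size; spawning happens on ~12 discrete days per season; females are mated
with one or two same-day males per the program's rule; family sizes are
negative binomial (mean 1, dispersion 0.5 — overdispersion stresses the
assignment ranking); strays return to a different program per a
row-stochastic matrix. Observation adds per-gene-copy error, missing
calls, phenotypic-sex errors and unknowns, and spawn-date errors; the
Y-linked marker is only ever wrong through genotyping error, which is also
the only mechanism by which *genetic* sex can be wrong — about 1% of fish
at $\varepsilon=0.005$, and the source of the same-sex "improbable" trios
the pipeline removes.

Default parameter choices (each set once, on field plausibility): lineage
divergence $F_{ST} = 0.1$ between the coastal-derived and local lineages;
age-at-return favoring age 2 in the local lineage (0.65/0.30/0.04/…
females, 0.80/0.18/… males) and age 3 in the coastal lineage (0.12/0.80/…
females); iteroparity female-biased in the local lineage (12% F, 2% M) and
rare in the coastal one (0.2%); repeat spawning male-biased (20% M vs 1–3%
F); 1% total straying; inversion R-allele frequencies 0.15/0.20 with an
age-2 odds multiplier of 1.5 per R copy in the coastal lineage. What the
simulator does **not** model: environmental forcing of return rates,
genotyping batch effects, linkage between loci, family structure in
founders, length–age coupling beyond an age-dependent normal, and
non-random mate choice. Passing recovery tests on this generator therefore
demonstrates the statistical machinery under the stated error model — not
robustness to assay artifacts or demographic misspecification.

## Quality control conventions

* Seasons: dates from July 1 of year $y$ to June 30 of $y+1$ are season
  $y+1$ (spawning runs December–February), so a December spawner and a
  February spawner of one season share a spawn year; the boundary is
  configurable.
* Missing-call filter: a sample is kept when its missing calls are at most
  $\lceil 0.10\,L\rceil$ — with $L = 92$ that is "at least 82 successful
  calls", the convention of record for this panel size.
* Re-genotyped samples keep the most complete row; ties keep the
  latest-loaded and are logged.
* Genetic sex outranks phenotypic sex on conflict (the marker is the more
  objective datum); conflicts are logged because they are exactly the
  metadata errors the unconstrained parentage run is designed to absorb.

## Pedigree-derived summaries

Offspring age is return season minus the parents' mating season, the most
recent season both assigned parents spawned within the allowed age gap (a
rule needed only for iteroparous parents, for whom several shared seasons
can exist; the most recent is the only one consistent with the offspring
also being old enough to return). Straying uses the mating program as
origin and the offspring's first spawn program as return, with column
percentages per origin. Spawning use is classified per fish (once /
repeat / iteroparous / both), with the combined label counted as
iteroparous in use-exclusive tables. Reproductive success credits each
accepted trio to both parents at the mating season and reports per-event
and per-fish means by sex × use. The inversion summary reports karyotype
frequencies (AA/AR/RR), an exact Hardy–Weinberg test per program
(heterozygote-excess $D$ with the Levene–Haldane "selome" two-sided
p-value — the convention that reproduces published analyses of such
tables), and the 1:2:1 segregation test among offspring of AR × AR
matings, substituting an exact multinomial test when any expected cell is
below 5. Program/sex effects on multiple spawning use Kruskal–Wallis
rank-sum tests via `stats::kruskal.test`.

## Validation scales and reproducibility

The test suite validates the exact components against independent oracles
(exhaustive trio-likelihood enumeration at 3 loci to 1e-10; brute-force
Levene–Haldane sums to 1e-10 up to N = 5000; an independent Weir–Cockerham
transcription to 1e-10) and the pipeline against simulated truth at the
default study scale — 4 programs × 200 spawners × 6 seasons, 92 loci,
$\varepsilon = 0.005$, 3% missing — aggregated over 20 seeds for the
recovery and calibration properties, with smaller configurations (60–100
spawners, 4 seasons) for the structural unit tests; these sizes were chosen
so a full validation pass completes on a laptop in minutes. All randomness
descends from a single integer seed per run through `child_seed()`, every
emitted table records its seed, and re-running any stage from persisted
intermediates reproduces identical outputs.

## Known limitations

* Single-parent assignments are classified (mother-only / father-only) but
  not emitted as pedigree links; sibship reconstruction is out of scope.
* The FDR null conditions on pooled missingness patterns, not per-program
  ones, and treats pool composition as fixed (sampling-without-replacement
  effects in small pools are ignored).
* Identity resolution is threshold-based; a likelihood-ratio duplicate
  test would trade the split rate against false merges more gracefully at
  higher error rates.
* With ~90 informative loci the LOD separation between a true parent pair
  and (true parent, unrelated partner) is finite; order one percent of
  accepted trios carry a wrong partner at the 1% FDR operating point, and
  no threshold choice can remove them without costing recall.
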