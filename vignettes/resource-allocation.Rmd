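---
title: "Optimizing genotyping and phenotyping resources for genomic selection"
author: "selectGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing genotyping and phenotyping resources for genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(selectGS)
```

# The problem

Genomic selection trains a whole-genome regression on a phenotyped,
genotyped *training set* and uses it to predict the genetic merit (GEBV) of
selection candidates from markers alone. Its two dominant costs are
genotyping density (how many SNPs) and phenotyping effort (how many
genotypes in the field). `selectGS` implements a workflow for asking, on a
given population, how far both can be reduced: *selective genotyping*
(choosing a low-density marker panel) and *selective phenotyping* (choosing
a core subset of genotypes to phenotype), each evaluated by the prediction
ability they retain.

# The prediction model

All prediction goes through ridge-regression BLUP,

$$ y = \mu \mathbf{1} + X\beta + e,\qquad
   \beta_j \sim N(0, \sigma^2_u),\quad e_i \sim N(0, \sigma^2_e), $$

where $X$ is the column-centered dosage matrix (alternate-allele counts 0/1/2,
centered per marker, not variance-standardized — the conventional RR-BLUP
coding) and every marker effect carries the same prior variance. The BLUP of
$\beta$ at the variance ratio $\lambda = \sigma^2_e/\sigma^2_u$ is

$$ \hat\beta = X^\top (XX^\top + \lambda I)^{-1}(y - \hat\mu\mathbf{1})
            = (X^\top X + \lambda I)^{-1} X^\top (y - \hat\mu\mathbf{1}), $$

with $\hat\mu$ the generalized-least-squares intercept (not the raw mean; the
difference is small but the GLS form is what the mixed model defines). The
two algebraic forms are equivalent; `fitRRBLUP()` uses the $t\times t$ kernel
form when markers outnumber genotypes and the $m\times m$ ridge form
otherwise, and the test suite asserts their agreement to $10^{-8}$.

## Variance components

$\lambda$ is estimated by REML, profiled to a one-dimensional maximization
over $\log\lambda$ on $[\log 10^{-6}, \log 10^{6}]$ via the spectral
decomposition of the intercept-projected kernel (the standard efficient
mixed-model formulation: one eigendecomposition, then each likelihood
evaluation is $O(t)$). `optimize()` is used with tolerance $10^{-9}$; the
restricted likelihood in this parameterization is smooth and in practice
unimodal, and the estimate is cross-checked in the tests against a dense
brute-force profile (grid plus refinement of
$\log|V| + \log|\mathbf{1}^\top V^{-1}\mathbf{1}| + (t-1)\log(r^\top V^{-1} r)$).
Two numerical notes:

* When the profile is flat to machine precision (small noiseless problems
  where the kernel interpolates the data) any optimizer's $\hat\lambda$
  location inside the flat region is arbitrary; both the implementation and
  the oracle then pin to the shared lower search bound.
* A constant phenotype makes the model unidentifiable; the fit degenerates
  explicitly ($\hat\mu = \bar y$, $\hat\beta = 0$, flagged) rather than
  returning spurious components.

The genomic heritability reported by a fit is
$\hat h^2 = \hat\sigma^2_u S / (\hat\sigma^2_u S + \hat\sigma^2_e)$ with $S$
the summed marker variances of the training panel — the model-scale analogue
of the simulator's realized $\mathrm{var}(g)/\mathrm{var}(y)$.

Prediction ability is always the Pearson correlation between observed
phenotypes and GEBVs: `r_cv` inside repeated k-fold cross-validation (the
default design is 20 repetitions of a 10-fold scheme, aggregated over all
fold-level correlations rather than over repetition means — the two differ
negligibly but the convention is fixed), and `r_ev` against an external set
never seen in training. Zero-variance folds are skipped and counted, never
imputed as 0; a correlation of an undefined quantity is an error, not a zero.

# Selective genotyping

Panels are first pruned to approximate linkage equilibrium: a greedy
left-to-right scan per chromosome removes a marker iff its squared dosage
correlation with an already-retained marker inside a trailing window exceeds
a threshold (default $r^2 = 0.95$). The window is 100 consecutive markers by
default, with a base-pair window available when a physical map is present;
the window definition is a documented dialect choice (standard
sliding-window pruners differ here). The earlier
marker of a high-LD pair always wins, making the scan deterministic, and a
post-hoc audit (all retained pairs within a window) is part of the test
suite. Monomorphic markers have undefined correlation; they are defined to
$r^2 = 0$ with a warning and never trigger pruning.

From the pruned count the size schedule keeps a fixed fraction per step —
$s \leftarrow \lfloor 0.30\, s\rfloor$, stopping below 48 markers. Floor is
the only rounding that reproduces the canonical chain
$20{,}242 \to 6072 \to 1821 \to 546 \to 163 \to 48$; smaller panels reuse the
tail of the chain via `restrictSchedule()` (1,044 pruned markers yield
546/163/48). Four strategies then build panels at each size:

* **NRE-MB** — fit once on the pruned set, rank by $|\hat\beta|$, take the
  top $s$ (nested by construction; ties broken toward the earlier marker).
* **NRE-R** — uniform random panels, replicated (1000 replicates at full
  scale; summaries report the mean, minimum and maximum ability).
* **RE-MaB** — like NRE-MB but the model is refit on the current set at
  every step, so the ranking uses re-estimated effects.
* **RE-MoB** — at each size, draw many random subsets *of the current entry
  set*, score each with an evaluator, and keep the argmax as the new entry
  set (ties: first encountered; all candidate scores are retained for
  inspection).

The RE-MoB evaluator is deliberately a *single fixed* k-fold partition
(default k = 5) shared by all candidates in a run: the best-of-random
recursion does not by itself pin down how each candidate model should be
scored, and a shared partition makes candidate scores comparable
while halving cost. Re-drawing folds per candidate would add noise to the
argmax without changing the selection principle. Drawing candidates from the
current entry set (rather than the full pruned set) makes the chain nested,
matching the "winning markers become the new entry set" recursion.

# Selective phenotyping

Genotype reduction works on the identity-by-state distance
$d(i,j) = \tfrac{1}{2m}\sum_k |g_{ik} - g_{jk}|$ (0 for identical inbred
lines, 1 for opposite homozygotes; the companion kinship is $1-d$). Core
sizes for a sampling fraction use nearest-integer rounding with exact .5
ties rounded *down* — the only convention consistent with the canonical core
sizes 45 (20% of 227), 55 and 111 (5% and 10% of 1,107), 113 and 553 (50% of
227 and 1,107). Two single objectives are supported:

* **EN** (maximized): the mean distance from each core entry to its nearest
  other entry — diverse cores that spread across the collection, including
  its extremes.
* **AN** (minimized): the mean distance from *every* accession in the
  collection to its nearest core entry — representative cores that sit at
  cluster centers.

The optimizer is a restarted steepest single-swap local search: from a
seeded random core, apply the best improving swap of one selected against
one unselected genotype until a local optimum, and keep the best of
`nRestarts` (default 10) restarts. This replaces the parallel-tempered
search of dedicated core-selection software with something simpler,
deterministic under a seed, and verifiable: on every instance small enough
to enumerate ($n \le 12$, core $\le 4$) the tests require the exhaustive
global optimum. Nearest-entry ties resolve to the smallest index; the
reported objective is always re-derived from the final subset.

# The experiment drivers

`runStrategyComparison()` crosses strategies with the size schedule
(plus an all-markers baseline row); `runTSSizeSweep()` crosses EN/AN/random
cores with training-set fractions (random cores summarized as mean/min/max,
the Ra/Rmin/Rmax convention); `runGrid()` crosses RE-MoB panel sizes with AN
core fractions. In the grid, marker selection is re-run *inside each core*:
selecting markers on the full population and then shrinking the training set
would leak information from genotypes that are supposed to be unphenotyped,
so the leakage-safe reading is used even though it is the more expensive
one. `runPipeline()` chains load/simulate → filter → impute → prune →
schedule → strategies (→ sweep) from one configuration, writes every
intermediate artifact, and records seeds, timings and versions in a JSON
manifest; reruns reproduce result files byte for byte.

One global seed is expanded into named substreams (simulation, folds,
random panels, RE-MoB draws, core restarts), so changing how many draws one
stage consumes never shifts another stage's stream.

# The synthetic populations

Because the real datasets behind this workflow are external and large, the
package ships a generator for three archetypes at analysis scale, and the
defaults are the study conditions the workflow targets:

* **RIL** — 137 F5-derived biparental recombinant inbred lines on a ~3k SNP
  panel: F1 between two inbred founders, then 4 rounds of selfing with
  crossovers as a Poisson process on a 20-chromosome, 120 cM-per-chromosome
  genetic map (Haldane mapping, no interference — the simplest defensible
  meiosis model; nothing in the workflow depends on interference).
* **MULTIFAM** — a 227-line breeding panel: 5 biparental families bred from
  a shared founder pool by the same F1-plus-selfing process.
* **GERMPLASM** — a structured collection, 300 accessions by default
  standing in for a much larger germplasm bank: subpopulation allele
  frequencies follow a Balding–Nichols model (ancestral frequency
  Uniform(0.1, 0.9); subpopulation frequency
  Beta$(p(1-F_{st})/F_{st}, (1-p)(1-F_{st})/F_{st})$, default $F_{st}=0.15$
  over 3 subpopulations), and each accession's two haplotypes are
  independent block mosaics of 16 founder haplotypes per subpopulation
  (geometric block length, mean 20 markers). Block mosaics give tunable
  $r^2$ decay for the pruning stage at desk scale, which a full coalescent
  simulation would not add much to here; independent haplotype draws give
  Hardy–Weinberg genotype frequencies within subpopulations.

Phenotypes are additive: `nQtl` markers (default 100) get effects
$N(0,1)$; breeding values are centered-dosage sums; the residual variance is
set from the realized genetic variance so that
$\mathrm{var}(g)/(\mathrm{var}(g)+\mathrm{var}(e))$ equals the target $h^2$
(default 0.5; $h^2=1$ means zero residual, $h^2=0$ means pure unit-variance
noise with the breeding values still recorded). QTL are markers by default;
a `hiddenQtl` flag drops them from the returned panel to emulate incomplete
LD between panel and causal loci. The trait intercept defaults to 0.

What the generator does *not* emulate: multi-environment trials and
across-environment BLUP (it emits one value per genotype), dominance and
epistasis, genotyping error, and the allele-frequency spectra of real
genotyping platforms. Tests passing on these populations therefore
demonstrate that the machinery is correct and that the qualitative orderings
(effect-ranked panels inflate cross-validated ability; best-of-random panels
beat the worst random panels; representative cores beat the worst random
cores; ability rises with heritability and training-set size) emerge under
the stated generating assumptions — not that any particular real population
will reproduce a given number.

# Problem sizes and stochastic checks

The test suite and the acceptance script run at analysis scale (hundreds of
genotypes, a few hundred to two thousand markers, tens of candidate models),
sizes chosen so the full suite exercises every driver end to end in a few
minutes while leaving the estimators in their well-behaved regime.
Properties of stochastic quantities are asserted at the level at which they
are statistically decidable: near-deterministic properties (FST recovery,
RIL heterozygosity, exhaustive-optimum equivalence, best-of-random
dominating the worst random panel under a shared evaluator) per replicate,
and noisy ones (null cross-validation ability, heritability recovery, the
training-set-size trend) on across-replicate averages — e.g. the
per-replicate REML $\hat h^2$ sampling SD at $n = 400$ is about 0.1, so its
±0.15 recovery band is a statement about the mean, not about every draw.

# Known limitations

* RR-BLUP only: no Bayesian alternatives, pedigree GBLUP, fixed covariates
  beyond the intercept, or non-additive terms.
* Mean imputation of missing dosages (haplotype-aware imputation is out of
  scope); biallelic SNPs only.
* The core optimizer's single objectives (EN, AN) — no allele-coverage or
  multi-objective weighting.
* The greedy pruner is a single pass, as in standard sliding-window tools;
  it does not iterate to a global fixed point across windows.
* External-validation ability on small validation sets (tens of genotypes)
  is intrinsically noisy; compare strategies on replicated summaries, not
  single r values.
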