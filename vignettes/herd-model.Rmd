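---
title: "A deterministic model of national dairy selection and crossbreeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic model of national dairy selection and crossbreeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdsim)
```

`herdsim` simulates the New Zealand-style national dairy population as a set
of deterministic cohorts — no individual animals, no stochastic demography —
and asks how within-breed index selection and between-breed mating policy
jointly move the herd's genetic merit and breed composition over decades.
This vignette is the package's account of the model: what is assumed, which
knobs matter, and what the defaults do and do not represent.

## The selection machinery

Merit is economic. The aggregate genotype of an animal is
$T = \sum_j v_j G_j$ over milk volume, fat, protein and liveweight, with
default economic values $v = (-0.05, 0.47, 4.054, -0.427)$ NZ\$ per L or kg.
Breeding worth, $\mathrm{BW} = \sum_j v_j \,\mathrm{EBV}_j$, is its estimate.
Milk volume and liveweight carry negative values: volume attracts a
processing penalty, and liveweight's feed cost for maintenance exceeds cull
revenue.

The genetic covariance matrix is not treated as a free set of constants.
Published parameter estimates for these traits vary widely; what the model
pins down instead is the SD of the aggregate genotype. We therefore start
from literature-ballpark genetic SDs (450 L, 18 kg, 14 kg, 25 kg),
heritabilities (0.30, 0.30, 0.30, 0.35) and genetic correlations
(milk–fat 0.55, milk–protein 0.85, fat–protein 0.65, 0.25–0.30 with
liveweight), then rescale all genetic SDs by one factor so that
$\sigma_T = \sqrt{v' G v}$ equals NZ\$26 exactly. The calibration anchor is
the source of truth; the starting SDs only set relative proportions. The
phenotypic matrix follows from the heritabilities with slightly attenuated
correlations, and is validated to leave $P - G$ positive semi-definite.

Selection acts by truncation across overlapping age classes: a single
threshold $x^*$ is solved by bisection (absolute tolerance $10^{-8}$ NZ\$)
such that the expected count above it, summed over candidate pools that are
normal with mean equal to the cohort's estimated worth and SD
$\sqrt{r}\,\sigma_T$, equals the number required. Classes with zero SD are
all-or-nothing; exact ties at the threshold split proportionally, which
keeps the solver total-exact and deterministic. Realized per-class
intensities $i = \phi(z)/\bar\Phi(z)$ feed the response formula
$\Delta_j = i \sqrt{r} \,(Gv)_j / \sigma_T$ — the regression of trait values
on the index. Reliabilities come from the repeated-records formula for cows
(lactations accumulate with age; the index repeatability is collapsed to a
single 0.55) and the half-sib progeny-test formula for bulls (74 daughters,
reliability ≈ 0.86 at proving). Parent-average information is deliberately
excluded: an unrecorded animal has zero reliability.

Fractional animals are allowed throughout; integer rounding happens only in
reporting. There is no Mendelian-sampling variance reduction from selection
(no Bulmer effect) and no inbreeding accounting — both are outside the
model's scope and would slightly lower the predicted long-run gain.

## Crossbreeding

Breed ancestry is carried as continuous gene fractions of F, J and A that
sum to one; progeny take the parental midpoint. Heterosis is parameterized
by expected breed-of-origin heterozygosity $h = 1 - \sum_b s_b d_b$ — an
expected-heterozygosity rule rather than a dominance-coefficient model — and
adds $h \cdot \delta_j \cdot (\text{parental mean})_j$ to phenotypes, with
default fractions $\delta$ of 4.8–5 % for yields and 3 % for liveweight.
Heterosis is phenotypic only; it does not enter genetic means or breeding
worth. Closed forms anchor the property tests: two-breed rotations converge
to 2/3 retained heterozygosity, three-breed rotations to 6/7, and upgrading
halves every non-target fraction per generation.

Animals are labelled for reporting by the 7/8 rule (boundary inclusive): a
cohort is "J" at $f_J \ge 7/8$, a two-breed cross when the top two fractions
jointly reach 7/8, otherwise "multi". The same purity bound doubles as the
bull-mother eligibility rule, together with at least three consecutive
generations of artificial-breeding sires on the maternal side. The
AB-generation counter is capped at 3 in state, since only "at least 3"
matters, and resets to 0 after a natural-service mating.

## Demography and the bull pipeline

Cows occupy ages 2–10 with annual survival 0.83 (both configurable); the
base population sits at the implied equilibrium age structure. Total cow
places grow geometrically at 1.5 %/yr. Aging is an exact accounting
identity: survivors move up one class, the oldest class exits, and
replacements — sired by the mating plan of two years earlier, the seasonal
gestation-plus-rearing lag — enter at age 2 as the balancing item.

Young bulls enter the pipeline at age 1 with midparent merit: dam side from
bull mothers chosen by truncation over eligible cohorts (6.6 contract
matings per young bull), sire side from the 3 best proven bulls at ages 5–7,
dead or alive — stored semen of dead proven bulls remains usable for this
elite pathway only. Proving happens at age 5, when reliability jumps to the
progeny-test value; commercial teams are the top live proven bulls at ages
5–7, sized by semen demand at 100,000 doses per bull per year. The number of
young bulls tested per breed is ten times the anticipated team size
(`test_ratio = 10`), reflecting that a progeny-test scheme tests an order of
magnitude more bulls than it graduates; without this multiple the
sire-to-breed-cows pathway would carry no selection intensity at all. The
cow-to-cow pathway carries none by design — its selection differential is
treated as negligible — but its generation interval still dilutes annual
gain, as the Rendel–Robertson aggregation in `pathway_contribution()` makes
explicit.

A run starts with the bull pipeline at the steady state implied by zero
prior selection, so the first four years show rising gain while selected
cohorts fill the teams. This burn-in is a modelling statement, not an
artifact to hide: a real scheme switching policy would experience the same
lag.

## Mating strategies and allocation

Nine strategies cover the policy space: straightbreeding, upgrading to each
breed, three two-breed rotations, the three-breed rotation, and best-bulls
(every commercial cow to the top team on breeding worth regardless of
breed). Allocation is deterministic and ordered: straightbred floors first —
at least 44,000 cows per breed mated within breed, taken from the
highest-worth straightbred cohorts, preserving a bull-mother nucleus — then
the artificial-breeding fraction of each cohort per the strategy, then
natural service.

Two demographic choices deserve emphasis because they are the package's own,
not published constants. First, `ab_fraction = 0.70`: 70 % of matings use
AB sires per the strategy, the remainder unselected natural-service bulls of
the cohort's own composition. The AB-ancestry bookkeeping in the
bull-mother rule only has meaning if natural matings exist, and a ~30 %
natural-service share is the New Zealand norm of the period. Second,
rotation phase is tracked per cohort via the last AB sire breed; foundation
crossbreds enter the rotation at the breed of their minority gene fraction.
Cohorts — keyed by (label, AB-generation bucket, last sire breed, age) — are
the simulation unit, so progeny of one year that share a key merge with
count-weighted composition and merit. This keeps the state bounded
(~10²–10³ cohorts) at the cost of within-label composition spread.

## What the defaults represent

The shipped base year is a 3.2-million-cow population with label shares
F 0.60, J 0.24, F×J 0.13, A 0.03 and base breed merits (deviations from the
1996 reference) of F (+150 L, +1, +4, +25 kg), J (−550, +1, −6, −80) and
A (−250, −6, −6, −30). These are documented assumptions chosen so that
Jersey holds the top 1996 breeding worth (≈ +NZ\$39 over F, mostly from its
lower volume and liveweight at similar fat), while F leads milk volume and
liveweight — the ranking that makes best-bulls equivalent to gradual
Jersey-ward conversion. Age-adjustment factors (0.80 at age 2 rising to 1.0
at maturity, 0.97 at 9+) and a mature phenotype base of 3700 L / 170 kg /
130 kg / 450 kg complete the phenotypic layer.

Because the model is cohort-based and deterministic, runtime is independent
of the cow count; full national scale is used everywhere, including tests.
A 23-year national run takes a few seconds. The absolute 44,000-cow floor
only makes sense at national scale — at toy scales it would swallow the
whole herd, which the allocator flags as an infeasible-floor warning.

## Sensitivity and known limitations

The headline composition outcome — how much of the herd sits in the F×J
label versus the J label after two decades of best-bulls mating — is
governed by the product of replacement rate, AB fraction and the labelling
bound. With survival 0.83 (≈ 22 %/yr replacement) and AB fraction 0.70, an
average maternal lineage accumulates roughly 2.5 Jersey backcrosses by
2018; three backcrosses reach the inclusive 7/8 bound, so the bulk of
F-origin lineages cross into the J label within the horizon and the F×J
label peaks near 60 % around 2006 before draining into J. Lower effective
exposure (≈ 0.4 crosses per generation) or a stricter reporting bound
(15/16) would instead hold half the herd in the F×J label in 2018. Users
studying composition trajectories should treat `ab_fraction`, survival and
`label_threshold` as first-order controls; all are configurable.

The same gene-flow rate dominates the national liveweight trend (the J−F
base difference is −105 kg, so each percent of herd-level gene flow toward J
moves mean liveweight by about −1 kg) and, to a lesser degree, the fat
trend. The within-breed gain, by contrast, is robust: ≈ NZ\$6.9/yr of
breeding worth at steady state, split across traits in proportion to
$(Gv)_j$.

The fixture module generates scaled base populations (with a small seeded
merit jitter so selection is non-trivial in toy herds) and synthetic
"actuals" tables with injected linear trends for exercising the reporting
layer. These fixtures emulate the *format* and first moments of national
statistics, not their serial correlation, management-driven level shifts,
or payment-system history — passing recovery tests shows the estimators are
correct, not that real industry series behave this simply.

Not modelled, by scope: genomic selection, fertility and survival as
breeding-objective traits, environmental/herd-year effects (predicted
phenotypes have no annual fluctuations), inbreeding, the Bulmer effect, and
individual-animal mate allocation.
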