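---
title: "Modelling somatic incompatibility in basidiomycete fungi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling somatic incompatibility in basidiomycete fungi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basidioSI)
```

## The problem

Mycologists delimit fungal individuals by pairing isolates on a plate:
genetically distinct mycelia fuse and then kill the fusion cell — somatic
incompatibility (SI) — while clonal isolates merge into one network. In
basidiomycetes this practice hides a puzzle. The dominant life stage is
the heterokaryon, a mycelium whose every cell carries **two** genetically
different haploid nuclei in one cytoplasm, and SI is observed *between*
heterokaryons. Any recognition mechanism based on direct interaction of
allelic products would fire inside the heterokaryon itself; any mechanism
switched off outside the heterokaryotic stage cannot explain why fusion
cells between sexually compatible homokaryons are nevertheless seen to
die. `basidioSI` implements, as executable models, the resolution in
which nonself recognition works through post-translational modification
(a reader/writer system) at every life stage, and matings succeed anyway
because nuclear migration lets nuclei escape the dying fusion cell.

The package has three layers — compatibility genetics, reader/writer
kinetics, and lifecycle adjudication — kept deliberately independent, so
each can be interrogated on its own.

## Compatibility genetics

An incompatibility locus is a set of allele labels with population
frequencies (`locus()`); a haploid nucleus carries one allele per locus;
a mycelium carries 1–3 nuclei. The compatibility predicate is allele-set
equality: two mycelia are compatible iff at every locus they carry
identical *unordered* sets of alleles (`is_compatible()`). This single
rule reproduces the characteristic observations: a heterokaryon is
compatible with itself, `A1/A2` matches `A2/A1`, a homokaryon never
matches a heterokaryon, and two heterokaryons sharing a common nucleus
(`A+B` vs `A+C`) are incompatible. Because set equality is transitive,
compatibility partitions any collection of isolates into exact
compatibility groups — the "individuals" of an SI survey.

Genotypes are kept as **ordered** nucleus pairs internally
(`enumerate_heterokaryons()`), so the 4×4 and 9×9 compatibility tables
for uniform bi- and triallelic loci come out row-for-row in the
conventional layout, while the predicate itself uses unordered sets.

For a locus with frequencies $p_1,\dots,p_k$, the probability that two
independently assembled heterokaryons carry equal allele sets is

$$f = \sum_i p_i^4 \;+\; \sum_{i<j} 4\,p_i^2 p_j^2
    \;=\; 2\Bigl(\sum_i p_i^2\Bigr)^2 - \sum_i p_i^4 ,$$

the first term matching homozygous pairs, the second the $2 \times 2$
orderings of a shared heterozygous set. At uniform frequencies this is
$(2k-1)/k^3$: 37.5% for $k=2$, $15/81 \approx 18.5\%$ for $k=3$.
Unlinked loci segregate independently, so per-locus fractions multiply;
two uniform triallelic loci already leave only
$(15/81)^2 \approx 3.4\%$ of random heterokaryon pairs compatible (97%
incompatible). Three routes to the same number are exposed and tested
against each other: the closed form (`compatible_fraction_analytic()`),
exact enumeration over the genotype space
(`compatible_fraction_enumerate()`, the brute-force oracle), and Monte
Carlo sampling (`compatible_fraction_mc()`) with binomial standard
errors for spaces too large to enumerate. Enumeration groups genotypes
by their allele-set signature, which turns the double sum over ordered
genotype pairs into a sum of squared class masses — algebraically
identical, linear cost. It still refuses spaces above a configurable cap
(default $10^6$ ordered pairs) to keep memory predictable; the Monte
Carlo path is the escape hatch.

`sibling_cohort()` models the offspring of one fruiting body: spores
take either parental allele per locus with probability 1/2, so the
cohort is the same enumeration with half-frequencies — which is why a
single segregating biallelic locus already makes 62.5% of sibling
heterokaryon pairs incompatible. Mating-type constraints on which
siblings can actually mate are deliberately ignored in these fractions
(they are a property of the mating system, not of the recognition
system); a mating-compatibility flag exists only in the lifecycle layer.
`population_si_survey()` wraps the predicate into the field workflow:
sample isolates, score all pairs, count compatibility groups, and report
the false-clonemate rate, whose expectation is the analytic fraction —
a direct estimate of how often an SI survey mistakes distinct genotypes
for one individual.

## Reader/writer kinetics

The recognition mechanism itself is modelled as mass-action kinetics in
one (possibly fused) cell. Each allele $i$ of the locus encodes a
bifunctional reader/writer protein $R_i$ and has a cognate target pool;
$U_i$ is the **unmodified** part of that pool. Writing marks targets as
self; reading detects unmarked cognate targets and feeds an integrating
death signal $S$:

$$\frac{dR_i}{dt} = \alpha\,[i\ \text{present}] - \delta_R R_i,\qquad
  \frac{dU_i}{dt} = \beta - k_w R_i U_i - \delta_T U_i,\qquad
  \frac{dS}{dt} = \sum_i k_r R_i U_i - \delta_S S,$$

with death when $S$ first reaches the threshold $\theta$. Thresholded
death effectors are the norm in programmed cell death, and the threshold
is what makes the whole account work: it separates the slow trickle of
signal in a growing heterokaryon from the spike caused by cytoplasmic
mixing. Design choices, made once and documented here because no
published rate measurements exist for this system:

* **Targets are produced constitutively in every cell** ($\beta$ per
  allele), whether or not the matching nucleus is present: the targets
  are ordinary cytoplasmic proteins, and it is precisely the unmodified
  *foreign-cognate* pool accumulating to $\beta/\delta_T$ that makes a
  cell lethal to fuse with.
* **Reading does not consume the target.** Whether detection sequesters
  the target is unknown; the non-consuming choice is the more
  conservative one (it maximises the signal a given unmodified pool can
  generate) and needs no extra parameter.
* **Readers act only on their own cognate targets** — per-allele pools,
  no cross-talk.
* **Defaults** (arbitrary units): $\alpha = 1$, $\delta_R = 0.1$,
  $\beta = 1$, $\delta_T = 0.05$, $k_w = 0.2$, $k_r = 1.0$ — the reader
  five times more active than the writer — and $\delta_S = 0.5$. The
  5× ratio is the one quantitative anchor the biology provides; the
  remaining rates are round numbers giving protein-like separation of
  timescales (reader lifetime 10 time units, target lifetime 20, signal
  lifetime 2).
* **The threshold is calibrated, not asserted.**
  `calibrate_death_threshold()` runs the two canonical scenarios with
  the threshold suppressed — fertilization of homokaryon A by a
  migrating B nucleus (no cytoplasmic mixing) and fusion of AB with AC
  heterokaryons (equal-volume mixing) — and sets $\theta$ to the
  geometric mean of the two signal peaks ($\approx 57.7$ under the
  defaults, between the fertilization peak $\approx 46.8$ and the fusion
  peak $\approx 71.1$). Any parameter set whose two peaks differ
  therefore yields the qualitative contrast by construction;
  `death_margin()` reports the margin and flags parameter sets where the
  ordering breaks (it can — e.g. a 100-fold hotter reader with $\theta$
  held fixed — and that is reported, not raised).

Under the defaults the four canonical outcomes follow without further
tuning: fertilization survives ($S$ peaks below $\theta$ as the incoming
writer gradually marks its accumulating targets); heterokaryon ×
heterokaryon fusion dies fast (each side's stockpiled foreign-cognate
targets, $\beta/\delta_T = 20$ per absent allele, meet the other side's
concentrated readers); homokaryon × homokaryon fusion also dies, but
later (death at $t \approx 0.96$ vs $0.59$ — mixing halves the reader
concentrations and each side brings only one reader species), matching
the microscopy reports of slower homokaryon fusion-cell death; and an
identical-karyotype fusion blends two identical steady states and never
leaves them — self is never rejected.

Numerics: fixed-step classical Runge–Kutta (via `deSolve`, method
`"rk4"`), default `dt = 0.01` and `t_max = 200`, which resolves the
fastest default relaxation ($k_w R^\ast \approx 2$ per time unit) with
step error far below the $10^{-6}$ relative tolerance asserted in the
convergence test. Threshold crossing is localized by linear
interpolation inside the step; death is absorbing, so the trajectory is
frozen from the crossing on. Concentrations more negative than
$-10^{-9}$ abort with advice to reduce `dt`; smaller excursions are
clamped to zero. The mixing fraction `phi` defaults to 0.5 (equal
volumes); the steady state is available in closed form and is verified
to be a fixed point of the integrator. The modified-target pool is not a
state variable — only $U_i$ enters the equations — but mass balance
($\beta t$ = unmodified + written, with decay off) is checked in the
tests by quadrature.

## Lifecycle adjudication

`fusion_cell_fate()` encodes five candidate recognition mechanisms as
fate rules for an anastomosis, and `adjudicate()` scores each against
six observations any mechanism must reproduce: the standalone
heterokaryon is viable (C1); distinct heterokaryons show SI (C2);
homokaryon × homokaryon matings succeed (C3); Buller
(heterokaryon × homokaryon) matings succeed (C4); fusion-cell death
nevertheless occurs in homokaryon matings (C5); common-nucleus
heterokaryon pairs show SI (C6).

* *Allelic / non-allelic interaction*: death whenever the merged
  cytoplasm is polymorphic at a locus — which already kills the
  heterokaryon itself (fails C1).
* *Heterokaryon-only differential expression*: recognition products are
  present only in heterokaryotic cells. We score a fusion as recognized
  when **at least one** participant is heterokaryotic and the allele
  sets differ: the heterokaryotic partner's cytoplasm arrives preloaded
  with readers and targets, so a Buller fusion cell is recognized even
  though the homokaryon partner expresses nothing. Two homokaryons,
  by contrast, fuse unrecognized. The model therefore predicts no
  homokaryon fusion-cell death (fails C5, contradicting the microscopy)
  and, lacking any escape mechanism, failed Buller matings (fails C4).
  A variant in which differential expression is *combined* with
  migration escape is conceivable but is not one of the five candidate
  rule sets adjudicated here.
* *Reader/writer PTM*: death iff the partners' allele sets differ —
  exactly `is_compatible()`. Alone it fails C3/C4 (every mating's
  fusion cell dies with no way out); combined with nuclear migration it
  passes all six.

Migration follows the topology of the mating reaction: nuclei migrate
only *into* homokaryons (reciprocally between two homokaryons,
unidirectionally into the homokaryon of a Buller mating, not at all
between heterokaryons — which is why heterokaryon SI is a true barrier).
The race between migration and death is modelled minimally: migration
initiation is exponential with rate $r$ per fusion cell, death is
deterministic at $t_d$ (taken from the kinetics when `rw_params` are
supplied, per locus, else from the scenario), so with $N$ independent
fusion cells

$$P(\text{escape}) = 1 - \bigl(1 - (1 - e^{-r t_d})\bigr)^N .$$

One escaping nucleus suffices: once past the fusion cell it carries no
cytoplasm, so migration itself triggers nothing. In the low-migration
regime ($r t_d \ll 1$) the expected number of successful heterokaryotic
sectors is $\approx N r t_d$ (`tuft_count_expectation()`) — small but
positive, the "few tufts" phenotype of species with little nuclear
migration. In a Buller mating the migrating nucleus is drawn uniformly
from the heterokaryon's two haplotypes; the biology does not specify
the choice and nothing downstream depends on it.

## Synthetic data, test scale, and limitations

The package needs no external data: all acceptance-relevant inputs are
tiny (printed tables, allele counts, the 5× ratio), and
`generate_fixtures()` creates deterministic synthetic inputs — random
loci with 2–4 alleles, a 12-isolate population with one planted clonal
pair, the four canonical pairing scenarios, and the default kinetic
parameters. The generator emulates idealised study conditions:
Hardy-Weinberg-style independent draws of nuclei, exact allele
frequencies, no linkage, no population structure, no genotyping error.
Passing tests therefore validate the combinatorics and the model logic,
not the messiness of real isolate collections (where relatedness and
mating-type constraints bias which heterokaryons exist).

Test problem sizes were chosen so the whole suite runs in well under a
minute: enumeration properties use up to 5 alleles × 3 loci, Monte Carlo
checks use $10^4$–$10^6$ draws against 4-standard-error bands, the
migration-race simulation uses $10^5$ replicates, and the random-kinetics
non-negativity sweep uses 100 parameter draws with steps sized to each
draw's fastest relaxation rate.

Known limitations, all deliberate: no spatial structure (a fusion cell
is one well-mixed volume; colony-interface geometry and the number of
anastomoses enter only through $N$); no stochastic chemical kinetics; no
prion-like conformational dynamics; no transcription/translation delay;
no linkage between loci; no evolutionary dynamics of allele frequencies
(balancing selection is background, not simulated); mating types are a
boolean, not modelled loci. The kinetic parameters are order-of-magnitude
choices — the package's claims are the *orderings* (fertilization
< threshold < fusion; homokaryon death slower than heterokaryon death),
which are calibration-stable, not the absolute times.

## A worked session

```{r example}
# 97% of random heterokaryon pairs incompatible at two triallelic loci
two <- compatible_fraction_analytic(list(uniform_locus(3, "L1"),
                                         uniform_locus(3, "L2")))
format_percent(two$incompatible_fraction, 0)

# the calibrated kinetic contrast
death_margin(rw_params())

# and the adjudication of the candidate mechanisms
adjudicate_all()
```
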