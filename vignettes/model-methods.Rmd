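---
title: "Model and methods: simulating B16-OVA melanoma immunotherapy on a hexagonal lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological scenario

B16-OVA is a poorly immunogenic murine melanoma transduced with chicken
ovalbumin as a model tumor antigen.  Injected subcutaneously it grows
unchecked; neither agonist anti-CD137 (4-1BB) antibody nor adoptive
transfer of OVA-specific OT-1 CD8 T cells controls it as monotherapy, but
a single combined administration of both on day 3 rejects it almost
completely by day 20.  CD137 is also expressed on tumor endothelium, where
its ligation promotes CTL entry into the tumor — so the therapy acts on
two fronts: it arms the effector cells and opens the door to the tumor.

`b16ovasim` is a stochastic agent-based model of this scenario.  A
two-dimensional tissue section carries individual immune-cell agents and
per-site molecule quantities on a hexagonal lattice; tumor cells grow by a
fitted Gompertz law; the six treatment arms (control, anti-CD137, naive or
activated OT-1, and both combinations) are simulated as seeded, replicable
experiments, plus an endothelial-CD137-knockout scenario that cannot be
realized in a wet lab.

## Space and time

The tissue is an `L x L` hexagonal lattice: six neighbors per interior
site, periodic left/right, rigid walls top and bottom.  The full-scale
reference is `L = 946` for 60 mm x 60 mm of tissue; the package's working
default is `L = 200` representing the same tissue at coarser resolution
(0.3 mm sites), with agent densities, doses and the per-site tumor
capacity rescaled by the area ratio.  All interactions are site-local: a
rule only ever reads and writes entities co-located on one site at the
start of the 8-hour timestep.  The 8-hour step is shorter than every
characteristic time in the model (the fastest half-life, IL-2 and
chemoattractant at 1.6 days, is ~5 steps).

Cells hop between neighboring sites; mobile agents take
`moves_per_step = 8` hops per 8-hour step, matching lymphocyte motility of
order 10 um/min at the 0.3 mm site pitch.  Molecules spread by
conservative integer diffusion (each site exports a binomial fraction of
its quanta, split multinomially among neighbors) applied in several
rounds per step — molecular diffusion covers millimeters in 8 hours, so
molecules must move faster than cells.  Chemoattractant uses 6 rounds,
IL-2 and antigen 2, antibody 3.

## Entities

Eight leukocyte types (B, TH, TC, cDC, M, EP, NK, P) are individual
agents with a type, a state (naive, active, presenting on MHC-II or on
both classes, duplicating, plasma-secreting), a bit-string receptor, a
lattice position and phenotype flags.  Initial densities per microliter
(B 260, TH 200, TC 434, cDC/M/EP/NK 351, P 0) are mapped to agent counts
by a single `density_scale` (about 2 x 10^4 resting leukocytes at
L = 200).  Every cell dies stochastically with a 3.3-day half-life
(`1 - 2^(-dt/h)` per step) and the bone marrow refills each type toward
its initial census.  Plasma cells are never replenished.  NK cells exist,
move and decay but have no interaction rule — a documented placeholder,
not an inference about their biology.  Plasmacytoid DCs are deliberately
absent; only conventional DCs present antigen.

Tumor cells are a special case: they never move, all carry the same MHC-I
peptide, and at full scale they number in the millions.  The engine
therefore stores them as per-site integer counts with a per-site capacity
(8 cells at the 63-um full-scale site, rescaled with site area), rather
than as agent rows.  Their half-life is 10 years — effectively immortal;
only cytotoxic killing removes them.

Molecules are integer quanta per site: IL-2, chemoattractant and
anti-CD137 as plain fields; IgG, antigen and immune complexes carry a
receptor tag (sparse site/receptor/quantity triplets).  Quanta decay by
the same half-life law (IL-2 and chemoattractant 1.6 d, immune complexes
and antigen 4 d, IgG and anti-CD137 23 d).

## Specific recognition: the bit-string repertoire

All specific binding — TCR vs presented peptide, BCR and antibody vs
antigen epitope — is a comparison of `nbit_str = 12`-bit strings, a
potential repertoire of 4096 receptors.  "Match" is bitwise
complementarity (XOR popcount), the lock-and-key convention of the
cellular-automaton immune-simulation lineage this model belongs to; an
equality convention is available behind `match_mode = "identity"` since
the literature uses both and the choice is not dictated by the scenario.

Binding probability is zero below `min_match = 9` complementary bits,
`affinity_level = 0.05` at exactly 9, and interpolates geometrically up to
1 at a perfect match:

    p(m) = affinity_level^((nbit_str - m) / (nbit_str - min_match))

The geometric form is the one-parameter curve that is exact at both fixed
endpoints and monotone in between.  Antibody lineages hypermutate: each
bit of a plasma daughter's receptor flips independently with probability
`hyper_mut = 1e-4` per step.

T-cell precursors pass thymic negative selection: a thymocyte whose best
match against the simulation's self-peptide panel reaches `min_match` is
deleted with probability `thym_eff = 99.9%`.  The panel is drawn once per
simulation; its default size is 6.  This size is a deliberate choice: with
12-bit complementarity matching, a random receptor pair is reactive with
probability 299/4096 ~ 7.3%, so a panel of `k` self peptides makes a
fraction `1 - (1 - 0.073)^k` of thymocytes self-reactive.  At `k = 6`
about 37% are deleted and the released autoreactive fraction is ~0.06%,
comfortably below the 0.1% physiological bound on circulating
autoreactive TH cells; at `k = 16` the bound would be violated (~0.24%
released).  Selection applies to both TH and TC precursors by default
(`select_tc` restricts it to TH).  Transferred OT-1 cohorts bypass the
thymus: every member carries the exact bit-complement of the OVA peptide.

## Tumor growth

Melanoma growth follows the two-parameter Gompertz law
`dx/dt = x (a - b ln x)` — a growth factor that decays in time against a
constant mortality factor, with carrying capacity `K = exp(a/b)` and the
sigmoid closed form `x(t) = K exp(ln(x0/K) exp(-bt))`.  The simulator
advances it by forward Euler at `dt` = 1 step, introducing
`w = x_{t+1} - x_t` newborn cells per step; the fractional part of `w` is
carried between steps so no growth is lost to rounding, and the increment
is clamped at zero at or above `K`.  Newborns are placed innermost-first
onto tumor sites with spare capacity, then spill onto the nearest empty
ring, producing the compact expanding disk seen in tissue sections.

The injection of 0.5 x 10^6 cells engrafts `x0 = 200000` (60% die before
settling).  Under the disk model — a tumor of diameter `d` holds
`(d / d_cell)^2` cells of diameter `d_cell = 20 um` — sacrifice at
450 mm^2 corresponds to 1.125 x 10^6 cells.  Because no caliper series is
deposited, the shipped `(a, b) = (0.1364, 0.00884)` per 8-hour step are
anchored to the published endpoints: the sacrifice threshold is crossed
near day 29, inside the 25-33-day window, with `K = 5 x 10^6` cells
(still far from saturation at sacrifice, matching the steadily rising
observed curves).  `scripts/calibrate_growth.R` derives these numbers.

`fit_gompertz()` recovers `(a, b)` from caliper series by
Levenberg-Marquardt least squares on log counts with `x0` fixed, pooling
several mice that share the growth law when a `mouse` column is present.
`generate_growth_fixture()` emulates the undeposited measurements:
closed-form diameters, each the mean of two perpendicular caliper reads
carrying lognormal noise (`noise_cv` per read), optionally for a cage of
`n_mice`.  Recovery is exact to <1% on noise-free series.  With 5%
caliper noise a single 10-point series identifies `b` only to ~25-30%
median error — the curve is near-exponential over a 30-day window, so the
deceleration parameter is weakly identified from one mouse; the package's
recovery claim (<10% median error over 100 seeds) therefore refers to the
study's actual design, a pooled cage of six mice, and the fixture
generator produces exactly that.

## The interaction rules

The six canonical rules, each firing with the bind probability of the
relevant receptor pair:

1. **B-TH help.** A TH meeting a B cell presenting on MHC-II enters the
   duplicating state and secretes IL-2; the B cell duplicates, its
   daughters differentiating into plasma cells (with hypermutated
   receptors).
2. **M-TH help.** As above with a presenting macrophage; TH side only.
3. **cDC antigen capture.** A cDC co-located with antigen internalizes a
   quantum with probability 2 x 10^-2 per step and cross-presents the
   peptide on MHC-I and MHC-II.  Macrophages do the same at 10^-2
   (antigen) and 10^-1 (immune complexes), MHC-II only; B cells bind
   antigen through their receptor at 10^-2 times the bind probability.
4. **TC priming.** A naive TC meeting a cross-presenting cDC becomes
   activated.
5. **TC kill.** An effector TC (active or duplicating) on a tumor site
   contacts up to `kill_contacts` tumor cells; each contact kills with
   probability `bind x base_kill_prob x cd137_kill_mult^boosted x f(IL-2)`
   where `f` is a saturating IL-2 factor with a floor (below).  Killed
   cells release antigen debris; successful killers secrete IL-2 and may
   re-enter duplication (restimulation).
6. **Anti-CD137 boost.** An activated TC co-located with an antibody
   quantum consumes it and is permanently boosted: cytotoxicity,
   duplication rate, chemotaxis sensitivity — and survival — are
   multiplied.

Two readings of rule 5's IL-2/anti-CD137 requirement are possible; strict
conjunction would make the activated-OT-1-monotherapy arm identical to
control, contradicting the observed partial effect.  The package
therefore reads IL-2 as a stimulatory factor
(`floor + (1 - floor) * q/(q + k_half)`, floor 0.5) and anti-CD137 as an
amplifying multiplier.  Pre-activated effectors secrete IL-2 on kills
(autocrine effector secretion), so sustained killing maintains its own
IL-2 microenvironment; helper-derived IL-2 from rules 1-2 adds to it.

Duplicating cells attempt one daughter per step with probability
`min(1, max_lfact / n_same_type_here) x IL2factor` over a `B_dup = TH_dup
= TC_dup = 16`-step window (`max_lfact = 5` is the local crowding
throttle); daughters inherit the receptor and revert to active.  Boosted
TCs halve the window (`cd137_dup_mult = 2`) and double their
restimulation rate; daughters are *not* born boosted — each generation
must capture its own antibody quantum, which ties therapeutic pressure to
the available antibody.

## Movement, chemotaxis, and the infiltration gate

A mobile agent's hop destination is drawn over the current site and its
neighbors with weight `1 + sensitivity x CA(site)`.  TC, M and cDC sense
the chemoattractant (sensitivity 1); boosting multiplies a TC's
sensitivity by `cd137_chemo_mult = 12`.  Chemoattractant is released by
endothelial agents (rate 0.02/step), by presenting macrophages, and by
activated OT-1 cells — the latter only when engaged on or adjacent to
tumor sites, so the gradient converges on the lesion rather than on
wherever effector cells happen to cluster.

A TC hopping from a tumor-free site into a tumor-occupied one passes the
endothelial CD137 gate: admission probability `infiltration_prob_wt = 0.8`
per attempt when CD137 is expressed on endothelium *and* anti-CD137 is
present systemically, else `infiltration_prob_ko = 0.01`.  The knockout
scenario (`cd137_on_endothelium = FALSE`) forces the low branch
regardless of antibody — the model's testable prediction is that this
single switch abolishes therapy by starving the tumor of infiltrating
killers.

Intravenous cells enter at endothelial (vessel) sites rather than only at
the lattice walls: agents cannot cross tens of millimeters of tissue by a
biased random walk within the 33-day horizon, and the observed presence
of transferred cells around the central tumor by day 14 physically
requires vascular delivery.  Entry sites exclude tumor-occupied sites so
that tumor entry always goes through the gate; `entry_mode = "walls"`
restores wall-row-only entry, and `placement_iv()` implements (and the
tests exercise) the wall placement used for the i.p. compound in the
figure convention.  Injected antibody likewise recirculates: each step a
fraction (`mab_recirculate = 0.5`) of the field returns to the blood and
redeposits across vessel sites, reflecting that blood redistribution is
fast compared with the 8-hour step; without it the single bolus never
reaches the T cells fighting inside the tumor and the boost economy
collapses.

## Calibration of the free parameters

The model has a class of parameters with no literature value.  The
shipped defaults (`base_kill_prob = 0.006` per contact,
`kill_contacts = 150`, `cd137_kill_mult = 60`, `cd137_survival_mult = 2`,
`restim_prob = 0.5`, gate probabilities 0.8/0.01, antibody scale 900
quanta/ug) were chosen, via `scripts/calibrate_arms.R`, to reproduce the
arm-level outcomes at L = 200: the three no-effect arms indistinguishable
from control (sacrifice near day 29); the two partial arms reduced in
area without rejection; the day-3 combination rejecting with median
elimination day ~19; the knockout failing with far fewer intratumoral
TCs at day 14 than wild type.  The tumor antigen shedding rate
(`antigen_shed_prob = 5e-5` per cell per step) is deliberately low: it
sets the pace of cross-priming of naive transferred cells, and B16 is
poorly immunogenic — at tenfold higher shedding the naive-OT-1 +
anti-CD137 arm would reject the tumor, contradicting the observed light
reduction.  Two scale notes make the large
`kill_contacts` legitimate: one transferred-cohort agent stands for
several hundred physical CTLs under the dose scaling
(`dose_to_density = 5e-4`), and a CTL kills a handful of targets per
8 hours, so the per-agent budget of 150 contacts is well below the
physical equivalent.

One arm-level observation resists this model class: combined therapy
started at day 8 observed in vivo to be *completely* ineffective.  Between
day 3 and day 8 the fitted Gompertz tumor grows only ~1.4-fold, so any
kill capacity that clears the day-3 tumor by day 20 also clears the
day-8 tumor before day 33 — the fight shifts by roughly the treatment
delay (rejection near day 27-28) instead of failing outright.  A complete
failure would need a sharply size-dependent suppression mechanism
(established stroma, physical exclusion) that is not among the six rules,
and we chose not to invent one.  The delayed, slowed clearance and the
much larger day-20 burden are asserted in the test suite; the strict
no-rejection clause is knowingly left unmet and is discussed here rather
than papered over by tuning.

## What the synthetic data does and does not emulate

The growth-fixture generator reproduces: Gompertz kinetics from the
engrafted load, the disk geometry linking diameters to cell counts,
two-perpendicular-caliper measurement with multiplicative noise, and
cage-of-six replication.  It does not emulate measurement truncation at
small diameters, mouse-to-mouse growth-parameter heterogeneity (all mice
share one `(a, b)` — the fit pools them on that assumption), missed
visits, or sacrifice-censored series.  Passing recovery tests therefore
show the fitting machinery is correct and well-conditioned for the
study's design; they do not show robustness to biological heterogeneity
real cohorts would add.

Likewise the simulator's tests validate internal consistency (census
accounting, conservation, locality, reproducibility) and the calibrated
arm-level ordering; they are not evidence about tissues beyond the
modeled 2D section, and the deliberately simplified humoral arm (no class
switching, no ADCC) plays no role in the therapy outcome.

## Numerical choices and degenerate inputs

* Integer quanta everywhere: secretion, decay and diffusion act on
  integers (binomial/multinomial draws), conserving mass exactly and
  keeping floating-point arithmetic out of the stochastic core.
* Update order within a step is fixed (growth, molecules, decay,
  interactions, duplication, movement, homeostasis, treatment,
  observables); candidates competing for limited per-site resources are
  admitted in uniformly random order up to availability.  Fixed phase
  order plus seeded shuffles gives bit-identical reruns from
  `(config, seed)`; replicate `k` of an experiment uses `base_seed + k - 1`
  so any replicate is reproducible alone.
* Rejection is declared at zero tumor cells; the headline "elimination
  day" is the first day tumor area falls below 1% of its peak, which is
  robust to a handful of straggler cells.
* Degenerate inputs fail fast with named errors: fewer than 3
  measurements or a flat series in `fit_gompertz()`, out-of-range
  receptors, unknown or out-of-range configuration keys (each error names
  the key and its valid range).
* `euler_newborns()` at `x = 0` returns 0 — an extinct tumor stays
  extinct by growth; at `b = 0` the law degenerates to pure exponential
  growth.

## Problem sizes used by the tests

Module tests run on lattices of 16-48 sites per side in seconds.  The
acceptance-level suites use the calibrated reference scale L = 200
(~2 x 10^4 leukocyte agents, tumor up to ~3.6 x 10^5 cells): 10
replicates per arm for the six day-3 arms, the day-8 arm and the
knockout, plus a 10-replicate rejection-day panel — about 10 minutes in
total.  Full-scale L = 946 runs are supported but are desk-scale
exercises, not part of the default suite.

## Known limitations

* 2D tissue with no vascular network geometry, pressure or adhesion.
* NK cells are inert; no Treg/myeloid suppression, checkpoint molecules,
  antibody effector functions, or anti-CD137 hepatotoxicity.
* The day-8 complete-failure observation is reproduced only as delayed,
  slowed clearance (analysis above).
* The Gompertz defaults are anchored to published endpoints, not to a
  deposited caliper dataset; all quantitative outcomes at other scales
  inherit the L = 200 calibration only qualitatively.
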