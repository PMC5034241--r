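---
title: "Measuring mutual entanglement in domain-swapped protein dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mutual entanglement in domain-swapped protein dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerlink)
```

## The problem

Three-dimensional domain swapping lets two protein chains exchange an
identical structural element, turning intra-molecular contacts into
inter-molecular ones. The resulting dimers can be deeply interpenetrated:
one backbone winds around the other in a way that is obvious to the eye in
a structure viewer but is not captured by contact counts or interface
areas. `dimerlink` quantifies that winding from Cα coordinates alone, with
two complementary estimators and a dynamical cross-check.

## Estimators

**Gauss double sum.** For two oriented closed curves the Gauss linking
integral

$$
Lk(\gamma_1, \gamma_2) \;=\; \frac{1}{4\pi} \oint_{\gamma_1}\oint_{\gamma_2}
\frac{\mathbf r_1 - \mathbf r_2}{|\mathbf r_1 - \mathbf r_2|^3}\cdot
(\mathrm d\mathbf r_1 \times \mathrm d\mathbf r_2)
$$

is an integer counting signed mutual windings. On polygonal curves the
package discretises it with the midpoint rule: every bond contributes its
midpoint $\mathbf m_i$ and bond vector $\mathbf b_i$, and the double sum
runs over all bond pairs *between* the two curves (never within one). Both
chains are traversed N→C, which fixes all signs. The kernel is implemented
in C++ with row-blocked accumulation; a pair of midpoints closer than
$10^{-9}$ Å raises a singular-pair error rather than contributing an
arbitrarily large term (crystallographic coordinates never trigger this;
degenerate synthetic input does, loudly).

**Open-chain Gaussian entanglement G′.** Evaluating the same double sum on
the two *open* Cα traces gives a real number, not a topological invariant,
but one that is cheap (no closure, no averaging, $O(N^2)$) and tracks the
closure-averaged linking number closely across the packaged cohort
(Pearson r ≈ 0.92 on the reference table, 0.96 with its one closure
outlier removed). G′ is the screening tool; the closures are the
topological anchor.

**Closure-averaged linking number G.** Each chain is closed
deterministically: from each terminus a straight arm of $n = 25$ artificial
residues (spacing 3.8 Å, the typical Cα–Cα distance) grows along the
direction pointing from the dimer centre of mass through that terminus —
the centre acts as a repeller, pushing the artificial path away from the
dimer core where it could pick up spurious winding. The two artificial
termini are then joined by a semicircle of diameter $|PQ|$ lying in a plane
through the P–Q axis, sampled so its spacing is as close as possible to
3.8 Å. Rotating that plane in 12 equal dihedral steps yields 12 closures
per chain; the phase origin is the plane containing the dimer centre of
mass, so the whole construction is deterministic and reproducible. For each
of the 12 × 12 = 144 closure pairs the Gauss sum is evaluated on the closed
curves and rounded to the nearest integer (a closed pair has an integer
linking number; the midpoint sum lands near it, and the largest residual is
reported as a quality metric with a warning above 0.2). G is the plain,
equally weighted average of the 144 integers — non-integer whenever
different closures disagree. A closure pair whose arc grazes the partner
curve within the singularity guard is excluded from the average and
counted; this is the package's policy for the rare pathological arcs, and
the exclusion count is surfaced in the result rather than hidden.

**Chain integrity.** A chain with a gap — two consecutively listed Cα more
than 10 Å apart — cannot be trusted for either estimator, because there is
no defensible way to invent the missing geometry. The filter is strict
(exactly 10 Å passes) and is the only integrity check; missing residues are
never interpolated. Alternate locations resolve to the highest occupancy
(first record on ties), and when a file holds more than two chains the two
with the most Cα atoms are used unless chains are named explicitly.

## Cohort statistics

The package ships a reference table of 110 non-redundant domain-swapped
dimers (G′, G, chain length, human flag) so cohort statistics run with no
downloads. `threshold_counts()` counts dimers past the |G′| = 1 thresholds
with strict inequalities; `fit_gprime_distribution()` fits either a
Gaussian to the G′ histogram (bin width 0.25, bins centred on zero —
bin-dependent, so treated as descriptive) or, preferably, the normal CDF to
the empirical cumulative distribution evaluated at the sorted sample
points. The ECDF convention is the fraction of values at most $x$. Two
width scales are reported: the Gaussian standard deviation $\sigma$, and
the error-function width $\Delta = \sqrt{2}\sigma$ that appears directly in
$F(x) = \tfrac12[1 + \mathrm{erf}((x - m)/\Delta)]$. Published erf-fit
widths for this cohort are on the $\Delta$ scale — the reference table's
G′ column has a sample standard deviation near 0.66, so a "width" of 0.85
can only be the erf parameter, and `erf_width` is the field to compare
against such values. `length_trend()` orders the cohort by chain length and
applies a centred 21-point running mean of |G′| (truncated at the edges) to
check for size bias; on the packaged table the trend is flat to slightly
decreasing.

## Dissociation dynamics

A static G′ can be inflated or masked by incidental geometry near the
termini. The dynamical check thermally dissolves the dimer and watches the
entanglement decay: each chain becomes a bead-spring polymer (beads on the
Cα positions, harmonic bonds, WCA excluded volume between all non-bonded
pairs, no attractions — equivalent to unfolding at high temperature), and
the ensemble average of G′(t) over independent overdamped Langevin
trajectories is fitted to $G^* e^{-t/\tau}$ after discarding the first 100
recorded points. $G^*$ extrapolates the decay back to $t = 0$ and need not
match the static G′; $\tau$ is the disentanglement timescale, expected to
grow with chain length as in Rouse phenomenology. Uncertainties come from
bootstrap resampling of whole trajectories (200 resamples by default).

Reduced units: the bead diameter σ is the length unit, $\epsilon = k_BT$
the energy unit, $\tau_{\rm sim} = \sigma^2\gamma/\epsilon$ the time unit.
The bond rest length is pinned to 1.5 σ, the mean Cα–Cα spacing of the bead
model, so σ maps to roughly 2.5 Å; input coordinates are rescaled uniformly
to that convention, which leaves G′ untouched because the kernel is
scale-free.

### Numerical choices

* **Integrator.** Overdamped Euler–Maruyama with
  $\langle\eta^2\rangle = 2\gamma k_BT/\mathrm{d}t$ per component. The
  friction-dominated, inertia-free limit is the natural discretisation for
  a Rouse-level model; a free-diffusion control (interactions off) checks
  $\mathrm{MSD} = 6(k_BT/\gamma)\,t$ to within 5%.
* **Time step.** dt = 0.001 τ_sim. The WCA core is stiff: at dt = 0.01 the
  rms noise step (~0.14 σ per component) lands non-bonded beads deep inside
  the core and every trajectory diverges; dt = 0.005 is the empirical
  stability edge and 0.001 leaves margin for the stiffer bonds below.
* **Bond stiffness.** spring_k = 300 ε/σ². The bond invariant the package
  tests — instantaneous lengths within 20% of rest — needs the equilibrium
  bond fluctuation $\sqrt{k_BT/k}$ to sit near 4% of the rest length so
  that 4–5 σ excursions stay inside the band; k = 100 (fluctuation ≈ 7%)
  fails it routinely among ~60 bonds.
* **Overlap guard.** A bead pair closer than 0.05 σ has its WCA force
  clamped, and the deterministic displacement of any bead in one step is
  capped at 0.25 σ; without the cap a rare deep overlap catapults a bead
  out of the structure with a finite but absurd displacement. Both events
  are counted and reported.
* **Recording.** G′ evaluation is the $O(N^2)$ bottleneck, so it is
  throttled by `record_every`; the neighbour-list integrator itself is
  near-$O(N)$ per step. `sim_config()` refuses configurations whose trace
  would be shorter than the 100 records the decay fit discards.
* **Fit.** `nlsLM` with a log-linear start on the smoothed |trace| and a
  ladder of fallback timescale starts; a fit whose amplitude is
  indistinguishable from zero is rejected as unidentifiable rather than
  reported.

## Synthetic fixtures, and what they do and do not show

All ground truth is generated in code: Hopf links (Lk = +1 under the
package's orientation convention), (1, k) torus links (Lk = +k), unlinked
circle pairs, random open coils with protein-like 3.8 Å bonds and a soft
self-avoidance bias, and the *cut-Hopf dimer* — a Hopf link with an arc
removed from each circle at the point farthest from the partner, giving an
open two-chain toy whose G′ sits near 1 (0.909 for the default geometry)
and whose every closure pair links exactly once. The closed fixtures are
verified against an exact, discretisation-free reference: the linking
number of two closed polygons computed segment pair by segment pair as
signed solid angles (the Klenin–Langowski closed form), implemented
independently in the test suite.

These fixtures exercise the topology, the closures, and the dynamics
end-to-end, but they are smooth, well-separated curves: they do not emulate
secondary structure, side-chain packing, missing residues, altloc
ambiguity, or the near-contact backbone geometry of real interfaces. Tests
passing on them validate the machinery, not the biology; the cohort-level
numbers come from the packaged reference table, and per-structure
recomputation requires the experimental coordinates, which the package does
not redistribute.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script ensembles are deliberately modest, as
scaled-down study conditions: the dissociation checks use a 2 × 50-bead
cut-Hopf dimer with 20 trajectories to t_max = 2000 τ_sim (about ten times
the Rouse estimate $\gamma N^2 b^2 / 3\pi^2 k_BT \approx 190\,\tau_{\rm
sim}$ for a 50-bead chain, so the decay completes well inside the window),
recording every 0.5 τ_sim; the length-dependence check compares 50-bead
against 200-bead chains with 6 trajectories each. Full-scale runs (100
trajectories, real dimer sizes) use the same code paths through
`sim_config()`.

## Known limitations

* G is only as good as its closures: an arc passing near the partner chain
  can add spurious winding, which is why the per-closure integer residual
  and the exclusion count are part of the result, and why G′ is preferred
  for screening. The packaged cohort contains one such outlier (a dimer
  with G > 2 but G′ ≈ 0).
* The dissociation model has no attractions, so τ measures untangling under
  pure excluded volume at high temperature; timescales are in reduced
  units and depend on the integrator and stiffness conventions above, so
  only signs, trends and orders of magnitude are comparable across
  implementations.
* mmCIF input is not supported; PDB-format Cα records are the contract.
* The human/non-human split and any pathology annotations are taken as
  given in the reference table; the package computes statistics over them
  but draws no biological conclusions.
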