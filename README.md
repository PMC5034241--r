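# dimerlink

Quantifying how much the two chains of a domain-swapped protein dimer wind
around each other, from Cα coordinates alone.

Domain-swapped dimers exchange an identical structural element between two
chains, and the swapped arms can wrap one backbone around the other. For
closed curves that winding is the integer Gauss linking number

Lk = (1/4π) ∮∮ (**r**₁ − **r**₂) · (d**r**₁ × d**r**₂) / |**r**₁ − **r**₂|³ ,

discretised here with the midpoint rule over bond segments. `dimerlink`
computes:

* **G′ — Gaussian entanglement**: the same double sum evaluated directly on
  the two *open* Cα traces (both traversed N→C). Not a topological
  invariant, but fast and strongly correlated with the closed-curve linking
  number; the screening statistic of choice.
* **G — closure-averaged linking number**: each chain is closed by two
  straight 25-residue arms growing away from the dimer centre of mass
  (which acts as a repeller) plus a meridian semicircle; 12 deterministic
  meridians per chain give 12 × 12 = 144 closure pairs, each an integer
  linking number, averaged into G.
* **Cohort statistics** over a packaged reference table of 110
  non-redundant swapped dimers: counts beyond |G′| = 1, negative-G′
  fractions by human/non-human, error-function fits to the empirical CDF of
  G′, and the running mean of |G′| against chain length.
* **Dissociation dynamics**: a coarse-grained overdamped Langevin model
  (bead-spring chains, WCA excluded volume, no attractions) monitors G′(t)
  while the dimer dissolves; fitting G\* · exp(−t/τ) to the ensemble
  average gives a dynamical entanglement amplitude G\* and a
  disentanglement timescale τ.

Structures are read from PDB files (`ATOM`/CA records; altlocs resolved to
highest occupancy; chains with a >10 Å gap between consecutive Cα are
flagged as unusable). Synthetic generators (Hopf links, torus links, random
coils, an openable "cut-Hopf" toy dimer) provide exact ground truth so the
whole pipeline is testable offline.

## Worked example

```r
library(dimerlink)

# a toy dimer with known topology: a Hopf link cut open on each ring
toy <- fixture_as_dimer(make_fixture("cut_hopf_dimer", n_vertices = 60))
gaussian_entanglement(toy)
#> [1] 0.9103999

closure_linking_number(toy)
#> <linking_result> CUT_HOPF_DIMER: G' = 0.910, G = 1.000 (144 closure pairs), max rounding residual 0.001

# cohort statistics over the packaged 110-dimer reference table
tab <- swapped_dimer_cohort()
threshold_counts(tab)
#> <threshold_counts> 110 dimers (33 human)
#>   G' < -1: 15   G' > 1: 4   |G'| > 1: 17%
#>   G' < 0: 64% overall, 67% human, 62% non-human

fit_gprime_distribution(tab$g_prime, "erf_cdf")
#> <distribution_fit> erf_cdf: mean = -0.172, sd = 0.615, erf width = 0.870 (RSS 1.44e-01)
```

The toy dimer's open-chain G′ (0.91) sits just below the closed-curve value
its geometry encodes, and every one of the 144 artificial closures rounds
to linking number 1, so G = 1 exactly. On the reference cohort, 15 dimers
fall below G′ = −1 and 4 above +1 (about 17% strongly intertwined), about
two thirds of dimers have negative G′, and the error-function fit to the
cumulative distribution has width Δ ≈ 0.87 (Gaussian σ ≈ 0.62).

For a real structure, point the reader at a PDB file:

```r
d <- read_ca_chains("1m0d.pdb")        # first two (largest) chains
gaussian_entanglement(d)               # G' of the crystal
closure_linking_number(d)              # 144-closure average G
```

A thin command-line front-end with `compute`, `cohort`, `simulate` and
`fixtures` subcommands ships at `inst/cli/dimerlink.R`.

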