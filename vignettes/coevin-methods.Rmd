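---
title: "Models and methods behind coevin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coevin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevin)
```

`coevin` bundles the three analysis layers used when dissecting how a
J-domain cochaperone activates its Hsp70 partner: geometric analysis of
the protein-protein interface, free-energy post-processing of biased
sampling along collective variables, and a phylogenetic test for
coevolving residue pairs across the interface. Because the original
data behind such studies (microsecond molecular-dynamics trajectories,
curated ortholog databases) are far beyond desk scale, the package
carries a first-class synthetic-data module whose generators have known
ground truth; every estimator in the package is validated against that
ground truth rather than against irreproducible inputs.

This vignette records the models, the parameter choices and their
rationale, and the numerical decisions. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Geometric interface analysis

All coordinates are handled in nanometres internally; PDB input/output
converts from and to the Angstrom convention (I/O is delegated to
`bio3d`, with alternate locations resolved to the highest occupancy and
waters dropped on read).

The detectors follow the standard criteria for chaperone interface
work:

* **Contacts** — pairs of non-hydrogen atoms from the two interface
  sides within 0.5 nm.
* **Ion pairs** — oppositely charged side-chain groups (Arg guanidine
  NE/CZ/NH1/NH2, Lys NZ, Asp CG/OD1/OD2, Glu CD/OE1/OE2) whose
  *mass-weighted* centres of mass lie within 0.5 nm. Terminal
  amine/carboxylate groups are not considered; histidine is treated as
  uncharged throughout, including in `charged_fraction()`.
* **Hydrogen bonds** — donor-acceptor distance below 0.35 nm and
  hydrogen-donor-acceptor angle below 30 degrees. When a structure
  carries no hydrogens at all (common for crystal structures), the
  angle test cannot be evaluated; the detector then applies the
  distance criterion alone and says so. This is a deliberate downgrade,
  not a silent one.

Every cutoff is **strict** (`<`). The boundary convention is stated
because contact counts are only reproducible when it is fixed; a pair
at exactly the cutoff is *not* reported.

Solvent-accessible surface area uses the Shrake-Rupley construction: a
deterministic golden-spiral quadrature of (by default) 960 points per
atom on the solvent-expanded sphere (element-based Bondi radii, probe
0.14 nm). The quadrature directions are expressed in a molecule-fixed
principal-axes frame, which makes the computed areas exactly invariant
under rigid-body motion of the whole structure — a property the test
suite asserts to 1e-6 nm^2. Buried hydrophobic surface is the
dissociated-minus-bound SASA of hydrophobic residues
(Ala/Val/Leu/Ile/Met/Phe/Trp/Pro; glycine excluded, configurable), with
all three terms evaluated in the *complex* frame so that they cancel
exactly when the chains do not occlude each other.

Conformational heterogeneity is summarized by Kabsch superposition
(SVD, proper rotation enforced) and single-linkage clustering at an
RMSD cutoff (0.18 nm by default, matching the bound-ensemble analysis
this package emulates). Single linkage is implemented literally as the
connected components of the graph with edges `RMSD < cutoff`, via a
small union-find — not through a dendrogram cut — so the strict
boundary rule and order-invariance hold exactly. Cluster centroids
minimize the summed within-cluster RMSD.

## Free-energy estimators

Thermal energy uses `kB = 0.0083144621` kJ/mol/K; the default
temperature is 300 K.

**WHAM.** Umbrella windows (restraint centre, spring constant, scalar
samples) are combined by the standard self-consistent iteration on a
common histogram (default 100 bins spanning the pooled sample range).
Unvisited bins are reported as `+Inf`, never extrapolated. Convergence
is declared when no window offset F_i moves by more than 1e-8 kJ/mol;
non-convergence is a warning on the result, not a silent pass. Windows
whose sample supports do not overlap produce an error naming the gap.
Bootstrap errors follow the Monte Carlo recipe: windows are resampled
with replacement and WHAM re-solved on the same bin grid; the per-bin
standard deviation over replicates is the error estimate. Samples are
treated as decorrelated draws — the synthetic generator's windows
decorrelate within tens of steps, but for genuinely autocorrelated MD
data the plain bootstrap underestimates errors.

**Well-tempered metadynamics.** The generator deposits Gaussians of
height 0.1 kJ/mol and width 0.04 nm every 250 integrator steps,
tempered by `exp(-V/((gamma-1) kT))` with bias factor gamma = 15 —
the deposition protocol of the free-energy mapping this package
emulates. The accumulated bias lives on a regular grid (value and
analytic gradient grids, bilinear interpolation), and one-sided
harmonic walls of 3000 kJ/mol/nm^2 confine the walker to the gridded
region. The free-energy estimate is `F(s) = -gamma/(gamma-1) V(s)`,
re-zeroed at its finite minimum. A single walker is used: multiple
walkers only parallelize sampling, they do not change the estimator.

**Langevin integrator.** All biased sampling uses overdamped
Euler-Maruyama dynamics, `dx = -grad U dt / friction +
sqrt(2 kT dt / friction) dW`. The default step `dt = 1e-5` was chosen
by the restraint-statistics validation: under the stiffest default
restraint (2500 kJ/mol/nm^2) the sampled variance must match the
analytic `kT/k` within a few percent (first-order Euler-Maruyama bias
is `~ k dt / 2 friction`, about 1.3% at the default). Larger steps
visibly distort the recovered PMFs.

**Four-state populations.** A 2D free-energy surface over two
ion-pair distances is converted to probabilities
`p ~ exp(-F/kT) * bin volume` and integrated over the four quadrants
defined by a 0.5 nm contact threshold on each axis (bound iff
`d < 0.5`, strict, matching the geometric detectors). Bins are
assigned to quadrants by their centres, so placing the threshold on a
bin edge (as the defaults do) makes the quadrature exact to the grid
resolution. When several block maps are averaged, each map is first
re-zeroed at its own finite minimum — the free-energy gauge is
arbitrary per block — and the per-bin standard deviation is attached.
Populations may be computed from the averaged map or averaged over
per-block populations; both orders are available since the choice is
not canonical.

**Reweighting.** Observables measured in restrained windows are
unbiased with the factor `exp((U_i(r) - F_i)/kT)` using the window
offsets F_i from WHAM, binned along the coordinate; empty bins are
reported as missing rather than zero.

## The coevolution test

**Independent model.** Single columns evolve under the symmetric,
equal-frequency substitution chain on the residues observed in that
column, normalized to one expected substitution per unit branch length
and scaled by a free per-column rate. Its transition probabilities have
the closed form `P_ij(t) = 1/N + (delta_ij - 1/N) exp(-N t/(N-1))`, so
the pruning likelihood needs no matrix exponential. The restriction to
observed residues (rather than all 20) keeps the pair state space below
400 states; the likelihood of the observed data is essentially
unchanged because unobserved states enter only through vanishing
partial likelihoods.

**Coevolution model.** A column pair evolves as one Markov chain on
the product space of the two observed residue sets. Only one position
changes per event; a move into a pair belonging to the *coevolving
profile* P has rate `s`, a move anywhere else has rate `d`. The chain
is reversible with the closed-form stationary law
`pi(state) ~ (s/d)^[state in P]`, which both seeds the root
distribution and enables the matrix exponential via symmetrized
eigendecomposition (`S = D^{1/2} Q D^{-1/2}` with `D = diag(pi)`).
When fitting real column pairs the profile is fixed to the residue
pairs observed to co-occur at the leaves; for parameter-recovery
studies on synthetic data the generative profile is supplied. With
`s = d` the model factorizes exactly into two independent symmetric
chains — the test suite checks this identity to 1e-8, which ties the
two likelihood implementations together.

**Model comparison.** Both fits carry two free parameters (one rate
per column vs `(s, d)`), so `dAIC = AIC_independent - AIC_Coev =
2 (logL_Coev - logL_independent)`. This bookkeeping is stated
explicitly because any change in the parameter count shifts every
threshold. Optimization is on log parameters with box bounds
(`exp(-9)` to `exp(7)`): a 5x5 coarse grid over `(log s, log d)` seeds
a bounded quasi-Newton (L-BFGS-B) refinement from the two best grid
points. The grid stage plays the role of dispersed restarts against
local optima at a fraction of the cost; total failure of every start is
raised as an error and non-convergence is flagged on the result.

**Calibration.** Significance is *not* read from an asymptotic
distribution. Alignments are simulated under the independent model on
the same tree, dAIC is computed for every pair of simulated positions,
and the 99th percentile (linear-interpolation definition, `quantile`
type 7) of the pooled distribution is the threshold for calling a pair
coevolving with p < 0.01; values are pooled across all pairs and
replicates rather than per pair. Ties at the threshold are *called*
(inclusive `>=`). Pairs with fewer than four species ungapped in both
columns are skipped as unidentifiable, with a recorded reason.

## The synthetic-data module and the study conditions

The generators are pure functions of their arguments and a seed; each
draws from its own named stream derived from the master seed, so
results are reproducible across platforms and call orders. The study
conditions used by the validation suite were fixed once:

* **Tree**: a 64-leaf Yule tree with birth rate 1 (total length about
  63 expected substitutions per unit rate), standing in for an
  ortholog-family phylogeny of realistic breadth.
* **Null columns**: per-column rate 0.05, i.e. a handful of
  substitutions per column across the family — interface positions are
  strongly conserved, and this is the regime in which the calibrated
  test must control its false-call rate.
* **Coevolving pairs**: a matched-pair profile of six
  charge- or volume-complementary pairs (`DR, NK, ST, EQ, GA, LV`) on a
  6 x 6 pair space, with `s = 0.5`, `d = 0.05` (`s/d = 10`, about 83%
  of stationary mass on the profile). A profile of several
  complementary combinations — rather than one or two — is what makes
  the coevolution signature strong: leaves concentrate on a sparse
  subset of a large product space, which no independent model can
  match. Parameter recovery is assessed at `s/d = 5` with the
  generative profile supplied.
* **Sequence simulation** is exact: closed-form state propagation per
  branch for the independent chain and Gillespie simulation on the pair
  space for the coevolving chain. There is no discretization error in
  the ground truth.
* **Toy complexes** plant an Arg-Asp ion pair at a COM distance of
  0.45 nm, a Ser-Ser hydrogen bond at 0.30 nm/10 degrees, and the
  cross-chain contacts implied by the construction; the ground-truth
  list is enumerated at build time and the geometric detectors must
  reproduce it exactly.
* **Biased sampling** runs on analytic potentials (flat, harmonic,
  double-well) whose free energies are known in closed form. WHAM is
  validated on a harmonic PMF sampled by five windows with the
  2500 kJ/mol/nm^2 restraint (recovered profile within 0.2 kT RMS over
  the restrained range — tail bins outside the outermost window
  centres are reported but essentially unsampled); metadynamics on a
  5 kJ/mol double-well barrier (recovered within 0.5 kT).

What the generators deliberately do **not** emulate: indel processes
and alignment error, rate heterogeneity across sites, across-branch
compositional drift, solvent and force-field detail, autocorrelated MD
noise, and replica exchange between windows. Passing the suite
therefore demonstrates the correctness of the estimators and the
internal consistency of the calibration — not robustness to
misalignment or force-field artefacts in real data.

## Numerical choices and degenerate inputs

* Gaps are missing data everywhere in the likelihood machinery
  (partial-likelihood vectors of ones); a gap in either column of a
  pair makes the whole leaf pair missing.
* A constant column has a single observed state; its restricted-chain
  likelihood is 1 and its rate is reported as indeterminate (`NA`)
  while still counting toward `k = 2`.
* Per-edge partial likelihoods are rescaled by their maximum, so
  hundreds of taxa do not underflow.
* The profile-HMM filter (match columns = columns under 50% gaps, +1
  pseudocounts, shared background insert emissions) runs
  forward-backward in log space; a residue's confidence is the
  posterior probability of the match or insert state its alignment
  column assigns to it, and residues below the threshold (default 0.7)
  are replaced by gaps individually — masking is per residue, not per
  column, since the confidence is per sequence.
* Alignment columns are reported 1-based at every interface.
* `quantile` type 7 is used for the percentile threshold; the
  calibration seed and replicate count are recorded with the
  threshold.

## Known limitations

* The two-parameter coevolution model deliberately omits
  position-specific exchangeabilities and equilibrium frequencies; the
  calibration-by-simulation makes calls internally consistent, but the
  dAIC scale is not comparable across trees or alignment depths.
* With `s/d` around 10 and a small profile, roughly one leaf in six
  sits outside the profile; if the product space is small (2 x 2) every
  cell is observed and the fitted profile degenerates to the full
  space, where the model loses power by construction. Detection is a
  large-state-space phenomenon.
* Euler-Maruyama is first-order: pushing `dt` much above the default
  with stiff restraints biases window variances measurably.
* SASA rigid-body invariance relies on a principal-axes frame and can
  degrade for structures with (near-)degenerate inertia axes.
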