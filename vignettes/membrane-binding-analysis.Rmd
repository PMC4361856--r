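---
title: "Methods: membrane-glycopeptide binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane-glycopeptide binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

memglyco analyses funnel-restrained simulations of a helical glycopeptide
binding a phospholipid bilayer. This vignette documents the model, every
numerical parameter with its unit, default and rationale, and the scope
and limits of the synthetic-data generators used to validate the analysis
stages. Units throughout: Angstrom (A), kcal/mol, picoseconds, Kelvin; the
bilayer normal is the +z axis and z = 0 sits at the membrane centre.

## Funnel restraint

The restraint boundary combines a cone (wide end at the membrane,
half-angle `alpha`) with a cylinder of radius `rcyl` directed toward the
solvent, switching at height `zcc`:

$$ r(z) = R_\mathrm{cyl} + \max(0,\, Z_{cc} - z)\tan\alpha $$

Outside the boundary a harmonic one-sided wall applies
$\tfrac12 k_\mathrm{wall}(\rho - r(z))^2$; an optional top wall caps the
funnel at `zmax`. Defaults: `alpha` 0.8 rad, `rcyl` 1 A, `zcc` 35 A —
the standard funnel-restrained sampling geometry for a peptide-bilayer
system. The wall stiffness (10 kcal mol^-1 A^-2) and the top wall
(45 A, 10 A beyond the switch height) are configurable because the
literature setup leaves them open. Points exactly on the boundary are
unbiased (closed interior), so frame-exclusion flags are deterministic.
Frames whose tracked-selection geometric centre feels a non-zero wall
energy are excluded from all downstream statistics.

## Contact collective variable

Peptide-membrane contacts are counted smoothly with the rational
switching function

$$ s(r) = \frac{1 - (r/r_0)^n}{1 - (r/r_0)^m}, \qquad
   r_0 = 5\ \mathrm{A},\ n = 8,\ m = 16, $$

whose removable singularity at $r = r_0$ is handled analytically
($s(r_0) = n/m$); for $m = 2n$ the algebraically equivalent stable form
$1/(1 + (r/r_0)^n)$ is used. The frame value is the sum over all pairs
between a peptide-side Calpha selection and the membrane phosphate
atoms, divided by the peptide-side atom count (per-group-atom
normalisation), so one ideal contact per tracked atom gives s of order 1
and the absolute bound threshold s > 0.5 (strict) is meaningful. A
raw-sum mode is retained for sensitivity analysis. Distances use the
minimum-image convention when a box is present.

## Pose clustering

Bound poses (s > 0.5 on either side, funnel-excluded frames never
bound) are compared by superposition-minimised RMSD over the Calpha
atoms of the helix core (residues 5-12), computed by Kabsch/SVD
superposition with the determinant sign correction. The pairwise matrix
is agglomerated with unweighted average linkage (UPGMA) and cut to a
configurable family count (default 10). Each family's representative is
the member with the lowest core RMSD to the family's average structure,
built by iterative superposition onto the running mean (tolerance
1e-6 A); ties go to the lowest frame index. For runtime control the
pipeline subsamples at most 400 bound frames (evenly over time) before
building the quadratic-cost matrix; this is a package choice, not a
physical parameter.

## Chain order parameters

Per-carbon deuterium order parameters of the acyl chains c1/c2 (carbons
2-14, DMPC-like myristoyl chains):

$$ S_{CD} = \left\langle \tfrac12 (3\cos^2\theta - 1) \right\rangle $$

with $\theta$ the angle of each C-H vector to the bilayer normal, pooled
over hydrogens, lipids and retained frames; uncertainties come from block
averaging (5 blocks). Hydrogens are taken explicitly when present, or
reconstructed with ideal tetrahedral methylene geometry from the two
chain-neighbour carbons (terminal methyls excluded). Both the signed
value and |S_CD| are reported. Profile comparison flags carbons where
|Delta| exceeds twice the combined standard error (plus a 1e-9 absolute
guard against float noise) and reports the deepest perturbed carbon per
chain. The normal is the fixed +z (systems are built pre-oriented);
leaflets are pooled.

## Synthetic generators: scope and frozen conditions

The generators produce every test input with constructed ground truth.
They are deliberately coarse: the peptide is a rigid Calpha bead helix
(canonical geometry: rise 1.5 A, twist 100 deg, radius 2.3 A, one glycan
bead 3 A radially outside residue 7), the membrane is an implicit smooth
well per bead, and no force field, water or electrostatics is attempted.
Their purpose is known truth, not realism.

`simulate_funnel_langevin()` integrates rigid-body BAOAB Langevin
dynamics over four degrees of freedom (axis centre x, y, z and the roll
angle about the helix axis) at 300 K, friction 1 ps^-1, time step 10 fs,
2e5 steps by default. Each bead of class c feels a Gaussian membrane
well

$$ U_c(z_b) = -d_c \exp\!\big( -(z_b - z_s - o_c)^2 / 2w^2 \big) $$

of width w = 2.5 A centred at a per-class height above the phosphate
plane $z_s$ = 18 A, plus a harmonic repulsion (5 kcal mol^-1 A^-2) below
15 A that stands in for the membrane core, and the funnel wall. The
frozen study conditions are

| class | depth d_c (kcal/mol) | offset o_c (A) | rationale |
|---|---|---|---|
| glycan   | 5.0  | 0   | sugar-phosphate hydrogen bonding at the head groups |
| basic    | 2.5  | 0.5 | Arg/Lys/His salt bridges just above the phosphates |
| aromatic | 1.5  | 2   | Trp/Tyr/Phe partitioning at the choline level |
| other    | 0.25 | 4   | backbone riding on top of the head groups |

The per-class centre offsets are essential: with a single shared centre
the glycan-down and glycan-sideways orientations are nearly
isoenergetic and neither face dominates. With the offsets, Boltzmann
quadrature over (z, roll) gives the glycosylated face ("Side 1") a
weight of about 0.96 among bound states, which is what the analysis
pipeline is asked to recover. These values were fixed from that
energy-landscape analysis before the statistical tests were written and
are not tuned against test outcomes.

Ground-truth rules, recomputed from the emitted (jittered, sigma =
0.1 A) coordinates so they are self-consistent: a frame is bound when
the mean peptide-bead height is below 26 A (the wells' capture range);
a bound frame is Side 1 when the glycan bead lies below the mean Calpha
height. Noise comes from R's RNG, so `set.seed()` makes every trajectory
bitwise reproducible.

`gen_bilayer_frames()` places DMPC-like chains on a lattice, two
mirrored leaflets, and samples each C-H orientation at the fixed polar
angle $\theta^* = \arccos\sqrt{(2S^*+1)/3}$ with uniform azimuth, which
recovers the target order exactly (the azimuth does not change
$\cos\theta$); noisy and isotropic modes exist for stress tests.
`make_cluster_fixture()` draws labelled frames around reference
conformations with Gaussian noise plus random rigid moves.

## Numerical choices

- Integrator: BAOAB splitting; with friction 0 it reduces to velocity
  Verlet and conserves energy to O(dt^2) (verified by halving dt).
- Mass: 2300 amu total, converted to kcal mol^-1 ps^2 A^-2 via
  2.39006e-3; kB = 1.9872041e-3 kcal mol^-1 K^-1.
- Equipartition, the Boltzmann bound-fraction oracle and the exclusion
  rules are all exercised in the test suite against independent
  reference computations (finite differences, brute-force pair sums,
  exhaustive agglomeration, numeric quadrature).
- Problem sizes in tests (e.g. 2000-frame runs, 400-frame clustering
  cap, 64-lipid bilayers) are package choices balancing statistical
  power against a single-CPU runtime budget.

## Limitations

The simulator's four rigid degrees of freedom cannot express internal
peptide flexibility, helix tilt relative to the membrane plane, or lipid
response; the implicit membrane has no lateral structure; and the
synthetic bilayer encodes orientational order only, not positional
packing. Results on synthetic systems validate the analysis code, not
any biophysical claim about a particular peptide.

## A small worked run

```{r, eval = FALSE}
library(memglyco)
hx <- build_ideal_helix()
sim <- simulate_funnel_langevin(hx, sim_config(seed = 1))
report <- run_binding_analysis(
  list(selections = list(), funnel = list(), contact = list(),
       clustering = list()),
  trajectory = sim$trajectory)
print(report)
```
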