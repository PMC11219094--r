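---
title: "Alchemical free energy machinery at desk scale: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alchemical free energy machinery at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemforge)
```

## What this package models

Relative free energy calculations estimate how a residue mutation shifts a
binding (or transfer) free energy. Rather than simulating the WT and mutant
systems separately, a single *hybrid* system carries both residues and an
alchemical parameter $\lambda \in [0,1]$ interpolates between the two
physical Hamiltonians: at $\lambda = 0$ the WT residue is fully interacting
and the mutant-only atoms are non-interacting "dummies" that keep only their
valence terms; at $\lambda = 1$ the roles are reversed. The difference of the
per-phase free energies $\Delta G_{\text{complex}} - \Delta G_{\text{apo}}$
is the relative binding free energy $\Delta\Delta G$.

`alchemforge` implements this machinery — hybrid topology construction,
$\lambda$-interpolated softcore nonbonded potentials, counterion transforms
for charge-changing mutations, replica exchange over alchemical states
(AREX) with Gibbs-sampled state permutations, solute tempering (AREST),
MBAR estimation with bootstrap uncertainties, and a sampling-diagnostics
workflow — at *desk scale*: every claim the package makes is validated on
toy systems with known answers (analytic Gaussian ladders, planted slow
coordinates, bead-level residue chains), not on solvated proteins.
Production-scale concerns (periodic boundary conditions, reciprocal-space
Ewald sums, force-field parameter assignment, GPU execution) are explicitly
out of scope.

## The hybrid topology

Atoms are mapped between the WT and mutant residues by label: all backbone
atoms up to and including the beta carbon are shared (beta hydrogens never
are), and hydrogens whose constrained bond length would change between the
endstates are un-mapped, since a shared coordinate cannot satisfy two
different constraints. Every atom then falls into one of four classes:

* `unique_old` / `unique_new` — unmapped atoms present in only one endstate;
  dummies at the other endstate.
* `core` — mapped atoms in the mutating residue or its sequence neighbours
  (their nonbonded parameters interpolate).
* `environment` — every other mapped atom (parameters identical at both
  endstates).

Two design points deserve comment because the construction does not force
them:

* **`unique_old` x `unique_new` pairs are always excluded.** The two dummy
  sets coexist only in the hybrid; letting them interact at any
  $\lambda$ would let a non-physical interaction bias the physical
  endstates.
* **Valence terms are never $\lambda$-interpolated.** The bead templates
  give mapped atoms identical valence parameters at both endstates, so every
  bond is "shared" unless it touches a unique atom, in which case it is
  tagged `old`/`new` and kept on at *all* $\lambda$ (dummy atoms retain
  their valence terms; this is what keeps them tethered and gives the exact
  endstate identity $U(\lambda{=}0) = U_{\text{WT}} +
  U_{\text{dummy-new valence}}$). A corollary, exploited by the tests, is
  that valence terms contribute exactly zero to $\partial U/\partial\lambda$.

For charge-changing mutations the residue's net-charge change $\Delta q$
(at most $\pm 1$ e here) is compensated by co-alchemically transforming a
water-like particle into a monovalent ion carrying $-\Delta q$ at the mutant
endstate, so both endstates are electrostatically neutral to $10^{-10}$ e.
Which water is transformed is a caller choice (the first index of the
supplied eligible list); no distance-based selection policy is imposed.

## Energies, softcore, and units

All internal energies are *reduced*: multiples of $kT$ at the reference
temperature (300 K), with distances in nm and charges in e. Reports convert
to kcal/mol via `kt_to_kcal()` ($kT \approx 0.596$ kcal/mol at 300 K).

Electrostatics uses the direct-space Ewald form
$C\,q_i(\lambda)q_j(\lambda)\,\mathrm{erfc}(\alpha r_{\text{eff}})/r_{\text{eff}}$
with linearly interpolated charges; a plain-Coulomb mode replaces the erfc
factor by 1 and is the $\alpha \to 0$ limit. Reciprocal-space and
self-energy terms are omitted: the desk systems are non-periodic, so the
direct-space form *is* the full electrostatics here. Sterics is a 12-6
Lennard-Jones potential with per-atom $\lambda$-interpolated $\sigma$ and
$\epsilon$ (arithmetic/geometric combination).

Singularities from vanishing atoms are avoided by *lifting* the interaction
distance into a 4th dimension: $r_{\text{eff}} = \sqrt{r^2 + w(\lambda)^2}$
with $w = w_{\text{lifting}}\lambda$ for pairs involving a `unique_old` atom
and $w = w_{\text{lifting}}(1-\lambda)$ for `unique_new` pairs. The default
$w_{\text{lifting}} = 0.4$ nm is a package choice (configurable); the
boundedness and continuity tests are written to hold for any positive value.
$\partial U/\partial\lambda$ is computed by central finite difference
(step $10^{-4}$, one-sided at the endpoints); on potentials linear in
$\lambda$ the difference is exact.

The $\lambda$ protocol is uniform, $\lambda_k = k/(K-1)$, with a hook for
custom schedules. $K$ is chosen per system for adjacent-state overlap —
checked with `mixing_statistics()`, never assumed: the bead-chain systems
here use $K$ of 4-8 for neutral mutations and the charge-change trio uses
$K = 12$ (the desk-scale analogue of using more states for charge
mutations, whose thermodynamic length is larger).

## AREST: solute tempering on top of AREX

AREST multiplies interaction energies by a class-dependent factor:
$u_{\text{total}} = \alpha u_{\text{rest}} + \alpha^p u_{\text{inter}} +
u_{\text{nonrest}}$, where membership is fixed from the *initial*
conformation (all atoms of a term in the REST region / none / mixed). The
schedule $\alpha(\lambda)$ interpolates the effective *inverse* temperature
linearly from $\beta(T_0)$ at the endstates to $\beta(T_{\max})$ at
$\lambda = 0.5$, so $\alpha(0) = \alpha(1) = 1$ exactly (the endstates are
bit-identical to AREX — a property the tests assert with `identical()`, not
with a tolerance) and $\alpha(0.5) = T_0/T_{\max}$.

The exponent $p$ on the boundary-straddling (`inter`) terms is configurable:
$p = 0.5$ (the REST2 convention, geometric-mean scaling) is the default,
$p = 1$ (scaling inter terms like rest terms) is also supported. Published
descriptions of this scheme differ on this point; we default to the
solute-tempering convention rather than guessing.

## Sampling

Replicas are propagated with BAOAB Langevin dynamics (unit masses, $kT=1$);
the integrator identity was verified against the stationary variance of a
harmonic oscillator (the equipartition test). State labels are updated by a
Gibbs sweep: `n_attempts` uniformly random pair proposals, each accepted by
the Metropolis criterion on the reduced-potential matrix, default
$K^3$ attempts so the result approximates an independent permutation draw.
One subtlety the test suite documents: with *exactly equal* energies every
proposal is accepted, so a fixed attempt count reaches only permutations of
one parity — the uniformity test is therefore run within a parity class.
Velocities persist across label swaps (labels move, not coordinates).

Randomness is a single seeded R stream per run; archives are bit-reproducible
given the seed and configuration. (A counter-based RNG split per replica
would permit out-of-order execution; base R does not provide one, and
sequential execution makes the single stream exactly reproducible.)

Archives store the per-iteration reduced-potential matrix $u_{kl}$ (every
replica at every state), the replica-to-state trace, $\partial
U/\partial\lambda$, and registered degree-of-freedom observables, serialized
as versioned JSON (`alchemforge-archive-1`) with CSV export.

## Estimation and diagnostics

MBAR is solved by self-consistent iteration accelerated with Newton steps on
the convex MBAR objective (tolerance $10^{-10}$ in the reduced free
energies); on two states it reproduces an independent BAR solver to
$10^{-8}$. Samples are pooled over replicas with the generating state taken
from the Gibbs-updated assignment; each state block is subsampled at the
statistical inefficiency of its reduced-potential series before estimation.
Uncertainty is by state-blocked bootstrap (200 replicates by default, the
convention for this workflow); no analytic MBAR covariance is implemented.

The diagnostics mirror the sampling-problem identification workflow:

* **Convergence**: $\Delta G(t)$ on growing data prefixes (10 points by
  default; the last point equals the full-data estimate bit-exactly), OLS
  slope of the trailing half, verdict "converged" iff slope $\pm 2$ SE
  intersects the flatness band. On real data the band is 0.1 kcal/mol/ns;
  on the toy archives the tests use the same construction with a band of
  0.001 reduced units per recorded iteration.
* **Internal consistency**: forward and negated-reverse $\Delta\Delta G$
  must be within 1 kcal/mol of each other's 95% CI.
* **Mixing**: empirical state-transition matrix, subdominant eigenvalue,
  and a bottleneck flag for low adjacent-state exchange or a disconnected
  transition graph.
* **Slow-DOF scan**: Pearson correlation between $\partial
  U/\partial\lambda$ and each catalogued degree of freedom, per replica,
  combined by Fisher-z mean, with CIs using an effective sample size
  $n/g_{\max}$. The report gives, per category, the max $|PCC|$ with its
  arg-max observable — the one-row analogue of the category heat map; $g$
  of $\partial U/\partial\lambda$ orders multi-archive summaries.

Statistical inefficiency uses $g = 1 + 2\tau$ with the integrated
autocorrelation time summed (FFT autocovariance, unbiased normalization,
$(1 - t/N)$ weights) up to the first non-positive autocorrelation. Angles
are correlated as unwrapped linear quantities, not via sin/cos embedding —
a documented limitation for circular observables near the wrap point.

## The toy systems and what passing means

* **Harmonic ladder** — $K$ Gaussian states with exact free energies
  $f_k = \tfrac12\log(\beta K_k/2\pi)$, recomputed from parameters at build
  time. The MBAR oracle.
* **Planted slow-DOF landscape** — a double-well coordinate $x$ (barrier
  6 kT between minima at $\pm 1$) linearly coupled to $\lambda$ (strength
  2 kT), a fast harmonic bath coordinate with a weaker coupling (0.5 kT,
  deliberately *not* in the DOF catalog, so that the $x$ correlation is
  strong but not trivially 1), and uncoupled spectator coordinates as
  nulls. By construction $\partial U/\partial\lambda = 2x + 0.5b$.
* **Charge-change trio** — three tethered beads (+1 -> 0 on the middle
  "residue") plus the transformable water bead; forward and reverse builds
  satisfy $U_{\text{rev}}(x;\lambda) = U_{\text{fwd}}(x;1-\lambda)$ exactly,
  so forward/reverse cancellation probes the whole sampling + estimation
  pipeline, not the energy model.
* **Bead-residue chain** — PDB-named bead templates (ALA, GLY, SER, THR,
  ARG, ASP) assembled into a short chain with a tethered water and, in the
  complex phase, a tethered charged partner cluster, so the full two-phase
  $\Delta\Delta G$ workflow runs end to end in minutes on one CPU.

These toys emulate the *structure* of the real problem — atom classes,
charge changes, slow coordinates coupled to the alchemical coordinate,
two-phase thermodynamic cycles — but not its physics: no explicit solvent,
no periodic electrostatics, no force-field realism, interaction networks of
a handful of beads rather than a protein interface. Passing tests therefore
certify the *machinery* (energies, samplers, estimators, diagnostics are
mutually consistent and match analytic references), not the accuracy of any
production prediction.

## Problem sizes

The validation suite and the acceptance script use: 5,000 samples/state and
200 bootstrap replicates for the MBAR oracle; $10^4$ swap attempts against
2-D quadrature; $10^5$-point AR(1) series for the inefficiency oracle; 300-
iteration AREX runs (6 states) for planted-DOF recovery over 10-20 seeds;
2,400-iteration runs (40 MD steps each) for the AREST-vs-AREX comparison
over 5 seeds; and 250-iteration, 12-state runs for the charge-change trio.
These sizes were chosen so each property is resolved well beyond its decision
threshold while the whole suite completes in minutes on a single CPU.

## Known limitations

* Direct-space electrostatics only; no reciprocal-space or self terms, no
  periodic boundary conditions, no neighbour lists (all-pairs $O(N^2)$).
* Bead-level residue templates with invented (if plausible) parameters;
  no proline/backbone-cycle mutations; $|\Delta q| \le 1$.
* Finite-difference $\partial U/\partial\lambda$ (exact only for
  $\lambda$-linear potentials).
* The statistical inefficiency of a trace that never crosses a barrier
  *underestimates* the true correlation time — the AREST-vs-AREX
  comparison therefore uses runs long enough that both samplers hop.
* Circular observables are unwrapped, not embedded.
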