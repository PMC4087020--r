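---
title: "Methods: mixed-micelle thermodynamics and coarse-grained self-assembly analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-micelle thermodynamics and coarse-grained self-assembly analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micellemix)
```

`micellemix` analyses binary mixed micellisation of sodium cholate (NaCA, a
rigid biplanar bile-salt surfactant) and sodium dodecylsulphate (SDS, a
classical single-tail anionic surfactant) on three levels: regular-solution
thermodynamics of the critical micelle concentration (cmc), extraction of
cmc values from raw measurement curves, and structural statistics of
coarse-grained (CG) self-assembly trajectories. This vignette records the
models, the tunable parameters, the design choices made where the design
was genuinely open, and the limits of what the synthetic data can show.

## 1. Regular-solution thermodynamics

For a binary surfactant mixture with bulk mole fraction $\alpha_1$ of
component 1 and pure-component cmc values $c_1$, $c_2$, ideal mixing
predicts the mixed cmc through Clint's relation

$$\frac{1}{c^{id}} = \frac{\alpha_1}{c_1} + \frac{1-\alpha_1}{c_2}.$$

Rubingh's regular-solution treatment of the micellar pseudo-phase yields
the micellar mole fraction $x_1$ of component 1 as the root of

$$x_1^2 \ln\frac{\alpha_1 c^{mix}}{x_1 c_1} =
  (1-x_1)^2 \ln\frac{(1-\alpha_1)\, c^{mix}}{(1-x_1)\, c_2},$$

and the interaction parameter

$$\beta_{1,2} = \frac{\ln\left(\alpha_1 c^{mix} / (x_1 c_1)\right)}{(1-x_1)^2}.$$

$\beta_{1,2} < 0$ signals synergism: net attractive interactions between
the unlike building units that push the mixed cmc below the ideal
prediction. For NaCA + SDS the packaged table (`nacasds_cmc_table()`)
gives $\beta_{1,2}$ between roughly $-3$ and $-4.3$ over 0--50 °C, with an
essentially equimolar micelle ($x_1 \approx 0.50$--$0.51$).

*Numerical choices.* The root is found with Brent's method
(`stats::uniroot`) on the bracket $(10^{-6}, 1-10^{-6})$ with tolerance
$10^{-12}$; the residual at the returned root must be below $10^{-10}$ or
the call fails explicitly. When the residual does not change sign on the
bracket there is no physical micellar composition for the inputs and the
function says so rather than returning a boundary value. The two
equivalent component-wise expressions for $\beta$ agree to $10^{-6}$ at
the root — this is tested, since it *is* the statement that the implicit
equation holds. Full precision is carried throughout;
rounding to the table's printed precision (two decimals for cmc and
$\beta$, three for $x_1$) happens only when comparing with printed values.
The mixture cmc used in the Rubingh step is the fluorimetric one: it is
the series that reproduces the table's derived columns. Experimental
uncertainties are carried as columns of the packaged table but are not
propagated through the equations.

## 2. cmc extraction from raw curves

**Fluorimetric titrations.** The pyrene $I_1/I_3$ polarity ratio falls
sigmoidally at micellisation. `fit_boltzmann()` fits
$y = a_2 + (a_1-a_2)/(1+\exp((x-x_0)/dx))$ by Levenberg--Marquardt least
squares (`minpack.lm::nlsLM`) with data-driven starts: plateaus from the
first/last quartile means, $x_0$ from the steepest finite-difference
point, and a ladder of width guesses ($\mathrm{span}/10, /20, /5, /40,
/3$) tried in turn, which makes convergence robust without any internal
randomness. The cmc is reported as the inflection $x_0$ — the paperless
convention choice here; the inflection is symmetric in the two plateaus,
whereas "onset" definitions depend on an arbitrary threshold. A fitted
$dx<0$ is normalised to $dx>0$ by swapping the plateaus (the same curve).

**Conductivity.** $\kappa(c)$ of an ionic surfactant breaks slope at the
cmc because micelle-bound counterions stop contributing independently.
`fit_breakpoint()` grid-searches candidate breakpoints (each interior
point and the midpoints between consecutive points, with at least 3
points per side), fits independent least-squares lines to the two
segments, and accepts the segmented model only if (i) an F-test against
the single-line fit gives $p < 0.05$ *and* (ii) the post/pre slope ratio
differs from 1 by more than 5%. Both guards are needed: with exact or
near-exact data the F statistic alone is unstable, and a significant but
tiny slope change is physically meaningless. The accepted breakpoint is
refined to the intersection of the two fitted lines. The counterion
binding fraction is the ratio-of-slopes convention
$f = 1 - S_2/S_1$, clipped to $[0,1]$. A mixture whose micelle surface
charge is *not* neutralised by counterions shows no breakpoint; the
deliberately conservative two-guard rule reproduces that verdict on
single-line synthetic data without false positives.

**Tensiometry.** `fit_cmc()` applies the same breakpoint machinery to
(log$_{10}$ concentration, surface tension) — the standard
$\gamma$--$\log c$ analysis — and maps the breakpoint back to
concentration. The binding fraction is not reported for tension data.

## 3. The coarse-grained data model

SDS is mapped to 4 beads (tail C4--C2--C1 and the charged SO3 head), the
cholate anion to 8 beads (hydrophobic steroid-face beads R1--R3, the
hydrophilic-face beads RO2, RO3, ROH, a C1 tail bead — classed
hydrophobic — and the charged carboxylate OCO), and Na$^+$ to one bead.
Net charges are $-1$ per surfactant and $+1$ per counterion, so a neutral
system carries one Na$^+$ per surfactant. Internal lengths are Angstrom
(the analysis cutoffs are quoted in Å); GRO files (nm) are converted on
read and write. Beads are mass-unweighted in all centre-of-mass and
gyration computations: CG bead masses are near-uniform and no bead masses
are part of the model — this is a documented knob, not a fitted choice.
Water is implicit everywhere.

Geometry under cubic periodic boundary conditions uses the minimum-image
convention. Cluster-level quantities first unwrap the cluster by
minimum-image displacement relative to its first bead, which is exact for
aggregates smaller than half the box — true by construction for every
configuration considered here.

## 4. Cluster, shape, ion and orientation statistics

Two surfactants are directly linked when their *closest-bead*
minimum-image distance is strictly below the 7 Å cutoff; clusters are the
connected components of this graph (igraph), with singletons counted as
size-1 clusters. The strict `<` at the cutoff is pinned by a test. Ions
and water never participate in clustering.

The number of clusters (NOC), condensed/free counterion counts, and any
other per-frame observable are summarised with block averages: 100 ns
blocks over an analysis window (default 0.6--10 µs, the post-assembly
regime), reporting per-block means plus the overall mean and standard
deviation of the per-frame values in the window. A trailing partial block
is dropped with a warning.

A Na$^+$ ion is *condensed* when it sits within 7 Å (strict) of any
negatively charged surfactant bead (SO3 or OCO) — a per-ion, per-bead
criterion, not a per-micelle one. Condensed + free = total in every
frame, by construction.

Shape is described by the mass-unweighted gyration tensor
$S = \langle (r-\bar r)(r-\bar r)^T\rangle$ with sorted eigenvalues
$\lambda_x \ge \lambda_y \ge \lambda_z$ and the relative shape anisotropy

$$K^2 = 1 - 3\,\frac{\lambda_x\lambda_y + \lambda_y\lambda_z +
\lambda_x\lambda_z}{(\lambda_x+\lambda_y+\lambda_z)^2},$$

which is 0 for spherically symmetric bead sets, 1 for collinear ones, and
$1/3$ for $\lambda = (2,1,0)$. A fully degenerate cluster (all beads
coincident) is defined to have $K^2 = 0$.

Radial profiles histogram the distance of selected beads (molecule kind +
bead name) from their cluster's unwrapped centre of mass, pooled over
clusters of at least 20 molecules, in 1 Å left-closed bins (a bead exactly
on an edge belongs to the outer bin), each selector normalised to sum
to 1. The raw normalised histogram is the default; an $r^2$-weighted
(shell-volume) density is available via `r_weighted = TRUE` — the choice
between the two conventions is genuinely open for this kind of analysis,
so it is a switch rather than a fixed decision.

SDS orientation inside a micelle is the angle $\Theta$ between the
head-to-tail vector (SO3 → C4) and the head-to-centre vector (SO3 →
cluster COM): $\Theta = 0$ means the tail points along the radius toward
the core, $\Theta = 180°$ radially outward. This vector pair is the
simple definition under which "$\Theta$ near zero = radially oriented
toward the COM" is true; molecules with a degenerate (zero-length) vector
are skipped and counted.

The per-size SDS content $x_2$ averages the per-cluster SDS fraction with
*equal weight per cluster* ("averaged over all aggregates"), not weighted
by cluster size; sizes observed only once report `NA`, not 0, for their
spread.

## 5. Synthetic data: what it emulates and what it cannot show

Every analysis stage is exercised against generated inputs with known
ground truth; all generators are bit-reproducible given their seed and
leave the caller's RNG stream untouched.

**Curves** (`generate_curve()`): Boltzmann sigmoids, one- or two-segment
conductivity lines, and $\gamma$--$\log c$ tension curves, plus additive
Gaussian noise. The default recovery experiments use 30 points over
1--10 mM with $\sigma = 0.01$ on the $I_1/I_3$ ratio, a noise level
consistent with a titration whose relative cmc error stays within a few
percent.

**Constructed configurations** (`build_configuration()`): aggregates with
chosen composition and geometry (molecule centres uniform in a ball, or a
bounded-step random walk inside a cylinder for rods), free monomers, and
a planted counterion partition. Distinct groups are separated by more
than 14 Å at their closest beads and aggregates are internally connected
under the 7 Å criterion (verified, with bounded retries), so the cluster
and ion analyses must recover the planted truth *exactly* — these
round-trips are the backbone of the trajectory-analysis tests. Planted
condensed ions are placed 2.5--6 Å from a charged bead, free ions beyond
10 Å of all of them.

**Toy aggregation** (`run_toy_aggregation()`): overdamped Langevin
dynamics ($\gamma = 1$, $k_BT = 1$, step 0.02 reduced time units) on bead
chains with harmonic bonds ($k = 10$, $b_0 = 4$ Å), Lennard-Jones
interactions ($\sigma = 4.3$ Å, cutoff 12 Å) and a screened-Coulomb term
(strength 15, screening length 10 Å) between charged beads. The well
depths encode the driving forces of the mixed system: SDS-tail pairs are
deep (base 0.3 + 4.5), tail--cholate-ring pairs intermediate
(base + 30%), cholate--cholate shallow (base + 5%), everything else
essentially excluded-volume. The default run is 30 SDS + 30 CA + 60
Na$^+$ in a cubic box sized to the reference effective surfactant
concentration of 12.28 mM (edge ≈ 201 Å), integrated for 40 000 steps
with a frame every 400; frame times are mapped linearly onto a nominal
0--10 µs span so the windowed analyses can run with their physical
defaults. Forces are component-capped (60 reduced units) for stability
and the integrator aborts on any non-finite coordinate.

These choices were made once, as generator design, to produce the
mechanism the analyses need to see: spontaneous aggregation from a
dispersed start (NOC drops from ~52 to ~34 at the default seed),
SDS-enriched cores in the largest aggregates, loosely bound cholate that
exchanges with the free-monomer pool, and a small condensed-ion
population. The simulator makes *no* claim of Martini fidelity: it has no
explicit water, no realistic hydrodynamics, and its clock is nominal.
Quantities that depend on the real force field and on microsecond-scale
equilibration — the equilibrium NOC, the 66.6% mean SDS content, the
5.9/54.0 condensed/free split, the trimodal size distribution — are
treated as qualitative reference points only; the package's quantitative
tests for the trajectory stack are oracle-equivalence, planted-truth
round-trips, exact landmark values of $K^2$, conservation laws, and the
qualitative aggregation mechanism at a fixed seed. Passing them shows the
*operations* are correct, not that the toy model reproduces the physical
system.

## 6. Problem sizes

The test suite runs entirely on synthetic data built at call time:
brute-force oracle comparisons use up to 20 molecules per frame (100
random frames), planted round-trips use 50 randomised configurations,
the $K^2$ bound is checked on 1000 random bead sets, titration recovery
uses 100 seeded curves, and one toy trajectory at the full 30 + 30
reference composition is analysed end to end. These sizes keep the whole
suite within a few minutes on one CPU while leaving every code path
exercised at the same composition and parameter values the reference
system uses.

## 7. Known limitations

* The printed reference table's $x_1$ values at the temperature extremes
  differ from the exact root of the standard Rubingh system by up to
  0.002 (and the $\beta$ values correspondingly by a few hundredths);
  they were most plausibly computed from unrounded experimental cmc
  values. The package keeps the standard equations at full precision and
  documents the comparison at printed precision.
* Counterion binding from conductivity uses the ratio-of-slopes
  convention; other conventions (e.g. Evans' equation) are out of scope.
* The GRO reader supports the fixed-column single-precision layout with
  cubic boxes only, and velocities are ignored.
* Cluster unwrapping assumes aggregates smaller than half the box edge.
* The toy simulator's time axis is nominal; rates measured on it are not
  physical rates.
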