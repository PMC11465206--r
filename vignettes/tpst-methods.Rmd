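---
title: "Trivariate penalized splines over tetrahedral triangulations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trivariate penalized splines over tetrahedral triangulations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpst3d)
```

## The problem and the model

Volumetric measurements — PET intensities over a brain mask, scattered
sensor readings in a 3D region, any noisy point cloud with responses — often
live on domains that are non-convex or have holes.  Tensor-product and
thin-plate smoothers measure closeness in Euclidean distance and therefore
*leak* across gaps: two points on opposite arms of a horseshoe are close in
space but far apart within the domain.

`tpst3d` fits the nonparametric regression model

$$W_i = m(p_i) + \sigma(p_i)\,\varepsilon_i, \qquad p_i \in \Omega \subset \mathbb{R}^3,$$

with $m$ a smooth unknown function, $\sigma(\cdot)$ a possibly
heteroscedastic noise scale, and $\varepsilon_i$ i.i.d. mean-zero,
unit-variance errors.  The estimator is a *trivariate penalized spline over
a triangulation* (TPST): the domain is partitioned into tetrahedra
$\Delta = \{T_1,\dots,T_N\}$, and $m$ is estimated within the spline space
$\mathcal{S}_d^r(\Delta)$ of piecewise degree-$d$ polynomials that are
globally $C^r$.  Because basis functions are supported on single tetrahedra
and smoothness is imposed only across *shared faces*, no information travels
across holes or gaps — the partition itself encodes the domain geometry.

## Bernstein–Bézier form

On a tetrahedron $T = \langle v_1, v_2, v_3, v_4\rangle$ every point has
barycentric coordinates $b_1,\dots,b_4$ ($\sum b_m = 1$), and the degree-$d$
Bernstein basis is

$$B^{d}_{ijkl}(p) = \frac{d!}{i!\,j!\,k!\,l!}\, b_1^i b_2^j b_3^k b_4^l,
\qquad i+j+k+l = d,$$

with $M = \binom{d+3}{3}$ members.  A spline is stored as the stacked
vector $\gamma$ of per-tetrahedron B-coefficient blocks
(`multiindex_table()` fixes the within-block order: lexicographic with the
first index outermost, descending).  Evaluation uses direct basis summation;
the de Casteljau recurrence is implemented as an independent cross-check and
the two agree to $10^{-12}$ relative in the test suite.  Directional
derivatives obey the coefficient recurrence
$D_u s = d \sum_m a_m \gamma_{\eta + e_m} B^{d-1}_\eta$ where $a$ is the
(constant) barycentric representation of the direction $u$; Cartesian
operators $D^\alpha$, $|\alpha| \le 2$, are compositions of axis
directions and commute exactly.

## Smoothness constraints

$C^r$ continuity across an interior face is a set of linear conditions on
the B-coefficients of the two incident tetrahedra.  With the face vertices
taken in sorted global order $(f_1,f_2,f_3)$, the lower-index tetrahedron
$T = \langle w, f_1,f_2,f_3\rangle$ as source and the higher-index
$\tilde T = \langle \tilde w, f_1,f_2,f_3\rangle$ as target, the order-$m$
condition reads

$$\tilde\gamma_{m,j,k,l} \;=\; \sum_{|\mu| = m}
  \gamma_{\mu_1,\, j+\mu_2,\, k+\mu_3,\, l+\mu_4}\;
  B^{m}_{\mu}(b(\tilde w)),$$

for all $(j,k,l)$ with $j+k+l = d-m$ and all $m = 0,\dots,r$, where
$b(\tilde w)$ are the barycentric coordinates of the target's off-face
vertex relative to $T$.  Stacking these rows over all interior faces gives
the sparse constraint matrix $H$ with $H\gamma = 0$ exactly characterising
$\mathcal{S}_d^r$.  The package's ground-truth test evaluates random
constrained splines from both sides of every face (values, and first
derivatives when $r \ge 1$) — this pins the semantics of $H$ independently
of its algebra.

The constraints are removed by an orthonormal null-space basis $Q_2$
($\gamma = Q_2\theta$):

* for $r \ge 1$, a dense SVD of $H$, treating singular values below
  `rank_tol` (default $10^{-9}$, relative) as zero — $H$ is genuinely
  rank-deficient whenever constraint cycles close around interior edges, so
  rank detection matters;
* for $r = 0$, an exact combinatorial route: the $C^0$ conditions simply
  identify matching face-lattice coefficients, so union–find over these
  identifications yields disjoint coefficient classes whose normalized
  indicator vectors form a sparse orthonormal basis.  The two routes agree
  on every test mesh (including meshes with holes, where a purely geometric
  merge would be wrong — touching tetrahedra without a shared face must not
  be identified).

## Roughness penalty

Overfitting is controlled by the thin-plate-type energy

$$\mathcal{E}(s) = \sum_{|\alpha| = 2} \binom{2}{\alpha_1\,\alpha_2\,\alpha_3}
  \int_\Omega \bigl(D^\alpha s\bigr)^2,$$

i.e. weights $(1,2,2,1,2,1)$ on
$(s_{xx}, s_{xy}, s_{xz}, s_{yy}, s_{yz}, s_{zz})$ — the multinomial
weighting that makes the energy rotation-invariant (a property the test
suite verifies under random rigid motions).  Per tetrahedron,
$\mathcal{E}(s_T) = \gamma_T^\top P_T \gamma_T$ with

$$P_T = \sum_{|\alpha|=2} w_\alpha\, G_\alpha^\top\, \mathrm{Gram}_{d-2}\, G_\alpha,$$

where $G_\alpha$ is the Cartesian derivative operator and the Gram matrix of
the degree-$(d-2)$ basis has the closed form
$V_T \prod_m \binom{\alpha_m+\beta_m}{\alpha_m} \big/
\bigl[\binom{2d'}{d'}\binom{2d'+3}{3}\bigr]$.  Assembly is therefore exact —
no quadrature, no tuning of integration degree; Gauss–Legendre quadrature
(via the Duffy transform) appears only as the independent oracle in tests.
$P_T$ is positive semidefinite with null space exactly the affine
polynomials, so $P = \mathrm{diag}(P_T)$ vanishes precisely on piecewise
affine splines.

## The estimator

TPST solves

$$\min_{\gamma}\ \sum_i \bigl(W_i - B^d(p_i)^\top\gamma\bigr)^2
  + \rho\, \gamma^\top P \gamma
  \quad\text{s.t.}\quad H\gamma = 0,$$

which after the substitution $\gamma = Q_2\theta$ has the closed form

$$\hat\theta_\rho = \bigl(Q_2^\top B^\top B Q_2 + \rho\, Q_2^\top P Q_2\bigr)^{-1}
 Q_2^\top B^\top W, \qquad \hat m_\rho(p) = B^d(p)^\top Q_2 \hat\theta_\rho.$$

The reduced $q \times q$ system is solved by Cholesky factorization.  Two
limits anchor the estimator and are tested: at $\rho = 0$ it is the
unpenalized least-squares spline (exact reproduction of noiseless
degree-$\le d$ polynomial data), and as $\rho \to \infty$ it shrinks to the
least-squares fit in the penalty's null space — the global affine fit for
$r \ge 1$ on a connected domain (effective degrees of freedom $\to 4$), the
continuous piecewise-linear fit for $r = 0$.  On small meshes the
reduced-solver solution is checked against a dense Lagrange-multiplier
(KKT) solve of the constrained problem.

**Degenerate designs.**  Data-free tetrahedra (inevitable under block
cross-validation and block missingness) can make the reduced system
singular.  The default policy adds a flagged relative ridge
($10^{-10} \cdot \operatorname{mean diag}$) only when the Cholesky
factorization fails; `ridge = 0` turns this into an error that names the
data-free tetrahedra.  With $\rho > 0$ and $r \ge 1$ the penalty usually
regularizes everything except the cases the ridge exists for.

**Effective degrees of freedom.**  $\mathrm{edf} = \operatorname{tr}\!\bigl[
B Q_2 A^{-1} Q_2^\top B^\top\bigr] = \operatorname{tr}(A^{-1} G_r)$ is
computed exactly from the Cholesky factor whenever $q \le 5000$ (always the
case at the package's study sizes); a seeded Hutchinson estimator is the
fallback beyond that.

## Choosing the penalty parameter

Two selectors are provided, both returning the full per-$\rho$ table:

* **GCV**: $n\,\mathrm{RSS}(\rho) / (n - \mathrm{edf}(\rho))^2$, the
  canonical criterion for penalized linear smoothers.
* **Tetrahedron-block CV**: spatially dependent data make pointwise CV
  over-optimistic, so whole tetrahedra are randomly assigned to $k$ folds
  (default 5) and all points of a fold's tetrahedra are held out together.
  Fold assignment is seed-parameterized and recorded in the fit.

The default grid is 20 log-spaced points on $[10^{-6}, 10^4] \times s$ with
the scale-equivariant bracket
$s = \operatorname{tr}(Q_2^\top B^\top B Q_2) /
\operatorname{tr}(Q_2^\top P Q_2)$; ties in the grid argmin resolve to the
smaller $\rho$ (less bias).

## Wild-bootstrap uncertainty maps

Exact variance formulas for the TPST estimator are unwieldy, and the noise
is typically heteroscedastic, so standard errors come from the wild
bootstrap: residuals $\hat e_i = W_i - \hat m(p_i)$ are perturbed as
$W_i^* = \hat m(p_i) + \delta_i \hat e_i$ with i.i.d. two-point
golden-ratio weights $\delta_i = (1 \pm \sqrt5)/2$ with probabilities
$(5 \mp \sqrt5)/10$ (mean 0, variance 1, third moment 1); the estimator is
re-applied with the *identical* mesh, degree, smoothness and $\rho$ (no
re-selection inside the bootstrap — the replicate must mimic the original
fit, and re-selection would be far costlier); and

$$\widehat{SE}(p) = \Bigl[\tfrac1B \sum_b
  \bigl(\hat m^*_b(p) - \bar{\hat m}^*(p)\bigr)^2\Bigr]^{1/2},$$

with divisor $B$ (default $B = 100$).  Since the design matrix is unchanged,
each replicate reuses the stored Cholesky factor and costs one triangular
solve.  A replication study in the test suite (horseshoe domain, noise SD
$\sigma(p) = 6 - \lVert p - (1.25,0,0)\rVert$ decreasing along the arms,
100 Monte-Carlo replicates) confirms the mean bootstrap SE tracks the
Monte-Carlo SD of $\hat m$ within a few percent at all probe points.

## Synthetic designs

The generators emulate the canonical simulation settings so that every
stage is testable without external data:

* **Domains.**  `box_with_hole`: a $3\times1\times1$ box with a
  $1\times0.4\times0.4$ hole centered inside — these proportions make the
  in-domain voxel counts of the $60\times20\times20$ and
  $75\times25\times25$ grid designs come out near 22,160 and 42,600.
  `horseshoe3d`: an extruded annular C (inner radius 0.5, outer 1,
  thickness 0.5) whose opening is a 15° half-angle wedge, with optional
  straight arms of length 1 prolonging the half-annulus; with arms present
  the arms' slab is the gap (the wedge is subsumed), without arms the wedge
  is the gap.  Membership is a closed-form predicate; a "pillar"
  construction that extended the cut faces *into* the opening was rejected
  because it fills the gap, and the gap is the scientific point of the
  domain.
* **Signals.**  Four fixed functions on rescaled coordinates
  ($\tilde x,\tilde y,\tilde z \in [0,1]$ over the domain's bounding box):
  $m_1 = \sin\pi\tilde x + \cos\pi\tilde y + \tilde z^2$,
  $m_2 = \sin3\pi\tilde x\cos3\pi\tilde y\sin2\pi\tilde z$,
  $m_3 = \cos\pi\tilde x\sin\pi\tilde y + \tilde z$,
  $m_4 = \sin2\pi\tilde x\cos2\pi\tilde y + \sin2\pi\tilde z\cos\pi\tilde x$.
  All four are $C^\infty$ on the whole bounding box — deliberately chosen
  over arc-length parametrisations of the horseshoe, whose angular
  coordinate has a branch cut inside the box.  The high-frequency variants
  $m_2, m_4$ have strictly larger empirical total variation than
  $m_1, m_3$ (asserted in tests), emulating signals of different roughness.
* **Noise.**  Gaussian; calibrated either by an explicit $\sigma$ (scalar
  or a function of location, e.g. `sigma_distance()` for the
  heteroscedastic SE study) or by a peak signal-to-noise ratio,
  $\sigma = \max|m| / 10^{\mathrm{PSNR}/20}$; PSNR 5 and 10 are the
  high/moderate-noise conventions.
* **Missingness.**  `random` removes exactly $\lfloor \mathrm{rate}\cdot
  n\rfloor$ points (an exact count, not Bernoulli thinning, so tests can
  assert sizes); `block` removes an axis-aligned sub-box holding about 12%
  of the data (seeded center, half-widths found by bisection on the
  captured fraction) and then applies the random scheme to the remainder.

What the generators do *not* emulate: spatially correlated noise,
non-Gaussian errors, intensity-dependent PET noise, scanner point-spread
blur.  Passing tests therefore demonstrate correctness of the estimator
pipeline under idealized noise, not end-to-end fidelity on a real scanner.

## Meshes

Arbitrary tetrahedral meshes come in via TetGen `.node`/`.ele` pairs (0- or
1-based, auto-detected) or a JSON dialect; the built-in generator covers
fixtures and the simulation studies by Kuhn-splitting each cell of a
regular grid into 6 tetrahedra (conforming across cells) and keeping a
tetrahedron iff its centroid lies in the domain.  Stored vertex order is
canonicalized to positive signed volume; all index conventions downstream
refer to the canonical order.  `suggest_mesh_size()` implements the
$N \approx \lfloor c_1 n^{\gamma}\log n + c_2\rfloor$ fineness heuristic.
Surface reconstruction, constrained Delaunay meshing, and refinement loops
are out of scope — the centroid rule means the mesh only approximates the
domain near curved or off-grid boundaries, so a small fraction of boundary
points can fall outside the mesh and are dropped with a warning.

## Numerical choices

* Point location: a point belongs to a tetrahedron when all barycentric
  coordinates are $\ge -10^{-10}\cdot|\Delta|$; face/edge/vertex ties
  resolve deterministically to the lowest tetrahedron index.
* Overlap validation samples a fixed interior point set per tetrahedron
  (bounding-box-filtered pairs); exact geometric predicates are a non-goal.
* `rank_tol` $= 10^{-9}$ (relative) for the SVD rank decision; the
  resulting basis always satisfies $\lVert H Q_2\rVert_\max < 10^{-10}$ in
  tests.
* All randomness (cloud generation, folds, bootstrap weights, probes) is
  seed-parameterized, and seeded helpers restore the caller's RNG state.
* Model archives serialize doubles as `%.17g` strings, so save/load
  round-trips reproduce predictions bit-for-bit; the mesh travels with an
  md5 content hash, and $Q_2$ is rebuilt deterministically from
  (mesh, $d$, $r$, `rank_tol`) rather than stored.

## Study sizes and defaults

Defaults are $d = 3$, $r = 1$ — cubic splines with one order of global
smoothness, the standard compromise between flexibility and dimension.  The
package's built-in studies use:

* convergence: box-with-hole, random design, $n = 5{,}000$ vs $40{,}000$,
  PSNR 10, signal $m_2$, meshes $6\times2\times2$ (140 tets) and
  $9\times3\times3$ (468 tets) at $d = 2, r = 0$ — the $C^0$ quadratic
  space grows richly with refinement, which is what a mesh-resolution
  comparison needs (low-degree $C^1$ spaces are well known to lock);
* missing data: the $60\times20\times20$ grid design at $d = 3, r = 1$.
  This choice is substantive: with a 12% contiguous block removed, a $C^0$
  space leaves unpinned penalty-null directions inside the block, whereas
  the $C^1$ constraints and the energy penalty extend the fit smoothly
  through it;
* bootstrap calibration: horseshoe grid design ($\approx 8{,}400$ in-domain
  voxels), 100 Monte-Carlo replicates, $B = 50$ bootstrap samples, 10 probe
  points.

These sizes were chosen so each study isolates one property at a scale
where Monte-Carlo error is small relative to the effect being measured.

## Known limitations

* The null-space reduction is dense for $r \ge 1$; meshes beyond a few
  hundred tetrahedra at $d = 3$ become expensive.  Local (minimal
  determining set) bases and banded solvers are deliberately out of scope.
* Homoscedastic least squares only — no heteroscedastic weighting in the
  loss, no non-Gaussian likelihoods (uncertainty under heteroscedasticity
  is handled by the wild bootstrap instead).
* The structured mesh generator's centroid rule gives a staircase
  approximation of curved boundaries; high-quality boundary-conforming
  meshes should be produced externally and imported.
* Derivative operators stop at order 2 (all the penalty needs).
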