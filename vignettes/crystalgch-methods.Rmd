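---
title: "Methods: adapted kernels and generalized convex hulls for molecular crystal landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adapted kernels and generalized convex hulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystalgch)
```

# Scope and model

`crystalgch` analyses crystal structure prediction (CSP) landscapes of a
fixed molecule. Its inputs are periodic structures (extended XYZ or minimal
P1 CIF), each annotated with a lattice energy in kJ/mol and optionally a
density and a binary class label, plus the molecular topology (elements and
covalent bonds). Structure generation and lattice-energy calculation are
out of scope: the package consumes CSP output, it does not produce it.

## Atomic environments

Each atom's environment is described by the SOAP power spectrum. The
neighbour density of species $s$ around a central atom is a sum of
Gaussians of width $\sigma$ (default 0.5 Å) on all neighbours of that
species within the cutoff $r_c$, periodic images included and the central
atom included in its own species channel. The density is expanded as

$$ c^{s}_{blm} = \int g_b(r)\, Y_{lm}(\hat r)\, \rho_s(\mathbf r)\, d^3r $$

and contracted to the invariant power spectrum

$$ \rho(x)_{b_1 b_2 l}^{\alpha\beta} = \pi\sqrt{\tfrac{8}{2l+1}}
   \sum_m c^{\alpha}_{b_1 l m} c^{\beta}_{b_2 l m}, $$

with the local kernel between environments the plain dot product of these
vectors (exponent 1; normalization happens only at the global level).
Storage keeps each unordered species pair once, with $\sqrt2$ weights on
off-diagonal blocks so the dot product still equals the unrestricted sum.

**Radial basis and quadrature.** $g_b$ are spherical Gaussians centred
evenly on $[0, r_c]$ with width $r_c/\max(n_\mathrm{max}, 2)$,
orthonormalized symmetrically ($S^{-1/2}$) under the $r^2\,dr$ measure.
Radial integrals use Gauss–Legendre quadrature (60 nodes by default); the
per-neighbour radial kernel is evaluated through exponentially scaled
modified spherical Bessel functions, which is stable at all $r R/\sigma^2$.
The expansion is cross-checked in the tests against direct 3D grid
integration of the density (no Bessel identity involved) to $10^{-6}$.

**Defaults.** $n_\mathrm{max} = 8$, $l_\mathrm{max} = 6$, $\sigma = 0.5$ Å.
Only the cutoff is treated as a physically motivated choice (4 Å for
conformation-scale features, 8 Å for long-range features such as density);
results quoted anywhere should record all four parameters, and the kernel
files written by `save_kernel()` carry a parameter hash for that reason.
The cutoff is sharp at the atom centres; no smoothing function is applied.

## The analogous-atom kernel

For molecular crystals, atom pairs occupying different intramolecular
positions cannot be interchanged without breaking bonds, so their local
kernels should not enter a similarity measure. After
`partition_molecules()` maps every molecule copy onto a single reference
indexing (element-coloured VF2 graph isomorphism with exact edge-count
matching; periodic images unwrapped so molecules stay whole), the adapted
kernel only compares analogous atoms:

$$ K_q(A,B) = \frac{1}{N S T} \sum_{a=1}^{S}\sum_{b=1}^{T}\sum_{i=0}^{N-1}
   k(A_{a,i}, B_{b,q(i)}), \qquad
   K(A,B) = \frac{1}{Q}\sum_{q} K_q(A,B), $$

where $q$ runs over the molecular point-group operations realized as atom
permutations (`find_mappings()`: element-preserving bond-graph
automorphisms accepted when an orthogonal — proper or improper — best-fit
superposition of the permuted onto the reference coordinates has RMSD
below 0.1 Å; the tolerance is configurable and the accepted set always
forms a closed permutation group containing the identity). Averaging over
$q$ rather than maximizing preserves positive semidefiniteness. Mappings
are computed from one reference conformation, so symmetric molecules must
be conformationally rigid across the set; `validate_set()` flags violations
and flags mixed-Z′ sets of symmetric molecules as outside the kernel's
stated applicability.

**Factorized implementation.** Because the copy sums factorize, the kernel
matrix is built from per-index features averaged over molecule copies and
then over the mapping group; the matrix is their Gram matrix divided by
$N$. This is algebraically identical to the pairwise definition (the group
average is an orthogonal projector), exactly symmetric, and PSD by
construction; the pairwise routine `adapted_pair()` is kept as the
reference implementation and the two are required to agree to $10^{-10}$
in the tests. The final matrix is normalized once,
$K'(A,B) = K(A,B)/\sqrt{K(A,A)K(B,B)}$; normalization is not applied per
operator because the operator average is defined on raw kernels.

Comparisons for a crystal need only one copy of the asymmetric unit; for
the P1 cells used throughout, the asymmetric unit is the whole cell and
$Z'$ is the number of molecules in it.

## kPCA and the generalized convex hull

`kpca()` double-centers the normalized kernel and eigendecomposes it;
descriptor $j$ is $\sqrt{\lambda_j}\,v_j$. Eigenvalues below
$-10^{-8}\lambda_{\max}$ abort with a kernel-integrity error; smaller
negatives are clipped. Coordinates are unique up to per-component sign, and
every downstream quantity is sign-invariant (asserted by tests).

The hull is built over (leading $d$ kPCA coordinates, energy), energies
taken relative to the set minimum and descriptors on their raw kPCA scale
(no rescaling; the choice matters and is recorded here deliberately — the
hull is not invariant to relative descriptor/energy scaling). A structure's
**dressed energy** is its vertical distance above the lower convex
envelope at its own descriptor coordinates; the global minimum therefore
always has dressed energy 0.

**Numerical route.** The envelope value at a point is the optimum of the
convex-combination linear program
$\min_\lambda E^\top\lambda$ s.t. $C^\top\lambda = x$,
$\sum\lambda = 1$, $\lambda \ge 0$, solved per structure
(`boot::simplex`), with an exact monotone-chain fast path at $d = 1$. This
is mathematically identical to enumerating lower facets of the hull (by
Carathéodory the optimum is attained on a facet simplex) and avoids any
dependence on a facet-enumeration geometry code; hull vertices are
recovered as the dressed-energy-zero set. Degenerate descriptor geometry
(affine rank $< d$) falls back to the spanned subspace with a warning;
dressed energies below $10^{-9}$ kJ/mol are clipped to zero.

**Candidate pools.** The pool for a set of known polymorphs is every
structure whose dressed energy is at most the largest known dressed energy
(ties at the window included). Baselines: the smallest relative-energy
cutoff containing all knowns, and the same hull machinery run on a single
intuitive descriptor (density by default, any user descriptor accepted).

**Energy-noise resampling.** Uncertainty in calculated energies is
propagated by rebuilding hull and pool `iterations` times (default 250)
with i.i.d. noise added to every energy, drawn uniformly on
$[-e\sqrt3, +e\sqrt3]$ so its standard deviation equals the requested
error estimate $e$ — the only reading consistent with "uniform, centred on
zero, with a given standard deviation". kPCA coordinates are computed once
(energies do not enter the kPCA, so there is nothing to recenter per
iteration). One seeded generator draws the noise structure-by-structure in
a fixed order, making runs bitwise reproducible. Ensembles are compared
with the two-sided, tie-corrected normal-approximation Mann–Whitney U
test; known-polymorph rankings by dressed energy versus relative energy
with Kendall's tau.

## Descriptor interpretability

Density relationships are scored as the best ordinary-least-squares $R^2$
of density against each of the first 32 kPCA components individually.
Binary structural classes (e.g. a torsion above/below 90°, averaged over
asymmetric-unit copies with ties to class 1, or an approximate geometric
hydrogen-bond assignment: H⋯A < 2.5 Å, D–H⋯A > 120°) are scored by the
balanced accuracy of a linear soft-margin SVC over a hinge-loss weight
grid C ∈ {0.01, 0.1, 1, 10, 100}, either on each of the first 32
components singly or on every nonempty subset of the top five. Because the
original protocol's train/test split is not fixed anywhere we could follow,
accuracies here are estimated by stratified 5-fold cross-validation — a
deliberately conservative choice; in-sample accuracies would be higher.

## GPR energy prediction

The normalized structure kernel is used directly as the prior covariance:
$(K + \alpha I) w = y$ by Cholesky, predictions $K_\star w$. Targets are
energies relative to the current training pool's minimum, recomputed
whenever the pool grows or per fold; the prior mean is zero on those
relative energies and no further standardization is applied. $\alpha$
defaults to $10^{-6}$ (kJ/mol)² and is a jitter/noise setting, not a
fitted hyperparameter; there is no kernel hyperparameter optimization by
design. The learning-curve protocol holds out a fixed random test set,
grows the training set in random disjoint blocks, and reports RMSE/MAE per
cumulative size; k-fold cross-validation and energy-window subsetting
(structures within a window of the global minimum) follow the same
referencing rule.

## The synthetic generator

`make_landscape()` packs rigid copies of a toy molecule into cubic P1
cells: cell volume set exactly from a target density drawn uniformly from
`density_range`, random proper rotations per molecule, and rejection
sampling until no intermolecular (or self-image) contact falls below the
larger of 1.5 Å and the bond-perception cutoff plus 0.05 Å — the second
floor guarantees every generated structure satisfies the partition
invariant by construction. Energies come from a user energy model
(default: 35 kJ/mol per g/cm³, denser is more stable) plus optional
Gaussian noise; conformation is planted by rotating the terminal atom of
the 4-atom chain template to prescribed dihedrals.

Templates: a bent C–N–O triatomic (C1), a water-like AB₂ (one mirror swap,
Q = 2), a square-planar AB₄ (Q = 8), and a C–N–O–S chain with a
configurable dihedral (C1). The chain template exists because a planted
torsion needs four atoms and an *asymmetric* molecule — the adapted kernel
restricts symmetric molecules to rigid conformations, so a torsion-varying
landscape of AB₄ would be invalid by the kernel's own applicability rule.

**What the generator does and does not emulate.** It produces controlled
density–descriptor, conformation–class and energy–descriptor
relationships, which is exactly what the recovery tests need: with density
driving the dominant structural variation, the leading kPCA component of
an 8 Å-cutoff adapted kernel recovers density with $R^2 \approx 0.9$ (and
less at 4 or 10 Å — density is a long-range feature); planted separable
torsion classes are classified at balanced accuracy ≥ 0.95 from the top
five components. The landscapes are *not* physical: packings are random,
not lattice-energy minima; molecules carry no hydrogens; there are no
space-group symmetries, no polymorph basins, and no realistic energy
scale. Passing tests therefore demonstrate the correctness and
signal-recovery behaviour of the machinery, not chemical accuracy on real
CSP sets.

**Default conditions** (used by the tests and the acceptance script, and
chosen once as plausible for the hydrogen-free toy molecules): densities
0.8–1.25 g/cm³ (packing above ~1.3 g/cm³ becomes infeasible under the
contact floor), energy span ~15 kJ/mol per landscape, energy noise 0.8
kJ/mol where scatter is wanted (between the force-field and DFT error
estimates typical for CSP energies), resampling noise 0.5 kJ/mol, torsion
classes |τ| ∈ [30°, 55°] vs [145°, 175°] with random sign. Problem sizes:
100 structures for density/GCH studies, 120 for classification, 200 for
the resampling calibration, 640 (500 training in 100-structure blocks plus
140 test) for GPR learning curves, with SOAP at $n_\mathrm{max} = 4$,
$l_\mathrm{max} = 3$ — deliberately compact bases that keep every study
reproducible in minutes on one CPU while leaving all qualitative behaviour
intact.

## Known limitations

* Bond perception (covalent radii + 0.4 Å) and the rigid-conformation
  check are heuristics; molecules whose graph automorphisms are not
  realizable rigidly, yet map conformers onto each other, are out of scope
  (the direct-product treatment of flexible symmetric molecules is
  deliberately not implemented).
* The hull depends on the relative scaling of kPCA descriptors and energy;
  raw kPCA scale is a convention, not a law.
* The geometric hydrogen-bond detector is a convenience approximation, not
  a crystallographic motif search.
* SOAP parameter sensitivity: quantities derived from the kernel
  (pool sizes in particular) change with cutoff and basis size; the
  package records parameters with every kernel file rather than pretending
  a canonical setting exists.
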