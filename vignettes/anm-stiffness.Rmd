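---
title: "Native protein flexibility from all-atom anisotropic network models"
author: "anmflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Native protein flexibility from all-atom anisotropic network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anmflex)
```

## The model

A folded protein near its native state can be described as an elastic
network: every heavy (non-hydrogen) atom is a node, and every pair of nodes
closer than a cutoff $R_c$ is joined by a Hookean spring of uniform force
constant $\gamma$. The potential is

$$V = \sum_{j<l} \tfrac{1}{2} K_{jl}\,(r_{jl} - r^0_{jl})^2,
\qquad K_{jl} = \begin{cases}\gamma & r^0_{jl} \le R_c\\ 0 &
r^0_{jl} > R_c\end{cases}$$

with $r^0_{jl}$ the distances in the crystal structure. This is the
anisotropic network model (ANM) taken down to atomic resolution: because
every side-chain atom is a node, the contact topology — and with it the
mechanics — becomes sensitive to the amino-acid sequence, not just to the
backbone fold. That is the point of the all-atom variant: two domains with
the same fold but different sequences pack differently and get different
spring networks.

The $3N \times 3N$ Hessian of $V$ at the crystal coordinates decomposes
into normal modes. For a connected network six eigenvalues vanish (rigid
translations and rotations) and the remaining $3N-6$ eigenpairs
$(\kappa_i, \phi_i)$, sorted by ascending $\kappa_i$, describe the internal
motions; $\kappa_i$ is the spring constant of mode $i$ and
$k_BT/\kappa_i$ its thermal variance.

Two stiffness observables are computed from the modes:

* **Overall spring constant.**
  $k_\mathrm{protein} = k_BT/\sigma^2$ with
  $\sigma^2 = \sum_i k_BT/\kappa_i$ — equivalently the harmonic
  combination $1/\sum_i \kappa_i^{-1}$. It is dominated by the softest,
  most collective modes and converges after the first few of them; it
  measures the global breathing flexibility (compactness) of the
  structure.

* **Directional spring constant.** For a pulling axis defined by the
  equilibrium vector $r^0_{mn}$ between the C$\alpha$ atoms of residues
  $m$ and $n$,
  $$k_\mathrm{direct}(m,n) =
    \frac{\sum_i \kappa_i\, d^i_{mn}}{\sum_i d^i_{mn}}, \qquad
    d^i_{mn} = \sqrt{k_BT/\kappa_i}\;\lvert\cos\theta^i_{mn}\rvert\,
    \lvert u^i_{mn}\rvert,$$
  where $u^i_{mn}$ is the difference of the eigenvector components at the
  two C$\alpha$ atoms and $\cos\theta^i_{mn}$ its normalized projection
  onto the axis. The absolute values make the result independent of the
  arbitrary eigenvector phases. Unlike the overall measure, *all* modes
  matter here: localized high-frequency motions (side chains) can project
  substantially onto the axis and pull the weighted mean up, so the
  package defaults to summing every internal mode.

Typical use compares the N–C termini axes of homologous domains, the axis
stretched in single-molecule AFM unfolding experiments: a larger
$k_\mathrm{direct}$ predicts a mechanically more resistant domain.

## Parameters and units

* `gamma` (kcal/mol/Å², default 1). A uniform scale: both observables are
  exactly linear in it, so with the default only *relative* stiffness
  comparisons carry meaning. The SI conversion 1 kcal/mol/Å² =
  0.694769 N/m (4184 J·mol⁻¹ / $N_A$ / 10⁻²⁰ m²) is applied for the
  `value_si` fields.
* `cutoff` $R_c$ (Å, default 5). For heavy-atom networks values around
  5 Å are standard; larger cutoffs add physically dubious long-range
  springs and stiffen everything. The meaningful lower limit is
  structure-specific: below the minimum connected cutoff
  (`min_connected_cutoff()`) the network breaks into pieces and more than
  six zero modes appear; `cutoff_scan()` flags such rows and suppresses
  their stiffness values rather than reporting numbers for a mechanism.
* `temperature` (K, default 298.15, $k_BT = 0.5925$ kcal/mol). Both
  observables are temperature-invariant in model units — $k_BT$ cancels
  algebraically — so the temperature only scales the reported per-mode
  deformation amplitudes $d^i_{mn}$; the invariance is asserted in the
  test suite at 150 K versus 600 K to 1e-12 relative.
* `zero_tol_rel` (default 1e-6). Rigid-body modes are discarded below
  `zero_tol_rel * max(eigenvalue)`. The threshold is relative because the
  spectrum scales with $\gamma$; it is recorded in the fitted object.

## Numerical choices

The Hessian super-element for a contact with bond vector $b$ is
$-(\gamma/|b|^2)\, b b^\mathsf{T}$, the unique second derivative of $V$ at
its minimum; diagonal blocks are negated row sums, which places uniform
translations in the null space to machine precision. Contact enumeration
is an exact all-pairs distance search with an inclusive boundary
($r^0 \le R_c$). Diagonalization is a full dense symmetric
eigendecomposition — the observables sum over *all* modes, so truncated or
shift-invert solvers would not help — which takes seconds at
$3N \approx 2100$.

Degenerate eigenvalues deserve a caveat: within an exactly degenerate
subspace the eigenbasis is solver-dependent, and because the weights
$d^i_{mn}$ use absolute values their sum is not basis-invariant there.
Fitted objects flag retained eigenvalue gaps below 1e-9 relative. Real
protein structures are generically non-degenerate; the package's exact
Platonic test solids are not, which is why the synthetic generator
defaults to seeded jitter.

Degenerate inputs of another kind — exactly collinear chains — violate
the $3N-6$ rule itself: central-force springs do not resist transverse
motion, so a straight chain is a mechanism with many more than six zero
modes at any cutoff. `min_connected_cutoff()` treats this honestly (it
reports the zero-mode count and fails to find a connected cutoff) and the
limitation is documented rather than patched.

## The synthetic generator and what the tests show

`make_fixture()` produces deterministic toy structures (pair, triangle,
tetrahedron, cubic lattice, helix, two separated clusters, straight
chain), each atom a pseudo-residue with a C$\alpha$ label so the pulling
machinery applies unchanged. Seeded uniform jitter (default amplitudes
0.15–0.4 Å, chosen at the scale of crystallographic coordinate
uncertainty) breaks the symmetry of the exact solids and lifts their
degeneracies. Fixtures emulate the *geometry and topology* inputs of the
method — contact networks, rigid components, pulling axes — but not the
heterogeneous packing density, secondary structure or sequence of real
proteins, so passing fixture tests validates the computational machinery,
not biological conclusions.

Two independent oracles back the tests: a central-difference Hessian of
the potential (agreement within 1e-6 at step 1e-4 Å on ≤10-atom
fixtures), and a brute-force stiffness evaluator that assembles the
Hessian by a literal loop, diagonalizes by SVD instead of the symmetric
eigensolver, and evaluates the defining formulas as scalar loops
(agreement to 1e-10 relative). Property tests cover rotation invariance
of the spectrum, $\gamma$-linearity, $k_BT$ cancellation, eigenvector
sign invariance, the spectral bounds
$k_\mathrm{protein} \le \kappa_1$ and
$\kappa_\mathrm{min} \le k_\mathrm{direct} \le \kappa_\mathrm{max}$, and
the six-zero-modes-per-rigid-component rule.

The reference reproduction in the acceptance tests targets the
crystallographic fibronectin fragment (PDB entry 1fnh, type-III domains
12 and 13: heavy-atom selections over author residues 3–92 and 93–181,
N–C termini pulling pairs P3–E92 and N93–T181, $R_c = 5$ Å,
$\gamma = 1$). The PDB entry is not redistributed with the package; the
test looks for a user-supplied `1fnh.pdb` under `tests/testthat/` or
`inst/extdata/` and fails with instructions when absent. Problem sizes
used elsewhere are deliberate choices: small fixtures (≤64 atoms) for the
property suite, and 680/691-atom lattices — the size of the fibronectin
domains — for the end-to-end timing demonstration.

## A worked example

```{r example}
sel <- make_fixture("helix", n_atoms = 60, spacing = 3.8,
                    jitter = 0.15, seed = 1)
fit <- anm(sel, cutoff = 6)
summary(fit)

pr <- pulling_pair(sel, 1, 60)
k_direct(fit, pr)

head(cumulative_profile(fit, "overall"), 3)
cutoff_scan(sel, c(5.7, 6.0), pair_residues = c(1, 60))
```

The directional constant far exceeds the overall one: the overall measure
is a harmonic mean dominated by the softest collective mode, while the
directional mean also weights the stiff localized modes that resist
pulling along a specific axis.

## Known limitations

* Harmonic, native-state only: no unfolding forces, kinetics or
  anharmonicity; experimental unfolding forces are inputs for comparison,
  never outputs.
* No mass-weighting: eigenvalues are spring constants, not squared
  frequencies in time units.
* Absolute SI values inherit the uncalibrated $\gamma$; only relative
  comparisons between structures computed with the same $\gamma$ and
  $R_c$ are meaningful.
* Exactly collinear inputs and exactly degenerate spectra behave as
  described above — diagnosed, not corrected.
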