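---
title: "Models and methods behind qdhkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qdhkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`qdhkit` analyzes quadruplex–duplex hybrid (QDH) DNA structures and their
complexes with intercalating ligands. This vignette is the package's own
account of the models it implements, the conventions and defaults it
chose where several were defensible, and what its synthetic test bed does
and does not establish about real data.

## The coordinate model

A structure is a tidy atom table: one row per atom and model, with columns
`model`, `resid` (1-based along the 5′→3′ chain), `base`, `atom`,
`element`, `x`/`y`/`z` (Å, right-handed frame) and a `ligand` flag. PDB
reading and writing (multi-model, v3.3 fixed columns) is delegated to
`bio3d`; author numbering is retained in `resid_author`, water is
skipped, and alternate locations other than blank/"A" are dropped with a
warning. Primed atom names are accepted in both ASCII (`C1'`) and Unicode
(`C1′`) spelling and normalized to ASCII; the normalization is
idempotent.

A fold is declared, not inferred: `qdh_topology()` lists the sequence, the
G-quartets in Hoogsteen-cycle order, the Watson–Crick pairs in stacking
order from the junction, the syn set, and loop/overhang segments.
`so7_topology()` ships the 27-nt *PIM1*-promoter hybrid-1 fold used
throughout the examples. Two slightly different syn sets for this fold
circulate (differing in G25 vs G27); both variants are provided and
neither is privileged — the builder realizes whichever is declared.

## The idealized builder

`build_hybrid_qdh()` turns a declaration into coordinates using planar
idealized nucleotide templates (base ring and polar hydrogens, C1′, C2′,
O4′, H1′ and P) stored as plain text in `inst/extdata/base_templates.tsv`.
Only the atoms downstream operations consume are built; full-atom
fidelity is not a goal.

**Quartets.** One in-plane rigid placement (rotation plus translation) of
the guanine template is solved so that its four images under successive
90° rotations about the stack axis form a Hoogsteen-bonded cycle. The
solver targets both hydrogen and heavy-atom acceptor–donor distances
(H1···O6 1.85 Å, N1···O6 2.87 Å, amino-H···N7 1.95 Å, N2···N7 2.95 Å),
which pins the bonds near-linear without explicit angle terms, via a
coarse grid search over the three parameters followed by Nelder–Mead and
BFGS polish. The O6 half-diagonal parameter (default 2.5 Å) enters only
as a soft preference: with rigid ideal-geometry bases and exact H-bond
distances the O6 radius is fixed near 2.8 Å, so the builder honors the
H-bonds first. Quartet planes stack at the declared rise (3.3 Å) and
twist (30°).

**Amino-proton labels.** A geometric probe during development showed that
the *same* guanine amino proton — the one cis to N1 — donates both the
quartet N2–H···N7 bond and the Watson–Crick N2–H···O2 bond; dictionaries
disagree on whether that proton is called H21 or H22. The package labels
amino protons by hydrogen-bonding role, matching the restraint
nomenclature it generates: in quartet guanines the quartet-internal
proton is `H21`, in Watson–Crick guanines the O2-bonded proton is `H22`.
Detection rules and restraint generation use the same convention, so the
builder–detector round trip is exact.

**Duplex.** A G–C pair unit is solved the same way (three canonical bonds,
H and heavy-atom targets) and stacked coaxially beyond the junction gap
(default 3.3 Å; set `junction_gap = 6.8` — roughly two stacking
distances — to leave room for an intercalant) at 3.3 Å rise and 36°
twist per step.

**Glycosidic torsions.** After placement, the sugar/backbone atoms of each
residue are rotated about the glycosidic bond so that χ
(O4′–C1′–N9–C4 for purines, O4′–C1′–N1–C2 for pyrimidines) equals 60°
(syn set) or 240° (everything else) exactly. Declaring a pyrimidine syn
is an error.

**Loops.** Loop and overhang residues are placed on a smooth outer arc at
18 Å radius — far enough that no spurious hydrogen bond can reach the
core — and are decorative: no descriptor in this package measures loop
geometry, and nothing about loop conformations in real structures should
be inferred from them.

## Topology detection

`find_hbonds()` enumerates canonical base donors (G: N1–H1, N2–H21/H22;
C: N4–H41/H42; A: N6–H61/H62; T: N3–H3) against acceptors (G: O6, N7,
N3; C: O2, N3; A: N7, N1, N3; T: O2, O4), keeping inter-residue pairs
with H···A ≤ 2.5 Å and donor angle ≥ 120°. The defaults bracket the
1.7–2.1 Å restraint targets with enough slack that detection survives
0.2 Å Gaussian coordinate noise.

`detect_quartets()` finds directed 4-cycles of guanines in which each
member donates N1–H1→O6 and/or N2–H21→N7 to the next ("and/or" makes the
detector robust: both bonds of an edge must break before the cycle is
lost). Overlapping cycles are resolved by total bond count, ties by
lexicographic residue order; each quartet is reported once, starting at
its lowest residue index, oriented so the second element is the
Hoogsteen acceptor of the first. An exhaustive 4-cycle enumeration
serves as the test oracle. Bifurcated N2 bonds are not admitted as
edges. `detect_wc_pairs()` accepts G–C pairs with at least 2 of the 3
canonical bonds and A–T pairs with both. The syn window for
`classify_glycosidic()` is the half-open [0°, 120°).

## Restraint engineering

NOE volumes are calibrated under the isolated spin-pair approximation:
`d = 2.45 Å · (V_ref / V)^{1/6}`, with `V_ref` the average over cytosine
H5–H6 rows. Calibrated distances are binned by thresholds strong ≤ 2.8 Å
< medium ≤ 4.2 Å < weak ≤ 6.0 Å (beyond that, rejected); the thresholds
are module defaults placed inside the overlap regions of the published
bin *bounds* — (1.8, 3.6), (2.6, 5.0), (3.5, 6.5) Å — because only the
bounds, not the assignment rule, are fixed; both are configurable.

Generated categories: 8 Hoogsteen restraints per quartet (N7···H21
1.9–2.1 Å, O6···H1 1.7–1.9 Å per cyclic edge), 3 Watson–Crick restraints
per G–C pair (O2···H22, N3···H1, O6···H41, all 1.8–2.0 Å), and exactly
one χ restraint per residue: 60°±35° for the syn set, 240°±40° for anti
purines, 240°±70° for anti pyrimidines. Cytosines are restrained as anti
pyrimidines — the only scheme consistent with a one-per-nucleotide
total. A–T pairs raise an error: no bounds are defined for them here.
The planarity scheme (3 groups per quartet guanine, 3 per pair) is one
documented choice that reproduces the conventional 36 + 9 bookkeeping
for a three-quartet/three-pair fold; the count is reported, never used
as a correctness proof. Chirality restraints are engine-specific and not
generated. Force constants (distance/planarity 20, hydrogen bond 50,
torsion 200 kcal·mol⁻¹·unit⁻²) are stored as metadata only — the package
evaluates no energies.

## Junction geometry and the angular-position CV

Base planes are total-least-squares fits (eigen-decomposition of the
coordinate covariance); collinear input is an error. Rise is the
centroid separation projected on the mean normal, with near-antiparallel
normals (> 60°) rejected. Groove width is the cross-groove P–P distance,
reported either raw or with the conventional 5.8 Å phosphate-radius
correction ("refined", the default); because the convention shifts every
absolute width by the same constant, comparisons between structures
should use width *differences*, which cancel it. Superposition is Kabsch
via SVD with a proper rotation enforced; the test suite checks it
against an independent quaternion (Horn) oracle at 10⁻⁶ Å.

The angular-position CV is the pseudotorsion over four geometric centers
— P1: C2′/O4′ of the two duplex-adjacent quartet guanines; P2: the four
quartet O6; P3: the nine ligand CV atoms (three per aromatic moiety);
P4: the three moiety-I atoms — evaluated with the IUPAC `atan2` sign
convention in (−180°, 180°]. P1→P4 ordering follows the enumeration of
the defining points; the zero of the CV corresponds to the middle ring
sitting between the junction quartet and the adjacent base pair.
`place_ligand()` constructs a planar synthetic three-moiety ligand whose
moiety centers sit at 120° spacing around the quartet axis, so the
nine-atom center falls on the axis exactly and the requested CV value is
realized analytically (a linear relation in the moiety-I azimuth, solved
in closed form with one refinement step). Mapping the CV atom *labels*
of real Phen-DC3/360A depositions to deposited atom names is left to a
user-editable alias table (`inst/extdata/ligand_atom_map.tsv`), since
that mapping depends on the chemical dictionary of the deposition.

## Well-tempered metadynamics

Energies are kcal/mol, angles degrees, k_B = 0.0019872 kcal·mol⁻¹·K⁻¹.
The bias is a sum of periodic Gaussians; deposition at `s` appends a hill
of height `w₀ exp(−V(s)/k_B ΔT)` with ΔT = (γ−1)T, and the free energy is
recovered as `F = −γ/(γ−1) · V`, shifted so min F = 0. Defaults
(σ = 10°, w₀ = 0.2 kcal/mol, γ = 10, stride 500, T = 300 K) are
conventional values for a soft 1D angular coordinate; all are exposed.
The instantaneous end-of-run estimator oscillates hill-by-hill, so
`run_wtmetad()` also returns (and the tests use) a profile averaged over
the late half of the deposition schedule, the standard remedy.

The validation dynamics is overdamped Langevin (Euler–Maruyama) on
analytic periodic potentials — it validates the CV/bias/recovery
machinery, *not* any molecular ensemble. The validation runs use
σ = 15°, stride 250, dt = 20 and 3×10⁵ steps: hills comparable in width
to the wells give a smooth reconstruction, and this length reconstructs
a 3 kcal/mol double well to within 0.5 kcal/mol of the analytic profile
(up to the additive constant) with both minima localized to a few
degrees. Minima are counted on the periodic grid with a basin-depth
floor of 1 kcal/mol and a 20° merge radius; near-flat wells can jitter
the arg-min position by ~10–15° even when the count and depths are
stable, so minima *counts*, not positions, are the robust discriminator
between one-state and two-state landscapes.

## Two-state melting

The observed ellipticity is modeled as
θ(T) = f·(a_f + b_f T) + (1−f)·(a_u + b_u T) with the van't Hoff folded
fraction f(T) = 1/(1 + K), K = exp(−(ΔH/R)(1/T − 1/T_m)) in Kelvin
(R = 1.9872 cal·mol⁻¹·K⁻¹), so f(T_m) = 0.5 exactly and f decreases with
temperature. Fitting is Levenberg–Marquardt over (T_m, ΔH, four baseline
coefficients), seeded from the half-crossing of the baseline-subtracted
folded fraction — markedly more robust than a derivative extremum on
noisy curves. A fit is declared "no transition" when the baselines are
not genuinely separated at the fitted midpoint (amplitude < 5% of the
signal range) or the midpoint is not interior to the measured range. A
baseline-interpolation route (subtract end-segment baselines, read T_m
where f crosses 0.5) is available by flag; the van't Hoff route is the
default. `bootstrap_tm()` emulates replicate scatter by residual
resampling under a fixed seed.

**Applicability and a known limit.** A two-state fit with free baselines
needs both baselines observed. With the 5–95 °C measurement window, a
transition centered at 80 °C with ΔH ≈ 30–50 kcal/mol never completes
(the folded fraction at 95 °C is still 0.05–0.15), and (T_m, unfolded
baseline) become jointly unidentified: the *global* least-squares
optimum itself — not a convergence failure — displaces T_m downward by
several degrees at 2% noise. The recovery property test therefore
asserts unbiasedness on the resolvable part of the parameter grid
(folded fraction < 0.03 at the ceiling); one acceptance-style check runs
the full grid regardless and documents this information limit by
failing. Simulated-curve defaults (baselines 10 − 0.02 T folded,
2 − 0.01 T unfolded, ΔH 45 kcal/mol, 0.5 °C steps) are realistic for
molar-ellipticity G4 melts at 290 nm; they are generator choices, and
experimental melting values enter the package only as generator
parameters and worked-example arithmetic, never as fit targets.

## What the synthetic test bed shows — and what it does not

The builder produces geometrically exact, noise-free (or Gaussian-
perturbed) idealized structures: perfect planarity, exact χ, uniform
stacking. Passing the builder→detector round trip shows the detection
logic and conventions are self-consistent and robust to 0.2 Å noise; it
does not show that the hydrogen-bond thresholds are optimal for
experimental ensembles with non-ideal geometry, nor anything about loop
or backbone conformations, solvent, or ions. Likewise the r⁻⁶ NOE
generator assumes the isolated spin-pair approximation exactly (no spin
diffusion, single mixing time), so its exact inversion validates the
calibration algebra, not the approximation itself. Deposited-structure
comparisons (ensemble RMSD of real NMR bundles, groove/rise differences
between free and bound forms) are supported by `read_pdb()` +
`ensemble_rmsd()`/`groove_width()`/`rise()` on files the user downloads;
the tests exercise the same difference machinery on builder output,
where the expected values follow from the builder parameters.

## Interfaces

The package is library-first: the exported functions compose with the
pipe, `qdh_demo()` chains the full synthetic pipeline into a JSON
summary (embedding package version and seed), and
`scripts/acceptance.R` regenerates the headline numbers from the
installed package. File formats: NOE tables and melting curves as TSV,
restraints as versioned flat text, structures as PDB, reports as JSON.
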