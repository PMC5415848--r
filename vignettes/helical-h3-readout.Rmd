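---
title: "Methods: quantifying helical H3 tail readout by PHD fingers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying helical H3 tail readout by PHD fingers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixread)
```

# Scope and model

Most PHD fingers read the histone H3 N-terminal tail in a fully extended
conformation. A subclass instead forces the tail into a helical, folded-back
conformation after K4, stabilized by a conserved Asp/Glu ("acidic wall") on
the short helical turn preceding the domain's first beta-strand — BAZ2A
E1689 and BAZ2B E1944 are the model cases. `helixread` implements the
quantitative machinery needed to characterize this recognition mode from
four kinds of evidence:

1. **Backbone geometry** — hydrogen-bond detection and per-residue helicity
   over peptide conformer ensembles, and a three-way classification of the
   bound peptide (helical / bent / extended).
2. **Sequence conservation** — a census of reader-domain alignments for the
   acidic wall, the methyl-K4 reader tryptophan, and the double acidic
   patch, with a mutual-exclusivity summary.
3. **NMR chemical shift perturbations** — weighted combined shifts,
   mean/s.d. threshold classes, and the minimal-shift lower bound for
   slow-exchange spectra.
4. **ITC thermodynamics** — simulation and fitting of the single-site
   Wiseman isotherm, derived Gibbs energy and entropy with propagated
   errors, and affinity fold-change reporting.

A seeded synthetic-data module generates inputs with known planted truth
for every stage, so the full analysis runs and is tested without any
external downloads.

# Hydrogen bonds and helicity

## Electrostatic hydrogen-bond criterion

Published trajectory analyses of this system delegate secondary-structure
assignment to viewer plugins without stating a criterion. We adopt the DSSP
electrostatic model because it is fully reproducible and independent
reference implementations exist for cross-checking: the amide hydrogen is
reconstructed 1.00 Å from N, anti-parallel to the preceding residue's C=O
vector, and each donor NH / acceptor C=O pair is scored

$$E = 27.888\left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} - \frac{1}{r_{OH}} -
\frac{1}{r_{CN}}\right)\ \text{kcal/mol},$$

with a bond called when $E < -0.5$ kcal/mol. The first residue and prolines
cannot donate; the covalently linked preceding carbonyl is excluded. On an
ideal helical decamer this yields exactly the i→i+4 ladder (donors 5–10 to
acceptors 1–6), reproducing the canonical T3→A7 and K4→R8 bonds that
stabilize the bound H3 helix loop:

```{r hbonds}
detect_hbonds(make_ideal_chain("ARTKQTARKS", -57, -47))
```

Sidechain-to-backbone bonds (e.g. the T3 hydroxyl to the T6 amide) are not
covered by DSSP; we use a geometric criterion — donor–acceptor heavy-atom
distance ≤ 3.5 Å and donor angle ≥ 120° where the parent atom is resolvable
— both cutoffs configurable.

## Helicity assignment and profiles

A residue counts as helical when it lies inside a minimal helix of turn
length $n \in \{3, 4, 5\}$ (3₁₀, α and π): two consecutive $n$-turns at
$i$ and $i+1$ mark residues $i+1 \dots i+n$. This generalizes the DSSP
minimal-helix rule to all three helix types, matching the "α-, 3₁₀- or
π-helix" definition used for per-residue helicity percentages.

Helicity profiles over conformer ensembles discard the first
`burn_in_fraction` (default 0.25) of frames per replica — mirroring the
convention of analyzing only the last 60 ns of 80 ns trajectories — then
report the pooled per-residue fraction (frame-weighted mean) alongside the
median ± interquartile range across replicas. Both poolings are reported
because published per-residue percentages do not state whether frames are
pooled before or after the median.

Replica groups are compared with a two-tailed Mann–Whitney U test: exact
when both groups have ≤ 8 replicas and no ties (the fully separated 4 vs 4
case gives exactly $p = 2/70 \approx 0.0286$), otherwise the normal
approximation with continuity and tie correction. The test itself is
delegated to `stats::wilcox.test`; tests verify the exact branch against
full enumeration of all $\binom{8}{4}$ rank assignments.

## Conformation classes

The bound peptide segment (typically K4 onwards) is classified as
**helical** when ≥ 3 consecutive residues are assigned helical (one
complete turn), **extended** when the segment has no backbone hydrogen
bonds of sequence separation ≥ 3 *and* its end-to-end to contour-length
ratio is ≥ 0.8, and **bent** otherwise. The 0.8 ratio threshold is a
design choice: ideal extended geometry scores ≈ 0.95 and a single
two-residue kink drops the ratio below 0.8, so the two regimes are well
separated; the evidence (bond count, longest helical run, ratio) is always
returned so borderline cases can be audited.

# Acidic-wall census

The census consumes an existing alignment (aligned FASTA or Clustal;
alignment computation is out of scope). Diagnostic columns are resolved by
*reference anchoring*: a row with known construct numbering (e.g. BAZ2A,
anchor residue 1689) maps a residue number to the alignment column through
its ungapped sequence. Scoring rules, each chosen to read conservation off
the literal alignment the way a curator would:

* wall residues are exactly {D, E}; no near-acidic scoring of N/Q;
* a gap in a diagnostic column scores as *absent* — no imputation;
* the double acidic patch requires the wall residue itself acidic plus at
  least one acidic *sequence* neighbour (wall ± 1 in the ungapped row,
  since the motivating D1688/E1689 pair are sequence neighbours); the
  window is configurable because the published analysis does not state one;
* the Trp column is supplied by a second anchor, never inferred.

The summary reports $n_{total}$, wall, Trp, both, and double-patch counts
plus the 2×2 wall × Trp table; the invariant
$n_{both} \le \min(n_{wall}, n_{trp})$ is asserted in tests. The published
human PHD-ome counts (36/172 with the acidic wall, 5/36 also bearing the
reader Trp, 22/36 with the double patch) require the external human PHD
sequence set and a MAFFT-class alignment step; that is documented as an
external workflow and deliberately not packaged.

# Chemical shift perturbations

Weighted combined shifts follow
$\Delta\delta_{weighted} = |\Delta\delta_H| + 0.14\,|\Delta\delta_N|$,
the 0.14 factor rescaling the ¹⁵N range onto the amide-proton range.
Classes use inclusive thresholds over measured residues: weak ≥ μ,
medium ≥ μ+σ, strong ≥ μ+2σ. Numerical choices worth stating:

* σ is the **sample** standard deviation (n−1); the convention is recorded
  in the output metadata because published work rarely states it.
* μ and σ are computed over residues measured in both spectra by default
  (sidechain NH₂ pairs and unassigned residues excluded); computing over
  all assigned residues is available by filtering the table beforehand.
* If all shifts are equal, σ = 0 and every residue is ≥ μ, hence *strong* —
  a documented degenerate case forced by the inclusive rule.

The minimal-shift procedure pairs each assigned free-state peak with the
nearest bound-state peak under the metric
$\sqrt{\Delta\delta_H^2 + (0.14\,\Delta\delta_N)^2}$; many-to-one matching
is allowed, ties are broken towards smaller δH then smaller δN and flagged.
Because the nearest peak minimizes over candidates, the minimal shift never
exceeds the true assigned shift — asserted property-style on synthetic data
with planted assignments.

# ITC thermodynamics

The single-site Wiseman isotherm is implemented explicitly (published
fits delegate it to instrument software). After injection $i$, cumulative
volume $v$, the perfusion-corrected cell concentrations are
$M = M_0\frac{1 - v/2V_0}{1 + v/2V_0}$ and
$X = X_{syr}\frac{v/V_0}{1 + v/2V_0}$; the bound-site fraction is the
smaller root of
$\Theta^2 - \Theta(1 + X/NM + K_D/NM) + X/NM = 0$, and the injection heat
is $\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$
with $Q_i = N \Theta_i M_i V_0 \Delta H$. A bisection solver of the same
mass balance serves as the independent oracle in tests (agreement better
than $10^{-9}$ relative). The discrete perfusion correction is accurate to
$O((dV/V_0)^2)$ per injection, which is why the heat-conservation test
uses small injections.

Fitting is nonlinear least squares in $(\ln K_A, \Delta H, N,
\text{baseline})$ — the log parameterization conditions the problem — with
a small multistart over $K_D$ guesses spanning 0.01–10× the cell
concentration. The first injection (0.4 µl pre-injection convention) is
discarded from the residuals by default but still advances the running
concentrations. Parameter errors come from the covariance at the optimum.
The Wiseman c-value $N M_0 / K_D$ is always reported; when $c < 1$ and the
estimate exceeds the reporting ceiling the K_D is reported as a lower
bound (e.g. ">1000"), mirroring how weak binders are tabulated.

Derived quantities at $T$ = 298.15 K with $R = 1.9872 \times 10^{-3}$
kcal/(mol K):
$\Delta G = RT \ln K_D$ (K_D in M), $T\Delta S = \Delta H - \Delta G$,
$\delta\Delta G = RT\,\delta K_D / K_D$,
$\delta T\Delta S = \sqrt{\delta\Delta H^2 + \delta\Delta G^2}$. The
identity $\Delta G = \Delta H - T\Delta S$ holds exactly before rounding;
table output rounds ΔG to two decimals and TΔS to one, the printed-table
convention.

```{r thermo}
derive_thermo(51, 2, -5.8, 0.1)
```

`validate_table()` recomputes ΔG and TΔS for every numeric row of the
packaged tables and flags deviations beyond 0.03 / 0.1 kcal/mol — bands
that absorb the rounding of the printed K_D values. One recorded
discrepancy: the prose claim that the BAZ2B E1944Q mutation weakens
binding "up to 8-fold" does not match the tabulated dissociation constants
(660 vs 47 µM ≈ 14-fold); the validation report simply recomputes the
ratio and leaves the discrepancy visible.

# Helix-propensity scoring

Scoring is a plain window sum of per-residue ΔΔG values from a swappable
scale (packaged default: the Pace & Scholtz experimental consensus scale,
Ala = 0 reference). A nucleation–propagation model (Zimm–Bragg /
AGADIR-class) was deliberately not used: the claims at stake are ordinal —
the K4A/Q5A double-Ala mutant should out-rank wild type, which should
out-rank the double-Gly mutant — and a window sum reproduces orderings
without introducing fit parameters. The default window, residues 3–8,
is the observed helical segment of the bound H3 10-mer. Absolute scores
are scale-dependent and only orderings are meaningful.

# The synthetic-data generators

The generators exist to make every stage testable with *known planted
truth*; they emulate statistical structure, not physics.

* **Ideal chains** are built by natural-extension (NeRF) placement with
  ideal bond lengths (N–CA 1.458, CA–C 1.525, C–N 1.329, C=O 1.231 Å),
  standard backbone angles, trans peptide bonds, and uniform or
  per-residue (φ, ψ). The helical state is (−57°, −47°); coil frames are
  the extended state (−139°, 135°), which suffices to be non-helical under
  the assignment rule — no attempt is made at realistic coil ensembles.
* **Ensembles** plant per-residue helicity fractions by deterministic
  rounding (`floor(f · n_frames + 0.5)`) of whole-frame helix/extended
  choices, not Bernoulli draws, so zero-noise recovery is exact. Fractions
  are honoured per contiguous block of equal value; recovery is exact for
  uniform fractions (the tested regime). Helical frames are ordered first
  within each replica, which makes burn-in behaviour easy to reason about
  in tests.
* **Peak lists** lay free-state peaks on a deterministic comb across
  typical amide ranges (¹H 7.5–9.5, ¹⁵N 105–130 ppm); bound lists add the
  planted offsets plus seeded Gaussian jitter.
* **Titrations** use the experimental defaults throughout: 0.4 µl + 19 × 2
  µl injections, 200 µl cell, 100 µM cell concentration, 1500 µM syringe —
  inside the published ranges (80–120 µM protein, 1.5–3 mM peptide) — and
  the exemplar ground truth (K_D 51 µM, N 1.35, ΔH −5.8 kcal/mol) is the
  wild-type H3 10-mer / BAZ2A row of the packaged table. Heat noise of
  0.2 µcal s.d. is a realistic instrument-level figure for this cell size.
* **Alignments** plant wall/Trp/double-patch rows exactly and fill all
  other cells from the 17 non-D/E/W residues, so planted counts are the
  only possible counts; a numbering reference row is always appended.

What the generators deliberately do **not** emulate: force-field
energetics, solvent, realistic coil geometry, spectral overlap and peak
shapes, baseline drift in titrations, or alignment uncertainty. Passing
the planted-truth tests therefore demonstrates the correctness of the
analysis machinery, not the behaviour of the upstream experiments on real
data.

# Problem sizes and determinism

All analyses are desk-scale by design: ensembles of 40–100 frames of a
10-mer (hydrogen-bond detection is O(n²) per frame), alignments of ~10
rows × 60 columns, peak lists of 15–30 residues, titrations of 20
injections, and a 200-replicate noisy-recovery study for the ITC fit —
each stage runs in seconds. The published per-residue helicity percentages
from explicit-solvent MD (≈ 25% for wild type, > 60% for the double-Ala
mutant) come from 4 × 80 ns trajectories and are not reproducible at this
scale; the planted-fraction recovery and oracle-equivalence properties
stand in for them, and conformer ensembles from real trajectories can be
supplied as multi-model PDB when available. Every random draw flows
through a seeded generator that leaves the caller's RNG state untouched,
so identical configurations reproduce outputs byte for byte.

# Known limitations

* Secondary-structure conventions differ: STRIDE-class assignments can
  shift absolute helicity percentages by a few points relative to the
  DSSP-style rule used here; comparisons across conventions should be
  ordinal.
* The minimal-shift estimate is a lower bound, not an estimator of the
  true CSP; it is only as informative as the bound-state peak set is
  complete.
* The single-site model does not cover multi-site, sequential or
  competitive binding, and raw power traces are not integrated — inputs
  are per-injection heats.
* Low-c titrations (c < 1) leave K_D and N poorly identified; the fit
  reports the c-value and a bound rather than pretending to precision.
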