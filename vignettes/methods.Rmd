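---
title: "Methods: pocket geometry, rotamer scanning, and the non-inactivated fraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pocket geometry, rotamer scanning, and the non-inactivated fraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chanalyze)
```

This vignette records the models, numerical choices and deliberate
limitations behind the package, in the spirit of a methods section.

## The scientific setting

KCNQ1-class potassium channels are homotetramers; small-molecule
activators of the ML277 type bind in a hydrophobic transmembrane pocket
formed by the S4–S5 linker, S5 and S6 of one protomer and the S5′/S6′
helices of the adjacent protomer. Three analyses carry most of the
structural argument: (i) which residues line the pocket at a distance
cutoff, and how they differ across isoforms; (ii) whether a key pocket
leucine can rotate about χ₁ or is sterically locked by an accessory
subunit; (iii) how far residues move between liganded, apo and open
states after superposition on an anchor. On the functional side, the
signature of fast inactivation is a *hook* in the repolarization tail,
and the drug's current increase across a mutant panel correlates with how
inactivated each construct is.

## Pocket delineation and isoform comparison

A residue lines the pocket when any of its heavy atoms is within the
cutoff (default **5 Å**, the standard docking-site rule) of any ligand
heavy atom. Hydrogens are excluded throughout: deposited models are
heavy-atom. Roles (principal vs primed protomer) come from
`adjacent_protomer()`: the ligand must contact exactly two chains; the
principal chain is the one contributing S4–S5-linker contacts when a
linker range is configured, otherwise the chain with more contact atoms
(ties broken by closest atom, making the call deterministic).

Isoform comparison is a pure table lookup — no alignment is computed. The
shipped identity table carries the pocket positions with documented
correspondences (human numbering is +10 relative to the *Xenopus*
construct; e.g. the S5 leucine at 256 is a tryptophan in the other
isoforms); positions without a curated entry are reported as "—" and
flagged `unknown`, never dropped. Volume calls use standard mean residue
volumes (Zamyatnin) with a ±10 Å³ threshold: +61 Å³ for Leu→Trp is
"bulkier", −23 Å³ for Phe→Leu "smaller"; the threshold is far below both
so the calls are insensitive to it.

## Superposition and displacement maps

`kabsch()` is the standard SVD solution with reflection correction;
anchors default to the Cα atoms of a named selection. Which anchor a
figure-style comparison should use is genuinely open (publications rarely
enumerate the ranges), so `displacement_map()` records the anchor and its
RMSD in the output attributes, and reports displacements under explicit
atom rules side by side — `CA` for backbone claims, `sidechain_centroid`
for pocket side-chain shifts — because the convention behind any printed
number is usually unstated. Residues missing atoms under a rule are
flagged, not dropped.

## χ₁ scanning and the clash criterion

χ₁ is the N–Cα–Cβ–γ dihedral in (−180°, 180°], IUPAC signs, with the
standard γ-atom table (CG; CG1 for Ile/Val; OG/OG1 for Ser/Thr; SG for
Cys). `rotate_chi1()` rotates only atoms distal to Cβ about the Cα–Cβ
axis, so bonded geometry is exactly preserved and
construction/measurement form an inverse pair to 1e-6°.

Published clash statements ("VDW surfaces indicate potential clashes")
carry no numeric criterion, so the package makes one explicit: two heavy
atoms clash when d < r_i + r_j − tol with Bondi radii (C 1.70, N 1.55,
O 1.52, S 1.80 Å) and a default overlap tolerance of **0.4 Å** (a common
softening in steric screening). Because the printed χ₁ bounds for the
KCNE3-locked leucine (−80°/+50°) may have been read off surfaces with a
different softness, the acceptance check sweeps tol ∈ {0.0, 0.2, 0.4,
0.6} and accepts any member reproducing the onsets within ±5°. The scan
default is a 1° grid; onsets are reported at the allowed-side boundary
grid point, and allowed regions crossing ±180° are reported as two
intervals so that all intervals live in (−180°, 180°].

## Pore profile

The pore radius at height z along the symmetry axis is the radius of the
largest sphere centred in the axis-normal plane touching no atom:
max over centres of min_i(|c − x_i| − r_i). The classic implementation
uses Monte-Carlo search; this one uses a deterministic Nelder–Mead search
from the on-axis point (fixed 200-iteration budget) for reproducibility,
keeping the on-axis value whenever the search does not improve it —
hence the invariant that centre optimization can only widen the pore.
Slices with no atoms in reach are capped at 15 Å and flagged. The
open/closed call uses 1.4 Å, roughly the radius below which even a
dehydrated K⁺ ion cannot pass; it is a config value, and the package
makes only ordinal claims (closed < open), because published gate radii
are figure-level, not printed numbers.

## The synthetic gating world

No kinetic scheme is published for the system the package emulates, so
the generator's defaults are calibration choices of this artifact, fixed
once and documented here (they are never fitted to any published trace):

- Topology C₁–C₂–O–I — the smallest scheme whose tails show a
  recovery-from-inactivation hook. Rates k(V) = k₀·exp(z·V/25.7 mV)
  (25.7 mV = RT/F at 25 °C).
- **WT-like** rates put the O↔I balance at +60 mV near 70 % inactivated
  (the literature characterization is "more than 60 %"), with recovery at
  −120 mV (τ ≈ 17 ms) about 9× faster than deactivation (τ ≈ 150 ms) so
  the tail hook is well separated from the decay.
- **S338A-like** scales inactivation ×2.5 and halves deactivation;
  **non-inactivating** deletes the I pathway (the G272-mutant phenotype).
- Unitary conductance 0.5 pS with E_rev = −85 mV puts single-channel
  open levels at ~0.07 pA at +55 mV, the sub-0.1 pA regime reported for
  this channel family; single-channel noise is 0.05 pA SD before
  filtering, and the filter is four cascaded one-pole sections scaled to
  a common −3 dB point (a Bessel-like response; 2 kHz acquisition,
  200 Hz analysis are the conventional settings).
- The activator modifier removes inactivation (factor 0), slows
  deactivation (×0.25) and shifts activation −25 mV — the three hallmarks
  of the drug's action on wild-type channels.

What a green test on this world establishes: that the *analysis* code
recovers known constructions (fractions, shifts, amplitudes,
correlations) at the stated tolerances. What it does not establish:
anything about real recordings — leak, capacitance transients, rundown,
series-resistance error and multi-channel patches are all absent by
design, and no rate here is a measured quantity.

One stated invariant had to be narrowed: "removing inactivation can only
increase P_open at every time point" is false during the tail of a
hook-producing scheme — the inactivated state is a reservoir that
returns probability to O *after* deactivation has begun, which is exactly
why the hook exists — so the property is asserted pathwise through the
hold and depolarizing step and as time-integrated dominance over the
whole protocol.

## Tail back-extrapolation and the non-inactivated fraction

A hook is declared when the post-repolarization extremum exceeds the
initial amplitude by more than 3 baseline-noise SDs (the published rule
is visual; 3σ makes it deterministic, and the noise SD is estimated from
the detrended final 10 % of the window when not supplied). With no hook
the fraction is exactly 1, by rule.

For hooked tails the trace is modelled over the whole window as a decay
envelope minus a recovery component; both are exponentials, the taus are
profiled in an outer optimization while amplitudes and baseline are
solved linearly, and the extrapolated decay at t₀ is the baseline plus
the *positive*-amplitude components. On tails constructed as
A·(1 − f·e^(−t/τᵣ))·e^(−t/τ_d) this decomposition is exact (the
closed-form fraction is 1 − f), which is why the package prefers it to
the traditional "fit a single exponential from the hook peak and
extrapolate": the latter inherits a bias from the residual recovery
component near the peak (several percent for shallow hooks) and is kept
only as a fallback when the decomposition does not separate a rising
term. Fractions in (1, 1.05] are clipped to 1 and flagged (noise); values
outside (0, 1.05] are clipped and flagged as out of range.

Tail amplitudes for conductance–voltage work are taken *immediately upon
repolarization* (first sample at the tail potential), not as the window
maximum — using the maximum contaminates G–V points at voltages below
the tail potential, where the tail rises because the tail potential
itself activates the channel.

## Fits and statistics

- Boltzmann: G(V) = G_max/(1 + exp((V½ − V)/k)), Gauss–Newton from a
  deterministic logistic-linearization start with a Nelder–Mead fallback;
  the returned curve satisfies G(V½) = G_max/2 identically. A slope
  pinned at implausible bounds is flagged rather than silently accepted.
- Spearman: average ranks for ties; for n ≤ 9 the two-sided p-value is
  exhaustive over all n! rank permutations (the implementation is
  cross-checked in tests against both a brute-force enumeration written
  independently and the standard library's exact test); for larger n the
  t-approximation is used. No multiplicity correction is applied — the
  analysis reports a single headline correlation.
- All-points histograms: 0.01 pA bins; a two-component Gaussian mixture
  fitted by EM with deterministic initialization (baseline at the sample
  mode, open component at the 90th percentile, 200-iteration cap).
  Components closer than 2 SD merge into a flagged single-component
  result — this is what a blank sweep produces. The baseline component is
  the one nearer 0 pA, per the zero-current-baseline convention of
  cell-attached records.

## Degenerate inputs and determinism

Degenerate cases error loudly rather than guess: fewer than 3
superposition pairs or collinear anchors; a ligand contacting one chain
(no pocket) or three (ambiguous); Gly/Ala in χ₁ operations; unknown
elements in clash checks; constant vectors in rank correlation; zero
control tails in fold changes. Reports embed the package version, a
config hash and input checksums, and re-running a config reproduces the
JSON byte for byte; the only randomness anywhere is the explicit `seed`
given to stochastic simulations.

## Known limitations

- The mmCIF reader handles the `_atom_site` loop as written by the PDB
  (whitespace-separated); it is not a general CIF parser.
- Pore profiling uses axis-normal planes only — no curved-pathway
  tracing — and makes no conductance claims.
- The rotamer scan is χ₁-only, rigid-backbone, with no rotamer-library
  energetics; it answers "is this rotation sterically possible", not
  "is it favourable".
- The synthetic cohort's fold-changes arise purely from the
  remove-inactivation mechanism plus small lognormal measurement noise;
  real mutant panels add expression-level and voltage-dependence
  variation that the generator intentionally omits.
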